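#' Parameters of the joint model for a composite responder endpoint
#'
#' The joint model underlying the augmented binary analysis at a single
#' timepoint:
#' \deqn{y \mid z \sim N(\alpha + \theta z, \sigma^2)}
#' \deqn{b \mid y, z \sim \mathrm{Bernoulli}\{\Lambda(\gamma_0 + \gamma_1 z
#'   + \gamma_2 y)\}}
#' where \eqn{z} is the arm indicator and \eqn{\Lambda} the inverse logit.
#' `gamma2` carries the dependence between the binary and continuous
#' components; fixing it at 0 gives independent components.
#'
#' @param alpha control-arm mean of the continuous component.
#' @param theta arm effect on the mean of the continuous component.
#' @param sigma residual standard deviation (> 0).
#' @param gamma0 logistic intercept for the binary component.
#' @param gamma1 arm effect on the logit of the binary component.
#' @param gamma2 dependence of the logit of the binary component on `y`.
#' @return an object of class `joint_params`.
#' @examples
#' joint_params(alpha = 0, theta = 0.4, sigma = 1,
#'              gamma0 = 2, gamma1 = 0, gamma2 = 0.5)
#' @export
joint_params <- function(alpha = 0, theta = 0, sigma = 1,
                         gamma0 = 0, gamma1 = 0, gamma2 = 0) {
  sc1 <- function(x) as.numeric(x)[1L]     # drop any incoming names
  v <- c(alpha = sc1(alpha), theta = sc1(theta), sigma = sc1(sigma),
         gamma0 = sc1(gamma0), gamma1 = sc1(gamma1), gamma2 = sc1(gamma2))
  sigma <- v[["sigma"]]
  if (!is.numeric(v) || length(v) != 6L || !all(is.finite(v)))
    stop("all six parameters must be finite numbers", call. = FALSE)
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  structure(as.list(v), class = "joint_params")
}

.jp_names <- c("alpha", "theta", "sigma", "gamma0", "gamma1", "gamma2")

.jp_vec <- function(p) unlist(p[.jp_names])

.vec_jp <- function(v) do.call(joint_params, as.list(setNames(v, .jp_names)))

#' @export
print.joint_params <- function(x, ...) {
  cat("Joint model parameters:\n")
  print(round(.jp_vec(x), 4))
  invisible(x)
}

#' Joint log-likelihood of the continuous and binary components
#'
#' Sums, over subjects, the normal log-density of `y` and the Bernoulli
#' log-probability of `b` given `y`.  A missing `b` contributes the normal
#' term only (the Bernoulli factor marginalises to 1); a missing `y` with
#' observed `b` contributes the marginal Bernoulli probability obtained by
#' integrating the logistic success probability over the normal law of `y`
#' (40-node Gauss-Hermite quadrature).  A record with both components
#' missing contributes 0.
#'
#' @param params a [joint_params()] object.
#' @param data a [trial_data()] object.
#' @return the log-likelihood (single number).
#' @export
joint_loglik <- function(params, data) {
  if (!inherits(params, "joint_params")) params <- .vec_jp(.jp_vec(params))
  data <- as_trial_data(data)
  v <- .jp_vec(params)
  if (!all(is.finite(v))) stop("non-finite parameters", call. = FALSE)
  z <- data$arm; y <- data$y; b <- data$b
  mu <- params$alpha + params$theta * z
  ll <- 0
  oy <- !is.na(y)
  if (any(oy))
    ll <- ll + sum(dnorm(y[oy], mu[oy], params$sigma, log = TRUE))
  i <- oy & !is.na(b)
  if (any(i)) {
    eta <- params$gamma0 + params$gamma1 * z[i] + params$gamma2 * y[i]
    s <- 2 * b[i] - 1                     # +1 for b = 1, -1 for b = 0
    ll <- ll + sum(plogis(s * eta, log.p = TRUE))
  }
  j <- !oy & !is.na(b)
  if (any(j)) {
    gh <- .gh_rule()
    # y-nodes per record: mu_j + sqrt(2) sigma x_k
    Y <- outer(mu[j], sqrt(2) * params$sigma * gh$x, `+`)
    P <- plogis(params$gamma0 + params$gamma1 * z[j] + params$gamma2 * Y)
    pb1 <- drop(P %*% gh$w) / sqrt(pi)
    pb1 <- pmin(pmax(pb1, 1e-300), 1 - 1e-16)
    ll <- ll + sum(ifelse(b[j] == 1, log(pb1), log1p(-pb1)))
  }
  ll
}

# central-difference Hessian with relative step
.num_hessian <- function(f, x, rel_step = 1e-5) {
  k <- length(x)
  h <- rel_step * pmax(1, abs(x))
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    xp <- x; xp[i] <- x[i] + h[i]
    xm <- x; xm[i] <- x[i] - h[i]
    H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
    if (i < k) for (j in (i + 1L):k) {
      xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
      xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
      xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
      xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
      H[i, j] <- H[j, i] <-
        (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
    }
  }
  (H + t(H)) / 2
}

.num_grad <- function(f, x, rel_step = 1e-6) {
  h <- rel_step * pmax(1, abs(x))
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- x[i] + h[i]
    xm <- x; xm[i] <- x[i] - h[i]
    (f(xp) - f(xm)) / (2 * h[i])
  }, numeric(1))
}

# standalone logistic starting values; detects separation warnings
.logistic_start <- function(y, b, z, gamma2_free) {
  X <- if (gamma2_free) cbind(1, z, y) else cbind(1, z)
  sep <- FALSE
  fit <- tryCatch(
    withCallingHandlers(
      glm.fit(X, b, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (is.null(fit)) {
    g <- c(0, 0, 0)
    conv <- FALSE
  } else {
    g <- coef(fit)
    g <- c(g, rep(0, 3 - length(g)))
    g[!is.finite(g)] <- 0
    conv <- isTRUE(fit$converged)
  }
  list(gamma = pmin(pmax(g, -15), 15), separation = sep, converged = conv)
}

#' Fit the joint model by maximum likelihood
#'
#' Maximises [joint_loglik()].  Starting values are the per-arm moments of
#' `y` and a standalone logistic fit of `b` on arm and `y`.  When no record
#' has a missing `y` together with an observed `b`, the likelihood
#' factorises exactly into the normal and logistic sub-models and the MLE
#' is obtained from their closed-form / IRLS fits; otherwise the full joint
#' likelihood is maximised with BFGS (log-sigma parameterisation, no
#' randomness).  The covariance matrix is always the inverse observed
#' information of the full joint log-likelihood, computed by central
#' differences with relative step `1e-5` and symmetrised.
#'
#' Complete separation in the binary sub-model (including all observed `b`
#' identical) is flagged: the fit is returned with `converged = FALSE` and
#' `separation = TRUE` rather than raising an error.
#'
#' @param data a [trial_data()] object with both arms represented and at
#'   least two non-missing `y` per arm.
#' @param gamma2_free if `FALSE`, the dependence parameter `gamma2` is
#'   fixed at 0 (independent components).
#' @param boxcox `"off"` (default), `"auto"` (estimate a Box-Cox exponent
#'   from the data; requires all observed `y > 0`), or a single number
#'   giving a fixed exponent.  The model is then fitted to the transformed
#'   `y`; remember that rule thresholds must live on the same scale
#'   ([augbin_analysis()] transforms the threshold for you).
#' @param control optional list passed to [stats::optim()] for the coupled
#'   missing-data case.
#' @return an object of class `fitted_joint_model`: list with elements
#'   `params` ([joint_params()]), `vcov` (6x6), `loglik`, `n_used`,
#'   `converged`, `separation`, `boxcox_lambda` (`NULL` when no transform
#'   was applied), `n0`, `n1`.
#' @examples
#' sc <- scenario_config(n_per_arm = 50, seed = 1)
#' fit <- fit_joint_model(simulate_trial(sc))
#' fit
#' @export
fit_joint_model <- function(data, gamma2_free = TRUE, boxcox = "off",
                            control = list()) {
  data <- as_trial_data(data)
  z <- data$arm
  if (length(unique(z)) < 2L)
    stop("both arms must be represented", call. = FALSE)

  lambda <- NULL
  if (is.numeric(boxcox)) {
    lambda <- as.numeric(boxcox)[1L]
    if (!is.finite(lambda)) stop("fixed Box-Cox exponent must be finite",
                                 call. = FALSE)
  } else if (identical(boxcox, "auto")) {
    oy <- !is.na(data$y)
    lambda <- estimate_boxcox(data$y[oy], arm = z[oy])
  } else if (!identical(boxcox, "off")) {
    stop("`boxcox` must be \"off\", \"auto\" or a number", call. = FALSE)
  }
  if (!is.null(lambda)) data$y[!is.na(data$y)] <-
      apply_boxcox(data$y[!is.na(data$y)], lambda)

  y <- data$y; b <- data$b
  oy <- !is.na(y); ob <- !is.na(b)
  if (sum(oy & z == 0) < 2L || sum(oy & z == 1L) < 2L)
    stop("need at least 2 non-missing continuous values per arm",
         call. = FALSE)
  n_used <- sum(oy | ob)

  # normal sub-model starting values (per-arm moments; MLE for sigma uses /n)
  m0 <- mean(y[oy & z == 0]); m1 <- mean(y[oy & z == 1])
  rss <- sum((y[oy] - ifelse(z[oy] == 1, m1, m0))^2)
  s_hat <- sqrt(rss / sum(oy))
  if (s_hat <= 0 || !is.finite(s_hat))
    stop("continuous component is degenerate (zero residual variance)",
         call. = FALSE)

  cc <- oy & ob                          # complete cases for the logistic part
  if (!any(ob))
    stop("no observed binary component values", call. = FALSE)
  all_same_b <- length(unique(b[ob])) == 1L

  separation <- all_same_b
  if (all_same_b) {
    # degenerate Bernoulli: gamma0 driven to +/-Inf; return a capped,
    # flagged fit (normal part is still the MLE)
    r <- sum(b[ob]); m <- sum(ob)
    params <- joint_params(m0, m1 - m0, s_hat,
                           gamma0 = qlogis((r + 0.5) / (m + 1)))
    fn3 <- function(v) joint_loglik(
      joint_params(v[1], v[2], v[3], params$gamma0, 0, 0), data)
    H3 <- .num_hessian(fn3, c(m0, m1 - m0, s_hat))
    V <- matrix(0, 6, 6, dimnames = list(.jp_names, .jp_names))
    V3 <- tryCatch(solve(-H3), error = function(e) matrix(NA_real_, 3, 3))
    V[1:3, 1:3] <- V3
    return(structure(list(params = params, vcov = V,
                          loglik = joint_loglik(params, data),
                          n_used = n_used, converged = FALSE,
                          separation = TRUE, boxcox_lambda = lambda,
                          n0 = sum(z == 0), n1 = sum(z == 1)),
                     class = "fitted_joint_model"))
  }

  ls <- .logistic_start(y[cc], b[cc], z[cc], gamma2_free)
  separation <- separation || ls$separation
  g <- ls$gamma                          # (gamma0, gamma1[, gamma2])

  coupled <- any(!oy & ob)
  if (!coupled) {
    # likelihood factorises: normal closed form + logistic IRLS is the MLE
    params <- joint_params(m0, m1 - m0, s_hat, g[1], g[2],
                           if (gamma2_free) g[3] else 0)
    converged <- ls$converged && !separation
  } else {
    free <- if (gamma2_free) 1:6 else 1:5
    par0 <- c(m0, m1 - m0, log(s_hat), g[1], g[2],
              if (gamma2_free) g[3] else NULL)
    to_params <- function(p) {
      v <- c(p[1], p[2], exp(p[3]), p[4], p[5], if (gamma2_free) p[6] else 0)
      .vec_jp(v)
    }
    nll <- function(p) -joint_loglik(to_params(p), data)
    ctrl <- utils::modifyList(list(maxit = 500, reltol = 1e-10), control)
    opt <- optim(par0, nll, method = "BFGS", control = ctrl)
    params <- to_params(opt$par)
    converged <- opt$convergence == 0L && !separation
  }

  # observed information of the full joint likelihood on the natural scale
  v_hat <- .jp_vec(params)
  if (gamma2_free) {
    fn <- function(v) joint_loglik(.vec_jp(v), data)
    H <- .num_hessian(fn, v_hat)
    V <- tryCatch(solve(-H), error = function(e)
      stop("observed information is singular; consider a simpler model ",
           "(gamma2_free = FALSE)", call. = FALSE))
  } else {
    fn <- function(v5) joint_loglik(.vec_jp(c(v5, 0)), data)
    H <- .num_hessian(fn, v_hat[1:5])
    V5 <- tryCatch(solve(-H), error = function(e)
      stop("observed information is singular even with gamma2 fixed at 0",
           call. = FALSE))
    V <- matrix(0, 6, 6)
    V[1:5, 1:5] <- V5
  }
  V <- (V + t(V)) / 2
  dimnames(V) <- list(.jp_names, .jp_names)

  structure(list(params = params, vcov = V,
                 loglik = joint_loglik(params, data),
                 n_used = n_used, converged = converged,
                 separation = separation, boxcox_lambda = lambda,
                 n0 = sum(z == 0), n1 = sum(z == 1)),
            class = "fitted_joint_model")
}

#' @export
print.fitted_joint_model <- function(x, ...) {
  cat("Joint model fit (augmented binary method)\n")
  est <- .jp_vec(x$params)
  se <- sqrt(pmax(diag(x$vcov), 0))
  tab <- cbind(estimate = est, se = se)
  print(round(tab, 4))
  cat(sprintf("log-likelihood %.3f on %d subjects; converged: %s%s\n",
              x$loglik, x$n_used, x$converged,
              if (isTRUE(x$separation)) " (separation in binary sub-model)" else ""))
  if (!is.null(x$boxcox_lambda))
    cat(sprintf("Box-Cox exponent applied to y: %.3f\n", x$boxcox_lambda))
  invisible(x)
}

#' @export
vcov.fitted_joint_model <- function(object, ...) object$vcov

#' @export
logLik.fitted_joint_model <- function(object, ...) {
  structure(object$loglik, df = 6L, class = "logLik")
}
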