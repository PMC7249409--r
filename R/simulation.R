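#' Define a simulation scenario
#'
#' A scenario fixes the data-generating process (the joint model
#' parameters), the responder rule, the per-arm sample size, missingness
#' rates, replicate count, test level and master seed.  The defaults are
#' the package's documented effect scenario: standard-normal continuous
#' component with an arm shift of 0.4 SD, a binary component met with
#' probability \eqn{\Lambda(2 + 0.5 y)} (about 88% overall, mildly
#' dependent on the continuous value), responder = `y >= 0 AND b = 1`, and
#' 100 subjects per arm.
#'
#' @param n_per_arm subjects per arm (>= 10: scenarios are meant for model
#'   fitting).
#' @param params true [joint_params()].
#' @param rule the [composite_rule()] applied by the analyses.
#' @param miss_y,miss_b independent missingness probabilities in `[0, 1)`
#'   for the two components.
#' @param n_reps number of simulated trials for power-type studies.
#' @param alpha_level two-sided test level in (0, 1).
#' @param seed master seed; each replicate derives its own stream from
#'   `(seed, rep)`.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(n_per_arm = 100,
                            params = joint_params(alpha = 0, theta = 0.4,
                                                  sigma = 1, gamma0 = 2,
                                                  gamma1 = 0, gamma2 = 0.5),
                            rule = composite_rule(component_rule("at_least", 0)),
                            miss_y = 0, miss_b = 0,
                            n_reps = 1000, alpha_level = 0.05, seed = 1) {
  stopifnot(inherits(params, "joint_params"),
            inherits(rule, "composite_rule"))
  if (n_per_arm < 10) stop("`n_per_arm` must be at least 10", call. = FALSE)
  if (n_reps < 1) stop("`n_reps` must be at least 1", call. = FALSE)
  if (miss_y < 0 || miss_y >= 1 || miss_b < 0 || miss_b >= 1)
    stop("missingness probabilities must be in [0, 1)", call. = FALSE)
  if (alpha_level <= 0 || alpha_level >= 1)
    stop("`alpha_level` must be in (0, 1)", call. = FALSE)
  structure(list(n_per_arm = as.integer(n_per_arm), params = params,
                 rule = rule, miss_y = miss_y, miss_b = miss_b,
                 n_reps = as.integer(n_reps), alpha_level = alpha_level,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' @rdname scenario_config
#' @param ... overrides passed on to [scenario_config()].
#' @details `null_scenario()` is the matching no-effect scenario
#'   (`theta = 0`, `gamma1 = 0`), used for type-I error and coverage
#'   studies.
#' @export
null_scenario <- function(...) {
  args <- list(...)
  if (is.null(args$params))
    args$params <- joint_params(alpha = 0, theta = 0, sigma = 1,
                                gamma0 = 2, gamma1 = 0, gamma2 = 0.5)
  do.call(scenario_config, args)
}

# generate n_gen subjects per arm from the scenario's per-replicate stream,
# return the first `n` of each arm -- common random numbers across n
.simulate_trial_n <- function(scenario, rep_seed, n, n_gen = n) {
  stopifnot(n <= n_gen)
  set.seed(.rep_seed(scenario$seed, rep_seed))
  p <- scenario$params
  one_arm <- function(z) {
    eps <- rnorm(n_gen)
    u_b <- runif(n_gen)
    u_my <- runif(n_gen)
    u_mb <- runif(n_gen)
    y <- p$alpha + p$theta * z + p$sigma * eps
    b <- as.integer(u_b < plogis(p$gamma0 + p$gamma1 * z + p$gamma2 * y))
    y[u_my < scenario$miss_y] <- NA
    b[u_mb < scenario$miss_b] <- NA
    list(y = y[seq_len(n)], b = b[seq_len(n)])
  }
  a0 <- one_arm(0); a1 <- one_arm(1)
  trial_data(arm = rep(c(0L, 1L), each = n),
             y = c(a0$y, a1$y), b = c(a0$b, a1$b),
             id = c(sprintf("C%05d", seq_len(n)), sprintf("T%05d", seq_len(n))))
}

#' Simulate one trial from a scenario
#'
#' Draws `y` from the normal arm model and `b` from the logistic model
#' given the drawn `y` (before any masking), then masks each component
#' independently at the scenario's missingness rates.  Bit-reproducible
#' given `(scenario$seed, rep_seed)`.
#'
#' @param scenario a [scenario_config()].
#' @param rep_seed replicate index / sub-seed.
#' @return a [trial_data()] object with `n_per_arm` subjects per arm.
#' @export
simulate_trial <- function(scenario, rep_seed = 1L) {
  .simulate_trial_n(scenario, rep_seed, n = scenario$n_per_arm)
}

# analyse one simulated dataset with a named method; returns a list with
# at least p_value and ci_width (ci on the between-arm difference scale)
.analyze_method <- function(dat, scenario, method) {
  cl <- 1 - scenario$alpha_level
  if (method == "binary") {
    r <- binary_analysis(dat, scenario$rule, conf_level = cl)
    list(p_value = r$p_value, ci = r$ci_diff, diff = r$diff)
  } else if (method == "augmented") {
    r <- augbin_analysis(dat, scenario$rule, conf_level = cl)
    list(p_value = r$p_value, ci = r$ci_diff, diff = r$diff)
  } else if (method == "ttest") {
    tt <- t.test(dat$y[dat$arm == 1], dat$y[dat$arm == 0],
                 conf.level = cl)
    list(p_value = tt$p.value, ci = as.numeric(tt$conf.int),
         diff = unname(diff(rev(tt$estimate))))
  } else {
    stop("unknown analysis method: ", method, call. = FALSE)
  }
}

# rejection indicator vector for one method over the scenario's replicates,
# at per-arm size n (CRN subset of an n_gen-per-arm stream); failures are
# conservative non-rejections
.power_indicators <- function(scenario, method, n, n_gen = n) {
  vapply(seq_len(scenario$n_reps), function(r) {
    dat <- .simulate_trial_n(scenario, r, n = n, n_gen = n_gen)
    res <- tryCatch(.analyze_method(dat, scenario, method),
                    error = function(e) NULL)
    !is.null(res) && is.finite(res$p_value) &&
      res$p_value < scenario$alpha_level
  }, logical(1))
}

#' Monte-Carlo power study of the binary and augmented analyses
#'
#' Simulates `n_reps` trials from the scenario and analyses each with every
#' requested method, using common random numbers (the same simulated
#' dataset) across methods.  Rejection is the two-sided Wald test at the
#' scenario's `alpha_level`.  Failed fits count as non-rejections
#' (conservative) and are excluded from the CI-width and estimate means;
#' their count is reported, with a warning when more than 10% fail.
#'
#' @param scenario a [scenario_config()].
#' @param methods subset of `c("binary", "augmented", "ttest")`.
#' @return a data frame of class `power_result`, one row per method:
#'   `method`, `n_reps`, `n_fail`, `reject_rate`, `mc_se`
#'   (`sqrt(rate (1-rate) / n_reps)`), `mean_ci_width`, `mean_diff`,
#'   `cover_zero` (share of CIs containing 0).  Attributes `seed` and
#'   `config_hash` identify the run for exact rerun.
#' @export
run_power_study <- function(scenario, methods = c("binary", "augmented")) {
  stopifnot(inherits(scenario, "scenario_config"))
  nm <- length(methods)
  rej <- fail <- matrix(FALSE, scenario$n_reps, nm)
  wid <- dif <- cov0 <- matrix(NA_real_, scenario$n_reps, nm)
  for (r in seq_len(scenario$n_reps)) {
    dat <- simulate_trial(scenario, r)
    for (m in seq_len(nm)) {
      res <- tryCatch(.analyze_method(dat, scenario, methods[m]),
                      error = function(e) NULL)
      if (is.null(res) || !is.finite(res$p_value)) {
        fail[r, m] <- TRUE
      } else {
        rej[r, m] <- res$p_value < scenario$alpha_level
        wid[r, m] <- res$ci[2] - res$ci[1]
        dif[r, m] <- res$diff
        cov0[r, m] <- res$ci[1] <= 0 && 0 <= res$ci[2]
      }
    }
  }
  rate <- colMeans(rej)                    # failures already count as FALSE
  out <- data.frame(method = methods,
                    n_reps = scenario$n_reps,
                    n_fail = colSums(fail),
                    reject_rate = rate,
                    mc_se = sqrt(rate * (1 - rate) / scenario$n_reps),
                    mean_ci_width = colMeans(wid, na.rm = TRUE),
                    mean_diff = colMeans(dif, na.rm = TRUE),
                    cover_zero = colMeans(cov0, na.rm = TRUE),
                    stringsAsFactors = FALSE)
  if (scenario$n_reps == 1L)
    warning("n_reps = 1: rates are 0/1 and Monte-Carlo SEs are 0")
  if (any(out$n_fail > 0.1 * scenario$n_reps))
    warning("more than 10% of fits failed for at least one method")
  attr(out, "seed") <- scenario$seed
  attr(out, "config_hash") <- .config_hash(unclass(scenario))
  class(out) <- c("power_result", "data.frame")
  out
}

#' Effective sample-size gain of one analysis method over another
#'
#' Answers: by what percentage would the reference analysis need to inflate
#' the per-arm sample size to match the target analysis' power at the
#' scenario's size?  The target method's power is estimated at
#' `n_per_arm`; the reference method's power curve over per-arm sizes
#' `[n, n_max_factor * n]` is then inverted by integer bisection.  All
#' power estimates share common random numbers (each replicate draws
#' `n_max_factor * n` subjects per arm once and analyses the first `n`),
#' the evaluated power-vs-n points are smoothed isotonically
#' ([stats::isoreg()]) before each bisection decision, and the crossing
#' point is linearly interpolated inside the final bracket.
#'
#' @param scenario a [scenario_config()]; `n_reps` replicates are used for
#'   every power evaluation.
#' @param reference_method the method whose sample size is inflated
#'   (default `"binary"`).
#' @param target_method the method whose power must be matched (default
#'   `"augmented"`).
#' @param n_max_factor upper bracket for the search, as a multiple of
#'   `n_per_arm`.
#' @param n_tol bisection stops when the bracket is at most this wide
#'   (default `max(1, n_per_arm / 100)`).
#' @return the percent gain `100 * (n_ref / n - 1)`, with attributes
#'   `target_power`, `evaluations` (the reference power-vs-n points) and
#'   `seed`.
#' @export
effective_sample_size_gain <- function(scenario,
                                       reference_method = "binary",
                                       target_method = "augmented",
                                       n_max_factor = 10,
                                       n_tol = NULL) {
  stopifnot(inherits(scenario, "scenario_config"))
  n <- scenario$n_per_arm
  if (identical(reference_method, target_method))
    return(structure(0, target_power = NA_real_, evaluations = NULL,
                     seed = scenario$seed))
  if (is.null(n_tol)) n_tol <- max(1L, round(n / 100))
  n_gen <- as.integer(ceiling(n * n_max_factor))

  target_pow <- mean(.power_indicators(scenario, target_method, n,
                                       n_gen = n))
  if (target_pow <= 0.2 || target_pow >= 0.95)
    stop(sprintf(paste0("target power %.3f is outside (0.2, 0.95); choose a ",
                        "scenario where the comparison is numerically stable"),
                 target_pow), call. = FALSE)

  evals_n <- integer(0); evals_p <- numeric(0)
  ref_pow <- function(nn) {
    i <- match(nn, evals_n)
    if (!is.na(i)) return(evals_p[i])
    p <- mean(.power_indicators(scenario, reference_method, nn,
                                n_gen = n_gen))
    evals_n <<- c(evals_n, nn); evals_p <<- c(evals_p, p)
    p
  }
  smoothed <- function(nn) {
    o <- order(evals_n)
    if (length(evals_n) < 2L) return(evals_p[match(nn, evals_n)])
    iso <- isoreg(evals_n[o], evals_p[o])
    iso$yf[match(nn, evals_n[o])]
  }

  lo <- n; hi <- as.integer(n * n_max_factor)
  p_lo <- ref_pow(lo)
  if (p_lo >= target_pow) {
    gain <- 0
  } else {
    p_hi <- ref_pow(hi)
    if (p_hi < target_pow)
      stop(sprintf(paste0("reference power %.3f at %d per arm does not reach ",
                          "the target power %.3f; the power curve does not ",
                          "bracket within [n, %dn]"),
                   p_hi, hi, target_pow, n_max_factor), call. = FALSE)
    while (hi - lo > n_tol) {
      mid <- as.integer(floor((lo + hi) / 2))
      ref_pow(mid)
      if (smoothed(mid) < target_pow) lo <- mid else hi <- mid
    }
    plo <- smoothed(lo); phi <- smoothed(hi)
    n_ref <- if (phi > plo)
      lo + (hi - lo) * (target_pow - plo) / (phi - plo)
    else (lo + hi) / 2
    n_ref <- min(max(n_ref, lo), hi)
    gain <- 100 * (n_ref / n - 1)
  }
  structure(gain, target_power = target_pow,
            evaluations = data.frame(n = evals_n, power = evals_p),
            seed = scenario$seed)
}

#' Asymptotic cost of dichotomising a normal endpoint
#'
#' For a normally distributed endpoint under a small location shift, the
#' asymptotic ratio of sample sizes needed by a two-sample proportions test
#' on the dichotomised variable (cut so that a fraction `p` fall above the
#' threshold) relative to the two-sample comparison of means is
#' \deqn{\frac{p(1-p)}{\phi\{\Phi^{-1}(p)\}^2}.}
#' At the most favourable cut, the median (`p = 0.5`), the ratio is
#' \eqn{\pi/2 \approx 1.571}: even the best dichotomisation needs about
#' 57% more subjects, and any other cut needs more still.
#'
#' @param p response fraction implied by the cut, strictly in (0, 1).
#' @return the asymptotic sample-size ratio (>= pi/2).
#' @examples
#' dichotomisation_cost_analytic(0.5)     # pi/2
#' @export
dichotomisation_cost_analytic <- function(p) {
  if (!is.numeric(p) || any(p <= 0) || any(p >= 1))
    stop("`p` must be strictly inside (0, 1): the ratio diverges at 0 and 1",
         call. = FALSE)
  p * (1 - p) / dnorm(qnorm(p))^2
}

#' @export
print.power_result <- function(x, ...) {
  cat("Simulated operating characteristics",
      sprintf("(seed %s, config %s)\n", attr(x, "seed"),
              attr(x, "config_hash")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
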