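#' Model-based probability of response
#'
#' Under the joint model, the probability that a subject in arm `z` is a
#' responder is the integral of the normal density of `y` times the
#' logistic probability of meeting the binary criterion, over the region of
#' `y` where the continuous criterion is met:
#' \deqn{p(z) = \int_{R} N(y;\, \alpha + \theta z, \sigma^2)\,
#'   \Lambda(\gamma_0 + \gamma_1 z + \gamma_2 y)\, dy,}
#' with \eqn{R = [\tau, \infty)} for an `at_least` rule and
#' \eqn{(-\infty, \tau]} for `at_most`.  Computed by adaptive quadrature
#' to absolute tolerance `1e-8`.
#'
#' @param params a [joint_params()] object.
#' @param z arm indicator, 0 or 1.
#' @param rule a [composite_rule()] on the same `y` scale as `params`.
#' @param abs_tol absolute quadrature tolerance.
#' @return response probability in `[0, 1]`.
#' @examples
#' p <- joint_params(alpha = 0, sigma = 1, gamma0 = 0)
#' rule <- composite_rule(component_rule("at_least", 0))
#' response_probability(p, z = 0, rule)   # 0.25: Phi * Lambda factorise
#' @export
response_probability <- function(params, z, rule, abs_tol = 1e-8) {
  if (!inherits(rule, "composite_rule"))
    stop("`rule` must be a composite_rule object", call. = FALSE)
  if (!z %in% c(0, 1)) stop("`z` must be 0 or 1", call. = FALSE)
  if (params$sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  mu <- params$alpha + params$theta * z
  eta <- function(y) params$gamma0 + params$gamma1 * z + params$gamma2 * y
  f <- function(y) dnorm(y, mu, params$sigma) * plogis(eta(y))
  tau <- rule$continuous_rule$threshold
  # clip to the +/- 12 sigma support of the normal factor so the adaptive
  # quadrature never hunts over an effectively empty infinite interval;
  # the truncated mass is below dnorm's 12-sigma tail (~2e-32), far inside
  # the tolerance
  span <- 12 * params$sigma
  lims <- if (rule$continuous_rule$direction == "at_least")
    c(max(tau, mu - span), mu + span) else c(mu - span, min(tau, mu + span))
  if (lims[1] >= lims[2]) return(0)
  val <- integrate(f, lims[1], lims[2], abs.tol = abs_tol,
                   rel.tol = abs_tol)$value
  min(max(val, 0), 1)
}

# gradient of response_probability w.r.t. the six parameters
.resp_prob_grad <- function(params, z, rule, rel_step = 1e-6) {
  v <- .jp_vec(params)
  .num_grad(function(w) response_probability(.vec_jp(w), z, rule), v,
            rel_step = rel_step)
}

.response_estimate <- function(method, p0, p1, se_p0, se_p1, se_diff,
                               se_log_or, conf_level, n0, n1, extra = list()) {
  zq <- qnorm(1 - (1 - conf_level) / 2)
  diff <- p1 - p0
  log_or <- qlogis(p1) - qlogis(p0)
  ci_logit <- function(p, se) {
    if (p <= 0 || p >= 1 || !is.finite(se)) return(c(NA_real_, NA_real_))
    plogis(qlogis(p) + c(-1, 1) * zq * se / (p * (1 - p)))
  }
  z_stat <- diff / se_diff
  out <- c(list(method = method, p0 = p0, p1 = p1, diff = diff,
                log_or = log_or, se_p0 = se_p0, se_p1 = se_p1,
                se_diff = se_diff, se_log_or = se_log_or,
                conf_level = conf_level,
                ci_p0 = ci_logit(p0, se_p0), ci_p1 = ci_logit(p1, se_p1),
                ci_diff = pmin(pmax(diff + c(-1, 1) * zq * se_diff, -1), 1),
                ci_log_or = log_or + c(-1, 1) * zq * se_log_or,
                z = z_stat, p_value = 2 * pnorm(-abs(z_stat)),
                n0 = n0, n1 = n1),
           extra)
  class(out) <- "response_estimate"
  out
}

#' Augmented binary analysis of a composite responder endpoint
#'
#' Fits the joint model with [fit_joint_model()] and derives per-arm
#' response probabilities from the fitted model via
#' [response_probability()], keeping the responder definition of `rule`
#' unchanged.  Standard errors come from the delta method: the gradient of
#' each probability (and of the difference and log odds ratio) with respect
#' to the six parameters, propagated through the inverse observed
#' information.  Confidence intervals are on the logit scale per arm, the
#' identity scale for the difference and the log scale for the odds ratio.
#' The reported test is a two-sided Wald z-test on the difference.
#'
#' Subjects with a missing component are retained: the likelihood
#' marginalises over what is unobserved, which is the method's advantage
#' over discarding undetermined subjects.
#'
#' @param data a [trial_data()] object.
#' @param rule a [composite_rule()] (threshold on the raw `y` scale).
#' @param conf_level confidence level in (0, 1).
#' @param gamma2_free,boxcox,control passed to [fit_joint_model()].  When a
#'   Box-Cox transform is applied the rule threshold is transformed to the
#'   analysis scale automatically (it must then be positive).
#' @return an object of class `response_estimate` with fields `method`
#'   (`"augmented"`), `p0`, `p1`, `diff`, `log_or`, standard errors,
#'   confidence intervals, `z`, `p_value`, `n0`, `n1`, and the underlying
#'   `fit`.
#' @examples
#' sc <- scenario_config(n_per_arm = 80, seed = 4)
#' augbin_analysis(simulate_trial(sc), sc$rule)
#' @export
augbin_analysis <- function(data, rule, conf_level = 0.95,
                            gamma2_free = TRUE, boxcox = "off",
                            control = list()) {
  if (!is.numeric(conf_level) || conf_level <= 0 || conf_level >= 1)
    stop("`conf_level` must be in (0, 1)", call. = FALSE)
  fit <- fit_joint_model(data, gamma2_free = gamma2_free, boxcox = boxcox,
                         control = control)
  if (isTRUE(fit$separation))
    stop("joint model fit flagged complete separation in the binary ",
         "sub-model; the augmented analysis is not identified",
         call. = FALSE)
  if (!fit$converged)
    stop("joint model fit did not converge", call. = FALSE)
  rule_a <- rule
  if (!is.null(fit$boxcox_lambda)) {
    tau <- rule$continuous_rule$threshold
    if (tau <= 0)
      stop("rule threshold must be positive to be Box-Cox transformed ",
           "onto the analysis scale", call. = FALSE)
    rule_a$continuous_rule$threshold <- apply_boxcox(tau, fit$boxcox_lambda)
  }
  V <- fit$vcov
  p0 <- response_probability(fit$params, 0, rule_a)
  p1 <- response_probability(fit$params, 1, rule_a)
  g0 <- .resp_prob_grad(fit$params, 0, rule_a)
  g1 <- .resp_prob_grad(fit$params, 1, rule_a)
  qf <- function(g) sqrt(max(drop(g %*% V %*% g), 0))
  se_p0 <- qf(g0); se_p1 <- qf(g1)
  se_diff <- qf(g1 - g0)
  g_lor <- g1 / (p1 * (1 - p1)) - g0 / (p0 * (1 - p0))
  se_log_or <- qf(g_lor)
  .response_estimate("augmented", p0, p1, se_p0, se_p1, se_diff, se_log_or,
                     conf_level, fit$n0, fit$n1, extra = list(fit = fit))
}

#' Standard binary analysis of a composite responder endpoint
#'
#' Classifies subjects with [classify_responder()], drops undetermined
#' subjects (their count is recorded in the result), and compares raw
#' responder proportions: Wald standard error for the difference, and
#' `sqrt(sum of reciprocal cell counts)` for the log odds ratio.  A zero
#' cell either receives the Haldane-Anscombe 0.5 continuity correction
#' (applied to all four cells, for the odds ratio and per-arm intervals;
#' recorded via `corrected = TRUE`) or raises an error, per
#' `zero_cell_correction`.
#'
#' @param data a [trial_data()] object.
#' @param rule a [composite_rule()].
#' @param conf_level confidence level in (0, 1).
#' @param zero_cell_correction apply the 0.5 correction on zero cells
#'   instead of failing.
#' @return an object of class `response_estimate` with `method`
#'   (`"binary"`), counts (`r0`, `r1`), `n_undetermined` and `corrected`
#'   alongside the shared estimate fields.
#' @export
binary_analysis <- function(data, rule, conf_level = 0.95,
                            zero_cell_correction = TRUE) {
  if (!is.numeric(conf_level) || conf_level <= 0 || conf_level >= 1)
    stop("`conf_level` must be in (0, 1)", call. = FALSE)
  data <- as_trial_data(data)
  cls <- classify_responder(data$y, data$b, rule)
  det <- cls != "undetermined"
  n_undet <- sum(!det)
  z <- data$arm[det]
  resp <- cls[det] == "responder"
  n0 <- sum(z == 0); n1 <- sum(z == 1)
  if (n0 < 1L || n1 < 1L)
    stop("need at least one determined classification per arm",
         call. = FALSE)
  r0 <- sum(resp[z == 0]); r1 <- sum(resp[z == 1])
  p0 <- r0 / n0; p1 <- r1 / n1
  se_diff <- sqrt(p0 * (1 - p0) / n0 + p1 * (1 - p1) / n1)
  cells <- c(r0, n0 - r0, r1, n1 - r1)
  corrected <- FALSE
  if (any(cells == 0)) {
    if (!zero_cell_correction)
      stop("degenerate 2x2 table (zero cell); rerun with ",
           "`zero_cell_correction = TRUE` or collect more data",
           call. = FALSE)
    cells <- cells + 0.5
    corrected <- TRUE
  }
  p0c <- cells[1] / (cells[1] + cells[2])
  p1c <- cells[3] / (cells[3] + cells[4])
  se_log_or <- sqrt(sum(1 / cells))
  se_p0 <- sqrt(p0c * (1 - p0c) / (cells[1] + cells[2]))
  se_p1 <- sqrt(p1c * (1 - p1c) / (cells[3] + cells[4]))
  est <- .response_estimate("binary",
                            if (corrected) p0c else p0,
                            if (corrected) p1c else p1,
                            se_p0, se_p1, se_diff, se_log_or, conf_level,
                            n0, n1,
                            extra = list(r0 = r0, r1 = r1,
                                         n_undetermined = n_undet,
                                         corrected = corrected))
  # keep the uncorrected point estimates for diff (Wald test is on raw
  # proportions); the corrected ones only back the OR and per-arm CIs
  est$p0 <- p0; est$p1 <- p1
  est$diff <- p1 - p0
  est$z <- est$diff / se_diff
  est$p_value <- 2 * pnorm(-abs(est$z))
  est
}

#' @export
print.response_estimate <- function(x, ...) {
  cat(sprintf("%s analysis of composite responder endpoint\n",
              switch(x$method, augmented = "Augmented binary",
                     binary = "Binary", x$method)))
  cl <- 100 * x$conf_level
  cat(sprintf("  control   p0 = %.4f (%g%% CI %.4f, %.4f)\n",
              x$p0, cl, x$ci_p0[1], x$ci_p0[2]))
  cat(sprintf("  treatment p1 = %.4f (%g%% CI %.4f, %.4f)\n",
              x$p1, cl, x$ci_p1[1], x$ci_p1[2]))
  cat(sprintf("  difference   = %.4f (SE %.4f; %g%% CI %.4f, %.4f)\n",
              x$diff, x$se_diff, cl, x$ci_diff[1], x$ci_diff[2]))
  cat(sprintf("  log OR       = %.4f (SE %.4f; %g%% CI %.4f, %.4f)\n",
              x$log_or, x$se_log_or, cl, x$ci_log_or[1], x$ci_log_or[2]))
  cat(sprintf("  Wald z = %.3f, two-sided p = %.4g  (n0 = %d, n1 = %d)\n",
              x$z, x$p_value, x$n0, x$n1))
  if (!is.null(x$n_undetermined) && x$n_undetermined > 0)
    cat(sprintf("  %d undetermined subject(s) excluded\n", x$n_undetermined))
  invisible(x)
}

#' Per-patient response weights from a fitted joint model
#'
#' The augmented binary method can be viewed as replacing each patient's
#' 0/1 responder status by a fitted response weight in `[0, 1]` that is
#' smooth in the distance of the continuous value from the threshold.  The
#' default (`"gated"`) weight for a patient with observed components is
#' \eqn{\Phi((y - \tau)/\hat\sigma)} for an `at_least` rule (mirrored for
#' `at_most`) when the binary criterion is met, and 0 when it is not: the
#' fitted residual SD sets the smoothing scale, so a patient just under the
#' threshold (who may be misclassified by measurement error) retains
#' weight close to 0.5 rather than 0.  The `"model_based"` variant replaces
#' the hard binary gate by the fitted logistic probability
#' \eqn{\Lambda(\hat\gamma_0 + \hat\gamma_1 z + \hat\gamma_2 y)}.
#'
#' Missing components are handled predictively: a missing binary component
#' multiplies in its fitted probability; a missing continuous value uses
#' the model-based probability that the criterion is met given arm (and,
#' for the gated variant with `b = 1`, conditionally on the binary
#' outcome).
#'
#' @param fit a converged [fit_joint_model()] result.
#' @param data the [trial_data()] the weights are for.
#' @param rule a [composite_rule()] (raw scale; transformed internally if
#'   the fit used Box-Cox).
#' @param variant `"gated"` (default) or `"model_based"`.
#' @return numeric vector of weights in `[0, 1]`, one per subject.
#' @export
response_weights <- function(fit, data, rule,
                             variant = c("gated", "model_based")) {
  variant <- match.arg(variant)
  if (!inherits(fit, "fitted_joint_model"))
    stop("`fit` must come from fit_joint_model()", call. = FALSE)
  if (!fit$converged)
    stop("weights require a converged fit", call. = FALSE)
  data <- as_trial_data(data)
  p <- fit$params
  rule_a <- rule
  y <- data$y
  if (!is.null(fit$boxcox_lambda)) {
    y[!is.na(y)] <- apply_boxcox(y[!is.na(y)], fit$boxcox_lambda)
    rule_a$continuous_rule$threshold <-
      apply_boxcox(rule$continuous_rule$threshold, fit$boxcox_lambda)
  }
  tau <- rule_a$continuous_rule$threshold
  sgn <- if (rule_a$continuous_rule$direction == "at_least") 1 else -1
  z <- data$arm; b <- data$b
  cont_w <- pnorm(sgn * (y - tau) / p$sigma)
  pb <- plogis(p$gamma0 + p$gamma1 * z + p$gamma2 * y)
  marg <- function(zz) response_probability(p, zz, rule_a)
  pb_marg <- function(zz) {                # P(b = 1 | z), y integrated out
    gh <- .gh_rule()
    yk <- p$alpha + p$theta * zz + sqrt(2) * p$sigma * gh$x
    sum(gh$w * plogis(p$gamma0 + p$gamma1 * zz + p$gamma2 * yk)) / sqrt(pi)
  }
  n <- nrow(data)
  w <- numeric(n)
  for (i in seq_len(n)) {
    if (!is.na(y[i])) {
      w[i] <- if (variant == "model_based") cont_w[i] * pb[i]
      else if (is.na(b[i])) cont_w[i] * pb[i]       # predictive gate
      else if (b[i] == 1) cont_w[i]
      else 0
    } else {                                        # y missing
      if (variant == "gated" && !is.na(b[i]) && b[i] == 0) {
        w[i] <- 0
      } else if (variant == "gated" && !is.na(b[i]) && b[i] == 1) {
        w[i] <- marg(z[i]) / pb_marg(z[i])          # P(criterion | b = 1, z)
      } else {
        w[i] <- marg(z[i])
      }
    }
  }
  pmin(pmax(w, 0), 1)
}

#' Plot fitted response weights against the continuous component
#'
#' Visualises how the augmented analysis re-weights patients: the hard 0/1
#' responder status of the binary method against the smooth fitted weight,
#' by the continuous component value.  Patients failing the binary
#' criterion sit at weight 0 regardless of `y`.
#'
#' @param fit a converged [fit_joint_model()] result.
#' @param data the [trial_data()] to display.
#' @param rule the [composite_rule()].
#' @param variant passed to [response_weights()].
#' @param ... further arguments to [plot()].
#' @return the weights, invisibly.
#' @export
plot_response_weights <- function(fit, data, rule,
                                  variant = c("gated", "model_based"), ...) {
  data <- as_trial_data(data)
  w <- response_weights(fit, data, rule, variant = variant)
  ok <- !is.na(data$y)
  cls <- classify_responder(data$y, data$b, rule)
  plot(data$y[ok], w[ok], ylim = c(0, 1),
       pch = ifelse(data$arm[ok] == 1, 17, 1),
       col = ifelse(cls[ok] == "responder", "forestgreen", "grey40"),
       xlab = rule$continuous_rule$label, ylab = "fitted response weight",
       main = "Response weights vs hard dichotomisation", ...)
  graphics::abline(v = rule$continuous_rule$threshold, lty = 2)
  graphics::points(data$y[ok], as.numeric(cls[ok] == "responder"),
                   pch = ".", cex = 2, col = "firebrick")
  graphics::legend("topleft", bty = "n", pch = c(1, 17, NA, NA),
                   lty = c(NA, NA, NA, 2),
                   col = c("grey40", "grey40", "firebrick", "black"),
                   legend = c("control", "treatment",
                              "binary 0/1 status (dots)", "threshold"))
  invisible(w)
}
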