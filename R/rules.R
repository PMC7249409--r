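#' Define the continuous criterion of a responder endpoint
#'
#' A component rule dichotomises a continuous measurement: the criterion is
#' met when the value is at least (`"at_least"`) or at most (`"at_most"`)
#' the threshold.  Comparison at the threshold is inclusive, matching the
#' usual ">= x% shrinkage" / "<= x mmol/L" clinical definitions.
#'
#' Tumour shrinkage expressed as signed percent change from baseline is an
#' `"at_most"` rule (e.g. threshold -30: at least 30% shrinkage); direction
#' is always explicit configuration, never inferred from data.
#'
#' @param direction `"at_least"` or `"at_most"`.
#' @param threshold single finite numeric threshold, on the analysis scale
#'   of the continuous measurement.
#' @param label free-text label for reports.
#' @return an object of class `component_rule`.
#' @examples
#' component_rule("at_most", -30, "percent change in lesion diameter sum")
#' @export
component_rule <- function(direction = c("at_least", "at_most"), threshold,
                           label = "continuous component") {
  direction <- match.arg(direction)
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold))
    stop("`threshold` must be a single finite number", call. = FALSE)
  structure(list(direction = direction,
                 threshold = as.numeric(threshold),
                 label = as.character(label)[1L]),
            class = "component_rule")
}

#' Define a composite responder endpoint
#'
#' A composite rule declares a patient a responder when the continuous
#' criterion AND the binary criterion are both met.  Only a single
#' continuous component is supported: "m of k" definitions such as the
#' ACR20 item requiring improvement in three of five assessments cannot be
#' represented and are rejected.
#'
#' @param continuous_rule a [component_rule()].
#' @param binary_required must be `TRUE`: response always requires the
#'   binary criterion in this formulation.
#' @param description free-text endpoint description.
#' @return an object of class `composite_rule`.
#' @examples
#' tumour_response <- composite_rule(
#'   component_rule("at_most", -30, "percent change in lesion diameters"),
#'   description = "RECIST-style objective response")
#' @export
composite_rule <- function(continuous_rule, binary_required = TRUE,
                           description = "") {
  if (is.list(continuous_rule) && !inherits(continuous_rule, "component_rule") &&
      any(vapply(continuous_rule, inherits, logical(1), "component_rule")))
    stop("multi-component continuous rules ('m of k' definitions such as the ",
         "ACR20 assessment item) are not representable; supply a single ",
         "component_rule", call. = FALSE)
  if (!inherits(continuous_rule, "component_rule"))
    stop("`continuous_rule` must be a component_rule object", call. = FALSE)
  if (!isTRUE(binary_required))
    stop("`binary_required` must be TRUE: the composite endpoint is the ",
         "continuous criterion AND the binary criterion", call. = FALSE)
  structure(list(continuous_rule = continuous_rule,
                 binary_required = TRUE,
                 description = as.character(description)[1L]),
            class = "composite_rule")
}

#' @export
print.component_rule <- function(x, ...) {
  op <- if (x$direction == "at_least") ">=" else "<="
  cat(sprintf("Continuous criterion: %s %s %g\n", x$label, op, x$threshold))
  invisible(x)
}

#' @export
print.composite_rule <- function(x, ...) {
  if (nzchar(x$description)) cat(x$description, "\n")
  cat("Responder = continuous criterion AND binary criterion\n")
  print(x$continuous_rule)
  invisible(x)
}

# TRUE / FALSE / NA indicator for the continuous criterion
.cont_met <- function(y, rule) {
  cr <- rule$continuous_rule
  if (cr$direction == "at_least") y >= cr$threshold else y <= cr$threshold
}

#' Classify subjects as responders under a composite rule
#'
#' Applies the deterministic responder definition exactly as the standard
#' binary analysis would.  A subject is a responder when both criteria are
#' known to be met, a non-responder when either criterion is known to be
#' failed, and undetermined when neither holds (a component whose value
#' would still be needed is missing).  Missingness never raises an error.
#'
#' @param y numeric vector of continuous values (`NA` = missing).
#' @param b binary component values in `{0, 1}` (`NA` = missing).
#' @param rule a [composite_rule()].
#' @return factor with levels `responder`, `non_responder`, `undetermined`.
#' @examples
#' rule <- composite_rule(component_rule("at_most", -30))
#' classify_responder(c(-35, -10, NA), c(1, 1, 1), rule)
#' @export
classify_responder <- function(y, b, rule) {
  if (!inherits(rule, "composite_rule"))
    stop("`rule` must be a composite_rule object", call. = FALSE)
  n <- max(length(y), length(b))
  y <- rep_len(as.numeric(y), n)
  b <- rep_len(b, n)
  if (any(!is.na(b) & !(b %in% c(0, 1))))
    stop("`b` must be 0, 1 or NA", call. = FALSE)
  cont <- .cont_met(y, rule)           # NA propagates from missing y
  bin <- b == 1
  known_fail <- (!is.na(cont) & !cont) | (!is.na(bin) & !bin)
  known_pass <- !is.na(cont) & cont & !is.na(bin) & bin
  out <- rep("undetermined", n)
  out[known_fail] <- "non_responder"
  out[known_pass & !known_fail] <- "responder"
  factor(out, levels = c("responder", "non_responder", "undetermined"))
}

#' Classify a whole trial and tabulate responders by arm
#'
#' @param data a [trial_data()] object.
#' @param rule a [composite_rule()].
#' @return a list of class `trial_classification` with elements
#'   `classification` (factor, one entry per subject, in input order) and
#'   `counts` (arm x classification table).
#' @export
classify_trial <- function(data, rule) {
  data <- as_trial_data(data)
  if (nrow(data) == 0L) stop("`data` has no subjects", call. = FALSE)
  cls <- classify_responder(data$y, data$b, rule)
  counts <- table(arm = factor(data$arm, levels = c(0, 1)), class = cls)
  structure(list(classification = cls, counts = counts),
            class = "trial_classification")
}

#' @export
print.trial_classification <- function(x, ...) {
  cat("Responder classification by arm:\n")
  print(x$counts)
  invisible(x)
}
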