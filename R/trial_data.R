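#' Construct per-subject trial data
#'
#' The container for a two-arm trial with one continuous and one binary
#' endpoint component per subject.  Either component may be missing.
#'
#' @param arm arm indicator, 0 (control) or 1 (treatment); no missing
#'   values allowed.
#' @param y continuous component on the analysis scale (`NA` = missing).
#' @param b binary component, 1 = criterion met (`NA` = missing).
#' @param id subject identifiers (coerced to character; defaults to row
#'   numbers).
#' @return a data frame of class `trial_data` with columns
#'   `id`, `arm`, `y`, `b`.
#' @examples
#' trial_data(arm = c(0, 0, 1, 1), y = c(1.2, -0.3, 2.1, NA),
#'            b = c(1, 1, NA, 0))
#' @export
trial_data <- function(arm, y, b, id = NULL) {
  n <- length(arm)
  if (length(y) != n || length(b) != n)
    stop("`arm`, `y` and `b` must have equal length", call. = FALSE)
  if (is.null(id)) id <- as.character(seq_len(n))
  if (length(id) != n) stop("`id` must match the number of subjects",
                            call. = FALSE)
  if (anyNA(arm) || !all(arm %in% c(0, 1)))
    stop("`arm` must be 0 or 1 with no missing values", call. = FALSE)
  if (!is.numeric(y) && !all(is.na(y)))
    stop("`y` must be numeric", call. = FALSE)
  bad_b <- !is.na(b) & !(b %in% c(0, 1))
  if (any(bad_b))
    stop("`b` must be 0, 1 or NA (offending subject(s): ",
         paste(utils::head(id[bad_b], 5), collapse = ", "), ")",
         call. = FALSE)
  out <- data.frame(id = as.character(id), arm = as.integer(arm),
                    y = as.numeric(y), b = as.integer(b),
                    stringsAsFactors = FALSE)
  class(out) <- c("trial_data", "data.frame")
  out
}

#' @rdname trial_data
#' @param x object to convert (a data frame with columns `id`, `arm`,
#'   `y`, `b`, or an existing `trial_data`).
#' @export
as_trial_data <- function(x) {
  if (inherits(x, "trial_data")) return(x)
  if (!is.data.frame(x) || !all(c("arm", "y", "b") %in% names(x)))
    stop("cannot interpret `x` as trial data (need columns arm, y, b)",
         call. = FALSE)
  trial_data(arm = x$arm, y = x$y, b = x$b,
             id = if ("id" %in% names(x)) x$id else NULL)
}

#' Read trial data from CSV
#'
#' Expects exactly the header `id,arm,y,b`.  Empty cells are read as
#' missing.  Malformed rows (arm outside `{0,1}`, non-numeric `y`, `b`
#' outside `{0,1}`) raise an error naming the offending data row.
#'
#' @param path path to a CSV file.
#' @return a [trial_data()] object with one record per data row.
#' @export
read_trial_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", na.strings = "",
                         check.names = FALSE)
  if (!identical(names(raw), c("id", "arm", "y", "b")))
    stop("CSV header must be exactly `id,arm,y,b` (got: ",
         paste(names(raw), collapse = ","), ")", call. = FALSE)
  bad <- which(is.na(raw$arm) | !(raw$arm %in% c("0", "1")))
  if (length(bad))
    stop("invalid `arm` value (must be 0 or 1) at data row ", bad[1L],
         call. = FALSE)
  y <- suppressWarnings(as.numeric(raw$y))
  bad <- which(!is.na(raw$y) & is.na(y))
  if (length(bad))
    stop("non-numeric `y` value at data row ", bad[1L], call. = FALSE)
  bad <- which(!is.na(raw$b) & !(raw$b %in% c("0", "1")))
  if (length(bad))
    stop("invalid `b` value (must be 0, 1 or empty) at data row ", bad[1L],
         call. = FALSE)
  trial_data(arm = as.integer(raw$arm), y = y,
             b = suppressWarnings(as.integer(raw$b)), id = raw$id)
}

#' Write trial data to CSV
#'
#' Inverse of [read_trial_csv()]; missing components are written as empty
#' cells, so a write/read round trip is lossless.
#'
#' @param data a [trial_data()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(data, path) {
  data <- as_trial_data(data)
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "",
                   quote = FALSE)
  invisible(path)
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("Trial data: %d subjects (%d control, %d treatment); missing y: %d, missing b: %d\n",
              nrow(x), sum(x$arm == 0), sum(x$arm == 1),
              sum(is.na(x$y)), sum(is.na(x$b))))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
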