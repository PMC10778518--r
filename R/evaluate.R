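# Evaluation metrics and the weight-class breakdown: overall and per-class
# coefficient of determination and RMSE, classes assigned by the actual
# scale weight with half-open boundaries at 55 and 90 kg.

#' Root mean squared error
#' @param predicted,actual numeric vectors of equal nonzero length, kg.
#' @return RMSE in kg.
#' @export
rmse <- function(predicted, actual) {
  predicted <- as.numeric(predicted); actual <- as.numeric(actual)
  if (length(predicted) != length(actual) || length(actual) == 0L)
    stop("'predicted' and 'actual' must have equal nonzero length")
  sqrt(mean((predicted - actual)^2))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` with the total sum of squares about the mean of
#' `actual`. Unlike a squared correlation this can be negative for a
#' predictor worse than the mean; that is intended and documented.
#'
#' @param predicted,actual numeric vectors of equal length >= 2, kg.
#' @return dimensionless R-squared (at most 1, possibly negative).
#' @export
r_squared <- function(predicted, actual) {
  predicted <- as.numeric(predicted); actual <- as.numeric(actual)
  if (length(predicted) != length(actual))
    stop("'predicted' and 'actual' must have equal length")
  if (length(actual) < 2L) stop("need at least two samples")
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0)
    stop("undefined R-squared: all actual values are identical")
  1 - sum((actual - predicted)^2) / ss_tot
}

#' Weight-class membership
#'
#' Assigns a weight to its class under half-open boundaries: with the
#' default boundaries `c(55, 90)` the classes are below 55 kg
#' (`w < 55`), 55--90 kg (`55 <= w < 90`) and above 90 kg (`w >= 90`).
#'
#' @param weight numeric weights in kg (> 0).
#' @param boundaries strictly ascending positive class boundaries.
#' @return factor of class labels, ordered from lightest to heaviest.
#' @export
classify_weight <- function(weight, boundaries = c(55, 90)) {
  stopifnot(all(weight > 0), all(diff(boundaries) > 0), all(boundaries > 0))
  labs <- weight_class_labels(boundaries)
  idx <- findInterval(weight, boundaries) + 1L  # half-open: w >= b -> upper
  factor(labs[idx], levels = labs)
}

weight_class_labels <- function(boundaries) {
  b <- format(boundaries, trim = TRUE)
  n <- length(boundaries)
  c(paste0("<", b[1L]),
    if (n > 1L) paste0(b[-n], "-", b[-1L]),
    paste0(">=", b[n]))
}

#' Evaluate predictions overall and per weight class
#'
#' Computes the overall and per-class R-squared and RMSE, with class
#' membership determined by the actual scale weight. Per-class R-squared is
#' computed within the class (about the class mean of the actuals); classes
#' with fewer than two samples, or with constant actuals, report RMSE only
#' and `NA` for R-squared.
#'
#' @param predicted,actual numeric vectors of equal length >= 2, kg.
#' @param boundaries class boundaries, see [classify_weight()].
#' @return an object of class `evaluation_report`: list with `overall`
#'   (data.frame: n, r_squared, rmse) and `per_class` (one row per class).
#' @export
evaluate_predictions <- function(predicted, actual, boundaries = c(55, 90)) {
  predicted <- as.numeric(predicted); actual <- as.numeric(actual)
  if (length(predicted) != length(actual))
    stop("'predicted' and 'actual' must have equal length")
  if (length(actual) < 2L) stop("need at least two samples")
  cls <- classify_weight(actual, boundaries)
  one <- function(p, a) {
    r2 <- if (length(a) >= 2L && stats::var(a) > 0) r_squared(p, a)
          else NA_real_
    data.frame(n = length(a),
               r_squared = r2,
               rmse = if (length(a) > 0L) rmse(p, a) else NA_real_)
  }
  per <- do.call(rbind, lapply(levels(cls), function(lv) {
    i <- cls == lv
    row <- if (any(i)) one(predicted[i], actual[i])
           else data.frame(n = 0L, r_squared = NA_real_, rmse = NA_real_)
    cbind(class = lv, row)
  }))
  structure(list(overall = one(predicted, actual), per_class = per,
                 boundaries = boundaries),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 3L, ...) {
  cat("Weight-prediction evaluation (classes by actual scale weight, kg)\n")
  tab <- rbind(cbind(class = as.character(x$per_class$class),
                     x$per_class[, c("n", "r_squared", "rmse")]),
               cbind(class = "overall", x$overall))
  tab$r_squared <- round(tab$r_squared, digits)
  tab$rmse <- round(tab$rmse, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
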