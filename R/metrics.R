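#' Area-recovery ratios
#'
#' `aar()` is the actual (visible) area ratio `AD / (Area_1 + Area_2)`:
#' the composite visible area of an overlapped pair over the sum of the
#' two objects' true areas.  `car()` adds the recovered hidden-overlap
#' area, `(AD + CD) / (Area_1 + Area_2)`.  Neither ratio is clipped at 1:
#' an over-estimated hidden area legitimately yields CAR > 1 and the
#' summary statistics account for it.
#'
#' @param ad visible composite pixel area of the overlapped pair.
#' @param cd recovered hidden-overlap pixel area.
#' @param area_1,area_2 true pixel areas of the two objects.
#' @return dimensionless ratio (vectorized).
#' @export
aar <- function(ad, area_1, area_2) {
  denom <- area_1 + area_2
  if (any(denom <= 0)) stop("area_1 + area_2 must be positive")
  if (any(ad < 0)) stop("ad must be non-negative")
  ad / denom
}

#' @rdname aar
#' @export
car <- function(ad, cd, area_1, area_2) {
  if (any(cd < 0)) stop("cd must be non-negative")
  aar(ad, area_1, area_2) + cd / (area_1 + area_2)
}

#' Summarize per-sample area records
#'
#' Computes the average ratios `Avg_AAR = sum(AAR_i)/n` and
#' `Avg_CAR = sum(CAR_i)/n`, the per-sample increases `CAR_i - AAR_i`
#' (min / max / mean), and the count of negative optimizations — samples
#' where the correction moved the ratio FURTHER from 1 than it started,
#' i.e. `|CAR - 1| > |AAR - 1|`.
#'
#' @param records data frame with numeric columns `aar` and `car` (e.g.
#'   [area_record()] rows or [read_area_report()] output).
#' @return an object of class `area_summary`: list with `n`, `avg_aar`,
#'   `avg_car`, `min_increase`, `max_increase`, `mean_increase`,
#'   `negative_optimization_count`.
#' @examples
#' recs <- data.frame(aar = c(0.4, 0.8), car = c(0.5, 0.9))
#' summarize_area_records(recs)
#' @export
summarize_area_records <- function(records) {
  if (is.null(records) || !nrow(records)) stop("no records to summarize")
  a <- as.numeric(records$aar); cc <- as.numeric(records$car)
  inc <- cc - a
  structure(list(
    n = nrow(records),
    avg_aar = mean(a),
    avg_car = mean(cc),
    min_increase = min(inc),
    max_increase = max(inc),
    mean_increase = mean(inc),
    negative_optimization_count = sum(abs(cc - 1) > abs(a - 1))),
    class = "area_summary")
}

#' @export
print.area_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<area_summary> n = %d\n",
           "  Avg_AAR = %.3f, Avg_CAR = %.3f\n",
           "  increase (CAR - AAR): min %.3f, mean %.3f, max %.3f\n",
           "  negative optimizations: %d\n"),
    x$n, x$avg_aar, x$avg_car,
    x$min_increase, x$mean_increase, x$max_increase,
    x$negative_optimization_count))
  invisible(x)
}

#' @export
format.area_summary <- function(x, ...) {
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
}

#' Mean of a group of recognition confidences
#'
#' Arithmetic mean of percentage values, reported to 1 decimal (half-up),
#' as used to condense per-overlap-type recognition confidences into a
#' per-group figure.
#'
#' @param values non-empty numeric vector of percentages.
#' @return the mean, rounded half-up to 1 decimal.
#' @export
group_mean <- function(values) {
  if (!length(values)) stop("empty group")
  round_half_up(mean(values), 1L)
}

#' Half-up decimal rounding
#'
#' `round()` in R rounds half to even; printed reference tables use
#' conventional half-up rounding, reproduced here.
#'
#' @param x numeric vector.
#' @param digits decimals to keep.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 0L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}
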