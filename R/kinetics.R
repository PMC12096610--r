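#' Interval release rate
#'
#' Direct-difference release rate over one sampling interval:
#' \deqn{K = (D_{t_2} - D_{t_1}) / (t_2 - t_1)}
#' where \eqn{D_t} is the measured cumulative amount released at \eqn{t}
#' minutes. Both endpoints must lie in the same digestion phase (each phase
#' has its own clock), and the baseline \eqn{D_{t_1}} is the measured value
#' at the interval start, never an assumed zero. A negative rate -- possible
#' when replicate fluctuation makes the cumulative series dip -- is
#' returned as-is with a `cnsync_negative_rate` warning; it is never
#' clipped.
#'
#' @param curve A [release_curve()].
#' @param t1,t2 Interval endpoints in minutes, `t1 < t2`, both on the
#'   sampling grid of `phase` (unless `interpolate = TRUE`).
#' @param phase Digestion phase, default `"intestinal"`.
#' @param interpolate Allow linear interpolation off the sampling grid
#'   (intended for dense simulator output); default `FALSE`.
#' @return Release rate in curve units per minute.
#' @examples
#' rc <- release_curve("d1", "glucose", 1,
#'   "intestinal", c(0, 20, 60), c(0, 12, 30), "g/kg")
#' interval_rate(rc, 0, 20) # 0.6 g/kg/min
#' @export
interval_rate <- function(curve, t1, t2, phase = "intestinal",
                          interpolate = FALSE) {
  stopifnot(inherits(curve, "release_curve"))
  phase <- match.arg(phase, .PHASES)
  if (!is.numeric(t1) || !is.numeric(t2) || t1 >= t2) {
    .stop("`t1` must be strictly less than `t2`")
  }
  d1 <- .curve_value_at(curve, t1, phase, interpolate)
  d2 <- .curve_value_at(curve, t2, phase, interpolate)
  k <- (d2 - d1) / (t2 - t1)
  if (k < 0) {
    .warn(sprintf(
      "negative release rate (%.4g/min) over %s %g-%g min for %s/%s",
      k, phase, t1, t2, curve$substrate_id, curve$nutrient
    ), class = "cnsync_negative_rate")
  }
  k
}

#' Release-rate series over consecutive sampling intervals
#'
#' One interval rate per consecutive pair of a grid of sampled times, in
#' grid order. Negative rates are flagged in the `flag_negative` column
#' rather than warned about point-by-point.
#'
#' @inheritParams interval_rate
#' @param grid Numeric vector (>= 2 points) of times, a subset of the
#'   sampled times of `phase`.
#' @return A tibble with columns `substrate_id`, `nutrient`, `replicate`,
#'   `phase`, `t1`, `t2`, `rate`, `unit_per_min`, `flag_negative`.
#' @export
rate_series <- function(curve, grid, phase = "intestinal") {
  stopifnot(inherits(curve, "release_curve"))
  phase <- match.arg(phase, .PHASES)
  if (length(grid) < 2) .stop("`grid` needs at least 2 points")
  sampled <- curve$data$time_min[curve$data$phase == phase]
  if (!all(grid %in% sampled)) {
    .stop("`grid` must be a subset of the sampled ", phase, " times")
  }
  d <- vapply(grid, function(t) .curve_value_at(curve, t, phase), numeric(1))
  k <- diff(d) / diff(grid)
  tibble(
    substrate_id = curve$substrate_id,
    nutrient = curve$nutrient,
    replicate = curve$replicate,
    phase = phase,
    t1 = grid[-length(grid)],
    t2 = grid[-1],
    rate = k,
    unit_per_min = paste0(curve$unit, "/min"),
    flag_negative = k < 0
  )
}

#' Pointwise replicate mean and SEM of release curves
#'
#' Averages replicate curves of the same substrate and nutrient on a shared
#' time grid, the way replicate wet-assay curves (n = 3 per substrate) are
#' reported as mean with standard error.
#'
#' @param curves List of [release_curve()] objects (>= 2) sharing
#'   substrate, nutrient, unit and sampling grid.
#' @return A tibble with columns `substrate_id`, `nutrient`, `phase`,
#'   `time_min`, `mean`, `sem` (sd/sqrt(n)), `n`, `unit`.
#' @export
summarize_replicates <- function(curves) {
  if (!is.list(curves) || length(curves) < 2) {
    .stop("need at least 2 replicate curves")
  }
  stopifnot(all(vapply(curves, inherits, logical(1), "release_curve")))
  ref <- curves[[1]]
  for (cv in curves[-1]) {
    if (cv$substrate_id != ref$substrate_id || cv$nutrient != ref$nutrient) {
      .stop("all curves must share one substrate and nutrient")
    }
    if (cv$unit != ref$unit) .stop("all curves must share one unit")
    if (!identical(cv$data$phase, ref$data$phase) ||
        !identical(cv$data$time_min, ref$data$time_min)) {
      .stop("replicate curves have mismatched sampling grids")
    }
  }
  mat <- vapply(curves, function(cv) cv$data$cumulative,
                numeric(nrow(ref$data)))
  mat <- matrix(mat, nrow = nrow(ref$data))
  n <- length(curves)
  tibble(
    substrate_id = ref$substrate_id,
    nutrient = ref$nutrient,
    phase = ref$data$phase,
    time_min = ref$data$time_min,
    mean = rowMeans(mat),
    sem = apply(mat, 1, sd) / sqrt(n),
    n = n,
    unit = ref$unit
  )
}

# Defined unit conversions: multiplicative factors only.
.UNIT_FACTORS <- list(
  "g/100g->g/kg" = 10,
  "g/kg->g/100g" = 0.1
)

#' Convert release-curve units
#'
#' Diet-level glucose is carried internally in g/kg dry matter while
#' ingredient-level release is conventionally reported in g/100 g; the two
#' differ by a factor of 10. Conversions that need extra information (e.g.
#' mmol/kg to g/kg, which requires a molar mass) are refused.
#'
#' @param curve A [release_curve()].
#' @param target_unit One of `"g/kg"`, `"g/100g"` (or the curve's own unit,
#'   a no-op).
#' @return A new [release_curve()] with scaled amounts and updated unit.
#' @export
convert_units <- function(curve, target_unit) {
  stopifnot(inherits(curve, "release_curve"))
  if (identical(curve$unit, target_unit)) return(curve)
  key <- paste0(curve$unit, "->", target_unit)
  f <- .UNIT_FACTORS[[key]]
  if (is.null(f)) {
    .stop("no defined conversion from '", curve$unit, "' to '",
          target_unit, "'")
  }
  release_curve(curve$substrate_id, curve$nutrient, curve$replicate,
                curve$data$phase, curve$data$time_min,
                curve$data$cumulative * f, target_unit)
}
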