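#' Diet formulation specification
#'
#' Ingredient inclusion map on an as-fed percentage basis. Inclusions are
#' carried as exact hundredths of a percent internally so sum-to-100
#' checks do not drift with floating point.
#'
#' @param diet_id Diet identifier.
#' @param ingredients Named numeric vector, ingredient -> inclusion % (two
#'   decimal places).
#' @param marker Marker ingredient name; default `"Cr2O3"`.
#' @param marker_level Declared marker inclusion %, default 0.3.
#' @param nitrogen_free Logical tag for the nitrogen-free diet.
#' @return Object of class `diet_spec`.
#' @export
diet_spec <- function(diet_id, ingredients, marker = "Cr2O3",
                      marker_level = 0.3, nitrogen_free = FALSE) {
  if (is.null(names(ingredients)) || any(names(ingredients) == "")) {
    .stop("`ingredients` must be a named vector")
  }
  if (any(ingredients < 0)) .stop("inclusions must be >= 0")
  structure(
    list(
      diet_id = as.character(diet_id),
      ingredients = ingredients,
      marker = marker,
      marker_level = marker_level,
      nitrogen_free = isTRUE(nitrogen_free)
    ),
    class = "diet_spec"
  )
}

#' @export
print.diet_spec <- function(x, ...) {
  cat(sprintf("<diet_spec> %s (%d ingredients, sum %.2f%%)\n",
              x$diet_id, length(x$ingredients), sum(x$ingredients)))
  invisible(x)
}

#' Equally spaced base/substitute starch inclusion gradient
#'
#' Splits a fixed total starch inclusion between two sources (e.g. waxy
#' maize starch stepped out for high-amylose maize starch) in `n_levels`
#' equal steps: substitute level \eqn{i} (0-indexed) is
#' `total * i / (n_levels - 1)` and the base makes up the remainder, so
#' every pair sums to `total` exactly. Arithmetic is done in integer
#' hundredths of a percent, matching two-decimal formulation sheets.
#'
#' @param total Total starch inclusion % shared by the pair (> 0).
#' @param n_levels Number of gradient levels (>= 2).
#' @return Tibble with columns `level` (1-based), `base_pct`,
#'   `substitute_pct`.
#' @examples
#' substitution_gradient(69.20, 5)
#' @export
substitution_gradient <- function(total, n_levels) {
  if (!is.numeric(n_levels) || n_levels < 2 || n_levels != round(n_levels)) {
    .stop("`n_levels` must be an integer >= 2")
  }
  if (!is.numeric(total) || total <= 0) .stop("`total` must be > 0")
  total_h <- round(total * 100)
  sub_h <- round(total_h * (seq_len(n_levels) - 1) / (n_levels - 1))
  tibble(
    level = seq_len(n_levels),
    base_pct = (total_h - sub_h) / 100,
    substitute_pct = sub_h / 100
  )
}

#' Complete a formulation to 100% with a filler ingredient
#'
#' @param fixed Named numeric vector of fixed inclusions (%); must sum to
#'   < 100.
#' @param filler_name Ingredient receiving the remainder.
#' @param diet_id Identifier for the resulting spec.
#' @param ... Passed to [diet_spec()] (e.g. `nitrogen_free = TRUE`).
#' @return A [diet_spec()] whose inclusions sum to 100 exactly (filler
#'   rounded to 2 decimal places).
#' @export
complete_formula <- function(fixed, filler_name, diet_id = "diet", ...) {
  if (length(fixed) > 0 &&
      (is.null(names(fixed)) || any(names(fixed) == ""))) {
    .stop("`fixed` must be a named vector")
  }
  if (any(fixed < 0)) .stop("inclusions must be >= 0")
  total_h <- sum(round(fixed * 100))
  if (total_h >= 10000) .stop("fixed inclusions already reach 100%")
  filler <- (10000 - total_h) / 100
  diet_spec(diet_id, c(fixed, setNames(filler, filler_name)), ...)
}

#' Validate a diet specification
#'
#' Checks non-negativity, sum-to-100 within `tol` percentage points, and
#' presence of the marker ingredient at its declared level.
#'
#' @param spec A [diet_spec()].
#' @param tol Allowed deviation of the inclusion sum from 100; default
#'   0.01 percentage points.
#' @return List with `pass` (logical) and `checks` (tibble of `check`,
#'   `pass`, `detail`).
#' @export
validate_diet <- function(spec, tol = 0.01) {
  stopifnot(inherits(spec, "diet_spec"))
  total <- sum(spec$ingredients)
  nonneg <- all(spec$ingredients >= 0)
  sum_ok <- abs(total - 100) <= tol
  has_marker <- spec$marker %in% names(spec$ingredients)
  marker_ok <- has_marker &&
    abs(spec$ingredients[[spec$marker]] - spec$marker_level) <= tol
  checks <- tibble(
    check = c("non_negative", "sum_to_100", "marker_present",
              "marker_level"),
    pass = c(nonneg, sum_ok, has_marker, marker_ok),
    detail = c(
      if (nonneg) "all inclusions >= 0" else "negative inclusion present",
      sprintf("inclusions sum to %.2f%%", total),
      if (has_marker) paste(spec$marker, "present") else "marker absent",
      if (marker_ok) {
        sprintf("%s at %.2f%%", spec$marker, spec$marker_level)
      } else if (has_marker) {
        sprintf("%s at %.2f%%, declared %.2f%%",
                spec$marker, spec$ingredients[[spec$marker]],
                spec$marker_level)
      } else "marker absent"
    )
  )
  list(pass = all(checks$pass), checks = checks)
}

#' The six study diet formulations
#'
#' Reconstructs the purified-diet panel: five diets sharing a fixed
#' protein/mineral base (casein, whey protein isolate, isolated soybean
#' protein, oil, cellulose acetate, minerals, 0.3% chromic oxide marker,
#' premix) with 69.20% total maize starch split between waxy (rapidly
#' digested) and high-amylose (slowly digested) sources in five equal
#' steps, plus a nitrogen-free diet whose protein is replaced by normal
#' maize starch filling the formula to 100%.
#'
#' @return Named list of six [diet_spec()] objects: `RGR_HGR`,
#'   `MRGR_MHGR`, `MGR_MGR`, `MSGR_MLGR`, `SGR_LGR`, `NF`.
#' @export
starch_gradient_diets <- function() {
  base_common <- c(
    "Soybean oil" = 3.00, "Cellulose acetate" = 4.00,
    "Limestone" = 0.50, "Dicalcium phosphate" = 2.50,
    "Cr2O3" = 0.30, "NaCl" = 0.45, "K2CO3" = 0.30, "MgO" = 0.10,
    "Vitamin trace-mineral premix" = 0.50
  )
  protein_mix <- c(
    "Isolated soybean protein" = 2.05, "Casein" = 14.38,
    "Whey protein isolate" = 2.72
  )
  ids <- c("RGR_HGR", "MRGR_MHGR", "MGR_MGR", "MSGR_MLGR", "SGR_LGR")
  grad <- substitution_gradient(69.20, 5)
  diets <- lapply(seq_along(ids), function(i) {
    diet_spec(ids[i], c(
      "Waxy maize starch" = grad$base_pct[i],
      "High amylose maize starch" = grad$substitute_pct[i],
      protein_mix, base_common
    ))
  })
  names(diets) <- ids
  diets$NF <- complete_formula(base_common, "Normal maize starch",
                               diet_id = "NF", nitrogen_free = TRUE)
  diets
}
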