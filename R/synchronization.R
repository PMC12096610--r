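#' Across-diet reference release rate
#'
#' The reference rate for a nutrient is the arithmetic mean of the per-diet
#' mean release rates across all diets in the panel; relative rates are
#' per-diet rates divided by it, so the mean relative rate over diets is
#' exactly 1.
#'
#' @param k Named numeric vector of per-diet mean release rates (one value
#'   per diet, common window and unit).
#' @return The reference rate (scalar mean).
#' @export
reference_rates <- function(k) {
  if (!is.numeric(k) || length(k) < 2) {
    .stop("need per-diet rates for at least 2 diets")
  }
  if (any(!is.finite(k))) .stop("rates must be finite")
  mean(k)
}

#' Synchronization context: per-diet and reference rates for one window
#'
#' Bundles the per-diet release rates of glucose (g/kg/min), soluble
#' nitrogen (g/kg/min) and total amino acids (mmol/kg/min) over one
#' interval (default the 0-20 min intestinal window, where all diets
#' release nutrients fastest) with the across-diet reference rates that
#' normalize them.
#'
#' @param k_glucose,k_nitrogen,k_aa Named numeric vectors of per-diet rates
#'   with identical diet names.
#' @param window Length-2 numeric interval in intestinal minutes;
#'   default `c(0, 20)`.
#' @return Object of class `sync_context`.
#' @export
sync_context <- function(k_glucose, k_nitrogen, k_aa, window = c(0, 20)) {
  diets <- names(k_glucose)
  if (is.null(diets) || length(diets) < 2) {
    .stop("rates must be named by diet, with at least 2 diets")
  }
  if (!identical(sort(diets), sort(names(k_nitrogen))) ||
      !identical(sort(diets), sort(names(k_aa)))) {
    .stop("the three rate vectors must cover the same diets")
  }
  k_nitrogen <- k_nitrogen[diets]
  k_aa <- k_aa[diets]
  if (any(k_glucose < 0)) {
    .stop("negative glucose release rate; widen the rate window ",
          "so fluctuation does not dominate")
  }
  for (nm in c("k_nitrogen", "k_aa")) {
    v <- get(nm)
    if (any(v < 0)) {
      .stop("negative ", nm, " rate; widen the rate window ",
            "so fluctuation does not dominate")
    }
    if (any(v == 0)) {
      .stop(nm, " is zero for some diet: the G/N and G/AA indices ",
            "are undefined")
    }
  }
  if (length(window) != 2 || window[1] >= window[2]) {
    .stop("`window` must be (t1, t2) with t1 < t2")
  }
  structure(
    list(
      diets = diets,
      k_glucose = k_glucose, k_nitrogen = k_nitrogen, k_aa = k_aa,
      k_glucose_r = reference_rates(k_glucose),
      k_nitrogen_r = reference_rates(k_nitrogen),
      k_aa_r = reference_rates(k_aa),
      window = as.numeric(window)
    ),
    class = "sync_context"
  )
}

#' The four carbon-nitrogen synchronization indices
#'
#' For each diet in a context, computes
#' \deqn{Relative\,G/N = (K_{Glucose}/K_{GlucoseR}) / (K_{Nitrogen}/K_{NitrogenR})}
#' \deqn{Relative\,G/AA = (K_{Glucose}/K_{GlucoseR}) / (K_{AA}/K_{AAR})}
#' \deqn{G/N = K_{Glucose}/K_{Nitrogen}, \quad G/AA = K_{Glucose}/K_{AA}}
#' where the reference rates \eqn{K_{\cdot R}} are the across-diet
#' averages. The relative indices compare a diet's carbon-to-nitrogen
#' release balance with the panel norm (1 = perfectly in step); the
#' absolute ratios carry units (G/N g/g, G/AA g/mmol).
#'
#' @param context A [sync_context()].
#' @return Tibble with columns `diet`, `rel_gn`, `rel_gaa`, `gn`, `gaa`,
#'   `window_t1`, `window_t2`.
#' @examples
#' ctx <- sync_context(
#'   k_glucose = c(d1 = 2, d2 = 1),
#'   k_nitrogen = c(d1 = 0.1, d2 = 0.2),
#'   k_aa = c(d1 = 3, d2 = 4)
#' )
#' sync_indices(ctx)
#' @export
sync_indices <- function(context) {
  stopifnot(inherits(context, "sync_context"))
  rel_g <- context$k_glucose / context$k_glucose_r
  rel_n <- context$k_nitrogen / context$k_nitrogen_r
  rel_a <- context$k_aa / context$k_aa_r
  out <- tibble(
    diet = context$diets,
    rel_gn = unname(rel_g / rel_n),
    rel_gaa = unname(rel_g / rel_a),
    gn = unname(context$k_glucose / context$k_nitrogen),
    gaa = unname(context$k_glucose / context$k_aa),
    window_t1 = context$window[1],
    window_t2 = context$window[2]
  )
  if (any(!is.finite(unlist(out[, c("rel_gn", "rel_gaa", "gn", "gaa")])))) {
    .stop("non-finite synchronization index computed")
  }
  out
}

#' Classify release synchrony from Relative G/AA
#'
#' Diets are labelled by how far the relative glucose-to-amino-acid release
#' balance sits from the panel norm of 1: `Syn` (synchronized) inside the
#' closed band `[lower, upper]`; `Asyn_C` above it (relatively excessive
#' glucose, insufficient nitrogen supply); `Asyn_N` below it (relatively
#' excessive nitrogen, insufficient glucose). Relative G/AA is the deciding
#' index because a diet can look balanced on soluble nitrogen while its
#' amino-acid release runs well ahead of its glucose release.
#'
#' @param rel_gaa Numeric vector of Relative G/AA values (e.g. per-diet
#'   means).
#' @param lower,upper Band limits, default 0.75 and 1.50.
#' @return Factor with levels `Syn`, `Asyn_C`, `Asyn_N` and attributes
#'   `lower`/`upper` recording the thresholds used.
#' @examples
#' classify_sync(c(1.28, 1.40, 1.63, 0.41, 0.71))
#' @export
classify_sync <- function(rel_gaa, lower = 0.75, upper = 1.50) {
  if (lower >= upper) .stop("`lower` must be < `upper`")
  if (any(!is.finite(rel_gaa))) .stop("indices must be finite")
  lab <- ifelse(rel_gaa > upper, "Asyn_C",
                ifelse(rel_gaa < lower, "Asyn_N", "Syn"))
  structure(factor(lab, levels = c("Syn", "Asyn_C", "Asyn_N")),
            lower = lower, upper = upper)
}

# Per-replicate 0-20 min (or custom window) rates for one nutrient of one
# diet, as a named-by-replicate numeric vector.
.window_rates <- function(curves, window, phase) {
  vapply(curves, function(cv) {
    suppressWarnings(interval_rate(cv, window[1], window[2], phase = phase))
  }, numeric(1))
}

#' Per-diet synchronization table with replicate SEM and Tukey letters
#'
#' Full pipeline from a panel of replicate release curves to the reported
#' synchronization table: per-replicate window rates for the three
#' nutrients, across-diet reference rates built from the per-diet mean
#' rates, per-replicate indices against that fixed context, then per-diet
#' mean and SEM with compact-letter-display groupings (ANOVA + Tukey) for
#' the Relative G/AA and G/AA columns, and a Syn/Asyn_C/Asyn_N class from
#' the per-diet mean Relative G/AA.
#'
#' @param curves Long-format tibble (or list of [release_curve()]) holding,
#'   for every diet, replicate curves of all three nutrients:
#'   glucose, soluble_nitrogen, total_amino_acids.
#' @param window Rate window in intestinal minutes, default `c(0, 20)`.
#' @param phase Digestion phase of the window, default `"intestinal"`.
#' @param lower,upper Classification band, see [classify_sync()].
#' @param letters Attach Tukey letter groupings (requires >= 2 replicates
#'   per diet); default `TRUE`.
#' @return Tibble with one row per diet: `diet`, `n`, mean and SEM of all
#'   four indices, `letters_rel_gaa`, `letters_gaa`, `class`.
#' @export
sync_table <- function(curves, window = c(0, 20), phase = "intestinal",
                       lower = 0.75, upper = 1.50, letters = TRUE) {
  if (is.data.frame(curves)) curves <- curves_from_df(curves)
  if (inherits(curves, "release_curve")) curves <- list(curves)
  meta <- tibble(
    idx = seq_along(curves),
    diet = vapply(curves, `[[`, character(1), "substrate_id"),
    nutrient = vapply(curves, `[[`, character(1), "nutrient"),
    replicate = vapply(curves, `[[`, integer(1), "replicate")
  )
  diets <- unique(meta$diet)
  if (length(diets) < 2) .stop("need curves for at least 2 diets")
  for (d in diets) {
    have <- unique(meta$nutrient[meta$diet == d])
    miss <- setdiff(names(.NUTRIENTS), have)
    if (length(miss) > 0) {
      .stop("diet '", d, "' is missing curves for: ",
            paste(miss, collapse = ", "))
    }
  }

  # per-replicate window rates, one row per diet x nutrient x replicate
  rates <- purrr::map_dfr(seq_len(nrow(meta)), function(i) {
    cv <- curves[[meta$idx[i]]]
    tibble(
      diet = meta$diet[i], nutrient = meta$nutrient[i],
      replicate = meta$replicate[i],
      k = suppressWarnings(
        interval_rate(cv, window[1], window[2], phase = phase))
    )
  })
  diet_means <- rates |>
    dplyr::group_by(.data$diet, .data$nutrient) |>
    dplyr::summarise(k = mean(.data$k), .groups = "drop")
  k_of <- function(nutr) {
    d <- diet_means[diet_means$nutrient == nutr, ]
    setNames(d$k, d$diet)[diets]
  }
  ctx <- sync_context(k_of("glucose"), k_of("soluble_nitrogen"),
                      k_of("total_amino_acids"), window = window)

  # per-replicate indices against the fixed diet-mean-based references
  wide <- tidyr::pivot_wider(rates, names_from = "nutrient",
                             values_from = "k")
  if (any(wide$soluble_nitrogen <= 0) || any(wide$total_amino_acids <= 0)) {
    .stop("non-positive replicate nitrogen/amino-acid rate in window; ",
          "widen the window so fluctuation does not dominate")
  }
  rep_idx <- wide |>
    dplyr::mutate(
      rel_gn = (.data$glucose / ctx$k_glucose_r) /
        (.data$soluble_nitrogen / ctx$k_nitrogen_r),
      rel_gaa = (.data$glucose / ctx$k_glucose_r) /
        (.data$total_amino_acids / ctx$k_aa_r),
      gn = .data$glucose / .data$soluble_nitrogen,
      gaa = .data$glucose / .data$total_amino_acids
    )

  summ <- rep_idx |>
    dplyr::group_by(.data$diet) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(c("rel_gn", "rel_gaa", "gn", "gaa"),
                    list(mean = mean, sem = ~ sd(.x) / sqrt(length(.x)))),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$diet, diets))
  if (any(summ$n < 2)) .stop("need >= 2 replicates per diet")

  if (letters) {
    lg <- group_compare(rep_idx$rel_gaa, rep_idx$diet,
                        method = "anova_tukey")
    la <- group_compare(rep_idx$gaa, rep_idx$diet, method = "anova_tukey")
    summ$letters_rel_gaa <- unname(lg$letters[summ$diet])
    summ$letters_gaa <- unname(la$letters[summ$diet])
  } else {
    summ$letters_rel_gaa <- ""
    summ$letters_gaa <- ""
  }
  summ$class <- as.character(
    classify_sync(summ$rel_gaa_mean, lower = lower, upper = upper))
  summ
}
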