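#' Read release curves from a long-format CSV
#'
#' Expected columns (strict header match, UTF-8, decimal point):
#' `substrate_id, nutrient, replicate, phase, time_min, cumulative, unit`.
#'
#' @param path Path to the CSV file.
#' @return A list of [release_curve()] objects, one per
#'   substrate x nutrient x replicate, named
#'   `"<substrate>.<nutrient>.<replicate>"`.
#' @export
read_release_curves <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  curves_from_df(df)
}

#' Convert a long-format table to release-curve objects
#'
#' @param df Data frame with columns `substrate_id` (or `diet_id`),
#'   `nutrient`, `replicate`, `phase`, `time_min`, `cumulative`, `unit`.
#' @return Named list of [release_curve()] objects.
#' @export
curves_from_df <- function(df) {
  df <- as_tibble(df)
  if ("diet_id" %in% names(df) && !("substrate_id" %in% names(df))) {
    df <- dplyr::rename(df, substrate_id = "diet_id")
  }
  need <- c("substrate_id", "nutrient", "replicate", "phase",
            "time_min", "cumulative", "unit")
  if (!all(need %in% names(df))) {
    .stop("missing required columns: ",
          paste(setdiff(need, names(df)), collapse = ", "))
  }
  df <- dplyr::arrange(df, .data$substrate_id, .data$nutrient,
                       .data$replicate,
                       match(.data$phase, .PHASES), .data$time_min)
  keys <- split(
    df,
    interaction(df$substrate_id, df$nutrient, df$replicate,
                drop = TRUE, lex.order = TRUE)
  )
  lapply(keys, function(d) {
    u <- unique(d$unit)
    if (length(u) != 1) {
      .stop("curve ", d$substrate_id[1], "/", d$nutrient[1],
            " mixes units: ", paste(u, collapse = ", "))
    }
    release_curve(d$substrate_id[1], d$nutrient[1], d$replicate[1],
                  d$phase, d$time_min, d$cumulative, u)
  })
}

#' Flatten release-curve objects back to a long-format tibble
#'
#' @param curves A [release_curve()] or list of them.
#' @return Tibble in the same long schema read by [read_release_curves()].
#' @export
curves_to_df <- function(curves) {
  if (inherits(curves, "release_curve")) curves <- list(curves)
  purrr::map_dfr(curves, function(cv) {
    tibble(
      substrate_id = cv$substrate_id,
      nutrient = cv$nutrient,
      replicate = cv$replicate,
      phase = cv$data$phase,
      time_min = cv$data$time_min,
      cumulative = cv$data$cumulative,
      unit = cv$unit
    )
  })
}

#' Write a rate series (or any result table) to CSV
#'
#' Deterministic column order and full-precision numbers, so re-reading the
#' file reproduces values exactly.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' Published reference synchronization indices for the five gradient diets
#'
#' Mean values of the four synchronization indices (Relative G/N, Relative
#' G/AA, G/N in g/g, G/AA in g/mmol) reported for the five
#' waxy/high-amylose starch-gradient diets over the 0-20 min intestinal
#' window, bundled for cross-index consistency checks and classifier
#' validation.
#'
#' @return Tibble with columns `diet`, `rel_gn`, `rel_gaa`, `gn`, `gaa`.
#' @export
sync_reference_values <- function() {
  path <- system.file("extdata", "diet_sync_reference.csv",
                      package = "cnsync", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
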