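#' Apparent total tract digestibility
#'
#' \deqn{ATTD = (FI - Feces)/FI \times 100}
#' with `FI` the amount of nutrient (nitrogen g/d or gross energy MJ/d)
#' ingested and `Feces` the amount voided. Fecal output exceeding intake
#' yields a negative ATTD and a warning (it is reported, not truncated).
#'
#' @param intake,fecal Non-negative amounts in matching units; `intake > 0`.
#' @return ATTD in percent. Vectorized.
#' @examples
#' attd(40, 14.4) # 64
#' @export
attd <- function(intake, fecal) {
  if (any(intake <= 0)) .stop("`intake` must be > 0")
  if (any(fecal < 0)) .stop("`fecal` must be >= 0")
  if (any(fecal > intake)) {
    .warn("fecal output exceeds intake; ATTD is negative")
  }
  100 * (intake - fecal) / intake
}

#' Apparent ileal digestibility with an indigestible chromium marker
#'
#' \deqn{AID = [1 - (AA_{digesta}/AA_{diet}) (Cr_{diet}/Cr_{digesta})] \times 100}
#' The chromium ratio converts digesta concentrations to a per-unit-intake
#' basis because the marker passes the ileum undigested. Applies equally to
#' single amino acids and to crude protein. A negative AID (possible for
#' low-concentration amino acids) is warned about, never clipped.
#'
#' @param aa_digesta,aa_diet Nutrient concentrations (g/kg DM) in ileal
#'   digesta and diet; `aa_diet > 0` (for the nitrogen-free diet use
#'   [basal_endogenous_loss()] instead).
#' @param cr_diet,cr_digesta Chromium concentrations (g/kg DM) in diet and
#'   digesta, both > 0.
#' @return AID in percent (\eqn{\le 100}). Vectorized.
#' @examples
#' aid(5, 10, 2, 4) # 75
#' @export
aid <- function(aa_digesta, aa_diet, cr_diet, cr_digesta) {
  if (any(aa_diet <= 0)) {
    .stop("`aa_diet` must be > 0; for nitrogen-free-diet digesta use ",
          "basal_endogenous_loss()")
  }
  if (any(cr_diet <= 0) || any(cr_digesta <= 0)) {
    .stop("chromium concentrations must be > 0")
  }
  if (any(aa_digesta < 0)) .stop("`aa_digesta` must be >= 0")
  out <- (1 - (aa_digesta / aa_diet) * (cr_diet / cr_digesta)) * 100
  if (any(out < 0)) {
    .warn("negative AID computed; reported as-is")
  }
  out
}

#' Basal ileal endogenous amino-acid loss from nitrogen-free-fed animals
#'
#' For each animal fed the nitrogen-free diet,
#' \deqn{IAA = AA_{digesta} \times (Cr_{diet}/Cr_{digesta})}
#' expresses the endogenous flow in g per kg dry-matter intake; the basal
#' loss applied in the SID correction is the across-animal average (mean by
#' default, configurable to median) per amino acid.
#'
#' @param digesta Tibble of nitrogen-free-diet digesta assays with columns
#'   `animal_id`, `analyte`, `value` (g/kg DM) and `cr_digesta` (g/kg DM);
#'   alternatively `analyte == "chromium"` rows instead of a `cr_digesta`
#'   column.
#' @param cr_diet Chromium concentration of the nitrogen-free diet
#'   (g/kg DM).
#' @param fun Pooling function across animals; default [mean()].
#' @return Tibble with columns `analyte`, `iaa` (g/kg DM intake), `n`.
#' @export
basal_endogenous_loss <- function(digesta, cr_diet, fun = mean) {
  digesta <- as_tibble(digesta)
  if (nrow(digesta) == 0) .stop("no nitrogen-free digesta assays supplied")
  if (!"cr_digesta" %in% names(digesta)) {
    cr <- digesta[digesta$analyte == "chromium", c("animal_id", "value")]
    if (nrow(cr) == 0) {
      .stop("supply `cr_digesta` or 'chromium' analyte rows")
    }
    names(cr)[2] <- "cr_digesta"
    digesta <- dplyr::left_join(
      digesta[digesta$analyte != "chromium", ], cr, by = "animal_id")
  }
  if (any(cr_diet <= 0) || any(digesta$cr_digesta <= 0)) {
    .stop("chromium concentrations must be > 0")
  }
  if (any(digesta$value < 0)) .stop("digesta concentrations must be >= 0")
  digesta |>
    dplyr::mutate(iaa = .data$value * cr_diet / .data$cr_digesta) |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(iaa = fun(.data$iaa), n = dplyr::n(), .groups = "drop")
}

#' Standardized ileal digestibility
#'
#' \deqn{SID = AID + (IAA/AA_{diet}) \times 100}
#' corrects the apparent digestibility for the basal endogenous loss
#' measured with the nitrogen-free diet, so SID >= AID always, with
#' equality only when the endogenous loss is zero.
#'
#' @param aid AID in percent.
#' @param iaa Basal endogenous loss, g per kg DM intake (>= 0).
#' @param aa_diet Dietary concentration, g/kg DM (> 0).
#' @return SID in percent. Vectorized.
#' @examples
#' sid(75, 0.5, 10) # 80
#' @export
sid <- function(aid, iaa, aa_diet) {
  if (any(aa_diet <= 0)) .stop("`aa_diet` must be > 0")
  if (any(iaa < 0)) .stop("`iaa` must be >= 0")
  aid + (iaa / aa_diet) * 100
}

#' Energy and nitrogen balance fractions
#'
#' Per-animal excretion fractions relative to intake:
#' FE/FIGE (fecal energy / gross-energy intake), UE/FIGE (urinary energy /
#' gross-energy intake), FN/FIN (fecal nitrogen / nitrogen intake), UN/FIN
#' (urinary nitrogen / nitrogen intake), all in percent. By construction
#' `FE/FIGE + ATTD(GE) = 100` exactly, and likewise for nitrogen.
#'
#' @param fi_ge,fe_ge,ue_ge Gross-energy intake, fecal and urinary output
#'   (MJ/d); `fi_ge > 0`.
#' @param fi_n,fe_n,un_n Nitrogen intake, fecal and urinary output (g/d);
#'   `fi_n > 0`.
#' @return Tibble with columns `fe_fige`, `ue_fige`, `fn_fin`, `un_fin`
#'   (percent). Vectorized over animals.
#' @export
balance_fractions <- function(fi_ge, fe_ge, ue_ge, fi_n, fe_n, un_n) {
  if (any(fi_ge <= 0) || any(fi_n <= 0)) .stop("intakes must be > 0")
  amounts <- c(fe_ge, ue_ge, fe_n, un_n)
  if (any(amounts < 0)) .stop("outputs must be >= 0")
  tibble(
    fe_fige = 100 * fe_ge / fi_ge,
    ue_fige = 100 * ue_ge / fi_ge,
    fn_fin = 100 * fe_n / fi_n,
    un_fin = 100 * un_n / fi_n
  )
}

#' Average daily gain and feed intake
#'
#' @param bw_start,bw_end Body weights (kg) at the start and end of the
#'   test period; `bw_end >= 0`.
#' @param days Days on test (> 0).
#' @param feed_total Total feed consumed over the period (kg).
#' @return Tibble with columns `adg` (kg/d) and `adfi` (kg/d). Vectorized.
#' @export
growth_performance <- function(bw_start, bw_end, days, feed_total) {
  if (any(days <= 0)) .stop("`days` must be > 0")
  if (any(bw_end < 0) || any(bw_start < 0)) {
    .stop("body weights must be >= 0")
  }
  if (any(feed_total < 0)) .stop("`feed_total` must be >= 0")
  tibble(adg = (bw_end - bw_start) / days, adfi = feed_total / days)
}

#' Per-animal balance and performance table
#'
#' Computes ATTD of gross energy and nitrogen, the four excretion
#' fractions, ADG and ADFI for every animal of a balance trial.
#'
#' @param balance Tibble with columns `animal_id`, `diet_id`, `fi_ge`,
#'   `fe_ge`, `ue_ge` (MJ/d), `fi_n`, `fe_n`, `un_n` (g/d), `bw_start`,
#'   `bw_end` (kg), `days`, `feed_total` (kg).
#' @return Tibble with one row per animal: ids plus `adg`, `adfi`,
#'   `attd_ge`, `fe_fige`, `ue_fige`, `attd_n`, `fn_fin`, `un_fin`.
#' @export
balance_table <- function(balance) {
  balance <- as_tibble(balance)
  need <- c("animal_id", "diet_id", "fi_ge", "fe_ge", "ue_ge",
            "fi_n", "fe_n", "un_n", "bw_start", "bw_end", "days",
            "feed_total")
  miss <- setdiff(need, names(balance))
  if (length(miss) > 0) {
    .stop("missing balance columns: ", paste(miss, collapse = ", "))
  }
  gp <- growth_performance(balance$bw_start, balance$bw_end,
                           balance$days, balance$feed_total)
  fr <- balance_fractions(balance$fi_ge, balance$fe_ge, balance$ue_ge,
                          balance$fi_n, balance$fe_n, balance$un_n)
  dplyr::bind_cols(
    balance[, c("animal_id", "diet_id")],
    gp,
    tibble(
      attd_ge = attd(balance$fi_ge, balance$fe_ge),
      attd_n = attd(balance$fi_n, balance$fe_n)
    ),
    fr
  )
}

#' Ileal digestibility pipeline: AID, basal losses and SID per animal
#'
#' Joins diet and digesta assays, computes per-animal AID for every
#' analyte of every test diet, derives the basal endogenous losses from
#' the nitrogen-free-fed animals, and applies the SID correction.
#'
#' @param diet_assay Tibble: `diet_id`, `analyte`, `value` (g/kg DM);
#'   must include a `"chromium"` row per diet.
#' @param digesta_assay Tibble: `animal_id`, `diet_id`, `analyte`, `value`
#'   (g/kg DM); must include a `"chromium"` row per animal.
#' @param nf_diet Identifier of the nitrogen-free diet within the tables;
#'   default `"NF"`.
#' @param endogenous_fun Pooling function for the basal loss across
#'   nitrogen-free-fed animals; default [mean()].
#' @return List with elements `per_animal` (tibble: `animal_id`, `diet_id`,
#'   `analyte`, `aid`, `sid`) and `endogenous` (output of
#'   [basal_endogenous_loss()]).
#' @export
aid_sid_table <- function(diet_assay, digesta_assay, nf_diet = "NF",
                          endogenous_fun = mean) {
  diet_assay <- as_tibble(diet_assay)
  digesta_assay <- as_tibble(digesta_assay)

  cr_diet <- diet_assay[diet_assay$analyte == "chromium", ]
  if (nrow(cr_diet) == 0) .stop("diet assay lacks 'chromium' rows")
  cr_diet <- setNames(cr_diet$value, cr_diet$diet_id)
  cr_dig <- digesta_assay[digesta_assay$analyte == "chromium",
                          c("animal_id", "value")]
  names(cr_dig)[2] <- "cr_digesta"

  if (!nf_diet %in% digesta_assay$diet_id) {
    .stop("no digesta assays for nitrogen-free diet '", nf_diet, "'")
  }
  nf <- digesta_assay[digesta_assay$diet_id == nf_diet &
                        digesta_assay$analyte != "chromium", ] |>
    dplyr::left_join(cr_dig, by = "animal_id")
  endog <- basal_endogenous_loss(nf, cr_diet[[nf_diet]],
                                 fun = endogenous_fun)

  test <- digesta_assay[digesta_assay$diet_id != nf_diet &
                          digesta_assay$analyte != "chromium", ] |>
    dplyr::left_join(cr_dig, by = "animal_id") |>
    dplyr::left_join(
      dplyr::rename(diet_assay[diet_assay$analyte != "chromium", ],
                    aa_diet = "value"),
      by = c("diet_id", "analyte")
    ) |>
    dplyr::left_join(endog[, c("analyte", "iaa")], by = "analyte")
  if (any(is.na(test$aa_diet))) {
    .stop("digesta analytes missing from the diet assay: ",
          paste(unique(test$analyte[is.na(test$aa_diet)]), collapse = ", "))
  }
  test$iaa[is.na(test$iaa)] <- 0
  per_animal <- test |>
    dplyr::mutate(
      aid = aid(.data$value, .data$aa_diet,
                cr_diet[.data$diet_id], .data$cr_digesta),
      sid = sid(.data$aid, .data$iaa, .data$aa_diet)
    ) |>
    dplyr::select("animal_id", "diet_id", "analyte", "aid", "sid")
  list(per_animal = per_animal, endogenous = endog)
}
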