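# Deterministic sub-stream seed from one global seed plus a stream key.
# Keeps every derived seed inside 32-bit integer range.
.substream_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483646L + 1L)
}

# Noiseless first-order saturating release curve.
.first_order <- function(t, A, k, lag = 0) {
  A * (1 - exp(-k * pmax(0, t - lag)))
}

#' First-order release kinetic parameters
#'
#' Parameters of the simulator's saturating release model
#' \deqn{D(t) = A (1 - e^{-k \max(0, t - lag)})}
#' for one substrate x nutrient x phase: `A` is the asymptotic cumulative
#' release (curve units), `k` the first-order rate constant (/min), `lag`
#' a delay before release starts (min), and `sigma` the additive Gaussian
#' replicate noise SD (curve units, applied per sampled point and clipped
#' at zero).
#'
#' @param A,k,lag,sigma Non-negative numerics as described above.
#' @return A `kinetic_params` list.
#' @export
kinetic_params <- function(A, k, lag = 0, sigma = 0) {
  vals <- c(A = A, k = k, lag = lag, sigma = sigma)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    .stop("kinetic parameters must be finite and >= 0")
  }
  structure(list(A = A, k = k, lag = lag, sigma = sigma),
            class = "kinetic_params")
}

#' Simulate replicate release curves for one substrate and nutrient
#'
#' Generates noiseless first-order cumulative release per phase, then adds
#' independent Gaussian noise per sampled point (clipped at zero), so
#' noisy replicates can show the occasional adjacent-time decreases seen
#' in wet assays. The same seed always reproduces the same curves.
#'
#' @param substrate_id,nutrient,unit Passed through to [release_curve()].
#' @param params A [kinetic_params()] (intestinal phase only) or a named
#'   list with elements `intestinal` and optionally `gastric`, each a
#'   [kinetic_params()].
#' @param schedule Named list of sampling times per phase, e.g.
#'   `list(intestinal = c(0, 20, 60, 90, 120, 240, 360, 480))`. Must cover
#'   every phase in `params`.
#' @param n_rep Number of replicate curves; default 3.
#' @param seed Integer seed; default 1.
#' @return List of `n_rep` [release_curve()] objects.
#' @examples
#' rc <- simulate_release_curve("d1", "glucose",
#'   kinetic_params(A = 150, k = 0.02), n_rep = 1)[[1]]
#' interval_rate(rc, 0, 20) # 150 * (1 - exp(-0.4)) / 20
#' @export
simulate_release_curve <- function(substrate_id, nutrient, params,
                                   schedule = list(
                                     intestinal = .SCHEDULE_INTESTINAL),
                                   n_rep = 3, seed = 1,
                                   unit = .NUTRIENTS[[nutrient]]) {
  if (inherits(params, "kinetic_params")) {
    params <- list(intestinal = params)
  }
  if (!all(names(params) %in% .PHASES) || length(params) == 0) {
    .stop("`params` must be kinetic_params per phase")
  }
  if (any(lengths(schedule[names(params)]) == 0) ||
      !all(names(params) %in% names(schedule))) {
    .stop("`schedule` must supply sampling times for every phase")
  }
  set.seed(.substream_seed(seed, paste0(substrate_id, nutrient)))
  phases <- intersect(.PHASES, names(params))
  lapply(seq_len(n_rep), function(r) {
    phase <- numeric(0); tt <- numeric(0); dd <- numeric(0)
    ph_v <- character(0)
    for (ph in phases) {
      p <- params[[ph]]
      t_ph <- sort(schedule[[ph]])
      d <- .first_order(t_ph, p$A, p$k, p$lag)
      if (p$sigma > 0) {
        d <- pmax(0, d + rnorm(length(d), 0, p$sigma))
      }
      ph_v <- c(ph_v, rep(ph, length(t_ph)))
      tt <- c(tt, t_ph); dd <- c(dd, d)
    }
    release_curve(substrate_id, nutrient, r, ph_v, tt, dd, unit)
  })
}

# Default diet-panel kinetic settings: the waxy endpoint digests fast and
# nearly fully, the high-amylose endpoint slowly and partially; the shared
# protein mix gives all diets the same nominal nitrogen/amino-acid release.
.PANEL_DEFAULTS <- list(
  glucose = list(fast = list(A = 520, k = 0.030),
                 slow = list(A = 240, k = 0.008)),
  nitrogen = list(intestinal = list(A = 14, k = 0.15),
                  gastric = list(A = 5, k = 0.02)),
  aa = list(intestinal = list(A = 900, k = 0.030),
            gastric = list(A = 150, k = 0.015))
)

#' Simulate a 5-diet release panel along the waxy starch gradient
#'
#' Emulates the in vitro panel: five diets whose glucose release
#' parameters interpolate linearly (by waxy starch fraction) between a
#' fast/high endpoint and a slow/low endpoint, with soluble nitrogen and
#' total amino acids released per shared protein-mix kinetics (or per-diet
#' overrides for designed synchrony patterns). Glucose appears only in the
#' intestinal phase (no amyloglucosidase earlier); nitrogen and amino
#' acids release in both phases. Output feeds [sync_table()] directly.
#'
#' @param waxy_fractions Waxy starch proportions in `[0, 1]`, one per
#'   diet; default `c(1, 0.75, 0.5, 0.25, 0)`.
#' @param diet_ids Diet names; default the five gradient diet codes.
#' @param glucose List with `fast` and `slow` endpoint lists `(A, k)`
#'   (g/kg, /min).
#' @param nitrogen,aa Shared kinetics per phase for soluble nitrogen
#'   (g/kg) and total amino acids (mmol/kg).
#' @param glucose_A,aa_A Optional per-diet overrides of the intestinal
#'   asymptote `A` (used by [design_panel_params()] to hit prescribed
#'   Relative G/AA targets); when given, the corresponding rate constant
#'   is shared across diets.
#' @param sigma_frac Replicate noise SD as a fraction of each curve's `A`;
#'   default 0.05.
#' @param n_rep Replicates per diet x nutrient; default 3.
#' @param seed Integer seed; default 1.
#' @return Long-format tibble of all simulated curves (see
#'   [curves_to_df()]).
#' @export
simulate_diet_panel <- function(waxy_fractions = c(1, 0.75, 0.5, 0.25, 0),
                                diet_ids = c("RGR_HGR", "MRGR_MHGR",
                                             "MGR_MGR", "MSGR_MLGR",
                                             "SGR_LGR"),
                                glucose = .PANEL_DEFAULTS$glucose,
                                nitrogen = .PANEL_DEFAULTS$nitrogen,
                                aa = .PANEL_DEFAULTS$aa,
                                glucose_A = NULL, aa_A = NULL,
                                sigma_frac = 0.05, n_rep = 3, seed = 1) {
  n_diet <- length(diet_ids)
  if (length(waxy_fractions) != n_diet ||
      any(waxy_fractions < 0 | waxy_fractions > 1)) {
    .stop("`waxy_fractions` must lie in [0, 1], one per diet")
  }
  if (is.null(glucose_A) &&
      (glucose$fast$A < glucose$slow$A)) {
    .warn("fast glucose endpoint has smaller asymptote than slow endpoint")
  }
  g_A <- glucose_A %||%
    (glucose$slow$A + waxy_fractions * (glucose$fast$A - glucose$slow$A))
  g_k <- if (is.null(glucose_A)) {
    glucose$slow$k + waxy_fractions * (glucose$fast$k - glucose$slow$k)
  } else {
    rep(glucose$fast$k, n_diet)
  }
  a_int_A <- aa_A %||% rep(aa$intestinal$A, n_diet)
  a_int_k <- aa$intestinal$k

  sched_gn <- list(gastric = .SCHEDULE_GASTRIC,
                   intestinal = .SCHEDULE_INTESTINAL)
  out <- purrr::map_dfr(seq_len(n_diet), function(i) {
    id <- diet_ids[i]
    gl <- simulate_release_curve(
      id, "glucose",
      kinetic_params(g_A[i], g_k[i], sigma = sigma_frac * g_A[i]),
      n_rep = n_rep, seed = .substream_seed(seed, paste0(id, "g")))
    ni <- simulate_release_curve(
      id, "soluble_nitrogen",
      list(
        gastric = kinetic_params(nitrogen$gastric$A, nitrogen$gastric$k,
                                 sigma = sigma_frac * nitrogen$gastric$A),
        intestinal = kinetic_params(
          nitrogen$intestinal$A, nitrogen$intestinal$k,
          sigma = sigma_frac * nitrogen$intestinal$A)
      ),
      schedule = sched_gn, n_rep = n_rep,
      seed = .substream_seed(seed, paste0(id, "n")))
    am <- simulate_release_curve(
      id, "total_amino_acids",
      list(
        gastric = kinetic_params(aa$gastric$A, aa$gastric$k,
                                 sigma = sigma_frac * aa$gastric$A),
        intestinal = kinetic_params(a_int_A[i], a_int_k,
                                    sigma = sigma_frac * a_int_A[i])
      ),
      schedule = sched_gn, n_rep = n_rep,
      seed = .substream_seed(seed, paste0(id, "a")))
    curves_to_df(c(gl, ni, am))
  })
  out
}

#' Per-diet amplitudes hitting prescribed Relative G/AA targets
#'
#' With a shared rate constant, the 0-20 min rate of the first-order model
#' scales with the asymptote `A`, so Relative G/AA of diet \eqn{d} equals
#' \eqn{(g_d/\bar g)/(a_d/\bar a)} for glucose and amino-acid amplitude
#' multipliers \eqn{g, a}. Given targets \eqn{r}, the solver sets
#' \eqn{a = 1 + \alpha (r - \bar r)} with
#' \eqn{\alpha = (1 - \bar r)/\mathrm{var}_{pop}(r)} and \eqn{g = r a},
#' which makes \eqn{\bar g = \bar a} and hence the noiseless panel
#' Relative G/AA exactly equal to the targets.
#'
#' @param rel_gaa_targets Numeric vector of desired per-diet Relative G/AA
#'   values (need not average 1).
#' @param glucose_A_mean,aa_A_mean Panel-mean amplitudes (g/kg, mmol/kg).
#' @return List with `glucose_A` and `aa_A` per-diet vectors, ready for
#'   [simulate_diet_panel()].
#' @export
design_panel_params <- function(rel_gaa_targets, glucose_A_mean = 400,
                                aa_A_mean = 900) {
  r <- rel_gaa_targets
  if (length(r) < 2 || any(r <= 0)) .stop("targets must be positive, >= 2")
  rbar <- mean(r)
  vr <- mean((r - rbar)^2)
  alpha <- if (vr == 0) 0 else (1 - rbar) / vr
  a <- 1 + alpha * (r - rbar)
  if (vr == 0 && abs(rbar - 1) > 1e-12) {
    .stop("equal targets must equal 1 (relative indices average to 1)")
  }
  if (any(a <= 0)) {
    .stop("target spread too extreme for positive amplitudes")
  }
  g <- r * a
  list(glucose_A = g / mean(g) * glucose_A_mean,
       aa_A = a / mean(a) * aa_A_mean)
}

# Archetype parameter regions for ingredient glucose release (g/100 g):
# release level sets A, release rate sets k, duration scales k (transient
# release finishes early, persistent release continues over the run).
.ARCHETYPE_A <- c(high = 80, low = 20)
.ARCHETYPE_K <- c(rapid = 0.040, slow = 0.008)
.ARCHETYPE_DUR <- c(persistent = 1, transient = 3)

#' Simulate ingredient glucose-release archetypes
#'
#' Feed ingredients differ in glucose release rate (rapid/slow), amount
#' (high/low) and duration (persistent/transient); each combination maps
#' to a distinct first-order parameter region, with 3 replicate curves per
#' archetype in g/100 g units on the intestinal sampling schedule.
#'
#' @param archetypes Data frame (or list of length-3 character vectors)
#'   with columns/elements `rate`, `level`, `duration`.
#' @param sigma_frac Noise SD as a fraction of `A`; default 0 (noiseless).
#' @param n_rep Replicates per archetype; default 3.
#' @param seed Integer seed; default 1.
#' @return List of [release_curve()] objects
#'   (`length(archetypes) * n_rep`).
#' @export
simulate_ingredient_panel <- function(archetypes, sigma_frac = 0,
                                      n_rep = 3, seed = 1) {
  if (is.data.frame(archetypes)) {
    archetypes <- purrr::pmap(
      archetypes[, c("rate", "level", "duration")], c)
  }
  if (length(archetypes) < 1) .stop("need at least one archetype")
  curves <- purrr::map(seq_along(archetypes), function(i) {
    a <- archetypes[[i]]
    rate <- a[[1]]; level <- a[[2]]; duration <- a[[3]]
    if (!rate %in% names(.ARCHETYPE_K)) {
      .stop("unknown rate token '", rate, "'")
    }
    if (!level %in% names(.ARCHETYPE_A)) {
      .stop("unknown level token '", level, "'")
    }
    if (!duration %in% names(.ARCHETYPE_DUR)) {
      .stop("unknown duration token '", duration, "'")
    }
    A <- .ARCHETYPE_A[[level]]
    k <- .ARCHETYPE_K[[rate]] * .ARCHETYPE_DUR[[duration]]
    id <- paste(rate, level, duration, i, sep = "_")
    simulate_release_curve(
      id, "glucose", kinetic_params(A, k, sigma = sigma_frac * A),
      n_rep = n_rep, seed = .substream_seed(seed, id), unit = "g/100g")
  })
  unlist(curves, recursive = FALSE)
}
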