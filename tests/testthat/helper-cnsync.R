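# Shared builders for small in-memory fixtures.

glucose_curve <- function(cumulative, time_min = c(0, 20, 60),
                          substrate = "d1", rep = 1, unit = "g/kg",
                          phase = "intestinal") {
  release_curve(substrate, "glucose", rep, phase, time_min, cumulative,
                unit)
}

# A deterministic 2-diet panel whose diet-mean window rates reproduce the
# hand-computed two-diet example: K_G = (2, 1), K_N = (0.1, 0.2),
# K_AA = (4, 2); constant rates over 0-20 min so replicate curves are flat
# lines through the origin.
two_diet_panel <- function(n_rep = 2) {
  k <- list(
    d1 = c(glucose = 2, soluble_nitrogen = 0.1, total_amino_acids = 4),
    d2 = c(glucose = 1, soluble_nitrogen = 0.2, total_amino_acids = 2)
  )
  curves <- list()
  for (d in names(k)) {
    for (nutr in names(k[[d]])) {
      unit <- cnsync:::.NUTRIENTS[[nutr]]
      for (r in seq_len(n_rep)) {
        curves[[length(curves) + 1]] <- release_curve(
          d, nutr, r, "intestinal", c(0, 20), c(0, 20 * k[[d]][[nutr]]),
          unit)
      }
    }
  }
  curves
}
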