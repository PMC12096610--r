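#' Mean and standard error of the mean
#'
#' @param values Numeric vector, n >= 2.
#' @return Named numeric vector `c(mean, sem)` with
#'   `sem = sd(values)/sqrt(n)` (n-1 denominator sd).
#' @examples
#' mean_sem(c(9, 10, 11))
#' @export
mean_sem <- function(values) {
  if (length(values) < 2) .stop("need n >= 2 for a SEM")
  if (any(!is.finite(values))) .stop("values must be finite")
  c(mean = mean(values), sem = sd(values) / sqrt(length(values)))
}

# Compact letter display by insert-and-absorb over a pairwise p matrix.
# `groups` are ordered (highest mean first gets 'a'); `pmat` is a symmetric
# matrix of pairwise p-values with dimnames = groups.
.cld_letters <- function(groups, pmat, alpha = 0.05) {
  cols <- list(groups) # each column: set of groups sharing one letter
  pairs <- which(upper.tri(pmat), arr.ind = TRUE)
  for (i in seq_len(nrow(pairs))) {
    g1 <- rownames(pmat)[pairs[i, 1]]
    g2 <- colnames(pmat)[pairs[i, 2]]
    p <- pmat[pairs[i, 1], pairs[i, 2]]
    if (is.na(p) || p >= alpha) next
    for (ci in seq_along(cols)) {
      if (all(c(g1, g2) %in% cols[[ci]])) {
        cols[[length(cols) + 1]] <- setdiff(cols[[ci]], g1)
        cols[[ci]] <- setdiff(cols[[ci]], g2)
      }
    }
    # absorb columns that are subsets of another column
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) {
      for (b in seq_along(cols)) {
        if (a != b && keep[a] && keep[b] &&
            all(cols[[a]] %in% cols[[b]])) {
          keep[a] <- FALSE
        }
      }
    }
    cols <- cols[keep]
  }
  # order columns by the best-ranked group they contain, letter them
  first <- vapply(cols, function(cl) min(match(cl, groups)), numeric(1))
  cols <- cols[order(first)]
  out <- setNames(rep("", length(groups)), groups)
  for (ci in seq_along(cols)) {
    for (g in cols[[ci]]) out[g] <- paste0(out[g], letters[ci])
  }
  out
}

# Pairwise p-value matrix for the chosen method, dimnames in `lv` order.
.pairwise_p <- function(values, groups, lv, method) {
  k <- length(lv)
  pmat <- matrix(NA_real_, k, k, dimnames = list(lv, lv))
  if (method == "anova_tukey") {
    fit <- aov(values ~ g, data = data.frame(values = values,
                                             g = factor(groups, levels = lv)))
    tk <- TukeyHSD(fit)$g
    for (r in rownames(tk)) {
      gg <- strsplit(r, "-", fixed = TRUE)[[1]]
      pmat[gg[1], gg[2]] <- pmat[gg[2], gg[1]] <- tk[r, "p adj"]
    }
  } else if (method == "kw_wilcoxon") {
    pw <- suppressWarnings(
      pairwise.wilcox.test(values, factor(groups, levels = lv),
                           p.adjust.method = "none", exact = FALSE))$p.value
    for (r in rownames(pw)) {
      for (cc in colnames(pw)) {
        if (!is.na(pw[r, cc])) pmat[r, cc] <- pmat[cc, r] <- pw[r, cc]
      }
    }
  } else { # ttest
    for (a in seq_len(k - 1)) {
      for (b in seq(a + 1, k)) {
        p <- t.test(values[groups == lv[a]],
                    values[groups == lv[b]])$p.value
        pmat[a, b] <- pmat[b, a] <- p
      }
    }
  }
  pmat
}

#' Group comparison with compact letter display
#'
#' Runs the study's routine comparisons -- one-way ANOVA with Tukey's
#' post-hoc test, the two-group t-test, or Kruskal-Wallis with pairwise
#' Wilcoxon rank-sum tests -- and assigns superscript-style letters so
#' that groups sharing a letter do not differ at `alpha`. The group with
#' the highest mean gets letter "a". An optional second tier (letters
#' x/y at `trend_alpha`, conventionally 0.10) marks trends.
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length as `values`.
#' @param method One of `"anova_tukey"`, `"ttest"`, `"kw_wilcoxon"`.
#' @param alpha Significance level for the letter display; default 0.05.
#' @param trend_alpha Optional second-tier level (e.g. 0.10); default
#'   `NULL` (off).
#' @return List with `method`, `p_omnibus`, `pairwise` (tibble `g1`, `g2`,
#'   `p`), `letters` (named by group) and, when requested,
#'   `letters_trend` (x/y tier).
#' @export
group_compare <- function(values, groups,
                          method = c("anova_tukey", "ttest",
                                     "kw_wilcoxon"),
                          alpha = 0.05, trend_alpha = NULL) {
  method <- match.arg(method)
  groups <- as.character(groups)
  if (length(values) != length(groups)) {
    .stop("`values` and `groups` lengths differ")
  }
  lv0 <- unique(groups)
  if (length(lv0) < 2) .stop("need at least 2 groups")
  if (any(table(groups) < 2)) .stop("each group needs n >= 2")
  if (method == "ttest" && length(lv0) != 2) {
    .stop("`ttest` requires exactly 2 groups")
  }
  means <- tapply(values, groups, mean)
  lv <- names(sort(means, decreasing = TRUE)) # 'a' = highest mean

  p_omnibus <- switch(
    method,
    anova_tukey = {
      fit <- aov(values ~ g,
                 data = data.frame(values = values, g = factor(groups)))
      summary(fit)[[1]][["Pr(>F)"]][1]
    },
    ttest = t.test(values[groups == lv[1]],
                   values[groups == lv[2]])$p.value,
    kw_wilcoxon = kruskal.test(values, factor(groups))$p.value
  )

  pmat <- .pairwise_p(values, groups, lv, method)
  pairs <- which(upper.tri(pmat), arr.ind = TRUE)
  pairwise <- tibble(
    g1 = rownames(pmat)[pairs[, 1]],
    g2 = colnames(pmat)[pairs[, 2]],
    p = pmat[pairs]
  )
  out <- list(
    method = method,
    p_omnibus = unname(p_omnibus),
    pairwise = pairwise,
    letters = .cld_letters(lv, pmat, alpha)[lv0]
  )
  if (!is.null(trend_alpha)) {
    trend <- .cld_letters(lv, pmat, trend_alpha)
    idx <- match(trend, letters)
    out$letters_trend <-
      setNames(vapply(trend, function(s) {
        paste(c("x", "y", "z", "w")[match(strsplit(s, "")[[1]], letters)],
              collapse = "")
      }, character(1)), names(trend))[lv0]
  }
  out
}

#' Pearson correlation between two release-rate series
#'
#' @param rates_a,rates_b Numeric vectors of equal length >= 3 with
#'   non-zero variance.
#' @return List with `r` (Pearson coefficient in `[-1, 1]`), `p`
#'   (two-sided) and `n`.
#' @export
rate_correlation <- function(rates_a, rates_b) {
  if (length(rates_a) != length(rates_b) || length(rates_a) < 3) {
    .stop("need equal-length series of at least 3 rates")
  }
  if (sd(rates_a) == 0 || sd(rates_b) == 0) {
    .stop("zero variance in a rate series; correlation undefined")
  }
  ct <- cor.test(rates_a, rates_b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(rates_a))
}

#' Render result tables to CSV reports
#'
#' Writes each table with a deterministic column order and, for every
#' `<x>_mean`/`<x>_sem` column pair, an added display column
#' `<x>_fmt` ("mean ± SEM" at 3 significant figures). Numeric columns
#' keep full precision so a round-trip read reproduces the values.
#'
#' @param tables Named list of data frames.
#' @param dir Output directory (created if needed).
#' @return Named character vector of files written, invisibly.
#' @export
render_tables <- function(tables, dir) {
  if (is.null(names(tables)) || any(names(tables) == "")) {
    .stop("`tables` must be a named list")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    tab <- as_tibble(tables[[nm]])
    if (nrow(tab) == 0) .stop("table '", nm, "' is empty")
    mean_cols <- grep("_mean$", names(tab), value = TRUE)
    for (mc in mean_cols) {
      sc <- sub("_mean$", "_sem", mc)
      if (sc %in% names(tab)) {
        tab[[sub("_mean$", "_fmt", mc)]] <- paste0(
          signif(tab[[mc]], 3), " ± ", signif(tab[[sc]], 3))
      }
    }
    tab <- tab[, order(names(tab) %in% grep("_fmt$", names(tab),
                                            value = TRUE))]
    path <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tab, path)
    path
  }, character(1))
  invisible(paths)
}
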