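#' Per-group alt-allele frequencies
#'
#' @param gm A [genotype_matrix()].
#' @param groups Group labels, in order (e.g. `c("P1","P2","P3","O")`).
#' @return Matrix sites x groups; NA where a group is fully missing.
#' @export
group_freqs <- function(gm, groups = sort(unique(gm$groups))) {
  out <- vapply(groups, function(g) {
    ct <- site_counts(gm, group_samples(gm, g))
    ifelse(ct$n_called > 0, ct$n_alt / ct$n_called, NA_real_)
  }, numeric(length(gm$pos)))
  colnames(out) <- groups
  out
}

#' Patterson's D (ABBA-BABA) from population allele frequencies
#'
#' Site patterns are frequency-based: with alt frequencies p1..p4 on the
#' tree (((P1,P2),P3),O), `ABBA_i = (1-p1) p2 p3 (1-p4)` and
#' `BABA_i = p1 (1-p2) p3 (1-p4)`; `D = (sum ABBA - sum BABA) /
#' (sum ABBA + sum BABA)`. Sites where any group is fully missing are
#' skipped. The Z score comes from an m-block delete-one jackknife over
#' blocks of equal site counts.
#'
#' @param freqs Matrix sites x 4 (P1, P2, P3, outgroup), e.g. from
#'   [group_freqs()].
#' @param n_blocks Jackknife block count (reduced if there are fewer
#'   sites).
#' @return Object of class `dstat_result`: `abba`, `baba`, `d`, `se`,
#'   `z`, `n_sites`, `n_blocks`.
#' @export
patterson_d <- function(freqs, n_blocks = 100) {
  stopifnot(ncol(freqs) == 4)
  ok <- complete.cases(freqs)
  f <- freqs[ok, , drop = FALSE]
  abba <- (1 - f[, 1]) * f[, 2] * f[, 3] * (1 - f[, 4])
  baba <- f[, 1] * (1 - f[, 2]) * f[, 3] * (1 - f[, 4])
  tot_a <- sum(abba); tot_b <- sum(baba)
  n <- nrow(f)
  d <- if (tot_a + tot_b > 0) (tot_a - tot_b) / (tot_a + tot_b)
  else NA_real_
  se <- z <- NA_real_
  m <- min(n_blocks, n)
  if (!is.na(d) && m >= 2) {
    block <- ceiling(seq_len(n) / ceiling(n / m))
    a_b <- tapply(abba, block, sum)
    b_b <- tapply(baba, block, sum)
    d_j <- (tot_a - a_b - (tot_b - b_b)) / (tot_a - a_b + tot_b - b_b)
    d_j <- d_j[is.finite(d_j)]
    m_eff <- length(d_j)
    if (m_eff >= 2) {
      se <- sqrt((m_eff - 1) / m_eff * sum((d_j - mean(d_j))^2))
      z <- if (se > 0) d / se else NA_real_
    }
  }
  structure(list(abba = tot_a, baba = tot_b, d = d, se = se, z = z,
                 n_sites = n, n_blocks = m), class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf(
    "Patterson's D = %.4f (ABBA %.1f, BABA %.1f, %d sites), Z = %.2f\n",
    x$d, x$abba, x$baba, x$n_sites, x$z))
  invisible(x)
}

#' Per-window Patterson's D
#'
#' @param gm A [genotype_matrix()] whose groups are the four taxa.
#' @param windows Window table.
#' @param taxa Group labels in tree order (P1, P2, P3, outgroup).
#' @return Numeric vector of window D values aligned with `windows`
#'   rows (NA where ABBA + BABA = 0 or no sites).
#' @export
window_d <- function(gm, windows, taxa) {
  stopifnot(length(taxa) == 4)
  freqs <- group_freqs(gm, taxa)
  widx <- site_window_index(gm, windows)
  ok <- complete.cases(freqs) & !is.na(widx)
  abba <- (1 - freqs[, 1]) * freqs[, 2] * freqs[, 3] * (1 - freqs[, 4])
  baba <- freqs[, 1] * (1 - freqs[, 2]) * freqs[, 3] * (1 - freqs[, 4])
  a <- tab_by_window(ifelse(ok, abba, 0), ifelse(ok, widx, NA), windows$window_id, sum)
  b <- tab_by_window(ifelse(ok, baba, 0), ifelse(ok, widx, NA), windows$window_id, sum)
  ifelse(a + b > 0, (a - b) / (a + b), NA_real_)
}

#' N-interact versus non-N-interact windowed D comparison
#'
#' Upper-tail permutation test of the difference in mean window D
#' between N-interact and non-N-interact windows (nongenic windows and
#' windows with undefined D are dropped; the dropped count is
#' reported).
#'
#' @param d_values Window D values from [window_d()].
#' @param classes Window class labels aligned with `d_values`.
#' @param B Permutations.
#' @param seed Integer seed.
#' @return A `resampling_result` with an extra `n_dropped` field.
#' @export
windowed_d_comparison <- function(d_values, classes, B = 1000, seed = 1) {
  genic <- classes %in% c("N_INTERACT", "NON_N_INTERACT")
  keep <- genic & !is.na(d_values)
  n_dropped <- sum(genic) - sum(keep)
  if (sum(keep & classes == "N_INTERACT") < 5 ||
      sum(keep & classes == "NON_N_INTERACT") < 5)
    stop("need >= 5 windows with defined D in each class")
  res <- permutation_test(d_values[keep], classes[keep], "upper",
                          B = B, seed = seed)
  res$n_dropped <- n_dropped
  res
}
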