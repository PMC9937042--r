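#' Per-site nucleotide diversity
#'
#' The average proportion of differences between all pairs of sequences
#' at one site: `2 * n_ref * n_alt / (n * (n - 1))` with `n` the number
#' of called alleles. Undefined (NA) when fewer than two alleles are
#' called. Vectorised.
#'
#' @param n_alt Alt allele count(s).
#' @param n_called Called allele count(s) (2 per called diploid).
#' @return Numeric vector in [0, 1].
#' @examples
#' site_pi(2, 4)    # 2 ref + 2 alt -> 4 of 6 pairs differ = 0.667
#' site_pi(1, 10)   # singleton among 10 alleles = 0.2
#' @export
site_pi <- function(n_alt, n_called) {
  out <- 2 * (n_called - n_alt) * n_alt / (n_called * (n_called - 1))
  out[n_called < 2] <- NA_real_
  out
}

#' Per-site F_ST between two groups
#'
#' Default is the Weir & Cockerham (1984) single-site two-population
#' estimator (variance components a, b, c from allele frequencies,
#' sample sizes and observed heterozygosity); negative estimates are
#' retained. `"hudson"` selects the plain Hudson-style ratio
#' `(p1 - p2)^2 / (p1 (1 - p2) + p2 (1 - p1))`, which is exactly zero at
#' equal sample frequencies. Vectorised over sites.
#'
#' @param n_alt1,n_called1,n_het1 Alt-allele counts, called-allele
#'   counts and heterozygote counts in group 1 (see [site_counts()]).
#' @param n_alt2,n_called2,n_het2 Same for group 2.
#' @param estimator `"wc"` or `"hudson"`.
#' @return Numeric vector; NA where undefined.
#' @export
site_fst <- function(n_alt1, n_called1, n_het1,
                     n_alt2, n_called2, n_het2,
                     estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  p1 <- n_alt1 / n_called1
  p2 <- n_alt2 / n_called2
  if (estimator == "hudson") {
    num <- (p1 - p2)^2
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    out <- num / den
    out[den == 0 | n_called1 < 2 | n_called2 < 2] <- NA_real_
    return(out)
  }
  r <- 2
  n1 <- n_called1 / 2; n2 <- n_called2 / 2      # diploid sample sizes
  h1 <- n_het1 / n1; h2 <- n_het2 / n2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  den <- a + b + cc
  out <- a / den
  out[den == 0 | n1 < 1 | n2 < 1 | nbar <= 1] <- NA_real_
  out
}

#' Tajima's D from summary quantities
#'
#' Direct evaluation of Tajima (1989):
#' `D = (k - S/a1) / sqrt(e1 S + e2 S (S - 1))`, with the constants a1,
#' a2, b1, b2, c1, c2, e1, e2 computed from the number of sequences `n`
#' and `k` the mean number of pairwise differences.
#'
#' @param k Mean pairwise differences across the window.
#' @param S Number of segregating sites.
#' @param n Number of sequences (integer >= 2).
#' @return Tajima's D, or NA when S = 0 or the variance is 0.
#' @export
tajima_d <- function(k, S, n) {
  if (is.na(S) || is.na(n) || S < 1 || n < 2) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (k - S / a1) / sqrt(v)
}

#' Per-window population-genetic statistics
#'
#' For every window and group, computes pi (the mean of [site_pi()] over
#' sites polymorphic within the group; NA when the window holds none), a
#' per-bp variant (`pi_per_bp`, the same sum divided by window length),
#' and Tajima's D (from the segregating-site count, the summed pairwise
#' differences and the window-median called-allele count, rounded to an
#' integer). For every ordered pair of groups it computes window F_ST as
#' the arithmetic mean of per-site estimates at sites whose pooled minor
#' allele frequency passes `maf_cutoff` (not a ratio of sums — each
#' variable position contributes its own estimate).
#'
#' @param gm A [genotype_matrix()].
#' @param windows Classified window table from [classify_intervals()].
#' @param maf_cutoff Pooled MAF cutoff for F_ST sites.
#' @param estimator F_ST estimator, `"wc"` or `"hudson"`.
#' @return List with `per_group` (window x group rows: `n_segregating`,
#'   `pi`, `pi_per_bp`, `tajima_d`) and `per_pair` (window x group-pair
#'   rows: `n_fst_sites`, `fst`), both keyed by `window_id`.
#' @export
window_stats <- function(gm, windows, maf_cutoff = 0.05,
                         estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  validate_genotype_matrix(gm)
  widx <- site_window_index(gm, windows)
  groups <- sort(unique(gm$groups))
  counts <- lapply(groups, function(g)
    site_counts(gm, group_samples(gm, g)))
  names(counts) <- groups
  wid <- windows$window_id
  wlen <- windows$end - windows$start

  per_group <- do.call(rbind, lapply(groups, function(g) {
    ct <- counts[[g]]
    poly <- ct$n_alt > 0 & ct$n_alt < ct$n_called & ct$n_called >= 2
    sp <- site_pi(ct$n_alt, ct$n_called)
    S <- tab_by_window(poly, widx, wid, sum)
    pi_sum <- tab_by_window(ifelse(poly, sp, 0), widx, wid, sum)
    med_n <- vapply(wid, function(w) {
      nn <- ct$n_called[which(widx == w & poly)]
      if (!length(nn)) NA_real_ else round(median(nn))
    }, numeric(1))
    td <- vapply(seq_along(wid), function(i)
      tajima_d(pi_sum[i], S[i], med_n[i]), numeric(1))
    data.frame(window_id = wid, group = g, n_segregating = S,
               pi = ifelse(S > 0, pi_sum / S, NA_real_),
               pi_per_bp = pi_sum / wlen,
               tajima_d = td, stringsAsFactors = FALSE)
  }))

  per_pair <- NULL
  if (length(groups) >= 2) {
    prs <- combn(groups, 2)
    per_pair <- do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
      g1 <- prs[1, j]; g2 <- prs[2, j]
      c1 <- counts[[g1]]; c2 <- counts[[g2]]
      pooled_p <- (c1$n_alt + c2$n_alt) / (c1$n_called + c2$n_called)
      maf <- pmin(pooled_p, 1 - pooled_p)
      ok <- maf >= maf_cutoff & c1$n_called >= 2 & c2$n_called >= 2
      fs <- site_fst(c1$n_alt, c1$n_called, c1$n_het,
                     c2$n_alt, c2$n_called, c2$n_het, estimator)
      fs[!ok] <- NA_real_
      n_ok <- tab_by_window(ok & !is.na(fs), widx, wid, sum)
      f_sum <- tab_by_window(ifelse(is.na(fs), 0, fs), widx, wid, sum)
      data.frame(window_id = wid, group1 = g1, group2 = g2,
                 n_fst_sites = n_ok,
                 fst = ifelse(n_ok > 0, f_sum / n_ok, NA_real_),
                 stringsAsFactors = FALSE)
    }))
  }
  list(per_group = per_group, per_pair = per_pair)
}

# Aggregate a per-site vector by window id, 0/NA where a window is empty.
tab_by_window <- function(x, widx, wid, fun) {
  ok <- !is.na(widx)
  agg <- tapply(x[ok], widx[ok], fun)
  out <- rep(0, length(wid))
  m <- match(wid, as.integer(names(agg)))
  out[!is.na(m)] <- agg[m[!is.na(m)]]
  out
}

#' Windowed pi for one group
#'
#' Convenience wrapper around [window_stats()] returning the mean
#' per-polymorphic-site diversity per window for a single group.
#'
#' @inheritParams window_stats
#' @param group Group label.
#' @return Numeric vector aligned with `windows` rows (NA where the
#'   window has no site polymorphic within the group).
#' @export
window_pi <- function(gm, windows, group) {
  st <- window_stats(gm, windows)$per_group
  st$pi[st$group == group][match(windows$window_id,
                                 st$window_id[st$group == group])]
}

#' Windowed F_ST for one group pair
#'
#' @inheritParams window_stats
#' @param group1,group2 Group labels.
#' @return Numeric vector aligned with `windows` rows.
#' @export
window_fst <- function(gm, windows, group1, group2, maf_cutoff = 0.05,
                       estimator = c("wc", "hudson")) {
  st <- window_stats(gm, windows, maf_cutoff, estimator)$per_pair
  sel <- (st$group1 == group1 & st$group2 == group2) |
    (st$group1 == group2 & st$group2 == group1)
  st <- st[sel, , drop = FALSE]
  st$fst[match(windows$window_id, st$window_id)]
}

#' Windowed Tajima's D for one group
#'
#' @inheritParams window_pi
#' @return Numeric vector aligned with `windows` rows.
#' @export
window_tajima_d <- function(gm, windows, group) {
  st <- window_stats(gm, windows)$per_group
  st <- st[st$group == group, , drop = FALSE]
  st$tajima_d[match(windows$window_id, st$window_id)]
}
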