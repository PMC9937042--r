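# Independent brute-force oracles. Each one recomputes a statistic from
# first principles by enumeration or refitting, deliberately avoiding the
# package's code paths.

# Per-site pi by exhaustive enumeration of all allele pairs.
oracle_site_pi <- function(n_alt, n_called) {
  alleles <- c(rep(1L, n_alt), rep(0L, n_called - n_alt))
  prs <- combn(n_called, 2)
  mean(alleles[prs[1, ]] != alleles[prs[2, ]])
}

# Weir & Cockerham (1984) single-site theta for two populations, written
# as scalar arithmetic straight from the variance-component definitions.
oracle_wc_fst <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  n1 <- length(g1); n2 <- length(g2); r <- 2
  p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
  h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
  n_bar <- (n1 + n2) / 2
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s_sq <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s_sq - (p_bar * (1 - p_bar) - ((r - 1) / r) * s_sq - h_bar / 4) /
       (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s_sq -
       ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  a / (a + b + cc)
}

# Tajima's D evaluated directly from the 1989 definitions (independent
# spelling of the constants).
oracle_tajima_d <- function(k_hat, S, n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n * n + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  (k_hat - S / a1) /
    sqrt((c1 / a1) * S + (c2 / (a1 * a1 + a2)) * S * (S - 1))
}

# Exhaustive most-probable-path search for the 2-state ROH HMM: evaluate
# the joint probability of every state sequence.
oracle_viterbi_az <- function(het, pos, p, params) {
  m <- length(het)
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  emis <- function(state, i) {
    if (state == 2) { if (het[i]) params$het_emission_in_az
      else 1 - params$het_emission_in_az }
    else { h <- 2 * p[i] * (1 - p[i]); if (het[i]) h else 1 - h }
  }
  trans <- function(s1, s2, d) {
    t_in <- 1 - exp(-params$rate_into_az * d)
    t_out <- 1 - exp(-params$rate_out_of_az * d)
    if (s1 == 1 && s2 == 2) t_in else if (s1 == 1) 1 - t_in
    else if (s2 == 1) t_out else 1 - t_out
  }
  best <- NULL; best_lp <- -Inf
  for (mask in 0:(2^m - 1)) {
    states <- bitwAnd(bitwShiftR(mask, seq_len(m) - 1), 1L) + 1L
    lp <- log(0.5) + log(emis(states[1], 1))
    if (m > 1) for (i in 2:m)
      lp <- lp + log(trans(states[i - 1], states[i],
                           pos[i] - pos[i - 1])) +
        log(emis(states[i], i))
    if (lp > best_lp + 1e-12) { best_lp <- lp; best <- states }
  }
  best == 2L
}

# Cook's distance from explicit leave-one-out refits.
oracle_cooks <- function(x, y) {
  n <- length(y)
  fit <- lm(y ~ x)
  yhat <- fitted(fit)
  p <- 2
  s2 <- sum(resid(fit)^2) / (n - p)
  vapply(seq_len(n), function(i) {
    fi <- lm(y[-i] ~ x[-i])
    yhat_i <- coef(fi)[1] + coef(fi)[2] * x
    sum((yhat - yhat_i)^2) / (p * s2)
  }, numeric(1))
}

# Patterson's D by an explicit site-by-site loop.
oracle_patterson_d <- function(freqs) {
  abba <- 0; baba <- 0
  for (i in seq_len(nrow(freqs))) {
    f <- freqs[i, ]
    if (any(is.na(f))) next
    abba <- abba + (1 - f[1]) * f[2] * f[3] * (1 - f[4])
    baba <- baba + f[1] * (1 - f[2]) * f[3] * (1 - f[4])
  }
  (abba - baba) / (abba + baba)
}

# Tiny genotype matrix from a dosage matrix (sites x samples).
make_gm <- function(geno, pos = NULL, chrom = NULL, groups = NULL) {
  n_sites <- nrow(geno); n_samp <- ncol(geno)
  samples <- colnames(geno) %||% sprintf("s%02d", seq_len(n_samp))
  colnames(geno) <- samples
  if (is.null(pos)) pos <- seq_len(n_sites) * 100L
  if (is.null(chrom)) chrom <- rep("chr1", n_sites)
  if (is.null(groups))
    groups <- setNames(rep(c("g1", "g2"), length.out = n_samp), samples)
  genotype_matrix(chrom, pos, rep("A", n_sites), rep("T", n_sites),
                  geno, samples, groups)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
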