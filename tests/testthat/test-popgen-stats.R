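test_that("site pi equals exhaustive pair enumeration for all n <= 12", {
  for (n in 2:12) for (k in 0:n)
    expect_equal(site_pi(k, n), oracle_site_pi(k, n),
                 label = sprintf("n=%d k=%d", n, k))
  expect_equal(site_pi(2, 4), 2 / 3, tolerance = 1e-4)   # 4 of 6 pairs
  expect_equal(site_pi(1, 10), 0.2)                      # 9 of 45 pairs
  expect_equal(site_pi(0, 10), 0)                        # monomorphic
  expect_true(is.na(site_pi(1, 1)))
})

test_that("windowed pi averages site pi over polymorphic sites only", {
  # group g1 = samples 1,2: site1 has 2 alt of 4 alleles (pi = 2/3),
  # site2 is monomorphic in g1, site3 has 1 alt of 4 (pi = 1/2)
  geno <- rbind(c(1L, 1L, 0L, 0L),
                c(0L, 0L, 1L, 1L),
                c(1L, 0L, 2L, 2L))
  gm <- make_gm(geno, groups = setNames(c("g1", "g1", "g2", "g2"),
                                        sprintf("s%02d", 1:4)))
  w <- tile_windows(c(chr1 = 1000), 1000)
  expect_equal(window_pi(gm, w, "g1"), mean(c(2 / 3, 1 / 2)))
  # all sites monomorphic in the group -> missing
  gm2 <- make_gm(rbind(c(0L, 0L, 1L, 1L)),
                 groups = setNames(c("g1", "g1", "g2", "g2"),
                                   sprintf("s%02d", 1:4)))
  expect_true(is.na(window_pi(gm2, tile_windows(c(chr1 = 1000), 1000),
                              "g1")))
})

test_that("per-site Weir-Cockerham F_ST matches an independent reimplementation", {
  set.seed(7)
  for (case in 1:50) {
    n1 <- sample(4:12, 1); n2 <- sample(4:12, 1)
    g1 <- sample(0:2, n1, replace = TRUE)
    g2 <- sample(0:2, n2, replace = TRUE)
    if (sum(g1) + sum(g2) == 0 || sum(g1) + sum(g2) == 2 * (n1 + n2)) next
    got <- site_fst(sum(g1), 2 * n1, sum(g1 == 1),
                    sum(g2), 2 * n2, sum(g2 == 1), "wc")
    expect_equal(got, oracle_wc_fst(g1, g2), tolerance = 1e-12)
  }
})

test_that("F_ST is 1 at fixed differences and Hudson is 0 at equal frequencies", {
  expect_equal(site_fst(0, 20, 0, 20, 20, 0, "wc"), 1)
  expect_equal(site_fst(0, 20, 0, 20, 20, 0, "hudson"), 1)
  expect_equal(site_fst(10, 20, 4, 10, 20, 6, "hudson"), 0)
})

test_that("sites below the pooled MAF cutoff are excluded from window F_ST", {
  # 13 diploids: site 1 fully differentiated (pooled MAF ~ 0.46);
  # site 2 a single het, pooled MAF 1/26 = 0.038 < 0.05
  geno <- rbind(c(rep(0L, 6), rep(2L, 7)),
                c(rep(0L, 6), 1L, rep(0L, 6)))
  gm <- make_gm(geno, groups = setNames(rep(c("g1", "g2"), c(6, 7)),
                                        sprintf("s%02d", 1:13)))
  w <- tile_windows(c(chr1 = 1000), 1000)
  with_maf <- window_fst(gm, w, "g1", "g2", maf_cutoff = 0.05)
  no_maf <- window_fst(gm, w, "g1", "g2", maf_cutoff = 0)
  only_site1 <- site_fst(0, 12, 0, 14, 14, 0, "wc")
  expect_equal(with_maf, only_site1)
  expect_false(isTRUE(all.equal(no_maf, with_maf)))
})

test_that("window F_ST is the mean of per-site values and is symmetric", {
  sim <- simulate_genotypes(simulation_config(seed = 21, n_sites = 500,
                                              n_genes = 20))
  w <- sim$truth$windows
  f12 <- window_fst(sim$genotypes, w, "pop1", "pop2")
  f21 <- window_fst(sim$genotypes, w, "pop2", "pop1")
  expect_equal(f12, f21)
  # single qualifying site -> that site's value (engineered window)
  geno <- rbind(c(0L, 0L, 2L, 2L))
  gm <- make_gm(geno, groups = setNames(c("g1", "g1", "g2", "g2"),
                                        sprintf("s%02d", 1:4)))
  expect_equal(window_fst(gm, tile_windows(c(chr1 = 1000), 1000),
                          "g1", "g2"), 1)
})

test_that("window pi is invariant under sample reordering", {
  sim <- simulate_genotypes(simulation_config(seed = 22, n_sites = 400,
                                              n_genes = 20))
  gm <- sim$genotypes
  w <- sim$truth$windows
  perm <- sample(ncol(gm$geno))
  gm2 <- genotype_matrix(gm$chrom, gm$pos, gm$ref, gm$alt,
                         gm$geno[, perm], gm$samples[perm],
                         gm$groups[gm$samples[perm]])
  expect_equal(window_pi(gm, w, "pop1"), window_pi(gm2, w, "pop1"))
})

test_that("Tajima's D reproduces the four-haplotype worked example", {
  # haplotypes AAA, AAT, ATT, TTT over 3 segregating sites:
  # mean pairwise differences 10/6, a1 = 11/6
  expect_equal(tajima_d(10 / 6, 3, 4), 0.168, tolerance = 5e-3)
  expect_equal(tajima_d(10 / 6, 3, 4), oracle_tajima_d(10 / 6, 3, 4))
})

test_that("an excess of singletons drives Tajima's D negative", {
  S <- 20; n <- 40
  k_hat <- S * site_pi(1, n)   # every site a singleton
  expect_lt(tajima_d(k_hat, S, n), 0)
})

test_that("windowed Tajima's D matches direct formula evaluation on 100 windows", {
  sim <- simulate_genotypes(simulation_config(seed = 23, n_sites = 3000,
                                              n_genes = 50))
  gm <- sim$genotypes
  w <- sim$truth$windows
  expect_gte(nrow(w), 100)
  got <- window_tajima_d(gm, w, "pop1")
  samples <- names(gm$groups)[gm$groups == "pop1"]
  ct <- site_counts(gm, samples)
  widx <- mitoscan:::site_window_index(gm, w)
  for (i in seq_len(nrow(w))) {
    ii <- which(widx == w$window_id[i])
    poly <- ii[ct$n_alt[ii] > 0 & ct$n_alt[ii] < ct$n_called[ii] &
                 ct$n_called[ii] >= 2]
    if (!length(poly)) { expect_true(is.na(got[i])); next }
    k_hat <- sum(site_pi(ct$n_alt[poly], ct$n_called[poly]))
    n_seq <- round(median(ct$n_called[poly]))
    expect_equal(got[i], oracle_tajima_d(k_hat, length(poly), n_seq),
                 tolerance = 1e-6)
  }
})

test_that("a panmictic population split at random shows no structure", {
  set.seed(31)
  n_sites <- 4000; n_samp <- 16
  p <- 0.01 * (0.99 / 0.01)^runif(n_sites)
  geno <- matrix(rbinom(n_sites * n_samp, 2, rep(p, n_samp)),
                 n_sites, n_samp)
  colnames(geno) <- sprintf("s%02d", seq_len(n_samp))
  groups <- setNames(sample(rep(c("a", "b"), each = n_samp / 2)),
                     colnames(geno))
  gm <- make_gm(geno, pos = sort(sample.int(2e6, n_sites)),
                groups = groups)
  w <- tile_windows(c(chr1 = 2e6), 3e4)
  st <- window_stats(gm, w)
  expect_lt(abs(mean(st$per_pair$fst, na.rm = TRUE)), 0.02)
  expect_lt(abs(mean(st$per_group$tajima_d, na.rm = TRUE)), 0.5)
})
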