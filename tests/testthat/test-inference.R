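make_intervals <- function(n = 40, seed = 1, beta = c(2, 1, 0, 0),
                           noise = 0, rho = 0) {
  set.seed(seed)
  cls <- rep(c("N_INTERACT", "NON_N_INTERACT"), length.out = n)
  g <- rpois(n, 2) + 1
  ni <- as.integer(cls == "N_INTERACT")
  eps <- if (rho > 0) as.numeric(arima.sim(list(ar = rho), n)) * noise
  else rnorm(n, 0, noise)
  if (noise == 0) eps <- rep(0, n)
  data.frame(chrom = "chr1", start = seq_len(n) * 1000, class = cls,
             gene_number = g,
             fst = beta[1] + beta[2] * ni + beta[3] * g +
               beta[4] * ni * g + eps,
             stringsAsFactors = FALSE)
}

test_that("a noise-free constructed response is interpolated exactly", {
  d <- make_intervals(n = 40, beta = c(2, 1, 0, 0))
  fit <- suppressWarnings(fit_interaction_model(d, "fst"))
  expect_equal(unname(coef(fit)), c(2, 1, 0, 0), tolerance = 1e-10)
  d2 <- make_intervals(n = 40, beta = c(0.5, 0.2, 0.05, -0.03))
  fit2 <- suppressWarnings(fit_interaction_model(d2, "fst"))
  expect_equal(unname(coef(fit2)), c(0.5, 0.2, 0.05, -0.03),
               tolerance = 1e-10)
})

test_that("the marginal class gap at gene number g equals beta1 + beta3 g", {
  d <- make_intervals(n = 200, seed = 3, beta = c(0.1, 0.04, 0.01, -0.005),
                      noise = 0.02)
  fit <- fit_interaction_model(d, "fst")
  mm <- marginal_means(fit)
  b <- coef(fit)
  for (g in unique(mm$gene_number)) {
    gap <- mm$predicted[mm$gene_number == g & mm$class == "N_INTERACT"] -
      mm$predicted[mm$gene_number == g & mm$class == "NON_N_INTERACT"]
    expect_equal(gap, unname(b[2] + b[4] * g), tolerance = 1e-10)
  }
  # grid spans the 1st to 90th percentile of gene numbers
  qs <- quantile(fit$data$gene_number, c(0.01, 0.90), names = FALSE)
  expect_gte(min(mm$gene_number), max(1, ceiling(qs[1])))
  expect_lte(max(mm$gene_number), max(1, floor(qs[2])))
})

test_that("single-class or undersized inputs are refused", {
  d <- make_intervals(n = 30)
  expect_error(fit_interaction_model(d[d$class == "N_INTERACT", ], "fst"),
               "N-interact")
  expect_error(fit_interaction_model(d[1:10, ], "fst"), "fewer than")
})

test_that("a constant response gives zero bootstrap SEs and NA p-values", {
  d <- make_intervals(n = 60, beta = c(0.3, 0, 0, 0))
  d$fst <- 0.3
  fit <- suppressWarnings(fit_interaction_model(d, "fst"))
  fb <- block_bootstrap(fit, block_size = 10, B = 50, seed = 1)
  expect_true(all(fb$boot$se < 1e-12))
  expect_true(all(is.na(fb$boot$p)))
  expect_error(block_bootstrap(fit, B = 1), "B must be")
})

test_that("permutation p-values follow the +1 convention", {
  # observed difference beats every null draw
  v <- c(101:110, 1:10)
  lab <- rep(c(TRUE, FALSE), each = 10)
  res <- permutation_test(v, lab, "upper", B = 1000, seed = 1,
                          target = TRUE)
  expect_equal(res$p, 1 / 1001, tolerance = 1e-12)
  # constant values: p = 1 exactly
  res0 <- permutation_test(rep(3.7, 20), lab, "upper", B = 200, seed = 1,
                           target = TRUE)
  expect_equal(res0$observed, 0)
  expect_equal(res0$p, 1)
  expect_error(permutation_test(v, lab, "upper", B = 0, target = TRUE),
               "B must be")
  expect_error(permutation_test(v, rep(TRUE, 20), target = TRUE),
               "both classes")
})

test_that("permutation p is invariant to adding a constant to all values", {
  set.seed(9)
  v <- rnorm(50)
  lab <- runif(50) < 0.4
  p1 <- permutation_test(v, lab, "upper", B = 299, seed = 4,
                         target = TRUE)$p
  p2 <- permutation_test(v + 7, lab, "upper", B = 299, seed = 4,
                         target = TRUE)$p
  expect_identical(p1, p2)
})

test_that("Fisher's method matches the chi-squared form and is monotone", {
  fc <- fisher_combine(c(0.5, 0.5))
  expect_equal(fc$x2, 2.7726, tolerance = 1e-4)
  expect_equal(fc$df, 4L)
  expect_equal(fc$p, 0.596, tolerance = 1e-3)

  expect_equal(fisher_combine(rep(1, 3))$x2, 0)
  expect_equal(fisher_combine(rep(1, 3))$p, 1)

  ps <- vapply(c(0.9, 0.5, 0.2, 0.05, 0.01),
               function(p) fisher_combine(rep(p, 4))$p, numeric(1))
  expect_true(all(diff(ps) < 0))

  expect_warning(fisher_combine(c(0, 0.5)), "clamped")
  # a single p combines to itself through the chi-squared(2) map
  for (p in c(0.9, 0.3, 0.01))
    expect_equal(fisher_combine(p)$p, p, tolerance = 1e-12)
})

test_that("Cook's distance matches leave-one-out refits on a 20-point fixture", {
  set.seed(14)
  x <- rnorm(20)
  y <- 0.5 + 0.3 * x + rnorm(20, 0, 0.4)
  y[7] <- y[7] + 3   # plant an influential point
  fit <- lm(y ~ x)
  expect_equal(unname(cooks.distance(fit)), unname(oracle_cooks(x, y)),
               tolerance = 1e-8)
})

test_that("the outlier excess test flags directed outliers and counts N-interact hits", {
  set.seed(15)
  n <- 200
  w <- data.frame(window_id = seq_len(n),
                  class = rep(c("N_INTERACT", "NON_N_INTERACT"),
                              c(40, 160)),
                  gene_number = rpois(n, 2) + 1)
  w$fst <- 0.05 + 0.002 * w$gene_number + rnorm(n, 0, 0.01)
  planted <- c(1:4, 101:102)   # 4 N-interact + 2 background outliers
  w$fst[planted] <- w$fst[planted] + 0.2
  rep <- cooks_outlier_excess(w, "fst", "upper")
  expect_true(all(planted %in% rep$outlier_window_ids))
  expect_gte(rep$n_outliers_n_interact, 4)
  expect_equal(rep$p0, 0.2)
  # reported p equals the explicit binomial upper-tail sum
  p_manual <- sum(vapply(rep$n_outliers_n_interact:rep$n_outliers,
                         function(k) choose(rep$n_outliers, k) *
                           rep$p0^k * (1 - rep$p0)^(rep$n_outliers - k),
                         numeric(1)))
  expect_equal(rep$p, p_manual, tolerance = 1e-12)
  # lower-direction: the same windows are not lower outliers
  rep_lo <- cooks_outlier_excess(w, "fst", "lower")
  expect_false(any(planted %in% rep_lo$outlier_window_ids))
})

test_that("identical statistics yield zero outliers and p = 1", {
  w <- data.frame(window_id = 1:50,
                  class = rep(c("N_INTERACT", "NON_N_INTERACT"), 25),
                  gene_number = rep(1:5, 10), fst = 0.1)
  rep <- cooks_outlier_excess(w, "fst", "upper")
  expect_equal(rep$n_outliers, 0)
  expect_equal(rep$p, 1)
})

test_that("Tajima class comparison reports the nongenic class descriptively", {
  w <- data.frame(window_id = 1:60,
                  class = rep(c("N_INTERACT", "NON_N_INTERACT",
                                "NONGENIC"), 20),
                  tajima_d = rep(c(-0.5, -0.5, 0.2), 20))
  res <- tajima_class_comparison(w, B = 99, seed = 1)
  expect_equal(res$test$observed, 0)   # identical genic distributions
  expect_setequal(res$class_summary$class,
                  c("N_INTERACT", "NONGENIC", "NON_N_INTERACT"))
  expect_equal(res$class_summary$mean[res$class_summary$class ==
                                        "NONGENIC"], 0.2)
})

test_that("cross-metric overlap counts comparisons and ROH residence", {
  mk_report <- function(ids) structure(
    list(outlier_window_ids = ids), class = "outlier_report")
  reports <- list(fst_a = mk_report(c(1, 2)), fst_b = mk_report(c(1, 3)),
                  pi_a = mk_report(c(1, 2)), pi_b = mk_report(1))
  windows <- data.frame(window_id = 1:4, chrom = "chr1",
                        start = (0:3) * 1e4, end = (1:4) * 1e4,
                        class = c("N_INTERACT", "N_INTERACT",
                                  "NON_N_INTERACT", "NONGENIC"))
  rohs <- data.frame(sample = "s1", chrom = "chr1", start = 5000,
                     end = 12000, class = "N_INTERACT")
  ov <- cross_metric_overlap(reports, windows, rohs)
  expect_equal(ov$n_comparisons[ov$window_id == 1], 4)
  expect_equal(ov$n_comparisons[ov$window_id == 3], 1)
  expect_true(ov$in_roh[ov$window_id == 1])    # [5000,12000) hits [0,1e4)
  expect_false(ov$in_roh[ov$window_id == 3])   # class mismatch
  empty <- cross_metric_overlap(list(a = mk_report(integer(0))),
                                windows, rohs)
  expect_equal(nrow(empty), 0)
})
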