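#' Fit the interaction linear model of a statistic on N-interact status
#'
#' Ordinary least squares of `response ~ n_interact + gene_number +
#' n_interact:gene_number` over gene-bearing intervals. For ROH lengths
#' the response is `log(length / 1e5)` (natural log of length in 100-kb
#' units; the raw lengths are strongly right-skewed); window F_ST and pi
#' enter untransformed. The marginal N-interact gap at gene number g is
#' `beta1 + beta3 * g`.
#'
#' @param intervals data.frame with `class`, `gene_number`, and the
#'   response column; `NONGENIC` rows and rows with missing response are
#'   dropped.
#' @param response One of `"log_roh_length"` (expects a `length`
#'   column), `"fst"`, `"pi"`, or the name of a numeric column to use
#'   untransformed.
#' @param min_per_class Minimum observations required in each class.
#' @return Object of class `mitoscan_fit` wrapping the `lm` fit.
#' @export
fit_interaction_model <- function(intervals, response,
                                  min_per_class = 10) {
  d <- intervals[intervals$class != "NONGENIC", , drop = FALSE]
  y <- if (response == "log_roh_length") log(d$length / 1e5)
  else d[[response]]
  if (is.null(y)) stop("no response column for '", response, "'")
  keep <- !is.na(y) & is.finite(y)
  d <- d[keep, , drop = FALSE]
  y <- y[keep]
  d$n_interact_flag <- as.integer(d$class == "N_INTERACT")
  tab <- table(factor(d$n_interact_flag, levels = 0:1))
  if (any(tab == 0))
    stop("both N-interact and non-N-interact intervals are required")
  if (any(tab < min_per_class))
    stop("fewer than ", min_per_class, " observations in a class")
  dat <- data.frame(y = y, n_interact = d$n_interact_flag,
                    gene_number = d$gene_number)
  if ("chrom" %in% names(d)) dat$chrom <- d$chrom
  if ("start" %in% names(d)) dat$start <- d$start
  fit <- lm(y ~ n_interact * gene_number, data = dat)
  if (fit$rank < 4)
    stop("design matrix is rank deficient; fit refused")
  structure(list(fit = fit, response = response, data = dat,
                 se = summary(fit)$coefficients[, "Std. Error"],
                 boot = NULL),
            class = "mitoscan_fit")
}

#' @export
print.mitoscan_fit <- function(x, ...) {
  cat("Interaction linear model for", x$response, "on",
      nrow(x$data), "intervals\n")
  print(coef(x$fit))
  if (!is.null(x$boot))
    cat("block-bootstrap SEs from", nrow(x$boot$coefficients),
        "replicates (block size", x$boot$block_size, ")\n")
  invisible(x)
}

#' @export
coef.mitoscan_fit <- function(object, ...) coef(object$fit)

#' @export
predict.mitoscan_fit <- function(object, newdata, ...)
  predict(object$fit, newdata = newdata, ...)

#' @export
summary.mitoscan_fit <- function(object, ...) {
  se <- if (!is.null(object$boot)) object$boot$se else object$se
  p <- 2 * pnorm(-abs(coef(object$fit) / se))
  cbind(estimate = coef(object$fit), se = se, p = p)
}

#' Block-bootstrap standard errors for an interaction fit
#'
#' Neighbouring genomic windows are autocorrelated, so ordinary OLS
#' standard errors are too small. Intervals (in genome order, per
#' chromosome) are grouped into consecutive blocks of `block_size`;
#' each replicate resamples blocks with replacement (the same number of
#' blocks per chromosome), refits the model, and the SE of each
#' coefficient is the standard deviation over replicates. Two-sided
#' p-values come from the normal approximation `2 (1 - Phi(|beta|/SE))`.
#' Rank-deficient replicates are redrawn and counted.
#'
#' @param fit A `mitoscan_fit` (its data must be in genome order).
#' @param block_size Block size in intervals.
#' @param B Number of replicates (>= 2).
#' @param seed Integer seed.
#' @return The fit with a `boot` component (`se`, `p`, `coefficients`
#'   matrix, `n_redrawn`, `block_size`).
#' @export
block_bootstrap <- function(fit, block_size = 30, B = 1000, seed = 1) {
  stopifnot(inherits(fit, "mitoscan_fit"))
  if (B < 2) stop("B must be >= 2")
  set.seed(seed)
  dat <- fit$data
  chrom <- if ("chrom" %in% names(dat)) dat$chrom else rep("g", nrow(dat))
  # consecutive block ids within each chromosome
  block <- unlist(lapply(split(seq_len(nrow(dat)), chrom), function(ii)
    paste(chrom[ii[1]], (seq_along(ii) - 1L) %/% block_size)),
    use.names = FALSE)
  block <- block[order(unlist(split(seq_len(nrow(dat)), chrom),
                              use.names = FALSE))]
  rows_by_block <- split(seq_len(nrow(dat)), block)
  blocks_by_chrom <- split(names(rows_by_block),
                           vapply(rows_by_block, function(ii)
                             chrom[ii[1]], character(1)))
  X <- model.matrix(~ n_interact * gene_number, dat)
  y <- dat$y
  coefs <- matrix(NA_real_, B, ncol(X), dimnames = list(NULL, colnames(X)))
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      rows <- unlist(lapply(blocks_by_chrom, function(bl)
        unlist(rows_by_block[sample(bl, length(bl), replace = TRUE)],
               use.names = FALSE)), use.names = FALSE)
      f <- lm.fit(X[rows, , drop = FALSE], y[rows])
      if (f$rank == ncol(X)) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 100L * B) stop("bootstrap replicates keep failing")
    }
    coefs[b, ] <- f$coefficients
  }
  se <- apply(coefs, 2, sd)
  beta <- coef(fit$fit)
  # SEs that are zero to numerical precision make p undefined
  degenerate <- se <= 1e-10 * (abs(beta) + 1)
  p <- ifelse(degenerate, NA_real_, 2 * pnorm(-abs(beta / se)))
  fit$boot <- list(se = se, p = p, coefficients = coefs,
                   n_redrawn = n_redrawn, block_size = block_size)
  fit
}

#' Marginal means of the interaction model over gene numbers
#'
#' Predicted responses for both classes on an integer gene-number grid
#' from the 1st to the 90th percentile of the observed (pooled)
#' gene-number distribution — the range over which most intervals'
#' gene counts actually fall. Confidence bands come from bootstrap
#' replicate predictions (2.5/97.5 percentiles) when [block_bootstrap()]
#' has run, otherwise from the analytic OLS confidence interval.
#'
#' @param fit A `mitoscan_fit`.
#' @param percentile_range Two percentiles of gene_number, default
#'   `c(1, 90)`.
#' @return data.frame with `gene_number`, `class`, `predicted`, `lower`,
#'   `upper`.
#' @export
marginal_means <- function(fit, percentile_range = c(1, 90)) {
  g <- fit$data$gene_number
  qs <- quantile(g, percentile_range / 100, names = FALSE)
  grid <- seq(max(1, ceiling(qs[1])), max(1, floor(qs[2])))
  if (!length(grid)) grid <- max(1, round(qs[1]))
  nd <- data.frame(n_interact = rep(c(1, 0), each = length(grid)),
                   gene_number = rep(grid, 2))
  if (!is.null(fit$boot)) {
    X <- model.matrix(~ n_interact * gene_number, nd)
    pred <- X %*% coef(fit$fit)
    reps <- X %*% t(fit$boot$coefficients)
    ci <- t(apply(reps, 1, quantile, c(0.025, 0.975)))
    out <- data.frame(gene_number = nd$gene_number,
                      class = ifelse(nd$n_interact == 1, "N_INTERACT",
                                     "NON_N_INTERACT"),
                      predicted = as.vector(pred),
                      lower = ci[, 1], upper = ci[, 2])
  } else {
    pr <- predict(fit$fit, newdata = nd, interval = "confidence")
    out <- data.frame(gene_number = nd$gene_number,
                      class = ifelse(nd$n_interact == 1, "N_INTERACT",
                                     "NON_N_INTERACT"),
                      predicted = pr[, "fit"], lower = pr[, "lwr"],
                      upper = pr[, "upr"])
  }
  rownames(out) <- NULL
  out
}

#' One-sided permutation test of a class difference in means
#'
#' The observed difference of means (target class minus the rest) is
#' compared with `B` label-shuffled differences. The one-sided p-value
#' uses the +1 convention, `p = (#{null >= obs} + 1) / (B + 1)` for the
#' upper tail (`<=` for the lower), so p is never zero. In the scan the
#' upper tail is used for ROH length, F_ST and dN/dS, the lower tail
#' for pi and Tajima's D.
#'
#' @param values Numeric vector (NAs dropped with their labels).
#' @param labels Logical vector (TRUE = target class) or vector coercible
#'   via comparison with `target`.
#' @param tail `"upper"` or `"lower"`.
#' @param B Number of permutations (>= 1).
#' @param seed Integer seed.
#' @param target When `labels` is not logical, the level treated as the
#'   target class (default `"N_INTERACT"`).
#' @return Object of class `resampling_result`: observed difference,
#'   null summary, p-value, B, seed.
#' @export
permutation_test <- function(values, labels, tail = c("upper", "lower"),
                             B = 1000, seed = 1,
                             target = "N_INTERACT") {
  tail <- match.arg(tail)
  if (B < 1) stop("B must be >= 1")
  if (!is.logical(labels)) labels <- labels == target
  keep <- !is.na(values) & !is.na(labels)
  v <- values[keep]; lab <- labels[keep]
  if (!any(lab) || all(lab))
    stop("both classes must be present")
  set.seed(seed)
  nA <- sum(lab); n <- length(v); tot <- sum(v)
  obs <- mean(v[lab]) - mean(v[!lab])
  null <- vapply(seq_len(B), function(b) {
    sA <- sum(v[sample.int(n, nA)])
    sA / nA - (tot - sA) / (n - nA)
  }, numeric(1))
  p <- if (tail == "upper") (sum(null >= obs) + 1) / (B + 1)
  else (sum(null <= obs) + 1) / (B + 1)
  structure(list(observed = obs, p = p, tail = tail, B = B, seed = seed,
                 null_mean = mean(null), null_sd = sd(null),
                 n_target = nA, n_other = n - nA),
            class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf(
    "permutation test (%s tail): observed diff %.4g, p = %.4g (B = %d)\n",
    x$tail, x$observed, x$p, x$B))
  invisible(x)
}

#' Cook's-distance outlier excess test
#'
#' Fits `statistic ~ gene_number` by OLS over all gene-bearing windows,
#' computes Cook's distance for every window, and flags windows with
#' `D_i > 4/n` whose residual sign matches `direction` (positive for
#' upper-F_ST outliers, negative for lower-pi outliers). Whether
#' N-interact windows are over-represented among the outliers is then a
#' one-sided binomial test: `P(X >= k)` with `X ~ Binomial(n_outliers,
#' p0)` and `p0` the N-interact share of all gene-bearing windows.
#'
#' @param windows Classified window table containing the statistic.
#' @param statistic Column name (`"fst"` or `"pi"`, typically).
#' @param direction `"upper"` or `"lower"`.
#' @param threshold Cook's distance cutoff; default `4/n`.
#' @return Object of class `outlier_report`: outlier window ids, counts,
#'   `p0`, binomial p.
#' @export
cooks_outlier_excess <- function(windows, statistic,
                                 direction = c("upper", "lower"),
                                 threshold = NULL) {
  direction <- match.arg(direction)
  d <- windows[windows$class != "NONGENIC" &
                 !is.na(windows[[statistic]]), , drop = FALSE]
  n <- nrow(d)
  if (n < 3) stop("need at least 3 gene-bearing windows")
  fit <- lm(d[[statistic]] ~ d$gene_number)
  cd <- cooks.distance(fit)
  r <- resid(fit)
  thr <- threshold %||% (4 / n)
  # residuals at numerical zero carry no direction
  r_eps <- 1e-8 * max(abs(d[[statistic]]), 1)
  out <- is.finite(cd) & cd > thr &
    if (direction == "upper") r > r_eps else r < -r_eps
  out[is.na(out)] <- FALSE
  k <- sum(out & d$class == "N_INTERACT")
  n_out <- sum(out)
  p0 <- mean(d$class == "N_INTERACT")
  p <- if (n_out == 0) 1 else pbinom(k - 1, n_out, p0, lower.tail = FALSE)
  structure(list(statistic = statistic, direction = direction,
                 outlier_window_ids = d$window_id[out],
                 n_outliers = n_out, n_outliers_n_interact = k,
                 p0 = p0, p = p, threshold = thr, n_windows = n),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf(
    "%s %s outliers: %d of %d windows (%d N-interact), binomial p = %.4g\n",
    x$direction, x$statistic, x$n_outliers, x$n_windows,
    x$n_outliers_n_interact, x$p))
  invisible(x)
}

#' Combine p-values with Fisher's method
#'
#' `X2 = -2 sum(log p_i)` is chi-squared with `2k` degrees of freedom
#' under independence. Zero p-values (impossible under the permutation
#' +1 convention) are clamped to `1/(B+1)` with a warning.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param clamp_b Permutation count used for the zero clamp.
#' @return List with `x2`, `df`, `p`.
#' @export
fisher_combine <- function(p_values, clamp_b = 1000) {
  p <- p_values[!is.na(p_values)]
  if (!length(p)) return(list(x2 = NA_real_, df = 0L, p = NA_real_))
  if (any(p <= 0)) {
    warning("p-value(s) of 0 clamped to 1/(B+1)")
    p[p <= 0] <- 1 / (clamp_b + 1)
  }
  if (any(p > 1)) stop("p-values must lie in (0, 1]")
  x2 <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(x2 = x2, df = df, p = pchisq(x2, df, lower.tail = FALSE))
}

#' Three-class Tajima's D comparison
#'
#' Lower-tail permutation test of mean Tajima's D, N-interact versus
#' non-N-interact windows (the selection expectation is a more negative
#' D at mitonuclear loci); nongenic windows are summarised
#' descriptively, since genome-wide demography moves all three classes
#' together.
#'
#' @param windows Window table with `class` and `tajima_d`.
#' @param B Permutations.
#' @param seed Integer seed.
#' @return List with `test` (a `resampling_result`) and
#'   `class_summary` (per-class mean/median/n).
#' @export
tajima_class_comparison <- function(windows, B = 1000, seed = 1) {
  d <- windows[!is.na(windows$tajima_d), , drop = FALSE]
  cs <- do.call(rbind, lapply(split(d$tajima_d, d$class), function(v)
    data.frame(n = length(v), mean = mean(v), median = median(v))))
  cs$class <- rownames(cs); rownames(cs) <- NULL
  genic <- d[d$class != "NONGENIC", , drop = FALSE]
  test <- NULL
  if (length(unique(genic$class)) == 2)
    test <- permutation_test(genic$tajima_d, genic$class, "lower",
                             B = B, seed = seed)
  list(test = test, class_summary = cs)
}

#' Cross-metric outlier overlap and ROH residence
#'
#' Tabulates, for every window that is an outlier anywhere, which
#' comparisons flagged it, the number of comparisons in which it was
#' flagged, and whether it overlaps a same-class ROH of any sample.
#'
#' @param reports Named list of `outlier_report` objects sharing window
#'   coordinates.
#' @param windows The classified window table the reports refer to.
#' @param rohs Optional classified ROH table.
#' @return data.frame with one row per flagged window: `window_id`, one
#'   logical column per report, `n_comparisons`, `in_roh`.
#' @export
cross_metric_overlap <- function(reports, windows, rohs = NULL) {
  ids <- sort(unique(unlist(lapply(reports, `[[`,
                                   "outlier_window_ids"))))
  out <- data.frame(window_id = ids)
  for (nm in names(reports))
    out[[nm]] <- ids %in% reports[[nm]]$outlier_window_ids
  out$n_comparisons <- if (nrow(out)) rowSums(as.matrix(
    out[, names(reports), drop = FALSE])) else integer(0)
  out$in_roh <- logical(nrow(out))
  if (!is.null(rohs) && nrow(rohs) && nrow(out)) {
    w <- windows[match(ids, windows$window_id), , drop = FALSE]
    for (i in seq_len(nrow(out))) {
      same <- rohs$class == w$class[i] & rohs$chrom == w$chrom[i]
      out$in_roh[i] <- any(same & rohs$start < w$end[i] &
                             rohs$end > w$start[i])
    }
  }
  out
}
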