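#' Run the full selection scan on one data set
#'
#' Orchestrates the whole analysis: windows are tiled at each configured
#' size and classified against the annotation; per-window F_ST (every
#' group pair), pi and Tajima's D (every group) are computed; each
#' statistic is modelled as `statistic ~ n_interact * gene_number` with
#' block-bootstrap standard errors and marginal means; one-sided
#' permutation tests compare N-interact with non-N-interact intervals
#' (upper tail for F_ST and ROH length, lower for pi and Tajima's D);
#' Cook's-distance outlier excess tests run for upper-F_ST and lower-pi
#' outliers; ROHs are called per sample with the two-state HMM and
#' modelled on the log scale; optional CDS alignments yield the dN/dS
#' comparison; an optional four-taxon data set yields Patterson's D
#' genome-wide and per window. Permutation p-values are finally combined
#' per metric and window size with Fisher's method.
#'
#' @param genotypes A [genotype_matrix()] with group assignments.
#' @param annotations Annotation data.frame from [read_annotations()]
#'   (or the simulator's truth).
#' @param config A [pipeline_config()].
#' @param chromosome_lengths Named vector; defaults to the last variant
#'   position per chromosome.
#' @param cds Optional named list of CDS alignments for dN/dS.
#' @param dstat Optional list `list(genotypes=, taxa=, annotations=)`
#'   describing a four-taxon data set for Patterson's D.
#' @param roh_model A [roh_params()].
#' @return Object of class `mitoscan_report`.
#' @export
run_scan <- function(genotypes, annotations, config = pipeline_config(),
                     chromosome_lengths = NULL, cds = NULL,
                     dstat = NULL, roh_model = roh_params()) {
  validate_genotype_matrix(genotypes)
  if (is.null(chromosome_lengths)) {
    chromosome_lengths <- tapply(genotypes$pos, genotypes$chrom, max)
    chromosome_lengths <- setNames(as.numeric(chromosome_lengths),
                                   names(chromosome_lengths))
  }
  seeds <- derive_seeds(config$seed, 64)
  si <- 0L
  next_seed <- function() { si <<- si + 1L; seeds[si] }
  groups <- sort(unique(genotypes$groups))
  perm_rows <- list()
  add_perm <- function(metric, wsize, comparison, p)
    perm_rows[[length(perm_rows) + 1L]] <<- data.frame(
      metric = metric, window_size = wsize, comparison = comparison,
      p = p, stringsAsFactors = FALSE)

  by_size <- list()
  for (wsize in config$window_sizes) {
    windows <- classify_intervals(
      tile_windows(chromosome_lengths, wsize), annotations)
    st <- window_stats(genotypes, windows, config$maf_cutoff,
                       config$fst_estimator)
    res <- list(windows = windows, stats = st, fst = list(),
                pi = list(), tajima = list(), outliers = list())

    if (!is.null(st$per_pair)) {
      pairs <- unique(st$per_pair[, c("group1", "group2")])
      for (k in seq_len(nrow(pairs))) {
        g1 <- pairs$group1[k]; g2 <- pairs$group2[k]
        lab <- paste(g1, g2, sep = ":")
        pp <- st$per_pair[st$per_pair$group1 == g1 &
                            st$per_pair$group2 == g2, ]
        w <- windows
        w$fst <- pp$fst[match(w$window_id, pp$window_id)]
        entry <- list()
        entry$fit <- tryCatch({
          f <- fit_interaction_model(w, "fst")
          f <- block_bootstrap(f, config$block_size,
                               config$n_bootstrap, next_seed())
          f
        }, error = function(e) {
          warning("F_ST model skipped for ", lab, ": ",
                  conditionMessage(e)); NULL
        })
        if (!is.null(entry$fit))
          entry$marginal_means <- marginal_means(
            entry$fit, config$percentile_range)
        genic <- w$class != "NONGENIC"
        entry$permutation <- tryCatch(
          permutation_test(w$fst[genic], w$class[genic], "upper",
                           config$n_permutations, next_seed()),
          error = function(e) NULL)
        if (!is.null(entry$permutation))
          add_perm("fst", wsize, lab, entry$permutation$p)
        entry$outliers <- tryCatch(
          cooks_outlier_excess(w, "fst", "upper"),
          error = function(e) NULL)
        res$fst[[lab]] <- entry
      }
    }

    for (g in groups) {
      pg <- st$per_group[st$per_group$group == g, ]
      w <- windows
      w$pi <- pg$pi[match(w$window_id, pg$window_id)]
      w$tajima_d <- pg$tajima_d[match(w$window_id, pg$window_id)]
      entry <- list()
      entry$fit <- tryCatch({
        f <- fit_interaction_model(w, "pi")
        block_bootstrap(f, config$block_size, config$n_bootstrap,
                        next_seed())
      }, error = function(e) {
        warning("pi model skipped for ", g, ": ",
                conditionMessage(e)); NULL
      })
      if (!is.null(entry$fit))
        entry$marginal_means <- marginal_means(entry$fit,
                                               config$percentile_range)
      genic <- w$class != "NONGENIC"
      entry$permutation <- tryCatch(
        permutation_test(w$pi[genic], w$class[genic], "lower",
                         config$n_permutations, next_seed()),
        error = function(e) NULL)
      if (!is.null(entry$permutation))
        add_perm("pi", wsize, g, entry$permutation$p)
      entry$outliers <- tryCatch(
        cooks_outlier_excess(w, "pi", "lower"),
        error = function(e) NULL)
      res$pi[[g]] <- entry

      tj <- tryCatch(
        tajima_class_comparison(w, config$n_permutations, next_seed()),
        error = function(e) NULL)
      if (!is.null(tj) && !is.null(tj$test))
        add_perm("tajima_d", wsize, g, tj$test$p)
      res$tajima[[g]] <- tj
    }
    by_size[[as.character(wsize)]] <- res
  }

  # --- ROHs (window-size independent) -------------------------------
  rohs <- call_roh_all(genotypes, roh_model)
  rohs <- classify_roh(rohs, annotations)
  roh_res <- list(intervals = rohs, by_group = list())
  if (nrow(rohs)) for (g in groups) {
    rg <- rohs[rohs$group == g, , drop = FALSE]
    entry <- list()
    entry$fit <- tryCatch(
      fit_interaction_model(rg, "log_roh_length"),
      error = function(e) NULL)
    if (!is.null(entry$fit))
      entry$marginal_means <- marginal_means(entry$fit,
                                             config$percentile_range)
    genic <- rg$class != "NONGENIC"
    entry$permutation <- tryCatch(
      permutation_test(rg$length[genic], rg$class[genic], "upper",
                       config$n_permutations, next_seed()),
      error = function(e) NULL)
    if (!is.null(entry$permutation))
      add_perm("roh_length", NA_real_, g, entry$permutation$p)
    roh_res$by_group[[g]] <- entry
  }

  # --- dN/dS ---------------------------------------------------------
  dnds_res <- NULL
  if (!is.null(cds)) {
    ni_ids <- annotations$gene_id[annotations$n_interact]
    tab <- dnds_table(cds, ni_ids, config$omega_cap)
    cmp <- tryCatch(
      dnds_comparison(tab, config$background_genes,
                      config$n_permutations, next_seed()),
      error = function(e) NULL)
    if (!is.null(cmp)) add_perm("dnds", NA_real_, "all", cmp$p)
    dnds_res <- list(records = tab, comparison = cmp)
  }

  # --- Patterson's D -------------------------------------------------
  dstat_res <- NULL
  if (!is.null(dstat)) {
    g4 <- dstat$genotypes
    freqs <- group_freqs(g4, dstat$taxa)
    genome <- patterson_d(freqs)
    lens4 <- tapply(g4$pos, g4$chrom, max)
    lens4 <- setNames(as.numeric(lens4), names(lens4))
    per_size <- list()
    for (wsize in config$window_sizes) {
      w4 <- classify_intervals(tile_windows(lens4, wsize),
                               dstat$annotations)
      dv <- window_d(g4, w4, dstat$taxa)
      cmp <- tryCatch(
        windowed_d_comparison(dv, w4$class, config$n_permutations,
                              next_seed()),
        error = function(e) NULL)
      if (!is.null(cmp)) add_perm("dstat", wsize, "all", cmp$p)
      per_size[[as.character(wsize)]] <-
        list(windows = w4, d = dv, comparison = cmp)
    }
    dstat_res <- list(genome_wide = genome, by_size = per_size,
                      taxa = dstat$taxa)
  }

  perm_table <- if (length(perm_rows)) do.call(rbind, perm_rows)
  else data.frame(metric = character(), window_size = numeric(),
                  comparison = character(), p = numeric())
  fisher <- combine_across_comparisons(perm_table,
                                       clamp_b = config$n_permutations)

  structure(list(by_size = by_size, roh = roh_res, dnds = dnds_res,
                 dstat = dstat_res, permutation_table = perm_table,
                 fisher = fisher,
                 provenance = list(
                   config = config, seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("mitoscan")),
                   dnds_method = if (!is.null(dnds_res))
                     attr(dnds_res$records, "method"),
                   note = paste("F_ST p-values are not independent",
                                "across pairwise comparisons; Fisher",
                                "combinations over them are",
                                "anticonservative"))),
            class = "mitoscan_report")
}

#' Combine permutation p-values across comparisons with Fisher's method
#'
#' One combination per (metric, window size) across groups or group
#' pairs; the recorded degrees of freedom are `2k` for `k` combined
#' p-values (e.g. five per-clade Tajima's D tests combine with df = 10,
#' four per-data-set dN/dS tests with df = 8).
#'
#' @param perm_table data.frame with `metric`, `window_size`,
#'   `comparison`, `p`.
#' @param clamp_b Permutation count for the zero-p clamp.
#' @return data.frame with `metric`, `window_size`, `k`, `x2`, `df`, `p`.
#' @export
combine_across_comparisons <- function(perm_table, clamp_b = 1000) {
  if (!nrow(perm_table))
    return(data.frame(metric = character(), window_size = numeric(),
                      k = integer(), x2 = numeric(), df = integer(),
                      p = numeric()))
  key <- paste(perm_table$metric, perm_table$window_size)
  rows <- lapply(split(perm_table, key), function(d) {
    fc <- fisher_combine(d$p, clamp_b)
    data.frame(metric = d$metric[1], window_size = d$window_size[1],
               k = nrow(d), x2 = fc$x2, df = fc$df, p = fc$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$metric, out$window_size), , drop = FALSE]
}

#' @export
print.mitoscan_report <- function(x, ...) {
  cat("mitoscan report (seed", x$provenance$seed, ")\n")
  for (ws in names(x$by_size)) {
    res <- x$by_size[[ws]]
    cat(sprintf("  %s bp windows: %d windows (%d N-interact)\n", ws,
                nrow(res$windows),
                sum(res$windows$class == "N_INTERACT")))
  }
  if (!is.null(x$roh) && nrow(x$roh$intervals))
    cat("  ROHs called:", nrow(x$roh$intervals), "\n")
  if (!is.null(x$dnds))
    cat("  dN/dS records:", nrow(x$dnds$records),
        sprintf("(comparison p = %.4g)\n",
                x$dnds$comparison$p %||% NA))
  if (!is.null(x$dstat))
    cat(sprintf("  Patterson's D = %.4f (Z = %.2f)\n",
                x$dstat$genome_wide$d, x$dstat$genome_wide$z))
  if (nrow(x$fisher)) {
    cat("  Fisher combinations:\n")
    print(x$fisher, row.names = FALSE)
  }
  invisible(x)
}

#' Write a scan report's tables to disk
#'
#' Emits the window tables (TSV), the permutation and Fisher tables,
#' outlier windows and ROHs as BED, and a provenance JSON.
#'
#' @param report A `mitoscan_report`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_results <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ws in names(report$by_size)) {
    res <- report$by_size[[ws]]
    write_window_table(res$windows,
                       file.path(dir, paste0("windows_", ws, ".tsv")))
    write_window_table(res$stats$per_group,
                       file.path(dir, paste0("stats_group_", ws, ".tsv")))
    if (!is.null(res$stats$per_pair))
      write_window_table(res$stats$per_pair,
                         file.path(dir, paste0("stats_pair_", ws, ".tsv")))
    out_ids <- unique(unlist(c(
      lapply(res$fst, function(e)
        if (!is.null(e$outliers)) e$outliers$outlier_window_ids),
      lapply(res$pi, function(e)
        if (!is.null(e$outliers)) e$outliers$outlier_window_ids))))
    ow <- res$windows[res$windows$window_id %in% out_ids, , drop = FALSE]
    write_bed(ow, file.path(dir, paste0("outlier_windows_", ws, ".bed")),
              name_col = "class")
  }
  if (nrow(report$roh$intervals))
    write_bed(report$roh$intervals, file.path(dir, "rohs.bed"),
              name_col = "sample")
  write_window_table(report$permutation_table,
                     file.path(dir, "permutation_tests.tsv"))
  write_window_table(report$fisher, file.path(dir, "fisher_combined.tsv"))
  if (!is.null(report$dnds))
    write_window_table(report$dnds$records, file.path(dir, "dnds.tsv"))
  jsonlite::write_json(
    list(seed = report$provenance$seed,
         package_version = report$provenance$package_version,
         dnds_method = report$provenance$dnds_method,
         note = report$provenance$note),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    null = "null", pretty = TRUE)
  invisible(dir)
}
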