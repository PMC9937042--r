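#' Configuration for the synthetic-data generator
#'
#' The generator emulates the inputs of a mitonuclear selection scan:
#' several populations differentiated under a Balding-Nichols model, a
#' gene annotation with a flagged N-interact subset, window-localised
#' selection signatures (elevated F_ST, reduced diversity, an excess of
#' rare alleles), planted homozygous tracts, per-gene omega differences
#' and an optional four-taxon introgression scenario.
#'
#' @param n_populations Number of populations.
#' @param samples_per_population Diploid samples per population.
#' @param chromosome_length Chromosome length in bp (single autosome by
#'   default; pass `chromosomes` for several).
#' @param chromosomes Named vector of chromosome lengths; overrides
#'   `chromosome_length`.
#' @param n_sites Total biallelic SNP count across chromosomes.
#' @param baseline_fst Balding-Nichols dispersion outside selected
#'   windows, in (0,1).
#' @param selected_fst Dispersion inside selected windows; must be >=
#'   `baseline_fst`. Equal values plant no differentiation signal.
#' @param selected_window_fraction Fraction of N-interact windows that
#'   receive the selection signature.
#' @param sfs_skew Excess-rare-allele weight (>= 0) for selected windows:
#'   ancestral frequencies there are drawn from a Beta(0.5, 5) component
#'   with probability `sfs_skew / (1 + sfs_skew)`, producing reduced pi
#'   and negative Tajima's D without haplotype simulation.
#' @param n_genes Number of genes placed on the genome.
#' @param n_interact_fraction Fraction of genes flagged N-interact.
#' @param planted_roh data.frame with `sample`, `start`, `end` (0-based
#'   half-open bp on the first chromosome) of homozygous tracts to plant.
#' @param omega_background,omega_selected True dN/dS for non-N-interact
#'   and N-interact genes in [simulate_cds()].
#' @param introgression_fraction Fraction `f` of target windows whose P2
#'   allele frequencies are copied from P3 in [simulate_four_taxon()].
#' @param introgression_target `"n_interact"` (default) or `"all"`:
#'   which windows can receive introgression.
#' @param window_size Window size (bp) used to lay out planted signals.
#' @param cds_subs_per_codon Expected substitution attempts per codon per
#'   branch in [simulate_cds()].
#' @param seed Integer seed; fully determines all outputs.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_populations = 2,
                              samples_per_population = 10,
                              chromosome_length = 1e7,
                              chromosomes = NULL,
                              n_sites = 8000,
                              baseline_fst = 0.05,
                              selected_fst = 0.3,
                              selected_window_fraction = 0.1,
                              sfs_skew = 1,
                              n_genes = 150,
                              n_interact_fraction = 0.25,
                              planted_roh = NULL,
                              omega_background = 0.2,
                              omega_selected = 0.6,
                              introgression_fraction = 0,
                              introgression_target = c("n_interact", "all"),
                              window_size = 30000,
                              cds_subs_per_codon = 0.15,
                              seed = 1) {
  if (is.null(chromosomes)) chromosomes <- c(chr1 = chromosome_length)
  cfg <- list(
    n_populations = as.integer(n_populations),
    samples_per_population = as.integer(samples_per_population),
    chromosomes = chromosomes,
    n_sites = as.integer(n_sites),
    baseline_fst = baseline_fst, selected_fst = selected_fst,
    selected_window_fraction = selected_window_fraction,
    sfs_skew = sfs_skew, n_genes = as.integer(n_genes),
    n_interact_fraction = n_interact_fraction,
    planted_roh = planted_roh,
    omega_background = omega_background,
    omega_selected = omega_selected,
    introgression_fraction = introgression_fraction,
    introgression_target = match.arg(introgression_target),
    window_size = window_size,
    cds_subs_per_codon = cds_subs_per_codon,
    seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (n_sites < 1L) stop("n_sites must be >= 1")
    if (n_populations < 1L || samples_per_population < 1L)
      stop("populations must be non-empty")
    if (baseline_fst <= 0 || baseline_fst >= 1 ||
        selected_fst <= 0 || selected_fst >= 1)
      stop("F_ST parameters must lie in (0, 1)")
    if (selected_fst < baseline_fst)
      stop("selected_fst must be >= baseline_fst")
    if (sfs_skew < 0) stop("sfs_skew must be >= 0")
    if (omega_background < 0 || omega_selected < 0)
      stop("omega parameters must be >= 0 (0 = no protein evolution)")
    if (introgression_fraction < 0 || introgression_fraction > 1)
      stop("introgression_fraction must lie in [0, 1]")
    if (!is.null(planted_roh)) {
      stopifnot(all(c("sample", "start", "end") %in% names(planted_roh)))
      if (any(planted_roh$start < 0) ||
          any(planted_roh$end > chromosomes[[1]]))
        stop("planted ROH intervals must lie within the first chromosome")
      if (any(planted_roh$end <= planted_roh$start))
        stop("planted ROH intervals must have end > start")
    }
  })
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config:", x$n_populations, "pops x",
      x$samples_per_population, "samples,", x$n_sites, "sites,",
      x$n_genes, "genes; F_ST", x$baseline_fst, "->", x$selected_fst,
      "; seed", x$seed, "\n")
  invisible(x)
}

# Balding-Nichols draw: population frequency around ancestral p with
# dispersion F; F = 0 degenerates to a copy.
rbn <- function(p, f) {
  f <- rep_len(f, length(p))
  out <- p
  pos <- f > 0
  if (any(pos))
    out[pos] <- rbeta(sum(pos), p[pos] * (1 - f[pos]) / f[pos],
                      (1 - p[pos]) * (1 - f[pos]) / f[pos])
  out
}

# Ancestral allele-frequency prior: density proportional to 1/p on
# [0.01, 0.99] (log-uniform), the shape of the neutral site-frequency
# spectrum; keeps windowed Tajima's D near zero without selection.
ranc <- function(n) 0.01 * (0.99 / 0.01)^runif(n)

# Shared scaffolding: positions, gene annotation, classified windows.
sim_scaffold <- function(cfg) {
  lens <- cfg$chromosomes
  n_per <- pmax(1L, round(cfg$n_sites * lens / sum(lens)))
  chrom <- rep(names(lens), n_per)
  pos <- unlist(lapply(seq_along(lens), function(i)
    sort(sample.int(lens[[i]] - 1L, n_per[[i]])) + 1L), use.names = FALSE)

  tss_chr <- sample(names(lens), cfg$n_genes, replace = TRUE,
                    prob = lens / sum(lens))
  tss <- floor(runif(cfg$n_genes, 0, lens[tss_chr]))
  glen <- floor(runif(cfg$n_genes, 2000, 10000))
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  start <- ifelse(strand == "+", tss, pmax(0, tss - glen + 1))
  end <- ifelse(strand == "+", pmin(lens[tss_chr], tss + glen), tss + 1)
  n_ni <- max(1L, round(cfg$n_genes * cfg$n_interact_fraction))
  ni <- seq_len(cfg$n_genes) %in% sample.int(cfg$n_genes, n_ni)
  cat4 <- sample(c("OXPHOS", "ARS2", "MRP", "REP"), cfg$n_genes,
                 replace = TRUE, prob = c(101, 77, 17, 4))
  ann <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(cfg$n_genes)),
    chrom = tss_chr, start = start, end = end, strand = strand,
    tss = tss, n_interact = ni,
    category = ifelse(ni, cat4, "OTHER"), stringsAsFactors = FALSE)
  ann <- ann[order(ann$chrom, ann$start), , drop = FALSE]
  rownames(ann) <- NULL

  windows <- classify_intervals(tile_windows(lens, cfg$window_size), ann)
  list(chrom = chrom, pos = pos, ann = ann, windows = windows, lens = lens)
}

#' Simulate differentiated genotypes with planted selection signatures
#'
#' Allele frequencies are drawn per population from a Balding-Nichols
#' Beta distribution around a shared ancestral frequency, with dispersion
#' `baseline_fst` (or `selected_fst` inside selected windows); genotypes
#' are binomial draws assuming Hardy-Weinberg proportions. Selected
#' windows are drawn from the N-interact windows (or all windows if there
#' are none) and additionally receive ancestral frequencies with extra
#' mass near zero, governed by `sfs_skew`, which lowers diversity and
#' skews the site-frequency spectrum. Planted ROH tracts overwrite the
#' named sample's genotypes with the population-major homozygote.
#'
#' @param config A [simulation_config()].
#' @return List with `genotypes` (a [genotype_matrix()]) and `truth`
#'   (selected window ids, planted ROHs, true per-gene omega, plus the
#'   annotation and classified window tables used to plant them).
#' @export
simulate_genotypes <- function(config) {
  cfg <- validate_simulation_config(config)
  set.seed(cfg$seed)
  sc <- sim_scaffold(cfg)
  n_sites <- length(sc$pos)

  ni_windows <- sc$windows$window_id[sc$windows$class == "N_INTERACT"]
  pool <- if (length(ni_windows)) ni_windows else sc$windows$window_id
  n_sel <- round(length(pool) * cfg$selected_window_fraction)
  selected <- sort(sample(pool, n_sel))

  gm0 <- list(chrom = sc$chrom, pos = sc$pos)
  widx <- site_window_index(gm0, sc$windows)
  swept <- widx %in% selected

  # ancestral frequencies from the neutral-spectrum-shaped prior
  # (density ~ 1/p, i.e. log-uniform): keeps Tajima's D near zero in
  # unselected windows
  p_anc <- ranc(n_sites)
  # swept sites that carry the rare-allele signature: with probability
  # sfs_skew/(1+sfs_skew) the POPULATION frequency is drawn directly
  # from Beta(0.5, 5), independently per population (young variants
  # after a sweep) — low pi, left-skewed SFS and extra differentiation
  use_skew <- rep(FALSE, n_sites)
  if (cfg$sfs_skew > 0 && any(swept)) {
    w <- cfg$sfs_skew / (1 + cfg$sfs_skew)
    use_skew <- swept & runif(n_sites) < w
  }
  f_site <- ifelse(swept, cfg$selected_fst, cfg$baseline_fst)

  pops <- paste0("pop", seq_len(cfg$n_populations))
  samples <- unlist(lapply(pops, function(p)
    sprintf("%s_s%02d", p, seq_len(cfg$samples_per_population))))
  groups <- setNames(rep(pops, each = cfg$samples_per_population), samples)

  geno <- matrix(NA_integer_, n_sites, length(samples),
                 dimnames = list(NULL, samples))
  pop_freq <- matrix(0, n_sites, cfg$n_populations)
  for (j in seq_along(pops)) {
    pf <- rbn(p_anc, f_site)
    if (any(use_skew))
      pf[use_skew] <- pmin(pmax(rbeta(sum(use_skew), 0.5, 5), 0.005),
                           0.995)
    pop_freq[, j] <- pf
    cols <- which(groups == pops[j])
    geno[, cols] <- rbinom(n_sites * length(cols), 2L,
                           rep(pf, length(cols)))
  }

  if (!is.null(cfg$planted_roh)) {
    first_chr <- names(cfg$chromosomes)[1]
    for (i in seq_len(nrow(cfg$planted_roh))) {
      pr <- cfg$planted_roh[i, ]
      sel <- sc$chrom == first_chr &
        (sc$pos - 1L) >= pr$start & (sc$pos - 1L) < pr$end
      pj <- match(groups[[pr$sample]], pops)
      geno[sel, pr$sample] <- ifelse(pop_freq[sel, pj] > 0.5, 2L, 0L)
    }
  }

  alleles <- vapply(seq_len(n_sites), function(i)
    sample(c("A", "C", "G", "T"), 2), character(2))
  gm <- genotype_matrix(sc$chrom, sc$pos, alleles[1, ], alleles[2, ],
                        geno, samples, groups)
  truth <- list(selected_window_ids = selected,
                planted_roh = cfg$planted_roh,
                per_gene_true_omega = setNames(
                  ifelse(sc$ann$n_interact, cfg$omega_selected,
                         cfg$omega_background), sc$ann$gene_id),
                introgressed_window_ids = integer(0),
                annotations = sc$ann, windows = sc$windows)
  list(genotypes = gm, truth = truth)
}

# --- codon-level CDS simulation -------------------------------------------

stop_codons <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  nt <- c("A", "C", "G", "T")
  as.vector(outer(outer(nt, nt, paste0), nt, paste0))
}

#' Simulate per-gene coding-sequence alignments under a target omega
#'
#' Each gene evolves from a random ancestor (ATG first codon, no stop
#' codons) along a star tree with `n_taxa` tips. Substitution attempts
#' arrive as a Poisson process per branch; an attempt changing the amino
#' acid is accepted with probability `min(1, omega)` while a synonymous
#' one is accepted with probability `min(1, 1/omega)`, so the realised
#' nonsynonymous/synonymous rate ratio equals the gene's omega. Attempts
#' creating a stop codon are rejected and the first codon never mutates.
#'
#' @param config A [simulation_config()]; supplies omega values, the
#'   N-interact fraction and the seed.
#' @param n_taxa Tips of the star tree (>= 2).
#' @param codons_per_gene Codons per gene (>= 30).
#' @param genes Optional data.frame with `gene_id`, `n_interact` to reuse
#'   an existing annotation; defaults to a fresh set of `n_genes` genes.
#' @return List with `alignments` (named list of named character vectors,
#'   one per gene) and `truth` (data.frame of gene id, n_interact flag,
#'   true omega).
#' @export
simulate_cds <- function(config, n_taxa = 4, codons_per_gene = 100,
                         genes = NULL) {
  cfg <- validate_simulation_config(config)
  stopifnot(codons_per_gene >= 30, n_taxa >= 2)
  set.seed(cfg$seed + 1L)
  if (is.null(genes)) {
    n_ni <- max(1L, round(cfg$n_genes * cfg$n_interact_fraction))
    genes <- data.frame(
      gene_id = sprintf("gene%04d", seq_len(cfg$n_genes)),
      n_interact = seq_len(cfg$n_genes) %in%
        sample.int(cfg$n_genes, n_ni), stringsAsFactors = FALSE)
  }
  omega <- ifelse(genes$n_interact, cfg$omega_selected,
                  cfg$omega_background)
  sense <- setdiff(all_codons(), stop_codons)
  aa <- Biostrings::GENETIC_CODE
  taxa <- sprintf("t%02d", seq_len(n_taxa))
  nt <- c("A", "C", "G", "T")

  evolve <- function(codons, om) {
    n_att <- rpois(1, cfg$cds_subs_per_codon * length(codons))
    if (n_att == 0) return(codons)
    for (k in seq_len(n_att)) {
      ci <- sample(2:length(codons), 1)  # first codon (ATG) immutable
      pos <- sample(3, 1)
      old <- codons[ci]
      alt <- sample(setdiff(nt, substr(old, pos, pos)), 1)
      new <- old
      substr(new, pos, pos) <- alt
      if (new %in% stop_codons) next
      p_acc <- if (aa[[new]] == aa[[old]]) min(1, 1 / om) else min(1, om)
      if (runif(1) < p_acc) codons[ci] <- new
    }
    codons
  }

  alignments <- vector("list", nrow(genes))
  names(alignments) <- genes$gene_id
  for (g in seq_len(nrow(genes))) {
    anc <- c("ATG", sample(sense, codons_per_gene - 1, replace = TRUE))
    seqs <- vapply(taxa, function(t)
      paste(evolve(anc, omega[g]), collapse = ""), character(1))
    alignments[[g]] <- seqs
  }
  list(alignments = alignments,
       truth = data.frame(gene_id = genes$gene_id,
                          n_interact = genes$n_interact,
                          omega = omega, stringsAsFactors = FALSE))
}

#' Simulate a four-taxon introgression scenario
#'
#' Populations P1, P2, P3 and O evolve on the tree (((P1,P2),P3),O) with
#' Balding-Nichols drift of `baseline_fst` per branch (the outgroup
#' branch gets three times that, capped at 0.6). In a fraction
#' `introgression_fraction` of target windows (N-interact windows by
#' default), P2's allele frequencies are copied from P3 instead of
#' descending from the (P1,P2) ancestor, creating an ABBA-directed
#' excess detectable with Patterson's D.
#'
#' @param config A [simulation_config()].
#' @return List with `genotypes` (groups P1, P2, P3, O) and `truth`
#'   (introgressed window ids, annotation, window table).
#' @export
simulate_four_taxon <- function(config) {
  cfg <- validate_simulation_config(config)
  set.seed(cfg$seed + 2L)
  sc <- sim_scaffold(cfg)
  n_sites <- length(sc$pos)
  f <- cfg$baseline_fst
  f_out <- min(0.6, 3 * f)

  pool <- if (cfg$introgression_target == "n_interact")
    sc$windows$window_id[sc$windows$class == "N_INTERACT"]
  else sc$windows$window_id
  n_inx <- round(length(pool) * cfg$introgression_fraction)
  introgressed <- sort(sample(pool, n_inx))
  widx <- site_window_index(list(chrom = sc$chrom, pos = sc$pos),
                            sc$windows)
  inx_site <- widx %in% introgressed

  # terminal branches of the sister pair are short (f/5): most drift
  # separates (P1,P2) from P3, which is what makes copied-in P3
  # frequencies stand out as an ABBA excess
  p0 <- ranc(n_sites)
  p123 <- rbn(p0, f)
  p12 <- rbn(p123, f)
  p1 <- rbn(p12, f / 5)
  p2 <- rbn(p12, f / 5)
  p3 <- rbn(p123, f)
  p4 <- rbn(p0, f_out)
  p2[inx_site] <- p3[inx_site]   # introgression: P2 copies P3

  pops <- c("P1", "P2", "P3", "O")
  freq <- cbind(p1, p2, p3, p4)
  samples <- unlist(lapply(pops, function(p)
    sprintf("%s_s%02d", p, seq_len(cfg$samples_per_population))))
  groups <- setNames(rep(pops, each = cfg$samples_per_population), samples)
  geno <- matrix(NA_integer_, n_sites, length(samples),
                 dimnames = list(NULL, samples))
  for (j in seq_along(pops)) {
    cols <- which(groups == pops[j])
    geno[, cols] <- rbinom(n_sites * length(cols), 2L,
                           rep(freq[, j], length(cols)))
  }
  alleles <- vapply(seq_len(n_sites), function(i)
    sample(c("A", "C", "G", "T"), 2), character(2))
  gm <- genotype_matrix(sc$chrom, sc$pos, alleles[1, ], alleles[2, ],
                        geno, samples, groups)
  list(genotypes = gm,
       truth = list(introgressed_window_ids = introgressed,
                    annotations = sc$ann, windows = sc$windows))
}

#' Write a complete synthetic input bundle to disk
#'
#' Emits everything the pipeline reads — VCF genotypes, GFF3 annotation,
#' sample-to-group TSV, N-interact gene list, per-gene CDS FASTA files, a
#' BED of truth windows — plus the serialized truth table (JSON). Two
#' runs with the same config are byte-identical.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if absent).
#' @return Named list of file paths (`vcf`, `gff3`, `groups`,
#'   `gene_list`, `cds_dir`, `truth_bed`, `truth_json`), invisibly
#'   wrapped with the in-memory simulation under `$sim`.
#' @export
write_fixture_bundle <- function(config, dir) {
  cfg <- validate_simulation_config(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genotypes(cfg)
  cds <- simulate_cds(cfg, genes = sim$truth$annotations[,
    c("gene_id", "n_interact")])
  ann <- sim$truth$annotations

  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    gff3 = file.path(dir, "genes.gff3"),
    groups = file.path(dir, "groups.tsv"),
    gene_list = file.path(dir, "n_interact_genes.tsv"),
    cds_dir = file.path(dir, "cds"),
    truth_bed = file.path(dir, "truth_selected_windows.bed"),
    truth_json = file.path(dir, "truth.json"))

  write_vcf(sim$genotypes, paths$vcf, contigs = cfg$chromosomes)

  gr <- GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand)
  gr$ID <- ann$gene_id
  gr$type <- "gene"
  gr$source <- "mitoscan_sim"
  rtracklayer::export(gr, paths$gff3, format = "gff3")

  write.table(data.frame(sample = names(sim$genotypes$groups),
                         group = unname(sim$genotypes$groups)),
              paths$groups, sep = "\t", quote = FALSE, row.names = FALSE)
  ni <- ann[ann$n_interact, c("gene_id", "category")]
  write.table(ni, paths$gene_list, sep = "\t", quote = FALSE,
              row.names = FALSE)

  dir.create(paths$cds_dir, showWarnings = FALSE)
  for (g in names(cds$alignments)) {
    ss <- Biostrings::DNAStringSet(cds$alignments[[g]])
    Biostrings::writeXStringSet(ss, file.path(paths$cds_dir,
                                              paste0(g, ".fa")))
  }

  selw <- sim$truth$windows[sim$truth$windows$window_id %in%
                              sim$truth$selected_window_ids, , drop = FALSE]
  if (nrow(selw)) {
    grb <- GenomicRanges::GRanges(
      seqnames = selw$chrom,
      ranges = IRanges::IRanges(start = selw$start + 1L, end = selw$end))
    grb$name <- paste0("selected_", selw$window_id)
    rtracklayer::export(grb, paths$truth_bed, format = "bed")
  } else {
    writeLines(character(0), paths$truth_bed)
  }

  truth <- sim$truth
  truth$annotations <- NULL
  truth$windows <- NULL
  truth$per_gene_true_omega <- as.list(truth$per_gene_true_omega)
  jsonlite::write_json(truth, paths$truth_json, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  out <- paths
  out$sim <- sim
  out$cds <- cds
  invisible(out)
}
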