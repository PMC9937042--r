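SEX_CHROM_ALIASES <- c("X", "Y", "MT", "M", "CHRX", "CHRY", "CHRM", "CHRMT")

#' Read a VCF into a genotype matrix
#'
#' Parses diploid GT fields with vcfR, keeping only biallelic SNPs on
#' autosomes. Multiallelic records, indels/non-SNPs, records on sex or
#' mitochondrial chromosomes, and duplicated positions are dropped with a
#' message reporting each count (sex chromosomes are excluded because
#' hemizygosity, effective population size and mutation rate all differ
#' from the autosomes). Missing genotypes (`./.`) become `NA` dosages.
#'
#' @param path VCF file (v4.2, plain or gzipped).
#' @param group_map Named character vector mapping sample -> group, a
#'   data.frame with `sample`/`group` columns, or a path to such a TSV.
#'   `NULL` puts every sample in group `"all"`.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, group_map = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, names(gt)))
  chrom <- fix[, "CHROM"]; ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  pos <- as.integer(fix[, "POS"])

  is_sex <- toupper(chrom) %in% SEX_CHROM_ALIASES
  is_multi <- grepl(",", alt, fixed = TRUE)
  is_snp <- !is_multi & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  keep <- !is_sex & is_snp
  dup <- duplicated(paste(chrom, pos))
  keep <- keep & !dup
  n_drop <- c(sex_chromosome = sum(is_sex), multiallelic = sum(is_multi),
              non_snp = sum(!is_multi & !is_snp & !is_sex),
              duplicate_position = sum(dup & !is_sex & is_snp))
  if (any(n_drop > 0))
    message("read_vcf: dropped ",
            paste(sprintf("%d %s", n_drop[n_drop > 0],
                          gsub("_", " ", names(n_drop)[n_drop > 0])),
                  collapse = ", "), " record(s)")
  chrom <- chrom[keep]; pos <- pos[keep]; ref <- ref[keep]
  alt <- alt[keep]
  gt <- gt[keep, , drop = FALSE]

  # GT string -> alt dosage via a lookup over the observed codes
  codes <- unique(as.vector(gt))
  dose1 <- vapply(codes, function(g) {
    if (is.na(g)) return(NA_integer_)
    a <- strsplit(g, "[/|]")[[1]]
    if (any(a == ".") || !length(a)) return(NA_integer_)
    sum(a != "0")
  }, integer(1))
  geno <- matrix(dose1[match(as.vector(gt), codes)], nrow = nrow(gt),
                 dimnames = list(NULL, colnames(gt)))

  samples <- colnames(geno)
  groups <- resolve_group_map(group_map, samples)
  ord <- order(chrom, pos)
  genotype_matrix(chrom[ord], pos[ord], ref[ord], alt[ord],
                  geno[ord, , drop = FALSE], samples, groups)
}

resolve_group_map <- function(group_map, samples) {
  if (is.null(group_map))
    return(setNames(rep("all", length(samples)), samples))
  if (is.character(group_map) && length(group_map) == 1 &&
      file.exists(group_map))
    group_map <- read_group_map(group_map)
  if (is.data.frame(group_map))
    group_map <- setNames(as.character(group_map$group),
                          group_map$sample)
  missing <- setdiff(names(group_map), samples)
  if (length(missing))
    stop("group map samples not found in VCF: ",
         paste(missing, collapse = ", "))
  group_map
}

#' Read a sample-to-group TSV (columns `sample`, `group`)
#' @param path TSV path.
#' @return Named character vector, sample -> group.
#' @export
read_group_map <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "group") %in% names(d)))
  setNames(as.character(d$group), d$sample)
}

#' Write a genotype matrix as a minimal VCFv4.2 file (GT field only)
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @param contigs Optional named vector of chromosome lengths for contig
#'   header lines.
#' @export
write_vcf <- function(gm, path, contigs = NULL) {
  validate_genotype_matrix(gm)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=mitoscan",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(contigs))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", gm$samples),
                      collapse = "\t"))
  code <- c("0/0", "0/1", "1/1")
  gt <- matrix(ifelse(is.na(gm$geno), "./.", code[gm$geno + 1L]),
               nrow = nrow(gm$geno))
  body <- paste(gm$chrom, gm$pos, ".", gm$ref, gm$alt, ".", "PASS", ".",
                "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read gene annotations (GFF3 or BED) and flag N-interact genes
#'
#' Gene records are imported with rtracklayer; the transcription start
#' site is strand-aware (interval start for `+`, `end - 1` for `-`, both
#' in 0-based coordinates). When a GFF3 contains several records per
#' gene id, the first listed gene record wins. Entries of the N-interact
#' list absent from the annotation are reported in a warning with a
#' count and ignored; matching is case-sensitive.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or BED file of gene records.
#' @param n_interact_list Character vector of gene ids, a data.frame
#'   with `gene_id` (and optionally `category`), or a path to such a
#'   TSV. `NULL` flags nothing.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `tss`, `n_interact`, `category`.
#' @export
read_annotations <- function(path, n_interact_list = NULL) {
  ext <- tolower(tools::file_ext(path))
  gr <- rtracklayer::import(path,
                            format = if (ext == "bed") "bed" else "gff3")
  md <- as.data.frame(gr)
  if ("type" %in% names(md)) {
    keep <- md$type == "gene"
    if (any(keep)) { gr <- gr[keep]; md <- md[keep, , drop = FALSE] }
  }
  id <- md$ID %||% md$name %||% md$gene_id
  if (is.null(id)) stop("no gene identifiers found in ", path)
  strand <- as.character(md$strand)
  strand[!strand %in% c("+", "-")] <- "+"
  start0 <- md$start - 1L                 # GRanges is 1-based closed
  end0 <- md$end
  if (any(end0 <= start0)) stop("gene with end <= start in ", path)
  ann <- data.frame(gene_id = as.character(id), chrom = as.character(md$seqnames),
                    start = start0, end = end0, strand = strand,
                    tss = ifelse(strand == "+", start0, end0 - 1L),
                    stringsAsFactors = FALSE)
  ann <- ann[!duplicated(ann$gene_id), , drop = FALSE]  # first record wins

  ann$n_interact <- FALSE
  ann$category <- "OTHER"
  if (!is.null(n_interact_list)) {
    if (is.character(n_interact_list) && length(n_interact_list) == 1 &&
        file.exists(n_interact_list))
      n_interact_list <- read.delim(n_interact_list,
                                    stringsAsFactors = FALSE)
    if (is.character(n_interact_list))
      n_interact_list <- data.frame(gene_id = n_interact_list,
                                    stringsAsFactors = FALSE)
    hit <- match(n_interact_list$gene_id, ann$gene_id)
    n_miss <- sum(is.na(hit))
    if (n_miss)
      warning(n_miss, " N-interact list entr",
              if (n_miss == 1) "y" else "ies",
              " absent from the annotation; ignored")
    ok <- !is.na(hit)
    ann$n_interact[hit[ok]] <- TRUE
    if ("category" %in% names(n_interact_list))
      ann$category[hit[ok]] <- n_interact_list$category[ok]
  }
  rownames(ann) <- NULL
  ann
}

#' Read a directory of per-gene CDS FASTA alignments
#'
#' @param path Directory of `.fa`/`.fasta` files, one aligned gene each;
#'   the file stem is the gene id.
#' @return Named list of named character vectors (taxon -> sequence).
#' @export
read_cds_dir <- function(path) {
  files <- list.files(path, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  out <- lapply(files, function(f) {
    ss <- Biostrings::readDNAStringSet(f)
    setNames(as.character(ss), names(ss))
  })
  names(out) <- sub("\\.(fa|fasta)$", "", basename(files))
  out
}

#' Write a window/interval table as TSV
#' @param x data.frame.
#' @param path Output path.
#' @export
write_window_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_window_table()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_window_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Export intervals as BED (0-based half-open)
#'
#' @param intervals data.frame with `chrom`, `start`, `end`; an optional
#'   `name_col` becomes BED column 4.
#' @param path Output path.
#' @param name_col Column to use as the BED name field.
#' @export
write_bed <- function(intervals, path, name_col = NULL) {
  cols <- paste(intervals$chrom, format(intervals$start, scientific = FALSE,
                                        trim = TRUE),
                format(intervals$end, scientific = FALSE, trim = TRUE),
                sep = "\t")
  if (!is.null(name_col))
    cols <- paste(cols, intervals[[name_col]], sep = "\t")
  writeLines(cols, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Defaults mirror the scan's study conditions: windows of 30 and 100
#' kb, a pooled minor-allele-frequency cutoff of 0.05 for F_ST, 1,000
#' permutation randomizations, block bootstrap with a block size of 30
#' windows and 1,000 replicates, marginal means over the 1st-90th
#' percentile of gene numbers, 3,000 background genes for the dN/dS
#' comparison, and an omega cap of 5.
#'
#' @param window_sizes Window sizes in bp.
#' @param maf_cutoff Pooled MAF cutoff for per-site F_ST, in [0, 0.5).
#' @param n_permutations Permutation replicates.
#' @param block_size Bootstrap block size, in windows.
#' @param n_bootstrap Bootstrap replicates.
#' @param percentile_range Marginal-mean gene-number percentiles.
#' @param background_genes Background genes sampled for dN/dS.
#' @param omega_cap Genes with estimated omega above this are discarded.
#' @param fst_estimator `"wc"` (Weir-Cockerham 1984) or `"hudson"`.
#' @param seed Integer seed for every resampling stage.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(window_sizes = c(30000, 100000),
                            maf_cutoff = 0.05,
                            n_permutations = 1000,
                            block_size = 30,
                            n_bootstrap = 1000,
                            percentile_range = c(1, 90),
                            background_genes = 3000,
                            omega_cap = 5,
                            fst_estimator = c("wc", "hudson"),
                            seed = 1) {
  stopifnot(maf_cutoff >= 0, maf_cutoff < 0.5, block_size >= 1,
            all(percentile_range >= 0), all(percentile_range <= 100),
            n_permutations >= 1, n_bootstrap >= 2)
  structure(list(window_sizes = window_sizes, maf_cutoff = maf_cutoff,
                 n_permutations = as.integer(n_permutations),
                 block_size = as.integer(block_size),
                 n_bootstrap = as.integer(n_bootstrap),
                 percentile_range = percentile_range,
                 background_genes = as.integer(background_genes),
                 omega_cap = omega_cap,
                 fst_estimator = match.arg(fst_estimator),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}
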