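`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a genotype matrix object
#'
#' @param gm A `genotype_matrix`.
#' @return `gm`, invisibly; stops on violation.
#' @keywords internal
validate_genotype_matrix <- function(gm) {
  stopifnot(
    inherits(gm, "genotype_matrix"),
    length(gm$pos) == nrow(gm$geno),
    length(gm$chrom) == length(gm$pos),
    is.matrix(gm$geno),
    identical(colnames(gm$geno), gm$samples)
  )
  # positions strictly increasing within each chromosome
  for (ch in unique(gm$chrom)) {
    p <- gm$pos[gm$chrom == ch]
    if (any(diff(p) <= 0)) stop("positions not strictly increasing on ", ch)
  }
  if (!all(names(gm$groups) %in% gm$samples))
    stop("group map names samples absent from the genotype matrix")
  bad <- gm$geno[!is.na(gm$geno)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotype dosages must be 0, 1, 2 or NA")
  invisible(gm)
}

#' Construct a genotype matrix
#'
#' Container for biallelic diploid genotypes: alt-allele dosages (0/1/2,
#' NA = missing) at 1-based positions, plus a sample-to-group map.
#'
#' @param chrom Character vector, chromosome per site.
#' @param pos Integer vector, 1-based positions, strictly increasing
#'   within chromosome.
#' @param ref,alt Character vectors of alleles.
#' @param geno Integer matrix, sites x samples.
#' @param samples Sample identifiers (must match `colnames(geno)`).
#' @param groups Named character vector mapping sample -> group label.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, geno, samples, groups) {
  if (is.null(colnames(geno))) colnames(geno) <- samples
  gm <- structure(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         ref = as.character(ref), alt = as.character(alt),
         geno = geno, samples = samples, groups = groups),
    class = "genotype_matrix")
  validate_genotype_matrix(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$pos), "sites x", length(x$samples),
      "samples on", length(unique(x$chrom)), "chromosome(s)\n")
  if (length(x$groups))
    cat("groups:", paste(sprintf("%s (%d)", names(table(x$groups)),
                                 table(x$groups)), collapse = ", "), "\n")
  invisible(x)
}

#' Samples belonging to a group
#' @keywords internal
group_samples <- function(gm, group) {
  s <- names(gm$groups)[gm$groups == group]
  if (!length(s)) stop("no samples in group '", group, "'")
  s
}

#' Per-site allele counts for a set of samples
#'
#' @return List with `n_alt`, `n_called` (allele counts; 2 per called
#'   genotype), `n_het` (heterozygote counts), `n_dip` (called diploids).
#' @keywords internal
site_counts <- function(gm, samples) {
  g <- gm$geno[, samples, drop = FALSE]
  called <- !is.na(g)
  list(n_alt = unname(rowSums(g, na.rm = TRUE)),
       n_called = unname(2L * rowSums(called)),
       n_het = unname(rowSums(g == 1L, na.rm = TRUE)),
       n_dip = unname(rowSums(called)))
}

#' Derive a stream of sub-seeds from one master seed
#'
#' Keeps every derived seed below 2^31 so it is a valid R integer.
#' @keywords internal
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
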