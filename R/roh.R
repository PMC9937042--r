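#' Parameters of the two-state ROH hidden Markov model
#'
#' State AZ (autozygous) emits a heterozygote with probability
#' `het_emission_in_az`; state HW (Hardy-Weinberg) emits a heterozygote
#' with probability `2 p (1 - p)` from the cohort allele frequency at
#' the site. The transition probability between adjacent sites `d` bp
#' apart is `1 - exp(-rate * d)` in each direction. Defaults follow the
#' published defaults of the external ROH caller this module replaces
#' (hard-genotype mode); both states start with probability 1/2.
#'
#' @param rate_into_az Per-bp HW -> AZ transition rate.
#' @param rate_out_of_az Per-bp AZ -> HW transition rate.
#' @param het_emission_in_az Heterozygote emission probability in AZ.
#' @return Object of class `roh_params`.
#' @export
roh_params <- function(rate_into_az = 6.7e-8, rate_out_of_az = 5e-9,
                       het_emission_in_az = 1e-3) {
  stopifnot(rate_into_az > 0, rate_out_of_az > 0,
            het_emission_in_az > 0, het_emission_in_az < 1)
  structure(list(rate_into_az = rate_into_az,
                 rate_out_of_az = rate_out_of_az,
                 het_emission_in_az = het_emission_in_az),
            class = "roh_params")
}

# Viterbi decode for one chromosome of one sample.
# het: logical vector (TRUE = heterozygous), pos: 1-based positions,
# p: cohort alt-allele frequencies. Returns logical vector: AZ state.
viterbi_az <- function(het, pos, p, params) {
  m <- length(het)
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  h_hw <- 2 * p * (1 - p)
  eps <- params$het_emission_in_az
  # emission log-probs: rows = state (1 HW, 2 AZ)
  e_hw <- log(ifelse(het, h_hw, 1 - h_hw))
  e_az <- log(ifelse(het, eps, 1 - eps))
  d <- diff(pos)
  t_in <- 1 - exp(-params$rate_into_az * d)    # HW -> AZ
  t_out <- 1 - exp(-params$rate_out_of_az * d) # AZ -> HW
  v_hw <- log(0.5) + e_hw[1]
  v_az <- log(0.5) + e_az[1]
  back <- matrix(NA_integer_, 2, m)  # 1 = came from HW, 2 = came from AZ
  if (m > 1) for (i in 2:m) {
    # into HW
    from_hw <- v_hw + log(1 - t_in[i - 1])
    from_az <- v_az + log(t_out[i - 1])
    if (from_hw >= from_az) { nv_hw <- from_hw; back[1, i] <- 1L }
    else { nv_hw <- from_az; back[1, i] <- 2L }
    # into AZ
    from_hw2 <- v_hw + log(t_in[i - 1])
    from_az2 <- v_az + log(1 - t_out[i - 1])
    if (from_az2 >= from_hw2) { nv_az <- from_az2; back[2, i] <- 2L }
    else { nv_az <- from_hw2; back[2, i] <- 1L }
    v_hw <- nv_hw + e_hw[i]
    v_az <- nv_az + e_az[i]
  }
  state <- integer(m)
  state[m] <- if (v_hw >= v_az) 1L else 2L   # ties resolve to HW
  if (m > 1) for (i in m:2) state[i - 1] <- back[state[i], i]
  state == 2L
}

#' Call runs of homozygosity for one sample
#'
#' Viterbi decoding of the two-state HMM of [roh_params()] over the
#' sample's called genotypes, using cohort allele frequencies for the
#' Hardy-Weinberg emission. Missing genotypes are skipped and do not
#' break runs. Each maximal AZ run becomes one ROH spanning its first to
#' last site, reported 0-based half-open (`end` = last site position).
#'
#' @param gm A [genotype_matrix()].
#' @param sample Sample id.
#' @param params A [roh_params()].
#' @param allele_freqs Optional per-site alt frequencies; defaults to
#'   the whole-cohort frequencies.
#' @return data.frame with `sample`, `chrom`, `start`, `end`, `length`,
#'   `n_sites`.
#' @export
call_roh <- function(gm, sample, params = roh_params(),
                     allele_freqs = NULL) {
  validate_genotype_matrix(gm)
  if (is.null(allele_freqs)) {
    ct <- site_counts(gm, gm$samples)
    allele_freqs <- ct$n_alt / pmax(ct$n_called, 1L)
  }
  g <- gm$geno[, sample]
  out <- list()
  for (ch in unique(gm$chrom)) {
    sel <- which(gm$chrom == ch & !is.na(g))
    if (length(sel) < 2) next
    az <- viterbi_az(g[sel] == 1L, gm$pos[sel], allele_freqs[sel], params)
    if (!any(az)) next
    r <- rle(az)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i1 <- sel[starts[k]]; i2 <- sel[ends[k]]
      out[[length(out) + 1L]] <- data.frame(
        sample = sample, chrom = ch,
        start = gm$pos[i1] - 1L, end = gm$pos[i2],
        length = gm$pos[i2] - gm$pos[i1] + 1L,
        n_sites = ends[k] - starts[k] + 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      length = numeric(), n_sites = integer()))
  do.call(rbind, out)
}

#' Call ROHs for every sample in the cohort
#'
#' @inheritParams call_roh
#' @param samples Samples to decode (default: all).
#' @return Row-bound data.frame of [call_roh()] results with the
#'   sample's group attached.
#' @export
call_roh_all <- function(gm, params = roh_params(), samples = NULL) {
  samples <- samples %||% gm$samples
  ct <- site_counts(gm, gm$samples)
  freqs <- ct$n_alt / pmax(ct$n_called, 1L)
  rohs <- do.call(rbind, lapply(samples, function(s)
    call_roh(gm, s, params, freqs)))
  if (nrow(rohs)) rohs$group <- unname(gm$groups[rohs$sample])
  rohs
}

#' Attach gene counts and class labels to ROH intervals
#'
#' Uses the same transcription-start-site rule as window
#' classification. ROHs carrying no gene TSS (class `NONGENIC`) are
#' retained in the table but excluded from length models downstream.
#'
#' @param rohs ROH table from [call_roh_all()].
#' @param annotations Annotation data.frame (see [read_annotations()]).
#' @return `rohs` with `gene_number`, `n_interact_gene_number`, `class`.
#' @export
classify_roh <- function(rohs, annotations) {
  if (!nrow(rohs)) {
    rohs$gene_number <- integer(0)
    rohs$n_interact_gene_number <- integer(0)
    rohs$class <- character(0)
    return(rohs)
  }
  classify_intervals(rohs, annotations)
}
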