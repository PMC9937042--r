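# Cached Nei-Gojobori codon tables: per-codon synonymous site counts and
# per-codon-pair average pathway difference counts. Built once per
# session from the standard genetic code.
.ng86_cache <- new.env(parent = emptyenv())

ng86_tables <- function() {
  if (!is.null(.ng86_cache$tables)) return(.ng86_cache$tables)
  codons <- all_codons()
  aa <- Biostrings::GENETIC_CODE[codons]
  nt <- c("A", "C", "G", "T")
  n_codon <- length(codons)

  # synonymous site count per codon: at each position, the fraction of
  # the 3 possible changes that preserve the amino acid; a change to a
  # stop codon counts as nonsynonymous (so syn + nonsyn sites = 3).
  syn_sites <- numeric(n_codon)
  names(syn_sites) <- codons
  for (c1 in codons) {
    if (c1 %in% stop_codons) { syn_sites[c1] <- NA; next }
    s <- 0
    for (pos in 1:3) for (alt in setdiff(nt, substr(c1, pos, pos))) {
      c2 <- c1; substr(c2, pos, pos) <- alt
      if (!(c2 %in% stop_codons) && aa[[c2]] == aa[[c1]]) s <- s + 1 / 3
    }
    syn_sites[c1] <- s
  }

  # pathway-averaged synonymous / nonsynonymous difference counts for
  # every codon pair; pathways through stop codons are excluded (all
  # pathways used if none is stop-free).
  path_counts <- function(c1, c2) {
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    k <- length(pos)
    if (k == 0) return(c(0, 0))
    orders <- if (k == 1) list(pos) else
      lapply(asplit(permutations_of(k), 1), function(o) pos[o])
    tally <- function(order, allow_stop) {
      cur <- c1; sd <- 0; nd <- 0
      for (p in order) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (!allow_stop && nxt %in% stop_codons) return(NULL)
        if (nxt %in% stop_codons || cur %in% stop_codons ||
            aa[[nxt]] != aa[[cur]]) nd <- nd + 1 else sd <- sd + 1
        cur <- nxt
      }
      c(sd, nd)
    }
    res <- Filter(Negate(is.null), lapply(orders, tally,
                                          allow_stop = FALSE))
    if (!length(res)) res <- lapply(orders, tally, allow_stop = TRUE)
    colMeans(do.call(rbind, res))
  }

  sd_mat <- matrix(0, n_codon, n_codon, dimnames = list(codons, codons))
  nd_mat <- sd_mat
  for (i in seq_len(n_codon)) for (j in seq_len(n_codon)) {
    if (i == j) next
    pc <- path_counts(codons[i], codons[j])
    sd_mat[i, j] <- pc[1]; nd_mat[i, j] <- pc[2]
  }
  .ng86_cache$tables <- list(codons = codons, syn_sites = syn_sites,
                             sd = sd_mat, nd = nd_mat)
  .ng86_cache$tables
}

# all permutations of 1..k as a matrix (k <= 3 here)
permutations_of <- function(k) {
  if (k == 1) return(matrix(1))
  sub <- permutations_of(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- setdiff(seq_len(k), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Quality-control a coding-sequence alignment
#'
#' A gene passes when every sequence starts with ATG, the alignment
#' length is a multiple of three, and no sequence contains an internal
#' stop codon (a terminal stop is allowed).
#'
#' @param alignment Named character vector of equal-length sequences.
#' @return One of `"PASS"`, `"NO_ATG"`, `"PREMATURE_STOP"`,
#'   `"LENGTH_NOT_MULTIPLE_OF_3"`.
#' @export
qc_gene <- function(alignment) {
  len <- unique(nchar(alignment))
  if (length(len) != 1) stop("sequences have unequal lengths")
  if (len %% 3 != 0) return("LENGTH_NOT_MULTIPLE_OF_3")
  if (!all(substr(alignment, 1, 3) == "ATG")) return("NO_ATG")
  n_codons <- len / 3
  for (s in alignment) {
    cod <- substring(s, seq(1, len, 3), seq(3, len, 3))
    internal <- cod[seq_len(max(0, n_codons - 1))]
    if (any(internal %in% stop_codons)) return("PREMATURE_STOP")
  }
  "PASS"
}

#' Nei-Gojobori (1986) counting dN/dS for one gene
#'
#' For each pair of sequences: synonymous and nonsynonymous site counts
#' are codon-averaged over the pair; differences are averaged with
#' equal weight over the minimal mutational pathways between differing
#' codons, excluding pathways through stop codons; the proportions
#' `pS = Sd/S` and `pN = Nd/N` receive the Jukes-Cantor correction
#' `d = -3/4 log(1 - 4/3 p)`. The gene's dN and dS are means over all
#' pairs; omega = dN/dS is missing when dS is zero or uncorrectable.
#' Codons containing non-ACGT characters in either sequence of a pair
#' are skipped. A terminal stop codon is ignored.
#'
#' @param alignment Named character vector (>= 2 equal-length
#'   sequences), QC-passing.
#' @param omega_cap Estimates above this get `qc_status`
#'   `"OMEGA_GT_CAP"` (the scan's discard rule).
#' @return List (class `dnds_record`): `dn`, `ds`, `omega`,
#'   `qc_status`, per-pair table.
#' @export
ng86_dnds <- function(alignment, omega_cap = 5) {
  status <- qc_gene(alignment)
  if (status != "PASS")
    return(structure(list(dn = NA_real_, ds = NA_real_,
                          omega = NA_real_, qc_status = status,
                          pairs = NULL), class = "dnds_record"))
  if (length(alignment) < 2) stop("need >= 2 sequences")
  tb <- ng86_tables()
  len <- nchar(alignment[1])
  starts <- seq(1, len, 3)
  cod <- vapply(alignment, function(s)
    substring(s, starts, starts + 2), character(length(starts)))
  # drop a terminal stop column if every sequence ends with one
  if (all(cod[nrow(cod), ] %in% stop_codons))
    cod <- cod[-nrow(cod), , drop = FALSE]
  idx <- matrix(match(cod, tb$codons), nrow(cod))

  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  prs <- combn(seq_along(alignment), 2)
  pair_tab <- data.frame(seq1 = character(0), seq2 = character(0),
                         S = numeric(0), N = numeric(0),
                         Sd = numeric(0), Nd = numeric(0),
                         dn = numeric(0), ds = numeric(0))
  for (j in seq_len(ncol(prs))) {
    i1 <- idx[, prs[1, j]]; i2 <- idx[, prs[2, j]]
    ok <- !is.na(i1) & !is.na(i2) &
      !is.na(tb$syn_sites[i1]) & !is.na(tb$syn_sites[i2])
    S <- sum((tb$syn_sites[i1[ok]] + tb$syn_sites[i2[ok]]) / 2)
    N <- 3 * sum(ok) - S
    Sd <- sum(tb$sd[cbind(i1[ok], i2[ok])])
    Nd <- sum(tb$nd[cbind(i1[ok], i2[ok])])
    ds <- jc(if (S > 0) Sd / S else NA_real_)
    dn <- jc(if (N > 0) Nd / N else NA_real_)
    pair_tab[j, ] <- list(names(alignment)[prs[1, j]],
                          names(alignment)[prs[2, j]],
                          S, N, Sd, Nd, dn, ds)
  }
  dn <- mean(pair_tab$dn, na.rm = TRUE)
  ds <- mean(pair_tab$ds, na.rm = TRUE)
  if (is.nan(dn)) dn <- NA_real_
  if (is.nan(ds)) ds <- NA_real_
  omega <- if (!is.na(ds) && !is.na(dn) && ds > 0) dn / ds
  else if (!is.na(dn) && dn == 0 && sum(pair_tab$Sd) > 0) 0
  # no synonymous divergence and dn > 0: ratio undefined
  else NA_real_
  if (!is.na(omega) && omega > omega_cap) status <- "OMEGA_GT_CAP"
  structure(list(dn = dn, ds = ds, omega = omega, qc_status = status,
                 pairs = pair_tab), class = "dnds_record")
}

#' @export
print.dnds_record <- function(x, ...) {
  cat(sprintf("dN = %.4g, dS = %.4g, omega = %.4g [%s]\n",
              x$dn, x$ds, x$omega, x$qc_status))
  invisible(x)
}

#' Per-gene dN/dS table for a set of alignments
#'
#' @param alignments Named list of alignments (see [read_cds_dir()]).
#' @param n_interact_ids Gene ids to flag as N-interact.
#' @param omega_cap Discard threshold for omega.
#' @return data.frame: `gene_id`, `n_interact`, `dn`, `ds`, `omega`,
#'   `qc_status`. Estimation method recorded in the
#'   `"method"` attribute (counting estimator, not a
#'   maximum-likelihood codon model).
#' @export
dnds_table <- function(alignments, n_interact_ids = character(0),
                       omega_cap = 5) {
  recs <- lapply(alignments, ng86_dnds, omega_cap = omega_cap)
  out <- data.frame(
    gene_id = names(alignments),
    n_interact = names(alignments) %in% n_interact_ids,
    dn = vapply(recs, `[[`, numeric(1), "dn"),
    ds = vapply(recs, `[[`, numeric(1), "ds"),
    omega = vapply(recs, `[[`, numeric(1), "omega"),
    qc_status = vapply(recs, `[[`, character(1), "qc_status"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "method") <- "NG86 pairwise counting with Jukes-Cantor correction"
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic neighbor-joining (via ape) with a deterministic tie-break:
#' taxa are ordered lexicographically before joining, so identical
#' inputs always give identical trees. Fewer than three taxa yield a
#' trivial tree.
#'
#' @param d Symmetric, non-negative distance matrix (or `dist`).
#' @return An `ape::phylo` tree (unrooted for >= 4 taxa).
#' @export
nj_tree <- function(d) {
  m <- as.matrix(d)
  if (any(m < 0) || !isSymmetric(unname(m)))
    stop("distance matrix must be symmetric and non-negative")
  taxa <- sort(rownames(m))
  m <- m[taxa, taxa]
  if (length(taxa) < 2) stop("need >= 2 taxa")
  if (length(taxa) == 2) {
    tr <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);", taxa[1],
                                        m[1, 2] / 2, taxa[2], m[1, 2] / 2))
    return(tr)
  }
  ape::nj(as.dist(m))
}

#' N-interact versus background dN/dS permutation comparison
#'
#' Draws `background_n` genes at random from the QC-passing
#' non-N-interact pool (all of them, with a warning, if the pool is
#' smaller), computes the observed difference of mean omega (N-interact
#' minus background), and runs an upper-tail permutation test over the
#' pooled labels.
#'
#' @param records Table from [dnds_table()].
#' @param background_n Background pool size (3,000 in the full scan).
#' @param B Permutations.
#' @param seed Integer seed.
#' @return A `resampling_result`.
#' @export
dnds_comparison <- function(records, background_n = 3000, B = 1000,
                            seed = 1) {
  ok <- records$qc_status == "PASS" & !is.na(records$omega)
  ni <- records[ok & records$n_interact, , drop = FALSE]
  bg <- records[ok & !records$n_interact, , drop = FALSE]
  if (!nrow(ni) || !nrow(bg))
    stop("need QC-passing records in both classes")
  set.seed(seed)
  if (nrow(bg) > background_n)
    bg <- bg[sample.int(nrow(bg), background_n), , drop = FALSE]
  else if (nrow(bg) < background_n)
    warning("background pool (", nrow(bg), ") smaller than requested ",
            background_n, "; using all")
  permutation_test(c(ni$omega, bg$omega),
                   c(rep(TRUE, nrow(ni)), rep(FALSE, nrow(bg))),
                   tail = "upper", B = B, seed = seed + 1L)
}
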