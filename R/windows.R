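#' Tile chromosomes into fixed-size windows
#'
#' Windows are consecutive 0-based half-open intervals `[0,w), [w,2w), ...`
#' anchored at position 0; a trailing partial window is retained with its
#' true length and flagged (`partial`), since all per-window statistics in
#' this package are per-site averages.
#'
#' @param chromosome_lengths Named numeric vector of chromosome lengths (bp).
#' @param window_size Window size in bp (> 0).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `window_id` (unique integer), `partial`.
#' @examples
#' tile_windows(c(chr1 = 1e5), 3e4)
#' @export
tile_windows <- function(chromosome_lengths, window_size) {
  stopifnot(window_size > 0, length(names(chromosome_lengths)) ==
              length(chromosome_lengths))
  out <- lapply(names(chromosome_lengths), function(ch) {
    len <- chromosome_lengths[[ch]]
    if (len <= 0) return(NULL)
    starts <- seq(0, len - 1, by = window_size)
    ends <- pmin(starts + window_size, len)
    data.frame(chrom = ch, start = starts, end = ends,
               partial = (ends - starts) < window_size,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), window_id = integer(),
                      partial = logical()))
  out$window_id <- seq_len(nrow(out))
  out[, c("chrom", "start", "end", "window_id", "partial")]
}

#' Count gene starts per interval and assign the three-way class
#'
#' An interval is classed `N_INTERACT` if the transcription start site
#' (TSS) of at least one N-interact gene lies inside it,
#' `NON_N_INTERACT` if it holds at least one gene TSS but none from an
#' N-interact gene, and `NONGENIC` if no TSS falls in it. Membership uses
#' the half-open test `start <= tss < end`, so a TSS on a window boundary
#' belongs to the right-hand window. Duplicate gene ids are collapsed;
#' distinct genes sharing a TSS are all counted.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [tile_windows()] or [call_roh()].
#' @param annotations Gene annotation data.frame from
#'   [read_annotations()] (needs `gene_id`, `chrom`, `tss`, `n_interact`).
#' @return `intervals` with added `gene_number`,
#'   `n_interact_gene_number`, `class` columns.
#' @export
classify_intervals <- function(intervals, annotations) {
  ann <- annotations[!duplicated(annotations$gene_id), , drop = FALSE]
  n <- nrow(intervals)
  gene_number <- integer(n)
  ni_number <- integer(n)
  if (n) for (ch in unique(intervals$chrom)) {
    ii <- which(intervals$chrom == ch)
    a <- ann[ann$chrom == ch, , drop = FALSE]
    if (!nrow(a)) next
    iv <- intervals[ii, , drop = FALSE]
    # intervals may overlap (ROHs), so test each one directly
    for (k in seq_along(ii)) {
      inside <- a$tss >= iv$start[k] & a$tss < iv$end[k]
      gene_number[ii[k]] <- sum(inside)
      ni_number[ii[k]] <- sum(inside & a$n_interact)
    }
  }
  intervals$gene_number <- gene_number
  intervals$n_interact_gene_number <- ni_number
  intervals$class <- ifelse(ni_number >= 1L, "N_INTERACT",
                            ifelse(gene_number >= 1L, "NON_N_INTERACT",
                                   "NONGENIC"))
  intervals
}

#' Map each variant site to its window
#'
#' @return Integer vector of `window_id`s (NA where no window covers the
#'   site's chromosome/position).
#' @keywords internal
site_window_index <- function(gm, windows) {
  idx <- rep(NA_integer_, length(gm$pos))
  for (ch in unique(gm$chrom)) {
    sel <- which(gm$chrom == ch)
    w <- windows[windows$chrom == ch, , drop = FALSE]
    if (!nrow(w)) next
    w <- w[order(w$start), , drop = FALSE]
    pos0 <- gm$pos[sel] - 1L          # VCF 1-based -> internal 0-based
    j <- findInterval(pos0, w$start)
    ok <- j >= 1L & pos0 < w$end[pmax(j, 1L)]
    idx[sel[ok]] <- w$window_id[j[ok]]
  }
  idx
}
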