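# Differential accessibility over a union peak set: merge replicate peak
# calls, count fragment ends per peak per condition, and classify peaks as
# lost / gained / independent with a library-size-normalized exact binomial
# test (a documented closed-form stand-in for a count-model fit; replicate
# dispersion modelling is out of scope) at fold change >= 2 and FDR < 0.01.

#' Merge replicate peak sets into a union peak set
#'
#' Single-linkage merging of peaks whose gap is at most `max_gap` bp
#' (touching or overlapping peaks always merge); a merged peak spans the
#' minimum start to the maximum end of its cluster. The result does not
#' depend on input order.
#'
#' @param peak_sets a list of BED3-like data frames (or a single one).
#' @param max_gap maximum gap for merging, bp.
#' @return BED3 data frame of non-overlapping union peaks, sorted.
#' @export
merge_union_peaks <- function(peak_sets, max_gap = 300L) {
  if (is.data.frame(peak_sets)) peak_sets <- list(peak_sets)
  all <- do.call(rbind, lapply(peak_sets, function(p) p[, c("chrom", "start", "end")]))
  if (nrow(all) == 0L) return(all)
  out <- lapply(sort(unique(all$chrom)), function(ch) {
    p <- all[all$chrom == ch, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(start = p$start + 1L, end = p$end),
                          min.gapwidth = max_gap + 1L)
    data.frame(chrom = ch, start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count fragment ends over peaks
#'
#' Counts both endpoints of every fragment (the left end at `start`, the
#' right end at the last covered base `end - 1`) over a non-overlapping peak
#' set, split by the fragment `sample` label. An end at coordinate `e`
#' overlaps a peak iff `start <= e < end`.
#'
#' @param frags fragment data frame with a `sample` column.
#' @param peaks BED3 data frame of non-overlapping peaks (merge first).
#' @return data frame: chrom, start, end, then one integer count column per
#'   sample label.
#' @export
count_read_ends <- function(frags, peaks) {
  if (peaks_overlap(peaks)) {
    stop("peaks overlap; run merge_union_peaks() first")
  }
  samples <- sort(unique(frags$sample))
  res <- peaks[, c("chrom", "start", "end")]
  for (s in samples) res[[s]] <- 0L
  for (ch in unique(peaks$chrom)) {
    pk <- which(peaks$chrom == ch)
    fr <- frags[frags$chrom == ch, , drop = FALSE]
    if (!length(pk) || !nrow(fr)) next
    ends <- c(fr$start, fr$end - 1L)
    smp <- factor(rep(fr$sample, 2L), levels = samples)
    ir_pk <- IRanges::IRanges(start = peaks$start[pk] + 1L, end = peaks$end[pk])
    ir_e <- IRanges::IRanges(start = ends + 1L, width = 1L)
    ov <- IRanges::findOverlaps(ir_e, ir_pk)
    q <- S4Vectors::queryHits(ov); sj <- S4Vectors::subjectHits(ov)
    tab <- table(factor(sj, levels = seq_along(pk)), smp[q])
    for (s in samples) res[pk, s] <- res[pk, s] + as.integer(tab[, s])
  }
  res
}

peaks_overlap <- function(peaks) {
  for (ch in unique(peaks$chrom)) {
    p <- peaks[peaks$chrom == ch, , drop = FALSE]
    ir <- IRanges::IRanges(start = p$start + 1L, end = p$end)
    if (length(IRanges::reduce(ir, min.gapwidth = 0L)) < nrow(p)) return(TRUE)
  }
  FALSE
}

#' Classify differentially accessible peaks
#'
#' For each peak, a two-sided exact binomial test of the control count
#' against the library-size expectation (control library / total library),
#' BH-adjusted across peaks. Fold change is computed on library-size
#' normalized counts with a 0.5 pseudocount on both sides. A peak is
#' `lost` if significantly lower in the perturbed condition with normalized
#' fold change at least `fc_threshold`, `gained` for the converse, otherwise
#' `independent`. Peaks with zero total count are `independent` with FDR 1.
#'
#' @param counts data frame from [count_read_ends()] (chrom, start, end,
#'   then count columns).
#' @param control,perturbed names of the two count columns; default the 4th
#'   and 5th columns.
#' @param fc_threshold minimum normalized fold change (in the labeled
#'   direction) to call a peak differential.
#' @param fdr_threshold BH FDR cutoff.
#' @return the input with added columns `fc` (perturbed/control normalized
#'   ratio), `p`, `fdr`, `label`.
#' @export
classify_differential <- function(counts, control = names(counts)[4L],
                                  perturbed = names(counts)[5L],
                                  fc_threshold = 2, fdr_threshold = 0.01) {
  stopifnot(nrow(counts) >= 1L, control %in% names(counts),
            perturbed %in% names(counts))
  c1 <- counts[[control]]
  c2 <- counts[[perturbed]]
  N1 <- sum(c1); N2 <- sum(c2)
  if (N1 <= 0 || N2 <= 0) stop("both conditions need a positive library size")
  p_expect <- N1 / (N1 + N2)
  n <- c1 + c2
  p <- vapply(seq_along(n), function(i) {
    if (n[i] == 0L) return(1)
    stats::binom.test(c1[i], n[i], p = p_expect)$p.value
  }, numeric(1))
  fc <- ((c2 + 0.5) / N2) / ((c1 + 0.5) / N1)
  fdr <- stats::p.adjust(p, method = "BH")
  fdr[n == 0L] <- 1
  label <- rep("independent", length(n))
  if (is.finite(fc_threshold)) {
    label[fdr < fdr_threshold & fc <= 1 / fc_threshold] <- "lost"
    label[fdr < fdr_threshold & fc >= fc_threshold] <- "gained"
  }
  out <- counts
  out$fc <- fc
  out$p <- p
  out$fdr <- fdr
  out$label <- label
  out
}

#' Hypergeometric set-overlap significance
#'
#' Upper-tail probability `P(X >= overlap)` of drawing at least the observed
#' overlap when `set_b` elements are sampled without replacement from a
#' universe containing `set_a` marked elements.
#'
#' @param set_a,set_b sizes of the two sets.
#' @param overlap observed intersection size.
#' @param universe universe size.
#' @return the hypergeometric upper-tail p-value.
#' @export
overlap_significance <- function(set_a, set_b, overlap, universe) {
  if (set_a > universe || set_b > universe) {
    stop("set sizes exceed the universe")
  }
  if (overlap > min(set_a, set_b) || overlap < max(0, set_a + set_b - universe)) {
    stop("impossible overlap configuration: overlap=", overlap,
         " for |A|=", set_a, ", |B|=", set_b, ", universe=", universe)
  }
  stats::phyper(overlap - 1, set_a, universe - set_a, set_b,
                lower.tail = FALSE)
}

#' Write a differential-accessibility table
#'
#' TSV with header (chrom, start, end, counts, fc, p, fdr, label).
#'
#' @param table output of [classify_differential()].
#' @param path output path.
#' @export
write_diff_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
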