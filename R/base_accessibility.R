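# Single-nucleotide-resolution accessibility: the first base of each
# Tn5-corrected read marks one insertion, so per-base cut-site counts around
# a motif read out how accessible the recognition sequence itself is.

#' Per-base cut-site profile around motif sites
#'
#' Counts corrected Tn5 insertion positions at every base offset in
#' `[-window/2, window/2]` (strand-oriented), averages across sites, and
#' normalizes per million cuts in the library.
#'
#' @param cuts cut-site data frame from [tn5_correct()]; must carry the
#'   `tn5_corrected` attribute.
#' @param sites site data frame.
#' @param window total window, bp; the profile has `window + 1` offsets.
#' @param condition label recorded on the profile.
#' @return a `base_profile`: list with `offsets`, `counts` (per-base mean
#'   across sites, per million cuts), `condition`, `library_size`, `window`.
#' @export
cutsite_base_profile <- function(cuts, sites, window = 200L,
                                 condition = "NA") {
  if (!isTRUE(attr(cuts, "tn5_corrected"))) {
    stop("cut sites are not Tn5-corrected; run tn5_correct() first")
  }
  stopifnot(nrow(sites) > 0, nrow(cuts) > 0)
  half <- window %/% 2L
  n_off <- window + 1L
  counts <- numeric(n_off)
  for (ch in unique(sites$chrom)) {
    si <- sites[sites$chrom == ch, , drop = FALSE]
    pos <- cuts$pos[cuts$chrom == ch]
    if (!length(pos) || !nrow(si)) next
    win <- IRanges::IRanges(start = si$center - half + 1L,
                            end = si$center + half + 1L)
    pts <- IRanges::IRanges(start = pos + 1L, width = 1L)
    ov <- IRanges::findOverlaps(pts, win)
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    off <- pos[q] - si$center[s]
    off <- ifelse(si$strand[s] == "-", -off, off)
    off <- pmax(pmin(off, half), -half)
    counts <- counts + tabulate(off + half + 1L, nbins = n_off)
  }
  structure(list(
    offsets = seq(-half, half),
    counts = (counts / nrow(sites)) / (nrow(cuts) / 1e6),
    condition = condition, library_size = nrow(cuts), window = window
  ), class = "base_profile")
}

#' Accessibility change at the motif core
#'
#' Log2 ratio of mean normalized cut counts in the motif core
#' (center +/- `core` bp) between a perturbed and a control profile.
#' Negative values mean the motif became less accessible. If either core
#' mean is zero the ratio is undefined and flagged rather than returned as
#' infinite.
#'
#' @param control,perturbed `base_profile`s with identical windows.
#' @param core half-width of the motif core, bp.
#' @return list with `log2_ratio` (NA when undefined), `undefined` flag, and
#'   the two core means.
#' @export
motif_accessibility_change <- function(control, perturbed, core = 10L) {
  if (control$window != perturbed$window) {
    stop("profiles have different windows (",
         control$window, " vs ", perturbed$window, ")")
  }
  sel <- abs(control$offsets) <= core
  m_ctrl <- mean(control$counts[sel])
  m_pert <- mean(perturbed$counts[sel])
  if (m_ctrl == 0 || m_pert == 0) {
    return(list(log2_ratio = NA_real_, undefined = TRUE,
                control_core = m_ctrl, perturbed_core = m_pert))
  }
  list(log2_ratio = log2(m_pert / m_ctrl), undefined = FALSE,
       control_core = m_ctrl, perturbed_core = m_pert)
}

#' Export a base profile as a table
#'
#' @param p a `base_profile`.
#' @param path optional TSV output path (offset, count).
#' @return data frame with columns `offset` and `count`.
#' @export
base_profile_table <- function(p, path = NULL) {
  df <- data.frame(offset = p$offsets, count = p$counts)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
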