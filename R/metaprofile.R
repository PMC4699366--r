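# Fragment-center metaprofiles around motif anchors.
#
# Pipeline: bin fragment midpoints in a 1-kb window (100 x 10-bp bins),
# normalize to the first five (background) bins, rescale across conditions
# with an affine transform fitted on CTCF anchor profiles, smooth with a
# cubic smoothing spline, then localize the flanking mononucleosome summits
# and estimate compaction as the change in inter-summit distance.

#' Metaprofile parameters
#'
#' @param window total window width centered on the anchor, bp.
#' @param n_bins number of bins; `window` must be divisible by `n_bins`
#'   (defaults give 10-bp bins).
#' @param n_background_bins leading bins treated as background tail.
#' @param smoothing_parameter `spar` for the cubic smoothing spline, in
#'   (0, 1]; larger is smoother. Profiles from sparse libraries are smoothed
#'   with values in 0.3-0.5.
#' @param summit_search_range bp interval on each flank searched for the
#'   mononucleosome summit.
#' @return list with class `profile_params`.
#' @export
profile_params <- function(window = 1000L, n_bins = 100L,
                           n_background_bins = 5L,
                           smoothing_parameter = 0.4,
                           summit_search_range = c(60, 400)) {
  stopifnot(window %% n_bins == 0, n_background_bins < n_bins / 2,
            length(summit_search_range) == 2,
            summit_search_range[1] < summit_search_range[2])
  structure(list(
    window = as.integer(window), n_bins = as.integer(n_bins),
    n_background_bins = as.integer(n_background_bins),
    smoothing_parameter = smoothing_parameter,
    summit_search_range = summit_search_range,
    bin_width = as.integer(window / n_bins)
  ), class = "profile_params")
}

new_meta_profile <- function(bin_centers, signal, size_class, condition,
                             n_sites, n_fragments, params,
                             normalized = FALSE, smoothed = FALSE) {
  structure(list(
    bin_centers = bin_centers, signal = signal, size_class = size_class,
    condition = condition, normalized = normalized, smoothed = smoothed,
    n_sites = n_sites, n_fragments = n_fragments, params = params
  ), class = "meta_profile")
}

#' @export
print.meta_profile <- function(x, ...) {
  cat("<meta_profile>", x$size_class, "/", x$condition, "\n")
  cat("  bins:", length(x$signal), "x", x$params$bin_width, "bp;",
      "sites:", x$n_sites, "; fragments:", x$n_fragments, "\n")
  cat("  normalized:", x$normalized, "; smoothed:", x$smoothed, "\n")
  invisible(x)
}

# Usable sites: the full window must fit on the chromosome. chrom_length, if
# known, bounds the right edge; sites too close to an end are dropped.
usable_sites <- function(sites, window) {
  half <- window %/% 2L
  ok <- sites$center - half >= 0L
  L <- attr(sites, "chrom_length")
  if (!is.null(L)) ok <- ok & (sites$center + half <= L)
  if (!all(ok)) {
    warning(sum(!ok), " site(s) within window/2 of a chromosome end dropped")
  }
  s <- sites[ok, , drop = FALSE]
  if (nrow(s) == 0L) stop("no usable sites: all within window/2 of an end")
  s
}

# Strand-oriented offset of positions relative to each matched site.
# Minus-strand sites negate the genomic offset; binning is floor-based with
# the single out-of-range value +window/2 clamped into the last bin so a
# position exactly at the anchor lands in the same bin on either strand.
oriented_bin <- function(offset, minus, window, bin_width) {
  off <- ifelse(minus, -offset, offset)
  idx <- (off + window %/% 2L) %/% bin_width + 1L
  pmin(idx, window %/% bin_width)
}

# Match point coordinates to site windows; returns a data frame of
# (query row, site row, genomic offset). Interval overlap is used so each
# point can hit several nearby sites. The window covers offsets
# [-half_window, half_window - 1] for plus-strand orientation plus the
# single extra coordinate +half_window used by minus-strand sites.
match_positions <- function(pos, chroms, sites, half_window) {
  out_row <- integer(0); out_site <- integer(0); out_off <- integer(0)
  for (ch in unique(sites$chrom)) {
    si <- which(sites$chrom == ch)
    pi <- which(chroms == ch)
    if (!length(si) || !length(pi)) next
    win <- IRanges::IRanges(start = sites$center[si] - half_window + 1L,
                            end = sites$center[si] + half_window)
    pts <- IRanges::IRanges(start = pos[pi] + 1L, width = 1L)
    ov <- IRanges::findOverlaps(pts, win)
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    out_row <- c(out_row, pi[q])
    out_site <- c(out_site, si[s])
    out_off <- c(out_off, pos[pi][q] - sites$center[si[s]])
  }
  data.frame(row = out_row, site = out_site, offset = out_off)
}

#' Fragment-center metaprofile
#'
#' Counts fragment midpoints per bin in a window centered on each anchor
#' site, orienting offsets by site strand, and averages the per-bin counts
#' across sites.
#'
#' @param frags fragment data frame.
#' @param sites site data frame ([as_site_set()]); sites whose window would
#'   run off a chromosome end are dropped with a warning.
#' @param params a [profile_params()].
#' @param size_class label recorded on the profile (set it to the filter you
#'   applied, e.g. `"mono"`).
#' @param condition label recorded on the profile; defaults to the fragment
#'   sample label.
#' @return a `meta_profile`.
#' @export
fragment_center_profile <- function(frags, sites, params = profile_params(),
                                    size_class = "all", condition = NULL) {
  stopifnot(nrow(sites) > 0)
  if (is.null(condition)) {
    condition <- if (nrow(frags)) frags$sample[1L] else "NA"
  }
  sites <- usable_sites(sites, params$window)
  half <- params$window %/% 2L
  mids <- fragment_midpoints(frags)
  m <- match_positions(mids, frags$chrom, sites, half)
  idx <- oriented_bin(m$offset, sites$strand[m$site] == "-",
                      params$window, params$bin_width)
  counts <- tabulate(idx, nbins = params$n_bins)
  bin_centers <- -half + params$bin_width * (seq_len(params$n_bins) - 0.5)
  new_meta_profile(bin_centers, counts / nrow(sites), size_class, condition,
                   n_sites = nrow(sites), n_fragments = nrow(frags),
                   params = params)
}

#' Normalize a metaprofile to its background bins
#'
#' Divides every bin by the mean of the first `n_background_bins` bins so
#' the background signal is one. Idempotent: an already-normalized profile
#' is returned unchanged.
#'
#' @param p a `meta_profile`.
#' @param params a [profile_params()]; defaults to the profile's own.
#' @return normalized `meta_profile`.
#' @export
normalize_background <- function(p, params = NULL) {
  if (isTRUE(p$normalized)) return(p)
  if (is.null(params)) params <- p$params
  bg <- mean(p$signal[seq_len(params$n_background_bins)])
  if (bg <= 0) {
    stop("background bins have zero mean signal; simulate/collect more ",
         "fragments or sites (a pseudocount is deliberately not applied)")
  }
  p$signal <- p$signal / bg
  p$normalized <- TRUE
  p
}

#' Affine cross-condition rescaling anchored on a reference feature
#'
#' Library signal-to-noise differs between conditions; profiles at a stable
#' reference feature (CTCF anchors) are used to fit a linear transform
#' `scale * x + offset` mapping one condition's profile onto the other's by
#' ordinary least squares over all bins. The same transform is then applied
#' to profiles at the feature of interest.
#'
#' @param reference_profile reference-condition profile at CTCF-like sites.
#' @param other_profile same feature and size class, other condition.
#' @return a `linear_transform` (list with `scale` and `offset`).
#' @export
fit_reference_transform <- function(reference_profile, other_profile) {
  stopifnot(length(reference_profile$signal) == length(other_profile$signal))
  if (!identical(reference_profile$size_class, other_profile$size_class)) {
    stop("profiles must share a size class to be rescaled")
  }
  x <- other_profile$signal
  y <- reference_profile$signal
  if (stats::sd(x) == 0) {
    stop("other profile is constant; scale is unidentifiable")
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  structure(list(offset = unname(fit$coefficients[1L]),
                 scale = unname(fit$coefficients[2L])),
            class = "linear_transform")
}

#' @rdname fit_reference_transform
#' @param p profile to transform.
#' @param t fitted `linear_transform`.
#' @export
apply_transform <- function(p, t) {
  stopifnot(inherits(t, "linear_transform"), t$scale != 0)
  p$signal <- t$scale * p$signal + t$offset
  p
}

#' Smooth a metaprofile with a cubic smoothing spline
#'
#' Fits `stats::smooth.spline` to the binned signal and evaluates it back at
#' the bin centers. Smoothing strength is `spar` with its usual monotone
#' meaning (larger is smoother).
#'
#' @param p a `meta_profile`.
#' @param params a [profile_params()]; `smoothing_parameter` must be in
#'   (0, 1].
#' @return smoothed `meta_profile`.
#' @export
smooth_profile <- function(p, params = NULL) {
  if (is.null(params)) params <- p$params
  spar <- params$smoothing_parameter
  if (spar <= 0 || spar > 1) {
    stop("smoothing_parameter must be in (0, 1], got ", spar)
  }
  stopifnot(length(p$signal) >= 10L)
  fit <- stats::smooth.spline(p$bin_centers, p$signal, spar = spar)
  p$signal <- stats::predict(fit, p$bin_centers)$y
  p$smoothed <- TRUE
  p
}

#' Locate flanking nucleosome summits
#'
#' Finds, on each flank of the anchor, the maximum of the (normalized,
#' smoothed) mononucleosome profile within the summit search range, refined
#' below bin resolution by quadratic interpolation through the maximum bin
#' and its two neighbours. Ties break toward the position farther from the
#' anchor.
#'
#' @param p a normalized, smoothed `meta_profile`.
#' @param params a [profile_params()].
#' @return a `summit_pair`: list with `left` (< 0), `right` (> 0) offsets in
#'   bp and `inter_summit_distance = right - left`.
#' @export
locate_summits <- function(p, params = NULL) {
  if (is.null(params)) params <- p$params
  if (!isTRUE(p$normalized) || !isTRUE(p$smoothed)) {
    stop("locate_summits expects a normalized, smoothed profile")
  }
  r <- params$summit_search_range
  right <- flank_summit(p, which(p$bin_centers >= r[1] & p$bin_centers <= r[2]),
                        anchor_side = 1)
  left <- flank_summit(p, which(p$bin_centers <= -r[1] & p$bin_centers >= -r[2]),
                       anchor_side = -1)
  structure(list(left = left, right = right,
                 inter_summit_distance = right - left),
            class = "summit_pair")
}

flank_summit <- function(p, idx, anchor_side) {
  stopifnot(length(idx) >= 3L)
  sig <- p$signal
  n <- length(sig)
  is_locmax <- vapply(idx, function(j) {
    lo <- if (j > 1L) sig[j - 1L] else -Inf
    hi <- if (j < n) sig[j + 1L] else -Inf
    sig[j] >= lo && sig[j] >= hi && (sig[j] > lo || sig[j] > hi)
  }, logical(1))
  cand <- idx[is_locmax]
  if (length(cand) == 0L) {
    stop("no interior local maximum in the summit search range ",
         "(profile monotone on this flank)")
  }
  best <- cand[sig[cand] == max(sig[cand])]
  # ties toward the position farther from the anchor
  j <- best[which.max(abs(p$bin_centers[best]))]
  if (j == idx[1L] || j == idx[length(idx)]) {
    warning("summit at a search-range boundary; range may truncate the peak")
  }
  refine_quadratic(p, j)
}

# 3-point quadratic vertex through the max bin and neighbours; half-bin clamp
# keeps the refinement inside the winning bin.
refine_quadratic <- function(p, j) {
  sig <- p$signal
  bw <- p$params$bin_width
  if (j == 1L || j == length(sig)) return(p$bin_centers[j])
  ym <- sig[j - 1L]; y0 <- sig[j]; yp <- sig[j + 1L]
  denom <- ym - 2 * y0 + yp
  delta <- if (denom == 0) 0 else 0.5 * (ym - yp) / denom
  delta <- max(min(delta, 0.5), -0.5)
  p$bin_centers[j] + delta * bw
}

#' Estimate nucleosome compaction between conditions
#'
#' Compaction is the reduction of the inter-summit distance of the flanking
#' mononucleosome signal: `inter_summit(control) - inter_summit(perturbed)`.
#' Per-flank shifts are reported signed toward the anchor (positive = the
#' summit moved toward the motif center).
#'
#' @param control,perturbed normalized, smoothed mononucleosome profiles
#'   built with the same parameters and scaled to a common reference.
#' @param params a [profile_params()].
#' @return list with `per_flank_shift` (named left/right, bp) and
#'   `total_compaction` (bp), plus both summit pairs.
#' @export
estimate_compaction <- function(control, perturbed, params = NULL) {
  if (is.null(params)) params <- control$params
  sc <- locate_summits(control, params)
  sp <- locate_summits(perturbed, params)
  shift_left <- sp$left - sc$left      # left summit moving right = toward anchor
  shift_right <- sc$right - sp$right   # right summit moving left = toward anchor
  list(
    per_flank_shift = c(left = shift_left, right = shift_right),
    total_compaction = sc$inter_summit_distance - sp$inter_summit_distance,
    control_summits = sc, perturbed_summits = sp
  )
}

#' Coverage metaplot of read or cut-site positions
#'
#' Bins record positions (10-bp bins by default) around anchor sites,
#' averages per-bin counts across sites, and normalizes to library size
#' (counts per million records). For stranded BED records the position is
#' the 5' coordinate (start for `+`, end - 1 for `-`); for cut-site sets it
#' is the corrected insertion position.
#'
#' @param records BED data frame or cut-site data frame ([tn5_correct()]).
#' @param sites site data frame.
#' @param bin bin width, bp.
#' @param window total window, bp.
#' @return a `meta_profile` (size_class `"coverage"`), library-normalized.
#' @export
coverage_metaplot <- function(records, sites, bin = 10L, window = 1000L) {
  stopifnot(nrow(sites) > 0)
  if (nrow(records) == 0L) stop("no records to profile")
  if ("pos" %in% names(records)) {
    pos <- records$pos
  } else if ("strand" %in% names(records)) {
    pos <- ifelse(records$strand == "-", records$end - 1L, records$start)
  } else {
    pos <- records$start
  }
  params <- profile_params(window = window, n_bins = window %/% bin)
  sites <- usable_sites(sites, window)
  m <- match_positions(pos, records$chrom, sites, window %/% 2L)
  idx <- oriented_bin(m$offset, sites$strand[m$site] == "-", params$window,
                      params$bin_width)
  counts <- tabulate(idx, nbins = params$n_bins)
  signal <- (counts / nrow(sites)) / (nrow(records) / 1e6)
  half <- window %/% 2L
  bin_centers <- -half + params$bin_width * (seq_len(params$n_bins) - 0.5)
  new_meta_profile(bin_centers, signal, "coverage",
                   condition = if ("sample" %in% names(records))
                     records$sample[1L] else "NA",
                   n_sites = nrow(sites), n_fragments = nrow(records),
                   params = params, normalized = FALSE)
}

#' Export a metaprofile as a two-column table
#'
#' @param p a `meta_profile`.
#' @param path optional output path (TSV with header offset/signal).
#' @return data frame with columns `offset` and `signal`.
#' @export
profile_table <- function(p, path = NULL) {
  df <- data.frame(offset = p$bin_centers, signal = p$signal)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}

#' Full compaction pipeline between two conditions
#'
#' Convenience wrapper running the complete analysis: filter mononucleosome
#' fragments, build fragment-center metaprofiles at the target sites and at
#' CTCF-like reference sites for both conditions, background-normalize,
#' rescale the perturbed condition onto the control via the reference
#' transform, smooth, and estimate compaction.
#'
#' @param frags_control,frags_perturbed fragment data frames.
#' @param target_sites anchor sites of interest (e.g. p63-like).
#' @param reference_sites stable reference anchors (CTCF-like).
#' @param params a [profile_params()].
#' @return the [estimate_compaction()] result, plus the two final profiles.
#' @export
run_compaction_analysis <- function(frags_control, frags_perturbed,
                                    target_sites, reference_sites,
                                    params = profile_params()) {
  mono_c <- filter_by_length(frags_control, preset = "mono")
  mono_p <- filter_by_length(frags_perturbed, preset = "mono")
  prof <- function(fr, sites, cls) {
    normalize_background(
      fragment_center_profile(fr, sites, params, size_class = "mono",
                              condition = cls), params)
  }
  tgt_c <- prof(mono_c, target_sites, "control")
  tgt_p <- prof(mono_p, target_sites, "perturbed")
  ref_c <- prof(mono_c, reference_sites, "control")
  ref_p <- prof(mono_p, reference_sites, "perturbed")
  tr <- fit_reference_transform(ref_c, ref_p)
  tgt_p <- apply_transform(tgt_p, tr)
  tgt_c <- smooth_profile(tgt_c, params)
  tgt_p <- smooth_profile(tgt_p, params)
  res <- estimate_compaction(tgt_c, tgt_p, params)
  res$control_profile <- tgt_c
  res$perturbed_profile <- tgt_p
  res$reference_transform <- tr
  res
}
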