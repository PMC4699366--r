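# In-code fixtures shared across test files.

# Site set with given centers on one chromosome; 10-bp intervals so the
# center is strictly inside.
tiny_sites <- function(centers, strand = "+", site_class = "p63-like",
                       chrom = "chrT", chrom_length = NULL) {
  bed <- data.frame(
    chrom = chrom, start = centers - 5L, end = centers + 5L,
    name = paste0("s", seq_along(centers)), score = 0,
    strand = rep_len(strand, length(centers)),
    stringsAsFactors = FALSE
  )
  as_site_set(bed, site_class = site_class, chrom_length = chrom_length)
}

# Fragment table from explicit coordinates.
make_frags <- function(starts, ends, sample = "s1", chrom = "chrT") {
  data.frame(
    chrom = chrom, start = as.integer(starts), end = as.integer(ends),
    name = paste0("f", seq_along(starts)), sample = sample,
    length = as.integer(ends - starts), stringsAsFactors = FALSE
  )
}

# Hand-built metaprofile (for operations downstream of binning).
manual_profile <- function(signal, params = profile_params(),
                           normalized = FALSE, smoothed = FALSE,
                           size_class = "mono", condition = "test") {
  half <- params$window %/% 2L
  structure(list(
    bin_centers = -half + params$bin_width * (seq_along(signal) - 0.5),
    signal = signal, size_class = size_class, condition = condition,
    normalized = normalized, smoothed = smoothed,
    n_sites = 1L, n_fragments = NA_integer_, params = params
  ), class = "meta_profile")
}

# Profile with Gaussian bumps at the given offsets (plus flat baseline),
# marked normalized + smoothed so summit calling accepts it.
bump_profile <- function(bump_at, sd = 30, params = profile_params()) {
  half <- params$window %/% 2L
  x <- -half + params$bin_width * (seq_len(params$n_bins) - 0.5)
  sig <- 1 + Reduce(`+`, lapply(bump_at, function(b) {
    2 * exp(-(x - b)^2 / (2 * sd^2))
  }))
  manual_profile(sig, params, normalized = TRUE, smoothed = TRUE)
}

# Brute-force fragment-center binning oracle: per-site, per-fragment double
# loop with the package's stated conventions (floor((start+end)/2) midpoint,
# strand negation, floor binning with last-bin clamp).
oracle_center_profile <- function(frags, sites, params) {
  half <- params$window %/% 2L
  bw <- params$bin_width
  counts <- numeric(params$n_bins)
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(nrow(frags))) {
      if (frags$chrom[j] != sites$chrom[i]) next
      mid <- (frags$start[j] + frags$end[j]) %/% 2L
      d <- mid - sites$center[i]
      if (d < -half || d >= half) next
      off <- if (sites$strand[i] == "-") -d else d
      k <- min((off + half) %/% bw + 1L, params$n_bins)
      counts[k] <- counts[k] + 1
    }
  }
  counts / nrow(sites)
}

# Two-sided exact binomial p-value by direct tail summation (the minimum-
# likelihood method), independent of stats::binom.test.
oracle_binom_p <- function(x, n, p) {
  d <- stats::dbinom(0:n, n, p)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

default_fixture_seed <- 42L
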