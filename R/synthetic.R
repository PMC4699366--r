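# Synthetic Tn5 fragment libraries with planted nucleosome geometry.
#
# The generator emulates what the downstream analyses assume about real
# ATAC-seq at a lineage TF's motif sites: a nucleosome-free region over the
# motif, phased flanking nucleosomes whose dyads sit a fixed distance from
# the motif center, the 9-bp staggered double insertion of the Tn5 dimer,
# and condition-specific perturbations (reduced NFR signal, per-flank dyad
# shift toward the motif, increased phasing jitter). CTCF-like anchor sites
# are never perturbed, mirroring their empirical stability.

#' Genome model for simulation
#'
#' @param chrom_name chromosome name.
#' @param chrom_length chromosome length in bp; all generated coordinates lie
#'   in `[0, chrom_length)`.
#' @return a list with class `genome_model`.
#' @export
genome_model <- function(chrom_name = "chrS", chrom_length = 2e6) {
  stopifnot(chrom_length > 0)
  structure(list(chrom_name = chrom_name,
                 chrom_length = as.integer(chrom_length)),
            class = "genome_model")
}

#' Condition profiles for fragment simulation
#'
#' A condition profile fixes the fragment class mixture and the planted
#' nucleosome geometry at perturbed (p63-like) sites:
#'
#' * `CTRL`: 35% nucleosome-free, 45% mononucleosome, flanking dyads 185 bp
#'   from the motif center, no shift, 20 bp placement jitter.
#' * `BAFi` (chromatin-remodeler loss): NFR weight drops to 14%, each
#'   flanking dyad moves 20 bp toward the motif (total planted compaction
#'   40 bp), jitter rises to 35 bp.
#' * `p63i` (TF loss): NFR weight 14%, per-flank shift alternating 12/13 bp
#'   across sites so the mean total compaction is exactly 25 bp, jitter 35 bp.
#'
#' @param name `"CTRL"`, `"BAFi"`, `"p63i"`, or a custom label (custom labels
#'   start from CTRL defaults).
#' @param nfr_weight,mono_weight fragment class fractions (background is the
#'   remainder, placed uniformly genome-wide).
#' @param dyad_distance bp from motif center to the first flanking dyad.
#' @param dyad_shift per-flank displacement toward the motif center, bp. A
#'   non-integer value is realized by alternating `floor` and `ceiling`
#'   deterministically across sites, so the planted mean is exact.
#' @param phasing_jitter_sd SD of dyad placement noise, bp.
#' @param depth_factor library-size multiplier.
#' @return a list with class `condition_profile`.
#' @export
condition_profile <- function(name = "CTRL",
                              nfr_weight = NULL, mono_weight = NULL,
                              dyad_distance = 185, dyad_shift = NULL,
                              phasing_jitter_sd = NULL, depth_factor = 1.0) {
  defaults <- switch(name,
    BAFi = list(nfr = 0.14, shift = 20, jitter = 35),
    p63i = list(nfr = 0.14, shift = 12.5, jitter = 35),
    list(nfr = 0.35, shift = 0, jitter = 20)
  )
  nfr_weight <- if (is.null(nfr_weight)) defaults$nfr else nfr_weight
  mono_weight <- if (is.null(mono_weight)) 0.45 else mono_weight
  dyad_shift <- if (is.null(dyad_shift)) defaults$shift else dyad_shift
  phasing_jitter_sd <-
    if (is.null(phasing_jitter_sd)) defaults$jitter else phasing_jitter_sd
  stopifnot(
    nfr_weight >= 0, mono_weight >= 0, nfr_weight + mono_weight <= 1,
    dyad_shift < dyad_distance, phasing_jitter_sd >= 0, depth_factor > 0
  )
  structure(list(
    name = name, nfr_weight = nfr_weight, mono_weight = mono_weight,
    background_weight = 1 - nfr_weight - mono_weight,
    dyad_distance = dyad_distance, dyad_shift = dyad_shift,
    phasing_jitter_sd = phasing_jitter_sd, depth_factor = depth_factor
  ), class = "condition_profile")
}

#' Fragment length model
#'
#' Size classes follow the empirical ATAC-seq fragment-length distribution:
#' sub-100 bp nucleosome-free fragments, mononucleosome fragments around
#' 210 bp truncated to the 180-247 bp analysis window, and dinucleosome
#' fragments around 400 bp.
#'
#' @param nfr_range inclusive uniform range for NFR fragment lengths, bp.
#' @param mono_mean,mono_sd,mono_range truncated-normal mononucleosome model.
#' @param di_mean,di_sd,di_range truncated-normal dinucleosome model.
#' @return a list with class `fragment_length_model`.
#' @export
fragment_length_model <- function(nfr_range = c(30L, 99L),
                                  mono_mean = 210, mono_sd = 15,
                                  mono_range = c(180L, 247L),
                                  di_mean = 400, di_sd = 30,
                                  di_range = c(315L, 473L)) {
  structure(list(
    nfr_range = nfr_range,
    mono_mean = mono_mean, mono_sd = mono_sd, mono_range = mono_range,
    di_mean = di_mean, di_sd = di_sd, di_range = di_range
  ), class = "fragment_length_model")
}

# Rounded normal draws resampled into [lo, hi]; lengths always in range.
rtrunc_norm_int <- function(n, mean, sd, lo, hi) {
  x <- round(stats::rnorm(n, mean, sd))
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0L) {
    x[bad] <- round(stats::rnorm(length(bad), mean, sd))
    bad <- which(x < lo | x > hi)
  }
  as.integer(x)
}

#' Generate motif-like anchor sites
#'
#' Places `n_sites` anchors on the simulated chromosome with pairwise center
#' distance at least `min_spacing`, strands uniform at random. An `edge_margin`
#' keeps every site far enough from the chromosome ends for 1-kb profile and
#' V-plot windows.
#'
#' @param genome a [genome_model()].
#' @param n_sites number of anchors.
#' @param site_class `"p63-like"` or `"CTCF-like"`.
#' @param min_spacing minimum pairwise center distance, bp.
#' @param seed integer RNG seed; output is deterministic given the seed.
#' @param edge_margin bp kept free at each chromosome end.
#' @return a site data frame as from [as_site_set()].
#' @export
generate_sites <- function(genome, n_sites, site_class = c("p63-like", "CTCF-like"),
                           min_spacing = 2000, seed = 1,
                           edge_margin = 1100) {
  site_class <- match.arg(site_class)
  L <- genome$chrom_length
  span <- L - 2 * edge_margin - (n_sites - 1) * min_spacing
  if (n_sites * min_spacing >= L || span <= 0) {
    stop("cannot place ", n_sites, " sites with spacing ", min_spacing,
         " bp on a ", L, " bp chromosome")
  }
  set.seed(seed)
  u <- sort(stats::runif(n_sites, 0, span))
  centers <- as.integer(round(u)) + edge_margin +
    (seq_len(n_sites) - 1L) * as.integer(min_spacing)
  strands <- sample(c("+", "-"), n_sites, replace = TRUE)
  bed <- data.frame(
    chrom = genome$chrom_name,
    start = centers - 5L, end = centers + 5L,
    name = sprintf("%s_%04d", sub("-like", "", site_class), seq_len(n_sites)),
    score = 0, strand = strands, stringsAsFactors = FALSE
  )
  as_site_set(bed, site_class = site_class, chrom_length = L)
}

# Per-site integer shift: alternate floor/ceiling for fractional shifts so
# the planted mean is exact without fractional coordinates.
site_shifts <- function(dyad_shift, n) {
  lo <- floor(dyad_shift)
  if (lo == dyad_shift) return(rep(as.integer(lo), n))
  rep_len(c(as.integer(lo), as.integer(ceiling(dyad_shift))), n)
}

#' Simulate an ATAC-seq fragment library at anchor sites
#'
#' For each site, fragments are drawn from the condition's class mixture:
#'
#' * nucleosome-free fragments centered Normal(motif center, 25 bp);
#' * mononucleosome fragments centered on a planted flanking dyad (left or
#'   right, equiprobable) perturbed by `phasing_jitter_sd`; dyads sit
#'   `dyad_distance - dyad_shift` bp from the center, the shift applied only
#'   at p63-like sites — CTCF-like sites always use unperturbed CTRL weights
#'   and geometry;
#' * background fragments with uniform starts genome-wide and lengths from
#'   the full NFR/mono/dinucleosome mixture.
#'
#' Each fragment also emits the four uncorrected read starts of its two Tn5
#' insertion events (plus and minus strand per event, sharing an event id in
#' the BED name): the two per-event coordinates are 9 bp apart and collapse
#' onto the physical insertion center under the +4/-5 correction.
#'
#' @param sites site data frame from [generate_sites()] / [as_site_set()].
#' @param profile a [condition_profile()].
#' @param lengths a [fragment_length_model()].
#' @param frags_per_site expected fragments per site (times `depth_factor`).
#' @param seed integer RNG seed.
#' @return list with elements `fragments` (fragment data frame), `reads`
#'   (BED6 read starts), and `truth` (per-site planted dyad positions).
#' @export
simulate_fragments <- function(sites, profile, lengths = fragment_length_model(),
                               frags_per_site = 100, seed = 1) {
  stopifnot(nrow(sites) > 0, frags_per_site > 0)
  if (profile$dyad_shift >= profile$dyad_distance) {
    stop("dyad_shift must be smaller than dyad_distance ",
         "(nucleosome would cross the motif center)")
  }
  L <- attr(sites, "chrom_length")
  if (is.null(L)) L <- max(sites$end) + 10000L
  chrom <- sites$chrom[1L]
  set.seed(seed)

  ns <- nrow(sites)
  ctrl <- condition_profile("CTRL")
  perturb <- sites$class == "p63-like"

  # planted truth: dyad positions after shift, before jitter
  shift <- ifelse(perturb, 1, 0) * site_shifts(profile$dyad_shift, ns)
  ddist <- ifelse(perturb, profile$dyad_distance, ctrl$dyad_distance)
  truth <- data.frame(
    name = sites$name, class = sites$class, center = sites$center,
    strand = sites$strand,
    left_dyad = sites$center - (ddist - shift),
    right_dyad = sites$center + (ddist - shift),
    shift = shift, stringsAsFactors = FALSE
  )

  n_total <- as.integer(round(ns * frags_per_site * profile$depth_factor))
  site_id <- sample.int(ns, n_total, replace = TRUE)
  p_site <- perturb[site_id]
  nfr_w <- ifelse(p_site, profile$nfr_weight, ctrl$nfr_weight)
  mono_w <- ifelse(p_site, profile$mono_weight, ctrl$mono_weight)
  jitter <- ifelse(p_site, profile$phasing_jitter_sd, ctrl$phasing_jitter_sd)

  u <- stats::runif(n_total)
  klass <- ifelse(u < nfr_w, "nfr", ifelse(u < nfr_w + mono_w, "mono", "bg"))

  len <- integer(n_total)
  center <- integer(n_total)

  i_nfr <- which(klass == "nfr")
  if (length(i_nfr)) {
    len[i_nfr] <- sample(seq(lengths$nfr_range[1], lengths$nfr_range[2]),
                         length(i_nfr), replace = TRUE)
    center[i_nfr] <- sites$center[site_id[i_nfr]] +
      as.integer(round(stats::rnorm(length(i_nfr), 0, 25)))
  }

  i_mono <- which(klass == "mono")
  if (length(i_mono)) {
    len[i_mono] <- rtrunc_norm_int(length(i_mono), lengths$mono_mean,
                                   lengths$mono_sd, lengths$mono_range[1],
                                   lengths$mono_range[2])
    flank <- sample(c(-1L, 1L), length(i_mono), replace = TRUE)
    dyad <- ifelse(flank < 0L, truth$left_dyad[site_id[i_mono]],
                   truth$right_dyad[site_id[i_mono]])
    center[i_mono] <- as.integer(round(dyad +
      stats::rnorm(length(i_mono), 0, jitter[i_mono])))
  }

  i_bg <- which(klass == "bg")
  if (length(i_bg)) {
    mix <- sample(c("nfr", "mono", "di"), length(i_bg), replace = TRUE,
                  prob = c(0.40, 0.45, 0.15))
    bl <- integer(length(i_bg))
    bl[mix == "nfr"] <- sample(seq(lengths$nfr_range[1], lengths$nfr_range[2]),
                               sum(mix == "nfr"), replace = TRUE)
    bl[mix == "mono"] <- rtrunc_norm_int(sum(mix == "mono"), lengths$mono_mean,
                                         lengths$mono_sd, lengths$mono_range[1],
                                         lengths$mono_range[2])
    bl[mix == "di"] <- rtrunc_norm_int(sum(mix == "di"), lengths$di_mean,
                                       lengths$di_sd, lengths$di_range[1],
                                       lengths$di_range[2])
    len[i_bg] <- bl
    center[i_bg] <- as.integer(floor(stats::runif(length(i_bg),
                                                  bl / 2, L - bl / 2)))
  }

  start <- center - len %/% 2L
  start <- pmax(start, 0L)
  start <- pmin(start, L - len)
  end <- start + len

  frags <- data.frame(
    chrom = chrom, start = start, end = end,
    name = sprintf("frag_%07d", seq_len(n_total)),
    sample = profile$name, length = len,
    class = klass, site = sites$name[site_id],
    stringsAsFactors = FALSE
  )

  # Tn5 events: the left insertion center is start + 4, the right end - 6;
  # each event yields a plus read start at center - 4 and a minus-strand 5'
  # end at center + 5 (stored as end - 1 of a 1-bp record).
  ev_center <- c(start + 4L, end - 6L)
  ev_id <- c(paste0(frags$name, "_L"), paste0(frags$name, "_R"))
  reads <- data.frame(
    chrom = chrom,
    start = c(ev_center - 4L, ev_center + 5L),
    end = c(ev_center - 3L, ev_center + 6L),
    name = c(ev_id, ev_id),
    score = 0,
    strand = rep(c("+", "-"), each = 2L * n_total),
    stringsAsFactors = FALSE
  )

  list(fragments = frags, reads = reads, truth = truth)
}

#' Simulate a region-by-cell-type DHS count matrix
#'
#' Draws negative-binomial accessibility counts for synthetic regions over
#' several cell types, with planted classes: `shared_open` regions are high
#' in every cell type, `lineage_specific` regions high in exactly one, and
#' `closed` regions low everywhere. Variance follows the usual count-model
#' parameterisation `mu + dispersion * mu^2`.
#'
#' @param n_regions number of regions.
#' @param cell_types character vector of at least two cell-type labels.
#' @param class_proportions named fractions for `shared_open`,
#'   `lineage_specific`, `closed`; must sum to 1.
#' @param mean_open,mean_closed NB means for accessible / inaccessible
#'   region-cell combinations; `mean_open > mean_closed`.
#' @param dispersion NB dispersion (phi); counts use `size = 1/phi`.
#' @param seed integer RNG seed.
#' @return list with `counts` (data frame: chrom, start, end, then one count
#'   column per cell type) and `truth` (region class and, for
#'   lineage-specific regions, the open cell type).
#' @export
simulate_dhs_counts <- function(n_regions, cell_types,
                                class_proportions = c(shared_open = 0.4,
                                                      lineage_specific = 0.2,
                                                      closed = 0.4),
                                mean_open = 100, mean_closed = 5,
                                dispersion = 0.1, seed = 1) {
  if (length(cell_types) < 2L) {
    stop("at least 2 cell types are required (z-scores undefined otherwise)")
  }
  stopifnot(abs(sum(class_proportions) - 1) < 1e-8,
            mean_open > mean_closed, mean_closed >= 0, dispersion > 0)
  set.seed(seed)
  classes <- sample(names(class_proportions), n_regions, replace = TRUE,
                    prob = class_proportions)
  spec_cell <- rep(NA_character_, n_regions)
  i_spec <- which(classes == "lineage_specific")
  spec_cell[i_spec] <- sample(cell_types, length(i_spec), replace = TRUE)

  k <- length(cell_types)
  mu <- matrix(mean_closed, n_regions, k, dimnames = list(NULL, cell_types))
  mu[classes == "shared_open", ] <- mean_open
  mu[cbind(i_spec, match(spec_cell[i_spec], cell_types))] <- mean_open

  counts <- matrix(stats::rnbinom(n_regions * k, mu = mu, size = 1 / dispersion),
                   n_regions, k, dimnames = list(NULL, cell_types))
  df <- data.frame(
    chrom = "chrS",
    start = (seq_len(n_regions) - 1L) * 1000L,
    end = (seq_len(n_regions) - 1L) * 1000L + 500L,
    stringsAsFactors = FALSE
  )
  df <- cbind(df, as.data.frame(counts))
  truth <- data.frame(
    region = seq_len(n_regions), class = classes, cell = spec_cell,
    stringsAsFactors = FALSE
  )
  list(counts = df, truth = truth)
}

#' Write a region-by-cell-type count matrix
#'
#' TSV with a header row: chrom, start, end, then one column per cell type.
#'
#' @param counts count data frame as from [simulate_dhs_counts()].
#' @param path output path.
#' @export
write_count_matrix <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  df
}
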