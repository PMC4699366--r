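# Coordinates are 0-based half-open (BED convention) throughout the package.
# A fragment midpoint is floor((start + end) / 2); even-length ties resolve
# downward so integer arithmetic is deterministic.

FRAGMENT_COLS <- c("chrom", "start", "end", "name", "sample", "length")
BED6_COLS <- c("chrom", "start", "end", "name", "score", "strand")

#' Fragment midpoints
#'
#' Midpoint of each fragment interval, defined as `floor((start + end) / 2)`
#' (0-based coordinate of the base at or just left of the physical center).
#'
#' @param frags fragment data frame with `start` and `end` columns.
#' @return integer vector of midpoint coordinates.
#' @export
fragment_midpoints <- function(frags) {
  (frags$start + frags$end) %/% 2L
}

validate_fragments <- function(frags) {
  stopifnot(is.data.frame(frags), all(FRAGMENT_COLS %in% names(frags)))
  if (any(frags$start >= frags$end)) {
    stop("fragment records with start >= end are invalid")
  }
  if (any(frags$length != frags$end - frags$start)) {
    stop("fragment length column inconsistent with end - start")
  }
  invisible(frags)
}

#' Read a fragment table
#'
#' Reads a 6-column tab-separated fragment file (chrom, start, end, name,
#' sample, length; no header). Records that fail to parse, or whose
#' coordinates violate `0 <= start < end`, are rejected with a message giving
#' their line numbers; the remainder are returned.
#'
#' @param path path to a fragment TSV.
#' @return data frame with columns chrom, start, end, name, sample, length.
#' @export
read_fragments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty fragment file: ", path)
    return(empty_fragment_set())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad_fields <- which(nfield < 6L)
  keep <- setdiff(seq_along(parts), bad_fields)
  chrom <- vapply(parts[keep], `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(parts[keep], `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts[keep], `[`, "", 3L)))
  name <- vapply(parts[keep], `[`, "", 4L)
  sample <- vapply(parts[keep], `[`, "", 5L)
  bad_parse <- is.na(start) | is.na(end)
  bad_coord <- !bad_parse & (start < 0L | start >= end)
  rejected <- keep[bad_parse | bad_coord]
  if (length(bad_fields) || length(rejected)) {
    message(
      "rejected ", length(bad_fields) + length(rejected),
      " malformed fragment line(s): ",
      paste(utils::head(sort(c(bad_fields, rejected)), 20L), collapse = ", ")
    )
  }
  ok <- !(bad_parse | bad_coord)
  out <- data.frame(
    chrom = chrom[ok], start = start[ok], end = end[ok],
    name = name[ok], sample = sample[ok],
    length = end[ok] - start[ok],
    stringsAsFactors = FALSE
  )
  out
}

empty_fragment_set <- function() {
  data.frame(
    chrom = character(), start = integer(), end = integer(),
    name = character(), sample = character(), length = integer(),
    stringsAsFactors = FALSE
  )
}

#' Write a fragment table
#'
#' @param frags fragment data frame (see [read_fragments()]).
#' @param path output path; tab-separated, no header.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(frags, path) {
  validate_fragments(frags)
  utils::write.table(
    frags[, FRAGMENT_COLS], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read / write BED files
#'
#' Plain tab-separated BED3 or BED6, no header. `read_bed()` returns a data
#' frame with as many of the standard columns (chrom, start, end, name,
#' score, strand) as the file has.
#'
#' @param path file path.
#' @return data frame of intervals.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- BED6_COLS[seq_len(min(ncol(df), 6L))]
  if (any(df$start >= df$end)) stop("BED records with start >= end")
  df
}

#' @rdname read_bed
#' @param x interval data frame (BED3 or BED6 columns).
#' @export
write_bed <- function(x, path) {
  cols <- intersect(BED6_COLS, names(x))
  utils::write.table(x[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Remove duplicate fragments
#'
#' Keeps exactly one representative per identical (chrom, start, end, sample)
#' tuple, emulating PCR-duplicate removal. Strand is not part of the key
#' (fragments are unstranded); the result does not depend on input order.
#'
#' @param frags fragment data frame.
#' @return deduplicated fragment data frame.
#' @export
dedupe_fragments <- function(frags) {
  key <- paste(frags$chrom, frags$start, frags$end, frags$sample, sep = "\r")
  out <- frags[!duplicated(key), , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end, out$sample), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter fragments by length
#'
#' Retains fragments with `lo <= length <= hi`. The nucleosome-free preset is
#' \[1, 99\] (strictly shorter than 100 bp) and the mononucleosome preset
#' \[180, 247\], the size classes used to separate transposase insertions
#' into open DNA from insertions flanking a single nucleosome.
#'
#' @param frags fragment data frame.
#' @param lo,hi inclusive length bounds in bp.
#' @param preset `"nfr"` or `"mono"`; overrides `lo`/`hi`.
#' @return filtered fragment data frame.
#' @export
filter_by_length <- function(frags, lo = 1L, hi = .Machine$integer.max,
                             preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("nfr", "mono"))
    if (preset == "nfr") { lo <- 1L; hi <- 99L } else { lo <- 180L; hi <- 247L }
  }
  if (lo > hi) stop("lo must be <= hi (got lo=", lo, ", hi=", hi, ")")
  frags[frags$length >= lo & frags$length <= hi, , drop = FALSE]
}

#' Tn5 insertion offset correction
#'
#' The Tn5 transposase binds as a dimer and duplicates 9 bp at each insertion,
#' so the two strand-specific read starts of one insertion event sit 9 bp
#' apart. Shifting plus-strand read starts by +4 and minus-strand 5' ends by
#' -5 collapses both onto the physical insertion center.
#'
#' Input records follow the package BED convention: for a minus-strand read
#' the 5' end (the larger genomic coordinate) is stored as `end - 1` of the
#' alignment interval.
#'
#' @param reads BED6 data frame of read alignments with strand `+` or `-`.
#' @return a cut-site data frame with columns chrom, pos, source_strand and
#'   attribute `tn5_corrected = TRUE`; one row per input record.
#' @export
tn5_correct <- function(reads) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(reads)))
  if (any(!reads$strand %in% c("+", "-"))) {
    stop("Tn5 correction undefined for strand '.'; records must be + or -")
  }
  plus <- reads$strand == "+"
  pos <- integer(nrow(reads))
  pos[plus] <- reads$start[plus] + 4L
  pos[!plus] <- (reads$end[!plus] - 1L) - 5L
  out <- data.frame(
    chrom = reads$chrom, pos = pos, source_strand = reads$strand,
    stringsAsFactors = FALSE
  )
  attr(out, "tn5_corrected") <- TRUE
  out
}

#' Motif-centered anchor sites
#'
#' Builds a site set from a BED6 data frame: each interval gets a defined
#' center `floor((start + end) / 2)` and a class label (e.g. p63-like or
#' CTCF-like anchors).
#'
#' @param bed BED6 data frame.
#' @param site_class class label recycled across sites.
#' @param chrom_length optional chromosome length; enables dropping sites
#'   whose profile window would run off the right end.
#' @return site data frame with columns chrom, start, end, name, score,
#'   strand, center, class.
#' @export
as_site_set <- function(bed, site_class = "site", chrom_length = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(bed)))
  out <- data.frame(
    chrom = bed$chrom, start = bed$start, end = bed$end,
    name = if ("name" %in% names(bed)) bed$name else
      paste0("site_", seq_len(nrow(bed))),
    score = if ("score" %in% names(bed)) bed$score else 0,
    strand = if ("strand" %in% names(bed)) bed$strand else "+",
    stringsAsFactors = FALSE
  )
  out$center <- (out$start + out$end) %/% 2L
  stopifnot(all(out$center >= out$start & out$center < out$end))
  out$class <- rep_len(site_class, nrow(out))
  if (!is.null(chrom_length)) attr(out, "chrom_length") <- chrom_length
  out
}
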