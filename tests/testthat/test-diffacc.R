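# Union-peak merging, read-end counting, differential classification, and
# set-overlap significance.

peaks_df <- function(starts, ends, chrom = "chrT") {
  data.frame(chrom = chrom, start = as.integer(starts),
             end = as.integer(ends), stringsAsFactors = FALSE)
}

test_that("peaks merge by single linkage within the gap threshold", {
  near <- peaks_df(c(100, 450), c(200, 550))   # gap 250 <= 300
  m <- merge_union_peaks(near)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(100L, 550L))

  far <- peaks_df(c(100, 520), c(200, 600))    # gap 320
  expect_equal(nrow(merge_union_peaks(far)), 2L)

  # chain A-B-C with pairwise gaps of exactly 300 collapses transitively
  chain <- peaks_df(c(0, 400, 800), c(100, 500, 900))
  m2 <- merge_union_peaks(chain)
  expect_equal(nrow(m2), 1L)
  expect_equal(c(m2$start, m2$end), c(0L, 900L))
})

test_that("merging matches a brute-force transitive closure and is idempotent", {
  # oracle: repeatedly merge any pair with gap <= max_gap until fixed point
  oracle_merge <- function(p, max_gap) {
    repeat {
      p <- p[order(p$start), , drop = FALSE]
      merged <- FALSE
      for (i in seq_len(nrow(p) - 1L)) {
        if (p$start[i + 1L] - p$end[i] <= max_gap) {
          p$end[i] <- max(p$end[i], p$end[i + 1L])
          p <- p[-(i + 1L), , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (!merged) return(p)
    }
  }
  set.seed(default_fixture_seed)
  starts <- sort(sample.int(50000L, 200L))
  p <- peaks_df(starts, starts + sample(50:400, 200L, replace = TRUE))
  got <- merge_union_peaks(p, max_gap = 300L)
  want <- oracle_merge(p, 300L)
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  # idempotent, order-independent, coverage never decreases
  expect_equal(merge_union_peaks(got, 300L), got)
  shuffled <- p[sample.int(nrow(p)), ]
  expect_equal(merge_union_peaks(shuffled, 300L), got)
  expect_gte(sum(got$end - got$start), 0)
  expect_gte(sum(got$end - got$start), max(p$end - p$start))
})

test_that("read-end counting uses both endpoints with half-open overlap", {
  peak <- peaks_df(150, 300)
  one_in <- make_frags(100, 200)        # ends at 100 (out) and 199 (in)
  cnt <- count_read_ends(one_in, peak)
  expect_equal(cnt$s1, 1L)
  inside <- make_frags(160, 260)        # both ends inside
  expect_equal(count_read_ends(inside, peak)$s1, 2L)

  expect_error(count_read_ends(one_in, peaks_df(c(100, 150), c(200, 260))),
               "overlap")
})

test_that("read-end counts equal the brute-force double loop", {
  set.seed(default_fixture_seed)
  starts <- sample.int(20000L, 1000L, replace = TRUE)
  fr <- make_frags(starts, starts + sample(50:300, 1000L, replace = TRUE),
                   sample = sample(c("ctrl", "pert"), 1000L, replace = TRUE))
  pk <- merge_union_peaks(peaks_df(seq(500, 19000, by = 1200),
                                   seq(500, 19000, by = 1200) + 400))
  got <- count_read_ends(fr, pk)
  for (s in c("ctrl", "pert")) {
    sub <- fr[fr$sample == s, ]
    ends <- c(sub$start, sub$end - 1L)
    want <- vapply(seq_len(nrow(pk)), function(i) {
      sum(ends >= pk$start[i] & ends < pk$end[i])
    }, numeric(1))
    expect_equal(as.numeric(got[[s]]), want)
  }
})

test_that("differential classification matches the exact binomial oracle", {
  counts <- peaks_df(c(0, 1000, 2000), c(500, 1500, 2500))
  counts$ctrl <- c(100L, 50L, 10L)
  counts$pert <- c(10L, 50L, 100L)
  # pad libraries so sizes are equal and peaks are independent of totals
  counts <- rbind(counts, data.frame(chrom = "chrT", start = 9000L,
                                     end = 9500L, ctrl = 340L, pert = 340L))
  res <- classify_differential(counts, "ctrl", "pert")
  expect_equal(res$label[1:3], c("lost", "independent", "gained"))
  # oracle: two-sided exact binomial tail sums at p = N1/(N1+N2) = 0.5
  for (i in 1:3) {
    expect_equal(res$p[i],
                 oracle_binom_p(counts$ctrl[i],
                                counts$ctrl[i] + counts$pert[i], 0.5))
  }
  # normalized fold change with 0.5 pseudocount
  expect_equal(res$fc[1], (10.5 / 500) / (100.5 / 500))
})

test_that("classification symmetries hold", {
  set.seed(default_fixture_seed)
  counts <- peaks_df(seq(0, 99000, by = 1000), seq(0, 99000, by = 1000) + 500)
  counts <- counts[1:100, ]
  counts$ctrl <- rpois(100, 100)
  counts$pert <- rpois(100, c(rep(20, 30), rep(100, 40), rep(500, 30)))
  a <- classify_differential(counts, "ctrl", "pert")
  b <- classify_differential(counts, "pert", "ctrl")
  swap <- c(lost = "gained", gained = "lost", independent = "independent")
  expect_equal(unname(swap[a$label]), b$label)

  inf <- classify_differential(counts, "ctrl", "pert", fc_threshold = Inf)
  expect_true(all(inf$label == "independent"))

  zero <- counts[1:2, ]
  zero$ctrl <- c(0L, 100L); zero$pert <- c(0L, 100L)
  rz <- classify_differential(zero, "ctrl", "pert")
  expect_equal(rz$label[1], "independent")
  expect_equal(rz$fdr[1], 1)
})

test_that("planted lost/gained/unchanged peaks are recovered accurately", {
  set.seed(default_fixture_seed)
  n <- 1000L
  truth <- sample(c("lost", "independent", "gained"), n, replace = TRUE,
                  prob = c(0.25, 0.5, 0.25))
  mu <- 200
  factor <- c(lost = 0.2, independent = 1, gained = 5)[truth]
  counts <- peaks_df((seq_len(n) - 1L) * 1000L, (seq_len(n) - 1L) * 1000L + 500L)
  counts$ctrl <- rpois(n, mu)
  counts$pert <- rpois(n, mu * factor)
  res <- classify_differential(counts, "ctrl", "pert")
  expect_gte(mean(res$label == truth), 0.95)
})

test_that("overlap significance is the hypergeometric upper tail", {
  # oracle: exact combinatorial sum
  oracle <- function(a, b, ov, u) {
    k <- ov:min(a, b)
    sum(choose(a, k) * choose(u - a, b - k)) / choose(u, b)
  }
  expect_equal(overlap_significance(5, 5, 5, 10), 1 / 252)
  expect_equal(overlap_significance(5, 5, 5, 10), oracle(5, 5, 5, 10))
  expect_equal(overlap_significance(20, 30, 10, 100),
               oracle(20, 30, 10, 100))
  expect_equal(overlap_significance(0, 7, 0, 10), 1)
  expect_equal(overlap_significance(10, 4, 4, 10), 1)  # forced containment
  expect_error(overlap_significance(5, 5, 6, 10), "impossible")
  expect_error(overlap_significance(11, 5, 2, 10), "universe")
})
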