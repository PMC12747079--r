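# Coverage arithmetic, the strict presence gate, island detection and
# fragment ANI.

test_that("coverage matches brute-force position counting", {
  aln <- tibble::tibble(read_id = "r1", ref_id = "ref",
                        start = 1L, end = 100L, identity = 1)
  tr <- coverage_track(aln, 200, bin = 1)
  expect_equal(attr(tr, "covered_fraction"), 0.5)
  # no reads: all-zero track
  tr0 <- coverage_track(aln[0, ], 200, bin = 10)
  expect_true(all(tr0$depth == 0))
  expect_equal(attr(tr0, "covered_fraction"), 0)
  # random read set vs oracle depth
  set.seed(51)
  n <- 1000
  starts <- sample(1:900, n, replace = TRUE)
  a <- tibble::tibble(read_id = paste0("r", 1:n), ref_id = "ref",
                      start = starts, end = pmin(starts + 49L, 1000L),
                      identity = 1)
  tr1 <- coverage_track(a, 1000, bin = 1)
  expect_equal(tr1$depth, as.numeric(oracle_depth(a$start, a$end, 1000)))
  # malformed rows are rejected with their row number
  bad <- a; bad$end[7] <- 2000L
  expect_error(coverage_track(bad, 1000), "7")
})

test_that("recruit applies RPKM arithmetic and the strict >0.5 gate", {
  mk_aln <- function(n, start, end, ref = "ref") tibble::tibble(
    read_id = paste0("r", seq_len(n)), ref_id = ref,
    start = as.integer(start), end = as.integer(end), identity = 1)
  # 1000 reads, 10-kb ref, library 1e6, cf = 0.9 -> RPKM 100, present
  starts <- 9L * (0:999) + 1L  # tile [1, 9000] exactly
  a <- mk_aln(1000, starts, starts + 8L)
  r <- recruit(c(ref = 10000L), a, 1e6)
  expect_equal(r$covered_fraction, 0.9)
  expect_true(r$present)
  expect_equal(r$rpkm, 100)
  # cf = 0.4: absent, RPKM forced to zero regardless of mapped count
  a2 <- mk_aln(500, 1, 4000)
  r2 <- recruit(c(ref = 10000L), a2, 1e6)
  expect_equal(r2$covered_fraction, 0.4)
  expect_false(r2$present)
  expect_equal(r2$rpkm, 0)
  # cf = 0.5 exactly: strict inequality keeps it absent
  a3 <- mk_aln(1, 1, 5000)
  r3 <- recruit(c(ref = 10000L), a3, 1e6)
  expect_equal(r3$covered_fraction, 0.5)
  expect_false(r3$present)
  expect_equal(r3$rpkm, 0)
  # scale consistency: doubling mapped reads and library size preserves rpkm
  a4 <- dplyr::bind_rows(a, dplyr::mutate(a, read_id = paste0(read_id, "b")))
  r4 <- recruit(c(ref = 10000L), a4, 2e6)
  expect_equal(r4$rpkm, r$rpkm)
  expect_error(recruit(c(ref = 10000L), a, 0), "positive")
  expect_error(recruit(c(ref = 10000L), a, 10), ">= mapped")
})

test_that("reads spread across references conserve totals", {
  set.seed(52)
  aln <- tibble::tibble(
    read_id = paste0("r", 1:300),
    ref_id = sample(c("A", "B", "C"), 300, replace = TRUE),
    start = sample(1:900, 300, replace = TRUE))
  aln$end <- aln$start + 49L
  per_ref <- vapply(c("A", "B", "C"), function(id) {
    recruit(setNames(1000L, id), aln, 1000)$mapped_reads
  }, integer(1))
  expect_equal(sum(per_ref), 300)
})

test_that("island detection matches a run scan and refines stably", {
  ref_len <- 50000L
  excl <- data.frame(start = 20001, end = 32000)
  aln <- gen_alignments(c(GV = ref_len), 5000, 100, excluded = excl, seed = 3)
  tr <- coverage_track(aln, ref_len, bin = 100)
  isl <- detect_islands(tr, max_depth = 0, min_len = 5000)
  expect_equal(nrow(isl), 1)
  expect_lte(abs(isl$start - 20001), 100)  # within one bin
  expect_lte(abs(isl$end - 32000), 100)
  # bin refinement moves boundaries by at most one (coarser) bin
  isl2 <- detect_islands(coverage_track(aln, ref_len, bin = 50),
                         max_depth = 0, min_len = 5000)
  expect_lte(abs(isl2$start - isl$start), 100)
  expect_lte(abs(isl2$end - isl$end), 100)
  # uniform coverage: no islands
  aln_u <- gen_alignments(c(GV = ref_len), 5000, 100, seed = 4)
  expect_equal(nrow(detect_islands(coverage_track(aln_u, ref_len, bin = 100),
                                   min_len = 5000)), 0)
  # two gaps separated by a single covered bin merge into one island
  fake <- tibble::tibble(bin_start = seq(1, 1000, by = 100))
  fake$bin_end <- fake$bin_start + 99
  fake$depth <- c(0, 0, 0, 5, 0, 0, 0, 5, 5, 5)
  class(fake) <- c("coverage_track", class(fake))
  m <- detect_islands(fake, max_depth = 0, min_len = 100)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 1); expect_equal(m$end, 700)
})

test_that("SAM round trip preserves the alignment table", {
  aln <- gen_alignments(c(GV = 5000L), 200, 100, seed = 6)
  sam <- tempfile(fileext = ".sam")
  write_sam(aln, c(GV = 5000L), sam)
  back <- read_alignments(sam)
  expect_equal(nrow(back), 200)
  expect_equal(sort(back$start), sort(aln$start))
  expect_equal(back$end - back$start, rep(99L, 200))
  # TSV dialect
  tsv <- tempfile(fileext = ".tsv")
  write_alignment_tsv(aln, tsv)
  back2 <- read_alignments(tsv)
  expect_equal(back2$start, aln$start)
})

test_that("fragment ANI: self-identity, mutation model, symmetry", {
  set.seed(61)
  a <- random_dna(30000, 0.4)
  self <- fragment_ani(a, a)
  expect_equal(self$ani, 100)
  expect_equal(self$n_fragments_used, self$n_fragments_total)
  # i.i.d. substitutions at 5%: ANI close to 95
  b <- mutate_sequence(a, 0.05, seed = 62)
  ab <- fragment_ani(a, b)
  expect_lt(abs(ab$ani - 95), 1)
  # reverse complement of the subject changes nothing (both strands searched)
  ab_rc <- fragment_ani(a, revcomp(b))
  expect_equal(ab_rc$ani, ab$ani, tolerance = 1e-6)
  # unrelated genomes: no fragment passes, ANI undefined but not an error
  u <- fragment_ani(a, random_dna(30000, 0.4))
  expect_true(is.na(u$ani))
  expect_equal(u$n_fragments_used, 0)
  sym <- fragment_ani(a, b, symmetric = TRUE)
  expect_lt(abs(sym$ani - ab$ani), 0.5)
  expect_error(fragment_ani(a, ""), "non-empty")
})
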