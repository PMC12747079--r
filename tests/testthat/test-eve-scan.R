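# GC tracks, low-GC segmentation, terminal repeat and TSD finders, and the
# whole-genome caller, each checked against independent oracles or the
# generator's truth sets.

test_that("gc_track matches a naive per-window recount", {
  expect_equal(gc_track("GGGG", window = 4, step = 4)$gc, 1.0)
  expect_equal(gc_track("ATGC", window = 4, step = 4)$gc, 0.5)
  set.seed(21)
  s <- random_dna(10000, 0.45)
  tr <- gc_track(s, window = 1000, step = 200)
  expect_equal(tr$gc, oracle_gc_track(s, 1000, 200))
  expect_equal(nrow(tr), floor((10000 - 1000) / 200) + 1)
  # ambiguous bases leave the denominator; saturated windows go missing
  s2 <- paste0(strrep("N", 600), strrep("G", 400))
  expect_true(is.na(gc_track(s2, 1000, 1000)$gc))
  s3 <- paste0(strrep("N", 400), strrep("G", 300), strrep("A", 300))
  expect_equal(gc_track(s3, 1000, 1000)$gc, 0.5)
  expect_error(gc_track("", 10, 5), "empty|shorter")
})

test_that("segment_low_gc finds implants and keeps close pairs apart", {
  # flat track at baseline yields nothing
  flat <- gc_track(strrep("ACGT", 5000), 1000, 200)
  expect_equal(nrow(segment_low_gc(flat, baseline = 0.5)), 0)
  # implanted 20-kb low-GC elements are recovered (>= 90% reciprocal overlap)
  for (seed in 1:10) {
    sg <- gen_host_genome(1, 120000, gc = 0.52, end_plan = "none", seed = seed)
    sg <- implant_eve(sg, "C1", 40000,
                      element_spec(20000, 0.35, "none"), seed = seed + 50)
    tr <- gc_track(as.character(sg$genome[[1]]), 1000, 200)
    seg <- segment_low_gc(tr, baseline = 0.52)
    expect_equal(nrow(seg), 1)
    seg$contig_id <- "C1"
    m <- match_calls(seg, sg$truth$eves)
    expect_equal(m$recall, 1)
  }
  # two implants 2 kb apart stay two intervals
  sg <- gen_host_genome(1, 120000, gc = 0.52, end_plan = "none", seed = 77)
  sg <- implant_eve(sg, "C1", 30000, element_spec(12000, 0.35, "none"),
                    seed = 1)
  end1 <- sg$truth$eves$end[1]
  sg <- implant_eve(sg, "C1", end1 + 2000, element_spec(12000, 0.35, "none"),
                    seed = 2)
  tr <- gc_track(as.character(sg$genome[[1]]), 1000, 200)
  seg <- segment_low_gc(tr, baseline = 0.52)
  expect_equal(nrow(seg), 2)
})

test_that("find_terminal_repeats matches the exhaustive oracle", {
  # forced constructions
  set.seed(31)
  R <- random_dna(500, 0.4); core <- random_dna(8000, 0.4)
  tir <- paste0(R, core, oracle_revcomp(R))
  res <- find_terminal_repeats(tir)
  expect_equal(res$kind, "TIR"); expect_equal(res$length, 500)
  expect_equal(res$identity, 1.0)
  expect_equal(res$right_start, nchar(tir) - 499)
  res2 <- find_terminal_repeats(paste0(substring(R, 1, 266), core,
                                       substring(R, 1, 266)))
  expect_equal(res2$kind, "TDR"); expect_equal(res2$length, 266)
  expect_error(find_terminal_repeats(core, min_len = 3000,
                                     search_margin = 2000), "search_margin")

  # property: agreement with brute force on random sequences, with and
  # without planted (possibly mismatched) repeats
  set.seed(32)
  for (i in 1:60) {
    n <- sample(600:5000, 1)
    s <- random_dna(n, runif(1, 0.3, 0.6))
    if (i %% 2 == 0) {
      L <- sample(100:min(600, n %/% 3), 1)
      kind <- sample(c("TIR", "TDR"), 1)
      rep_seq <- random_dna(L, 0.4)
      right <- if (kind == "TIR") oracle_revcomp(rep_seq) else rep_seq
      nmm <- sample(0:floor(0.05 * L), 1)
      if (nmm > 0) right <- mutate_sequence(right, nmm / L)
      s <- paste0(rep_seq, substring(s, L + 1, n - L), right)
    }
    got <- find_terminal_repeats(s, min_len = 100, max_mismatch_frac = 0.05,
                                 search_margin = 2000)
    want <- oracle_terminal_repeat(s, 100, 0.05, 2000)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$kind, want$kind)
      expect_equal(got$length, want$length)
    }
  }
})

test_that("find_tsd matches enumeration and prefers the longest k", {
  # forced 5-mer
  res <- find_tsd("GTCATGCATGCCTGAAACGT", "AACGTTGCACTGATCGGTAC")
  expect_equal(res$sequence, "AACGT"); expect_equal(res$length, 5)
  # longest-match rule: a 6-mer beats the nested 5-mer
  res6 <- find_tsd("GTCATGCATGCCTGAAACGT", "AAACGTTGCACTGATCGGTA")
  expect_equal(res6$length, 6)
  # N breaks the match
  expect_equal(nrow(find_tsd("GTCATGCATGCCTGAANCGT", "AANCGTTGCACTGATCGGTA")),
               0)
  expect_error(find_tsd("ACGTX", "ACGTA"), "characters")
  # enumeration oracle on random independent flanks
  set.seed(41)
  for (i in 1:200) {
    l <- random_dna(20, 0.5); r <- random_dna(20, 0.5)
    got <- find_tsd(l, r)
    want <- oracle_tsd(l, r)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$sequence, want$seq)
    }
  }
})

test_that("call_eves recovers implants with kinds, spans and TSDs", {
  sg <- make_eve_genome(seed = 3, n_implants = 3)
  truth <- sg$truth$eves
  calls <- call_eves(sg, anchors = "MAGWNDKTHQLV")
  expect_equal(nrow(calls), 3)
  expect_equal(calls$repeat_kind, truth$repeat_kind)
  expect_true(all(abs(calls$start - truth$start) <= 50))
  expect_true(all(abs(calls$end - truth$end) <= 50))
  # TSDs recovered where planted (exact spans make flanks exact)
  exact <- calls$start == truth$start & calls$end == truth$end
  expect_equal(calls$tsd_len[exact], truth$tsd_len[exact])
  # a low-GC segment without an anchor yields no call
  sg2 <- gen_host_genome(1, 100000, gc = 0.52, end_plan = "none", seed = 9)
  sg2 <- implant_eve(sg2, "C1", 30000, element_spec(20000, 0.35, "TIR",
                                                    repeat_len = 400),
                     seed = 10)
  expect_equal(nrow(call_eves(sg2, anchors = "MAGWNDKTHQLV")), 0)
  # anchor evidence is mandatory
  expect_error(call_eves(sg2, anchors = NULL), "mandatory")
  expect_error(call_eves(sg2, anchors = character()), "mandatory")
})

test_that("call_eves works from GFF3 anchor annotations", {
  skip_if_not_installed("rtracklayer")
  sg <- make_eve_genome(seed = 12, n_implants = 3)
  gff <- tempfile(fileext = ".gff3")
  write_truth_gff3(sg, gff)
  calls <- call_eves(sg, anchors = gff)
  expect_equal(nrow(calls), 3)
  m <- match_calls(calls, sg$truth$eves)
  expect_equal(m$recall, 1)
})

test_that("raising thresholds never increases calls; masking empties them", {
  sg <- make_eve_genome(seed = 6, n_implants = 4)
  base <- call_eves(sg, anchors = "MAGWNDKTHQLV")
  for (delta in c(10, 14)) {
    n2 <- nrow(call_eves(sg, anchors = "MAGWNDKTHQLV",
                         params = eve_params(min_delta = delta)))
    expect_lte(n2, nrow(base))
  }
  for (ml in c(16000, 30000)) {
    n3 <- nrow(call_eves(sg, anchors = "MAGWNDKTHQLV",
                         params = eve_params(min_len = ml)))
    expect_lte(n3, nrow(base))
  }
  # idempotence: hard-masking called spans removes every call
  masked <- mask_intervals(sg$genome, base)
  expect_equal(nrow(call_eves(masked, anchors = "MAGWNDKTHQLV")), 0)
})

test_that("classification follows repeat kind and integrase enzyme", {
  calls <- tibble::tibble(
    contig_id = c("C1", "C2", "C3", "C4"),
    start = 1L, end = 100L,
    repeat_kind = c("TDR", "TIR", "TIR", "TDR"),
    tsd_len = c(0L, 5L, 0L, 5L))
  out <- suppressWarnings(
    classify_eves(calls, c("YREC", "rve-INT", "none", "YREC")))
  expect_equal(out$class_label,
               c("yrec-TDR-type", "canonical-polinton-like", "unclassified",
                 "yrec-TDR-type"))
  # TDR co-occurring with a TSD draws the consistency warning
  expect_warning(classify_eves(calls, c("YREC", "rve-INT", "none", "YREC")),
                 "TDR")
  expect_true(out$tdr_tsd_warning[4])
  expect_false(any(out$tdr_tsd_warning[1:3]))
})

test_that("summaries use the lower median and handle empty input", {
  calls <- tibble::tibble(length = c(10, 20, 30), gc = 0.35,
                          repeat_kind = "TIR", repeat_len = c(100, 200, 300))
  expect_equal(summarize_eves(calls)$median_length, 20)
  even <- tibble::tibble(length = c(10, 20, 30, 40), gc = 0.35,
                         repeat_kind = "none", repeat_len = 0L)
  expect_equal(summarize_eves(even)$median_length, 20)          # lower
  expect_equal(summarize_eves(even, "midpoint")$median_length, 25)
  empty <- calls[0, ]
  s <- summarize_eves(empty)
  expect_equal(s$n, 0)
  expect_true(is.na(s$median_length))
})
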