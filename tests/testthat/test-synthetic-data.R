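# Generators: determinism, composition guarantees, truth consistency.

test_that("host genome generation is deterministic and honours the plan", {
  sg1 <- gen_host_genome(3, c(30000, 40000), gc = 0.52,
                         end_plan = c("both", "one", "none"), seed = 5)
  sg2 <- gen_host_genome(3, c(30000, 40000), gc = 0.52,
                         end_plan = c("both", "one", "none"), seed = 5)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(sg1$genome, f1); write_fasta(sg2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical FASTA
  sg3 <- gen_host_genome(3, c(30000, 40000), gc = 0.52,
                         end_plan = c("both", "one", "none"), seed = 6)
  expect_false(identical(as.character(sg1$genome), as.character(sg3$genome)))
  expect_equal(sg1$truth$telomeres$status, c("both", "one", "none"))
  # the scanner recovers exactly the planned labels (truth consistency)
  tel <- scan_telomeres(sg1, "TTAGGG")
  expect_equal(tel$status, c("both", "one", "none"))
})

test_that("host background GC is realised near the target", {
  gcs <- vapply(1:20, function(s) {
    sg <- gen_host_genome(1, 100000, gc = 0.52, end_plan = "none", seed = s)
    Biostrings::letterFrequency(sg$genome[[1]], "GC", as.prob = TRUE)[[1]]
  }, double(1))
  # binomial sd at n = 1e5 is ~0.0016; every draw sits well inside +/- 2pp
  expect_true(all(gcs >= 0.50 & gcs <= 0.54))
  expect_lt(abs(mean(gcs) - 0.52), 0.005)
})

test_that("generator input validation rejects bad plans and ranges", {
  expect_error(gen_host_genome(2, c(50, 60), end_plan = "both"),
               "telomere tract")
  expect_error(gen_host_genome(2, c(30000, 40000), end_plan = "left"),
               "end_plan")
  expect_error(gen_host_genome(1, 30000, telomere_motif = "TTA"), "4-10")
  expect_error(element_spec(1000, 0.35, "TIR", repeat_len = 600), "repeat_len")
  expect_error(element_spec(10000, 0.35, "TIR", repeat_len = 100, tsd_len = 3),
               "tsd_len")
})

test_that("implanted elements carry the declared repeat, TSD and anchors", {
  sg <- gen_host_genome(1, 60000, gc = 0.52, end_plan = "none", seed = 2)
  before <- Biostrings::width(sg$genome)[1]

  spec <- element_spec(16000, 0.35, "TIR", repeat_len = 500, tsd_len = 5,
                       anchor_peptides = "MAGWNDKTHQLV")
  sg <- implant_eve(sg, "C1", 20000, spec, seed = 3)
  tr <- sg$truth$eves[1, ]
  el <- substring(as.character(sg$genome[["C1"]]), tr$start, tr$end)
  # TIR: first 500 bp equal the reverse complement of the last 500 bp
  expect_identical(substring(el, 1, 500),
                   oracle_revcomp(substring(el, 16000 - 499, 16000)))
  # 5-bp TSD: host bases left of the insertion duplicated right of it
  contig <- as.character(sg$genome[["C1"]])
  expect_identical(substring(contig, tr$start - 5, tr$start - 1),
                   substring(contig, tr$end + 1, tr$end + 5))
  # conservation: length grew by element + TSD
  expect_equal(Biostrings::width(sg$genome)[1], before + 16000 + 5)
  # element GC within 3 pp of the requested 35%
  expect_lt(abs(tr$gc - 0.35), 0.03)
  # anchor peptide is an exact in-frame translation inside the element
  hits <- scan_anchor_peptides(el, "MAGWNDKTHQLV")
  expect_gte(nrow(hits), 1)
  expect_true(any(hits$strand == "+"))

  # TDR without TSD, paper-reported median length for the direct repeats
  spec2 <- element_spec(15000, 0.35, "TDR", repeat_len = 266, tsd_len = 0)
  sg <- implant_eve(sg, "C1", 50000, spec2, seed = 4)
  tr2 <- sg$truth$eves[sg$truth$eves$repeat_kind == "TDR", ]
  el2 <- substring(as.character(sg$genome[["C1"]]), tr2$start, tr2$end)
  expect_identical(substring(el2, 1, 266),
                   substring(el2, 15000 - 265, 15000))
  # reverse-strand anchors are found on the minus strand
  spec3 <- element_spec(14000, 0.35, "TIR", repeat_len = 300, tsd_len = 6,
                        anchor_peptides = "MHEVLRKPTWDY",
                        anchor_strand = "-")
  sg <- implant_eve(sg, "C1", 40000, spec3, seed = 5)
  tr3 <- sg$truth$eves[sg$truth$eves$tsd_len == 6, ]
  el3 <- substring(as.character(sg$genome[["C1"]]), tr3$start, tr3$end)
  h3 <- scan_anchor_peptides(el3, "MHEVLRKPTWDY")
  expect_true(any(h3$strand == "-"))
})

test_that("implant rejects out-of-range and overlapping positions", {
  sg <- gen_host_genome(1, 40000, gc = 0.5, end_plan = "none", seed = 1)
  spec <- element_spec(14000, 0.35, "TIR", repeat_len = 300)
  expect_error(implant_eve(sg, "C1", 500, spec), "1 kb")
  expect_error(implant_eve(sg, "C1", 39500, spec), "1 kb")
  sg <- implant_eve(sg, "C1", 10000, spec, seed = 2)
  expect_error(implant_eve(sg, "C1", 10005, spec, seed = 3), "overlap")
})

test_that("alignment generation respects exclusions and coverage closed form", {
  ref_len <- c(GV = 50000L)
  excl <- data.frame(start = 20001, end = 30000)
  aln <- gen_alignments(ref_len, 3000, 100, excluded = excl, seed = 9)
  expect_equal(nrow(aln), 3000)
  # zero reads overlap the excluded window
  expect_false(any(aln$start <= 30000 & aln$end >= 20001))
  # n_reads = 0 gives an empty but valid table
  empty <- gen_alignments(ref_len, 0, 100, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("read_id", "ref_id", "start", "end", "identity"))
  expect_error(gen_alignments(ref_len, 10, 100,
                              excluded = data.frame(start = 1, end = 50000)),
               "whole reference")
  # determinism
  expect_identical(gen_alignments(ref_len, 500, 100, seed = 3),
                   gen_alignments(ref_len, 500, 100, seed = 3))
  # mean depth over the usable region matches n*L/usable over 10 seeds
  usable <- 50000 - 10000
  exp_mean <- 3000 * 100 / usable
  means <- vapply(1:10, function(s) {
    a <- gen_alignments(ref_len, 3000, 100, excluded = excl, seed = s)
    d <- oracle_depth(a$start, a$end, 50000)
    mean(d[-(20001:30000)])
  }, double(1))
  expect_lt(abs(mean(means) - exp_mean) / exp_mean, 0.05)
})

test_that("survey generator matches its Beta model and null couplings", {
  # a/(a+b) = 0.165 for the default shapes
  sv <- gen_survey(1000, cry1a_beta = c(0.73, 3.69), seed = 11)
  expect_equal(nrow(sv), 1000)
  expect_lt(abs(mean(sv$cry1a_pct) - 16.5), 2)  # within 2 pp of the Beta mean
  expect_true(all(sv$cry1a_count <= sv$hnf_count))
  scr <- correlation_screen(sv)
  expect_true(all(abs(scr$pearson_r) < 0.2))  # uncoupled covariates
  expect_false(any(scr$flagged))
  # a coupled covariate is recovered
  sv2 <- gen_survey(1000, env_vars = list(
    temperature = list(mean = 15, sd = 5, coupling = 0.8)), seed = 12)
  scr2 <- correlation_screen(sv2)
  expect_true(scr2$flagged[scr2$covariate == "env_temperature"])
  # n_samples = 263 emulates the study size
  expect_equal(nrow(gen_survey(263, seed = 1)), 263)
  expect_identical(gen_survey(50, seed = 4), gen_survey(50, seed = 4))
})

test_that("growth generator follows its piecewise model", {
  tp <- seq(0, 480, by = 24)
  g <- gen_growth(inoculum = 100, lag = 96, mu = 0.03, t_collapse = 360,
                  collapse_frac = 0.8, cv = 0, timepoints = tp)
  expect_equal(g$count[g$time_h < 96], rep(100, sum(tp < 96)))
  i <- which(g$time_h == 240)
  expect_equal(g$count[i], 100 * exp(0.03 * (240 - 96)))
  j <- which(g$time_h == 360)
  expect_equal(g$count[j], 100 * exp(0.03 * (360 - 96)) * 0.2)
  # noiseless inversion: the fit recovers mu exactly
  fit <- fit_exponential(gen_growth(mu = log(2) / 29, cv = 0,
                                    timepoints = seq(0, 600, 24), lag = 96))
  expect_equal(fit$doubling_h, 29, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_error(gen_growth(timepoints = c(0, 48, 24)), "increasing")
  expect_identical(gen_growth(seed = 8), gen_growth(seed = 8))
})
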