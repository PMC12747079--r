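# Brute-force oracles and synthetic fixture builders shared across the test
# files. Oracles are written from first principles (plain loops over the
# definitions) and stay independent of the package implementation.

# reverse complement without Biostrings
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# exhaustive anchored prefix/suffix repeat search: every candidate length L
# is recounted directly; among fraction-valid lengths the score
# (matches - 2 * mismatches) decides, ties to the longer L, TIR preferred
# over TDR on a score tie — the declared selection rule, recomputed from
# scratch
oracle_terminal_repeat <- function(seq, min_len, eps, margin) {
  n <- nchar(seq)
  M <- min(margin, n %/% 2)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  rc <- strsplit(oracle_revcomp(seq), "", fixed = TRUE)[[1]]
  isN <- function(x) x == "N"
  best <- list(TIR = NULL, TDR = NULL)
  for (L in seq(min_len, M)) {
    pre <- ch[1:L]
    suf <- ch[(n - L + 1):n]
    m_tdr <- sum(pre != suf | isN(pre) | isN(suf))
    m_tir <- sum(pre != rc[1:L] | isN(pre) | isN(rc[1:L]))
    if (m_tir <= floor(eps * L)) {
      sc <- L - 3 * m_tir
      if (is.null(best$TIR) || sc >= best$TIR$score) {
        best$TIR <- list(kind = "TIR", length = L, score = sc)
      }
    }
    if (m_tdr <= floor(eps * L)) {
      sc <- L - 3 * m_tdr
      if (is.null(best$TDR) || sc >= best$TDR$score) {
        best$TDR <- list(kind = "TDR", length = L, score = sc)
      }
    }
  }
  s_tir <- if (is.null(best$TIR)) -Inf else best$TIR$score
  s_tdr <- if (is.null(best$TDR)) -Inf else best$TDR$score
  if (s_tir == -Inf && s_tdr == -Inf) return(NULL)
  if (s_tir >= s_tdr) best$TIR else best$TDR
}

# enumeration oracle for anchored target-site duplications
oracle_tsd <- function(left, right, k_min = 4, k_max = 8) {
  nl <- nchar(left); nr <- nchar(right)
  for (k in seq(min(k_max, nl, nr), k_min)) {
    if (k < k_min) break
    a <- substring(left, nl - k + 1, nl)
    b <- substring(right, 1, k)
    if (!grepl("N", a) && !grepl("N", b) && a == b) return(list(seq = a, k = k))
  }
  NULL
}

# naive per-window GC recount
oracle_gc_track <- function(seq, window, step) {
  n <- nchar(seq)
  starts <- seq(1, n - window + 1, by = step)
  sapply(starts, function(s) {
    w <- strsplit(substring(seq, s, s + window - 1), "", fixed = TRUE)[[1]]
    amb <- sum(w == "N")
    if (amb > window / 2) return(NA_real_)
    sum(w %in% c("G", "C")) / (window - amb)
  })
}

# per-base depth by direct position counting
oracle_depth <- function(starts, ends, ref_len) {
  d <- integer(ref_len)
  for (i in seq_along(starts)) {
    idx <- starts[i]:ends[i]
    d[idx] <- d[idx] + 1L
  }
  d
}

# reciprocal-overlap matching of call intervals against truth intervals
match_calls <- function(calls, truth, min_recip = 0.9) {
  hit <- logical(nrow(truth))
  used <- logical(nrow(calls))
  for (i in seq_len(nrow(truth))) {
    for (j in seq_len(nrow(calls))) {
      if (used[j] || calls$contig_id[j] != truth$contig_id[i]) next
      ov <- min(calls$end[j], truth$end[i]) - max(calls$start[j], truth$start[i]) + 1
      if (ov <= 0) next
      if (ov / (truth$end[i] - truth$start[i] + 1) >= min_recip &&
          ov / (calls$end[j] - calls$start[j] + 1) >= min_recip) {
        hit[i] <- TRUE; used[j] <- TRUE; break
      }
    }
  }
  list(recall = mean(hit),
       precision = if (nrow(calls)) sum(used) / nrow(calls) else NA_real_)
}

# random genome with 3-8 implanted elements (one per contig), returning the
# synth_genome; used by recovery and property tests
make_eve_genome <- function(seed, n_implants = NULL) {
  set.seed(seed * 97 + 1)
  n_imp <- n_implants %||% sample(3:8, 1)
  draw <- list(
    len = sample(14000:40000, n_imp, replace = TRUE),
    kind = sample(c("TIR", "TDR"), n_imp, replace = TRUE, prob = c(0.8, 0.2)),
    tsd = sample(c(0L, 5L, 6L), n_imp, replace = TRUE),
    pos = sample(10000:50000, n_imp, replace = TRUE))
  rep_len <- ifelse(draw$kind == "TIR", sample(300:600, n_imp, replace = TRUE),
                    sample(200:350, n_imp, replace = TRUE))
  sg <- gen_host_genome(n_imp, c(95000, 105000), gc = 0.52,
                        end_plan = "none", seed = seed)
  for (i in seq_len(n_imp)) {
    spec <- element_spec(draw$len[i], 0.35, draw$kind[i],
                         repeat_len = rep_len[i], tsd_len = draw$tsd[i],
                         anchor_peptides = "MAGWNDKTHQLV")
    sg <- implant_eve(sg, paste0("C", i), draw$pos[i], spec,
                      seed = seed * 131 + i)
  }
  sg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
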