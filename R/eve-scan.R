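# Primitives for endogenous viral element detection: sliding-window GC
# tracks, low-GC segmentation, terminal repeat (TIR/TDR) detection anchored
# at sequence termini, and target-site duplication calling on 20-bp flanks.

#' Sliding-window GC track
#'
#' Window `i` covers bases `[(i-1)*step + 1, (i-1)*step + window]`. The GC
#' fraction excludes ambiguous bases (N) from the denominator; windows with
#' more than 50% ambiguous bases yield `NA`.
#'
#' @param seq A DNA sequence (character, `DNAString`) of length >= `window`.
#' @param window Window size in bp.
#' @param step Step size in bp (`step <= window`).
#' @return A tibble of class `gc_track` with `start`, `end`, `gc`,
#'   `n_ambiguous`; window/step kept as attributes.
#' @export
gc_track <- function(seq, window = 1000L, step = 200L) {
  window <- as.integer(window); step <- as.integer(step)
  if (step < 1L || window < step) abort("need window >= step >= 1")
  s <- Biostrings::DNAString(as_seq_chr(seq))
  n <- length(s)
  if (n == 0L) abort("empty sequence")
  if (n < window) abort("sequence shorter than one window")
  starts <- seq.int(1L, n - window + 1L, by = step)
  v <- Biostrings::Views(s, start = starts, width = window)
  f <- Biostrings::letterFrequency(v, c("G", "C", "N"))
  amb <- f[, "N"]
  denom <- window - amb
  gc <- ifelse(amb > window / 2, NA_real_, (f[, "G"] + f[, "C"]) / denom)
  out <- tibble(start = starts, end = starts + window - 1L,
                gc = as.numeric(gc), n_ambiguous = as.integer(amb))
  class(out) <- c("gc_track", class(out))
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "seq_len") <- n
  out
}

#' Segment a GC track into candidate low-GC intervals
#'
#' Maximal runs of consecutive windows with GC at or below
#' `baseline - min_delta/100` are merged across gaps of at most one window,
#' converted to base intervals (first window start to last window end) and
#' filtered to `[min_len, max_len]`.
#'
#' @param track A [gc_track()].
#' @param baseline Host baseline GC fraction in (0, 1).
#' @param min_delta Minimum GC depression in percentage points.
#' @param min_len,max_len Retained interval length range in bp.
#' @return A sorted, non-overlapping tibble `start`, `end`, `length`,
#'   `n_windows`, `mean_gc`.
#' @export
segment_low_gc <- function(track, baseline, min_delta = 8, min_len = 5000L,
                           max_len = 60000L) {
  if (baseline <= 0 || baseline >= 1) abort("baseline must lie in (0, 1)")
  low <- !is.na(track$gc) & track$gc <= baseline - min_delta / 100
  empty <- tibble(start = integer(), end = integer(), length = integer(),
                  n_windows = integer(), mean_gc = double())
  if (!any(low)) return(empty)
  idx <- which(low)
  # merge runs separated by gaps of <= 1 window
  brk <- which(diff(idx) > 2L)
  grp_start <- idx[c(1L, brk + 1L)]
  grp_end <- idx[c(brk, length(idx))]
  out <- tibble(
    start = track$start[grp_start],
    end = track$end[grp_end],
    n_windows = grp_end - grp_start + 1L,
    mean_gc = vapply(seq_along(grp_start), function(i) {
      mean(track$gc[grp_start[i]:grp_end[i]], na.rm = TRUE)
    }, double(1)))
  out$length <- out$end - out$start + 1L
  out <- out[out$length >= min_len & out$length <= max_len,
             c("start", "end", "length", "n_windows", "mean_gc")]
  arrange(out, .data$start)
}

# mismatch counts between prefix chars p and the suffix-anchored L-mer of
# tail chars t, for one candidate repeat length L
tdr_mismatch <- function(p, t, L) {
  M <- length(t)
  sum(p[seq_len(L)] != t[(M - L + 1L):M])
}

#' Find a terminal repeat (TIR or TDR) anchored at sequence termini
#'
#' Compares the first `search_margin` bp against the last `search_margin`
#' bp in direct orientation (terminal direct repeat: prefix equals suffix)
#' and reverse-complement orientation (terminal inverted repeat: prefix
#' equals the reverse complement of the suffix). Among candidate lengths
#' whose mismatch fraction is at most `max_mismatch_frac`, the reported
#' repeat maximises the alignment score (match +1, mismatch -2), so the
#' boundary is never extended into flanking sequence merely because the
#' budget allows it; score ties go to the longer repeat, and a TIR is
#' preferred over a TDR on an exact length tie. Ambiguous bases never
#' match.
#'
#' @param seq DNA sequence, longer than `2 * min_len`.
#' @param min_len,max_len Repeat length bounds in bp.
#' @param max_mismatch_frac Maximum tolerated mismatch fraction.
#' @param search_margin How many terminal bp to compare on each side.
#' @return A one-row tibble `kind`, `length`, `identity`, `left_start`,
#'   `left_end`, `right_start`, `right_end`, or a zero-row tibble when no
#'   repeat of at least `min_len` is found.
#' @export
find_terminal_repeats <- function(seq, min_len = 100L, max_len = Inf,
                                  max_mismatch_frac = 0.05,
                                  search_margin = 2000L) {
  seq <- as_seq_chr(seq)
  check_dna(seq)
  n <- nchar(seq)
  min_len <- as.integer(min_len)
  if (min_len > search_margin) abort("min_len exceeds search_margin")
  if (n <= 2L * min_len) abort("sequence must be longer than 2 * min_len")
  M <- min(as.integer(search_margin), n %/% 2L)
  Lmax <- as.integer(min(max_len, M))
  p <- strsplit(substring(seq, 1L, M), "", fixed = TRUE)[[1]]
  tail_seq <- substring(seq, n - M + 1L, n)
  t_chr <- strsplit(tail_seq, "", fixed = TRUE)[[1]]
  rc_chr <- strsplit(revcomp(tail_seq), "", fixed = TRUE)[[1]]
  # N never matches
  pN <- p == "N"; tN <- t_chr == "N"; rcN <- rc_chr == "N"

  # score = matches - 2 * mismatches = L - 3 * mism; pick the best-scoring
  # fraction-valid length (ties -> longer)
  pick <- function(Ls, mism) {
    ok <- mism <= floor(max_mismatch_frac * Ls)
    if (!any(ok)) return(NULL)
    Ls <- Ls[ok]; mism <- mism[ok]
    score <- Ls - 3L * mism
    top <- which(score == max(score))
    i <- top[which.max(Ls[top])]
    list(length = Ls[i], mism = mism[i], score = score[i])
  }

  # TIR: prefix[1..L] vs revcomp(last L bases) = rc_chr[1..L]; cumulative
  mism_tir <- cumsum(p != rc_chr | pN | rcN)
  Ls <- seq.int(min_len, Lmax)
  best_tir <- if (min_len <= Lmax) pick(Ls, mism_tir[Ls]) else NULL

  # TDR: prefix[1..L] vs tail[(M-L+1)..M]; brute force for small margins,
  # exact-seed candidates otherwise
  neq <- function(L) {
    i <- seq_len(L); j <- (M - L + 1L):M
    sum(p[i] != t_chr[j] | pN[i] | tN[j])
  }
  if (M <= 5000L && min_len <= Lmax) {
    cand <- Ls
  } else {
    k <- 16L
    cand <- integer()
    for (o in c(1L, 17L, 33L, 49L)) {
      if (o + k - 1L > M) next
      seed <- substring(seq, o, o + k - 1L)
      if (grepl("N", seed)) next
      hits <- IRanges::start(Biostrings::matchPattern(
        Biostrings::DNAString(seed), Biostrings::DNAString(tail_seq)))
      cand <- c(cand, M - hits + o)  # implied repeat length
    }
    cand <- sort(unique(cand[cand >= min_len & cand <= Lmax]))
  }
  best_tdr <- if (length(cand)) {
    pick(cand, vapply(cand, neq, double(1)))
  } else NULL

  if (is.null(best_tir) && is.null(best_tdr)) {
    return(tibble(kind = character(), length = integer(), identity = double(),
                  left_start = integer(), left_end = integer(),
                  right_start = integer(), right_end = integer()))
  }
  s_tir <- if (is.null(best_tir)) -Inf else best_tir$score
  s_tdr <- if (is.null(best_tdr)) -Inf else best_tdr$score
  if (s_tir >= s_tdr) {  # TIR preferred on exact tie
    L <- best_tir$length; kind <- "TIR"; mism <- best_tir$mism
  } else {
    L <- best_tdr$length; kind <- "TDR"; mism <- best_tdr$mism
  }
  tibble(kind = kind, length = as.integer(L),
         identity = 1 - mism / L,
         left_start = 1L, left_end = as.integer(L),
         right_start = as.integer(n - L + 1L), right_end = as.integer(n))
}

#' Call a target-site duplication from 20-bp flanks
#'
#' Returns the longest `k` in `[k_min, k_max]` such that the k-mer *ending*
#' at the last position of the left flank equals the k-mer *starting* at the
#' first position of the right flank. Matching is exact; any N inside the
#' compared k-mers breaks the match at that `k`.
#'
#' @param left_flank,right_flank Flanking DNA, nominally 20 bp (shorter
#'   flanks at contig ends are accepted and flagged).
#' @param k_min,k_max Duplication length bounds in bp.
#' @return A one-row tibble `sequence`, `length`, `short_flank`, or a
#'   zero-row tibble when no duplication is found.
#' @export
find_tsd <- function(left_flank, right_flank, k_min = 4L, k_max = 8L) {
  left_flank <- as_seq_chr(left_flank); right_flank <- as_seq_chr(right_flank)
  check_dna(left_flank, "left flank"); check_dna(right_flank, "right flank")
  nl <- nchar(left_flank); nr <- nchar(right_flank)
  short <- nl < 20L || nr < 20L
  kk <- min(k_max, nl, nr)
  if (kk >= k_min) {
    for (k in kk:k_min) {
      a <- substring(left_flank, nl - k + 1L, nl)
      b <- substring(right_flank, 1L, k)
      if (!grepl("N", a) && !grepl("N", b) && a == b) {
        return(tibble(sequence = a, length = as.integer(k),
                      short_flank = short))
      }
    }
  }
  tibble(sequence = character(), length = integer(), short_flank = logical())
}
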