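# Telomere-based chromosome accounting: classify contig ends by tandem
# telomeric motif runs, derive a minimum chromosome number, and compute
# standard assembly statistics.

# Count tandem motif copies starting at offset `s` of `chars` (a character
# vector of the terminal window). A chunk counts as a copy when it has at
# most one mismatching base; the run stops when cumulative mismatched bases
# exceed one per three copies.
count_tandem <- function(chars, motif_chars, s) {
  m <- length(motif_chars)
  K <- (length(chars) - s + 1L) %/% m
  if (K < 1L) return(0L)
  block <- matrix(chars[s:(s + K * m - 1L)], nrow = m)
  mism <- colSums(block != motif_chars | block == "N")
  ok <- mism <= 1L & cumsum(mism) <= floor(seq_len(K) / 3)
  bad <- which(!ok)
  if (!length(bad)) K else bad[1] - 1L
}

best_run_at_end <- function(end_seq, motif, max_offset) {
  chars <- strsplit(end_seq, "", fixed = TRUE)[[1]]
  best <- 0L
  for (m in c(motif, revcomp(motif))) {
    mc <- strsplit(m, "", fixed = TRUE)[[1]]
    for (s in seq_len(min(max_offset + 1L, length(chars)))) {
      cnt <- count_tandem(chars, mc, s)
      if (cnt > best) best <- cnt
    }
  }
  best
}

#' Classify contig ends by telomeric repeat content
#'
#' An end is called telomeric when a tandem run of at least `min_copies`
#' motif copies (either orientation) starts within `max_offset` bp of the
#' terminus. Run counting tolerates one mismatching base per copy and one
#' mismatch per three copies overall. The right end is scanned on the
#' reverse complement, so results are invariant under reverse-complementing
#' a contig (ends swap, status is preserved).
#'
#' @param genome Genome input ([as_genome()] or `synth_genome`).
#' @param motif Telomeric repeat unit, 4-10 bp, unambiguous.
#' @param terminal_window How many terminal bp to scan, per end.
#' @param min_copies Minimum tandem copies for a telomere call.
#' @param max_offset Maximum distance (bp) of the run start from the
#'   terminus.
#' @return A tibble of class `telomere_calls`: `contig_id`, `left_end`,
#'   `right_end`, `left_copies`, `right_copies`, `status`
#'   (both/one/none).
#' @export
scan_telomeres <- function(genome, motif, terminal_window = 2000L,
                           min_copies = 6L, max_offset = 100L) {
  if (inherits(genome, "synth_genome")) genome <- genome$genome
  genome <- as_genome(genome)
  motif <- as_seq_chr(motif)
  if (grepl("[^ACGT]", motif)) abort("motif must contain only A/C/G/T")
  if (nchar(motif) < 4 || nchar(motif) > 10) abort("motif must be 4-10 bp")
  res <- map_dfr(names(genome), function(cid) {
    s <- as.character(genome[[cid]])
    n <- nchar(s)
    w <- min(terminal_window, n)
    left <- best_run_at_end(substring(s, 1L, w), motif, max_offset)
    right <- best_run_at_end(revcomp(substring(s, n - w + 1L, n)), motif,
                             max_offset)
    tibble(contig_id = cid,
           left_copies = left, right_copies = right,
           left_end = if (left >= min_copies) "telomere" else "none",
           right_end = if (right >= min_copies) "telomere" else "none")
  })
  res$status <- dplyr::case_when(
    res$left_end == "telomere" & res$right_end == "telomere" ~ "both",
    res$left_end == "telomere" | res$right_end == "telomere" ~ "one",
    TRUE ~ "none")
  res <- res[, c("contig_id", "left_end", "right_end", "left_copies",
                 "right_copies", "status")]
  class(res) <- c("telomere_calls", class(res))
  res
}

#' Minimum chromosome number from telomere counts
#'
#' Each chromosome has two telomeres, so `n_both` telomere-to-telomere
#' contigs are complete chromosomes and `n_one` single-telomere contigs can
#' at best pair up two per chromosome: the minimum is
#' `n_both + ceiling(n_one / 2)`.
#'
#' @param n_both Number of contigs with telomeres at both ends.
#' @param n_one Number of contigs with exactly one telomeric end.
#' @return An integer lower bound on the chromosome number.
#' @export
min_chromosomes <- function(n_both, n_one) {
  if (n_both < 0 || n_one < 0) abort("counts must be non-negative")
  as.integer(n_both + ceiling(n_one / 2))
}

#' Assembly summary statistics
#'
#' N50 is the standard descending-sort definition: the length `L` such that
#' contigs of length `>= L` sum to at least half of the total. GC excludes
#' N bases from the denominator.
#'
#' @param genome Genome input ([as_genome()] or `synth_genome`).
#' @return A one-row tibble: `n_contigs`, `total_bp`, `gc`, `min_len`,
#'   `max_len`, `mean_len`, `n50`.
#' @export
asm_stats <- function(genome) {
  if (inherits(genome, "synth_genome")) genome <- genome$genome
  genome <- as_genome(genome)
  if (!length(genome)) abort("empty assembly")
  lens <- Biostrings::width(genome)
  total <- sum(lens)
  sorted <- sort(lens, decreasing = TRUE)
  n50 <- sorted[which(cumsum(as.numeric(sorted)) >= total / 2)[1]]
  tibble(n_contigs = length(lens), total_bp = total,
         gc = genome_gc_excluding(genome, NULL),
         min_len = min(lens), max_len = max(lens),
         mean_len = mean(lens), n50 = as.integer(n50))
}
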