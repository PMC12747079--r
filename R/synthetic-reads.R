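# Synthetic read alignments emulating metagenomic fragment recruitment:
# uniformly placed reads with optional excluded intervals (the ground truth
# for metagenomic-island detection).

#' Generate uniformly placed read alignments against one reference
#'
#' Read start positions are uniform over all positions whose read interval
#' lies entirely outside every `excluded` interval, so coverage within the
#' excluded regions is exactly zero: the construction used to emulate a
#' metagenomic island.
#'
#' @param reference A genome input ([as_genome()]) whose first sequence is the
#'   reference, or a single named integer giving the reference length.
#' @param n_reads Number of reads.
#' @param read_len Read length in bp.
#' @param excluded Optional tibble/data.frame with `start`, `end` (1-based
#'   closed) intervals that must recruit no reads.
#' @param identity_range Range for the per-read identity column.
#' @param seed Integer seed.
#' @return A tibble with `read_id`, `ref_id`, `start`, `end`, `identity`,
#'   carrying the truth islands as attribute `"islands"`.
#' @export
gen_alignments <- function(reference, n_reads, read_len, excluded = NULL,
                           identity_range = c(0.95, 1), seed = 1L) {
  if (is.numeric(reference)) {
    ref_len <- as.integer(reference[[1]])
    ref_id <- names(reference) %||% "ref"
  } else {
    g <- as_genome(reference)
    ref_len <- Biostrings::width(g)[1]
    ref_id <- names(g)[1]
  }
  read_len <- as.integer(read_len)
  if (read_len > ref_len) abort("read_len exceeds reference length")
  ok <- IRanges::IRanges(1L, ref_len - read_len + 1L)
  if (!is.null(excluded) && nrow(as.data.frame(excluded))) {
    excluded <- as_tibble(excluded)
    if (any(excluded$start < 1 | excluded$end > ref_len)) {
      abort("excluded intervals must lie within the reference")
    }
    # a read starting in [s - read_len + 1, e] would overlap [s, e]
    bad <- IRanges::IRanges(pmax(1L, excluded$start - read_len + 1L),
                            excluded$end)
    ok <- IRanges::setdiff(ok, bad)
  }
  if (sum(IRanges::width(ok)) == 0L) {
    abort("excluded intervals cover the whole reference")
  }
  set.seed(seed)
  if (n_reads == 0) {
    out <- tibble(read_id = character(), ref_id = character(),
                  start = integer(), end = integer(), identity = double())
  } else {
    # uniform over the allowed start positions
    offs <- sample.int(sum(IRanges::width(ok)), n_reads, replace = TRUE)
    cum <- cumsum(IRanges::width(ok))
    block <- findInterval(offs - 1L, cum) + 1L
    starts <- IRanges::start(ok)[block] + (offs - c(0L, cum)[block] - 1L)
    out <- tibble(
      read_id = sprintf("read%06d", seq_len(n_reads)),
      ref_id = ref_id,
      start = as.integer(starts),
      end = as.integer(starts + read_len - 1L),
      identity = round(runif(n_reads, identity_range[1], identity_range[2]), 4))
  }
  attr(out, "islands") <- if (is.null(excluded)) {
    tibble(start = integer(), end = integer())
  } else {
    as_tibble(excluded)[, c("start", "end")]
  }
  attr(out, "ref_len") <- ref_len
  out
}

#' Write an alignment table as TSV
#'
#' @param alignments Tibble from [gen_alignments()] or compatible.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_tsv <- function(alignments, path) {
  readr::write_tsv(alignments[, c("read_id", "ref_id", "start", "end", "identity")],
                   path)
  invisible(path)
}

#' Write alignments as a minimal SAM file
#'
#' Emits an `@SQ`-headed SAM with one mapped record per alignment row
#' (FLAG 0, full-length match CIGAR, `*` sequence). Sufficient for any
#' SAM-consuming coverage tool; no base-level information is simulated.
#'
#' @param alignments Alignment tibble (`read_id`, `ref_id`, `start`, `end`).
#' @param ref_lengths Named integer vector of reference lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, ref_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (i in seq_along(ref_lengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths)[i],
                       as.integer(ref_lengths[i])), con)
  }
  if (nrow(alignments)) {
    w <- alignments$end - alignments$start + 1L
    writeLines(sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                       alignments$read_id, alignments$ref_id,
                       alignments$start, w), con)
  }
  invisible(path)
}
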