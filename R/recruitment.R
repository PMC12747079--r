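# Metagenomic read recruitment: per-reference coverage tracks, covered
# fraction with a strict presence gate, RPKM, and metagenomic island
# detection. Alignments come in as a 5-column TSV or a SAM file; read
# mapping itself is out of scope.

#' Read an alignment table (TSV or SAM)
#'
#' TSV input must carry the documented header `read_id`, `ref_id`, `start`,
#' `end`, `identity` (1-based closed coordinates). SAM input is converted
#' with Rsamtools and only primary, mapped records are kept (secondary and
#' supplementary alignments are dropped, CoverM-like semantics).
#'
#' @param path Alignment file path.
#' @param format `"auto"` (by extension), `"tsv"` or `"sam"`.
#' @return A tibble `read_id`, `ref_id`, `start`, `end`, `identity`.
#' @export
read_alignments <- function(path, format = c("auto", "tsv", "sam")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "tsv"
  }
  if (format == "tsv") {
    out <- readr::read_tsv(path, show_col_types = FALSE)
    need <- c("read_id", "ref_id", "start", "end")
    if (!all(need %in% names(out))) {
      abort("alignment TSV must have columns read_id, ref_id, start, end[, identity]")
    }
    if (!"identity" %in% names(out)) out$identity <- NA_real_
    bad <- which(!is.finite(out$start) | !is.finite(out$end) |
                   out$start < 1 | out$end < out$start)
    if (length(bad)) {
      abort(paste0("malformed alignment row(s): ",
                   paste(head(bad, 5), collapse = ", ")))
    }
    return(as_tibble(out[, c("read_id", "ref_id", "start", "end", "identity")]))
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(flag = flags, what = "qname"))
  tibble(read_id = S4Vectors::mcols(ga)$qname,
         ref_id = as.character(GenomicAlignments::seqnames(ga)),
         start = GenomicAlignments::start(ga),
         end = GenomicAlignments::end(ga),
         identity = NA_real_)
}

#' Per-bin coverage track from an alignment table
#'
#' Depth is computed at base resolution by interval stabbing and averaged
#' per bin; the base-resolution covered fraction (proportion of positions
#' with depth >= 1) is kept as an attribute.
#'
#' @param alignments Alignment tibble (`start`, `end`, 1-based closed).
#' @param ref_len Reference length in bp.
#' @param bin Bin size in bp.
#' @param ref_id Optional reference name; defaults to the one in
#'   `alignments` (or `"ref"` when empty).
#' @return A tibble of class `coverage_track` with `bin_start`, `bin_end`,
#'   `depth`; attributes `ref_len`, `bin`, `covered_fraction`,
#'   `mapped_reads`, `ref_id`.
#' @export
coverage_track <- function(alignments, ref_len, bin = 100L, ref_id = NULL) {
  ref_len <- as.integer(ref_len)
  alignments <- as_tibble(alignments)
  if (nrow(alignments)) {
    bad <- which(alignments$start < 1 | alignments$end > ref_len |
                   alignments$end < alignments$start)
    if (length(bad)) {
      abort(paste0("alignment row(s) outside [1, ref_len] or malformed: ",
                   paste(head(bad, 5), collapse = ", ")))
    }
  }
  ref_id <- ref_id %||%
    (if (nrow(alignments)) alignments$ref_id[1] else "ref")
  cov <- IRanges::coverage(
    IRanges::IRanges(alignments$start, alignments$end), width = ref_len)
  bin_start <- seq.int(1L, ref_len, by = bin)
  bin_end <- pmin(bin_start + bin - 1L, ref_len)
  depth <- IRanges::viewMeans(IRanges::Views(cov, bin_start, bin_end))
  out <- tibble(bin_start = bin_start, bin_end = bin_end,
                depth = as.numeric(depth))
  class(out) <- c("coverage_track", class(out))
  attr(out, "ref_len") <- ref_len
  attr(out, "bin") <- as.integer(bin)
  attr(out, "covered_fraction") <- sum(cov > 0) / ref_len
  attr(out, "mapped_reads") <- nrow(alignments)
  attr(out, "ref_id") <- ref_id
  out
}

#' Recruit a read set against a reference
#'
#' Computes mapped reads, base-resolution covered fraction and RPKM
#' (reads per kilobase of reference per million reads in the library). A
#' reference is called present only when its covered fraction is strictly
#' greater than 0.5; RPKM is set to zero otherwise.
#'
#' @param ref Genome input or a single integer reference length (optionally
#'   named).
#' @param alignments Alignment tibble for this sample; rows are filtered to
#'   the reference name when a `ref_id` column is present.
#' @param library_size Total reads in the sample (>= mapped reads).
#' @return A one-row tibble: `ref_id`, `ref_len`, `mapped_reads`,
#'   `covered_fraction`, `rpkm`, `present`.
#' @export
recruit <- function(ref, alignments, library_size) {
  if (is.numeric(ref)) {
    ref_len <- as.integer(ref[[1]])
    ref_id <- names(ref) %||% "ref"
  } else {
    g <- as_genome(ref)
    ref_len <- Biostrings::width(g)[1]
    ref_id <- names(g)[1]
  }
  if (library_size <= 0) abort("library_size must be positive")
  alignments <- as_tibble(alignments)
  if ("ref_id" %in% names(alignments)) {
    alignments <- alignments[alignments$ref_id == ref_id, , drop = FALSE]
  }
  mapped <- nrow(alignments)
  if (library_size < mapped) abort("library_size must be >= mapped reads")
  cov <- coverage_track(alignments, ref_len, bin = max(1L, ref_len %/% 1000L),
                        ref_id = ref_id)
  cf <- attr(cov, "covered_fraction")
  rpkm_raw <- mapped / ((ref_len / 1e3) * (library_size / 1e6))
  present <- cf > 0.5  # strict, per the covered-fraction gate
  tibble(ref_id = ref_id, ref_len = ref_len, mapped_reads = mapped,
         covered_fraction = cf, rpkm = if (present) rpkm_raw else 0,
         present = present)
}

#' Detect metagenomic islands in a coverage track
#'
#' Islands are maximal runs of bins with depth at most `max_depth`, merged
#' across single-bin interruptions and retained when the merged run spans at
#' least `min_len` bp.
#'
#' @param track A [coverage_track()].
#' @param max_depth Maximum per-bin mean depth inside an island.
#' @param min_len Minimum island length in bp.
#' @return A sorted tibble `start`, `end`, `length`, `n_bins`.
#' @export
detect_islands <- function(track, max_depth = 0, min_len = 5000L) {
  low <- track$depth <= max_depth
  empty <- tibble(start = integer(), end = integer(), length = integer(),
                  n_bins = integer())
  if (!any(low)) return(empty)
  idx <- which(low)
  brk <- which(diff(idx) > 2L)  # gaps of a single covered bin are bridged
  gs <- idx[c(1L, brk + 1L)]
  ge <- idx[c(brk, length(idx))]
  out <- tibble(start = track$bin_start[gs], end = track$bin_end[ge],
                n_bins = ge - gs + 1L)
  out$length <- out$end - out$start + 1L
  out <- out[out$length >= min_len, c("start", "end", "length", "n_bins")]
  arrange(out, .data$start)
}

#' Write islands as a BED file
#'
#' @param islands Tibble from [detect_islands()].
#' @param ref_id Reference name for the BED chrom column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_islands_bed <- function(islands, ref_id, path) {
  df <- data.frame(chrom = ref_id, start = islands$start - 1L,  # BED half-open
                   end = islands$end)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}
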