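# Synthetic host genomes with telomere tracts and implanted polinton-like
# elements, each paired with a machine-readable truth set so the scanners can
# be scored against known answers.

#' Describe a synthetic endogenous viral element
#'
#' The descriptor mirrors the anatomy of an integrated polinton-like virus:
#' a low-GC body of `length` bp bounded by terminal inverted (TIR) or direct
#' (TDR) repeats of `repeat_len` bp, optionally a 4-8 bp target-site
#' duplication created on insertion, and one or more hallmark peptide
#' "anchors" encoded as exact in-frame ORFs.
#'
#' @param length Element length in bp (terminal repeats included).
#' @param gc Element GC fraction in (0, 1).
#' @param repeat_kind One of `"TIR"`, `"TDR"`, `"none"`.
#' @param repeat_len Terminal repeat length in bp (ignored for `"none"`).
#' @param tsd_len Target-site duplication length: 0 (none) or 4-8 bp.
#' @param anchor_peptides Character vector of short peptide motifs to embed
#'   as forward-strand ORFs.
#' @param anchor_strand `"+"` (default) or `"-"`: strand carrying the anchors.
#' @return A list of class `element_spec`.
#' @export
element_spec <- function(length, gc, repeat_kind = c("TIR", "TDR", "none"),
                         repeat_len = 0L, tsd_len = 0L,
                         anchor_peptides = character(),
                         anchor_strand = "+") {
  repeat_kind <- match.arg(repeat_kind)
  length <- as.integer(length); repeat_len <- as.integer(repeat_len)
  tsd_len <- as.integer(tsd_len)
  if (repeat_kind == "none") repeat_len <- 0L
  if (2L * repeat_len >= length) abort("2 * repeat_len must be < length")
  if (gc <= 0 || gc >= 1) abort("gc must lie in (0, 1)")
  if (!(tsd_len == 0L || (tsd_len >= 4L && tsd_len <= 8L))) {
    abort("tsd_len must be 0 or in 4..8")
  }
  if (!anchor_strand %in% c("+", "-")) abort("anchor_strand must be '+' or '-'")
  structure(list(length = length, gc = gc, repeat_kind = repeat_kind,
                 repeat_len = repeat_len, tsd_len = tsd_len,
                 anchor_peptides = toupper(anchor_peptides),
                 anchor_strand = anchor_strand),
            class = "element_spec")
}

empty_eve_truth <- function() {
  tibble(contig_id = character(), start = integer(), end = integer(),
         length = integer(), gc = double(), repeat_kind = character(),
         repeat_len = integer(), tsd_len = integer(), tsd_seq = character(),
         anchors = list())
}

new_truth_set <- function(telomeres = NULL, eves = empty_eve_truth(),
                          islands = NULL, growth_params = NULL) {
  structure(list(telomeres = telomeres, eves = eves, islands = islands,
                 growth_params = growth_params),
            class = "truth_set")
}

#' Generate a multi-contig host genome with planned telomere tracts
#'
#' Background bases are i.i.d. at the requested GC; each contig end flagged
#' in `end_plan` carries a tandem tract of the telomere motif (forward motif
#' at the left terminus, reverse complement at the right) starting exactly at
#' the terminus.
#'
#' @param n_contigs Number of contigs.
#' @param length_range Two-element bp range; contig lengths are drawn
#'   uniformly from it.
#' @param gc Background GC fraction in (0, 1).
#' @param telomere_motif Telomeric repeat unit, 4-10 bp of unambiguous DNA.
#' @param end_plan Per-contig labels, recycled if length 1: `"both"`,
#'   `"one"` (left end only) or `"none"`.
#' @param n_motif_copies Tandem copies planted per telomeric end.
#' @param seed Integer seed; identical seeds give byte-identical genomes.
#' @return A list of class `synth_genome` with elements `genome`
#'   (`DNAStringSet`) and `truth` (a `truth_set` whose `$telomeres` tibble
#'   records the plan).
#' @export
gen_host_genome <- function(n_contigs, length_range, gc = 0.52,
                            telomere_motif = "TTAGGG",
                            end_plan = "none", n_motif_copies = 12L,
                            seed = 1L) {
  stopifnot(n_contigs >= 1)
  telomere_motif <- as_seq_chr(telomere_motif)
  check_dna(telomere_motif, "telomere motif")
  if (grepl("N", telomere_motif)) abort("telomere motif must be unambiguous")
  mlen <- nchar(telomere_motif)
  if (mlen < 4 || mlen > 10) abort("telomere motif must be 4-10 bp")
  if (gc <= 0 || gc >= 1) abort("gc must lie in (0, 1)")
  length_range <- as.integer(length_range)
  if (length(length_range) == 1L) length_range <- rep(length_range, 2L)
  tract <- mlen * n_motif_copies
  if (length_range[1] < 2L * tract) {
    abort("length_range must allow at least twice the telomere tract length")
  }
  end_plan <- rep_len(end_plan, n_contigs)
  if (!all(end_plan %in% c("both", "one", "none"))) {
    abort("end_plan labels must be 'both', 'one' or 'none'")
  }
  set.seed(seed)
  lens <- if (length_range[1] == length_range[2]) {
    rep(length_range[1], n_contigs)
  } else {
    sample(seq(length_range[1], length_range[2]), n_contigs, replace = TRUE)
  }
  left_tel <- paste(rep(telomere_motif, n_motif_copies), collapse = "")
  right_tel <- paste(rep(revcomp(telomere_motif), n_motif_copies), collapse = "")
  seqs <- character(n_contigs)
  for (i in seq_len(n_contigs)) {
    has_left <- end_plan[i] %in% c("both", "one")
    has_right <- end_plan[i] == "both"
    core_len <- lens[i] - has_left * tract - has_right * tract
    seqs[i] <- paste0(if (has_left) left_tel else "",
                      random_dna(core_len, gc),
                      if (has_right) right_tel else "")
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- paste0("C", seq_len(n_contigs))
  telomeres <- tibble(
    contig_id = names(genome),
    length = lens,
    status = end_plan,
    left_end = ifelse(end_plan %in% c("both", "one"), "telomere", "none"),
    right_end = ifelse(end_plan == "both", "telomere", "none"),
    planted_copies = as.integer(n_motif_copies)
  )
  structure(list(genome = genome,
                 truth = new_truth_set(telomeres = telomeres),
                 telomere_motif = telomere_motif, gc = gc, seed = seed),
            class = "synth_genome")
}

# Deterministic aa -> codon map (first codon alphabetically per residue),
# so embedded ORFs translate back to the requested peptide exactly.
codon_for <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- vapply(split(names(gc), gc), function(x) sort(x)[1], character(1))
    }
    tab
  }
})

encode_orf <- function(peptide) {
  peptide <- toupper(peptide)
  if (grepl("[^A-Z]", peptide) || grepl("[BJOUXZ*]", peptide)) {
    abort("anchor peptides must use the 20 standard amino-acid letters")
  }
  codons <- codon_for()[strsplit(peptide, "")[[1]]]
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

build_element <- function(spec) {
  rep_seq <- if (spec$repeat_len > 0) random_dna(spec$repeat_len, spec$gc) else ""
  core_len <- spec$length - 2L * spec$repeat_len
  core <- random_dna(core_len, spec$gc)
  anchors <- tibble(name = character(), offset = integer(),
                    strand = character(), width = integer())
  if (length(spec$anchor_peptides)) {
    pos <- 101L  # offset of first ORF within the core
    for (p in spec$anchor_peptides) {
      orf <- encode_orf(p)
      if (spec$anchor_strand == "-") orf <- revcomp(orf)
      w <- nchar(orf)
      if (pos + w - 1L > core_len - 100L) {
        abort("element core too short to hold the requested anchor ORFs")
      }
      substring(core, pos, pos + w - 1L) <- orf
      anchors <- bind_rows(anchors, tibble(
        name = p, offset = spec$repeat_len + pos, strand = spec$anchor_strand,
        width = w))
      pos <- pos + w + 50L
    }
  }
  tail_seq <- switch(spec$repeat_kind,
                     TIR = revcomp(rep_seq),
                     TDR = rep_seq,
                     none = "")
  list(seq = paste0(rep_seq, core, tail_seq), anchors = anchors)
}

#' Implant a synthetic viral element into a host genome
#'
#' Inserts an element built from `spec` after position `pos` of a contig.
#' When `spec$tsd_len > 0` the `tsd_len` host bases immediately left of the
#' insertion point are duplicated immediately right of the element,
#' emulating a target-site duplication. Host bases are otherwise unchanged
#' and total length grows by exactly `spec$length + spec$tsd_len`.
#'
#' @param x A `synth_genome` from [gen_host_genome()], or any genome input
#'   accepted by [as_genome()].
#' @param contig_id Contig to modify.
#' @param pos 1-based host position after which the element is inserted;
#'   must be at least 1 kb from either contig end.
#' @param spec An [element_spec()].
#' @param seed Integer seed for the element's random sequence.
#' @return A `synth_genome` whose truth set gained one element record
#'   (element span in post-insertion coordinates).
#' @export
implant_eve <- function(x, contig_id, pos, spec, seed = 1L) {
  if (!inherits(x, "synth_genome")) {
    x <- structure(list(genome = as_genome(x), truth = new_truth_set()),
                   class = "synth_genome")
  }
  stopifnot(inherits(spec, "element_spec"))
  genome <- x$genome
  if (!contig_id %in% names(genome)) abort("unknown contig_id")
  host <- as.character(genome[[contig_id]])
  n <- nchar(host)
  pos <- as.integer(pos)
  if (pos < max(1000L, spec$tsd_len) || pos > n - 1000L) {
    abort("pos must be at least 1 kb from either contig end")
  }
  prev <- x$truth$eves
  if (nrow(prev)) {
    same <- prev[prev$contig_id == contig_id, , drop = FALSE]
    if (nrow(same) && any(pos >= same$start - 20L & pos <= same$end + 20L)) {
      abort("insertion position overlaps a previously implanted element")
    }
  }
  set.seed(seed)
  el <- build_element(spec)
  tsd_seq <- if (spec$tsd_len > 0) substring(host, pos - spec$tsd_len + 1L, pos) else ""
  new_seq <- paste0(substring(host, 1L, pos), el$seq, tsd_seq,
                    substring(host, pos + 1L, n))
  genome[[contig_id]] <- Biostrings::DNAString(new_seq)
  start <- pos + 1L
  end <- pos + spec$length
  shift <- spec$length + spec$tsd_len
  truth <- x$truth
  if (nrow(truth$eves)) {
    idx <- truth$eves$contig_id == contig_id & truth$eves$start > pos
    truth$eves$start[idx] <- truth$eves$start[idx] + shift
    truth$eves$end[idx] <- truth$eves$end[idx] + shift
  }
  if (!is.null(truth$telomeres)) {
    idx <- truth$telomeres$contig_id == contig_id
    truth$telomeres$length[idx] <- truth$telomeres$length[idx] + shift
  }
  anchors <- el$anchors
  anchors$offset <- anchors$offset + pos  # absolute contig coordinate
  truth$eves <- bind_rows(truth$eves, tibble(
    contig_id = contig_id, start = start, end = end, length = spec$length,
    gc = gc_fraction(el$seq), repeat_kind = spec$repeat_kind,
    repeat_len = spec$repeat_len, tsd_len = spec$tsd_len, tsd_seq = tsd_seq,
    anchors = list(anchors)))
  truth$eves <- arrange(truth$eves, .data$contig_id, .data$start)
  x$genome <- genome
  x$truth <- truth
  x
}

#' Export a synthetic truth set's element records as GFF3
#'
#' @param x A `synth_genome` or `truth_set`.
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_truth_gff3 <- function(x, path) {
  truth <- if (inherits(x, "synth_genome")) x$truth else x
  eves <- truth$eves
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(eves)) {
    for (i in seq_len(nrow(eves))) {
      id <- sprintf("EVE%03d", i)
      writeLines(sprintf(
        "%s\tevekit\tviral_element\t%d\t%d\t.\t+\t.\tID=%s;repeat_kind=%s;tsd_len=%d",
        eves$contig_id[i], eves$start[i], eves$end[i], id,
        eves$repeat_kind[i], eves$tsd_len[i]), con)
      an <- eves$anchors[[i]]
      if (!is.null(an) && nrow(an)) {
        writeLines(sprintf(
          "%s\tevekit\thallmark_gene\t%d\t%d\t.\t%s\t0\tParent=%s;Name=%s",
          eves$contig_id[i], an$offset, an$offset + an$width - 1L,
          an$strand, id, an$name), con)
      }
    }
  }
  invisible(path)
}
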