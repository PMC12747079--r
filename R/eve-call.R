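# Whole-genome endogenous viral element calling: low-GC candidate intervals
# must contain hallmark-gene (anchor) evidence; boundaries are refined to
# terminal repeat ends found by seed-and-extend inside the candidate region;
# target-site duplications are read off the refined flanks.

#' Default parameters for [call_eves()]
#'
#' @param window,step GC track granularity in bp.
#' @param min_delta Minimum GC depression below baseline, percentage points.
#' @param min_len,max_len Element length bounds in bp.
#' @param repeat_min_len Minimum terminal repeat length in bp.
#' @param max_mismatch_frac Maximum terminal repeat mismatch fraction.
#' @param refine_zone How far (bp) from each candidate-region end to search
#'   for repeat copies during boundary refinement.
#' @param boundary_pad Padding (bp) added around each GC candidate before
#'   refinement, absorbing window-resolution boundary error.
#' @param tsd_k Two-element TSD length range in bp.
#' @return A named list of parameters.
#' @export
eve_params <- function(window = 1000L, step = 200L, min_delta = 8,
                       min_len = 5000L, max_len = 60000L,
                       repeat_min_len = 100L, max_mismatch_frac = 0.05,
                       refine_zone = 3000L, boundary_pad = 1000L,
                       tsd_k = c(4L, 8L)) {
  list(window = as.integer(window), step = as.integer(step),
       min_delta = min_delta, min_len = as.integer(min_len),
       max_len = as.integer(max_len),
       repeat_min_len = as.integer(repeat_min_len),
       max_mismatch_frac = max_mismatch_frac,
       refine_zone = as.integer(refine_zone),
       boundary_pad = as.integer(boundary_pad),
       tsd_k = as.integer(tsd_k))
}

#' Locate exact peptide anchors by six-frame translation
#'
#' Translates all six reading frames and reports exact occurrences of each
#' peptide, with coordinates on the forward strand.
#'
#' @param seq DNA sequence.
#' @param peptides Character vector of peptide motifs.
#' @return A tibble `name`, `strand`, `frame`, `start`, `end`.
#' @export
scan_anchor_peptides <- function(seq, peptides) {
  seq <- as_seq_chr(seq)
  n <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (f in 0:2) {
      len <- ((n - f) %/% 3L) * 3L
      if (len < 3L) next
      aa <- as.character(suppressWarnings(Biostrings::translate(
        Biostrings::DNAString(substring(s, f + 1L, f + len)),
        if.fuzzy.codon = "X")))
      for (p in peptides) {
        hits <- gregexpr(p, aa, fixed = TRUE)[[1]]
        if (hits[1] == -1L) next
        nt_start <- f + 3L * (as.integer(hits) - 1L) + 1L  # on strand s
        nt_end <- nt_start + 3L * nchar(p) - 1L
        if (strand == "-") {
          tmp <- n - nt_end + 1L
          nt_end <- n - nt_start + 1L
          nt_start <- tmp
        }
        out[[length(out) + 1L]] <- tibble(
          name = p, strand = strand, frame = f + 1L,
          start = nt_start, end = nt_end)
      }
    }
  }
  if (!length(out)) {
    return(tibble(name = character(), strand = character(), frame = integer(),
                  start = integer(), end = integer()))
  }
  arrange(bind_rows(out), .data$start)
}

# Seed-and-extend search for the best repeat pair between the two ends of a
# candidate region (copies need not touch the region termini). Returns NULL
# or list(kind, left_start, left_end, right_start, right_end, length,
# identity) in region coordinates.
seed_repeat_pair <- function(region, zone_len, min_len, max_mismatch_frac,
                             k = 20L) {
  n <- nchar(region)
  zl <- min(as.integer(zone_len), n %/% 2L)
  if (zl < k) return(NULL)
  left <- substring(region, 1L, zl)
  right <- substring(region, n - zl + 1L, n)
  lch <- strsplit(left, "", fixed = TRUE)[[1]]

  kmers <- function(x, nx) substring(x, 1:(nx - k + 1L), k:nx)
  lk <- kmers(left, zl)

  best <- NULL
  for (kind in c("TIR", "TDR")) {
    target <- if (kind == "TIR") revcomp(right) else right
    tk <- kmers(target, zl)
    shared <- intersect(lk, tk)
    shared <- shared[!grepl("N", shared)]
    if (!length(shared)) next
    li <- which(lk %in% shared)
    ti <- which(tk %in% shared)
    lpos <- split(li, lk[li])
    tpos <- split(ti, tk[ti])
    anchors <- list()
    for (km in shared) {
      for (i in lpos[[km]]) for (j in tpos[[km]]) {
        anchors[[length(anchors) + 1L]] <- c(i, j)
      }
      if (length(anchors) > 5000L) break
    }
    if (!length(anchors)) next
    am <- do.call(rbind, anchors)
    diag <- am[, 1] - am[, 2]
    keep <- !duplicated(diag)
    am <- am[keep, , drop = FALSE]
    tch <- strsplit(target, "", fixed = TRUE)[[1]]
    look <- 8L  # a mismatch is crossed only when followed by `look` exact matches
    match_at <- function(ii, jj) lch[ii] == tch[jj] & lch[ii] != "N" &
      tch[jj] != "N"
    run_ok <- function(ii, jj, dir) {
      idx <- seq_len(look)
      ii2 <- ii + dir * idx; jj2 <- jj + dir * idx
      keep <- ii2 >= 1L & ii2 <= zl & jj2 >= 1L & jj2 <= zl
      all(match_at(ii2[keep], jj2[keep]))
    }
    for (r in seq_len(nrow(am))) {
      i <- am[r, 1]; j <- am[r, 2]
      mism <- 0L
      # extend left
      while (i > 1L && j > 1L) {
        if (match_at(i - 1L, j - 1L)) {
          i <- i - 1L; j <- j - 1L
        } else if (i > 2L && j > 2L && run_ok(i - 1L, j - 1L, -1L)) {
          mism <- mism + 1L; i <- i - 1L; j <- j - 1L
        } else break
      }
      ie <- am[r, 1] + k - 1L; je <- am[r, 2] + k - 1L
      # extend right
      while (ie < zl && je < zl) {
        if (match_at(ie + 1L, je + 1L)) {
          ie <- ie + 1L; je <- je + 1L
        } else if (ie < zl - 1L && je < zl - 1L && run_ok(ie + 1L, je + 1L, 1L)) {
          mism <- mism + 1L; ie <- ie + 1L; je <- je + 1L
        } else break
      }
      len <- ie - i + 1L
      if (len < min_len) next
      identity <- 1 - mism / len
      if (identity < 1 - max_mismatch_frac) next
      # map target coords back to region coords
      if (kind == "TIR") {
        # target position q corresponds to region position n - q + 1
        rs <- n - je + 1L; re <- n - j + 1L
      } else {
        rs <- n - zl + j; re <- n - zl + je
      }
      if (rs <= i + len - 1L) next  # copies must not overlap
      cand <- list(kind = kind, left_start = i, left_end = ie,
                   right_start = rs, right_end = re,
                   length = len, identity = identity)
      if (is.null(best) || len > best$length ||
          (len == best$length && kind == "TIR" && best$kind == "TDR")) {
        best <- cand
      }
    }
  }
  best
}

#' Hard-mask intervals of a genome with N
#'
#' @param genome Genome input ([as_genome()]).
#' @param intervals Tibble with `contig_id`, `start`, `end`.
#' @return The masked `DNAStringSet`.
#' @export
mask_intervals <- function(genome, intervals) {
  genome <- as_genome(genome)
  for (cid in unique(intervals$contig_id)) {
    s <- as.character(genome[[cid]])
    iv <- intervals[intervals$contig_id == cid, , drop = FALSE]
    for (r in seq_len(nrow(iv))) {
      substring(s, iv$start[r], iv$end[r]) <-
        strrep("N", iv$end[r] - iv$start[r] + 1L)
    }
    genome[[cid]] <- Biostrings::DNAString(s)
  }
  genome
}

genome_gc_excluding <- function(genome, intervals) {
  if (!is.null(intervals) && nrow(intervals)) {
    genome <- mask_intervals(genome, intervals)
  }
  f <- Biostrings::letterFrequency(genome, c("G", "C", "N"))
  denom <- sum(Biostrings::width(genome)) - sum(f[, "N"])
  if (denom == 0) return(NA_real_)
  sum(f[, "G"] + f[, "C"]) / denom
}

read_anchor_annotations <- function(anchors) {
  if (is.character(anchors) && length(anchors) == 1L && file.exists(anchors)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("reading GFF3 anchors requires the rtracklayer package")
    }
    gr <- rtracklayer::import(anchors)
    gr <- gr[gr$type %in% c("hallmark_gene", "gene", "CDS")]
    df <- as.data.frame(gr)
    nm <- df$Name %||% df$ID %||% rep("anchor", nrow(df))
    return(tibble(contig_id = as.character(df$seqnames),
                  start = df$start, end = df$end,
                  name = as.character(nm)))
  }
  as_tibble(anchors)
}

#' Call endogenous viral elements in a genome
#'
#' Detection follows a hallmark-first strategy: GC-depressed candidate
#' intervals (relative to a host baseline re-estimated once with candidate
#' intervals excluded) are retained only when they contain at least one
#' hallmark anchor - either a peptide motif located by exact six-frame scan
#' or a supplied annotation. Candidate boundaries are refined to the
#' outermost coordinates of a terminal repeat pair when one is found, and
#' target-site duplications are read from the 20-bp flanks of the refined
#' span.
#'
#' @param genome Genome input ([as_genome()] or a `synth_genome`).
#' @param anchors Hallmark evidence: a character vector of peptide motifs, a
#'   tibble with `contig_id`, `start`, `end` (and optionally `name`), or a
#'   GFF3 file path. Mandatory.
#' @param params Parameter list from [eve_params()].
#' @return A tibble of class `eve_calls`, one row per element, sorted by
#'   contig and start; the final host baseline GC is kept as attribute
#'   `"baseline_gc"`.
#' @export
call_eves <- function(genome, anchors, params = eve_params()) {
  if (inherits(genome, "synth_genome")) genome <- genome$genome
  genome <- as_genome(genome)
  if (missing(anchors) || is.null(anchors) || !length(anchors)) {
    abort("anchor evidence is mandatory: supply hallmark peptides or annotations")
  }
  peptide_mode <- is.character(anchors) &&
    !(length(anchors) == 1L && file.exists(anchors))
  anno <- if (!peptide_mode) read_anchor_annotations(anchors) else NULL
  if (!peptide_mode && !nrow(anno)) {
    abort("anchor evidence is mandatory: the annotation set is empty")
  }

  tracks <- lapply(as.character(genome), gc_track,
                   window = params$window, step = params$step)
  segment_all <- function(baseline) {
    map_dfr(names(tracks), function(cid) {
      seg <- segment_low_gc(tracks[[cid]], baseline, params$min_delta,
                            params$min_len, params$max_len)
      if (nrow(seg)) seg$contig_id <- cid
      seg
    })
  }
  baseline0 <- genome_gc_excluding(genome, NULL)
  cand0 <- segment_all(baseline0)
  baseline <- genome_gc_excluding(genome, cand0)  # one refinement iteration
  cand <- segment_all(baseline)

  calls <- list()
  for (r in seq_len(nrow(cand))) {
    cid <- cand$contig_id[r]
    contig <- as.character(genome[[cid]])
    n <- nchar(contig)
    rs <- max(1L, cand$start[r] - params$boundary_pad)
    re <- min(n, cand$end[r] + params$boundary_pad)
    region <- substring(contig, rs, re)
    if (peptide_mode) {
      hits <- scan_anchor_peptides(region, anchors)
      if (nrow(hits)) {
        hits$start <- hits$start + rs - 1L
        hits$end <- hits$end + rs - 1L
      }
    } else {
      a <- anno[anno$contig_id == cid & anno$start <= re & anno$end >= rs, ]
      hits <- tibble(name = a$name %||% "anchor", strand = NA_character_,
                     frame = NA_integer_, start = a$start, end = a$end)
    }
    if (!nrow(hits)) next  # anchor evidence is mandatory

    rp <- seed_repeat_pair(region, params$refine_zone, params$repeat_min_len,
                           params$max_mismatch_frac)
    if (!is.null(rp)) {
      span_start <- rs + rp$left_start - 1L
      span_end <- rs + rp$right_end - 1L
      repeat_kind <- rp$kind
      repeat_len <- rp$length
      repeat_identity <- rp$identity
    } else {
      span_start <- cand$start[r]; span_end <- cand$end[r]
      repeat_kind <- "none"; repeat_len <- 0L; repeat_identity <- NA_real_
    }
    lf <- substring(contig, max(1L, span_start - 20L), span_start - 1L)
    rf <- substring(contig, span_end + 1L, min(n, span_end + 20L))
    tsd <- if (nchar(lf) >= params$tsd_k[1] && nchar(rf) >= params$tsd_k[1]) {
      find_tsd(lf, rf, params$tsd_k[1], params$tsd_k[2])
    } else {
      find_tsd("A", "C")  # empty result shape
    }
    span_seq <- substring(contig, span_start, span_end)
    inside <- hits[hits$start >= span_start & hits$end <= span_end, ]
    calls[[length(calls) + 1L]] <- tibble(
      contig_id = cid, start = span_start, end = span_end,
      length = span_end - span_start + 1L,
      gc = gc_fraction(span_seq),
      repeat_kind = repeat_kind, repeat_len = as.integer(repeat_len),
      repeat_identity = repeat_identity,
      tsd_len = if (nrow(tsd)) tsd$length else 0L,
      tsd_seq = if (nrow(tsd)) tsd$sequence else NA_character_,
      n_anchors = nrow(inside), anchors = list(inside))
  }
  out <- if (length(calls)) bind_rows(calls) else tibble(
    contig_id = character(), start = integer(), end = integer(),
    length = integer(), gc = double(), repeat_kind = character(),
    repeat_len = integer(), repeat_identity = double(), tsd_len = integer(),
    tsd_seq = character(), n_anchors = integer(), anchors = list())
  out <- distinct(out, .data$contig_id, .data$start, .data$end,
                  .keep_all = TRUE)
  out <- arrange(out, .data$contig_id, .data$start)
  out$eve_id <- if (nrow(out)) sprintf("EVE_%s_%d", out$contig_id, out$start)
                else character()
  class(out) <- c("eve_calls", class(out))
  attr(out, "baseline_gc") <- baseline
  attr(out, "params") <- params
  out
}

#' Classify elements by terminal repeat kind and integration enzyme
#'
#' Elements with terminal direct repeats and a tyrosine recombinase are the
#' YREC/TDR type; terminal inverted repeats with a canonical retroviral-like
#' integrase are the canonical polinton-like type; everything else is left
#' unclassified. A consistency warning column flags TDR elements that also
#' carry a target-site duplication, since tyrosine-recombinase integration
#' via a circular intermediate is not expected to create one.
#'
#' @param calls An `eve_calls` tibble.
#' @param integrase Integration enzyme per element: a character vector
#'   (`"rve-INT"`, `"YREC"`, `"rve-other"`, `"none"`) parallel to `calls`,
#'   or a tibble with `contig_id`, `start` (a position inside the element)
#'   and `integrase`.
#' @return `calls` with `integrase`, `class_label` and `tdr_tsd_warning`
#'   columns added.
#' @export
classify_eves <- function(calls, integrase) {
  if (is.data.frame(integrase)) {
    intg <- rep(NA_character_, nrow(calls))
    for (i in seq_len(nrow(calls))) {
      hit <- integrase$contig_id == calls$contig_id[i] &
        integrase$start >= calls$start[i] - 100 &
        integrase$start <= calls$end[i] + 100
      if (any(hit)) intg[i] <- integrase$integrase[which(hit)[1]]
    }
  } else {
    intg <- rep_len(as.character(integrase), nrow(calls))
  }
  intg[is.na(intg)] <- "none"
  label <- dplyr::case_when(
    calls$repeat_kind == "TDR" & intg == "YREC" ~ "yrec-TDR-type",
    calls$repeat_kind == "TIR" & intg == "rve-INT" ~ "canonical-polinton-like",
    TRUE ~ "unclassified")
  warn_flag <- calls$repeat_kind == "TDR" & calls$tsd_len > 0
  if (any(warn_flag)) {
    warn("TDR element(s) with a target-site duplication: unexpected for tyrosine-recombinase integration")
  }
  calls$integrase <- intg
  calls$class_label <- label
  calls$tdr_tsd_warning <- warn_flag
  calls
}

lower_median <- function(x) {
  x <- sort(x)
  if (!length(x)) return(NA_real_)
  as.numeric(x[ceiling(length(x) / 2)])
}

#' Summarise a set of element calls
#'
#' @param calls An `eve_calls` tibble (optionally classified).
#' @param even_median `"lower"` (default) takes the lower of the two middle
#'   order statistics for even counts; `"midpoint"` averages them.
#' @return A one-row tibble: `n`, `median_length`, `mean_gc`,
#'   `median_tir_len`, `median_tdr_len`, `n_tir`, `n_tdr`, and per-class
#'   counts when a `class_label` column is present.
#' @export
summarize_eves <- function(calls, even_median = c("lower", "midpoint")) {
  even_median <- match.arg(even_median)
  med <- if (even_median == "lower") lower_median else
    function(x) if (length(x)) median(x) else NA_real_
  tir <- calls$repeat_len[calls$repeat_kind == "TIR"]
  tdr <- calls$repeat_len[calls$repeat_kind == "TDR"]
  out <- tibble(
    n = nrow(calls),
    median_length = med(calls$length),
    mean_gc = if (nrow(calls)) mean(calls$gc) else NA_real_,
    median_tir_len = med(tir), median_tdr_len = med(tdr),
    n_tir = length(tir), n_tdr = length(tdr))
  if ("class_label" %in% names(calls)) {
    for (cl in c("canonical-polinton-like", "yrec-TDR-type", "unclassified")) {
      out[[paste0("n_", gsub("-", "_", cl))]] <- sum(calls$class_label == cl)
    }
  }
  out
}
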