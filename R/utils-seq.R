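# Sequence helpers shared across modules. Genomes travel as Biostrings
# DNAStringSet; single sequences may be character scalars or DNAString.
# All coordinates are 1-based closed (IRanges/GFF3 convention).

#' Coerce input to a DNAStringSet
#'
#' Accepts a `DNAStringSet`, a `DNAString`, a (named) character vector of
#' sequences, or a path to a FASTA file.
#'
#' @param x Genome input.
#' @return A named `DNAStringSet`.
#' @export
as_genome <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    if (length(x) && is.null(names(x))) names(x) <- paste0("C", seq_along(x))
    return(x)
  }
  if (methods::is(x, "DNAString")) {
    out <- Biostrings::DNAStringSet(x)
    names(out) <- "C1"
    return(out)
  }
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      !grepl("^[ACGTNacgtn]+$", x)) {
    return(Biostrings::readDNAStringSet(x))
  }
  if (is.character(x)) {
    out <- Biostrings::DNAStringSet(x)
    names(out) <- names(x) %||% paste0("C", seq_along(out))
    return(out)
  }
  abort("cannot interpret input as a genome (DNAStringSet, character or FASTA path)")
}

# single sequence as plain uppercase character scalar
as_seq_chr <- function(x) {
  if (methods::is(x, "DNAString") || methods::is(x, "DNAStringSet")) {
    x <- as.character(x)
  }
  if (!is.character(x) || length(x) != 1L) {
    abort("expected a single DNA sequence")
  }
  toupper(x)
}

check_dna <- function(x, what = "sequence") {
  if (grepl("[^ACGTN]", x)) {
    abort(paste0(what, " contains characters other than A/C/G/T/N"))
  }
  invisible(x)
}

#' Reverse complement of a DNA string
#'
#' @param x A DNA sequence (character scalar or `DNAString`).
#' @return A character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(as_seq_chr(x))))
}

#' Sample a random DNA sequence at a target GC content
#'
#' Bases are drawn i.i.d. with P(G) + P(C) = `gc`, split evenly between G and
#' C (and A and T). Uses the current RNG state; callers control the seed.
#'
#' @param n Sequence length in bp.
#' @param gc Target GC fraction in (0, 1).
#' @return A character scalar of length-`n` DNA.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc > 0, gc < 1)
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Introduce i.i.d. substitutions into a sequence
#'
#' Each position is substituted with probability `rate`, always to a
#' *different* base, so the expected identity to the input is `1 - rate`.
#'
#' @param x DNA sequence.
#' @param rate Per-base substitution probability.
#' @param seed Optional integer seed for reproducibility.
#' @return Mutated sequence as a character scalar.
#' @export
mutate_sequence <- function(x, rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- strsplit(as_seq_chr(x), "", fixed = TRUE)[[1]]
  hit <- which(runif(length(s)) < rate)
  if (length(hit)) {
    alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
    s[hit] <- vapply(s[hit], function(b) {
      substring(alt[[b]], k <- sample.int(3, 1), k)
    }, character(1))
  }
  paste(s, collapse = "")
}

# GC fraction of a sequence, N excluded from the denominator
gc_fraction <- function(x) {
  x <- Biostrings::DNAString(as_seq_chr(x))
  f <- Biostrings::letterFrequency(x, c("G", "C", "N"))
  denom <- length(x) - f[["N"]]
  if (denom == 0) return(NA_real_)
  (f[["G"]] + f[["C"]]) / denom
}

#' Write a DNAStringSet to FASTA (80-column wrap)
#'
#' @param genome Genome input coercible by [as_genome()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(as_genome(genome), path, width = 80L)
  invisible(path)
}
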