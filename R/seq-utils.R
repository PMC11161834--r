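# Low-level sequence helpers.  All coordinates in this package are 0-based,
# half-open; strand "-" means the reverse complement of the named interval.

#' Reverse complement of DNA strings
#'
#' Vectorized reverse complement over plain character vectors.  IUPAC
#' ambiguity codes other than N are not supported.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N, case-insensitive).
#' @return character vector of reverse complements.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Random DNA sequence
#'
#' Draws bases i.i.d. uniform over A/C/G/T from the current RNG stream.
#'
#' @param n sequence length in bp.
#' @param gc GC fraction (default 0.5).
#' @return a single DNA string of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.  seed = NULL evaluates in the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# substring with 0-based half-open coordinates
substr0 <- function(x, start, end) substr(x, start + 1L, end)

# length of the exact common prefix of two strings
common_prefix_len <- function(a, b) cpp_common_prefix(a, b)

# split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

is_dna <- function(x) {
  all(grepl("^[ACGTNacgtn]*$", x))
}

#' Read sequences from FASTA/FASTQ
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning a plain named
#' character vector, the representation used throughout this package.
#'
#' @param path file path.
#' @param format `"fasta"` or `"fastq"`; guessed from the extension by default.
#' @return named character vector of sequences.
#' @export
read_seqs <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  }
  x <- Biostrings::readDNAStringSet(path, format = format)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA or FASTQ
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output file path.
#' @param format `"fasta"` (default) or `"fastq"`. FASTQ records carry a fixed
#'   quality (`"I"`, Phred 40), appropriate for simulated circular-consensus
#'   reads whose error process is modelled explicitly.
#' @return `path`, invisibly.
#' @export
write_seqs <- function(seqs, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- Biostrings::DNAStringSet(seqs)
  if (format == "fasta") {
    Biostrings::writeXStringSet(x, path)
  } else {
    qual <- Biostrings::BStringSet(vapply(nchar(seqs), function(n) {
      paste(rep("I", n), collapse = "")
    }, character(1)))
    qx <- Biostrings::QualityScaledDNAStringSet(
      x, Biostrings::PhredQuality(qual))
    Biostrings::writeQualityScaledXStringSet(qx, path)
  }
  invisible(path)
}
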