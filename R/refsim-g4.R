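# G-quadruplex consensus scanning.
#
# The canonical quadruplex consensus is four tracts of >= 3 G's separated by
# loops of 1..max_loop arbitrary bases.  Matches are reported as maximal
# (not extendable into a longer match) non-nested intervals; the reverse
# complement (C-tract) consensus is reported with strand "-".

g4_regex <- function(max_loop) {
  sprintf("^G{3,}([ACGTN]{1,%d}G{3,}){3}$", max_loop)
}

# maximal consensus matches on the + strand of `seq`
g4_scan_plus <- function(seq, max_loop) {
  n <- nchar(seq)
  if (n < 15) return(data.frame(start = integer(), end = integer()))
  b <- chars(seq)
  isg <- b == "G"
  r <- rle(isg)
  ends_all <- cumsum(r$lengths)
  starts_all <- ends_all - r$lengths
  runs <- which(r$values & r$lengths >= 3)
  if (!length(runs)) return(data.frame(start = integer(), end = integer()))
  rs <- starts_all[runs]          # 0-based run starts
  re <- ends_all[runs]            # 0-based run ends (half-open)
  pat <- g4_regex(max_loop)
  hits <- list()
  for (i in seq_along(rs)) {
    for (j in rev(seq_along(re))) {
      if (re[j] - rs[i] < 15) break
      if (grepl(pat, substr0(seq, rs[i], re[j]), perl = TRUE)) {
        hits[[length(hits) + 1L]] <- c(rs[i], re[j])
        break   # longest end for this start
      }
    }
  }
  if (!length(hits)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, hits)
  out <- data.frame(start = m[, 1], end = m[, 2])
  # drop intervals nested inside another match
  keep <- vapply(seq_len(nrow(out)), function(i) {
    !any(out$start <= out$start[i] & out$end >= out$end[i] &
           (out$start < out$start[i] | out$end > out$end[i]))
  }, logical(1))
  out[keep, , drop = FALSE]
}

#' Scan a sequence for canonical G-quadruplex consensus matches
#'
#' Finds all maximal, non-nested matches to four G3+ tracts separated by
#' loops of `1..max_loop` arbitrary bases, on both strands.  Minus-strand
#' matches (C-tract consensus) are reported in plus-strand coordinates with
#' `strand = "-"`.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param max_loop maximum loop length in bases (default 7).
#' @return data.frame with columns `start`, `end` (0-based half-open) and
#'   `strand`, sorted by start.
#' @examples
#' scan_g4_consensus("GGGAGGGTGGGAGGG")
#' @export
scan_g4_consensus <- function(seq, max_loop = 7L) {
  if (!is.numeric(max_loop) || max_loop < 1) {
    stop("max_loop must be >= 1", call. = FALSE)
  }
  seq <- toupper(seq)
  if (!is_dna(seq)) stop("seq must be DNA over {A,C,G,T,N}", call. = FALSE)
  n <- nchar(seq)
  plus <- g4_scan_plus(seq, max_loop)
  plus$strand <- rep("+", nrow(plus))
  minus <- g4_scan_plus(revcomp(seq), max_loop)
  minus <- data.frame(start = n - minus$end, end = n - minus$start,
                      strand = rep("-", nrow(minus)))
  out <- rbind(plus, minus)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
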