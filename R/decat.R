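# Decatenation of concatemeric circular-consensus reads into monomer PCR
# products: approximate primer-site search, strand normalization, the
# ectopic-site specificity filter, and exact-sequence deduplication.

#' Find approximate primer occurrences in a read
#'
#' Locates all occurrences of the forward and reverse primers and their
#' reverse complements at edit distance `<= max_edits` (unit-cost
#' substitutions and indels).  Overlapping candidates are resolved in favour
#' of lower edit distance, then leftmost position.
#'
#' @param read DNA string.
#' @param fwd,rev primer sequences (>= 15 bp each; shorter primers are
#'   rejected as ambiguity-prone).
#' @param max_edits maximum edit distance (default 2).
#' @return data.frame with columns `primer` (`"forward"`/`"reverse"`),
#'   `strand` (`"+"` if the primer's sense sequence matches, `"-"` if its
#'   reverse complement does), `start`, `end` (0-based half-open) and
#'   `edits`, sorted by `start`.
#' @export
find_primer_sites <- function(read, fwd, rev, max_edits = 2L) {
  if (nchar(fwd) < 15 || nchar(rev) < 15) {
    stop("primers must be at least 15 bp", call. = FALSE)
  }
  stopifnot(max_edits >= 0)
  pats <- list(
    list(primer = "forward", strand = "+", seq = fwd),
    list(primer = "forward", strand = "-", seq = revcomp(fwd)),
    list(primer = "reverse", strand = "+", seq = rev),
    list(primer = "reverse", strand = "-", seq = revcomp(rev)))
  hits <- lapply(pats, function(p) {
    h <- cpp_approx_find(read, p$seq, max_edits)
    if (nrow(h) == 0) return(NULL)
    data.frame(primer = p$primer, strand = p$strand,
               start = h$start, end = h$end, edits = h$edits)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits) || nrow(hits) == 0) {
    return(data.frame(primer = character(), strand = character(),
                      start = integer(), end = integer(),
                      edits = integer()))
  }
  hits <- hits[order(hits$edits, hits$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(hits)) > i)
    if (length(later)) {
      ov <- hits$start[later] < hits$end[i] & hits$end[later] > hits$start[i]
      keep[later[ov]] <- FALSE
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# transform primer hits onto the reverse complement of a read
flip_hits <- function(hits, read_len) {
  out <- hits
  out$start <- read_len - hits$end
  out$end <- read_len - hits$start
  out$strand <- ifelse(hits$strand == "+", "-", "+")
  out[order(out$start), , drop = FALSE]
}

#' Split one concatemer read into orientation-normalized monomers
#'
#' Monomer termini are the forward-primer starts (on the read's consistent
#' strand).  Reads whose primer hits lie on the minus strand are reverse
#' complemented first, so every monomer begins with the forward primer.
#' Leading fragments before the first forward primer, monomers lacking a
#' reverse primer, and reads with inconsistent interleaved orientations are
#' discarded and counted.
#'
#' @param read DNA string.
#' @param hits primer hits from [find_primer_sites()] on `read`.
#' @param read_id read name used in monomer ids.
#' @return list with `monomers` (data.frame: read, index, id, seq, f_start,
#'   f_end, r_start, r_end, strand, edits) and `discarded` (data.frame:
#'   read, start, end, reason), with intervals on the normalized read.
#' @export
decatenate <- function(read, hits, read_id = "read") {
  n <- nchar(read)
  empty_m <- data.frame(read = character(), index = integer(),
                        id = character(), seq = character(),
                        f_start = integer(), f_end = integer(),
                        r_start = integer(), r_end = integer(),
                        strand = character(), edits = integer())
  disc <- function(start, end, reason) {
    data.frame(read = rep(read_id, length(start)), start = start, end = end,
               reason = reason)
  }
  if (nrow(hits) == 0) {
    return(list(monomers = empty_m, discarded = disc(0L, n, "no_primer")))
  }
  fwd_plus <- sum(hits$primer == "forward" & hits$strand == "+")
  fwd_minus <- sum(hits$primer == "forward" & hits$strand == "-")
  if (fwd_plus > 0 && fwd_minus > 0) {
    return(list(monomers = empty_m, discarded = disc(0L, n, "ambiguous")))
  }
  strand <- if (fwd_minus > 0 || (fwd_plus == 0 &&
                                  any(hits$primer == "reverse" &
                                      hits$strand == "+"))) "-" else "+"
  if (strand == "-") {
    read <- revcomp(read)
    hits <- flip_hits(hits, n)
  }
  fstart <- hits$start[hits$primer == "forward" & hits$strand == "+"]
  if (length(fstart) == 0) {
    return(list(monomers = empty_m, discarded = disc(0L, n, "no_forward")))
  }
  fstart <- sort(fstart)
  bounds <- c(fstart, n)
  mono <- list()
  discarded <- list()
  if (fstart[1] > 0) {
    discarded[[length(discarded) + 1L]] <- disc(0L, fstart[1], "partial")
  }
  idx <- 0L
  for (i in seq_along(fstart)) {
    s <- bounds[i]; e <- bounds[i + 1L]
    sub <- hits[hits$start >= s & hits$end <= e, , drop = FALSE]
    fh <- sub[sub$primer == "forward" & sub$start == s, , drop = FALSE]
    rh <- sub[sub$primer == "reverse" & sub$strand == "-", , drop = FALSE]
    bad <- sub[(sub$primer == "reverse" & sub$strand == "+") |
                 (sub$primer == "forward" & sub$strand == "-"),
               , drop = FALSE]
    if (nrow(bad) > 0) {
      discarded[[length(discarded) + 1L]] <- disc(s, e, "ambiguous")
      next
    }
    if (nrow(rh) == 0) {
      discarded[[length(discarded) + 1L]] <- disc(s, e, "no_reverse")
      next
    }
    rh <- rh[nrow(rh), , drop = FALSE]      # last reverse hit in the monomer
    idx <- idx + 1L
    mono[[idx]] <- data.frame(
      read = read_id, index = idx,
      id = paste0(read_id, "/", idx),
      seq = substr0(read, s, e),
      f_start = 0L, f_end = fh$end[1] - s,
      r_start = rh$start - s, r_end = rh$end - s,
      strand = strand, edits = fh$edits[1] + rh$edits)
  }
  monomers <- if (length(mono)) do.call(rbind, mono) else empty_m
  discarded <- if (length(discarded)) do.call(rbind, discarded) else
    disc(integer(), integer(), character())
  list(monomers = monomers, discarded = discarded)
}

#' Decatenate a set of reads
#'
#' Applies [find_primer_sites()] and [decatenate()] to every read and binds
#' the results, with a per-read ledger of monomer and discard counts.
#'
#' @param reads named character vector of read sequences.
#' @param fwd,rev primer sequences.
#' @param max_edits maximum primer edit distance.
#' @return list with `monomers`, `discarded` and `ledger` (read, n_monomers,
#'   n_discarded).
#' @export
decat_reads <- function(reads, fwd, rev, max_edits = 2L) {
  if (length(reads) == 0) {
    empty <- decatenate("A", data.frame(primer = character(),
                                        strand = character(),
                                        start = integer(), end = integer(),
                                        edits = integer()))$monomers
    return(list(monomers = empty,
                discarded = data.frame(read = character(), start = integer(),
                                       end = integer(),
                                       reason = character()),
                ledger = data.frame(read = character(),
                                    n_monomers = integer(),
                                    n_discarded = integer())))
  }
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%05d", seq_along(reads))
  out_m <- vector("list", length(reads))
  out_d <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    h <- find_primer_sites(reads[[i]], fwd, rev, max_edits)
    r <- decatenate(reads[[i]], h, read_id = ids[i])
    out_m[[i]] <- r$monomers
    out_d[[i]] <- r$discarded
  }
  monomers <- do.call(rbind, out_m)
  discarded <- do.call(rbind, out_d)
  nm <- table(factor(monomers$read, levels = ids))
  nd <- table(factor(discarded$read, levels = ids))
  list(monomers = monomers, discarded = discarded,
       ledger = data.frame(read = ids, n_monomers = as.integer(nm),
                           n_discarded = as.integer(nd)))
}

#' Ectopic-site specificity filter
#'
#' A monomer is ectopic-site specific when at least `k` bases immediately 3'
#' of each iPCR primer match the expected ectopic-site flank exactly: the
#' `k` bases after the forward-primer match, and the `k` bases before the
#' reverse-primer match (3' of the reverse primer on its own strand).
#' Nonspecific monomers are removed and counted.
#'
#' @param monomers monomer data.frame from [decat_reads()].
#' @param es_seq ectopic-site contig sequence.
#' @param primers list with `fwd` and `rev` primers (exact sites expected in
#'   `es_seq`).
#' @param k flank length in bp (default 6).
#' @return list with `kept`, `removed` data.frames; both carry a `specific`
#'   column.
#' @export
filter_specific <- function(monomers, es_seq, primers, k = 6L) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  f0 <- regexpr(primers$fwd, es_seq, fixed = TRUE)[1] - 1L
  r0 <- regexpr(revcomp(primers$rev), es_seq, fixed = TRUE)[1] - 1L
  if (f0 < 0 || r0 < 0) {
    stop("primer sites not found in the ectopic-site sequence", call. = FALSE)
  }
  fwd_flank <- substr0(es_seq, f0 + nchar(primers$fwd),
                       f0 + nchar(primers$fwd) + k)
  rev_flank <- substr0(es_seq, r0 - k, r0)
  ok <- vapply(seq_len(nrow(monomers)), function(i) {
    m <- monomers[i, ]
    after_f <- substr0(m$seq, m$f_end, m$f_end + k)
    before_r <- substr0(m$seq, m$r_start - k, m$r_start)
    nchar(after_f) == k && nchar(before_r) == k &&
      after_f == fwd_flank && before_r == rev_flank
  }, logical(1))
  monomers$specific <- ok
  list(kept = monomers[ok, , drop = FALSE],
       removed = monomers[!ok, , drop = FALSE])
}

#' Collapse exact-duplicate monomers
#'
#' PCR amplification over-represents identical recombinants; duplicates are
#' collapsed at exact sequence identity (after orientation normalization),
#' keeping the first occurrence by (read id, index).  Idempotent.
#'
#' @param monomers monomer data.frame.
#' @return list with `monomers` (unique, `duplicate_of = NA`) and
#'   `duplicates` (removed rows, `duplicate_of` = representative id).
#' @export
deduplicate <- function(monomers) {
  if (nrow(monomers) == 0) {
    monomers$duplicate_of <- character(0)
    return(list(monomers = monomers, duplicates = monomers))
  }
  ord <- order(monomers$read, monomers$index)
  m <- monomers[ord, , drop = FALSE]
  first <- !duplicated(m$seq)
  rep_id <- m$id[first][match(m$seq, m$seq[first])]
  m$duplicate_of <- ifelse(first, NA_character_, rep_id)
  list(monomers = m[first, , drop = FALSE],
       duplicates = m[!first, , drop = FALSE])
}
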