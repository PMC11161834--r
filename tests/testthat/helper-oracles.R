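# Independent brute-force oracles used to check the implementation paths.

# exhaustive G-quadruplex consensus scan: test every substring against the
# anchored consensus regex, keep maximal (non-nested) matches, both strands
brute_g4_scan <- function(seq, max_loop = 7L) {
  pat <- sprintf("^G{3,}([ACGTN]{1,%d}G{3,}){3}$", max_loop)
  one_strand <- function(s) {
    n <- nchar(s)
    hits <- list()
    for (a in 0:(max(0, n - 15))) {
      for (b in (a + 15):n) {
        if (b > n) break
        if (grepl(pat, substr(s, a + 1, b), perl = TRUE)) {
          hits[[length(hits) + 1L]] <- c(a, b)
        }
      }
    }
    if (!length(hits)) return(data.frame(start = integer(), end = integer()))
    m <- unique(do.call(rbind, hits))
    keep <- vapply(seq_len(nrow(m)), function(i) {
      !any(m[, 1] <= m[i, 1] & m[, 2] >= m[i, 2] &
             (m[, 1] < m[i, 1] | m[, 2] > m[i, 2]))
    }, logical(1))
    data.frame(start = m[keep, 1], end = m[keep, 2])
  }
  n <- nchar(seq)
  plus <- one_strand(seq)
  plus$strand <- rep("+", nrow(plus))
  minus <- one_strand(revcomp(seq))
  minus <- data.frame(start = n - minus$end, end = n - minus$start,
                      strand = rep("-", nrow(minus)))
  out <- rbind(plus, minus)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# brute-force approximate occurrence check: minimal edit distance of the
# pattern against any window of the text (via adist)
brute_min_window_dist <- function(text, pattern) {
  m <- nchar(pattern)
  n <- nchar(text)
  best <- Inf
  for (a in 0:(n - 1)) {
    for (len in max(1, m - 3):min(n - a, m + 3)) {
      d <- utils::adist(pattern, substr(text, a + 1, a + len))[1, 1]
      if (d < best) best <- d
    }
  }
  best
}

# brute-force junction microhomology: maximal l + r such that the l read
# bases before the downstream segment start match the downstream locus
# continuation and the r read bases after the upstream segment end match the
# upstream locus continuation; insertion when the maximal extensions leave
# unexplained read bases
brute_junction_overlap <- function(up, down, read, ref) {
  upc <- ref$contigs[[up$contig]]
  dnc <- ref$contigs[[down$contig]]
  y <- up$q_end
  u <- down$q_start
  r <- 0L
  repeat {
    rb <- substr(read, y + r + 1, y + r + 1)
    tb <- if (up$strand == "+") {
      substr(upc, up$t_end + r + 1, up$t_end + r + 1)
    } else {
      p <- up$t_start - r
      if (p < 1) "" else revcomp(substr(upc, p, p))
    }
    if (rb == "" || tb == "" || rb != tb) break
    r <- r + 1L
  }
  l <- 0L
  repeat {
    if (u - l - 1 < 0) break
    rb <- substr(read, u - l, u - l)
    tb <- if (down$strand == "+") {
      p <- down$t_start - l
      if (p < 1) "" else substr(dnc, p, p)
    } else {
      p <- down$t_end + l + 1
      if (p > nchar(dnc)) "" else revcomp(substr(dnc, p, p))
    }
    if (rb == "" || tb == "" || rb != tb) break
    l <- l + 1L
  }
  y2 <- y + r
  u2 <- u - l
  if (y2 >= u2) {
    list(overlap_len = y2 - u2, inserted_len = 0L)
  } else {
    list(overlap_len = 0L, inserted_len = u2 - y2)
  }
}

# exhaustive chain enumeration over candidate segments (<= ~12): all
# index subsets in query order satisfying the colinearity constraints,
# ranked by (score desc, junctions asc, target starts lex, query starts lex)
enumerate_best_chain <- function(segs, max_query_overlap = 300L) {
  segs <- segs[order(segs$q_start, segs$q_end, segs$t_start), , drop = FALSE]
  rownames(segs) <- NULL
  n <- nrow(segs)
  compat <- function(i, j) {
    segs$q_start[i] < segs$q_start[j] && segs$q_end[i] < segs$q_end[j] &&
      segs$q_start[j] >= segs$q_end[i] - max_query_overlap
  }
  best <- NULL
  best_key <- NULL
  subsets <- function(prefix, next_min) {
    if (length(prefix)) {
      key <- list(score = sum(segs$score[prefix]),
                  njunc = length(prefix) - 1L,
                  tseq = segs$t_start[prefix],
                  qseq = segs$q_start[prefix])
      better <- is.null(best_key) || {
        if (key$score != best_key$score) key$score > best_key$score
        else if (key$njunc != best_key$njunc) key$njunc < best_key$njunc
        else {
          cmp <- 0L
          if (length(key$tseq) == length(best_key$tseq)) {
            d <- which(key$tseq != best_key$tseq)
            if (length(d)) cmp <- sign(best_key$tseq[d[1]] - key$tseq[d[1]])
            if (cmp == 0L) {
              d <- which(key$qseq != best_key$qseq)
              if (length(d)) cmp <- sign(best_key$qseq[d[1]] - key$qseq[d[1]])
            }
          }
          cmp > 0L
        }
      }
      if (better) { best <<- prefix; best_key <<- key }
    }
    for (j in next_min:n) {
      if (j > n) break
      if (!length(prefix) || compat(prefix[length(prefix)], j)) {
        subsets(c(prefix, j), j + 1L)
      }
    }
  }
  if (n > 0) subsets(integer(), 1L)
  segs[best, , drop = FALSE]
}

# small shared fixtures
tiny_ref <- function(seed = 1L) default_reference("CAG102", seed = seed)

# two-contig fixture with a planted junction: the up locus ends with an
# o-mer that also starts the down locus; flanks are pinned divergent so the
# measured microhomology is exactly o
make_junction_fixture <- function(o, flank = 120L) {
  m <- random_dna(o)
  upA <- paste0(substr(random_dna(flank), 1, flank - 1), "T")
  dnB <- paste0("C", substr(random_dna(flank), 2, flank))
  up_seq <- paste0(upA, m)
  dn_seq <- paste0(m, dnB)
  up_ct <- paste0("T", up_seq, "A", random_dna(20))
  dn_ct <- paste0(random_dna(20), "G", dn_seq, "C")
  ref <- hybrid_reference(c(u = up_ct, d = dn_ct), "u")
  read <- paste0(upA, m, dnB)
  up <- data.frame(monomer = "m1", q_start = 0L, q_end = flank + o,
                   contig = "u", t_start = 1L, t_end = 1L + flank + o,
                   strand = "+")
  dn <- data.frame(monomer = "m1", q_start = flank,
                   q_end = flank + o + flank,
                   contig = "d", t_start = 21L,
                   t_end = 21L + o + flank, strand = "+")
  list(ref = ref, read = read, up = up, down = dn, o = o)
}

random_segments <- function(n, qlen = 1000L, tlen = 2000L) {
  q1 <- sort(sample.int(qlen - 50L, n))
  len <- sample(30:200, n, replace = TRUE)
  data.frame(
    monomer = "m1",
    q_start = q1, q_end = pmin(qlen, q1 + len),
    contig = sample(c("ES", "chr8_frag"), n, replace = TRUE),
    t_start = ts <- sample.int(tlen - 250L, n),
    t_end = ts + len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    cigar = paste0(len, "="),
    nmatch = len, nmismatch = 0L, ins_events = 0L, del_events = 0L,
    ins_len = 0L, del_len = 0L, identity = 1,
    score = as.numeric(sample(20:200, n, replace = TRUE)))
}
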