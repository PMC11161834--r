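# Monomer-to-reference segmentation: an internal seed-and-extend local
# aligner (exact k-mer seeds, diagonal clustering, banded DP, maximal exact
# end extension), query-colinear chaining into template-switch domains,
# intra-site vs nonallelic classification, and SAM/PAF/BED interchange.

#' Build the k-mer seed index for a hybrid reference
#'
#' Exact k-mer index over the forward strand of every contig; k-mers with
#' more than `max_occ` occurrences are masked (repeat control; microsatellite
#' interiors are bridged by the banded extension instead).
#'
#' @param ref a [hybrid_reference()].
#' @param k seed length (default 15).
#' @param max_occ occurrence mask threshold (default 16).
#' @return a `seg_index` object.
#' @export
seg_index <- function(ref, k = 15L, max_occ = 16L) {
  ptr <- cpp_build_index(unname(ref$contigs), as.integer(k),
                         as.integer(max_occ))
  structure(list(ptr = ptr, k = as.integer(k),
                 contigs = names(ref$contigs),
                 lens = unname(nchar(ref$contigs)),
                 offsets = cumsum(c(0, unname(nchar(ref$contigs))))),
            class = "seg_index")
}

common_suffix_len <- function(a, b) {
  ra <- utf8ToInt(a); rb <- utf8ToInt(b)
  n <- min(length(ra), length(rb))
  if (n == 0) return(0L)
  ra <- rev(ra)[seq_len(n)]; rb <- rev(rb)[seq_len(n)]
  d <- which(ra != rb)
  if (!length(d)) n else d[1] - 1L
}

# group seeds into per-locus clusters: same contig, diagonal within
# diag_tol, query gaps <= merge_gap, target monotone
cluster_seeds <- function(qv, tv, idx, diag_tol, merge_gap) {
  k <- idx$k
  ci <- findInterval(tv, idx$offsets)   # 1-based contig index
  tl <- tv - idx$offsets[ci]
  dg <- tl - qv
  o <- order(ci, dg, qv)
  ci <- ci[o]; tl <- tl[o]; dg <- dg[o]; qv <- qv[o]
  brk <- c(TRUE, diff(ci) != 0 | diff(dg) > diag_tol)
  clusters <- list()
  for (g in split(seq_along(qv), cumsum(brk))) {
    g <- g[order(qv[g], tl[g])]
    brk2 <- c(TRUE, diff(qv[g]) > merge_gap | diff(tl[g]) < 0)
    for (h in split(g, cumsum(brk2))) {
      clusters[[length(clusters) + 1L]] <- list(
        contig = ci[h[1]],
        qs = qv[h[1]], qe = qv[h[length(h)]] + k,
        ts = tl[h[1]], te = tl[h[length(h)]] + k,
        spread = max(dg[h]) - min(dg[h]),
        qv = qv[h], tv = tl[h])
    }
  }
  clusters
}

# Trim a global-on-cluster alignment to its maximal-scoring contiguous run
# subsequence (match +1, mismatch -2, indel -(4 + length)), converting the
# cluster alignment into a properly local one: low-quality tails dragged in
# by incidental near-diagonal homology are dropped.
trim_alignment <- function(cigar) {
  cc <- cigar_consumed(cigar)
  w <- ifelse(cc$op == "=", cc$len,
              ifelse(cc$op == "X", -2L * cc$len, -(4L + cc$len)))
  # Kadane over runs, tracking the best window
  best <- -Inf; best_i <- 1L; best_j <- 0L
  cur <- 0; cur_i <- 1L
  for (j in seq_along(w)) {
    if (cur <= 0) { cur <- w[j]; cur_i <- j } else cur <- cur + w[j]
    if (cur > best) { best <- cur; best_i <- cur_i; best_j <- j }
  }
  if (best_j == 0L) return(NULL)
  qc <- ifelse(cc$op %in% c("=", "X", "I"), cc$len, 0L)
  tc <- ifelse(cc$op %in% c("=", "X", "D"), cc$len, 0L)
  pre <- seq_len(best_i - 1L)
  post <- if (best_j < length(w)) (best_j + 1L):length(w) else integer()
  keep <- best_i:best_j
  list(cigar = paste0(cc$len[keep], cc$op[keep], collapse = ""),
       q_left = sum(qc[pre]), t_left = sum(tc[pre]),
       q_right = sum(qc[post]), t_right = sum(tc[post]))
}

# align one oriented query (qseq is the monomer, or its reverse complement
# for minus-strand clusters) against one contig interval
align_cluster <- function(qseq, contig_seq, cl, band_floor = 16L,
                          max_ext = 512L) {
  qs <- cl$qs; qe <- cl$qe; ts <- cl$ts; te <- cl$te
  pad <- max(band_floor, cl$spread + band_floor)
  aln <- cpp_banded_global(substr0(qseq, qs, qe), substr0(contig_seq, ts, te),
                           as.integer(pad))
  if (!isTRUE(aln$ok)) return(NULL)
  tr <- trim_alignment(aln$cigar)
  if (is.null(tr)) return(NULL)
  qs <- qs + tr$q_left; qe <- qe - tr$q_right
  ts <- ts + tr$t_left; te <- te - tr$t_right
  st <- cigar_stats(tr$cigar)
  # maximal exact extension at both ends
  el <- common_suffix_len(substr0(qseq, max(0L, qs - max_ext), qs),
                          substr0(contig_seq, max(0L, ts - max_ext), ts))
  er <- common_prefix_len(substr0(qseq, qe, qe + max_ext),
                          substr0(contig_seq, te, te + max_ext))
  cigar <- tr$cigar
  if (el > 0) cigar <- paste0(el, "=", cigar)
  if (er > 0) cigar <- paste0(cigar, er, "=")
  list(qs = qs - el, qe = qe + er, ts = ts - el, te = te + er,
       cigar = cigar,
       nmatch = st$nmatch + el + er, nmismatch = st$nmismatch,
       ins_events = st$ins_events, del_events = st$del_events,
       ins_len = st$ins_len, del_len = st$del_len)
}

empty_segments <- function() {
  data.frame(monomer = character(), q_start = integer(), q_end = integer(),
             contig = character(), t_start = integer(), t_end = integer(),
             strand = character(), cigar = character(), nmatch = integer(),
             nmismatch = integer(), ins_events = integer(),
             del_events = integer(), ins_len = integer(),
             del_len = integer(), identity = numeric(), score = numeric())
}

seg_row <- function(monomer, a, contig, strand, qlen) {
  if (strand == "+") {
    q_start <- a$qs; q_end <- a$qe
  } else {
    q_start <- qlen - a$qe; q_end <- qlen - a$qs
  }
  alen <- a$nmatch + a$nmismatch + a$ins_len + a$del_len
  data.frame(monomer = monomer, q_start = q_start, q_end = q_end,
             contig = contig, t_start = a$ts, t_end = a$te, strand = strand,
             cigar = a$cigar, nmatch = a$nmatch, nmismatch = a$nmismatch,
             ins_events = a$ins_events, del_events = a$del_events,
             ins_len = a$ins_len, del_len = a$del_len,
             identity = if (alen > 0) a$nmatch / alen else 0,
             score = a$nmatch - 2 * a$nmismatch -
               3 * (a$ins_events + a$del_events) - (a$ins_len + a$del_len))
}

# Align a cluster; when a loosely merged cluster aligns below the identity
# threshold (disjoint homology islands chained through a mismatch sea),
# split it at the widest seed gap and align the halves recursively.
align_cluster_split <- function(qseq, contig_seq, cl, k, min_identity,
                                depth = 8L) {
  a <- align_cluster(qseq, contig_seq, cl)
  ok <- !is.null(a) && {
    alen <- a$nmatch + a$nmismatch + a$ins_len + a$del_len
    alen > 0 && a$nmatch / alen >= min_identity
  }
  if (ok) return(list(a))
  n <- length(cl$qv)
  if (depth <= 0 || n < 2) return(list())
  gap <- diff(cl$qv) + diff(cl$tv)
  i <- which.max(gap)
  mk <- function(sel) {
    qv <- cl$qv[sel]; tv <- cl$tv[sel]
    list(contig = cl$contig, qs = qv[1], qe = qv[length(qv)] + k,
         ts = tv[1], te = tv[length(tv)] + k,
         spread = max(tv - qv) - min(tv - qv), qv = qv, tv = tv)
  }
  c(align_cluster_split(qseq, contig_seq, mk(seq_len(i)), k, min_identity,
                        depth - 1L),
    align_cluster_split(qseq, contig_seq, mk((i + 1L):n), k, min_identity,
                        depth - 1L))
}

align_one <- function(id, seq, ref, idx, min_len, min_identity,
                      stride, diag_tol, merge_gap) {
  qlen <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    qseq <- if (strand == "+") seq else revcomp(seq)
    sd <- cpp_find_seeds(idx$ptr, qseq, as.integer(stride))
    if (nrow(sd) == 0) next
    cls <- cluster_seeds(sd$q, sd$t, idx, diag_tol, merge_gap)
    for (cl in cls) {
      contig_name <- idx$contigs[cl$contig]
      for (a in align_cluster_split(qseq, ref$contigs[[contig_name]], cl,
                                    idx$k, min_identity)) {
        out[[length(out) + 1L]] <- seg_row(id, a, contig_name, strand, qlen)
      }
    }
  }
  if (!length(out)) return(empty_segments())
  segs <- do.call(rbind, out)
  segs <- segs[segs$q_end - segs$q_start >= min_len &
                 segs$identity >= min_identity, , drop = FALSE]
  segs <- segs[!duplicated(segs[, c("q_start", "q_end", "contig",
                                    "t_start", "t_end", "strand")]),
               , drop = FALSE]
  segs <- segs[order(segs$q_start, segs$q_end, segs$contig, segs$t_start), ,
               drop = FALSE]
  rownames(segs) <- NULL
  segs
}

#' Align monomers to the hybrid reference
#'
#' Internal seed-and-extend local aligner: exact 15-mer seeds on both
#' strands, diagonal-band clustering, banded global DP per cluster with
#' run-length edit operations, and maximal exact extension of both ends.
#' All local alignments with query span `>= min_len` and identity
#' `>= min_identity` are returned; deterministic given its inputs.
#' Externally produced alignments can be substituted via [read_paf()] /
#' [read_sam_segments()].
#'
#' @param monomers data.frame with `id` and `seq` columns (as from
#'   [decat_reads()]), or a named character vector of sequences.
#' @param ref a [hybrid_reference()].
#' @param min_len minimum aligned query span in bp (default 30).
#' @param min_identity minimum alignment identity (default 0.8).
#' @param index optional prebuilt [seg_index()].
#' @param stride seed sampling stride on the query (default 1).
#' @param diag_tol diagonal tolerance when clustering seeds (bounds the
#'   cumulative indel length bridged within one segment; default 200).
#' @param merge_gap maximum seedless query gap bridged within one segment
#'   (covers masked microsatellite interiors; default 400).
#' @return data.frame of segment alignments (one row per local alignment)
#'   with query/target intervals, strand, run-length `cigar` over
#'   `=`/`X`/`I`/`D`, per-segment event tallies, identity and score.
#' @export
align_segments <- function(monomers, ref, min_len = 30L, min_identity = 0.8,
                           index = NULL, stride = 1L, diag_tol = 200L,
                           merge_gap = 400L) {
  if (length(ref$contigs) == 0) stop("empty reference", call. = FALSE)
  if (is.character(monomers)) {
    monomers <- data.frame(id = names(monomers), seq = unname(monomers))
  }
  if (is.null(index)) index <- seg_index(ref)
  res <- vector("list", nrow(monomers))
  for (i in seq_len(nrow(monomers))) {
    res[[i]] <- align_one(monomers$id[i], monomers$seq[i], ref, index,
                          min_len, min_identity, stride, diag_tol, merge_gap)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# lexicographic chain comparison: higher score, then fewer junctions, then
# leftmost target starts, then leftmost query starts
chain_better <- function(score_a, chain_a, score_b, chain_b, segs) {
  if (score_a != score_b) return(score_a > score_b)
  if (length(chain_a) != length(chain_b)) {
    return(length(chain_a) < length(chain_b))
  }
  ta <- segs$t_start[chain_a]; tb <- segs$t_start[chain_b]
  d <- which(ta != tb)
  if (length(d)) return(ta[d[1]] < tb[d[1]])
  qa <- segs$q_start[chain_a]; qb <- segs$q_start[chain_b]
  d <- which(qa != qb)
  if (length(d)) return(qa[d[1]] < qb[d[1]])
  FALSE
}

#' Chain segment alignments into an ordered domain chain
#'
#' Selects the maximal-score, query-colinear subset of one monomer's local
#' alignments by dynamic programming over query intervals.  Adjacent
#' selected segments may overlap on the query by up to `max_query_overlap`
#' bases — the microhomology allowance, matching the up-to-roughly-300-bp
#' overlap homologies seen at template-switch junctions.  Equal-score chains
#' resolve to fewer junctions, then leftmost target start.
#'
#' @param segments segment alignments of one monomer ([align_segments()]).
#' @param max_query_overlap microhomology allowance in bp (default 300).
#' @return a `domain_chain`: list(monomer, domains, junctions, unmapped).
#'   `junctions` has one row per adjacent pair (up, down row indices into
#'   `domains`, and the signed query gap `q_gap`; negative = query overlap).
#' @export
chain_domains <- function(segments, max_query_overlap = 300L) {
  mono <- if (nrow(segments)) segments$monomer[1] else NA_character_
  if (nrow(segments) == 0) {
    return(structure(list(monomer = mono, domains = empty_segments(),
                          junctions = data.frame(up = integer(),
                                                 down = integer(),
                                                 q_gap = integer()),
                          unmapped = TRUE),
                     class = "domain_chain"))
  }
  if (length(unique(segments$monomer)) > 1) {
    stop("chain_domains expects alignments of a single monomer",
         call. = FALSE)
  }
  segs <- segments[order(segments$q_start, segments$q_end,
                         segments$t_start), , drop = FALSE]
  rownames(segs) <- NULL
  n <- nrow(segs)
  best_score <- segs$score
  best_chain <- lapply(seq_len(n), function(i) i)
  for (j in seq_len(n)) {
    for (i in seq_len(max(0L, j - 1L))) {
      if (segs$q_start[i] >= segs$q_start[j]) next
      if (segs$q_end[i] >= segs$q_end[j]) next
      if (segs$q_start[j] < segs$q_end[i] - max_query_overlap) next
      cand_score <- best_score[i] + segs$score[j]
      cand_chain <- c(best_chain[[i]], j)
      if (chain_better(cand_score, cand_chain, best_score[j],
                       best_chain[[j]], segs)) {
        best_score[j] <- cand_score
        best_chain[[j]] <- cand_chain
      }
    }
  }
  top <- 1L
  for (j in seq_len(n)) {
    if (chain_better(best_score[j], best_chain[[j]], best_score[top],
                     best_chain[[top]], segs)) {
      top <- j
    }
  }
  sel <- best_chain[[top]]
  domains <- segs[sel, , drop = FALSE]
  rownames(domains) <- NULL
  nj <- max(0L, length(sel) - 1L)
  junctions <- data.frame(
    up = seq_len(nj), down = seq_len(nj) + 1L,
    q_gap = if (nj > 0) domains$q_start[-1] - domains$q_end[-nrow(domains)]
            else integer())
  structure(list(monomer = mono, domains = domains, junctions = junctions,
                 unmapped = FALSE),
            class = "domain_chain")
}

#' @export
print.domain_chain <- function(x, ...) {
  cat("domain_chain <", x$monomer, ">: ", nrow(x$domains), " domain(s)",
      if (x$unmapped) " [unmapped]", "\n", sep = "")
  invisible(x)
}

#' Chain all monomers' alignments
#'
#' @param segments combined segment data.frame from [align_segments()].
#' @param max_query_overlap microhomology allowance in bp.
#' @return named list of `domain_chain` objects (one per monomer present).
#' @export
chain_all <- function(segments, max_query_overlap = 300L) {
  sp <- split(segments, segments$monomer)
  out <- lapply(sp, chain_domains, max_query_overlap = max_query_overlap)
  out[order(names(out))]
}

#' Classify chain domains as intra-site or nonallelic
#'
#' Domains mapping to the ectopic-site contig are `intra_es`; all others are
#' `nonallelic`.  Each nonallelic domain is annotated with the copy
#' direction along the donor chromosome axis (contigs are oriented
#' p-arm-first): a plus-strand copy progresses p->q, a minus-strand copy
#' q->p; runs of consecutive plus-strand domains on one donor whose target
#' coordinates decrease are marked q->p (the chain progressed toward the
#' short arm).
#'
#' @param chain a `domain_chain`.
#' @param ref the [hybrid_reference()].
#' @return the chain with `class` and `direction` columns added to
#'   `$domains` and a `$class_counts` summary.
#' @export
classify_domains <- function(chain, ref) {
  d <- chain$domains
  if (nrow(d) == 0) {
    chain$class_counts <- c(intra_es = 0L, nonallelic = 0L)
    return(chain)
  }
  d$class <- ifelse(d$contig == ref$es_contig, "intra_es", "nonallelic")
  d$direction <- ifelse(d$class == "nonallelic",
                        ifelse(d$strand == "+", "p_to_q", "q_to_p"),
                        NA_character_)
  if (nrow(d) > 1) {
    for (i in 2:nrow(d)) {
      if (d$class[i] == "nonallelic" && d$class[i - 1] == "nonallelic" &&
          d$contig[i] == d$contig[i - 1] &&
          d$strand[i] == "+" && d$strand[i - 1] == "+" &&
          d$t_start[i] < d$t_start[i - 1]) {
        d$direction[i] <- "q_to_p"
      }
    }
  }
  chain$domains <- d
  chain$class_counts <- c(intra_es = sum(d$class == "intra_es"),
                          nonallelic = sum(d$class == "nonallelic"))
  chain
}

#' Verify a nonallelic domain by donor-unique sequence
#'
#' A nonallelic call is supported when the domain's read sequence contains
#' at least one k-mer absent from the ectopic-site contig (either strand);
#' otherwise the domain could be a misalignment of site sequence.
#'
#' @param domain_seq the domain's read-space sequence (oriented as read).
#' @param es_seq ectopic-site contig sequence.
#' @param k k-mer length (default 25).
#' @return `TRUE` (verified), `FALSE` (no site-absent k-mer), or `NA` if the
#'   domain is shorter than `k` (indeterminate).
#' @export
verify_nonallelic <- function(domain_seq, es_seq, k = 25L) {
  n <- nchar(domain_seq)
  if (n < k) return(NA)
  kmers <- substring(domain_seq, 1:(n - k + 1), k:n)
  es2 <- paste0(es_seq, "N", revcomp(es_seq))
  nes <- nchar(es2)
  es_kmers <- substring(es2, 1:(nes - k + 1), k:nes)
  any(!(kmers %in% es_kmers))
}

# read-space oriented query sequence of one segment row
seg_query_seq <- function(seg, monomer_seq) {
  s <- substr0(monomer_seq, seg$q_start, seg$q_end)
  if (seg$strand == "-") revcomp(s) else s
}
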