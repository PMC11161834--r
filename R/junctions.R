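# Microhomology at template-switch and circularization junctions.
#
# Overlap is measured in reference space: the maximal run of read bases
# spanning the junction that aligns exactly both to the suffix of the
# upstream donor locus and to the prefix of the downstream donor locus
# (shared homology of the two loci, realized once in the read).  Read bases
# between the mapped segments matching neither flank are a nontemplated
# insertion; overlap and insertion are mutually exclusive per junction.

# maximal run of read bases from position rp rightward equal to the
# reference continuation after the (contig, tpos) anchor, in read orientation
ext_right_ref <- function(read, rp, contig_seq, tpos, strand) {
  n <- 0L
  tlen <- nchar(contig_seq)
  repeat {
    rb <- substr0(read, rp + n, rp + n + 1L)
    if (rb == "") break
    tb <- if (strand == "+") {
      if (tpos + n >= tlen) "" else substr0(contig_seq, tpos + n, tpos + n + 1L)
    } else {
      if (tpos - n - 1L < 0) "" else
        revcomp(substr0(contig_seq, tpos - n - 1L, tpos - n))
    }
    if (tb == "" || rb != tb) break
    n <- n + 1L
  }
  n
}

# maximal run of read bases ending at rp (leftward) equal to the reference
# continuation before the anchor
ext_left_ref <- function(read, rp, contig_seq, tpos, strand) {
  n <- 0L
  tlen <- nchar(contig_seq)
  repeat {
    if (rp - n - 1L < 0) break
    rb <- substr0(read, rp - n - 1L, rp - n)
    tb <- if (strand == "+") {
      if (tpos - n - 1L < 0) "" else
        substr0(contig_seq, tpos - n - 1L, tpos - n)
    } else {
      if (tpos + n >= tlen) "" else
        revcomp(substr0(contig_seq, tpos + n, tpos + n + 1L))
    }
    if (tb == "" || rb != tb) break
    n <- n + 1L
  }
  n
}

# read-end anchors of a segment in reference space
seg_end_anchor <- function(seg) {
  if (seg$strand == "+") seg$t_end else seg$t_start
}
seg_start_anchor <- function(seg) {
  if (seg$strand == "+") seg$t_start else seg$t_end
}

#' Microhomology overlap (or nontemplated insertion) at one junction
#'
#' Bidirectional extension in reference space from the two mapped segments
#' adjacent in a chain: the overlap is the maximal window of read bases
#' spanning the junction matching both the upstream locus continuation and
#' the downstream locus continuation; if the maximal extensions leave read
#' bases matching neither flank, those bases are a nontemplated insertion.
#'
#' @param up,down adjacent segment rows of one chain (up precedes down on
#'   the query).
#' @param monomer_seq the monomer sequence (orientation-normalized).
#' @param ref the [hybrid_reference()].
#' @return list: `overlap_len`, `overlap_seq`, `inserted_len`,
#'   `inserted_seq` (one of the pairs is empty/zero), and the read window
#'   `read_start`, `read_end` of the overlap or insertion.
#' @export
junction_overlap <- function(up, down, monomer_seq, ref) {
  y <- up$q_end
  u <- down$q_start
  up_ct <- ref$contigs[[up$contig]]
  dn_ct <- ref$contigs[[down$contig]]
  y2 <- y + ext_right_ref(monomer_seq, y, up_ct, seg_end_anchor(up),
                          up$strand)
  u2 <- u - ext_left_ref(monomer_seq, u, dn_ct, seg_start_anchor(down),
                         down$strand)
  if (y2 >= u2) {
    list(overlap_len = y2 - u2,
         overlap_seq = substr0(monomer_seq, u2, y2),
         inserted_len = 0L, inserted_seq = "",
         read_start = u2, read_end = y2)
  } else {
    list(overlap_len = 0L, overlap_seq = "",
         inserted_len = u2 - y2,
         inserted_seq = substr0(monomer_seq, y2, u2),
         read_start = y2, read_end = u2)
  }
}

# map a read window at a segment boundary into reference coordinates on the
# downstream segment's contig (used for mediating-feature annotation)
window_on_down_locus <- function(down, read_start, read_end) {
  u <- down$q_start
  if (down$strand == "+") {
    a <- down$t_start - (u - read_start)
    c(a, a + (read_end - read_start))
  } else {
    b <- down$t_end + (u - read_start)
    c(b - (read_end - read_start), b)
  }
}

# which annotated repeat feature (frt/alu) covers the majority of an
# ES-contig interval; "other" when none covers > 50%
mediating_feature <- function(ref, contig, start, end) {
  fe <- ref$features
  if (is.null(fe) || contig != ref$es_contig || end <= start) {
    return(list(repeat_kind = "other", in_dT_tail = FALSE))
  }
  fe <- fe[fe$kind %in% c("frt", "alu"), , drop = FALSE]
  if (nrow(fe) == 0) return(list(repeat_kind = "other", in_dT_tail = FALSE))
  cov <- pmax(0, pmin(end, fe$end) - pmax(start, fe$start))
  i <- which.max(cov)
  if (cov[i] <= (end - start) / 2) {
    return(list(repeat_kind = "other", in_dT_tail = FALSE))
  }
  tail_start <- fe$end[i] - 29L
  list(repeat_kind = fe$kind[i],
       in_dT_tail = fe$kind[i] == "alu" && start >= tail_start)
}

#' Annotate all junctions of a chain with microhomology and class
#'
#' Computes [junction_overlap()] for every adjacent domain pair and
#' classifies each junction (`intra_es` when both flanking domains map to
#' the ectopic-site contig, else `nonallelic`); the circle-closing junction
#' found by [detect_circularization_junction()] is reclassified as
#' `circularization` with its mediating repeat.
#'
#' @param chain a classified `domain_chain` ([classify_domains()]).
#' @param monomer_seq the monomer's sequence.
#' @param ref the [hybrid_reference()].
#' @return data.frame, one row per junction: up/down domain indices,
#'   overlap/insertion lengths and sequences, read window, class,
#'   mediating_repeat, in_dT_tail.
#' @export
annotate_junctions <- function(chain, monomer_seq, ref) {
  d <- chain$domains
  nj <- nrow(chain$junctions)
  if (nj == 0) {
    return(data.frame(monomer = character(), up = integer(),
                      down = integer(), overlap_len = integer(),
                      overlap_seq = character(), inserted_len = integer(),
                      inserted_seq = character(), read_start = integer(),
                      read_end = integer(), junction_class = character(),
                      mediating_repeat = character(),
                      in_dT_tail = logical()))
  }
  rows <- vector("list", nj)
  for (j in seq_len(nj)) {
    up <- d[chain$junctions$up[j], ]
    dn <- d[chain$junctions$down[j], ]
    jo <- junction_overlap(up, dn, monomer_seq, ref)
    cls <- if (up$contig == ref$es_contig && dn$contig == ref$es_contig) {
      "intra_es"
    } else {
      "nonallelic"
    }
    w <- window_on_down_locus(dn, jo$read_start, jo$read_end)
    mf <- mediating_feature(ref, dn$contig, w[1], w[2])
    rows[[j]] <- data.frame(
      monomer = chain$monomer, up = chain$junctions$up[j],
      down = chain$junctions$down[j],
      overlap_len = jo$overlap_len, overlap_seq = jo$overlap_seq,
      inserted_len = jo$inserted_len, inserted_seq = jo$inserted_seq,
      read_start = jo$read_start, read_end = jo$read_end,
      junction_class = cls, mediating_repeat = mf$repeat_kind,
      in_dT_tail = mf$in_dT_tail)
  }
  out <- do.call(rbind, rows)
  ci <- detect_circ_index(chain, ref$es_contig)
  if (!is.na(ci)) out$junction_class[ci] <- "circularization"
  out
}

# The monomer is orientation-normalized (forward primer at its 5' end); the
# forward-primer extension walks downstream on the site until the sealed
# circle boundary, where the chain wraps back toward the reverse-primer
# territory.  The circle-closing junction therefore follows the ectopic-site
# domain of maximal downstream reach (largest target end) among the domains
# that have a successor.
detect_circ_index <- function(chain, es_contig = "ES") {
  d <- chain$domains
  n <- nrow(d)
  if (n < 2) return(NA_integer_)
  cand <- which(d$contig[-n] == es_contig)
  if (!length(cand)) cand <- seq_len(n - 1L)
  cand[which.max(d$t_end[cand])]
}

#' Detect the eccDNA circularization junction of a chain
#'
#' On an orientation-normalized monomer the circle-closing boundary is the
#' junction following the forward-primer-anchored terminal domain.  The
#' junction is annotated with the repeat mediating it (`frt`, `alu` with
#' d(T)-tail flag, or `other`).
#'
#' @inheritParams annotate_junctions
#' @return single-row junction data.frame (class `circularization`), or
#'   `NULL` for single-domain chains.
#' @export
detect_circularization_junction <- function(chain, monomer_seq, ref) {
  ci <- detect_circ_index(chain, ref$es_contig)
  if (is.na(ci)) return(NULL)
  ann <- annotate_junctions(chain, monomer_seq, ref)
  ann[ci, , drop = FALSE]
}

#' Overlap-length distribution over a set of junctions
#'
#' One junction contributes one overlap event (a read with several template
#' switches contributes several events).
#'
#' @param junctions junction data.frame ([annotate_junctions()] rows).
#' @param classes optional junction classes to keep.
#' @return an `overlap_distribution`: list(values, by_class, mode, mean,
#'   histogram).
#' @export
overlap_distribution <- function(junctions, classes = NULL) {
  if (!is.null(classes)) {
    junctions <- junctions[junctions$junction_class %in% classes, ,
                           drop = FALSE]
  }
  v <- junctions$overlap_len
  if (length(v) == 0) {
    return(structure(list(values = integer(), by_class = list(),
                          mode = integer(), mean = NaN,
                          histogram = table(integer())),
                     class = "overlap_distribution"))
  }
  tab <- table(v)
  modes <- as.integer(names(tab)[tab == max(tab)])
  structure(list(values = v,
                 by_class = split(v, junctions$junction_class),
                 mode = modes, mean = mean(v), histogram = tab),
            class = "overlap_distribution")
}

#' @export
print.overlap_distribution <- function(x, ...) {
  cat("overlap_distribution: ", length(x$values), " events, mean ",
      round(x$mean, 2), " bp, mode {",
      paste(x$mode, collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' Test an overlap-length distribution against a random null
#'
#' Compares observed microhomology lengths with a seeded random array drawn
#' from the null model (uniform integers on `[0, max_val]`, size-matched).
#' Reports the two-sample t statistic and, as the recommended primary
#' result, a permutation p-value for the difference in means.
#'
#' @param dist an [overlap_distribution()] or integer vector of overlaps.
#' @param null_model `"uniform"` (integers on `[0, max_val]`).
#' @param max_val upper bound of the null (default: max observed overlap).
#' @param seed seed for the null draw and permutations (default 1729).
#' @param n_perm number of label permutations (default 999).
#' @return list: `statistic`, `p_t` (NA with `t_applicable = FALSE` in the
#'   zero-variance degenerate case), `p_perm`, `null` (model, max_val, n,
#'   seed), `n_obs`.
#' @export
test_nonrandom <- function(dist, null_model = "uniform", max_val = NULL,
                           seed = 1729L, n_perm = 999L) {
  obs <- if (inherits(dist, "overlap_distribution")) dist$values else dist
  obs <- as.numeric(obs)
  if (length(obs) < 2) stop("need >= 2 observations", call. = FALSE)
  null_model <- match.arg(null_model, "uniform")
  if (is.null(max_val)) max_val <- max(obs)
  with_seed(seed, {
    null <- sample.int(max_val + 1L, length(obs), replace = TRUE) - 1L
    t_ok <- sd(obs) > 0 || sd(null) > 0
    tt <- if (t_ok) t.test(obs, null) else NULL
    comb <- c(obs, null)
    n1 <- length(obs); n2 <- length(null); S <- sum(comb)
    stat <- mean(obs) - mean(null)
    s1 <- vapply(seq_len(n_perm), function(i) {
      sum(comb[sample.int(n1 + n2, n1)])
    }, numeric(1))
    perm <- s1 / n1 - (S - s1) / n2
    p_perm <- (1 + sum(abs(perm) >= abs(stat) - 1e-12)) / (n_perm + 1)
    list(statistic = stat,
         t_statistic = if (t_ok) unname(tt$statistic) else NA_real_,
         p_t = if (t_ok) tt$p.value else NA_real_,
         t_applicable = t_ok,
         p_perm = p_perm,
         null = list(model = null_model, max_val = max_val,
                     n = length(null), seed = seed),
         n_obs = length(obs), n_perm = n_perm)
  })
}
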