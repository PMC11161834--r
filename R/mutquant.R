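# Mutation quantitation over template-switch domains: per-position pileups,
# the per-generation rate table (rows A-H), per-kilobase deletion metrics,
# the per-read mutation threshold, and trinucleotide substitution signatures.

# walk one segment's run-length edit operations; returns per-event records
# in target (contig) coordinates, with read-observed alternate bases
walk_segment <- function(seg, monomer_seq) {
  cc <- cigar_consumed(seg$cigar)
  qseq <- seg_query_seq(seg, monomer_seq)    # oriented: walks t ascending
  t <- seg$t_start
  qi <- 0L
  mis <- list(); del <- list(); ins <- list()
  for (i in seq_along(cc$op)) {
    op <- cc$op[i]; len <- cc$len[i]
    if (op == "=") {
      t <- t + len; qi <- qi + len
    } else if (op == "X") {
      mis[[length(mis) + 1L]] <- data.frame(
        pos = t + 0:(len - 1L),
        alt = chars(substr0(qseq, qi, qi + len)))
      t <- t + len; qi <- qi + len
    } else if (op == "D") {
      del[[length(del) + 1L]] <- data.frame(pos = t, len = len)
      t <- t + len
    } else if (op == "I") {
      ins[[length(ins) + 1L]] <- data.frame(
        pos = t, seq = substr0(qseq, qi, qi + len))
      qi <- qi + len
    } else if (op == "M") {
      stop("alignment without explicit match/mismatch operations; ",
           "re-align or supply =/X CIGARs (SAM with extended CIGAR)",
           call. = FALSE)
    }
  }
  list(mismatch = if (length(mis)) do.call(rbind, mis) else NULL,
       del = if (length(del)) do.call(rbind, del) else NULL,
       ins = if (length(ins)) do.call(rbind, ins) else NULL,
       contig = seg$contig, monomer = seg$monomer,
       span = seg$t_end - seg$t_start)
}

#' Per-position pileup over template-switch domains
#'
#' Tallies mismatches, deletion events (one maximal run of contiguous
#' deleted reference bases, counted once at its start column), deleted-base
#' coverage, and insertion events (one contiguous inserted string anchored
#' between two reference positions) across all chained domains, restricted
#' to the domain intervals.  Each read's mismatch counts once per column
#' (no consensus calling).
#'
#' @param chains list of `domain_chain` objects ([chain_all()]).
#' @param monomers monomer data.frame (`id`, `seq`).
#' @param ref the [hybrid_reference()].
#' @return a `pileup` object: `columns` (data.table of event-bearing
#'   columns: contig, pos, ref, depth, mismatch counts per base, del_starts,
#'   del_cov, ins_events), `totals`, `aligned_bp`, `mismatch_calls`,
#'   `read_stats` (per-monomer event and aligned-bp tallies), `coverage`
#'   (per-contig [IRanges::Rle]).
#' @export
pileup <- function(chains, monomers, ref) {
  seqs <- setNames(monomers$seq, monomers$id)
  events <- list()
  for (ch in chains) {
    d <- ch$domains
    for (i in seq_len(nrow(d))) {
      events[[length(events) + 1L]] <- walk_segment(d[i, ], seqs[[d$monomer[i]]])
    }
  }
  mk <- function(field) {
    rbindlist(lapply(events, function(e) {
      x <- e[[field]]
      if (is.null(x)) return(NULL)
      x$contig <- e$contig; x$monomer <- e$monomer
      x
    }))
  }
  mis <- mk("mismatch")
  del <- mk("del")
  ins <- mk("ins")
  # per-contig coverage from domain target intervals
  iv <- rbindlist(lapply(chains, function(ch) {
    d <- ch$domains
    if (nrow(d) == 0) return(NULL)
    data.table(contig = d$contig, start = d$t_start, end = d$t_end,
               monomer = d$monomer)
  }))
  coverage <- list()
  if (!is.null(iv) && nrow(iv)) {
    for (ct in unique(iv$contig)) {
      s <- iv[contig == ct]
      coverage[[ct]] <- IRanges::coverage(
        IRanges::IRanges(start = s$start + 1L, end = s$end),
        width = nchar(ref$contigs[[ct]]))
    }
  }
  aligned_bp <- if (!is.null(iv) && nrow(iv)) sum(iv$end - iv$start) else 0L

  # event-bearing columns
  cols <- NULL
  if (!is.null(mis) && nrow(mis)) {
    mtab <- mis[, .(n = .N), by = .(contig, pos, alt)]
    wide <- data.table::dcast(mtab, contig + pos ~ alt, value.var = "n",
                              fill = 0L)
    for (b in c("A", "C", "G", "T")) {
      if (!b %in% names(wide)) wide[[b]] <- 0L
    }
    cols <- wide[, c("contig", "pos", "A", "C", "G", "T"), with = FALSE]
  } else {
    cols <- data.table(contig = character(), pos = integer(),
                       A = integer(), C = integer(), G = integer(),
                       T = integer())
  }
  dtab <- if (!is.null(del) && nrow(del)) {
    del[, .(del_starts = .N, del_cov_here = sum(len)), by = .(contig, pos)]
  } else {
    data.table(contig = character(), pos = integer(),
               del_starts = integer(), del_cov_here = integer())
  }
  itab <- if (!is.null(ins) && nrow(ins)) {
    ins[, .(ins_events = .N,
            ins_seqs = paste(seq, collapse = ",")), by = .(contig, pos)]
  } else {
    data.table(contig = character(), pos = integer(),
               ins_events = integer(), ins_seqs = character())
  }
  columns <- merge(merge(cols, dtab, by = c("contig", "pos"), all = TRUE),
                   itab, by = c("contig", "pos"), all = TRUE)
  for (b in c("A", "C", "G", "T", "del_starts", "del_cov_here",
              "ins_events")) {
    columns[[b]][is.na(columns[[b]])] <- 0L
  }
  if (nrow(columns)) {
    columns$ref <- vapply(seq_len(nrow(columns)), function(i) {
      substr0(ref$contigs[[columns$contig[i]]], columns$pos[i],
              columns$pos[i] + 1L)
    }, character(1))
    columns$depth <- vapply(seq_len(nrow(columns)), function(i) {
      cv <- coverage[[columns$contig[i]]]
      if (is.null(cv)) 0L else as.integer(cv[columns$pos[i] + 1L])
    }, integer(1))
  } else {
    columns$ref <- character(0)
    columns$depth <- integer(0)
  }
  data.table::setcolorder(columns, c("contig", "pos", "ref", "depth"))
  data.table::setorder(columns, contig, pos)

  mismatch_calls <- if (!is.null(mis) && nrow(mis)) {
    mc <- mis[, .(contig, pos, alt, monomer)]
    mc$ref <- vapply(seq_len(nrow(mc)), function(i) {
      substr0(ref$contigs[[mc$contig[i]]], mc$pos[i], mc$pos[i] + 1L)
    }, character(1))
    as.data.frame(mc)
  } else {
    data.frame(contig = character(), pos = integer(), alt = character(),
               monomer = character(), ref = character())
  }

  if (is.null(iv) || nrow(iv) == 0) {
    iv <- data.table(contig = character(), start = integer(),
                     end = integer(), monomer = character())
  }
  rs <- data.table(monomer = unique(iv$monomer))
  add <- function(rs, x, f, nm) {
    if (!is.null(x) && nrow(x)) {
      agg <- x[, .(v = f(.SD)), by = monomer]
      rs <- merge(rs, agg, by = "monomer", all.x = TRUE)
    } else {
      rs$v <- NA_real_
    }
    rs$v[is.na(rs$v)] <- 0
    data.table::setnames(rs, "v", nm)
    rs
  }
  rs <- add(rs, mis, function(s) nrow(s), "mismatches")
  rs <- add(rs, del, function(s) nrow(s), "del_events")
  rs <- add(rs, del, function(s) sum(s$len), "del_nt")
  rs <- add(rs, ins, function(s) nrow(s), "ins_events")
  rs <- add(rs, ins, function(s) sum(nchar(s$seq)), "ins_nt")
  ab <- iv[, .(aligned_bp = sum(end - start)), by = monomer]
  rs <- merge(rs, ab, by = "monomer", all.x = TRUE)

  totals <- list(
    mismatches = if (is.null(mis)) 0L else nrow(mis),
    del_events = if (is.null(del)) 0L else nrow(del),
    del_nt = if (is.null(del) || !nrow(del)) 0L else sum(del$len),
    ins_events = if (is.null(ins)) 0L else nrow(ins),
    ins_nt = if (is.null(ins) || !nrow(ins)) 0L else sum(nchar(ins$seq)))
  structure(list(columns = columns, totals = totals,
                 aligned_bp = aligned_bp, mismatch_calls = mismatch_calls,
                 read_stats = as.data.frame(rs), coverage = coverage),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat("pileup: ", x$aligned_bp, " aligned bp; ",
      x$totals$mismatches, " mismatches, ",
      x$totals$del_events, " deletion events (", x$totals$del_nt, " nt), ",
      x$totals$ins_events, " insertion events (", x$totals$ins_nt, " nt)\n",
      sep = "")
  invisible(x)
}

#' Per-generation mutation-rate table (rows A-H)
#'
#' A mismatches, B deletion events (tracts of contiguous deletion), C
#' deleted nucleotides, E insertion events (tracts of contiguous insertion)
#' and F inserted nucleotides, each per aligned bp per generation; D = C/B
#' deleted nucleotides per deletion event; G = F/E inserted nucleotides per
#' insertion event; H = A + C + F (indels + substitutions).  Ratios are NA
#' when their denominators are zero.
#'
#' @param totals event totals (list as in `pileup$totals`, or a [pileup()]).
#' @param aligned_bp total reference bases covered by template-switch
#'   domains (the rate denominator).
#' @param generations cell doublings.
#' @return a one-row `rate_table` data.frame with columns A..H,
#'   `aligned_bp`, `generations`.
#' @export
mutation_rates <- function(totals, aligned_bp = NULL, generations = 200L) {
  if (inherits(totals, "pileup")) {
    if (is.null(aligned_bp)) aligned_bp <- totals$aligned_bp
    totals <- totals$totals
  }
  if (is.null(aligned_bp) || aligned_bp <= 0) {
    stop("aligned_bp must be > 0", call. = FALSE)
  }
  if (generations <= 0) stop("generations must be > 0", call. = FALSE)
  denom <- aligned_bp * generations
  A <- totals$mismatches / denom
  B <- totals$del_events / denom
  C <- totals$del_nt / denom
  E <- totals$ins_events / denom
  F <- totals$ins_nt / denom
  out <- data.frame(A = A, B = B, C = C,
                    D = if (B > 0) C / B else NA_real_,
                    E = E, F = F,
                    G = if (E > 0) F / E else NA_real_,
                    H = A + C + F,
                    aligned_bp = aligned_bp, generations = generations)
  class(out) <- c("rate_table", "data.frame")
  out
}

#' Per-kilobase deletion metrics
#'
#' Deleted bases and deletion events per 1,000 aligned bp, with no
#' generation normalization (the scale used to compare deletion breadth
#' between conditions).
#'
#' @inheritParams mutation_rates
#' @return named numeric vector: `deleted_bases_per_kb`,
#'   `deletion_events_per_kb`.
#' @export
per_kb_deletion_metrics <- function(totals, aligned_bp = NULL) {
  if (inherits(totals, "pileup")) {
    if (is.null(aligned_bp)) aligned_bp <- totals$aligned_bp
    totals <- totals$totals
  }
  if (is.null(aligned_bp) || aligned_bp <= 0) {
    stop("aligned_bp must be > 0", call. = FALSE)
  }
  c(deleted_bases_per_kb = totals$del_nt / aligned_bp * 1000,
    deletion_events_per_kb = totals$del_events / aligned_bp * 1000)
}

#' Remove reads below a mutation-density threshold
#'
#' Reads whose total mutation events (mismatches + deletion events +
#' insertion events) per aligned kb fall below the threshold are removed;
#' rates are recomputed on the kept set by the caller.
#'
#' @param read_stats per-read tallies (`pileup$read_stats`).
#' @param threshold mutations per kb (default 2).
#' @return list: `kept`, `removed` data.frames, each with a
#'   `mutations_per_kb` column.
#' @export
apply_mutation_threshold <- function(read_stats, threshold = 2) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  mpk <- (read_stats$mismatches + read_stats$del_events +
            read_stats$ins_events) / (read_stats$aligned_bp / 1000)
  read_stats$mutations_per_kb <- mpk
  keep <- mpk >= threshold
  list(kept = read_stats[keep, , drop = FALSE],
       removed = read_stats[!keep, , drop = FALSE])
}

BASES <- c("A", "C", "G", "T")
SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

comp1 <- function(b) chartr("ACGT", "TGCA", b)

#' Trinucleotide substitution signature
#'
#' Folds every substitution to the pyrimidine-centred convention (a G>A call
#' in context NGN is recorded as C>T in the reverse-complement context) and
#' tallies the 96 channels (6 substitution classes x 16 flanking
#' trinucleotide contexts), together with the 6-class and 16-context
#' marginals used for bar plots.  Calls at contig edges or with N in the
#' context are skipped and counted.
#'
#' @param mismatch_calls data.frame with `contig`, `pos`, `ref`, `alt`
#'   (`pileup$mismatch_calls`).
#' @param ref the [hybrid_reference()].
#' @return a `signature` object: `channels` (96-row data.frame: context,
#'   class, count, fraction), `six_class`, `context16`, `n_used`,
#'   `n_skipped`.
#' @export
trinucleotide_signature <- function(mismatch_calls, ref) {
  grid <- expand.grid(up = BASES, down = BASES, class = SUB_CLASSES,
                      stringsAsFactors = FALSE)
  grid$context <- paste0(grid$up, substr(grid$class, 1, 1), grid$down)
  counts <- setNames(rep(0L, nrow(grid)),
                     paste(grid$context, grid$class))
  skipped <- 0L
  n <- nrow(mismatch_calls)
  for (i in seq_len(n)) {
    ct <- mismatch_calls$contig[i]
    p <- mismatch_calls$pos[i]
    cs <- ref$contigs[[ct]]
    if (p < 1 || p > nchar(cs) - 2L) { skipped <- skipped + 1L; next }
    tri <- substr0(cs, p - 1L, p + 2L)
    refb <- mismatch_calls$ref[i]
    altb <- mismatch_calls$alt[i]
    if (grepl("N", tri) || refb == "N" || altb == "N") {
      skipped <- skipped + 1L; next
    }
    if (refb %in% c("G", "A")) {
      refb <- comp1(refb); altb <- comp1(altb); tri <- revcomp(tri)
    }
    key <- paste(tri, paste0(refb, ">", altb))
    counts[key] <- counts[key] + 1L
  }
  used <- sum(counts)
  channels <- data.frame(context = grid$context, class = grid$class,
                         count = as.integer(counts),
                         fraction = if (used > 0) counts / used else
                           rep(0, length(counts)))
  six <- tapply(channels$count, channels$class, sum)[SUB_CLASSES]
  ctx16 <- tapply(channels$count, channels$context, sum)
  structure(list(channels = channels,
                 six_class = setNames(as.integer(six), SUB_CLASSES),
                 context16 = ctx16, n_used = used, n_skipped = skipped),
            class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat("trinucleotide signature: ", x$n_used, " substitutions (",
      x$n_skipped, " skipped)\n", sep = "")
  print(x$six_class)
  invisible(x)
}

#' Published eccDNA mutation-rate table (simulation presets)
#'
#' Per-generation mutation rates of eccDNAs quantitated over template-switch
#' domains for six non-B microsatellite ectopic-site cell clones and one
#' polymerase-eta knockdown: rows A (mismatches/bp/generation), B (deletion
#' events), C (deleted nucleotides), D = C/B, E (insertion events), F
#' (inserted nucleotides), G = F/E and H (A + C + F), with the approximate
#' generation counts used for normalization.  Used as simulation presets
#' and for rate-identity checks.
#'
#' @return data.frame with one column per clone and rows A..H plus
#'   `generations`.
#' @export
published_rate_table <- function() {
  tab <- data.frame(
    CAG102_c10 = c(1.28e-06, 8.00e-06, 8.75e-05, 10.9, 7.15e-06,
                   1.67e-05, 2.3, 1.04e-04, 200),
    CAG102_c13 = c(2.46e-06, 8.72e-06, 4.07e-05, 4.7, 6.09e-06,
                   9.07e-06, 1.5, 5.37e-05, 200),
    CAG102_c13_POLH_kd = c(2.16e-06, 8.10e-06, 4.21e-05, 5.2, 5.43e-06,
                           4.79e-05, 8.8, 9.22e-05, 200),
    G4_c1 = c(4.70e-06, 5.81e-06, 1.27e-05, 2.2, 8.00e-06,
              1.02e-05, 1.3, 7.30e-05, 150),
    G4_c6 = c(5.00e-06, 1.70e-06, 8.58e-06, 5.0, 8.58e-06,
              2.16e-05, 2.5, 4.36e-05, 150),
    H3 = c(3.99e-06, 1.40e-06, 8.35e-06, 6.0, 9.98e-06,
           2.05e-05, 2.1, 3.85e-05, 150),
    ATTCT47 = c(4.22e-06, 4.72e-06, 7.78e-06, 1.7, 4.42e-06,
                5.27e-06, 1.2, 5.67e-05, 200))
  rownames(tab) <- c("A", "B", "C", "D", "E", "F", "G", "H", "generations")
  tab
}
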