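# Segment-alignment interchange: PAF and BED writers/readers and SAM import,
# so externally produced alignments (e.g. a BWA-MEM run on real data) can be
# substituted for the internal aligner.

cigar_consumed <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[=XIDMSH]", cigar))[[1]]
  len <- as.integer(sub("[=XIDMSH]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  list(op = op, len = len,
       q = sum(len[op %in% c("=", "X", "I", "M", "S")]),
       t = sum(len[op %in% c("=", "X", "D", "M")]))
}

cigar_stats <- function(cigar) {
  cc <- cigar_consumed(cigar)
  ins <- cc$op == "I"; del <- cc$op == "D"
  data.frame(nmatch = sum(cc$len[cc$op == "="]),
             nmismatch = sum(cc$len[cc$op == "X"]),
             ins_events = sum(ins), del_events = sum(del),
             ins_len = sum(cc$len[ins]), del_len = sum(cc$len[del]))
}

#' Write segment alignments as PAF
#'
#' Standard 12-column PAF with the run-length edit operations in a `cg:Z:`
#' tag; query coordinates are on the original read orientation, per the PAF
#' column definition.
#'
#' @param segments segment data.frame ([align_segments()]).
#' @param qlens named integer vector of query (monomer) lengths.
#' @param tlens named integer vector of target contig lengths.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(segments, qlens, tlens, path) {
  alnlen <- segments$nmatch + segments$nmismatch + segments$ins_len +
    segments$del_len
  rows <- data.frame(
    qname = segments$monomer,
    qlen = as.integer(qlens[segments$monomer]),
    qstart = segments$q_start, qend = segments$q_end,
    strand = segments$strand,
    tname = segments$contig,
    tlen = as.integer(tlens[segments$contig]),
    tstart = segments$t_start, tend = segments$t_end,
    nmatch = segments$nmatch, alnlen = alnlen, mapq = 255L,
    cg = paste0("cg:Z:", segments$cigar))
  write.table(rows, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read segment alignments from PAF
#'
#' Restores coordinates, strand and (when a `cg:Z:` tag is present) the edit
#' operations; per-segment tallies are recomputed from the operations.
#' Malformed rows are skipped with a warning, or raise an error in strict
#' mode.
#'
#' @param path PAF file path.
#' @param strict error on malformed rows instead of skipping.
#' @return segment data.frame in the [align_segments()] layout.
#' @export
read_paf <- function(path, strict = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12 || is.na(suppressWarnings(as.integer(f[3])))) {
      msg <- paste0("malformed PAF row ", i)
      if (strict) stop(msg, call. = FALSE)
      warning(msg, ", skipped", call. = FALSE)
      next
    }
    cg <- grep("^cg:Z:", f[-(1:12)], value = TRUE)
    cigar <- if (length(cg)) sub("^cg:Z:", "", cg[1]) else NA_character_
    st <- if (!is.na(cigar)) cigar_stats(cigar) else
      data.frame(nmatch = as.integer(f[10]),
                 nmismatch = as.integer(f[11]) - as.integer(f[10]),
                 ins_events = NA_integer_, del_events = NA_integer_,
                 ins_len = NA_integer_, del_len = NA_integer_)
    alen <- st$nmatch + st$nmismatch +
      ifelse(is.na(st$ins_len), 0L, st$ins_len) +
      ifelse(is.na(st$del_len), 0L, st$del_len)
    out[[i]] <- cbind(
      data.frame(monomer = f[1], q_start = as.integer(f[3]),
                 q_end = as.integer(f[4]), contig = f[6],
                 t_start = as.integer(f[8]), t_end = as.integer(f[9]),
                 strand = f[5], cigar = cigar),
      st,
      data.frame(identity = ifelse(alen > 0, st$nmatch / alen, 0),
                 score = st$nmatch - 2 * st$nmismatch -
                   3 * (ifelse(is.na(st$ins_events), 0L, st$ins_events) +
                        ifelse(is.na(st$del_events), 0L, st$del_events)) -
                   (ifelse(is.na(st$ins_len), 0L, st$ins_len) +
                    ifelse(is.na(st$del_len), 0L, st$del_len))))
  }
  res <- do.call(rbind, out)
  if (is.null(res)) empty_segments() else res
}

#' Write domain intervals as BED
#'
#' 0-based half-open BED6: contig, start, end, name (monomer), score
#' (alignment score, floored at 0), strand.
#'
#' @param domains domain/segment data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(domains, path) {
  rows <- data.frame(domains$contig, domains$t_start, domains$t_end,
                     domains$monomer, pmax(0, round(domains$score)),
                     domains$strand)
  write.table(rows, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Import segment alignments from SAM
#'
#' Reads a SAM file (via Rsamtools), keeping primary and supplementary
#' alignments and grouping all records of one read name into that monomer's
#' alignment set.  Query intervals are recovered from the clipping
#' operations on the original read orientation.
#'
#' @param path SAM file path.
#' @return segment data.frame in the [align_segments()] layout (tallies
#'   require `=`/`X` CIGARs; `M`-CIGAR rows carry `NA` mismatch counts).
#' @export
read_sam_segments <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("SAM import requires the Rsamtools package", call. = FALSE)
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "qwidth"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(b$pos) & bitwAnd(b$flag, 4L) == 0L &
    bitwAnd(b$flag, 256L) == 0L           # drop unmapped and secondary
  out <- list()
  for (i in which(keep)) {
    cigar <- b$cigar[i]
    cc <- cigar_consumed(cigar)
    clip_lead <- if (cc$op[1] %in% c("S", "H")) cc$len[1] else 0L
    nop <- length(cc$op)
    clip_tail <- if (cc$op[nop] %in% c("S", "H")) cc$len[nop] else 0L
    core <- cc$op %in% c("=", "X", "I", "D", "M")
    qspan <- sum(cc$len[cc$op %in% c("=", "X", "I", "M")])
    tspan <- sum(cc$len[cc$op %in% c("=", "X", "D", "M")])
    qlen <- clip_lead + qspan + clip_tail
    rev <- bitwAnd(b$flag[i], 16L) != 0L
    q_start <- if (rev) clip_tail else clip_lead
    core_cigar <- paste0(cc$len[core], cc$op[core], collapse = "")
    st <- cigar_stats(core_cigar)
    if (st$nmatch + st$nmismatch == 0 && grepl("M", cigar)) {
      st$nmatch <- NA_integer_; st$nmismatch <- NA_integer_
    }
    alen <- qspan + sum(cc$len[cc$op == "D"]) - sum(cc$len[cc$op == "I"])
    out[[length(out) + 1L]] <- cbind(
      data.frame(monomer = b$qname[i], q_start = q_start,
                 q_end = q_start + qspan,
                 contig = as.character(b$rname[i]),
                 t_start = b$pos[i] - 1L, t_end = b$pos[i] - 1L + tspan,
                 strand = if (rev) "-" else "+", cigar = core_cigar),
      st,
      data.frame(identity = ifelse(!is.na(st$nmatch) & alen > 0,
                                   st$nmatch / alen, NA_real_),
                 score = ifelse(!is.na(st$nmatch),
                                st$nmatch - 2 * st$nmismatch -
                                  3 * (st$ins_events + st$del_events) -
                                  (st$ins_len + st$del_len), NA_real_)))
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty_segments())
  res <- res[order(res$monomer, res$q_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
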