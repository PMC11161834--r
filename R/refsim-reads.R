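# Inverse-PCR rolling-circle concatemer read simulation with ground truth.

#' Read model for simulated iPCR circular-consensus reads
#'
#' @param monomers_per_read numeric probability vector over 1..8 monomers per
#'   concatemer read (normalized internally), or a `function(n)` returning
#'   `n` integer monomer counts.
#' @param seq_error_rate background substitution error rate in errors/kb
#'   (circular-consensus scale; default 0.1, below the 0.2/kb control bound).
#' @param spanning_fraction probability that a read rolls through the
#'   unamplified inter-primer gap (rolling-circle artifact), in which case
#'   its monomer unit is the full circle rather than the amplicon.
#' @param n_reads number of reads to simulate.
#' @return a `read_model` object.
#' @export
read_model <- function(monomers_per_read = c(0.35, 0.25, 0.15, 0.10,
                                             0.07, 0.04, 0.02, 0.02),
                       seq_error_rate = 0.1, spanning_fraction = 0.02,
                       n_reads = 100L) {
  stopifnot(seq_error_rate >= 0, spanning_fraction >= 0,
            spanning_fraction <= 1, n_reads > 0)
  if (is.numeric(monomers_per_read)) {
    stopifnot(length(monomers_per_read) >= 1, all(monomers_per_read >= 0),
              sum(monomers_per_read) > 0)
  } else {
    stopifnot(is.function(monomers_per_read))
  }
  structure(list(monomers_per_read = monomers_per_read,
                 seq_error_rate = seq_error_rate,
                 spanning_fraction = spanning_fraction,
                 n_reads = as.integer(n_reads)),
            class = "read_model")
}

# circular exact/approximate location of a pattern on a circle
locate_on_circle <- function(circle, pattern, max_edits = 2L) {
  n <- nchar(circle)
  doubled <- paste0(circle, substr(circle, 1, min(n, nchar(pattern) + 8L)))
  h <- cpp_approx_find(doubled, pattern, max_edits)
  if (nrow(h) == 0) return(NULL)
  h <- h[order(h$edits, h$start), , drop = FALSE]
  h$start <- h$start %% n
  h[!duplicated(h$start), , drop = FALSE]
}

# substitution sequencing errors at `rate` errors/kb; returns seq + positions
apply_seq_errors <- function(seq, rate) {
  len <- nchar(seq)
  p <- rate / 1000
  if (p <= 0 || len == 0) {
    return(list(sequence = seq,
                errors = data.frame(pos = integer(), ref = character(),
                                    alt = character())))
  }
  n_err <- rbinom(1, len, p)
  if (n_err == 0) {
    return(list(sequence = seq,
                errors = data.frame(pos = integer(), ref = character(),
                                    alt = character())))
  }
  pos <- sort(sample.int(len, n_err)) - 1L
  v <- chars(seq)
  refb <- v[pos + 1L]
  altb <- vapply(refb, function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1), USE.NAMES = FALSE)
  v[pos + 1L] <- altb
  list(sequence = paste(v, collapse = ""),
       errors = data.frame(pos = pos, ref = refb, alt = altb))
}

#' Simulate iPCR concatemer reads from one eccDNA circle
#'
#' The inverse-PCR amplicon runs from the forward-primer start, around the
#' circle, to the reverse-primer end; the unamplified inter-primer gap is
#' excluded.  Each read is a tandem concatemer of 1..8 amplicon monomers; a
#' `spanning_fraction` subset instead concatenates full circle copies
#' (rolling through the gap).  Reads are reverse-complemented with
#' probability 1/2 and carry i.i.d. substitution errors.
#'
#' @param circle circle DNA string (as from [simulate_eccdna()]).
#' @param primers list with `fwd` and `rev` primer sequences; both sites must
#'   be present on the circle in head-to-head orientation.
#' @param model a [read_model()].
#' @param seed optional integer seed.
#' @param id_prefix read-name prefix.
#' @return list with `reads` (named character vector) and `truth`
#'   (data.frame: read, n_monomers, monomer_len, spanning, rc, n_seq_errors,
#'   amplicon_offset; plus attribute `amplicon`).
#' @export
simulate_ipcr_reads <- function(circle, primers, model, seed = NULL,
                                id_prefix = "read") {
  stopifnot(inherits(model, "read_model"))
  n <- nchar(circle)
  fh <- locate_on_circle(circle, primers$fwd)
  rh <- locate_on_circle(circle, revcomp(primers$rev))
  if (is.null(fh)) stop("forward primer absent from circle", call. = FALSE)
  if (is.null(rh)) stop("reverse primer absent from circle", call. = FALSE)
  f0 <- fh$start[1]
  rot <- paste0(substr0(circle, f0, n), substr0(circle, 0, f0))
  r_end_rot <- (rh$start[1] + nchar(primers$rev) - f0) %% n
  if (r_end_rot == 0) r_end_rot <- n
  amplicon <- substr0(rot, 0, r_end_rot)

  with_seed(seed, {
    nr <- model$n_reads
    m <- if (is.function(model$monomers_per_read)) {
      as.integer(model$monomers_per_read(nr))
    } else {
      pr <- model$monomers_per_read / sum(model$monomers_per_read)
      sample(seq_along(pr), nr, replace = TRUE, prob = pr)
    }
    spanning <- runif(nr) < model$spanning_fraction
    rc <- runif(nr) < 0.5
    reads <- character(nr)
    nerr <- integer(nr)
    ulen <- integer(nr)
    for (i in seq_len(nr)) {
      unit <- if (spanning[i]) rot else amplicon
      ulen[i] <- nchar(unit)
      rd <- strrep(unit, m[i])
      er <- apply_seq_errors(rd, model$seq_error_rate)
      rd <- er$sequence
      nerr[i] <- nrow(er$errors)
      if (rc[i]) rd <- revcomp(rd)
      reads[i] <- rd
    }
    ids <- sprintf("%s%05d", id_prefix, seq_len(nr))
    names(reads) <- ids
    truth <- data.frame(read = ids, n_monomers = m, monomer_len = ulen,
                        spanning = spanning, rc = rc, n_seq_errors = nerr,
                        amplicon_offset = f0)
    attr(truth, "amplicon") <- amplicon
    attr(truth, "circle_rotated") <- rot
    list(reads = reads, truth = truth)
  })
}

#' Simulate a complete dataset (reference, circle, reads, truth)
#'
#' Convenience driver used by tests, fixtures and the analysis scripts:
#' builds/receives a reference, simulates one eccDNA per the structural
#' model, then concatemer reads.
#'
#' @param ref a [hybrid_reference()] (e.g. [default_reference()]).
#' @param ecc_model an [eccdna_model()].
#' @param rd_model a [read_model()].
#' @param seed integer seed controlling mutation and read sampling.
#' @return list: `ref`, `circle`, `ecc_truth`, `reads`, `read_truth`.
#' @export
simulate_dataset <- function(ref, ecc_model, rd_model, seed = 1L) {
  ecc <- simulate_eccdna(ref, ecc_model, seed = seed)
  rr <- simulate_ipcr_reads(ecc$sequence, ref$site$primers, rd_model,
                            seed = seed + 1L)
  list(ref = ref, circle = ecc$sequence, ecc_truth = ecc$truth,
       reads = rr$reads, read_truth = rr$truth)
}

#' Simulate a population of independently mutated eccDNA molecules
#'
#' Each molecule receives its own draw from the mutation model; inverse PCR
#' only amplifies molecules whose primer sites survive mutagenesis (within
#' the primer-finding edit tolerance), so disrupted circles are skipped and
#' counted, as in a real iPCR library.
#'
#' @param ref a [hybrid_reference()] with `$site`.
#' @param ecc_model an [eccdna_model()] (typically with a mutation model).
#' @param n_molecules number of independent circles.
#' @param rd_model per-circle [read_model()] (default: one error-free
#'   single-monomer read per circle).
#' @param seed integer seed.
#' @return list: `reads` (named character vector over all molecules),
#'   `truths` (per-molecule [simulate_eccdna()] truths, amplified molecules
#'   only), `n_unamplifiable`.
#' @export
simulate_population <- function(ref, ecc_model, n_molecules,
                                rd_model = read_model(
                                  monomers_per_read = 1, seq_error_rate = 0,
                                  spanning_fraction = 0, n_reads = 1L),
                                seed = 1L) {
  reads <- list()
  truths <- list()
  skipped <- 0L
  for (i in seq_len(n_molecules)) {
    ecc <- simulate_eccdna(ref, ecc_model, seed = seed + 7L * i)
    rr <- tryCatch(
      simulate_ipcr_reads(ecc$sequence, ref$site$primers, rd_model,
                          seed = seed + 7L * i + 3L,
                          id_prefix = sprintf("mol%05d_r", i)),
      error = function(e) NULL)
    if (is.null(rr)) { skipped <- skipped + 1L; next }
    reads[[length(reads) + 1L]] <- rr$reads
    truths[[length(truths) + 1L]] <- ecc$truth
  }
  list(reads = unlist(reads), truths = truths, n_unamplifiable = skipped)
}

#' Write a simulated dataset to disk
#'
#' Reference contigs as FASTA, reads as FASTQ (fixed quality), the feature
#' table as BED (0-based half-open) and the ground truth as JSON.
#'
#' @param sim result of [simulate_dataset()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_seqs(sim$ref$contigs, file.path(outdir, "reference.fa"))
  write_seqs(sim$reads, file.path(outdir, "reads.fastq"), format = "fastq")
  fe <- sim$ref$features
  write.table(
    data.frame(contig = sim$ref$es_contig, start = fe$start, end = fe$end,
               name = fe$name, score = 0L, strand = fe$strand),
    file.path(outdir, "features.bed"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  truth <- list(ecc = sim$ecc_truth,
                reads = sim$read_truth,
                amplicon = attr(sim$read_truth, "amplicon"))
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
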