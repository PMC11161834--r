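# End-to-end orchestration: decatenate -> filter -> deduplicate -> align ->
# chain -> junctions -> mutation quantitation, with a machine-readable
# report; plus condition comparison and deterministic fixture bundles.

#' Pipeline configuration
#'
#' @param max_edits primer-match edit tolerance ([find_primer_sites()]).
#' @param k_specific specificity-filter flank length ([filter_specific()]).
#' @param min_len,min_identity segment-alignment filters
#'   ([align_segments()]).
#' @param max_query_overlap chaining microhomology allowance
#'   ([chain_domains()]).
#' @param verify_k donor-unique k-mer length ([verify_nonallelic()]).
#' @param generations cell doublings for rate normalization.
#' @param mutation_threshold optional per-read mutations/kb threshold; reads
#'   below it are additionally quantitated separately (`NULL` = off, the
#'   default analysis applies no threshold).
#' @return a named list of parameters.
#' @export
pipeline_config <- function(max_edits = 2L, k_specific = 6L, min_len = 30L,
                            min_identity = 0.8, max_query_overlap = 300L,
                            verify_k = 25L, generations = 200L,
                            mutation_threshold = NULL) {
  list(max_edits = max_edits, k_specific = k_specific, min_len = min_len,
       min_identity = min_identity, max_query_overlap = max_query_overlap,
       verify_k = verify_k, generations = generations,
       mutation_threshold = mutation_threshold)
}

#' Run the full eccDNA analysis pipeline
#'
#' @param reads named character vector of circular-consensus reads (or a
#'   FASTA/FASTQ path).
#' @param ref a [hybrid_reference()] (with `$site` for primer defaults).
#' @param primers list(fwd, rev); defaults to the reference site's primers.
#' @param config a [pipeline_config()].
#' @return a `run_report`: stage counts, monomers, chains, junction table,
#'   rate table, per-kb deletion metrics, signature, overlap distribution,
#'   and the pileup.
#' @export
run_pipeline <- function(reads, ref, primers = NULL,
                         config = pipeline_config()) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    reads <- read_seqs(reads)
  }
  if (is.null(primers)) {
    if (is.null(ref$site)) {
      stop("primers are required when the reference carries no site",
           call. = FALSE)
    }
    primers <- ref$site$primers
  }
  es_seq <- ref$contigs[[ref$es_contig]]
  counts <- list(reads = length(reads))
  if (length(reads) == 0) {
    warning("no input reads; returning an empty report", call. = FALSE)
  }

  dc <- decat_reads(reads, primers$fwd, primers$rev, config$max_edits)
  counts$monomers_raw <- nrow(dc$monomers)
  counts$fragments_discarded <- nrow(dc$discarded)

  fs <- if (nrow(dc$monomers)) {
    filter_specific(dc$monomers, es_seq, primers, config$k_specific)
  } else {
    list(kept = dc$monomers, removed = dc$monomers)
  }
  counts$nonspecific <- nrow(fs$removed)

  dd <- deduplicate(fs$kept)
  counts$duplicates <- nrow(dd$duplicates)
  monomers <- dd$monomers
  counts$monomers <- nrow(monomers)

  segs <- if (nrow(monomers)) {
    align_segments(monomers, ref, min_len = config$min_len,
                   min_identity = config$min_identity)
  } else {
    empty_segments()
  }
  chains <- chain_all(segs, config$max_query_overlap)
  chains <- lapply(chains, classify_domains, ref = ref)
  counts$unmapped <- sum(vapply(chains, function(ch) ch$unmapped,
                                logical(1))) +
    sum(!(monomers$id %in% names(chains)))

  seqs <- setNames(monomers$seq, monomers$id)
  junctions <- rbindlist(lapply(chains, function(ch) {
    if (nrow(ch$domains) == 0) return(NULL)
    annotate_junctions(ch, seqs[[ch$monomer]], ref)
  }))
  junctions <- if (is.null(junctions) || nrow(junctions) == 0) {
    annotate_junctions(chain_domains(empty_segments()), "", ref)
  } else {
    as.data.frame(junctions)
  }

  # donor-unique verification of nonallelic domains
  verified <- list()
  for (ch in chains) {
    d <- ch$domains
    for (i in seq_len(nrow(d))) {
      if (!is.null(d$class) && d$class[i] == "nonallelic") {
        v <- verify_nonallelic(seg_query_seq(d[i, ], seqs[[d$monomer[i]]]),
                               es_seq, config$verify_k)
        verified[[length(verified) + 1L]] <- data.frame(
          monomer = d$monomer[i], chain_pos = i, contig = d$contig[i],
          t_start = d$t_start[i], t_end = d$t_end[i], verified = v)
      }
    }
  }
  verified <- if (length(verified)) do.call(rbind, verified) else
    data.frame(monomer = character(), chain_pos = integer(),
               contig = character(), t_start = integer(),
               t_end = integer(), verified = logical())

  pl <- pileup(chains, monomers, ref)
  rates <- if (pl$aligned_bp > 0) {
    mutation_rates(pl, generations = config$generations)
  } else {
    NULL
  }
  perkb <- if (pl$aligned_bp > 0) per_kb_deletion_metrics(pl) else
    c(deleted_bases_per_kb = NA_real_, deletion_events_per_kb = NA_real_)
  sig <- trinucleotide_signature(pl$mismatch_calls, ref)
  odist <- overlap_distribution(junctions)

  thresholded <- NULL
  if (!is.null(config$mutation_threshold) && nrow(pl$read_stats)) {
    th <- apply_mutation_threshold(pl$read_stats, config$mutation_threshold)
    thresholded <- list(
      kept = th$kept, removed = th$removed,
      rates = if (nrow(th$kept) && sum(th$kept$aligned_bp) > 0) {
        mutation_rates(list(mismatches = sum(th$kept$mismatches),
                            del_events = sum(th$kept$del_events),
                            del_nt = sum(th$kept$del_nt),
                            ins_events = sum(th$kept$ins_events),
                            ins_nt = sum(th$kept$ins_nt)),
                       sum(th$kept$aligned_bp), config$generations)
      } else NULL)
  }

  stopifnot(counts$monomers_raw == counts$nonspecific + counts$duplicates +
              counts$monomers)
  structure(list(counts = counts, config = config, monomers = monomers,
                 segments = segs, chains = chains, junctions = junctions,
                 nonallelic_verified = verified, pileup = pl,
                 rate_table = rates, per_kb_deletion = perkb,
                 signature = sig, overlap_dist = odist,
                 thresholded = thresholded),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report:\n")
  cat("  reads            ", x$counts$reads, "\n")
  cat("  monomers (raw)   ", x$counts$monomers_raw, "\n")
  cat("  nonspecific      ", x$counts$nonspecific, "\n")
  cat("  duplicates       ", x$counts$duplicates, "\n")
  cat("  monomers (used)  ", x$counts$monomers, "\n")
  cat("  unmapped         ", x$counts$unmapped, "\n")
  if (!is.null(x$rate_table)) {
    cat("  aligned bp       ", x$rate_table$aligned_bp, "\n")
    cat(sprintf("  rates: A=%.3g B=%.3g C=%.3g D=%.3g E=%.3g F=%.3g G=%.3g H=%.3g\n",
                x$rate_table$A, x$rate_table$B, x$rate_table$C,
                x$rate_table$D, x$rate_table$E, x$rate_table$F,
                x$rate_table$G, x$rate_table$H))
  }
  invisible(x)
}

#' Compare run reports across conditions
#'
#' Side-by-side mutation rates, junction-class frequencies, per-kb deletion
#' metrics and six-class substitution profiles, with pairwise permutation
#' tests on the overlap-length distributions.
#'
#' @param reports named list of `run_report`s (>= 2).
#' @param seed seed for the permutation tests.
#' @return list: `rates` (condition x metric data.frame), `junction_classes`,
#'   `six_class`, `overlap_tests` (pairwise data.frame).
#' @export
compare_conditions <- function(reports, seed = 1729L) {
  if (length(reports) < 2) stop("need >= 2 reports", call. = FALSE)
  if (is.null(names(reports))) {
    names(reports) <- paste0("condition", seq_along(reports))
  }
  rates <- do.call(rbind, lapply(reports, function(r) {
    rt <- r$rate_table
    if (is.null(rt)) {
      rt <- data.frame(A = NA, B = NA, C = NA, D = NA, E = NA, F = NA,
                       G = NA, H = NA, aligned_bp = 0,
                       generations = r$config$generations)
    }
    cbind(rt, t(as.data.frame(r$per_kb_deletion)))
  }))
  rownames(rates) <- names(reports)
  jc <- do.call(rbind, lapply(reports, function(r) {
    tab <- table(factor(r$junctions$junction_class,
                        levels = c("intra_es", "nonallelic",
                                   "circularization")))
    as.integer(tab)
  }))
  colnames(jc) <- c("intra_es", "nonallelic", "circularization")
  rownames(jc) <- names(reports)
  six <- do.call(rbind, lapply(reports, function(r) r$signature$six_class))
  rownames(six) <- names(reports)

  pairs <- utils::combn(names(reports), 2)
  tests <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- reports[[pairs[1, i]]]$overlap_dist$values
    b <- reports[[pairs[2, i]]]$overlap_dist$values
    p <- if (length(a) >= 2 && length(b) >= 2) {
      perm_p_two_sample(a, b, seed = seed)
    } else {
      NA_real_
    }
    data.frame(a = pairs[1, i], b = pairs[2, i],
               mean_a = mean(a), mean_b = mean(b), p_perm = p)
  })
  list(rates = rates, junction_classes = jc, six_class = six,
       overlap_tests = do.call(rbind, tests))
}

# two-sample permutation p-value for a difference in means
perm_p_two_sample <- function(a, b, n_perm = 999L, seed = 1729L) {
  with_seed(seed, {
    comb <- c(a, b)
    n1 <- length(a); n2 <- length(b); S <- sum(comb)
    stat <- mean(a) - mean(b)
    s1 <- vapply(seq_len(n_perm), function(i) {
      sum(comb[sample.int(n1 + n2, n1)])
    }, numeric(1))
    perm <- s1 / n1 - (S - s1) / n2
    (1 + sum(abs(perm) >= abs(stat) - 1e-12)) / (n_perm + 1)
  })
}

#' Deterministic fixture bundles
#'
#' `tiny`: error-free, mutation-free reads over the FRT-closed single-domain
#' circle (completes in seconds; exercises decatenation, chaining and the
#' 48-bp circularization junction).  `demo`: two-domain circle with a 6-bp
#' internal microhomology, published-scale mutagenesis and sequencing
#' errors.
#'
#' @param scale `"tiny"` or `"demo"`.
#' @param seed integer seed; identical seeds give byte-identical bundles.
#' @param outdir optional directory; when given, FASTA/FASTQ/BED/JSON files
#'   are written via [write_dataset()].
#' @return the [simulate_dataset()] result, invisibly when writing.
#' @export
make_fixtures <- function(scale = c("tiny", "demo"), seed = 1L,
                          outdir = NULL) {
  scale <- match.arg(scale)
  ref <- default_reference("CAG102", seed = 1L)
  if (scale == "tiny") {
    em <- frt_circle_model(ref)
    rm_ <- read_model(monomers_per_read = c(0.5, 0.3, 0.2),
                      seq_error_rate = 0, spanning_fraction = 0,
                      n_reads = 10L)
  } else {
    tab <- published_rate_table()
    mm <- mutation_model_from_rates(
      A = tab["A", "CAG102_c10"], B = tab["B", "CAG102_c10"],
      C = tab["C", "CAG102_c10"], E = tab["E", "CAG102_c10"],
      F = tab["F", "CAG102_c10"],
      generations = tab["generations", "CAG102_c10"])
    em <- demo_ecc_model(ref, intra_overlap = 6L, mutation_model = mm)
    rm_ <- read_model(seq_error_rate = 0.1, spanning_fraction = 0.02,
                      n_reads = 60L)
  }
  sim <- simulate_dataset(ref, em, rm_, seed = seed)
  if (!is.null(outdir)) {
    write_dataset(sim, outdir)
    return(invisible(sim))
  }
  sim
}
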