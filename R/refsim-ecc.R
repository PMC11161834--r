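# eccDNA structure simulation: domains joined at engineered microhomologies,
# per-generation mutagenesis, ground truth.

#' Mutation model for eccDNA mutagenesis
#'
#' Rates are per base pair per cell generation, matching how eccDNA mutation
#' burdens are normalized: the expected number of events on a molecule is
#' rate x length x generations, with event counts Poisson and positions
#' uniform.  Deletion/insertion tract lengths default to geometric
#' distributions on {1, 2, ...} with the given means.
#'
#' @param mismatch_rate substitutions /bp/generation.
#' @param del_event_rate deletion events (tracts of contiguous deletion)
#'   /bp/generation.
#' @param del_len_mean mean deleted nucleotides per deletion event.
#' @param ins_event_rate insertion events /bp/generation.
#' @param ins_len_mean mean inserted nucleotides per insertion event.
#' @param generations number of cell doublings.
#' @param tandem_frac fraction of insertions that are tandem duplications of
#'   the preceding bases (the remainder insert uniform random bases).
#' @param del_len_dist,ins_len_dist optional `function(n)` returning `n`
#'   integer tract lengths >= 1, overriding the geometric defaults.
#' @return a `mutation_model` object.
#' @export
mutation_model <- function(mismatch_rate = 0, del_event_rate = 0,
                           del_len_mean = 1, ins_event_rate = 0,
                           ins_len_mean = 1, generations = 200L,
                           tandem_frac = 0,
                           del_len_dist = NULL, ins_len_dist = NULL) {
  stopifnot(mismatch_rate >= 0, del_event_rate >= 0, ins_event_rate >= 0,
            del_len_mean >= 1, ins_len_mean >= 1,
            tandem_frac >= 0, tandem_frac <= 1)
  if (generations <= 0) stop("generations must be > 0", call. = FALSE)
  geom1 <- function(mean) {
    force(mean)
    function(n) rgeom(n, prob = 1 / mean) + 1L
  }
  structure(list(
    mismatch_rate = mismatch_rate,
    del_event_rate = del_event_rate,
    del_len_dist = if (is.null(del_len_dist)) geom1(del_len_mean) else del_len_dist,
    ins_event_rate = ins_event_rate,
    ins_len_dist = if (is.null(ins_len_dist)) geom1(ins_len_mean) else ins_len_dist,
    generations = as.integer(generations),
    tandem_frac = tandem_frac
  ), class = "mutation_model")
}

#' Mutation model from a published rate-table column
#'
#' Converts mismatch (A), deletion-event (B), deleted-nucleotide (C),
#' insertion-event (E) and inserted-nucleotide (F) per-bp/generation rates
#' into a [mutation_model()]: tract-length means are C/B and F/E.
#'
#' @param A,B,C,E,F rates per bp per generation.
#' @param generations number of cell doublings.
#' @return a `mutation_model`.
#' @export
mutation_model_from_rates <- function(A, B, C, E, F, generations) {
  mutation_model(mismatch_rate = A, del_event_rate = B,
                 del_len_mean = if (B > 0) C / B else 1,
                 ins_event_rate = E,
                 ins_len_mean = if (E > 0) F / E else 1,
                 generations = generations)
}

#' eccDNA structural model
#'
#' An eccDNA is an ordered ring of template-switch domains; consecutive
#' domains (cyclically) are joined at junctions sharing an intended
#' microhomology overlap, realized once in the circle.
#'
#' @param domains data.frame with columns `contig`, `start`, `end` (0-based
#'   half-open on the reference) and `strand`.
#' @param junction_homologies integer vector, one per junction; junction `j`
#'   joins domain `j` to domain `j + 1` and the last junction (the
#'   circularization junction) joins the last domain back to the first.
#' @param circ_junction which repeated feature mediates circularization:
#'   `"frt"`, `"alu"` or `"other"`.
#' @param mutation_model optional [mutation_model()] applied to the circle.
#' @return an `eccdna_model` object.
#' @export
eccdna_model <- function(domains, junction_homologies,
                         circ_junction = c("other", "frt", "alu"),
                         mutation_model = NULL) {
  circ_junction <- match.arg(circ_junction)
  stopifnot(is.data.frame(domains), nrow(domains) >= 1,
            all(c("contig", "start", "end", "strand") %in% names(domains)))
  n <- nrow(domains)
  if (length(junction_homologies) != n) {
    stop("junction count must equal domain count (the ring is circular)",
         call. = FALSE)
  }
  if (any(junction_homologies < 0)) {
    stop("intended overlap lengths must be >= 0", call. = FALSE)
  }
  lens <- domains$end - domains$start
  for (j in seq_len(n)) {
    dn <- j %% n + 1L
    if (junction_homologies[j] > min(lens[j], lens[dn])) {
      stop("junction ", j, ": intended overlap exceeds the shorter flanking ",
           "domain", call. = FALSE)
    }
  }
  structure(list(domains = domains,
                 junction_homologies = as.integer(junction_homologies),
                 circ_junction = circ_junction,
                 mutation_model = mutation_model),
            class = "eccdna_model")
}

# oriented sequence of a reference interval
ref_seq <- function(ref, contig, start, end, strand = "+") {
  s <- substr0(ref$contigs[[contig]], start, end)
  if (strand == "-") revcomp(s) else s
}

# Sample and apply mutations to a sequence.  Event counts are Poisson with
# mean rate x length x generations; positions uniform.  Deletions are
# truncated at collisions; mismatches/insertions falling inside a deleted
# tract are recorded as masked (sampled but invisible in the product).
inject_mutations <- function(seq, model) {
  len <- nchar(seq)
  gens <- model$generations
  ev <- list()
  n_mis <- rpois(1, model$mismatch_rate * len * gens)
  n_del <- rpois(1, model$del_event_rate * len * gens)
  n_ins <- rpois(1, model$ins_event_rate * len * gens)
  v <- chars(seq)
  keep <- rep(TRUE, len)

  if (n_del > 0) {
    p <- sort(sample.int(len, min(n_del, len)) - 1L)
    L <- pmax(1L, as.integer(model$del_len_dist(length(p))))
    L <- pmin(L, len - p)                       # clip at the sequence end
    if (length(p) > 1) {                        # truncate at collisions
      L[-length(L)] <- pmin(L[-length(L)], diff(p))
    }
    for (i in seq_along(p)) keep[(p[i] + 1L):(p[i] + L[i])] <- FALSE
    ev$del <- data.frame(pos = p, type = "del", len = L,
                         ref = vapply(seq_along(p), function(i) {
                           substr0(seq, p[i], p[i] + L[i])
                         }, character(1)),
                         alt = "", masked = FALSE)
  }
  if (n_mis > 0) {
    p <- sample.int(len, min(n_mis, len)) - 1L
    refb <- v[p + 1L]
    altb <- vapply(refb, function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1), USE.NAMES = FALSE)
    masked <- !keep[p + 1L]
    v[p[!masked] + 1L] <- altb[!masked]
    ev$mis <- data.frame(pos = p, type = "mismatch", len = 1L,
                         ref = refb, alt = altb, masked = masked)
  }
  if (n_ins > 0) {
    p <- sample.int(len, min(n_ins, len)) - 1L
    L <- pmax(1L, as.integer(model$ins_len_dist(length(p))))
    tandem <- runif(length(p)) < model$tandem_frac
    ins <- vapply(seq_along(p), function(i) {
      if (tandem[i] && p[i] >= L[i]) {
        substr0(seq, p[i] - L[i], p[i])
      } else {
        random_dna(L[i])
      }
    }, character(1))
    masked <- !keep[pmin(p + 1L, len)]
    for (i in seq_along(p)) {
      if (!masked[i]) v[p[i] + 1L] <- paste0(ins[i], v[p[i] + 1L])
    }
    ev$ins <- data.frame(pos = p, type = "insertion", len = L,
                         ref = "", alt = ins, masked = masked)
  }
  v[!keep] <- ""
  events <- if (length(ev)) {
    out <- do.call(rbind, ev)
    out[order(out$pos), , drop = FALSE]
  } else {
    data.frame(pos = integer(), type = character(), len = integer(),
               ref = character(), alt = character(), masked = logical())
  }
  rownames(events) <- NULL
  list(sequence = paste(v, collapse = ""), events = events)
}

#' Simulate one eccDNA molecule
#'
#' Realizes each domain sequence, verifies that every junction's intended
#' microhomology is realizable (the upstream domain's suffix equals the
#' downstream domain's prefix over the intended overlap), assembles the
#' circle with each overlap realized once, and injects mutations per the
#' model's [mutation_model()].  The returned truth records domain placements
#' on the circle, junction positions/overlaps and all injected mutations.
#'
#' @param ref a [hybrid_reference()].
#' @param model an [eccdna_model()].
#' @param seed optional integer seed (mutation sampling).
#' @return list with `sequence` (the mutated circle, linearized at the
#'   circularization junction) and `truth` (domains, junctions, mutations;
#'   all positions 0-based on the pre-mutation circle).
#' @export
simulate_eccdna <- function(ref, model, seed = NULL) {
  stopifnot(inherits(ref, "hybrid_reference"), inherits(model, "eccdna_model"))
  dom <- model$domains
  n <- nrow(dom)
  for (ct in unique(dom$contig)) {
    if (!ct %in% names(ref$contigs)) {
      stop("domain contig '", ct, "' absent from reference", call. = FALSE)
    }
  }
  seqs <- vapply(seq_len(n), function(i) {
    ref_seq(ref, dom$contig[i], dom$start[i], dom$end[i], dom$strand[i])
  }, character(1))
  o <- model$junction_homologies
  for (j in seq_len(n)) {
    dn <- j %% n + 1L
    k <- o[j]
    if (k > 0) {
      up_suf <- substr(seqs[j], nchar(seqs[j]) - k + 1, nchar(seqs[j]))
      down_pre <- substr(seqs[dn], 1, k)
      if (up_suf != down_pre) {
        stop("junction ", j, ": requested ", k, "-bp homology is not ",
             "realizable (flanking reference sequences do not share it)",
             call. = FALSE)
      }
    }
  }
  # circle: trim each domain's prefix by the overlap with its predecessor
  o_prev <- c(o[n], o[-n])
  trimmed <- vapply(seq_len(n), function(i) {
    substr(seqs[i], o_prev[i] + 1, nchar(seqs[i]))
  }, character(1))
  tlens <- nchar(trimmed)
  cstart <- cumsum(c(0L, tlens[-n]))
  circle <- paste(trimmed, collapse = "")
  domains <- cbind(dom,
                   circle_start = as.integer(cstart),
                   circle_end = as.integer(cstart + tlens),
                   trimmed_prefix = as.integer(o_prev))
  junctions <- data.frame(
    junction = seq_len(n),
    up = seq_len(n), down = (seq_len(n) %% n) + 1L,
    circle_pos = as.integer(c(cstart[-1], 0L)),
    overlap = o,
    is_circ = c(rep(FALSE, n - 1L), TRUE))

  mutations <- data.frame(pos = integer(), type = character(),
                          len = integer(), ref = character(),
                          alt = character(), masked = logical())
  out_seq <- circle
  if (!is.null(model$mutation_model)) {
    mut <- with_seed(seed, inject_mutations(circle, model$mutation_model))
    out_seq <- mut$sequence
    mutations <- mut$events
  }
  list(sequence = out_seq,
       truth = list(domains = domains, junctions = junctions,
                    mutations = mutations, circ_junction = model$circ_junction,
                    circle_len = nchar(circle)))
}

# ---- planners against the default reference ------------------------------

# nudge a start position forward until both flank bases differ from the
# upstream end's flanks (so a 0-overlap junction measures exactly 0)
find_zero_overlap_start <- function(ref, up_contig, up_end, down_contig,
                                    start_hint, max_shift = 40L) {
  up <- ref$contigs[[up_contig]]
  down <- ref$contigs[[down_contig]]
  for (s in start_hint + 0:max_shift) {
    left_ok <- substr0(up, up_end - 1, up_end) !=
      substr0(down, s - 1, s)
    right_ok <- substr0(up, up_end, up_end + 1) !=
      substr0(down, s, s + 1)
    if (left_ok && right_ok) return(s)
  }
  stop("could not place a zero-overlap junction", call. = FALSE)
}

#' Single-domain eccDNA closed through the two FRT copies
#'
#' The domain runs from the first FRT copy to the end of the second; the
#' circularization junction then shares the full 48-bp FRT homology.
#'
#' @param ref a reference from [default_reference()].
#' @param mutation_model optional [mutation_model()].
#' @return an [eccdna_model()].
#' @export
frt_circle_model <- function(ref, mutation_model = NULL) {
  hp <- ref$homology_pairs
  frt <- hp[hp$class == "frt", ][1, ]
  dom <- data.frame(contig = frt$contig_a, start = frt$start_b,
                    end = frt$end_a, strand = "+")
  eccdna_model(dom, junction_homologies = frt$overlap,
               circ_junction = "frt", mutation_model = mutation_model)
}

#' Two-domain eccDNA with one intra-site template switch
#'
#' Domain 1 runs from the first FRT copy to a planted intra-site
#' microhomology; domain 2 resumes at the homology partner and runs to the
#' end of the second FRT copy; the circle closes through the FRT pair.
#'
#' @param ref a reference from [default_reference()].
#' @param intra_overlap overlap length (bp) of the internal template-switch
#'   junction; must be one of the reference's planted intra-site pairs.
#' @param mutation_model optional [mutation_model()].
#' @return an [eccdna_model()].
#' @export
demo_ecc_model <- function(ref, intra_overlap = 6L, mutation_model = NULL) {
  hp <- ref$homology_pairs
  frt <- hp[hp$class == "frt", ][1, ]
  pr <- hp[hp$class == "intra_es" & hp$overlap == intra_overlap, ]
  if (nrow(pr) == 0) {
    stop("no planted intra-site pair with overlap ", intra_overlap,
         call. = FALSE)
  }
  pr <- pr[1, ]
  dom <- data.frame(
    contig = c(pr$contig_a, pr$contig_b),
    start = c(frt$start_b, pr$start_b),
    end = c(pr$end_a, frt$end_a),
    strand = c("+", "+"))
  eccdna_model(dom, junction_homologies = c(pr$overlap, frt$overlap),
               circ_junction = "frt", mutation_model = mutation_model)
}

#' Three-domain eccDNA with a nonallelic template switch
#'
#' Domain 1 leaves the ectopic site at a planted ES-to-donor microhomology;
#' domain 2 copies donor sequence; domain 3 returns to the ES at a
#' zero-overlap junction and runs to the second FRT copy; the circle closes
#' through the FRT pair.
#'
#' @param ref a reference from [default_reference()].
#' @param nonallelic_overlap overlap (bp) of the ES-to-donor junction; one of
#'   the reference's planted nonallelic pairs.
#' @param donor_span donor bases copied before switching back.
#' @param mutation_model optional [mutation_model()].
#' @return an [eccdna_model()].
#' @export
nonallelic_ecc_model <- function(ref, nonallelic_overlap = 43L,
                                 donor_span = 500L, mutation_model = NULL) {
  hp <- ref$homology_pairs
  frt <- hp[hp$class == "frt", ][1, ]
  pr <- hp[hp$class == "nonallelic" & hp$overlap == nonallelic_overlap, ]
  if (nrow(pr) == 0) {
    stop("no planted nonallelic pair with overlap ", nonallelic_overlap,
         call. = FALSE)
  }
  pr <- pr[1, ]
  donor_end <- pr$start_b + nonallelic_overlap + donor_span
  fe <- ref$features
  origin <- fe[fe$kind == "origin", ][1, ]
  back <- find_zero_overlap_start(ref, pr$contig_b, donor_end,
                                  "ES", origin$start + 50L)
  dom <- data.frame(
    contig = c("ES", pr$contig_b, "ES"),
    start = c(frt$start_b, pr$start_b, back),
    end = c(pr$end_a, donor_end, frt$end_a),
    strand = "+")
  eccdna_model(dom,
               junction_homologies = c(pr$overlap, 0L, frt$overlap),
               circ_junction = "frt", mutation_model = mutation_model)
}
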