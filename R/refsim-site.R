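# Parameterized ectopic-site and hybrid-reference construction.
#
# The ectopic site (ES) emulated here is a single-copy chromosomal integration
# locus carrying, in order: a left flank, an FRT recombinase site, an upstream
# fluorescent reporter, an Alu-like repeat ending in a d(T)29 tail, a
# replication-origin cassette, the two head-to-head (outward-facing) inverse
# PCR primer sites separated by a short unamplified gap, a non-B DNA
# microsatellite insert, a second Alu repeat, a downstream reporter, a
# selection minigene, a second identical FRT copy and a right flank.  The two
# FRT copies and the two Alu copies provide the repeated homologies that
# mediate eccDNA circularization.

#' Canonical 48-bp FRT recombinase target site
#'
#' Full-length FLP recombinase target: two direct 13-bp repeats, an 8-bp
#' spacer and a third (inverted) repeat.  Both ES copies are byte-identical,
#' providing 48 bp of perfect homology for circularization.
#' @export
FRT_SITE <- "GAAGTTCCTATTCCGAAGTTCCTATTCTCTAGAAAGTATAGGAACTTC"

#' Default inverse-PCR primers (24-mers)
#'
#' Fixed default primers with no self- or cross-complementarity; real runs
#' supply their own primer pair.
#' @export
DEFAULT_PRIMERS <- list(
  fwd = "TACGGTAGCTCATCAGACGTTGCA",
  rev = "GATCCAGTTGAGCGTATCCTAGTG"
)

#' Construct a feature specification
#'
#' @param name feature label, unique within a site.
#' @param kind one of `reporter`, `origin`, `microsatellite`, `frt`, `alu`,
#'   `primer_site`, `spacer`.
#' @param sequence DNA string as embedded on the + strand of the contig.
#' @param strand `"+"` or `"-"`; for `primer_site` features, `"-"` means the
#'   primer anneals to the + strand and extends leftward (the embedded
#'   sequence is the reverse complement of the primer).
#' @return a `feature_spec` list.
#' @export
feature_spec <- function(name, kind, sequence, strand = "+") {
  kinds <- c("reporter", "origin", "microsatellite", "frt", "alu",
             "primer_site", "spacer")
  if (!kind %in% kinds) {
    stop("unknown feature kind '", kind, "'", call. = FALSE)
  }
  if (!is.character(sequence) || nchar(sequence) < 1) {
    stop("feature '", name, "': sequence must be a non-empty DNA string",
         call. = FALSE)
  }
  if (!is_dna(sequence)) {
    stop("feature '", name, "': sequence contains non-DNA characters",
         call. = FALSE)
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  if (kind == "alu" && !grepl("T{20,}$", toupper(sequence))) {
    stop("feature '", name,
         "': alu features must end in a run of >= 20 T's (d(T)29 tail)",
         call. = FALSE)
  }
  structure(list(name = name, kind = kind,
                 sequence = toupper(sequence), strand = strand),
            class = "feature_spec")
}

#' Construct an ectopic-site specification
#'
#' @param features ordered list of [feature_spec()] objects; the contig is the
#'   concatenation of their sequences.
#' @param contig_name contig name for the assembled site.
#' @param coordinates optional data.frame with columns `start`, `end`
#'   (0-based, half-open) giving per-feature intervals; they must be sorted,
#'   non-overlapping and tile the contig exactly.  Derived from feature
#'   lengths when omitted.
#' @return an `ectopic_site_spec` list.
#' @export
ectopic_site_spec <- function(features, contig_name = "ES",
                              coordinates = NULL) {
  stopifnot(length(features) >= 1)
  lapply(features, function(f) {
    if (!inherits(f, "feature_spec")) {
      stop("all features must be feature_spec objects", call. = FALSE)
    }
  })
  frt_seqs <- unique(vapply(
    Filter(function(f) f$kind == "frt", features),
    function(f) f$sequence, character(1)))
  if (length(frt_seqs) > 1) {
    stop("all frt features in one site must be byte-identical", call. = FALSE)
  }
  structure(list(features = features, contig_name = contig_name,
                 coordinates = coordinates),
            class = "ectopic_site_spec")
}

#' Assemble an ectopic-site contig from its feature specification
#'
#' Concatenates the feature sequences and returns the contig together with
#' the per-feature interval table.  Deterministic.
#'
#' @param spec an [ectopic_site_spec()].
#' @return list with elements `sequence` (DNA string) and `features`
#'   (data.frame: name, kind, start, end, strand; 0-based half-open).
#' @export
build_ectopic_site <- function(spec) {
  stopifnot(inherits(spec, "ectopic_site_spec"))
  feats <- spec$features
  lens <- vapply(feats, function(f) nchar(f$sequence), integer(1))
  starts <- cumsum(c(0L, lens[-length(lens)]))
  ends <- starts + lens
  if (!is.null(spec$coordinates)) {
    co <- spec$coordinates
    if (nrow(co) != length(feats)) {
      stop("coordinates must have one row per feature", call. = FALSE)
    }
    bad_order <- which(diff(co$start) <= 0)
    if (length(bad_order)) {
      nm <- vapply(feats, `[[`, character(1), "name")
      stop("features out of order: ",
           paste(nm[c(bad_order, bad_order + 1L)], collapse = ", "),
           call. = FALSE)
    }
    overlap <- which(co$start[-1] < co$end[-nrow(co)])
    if (length(overlap)) {
      nm <- vapply(feats, `[[`, character(1), "name")
      stop("overlapping features: ",
           paste(nm[c(overlap, overlap + 1L)], collapse = ", "),
           call. = FALSE)
    }
    if (co$start[1] != 0 || any(co$start[-1] != co$end[-nrow(co)]) ||
        any(co$end - co$start != lens)) {
      stop("coordinates must tile the contig exactly", call. = FALSE)
    }
    starts <- co$start; ends <- co$end
  }
  tab <- data.frame(
    name = vapply(feats, `[[`, character(1), "name"),
    kind = vapply(feats, `[[`, character(1), "kind"),
    start = as.integer(starts), end = as.integer(ends),
    strand = vapply(feats, `[[`, character(1), "strand"),
    stringsAsFactors = FALSE)
  list(sequence = paste(vapply(feats, `[[`, character(1), "sequence"),
                        collapse = ""),
       features = tab)
}

# fix the first/last base of a sequence (used to guarantee that repeat copies
# have divergent flanks, so measured junction homology equals repeat length)
set_first <- function(seq, base) paste0(base, substr(seq, 2, nchar(seq)))
set_last <- function(seq, base) paste0(substr(seq, 1, nchar(seq) - 1), base)

# Alu-like repeat: seeded-random body ending in a d(T)29 tail
alu_element <- function(len = 311, tail = 29) {
  paste0(random_dna(len - tail), strrep("T", tail))
}

# five canonical quadruplex consensus matches separated by G-free spacers
g4_insert <- function() {
  unit <- "GGGTTAGGGTTAGGGTTAGGG"
  spacers <- replicate(4, paste(sample(c("A", "C", "T"), 8, replace = TRUE),
                                collapse = ""))
  paste0(unit, paste0(spacers, unit, collapse = ""))
}

# homopurine mirror repeat (triplex-forming): purine half + centre + mirror
h3_insert <- function(half = 30) {
  h <- paste(sample(c("A", "G"), half, replace = TRUE, prob = c(0.45, 0.55)),
             collapse = "")
  set_last(paste0(h, "A", paste(rev(chars(h)), collapse = "")), "G")
}

microsat_insert <- function(preset) {
  switch(preset,
    CAG102  = strrep("CAG", 102),
    ATTCT47 = strrep("ATTCT", 47),
    G4      = g4_insert(),
    H3      = h3_insert(),
    stop("unknown microsatellite preset '", preset, "'", call. = FALSE))
}

#' Build the default ectopic site for one microsatellite preset
#'
#' Assembles the standard desk-scale site layout with seeded-random filler
#' sequences.  First/last bases of the features flanking the repeated FRT and
#' Alu copies are pinned to distinct bases so that the maximal shared homology
#' at each repeat pair equals the repeat length exactly.
#'
#' @param microsat one of `"CAG102"`, `"ATTCT47"`, `"G4"`, `"H3"`.
#' @param seed integer seed for the filler sequences.
#' @param primers list with `fwd` and `rev` primer strings (>= 15 bp).
#' @return an `ectopic_site` object: list(sequence, features, primers,
#'   contig_name, spec).
#' @export
ectopic_site <- function(microsat = c("CAG102", "ATTCT47", "G4", "H3"),
                         seed = 1L, primers = DEFAULT_PRIMERS) {
  microsat <- match.arg(microsat)
  stopifnot(nchar(primers$fwd) >= 15, nchar(primers$rev) >= 15)
  with_seed(seed, {
    alu <- alu_element()
    ms <- microsat_insert(microsat)
    feats <- list(
      feature_spec("flank_L", "spacer", set_last(random_dna(250), "A")),
      feature_spec("FRT_1", "frt", FRT_SITE),
      feature_spec("dTom", "reporter",
                   set_last(set_first(random_dna(700), "G"), "A")),
      feature_spec("Alu_1", "alu", alu),
      feature_spec("myc_origin", "origin", set_first(random_dna(1200), "C")),
      feature_spec("primer_R", "primer_site", revcomp(primers$rev),
                   strand = "-"),
      feature_spec("gap_spacer", "spacer", random_dna(150)),
      feature_spec("primer_F", "primer_site", primers$fwd),
      feature_spec(microsat, "microsatellite", ms),
      feature_spec("Alu_2", "alu", alu),
      feature_spec("eGFP", "reporter", set_first(random_dna(700), "A")),
      feature_spec("TK", "reporter", set_last(random_dna(400), "C")),
      feature_spec("FRT_2", "frt", FRT_SITE),
      feature_spec("flank_R", "spacer", set_first(random_dna(250), "T"))
    )
    spec <- ectopic_site_spec(feats)
    built <- build_ectopic_site(spec)
    structure(list(sequence = built$sequence, features = built$features,
                   primers = primers, contig_name = spec$contig_name,
                   microsat = microsat, spec = spec),
              class = "ectopic_site")
  })
}

#' @export
print.ectopic_site <- function(x, ...) {
  cat("ectopic_site <", x$contig_name, ">: ", nchar(x$sequence), " bp, ",
      nrow(x$features), " features (microsatellite ", x$microsat, ")\n",
      sep = "")
  invisible(x)
}

feature_interval <- function(site, name) {
  i <- match(name, site$features$name)
  if (is.na(i)) stop("no feature named '", name, "'", call. = FALSE)
  c(start = site$features$start[i], end = site$features$end[i])
}

#' Hybrid reference: ectopic-site contig plus host donor contigs
#'
#' @param contigs named character vector of DNA contigs; must include the
#'   ectopic-site contig.
#' @param es_contig name of the ectopic-site contig.
#' @param features per-feature interval table for the ES contig (as returned
#'   by [build_ectopic_site()]).
#' @param homology_pairs optional data.frame of planted microhomology pairs
#'   (columns: overlap, contig_a, end_a, contig_b, start_b, class) recorded by
#'   the reference builder for the eccDNA planner.
#' @return a `hybrid_reference` object.
#' @export
hybrid_reference <- function(contigs, es_contig, features = NULL,
                             homology_pairs = NULL) {
  stopifnot(is.character(contigs), !is.null(names(contigs)))
  if (anyDuplicated(names(contigs))) {
    stop("contig names must be unique", call. = FALSE)
  }
  if (!es_contig %in% names(contigs)) {
    stop("es_contig '", es_contig, "' not among contigs", call. = FALSE)
  }
  structure(list(contigs = contigs, es_contig = es_contig,
                 features = features, homology_pairs = homology_pairs),
            class = "hybrid_reference")
}

#' @export
print.hybrid_reference <- function(x, ...) {
  cat("hybrid_reference: ", length(x$contigs), " contigs (",
      sum(nchar(x$contigs)), " bp), ES contig '", x$es_contig, "'\n", sep = "")
  invisible(x)
}

# Plant one shared o-mer at two loci.  `seqs` is a named list of mutable
# sequences; a/b identify (sequence name, offset).  The o-mer is written at
# both loci and the flanking bases are pinned to differ, so the maximal
# shared homology anchored at the pair is exactly o.
plant_homology <- function(seqs, o, a_name, a_off, b_name, b_off) {
  m <- random_dna(o)
  put <- function(s, off, frag) {
    paste0(substr(s, 1, off), frag, substr(s, off + nchar(frag) + 1, nchar(s)))
  }
  seqs[[a_name]] <- put(seqs[[a_name]], a_off, m)
  # pin flanks: before/after the o-mer must differ between the two loci
  lb <- substr(seqs[[a_name]], a_off, a_off)   # base before m at A (1-based)
  rb <- substr(seqs[[a_name]], a_off + o + 1, a_off + o + 1)
  flip <- function(b) {
    if (is.na(b) || !nzchar(b)) return("A")
    unname(c(A = "C", C = "G", G = "T", T = "A", N = "A")[b])
  }
  seqs[[b_name]] <- put(seqs[[b_name]], b_off, m)
  seqs[[b_name]] <- put(seqs[[b_name]], b_off - 1, flip(lb))
  seqs[[b_name]] <- put(seqs[[b_name]], b_off + o, flip(rb))
  seqs
}

#' Build the default desk-scale hybrid reference
#'
#' Assembles the ectopic site for one microsatellite preset plus two host
#' donor-chromosome surrogates.  `chr8_frag` carries a full copy of the site
#' Alu (providing nonallelic Alu homology) embedded in unique sequence;
#' `chrX_frag` is unique sequence.  In addition, pairs of shared o-mers with
#' divergent flanks are planted (ES <-> ES and ES <-> donor) at the requested
#' overlap lengths and recorded in `homology_pairs`, so eccDNA structures with
#' exact intended junction microhomologies can be planned.  The FRT and Alu
#' repeat pairs are recorded as homology pairs of length 48 and 311.
#'
#' @inheritParams ectopic_site
#' @param intra_overlaps planted intra-ES overlap lengths (bp).
#' @param nonallelic_overlaps planted ES <-> donor overlap lengths (bp).
#' @param donor_len length of each donor contig.
#' @return a `hybrid_reference` with `$site` attached.
#' @export
default_reference <- function(microsat = "CAG102", seed = 1L,
                              primers = DEFAULT_PRIMERS,
                              intra_overlaps = c(2L, 5L, 6L, 10L, 14L),
                              nonallelic_overlaps = c(43L, 64L, 101L),
                              donor_len = 2500L) {
  site <- ectopic_site(microsat, seed = seed, primers = primers)
  with_seed(seed + 104729L, {
    es <- site$sequence
    alu <- substr0(es, feature_interval(site, "Alu_1")["start"],
                   feature_interval(site, "Alu_1")["end"])
    chr8 <- paste0(random_dna(donor_len %/% 2), alu,
                   random_dna(donor_len - donor_len %/% 2 - nchar(alu)))
    chrx <- random_dna(donor_len)
    seqs <- list(ES = es, chr8_frag = chr8, chrX_frag = chrx)

    # plant intra-ES pairs: A locus inside eGFP, B locus inside TK
    fe <- site$features
    iv <- function(nm) c(fe$start[fe$name == nm], fe$end[fe$name == nm])
    pairs <- list()
    egfp <- iv("eGFP"); tk <- iv("TK"); dtom <- iv("dTom")
    off_a <- egfp[1] + 40L
    off_b <- tk[1] + 40L
    for (o in intra_overlaps) {
      seqs <- plant_homology(seqs, o, "ES", off_a, "ES", off_b)
      pairs[[length(pairs) + 1L]] <- data.frame(
        overlap = o, contig_a = "ES", end_a = off_a + o,
        contig_b = "ES", start_b = off_b, class = "intra_es")
      off_a <- off_a + o + 30L
      off_b <- off_b + o + 30L
    }
    # plant nonallelic pairs: A locus inside dTom, B locus on chrX_frag
    off_a <- dtom[1] + 40L
    off_b <- 200L
    for (o in nonallelic_overlaps) {
      seqs <- plant_homology(seqs, o, "ES", off_a, "chrX_frag", off_b)
      pairs[[length(pairs) + 1L]] <- data.frame(
        overlap = o, contig_a = "ES", end_a = off_a + o,
        contig_b = "chrX_frag", start_b = off_b, class = "nonallelic")
      off_a <- off_a + o + 30L
      off_b <- off_b + o + 160L
    }
    frt1 <- iv("FRT_1"); frt2 <- iv("FRT_2")
    alu1 <- iv("Alu_1"); alu2 <- iv("Alu_2")
    pairs[[length(pairs) + 1L]] <- data.frame(
      overlap = 48L, contig_a = "ES", end_a = frt2[2],
      contig_b = "ES", start_b = frt1[1], class = "frt")
    pairs[[length(pairs) + 1L]] <- data.frame(
      overlap = as.integer(alu1[2] - alu1[1]), contig_a = "ES",
      end_a = alu2[2], contig_b = "ES", start_b = alu1[1], class = "alu")
    pairs <- do.call(rbind, pairs)

    site$sequence <- seqs$ES
    contigs <- c(ES = seqs$ES, chr8_frag = seqs$chr8_frag,
                 chrX_frag = seqs$chrX_frag)
    ref <- hybrid_reference(contigs, "ES", features = site$features,
                            homology_pairs = pairs)
    ref$site <- site
    ref
  })
}
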