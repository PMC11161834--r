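# Microhomology measurement, circularization-junction detection, overlap
# distributions and the nonrandomness test.

refj <- tiny_ref()

test_that("junction overlap equals the planted homology on basic cases", {
  withr::with_seed(3, {
    fx0 <- make_junction_fixture(0L)
    j0 <- junction_overlap(fx0$up, fx0$down, fx0$read, fx0$ref)
    expect_equal(j0$overlap_len, 0L)
    expect_equal(j0$inserted_len, 0L)
  })
  # constructed junction through the repeated 5-mer TTAGC; the up locus
  # continues with "C" (read continues with "G"), so extension stops
  up_ct <- paste0("A", strrep("CT", 40), "TTAGC", "C")
  dn_ct <- paste0("T", "TTAGC", strrep("GA", 40), "C")
  ref <- hybrid_reference(c(u = up_ct, d = dn_ct), "u")
  read <- paste0(strrep("CT", 40), "TTAGC", strrep("GA", 40))
  up <- data.frame(monomer = "m", q_start = 0L, q_end = 85L, contig = "u",
                   t_start = 1L, t_end = 86L, strand = "+")
  dn <- data.frame(monomer = "m", q_start = 80L, q_end = 165L, contig = "d",
                   t_start = 21L, t_end = 106L, strand = "+")
  j <- junction_overlap(up, dn, read, ref)
  expect_equal(j$overlap_len, 5L)
  expect_equal(j$overlap_seq, "TTAGC")
})

test_that("overlap matches brute force on randomized fixtures", {
  withr::with_seed(101, {
    for (i in 1:150) {
      o <- sample(0:60, 1)
      fx <- make_junction_fixture(o)
      got <- junction_overlap(fx$up, fx$down, fx$read, fx$ref)
      want <- brute_junction_overlap(fx$up, fx$down, fx$read, fx$ref)
      expect_equal(got$overlap_len, want$overlap_len)
      expect_equal(got$inserted_len, want$inserted_len)
      expect_equal(got$overlap_len, o)
    }
  })
})

test_that("unmatched read bases between segments are a nontemplated insertion", {
  withr::with_seed(55, {
    fx <- make_junction_fixture(0L)
    ins <- paste0("G", random_dna(33), "A")   # diverges from both flanks
    # splice untemplated bases at the junction
    read2 <- paste0(substr(fx$read, 1, 120), ins,
                    substr(fx$read, 121, nchar(fx$read)))
    up <- fx$up
    dn <- fx$down
    dn$q_start <- dn$q_start + 35L
    dn$q_end <- dn$q_end + 35L
    j <- junction_overlap(up, dn, read2, fx$ref)
    want <- brute_junction_overlap(up, dn, read2, fx$ref)
    expect_equal(j$inserted_len, want$inserted_len)
    expect_equal(j$inserted_len, 35L)
    expect_equal(j$inserted_seq, ins)
    expect_equal(j$overlap_len, 0L)
  })
})

test_that("overlaps are invariant under reverse-complementing the monomer", {
  withr::with_seed(9, fx <- make_junction_fixture(17L))
  # mirrored chain on the reverse-complemented read
  read_rc <- revcomp(fx$read)
  L <- nchar(fx$read)
  up_rc <- data.frame(monomer = "m1",
                      q_start = L - fx$down$q_end,
                      q_end = L - fx$down$q_start,
                      contig = "d", t_start = fx$down$t_start,
                      t_end = fx$down$t_end, strand = "-")
  dn_rc <- data.frame(monomer = "m1",
                      q_start = L - fx$up$q_end,
                      q_end = L - fx$up$q_start,
                      contig = "u", t_start = fx$up$t_start,
                      t_end = fx$up$t_end, strand = "-")
  j1 <- junction_overlap(fx$up, fx$down, fx$read, fx$ref)
  j2 <- junction_overlap(up_rc, dn_rc, read_rc, fx$ref)
  expect_equal(j1$overlap_len, j2$overlap_len)
  expect_equal(j1$overlap_seq, revcomp(j2$overlap_seq))
})

test_that("FRT-closed circles report a 48-bp circularization junction", {
  sim <- simulate_dataset(refj, frt_circle_model(refj),
                          read_model(monomers_per_read = 1,
                                     seq_error_rate = 0,
                                     spanning_fraction = 0, n_reads = 2),
                          seed = 12)
  rep <- run_pipeline(sim$reads, refj)
  circ <- rep$junctions[rep$junctions$junction_class == "circularization", ]
  expect_equal(nrow(circ), 1L)
  expect_equal(circ$overlap_len, 48L)
  expect_equal(circ$mediating_repeat, "frt")
})

test_that("single-domain chains have no circularization junction", {
  es <- refj$contigs[["ES"]]
  ch <- chain_domains(align_segments(setNames(substr(es, 1001, 2000), "m"),
                                     refj))
  expect_null(detect_circularization_junction(
    ch, substr(es, 1001, 2000), refj))
})

test_that("a circle closed at unique sequence has mediating repeat 'other'", {
  fe <- refj$features
  org <- fe[fe$name == "myc_origin", ]
  egfp <- fe[fe$name == "eGFP", ]
  # domain spanning both primer sites, closed at unique sequence with a
  # zero-overlap junction (start nudged so both flank bases diverge)
  up_end <- egfp$start + 300L
  back <- circsat:::find_zero_overlap_start(refj, "ES", up_end,
                                            "ES", org$start + 50L)
  dom <- data.frame(contig = "ES", start = back, end = up_end, strand = "+")
  em <- eccdna_model(dom, junction_homologies = 0L, circ_junction = "other")
  ecc <- simulate_eccdna(refj, em)
  rr <- simulate_ipcr_reads(ecc$sequence, refj$site$primers,
                            read_model(monomers_per_read = 1,
                                       seq_error_rate = 0,
                                       spanning_fraction = 0, n_reads = 1),
                            seed = 2)
  rep <- run_pipeline(rr$reads, refj)
  circ <- rep$junctions[rep$junctions$junction_class == "circularization", ]
  expect_equal(circ$overlap_len, 0L)
  expect_equal(circ$mediating_repeat, "other")
})

test_that("circles closed within the Alu d(T) tail lose a few T's and are annotated alu", {
  # two Alu copies whose bodies diverged but whose d(T)29 tails are shared
  # (so homology at the circularization junction lies within the tail); the
  # domain ends 3 nt short of the second tail's end, deleting d(T)
  # nucleotides at the junction
  built <- withr::with_seed(65, {
    alu_a <- paste0(circsat:::set_last(random_dna(282), "G"), strrep("T", 29))
    alu_b <- paste0(circsat:::set_last(random_dna(282), "G"), strrep("T", 29))
    build_ectopic_site(ectopic_site_spec(list(
      feature_spec("flank_L", "spacer", circsat:::set_last(random_dna(200), "A")),
      feature_spec("Alu_1", "alu", alu_a),
      feature_spec("mid", "spacer", circsat:::set_first(random_dna(300), "C")),
      feature_spec("primer_R", "primer_site", revcomp(DEFAULT_PRIMERS$rev),
                   strand = "-"),
      feature_spec("gap", "spacer", random_dna(80)),
      feature_spec("primer_F", "primer_site", DEFAULT_PRIMERS$fwd),
      feature_spec("mid2", "spacer", random_dna(200)),
      feature_spec("Alu_2", "alu", alu_b),
      feature_spec("flank_R", "spacer", circsat:::set_first(random_dna(200), "A")))))
  })
  ref2 <- hybrid_reference(c(ES = built$sequence), "ES",
                           features = built$features)
  fe <- built$features
  alu1_end <- fe$end[fe$name == "Alu_1"]
  alu2_end <- fe$end[fe$name == "Alu_2"]
  o <- 20L
  dom <- data.frame(contig = "ES", start = alu1_end - 24L,
                    end = alu2_end - 3L, strand = "+")
  em <- eccdna_model(dom, junction_homologies = o, circ_junction = "alu")
  ecc <- simulate_eccdna(ref2, em)
  rr <- simulate_ipcr_reads(ecc$sequence, DEFAULT_PRIMERS,
                            read_model(monomers_per_read = 1,
                                       seq_error_rate = 0,
                                       spanning_fraction = 0, n_reads = 1),
                            seed = 3)
  rep <- run_pipeline(rr$reads, ref2, primers = DEFAULT_PRIMERS)
  circ <- rep$junctions[rep$junctions$junction_class == "circularization", ]
  expect_equal(nrow(circ), 1L)
  expect_equal(circ$mediating_repeat, "alu")
  expect_true(circ$in_dT_tail)
  # the realized junction homology is a poly-T run inside the tail
  expect_true(grepl("^T+$", circ$overlap_seq))
  expect_gte(circ$overlap_len, o)
  expect_lte(circ$overlap_len, 29L)
})

test_that("overlap distributions summarize events per junction", {
  j <- data.frame(overlap_len = rep(6L, 10),
                  junction_class = "intra_es")
  d <- overlap_distribution(j)
  expect_equal(d$mode, 6L)
  expect_equal(d$mean, 6)
  expect_equal(length(d$values), 10L)
  # weighted two-mode fixture recovers both modes at n = 500
  withr::with_seed(19, v <- sample(c(2L, 5L), 500, replace = TRUE))
  d2 <- overlap_distribution(data.frame(overlap_len = v,
                                        junction_class = "intra_es"))
  expect_setequal(d2$mode, if (sum(v == 2) == sum(v == 5)) c(2L, 5L)
                  else if (sum(v == 2) > sum(v == 5)) 2L else 5L)
  expect_lt(abs(mean(v) - 3.5), 3 * sd(v) / sqrt(500))
  # empty input
  d3 <- overlap_distribution(j[0, ])
  expect_equal(length(d3$values), 0L)
})

test_that("per-class partitions separate short intra-site from long nonallelic", {
  j <- data.frame(
    overlap_len = c(rep(6L, 30), sample(43:101, 10, replace = TRUE)),
    junction_class = c(rep("intra_es", 30), rep("nonallelic", 10)))
  d <- overlap_distribution(j)
  expect_equal(unique(d$by_class$intra_es), 6L)
  expect_true(all(d$by_class$nonallelic >= 43))
})

test_that("test_nonrandom separates peaked from uniform and flags degeneracy", {
  r <- test_nonrandom(rep(14L, 60), max_val = 50L)
  expect_lt(r$p_perm, 0.01)
  expect_lt(r$p_t, 0.01)
  # fully degenerate: observations and null identical constants
  r2 <- test_nonrandom(rep(0L, 10), max_val = 0L)
  expect_false(r2$t_applicable)
  expect_true(is.na(r2$p_t))
  expect_false(is.na(r2$p_perm))
  expect_error(test_nonrandom(3L), ">= 2")
  # report records the null parameters and seed
  expect_equal(r$null$model, "uniform")
  expect_equal(r$null$seed, 1729L)
})
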