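# Pileup semantics, rate-table arithmetic, per-kb metrics, thresholding,
# trinucleotide signatures.

refm <- tiny_ref()

align_chain <- function(seqs) {
  segs <- align_segments(seqs, refm)
  chain_all(segs)
}

test_that("a single 3-bp deletion gives one event of three nucleotides", {
  es <- refm$contigs[["ES"]]
  m <- paste0(substr(es, 1401, 1700), substr(es, 1704, 2000))
  ch <- align_chain(setNames(m, "m1"))
  pl <- pileup(ch, data.frame(id = "m1", seq = m), refm)
  expect_equal(pl$totals$del_events, 1L)
  expect_equal(pl$totals$del_nt, 3L)
  expect_equal(pl$totals$mismatches, 0L)
  col <- pl$columns[pl$columns$del_starts > 0, ]
  expect_equal(nrow(col), 1L)
  # placement within the repeat-free ambiguity window of the deleted run
  expect_lte(abs(col$pos - 1700L), 3L)
  expect_equal(col$depth, 1L)
})

test_that("pileup column totals equal per-read event-log totals", {
  tab <- published_rate_table()
  mm <- mutation_model_from_rates(tab["A", "CAG102_c10"],
                                  tab["B", "CAG102_c10"],
                                  tab["C", "CAG102_c10"],
                                  tab["E", "CAG102_c10"],
                                  tab["F", "CAG102_c10"], 200)
  em <- demo_ecc_model(refm, 6L, mutation_model = mm)
  pop <- simulate_population(refm, em, 5, seed = 31)
  dc <- decat_reads(pop$reads, DEFAULT_PRIMERS$fwd, DEFAULT_PRIMERS$rev)
  ch <- chain_all(align_segments(setNames(dc$monomers$seq, dc$monomers$id),
                                 refm))
  pl <- pileup(ch, data.frame(id = dc$monomers$id, seq = dc$monomers$seq),
               refm)
  # independent route: per-segment tallies straight from the CIGAR strings
  segs <- do.call(rbind, lapply(ch, function(x) x$domains))
  st <- do.call(rbind, lapply(segs$cigar, circsat:::cigar_stats))
  expect_equal(pl$totals$mismatches, sum(st$nmismatch))
  expect_equal(pl$totals$del_events, sum(st$del_events))
  expect_equal(pl$totals$del_nt, sum(st$del_len))
  expect_equal(pl$totals$ins_events, sum(st$ins_events))
  expect_equal(pl$totals$ins_nt, sum(st$ins_len))
  # and the column table re-aggregates to the same totals
  expect_equal(sum(pl$columns$del_starts), pl$totals$del_events)
  expect_equal(sum(pl$columns$A + pl$columns$C + pl$columns$G +
                     pl$columns$T), pl$totals$mismatches)
  # depth never below the events at a column
  expect_true(all(pl$columns$depth >=
                    pmax(pl$columns$del_starts, pl$columns$ins_events)))
})

test_that("alignments without explicit edit operations are rejected", {
  segs <- random_segments(1)
  segs$cigar <- "100M"
  ch <- chain_domains(segs)
  expect_error(pileup(list(ch), data.frame(id = "m1", seq = strrep("A", 300)),
                      refm),
               "re-align|CIGAR")
})

test_that("rate table arithmetic follows the A-H definitions", {
  tot <- list(mismatches = 100L, del_events = 0L, del_nt = 0L,
              ins_events = 0L, ins_nt = 0L)
  rt <- mutation_rates(tot, aligned_bp = 5e6, generations = 200)
  expect_equal(rt$A, 1.0e-07)
  expect_true(is.na(rt$D))
  expect_equal(rt$H, rt$A)
  # published-column ratio identities at printed precision
  tab <- published_rate_table()
  expect_equal(round(tab["C", "CAG102_c10"] / tab["B", "CAG102_c10"], 1),
               10.9)
  expect_equal(round(tab["F", "G4_c6"] / tab["E", "G4_c6"], 1), 2.5)
  expect_error(mutation_rates(tot, 1e6, generations = 0), "generations")
})

test_that("doubling generations halves rates and leaves ratios unchanged", {
  tot <- list(mismatches = 120L, del_events = 40L, del_nt = 400L,
              ins_events = 30L, ins_nt = 90L)
  r1 <- mutation_rates(tot, 1e6, generations = 100)
  r2 <- mutation_rates(tot, 1e6, generations = 200)
  for (k in c("A", "B", "C", "E", "F")) {
    expect_equal(r2[[k]], r1[[k]] / 2)
  }
  expect_equal(r2$D, r1$D)
  expect_equal(r2$G, r1$G)
  expect_equal(r1$D, r1$C / r1$B)
  expect_equal(r1$G, r1$F / r1$E)
  expect_equal(r1$H, r1$A + r1$C + r1$F)
})

test_that("per-kb deletion metrics are generation-free", {
  tot <- list(mismatches = 0L, del_events = 17L, del_nt = 84L,
              ins_events = 0L, ins_nt = 0L)
  pk <- per_kb_deletion_metrics(tot, aligned_bp = 10000)
  expect_equal(unname(pk["deleted_bases_per_kb"]), 8.4)
  expect_equal(unname(pk["deletion_events_per_kb"]), 1.7)
  pk0 <- per_kb_deletion_metrics(list(mismatches = 0L, del_events = 0L,
                                      del_nt = 0L, ins_events = 0L,
                                      ins_nt = 0L), 1000)
  expect_equal(unname(pk0), c(0, 0))
})

test_that("the mutation threshold removes exactly the low-density reads", {
  rs <- data.frame(monomer = "r1", mismatches = 1, del_events = 0,
                   del_nt = 0, ins_events = 0, ins_nt = 0,
                   aligned_bp = 1000)
  expect_equal(nrow(apply_mutation_threshold(rs, 2)$kept), 0L)
  rs$mismatches <- 5
  expect_equal(nrow(apply_mutation_threshold(rs, 2)$kept), 1L)
  # constructed 50-read set with 18 below 2 mutations/kb
  withr::with_seed(23, {
    below <- sample(50, 18)
    n_mut <- integer(50)
    n_mut[below] <- sample(0:1, 18, replace = TRUE)
    n_mut[-below] <- sample(2:9, 32, replace = TRUE)
  })
  rs50 <- data.frame(monomer = sprintf("r%02d", 1:50),
                     mismatches = n_mut, del_events = 0, del_nt = 0,
                     ins_events = 0, ins_nt = 0, aligned_bp = 1000)
  th <- apply_mutation_threshold(rs50, 2)
  expect_equal(nrow(th$kept), 32L)
  expect_equal(sort(th$removed$monomer), sort(rs50$monomer[below]))
  expect_error(apply_mutation_threshold(rs50, -1), "threshold")
})

test_that("substitutions fold to pyrimidine-centred channels", {
  ref2 <- hybrid_reference(c(ES = "AACAATTGTT"), "ES")
  # C>T at context A_A
  calls <- data.frame(contig = "ES", pos = 2L, ref = "C", alt = "T",
                      monomer = "m")
  sig <- trinucleotide_signature(calls, ref2)
  expect_equal(sig$channels$count[sig$channels$context == "ACA" &
                                    sig$channels$class == "C>T"], 1L)
  expect_equal(sig$n_used, 1L)
  # G>A at T_G on the plus strand folds to C>T at the rc context
  ref3 <- hybrid_reference(c(ES = "AATGGAA"), "ES")
  calls3 <- data.frame(contig = "ES", pos = 3L, ref = "G", alt = "A",
                       monomer = "m")
  sig3 <- trinucleotide_signature(calls3, ref3)
  hit <- sig3$channels[sig3$channels$count > 0, ]
  expect_equal(hit$class, "C>T")
  expect_equal(hit$context, revcomp("TGG"))
})

test_that("folding matches a complement-enumeration oracle over all 192 pairs", {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n_checked <- 0L
  for (up in bases) for (ref_b in bases) for (down in bases) {
    for (alt in setdiff(bases, ref_b)) {
      tri <- paste0(up, ref_b, down)
      refx <- hybrid_reference(setNames(paste0("A", tri, "A"), "ES"), "ES")
      calls <- data.frame(contig = "ES", pos = 2L, ref = ref_b, alt = alt,
                          monomer = "m")
      sig <- trinucleotide_signature(calls, refx)
      hit <- sig$channels[sig$channels$count > 0, ]
      expect_equal(nrow(hit), 1L)
      # oracle: fold by complementing when the centre is a purine
      if (ref_b %in% c("G", "A")) {
        exp_class <- paste0(comp[[ref_b]], ">", comp[[alt]])
        exp_ctx <- paste0(comp[[down]], comp[[ref_b]], comp[[up]])
      } else {
        exp_class <- paste0(ref_b, ">", alt)
        exp_ctx <- tri
      }
      expect_equal(hit$class, exp_class)
      expect_equal(hit$context, exp_ctx)
      n_checked <- n_checked + 1L
    }
  }
  expect_equal(n_checked, 192L)
})

test_that("edge and N-context calls are skipped and counted", {
  refx <- hybrid_reference(c(ES = "CANCC"), "ES")
  calls <- data.frame(contig = "ES", pos = c(0L, 3L, 4L),
                      ref = c("C", "C", "C"), alt = c("T", "A", "A"),
                      monomer = "m")
  sig <- trinucleotide_signature(calls, refx)
  expect_equal(sig$n_used, 0L)
  expect_equal(sig$n_skipped, 3L)
})

test_that("a C/G>T/A-dominated fixture shows an elevated C>T marginal", {
  mmC <- mutation_model(mismatch_rate = 5e-5, generations = 200)
  em <- demo_ecc_model(refm, 6L, mutation_model = mmC)
  # bias the substitution spectrum by rejection: keep only C>T / G>A calls
  pop <- simulate_population(refm, em, 20, seed = 41)
  rep <- run_pipeline(pop$reads, refm)
  calls <- rep$pileup$mismatch_calls
  keep <- (calls$ref == "C" & calls$alt == "T") |
    (calls$ref == "G" & calls$alt == "A")
  sig <- trinucleotide_signature(calls[keep, ], refm)
  expect_equal(sum(sig$six_class), unname(sig$six_class["C>T"]))
})
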