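# Concatemer decatenation: primer search, splitting, specificity filter,
# deduplication.

fx <- local({
  ref <- tiny_ref()
  ecc <- simulate_eccdna(ref, frt_circle_model(ref))
  rr <- simulate_ipcr_reads(ecc$sequence, ref$site$primers,
                            read_model(monomers_per_read = 1,
                                       seq_error_rate = 0,
                                       spanning_fraction = 0, n_reads = 1),
                            seed = 1)
  list(ref = ref, amp = attr(rr$truth, "amplicon"))
})

test_that("exact and near-exact primer occurrences are found", {
  withr::with_seed(21, bg <- random_dna(400))
  read <- paste0(bg, DEFAULT_PRIMERS$fwd, random_dna(100))
  h <- find_primer_sites(read, DEFAULT_PRIMERS$fwd, DEFAULT_PRIMERS$rev, 2)
  expect_equal(nrow(h), 1L)
  expect_equal(h$primer, "forward")
  expect_equal(h$strand, "+")
  expect_equal(h$edits, 0L)
  expect_equal(h$start, 400L)

  # rc(rev) with one substitution at max_edits 2
  rcrev <- revcomp(DEFAULT_PRIMERS$rev)
  mut <- paste0(substr(rcrev, 1, 9), "A", substr(rcrev, 11, 24))
  if (mut == rcrev) mut <- paste0(substr(rcrev, 1, 9), "C", substr(rcrev, 11, 24))
  read2 <- paste0(bg, mut, random_dna(60))
  h2 <- find_primer_sites(read2, DEFAULT_PRIMERS$fwd, DEFAULT_PRIMERS$rev, 2)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$primer, "reverse")
  expect_equal(h2$strand, "-")
  expect_equal(h2$edits, 1L)

  # no primer at <= max_edits -> empty
  withr::with_seed(22, noise <- random_dna(500))
  h3 <- find_primer_sites(noise, DEFAULT_PRIMERS$fwd, DEFAULT_PRIMERS$rev, 2)
  expect_equal(nrow(h3), 0L)
  expect_error(find_primer_sites(noise, "ACGTACGT", DEFAULT_PRIMERS$rev),
               "15")
})

test_that("reported edit distances match a brute-force window scan", {
  withr::with_seed(31, {
    for (i in 1:15) {
      bg <- random_dna(200)
      p <- DEFAULT_PRIMERS$fwd
      nmut <- sample(0:2, 1)
      pv <- strsplit(p, "")[[1]]
      if (nmut > 0) {
        at <- sample(seq_along(pv), nmut)
        pv[at] <- vapply(pv[at], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }, "")
      }
      read <- paste0(bg, paste(pv, collapse = ""), random_dna(50))
      h <- find_primer_sites(read, DEFAULT_PRIMERS$fwd,
                             DEFAULT_PRIMERS$rev, 2)
      h <- h[h$primer == "forward", ]
      expect_equal(nrow(h), 1L)
      expect_equal(h$edits, brute_min_window_dist(read, DEFAULT_PRIMERS$fwd))
    }
  })
})

test_that("tandem concatemers split into identical monomers", {
  read <- strrep(fx$amp, 3)
  h <- find_primer_sites(read, DEFAULT_PRIMERS$fwd, DEFAULT_PRIMERS$rev, 2)
  r <- decatenate(read, h, "r1")
  expect_equal(nrow(r$monomers), 3L)
  expect_equal(unique(r$monomers$seq), fx$amp)
  expect_equal(nrow(r$discarded), 0L)
})

test_that("single and reverse-complement reads normalize to the amplicon", {
  for (read in c(fx$amp, revcomp(fx$amp))) {
    h <- find_primer_sites(read, DEFAULT_PRIMERS$fwd, DEFAULT_PRIMERS$rev, 2)
    r <- decatenate(read, h, "r1")
    expect_equal(nrow(r$monomers), 1L)
    expect_identical(r$monomers$seq, fx$amp)
  }
})

test_that("normalization is idempotent and conserves read bases", {
  reads <- setNames(c(strrep(fx$amp, 2), revcomp(strrep(fx$amp, 3)),
                      substr(fx$amp, 500, nchar(fx$amp))),
                    c("a", "b", "c"))
  dc <- decat_reads(reads, DEFAULT_PRIMERS$fwd, DEFAULT_PRIMERS$rev)
  # conservation: monomer + discarded spans tile each read
  for (id in names(reads)) {
    m <- dc$monomers[dc$monomers$read == id, ]
    spans <- nchar(m$seq)
    d <- dc$discarded[dc$discarded$read == id, ]
    expect_equal(sum(spans) + sum(d$end - d$start), nchar(reads[[id]]))
  }
  # re-decatenating a normalized monomer is a no-op
  m1 <- dc$monomers$seq[1]
  again <- decat_reads(setNames(m1, "m"), DEFAULT_PRIMERS$fwd,
                       DEFAULT_PRIMERS$rev)
  expect_identical(again$monomers$seq, m1)
})

test_that("specificity filter keeps >=k matching flank bases and drops scrambles", {
  ref <- fx$ref
  es <- ref$contigs[["ES"]]
  dc <- decat_reads(setNames(strrep(fx$amp, 1), "r"),
                    DEFAULT_PRIMERS$fwd, DEFAULT_PRIMERS$rev)
  good <- dc$monomers
  # boundary: scramble the 6th base after the forward primer -> removed;
  # scramble the 7th -> kept
  flip_at <- function(seq, pos0) {
    b <- substr(seq, pos0 + 1, pos0 + 1)
    paste0(substr(seq, 1, pos0), chartr("ACGT", "CGTA", b),
           substr(seq, pos0 + 2, nchar(seq)))
  }
  m6 <- good; m6$seq <- flip_at(m6$seq, m6$f_end + 5L)
  m7 <- good; m7$seq <- flip_at(m7$seq, m7$f_end + 6L)
  r6 <- filter_specific(m6, es, DEFAULT_PRIMERS, k = 6)
  r7 <- filter_specific(m7, es, DEFAULT_PRIMERS, k = 6)
  expect_equal(nrow(r6$kept), 0L)
  expect_equal(nrow(r7$kept), 1L)
  expect_error(filter_specific(good, es, DEFAULT_PRIMERS, k = 0), "k must")

  # 100 monomers, 20 with scrambled post-primer hexamers -> exactly 80 kept
  m100 <- good[rep(1, 100), ]
  m100$index <- 1:100
  m100$id <- paste0("r/", 1:100)
  withr::with_seed(17, bad <- sample(100, 20))
  for (i in bad) {
    at <- m100$f_end[i] + sample(0:5, 1)
    m100$seq[i] <- flip_at(m100$seq[i], at)
  }
  res <- filter_specific(m100, es, DEFAULT_PRIMERS, k = 6)
  expect_equal(nrow(res$kept), 80L)
  expect_equal(nrow(res$removed), 20L)
})

test_that("deduplication collapses exact duplicates and is idempotent", {
  dc <- decat_reads(setNames(c(strrep(fx$amp, 2), fx$amp), c("a", "b")),
                    DEFAULT_PRIMERS$fwd, DEFAULT_PRIMERS$rev)
  dd <- deduplicate(dc$monomers)
  expect_equal(nrow(dd$monomers), 1L)
  expect_equal(nrow(dd$duplicates), 2L)
  expect_true(all(dd$duplicates$duplicate_of == dd$monomers$id[1]))
  # one-base difference -> both kept
  m <- dc$monomers[1:2, ]
  m$seq[2] <- paste0("A", substr(m$seq[2], 2, nchar(m$seq[2])))
  m$id <- c("x/1", "y/1"); m$read <- c("x", "y")
  dd2 <- deduplicate(m)
  expect_equal(nrow(dd2$monomers), 2L)
  # idempotence on random duplicated fixtures
  withr::with_seed(5, {
    seqs <- replicate(6, random_dna(50))
    pick <- sample(6, 20, replace = TRUE)
  })
  mm <- data.frame(read = sprintf("r%02d", 1:20), index = 1L,
                   id = sprintf("r%02d/1", 1:20), seq = seqs[pick],
                   f_start = 0L, f_end = 10L, r_start = 40L, r_end = 50L,
                   strand = "+", edits = 0L)
  d1 <- deduplicate(mm)
  d2 <- deduplicate(d1$monomers)
  expect_identical(d1$monomers$seq, d2$monomers$seq)
  expect_equal(nrow(d1$monomers), length(unique(seqs[pick])))
})

test_that("decatenation recovers true monomer counts at ccs error rates", {
  ref <- fx$ref
  ecc <- simulate_eccdna(ref, frt_circle_model(ref))
  rr <- simulate_ipcr_reads(ecc$sequence, ref$site$primers,
                            read_model(monomers_per_read = c(.3, .3, .2, .2),
                                       seq_error_rate = 0.2,
                                       spanning_fraction = 0.02,
                                       n_reads = 120),
                            seed = 8)
  dc <- decat_reads(rr$reads, DEFAULT_PRIMERS$fwd, DEFAULT_PRIMERS$rev, 2)
  got <- dc$ledger$n_monomers[match(rr$truth$read, dc$ledger$read)]
  expect_gte(mean(got == rr$truth$n_monomers), 0.99)
})
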