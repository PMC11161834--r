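# Segment alignment, chaining, classification and interchange formats.

ref1 <- tiny_ref()

test_that("an exact reference interval aligns full-length at identity 1", {
  es <- ref1$contigs[["ES"]]
  # origin interior: single-copy sequence
  m <- setNames(substr(es, 1401, 1900), "m1")
  segs <- align_segments(m, ref1)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$q_start, 0L)
  expect_equal(segs$q_end, 500L)
  expect_equal(segs$t_start, 1400L)
  expect_equal(segs$t_end, 1900L)
  expect_equal(segs$identity, 1)
  ref0 <- ref1; ref0$contigs <- character(0)
  expect_error(align_segments(m, ref0), "empty")
})

test_that("a chimeric monomer yields both constituent alignments", {
  es <- ref1$contigs[["ES"]]
  m <- setNames(paste0(substr(es, 1401, 1900), substr(es, 2301, 2500)), "m1")
  segs <- align_segments(m, ref1)
  segs <- segs[order(segs$q_start), ]
  expect_gte(nrow(segs), 2L)
  expect_true(any(segs$t_start <= 1400 & segs$t_end >= 1880))
  expect_true(any(segs$t_start <= 2320 & segs$t_end >= 2480))
})

test_that("polarity reversal produces forward and reverse alignments", {
  es <- ref1$contigs[["ES"]]
  frag <- substr(es, 1501, 2000)
  m <- setNames(paste0(frag, revcomp(frag)), "m1")
  ch <- chain_domains(align_segments(m, ref1))
  expect_equal(nrow(ch$domains), 2L)
  expect_setequal(ch$domains$strand, c("+", "-"))
  expect_equal(ch$domains$t_start, c(1500L, 1500L))
})

test_that("mapping the reverse complement yields the mirror chain", {
  es <- ref1$contigs[["ES"]]
  m <- paste0(substr(es, 501, 1200), substr(es, 2501, 3200))
  ch_f <- chain_domains(align_segments(setNames(m, "f"), ref1))
  ch_r <- chain_domains(align_segments(setNames(revcomp(m), "r"), ref1))
  df <- ch_f$domains; dr <- ch_r$domains
  expect_equal(nrow(df), nrow(dr))
  expect_equal(df$t_start, rev(dr$t_start))
  expect_equal(df$t_end, rev(dr$t_end))
  expect_true(all(df$strand != rev(dr$strand)))
})

test_that("chaining matches exhaustive enumeration on random fixtures", {
  withr::with_seed(77, {
    for (i in 1:60) {
      segs <- random_segments(sample(2:6, 1))
      got <- chain_domains(segs)$domains
      want <- enumerate_best_chain(segs)
      expect_equal(got$q_start, want$q_start)
      expect_equal(got$t_start, want$t_start)
      expect_equal(sum(got$score), sum(want$score))
    }
  })
})

test_that("adjacent chained segments may overlap by the homology allowance", {
  segs <- random_segments(2)
  segs$q_start <- c(100L, 390L); segs$q_end <- c(400L, 700L)
  segs$score <- c(100, 100)
  ch <- chain_domains(segs, max_query_overlap = 300L)
  expect_equal(nrow(ch$domains), 2L)
  expect_equal(ch$junctions$q_gap, -10L)
  # overlap beyond the allowance forbids co-selection
  segs$q_start <- c(100L, 250L); segs$q_end <- c(500L, 650L)
  ch2 <- chain_domains(segs, max_query_overlap = 300L)
  expect_equal(nrow(ch2$domains), 2L)   # 250-bp overlap within allowance
  ch3 <- chain_domains(segs, max_query_overlap = 100L)
  expect_equal(nrow(ch3$domains), 1L)
})

test_that("a five-domain structure chains in query order", {
  es <- ref1$contigs[["ES"]]
  cuts <- list(c(330, 830), c(1400, 1900), c(2600, 3100),
               c(3450, 3900), c(4160, 4460))
  m <- paste(vapply(cuts, function(ab) substr(es, ab[1] + 1, ab[2]), ""),
             collapse = "")
  ch <- chain_domains(align_segments(setNames(m, "m1"), ref1))
  expect_equal(nrow(ch$domains), 5L)
  # boundaries recover to within the chance-extension tolerance
  expect_true(all(abs(ch$domains$t_start - vapply(cuts, `[`, 0, 1)) <= 2))
  expect_true(all(diff(ch$domains$q_start) > 0))
})

test_that("domains classify as intra-site or nonallelic with copy direction", {
  es <- ref1$contigs[["ES"]]
  don <- ref1$contigs[["chrX_frag"]]
  m <- paste0(substr(es, 501, 1100), substr(don, 1201, 1800))
  ch <- classify_domains(chain_domains(align_segments(setNames(m, "m1"),
                                                      ref1)), ref1)
  expect_equal(unname(ch$class_counts["intra_es"]), 1L)
  expect_equal(unname(ch$class_counts["nonallelic"]), 1L)
  d <- ch$domains
  expect_equal(d$direction[d$class == "nonallelic"], "p_to_q")
  # minus-strand donor copy runs q -> p
  m2 <- paste0(substr(es, 501, 1100), revcomp(substr(don, 1201, 1800)))
  ch2 <- classify_domains(chain_domains(align_segments(setNames(m2, "m1"),
                                                       ref1)), ref1)
  d2 <- ch2$domains
  expect_equal(d2$direction[d2$class == "nonallelic"], "q_to_p")
  # successive plus-strand donor domains with decreasing coordinates: q -> p
  m3 <- paste0(substr(don, 1501, 1900), substr(don, 301, 700))
  ch3 <- classify_domains(chain_domains(align_segments(setNames(m3, "m1"),
                                                       ref1)), ref1)
  expect_equal(ch3$domains$direction[2], "q_to_p")
})

test_that("nonallelic verification requires a site-absent k-mer", {
  es <- ref1$contigs[["ES"]]
  don <- ref1$contigs[["chrX_frag"]]
  expect_true(verify_nonallelic(substr(don, 1201, 1500), es))
  # a "donor" segment that is an exact ES copy fails verification
  expect_false(verify_nonallelic(substr(es, 1001, 1300), es))
  expect_true(is.na(verify_nonallelic(substr(don, 1, 20), es, k = 25)))
  # donor sharing an ES fragment but extending beyond it verifies
  shared <- paste0(substr(es, 2001, 2300), substr(don, 2001, 2100))
  expect_true(verify_nonallelic(shared, es))
  # exhaustive membership oracle agreement on short cases
  withr::with_seed(13, {
    for (i in 1:20) {
      s <- random_dna(40)
      k <- 12L
      km <- substring(s, 1:(40 - k + 1), k:40)
      es2 <- paste0(es, "N", revcomp(es))
      esk <- substring(es2, 1:(nchar(es2) - k + 1), k:nchar(es2))
      expect_equal(verify_nonallelic(s, es, k = k), any(!(km %in% esk)))
    }
  })
})

test_that("PAF round trips coordinates, strand and edit operations", {
  es <- ref1$contigs[["ES"]]
  m <- setNames(paste0(substr(es, 1401, 1900),
                       revcomp(substr(es, 2101, 2500))), "m1")
  segs <- align_segments(m, ref1)
  qlens <- setNames(nchar(m), names(m))
  tlens <- setNames(nchar(ref1$contigs), names(ref1$contigs))
  path <- tempfile(fileext = ".paf")
  write_paf(segs, qlens, tlens, path)
  back <- read_paf(path)
  expect_equal(back$q_start, segs$q_start)
  expect_equal(back$q_end, segs$q_end)
  expect_equal(back$t_start, segs$t_start)
  expect_equal(back$t_end, segs$t_end)
  expect_equal(back$strand, segs$strand)
  expect_equal(back$cigar, segs$cigar)
  # minus-strand rows keep query coordinates on the original read
  minus <- back[back$strand == "-", ]
  expect_equal(minus$q_start, 500L)
  # malformed rows: skipped with warning, error in strict mode
  writeLines(c(readLines(path), "garbage\trow"), path)
  expect_warning(back2 <- read_paf(path), "malformed")
  expect_equal(nrow(back2), nrow(segs))
  expect_error(read_paf(path, strict = TRUE), "malformed")
})

test_that("BED output is 0-based half-open", {
  segs <- random_segments(3)
  path <- tempfile(fileext = ".bed")
  write_bed(segs, path)
  b <- read.delim(path, header = FALSE)
  expect_equal(b$V2, segs$t_start)
  expect_equal(b$V3, segs$t_end)
  expect_equal(b$V6, segs$strand)
})

test_that("SAM supplementary alignments group into one monomer's set", {
  skip_if_not_installed("Rsamtools")
  es <- ref1$contigs[["ES"]]
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:ES\tLN:%d", nchar(es)),
    paste("m1", 0, "ES", 1001, 60, "500=400S",
          "*", 0, 0, paste0(substr(es, 1001, 1500), substr(es, 3001, 3400)),
          "*", sep = "\t"),
    paste("m1", 2048, "ES", 3001, 60, "500S400=",
          "*", 0, 0, "*", "*", sep = "\t")
  ), sam)
  segs <- read_sam_segments(sam)
  expect_equal(nrow(segs), 2L)
  expect_equal(unique(segs$monomer), "m1")
  expect_equal(segs$t_start, c(1000L, 3000L))
  expect_equal(segs$q_start, c(0L, 500L))
  expect_equal(segs$q_end, c(500L, 900L))
})
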