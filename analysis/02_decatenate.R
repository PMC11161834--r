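#!/usr/bin/env Rscript
# Decatenate the simulated concatemer reads into monomer PCR products,
# apply the ectopic-site specificity filter (>= 6 bp of site sequence 3' of
# each iPCR primer) and collapse exact duplicates.  Writes per-dataset
# monomer FASTA and a per-read ledger TSV under results/decat/.

suppressPackageStartupMessages(library(circsat))
dir.create("results/decat", recursive = TRUE, showWarnings = FALSE)

ref <- default_reference("CAG102", seed = 1L)
es <- ref$contigs[[ref$es_contig]]

for (nm in c("frt_circle", "intra_switch", "nonallelic_switch")) {
  reads <- read_seqs(file.path("results/sim", nm, "reads.fastq"))
  dc <- decat_reads(reads, DEFAULT_PRIMERS$fwd, DEFAULT_PRIMERS$rev,
                    max_edits = 2L)
  fs <- filter_specific(dc$monomers, es, DEFAULT_PRIMERS, k = 6L)
  dd <- deduplicate(fs$kept)
  cat(sprintf(paste0("%-18s %3d reads -> %3d monomers ",
                     "(%d nonspecific, %d duplicates, %d fragments)\n"),
              nm, length(reads), nrow(dd$monomers), nrow(fs$removed),
              nrow(dd$duplicates), nrow(dc$discarded)))
  hdr <- sprintf("%s strand=%s edits=%d", dd$monomers$id,
                 dd$monomers$strand, dd$monomers$edits)
  write_seqs(setNames(dd$monomers$seq, hdr),
             file.path("results/decat", paste0(nm, "_monomers.fasta")))
  write.table(dc$ledger,
              file.path("results/decat", paste0(nm, "_ledger.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
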