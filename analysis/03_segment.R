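#!/usr/bin/env Rscript
# Align the monomers to the hybrid reference with the internal
# seed-and-extend aligner, chain local alignments into template-switch
# domains, and classify each domain as intra-site or nonallelic.  Writes
# segment PAF, domain BED, a chain table and a Circos-style link table
# under results/segments/.

suppressPackageStartupMessages(library(circsat))
dir.create("results/segments", recursive = TRUE, showWarnings = FALSE)

ref <- default_reference("CAG102", seed = 1L)
idx <- seg_index(ref)
tlens <- setNames(nchar(ref$contigs), names(ref$contigs))

for (nm in c("frt_circle", "intra_switch", "nonallelic_switch")) {
  mono <- read_seqs(file.path("results/decat", paste0(nm, "_monomers.fasta")))
  segs <- align_segments(mono, ref, index = idx)
  chains <- lapply(chain_all(segs), classify_domains, ref = ref)
  doms <- do.call(rbind, lapply(chains, function(ch) ch$domains))
  cat(sprintf("%-18s %3d monomers, %3d domains (%d nonallelic)\n",
              nm, length(chains), nrow(doms),
              sum(doms$class == "nonallelic")))
  qlens <- setNames(nchar(mono), names(mono))
  write_paf(doms, qlens, tlens,
            file.path("results/segments", paste0(nm, ".paf")))
  write_bed(doms, file.path("results/segments", paste0(nm, "_domains.bed")))
  write.table(doms[, c("monomer", "q_start", "q_end", "contig", "t_start",
                       "t_end", "strand", "identity", "class")],
              file.path("results/segments", paste0(nm, "_chains.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  # Circos-style link table: consecutive domains of each chain
  links <- do.call(rbind, lapply(chains, function(ch) {
    d <- ch$domains
    if (nrow(d) < 2) return(NULL)
    data.frame(contig_a = d$contig[-nrow(d)], start_a = d$t_start[-nrow(d)],
               end_a = d$t_end[-nrow(d)], contig_b = d$contig[-1],
               start_b = d$t_start[-1], end_b = d$t_end[-1])
  }))
  write.table(links, file.path("results/segments", paste0(nm, "_links.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
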