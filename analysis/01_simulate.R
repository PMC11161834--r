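#!/usr/bin/env Rscript
# Build the hairpin-microsatellite ectopic site plus donor contigs, then
# simulate three eccDNA populations at published per-generation mutation
# rates: a circle closed through the 48-bp FRT homology, a circle with one
# intra-site template switch (6-bp microhomology), and a circle with a
# nonallelic switch to a donor chromosome (43-bp microhomology).  Writes
# reference, reads and ground truth under results/sim/.

suppressPackageStartupMessages(library(circsat))
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)
seed <- 20260920L

ref <- default_reference("CAG102", seed = 1L)
tab <- published_rate_table()
mm <- mutation_model_from_rates(
  A = tab["A", "CAG102_c10"], B = tab["B", "CAG102_c10"],
  C = tab["C", "CAG102_c10"], E = tab["E", "CAG102_c10"],
  F = tab["F", "CAG102_c10"],
  generations = tab["generations", "CAG102_c10"])

models <- list(
  frt_circle = frt_circle_model(ref, mutation_model = mm),
  intra_switch = demo_ecc_model(ref, intra_overlap = 6L,
                                mutation_model = mm),
  nonallelic_switch = nonallelic_ecc_model(ref, nonallelic_overlap = 43L,
                                           mutation_model = mm))

rd <- read_model(monomers_per_read = c(0.4, 0.3, 0.2, 0.1),
                 seq_error_rate = 0.1, spanning_fraction = 0.02,
                 n_reads = 40L)

for (nm in names(models)) {
  sim <- simulate_dataset(ref, models[[nm]], rd, seed = seed)
  write_dataset(sim, file.path("results/sim", nm))
  cat(sprintf("%-18s circle %5d bp, %3d reads, %3d injected mutations\n",
              nm, nchar(sim$circle), length(sim$reads),
              nrow(sim$ecc_truth$mutations)))
  seed <- seed + 1000L
}
cat("wrote results/sim/{frt_circle,intra_switch,nonallelic_switch}/\n")
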