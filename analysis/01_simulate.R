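#!/usr/bin/env Rscript

# Build the synthetic two-condition small-RNA study: a toy genome with 20
# planted miRNA hairpins, contaminant references, and paired
# control/treatment read libraries with planted response classes.
# Outputs go to results/simulation/.

library(miRvine)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

outdir <- "results/simulation"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

spec <- simulation_spec(seed = seed)
sim <- generate_genome(spec)
reads <- simulate_libraries(spec, sim)

write_fasta(sim$genome, file.path(outdir, "genome.fa"))
for (cls in names(sim$contaminants)) {
  write_fasta(sim$contaminants[[cls]],
              file.path(outdir, paste0("contaminant_", cls, ".fa")))
}
write_fastq(reads$control, file.path(outdir, "control.fastq"))
write_fastq(reads$treatment, file.path(outdir, "treatment.fastq"))
write.table(sim$truth, file.path(outdir, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(as.character(seed), file.path(outdir, "seed.txt"))

cat("Simulated study (seed ", seed, "):\n", sep = "")
cat("  genome: ", nchar(sim$genome[[1]]), " nt, ",
    nrow(sim$truth), " planted hairpins\n", sep = "")
cat("  reads:  control ", length(reads$control), ", treatment ",
    length(reads$treatment), "\n", sep = "")
print(table(sim$truth$true_class))
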