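#!/usr/bin/env Rscript

# Adapter-trim, length-filter and collapse the simulated libraries, then
# profile them: length distribution and first-nucleotide bias, the two
# standard sanity plots of a plant small-RNA library (21/24-nt peaks and
# the 5'U excess of miRNA-sized tags).

library(miRvine)

indir <- "results/simulation"
outdir <- "results/preprocess"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

adapter <- simulation_spec()$adapter
libs <- lapply(c(control = "control", treatment = "treatment"), function(cond) {
  reads <- read_sequences(file.path(indir, paste0(cond, ".fastq")), "fastq")
  trimmed <- trim_adapter(unname(reads), adapter)
  lib <- filter_and_collapse(trimmed, label = cond)
  tab <- lib$tags
  write.table(tab, file.path(outdir, paste0("tags_", cond, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  lib
})

for (cond in names(libs)) {
  lib <- libs[[cond]]
  cat(cond, ": ", lib$total_redundant, " reads -> ", nrow(lib$tags),
      " unique tags\n", sep = "")
  sd <- size_distribution(lib, "redundant")
  write.table(data.frame(length = names(sd), fraction = as.numeric(sd)),
              file.path(outdir, paste0("size_distribution_", cond, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat("  21-nt fraction ", round(sd["21"], 3),
      ", 24-nt fraction ", round(sd["24"], 3), "\n", sep = "")
  fb <- first_nt_bias(lib, "unique")
  write.table(fb, file.path(outdir, paste0("first_nt_bias_", cond, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  u21 <- fb$fraction[fb$length == 21 & fb$first_nt == "U"]
  cat("  5'U fraction of 21-nt tags: ", round(u21, 3), "\n", sep = "")
}
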