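#!/usr/bin/env Rscript

# Classify tags into annotation categories, then discover novel miRNA
# hairpins among the unannotated tags: exact genome mapping, window
# extraction, maximum-pairing folding, hairpin criteria and miRNA*
# detection. Emits the category breakdown, the candidate table and a GFF3
# of precursors.

library(miRvine)

simdir <- "results/simulation"
outdir <- "results/discovery"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

genome <- read_sequences(file.path(simdir, "genome.fa"))
classes <- list()
for (cls in c("rRNA", "tRNA", "snRNA", "snoRNA")) {
  fp <- file.path(simdir, paste0("contaminant_", cls, ".fa"))
  if (file.exists(fp)) classes[[cls]] <- read_sequences(fp)
}
idx <- build_annotation_index(classes)

libs <- lapply(c(control = "control", treatment = "treatment"), function(cond) {
  tab <- read.delim(file.path("results/preprocess",
                              paste0("tags_", cond, ".tsv")),
                    stringsAsFactors = FALSE)
  structure(list(label = cond, tags = tab,
                 total_redundant = sum(tab$count)),
            class = "tag_library")
})

for (cond in names(libs)) {
  bd <- category_breakdown(libs[[cond]], idx)
  write.table(bd$table,
              file.path(outdir, paste0("category_breakdown_", cond, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(cond, "unannotated share (redundant):",
      bd$table$redundant_pct[bd$table$category == "unann"], "%\n")
}

pooled <- sort(unique(c(libs$control$tags$sequence,
                        libs$treatment$tags$sequence)))
category <- vapply(pooled, classify_tag, character(1), index = idx)
unann <- pooled[category == "unann"]
unann <- unann[nchar(unann) >= 20 & nchar(unann) <= 22]
cat("unannotated tags of mature length:", length(unann), "\n")

novel <- discover_novel(unann, genome, libs)
write.table(novel, file.path(outdir, "novel_candidates.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_gff3(novel, file.path(outdir, "novel_candidates.gff3"))

cat("novel hairpin candidates:", nrow(novel), "\n")
cat("  with miRNA* evidence:", sum(novel$star_detected), "\n")
cat("  starting with 5'U:", sum(novel$five_prime_U), "\n")

truth <- read.delim(file.path(simdir, "truth.tsv"), stringsAsFactors = FALSE)
recovered <- vapply(seq_len(nrow(truth)), function(i)
  any(novel$mature_start <= truth$mature_end[i] &
        novel$mature_end >= truth$mature_start[i]), logical(1))
cat("planted hairpins recovered:", sum(recovered), "/", nrow(truth), "\n")
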