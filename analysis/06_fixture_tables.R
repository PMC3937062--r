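#!/usr/bin/env Rscript

# Summarize the packaged conserved (122-row) and novel (118-row) miRNA
# fixture tables: family structure and the five-way response
# classification from the printed normalized counts.

library(miRvine)

outdir <- "results/fixtures"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

known <- read_mirna_table(mirna_fixture("known"))
fs <- family_summary(known)
write.table(fs, file.path(outdir, "known_family_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("conserved miRNAs:", nrow(known), "in", nrow(fs), "families;",
    sum(fs$members == 1), "single-member families\n")

s <- summarize_responses(known)
cat("conserved response classes:\n")
print(s$mature[, "known"])

novel <- read_mirna_table(mirna_fixture("novel"))
fam <- assign_family(novel$mirna_id)
sn <- summarize_responses(novel)
cat("\nnovel matures:", sum(!fam$star), "with", sum(fam$star),
    "star records\n")
cat("novel mature response classes:\n")
print(sn$mature[, "novel"])

marked <- mark_responses(rbind(known[names(novel)], novel))
write.table(marked, file.path(outdir, "mirna_response_marks.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE,
            fileEncoding = "UTF-8")
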