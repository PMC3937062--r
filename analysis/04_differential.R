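#!/usr/bin/env Rscript

# Normalize candidate counts to reads-per-million and classify each
# mature's response to the treatment into the five classes
# (up / down / treatment-only / control-only / unchanged), then compare
# the calls with the planted truth.

library(miRvine)

outdir <- "results/differential"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

novel <- read.delim("results/discovery/novel_candidates.tsv",
                    stringsAsFactors = FALSE)
libs <- lapply(c(control = "control", treatment = "treatment"), function(cond) {
  tab <- read.delim(file.path("results/preprocess",
                              paste0("tags_", cond, ".tsv")),
                    stringsAsFactors = FALSE)
  sum(tab$count)
})

tab <- data.frame(
  mirna_id = paste0("Vvi-", novel$id),
  sequence = novel$sequence,
  nc_control = normalize_counts(novel$count_control, libs$control),
  nc_treatment = normalize_counts(novel$count_treatment, libs$treatment),
  stringsAsFactors = FALSE
)
tab <- mark_responses(tab)
rep_tab <- tab
rep_tab$nc_control <- format_nc(rep_tab$nc_control)
rep_tab$nc_treatment <- format_nc(rep_tab$nc_treatment)
write.table(rep_tab, file.path(outdir, "novel_response_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE,
            fileEncoding = "UTF-8")

cat("response classes over", nrow(tab), "candidates:\n")
print(table(tab$response))

truth <- read.delim("results/simulation/truth.tsv", stringsAsFactors = FALSE)
tru <- truth$true_class[match(tab$sequence, truth$mature)]
conf <- table(called = tab$response[!is.na(tru)], true = tru[!is.na(tru)])
print(conf)
write.table(as.data.frame(conf), file.path(outdir, "confusion.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
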