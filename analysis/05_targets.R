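#!/usr/bin/env Rscript

# Predict targets for the discovered matures on a synthetic transcript
# set with planted antisense sites, and validate simulated cleavage
# observations against the 9th-11th-nucleotide rule.

library(miRvine)

outdir <- "results/targets"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

seed <- as.integer(readLines("results/simulation/seed.txt"))
set.seed(seed + 2L)

novel <- read.delim("results/discovery/novel_candidates.tsv",
                    stringsAsFactors = FALSE)
matures <- unique(novel$sequence)[1:min(10, length(unique(novel$sequence)))]

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")
# one transcript per mature with a planted near-antisense site
transcripts <- vapply(matures, function(m) {
  site <- reverse_complement(m)
  paste0(rand_seq(200), site, rand_seq(200))
}, character(1))
names(transcripts) <- paste0("TX", seq_along(transcripts))

all_sites <- NULL
for (i in seq_along(matures)) {
  hits <- predict_targets(matures[i], transcripts)
  if (nrow(hits)) {
    hits <- cbind(mirna = matures[i], hits)
    # simulated RACE fragment starting opposite miRNA position 10
    for (j in seq_len(nrow(hits))) {
      obs <- list(transcript = hits$transcript[j],
                  coordinate = hits$end[j] - 9L)
      v <- validate_cleavage(hits[j, ], obs)
      hits$cleavage_position[j] <- v$position
      hits$cleavage_supported[j] <- v$status == "supported"
    }
    all_sites <- rbind(all_sites, hits)
  }
}
write.table(all_sites, file.path(outdir, "target_sites.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("predicted sites:", nrow(all_sites), "for", length(matures),
    "matures\n")
cat("cleavage-supported sites:", sum(all_sites$cleavage_supported), "\n")
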