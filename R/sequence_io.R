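#' Read sequences from FASTA or FASTQ
#'
#' Reads a sequence file and returns the records as an upper-cased,
#' DNA-normalized character vector named by record identifier. RNA input
#' (containing U, as miRBase mature sequences do) is converted to the DNA
#' alphabet on ingest so that all downstream mismatch counting happens over
#' a single alphabet \{A,C,G,T,N\}.
#'
#' @param path Path to the sequence file.
#' @param format Either `"fasta"` or `"fastq"`. FASTQ qualities are ignored
#'   (small-RNA pipelines here are sequence-driven).
#' @return Named character vector of residues; empty vector for an empty
#'   file.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgu"), fa)
#' read_sequences(fa)  # c(x = "ACGT")
#' @export
read_sequences <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (file.size(path) == 0) return(stats::setNames(character(0), character(0)))
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) stop("malformed ", format, " in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  res <- toupper(as.character(set))
  res <- chartr("U", "T", res)
  bad <- grep("[^ACGTN]", res)
  if (length(bad)) {
    stop("record ", bad[1], " ('", names(res)[bad[1]],
         "') contains characters outside {A,C,G,T,U,N}")
  }
  # FASTA identifiers: first whitespace-delimited token, miRBase style
  nm <- sub("\\s.*$", "", names(set))
  stats::setNames(res, nm)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of residues (DNA alphabet).
#' @param path Output path.
#' @param rna If `TRUE`, T is written as U (report form for mature miRNAs).
#' @export
write_fasta <- function(seqs, path, rna = FALSE) {
  out <- if (rna) chartr("T", "U", seqs) else seqs
  writeLines(paste0(">", names(out), "\n", out), path)
  invisible(path)
}

#' Reverse complement of a DNA sequence
#'
#' Length-preserving involution over \{A,C,G,T,N\}; N complements to N.
#'
#' @param seq Character scalar or vector of residues.
#' @return Reverse complement(s), same length(s).
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(seq) {
  bad <- grep("[^ACGTN]", seq)
  if (length(bad)) stop("non-alphabet character in sequence ", bad[1])
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Write hairpin candidates as GFF3
#'
#' Emits one `miRNA_primary_transcript` feature per precursor with child
#' `miRNA` features for the mature (and star when detected). Coordinates
#' follow the GFF3 convention (1-based, inclusive).
#'
#' @param hairpins A data frame of accepted hairpin candidates as produced
#'   by [discover_novel()] (columns `id`, `contig`, `start`, `end`,
#'   `strand`, `mature_start`, `mature_end`, `star_start`, `star_end`;
#'   star columns may be `NA`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(hairpins, path) {
  if (nrow(hairpins) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  pre <- GenomicRanges::GRanges(
    hairpins$contig,
    IRanges::IRanges(hairpins$start, hairpins$end),
    strand = hairpins$strand,
    type = "miRNA_primary_transcript",
    ID = hairpins$id
  )
  mat <- GenomicRanges::GRanges(
    hairpins$contig,
    IRanges::IRanges(hairpins$mature_start, hairpins$mature_end),
    strand = hairpins$strand,
    type = "miRNA",
    ID = paste0(hairpins$id, "_mature"),
    Parent = hairpins$id
  )
  feats <- c(pre, mat)
  has_star <- !is.na(hairpins$star_start)
  if (any(has_star)) {
    st <- GenomicRanges::GRanges(
      hairpins$contig[has_star],
      IRanges::IRanges(hairpins$star_start[has_star],
                       hairpins$star_end[has_star]),
      strand = hairpins$strand[has_star],
      type = "miRNA",
      ID = paste0(hairpins$id[has_star], "_star"),
      Parent = hairpins$id[has_star]
    )
    feats <- c(feats, st)
  }
  rtracklayer::export(feats, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 of hairpin features back as a GRanges
#'
#' Convenience wrapper used for round-trip checks and downstream interval
#' work.
#'
#' @param path GFF3 path.
#' @return A `GRanges`.
#' @export
read_gff3 <- function(path) {
  rtracklayer::import(path, format = "gff3")
}
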