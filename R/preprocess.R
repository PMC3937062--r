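#' Trim a 3' adapter from a read
#'
#' Finds the left-most position at which a prefix of the adapter, at least
#' `min_seed` long, matches the read with at most `max_mismatch`
#' mismatches, and returns the read prefix preceding it. If the adapter is
#' found at position 1 the read was adapter-only (empty insert) and `NA` is
#' returned. If no adapter occurrence is found the read is returned
#' unchanged.
#'
#' @param read Character vector of reads (residues).
#' @param adapter3 The 3' adapter sequence.
#' @param min_seed Minimum adapter-prefix length that can anchor a match.
#' @param max_mismatch Maximum mismatches tolerated within the matched
#'   adapter prefix.
#' @return Character vector: trimmed inserts, `NA` for adapter-only reads.
#' @export
trim_adapter <- function(read, adapter3, min_seed = 8L, max_mismatch = 1L) {
  if (nchar(adapter3) < min_seed) {
    stop("adapter shorter than min_seed (", min_seed, ")")
  }
  pos <- .adapter_scan(read, adapter3, as.integer(min_seed),
                       as.integer(max_mismatch))
  out <- read
  out[pos == 0L] <- NA_character_                      # adapter-only
  hit <- pos > 0L
  out[hit] <- substr(read[hit], 1L, pos[hit])          # insert before adapter
  out
}

#' Filter reads and collapse them into a tag library
#'
#' Drops reads outside the accepted small-RNA length range, reads
#' containing N, and polyA-dominated reads, then collapses identical
#' residues into unique tags with multiplicities.
#'
#' @param reads Character vector of adapter-trimmed reads.
#' @param label Library label (e.g. `"control"`, `"treatment"`).
#' @param min_len,max_len Accepted insert length range (default 18-30 nt).
#' @param polyA_frac Reads with at least this fraction of A are dropped.
#' @return A `tag_library`: list with `label`, `tags` (data frame with
#'   columns `sequence`, `count`), and `total_redundant`.
#' @export
filter_and_collapse <- function(reads, label = "library", min_len = 18L,
                                max_len = 30L, polyA_frac = 0.8) {
  reads <- reads[!is.na(reads)]
  reads <- reads[!grepl("N", reads, fixed = TRUE)]
  len <- nchar(reads)
  reads <- reads[len >= min_len & len <= max_len]
  if (length(reads)) {
    a_frac <- vapply(gregexpr("A", reads, fixed = TRUE), function(m) {
      if (m[1] == -1) 0L else length(m)
    }, integer(1)) / nchar(reads)
    reads <- reads[a_frac < polyA_frac]
  }
  if (length(reads)) {
    tab <- table(reads)
    tags <- data.frame(
      sequence = names(tab),
      count = as.integer(tab),
      stringsAsFactors = FALSE
    )
    tags <- tags[order(tags$sequence), , drop = FALSE]
    rownames(tags) <- NULL
  } else {
    tags <- data.frame(sequence = character(0), count = integer(0),
                       stringsAsFactors = FALSE)
  }
  structure(
    list(label = label, tags = tags, total_redundant = sum(tags$count)),
    class = "tag_library"
  )
}

#' @export
print.tag_library <- function(x, ...) {
  cat("tag_library '", x$label, "': ", nrow(x$tags), " unique tags, ",
      x$total_redundant, " redundant reads\n", sep = "")
  invisible(x)
}

#' Length distribution of a tag library
#'
#' @param lib A `tag_library`.
#' @param weighting `"unique"` counts each distinct tag once; `"redundant"`
#'   weights by read multiplicity.
#' @return Named numeric vector of fractions over the observed lengths
#'   (sums to 1).
#' @export
size_distribution <- function(lib, weighting = c("unique", "redundant")) {
  weighting <- match.arg(weighting)
  if (nrow(lib$tags) == 0) stop("empty library")
  len <- nchar(lib$tags$sequence)
  w <- if (weighting == "redundant") lib$tags$count else rep(1L, nrow(lib$tags))
  tot <- tapply(w, len, sum)
  frac <- as.numeric(tot) / sum(w)
  stats::setNames(frac, names(tot))
}

#' First-nucleotide bias by length
#'
#' For each tag length, the fraction of tags beginning with each
#' nucleotide, reported in the RNA alphabet (T shown as U) as is
#' conventional for mature miRNA 5' identity.
#'
#' @inheritParams size_distribution
#' @return Data frame with columns `length`, `first_nt` (A/C/G/U),
#'   `fraction`; fractions sum to 1 within each length.
#' @export
first_nt_bias <- function(lib, weighting = c("unique", "redundant")) {
  weighting <- match.arg(weighting)
  if (nrow(lib$tags) == 0) stop("empty library")
  len <- nchar(lib$tags$sequence)
  first <- chartr("T", "U", substr(lib$tags$sequence, 1L, 1L))
  w <- if (weighting == "redundant") lib$tags$count else rep(1L, nrow(lib$tags))
  agg <- stats::aggregate(w, list(length = len, first_nt = first), sum)
  tot <- stats::aggregate(w, list(length = len), sum)
  agg$fraction <- agg$x / tot$x[match(agg$length, tot$length)]
  agg <- agg[order(agg$length, agg$first_nt), c("length", "first_nt", "fraction")]
  rownames(agg) <- NULL
  agg
}
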