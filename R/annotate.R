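#' Annotation categories, in classification priority order
#'
#' Structural RNA classes take precedence over genic context, and a
#' known-miRNA hit takes precedence over everything; tags matching nothing
#' are `unann`. This is the standard small-RNA annotation convention.
#' @export
ANNOTATION_PRIORITY <- c(
  "miRNA", "rRNA", "tRNA", "snRNA", "snoRNA", "Repeat",
  "Exon_sense", "Exon_antisense", "Intron_sense", "Intron_antisense",
  "unann"
)

#' Build an annotation index from class reference sequences
#'
#' Contaminant and genic classes are supplied as named lists of reference
#' sequences (FASTA-derived character vectors). Classification is by exact
#' substring membership: a tag belongs to a class if it occurs verbatim in
#' any reference sequence of that class (sense) or in its reverse
#' complement (antisense, reported separately for exon/intron only).
#'
#' @param classes Named list; allowed names: `rRNA`, `tRNA`, `snRNA`,
#'   `snoRNA`, `repeat`, `exon`, `intron`. Each element a character vector
#'   of reference sequences (DNA alphabet).
#' @return An `annotation_index` object.
#' @export
build_annotation_index <- function(classes) {
  allowed <- c("rRNA", "tRNA", "snRNA", "snoRNA", "repeat", "exon", "intron")
  bad <- setdiff(names(classes), allowed)
  if (length(bad)) stop("unknown annotation class(es): ", paste(bad, collapse = ", "))
  idx <- lapply(classes, function(seqs) {
    seqs <- toupper(unname(unlist(seqs)))
    # concatenated subject with separators that can never match a tag
    list(
      sense = paste(seqs, collapse = "|"),
      antisense = paste(reverse_complement(seqs), collapse = "|")
    )
  })
  structure(idx, class = "annotation_index")
}

.in_class <- function(tag, subject) {
  grepl(tag, subject, fixed = TRUE)
}

#' Classify a tag into its annotation category
#'
#' Exactly one category per tag, chosen by the fixed priority of
#' [ANNOTATION_PRIORITY]: known-miRNA > rRNA > tRNA > snRNA > snoRNA >
#' repeat > exon (sense, then antisense) > intron (sense, then antisense) >
#' unannotated.
#'
#' @param tag Tag residues (character scalar).
#' @param index An `annotation_index`.
#' @param known_mirna_hit Logical: did the tag match the known mature miRNA
#'   reference (from [match_known()])?
#' @return Category label (one of [ANNOTATION_PRIORITY]).
#' @export
classify_tag <- function(tag, index, known_mirna_hit = FALSE) {
  if (known_mirna_hit) return("miRNA")
  for (cls in c("rRNA", "tRNA", "snRNA", "snoRNA")) {
    ref <- index[[cls]]
    if (!is.null(ref) &&
        (.in_class(tag, ref$sense) || .in_class(tag, ref$antisense))) {
      return(cls)
    }
  }
  ref <- index[["repeat"]]
  if (!is.null(ref) &&
      (.in_class(tag, ref$sense) || .in_class(tag, ref$antisense))) {
    return("Repeat")
  }
  for (cls in c("exon", "intron")) {
    ref <- index[[cls]]
    if (is.null(ref)) next
    lab <- c(exon = "Exon", intron = "Intron")[[cls]]
    if (.in_class(tag, ref$sense)) return(paste0(lab, "_sense"))
    if (.in_class(tag, ref$antisense)) return(paste0(lab, "_antisense"))
  }
  "unann"
}

#' Category breakdown of a tag library
#'
#' Tallies unique tags and redundant reads per annotation category, plus a
#' separate, non-exclusive mapped-to-genome tally (a tag can both map to
#' the genome and belong to, say, the rRNA class, so the mapping row is not
#' part of the exclusive partition).
#'
#' @param lib A `tag_library`.
#' @param index An `annotation_index`.
#' @param known_hits Character vector of tag sequences that matched the
#'   known-miRNA reference (default none).
#' @param genome Optional named character vector of contig sequences; when
#'   supplied, the mapped-to-genome tally is computed by exact occurrence
#'   on either strand.
#' @return A list with `table` (data frame: category, unique, unique_pct,
#'   redundant, redundant_pct), `mapped` (unique/redundant counts or `NA`),
#'   and per-tag `category` vector aligned with `lib$tags`.
#' @export
category_breakdown <- function(lib, index, known_hits = character(0),
                               genome = NULL) {
  tags <- lib$tags
  cat_vec <- vapply(
    seq_len(nrow(tags)),
    function(i) classify_tag(tags$sequence[i], index,
                             tags$sequence[i] %in% known_hits),
    character(1)
  )
  cats <- factor(cat_vec, levels = ANNOTATION_PRIORITY)
  uniq <- as.integer(table(cats))
  red <- as.integer(tapply(tags$count, cats, sum, default = 0L))
  tab <- data.frame(
    category = ANNOTATION_PRIORITY,
    unique = uniq,
    unique_pct = round(100 * uniq / nrow(tags), 2),
    redundant = red,
    redundant_pct = round(100 * red / lib$total_redundant, 2),
    stringsAsFactors = FALSE
  )
  mapped <- c(unique = NA_integer_, redundant = NA_integer_)
  if (!is.null(genome)) {
    hit <- vapply(tags$sequence, function(s) {
      nrow(map_exact(s, genome)) > 0
    }, logical(1), USE.NAMES = FALSE)
    mapped <- c(unique = sum(hit), redundant = sum(tags$count[hit]))
  }
  list(table = tab, mapped = mapped, category = cat_vec)
}
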