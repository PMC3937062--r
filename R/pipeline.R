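#' Pipeline configuration
#'
#' Collects inputs and thresholds for [run_pipeline()]. Inputs may be
#' in-memory objects (named character vectors / read vectors) or file
#' paths (FASTA/FASTQ), which are read on demand.
#'
#' @param reads Named list of two read sets (`control`, `treatment`):
#'   character vectors of raw reads, or FASTQ paths.
#' @param genome Named character vector of contigs, or FASTA path.
#' @param contaminants Named list of class reference sequence vectors
#'   (see [build_annotation_index()]), or `NULL`.
#' @param known_reference Named character vector of mature miRNA
#'   reference sequences, or FASTA path, or `NULL` to skip known matching.
#' @param transcripts Named character vector for target prediction, or
#'   `NULL` to skip.
#' @param adapter 3' adapter to trim (`NULL` to skip trimming).
#' @param max_mismatch_known Budget for [match_known()] (default 3).
#' @param max_mismatch_target Budget for [predict_targets()] (default 3).
#' @param fold_threshold Ratio cutoff for [classify_response()].
#' @param criteria A [hairpin_criteria()].
#' @param novel_len Mature length range considered for novel discovery.
#' @param outdir Output directory for report TSVs (`NULL` for no files).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(reads, genome, contaminants = NULL,
                            known_reference = NULL, transcripts = NULL,
                            adapter = NULL, max_mismatch_known = 3L,
                            max_mismatch_target = 3L, fold_threshold = 1.5,
                            criteria = hairpin_criteria(),
                            novel_len = c(20L, 22L), outdir = NULL) {
  stopifnot(all(c("control", "treatment") %in% names(reads)))
  structure(
    list(reads = reads, genome = genome, contaminants = contaminants,
         known_reference = known_reference, transcripts = transcripts,
         adapter = adapter, max_mismatch_known = max_mismatch_known,
         max_mismatch_target = max_mismatch_target,
         fold_threshold = fold_threshold, criteria = criteria,
         novel_len = novel_len, outdir = outdir),
    class = "pipeline_config"
  )
}

.load_reads <- function(x, format = "fastq") {
  if (length(x) == 1 && file.exists(x)) unname(read_sequences(x, format))
  else chartr("U", "T", toupper(x))
}

.load_fasta <- function(x) {
  if (is.character(x) && length(x) == 1 && is.null(names(x)) &&
      file.exists(x)) read_sequences(x, "fasta") else x
}

#' Run the small-RNA analysis pipeline end to end
#'
#' Stages, in order: adapter trimming; length/polyA filtering and tag
#' collapsing per library; library profiling (size distribution,
#' first-nucleotide bias); annotation-based classification; known-miRNA
#' matching; novel hairpin discovery on unannotated tags; reads-per-million
#' normalization and five-way response classification; optional target
#' prediction for novel matures. Identical inputs and configuration give
#' identical outputs. When `outdir` is set, Table-1/2/3-shaped TSVs and a
#' GFF3 of novel precursors are written there.
#'
#' @param config A [pipeline_config()].
#' @return A list of stage outputs: `libs`, `profiles`, `breakdown`,
#'   `known`, `novel`, `mirna_table`, `summary`, `targets`, `tally`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  genome <- .load_fasta(config$genome)
  if (is.null(genome) || !length(genome)) stop("stage config: no genome")
  tally <- list()

  # preprocess
  libs <- lapply(c(control = "control", treatment = "treatment"), function(cond) {
    reads <- .load_reads(config$reads[[cond]])
    tally[[paste0("raw_", cond)]] <<- length(reads)
    if (!is.null(config$adapter)) reads <- trim_adapter(reads, config$adapter)
    filter_and_collapse(reads, label = cond)
  })
  profiles <- lapply(libs, function(l) {
    list(size = size_distribution(l, "redundant"),
         first_nt = first_nt_bias(l, "unique"))
  })

  # annotate (pooled unique tags)
  all_tags <- sort(unique(c(libs$control$tags$sequence,
                            libs$treatment$tags$sequence)))
  known_ref <- config$known_reference
  known_match <- list()
  if (!is.null(known_ref)) {
    known_ref <- .load_fasta(known_ref)
    for (tag in all_tags) {
      m <- match_known(tag, known_ref, config$max_mismatch_known)
      if (!is.null(m)) known_match[[tag]] <- m
    }
  }
  idx <- build_annotation_index(
    if (is.null(config$contaminants)) list() else config$contaminants
  )
  category <- vapply(all_tags, function(tag) {
    classify_tag(tag, idx, known_mirna_hit = tag %in% names(known_match))
  }, character(1))
  breakdown <- lapply(libs, function(l) {
    category_breakdown(l, idx, known_hits = names(known_match))
  })

  # known-miRNA table: attribute each matched tag to its best reference,
  # summing raw counts per reference per library
  known_tab <- NULL
  if (length(known_match)) {
    ref_of <- vapply(known_match, `[[`, character(1), "reference")
    cnt <- function(lib, tags) {
      v <- lib$tags$count[match(tags, lib$tags$sequence)]
      sum(v, na.rm = TRUE)
    }
    refs <- sort(unique(ref_of))
    known_tab <- do.call(rbind, lapply(refs, function(rf) {
      tg <- names(ref_of)[ref_of == rf]
      data.frame(
        mirna_id = rf, sequence = known_ref[[rf]],
        raw_control = cnt(libs$control, tg),
        raw_treatment = cnt(libs$treatment, tg),
        stringsAsFactors = FALSE
      )
    }))
  }

  # novel discovery on unannotated tags of mature length
  unann <- all_tags[category == "unann"]
  unann <- unann[nchar(unann) >= config$novel_len[1] &
                   nchar(unann) <= config$novel_len[2]]
  novel <- discover_novel(unann, genome, libs, config$criteria)
  tally$unannotated <- length(unann)
  tally$novel_candidates <- nrow(novel)

  # differential classification over known + novel matures
  nc <- function(raw, lib) normalize_counts(raw, lib$total_redundant)
  mirna_table <- NULL
  if (!is.null(known_tab)) {
    mirna_table <- data.frame(
      mirna_id = known_tab$mirna_id, sequence = known_tab$sequence,
      nc_control = nc(known_tab$raw_control, libs$control),
      nc_treatment = nc(known_tab$raw_treatment, libs$treatment),
      origin = "known", stringsAsFactors = FALSE
    )
  }
  if (nrow(novel)) {
    novel_tab <- data.frame(
      mirna_id = paste0("Vvi-", novel$id), sequence = novel$sequence,
      nc_control = nc(novel$count_control, libs$control),
      nc_treatment = nc(novel$count_treatment, libs$treatment),
      origin = "novel", stringsAsFactors = FALSE
    )
    mirna_table <- rbind(mirna_table, novel_tab)
  }
  summary <- NULL
  if (!is.null(mirna_table)) {
    mirna_table <- mark_responses(mirna_table, config$fold_threshold)
    summary <- table(factor(mirna_table$response,
                            levels = names(RESPONSE_GLYPHS)),
                     mirna_table$origin)
  }

  # targets for novel matures
  targets <- NULL
  if (!is.null(config$transcripts) && nrow(novel)) {
    targets <- do.call(rbind, lapply(seq_len(nrow(novel)), function(i) {
      ts <- predict_targets(novel$sequence[i], config$transcripts,
                            config$max_mismatch_target)
      if (nrow(ts)) cbind(mirna_id = paste0("Vvi-", novel$id[i]), ts)
      else NULL
    }))
  }

  tally$tags_total <- length(all_tags)
  tally$tags_known <- length(known_match)

  out <- list(libs = libs, profiles = profiles, breakdown = breakdown,
              known = known_tab, novel = novel, mirna_table = mirna_table,
              summary = summary, targets = targets, tally = tally,
              category = category)
  if (!is.null(config$outdir)) .write_reports(out, config$outdir)
  out
}

.write_reports <- function(out, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, fn) {
    utils::write.table(df, file.path(outdir, fn), sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  for (cond in names(out$breakdown)) {
    wt(out$breakdown[[cond]]$table, paste0("category_breakdown_", cond, ".tsv"))
  }
  if (!is.null(out$mirna_table)) {
    rep_tab <- out$mirna_table
    rep_tab$nc_control <- format_nc(rep_tab$nc_control)
    rep_tab$nc_treatment <- format_nc(rep_tab$nc_treatment)
    wt(rep_tab, "mirna_response_table.tsv")
  }
  if (!is.null(out$novel) && nrow(out$novel)) {
    wt(out$novel, "novel_candidates.tsv")
    write_gff3(out$novel, file.path(outdir, "novel_candidates.gff3"))
  }
  if (!is.null(out$targets)) wt(out$targets, "target_sites.tsv")
  invisible(outdir)
}
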