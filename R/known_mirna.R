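#' Match a tag against a known mature miRNA reference
#'
#' Ungapped matching under a mismatch budget. For every reference and
#' every offset with absolute shift at most `max_shift`, the cost is the
#' number of mismatches inside the overlap plus the unaligned overhang of
#' the shorter sequence (so a 2-nt-shifted isomiR of equal length costs 2
#' even with a perfect overlap). The best hit with cost at most
#' `max_mismatch` is returned; ties break by lower cost, then smaller
#' absolute offset, then lexicographically smallest reference identifier.
#' N never matches anything.
#'
#' @param tag Tag residues (DNA alphabet).
#' @param reference Named character vector of mature reference sequences.
#' @param max_mismatch Cost budget (default 3, the conserved-miRNA rule).
#' @param max_shift Maximum |offset| of tag start relative to reference
#'   start (default 4).
#' @return A list `(reference, mismatches, offset)` or `NULL` when no
#'   reference is within budget.
#' @export
match_known <- function(tag, reference, max_mismatch = 3L, max_shift = 4L) {
  if (length(reference) == 0) return(NULL)
  best <- NULL
  tb <- strsplit(tag, "")[[1]]
  lt <- length(tb)
  ord <- order(names(reference))
  for (k in ord) {
    ref <- reference[[k]]
    rb <- strsplit(ref, "")[[1]]
    lr <- length(rb)
    for (off in seq(-max_shift, max_shift)) {
      # tag occupies [off, off+lt) in reference coordinates [0, lr)
      lo <- max(off, 0L)
      hi <- min(off + lt, lr)
      if (hi <= lo) next
      ov <- hi - lo
      ti <- (lo - off + 1L):(hi - off)
      ri <- (lo + 1L):hi
      mm <- sum(tb[ti] != rb[ri] | tb[ti] == "N" | rb[ri] == "N")
      cost <- mm + (min(lt, lr) - ov)
      if (cost > max_mismatch) next
      cand <- list(reference = names(reference)[k],
                   mismatches = cost, offset = off)
      if (is.null(best) ||
          cost < best$mismatches ||
          (cost == best$mismatches && abs(off) < abs(best$offset))) {
        best <- cand
      }
    }
  }
  best
}

#' Parse a miRNA identifier into its family
#'
#' Known identifiers such as `Vvi-miR156a` or `vv-miR408` map to family
#' `miR156` / `miR408`; novel identifiers such as `Vvi-miRC20*` map to
#' family `C20`. A trailing `*` marks the star (passenger) strand and is
#' recorded, not part of the family.
#'
#' @param identifier Character vector of miRNA identifiers.
#' @return Data frame with columns `identifier`, `family`, `star`.
#' @export
assign_family <- function(identifier) {
  pat <- "^[Vv]vi?-miR(C?)([0-9]+)([a-z]?)(\\*?)$"
  ok <- grepl(pat, identifier)
  if (any(!ok)) {
    stop("unparsable miRNA identifier: ",
         paste(identifier[!ok], collapse = ", "))
  }
  novel <- sub(pat, "\\1", identifier) == "C"
  num <- sub(pat, "\\2", identifier)
  fam <- ifelse(novel, paste0("C", num), paste0("miR", num))
  data.frame(
    identifier = identifier,
    family = fam,
    star = sub(pat, "\\4", identifier) == "*",
    stringsAsFactors = FALSE
  )
}

#' Per-family member counts and normalized-count sums
#'
#' Members are distinct non-star identifiers; star records contribute to
#' neither the member count nor the NC sums (they are passenger-strand
#' evidence, not family members).
#'
#' @param records Data frame with columns `mirna_id`, `nc_control`,
#'   `nc_treatment` (a Table-2/3-shaped table as read by
#'   [read_mirna_table()]).
#' @return Data frame: `family`, `members`, `nc_control`, `nc_treatment`.
#' @export
family_summary <- function(records) {
  if (nrow(records) == 0) {
    return(data.frame(family = character(0), members = integer(0),
                      nc_control = numeric(0), nc_treatment = numeric(0)))
  }
  fam <- assign_family(records$mirna_id)
  mat <- records[!fam$star, , drop = FALSE]
  famm <- fam$family[!fam$star]
  out <- data.frame(
    family = sort(unique(famm)),
    stringsAsFactors = FALSE
  )
  out$members <- as.integer(table(famm)[out$family])
  out$nc_control <- as.numeric(tapply(mat$nc_control, famm, sum)[out$family])
  out$nc_treatment <- as.numeric(tapply(mat$nc_treatment, famm, sum)[out$family])
  rownames(out) <- NULL
  out
}

#' Read a Table-2/3-shaped miRNA TSV
#'
#' The dialect used by the packaged fixtures and all report emission:
#' columns `mirna_id`, `sequence`, `nc_control`, `nc_treatment` and
#' optionally `mark`.
#'
#' @param path TSV path.
#' @return Data frame with numeric NC columns.
#' @export
read_mirna_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          encoding = "UTF-8", check.names = FALSE)
  need <- c("mirna_id", "sequence", "nc_control", "nc_treatment")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df$nc_control <- as.numeric(df$nc_control)
  df$nc_treatment <- as.numeric(df$nc_treatment)
  df
}

#' Path to a packaged fixture table
#'
#' @param which `"known"` (conserved miRNAs) or `"novel"` (novel
#'   candidates with star rows).
#' @return File path inside the installed package.
#' @export
mirna_fixture <- function(which = c("known", "novel")) {
  which <- match.arg(which)
  fn <- c(known = "table2_known_mirnas.tsv", novel = "table3_novel_mirnas.tsv")
  system.file("extdata", fn[[which]], package = "miRvine", mustWork = TRUE)
}
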