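#' Normalize a raw count to reads-per-million (NC)
#'
#' @param raw Raw read count(s).
#' @param library_total Total redundant reads of the library.
#' @return Normalized count(s), full precision (use [format_nc()] for the
#'   2-decimal report form).
#' @export
normalize_counts <- function(raw, library_total) {
  if (length(library_total) != 1 || library_total <= 0) {
    stop("library_total must be a single positive integer")
  }
  if (any(raw < 0)) stop("negative raw count")
  raw / library_total * 1e6
}

#' Format an NC value the way the report tables print it
#' @param nc Numeric NC value(s).
#' @return Character, two decimals.
#' @export
format_nc <- function(nc) sprintf("%.2f", nc)

#' Response class glyphs used in report tables
#'
#' up, down, treatment_only, control_only, unchanged.
#' @export
RESPONSE_GLYPHS <- c(up = "↑", down = "↓",
                     treatment_only = "▲", control_only = "▼",
                     unchanged = "●")

#' Classify a miRNA's response from its two normalized counts
#'
#' Presence/absence rules come first and are threshold-free: detected only
#' in the treatment is `treatment_only`, only in the control is
#' `control_only`, in neither is `unchanged`. When both are positive, the
#' fold ratio (treatment/control) decides: at least `fold_threshold` is
#' `up`, at most `1/fold_threshold` is `down`, anything between is
#' `unchanged`.
#'
#' @param nc_control,nc_treatment Normalized counts (vectors recycle).
#' @param fold_threshold Ratio cutoff, > 1 (default 1.5).
#' @return Character vector of classes; `fold_change` attribute carries
#'   the ratio (NA where either NC is zero).
#' @examples
#' classify_response(8.81, 513.79)  # "up"
#' classify_response(22.08, 0)      # "control_only"
#' @export
classify_response <- function(nc_control, nc_treatment, fold_threshold = 1.5) {
  if (fold_threshold <= 1) stop("fold_threshold must exceed 1")
  if (any(nc_control < 0) || any(nc_treatment < 0)) stop("negative NC")
  n <- max(length(nc_control), length(nc_treatment))
  nc_control <- rep_len(nc_control, n)
  nc_treatment <- rep_len(nc_treatment, n)
  ratio <- ifelse(nc_control > 0 & nc_treatment > 0,
                  nc_treatment / nc_control, NA_real_)
  cls <- ifelse(
    nc_control == 0 & nc_treatment > 0, "treatment_only",
    ifelse(nc_treatment == 0 & nc_control > 0, "control_only",
      ifelse(nc_control == 0 & nc_treatment == 0, "unchanged",
        ifelse(ratio >= fold_threshold, "up",
          ifelse(ratio <= 1 / fold_threshold, "down", "unchanged")))))
  attr(cls, "fold_change") <- ratio
  cls
}

#' Summarize response calls by class and origin
#'
#' @param records Data frame with columns `mirna_id`, `nc_control`,
#'   `nc_treatment` and optionally `origin` (`known`/`novel`; inferred
#'   from the identifier when absent). Star records (trailing `*`) are
#'   counted separately from mature records.
#' @param fold_threshold Passed to [classify_response()].
#' @return List with `calls` (per-record class vector), `mature` and
#'   `star` count tables (class x origin).
#' @export
summarize_responses <- function(records, fold_threshold = 1.5) {
  fam <- assign_family(records$mirna_id)
  origin <- if ("origin" %in% names(records)) records$origin else
    ifelse(grepl("^C", fam$family), "novel", "known")
  cls <- classify_response(records$nc_control, records$nc_treatment,
                           fold_threshold)
  lv <- names(RESPONSE_GLYPHS)
  tab <- function(sel) {
    table(factor(cls[sel], levels = lv),
          factor(origin[sel], levels = c("known", "novel")))
  }
  list(calls = cls,
       mature = tab(!fam$star),
       star = tab(fam$star))
}

#' Attach response classes and glyph marks to a miRNA table
#'
#' @inheritParams summarize_responses
#' @return The input data frame with `response` and `mark` columns added.
#' @export
mark_responses <- function(records, fold_threshold = 1.5) {
  cls <- classify_response(records$nc_control, records$nc_treatment,
                           fold_threshold)
  records$response <- as.character(cls)
  records$mark <- unname(RESPONSE_GLYPHS[records$response])
  records
}
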