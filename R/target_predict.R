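# Per-position pairing score between a miRNA base (5'->3') and the
# transcript base it faces: 0 for Watson-Crick, 0.5 for a G:U wobble,
# 1 for a mismatch. The miRNA pairs the transcript antisense, so position
# i of the miRNA faces transcript base (site_end - i + 1); comparing the
# miRNA against the reverse complement of the site makes this a direct
# positional comparison.
.position_scores <- function(mirna_b, site_rc_b) {
  n <- length(mirna_b)
  sc <- numeric(n)
  for (i in seq_len(n)) {
    a <- mirna_b[i]; b <- site_rc_b[i]
    if (a == b && a != "N") next
    # wobble: miRNA G facing transcript U (revcomp shows A here? no -)
    # In revcomp space a WC pair shows as equality; a G:U pair shows as
    # miRNA G vs revcomp A (transcript T) or miRNA T vs revcomp C
    # (transcript G).
    if ((a == "G" && b == "A") || (a == "T" && b == "C")) {
      sc[i] <- 0.5
    } else {
      sc[i] <- 1
    }
  }
  sc
}

#' Predict miRNA target sites on a transcript set
#'
#' Exhaustive ungapped scan: every transcript window of miRNA length is
#' scored against the miRNA by complementarity, with G:U wobbles counting
#' 0.5 toward the mismatch budget. Positional rules in the style of the
#' classical plant-miRNA target criteria are applied by default: no
#' mismatch opposite miRNA positions 10-11 (the cleavage site) and at most
#' one mismatch within positions 2-12 (the seed-proximal region); each
#' rule can be switched off.
#'
#' @param mirna Mature miRNA residues (DNA alphabet; 5' to 3').
#' @param transcripts Named character vector of transcript sequences.
#' @param max_mismatch Total score budget (default 3).
#' @param rule_cleavage_site Require perfect pairing at positions 10-11.
#' @param rule_seed Allow at most one full mismatch in positions 2-12.
#' @return Data frame: `transcript`, `start`, `end` (1-based, inclusive,
#'   transcript coordinates), `mismatches` (the score), `alignment`
#'   (miRNA over the reverse-complemented site).
#' @export
predict_targets <- function(mirna, transcripts, max_mismatch = 3,
                            rule_cleavage_site = TRUE, rule_seed = TRUE) {
  mb <- strsplit(mirna, "")[[1]]
  k <- length(mb)
  out <- list()
  for (tx in names(transcripts)) {
    s <- transcripts[[tx]]
    n <- nchar(s)
    if (n < k) next
    # reverse complement of every window, vectorized via the whole-seq rc
    rcs <- reverse_complement(s)
    for (st in seq_len(n - k + 1L)) {
      # window [st, st+k-1]; its revcomp is rcs[n-st-k+2 .. n-st+1]
      rb <- strsplit(substr(rcs, n - st - k + 2L, n - st + 1L), "")[[1]]
      sc <- .position_scores(mb, rb)
      if (sum(sc) > max_mismatch) next
      if (rule_cleavage_site && k >= 11 && any(sc[10:11] > 0)) next
      if (rule_seed && k >= 12 && sum(sc[2:12] == 1) > 1) next
      out[[length(out) + 1L]] <- data.frame(
        transcript = tx, start = st, end = st + k - 1L,
        mismatches = sum(sc),
        alignment = paste0(mirna, "/", paste(rb, collapse = "")),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(transcript = character(0), start = integer(0),
                      end = integer(0), mismatches = numeric(0),
                      alignment = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Validate a predicted cleavage site against a RACE observation
#'
#' The observed cleavage coordinate is the 5' end of the downstream RACE
#' fragment (1-based transcript coordinate). The miRNA position pairing
#' that base is `site_end - coordinate + 1` (counting 1 from the miRNA 5'
#' end); canonical slicing places it at position 9, 10 or 11.
#'
#' @param site One-row data frame from [predict_targets()] (`transcript`,
#'   `start`, `end`).
#' @param obs List or one-row data frame with `transcript` and
#'   `coordinate` (and optionally `clones`).
#' @return List with `status` (`"supported"`/`"unsupported"`) and
#'   `position` (miRNA position index, `NA` when the cleavage falls
#'   outside the site).
#' @export
validate_cleavage <- function(site, obs) {
  if (!identical(as.character(site$transcript), as.character(obs$transcript))) {
    stop("cleavage observation is on a different transcript")
  }
  co <- as.integer(obs$coordinate)
  if (co < site$start || co > site$end) {
    return(list(status = "unsupported", position = NA_integer_))
  }
  pos <- site$end - co + 1L
  list(status = if (pos %in% 9:11) "supported" else "unsupported",
       position = pos)
}
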