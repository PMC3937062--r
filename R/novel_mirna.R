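#' Exact genome mapping of a tag
#'
#' All exact occurrences of the tag on both strands of the genome;
#' minus-strand hits are found via the reverse complement and reported in
#' forward-strand coordinates (1-based, inclusive).
#'
#' @param tag Tag residues.
#' @param genome Named character vector of contig sequences.
#' @return Data frame with columns `contig`, `start`, `end`, `strand`
#'   (zero rows when the tag does not map).
#' @export
map_exact <- function(tag, genome) {
  out <- list()
  rc <- reverse_complement(tag)
  for (ctg in names(genome)) {
    subj <- Biostrings::DNAString(genome[[ctg]])
    for (str in c("+", "-")) {
      pat <- if (str == "+") tag else rc
      m <- Biostrings::matchPattern(pat, subj)
      if (length(m)) {
        out[[length(out) + 1L]] <- data.frame(
          contig = ctg,
          start = Biostrings::start(m),
          end = Biostrings::end(m),
          strand = str,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract candidate precursor windows around a mapped tag
#'
#' Two windows are returned so that a hairpin on either side of the mature
#' can be captured: one extends mostly upstream of the locus, the other
#' mostly downstream. Windows are clamped at contig edges, and
#' minus-strand loci are reverse-complemented so the mature always reads
#' 5' to 3' within the returned window.
#'
#' @param locus One-row data frame (`contig`, `start`, `end`, `strand`)
#'   as returned by [map_exact()].
#' @param genome Named character vector of contig sequences.
#' @param flank Long-side extension in nt (default 150).
#' @param pad Short-side extension in nt (default 20).
#' @return List of two windows, each a list with `seq`, `mature_start`,
#'   `mature_end` (window coordinates), and `genomic_start`,
#'   `genomic_end`, `contig`, `strand` of the window itself.
#' @export
extract_windows <- function(locus, genome, flank = 150L, pad = 20L) {
  ctg <- genome[[locus$contig]]
  if (is.null(ctg)) stop("unknown contig: ", locus$contig)
  clen <- nchar(ctg)
  if (locus$start < 1L || locus$end > clen) stop("locus outside contig")
  spans <- list(
    c(max(1L, locus$start - flank), min(clen, locus$end + pad)),
    c(max(1L, locus$start - pad), min(clen, locus$end + flank))
  )
  lapply(spans, function(sp) {
    ws <- sp[1]; we <- sp[2]
    s <- substr(ctg, ws, we)
    if (locus$strand == "-") {
      s <- reverse_complement(s)
      ms <- we - locus$end + 1L
    } else {
      ms <- locus$start - ws + 1L
    }
    list(seq = s,
         mature_start = ms,
         mature_end = ms + (locus$end - locus$start),
         genomic_start = ws, genomic_end = we,
         contig = locus$contig, strand = locus$strand)
  })
}

#' Fold a sequence by maximum base pairing
#'
#' Nussinov-style dynamic program maximizing the number of base pairs
#' under Watson-Crick + G:U wobble pairing, with no pseudoknots and a
#' minimum hairpin loop. The traceback is deterministic: within any
#' interval the leftmost base is paired with the smallest admissible
#' partner. This is a structure-counting objective, not a free-energy
#' minimization; an energy-based backend could be plugged in behind the
#' same contract.
#'
#' @param seq Residues (DNA alphabet; U is accepted and normalized).
#' @param min_loop Minimum unpaired span enclosed by a pair (default 3).
#' @return A `secondary_structure`: list with `dotbracket`, `pairs`
#'   (two-column matrix of 1-based positions, i < j), and `n_pairs`.
#' @examples
#' fold("GGGAAACCC")$n_pairs  # 3
#' @export
fold <- function(seq, min_loop = 3L) {
  seq <- chartr("U", "T", toupper(seq))
  n <- nchar(seq)
  if (n < min_loop + 2L) stop("sequence too short to fold (", n, " nt)")
  res <- .nussinov_fold(seq, as.integer(min_loop))
  pairs <- cbind(i = res$pair_i + 1L, j = res$pair_j + 1L)
  structure(
    list(dotbracket = res$dotbracket, pairs = pairs, n_pairs = res$n_pairs),
    class = "secondary_structure"
  )
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(x$dotbracket, "\n", x$n_pairs, " base pairs\n", sep = "")
  invisible(x)
}

#' Hairpin acceptance criteria
#'
#' Operational thresholds for calling a candidate precursor a miRNA
#' hairpin, in the spirit of the community criteria for plant miRNA
#' annotation: the mature must sit on a single arm of the foldback, be
#' nearly fully paired to the opposite arm, and the duplex must be free of
#' large bulges; the star is predicted with the canonical 2-nt 3'
#' overhangs.
#'
#' @param max_mismatches_in_duplex Maximum unpaired mature bases (default 4).
#' @param max_bulge Maximum bulge/asymmetry in the duplex, nt (default 3).
#' @param min_paired_mature Minimum paired mature bases (default 16).
#' @param star_overhang 3' overhang of the duplex, fixed at 2 nt.
#' @param flank_window Flank used when extracting windows (default 150).
#' @param min_precursor_len,max_precursor_len Precursor length range
#'   (default 50-300 nt).
#' @param min_loop Minimum hairpin loop passed to [fold()] (default 3).
#' @return A named list of class `hairpin_criteria`.
#' @export
hairpin_criteria <- function(max_mismatches_in_duplex = 4L, max_bulge = 3L,
                             min_paired_mature = 16L, star_overhang = 2L,
                             flank_window = 150L, min_precursor_len = 50L,
                             max_precursor_len = 300L, min_loop = 3L) {
  stopifnot(star_overhang == 2L, max_mismatches_in_duplex > 0,
            max_bulge > 0, min_paired_mature > 0)
  structure(
    list(max_mismatches_in_duplex = max_mismatches_in_duplex,
         max_bulge = max_bulge, min_paired_mature = min_paired_mature,
         star_overhang = star_overhang, flank_window = flank_window,
         min_precursor_len = min_precursor_len,
         max_precursor_len = max_precursor_len, min_loop = min_loop),
    class = "hairpin_criteria"
  )
}

#' Evaluate a candidate precursor window as a miRNA hairpin
#'
#' Accepts iff (a) the mature lies entirely on one arm (every paired
#' mature base points to the same side, none pairs within the mature
#' itself); (b) at least `min_paired_mature` mature bases are paired;
#' (c) at most `max_mismatches_in_duplex` mature bases are unpaired and no
#' bulge (run of unpaired mature bases, or asymmetric jump on the star
#' side) exceeds `max_bulge`; (d) the star is the opposite-arm region
#' pairing the mature, shifted to give the canonical 2-nt 3' overhangs.
#'
#' @param window Window residues.
#' @param mature Mature residues (must occur in `window`).
#' @param structure A `secondary_structure` folded from `window`.
#' @param criteria A [hairpin_criteria()].
#' @return A `hairpin_candidate` list (`window`, `mature`,
#'   `mature_start`, `mature_end`, `arm`, `star`, `star_start`,
#'   `star_end`, `n_paired`, `five_prime_U`) or `NULL` when rejected.
#' @export
evaluate_hairpin <- function(window, mature, structure,
                             criteria = hairpin_criteria()) {
  m1 <- as.integer(regexpr(mature, window, fixed = TRUE))
  if (m1 < 0) stop("mature does not occur in window")
  m2 <- m1 + nchar(mature) - 1L
  n <- nchar(window)
  partner <- rep(NA_integer_, n)
  if (nrow(structure$pairs)) {
    partner[structure$pairs[, 1]] <- structure$pairs[, 2]
    partner[structure$pairs[, 2]] <- structure$pairs[, 1]
  }
  mpos <- m1:m2
  mp <- partner[mpos]
  # a mature base pairing within the mature itself means the mature spans
  # the terminal loop: immediate rejection
  if (any(!is.na(mp) & mp >= m1 & mp <= m2)) return(NULL)
  # The duplex is the longest chain of paired mature bases whose partners
  # lie on one side, run antiparallel, and whose mature-side gaps and
  # star-side jumps stay within the bulge limit. Pairs outside the chain
  # (e.g. a loop-proximal base captured by the maximum-pairing objective)
  # count as mismatches, as do unpaired bases.
  pp <- mpos[!is.na(mp)]
  best <- integer(0)
  chain <- integer(0)
  flush <- function() if (length(chain) > length(best)) best <<- chain
  for (q in pp) {
    if (length(chain) == 0L) { chain <- q; next }
    p <- chain[length(chain)]
    dm <- q - p
    ds <- partner[p] - partner[q]  # antiparallel: partner must decrease
    same_side <- sign(partner[q] - m1) == sign(partner[p] - m1)
    if (same_side && ds > 0 && dm - 1L <= criteria$max_bulge &&
        abs(ds - dm) <= criteria$max_bulge) {
      chain <- c(chain, q)
    } else {
      flush(); chain <- q
    }
  }
  flush()
  n_paired <- length(best)
  if (n_paired < criteria$min_paired_mature) return(NULL)
  if (length(mpos) - n_paired > criteria$max_mismatches_in_duplex) return(NULL)
  # unpaired-gap check inside the chain is already enforced (dm - 1), but
  # bases outside the chain at the mature ends also form bulges
  if (best[1] - m1 > criteria$max_bulge) return(NULL)
  if (m2 - best[length(best)] > criteria$max_bulge) return(NULL)
  pp <- best
  arm <- if (partner[pp[1]] > m2) "5p" else "3p"
  # (d) predicted star: anchored at the loop-distal mature end (its
  # partner projection is robust; the loop-proximal register can be
  # perturbed by extra pairs the maximum-pairing objective squeezes into
  # the terminal loop), length = mature length, shifted +2 toward the
  # star's 3' direction (higher window coordinates on either arm)
  pfirst <- pp[1]; plast <- pp[length(pp)]
  L <- length(mpos)
  if (arm == "5p") {
    proj1 <- partner[pfirst] + (pfirst - m1)  # partner of mature 5' end
    se <- proj1 + criteria$star_overhang
    ss <- se - L + 1L
  } else {
    proj2 <- partner[plast] - (m2 - plast)    # partner of mature 3' end
    ss <- proj2 + criteria$star_overhang
    se <- ss + L - 1L
  }
  ss <- max(1L, ss); se <- min(n, se)
  if (se <= ss) return(NULL)
  structure(
    list(window = window, mature = mature,
         mature_start = m1, mature_end = m2, arm = arm,
         star = substr(window, ss, se), star_start = ss, star_end = se,
         n_paired = n_paired,
         five_prime_U = substr(mature, 1L, 1L) == "T"),
    class = "hairpin_candidate"
  )
}

#' Detect the predicted miRNA* among sequenced tags
#'
#' Looks for a library tag equal to the predicted star allowing end shifts
#' of up to `tolerance` nt on either end (sequenced stars, like matures,
#' have ragged ends).
#'
#' @param candidate A `hairpin_candidate`.
#' @param lib A `tag_library`.
#' @param tolerance Maximum end shift in nt (default 2).
#' @return List with `sequence` and `count` of the most abundant matching
#'   tag, or `NULL` when no star-like tag was sequenced.
#' @export
detect_star <- function(candidate, lib, tolerance = 2L) {
  n <- nchar(candidate$window)
  starts <- max(1L, candidate$star_start - tolerance):
    min(n, candidate$star_start + tolerance)
  ends <- max(1L, candidate$star_end - tolerance):
    min(n, candidate$star_end + tolerance)
  cand_seqs <- unique(unlist(lapply(starts, function(s) {
    vapply(ends[ends > s], function(e) substr(candidate$window, s, e),
           character(1))
  })))
  hit <- lib$tags[lib$tags$sequence %in% cand_seqs, , drop = FALSE]
  if (nrow(hit) == 0) return(NULL)
  best <- hit[which.max(hit$count), ]
  list(sequence = best$sequence, count = best$count)
}

# Precursor boundary refinement: a max-pairing fold of a long window can
# pair mature bases with distant background instead of the star, so the
# hairpin is searched over sub-windows anchored at the mature, smallest
# first, and the first acceptable one wins.
.scan_precursor <- function(window, criteria) {
  n <- nchar(window$seq)
  ms <- window$mature_start; me <- window$mature_end
  mature <- substr(window$seq, ms, me)
  # the long side must cover loop + star + overhang for the tightest
  # plausible hairpin (loop <= 12: 21 + 12 + 2), hence the 40-nt floor
  short <- c(5L, 15L)
  long <- seq(40L, max(41L, criteria$flank_window), by = 15L)
  trials <- rbind(
    expand.grid(a = short, b = long),   # hairpin downstream (5p mature)
    expand.grid(a = long, b = short)    # hairpin upstream (3p mature)
  )
  for (t in seq_len(nrow(trials))) {
    a <- trials$a[t]; b <- trials$b[t]
    s <- max(1L, ms - a); e <- min(n, me + b)
    plen <- e - s + 1L
    if (plen < criteria$min_precursor_len ||
        plen > criteria$max_precursor_len) next
    sub <- substr(window$seq, s, e)
    st <- fold(sub, criteria$min_loop)
    cand <- evaluate_hairpin(sub, mature, st, criteria)
    if (!is.null(cand)) {
      cand$offset_in_window <- s   # window coordinate of precursor start
      return(cand)
    }
  }
  NULL
}

#' Discover novel miRNA candidates from unannotated tags
#'
#' For each candidate tag: exact genome mapping, precursor-window
#' extraction at every locus, maximum-pairing folding with boundary
#' refinement, hairpin evaluation, and star detection against the pooled
#' tag libraries. Each distinct locus of a multi-locus tag yields its own
#' candidate (abundance is shared, not multiplied).
#'
#' @param tags Character vector of tag sequences to consider (typically
#'   the unannotated tags of suitable mature length).
#' @param genome Named character vector of contig sequences.
#' @param libs Named list of `tag_library` objects (e.g. control,
#'   treatment) used for star detection and per-library counts.
#' @param criteria A [hairpin_criteria()].
#' @param star_tolerance End-shift tolerance for [detect_star()].
#' @param max_loci Tags mapping to more loci than this are skipped as
#'   repeat-derived (default 5).
#' @return Data frame, one row per accepted candidate: `id`, `sequence`,
#'   `contig`, `start`, `end`, `strand` (precursor genomic coordinates),
#'   `mature_start`, `mature_end`, `arm`, `star_start`, `star_end`,
#'   `star_seq`, `star_detected`, `five_prime_U`, `n_loci`, plus
#'   `count_<lib>` and `star_count_<lib>` per library.
#' @export
discover_novel <- function(tags, genome, libs, criteria = hairpin_criteria(),
                           star_tolerance = 2L, max_loci = 5L) {
  rows <- list()
  for (tag in tags) {
    loci <- map_exact(tag, genome)
    if (nrow(loci) == 0 || nrow(loci) > max_loci) next
    for (li in seq_len(nrow(loci))) {
      windows <- extract_windows(loci[li, ], genome,
                                 flank = criteria$flank_window)
      cand <- NULL
      for (w in windows) {
        cand <- .scan_precursor(w, criteria)
        if (!is.null(cand)) { win <- w; break }
      }
      if (is.null(cand)) next
      # precursor genomic coordinates from oriented window offsets
      plen <- nchar(cand$window)
      if (win$strand == "+") {
        gstart <- win$genomic_start + cand$offset_in_window - 1L
        gend <- gstart + plen - 1L
        mstart <- gstart + cand$mature_start - 1L
        mend <- gstart + cand$mature_end - 1L
        sstart <- gstart + cand$star_start - 1L
        send <- gstart + cand$star_end - 1L
      } else {
        gend <- win$genomic_end - (cand$offset_in_window - 1L)
        gstart <- gend - plen + 1L
        mend <- gend - (cand$mature_start - 1L)
        mstart <- gend - (cand$mature_end - 1L)
        send <- gend - (cand$star_start - 1L)
        sstart <- gend - (cand$star_end - 1L)
      }
      star_hits <- lapply(libs, function(l) detect_star(cand, l, star_tolerance))
      detected <- any(!vapply(star_hits, is.null, logical(1)))
      row <- data.frame(
        sequence = tag, contig = loci$contig[li],
        start = gstart, end = gend, strand = loci$strand[li],
        mature_start = mstart, mature_end = mend, arm = cand$arm,
        star_start = sstart, star_end = send, star_seq = cand$star,
        star_detected = detected, five_prime_U = cand$five_prime_U,
        n_loci = nrow(loci),
        stringsAsFactors = FALSE
      )
      for (nm in names(libs)) {
        tl <- libs[[nm]]$tags
        cnt <- tl$count[match(tag, tl$sequence)]
        row[[paste0("count_", nm)]] <- ifelse(is.na(cnt), 0L, cnt)
        sh <- star_hits[[nm]]
        row[[paste0("star_count_", nm)]] <- if (is.null(sh)) 0L else sh$count
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) {
    return(data.frame(id = character(0), sequence = character(0),
                      contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      star_start = integer(0), star_end = integer(0),
                      mature_start = integer(0), mature_end = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  out <- cbind(id = sprintf("miRC%02d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
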