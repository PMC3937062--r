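#' Specification for a synthetic two-library small-RNA study
#'
#' Describes the toy study the generator emulates: one genome with planted
#' miRNA hairpin loci, contaminant reference classes, and a pair of
#' libraries (control and treatment) whose per-miRNA expression means
#' encode planted response classes, including presence/absence extremes.
#' Defaults reflect a two-condition plant small-RNA design: a 21/24-nt
#' dominated length distribution, a 5'U bias at the mature 5' end, and
#' single libraries per condition (hence Poisson counts, no dispersion).
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param genome_length Background genome length, nt.
#' @param n_hairpins Number of planted miRNA hairpin loci.
#' @param n_contaminants Named integer vector: reference sequences per
#'   contaminant class.
#' @param expression Optional data frame with columns `mean_control`,
#'   `mean_treatment` (one row per hairpin); when `NULL`, means are drawn
#'   in 20-200 with planted up (8x), down (1/8x), treatment-only,
#'   control-only and unchanged classes.
#' @param length_probs Named numeric vector of contaminant-tag length
#'   probabilities over 18-30 nt (default peaked at 21 and 24 with weights
#'   0.38 and 0.32).
#' @param five_prime_U_prob Probability a planted mature starts with U.
#' @param star_fraction Star read mean as a fraction of mature mean.
#' @param error_rate Per-read probability of one substitution error.
#' @param contaminant_mean Mean reads per contaminant reference per
#'   library; the default brings each library to roughly 50,000 reads, so
#'   that miRNA reads are a few percent of the library as in real plant
#'   small-RNA data.
#' @param end_jitter_prob Probability of a 1-nt end shift on a read.
#' @param adapter 3' adapter appended to every emitted read.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(seed = 1L,
                            genome_length = 100000L,
                            n_hairpins = 20L,
                            n_contaminants = c(rRNA = 4L, tRNA = 4L,
                                               snRNA = 2L, snoRNA = 2L),
                            expression = NULL,
                            length_probs = NULL,
                            five_prime_U_prob = 0.6,
                            star_fraction = 0.15,
                            error_rate = 0.01,
                            contaminant_mean = 3800,
                            end_jitter_prob = 0.1,
                            adapter = "TGGAATTCTCGGGTGCCAAGG") {
  if (is.null(length_probs)) {
    lens <- 18:30
    w <- rep(0.3 / 11, 13)
    names(w) <- lens
    w["21"] <- 0.38
    w["24"] <- 0.32
    length_probs <- w / sum(w)
  }
  stopifnot(five_prime_U_prob >= 0, five_prime_U_prob <= 1,
            error_rate >= 0, error_rate <= 1)
  structure(
    list(seed = as.integer(seed), genome_length = genome_length,
         n_hairpins = n_hairpins, n_contaminants = n_contaminants,
         expression = expression, length_probs = length_probs,
         five_prime_U_prob = five_prime_U_prob,
         star_fraction = star_fraction, error_rate = error_rate,
         contaminant_mean = contaminant_mean,
         end_jitter_prob = end_jitter_prob, adapter = adapter),
    class = "simulation_spec"
  )
}

.rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# default planted expression design: a mix of large fold changes (8x),
# presence/absence extremes, and unchanged loci, means in 20-200
.default_expression <- function(n_hairpins) {
  classes <- rep(c("up", "down", "treatment_only", "control_only",
                   "unchanged"), length.out = n_hairpins)
  base <- stats::runif(n_hairpins, 20, 200)
  mc <- mt <- base
  mt[classes == "up"] <- base[classes == "up"] * 8
  mc[classes == "up"] <- base[classes == "up"]
  mc[classes == "down"] <- base[classes == "down"] * 8
  mt[classes == "down"] <- base[classes == "down"]
  mc[classes == "treatment_only"] <- 0
  mt[classes == "control_only"] <- 0
  data.frame(mean_control = mc, mean_treatment = mt,
             true_class = classes, stringsAsFactors = FALSE)
}

#' Generate a toy genome with planted miRNA hairpins and contaminants
#'
#' The genome is random background with `n_hairpins` perfect-stem
#' precursors (mature 21 nt, loop 6-12 nt, star = exact reverse
#' complement) planted at non-overlapping loci. Contaminant class
#' reference sequences (80-200 nt) are generated alongside and also
#' embedded in the genome so contaminant tags are genome-mappable.
#' Deterministic given `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @return List with `genome` (named character vector, one contig),
#'   `contaminants` (named list of class sequence vectors), and `truth`
#'   (data frame of planted loci: `mature`, `star`, `precursor_start`,
#'   `precursor_end`, `mature_start`, `mature_end`, plus expression means
#'   and `true_class`).
#' @export
generate_genome <- function(spec) {
  set.seed(spec$seed)
  g <- .rand_seq(spec$genome_length)
  # plant hairpins at evenly spaced, jittered, non-overlapping offsets
  pre_max <- 21L + 12L + 21L
  slot <- spec$genome_length %/% (spec$n_hairpins + 1L)
  if (slot < pre_max + 100L && spec$n_hairpins > 0) {
    stop("genome too short to host ", spec$n_hairpins,
         " non-overlapping precursors")
  }
  truth <- NULL
  if (spec$n_hairpins > 0) {
    rows <- vector("list", spec$n_hairpins)
    for (i in seq_len(spec$n_hairpins)) {
      mature <- .rand_seq(21L)
      if (stats::runif(1) < spec$five_prime_U_prob) {
        mature <- paste0("T", substr(mature, 2, 21))
      }
      loop <- .rand_seq(sample(6:12, 1))
      prec <- paste0(mature, loop, reverse_complement(mature))
      pos <- i * slot + sample(-20:20, 1)
      g <- paste0(substr(g, 1, pos - 1L), prec,
                  substr(g, pos + nchar(prec), spec$genome_length))
      rows[[i]] <- data.frame(
        id = sprintf("mir%02d", i), mature = mature,
        star = reverse_complement(mature),
        precursor_start = pos, precursor_end = pos + nchar(prec) - 1L,
        mature_start = pos, mature_end = pos + 20L,
        stringsAsFactors = FALSE
      )
    }
    truth <- do.call(rbind, rows)
    expr <- spec$expression
    if (is.null(expr)) expr <- .default_expression(spec$n_hairpins)
    truth <- cbind(truth, expr)
  }
  contaminants <- lapply(spec$n_contaminants, function(k) {
    vapply(seq_len(k), function(i) .rand_seq(sample(80:200, 1)), character(1))
  })
  for (cls in names(contaminants)) {
    names(contaminants[[cls]]) <-
      paste0(cls, "_", seq_along(contaminants[[cls]]))
  }
  # embed contaminants in the genome tail so their tags also map
  genome <- paste0(g, paste(unlist(contaminants), collapse = ""))
  list(genome = c(chr1 = genome), contaminants = contaminants, truth = truth)
}

.mutate_read <- function(read, error_rate) {
  if (stats::runif(1) >= error_rate) return(read)
  p <- sample(nchar(read), 1)
  b <- substr(read, p, p)
  repl <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
  paste0(substr(read, 1, p - 1L), repl, substr(read, p + 1L, nchar(read)))
}

.jitter_read <- function(read, source_seq, at, prob) {
  # shift one end by 1 nt within the source sequence when possible
  if (stats::runif(1) >= prob) return(read)
  n <- nchar(read)
  ns <- nchar(source_seq)
  if (stats::runif(1) < 0.5 && at + n <= ns) {
    substr(source_seq, at + 1L, at + n)       # shift right
  } else if (at > 1L) {
    substr(source_seq, at - 1L, at + n - 2L)  # shift left
  } else {
    read
  }
}

#' Simulate the paired control/treatment read libraries
#'
#' Per condition, per planted miRNA: read counts are Poisson with the
#' planted means; reads are the mature sequence with optional 1-nt end
#' jitter and substitution errors, star reads at `star_fraction` of the
#' mature mean, and contaminant reads drawn as random 18-30-nt substrings
#' of the contaminant references with the 21/24-peaked length
#' distribution. The 3' adapter is appended to every read so trimming is
#' exercised. Deterministic given `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @param sim Output of [generate_genome()].
#' @return List of two character vectors of raw reads (`control`,
#'   `treatment`), each with the adapter appended.
#' @export
simulate_libraries <- function(spec, sim) {
  set.seed(spec$seed + 1L)
  truth <- sim$truth
  out <- list()
  for (cond in c("control", "treatment")) {
    reads <- character(0)
    mcol <- paste0("mean_", cond)
    if (!is.null(truth)) {
      for (i in seq_len(nrow(truth))) {
        k <- stats::rpois(1, truth[[mcol]][i])
        if (k > 0) {
          prec <- paste0(truth$mature[i],
                         substr(sim$genome[[1]],
                                truth$mature_end[i] + 1L,
                                truth$precursor_end[i]))
          rr <- vapply(seq_len(k), function(j) {
            r <- .jitter_read(truth$mature[i], prec, 1L,
                              spec$end_jitter_prob)
            .mutate_read(r, spec$error_rate)
          }, character(1))
          reads <- c(reads, rr)
        }
        ks <- stats::rpois(1, truth[[mcol]][i] * spec$star_fraction)
        if (ks > 0) reads <- c(reads, rep(truth$star[i], ks))
      }
    }
    lens <- as.integer(names(spec$length_probs))
    for (cls in names(sim$contaminants)) {
      for (ref in sim$contaminants[[cls]]) {
        k <- stats::rpois(1, spec$contaminant_mean)
        if (k == 0) next
        ln <- sample(lens, k, replace = TRUE, prob = spec$length_probs)
        st <- vapply(ln, function(l) sample(nchar(ref) - l + 1L, 1),
                     integer(1))
        reads <- c(reads, substr(rep(ref, k), st, st + ln - 1L))
      }
    }
    reads <- sample(reads)
    out[[cond]] <- paste0(reads, spec$adapter)
  }
  out
}

#' Write simulated reads as FASTQ
#'
#' @param reads Character vector of reads.
#' @param path Output path.
#' @param prefix Read-name prefix.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, prefix = "read") {
  qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
  writeLines(paste0("@", prefix, seq_along(reads), "\n", reads, "\n+\n", qual),
             path)
  invisible(path)
}
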