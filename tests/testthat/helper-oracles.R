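# Independent oracles and small builders used across the suite.

# complement lookup shared by the oracles (kept independent of the
# package's Biostrings-backed reverse_complement)
.comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(s) {
  paste(rev(.comp[strsplit(s, "")[[1]]]), collapse = "")
}

# can two bases pair (Watson-Crick + G:T wobble, DNA-encoded)?
oracle_can_pair <- function(a, b) {
  (a == "A" && b == "T") || (a == "T" && b == "A") ||
    (a == "G" && b == "C") || (a == "C" && b == "G") ||
    (a == "G" && b == "T") || (a == "T" && b == "G")
}

# maximum pair count by interval recursion with memoisation (pure R,
# independent of the package's C++ dynamic program)
oracle_max_pairs <- function(seq, min_loop = 3L) {
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i + 1L, j)  # i unpaired
    for (k in (i + min_loop + 1L):j) {
      if (oracle_can_pair(b[i], b[k])) {
        v <- 1L + rec(i + 1L, k - 1L) + if (k < j) rec(k + 1L, j) else 0L
        if (v > best) best <- v
      }
    }
    memo[[key]] <- best
    best
  }
  if (n < min_loop + 2L) return(0L)
  rec(1L, n)
}

# full enumeration of every valid structure (exponential; tiny inputs only)
oracle_enumerate_max_pairs <- function(seq, min_loop = 3L) {
  b <- strsplit(seq, "")[[1]]
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    counts <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (oracle_can_pair(b[i], b[k])) {
        counts <- c(counts,
                    1L + rec(i + 1L, k - 1L) +
                      if (k < j) rec(k + 1L, j) else 0L)
      }
    }
    max(counts)
  }
  if (length(b) < min_loop + 2L) return(0L)
  rec(1L, length(b))
}

# all exact occurrences of tag on both strands, by naive position scan
oracle_map <- function(tag, genome) {
  hits <- list()
  k <- nchar(tag)
  rc <- oracle_revcomp(tag)
  for (ctg in names(genome)) {
    s <- genome[[ctg]]
    for (p in seq_len(nchar(s) - k + 1L)) {
      w <- substr(s, p, p + k - 1L)
      if (w == tag) {
        hits[[length(hits) + 1L]] <- data.frame(
          contig = ctg, start = p, end = p + k - 1L, strand = "+",
          stringsAsFactors = FALSE)
      }
      if (w == rc) {
        hits[[length(hits) + 1L]] <- data.frame(
          contig = ctg, start = p, end = p + k - 1L, strand = "-",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$contig, out$start, out$strand), , drop = FALSE]
}

# per-window complementarity score between a miRNA and a transcript,
# computed in transcript space (miRNA position i faces window base
# k - i + 1); WC = 0, G:U wobble = 0.5, else 1
oracle_target_scores <- function(mirna, transcript) {
  mb <- strsplit(mirna, "")[[1]]
  k <- length(mb)
  n <- nchar(transcript)
  if (n < k) return(numeric(0))
  vapply(seq_len(n - k + 1L), function(st) {
    w <- strsplit(substr(transcript, st, st + k - 1L), "")[[1]]
    sum(vapply(seq_len(k), function(i) {
      a <- mb[i]; t <- w[k - i + 1L]
      if (t == .comp[[a]]) 0
      else if ((a == "G" && t == "T") || (a == "T" && t == "G")) 0.5
      else 1
    }, numeric(1)))
  }, numeric(1))
}

# perfect-stem hairpin builder
make_hairpin <- function(mature, loop = "ACGTTGCA") {
  paste0(mature, loop, oracle_revcomp(mature))
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
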