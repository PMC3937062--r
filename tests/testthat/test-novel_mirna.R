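test_that("exact mapping finds planted loci on both strands", {
  set.seed(41)
  tag <- random_seq(21)
  genome <- c(chr1 = paste0(random_seq(100), tag, random_seq(100),
                            oracle_revcomp(tag), random_seq(50)))
  hits <- map_exact(tag, genome)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$strand, c("+", "-"))
  expect_equal(hits$start[1], 101)
  expect_equal(hits$start[2], 222)
})

test_that("exact mapping equals a naive all-positions scan", {
  set.seed(42)
  genome <- c(chrA = random_seq(5000), chrB = random_seq(5000))
  for (i in 1:50) {
    # half planted, half random
    tag <- if (i %% 2 == 0) random_seq(21) else {
      p <- sample(4979, 1)
      substr(genome[[1 + i %% 2]], p, p + 20)
    }
    got <- map_exact(tag, genome)
    want <- oracle_map(tag, genome)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("window extraction does the flank arithmetic and clamps at edges", {
  genome <- c(chr1 = random_seq(2000))
  locus <- data.frame(contig = "chr1", start = 500, end = 520, strand = "+")
  w <- extract_windows(locus, genome, flank = 150, pad = 20)
  expect_equal(w[[1]]$genomic_start, 350)
  expect_equal(w[[1]]$genomic_end, 540)
  expect_equal(w[[2]]$genomic_start, 480)
  expect_equal(w[[2]]$genomic_end, 670)
  expect_equal(substr(w[[1]]$seq, w[[1]]$mature_start, w[[1]]$mature_end),
               substr(genome[[1]], 500, 520))
  # edge clamping, no error
  le <- data.frame(contig = "chr1", start = 10, end = 30, strand = "+")
  we <- extract_windows(le, genome, flank = 150)
  expect_equal(we[[1]]$genomic_start, 1)
  # out-of-bounds locus errors
  bad <- data.frame(contig = "chr1", start = 1990, end = 2010, strand = "+")
  expect_error(extract_windows(bad, genome), "outside")
})

test_that("minus-strand windows present the mature 5' to 3'", {
  set.seed(43)
  mature <- random_seq(21)
  genome <- c(chr1 = paste0(random_seq(300), oracle_revcomp(mature),
                            random_seq(300)))
  locus <- map_exact(mature, genome)
  expect_equal(locus$strand, "-")
  w <- extract_windows(locus, genome)[[1]]
  expect_equal(substr(w$seq, w$mature_start, w$mature_end), mature)
})

test_that("maximum-pairing fold matches exhaustive enumeration on a 9-mer", {
  st <- fold("GGGAAACCC")
  expect_equal(st$n_pairs, 3)
  expect_equal(st$n_pairs, oracle_enumerate_max_pairs("GGGAAACCC"))
  expect_identical(st$dotbracket, "(((...)))")
})

test_that("a base-free sequence folds into all dots", {
  st <- fold("AAAAAAA")
  expect_equal(st$n_pairs, 0)
  expect_identical(st$dotbracket, ".......")
  expect_error(fold("ACG"), "too short")
})

test_that("the dynamic program equals the independent recursion up to 30 nt", {
  set.seed(44)
  for (i in 1:100) {
    s <- random_seq(sample(10:30, 1))
    expect_equal(fold(s)$n_pairs, oracle_max_pairs(s), info = s)
  }
  # spot-check the pure-R recursion against full enumeration on tiny input
  for (i in 1:5) {
    s <- random_seq(12)
    expect_equal(oracle_max_pairs(s), oracle_enumerate_max_pairs(s))
  }
})

test_that("folded structures satisfy their invariants", {
  set.seed(45)
  for (i in 1:25) {
    s <- random_seq(40)
    st <- fold(s)
    p <- st$pairs
    if (nrow(p) == 0) next
    expect_true(all(p[, 2] - p[, 1] > 3))             # loop constraint
    expect_equal(anyDuplicated(c(p)), 0)              # each base once
    # non-crossing
    if (nrow(p) > 1) {
      for (a in 1:(nrow(p) - 1)) for (b in (a + 1):nrow(p)) {
        i1 <- p[a, 1]; j1 <- p[a, 2]; i2 <- p[b, 1]; j2 <- p[b, 2]
        crossing <- (i1 < i2 & i2 < j1 & j1 < j2) |
          (i2 < i1 & i1 < j2 & j2 < j1)
        expect_false(crossing)
      }
    }
  }
})

test_that("a perfect inverted repeat is accepted with a 2-nt-offset star", {
  mature <- "TTGACAGAAGAGAGGGAGCAC"
  prec <- make_hairpin(mature)
  cand <- evaluate_hairpin(prec, mature, fold(prec))
  expect_false(is.null(cand))
  expect_identical(cand$arm, "5p")
  expect_true(cand$five_prime_U)
  # canonical star is the reverse complement region shifted by the 2-nt
  # 3' overhang; at the precursor edge it is clamped
  expect_equal(cand$star_start, nchar(mature) + nchar("ACGTTGCA") + 3)
  expect_equal(cand$star_end, nchar(prec))
})

test_that("a mature spanning the terminal loop is rejected", {
  mature <- random_seq(21)
  prec <- make_hairpin(mature)
  spanning <- substr(prec, 15, 35)
  expect_null(evaluate_hairpin(prec, spanning, fold(prec)))
  expect_error(evaluate_hairpin(prec, "GGGGGGGGGGGGGGGGGGGGG", fold(prec)),
               "does not occur")
})

test_that("the paired-bases threshold is enforced exactly at the boundary", {
  mature <- "TTGACAGAAGAGAGGGAGCAC"  # 21 nt, fully paired in its hairpin
  prec <- make_hairpin(mature)
  st <- fold(prec)
  ok <- evaluate_hairpin(prec, mature, st,
                         hairpin_criteria(min_paired_mature = 21))
  expect_false(is.null(ok))
  too_strict <- evaluate_hairpin(prec, mature, st,
                                 hairpin_criteria(min_paired_mature = 22))
  expect_null(too_strict)
})

test_that("the novel-candidate mature starting with T flags five_prime_U", {
  mature <- "TTGGCTTGGAGATGGATCATT"
  prec <- make_hairpin(mature)
  cand <- evaluate_hairpin(prec, mature, fold(prec))
  expect_true(cand$five_prime_U)
})

test_that("star detection finds the planted star within tolerance", {
  set.seed(46)
  mature <- random_seq(21)
  prec <- make_hairpin(mature)
  cand <- evaluate_hairpin(prec, mature, fold(prec))
  star <- substr(prec, cand$star_start, cand$star_end)
  lib <- filter_and_collapse(c(rep(star, 4), random_seq(21)))
  hit <- detect_star(cand, lib)
  expect_equal(hit$count, 4)
  expect_identical(hit$sequence, star)
  # a 1-nt end-shifted star still detects; an unrelated library does not
  shifted <- substr(prec, cand$star_start - 1, cand$star_end)
  expect_equal(detect_star(cand, filter_and_collapse(rep(shifted, 2)))$count, 2)
  expect_null(detect_star(cand, filter_and_collapse(random_seq(22))))
})

test_that("stars are flagged for exactly the hairpins whose star was sequenced", {
  spec <- simulation_spec(seed = 47, n_hairpins = 10, genome_length = 20000,
                          contaminant_mean = 0,
                          error_rate = 0, end_jitter_prob = 0,
                          star_fraction = 0)
  sim <- generate_genome(spec)
  with_star <- sim$truth$id[1:5]
  # express stars for the first five hairpins only
  reads <- c(vapply(seq_len(nrow(sim$truth)), function(i)
    sim$truth$mature[i], character(1)) |> rep(20),
    rep(sim$truth$star[1:5], 10))
  libs <- list(control = filter_and_collapse(reads),
               treatment = filter_and_collapse(reads))
  nv <- discover_novel(unique(reads), sim$genome, libs)
  # candidates at the planted mature loci (5p arm, + strand)
  at_planted <- match(sim$truth$mature, nv$sequence)
  flagged <- sim$truth$id[sim$truth$mature %in%
                            nv$sequence[nv$star_detected]]
  expect_setequal(intersect(flagged, sim$truth$id), with_star)
})
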