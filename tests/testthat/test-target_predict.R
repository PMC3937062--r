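test_that("an exact antisense site is found with zero mismatches", {
  set.seed(61)
  mir <- random_seq(21)
  tx <- c(t1 = paste0(random_seq(50), oracle_revcomp(mir), random_seq(50)))
  hits <- predict_targets(mir, tx)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 51)
  expect_equal(hits$end, 71)
  expect_equal(hits$mismatches, 0)
})

test_that("four internal mismatches exclude a site", {
  set.seed(62)
  mir <- random_seq(21)
  site <- strsplit(oracle_revcomp(mir), "")[[1]]
  # mutate 4 positions away from both match and wobble (site positions
  # k-i+1 face miRNA positions i; avoid the 10-11 / seed-rule region by
  # turning the positional rules off)
  for (p in c(2, 7, 13, 19)) {
    old <- site[p]
    site[p] <- setdiff(c("A", "C", "G", "T"), c(old))[1]
  }
  tx <- c(t1 = paste0(random_seq(30), paste(site, collapse = ""),
                      random_seq(30)))
  sc <- oracle_target_scores(mir, tx[[1]])
  if (min(sc) > 3) {
    expect_equal(nrow(predict_targets(mir, tx, rule_cleavage_site = FALSE,
                                      rule_seed = FALSE)), 0)
  } else {
    succeed("mutations landed on wobble-tolerant bases; covered by oracle test")
  }
})

test_that("prediction equals the all-windows brute-force scorer", {
  set.seed(63)
  for (i in 1:10) {
    mir <- random_seq(21)
    tx <- random_seq(500)
    # plant a 2-mismatch site
    site <- strsplit(oracle_revcomp(mir), "")[[1]]
    for (p in c(3, 15)) site[p] <- setdiff(c("A", "C", "G", "T"), site[p])[1]
    tx <- paste0(tx, paste(site, collapse = ""), random_seq(40))
    txs <- c(t = tx)
    got <- predict_targets(mir, txs, rule_cleavage_site = FALSE,
                           rule_seed = FALSE)
    sc <- oracle_target_scores(mir, tx)
    expect_setequal(got$start, which(sc <= 3))
    expect_equal(got$mismatches, unname(sc[got$start]))
  }
})

test_that("planted sites at 0-3 mismatches are recovered, decoys excluded", {
  set.seed(64)
  mir <- random_seq(21)
  mm_of <- integer(0)
  txs <- character(0)
  for (i in 1:30) {
    k <- c(0:3, 4:6)[((i - 1) %% 7) + 1]
    site <- strsplit(oracle_revcomp(mir), "")[[1]]
    if (k > 0) {
      # mutate to transversion partners that cannot wobble-pair
      pos <- sample(setdiff(1:21, 1), k)
      for (p in pos) {
        a <- substr(mir, 22 - p, 22 - p)  # miRNA base facing this position
        bad <- switch(a, A = "G", C = "T", G = "G", T = "T")
        site[p] <- bad
      }
    }
    txs <- c(txs, paste0(random_seq(60), paste(site, collapse = ""),
                         random_seq(60)))
    mm_of <- c(mm_of, k)
  }
  names(txs) <- paste0("tx", seq_along(txs))
  hits <- predict_targets(mir, txs, rule_cleavage_site = FALSE,
                          rule_seed = FALSE)
  planted_found <- names(txs)[mm_of <= 3]
  # every transcript with a planted <=3-mismatch site has a hit at pos 61
  expect_true(all(planted_found %in% hits$transcript[hits$start == 61]))
  # no decoy transcript contributes a planted-site hit
  decoys <- names(txs)[mm_of > 3]
  expect_false(any(decoys %in% hits$transcript[hits$start == 61]))
})

test_that("positional rules veto cleavage-site and seed mismatches", {
  set.seed(65)
  mir <- random_seq(21)
  site <- strsplit(oracle_revcomp(mir), "")[[1]]
  # mismatch facing miRNA position 10 (site position 21 - 10 + 1 = 12)
  a <- substr(mir, 10, 10)
  site[12] <- switch(a, A = "G", C = "T", G = "G", T = "T")
  tx <- c(t = paste0(random_seq(20), paste(site, collapse = ""),
                     random_seq(20)))
  with_rule <- predict_targets(mir, tx)
  without <- predict_targets(mir, tx, rule_cleavage_site = FALSE)
  expect_false(21 %in% with_rule$start)
  expect_true(21 %in% without$start)
})

test_that("cleavage validation follows the 9th-11th nucleotide rule", {
  site <- data.frame(transcript = "t", start = 101, end = 121)
  # pairing with miRNA position 10 means coordinate end - 10 + 1
  v10 <- validate_cleavage(site, list(transcript = "t", coordinate = 112))
  expect_identical(v10$status, "supported")
  expect_equal(v10$position, 10)
  v2 <- validate_cleavage(site, list(transcript = "t", coordinate = 120))
  expect_identical(v2$status, "unsupported")
  expect_equal(v2$position, 2)
  out <- validate_cleavage(site, list(transcript = "t", coordinate = 50))
  expect_identical(out$status, "unsupported")
  expect_true(is.na(out$position))
  expect_error(validate_cleavage(site, list(transcript = "q",
                                            coordinate = 112)),
               "different transcript")
})

test_that("exactly three coordinates across a site are supported", {
  site <- data.frame(transcript = "t", start = 101, end = 121)
  supported <- vapply(101:121, function(co) {
    validate_cleavage(site, list(transcript = "t", coordinate = co))$status
  }, character(1))
  expect_equal(sum(supported == "supported"), 3)
})

test_that("the position index is invariant under coordinate shifts", {
  for (shift in c(0, 50, 1000)) {
    site <- data.frame(transcript = "t", start = 101 + shift,
                       end = 121 + shift)
    v <- validate_cleavage(site, list(transcript = "t",
                                      coordinate = 112 + shift))
    expect_equal(v$position, 10)
  }
})
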