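adapter <- "TGGAATTCTCGGGTGCCAAGG"

test_that("adapter trimming recovers the insert and flags adapter-only reads", {
  insert <- "TTGACAGAAGAGAGGGAGCAC"
  expect_identical(trim_adapter(paste0(insert, adapter), adapter), insert)
  expect_identical(trim_adapter(insert, adapter), insert)  # no adapter
  expect_true(is.na(trim_adapter(adapter, adapter)))       # adapter-only
})

test_that("trimming tolerates a planted mismatch in the adapter copy", {
  set.seed(7)
  for (i in 1:20) {
    insert <- random_seq(sample(18:26, 1))
    ad <- adapter
    p <- sample(nchar(ad), 1)
    b <- substr(ad, p, p)
    mut <- paste0(substr(ad, 1, p - 1),
                  sample(setdiff(c("A", "C", "G", "T"), b), 1),
                  substr(ad, p + 1, nchar(ad)))
    got <- trim_adapter(paste0(insert, mut), adapter, max_mismatch = 1)
    # brute-force left-most admissible position
    read <- paste0(insert, mut)
    expected <- read
    for (q in seq_len(nchar(read))) {
      ov <- min(nchar(adapter), nchar(read) - q + 1)
      if (ov < 8) break
      mm <- sum(strsplit(substr(read, q, q + ov - 1), "")[[1]] !=
                  strsplit(substr(adapter, 1, ov), "")[[1]])
      if (mm <= 1) { expected <- substr(read, 1, q - 1); break }
    }
    expect_identical(got, expected)
    expect_identical(got, insert)
  }
})

test_that("trimming never lengthens a read", {
  set.seed(8)
  reads <- vapply(1:50, function(i) random_seq(sample(18:45, 1)), character(1))
  expect_true(all(nchar(trim_adapter(reads, adapter)) <= nchar(reads),
                  na.rm = TRUE))
})

test_that("filtering drops short, polyA and N reads; collapsing counts", {
  r21 <- random_seq(21)
  lib <- filter_and_collapse(c(rep(r21, 3),
                               random_seq(17),              # too short
                               strrep("A", 21),             # polyA
                               paste0("N", random_seq(20))))  # contains N
  expect_equal(nrow(lib$tags), 1)
  expect_equal(lib$tags$count, 3)
  expect_equal(lib$total_redundant, 3)
})

test_that("collapsing conserves read mass", {
  set.seed(9)
  reads <- sample(vapply(1:30, function(i) random_seq(sample(18:30, 1)),
                         character(1)), 500, replace = TRUE)
  lib <- filter_and_collapse(reads)
  expect_equal(sum(lib$tags$count), length(reads))
  expect_equal(lib$total_redundant, length(reads))
})

test_that("size distribution sums to one and respects weighting", {
  lib <- filter_and_collapse(c(rep(random_seq(21), 3), random_seq(24)))
  d <- size_distribution(lib, "redundant")
  expect_equal(sum(d), 1, tolerance = 1e-9)
  expect_equal(unname(d[c("21", "24")]), c(0.75, 0.25))
  du <- size_distribution(lib, "unique")
  expect_equal(unname(du[c("21", "24")]), c(0.5, 0.5))
  expect_error(size_distribution(filter_and_collapse(character(0))), "empty")
})

test_that("library profiles are invariant to read input order", {
  set.seed(10)
  reads <- sample(vapply(1:40, function(i) random_seq(sample(18:30, 1)),
                         character(1)), 300, replace = TRUE)
  a <- filter_and_collapse(reads)
  b <- filter_and_collapse(rev(reads))
  expect_identical(size_distribution(a), size_distribution(b))
  expect_identical(first_nt_bias(a), first_nt_bias(b))
})

test_that("empirical length fractions recover the generator probabilities", {
  set.seed(11)
  n <- 50000
  lens <- sample(c(21, 24, 20), n, replace = TRUE, prob = c(0.38, 0.32, 0.30))
  reads <- vapply(lens, random_seq, character(1))
  d <- size_distribution(filter_and_collapse(reads), "redundant")
  expect_equal(unname(d["21"]), 0.38, tolerance = 0.01)
  expect_equal(unname(d["24"]), 0.32, tolerance = 0.01)
})

test_that("first-nucleotide bias reports the RNA alphabet per length", {
  lib <- filter_and_collapse("TTGACAGAAGAGAGGGAGCAC")
  b <- first_nt_bias(lib)
  expect_equal(b$length, 21)
  expect_equal(b$first_nt, "U")
  expect_equal(b$fraction, 1.0)
  lib2 <- filter_and_collapse(c(paste0("A", strrep("CG", 9)),
                                paste0("T", strrep("CG", 9))))
  b2 <- first_nt_bias(lib2)
  expect_setequal(b2$first_nt, c("A", "U"))
  expect_equal(b2$fraction, c(0.5, 0.5))
})

test_that("an estimated 5'U fraction matches the sampling probability", {
  set.seed(12)
  n <- 10000
  firsts <- sample(c("T", "A", "C", "G"), n, replace = TRUE,
                   prob = c(0.6, 0.2, 0.1, 0.1))
  reads <- paste0(firsts, vapply(rep(20, n), random_seq, character(1)))
  b <- first_nt_bias(filter_and_collapse(reads), "redundant")
  expect_equal(b$fraction[b$length == 21 & b$first_nt == "U"], 0.6,
               tolerance = 0.02)
})
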