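make_contigs <- function(seqs) Biostrings::DNAStringSet(seqs)

test_that("pseudo-counts shift composition by 1 and coverage by 0.01", {
  Z <- matrix(c(0L, 7L, 2L, 0L), 2, dimnames = list(c("a", "b"), c("AA", "AC")))
  Y <- matrix(c(0, 1.5, 2, 0), 2)
  pc <- add_pseudocounts(Z, Y)
  expect_equal(pc$Z[1, 1], 1)
  expect_equal(pc$Z[2, 1], 8)
  expect_equal(pc$Y[1, 1], 0.01)
  expect_equal(pc$Y[2, 2], 0.01)
  expect_equal(Z[1, 1], 0L)   # inputs untouched
})

test_that("coverage normalization: columns then rows, rows sum to 1", {
  Yp <- matrix(c(1, 3, 3, 1), 2)
  Q <- normalize_coverage(Yp)
  expect_equal(Q, matrix(c(0.25, 0.75, 0.75, 0.25), 2))

  # single sample: column of ones
  expect_equal(unname(normalize_coverage(matrix(c(2, 5, 0.1), 3))),
               matrix(1, 3, 1))

  set.seed(3)
  Y <- matrix(runif(40, 0.01, 50), 10, 4)
  Q <- normalize_coverage(Y)
  expect_equal(rowSums(Q), rep(1, 10), tolerance = 1e-12)

  # invariance to rescaling one whole sample column
  Y2 <- Y; Y2[, 2] <- Y2[, 2] * 37.5
  expect_equal(normalize_coverage(Y2), Q, tolerance = 1e-12)

  expect_error(normalize_coverage(matrix(c(1, 0), 2)),
               class = "pb_nonpositive_coverage")
})

test_that("nucleotide model estimates per-contig base probabilities", {
  x <- make_contigs(c(a = "AACG"))
  expect_equal(unname(nucleotide_model(x, smooth = FALSE)[1, ]),
               c(0.5, 0.25, 0.25, 0))
  expect_equal(unname(nucleotide_model(x, smooth = TRUE)[1, ]),
               c(3, 2, 2, 1) / 8)
  # N excluded from numerator and denominator
  xn <- make_contigs(c(a = "AANNCG"))
  expect_equal(nucleotide_model(xn), nucleotide_model(x))
  expect_error(nucleotide_model(make_contigs(c(a = "NNN"))),
               class = "pb_no_informative_bases")
})

test_that("k-mer occurrence probability: strict vs pair, palindromes", {
  p <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  expect_equal(kmer_probability(p, "AA", "strict"), 1 / 16)
  expect_equal(kmer_probability(p, "AA", "pair"), 1 / 8)
  expect_equal(kmer_probability(p, "AT", "pair"), 1 / 16)  # palindrome
  p2 <- c(A = 0.5, C = 0.1, G = 0.2, T = 0.2)
  expect_equal(kmer_probability(p2, "AC", "pair"), 0.5 * 0.1 + 0.2 * 0.2)
})

test_that("standardization matches the binomial z-score arithmetic", {
  # 100 bp with 25 of each base: smoothed model is exactly uniform
  seq <- paste(rep(c("A", "C", "G", "T"), 25), collapse = "")
  x <- make_contigs(c(c1 = seq))
  ck <- canonical_kmers(2)
  Zp <- matrix(1L, 1, length(ck$classes), dimnames = list("c1", ck$classes))
  Zp[, "AA"] <- 10L
  attr(Zp, "k") <- 2L
  Xt <- standardize_composition(Zp, x, mode = "pair")
  # class AA/TT: P = 2/16, mu = 12.5, sigma^2 = 0.125 * 0.875 * 100
  expect_equal(Xt[1, "AA"], (10 - 12.5) / sqrt(10.9375))
  # a count equal to its mean scores exactly 0
  Zp2 <- Zp
  Zp2[, "AC"] <- 12.5   # equals mu for class AC/GT under the uniform model
  Xt2 <- standardize_composition(Zp2, x, mode = "pair")
  expect_equal(unname(Xt2[1, "AC"]), 0)

  # zero variance is only reachable unsmoothed, and is a named error
  x0 <- make_contigs(c(c1 = paste(rep("AC", 50), collapse = "")))
  Zp0 <- matrix(1L, 1, length(ck$classes), dimnames = list("c1", ck$classes))
  attr(Zp0, "k") <- 2L
  expect_error(standardize_composition(Zp0, x0, mode = "pair", smooth = FALSE),
               class = "pb_zero_variance")
  expect_silent(standardize_composition(Zp0, x0, mode = "pair", smooth = TRUE))
})

test_that("column normalization: abs mode preserves sign, strict can degenerate", {
  X <- matrix(c(1, 1, 2), 3, 1)
  expect_equal(as.vector(normalize_columns(X, "abs")), c(0.25, 0.25, 0.5))
  X2 <- matrix(c(3, -1), 2, 1)
  expect_equal(as.vector(normalize_columns(X2, "abs")), c(0.75, -0.25))
  X3 <- matrix(c(1, -1), 2, 1)
  expect_warning(H3 <- normalize_columns(X3, "strict"), "zero denominator")
  expect_equal(as.vector(H3), c(0, 0))
  # abs mode gives unit absolute column sums
  set.seed(4)
  X4 <- matrix(rnorm(60), 10)
  expect_equal(colSums(abs(normalize_columns(X4, "abs"))), rep(1, 6))
})

test_that("feature assembly concatenates coverage before composition", {
  Q <- matrix(1, 2, 3)
  H <- matrix(2, 2, 5)
  FF <- assemble_features(Q, H)
  expect_identical(dim(FF), c(2L, 8L))
  expect_identical(attr(FF, "column_roles"),
                   c(coverage = 3L, composition = 5L))
  expect_error(assemble_features(Q, matrix(2, 3, 5)), class = "pb_row_mismatch")
  Hn <- H; Hn[1, 1] <- NaN
  expect_error(assemble_features(Q, Hn), class = "pb_nonfinite")
})

test_that("length split partitions contigs, fixed and quantile modes", {
  x <- make_contigs(c(a = paste(rep("A", 1000), collapse = ""),
                      b = paste(rep("C", 3000), collapse = "")))
  sp <- split_by_length(x, 2000)
  expect_identical(sp$long, 2L)
  expect_identical(sp$short, 1L)

  # all long: empty short set
  sp2 <- split_by_length(make_contigs(c(a = paste(rep("A", 2000), collapse = ""))),
                         2000)
  expect_length(sp2$short, 0L)

  expect_error(split_by_length(x, 5000), class = "pb_no_long_contigs")

  # quantile mode: exactly the 20 shortest of 100, ties by input order
  set.seed(9)
  lens <- sample(c(500:1500, 2500:9000), 100, replace = TRUE)
  lens[3] <- lens[7] <- 700   # a tie
  big <- make_contigs(setNames(
    vapply(lens, function(L) paste(rep("A", L), collapse = ""), ""),
    paste0("c", 1:100)))
  spq <- split_by_length(big, mode = "quantile", short_fraction = 0.20)
  expect_length(spq$short, 20L)
  expect_identical(sort(spq$short), spq$short)
  oracle_short <- sort(order(lens)[1:20])
  expect_identical(spq$short, oracle_short)
  expect_identical(sort(c(spq$long, spq$short)), 1:100)
})
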