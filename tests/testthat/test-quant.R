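mk_track <- function(values, chrom = "c") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(seq_along(values),
                                                       width = 1L),
                               score = values)
  coverage_track(gr[gr$score != 0], mode = "depth")
}

test_that("minimal intron is the intersection of the cluster", {
  expect_equal(unname(minimal_intron(100L, 200L)), c(100L, 200L))
  # [100,200) and [120,260) half-open = [100,199] and [120,259] closed
  expect_equal(unname(minimal_intron(c(100L, 120L), c(199L, 259L))),
               c(120L, 199L))
  expect_error(minimal_intron(c(100L, 160L), c(149L, 200L)), "overlap")
})

test_that("coverage summary averages intron and exon2 windows", {
  # uniform depth 10 over intron [11,20]
  tr <- mk_track(c(rep(0, 10), rep(10, 10), rep(6, 100)))
  s <- coverage_summary("c", 11L, 20L, "+", tr, J = 7L)
  expect_equal(s$I, 10)
  expect_equal(s$E2, 6)
  expect_false(s$e2_truncated)

  # depth 10 over half the intron, absent (0) elsewhere
  tr <- mk_track(c(rep(0, 10), rep(10, 5), rep(0, 5), rep(6, 100)))
  expect_equal(coverage_summary("c", 11L, 20L, "+", tr, J = 0L)$I, 5)

  # exon2 window truncated to 50 bases at the transcript end, depth 8
  tr <- mk_track(c(rep(0, 10), rep(10, 10), rep(8, 50)))
  s <- coverage_summary("c", 11L, 20L, "+", tr, J = 1L,
                        transcript_bounds = c(1L, 70L))
  expect_equal(s$E2, 8)
  expect_true(s$e2_truncated)

  # minus strand: exon2 is upstream in genomic coordinates
  tr <- mk_track(c(rep(3, 100), rep(10, 10)))
  s <- coverage_summary("c", 101L, 110L, "-", tr, J = 1L)
  expect_equal(s$E2, 3)
})

test_that("splicing indices follow the log2 contracts", {
  s <- function(J, I, E2 = 1) list(J = J, I = I, E2 = E2)
  expect_equal(splicing_indices(s(10, 10))$junction_intron, 0)
  expect_equal(splicing_indices(s(40, 10))$junction_intron, 2)
  expect_true(is.na(splicing_indices(s(10, 0))$junction_intron))
  expect_true(is.na(splicing_indices(s(0, 10))$junction_intron))
  expect_equal(splicing_indices(s(8, 2, 4))$intron_exon2, log2(2 / 4))
  expect_equal(splicing_indices(s(8, 2, 4))$junction_exon2, 1)
  # doubling J raises log2(J/I) by exactly 1
  set.seed(3)
  for (rep in 1:100) {
    J <- runif(1, 1, 1e4); I <- runif(1, 1, 1e4)
    expect_equal(splicing_indices(s(2 * J, I))$junction_intron,
                 splicing_indices(s(J, I))$junction_intron + 1)
  }
})

test_that("delta SJ index is antisymmetric and NA-propagating", {
  s <- function(J, I) list(J = J, I = I, E2 = 1)
  expect_equal(delta_sj_index(s(10, 10), s(40, 10)), 2)
  expect_equal(delta_sj_index(s(10, 10), s(10, 10)), 0)
  expect_true(is.na(delta_sj_index(s(10, 10), s(0, 10))))
  set.seed(4)
  for (rep in 1:100) {
    a <- s(runif(1, 1, 100), runif(1, 1, 100))
    b <- s(runif(1, 1, 100), runif(1, 1, 100))
    expect_equal(delta_sj_index(a, b), -delta_sj_index(b, a))
  }
})

test_that("percent spliced is bounded, monotone and matches its formula", {
  s <- function(J, I) list(J = J, I = I)
  expect_equal(percent_spliced(s(0, 10)), 0)
  expect_equal(percent_spliced(s(10, 10)), 50)
  expect_equal(percent_spliced(s(1, 99)), 1)
  expect_true(is.na(percent_spliced(s(0, 0))))
  set.seed(5)
  for (rep in 1:100) {
    J <- runif(1, 0, 100); I <- runif(1, 0, 100)
    p <- percent_spliced(s(J, I))
    expect_gte(p, 0); expect_lte(p, 100)
    expect_gte(percent_spliced(s(J + 1, I)), p)
    expect_lte(percent_spliced(s(J, I + 1)), p)
  }
})

test_that("median-of-ratios normalization absorbs global depth shifts", {
  counts <- matrix(c(100, 200, 50, 400, 80,
                     100, 200, 50, 400, 80), ncol = 2,
                   dimnames = list(paste0("g", 1:5), c("t0", "t60")))
  fc <- transcript_fold_change(counts, c("t0", "t60"))
  expect_equal(fc$fold_change, rep(1, 5))
  expect_true(all(fc$passes))

  doubled <- counts; doubled[, 2] <- doubled[, 2] * 2
  fc <- transcript_fold_change(doubled, c("t0", "t60"))
  expect_equal(fc$fold_change, rep(1, 5))  # size factor absorbs the shift

  one_up <- counts; one_up[1, 2] <- one_up[1, 2] * 2
  fc <- transcript_fold_change(one_up, c("t0", "t60"))
  expect_gt(fc$fold_change[1], 1.9)
  expect_false(fc$passes[1])
  expect_true(all(fc$passes[-1]))

  # size factors agree with the established reference implementation
  set.seed(8)
  m <- matrix(rpois(400, 50) + 1L, ncol = 4)
  expect_equal(size_factors(m),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("percent spliced recovers planted efficiency at depth", {
  set.seed(12)
  d <- 2000
  within3 <- logical(1000)
  for (r in seq_len(1000)) {
    e <- runif(1, 0.05, 0.95)
    J <- rpois(1, d * e)
    I <- mean(rpois(100L, d * (1 - e)))
    p <- percent_spliced(list(J = J, I = I)) / 100
    within3[r] <- abs(p - e) <= 3 * sqrt(e * (1 - e) / d)
  }
  expect_gte(mean(within3), 0.99)
})
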