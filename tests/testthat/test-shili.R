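test_that("min-max normalisation maps benefit and cost columns correctly", {
  dm <- make_dm(cbind(c(10, 20, 30), c(10, 20, 30)),
                directions = c("benefit", "cost"))
  nm <- minmax_normalize(dm)
  expect_equal(unname(nm$values[, 1]), c(0, 0.5, 1))
  expect_equal(unname(nm$values[, 2]), c(1, 0.5, 0))
})

test_that("normalisation is invariant to positive affine rescaling", {
  set.seed(21)
  for (rep in 1:5) {
    m <- sample(3:8, 1); n <- sample(2:4, 1)
    dirs <- sample(c("benefit", "cost"), n, replace = TRUE)
    B <- matrix(runif(m * n, -50, 50), m, n)
    a <- runif(n, 0.1, 10); c_ <- runif(n, -20, 20)
    B2 <- sweep(sweep(B, 2, a, `*`), 2, c_, `+`)
    nm1 <- minmax_normalize(make_dm(B, dirs))
    nm2 <- minmax_normalize(make_dm(B2, dirs))
    expect_equal(nm1$values, nm2$values, tolerance = 1e-12)
  }
})

test_that("constant columns normalise to zero with a warning and get zero weight", {
  dm <- make_dm(cbind(c(5, 5, 5), c(1, 2, 3)))
  expect_warning(nm <- minmax_normalize(dm), "constant")
  expect_equal(unname(nm$values[, 1]), c(0, 0, 0))
  w <- entropy_weights(nm)
  expect_equal(unname(w), c(0, 1))
})

test_that("entropy weights match the literal formula oracle", {
  set.seed(22)
  for (rep in 1:5) {
    B <- matrix(runif(24, 0, 100), 8, 3)
    nm <- minmax_normalize(make_dm(B))
    expect_equal(unname(entropy_weights(nm)),
                 oracle_entropy(oracle_normalize(B, rep("benefit", 3))),
                 tolerance = 1e-12)
  }
})

test_that("entropy weighting favours dispersion and respects symmetry", {
  # permuted copies of one multiset share a weight of 1/2
  dm <- make_dm(cbind(c(1, 5, 9, 3), c(3, 9, 1, 5)))
  expect_equal(unname(entropy_weights(minmax_normalize(dm))),
               c(0.5, 0.5), tolerance = 1e-12)
  # a polarized column (shares concentrated on one alternative) carries
  # lower entropy, hence more weight, than an evenly graded one
  dm2 <- make_dm(cbind(c(0, 0.5, 1), c(0, 0.1, 1)))
  w <- entropy_weights(minmax_normalize(dm2))
  expect_gt(w[["c2"]], w[["c1"]])
  # hand oracle for the same pair
  expect_equal(unname(w),
               oracle_entropy(cbind(c(0, 0.5, 1), c(0, 0.1, 1))),
               tolerance = 1e-12)
  # row shuffles leave weights unchanged
  set.seed(23)
  B <- matrix(runif(20), 5, 4)
  w1 <- entropy_weights(minmax_normalize(make_dm(B)))
  w2 <- entropy_weights(minmax_normalize(make_dm(B[sample(5), ])))
  expect_equal(w1, w2, tolerance = 1e-12)
})

test_that("all-constant matrix is a degenerate input", {
  dm <- make_dm(cbind(c(2, 2), c(7, 7)))
  nm <- suppressWarnings(minmax_normalize(dm))
  expect_error(entropy_weights(nm), "degenerate|no column")
})

test_that("TOPSIS closeness is 1 at the positive ideal and 0 at the negative", {
  dm <- make_dm(cbind(c(1, 0, 0.3), c(1, 0, 0.6)))
  nm <- minmax_normalize(dm)
  res <- topsis_rank(nm, c(c1 = 0.4, c2 = 0.6))
  expect_equal(res$closeness[1], 1)
  expect_equal(res$closeness[2], 0)
  expect_equal(res$rank, c(1L, 3L, 2L))
  expect_equal(res$d_plus[1], 0)
})

test_that("two-point geometry gives closeness (1, 0)", {
  dm <- make_dm(cbind(c(10, 2), c(8, 1)))
  nm <- minmax_normalize(dm)
  res <- topsis_rank(nm, c(c1 = 0.5, c2 = 0.5))
  expect_equal(res$closeness, c(1, 0))
})

test_that("crisp TOPSIS agrees with the literal equation oracle to 1e-12", {
  set.seed(24)
  for (rep in 1:20) {
    B <- matrix(runif(12, 0, 10), 4, 3)
    dirs <- sample(c("benefit", "cost"), 3, replace = TRUE)
    nm <- minmax_normalize(make_dm(B, dirs))
    w <- runif(3); w <- w / sum(w); names(w) <- paste0("c", 1:3)
    got <- topsis_rank(nm, w)$closeness
    want <- oracle_crisp_closeness(oracle_normalize(B, dirs), unname(w))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("the full Shili chain is invariant to affine column rescaling", {
  set.seed(25)
  B <- matrix(runif(40, 10, 500), 8, 5)
  dirs <- c("benefit", "benefit", "cost", "benefit", "cost")
  run <- function(B) {
    nm <- minmax_normalize(make_dm(B, dirs))
    topsis_rank(nm, entropy_weights(nm))
  }
  r1 <- run(B)
  B2 <- sweep(sweep(B, 2, runif(5, 0.2, 7), `*`), 2, runif(5, -5, 30), `+`)
  r2 <- run(B2)
  expect_equal(r1$closeness, r2$closeness, tolerance = 1e-9)
  expect_identical(r1$rank, r2$rank)
})

test_that("identical alternatives are rejected as degenerate", {
  dm <- make_dm(matrix(c(1, 1, 2, 2), 2))
  nm <- suppressWarnings(minmax_normalize(dm))
  expect_error(topsis_rank(nm, c(c1 = 0.5, c2 = 0.5)), "degenerate")
})

test_that("top-fraction retention uses the ceiling and keeps straddling ties", {
  res <- data.frame(id = letters[1:5], name = letters[1:5],
                    closeness = c(0.9, 0.8, 0.5, 0.5, 0.1),
                    rank = 1:5)
  expect_equal(nrow(retain_top_fraction(res, 0.5)$members), 4)  # tie kept
  res$closeness <- c(0.9, 0.8, 0.5, 0.4, 0.1)
  kept <- retain_top_fraction(res, 0.5)
  expect_equal(kept$members$id, c("a", "b", "c"))
  expect_identical(kept$stage_tag, "post_shili")
  expect_equal(nrow(retain_top_fraction(res, 1)$members), 5)
  expect_error(retain_top_fraction(res, 0))
})

test_that("22 ranked alternatives retain 11 at fraction one half", {
  set.seed(26)
  nm <- minmax_normalize(random_dm(22, 5))
  res <- topsis_rank(nm, entropy_weights(nm))
  expect_equal(nrow(retain_top_fraction(res, 0.5)$members), 11)
})
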