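test_that("the seven-term scale carries the canonical parameters", {
  sc <- linguistic_scale()
  expect_identical(names(sc), c("VL", "L", "ML", "M", "MH", "H", "VH"))
  expect_equal(from_linguistic("VH")$upper, c(9, 10, 10, 10, 1, 1))
  expect_equal(from_linguistic("VH")$lower, c(9.5, 10, 10, 10, 0.9, 0.9))
  expect_equal(from_linguistic("VL")$upper, c(0, 1, 1, 3, 1, 1))
  expect_equal(from_linguistic("VL")$lower, c(0.5, 1, 1, 2, 0.9, 0.9))
  expect_equal(from_linguistic("MH")$upper, c(7, 9, 9, 10, 1, 1))
  expect_error(from_linguistic("XX"), "valid terms")
})

test_that("it2fs constructor enforces shape invariants", {
  expect_error(it2fs(c(3, 2, 4, 5, 1, 1), c(3, 3, 4, 4, 1, 1)),
               "nondecreasing")
  expect_error(it2fs(c(1, 2, 3, 4, 1, 1), c(0, 2, 3, 4, 0.9, 0.9)),
               "support")
  expect_error(it2fs(c(1, 2, 3, 4, 0.8, 0.8), c(1, 2, 3, 4, 0.9, 0.9)),
               "heights")
  expect_error(it2fs(c(1, 2, 3, 4, 1.2, 1), c(1, 2, 3, 4, 0.9, 0.9)),
               "\\(0, 1\\]")
})

test_that("scalar weighting scales vertices and keeps heights", {
  vh <- from_linguistic("VH")
  expect_equal(scale_it2fs(1, vh), vh)
  half <- scale_it2fs(0.5, vh)
  expect_equal(half$upper, c(4.5, 5, 5, 5, 1, 1))
  expect_equal(half$lower, c(4.75, 5, 5, 5, 0.9, 0.9))
  zero <- scale_it2fs(0, vh)
  expect_equal(zero$upper[1:4], rep(0, 4))
  expect_equal(zero$upper[5:6], c(1, 1))
  expect_error(scale_it2fs(-0.1, vh), ">= 0")
})

test_that("rank value matches the componentwise oracle on the whole scale", {
  sc <- linguistic_scale()
  for (t in names(sc)) {
    trap2 <- rbind(sc[[t]]$upper, sc[[t]]$lower)
    for (hw in c("heights", "vertex")) {
      rb <- rank_value(sc[[t]], hw = hw)
      expect_equal(rb$rank_value, oracle_rank_value(trap2, hw),
                   tolerance = 1e-12, info = paste(t, hw))
      expect_equal(rb$rank_value, sum(rb$M) - sum(rb$S) / 4 + sum(rb$H),
                   tolerance = 1e-12)
    }
  }
  expect_equal(rank_value(from_linguistic("VH"))$rank_value, 62.700,
               tolerance = 5e-4)
})

test_that("crisp-degenerate sets obey the 6v + 4 closed form", {
  for (v in c(0, 0.37, 1, 2.5, 10)) {
    crisp <- it2fs(c(v, v, v, v, 1, 1), c(v, v, v, v, 1, 1))
    expect_equal(rank_value(crisp)$rank_value, 6 * v + 4,
                 tolerance = 1e-12)
  }
})

test_that("rank value increases strictly along the linguistic scale", {
  sc <- linguistic_scale()
  rv <- vapply(sc, function(v) rank_value(v)$rank_value, numeric(1))
  expect_true(all(diff(rv) > 0))
})

test_that("rank value is affine in the scalar weight", {
  vh <- from_linguistic("MH")
  base <- rank_value(vh)
  slope <- sum(base$M) - sum(base$S) / 4
  for (w in c(0.1, 0.5, 0.9)) {
    expect_equal(rank_value(scale_it2fs(w, vh))$rank_value,
                 w * slope + sum(base$H), tolerance = 1e-12)
  }
})

test_that("benefit normalisation divides by the column max upper endpoint", {
  fm <- fuzzy_decision_matrix(rbind("VH", "VH"), c("a", "b"), "c1")
  nm <- normalize_fuzzy_matrix(fm)
  expect_equal(nm$cells[[1]][[1]]$upper, c(0.9, 1, 1, 1, 1, 1))
  # single-element column: its own a4u maps to 1
  fm2 <- fuzzy_decision_matrix(matrix("ML"), "solo", "c1")
  nm2 <- normalize_fuzzy_matrix(fm2)
  expect_equal(nm2$cells[[1]][[1]]$upper[4], 1)
})

test_that("cost normalisation is the reciprocal reflection", {
  crisp <- function(v) it2fs(c(v, v, v, v, 1, 1), c(v, v, v, v, 1, 1))
  fm <- fuzzy_decision_matrix(rbind("M", "M"), c("a", "b"), "c1")
  fm$cells[[1]][[1]] <- crisp(2)
  fm$cells[[2]][[1]] <- crisp(4)
  nm <- normalize_fuzzy_matrix(fm, "cost")
  expect_equal(nm$cells[[1]][[1]]$upper[1:4], rep(1, 4))
  expect_equal(nm$cells[[2]][[1]]$upper[1:4], rep(0.5, 4))
  fm$cells[[1]][[1]] <- crisp(0)
  expect_error(normalize_fuzzy_matrix(fm, "cost"), "nonpositive")
})

test_that("normalisation preserves ordering and containment invariants", {
  set.seed(31)
  terms <- names(linguistic_scale())
  tmat <- matrix(sample(terms, 12, replace = TRUE), 4, 3)
  fm <- fuzzy_decision_matrix(tmat, paste0("a", 1:4), paste0("c", 1:3))
  nm <- normalize_fuzzy_matrix(fm, c("benefit", "cost", "benefit"))
  for (i in 1:4) for (j in 1:3) {
    v <- nm$cells[[i]][[j]]
    expect_true(all(diff(v$upper[1:4]) >= -1e-12))
    expect_true(all(diff(v$lower[1:4]) >= -1e-12))
    expect_gte(v$lower[1], v$upper[1] - 1e-12)
    expect_lte(v$lower[4], v$upper[4] + 1e-12)
  }
})

test_that("JSON serialisation of the scale is bit-exact", {
  sc <- linguistic_scale()
  for (t in names(sc)) {
    back <- it2fs_from_json(it2fs_to_json(sc[[t]]))
    expect_identical(back$upper, sc[[t]]$upper)
    expect_identical(back$lower, sc[[t]]$lower)
  }
})

test_that("a custom scale loads from YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    LO = list(upper = c(0, 1, 2, 3, 1, 1), lower = c(0.5, 1, 2, 2.5, 0.9, 0.9)),
    HI = list(upper = c(7, 8, 9, 10, 1, 1), lower = c(7.5, 8, 9, 9.5, 0.9, 0.9))),
    path)
  sc <- linguistic_scale(path)
  expect_identical(names(sc), c("LO", "HI"))
  expect_equal(from_linguistic("HI", sc)$upper, c(7, 8, 9, 10, 1, 1))
})
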