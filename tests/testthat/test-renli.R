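renli_w4 <- c(operability = 0.57, recovery = 0.06,
              operational_effect = 0.14, implementation_efficiency = 0.23)

test_that("linguistic matrices read from CSV with term validation", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,name,op,eff", "a,Alpha,MH,VH", "b,Beta,M,M"), path)
  fm <- read_linguistic_matrix(path)
  expect_identical(fm$criteria, c("op", "eff"))
  expect_equal(fm$cells[[1]][[1]]$upper, c(7, 9, 9, 10, 1, 1))  # MH
  expect_identical(fm$terms[2, ], c(op = "M", eff = "M"))
  writeLines(c("id,name,op,eff", "a,Alpha,MH,XX"), path)
  expect_error(read_linguistic_matrix(path), "'XX'.*column 'eff'")
  writeLines(c("id,name,op,eff", "a,Alpha,MH,"), path)
  expect_error(read_linguistic_matrix(path), "empty")
})

test_that("extremes attain closeness one and zero", {
  tmat <- rbind(c("VH", "VH"), c("VL", "VL"), c("M", "ML"))
  fm <- fuzzy_decision_matrix(tmat, c("best", "worst", "mid"),
                              c("c1", "c2"))
  res <- it2f_topsis(fm, c(c1 = 0.5, c2 = 0.5))
  expect_equal(res$closeness[res$id == "best"], 1)
  expect_equal(res$closeness[res$id == "worst"], 0)
  expect_identical(res$rank[res$id == "best"], 1L)
})

test_that("a unit weight on one criterion reproduces that column's rank order", {
  set.seed(41)
  terms <- names(linguistic_scale())
  tmat <- cbind(sample(terms, 5), sample(terms, 5, replace = TRUE))
  fm <- fuzzy_decision_matrix(tmat, paste0("a", 1:5), c("k", "other"))
  res <- it2f_topsis(fm, c(k = 1, other = 0))
  rv <- vapply(seq_len(5), function(i) {
    rank_value(normalize_fuzzy_matrix(fm)$cells[[i]][[1]])$rank_value
  }, numeric(1))
  expect_identical(order(-res$closeness), order(-rv))
})

test_that("fuzzy TOPSIS matches the literal transcription oracle to 1e-12", {
  set.seed(42)
  terms <- names(linguistic_scale())
  for (rep in 1:20) {
    tmat <- matrix(sample(terms, 6, replace = TRUE), 3, 2)
    if (length(unique(tmat[, 1])) == 1 && length(unique(tmat[, 2])) == 1) next
    fm <- fuzzy_decision_matrix(tmat, paste0("a", 1:3), c("c1", "c2"))
    w <- runif(2); w <- w / sum(w); names(w) <- c("c1", "c2")
    for (hw in c("heights", "vertex")) {
      got <- it2f_topsis(fm, w, hw = hw)$closeness
      want <- oracle_it2f_closeness(tmat, unname(w), hw)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("duplicating an alternative leaves the others' closeness unchanged", {
  tmat <- rbind(c("VH", "M"), c("L", "H"), c("ML", "MH"))
  fm <- fuzzy_decision_matrix(tmat, c("a", "b", "c"), c("c1", "c2"))
  res <- it2f_topsis(fm, c(c1 = 0.7, c2 = 0.3))
  fm2 <- fuzzy_decision_matrix(rbind(tmat, tmat[2, ]),
                               c("a", "b", "c", "b-copy"),
                               c("c1", "c2"))
  res2 <- it2f_topsis(fm2, c(c1 = 0.7, c2 = 0.3))
  expect_equal(res2$closeness[match(c("a", "b", "c"), res2$id)],
               res$closeness, tolerance = 1e-12)
})

test_that("crisp judgments reduce fuzzy TOPSIS to crisp TOPSIS", {
  # crisp unit-height cells: Rank = 6v + 4, so closeness must match the
  # crisp engine run on the same max-normalised values
  set.seed(43)
  vals <- matrix(runif(12, 1, 10), 4, 3)
  crisp <- function(v) it2fs(c(v, v, v, v, 1, 1), c(v, v, v, v, 1, 1))
  tmat <- matrix("M", 4, 3)
  fm <- fuzzy_decision_matrix(tmat, paste0("a", 1:4), paste0("c", 1:3))
  for (i in 1:4) for (j in 1:3) fm$cells[[i]][[j]] <- crisp(vals[i, j])
  w <- c(c1 = 0.2, c2 = 0.5, c3 = 0.3)
  res_f <- it2f_topsis(fm, w)
  maxnorm <- sweep(vals, 2, apply(vals, 2, max), `/`)
  res_c <- topsis_rank(maxnorm, w)
  expect_equal(res_f$closeness, res_c$closeness, tolerance = 1e-12)
})

test_that("exact ties break by Shili closeness, then input order", {
  tmat <- rbind(c("M", "M"), c("M", "M"), c("VL", "VL"))
  fm <- fuzzy_decision_matrix(tmat, c("a", "b", "c"), c("c1", "c2"))
  tie <- data.frame(id = c("a", "b", "c"), closeness = c(0.2, 0.8, 0.1))
  res <- it2f_topsis(fm, c(c1 = 0.5, c2 = 0.5), shili_tiebreak = tie)
  expect_identical(res$rank[res$id == "b"], 1L)
  expect_identical(res$rank[res$id == "a"], 2L)
  expect_true(all(res$tied[res$id %in% c("a", "b")]))
  # without tiebreak data, input order wins
  res2 <- it2f_topsis(fm, c(c1 = 0.5, c2 = 0.5))
  expect_identical(res2$rank[res2$id == "a"], 1L)
})

test_that("fully degenerate judgment matrices are rejected", {
  tmat <- matrix("MH", 3, 2)
  fm <- fuzzy_decision_matrix(tmat, paste0("a", 1:3), c("c1", "c2"))
  expect_error(it2f_topsis(fm, c(c1 = 0.5, c2 = 0.5)), "degenerate")
})

test_that("reconstructed Shanghai judgments reproduce the published closeness", {
  # the fixture is synthetic: fitted to the printed nine-decimal values,
  # so this asserts engine consistency with the published pipeline, not
  # an independent reproduction (max fitted deviation 3.93e-4)
  fm <- shanghai_renli_judgments()
  res <- it2f_topsis(fm, renli_w4)
  pub <- shanghai_case()$renli_ranking
  idx <- match(res$id, pub$id)
  expect_lt(max(abs(res$closeness - pub$closeness[idx])), 5e-4)
  expect_identical(res$rank, pub$rank[idx])
  expect_identical(res$name[res$rank == 1],
                   "National Convention and Exhibition Center (Shanghai)")
})
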