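test_that("published training design matches the printed concentration sets", {
  des <- cef_training_design()
  conc <- des$concentrations
  expect_equal(nrow(conc), 16L)
  expect_equal(unname(conc[1, ]), c(18, 0.13, 0.065))
  expect_equal(sort(unique(conc[, "CEF"])), c(18, 20, 24, 26))
  expect_equal(sort(unique(conc[, "7-ACA"])), c(0.13, 0.15, 0.18, 0.2))
  expect_equal(sort(unique(conc[, "5-MER"])), c(0.065, 0.07, 0.085, 0.09))
  # every level exactly 4 times per component
  for (j in 1:3) expect_true(all(table(conc[, j]) == 4))
})

test_that("published test design has 9 mixtures inside the training span", {
  te <- cef_test_design()$concentrations
  tr <- cef_training_design()$concentrations
  expect_equal(nrow(te), 9L)
  expect_equal(unname(te[1, ]), c(25, 0.17, 0.09))
  for (j in 1:3) {
    expect_true(all(te[, j] >= min(tr[, j])))
    expect_true(all(te[, j] <= max(tr[, j])))
  }
})

test_that("coded-level columns of the published design are orthogonal", {
  # direct Pearson correlation of the coded columns as the oracle
  coded <- cef_training_design()$coded_levels
  for (j in 1:2) for (k in (j + 1):3)
    expect_lt(abs(cor(coded[, j], coded[, k])), 1e-10)
})

test_that("balanced design builder satisfies balance and orthogonality for L in 2..5", {
  set.seed(11)
  for (L in 2:5) for (seed in c(1, 7)) {
    lv <- list(a = sort(runif(L)), b = sort(runif(L) * 10), c = seq_len(L))
    des <- build_balanced_design(lv, seed = seed)
    expect_equal(nrow(des$concentrations), L^2)
    rep_check <- validate_design(des)
    ortho <- rep_check[rep_check$check == "orthogonality", ]
    expect_true(all(ortho$pass))
    bal <- rep_check[rep_check$check == "level_balance", ]
    expect_true(all(bal$pass))
    for (j in 1:3) expect_true(all(table(des$coded_levels[, j]) == L))
  }
  # L=2, F=2 is the full factorial
  d22 <- build_balanced_design(list(a = c(1, 2), b = c(3, 4)), seed = 1)
  expect_equal(nrow(unique(d22$coded_levels)), 4L)
})

test_that("design builder is deterministic in its seed and validates inputs", {
  lv <- list(a = 1:4, b = 5:8, c = 9:12)
  d1 <- build_balanced_design(lv, seed = 3)
  d2 <- build_balanced_design(lv, seed = 3)
  d3 <- build_balanced_design(lv, seed = 4)
  expect_identical(d1$concentrations, d2$concentrations)
  expect_false(identical(d1$concentrations, d3$concentrations))
  expect_error(build_balanced_design(list(a = 1:4, b = 1:3), seed = 1),
               "same number of levels")
})

test_that("validate_design reports imbalance and degenerate columns without raising", {
  des <- cef_training_design()
  conc <- des$concentrations
  conc[1, ] <- conc[2, ]   # duplicate one row over another
  rep_bad <- validate_design(design_table(unclass(conc)))
  bal <- rep_bad[rep_bad$check == "level_balance", ]
  expect_true(any(!bal$pass))
  # single-level column: orthogonality reported as skipped
  one <- design_table(cbind(a = rep(1, 4), b = c(1, 2, 1, 2)))
  rep_one <- validate_design(one)
  ortho <- rep_one[rep_one$check == "orthogonality", ]
  expect_true(all(is.na(ortho$pass)))
})

test_that("shipped fixture CSVs match the in-code designs", {
  tr_path <- system.file("extdata", "cef_training_concentrations.csv",
                         package = "speccalib")
  te_path <- system.file("extdata", "cef_test_concentrations.csv",
                         package = "speccalib")
  expect_equal(unclass(read_concentration_csv(tr_path)),
               unclass(cef_training_design()$concentrations),
               ignore_attr = TRUE)
  expect_equal(unclass(read_concentration_csv(te_path)),
               unclass(cef_test_design()$concentrations),
               ignore_attr = TRUE)
  # the shipped synthetic JCAMP spectrum peaks at the analyte's maximum
  jdx <- system.file("extdata", "cef_synthetic_10ugml.jdx",
                     package = "speccalib")
  sp <- read_jcampdx(jdx)
  expect_equal(sp$wavelengths[which.max(sp$absorbance)], 229)
  expect_equal(length(sp$wavelengths), 91L)
})
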