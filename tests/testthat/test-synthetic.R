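test_that("pure spectra are Gaussian-band shaped, linear in concentration", {
  cef <- default_band_models()[["CEF"]]
  s10 <- pure_spectrum(cef, concentration = 10)
  expect_equal(s10$wavelengths[which.max(s10$absorbance)], 229)
  # concentration zero gives the zero spectrum; doubling doubles
  expect_true(all(pure_spectrum(cef, concentration = 0)$absorbance == 0))
  s20 <- pure_spectrum(cef, concentration = 20)
  expect_equal(s20$absorbance, 2 * s10$absorbance)
  expect_error(pure_spectrum(cef, concentration = -1), "non-negative")
})

test_that("noiseless mixtures are exact Beer-Lambert combinations", {
  mods <- default_band_models()
  des <- cef_training_design()
  mx <- mix_spectra(mods, des, sigma = 0, seed = 1)
  # single-component check: row spectra equal concentration-scaled pure shapes
  one <- design_table(cbind(CEF = c(5, 10, 20, 40)))
  m1 <- mix_spectra(mods["CEF"], one, sigma = 0, seed = 1)
  for (i in 1:4)
    expect_equal(unname(unclass(m1$spectra)[i, ]),
                 pure_spectrum(mods$CEF, concentration = c(5, 10, 20, 40)[i])$absorbance)
  # exactly three nonzero singular values (oracle: svd of noiseless X)
  sv <- svd(unclass(mx$spectra))$d
  expect_gt(sv[3] / sv[1], 1e-10)
  expect_lt(sv[4] / sv[1], 1e-12)
  # returned concentrations equal the design
  expect_equal(unclass(mx$concentrations), unclass(des$concentrations),
               ignore_attr = TRUE)
})

test_that("mixing is linear and noiseless X lies in the pure-spectrum span", {
  mods <- default_band_models()
  tr <- cef_training_design()
  te <- cef_test_design()
  mA <- mix_spectra(mods, tr, sigma = 0, seed = 1)$spectra
  # additivity of designs: (A + B) concentrations mix to sum of mixes
  dsum <- design_table(unclass(tr$concentrations) +
                       unclass(tr$concentrations)[16:1, ])
  mB <- mix_spectra(mods, design_table(unclass(tr$concentrations)[16:1, ]),
                    sigma = 0, seed = 1)$spectra
  mS <- mix_spectra(mods, dsum, sigma = 0, seed = 1)$spectra
  expect_equal(unclass(mS), unclass(mA) + unclass(mB), ignore_attr = TRUE)
  # projection onto the pure-component span leaves no residual
  S <- vapply(mods, function(m) pure_spectrum(m)$absorbance, numeric(91))
  X <- unclass(mix_spectra(mods, te, sigma = 0, seed = 1)$spectra)
  proj <- X %*% S %*% solve(crossprod(S)) %*% t(S)
  expect_lt(max(abs(X - proj)), 1e-10)
})

test_that("the default scenario has the documented shapes, overlap and noise behavior", {
  sc <- default_scenario(seed = 5)
  expect_equal(dim(sc$train$spectra), c(16L, 91L))
  expect_equal(dim(sc$train$concentrations), c(16L, 3L))
  expect_equal(dim(sc$test$spectra), c(9L, 91L))
  expect_equal(dim(sc$test$concentrations), c(9L, 3L))
  # heavy pairwise overlap of the pure spectra (direct dot-product oracle)
  S <- vapply(sc$models, function(m) pure_spectrum(m)$absorbance, numeric(91))
  cosv <- function(a, b) sum(a * b) / sqrt(sum(a * a) * sum(b * b))
  for (j in 1:2) for (k in (j + 1):3)
    expect_gte(cosv(S[, j], S[, k]), 0.7)
  # the major component dominates total absorbance in every mixture
  conc <- sc$train$concentrations
  contrib <- vapply(1:3, function(f) conc[, f] * sum(S[, f]), numeric(16))
  expect_true(all(contrib[, 1] > contrib[, 2] + contrib[, 3]))
  # determinism: identical seed, identical matrices
  sc2 <- default_scenario(seed = 5)
  expect_identical(unclass(sc$train$spectra), unclass(sc2$train$spectra))
  sc3 <- default_scenario(seed = 6)
  expect_false(identical(unclass(sc$train$spectra), unclass(sc3$train$spectra)))
})

test_that("mix_spectra validates component matching", {
  mods <- default_band_models()["CEF"]
  expect_error(mix_spectra(mods, cef_training_design(), sigma = 0, seed = 1),
               "missing")
})
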