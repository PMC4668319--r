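test_that("linear SVR recovers an exact linear law within the tube", {
  # 1-D data on the exact line c = 2x
  x <- seq(0.5, 4, length.out = 8)
  X <- spectra_matrix(cbind(x), wavelengths = 229)
  f <- svr_linear(X, 2 * x, epsilon = 0.1, cost = 1000)
  expect_lt(max(abs(residuals(f))), 0.1 + 1e-8)
  # the optimum is the flattest line through the tube: slope
  # 2 - 2 eps / range(x), not the generating slope 2 exactly
  slope_flat <- 2 - 2 * 0.1 / diff(range(x))
  expect_lt(abs(f$weights[1] - slope_flat), 1e-3)
  expect_lte(f$weights[1], 2 + 1e-9)
})

test_that("an over-wide tube yields the zero model", {
  set.seed(3)
  X <- spectra_matrix(matrix(rnorm(20, 1, .2), 5, 4), wavelengths = 210:213)
  y <- c(1, 1.2, 0.9, 1.1, 1.05)
  f <- svr_linear(X, y, epsilon = 2, cost = 10)
  expect_true(all(abs(f$dual_coefficients) < 1e-6))
  expect_equal(length(f$support), 0L)
  # constant prediction at the (biased) center
  p <- predict(f, X)
  expect_lt(diff(range(p)), 1e-6)
})

test_that("dual solution matches a brute-force QP oracle on 3-point problems", {
  for (seed in c(11, 22, 33, 44)) {
    set.seed(seed)
    X <- matrix(rnorm(6, 1, .4), 3, 2)
    colnames(X) <- c(210, 211)
    y <- drop(X %*% c(1, 2)) + rnorm(3, 0, .2)
    eps <- 0.05; C <- 5
    f <- svr_linear(spectra_matrix(X), y, eps, C)
    # oracle works on the same centered data the fit used
    Xc <- f$training_vectors
    yc <- y - f$centering$c_means[[1]]
    K <- tcrossprod(Xc)
    orc <- oracle_svr3_bruteforce(K, yc, eps, C)
    expect_lt(abs(f$objective - orc$objective), 1e-3)
    expect_lte(f$objective, orc$objective + 1e-6)  # never worse than the grid
  }
})

test_that("KKT conditions hold after every fit", {
  for (seed in 1:4) {
    sc <- default_scenario(seed = seed)
    f <- svr_linear(sc$train$spectra, sc$train$concentrations[, 1],
                    epsilon = 0.05, cost = 100)
    beta <- f$dual_coefficients
    alpha <- pmax(beta, 0); alpha_star <- pmax(-beta, 0)
    expect_true(all(alpha >= 0 & alpha <= f$cost + 1e-9))
    expect_true(all(alpha_star >= 0 & alpha_star <= f$cost + 1e-9))
    expect_lt(max(alpha * alpha_star), 1e-6 * f$cost^2)
    expect_lt(abs(sum(beta)), 1e-8 * f$cost)
  }
})

test_that("raising epsilon never increases the support-vector count", {
  sc <- default_scenario(seed = 9)
  X <- sc$train$spectra; y <- sc$train$concentrations[, 1]
  eps_seq <- c(0.01, 0.05, 0.2, 0.5, 1)
  nsv <- vapply(eps_seq, function(e)
    length(svr_linear(X, y, e, 100)$support), integer(1))
  expect_true(all(diff(nsv) <= 0))
})

test_that("weight-vector and kernel-sum predictions coincide", {
  sc <- default_scenario(seed = 5)
  f <- svr_linear(sc$train$spectra, sc$train$concentrations[, 1], 0.02, 280)
  Xnew <- center_apply(f$centering, sc$test$spectra)
  via_w <- (Xnew %*% f$weights)[, 1]
  via_k <- (Xnew %*% t(f$training_vectors) %*% f$dual_coefficients)[, 1]
  expect_lt(max(abs(via_w - via_k)), 1e-10)
})

test_that("SVR agrees with an independent reference implementation", {
  skip_if_not_installed("e1071")
  set.seed(17)
  for (rep in 1:4) {
    I <- 6 + 2 * rep
    X <- matrix(rnorm(I * 5, 1, .3), I, 5)
    colnames(X) <- 210:214
    y <- drop(X %*% rnorm(5, .5, .3)) + rnorm(I, 0, .1)
    eps <- c(0.05, 0.1, 0.2, 0.4)[rep]; C <- c(1, 10, 100, 50)[rep]
    f <- svr_linear(spectra_matrix(X), y, eps, C)
    ref <- e1071::svm(x = X, y = y, type = "eps-regression",
                      kernel = "linear", cost = C, epsilon = eps,
                      scale = FALSE, tolerance = 1e-8)
    expect_lt(max(abs(predict(f, spectra_matrix(X)) -
                      as.numeric(predict(ref, X)))), 1e-4)
  }
})

test_that("SVR validates inputs and degenerate geometry", {
  sc <- default_scenario(seed = 1)
  X <- sc$train$spectra; y <- sc$train$concentrations[, 1]
  expect_error(svr_linear(X, y, -0.1, 10), "epsilon")
  expect_error(svr_linear(X, y, 0.1, 0), "cost")
  Xsame <- spectra_matrix(matrix(1, 4, 3), wavelengths = 210:212)
  expect_error(svr_linear(Xsame, 1:4, 0.1, 10), "degenerate geometry")
})

test_that("SVR models round-trip through JSON with identical predictions", {
  sc <- default_scenario(seed = 8)
  f <- svr_linear(sc$train$spectra, sc$train$concentrations[, 1], 0.02, 280)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_svr_json(f, tmp)
  g <- read_svr_json(tmp)
  expect_equal(predict(g, sc$test$spectra), predict(f, sc$test$spectra),
               tolerance = 1e-12)
})
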