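# Hyperparameter selection: Monte-Carlo ("bootstrap") selection of the PLS
# latent-variable count, and grid-searched k-fold cross-validation for the
# linear SVR tube width and penalty.

#' Root mean square error between known and predicted concentrations
#'
#' `sqrt(mean((known - predicted)^2))`. Used for RMSEC (training
#' autoprediction), RMSEP (independent test set) and RMSECV (held-out
#' folds) alike; only the role of the inputs differs.
#'
#' @param known Numeric vector of reference concentrations (ug/mL).
#' @param predicted Numeric vector of predictions, same length.
#' @return Non-negative scalar (ug/mL).
#' @export
rmsep <- function(known, predicted) {
  known <- as.numeric(known); predicted <- as.numeric(predicted)
  if (length(known) == 0L) stop("empty input")
  if (length(known) != length(predicted)) stop("length mismatch")
  sqrt(mean((known - predicted)^2))
}

# PLS1 prediction path: fit once at ncomp_max, return test predictions for
# every component count 1..ncomp_max (matrix n_test x A_max).
pls1_path_predict <- function(X_train, y_train, X_test, ncomp_max) {
  fit <- pls1(X_train, y_train, ncomp_max)
  Xc <- center_apply(fit$centering, X_test)
  A <- fit$ncomp
  out <- matrix(NA_real_, nrow(X_test), ncomp_max)
  for (a in seq_len(A)) {
    W <- fit$x_weights[, seq_len(a), drop = FALSE]
    P <- fit$x_loadings[, seq_len(a), drop = FALSE]
    q <- fit$y_loadings[seq_len(a)]
    B <- W %*% solve(crossprod(P, W), q)
    out[, a] <- (Xc %*% B)[, 1] + fit$centering$c_means[[1]]
  }
  if (A < ncomp_max) out[, seq(A + 1L, ncomp_max)] <- out[, A]
  out
}

#' Select the PLS latent-variable count by repeated random splitting
#'
#' For each of `n_iterations` iterations the training set is divided into
#' two-thirds (inner training split, mean-centered anew every iteration via
#' the model fit) and one-third (inner test split); a PLS1 model is fitted
#' for every candidate component count and the held-out RMSEP recorded.
#' The default selection rule is the one-standard-error parsimony rule:
#' the fewest components whose mean RMSEP lies within one standard error
#' (of the Monte-Carlo mean at the minimizing count) of the minimum. With
#' `rule = "min"` the global minimum is taken instead, ties broken toward
#' fewer components. The parsimony rule is the robust choice when the
#' RMSEP curve flattens at the effective rank, where the global minimum is
#' decided by Monte-Carlo fluctuation alone.
#'
#' @param X Training spectra, I x J with I >= 6.
#' @param conc Single-component training concentrations, length I.
#' @param ncomp_max Largest candidate component count; must satisfy
#'   `ncomp_max <= round(2 I / 3) - 1`.
#' @param n_iterations Number of random splits (default 1000).
#' @param seed Integer seed; fixed seed gives identical results.
#' @param rule `"onese"` (default) or `"min"`, see above.
#' @param replace If `TRUE`, draw the inner training split with
#'   replacement (resampling variant) and hold out the unselected rows;
#'   the default `FALSE` divides the set without replacement.
#' @return Object of class `"lv_selection"`: list with
#'   `candidate_components`, `mean_rmsep` and `se_rmsep` (ug/mL per
#'   candidate), `n_iterations`, `selected`, `rule`, `seed`.
#' @export
select_ncomp_bootstrap <- function(X, conc, ncomp_max, n_iterations = 1000L,
                                   seed = 1L, rule = c("onese", "min"),
                                   replace = FALSE) {
  rule <- match.arg(rule)
  y <- as_response(conc, nrow(X))
  I <- nrow(X)
  if (I < 6L) stop("need >= 6 samples for a 2/3-1/3 split")
  n_train <- round(2 * I / 3)
  ncomp_max <- as.integer(ncomp_max)
  if (ncomp_max < 1L || ncomp_max > n_train - 1L)
    stop(sprintf("ncomp_max must be in 1..%d for I = %d", n_train - 1L, I))
  acc <- matrix(0, n_iterations, ncomp_max)
  with_seed(seed, {
    for (it in seq_len(n_iterations)) {
      if (replace) {
        idx <- sample.int(I, n_train, replace = TRUE)
        hold <- setdiff(seq_len(I), unique(idx))
        if (length(hold) == 0L || length(unique(idx)) < 2L) {
          acc[it, ] <- NA_real_
          next
        }
      } else {
        idx <- sample.int(I, n_train)
        hold <- setdiff(seq_len(I), idx)
      }
      a_max <- min(ncomp_max, length(unique(idx)) - 1L)
      pred <- pls1_path_predict(X[idx, , drop = FALSE], y[idx],
                                X[hold, , drop = FALSE], a_max)
      for (a in seq_len(ncomp_max))
        acc[it, a] <- rmsep(y[hold], pred[, min(a, a_max)])
    }
  })
  mean_rmsep <- colMeans(acc, na.rm = TRUE)
  n_ok <- colSums(!is.na(acc))
  se_rmsep <- apply(acc, 2L, stats::sd, na.rm = TRUE) / sqrt(pmax(n_ok, 1L))
  amin <- which.min(mean_rmsep)  # which.min takes the first (fewest LVs) on ties
  sel <- if (rule == "min") amin
         else min(which(mean_rmsep <= mean_rmsep[amin] + se_rmsep[amin]))
  structure(list(candidate_components = seq_len(ncomp_max),
                 mean_rmsep = mean_rmsep, se_rmsep = se_rmsep,
                 n_iterations = as.integer(n_iterations),
                 selected = as.integer(sel), rule = rule,
                 seed = as.integer(seed), replace = replace),
            class = "lv_selection")
}

#' @export
print.lv_selection <- function(x, ...) {
  cat("Latent-variable selection over ", x$n_iterations,
      " random 2/3-1/3 splits\n", sep = "")
  tab <- data.frame(LV = x$candidate_components,
                    mean_RMSEP = x$mean_rmsep)
  print(tab, row.names = FALSE, digits = 5)
  cat("Selected: ", x$selected, " latent variable(s)\n", sep = "")
  invisible(x)
}

#' Plot the mean RMSEP curve of a latent-variable selection
#'
#' @param x An `"lv_selection"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.lv_selection <- function(x, ...) {
  graphics::plot(x$candidate_components, x$mean_rmsep, type = "b",
                 xlab = "Number of PLS components",
                 ylab = "Mean RMSEP (ug/mL)", ...)
  graphics::abline(v = x$selected, lty = 3)
  invisible(x)
}

#' Default epsilon and C grids for the SVR search
#'
#' Log-spaced grids spanning the documented primary ranges: epsilon in
#' \[0.01, 1\], C in \[30, 1000\].
#' @return List with `epsilon` and `cost` numeric vectors.
#' @export
default_svr_grids <- function() {
  list(epsilon = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1),
       cost = c(30, 56, 100, 180, 280, 560, 1000))
}

#' Grid-search k-fold cross-validation for linear SVR hyperparameters
#'
#' For every (epsilon, C) pair on the grid, performs k-fold
#' cross-validation: each fold is predicted by a model trained (and
#' mean-centered) on the remaining samples, and RMSECV is the root mean
#' square error over all held-out predictions. The selected pair minimizes
#' RMSECV; ties break toward smaller C, then smaller epsilon.
#'
#' @param X Training spectra, I x J.
#' @param conc Single-component training concentrations, length I.
#' @param epsilon_grid,cost_grid Candidate values (defaults
#'   [default_svr_grids()]).
#' @param n_folds Number of folds (default 4); must divide I.
#' @param seed Integer seed for the fold assignment.
#' @return Object of class `"svr_grid_search"`: list with `table` (data
#'   frame epsilon/cost/rmsecv), `selected` (named list `epsilon`, `cost`),
#'   `fold_assignment` (integer vector of fold ids per sample), `n_folds`,
#'   `seed`.
#' @export
svr_grid_search <- function(X, conc, epsilon_grid = default_svr_grids()$epsilon,
                            cost_grid = default_svr_grids()$cost,
                            n_folds = 4L, seed = 1L) {
  y <- as_response(conc, nrow(X))
  I <- nrow(X)
  n_folds <- as.integer(n_folds)
  if (length(epsilon_grid) == 0L || length(cost_grid) == 0L)
    stop("empty hyperparameter grid")
  if (n_folds < 2L || I %% n_folds != 0L)
    stop(sprintf("n_folds (%d) must be >= 2 and divide the sample count (%d)",
                 n_folds, I))
  folds <- with_seed(seed, sample(rep(seq_len(n_folds), each = I / n_folds)))
  grid <- expand.grid(epsilon = epsilon_grid, cost = cost_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rmsecv <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pred <- numeric(I)
    for (k in seq_len(n_folds)) {
      hold <- which(folds == k)
      fit <- svr_linear(X[-hold, , drop = FALSE], y[-hold],
                        epsilon = grid$epsilon[g], cost = grid$cost[g])
      pred[hold] <- predict(fit, X[hold, , drop = FALSE])
    }
    rmsecv[g] <- rmsep(y, pred)
  }
  ord <- order(rmsecv, grid$cost, grid$epsilon)
  best <- ord[1]
  structure(list(table = cbind(grid, rmsecv = rmsecv),
                 selected = list(epsilon = grid$epsilon[best],
                                 cost = grid$cost[best]),
                 fold_assignment = folds, n_folds = n_folds,
                 seed = as.integer(seed)),
            class = "svr_grid_search")
}

#' @export
print.svr_grid_search <- function(x, ...) {
  cat("SVR grid search, ", x$n_folds, "-fold cross-validation over ",
      nrow(x$table), " (epsilon, C) pairs\n", sep = "")
  cat("Selected: epsilon = ", format(x$selected$epsilon), ", C = ",
      format(x$selected$cost), " (RMSECV = ",
      format(min(x$table$rmsecv), digits = 5), " ug/mL)\n", sep = "")
  invisible(x)
}
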