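# PLS1 multivariate calibration (NIPALS, orthogonal-scores convention).
#
# The bilinear model: X = T P' + E, c = T q + f, with scores T built from
# both the spectra and the single response. For one response the weight
# vector of each latent variable is obtained directly (no inner iteration):
#   w_a = X_a' y_a / ||X_a' y_a||,  t_a = X_a w_a,
#   q_a = t_a' y_a / t_a' t_a,      p_a = X_a' t_a / t_a' t_a,
#   X_{a+1} = X_a - t_a p_a'        (deflation of X only; y deflated
#                                    equivalently for the residual f).
# Prediction uses the regression vector B = W (P' W)^{-1} q on centered
# spectra, adding back the training response mean.

#' Fit a PLS1 calibration model
#'
#' Mean-centers spectra and response internally (the stored centering is
#' applied to any new data at prediction time), then extracts `ncomp`
#' latent variables by NIPALS deflation.
#'
#' @param X Training spectra: a [spectra_matrix()] or numeric matrix with
#'   wavelength column names, I x J.
#' @param conc Single-component training concentrations (ug/mL): numeric
#'   vector of length I or one-column [conc_table()].
#' @param ncomp Number of latent variables A, `1 <= A <= min(I-1, J)`.
#' @return Object of class `"pls1"` with components `ncomp`, `scores` (T,
#'   I x A), `x_loadings` (P, J x A), `x_weights` (W, J x A), `y_loadings`
#'   (q, length A), `coefficients` (B, length J, centered scale),
#'   `centering`, `fitted.values`, `residuals` (f), `x_residual` (E),
#'   `component` (response name if known).
#' @seealso [predict.pls1()], [select_ncomp_bootstrap()]
#' @export
pls1 <- function(X, conc, ncomp) {
  comp_name <- if (is.matrix(conc) && !is.null(colnames(conc)))
    colnames(conc)[1] else "response"
  y <- as_response(conc, nrow(X))
  I <- nrow(X); J <- ncol(X)
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > min(I - 1L, J))
    stop(sprintf("ncomp must be in 1..min(I-1, J) = 1..%d", min(I - 1L, J)))
  if (stats::sd(y) == 0) stop("degenerate response: zero variance")
  ctr <- center_fit(X, y)
  Xc <- center_apply(ctr, X)
  yc <- y - ctr$c_means[[1]]
  x0norm <- sqrt(sum(Xc^2))
  W <- P <- matrix(0, J, ncomp)
  Tm <- matrix(0, I, ncomp)
  q <- numeric(ncomp)
  Xa <- Xc; ya <- yc
  a_done <- 0L
  for (a in seq_len(ncomp)) {
    if (sqrt(sum(Xa^2)) < 1e-12 * max(x0norm, 1)) {
      warning(sprintf("X residual exhausted after %d component(s); returning a smaller model", a_done))
      break
    }
    w <- crossprod(Xa, ya)[, 1]
    wn <- sqrt(sum(w^2))
    if (wn < 1e-14 * max(x0norm, 1)) {
      warning(sprintf("no covariance left after %d component(s); returning a smaller model", a_done))
      break
    }
    w <- w / wn
    t <- Xa %*% w
    tt <- sum(t^2)
    q[a] <- sum(t * ya) / tt
    p <- crossprod(Xa, t)[, 1] / tt
    Xa <- Xa - tcrossprod(t, p)
    ya <- ya - q[a] * t[, 1]
    W[, a] <- w; P[, a] <- p; Tm[, a] <- t; q[a] <- q[a]
    a_done <- a
  }
  if (a_done == 0L) stop("could not extract any latent variable")
  W <- W[, seq_len(a_done), drop = FALSE]
  P <- P[, seq_len(a_done), drop = FALSE]
  Tm <- Tm[, seq_len(a_done), drop = FALSE]
  q <- q[seq_len(a_done)]
  B <- W %*% solve(crossprod(P, W), q)
  fitted <- (Xc %*% B)[, 1] + ctr$c_means[[1]]
  structure(list(ncomp = a_done, scores = Tm, x_loadings = P, x_weights = W,
                 y_loadings = q, coefficients = B[, 1], centering = ctr,
                 fitted.values = fitted, residuals = y - fitted,
                 x_residual = Xa, component = comp_name,
                 call = match.call()),
            class = "pls1")
}

#' Predict concentrations from a PLS1 model
#'
#' Applies the stored training centering to the new spectra, projects
#' through the regression vector and adds back the training response mean.
#'
#' @param object A `"pls1"` model.
#' @param newdata Spectra on the model's wavelength grid. Omit to return
#'   fitted values.
#' @param ... Unused.
#' @return Numeric vector of predicted concentrations (ug/mL).
#' @export
predict.pls1 <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L,
    dimnames = list(NULL, format_num(object$centering$wavelengths)))
  Xc <- center_apply(object$centering, newdata)
  (Xc %*% object$coefficients)[, 1] + object$centering$c_means[[1]]
}

#' @export
coef.pls1 <- function(object, ...) object$coefficients

#' @export
residuals.pls1 <- function(object, ...) object$residuals

#' @export
fitted.pls1 <- function(object, ...) object$fitted.values

#' @export
print.pls1 <- function(x, ...) {
  cat("PLS1 calibration model (", x$ncomp, " latent variable",
      if (x$ncomp > 1) "s", ") for '", x$component, "'\n", sep = "")
  cat("  spectra: ", nrow(x$scores), " samples x ",
      length(x$coefficients), " wavelengths\n", sep = "")
  cat("  RMSEC: ", format(rmsep(x$fitted.values + x$residuals,
                                x$fitted.values), digits = 5),
      " ug/mL\n", sep = "")
  invisible(x)
}

#' @export
summary.pls1 <- function(object, ...) {
  # modelled X sum of squares per component (orthogonal scores)
  tss <- colSums(object$scores^2) * colSums(object$x_loadings^2)
  y <- object$fitted.values + object$residuals
  out <- list(ncomp = object$ncomp, component = object$component,
              x_var = tss, rmsec = rmsep(y, object$fitted.values),
              r2 = 1 - sum(object$residuals^2) / sum((y - mean(y))^2))
  class(out) <- "summary.pls1"
  out
}

#' @export
print.summary.pls1 <- function(x, ...) {
  cat("PLS1 model for '", x$component, "': ", x$ncomp,
      " latent variables\n", sep = "")
  cat("  per-LV modelled X sum of squares: ",
      paste(format(x$x_var, digits = 4), collapse = ", "), "\n", sep = "")
  cat("  RMSEC = ", format(x$rmsec, digits = 5), " ug/mL,  R^2 = ",
      format(x$r2, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Serialize a PLS1 model to JSON
#'
#' Writes grid, centering means, weights, loadings and y-loadings in a
#' plain JSON layout; [read_pls1_json()] restores a model that predicts
#' identically.
#'
#' @param object A `"pls1"` model.
#' @param path Output file path.
#' @export
write_pls1_json <- function(object, path) {
  payload <- list(
    type = "pls1", ncomp = object$ncomp, component = object$component,
    wavelengths = object$centering$wavelengths,
    x_means = unname(object$centering$x_means),
    c_mean = unname(object$centering$c_means[[1]]),
    x_weights = unname(object$x_weights),
    x_loadings = unname(object$x_loadings),
    y_loadings = unname(object$y_loadings),
    coefficients = unname(object$coefficients))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(NULL)
}

#' Restore a PLS1 model from JSON
#' @param path File written by [write_pls1_json()].
#' @return A `"pls1"` model usable with [predict.pls1()] (fit-time fields
#'   such as scores and residuals are absent).
#' @export
read_pls1_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$type) || p$type != "pls1") stop("not a pls1 model file")
  ctr <- structure(list(wavelengths = p$wavelengths, x_means = p$x_means,
                        c_means = c(response = p$c_mean)),
                   class = "centering")
  structure(list(ncomp = p$ncomp, x_weights = as.matrix(p$x_weights),
                 x_loadings = as.matrix(p$x_loadings),
                 y_loadings = p$y_loadings, coefficients = p$coefficients,
                 centering = ctr, component = p$component),
            class = "pls1")
}
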