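# Linear epsilon-insensitive support vector regression.
#
# The standard dual in z = (alpha, alpha*):
#   minimize  1/2 z' Q z + c' z,   Q = [[K, -K], [-K, K]],
#             c = (eps - y, eps + y)
#   subject to sum(alpha) - sum(alpha*) = 0,  0 <= z <= C,
# with K the linear-kernel Gram matrix of the centered spectra. The solver
# is a primal-dual interior-point method on this box-and-one-equality QP:
# each Newton step solves a (2I+1)-dimensional KKT system, which for the
# sample sizes of calibration designs (I of order tens) is immediate, and
# the central-path barrier handles the rank-deficient Q that heavily
# collinear spectra produce without the zigzagging coordinate methods
# suffer there. beta = alpha - alpha* are the usual dual coefficients.

#' Fit a linear epsilon-SVR calibration model
#'
#' Mean-centers spectra and response internally (stored centering is
#' applied to new data at prediction time), then solves the epsilon-SVR
#' dual for the linear kernel.
#'
#' @param X Training spectra: a [spectra_matrix()] or numeric matrix with
#'   wavelength column names, I x J, I >= 2.
#' @param conc Single-component training concentrations (ug/mL), length I.
#' @param epsilon Half-width of the insensitive tube (in centered
#'   concentration units), >= 0.
#' @param cost Penalty constant C bounding the dual coefficients, > 0.
#' @param tol Convergence tolerance on the scaled duality gap and KKT
#'   residuals (default 1e-10).
#' @param max_iter Iteration budget for the interior-point solver (default
#'   200 Newton steps); exceeding it is an error.
#' @return Object of class `"svr_linear"` with `dual_coefficients`
#'   (beta = alpha - alpha*), `bias` (b, centered scale), `epsilon`,
#'   `cost`, `weights` (w = X_c' beta, length J), `training_vectors`
#'   (centered training spectra), `centering`, `fitted.values`,
#'   `residuals`, `objective` (final dual objective, minimization form),
#'   `support` (indices with |beta| > 1e-8 C), `component`.
#' @seealso [predict.svr_linear()], [svr_grid_search()]
#' @export
svr_linear <- function(X, conc, epsilon, cost, tol = 1e-10,
                       max_iter = 200L) {
  comp_name <- if (is.matrix(conc) && !is.null(colnames(conc)))
    colnames(conc)[1] else "response"
  y <- as_response(conc, nrow(X))
  if (epsilon < 0) stop("epsilon must be non-negative")
  if (cost <= 0) stop("cost must be positive")
  if (nrow(X) < 2L) stop("need >= 2 training samples")
  ctr <- center_fit(X, y)
  Xc <- center_apply(ctr, X)
  if (sum(Xc^2) == 0)
    stop("degenerate geometry: all training spectra are identical")
  yc <- y - ctr$c_means[[1]]
  K <- tcrossprod(Xc)
  sol <- solve_svr_dual(K, yc, epsilon, cost, tol, max_iter)
  w <- crossprod(Xc, sol$beta)[, 1]
  b <- svr_bias(sol$beta, yc, sol$Kbeta, epsilon, cost)
  fitted <- (Xc %*% w)[, 1] + b + ctr$c_means[[1]]
  sv <- which(abs(sol$beta) > 1e-8 * cost)
  structure(list(dual_coefficients = sol$beta, bias = b, epsilon = epsilon,
                 cost = cost, weights = w, training_vectors = Xc,
                 centering = ctr, fitted.values = fitted,
                 residuals = y - fitted, objective = sol$objective,
                 iterations = sol$iterations, support = sv, component = comp_name,
                 call = match.call()),
            class = "svr_linear")
}

# Primal-dual interior-point solve of the eps-SVR dual in z = (alpha,
# alpha*). Perturbed KKT conditions are Newton-iterated with a fixed
# centering factor; each step solves the symmetric (2I+1) KKT system.
# Returns beta = alpha - alpha*, the kernel expansion K beta, the dual
# objective (minimization form) and the iteration count.
solve_svr_dual <- function(K, y, epsilon, cost, tol, max_iter) {
  I <- length(y)
  n <- 2L * I
  Q <- rbind(cbind(K, -K), cbind(-K, K))
  cvec <- c(epsilon - y, epsilon + y)
  a <- c(rep(1, I), rep(-1, I))        # equality constraint a'z = 0
  scale <- max(abs(y), epsilon, 1)
  z <- rep(min(cost / 2, scale), n)    # strictly interior start
  s <- cost - z
  lam <- rep(scale, n); mu <- rep(scale, n); nu <- 0
  obj <- function(zz) 0.5 * sum(zz * (Q %*% zz)) + sum(cvec * zz)
  iters <- 0L
  repeat {
    iters <- iters + 1L
    if (iters > max_iter)
      stop(sprintf("SVR dual solver did not converge within the iteration budget of %d interior-point steps", max_iter))
    Qz <- (Q %*% z)[, 1]
    rd <- Qz + cvec + nu * a - lam + mu
    rp <- sum(a * z)
    gap <- (sum(z * lam) + sum(s * mu)) / (2 * n)
    if (max(abs(rd)) < tol * scale * max(1, cost) &&
        abs(rp) < tol * max(1, cost) && gap < tol * scale^2) break
    tau <- 0.1 * gap
    # cap the barrier diagonal: coordinates pinned at a bound otherwise
    # blow up the KKT system's condition number near convergence
    d <- pmin(lam / z + mu / s, 1e13 * max(1, mean(diag(Q))))
    H <- Q
    diag(H) <- diag(H) + d
    rhs <- -rd + (tau - z * lam) / z - (tau - s * mu) / s
    # KKT system [H a; a' 0] [dz; dnu] = [rhs; -rp]
    M <- rbind(cbind(H, a), c(a, 0))
    sol <- tryCatch(solve(M, c(rhs, -rp)), error = function(e) {
      M2 <- M
      diag(M2)[seq_len(n)] <- diag(M2)[seq_len(n)] + 1e-8 * max(diag(H))
      tryCatch(solve(M2, c(rhs, -rp)), error = function(e2) NULL)
    })
    if (is.null(sol)) {
      # KKT system numerically unsolvable: accept the iterate if it is
      # already essentially converged, otherwise report non-convergence
      if (gap < 1e-6 * scale^2 && abs(rp) < 1e-6 * max(1, cost)) break
      stop("SVR dual solver hit a numerically singular KKT system before convergence")
    }
    dz <- sol[seq_len(n)]; dnu <- sol[n + 1L]
    dlam <- (tau - z * lam - lam * dz) / z
    dmu <- (tau - s * mu + mu * dz) / s
    step_to <- function(v, dv) {
      neg <- dv < 0
      if (!any(neg)) 1 else min(1, 0.995 * min(-v[neg] / dv[neg]))
    }
    alpha <- min(step_to(z, dz), step_to(s, -dz),
                 step_to(lam, dlam), step_to(mu, dmu))
    z <- z + alpha * dz
    s <- cost - z
    lam <- lam + alpha * dlam
    mu <- mu + alpha * dmu
    nu <- nu + alpha * dnu
  }
  beta <- z[seq_len(I)] - z[I + seq_len(I)]
  # snap dual coefficients that the barrier left marginally off their
  # bound or off zero
  snap <- 1e-12 * cost
  beta[abs(beta) < snap] <- 0
  beta[beta > cost - snap] <- cost
  beta[beta < -cost + snap] <- -cost
  Kb <- (K %*% beta)[, 1]
  list(beta = beta, Kbeta = Kb,
       objective = 0.5 * sum(beta * Kb) - sum(y * beta) +
         epsilon * sum(abs(beta)),
       iterations = iters)
}

# KKT bias: average the equality values over unbounded support vectors;
# fall back to the midpoint of the KKT-feasible interval.
svr_bias <- function(beta, y, Kb, epsilon, cost) {
  r <- y - Kb
  svtol <- 1e-8 * cost
  up_free <- beta > svtol & beta < cost - svtol      # residual = +eps
  dn_free <- beta < -svtol & beta > -cost + svtol    # residual = -eps
  vals <- c(r[up_free] - epsilon, r[dn_free] + epsilon)
  if (length(vals)) return(mean(vals))
  b_up <- min(c(r[abs(beta) <= svtol] + epsilon,
                r[beta >= cost - svtol] - epsilon, Inf))
  b_lo <- max(c(r[abs(beta) <= svtol] - epsilon,
                r[beta <= -cost + svtol] + epsilon, -Inf))
  if (!is.finite(b_lo) && !is.finite(b_up)) return(0)
  if (!is.finite(b_lo)) return(b_up)
  if (!is.finite(b_up)) return(b_lo)
  (b_lo + b_up) / 2
}

#' Predict concentrations from a linear SVR model
#'
#' Computes `w . x + b` on the centered scale and adds back the training
#' response mean; identical (to numerical precision) to the kernel-sum
#' form `sum_i beta_i (x_i . x) + b`.
#'
#' @param object A `"svr_linear"` model.
#' @param newdata Spectra on the model's wavelength grid; omit for fitted
#'   values.
#' @param ... Unused.
#' @return Numeric vector of predicted concentrations (ug/mL).
#' @export
predict.svr_linear <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L,
    dimnames = list(NULL, format_num(object$centering$wavelengths)))
  Xc <- center_apply(object$centering, newdata)
  (Xc %*% object$weights)[, 1] + object$bias + object$centering$c_means[[1]]
}

#' @export
coef.svr_linear <- function(object, ...) object$weights

#' @export
residuals.svr_linear <- function(object, ...) object$residuals

#' @export
fitted.svr_linear <- function(object, ...) object$fitted.values

#' @export
print.svr_linear <- function(x, ...) {
  cat("Linear eps-SVR calibration model for '", x$component, "'\n", sep = "")
  cat("  epsilon = ", format(x$epsilon), ", C = ", format(x$cost),
      "; support vectors: ", length(x$support), "/",
      length(x$dual_coefficients), "\n", sep = "")
  cat("  RMSEC: ", format(rmsep(x$fitted.values + x$residuals,
                                x$fitted.values), digits = 5),
      " ug/mL\n", sep = "")
  invisible(x)
}

#' @export
summary.svr_linear <- function(object, ...) {
  y <- object$fitted.values + object$residuals
  out <- list(component = object$component, epsilon = object$epsilon,
              cost = object$cost, n_sv = length(object$support),
              n = length(object$dual_coefficients),
              rmsec = rmsep(y, object$fitted.values),
              objective = object$objective, iterations = object$iterations)
  class(out) <- "summary.svr_linear"
  out
}

#' @export
print.summary.svr_linear <- function(x, ...) {
  cat("Linear eps-SVR for '", x$component, "': epsilon = ",
      format(x$epsilon), ", C = ", format(x$cost), "\n", sep = "")
  cat("  ", x$n_sv, " of ", x$n, " samples are support vectors; dual objective ",
      format(x$objective, digits = 8), " after ", x$iterations, " interior-point steps\n",
      sep = "")
  cat("  RMSEC = ", format(x$rmsec, digits = 5), " ug/mL\n", sep = "")
  invisible(x)
}

#' Serialize a linear SVR model to JSON
#'
#' @param object A `"svr_linear"` model.
#' @param path Output file path.
#' @export
write_svr_json <- function(object, path) {
  payload <- list(
    type = "svr_linear", component = object$component,
    epsilon = object$epsilon, cost = object$cost, bias = object$bias,
    wavelengths = object$centering$wavelengths,
    x_means = unname(object$centering$x_means),
    c_mean = unname(object$centering$c_means[[1]]),
    dual_coefficients = unname(object$dual_coefficients),
    training_vectors = unname(object$training_vectors),
    weights = unname(object$weights))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(NULL)
}

#' Restore a linear SVR model from JSON
#' @param path File written by [write_svr_json()].
#' @return A `"svr_linear"` model usable with [predict.svr_linear()].
#' @export
read_svr_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$type) || p$type != "svr_linear") stop("not an svr_linear model file")
  ctr <- structure(list(wavelengths = p$wavelengths, x_means = p$x_means,
                        c_means = c(response = p$c_mean)),
                   class = "centering")
  structure(list(dual_coefficients = p$dual_coefficients, bias = p$bias,
                 epsilon = p$epsilon, cost = p$cost, weights = p$weights,
                 training_vectors = as.matrix(p$training_vectors),
                 centering = ctr, component = p$component,
                 support = which(abs(p$dual_coefficients) > 1e-8 * p$cost)),
            class = "svr_linear")
}
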