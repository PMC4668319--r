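# Evaluate an expression under a fixed RNG seed, restoring the caller's
# RNG state afterwards so package functions never disturb the session.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# single-response concentration input: accept a numeric vector or a
# one-column slice of a conc_table
as_response <- function(c, n = NULL) {
  if (is.matrix(c)) {
    if (ncol(c) != 1L) stop("expected a single-component concentration vector")
    c <- c[, 1]
  }
  c <- as.numeric(c)
  if (!is.null(n) && length(c) != n)
    stop("response length does not match number of spectra")
  if (any(!is.finite(c))) stop("non-finite concentrations")
  c
}

check_grid_match <- function(model_wl, new_wl) {
  if (length(model_wl) != length(new_wl) ||
      any(abs(model_wl - new_wl) > 1e-9))
    stop("wavelength grid does not match the fitted model's grid")
  invisible(TRUE)
}
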