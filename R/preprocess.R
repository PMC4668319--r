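# Mean centering of spectra and responses. Centering state is fitted once
# on training data and applied unchanged to any new data, so test spectra
# are always centered with training means (no leakage).

#' Fit mean-centering state
#'
#' Stores the column means of a spectra matrix and the mean of each
#' response column, for later application to training or new data.
#'
#' @param X A [spectra_matrix()] (or numeric matrix), I >= 2 rows.
#' @param conc Optional response(s): numeric vector or [conc_table()].
#' @return Object of class `"centering"`: list with `wavelengths`,
#'   `x_means` (length J), `c_means` (named, possibly length 0).
#' @export
center_fit <- function(X, conc = NULL) {
  if (nrow(X) < 2L) stop("need >= 2 samples to fit centering")
  x_means <- colMeans(unclass_mat(X))
  c_means <- numeric(0)
  if (!is.null(conc)) {
    cm <- if (is.matrix(conc)) colMeans(unclass_mat(conc))
          else c(response = mean(as.numeric(conc)))
    c_means <- cm
  }
  structure(list(wavelengths = as.numeric(colnames(X)), x_means = x_means,
                 c_means = c_means),
            class = "centering")
}

#' Apply stored centering to spectra
#'
#' Subtracts the stored training column means. Applying to the fitting
#' matrix yields zero column means.
#'
#' @param state A `"centering"` object from [center_fit()].
#' @param X Spectra on the same wavelength grid.
#' @return Centered numeric matrix (plain matrix; no longer a
#'   `spectra_matrix` since centered values may be negative and are on a
#'   different scale).
#' @export
center_apply <- function(state, X) {
  check_grid_match(state$wavelengths, as.numeric(colnames(X)))
  sweep(unclass_mat(X), 2L, state$x_means, "-")
}

#' Undo stored centering on spectra
#'
#' @param state A `"centering"` object.
#' @param Xc Centered matrix with matching column count.
#' @return Matrix with training means added back.
#' @export
center_invert <- function(state, Xc) {
  if (ncol(Xc) != length(state$x_means)) stop("column count mismatch")
  sweep(as.matrix(Xc), 2L, state$x_means, "+")
}

#' @export
print.centering <- function(x, ...) {
  cat("Centering state: ", length(x$x_means), " spectral means",
      if (length(x$c_means)) paste0("; response mean(s): ",
        paste(sprintf("%s=%.4g", names(x$c_means), x$c_means),
              collapse = ", ")) else "", "\n", sep = "")
  invisible(x)
}
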