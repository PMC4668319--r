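# Beer-Lambert spectral mixture simulator.
#
# Pure-component spectra are sums of Gaussian absorption bands; mixtures are
# linear in concentration at unit path length (Beer-Lambert), with additive
# homoscedastic Gaussian instrument noise. This emulates the statistical
# structure multivariate UV calibration assumes: three heavily overlapped
# absorbers, a major analyte dominating total absorbance, impurities at or
# below ~3% of the major component on a molar basis.

#' Gaussian band model for a pure-component spectrum
#'
#' @param component Component name.
#' @param centers Band centers (nm).
#' @param widths Band standard deviations (nm), all > 0.
#' @param coefs Peak absorptivity-like coefficients (AU per ug/mL at unit
#'   path length), all >= 0.
#' @return Object of class `"band_model"`.
#' @export
band_model <- function(component, centers, widths, coefs) {
  if (length(centers) < 1L) stop("at least one band required")
  if (length(widths) != length(centers) || length(coefs) != length(centers))
    stop("centers, widths and coefs must have equal length")
  if (any(widths <= 0)) stop("band widths must be positive")
  if (any(coefs < 0)) stop("band coefficients must be non-negative")
  structure(list(component = as.character(component)[1],
                 centers = as.numeric(centers), widths = as.numeric(widths),
                 coefs = as.numeric(coefs)),
            class = "band_model")
}

#' @export
print.band_model <- function(x, ...) {
  cat("Band model '", x$component, "': ", length(x$centers),
      " Gaussian band(s) at ", paste(x$centers, collapse = ", "),
      " nm\n", sep = "")
  invisible(x)
}

#' Default pure-component band models (CEF, 7-ACA, 5-MER)
#'
#' Fixture band parameters emulating three heavily overlapped UV absorbers:
#' the major analyte CEF with absorbance maximum at 229 nm and two
#' impurities whose spectra overlap it strongly (pairwise cosine similarity
#' 0.78-0.92 on the canonical grid). Impurity per-mass band coefficients
#' are set so that, accounting for molecular weight (roughly 667, 272 and
#' 116 g/mol), both impurities are strong chromophores of a few times the
#' major component's molar absorptivity: at their trace concentration
#' levels (at most ~3\% of CEF on a molar basis) this keeps each impurity's
#' spectral contribution well above the instrument noise floor, so the
#' mixture system has a detectable chemical rank of three. Overridable
#' wherever a list of band models is accepted.
#'
#' @return Named list of three [band_model()] objects.
#' @export
default_band_models <- function() {
  list(
    "CEF"   = band_model("CEF",   c(229, 262), c(13, 16), c(0.078, 0.012)),
    "7-ACA" = band_model("7-ACA", c(248, 216), c(14, 9),  c(0.48, 0.19)),
    "5-MER" = band_model("5-MER", c(218, 246), c(9, 17),  c(1.12, 0.48)))
}

#' Evaluate a pure-component spectrum at a concentration
#'
#' Absorbance at wavelength w is
#' `concentration * sum_k coef_k * exp(-(w - center_k)^2 / (2 width_k^2))`:
#' Gaussian bands, linear in concentration (Beer-Lambert at unit path
#' length).
#'
#' @param model A [band_model()].
#' @param grid Wavelength grid (nm), default [uv_grid()].
#' @param concentration Concentration in ug/mL, >= 0.
#' @return A [uv_spectrum()].
#' @export
pure_spectrum <- function(model, grid = uv_grid(), concentration = 1) {
  if (concentration < 0) stop("concentration must be non-negative")
  uv_spectrum(grid, concentration * band_shape(model, grid),
              label = model$component)
}

band_shape <- function(model, grid) {
  s <- numeric(length(grid))
  for (k in seq_along(model$centers))
    s <- s + model$coefs[k] *
      exp(-(grid - model$centers[k])^2 / (2 * model$widths[k]^2))
  s
}

#' Simulate mixture spectra on a design
#'
#' `X[i, j] = sum_f c[i, f] * s_f(w_j) + e[i, j]` with `e` iid
#' Gaussian(0, sigma^2) from the seeded generator. Component names of the
#' band models must match the design's components (order taken from the
#' design).
#'
#' @param models Named list of [band_model()] objects, one per design
#'   component.
#' @param design A [design_table()].
#' @param grid Wavelength grid (nm).
#' @param sigma Additive noise standard deviation (AU), >= 0.
#' @param seed Integer seed for the noise generator.
#' @return List with `spectra` (a [spectra_matrix()]) and `concentrations`
#'   (a [conc_table()] equal to the design's concentrations).
#' @export
mix_spectra <- function(models, design, grid = uv_grid(), sigma = 0.002,
                        seed = 1L) {
  conc <- design$concentrations
  comps <- colnames(conc)
  model_names <- vapply(models, `[[`, character(1), "component")
  names(models) <- model_names
  if (!all(comps %in% model_names))
    stop("band models missing for component(s): ",
         paste(setdiff(comps, model_names), collapse = ", "))
  if (sigma < 0) stop("sigma must be non-negative")
  S <- vapply(comps, function(f) band_shape(models[[f]], grid),
              numeric(length(grid)))          # J x F pure shapes at unit conc
  X <- unclass_mat(conc) %*% t(S)             # I x J noiseless mixtures
  if (sigma > 0)
    X <- X + with_seed(seed, matrix(stats::rnorm(length(X), 0, sigma),
                                    nrow(X), ncol(X)))
  list(spectra = spectra_matrix(X, wavelengths = grid,
                                samples = rownames(conc)),
       concentrations = conc)
}

#' Default end-to-end synthetic calibration scenario
#'
#' Simulates the full study layout: the published 16-mixture training and
#' 9-mixture test designs, the three default overlapped band models, and
#' additive Gaussian noise of 0.002 AU (a typical double-beam UV noise
#' floor). Training and test noise are drawn from independent streams
#' derived from `seed`.
#'
#' @param seed Integer seed.
#' @param sigma Noise standard deviation in AU (default 0.002).
#' @param models Band models (default [default_band_models()]).
#' @param grid Wavelength grid (default [uv_grid()]).
#' @return List with elements `train` and `test`, each a list with
#'   `spectra` and `concentrations`, plus `models`, `sigma`, `seed`.
#' @export
default_scenario <- function(seed = 1L, sigma = 0.002,
                             models = default_band_models(),
                             grid = uv_grid()) {
  seed <- as.integer(seed) %% 1073741824L  # keep derived seeds inside 32-bit
  tr <- mix_spectra(models, cef_training_design(), grid, sigma,
                    seed = seed)
  te <- mix_spectra(models, cef_test_design(), grid, sigma,
                    seed = seed + 1073741L)
  list(train = tr, test = te, models = models, sigma = sigma, seed = seed)
}
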