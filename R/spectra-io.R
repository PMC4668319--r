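#' Canonical UV wavelength grid
#'
#' The default instrument grid: 210 to 300 nm inclusive in 1 nm steps
#' (91 points), the range over which the spectra this package models are
#' recorded.
#'
#' @return Numeric vector of wavelengths in nm.
#' @export
uv_grid <- function() 210:300

#' Construct a single UV spectrum
#'
#' A spectrum is a wavelength grid (nm) with one absorbance value (AU) per
#' grid point, plus a label. Wavelengths must be strictly increasing.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly
#'   increasing.
#' @param absorbance Numeric vector of absorbances (AU), same length.
#' @param label Character identifier for the sample.
#' @return An object of class `"uv_spectrum"`: a list with elements
#'   `wavelengths`, `absorbance`, `label`.
#' @export
uv_spectrum <- function(wavelengths, absorbance, label = "spectrum") {
  wavelengths <- as.numeric(wavelengths)
  absorbance <- as.numeric(absorbance)
  if (length(wavelengths) != length(absorbance))
    stop("wavelengths and absorbance must have equal length")
  if (length(wavelengths) < 1L) stop("empty spectrum")
  if (any(!is.finite(wavelengths)) || any(!is.finite(absorbance)))
    stop("non-finite values in spectrum")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  structure(list(wavelengths = wavelengths, absorbance = absorbance,
                 label = as.character(label)[1]),
            class = "uv_spectrum")
}

#' @export
print.uv_spectrum <- function(x, ...) {
  cat("UV spectrum '", x$label, "': ", length(x$wavelengths), " points, ",
      min(x$wavelengths), "-", max(x$wavelengths), " nm, max A = ",
      format(max(x$absorbance), digits = 4), " AU at ",
      x$wavelengths[which.max(x$absorbance)], " nm\n", sep = "")
  invisible(x)
}

#' Construct a spectra matrix (samples x wavelengths)
#'
#' Holds the data matrix X of a calibration: one row per sample, one column
#' per wavelength. All rows share a single strictly increasing grid.
#'
#' @param values Numeric matrix, I samples x J wavelengths (AU).
#' @param wavelengths Numeric grid of length J (nm). Defaults to numeric
#'   column names of `values`.
#' @param samples Optional character row labels.
#' @return Numeric matrix of class `"spectra_matrix"` with wavelengths as
#'   column names.
#' @export
spectra_matrix <- function(values, wavelengths = NULL, samples = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(wavelengths)) {
    if (is.null(colnames(values)))
      stop("wavelengths must be given or present as column names")
    wavelengths <- suppressWarnings(as.numeric(colnames(values)))
  }
  wavelengths <- as.numeric(wavelengths)
  if (anyNA(wavelengths)) stop("non-numeric wavelengths")
  if (length(wavelengths) != ncol(values))
    stop("wavelength grid length does not match column count")
  if (nrow(values) < 1L || ncol(values) < 1L) stop("empty spectra matrix")
  if (any(diff(wavelengths) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (any(!is.finite(values))) stop("non-finite absorbance values")
  colnames(values) <- format_num(wavelengths)
  if (!is.null(samples)) rownames(values) <- samples
  else if (is.null(rownames(values)))
    rownames(values) <- paste0("s", seq_len(nrow(values)))
  class(values) <- c("spectra_matrix", class(values))
  values
}

#' Wavelength grid of a spectra matrix
#' @param x A `spectra_matrix` (or any matrix with numeric column names).
#' @return Numeric vector of wavelengths (nm).
#' @export
wavelengths <- function(x) as.numeric(colnames(x))

#' @export
print.spectra_matrix <- function(x, ...) {
  wl <- wavelengths(x)
  cat("Spectra matrix: ", nrow(x), " samples x ", ncol(x), " wavelengths (",
      min(wl), "-", max(wl), " nm)\n", sep = "")
  invisible(x)
}

#' Construct a concentration table (samples x components)
#'
#' Holds per-sample concentrations in ug/mL for each mixture component.
#' Values must be non-negative and finite.
#'
#' @param values Numeric matrix or data frame, I samples x F components.
#' @param components Optional character component names (default: column
#'   names of `values`).
#' @param samples Optional character row labels.
#' @return Numeric matrix of class `"conc_table"`.
#' @export
conc_table <- function(values, components = NULL, samples = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) < 1L) stop("concentration table needs at least one component")
  if (!is.null(components)) colnames(values) <- components
  if (is.null(colnames(values)))
    colnames(values) <- paste0("comp", seq_len(ncol(values)))
  if (any(!is.finite(values))) stop("non-finite concentrations")
  if (any(values < 0)) stop("concentrations must be non-negative")
  if (!is.null(samples)) rownames(values) <- samples
  else if (is.null(rownames(values)))
    rownames(values) <- paste0("s", seq_len(nrow(values)))
  class(values) <- c("conc_table", class(values))
  values
}

# drop class so arithmetic on subsets behaves as plain matrices
unclass_mat <- function(x) {
  x <- unclass(x)
  class(x) <- NULL
  as.matrix(x)
}

format_num <- function(x) formatC(x, format = "fg", digits = 15, width = 1)

#' Read a spectra matrix from delimited text
#'
#' Expected layout: first row is the wavelength header (nm, strictly
#' increasing); each subsequent row is one sample's absorbances. An optional
#' leading label column (non-numeric header cell) is used for sample names.
#'
#' @param path File path.
#' @param sep Field delimiter (default comma).
#' @return A [spectra_matrix()].
#' @export
read_spectra_csv <- function(path, sep = ",") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("spectra file needs a header and >= 1 data row")
  cells <- strsplit(lines, sep, fixed = TRUE)
  hdr <- trimws(cells[[1]])
  has_label <- is.na(suppressWarnings(as.numeric(hdr[1])))
  wl_cells <- if (has_label) hdr[-1] else hdr
  wl <- suppressWarnings(as.numeric(wl_cells))
  if (anyNA(wl)) stop("non-numeric wavelength in header")
  if (any(diff(wl) <= 0)) stop("wavelength grid must be strictly increasing")
  ncell <- length(hdr)
  vals <- matrix(NA_real_, length(cells) - 1L, length(wl))
  labs <- character(length(cells) - 1L)
  for (i in seq_along(cells)[-1]) {
    row <- trimws(cells[[i]])
    if (length(row) != ncell)
      stop(sprintf("ragged row %d: %d fields, expected %d", i, length(row), ncell))
    labs[i - 1L] <- if (has_label) row[1] else paste0("s", i - 1L)
    num <- suppressWarnings(as.numeric(if (has_label) row[-1] else row))
    if (anyNA(num)) {
      j <- which(is.na(num))[1]
      stop(sprintf("non-numeric cell at row %d, column %d", i, j + has_label))
    }
    vals[i - 1L, ] <- num
  }
  spectra_matrix(vals, wavelengths = wl, samples = labs)
}

#' Write a spectra matrix as delimited text
#'
#' Inverse of [read_spectra_csv()]; values are written with 15 significant
#' digits so the round trip preserves them past 12 significant digits.
#'
#' @param x A `spectra_matrix`.
#' @param path File path.
#' @param sep Field delimiter (default comma).
#' @export
write_spectra_csv <- function(x, path, sep = ",") {
  wl <- wavelengths(x)
  hdr <- paste(c("sample", format_num(wl)), collapse = sep)
  rows <- vapply(seq_len(nrow(x)), function(i)
    paste(c(rownames(x)[i], format_num(unclass_mat(x)[i, ])), collapse = sep),
    character(1))
  writeLines(c(hdr, rows), path)
  invisible(NULL)
}

#' Read a concentration table from delimited text
#'
#' First row holds component names; each subsequent row one sample's
#' concentrations (ug/mL). A leading `sample` column is used for row labels.
#'
#' @inheritParams read_spectra_csv
#' @return A [conc_table()].
#' @export
read_concentration_csv <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) >= 1L && tolower(names(df)[1]) == "sample") {
    labs <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  } else labs <- paste0("s", seq_len(nrow(df)))
  conc_table(as.matrix(df), samples = labs)
}

#' Write a concentration table as delimited text
#'
#' @param x A `conc_table`.
#' @inheritParams write_spectra_csv
#' @export
write_concentration_csv <- function(x, path, sep = ",") {
  if (ncol(x) < 1L) stop("concentration table has no components")
  hdr <- paste(c("sample", colnames(x)), collapse = sep)
  rows <- vapply(seq_len(nrow(x)), function(i)
    paste(c(rownames(x)[i], format_num(unclass_mat(x)[i, ])), collapse = sep),
    character(1))
  writeLines(c(hdr, rows), path)
  invisible(NULL)
}

#' Read a single-block JCAMP-DX spectrum
#'
#' Supports the AFFN `XYDATA=(X++(Y..Y))` dialect of JCAMP-DX 4.24: the
#' uncompressed form UV spectrophotometer software typically exports. Y
#' values are scaled by `##YFACTOR`, the grid is reconstructed from
#' `##FIRSTX`/`##LASTX`/`##NPOINTS`. Compressed dialects (DIF/DUP/SQZ/PAC
#' ordinate forms) are rejected explicitly.
#'
#' @param path File path to a single-block JCAMP-DX file.
#' @return A [uv_spectrum()].
#' @export
read_jcampdx <- function(path) {
  lines <- readLines(path)
  get_field <- function(name) {
    hit <- grep(paste0("^##", name, "="), lines, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub("^##[^=]*=", "", hit[1]))
  }
  xy_at <- grep("^##XYDATA=", lines, ignore.case = TRUE)
  if (!length(xy_at)) stop("JCAMP-DX format error: missing ##XYDATA block")
  dialect <- trimws(sub("^##XYDATA=", "", lines[xy_at[1]], ignore.case = TRUE))
  if (gsub("\\s", "", dialect) != "(X++(Y..Y))")
    stop("unsupported JCAMP-DX dialect: ", dialect, " (only (X++(Y..Y)) AFFN)")
  num_field <- function(name, default = NULL) {
    v <- get_field(name)
    if (is.null(v)) {
      if (is.null(default)) stop("JCAMP-DX format error: missing ##", name)
      return(default)
    }
    out <- suppressWarnings(as.numeric(v))
    if (is.na(out)) stop("JCAMP-DX format error: non-numeric ##", name)
    out
  }
  firstx <- num_field("FIRSTX")
  lastx <- num_field("LASTX")
  npoints <- num_field("NPOINTS")
  yfactor <- num_field("YFACTOR", 1)
  end_at <- grep("^##END", lines[-seq_len(xy_at[1])], ignore.case = TRUE)
  stop_at <- if (length(end_at)) xy_at[1] + end_at[1] - 1L else length(lines)
  body <- lines[seq(xy_at[1] + 1L, stop_at)]
  body <- body[!grepl("^##", body)]
  toks <- unlist(strsplit(trimws(body), "[\\s,;]+", perl = TRUE))
  toks <- toks[nzchar(toks)]
  if (any(grepl("[A-DF-Za-df-z%@]", toks)))
    stop("unsupported JCAMP-DX dialect: compressed (SQZ/DIF/DUP) ordinates")
  vals <- suppressWarnings(as.numeric(toks))
  if (anyNA(vals)) stop("JCAMP-DX format error: non-numeric data token")
  # each data line starts with an X value followed by Y values; reconstruct
  # by dropping the leading X token of every line
  ys <- numeric(0)
  for (ln in body) {
    t <- unlist(strsplit(trimws(ln), "[\\s,;]+", perl = TRUE))
    t <- t[nzchar(t)]
    if (length(t) < 2L) next
    ys <- c(ys, as.numeric(t[-1]))
  }
  if (length(ys) != npoints)
    stop(sprintf("JCAMP-DX format error: NPOINTS=%d but %d ordinates found",
                 npoints, length(ys)))
  # FIRSTX/LASTX carry actual axis values; XFACTOR only rescales raw X tokens,
  # which the reconstructed grid does not use
  x <- firstx + (lastx - firstx) * (seq_len(npoints) - 1) / max(npoints - 1, 1)
  title <- get_field("TITLE")
  uv_spectrum(x, ys * yfactor, label = if (is.null(title)) basename(path) else title)
}
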