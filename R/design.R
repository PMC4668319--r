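# Multilevel multifactor calibration designs.
#
# The shipped fixture is the published 4-level, 3-factor design for
# cefoperazone sodium (CEF) with its impurities 7-aminocephalosporanic acid
# (7-ACA) and 5-mercapto-1-methyl-tetrazole (5-MER): 16 training mixtures in
# which every component takes each of its 4 concentration levels exactly 4
# times and the mean-centered coded-level columns are mutually orthogonal,
# plus 9 independent test mixtures inside the training concentration space.

#' Construct a design table
#'
#' @param concentrations I x F numeric matrix of concentrations (ug/mL),
#'   components as named columns.
#' @return Object of class `"design_table"`: a list with `concentrations`
#'   (a [conc_table()]), `coded_levels` (I x F integer matrix, level index
#'   0..L-1 by ascending concentration) and `level_values` (per-component
#'   sorted unique concentrations).
#' @export
design_table <- function(concentrations) {
  conc <- conc_table(concentrations)
  level_values <- lapply(seq_len(ncol(conc)), function(j) sort(unique(conc[, j])))
  names(level_values) <- colnames(conc)
  coded <- vapply(seq_len(ncol(conc)), function(j)
    match(conc[, j], level_values[[j]]) - 1L,
    integer(nrow(conc)))
  coded <- matrix(coded, nrow = nrow(conc),
                  dimnames = dimnames(conc))
  structure(list(concentrations = conc, coded_levels = coded,
                 level_values = level_values),
            class = "design_table")
}

#' @export
print.design_table <- function(x, ...) {
  cat("Calibration design: ", nrow(x$concentrations), " mixtures x ",
      ncol(x$concentrations), " components (",
      paste(colnames(x$concentrations), collapse = ", "), ")\n", sep = "")
  cat("Levels per component: ",
      paste(vapply(x$level_values, length, integer(1)), collapse = ", "),
      "\n", sep = "")
  print(x$concentrations[, , drop = FALSE])
  invisible(x)
}

# Published concentrations (ug/mL): 16 training mixtures, 9 test mixtures.
.cef_train <- matrix(c(
  18, 0.13, 0.065,
  18, 0.15, 0.07,
  20, 0.15, 0.09,
  20, 0.20, 0.07,
  26, 0.15, 0.065,
  20, 0.13, 0.085,
  18, 0.18, 0.085,
  24, 0.18, 0.07,
  24, 0.15, 0.085,
  20, 0.18, 0.065,
  24, 0.13, 0.09,
  18, 0.20, 0.09,
  26, 0.20, 0.085,
  26, 0.18, 0.09,
  24, 0.20, 0.065,
  26, 0.13, 0.07), ncol = 3, byrow = TRUE,
  dimnames = list(NULL, c("CEF", "7-ACA", "5-MER")))

.cef_test <- matrix(c(
  25, 0.17, 0.09,
  19, 0.14, 0.07,
  22, 0.18, 0.075,
  21, 0.14, 0.08,
  23, 0.15, 0.065,
  25, 0.20, 0.085,
  19, 0.13, 0.08,
  22, 0.16, 0.07,
  21, 0.16, 0.08), ncol = 3, byrow = TRUE,
  dimnames = list(NULL, c("CEF", "7-ACA", "5-MER")))

#' Published 16-mixture training design (CEF / 7-ACA / 5-MER)
#'
#' The 4-level, 3-factor training design: CEF levels \{18, 20, 24, 26\}
#' ug/mL; 7-ACA \{0.13, 0.15, 0.18, 0.2\}; 5-MER \{0.065, 0.07, 0.085,
#' 0.09\}. Impurity amounts correspond to at most about 3\% of CEF on a
#' molar basis.
#'
#' @return A [design_table()] with 16 rows.
#' @export
cef_training_design <- function() design_table(.cef_train)

#' Published 9-mixture independent test set (CEF / 7-ACA / 5-MER)
#'
#' Nine mixtures distinct from the training set but inside its per-component
#' concentration span.
#'
#' @return A [design_table()] with 9 rows.
#' @export
cef_test_design <- function() design_table(.cef_test)

#' Build a balanced L-level, F-factor calibration design
#'
#' Constructs an L^2-run design in which every factor takes each of its L
#' levels exactly L times and the mean-centered coded-level columns are
#' exactly mutually orthogonal. Construction: full factorial in the first
#' two coded factors (a, b); factor j >= 3 is (a + k_j * b) mod L with k_j
#' chosen so that k_j and all pairwise differences are coprime with L (this
#' guarantees zero covariance between coded columns). The seed selects a
#' per-factor cyclic relabeling of levels, which preserves both balance and
#' exact orthogonality; construction is deterministic given the seed.
#'
#' @param level_values Named list: per component, the L ascending
#'   concentration values (ug/mL). All components must have the same L >= 2.
#' @param seed Integer; selects among equivalent constructions.
#' @return A [design_table()] with L^2 rows.
#' @export
build_balanced_design <- function(level_values, seed = 1L) {
  if (!is.list(level_values) || length(level_values) < 2L)
    stop("need a named list of level values for >= 2 factors")
  L <- unique(vapply(level_values, length, integer(1)))
  if (length(L) != 1L)
    stop("all components must have the same number of levels")
  if (L < 2L) stop("need >= 2 levels")
  nf <- length(level_values)
  if (is.null(names(level_values)))
    names(level_values) <- paste0("comp", seq_len(nf))
  # multipliers for factors 3..nf: k and all pairwise differences coprime to L
  ks <- integer(0)
  for (k in seq_len(L - 1L)) {
    ok <- gcd(k, L) == 1L && all(gcd(abs(k - ks), L) == 1L)
    if (ok) ks <- c(ks, k)
    if (length(ks) >= nf - 2L) break
  }
  if (length(ks) < nf - 2L)
    stop(sprintf("no orthogonal modular construction for %d factors at %d levels",
                 nf, L))
  ab <- expand.grid(a = 0:(L - 1L), b = 0:(L - 1L))
  coded <- matrix(0L, L * L, nf)
  coded[, 1] <- ab$a
  coded[, 2] <- ab$b
  for (j in seq_len(nf - 2L))
    coded[, j + 2L] <- (ab$a + ks[j] * ab$b) %% L
  # seeded cyclic relabeling per factor (preserves balance and orthogonality)
  shifts <- with_seed(seed, sample.int(L, nf, replace = TRUE)) - 1L
  for (j in seq_len(nf)) coded[, j] <- (coded[, j] + shifts[j]) %% L
  conc <- vapply(seq_len(nf), function(j)
    sort(level_values[[j]])[coded[, j] + 1L], numeric(L * L))
  colnames(conc) <- names(level_values)
  design_table(conc)
}

gcd <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) == 0L || length(b) == 0L) return(integer(0))
  out <- integer(max(length(a), length(b)))
  a <- rep_len(a, length(out)); b <- rep_len(b, length(out))
  for (i in seq_along(out)) {
    x <- a[i]; y <- b[i]
    while (y != 0L) { t <- x %% y; x <- y; y <- t }
    out[i] <- x
  }
  out
}

#' Validate a calibration design
#'
#' Checks, without raising: level balance (each level the same number of
#' times per factor), pairwise orthogonality of mean-centered coded-level
#' columns (Pearson correlation), and per-component span coverage (more
#' than one distinct level). Degenerate single-level columns are reported
#' as skipped for orthogonality.
#'
#' @param design A [design_table()].
#' @param tol Orthogonality tolerance on |Pearson r| (default 1e-10).
#' @return Data frame of class `"design_validation"`, one row per check:
#'   `check`, `component`, `value`, `pass` (NA = skipped).
#' @export
validate_design <- function(design, tol = 1e-10) {
  coded <- design$coded_levels
  nf <- ncol(coded)
  rows <- list()
  for (j in seq_len(nf)) {
    lv <- design$level_values[[j]]
    counts <- tabulate(coded[, j] + 1L, nbins = length(lv))
    rows[[length(rows) + 1L]] <- data.frame(
      check = "level_balance", component = colnames(coded)[j],
      value = max(counts) - min(counts),
      pass = length(unique(counts)) == 1L, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      check = "span_coverage", component = colnames(coded)[j],
      value = diff(range(lv)),
      pass = length(lv) > 1L, stringsAsFactors = FALSE)
  }
  for (j in seq_len(nf - 1L)) for (k in seq((j + 1L), nf)) {
    nm <- paste(colnames(coded)[j], colnames(coded)[k], sep = ":")
    if (stats::sd(coded[, j]) == 0 || stats::sd(coded[, k]) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        check = "orthogonality", component = nm, value = NA_real_,
        pass = NA, stringsAsFactors = FALSE)
    } else {
      r <- stats::cor(coded[, j], coded[, k])
      rows[[length(rows) + 1L]] <- data.frame(
        check = "orthogonality", component = nm, value = abs(r),
        pass = abs(r) <= tol, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("design_validation", class(out))
  out
}

#' @export
print.design_validation <- function(x, ...) {
  df <- as.data.frame(x)
  df$status <- ifelse(is.na(df$pass), "skipped", ifelse(df$pass, "pass", "FAIL"))
  print(df[, c("check", "component", "value", "status")], row.names = FALSE)
  invisible(x)
}
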