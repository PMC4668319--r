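# End-to-end orchestration: simulate (or load) spectra, select
# hyperparameters, fit both calibration models, evaluate on training and
# test sets, and export every artifact with the seeds that produced it.

#' Build a pipeline configuration
#'
#' @param mode `"simulate"` (generate the default synthetic scenario) or
#'   `"load"` (read spectra/concentration CSVs from `paths`).
#' @param out_dir Output directory for artifacts.
#' @param seed Master integer seed; simulation, split and fold seeds are
#'   derived from it.
#' @param sigma Simulation noise SD in AU (simulate mode).
#' @param n_iterations Random splits for latent-variable selection.
#' @param ncomp_max Largest candidate LV count.
#' @param epsilon_grid,cost_grid SVR search grids.
#' @param n_folds Cross-validation folds for the SVR search.
#' @param alpha Significance level for reporting.
#' @param plots If `TRUE`, write diagnostic PNG plots (RMSEP-vs-LV curve,
#'   RMSEP comparison bars).
#' @param paths Load mode: named list with `train_spectra`, `train_conc`,
#'   `test_spectra`, `test_conc` CSV paths.
#' @param component Response component to calibrate (default `"CEF"`).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(mode = c("simulate", "load"), out_dir = tempfile("run"),
                            seed = 1L, sigma = 0.002, n_iterations = 1000L,
                            ncomp_max = 6L,
                            epsilon_grid = default_svr_grids()$epsilon,
                            cost_grid = default_svr_grids()$cost,
                            n_folds = 4L, alpha = 0.05, plots = FALSE,
                            paths = NULL, component = "CEF") {
  mode <- match.arg(mode)
  if (mode == "load") {
    need <- c("train_spectra", "train_conc", "test_spectra", "test_conc")
    if (is.null(paths) || !all(need %in% names(paths)))
      stop("load mode requires paths: ", paste(need, collapse = ", "))
    missing <- !vapply(paths[need], file.exists, logical(1))
    if (any(missing))
      stop("missing input file(s): ",
           paste(unlist(paths[need][missing]), collapse = ", "))
  }
  seed <- as.integer(as.numeric(seed) %% 1073741824)  # stay inside 32-bit
  structure(list(mode = mode, out_dir = out_dir, seed = seed,
                 sigma = sigma, n_iterations = as.integer(n_iterations),
                 ncomp_max = as.integer(ncomp_max),
                 epsilon_grid = epsilon_grid, cost_grid = cost_grid,
                 n_folds = as.integer(n_folds), alpha = alpha,
                 plots = isTRUE(plots), paths = paths,
                 component = component),
            class = "pipeline_config")
}

#' Run the full calibration pipeline
#'
#' Stages: acquire data (simulate or load), validate shapes, select the
#' PLS latent-variable count by random splitting, grid-search the SVR
#' hyperparameters by k-fold cross-validation, fit both models on the full
#' training set, evaluate training (RMSEC) and test (RMSEP) assay reports,
#' and write all artifacts (CSV tables, JSON models and selections, a
#' plain-text log, optional PNG plots) under `config$out_dir`. Identical
#' config and seed give identical numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the fitted models, selection objects,
#'   assay reports and the artifact paths.
#' @export
run_pipeline <- function(config) {
  stage <- "configuration"
  result <- tryCatch({
    if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    log_lines <- character(0)
    logit <- function(...) {
      line <- sprintf(...)
      log_lines <<- c(log_lines, paste0(format(length(log_lines) + 1L), ": ", line))
    }

    stage <- "data"
    if (config$mode == "simulate") {
      sc <- default_scenario(seed = config$seed, sigma = config$sigma)
      Xtr <- sc$train$spectra; Ctr <- sc$train$concentrations
      Xte <- sc$test$spectra;  Cte <- sc$test$concentrations
      logit("data: simulated default scenario, seed=%d, sigma=%g AU",
            config$seed, config$sigma)
    } else {
      Xtr <- read_spectra_csv(config$paths$train_spectra)
      Ctr <- read_concentration_csv(config$paths$train_conc)
      Xte <- read_spectra_csv(config$paths$test_spectra)
      Cte <- read_concentration_csv(config$paths$test_conc)
      logit("data: loaded from %s (+3 more files)", config$paths$train_spectra)
    }
    if (nrow(Xtr) %% config$n_folds != 0L)
      stop(sprintf("n_folds=%d does not divide the %d training samples",
                   config$n_folds, nrow(Xtr)))
    if (!config$component %in% colnames(Ctr))
      stop("component '", config$component, "' absent from concentration table")
    ytr <- Ctr[, config$component]
    yte <- Cte[, config$component]

    stage <- "latent-variable selection"
    lv <- select_ncomp_bootstrap(Xtr, ytr, ncomp_max = config$ncomp_max,
                                 n_iterations = config$n_iterations,
                                 seed = config$seed + 1L)
    logit("lv-selection: %d iterations, seed=%d, selected A=%d",
          lv$n_iterations, lv$seed, lv$selected)

    stage <- "svr grid search"
    gs <- svr_grid_search(Xtr, ytr, epsilon_grid = config$epsilon_grid,
                          cost_grid = config$cost_grid,
                          n_folds = config$n_folds, seed = config$seed + 2L)
    logit("grid-search: %d-fold CV, seed=%d, selected epsilon=%g C=%g",
          gs$n_folds, gs$seed, gs$selected$epsilon, gs$selected$cost)

    stage <- "model fitting"
    pls_fit <- pls1(Xtr, ytr, ncomp = lv$selected)
    svr_fit <- svr_linear(Xtr, ytr, epsilon = gs$selected$epsilon,
                          cost = gs$selected$cost)
    logit("fit: pls1 A=%d; svr epsilon=%g C=%g, %d support vectors",
          pls_fit$ncomp, svr_fit$epsilon, svr_fit$cost, length(svr_fit$support))

    stage <- "evaluation"
    reports <- list(
      pls_train = assay_report(ytr, predict(pls_fit), "calibration"),
      pls_test  = assay_report(yte, predict(pls_fit, Xte), "prediction"),
      svr_train = assay_report(ytr, predict(svr_fit), "calibration"),
      svr_test  = assay_report(yte, predict(svr_fit, Xte), "prediction"))
    for (nm in names(reports))
      logit("evaluate: %s mean recovery %.2f%%, RMSE %.4f ug/mL", nm,
            reports[[nm]]$mean_recovery, reports[[nm]]$rmse)

    stage <- "export"
    out <- function(f) file.path(config$out_dir, f)
    write_spectra_csv(Xtr, out("train_spectra.csv"))
    write_concentration_csv(Ctr, out("train_concentrations.csv"))
    write_spectra_csv(Xte, out("test_spectra.csv"))
    write_concentration_csv(Cte, out("test_concentrations.csv"))
    for (nm in names(reports)) write_assay_csv(reports[[nm]], out(paste0(nm, ".csv")))
    utils::write.csv(data.frame(components = lv$candidate_components,
                                mean_rmsep = lv$mean_rmsep),
                     out("lv_curve.csv"), row.names = FALSE)
    utils::write.csv(gs$table, out("svr_grid.csv"), row.names = FALSE)
    jsonlite::write_json(list(
      seed = config$seed,
      lv = list(selected = lv$selected, seed = lv$seed,
                n_iterations = lv$n_iterations),
      svr = list(epsilon = gs$selected$epsilon, cost = gs$selected$cost,
                 seed = gs$seed, n_folds = gs$n_folds)),
      out("selection.json"), auto_unbox = TRUE, digits = NA)
    write_pls1_json(pls_fit, out("pls_model.json"))
    write_svr_json(svr_fit, out("svr_model.json"))
    if (config$plots) {
      grDevices::png(out("lv_curve.png"), width = 700, height = 500)
      plot(lv, main = "Latent-variable selection")
      grDevices::dev.off()
      grDevices::png(out("rmsep_comparison.png"), width = 500, height = 500)
      graphics::barplot(c(PLS = reports$pls_test$rmse,
                          SVR = reports$svr_test$rmse),
                        ylab = "RMSEP (ug/mL)", main = "Test-set RMSEP")
      grDevices::dev.off()
      logit("export: wrote diagnostic plots")
    }
    writeLines(log_lines, out("run_log.txt"))
    invisible(list(config = config, lv_selection = lv, grid_search = gs,
                   pls = pls_fit, svr = svr_fit, reports = reports,
                   out_dir = config$out_dir))
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}
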