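# End-to-end orchestration: load/synthesize -> preprocess -> Kennard-Stone
# split -> wavelength selection on the calibration set -> model fit ->
# evaluation on both sets, with JSON artifact persistence and a grid runner
# for the preprocessing x selector x model comparison.

#' Run configuration for the calibration pipeline
#'
#' @param input a [spectral_dataset()], a path to a spectra CSV, or a
#'   [synthetic_config()] (exactly one input source).
#' @param indicator response column name (`"SSC"`, `"MC"`, `"VC"`).
#' @param preprocess a [preprocess_spec()] or a method name.
#' @param split_ratio calibration:prediction ratio (default 3, i.e. 3:1), or
#'   `split` for explicit indices.
#' @param split optional precomputed [kennard_stone()] split (overrides
#'   `split_ratio`).
#' @param selector `"none"`, `"CARS"`, `"UVE"` or `"SPA"`.
#' @param selector_args list of arguments for the selector.
#' @param model `"PLSR"`, `"MLR"` or `"LSSVM"`.
#' @param model_args list of arguments for the model-fitting function (e.g.
#'   `n_factors` for PLSR, `gamma`/`sigma2` or `tune = TRUE` for LSSVM).
#' @param order `"preprocess_first"` (default: preprocessing statistics are
#'   fitted on all samples, then the split is computed on the preprocessed
#'   matrix) or `"split_first"` (split on the raw spectra, preprocessing
#'   fitted on the calibration rows only).
#' @param output_dir optional directory: when set, `run_pipeline` writes
#'   `model.json`, `selection.json`, `report.json` and `run_log.txt` there.
#' @param seed root seed; all pipeline randomness (selector Monte-Carlo,
#'   folds, synthesis) is derived from it through named substreams.
#' @return object of class `"run_config"`.
#' @export
run_config <- function(input, indicator, preprocess = "RAW",
                       split_ratio = 3, split = NULL,
                       selector = "none", selector_args = list(),
                       model = "PLSR", model_args = list(),
                       order = c("preprocess_first", "split_first"),
                       output_dir = NULL, seed = 1) {
  order <- match.arg(order)
  if (is.character(preprocess)) preprocess <- preprocess_spec(preprocess)
  selector <- match.arg(selector, c("none", "CARS", "UVE", "SPA"))
  model <- match.arg(model, c("PLSR", "MLR", "LSSVM"))
  if (!indicator %in% RESERVED_INDICATORS)
    stop("indicator must be one of: ", paste(RESERVED_INDICATORS, collapse = ", "))
  structure(list(input = input, indicator = indicator,
                 preprocess = preprocess, split_ratio = split_ratio,
                 split = split, selector = selector,
                 selector_args = selector_args, model = model,
                 model_args = model_args, order = order,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

resolve_input <- function(input) {
  if (inherits(input, "spectral_dataset")) return(input)
  if (inherits(input, "synthetic_config")) return(generate_dataset(input))
  if (is.character(input) && length(input) == 1) return(read_spectra_table(input))
  stop("input must be a spectral_dataset, a synthetic_config, or a file path")
}

run_selector <- function(cfg, X_cal, y_cal) {
  args <- cfg$selector_args
  seed <- args$seed %||% substream_seed(cfg$seed, paste0("sel-", cfg$selector))
  switch(cfg$selector,
    none = NULL,
    CARS = do.call(cars_select, c(list(X = X_cal, y = y_cal),
                                  args[setdiff(names(args), "seed")],
                                  list(seed = seed))),
    UVE = do.call(uve_select, c(list(X = X_cal, y = y_cal),
                                args[setdiff(names(args), "seed")],
                                list(seed = seed))),
    SPA = do.call(spa_select, c(list(X = X_cal, y = y_cal), args)))
}

run_model <- function(cfg, X_cal, y_cal, wl, prov) {
  args <- cfg$model_args
  switch(cfg$model,
    PLSR = {
      # cap the requested factor count at what the selected subset supports
      if (!is.null(args$n_factors) && is.numeric(args$n_factors))
        args$n_factors <- min(args$n_factors, nrow(X_cal) - 1L, ncol(X_cal))
      do.call(fit_plsr, c(list(X = X_cal, y = y_cal), args,
                          list(wavelengths_nm = wl, provenance = prov)))
    },
    MLR = do.call(fit_mlr, c(list(X = X_cal, y = y_cal), args,
                             list(wavelengths_nm = wl, provenance = prov))),
    LSSVM = {
      if (isTRUE(args$tune) || is.null(args$gamma) || is.null(args$sigma2)) {
        gg <- args$gamma_grid %||% c(1, 10, 100, 1000, 1e4)
        med <- median(dist(X_cal)^2)
        if (!is.finite(med) || med <= 0) med <- 1
        sg <- args$sigma2_grid %||% (med * c(0.25, 0.5, 1, 2, 4))
        tuned <- tune_lssvm(X_cal, y_cal, gg, sg,
                            folds = args$folds %||% 5,
                            seed = substream_seed(cfg$seed, "lssvm-tune"))
        fit_lssvm(X_cal, y_cal, tuned$gamma, tuned$sigma2,
                  wavelengths_nm = wl, provenance = prov)
      } else {
        fit_lssvm(X_cal, y_cal, args$gamma, args$sigma2,
                  wavelengths_nm = wl, provenance = prov)
      }
    })
}

#' Run the calibration pipeline end to end
#'
#' Executes the stages in order: obtain the spectra (file, in-memory dataset,
#' or synthetic generation), preprocess, Kennard-Stone split, wavelength
#' selection on the calibration set only, model fit on the calibration set,
#' and evaluation on both sets. With `output_dir` set, writes the fitted model,
#' selection, evaluation report (JSON) and a parameter log.
#'
#' @param cfg a [run_config()], or arguments to build one (passed to
#'   [run_config()] when `cfg` is not already a config).
#' @param ... when `cfg` is not a `run_config`, further [run_config()]
#'   arguments.
#' @return object of class `"spec_pipeline"`: list with `report`
#'   (an `evaluation_report`), `model`, `selection`, `split`, `preprocess`,
#'   `config`, `predictions` (per-set measured/predicted), and `dataset_dim`.
#' @export
run_pipeline <- function(cfg, ...) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg, ...)
  stage <- "load"
  out <- tryCatch({
    ds <- resolve_input(cfg$input)
    y_all <- ds$indicators[[cfg$indicator]]
    if (is.null(y_all))
      stop("dataset has no indicator '", cfg$indicator, "'")
    X_raw <- ds$reflectance

    if (cfg$order == "preprocess_first") {
      stage <- "preprocess"
      pp <- fit_preprocess(X_raw, cfg$preprocess)
      X_pp <- apply_preprocess(pp, X_raw)
      stage <- "split"
      split <- cfg$split %||% kennard_stone(X_pp, ratio = cfg$split_ratio)
      X_cal <- X_pp[split$calibration_idx, , drop = FALSE]
      X_pred <- X_pp[split$prediction_idx, , drop = FALSE]
    } else {
      stage <- "split"
      split <- cfg$split %||% kennard_stone(X_raw, ratio = cfg$split_ratio)
      stage <- "preprocess"
      pp <- fit_preprocess(X_raw[split$calibration_idx, , drop = FALSE],
                           cfg$preprocess)
      X_cal <- apply_preprocess(pp, X_raw[split$calibration_idx, , drop = FALSE])
      X_pred <- apply_preprocess(pp, X_raw[split$prediction_idx, , drop = FALSE])
    }
    y_cal <- y_all[split$calibration_idx]
    y_pred <- y_all[split$prediction_idx]

    stage <- "selection"
    selection <- run_selector(cfg, X_cal, y_cal)
    idx <- if (is.null(selection)) seq_len(ncol(X_cal)) else selection$selected_idx

    stage <- "fit"
    prov <- list(preprocess = cfg$preprocess, preprocess_fit = pp,
                 selection = selection)
    model <- run_model(cfg, X_cal[, idx, drop = FALSE], y_cal,
                       ds$wavelengths_nm[idx], prov)

    stage <- "evaluate"
    pred_cal <- predict(model, X_cal[, idx, drop = FALSE])
    pred_pred <- predict(model, X_pred[, idx, drop = FALSE])
    report <- regression_metrics(y_cal, pred_cal, y_pred, pred_pred)

    structure(list(report = report, model = model, selection = selection,
                   split = split, preprocess = pp, config = cfg,
                   selected_idx = idx,
                   predictions = list(
                     calibration = data.frame(measured = y_cal,
                                              predicted = pred_cal),
                     prediction = data.frame(measured = y_pred,
                                             predicted = pred_pred)),
                   dataset_dim = dim(X_raw)),
              class = "spec_pipeline")
  }, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
  if (!is.null(cfg$output_dir)) write_pipeline_artifacts(out, cfg$output_dir)
  out
}

report_as_list <- function(r) {
  r <- unclass(r)
  r$flags <- as.list(r$flags)
  r
}

write_pipeline_artifacts <- function(pipe, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_model(pipe$model, file.path(dir, "model.json"))
  if (!is.null(pipe$selection))
    jsonlite::write_json(
      list(method = pipe$selection$method,
           selected_idx = pipe$selection$selected_idx,
           n_selected = length(pipe$selection$selected_idx)),
      file.path(dir, "selection.json"), digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(report_as_list(pipe$report),
                       file.path(dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  cfg <- pipe$config
  log_lines <- c(
    paste0("indicator: ", cfg$indicator),
    paste0("preprocess: ", cfg$preprocess$method),
    paste0("order: ", cfg$order),
    paste0("selector: ", cfg$selector),
    paste0("model: ", cfg$model),
    paste0("seed: ", cfg$seed),
    paste0("n_cal: ", length(pipe$split$calibration_idx)),
    paste0("n_pred: ", length(pipe$split$prediction_idx)),
    paste0("n_selected: ", length(pipe$selected_idx)))
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.spec_pipeline <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<spec_pipeline> %s | %s -> %s -> %s\n", cfg$indicator,
              cfg$preprocess$method, cfg$selector, cfg$model))
  cat(sprintf("  %d calibration / %d prediction samples, %d selected channels\n",
              length(x$split$calibration_idx), length(x$split$prediction_idx),
              length(x$selected_idx)))
  print(x$report)
  invisible(x)
}

#' @export
predict.spec_pipeline <- function(object, newdata, ...) {
  ds <- if (inherits(newdata, "spectral_dataset")) newdata$reflectance
        else as.matrix(newdata)
  Xp <- apply_preprocess(object$preprocess, ds)
  predict(object$model, Xp[, object$selected_idx, drop = FALSE])
}

#' Run a grid of pipeline configurations and tabulate the comparison
#'
#' One row per configuration with the model size (Lvs or gamma/sigma2), RC,
#' RMSEC, RP, RMSEP and RPD, ordered by indicator then method labels; the
#' best-RPD row is flagged.
#'
#' @param input shared input (dataset / path / synthetic config).
#' @param indicator response name, or vector (one per config row).
#' @param preprocess_methods,selectors,models character vectors; the grid is
#'   their cross product.
#' @param split_ratio,seed shared pipeline settings.
#' @param model_args named list of per-model-extra arguments, e.g.
#'   `list(PLSR = list(n_factors = 10))`.
#' @param selector_args named list of per-selector arguments.
#' @return data.frame with one row per grid cell (columns `indicator`,
#'   `preprocess`, `selector`, `model`, `size`, `n_selected`, `rc`, `rmsec`,
#'   `rp`, `rmsep`, `rpd`, `best`), with the full pipeline objects attached as
#'   attribute `"pipelines"`.
#' @export
compare_grid <- function(input, indicator, preprocess_methods = "RAW",
                         selectors = "none", models = "PLSR",
                         split_ratio = 3, seed = 1,
                         model_args = list(), selector_args = list()) {
  grid <- expand.grid(indicator = indicator,
                      preprocess = preprocess_methods,
                      selector = selectors, model = models,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$indicator, grid$preprocess, grid$selector,
                     grid$model), , drop = FALSE]
  ds <- resolve_input(input)
  rows <- vector("list", nrow(grid))
  pipes <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    pipe <- run_pipeline(run_config(
      ds, g$indicator, preprocess = g$preprocess,
      split_ratio = split_ratio, selector = g$selector,
      selector_args = selector_args[[g$selector]] %||% list(),
      model = g$model, model_args = model_args[[g$model]] %||% list(),
      seed = seed))
    r <- pipe$report
    size <- switch(g$model,
      PLSR = as.character(pipe$model$n_factors),
      MLR = sprintf("%d vars", pipe$model$p),
      LSSVM = sprintf("g=%.4g,s2=%.4g", pipe$model$gamma, pipe$model$sigma2))
    rows[[i]] <- data.frame(
      indicator = g$indicator, preprocess = g$preprocess,
      selector = g$selector, model = g$model, size = size,
      n_selected = length(pipe$selected_idx),
      rc = r$rc, rmsec = r$rmsec, rp = r$rp, rmsep = r$rmsep, rpd = r$rpd,
      stringsAsFactors = FALSE)
    pipes[[i]] <- pipe
  }
  out <- do.call(rbind, rows)
  out$best <- FALSE
  if (any(is.finite(out$rpd))) out$best[which.max(out$rpd)] <- TRUE
  rownames(out) <- NULL
  attr(out, "pipelines") <- pipes
  out
}

#' Load a run configuration from a YAML file
#'
#' Accepts the keys of [run_config()]; `input` may be a path (string) or a
#' `synthetic:` mapping passed to [synthetic_config()]; `preprocess` may be a
#' method string or a mapping with `method`/`window`/`polyorder`.
#'
#' @param path YAML file path.
#' @param seed_override optional seed replacing the file's.
#' @return a [run_config()].
#' @export
read_run_config <- function(path, seed_override = NULL) {
  y <- yaml::read_yaml(path)
  input <- if (!is.null(y$synthetic)) do.call(synthetic_config, y$synthetic)
           else y$input
  pp <- y$preprocess %||% "RAW"
  if (is.list(pp)) pp <- do.call(preprocess_spec, pp)
  run_config(input = input, indicator = y$indicator, preprocess = pp,
             split_ratio = y$split_ratio %||% 3,
             selector = y$selector %||% "none",
             selector_args = y$selector_args %||% list(),
             model = y$model %||% "PLSR",
             model_args = y$model_args %||% list(),
             order = y$order %||% "preprocess_first",
             output_dir = y$output_dir,
             seed = seed_override %||% y$seed %||% 1)
}
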