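# End-to-end orchestration: simulate -> align -> preprocess -> fuse ->
# split -> train -> (permute) -> evaluate -> compare, driven by a single
# seeded configuration, producing a machine-readable study report.

#' Default model recipes
#'
#' The 24 dataset-by-level combinations analysed by the study design:
#' single-technique models, low-level fusions and mid-level fusions, for
#' the inner part, the epidermis, and the paired two-part combinations.
#'
#' @return Data frame with columns `name`, `level`, `part`, `channels`
#'   (`+`-separated).
#' @export
default_recipes <- function() {
  r <- function(level, part, channels) {
    data.frame(name = paste(level, part, gsub("\\+", "-", channels),
                            sep = "/"),
               level = level, part = part, channels = channels,
               stringsAsFactors = FALSE)
  }
  rbind(
    r("single", "inner", "FTIR"),
    r("single", "inner", "LC242"),
    r("single", "inner", "LC210"),
    r("single", "epidermis", "FTIR"),
    r("single", "epidermis", "LC242"),
    r("low", "inner", "FTIR+LC242"),
    r("low", "inner", "FTIR+LC210"),
    r("low", "inner", "LC242+LC210"),
    r("low", "inner", "FTIR+LC242+LC210"),
    r("low", "epidermis", "FTIR+LC242"),
    r("low", "epidermis", "FTIR+LC242+LC210"),
    r("low", "both", "FTIR"),
    r("low", "both", "LC242"),
    r("low", "both", "LC210"),
    r("mid", "inner", "FTIR+LC242"),
    r("mid", "inner", "FTIR+LC210"),
    r("mid", "inner", "FTIR+LC242+LC210"),
    r("mid", "epidermis", "FTIR+LC242"),
    r("mid", "epidermis", "FTIR+LC210"),
    r("mid", "epidermis", "LC242+LC210"),
    r("mid", "epidermis", "FTIR+LC242+LC210"),
    r("mid", "both", "FTIR"),
    r("mid", "both", "LC242"),
    r("mid", "both", "LC210")
  )
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. The single `seed` fans
#' out to per-stage child seeds so each stage is independently
#' reproducible.
#'
#' @param seed Integer master seed (mandatory source of all randomness).
#' @param sim [sim_params()] for the synthetic study.
#' @param cow List: `mode` (`"fixed"` uses `segment`/`slack` directly;
#'   `"search"` runs [grid_search_cow()] per chromatographic block with
#'   `segment_range`, `slack_range`, `area_tol`, scoring on the first
#'   `n_search_signals` signals), plus `cutoff_min` for the crop.
#' @param sg List: Savitzky-Golay `window` and `polyorder`.
#' @param exclude Wavenumber region `c(low, high)` removed from spectra.
#' @param recipes Data frame of model recipes (see [default_recipes()]).
#' @param folds,A_max,q2_threshold PLS-DA settings (see [fit_plsda()]).
#' @param k_max,pca_method Mid-level feature extraction settings (see
#'   [extract_features_pca()]).
#' @param split_ratio Calibration fraction for the Kennard-Stone split
#'   (2/3 gives 52 of 78).
#' @param n_permutations Iterations for the permutation test.
#' @param permute_recipes Character vector of recipe names to
#'   permutation-test (empty by default: the test is costly, so it is run
#'   on demand rather than for all 24 recipes).
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1,
                            sim = sim_params(),
                            cow = list(),
                            sg = list(window = 15, polyorder = 2),
                            exclude = c(1750, 2600),
                            recipes = default_recipes(),
                            folds = 7, A_max = 10, q2_threshold = 0.05,
                            k_max = 20,
                            pca_method = c("press", "cumvar"),
                            split_ratio = 2 / 3,
                            n_permutations = 30,
                            permute_recipes = character(0)) {
  if (is.null(seed)) stop("`seed` is mandatory")
  pca_method <- match.arg(pca_method)
  cow_defaults <- list(mode = "fixed", segment = 100, slack = 5,
                       segment_range = c(10, 200), slack_range = c(1, 20),
                       area_tol = 0.05, n_search_signals = 5,
                       grid = "coarse", cutoff_min = 11)
  cow <- utils::modifyList(cow_defaults, cow)
  stopifnot(is.data.frame(recipes),
            all(c("name", "level", "part", "channels") %in% names(recipes)))
  structure(list(seed = as.integer(seed), sim = sim, cow = cow, sg = sg,
                 exclude = exclude, recipes = recipes, folds = folds,
                 A_max = A_max, q2_threshold = q2_threshold,
                 k_max = k_max, pca_method = pca_method,
                 split_ratio = split_ratio,
                 n_permutations = n_permutations,
                 permute_recipes = permute_recipes),
            class = "pipeline_config")
}

recipe_blocks <- function(recipe, processed) {
  chans <- strsplit(recipe$channels, "+", fixed = TRUE)[[1]]
  if (recipe$part == "both") {
    if (length(chans) != 1) {
      stop("two-part recipes use a single channel")
    }
    ids <- paste0(chans, "-", c("inner", "epidermis"))
  } else {
    ids <- paste0(chans, "-", recipe$part)
  }
  missing <- setdiff(ids, names(processed))
  if (length(missing)) {
    stop("unknown block id: ", paste(missing, collapse = ", "))
  }
  list(blocks = processed[ids],
       pairing = if (recipe$part == "both") "by_sclerotium" else "by_sample")
}

run_recipe <- function(recipe, processed, config) {
  rb <- recipe_blocks(recipe, processed)
  low <- low_level_fuse(rb$blocks, rb$pairing)
  n <- nrow(low$matrix)
  n_cal <- round(config$split_ratio * n)
  # the split lives on the autoscaled low-level concatenation of the same
  # blocks, so low- and mid-level models of one block set share it
  split <- kennard_stone(suppressWarnings(autoscale(low$matrix))$X, n_cal)
  cal <- split$calibration_indices
  val <- split$validation_indices
  if (recipe$level == "mid") {
    fused <- mid_level_fuse(rb$blocks, rb$pairing, folds = config$folds,
                            k_max = config$k_max,
                            method = config$pca_method, fit_rows = cal)
    M <- fused$matrix
  } else {
    fused <- low
    M <- low$matrix
  }
  y <- low$row_meta$class_label
  model <- suppressWarnings(
    fit_plsda(M[cal, , drop = FALSE], y[cal], folds = config$folds,
              A_max = config$A_max, q2_threshold = config$q2_threshold))
  out <- list(recipe = recipe, split = split, n_vars = ncol(M),
              model = model)
  if (model$status == "failed") {
    out$status <- "failed"
    out$message <- "no latent variable passed cross-validation"
    return(out)
  }
  classes <- sort(unique(y))
  pred_cal <- predict(model, M[cal, , drop = FALSE])
  pred_val <- predict(model, M[val, , drop = FALSE])
  out$cm_cal <- confusion_matrix(y[cal], pred_cal, classes)
  out$cm_val <- confusion_matrix(y[val], pred_val, classes)
  out$metrics_cal <- class_metrics(out$cm_cal)
  out$metrics_val <- class_metrics(out$cm_val)
  out$status <- "fitted"
  if (recipe$name %in% config$permute_recipes) {
    out$permutation <- permutation_test(
      M[cal, , drop = FALSE], y[cal],
      n_iter = config$n_permutations,
      seed = child_seed(config$seed, 900, nrow(out$cm_cal)),
      folds = config$folds, A_max = config$A_max,
      q2_threshold = config$q2_threshold)
  }
  out
}

#' Run the full authentication pipeline
#'
#' Simulates the study, aligns and reduces the chromatographic blocks,
#' derivative-preprocesses the FTIR blocks, then fits and evaluates every
#' configured model recipe: Kennard-Stone split, PLS-DA with
#' cross-validated component selection, calibration/validation confusion
#' matrices and per-class metrics, and (for the configured recipes) the
#' permutation test. A failing recipe is recorded with
#' `status = "failed"`; it never aborts the run.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `"study_report"`: `models` (one summary row
#'   per recipe: `A`, `R2cum`, `Q2cum`, calibration/validation accuracy
#'   in percent, `status`), `details` (per-recipe confusion matrices,
#'   metrics, split, permutation result), `alignment` (per
#'   chromatographic block: chosen segment/slack, per-sample post-warp
#'   correlations), `flags` (see [compare_models()]), `seed`,
#'   `schema_version`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  study <- simulate_study(config$sim, config$seed)
  needed <- unique(unlist(lapply(seq_len(nrow(config$recipes)), function(i) {
    rec <- config$recipes[i, ]
    chans <- strsplit(rec$channels, "+", fixed = TRUE)[[1]]
    parts <- if (rec$part == "both") c("inner", "epidermis") else rec$part
    as.vector(outer(chans, parts, paste, sep = "-"))
  })))
  processed <- list()
  alignment <- list()
  for (id in intersect(names(study$blocks), needed)) {
    b <- study$blocks[[id]]
    if (startsWith(id, "FTIR")) {
      processed[[id]] <- preprocess_spectra(
        b, window = config$sg$window, polyorder = config$sg$polyorder,
        low = config$exclude[1], high = config$exclude[2])
    } else {
      prep <- if (config$cow$mode == "search") {
        align_bin_crop(b, reference = "auto",
                       search = list(
                         segment_range = config$cow$segment_range,
                         slack_range = config$cow$slack_range,
                         area_tol = config$cow$area_tol,
                         grid = config$cow$grid,
                         max_signals = config$cow$n_search_signals),
                       cutoff_min = config$cow$cutoff_min)
      } else {
        align_bin_crop(b, segment_length = config$cow$segment,
                       slack = config$cow$slack,
                       cutoff_min = config$cow$cutoff_min)
      }
      processed[[id]] <- prep$block
      alignment[[id]] <- prep
    }
  }
  details <- vector("list", nrow(config$recipes))
  names(details) <- config$recipes$name
  rows <- vector("list", nrow(config$recipes))
  for (i in seq_len(nrow(config$recipes))) {
    recipe <- config$recipes[i, ]
    res <- tryCatch(run_recipe(recipe, processed, config),
                    error = function(e) {
                      list(recipe = recipe, status = "failed",
                           message = conditionMessage(e))
                    })
    details[[i]] <- res
    fitted <- identical(res$status, "fitted")
    rows[[i]] <- data.frame(
      name = recipe$name, level = recipe$level, part = recipe$part,
      channels = recipe$channels,
      n_vars = res$n_vars %||% NA_integer_,
      A = if (fitted) res$model$A else NA_integer_,
      R2cum = if (fitted) res$model$R2cum else NA_real_,
      Q2cum = if (fitted) res$model$Q2cum else NA_real_,
      cal_acc = if (fitted) res$metrics_cal$accuracy_pct else NA_real_,
      val_acc = if (fitted) res$metrics_val$accuracy_pct else NA_real_,
      status = res$status,
      message = res$message %||% "",
      stringsAsFactors = FALSE)
  }
  models <- do.call(rbind, rows)
  rownames(models) <- NULL
  fitted_rows <- models[models$status == "fitted", , drop = FALSE]
  flags <- if (nrow(fitted_rows) >= 2) {
    attr(compare_models(fitted_rows), "flags")
  } else {
    NULL
  }
  structure(list(models = models, details = details,
                 alignment = alignment, flags = flags,
                 seed = config$seed, schema_version = "1.0"),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> seed %d, %d recipes (%d fitted)\n",
              x$seed, nrow(x$models),
              sum(x$models$status == "fitted")))
  print(x$models[, c("name", "A", "R2cum", "Q2cum", "cal_acc", "val_acc",
                     "status")], digits = 4)
  if (!is.null(x$flags)) {
    cat("flags:", paste(names(x$flags), unname(x$flags), sep = " = ",
                        collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a study report as JSON
#'
#' Serialises the summary table, alignment diagnostics and comparison
#' flags (not the full per-recipe matrices) to a machine-readable file.
#'
#' @param report A `"study_report"`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    schema_version = report$schema_version,
    seed = report$seed,
    models = report$models,
    flags = as.list(report$flags),
    alignment = lapply(report$alignment, function(a) {
      list(block = a$block$block_id, reference = a$reference,
           segment = a$segment_length, slack = a$slack,
           mean_correlation = a$mean_correlation,
           correlations = a$correlations)
    }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
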