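## Run configuration and the simulate -> reconstruct -> train -> calibrate ->
## evaluate pipeline. Every stage persists its outputs under the run
## directory and completed stages are skipped on resume.

#' Build a validated run configuration
#'
#' @param anatomy `"brain"`, `"knee"` or `"synthetic"`. For brain/knee the
#'   ACS fraction defaults to the protocol value at the given acceleration.
#' @param acceleration Nominal acceleration factor.
#' @param acs_fraction ACS fraction; `NULL` uses [protocol_acs_fraction()]
#'   (synthetic defaults to 0.08).
#' @param alpha_coverage Target interval coverage in (0, 1).
#' @param delta Hoeffding confidence parameter in (0, 1].
#' @param mode `"QR"` or `"ResM"`.
#' @param n_train,n_val,n_cal,n_test Partition sizes.
#' @param height,width,n_coils,n_anomalies,noise_sigma Simulation parameters.
#' @param seed Master seed.
#' @param lambda_grid Candidate calibration scales.
#' @param aggregate Risk aggregation for calibration (see
#'   [calibrate_lambda()]).
#' @param reconstructor `"zero_filled"` or `"unrolled"`.
#' @param train_iters,train_lr Training schedule for the offset predictor.
#' @param blur_sigma Gaussian blur SD for the correlation metrics.
#' @return Object of class `run_config`.
#' @export
run_config <- function(anatomy = "synthetic", acceleration = 4,
                       acs_fraction = NULL, alpha_coverage = 0.9,
                       delta = 0.1, mode = c("QR", "ResM"),
                       n_train = 8L, n_val = 0L, n_cal = 4L, n_test = 4L,
                       height = 64L, width = 64L, n_coils = 4L,
                       n_anomalies = 2L, noise_sigma = 0.01, seed = 1L,
                       lambda_grid = seq(0, 4, by = 0.01),
                       aggregate = c("pooled", "per_image"),
                       reconstructor = c("zero_filled", "unrolled"),
                       train_iters = 300L, train_lr = 0.1, blur_sigma = 2) {
  anatomy <- match.arg(anatomy, c("synthetic", "brain", "knee"))
  mode <- match.arg(mode)
  aggregate <- match.arg(aggregate)
  reconstructor <- match.arg(reconstructor)
  check_scalar_in(alpha_coverage, 0, 1, "alpha_coverage")
  check_scalar_in(delta, 0, 1, "delta", open = c(TRUE, FALSE))
  if (is.null(acs_fraction)) {
    acs_fraction <- if (anatomy == "synthetic") 0.08 else
      protocol_acs_fraction(anatomy, acceleration)
  }
  structure(list(
    anatomy = anatomy, acceleration = acceleration,
    acs_fraction = acs_fraction, alpha_coverage = alpha_coverage,
    delta = delta, mode = mode,
    n_train = n_train, n_val = n_val, n_cal = n_cal, n_test = n_test,
    height = height, width = width, n_coils = n_coils,
    n_anomalies = n_anomalies, noise_sigma = noise_sigma, seed = seed,
    lambda_grid = lambda_grid, aggregate = aggregate,
    reconstructor = reconstructor, train_iters = train_iters,
    train_lr = train_lr, blur_sigma = blur_sigma
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Unknown fields are rejected; missing fields take the [run_config()]
#' defaults; field domains are validated by the constructor.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) {
    stop_mriuq("unknown config fields: ", paste(bad, collapse = ", "),
               class = "mriuq_config_error")
  }
  if (!is.null(y$lambda_grid) && length(y$lambda_grid) == 3 &&
      !is.null(names(y$lambda_grid))) {
    y$lambda_grid <- seq(y$lambda_grid[["from"]], y$lambda_grid[["to"]],
                         by = y$lambda_grid[["by"]])
  }
  do.call(run_config, y)
}

#' Write a run configuration to YAML
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

log_stage <- function(run_dir, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
  message(line)
  cat(line, "\n", file = file.path(run_dir, "run.log"), append = TRUE)
}

stage_done <- function(run_dir, stage) {
  manifest <- file.path(run_dir, "manifest.json")
  done <- if (file.exists(manifest)) {
    jsonlite::read_json(manifest, simplifyVector = TRUE)$completed
  } else character(0)
  stage %in% done && file.exists(file.path(run_dir, paste0(stage, ".rds")))
}

mark_stage <- function(run_dir, stage, obj) {
  saveRDS(obj, file.path(run_dir, paste0(stage, ".rds")))
  manifest <- file.path(run_dir, "manifest.json")
  done <- if (file.exists(manifest)) {
    jsonlite::read_json(manifest, simplifyVector = TRUE)$completed
  } else character(0)
  jsonlite::write_json(
    list(completed = union(done, stage),
         r_version = R.version.string,
         package_version = as.character(utils::packageVersion("mriuq"))),
    manifest, auto_unbox = TRUE
  )
  obj
}

load_stage <- function(run_dir, stage) readRDS(file.path(run_dir, paste0(stage, ".rds")))

#' Run the full uncertainty-quantification pipeline
#'
#' Executes simulate, reconstruct, train, calibrate and evaluate in order,
#' logging each stage, persisting intermediates under `run_dir`, and skipping
#' stages already completed there (resumability). Deterministic end to end
#' for a fixed config.
#'
#' @param config A `run_config`.
#' @param run_dir Run directory (created if needed); a temporary directory by
#'   default.
#' @param stages Subset of stages to run (later stages load earlier results
#'   from `run_dir`).
#' @return List with `pairs_test`, `calibration` (a `calibration_record`),
#'   `reports` (per-test-slice `correlation_report`s), `report_df` (one row
#'   per test slice: correlations, coverage, normalized uncertainty),
#'   `predictor`, `mask`, `config`.
#' @export
run_pipeline <- function(config, run_dir = tempfile("mriuq_run_"),
                         stages = c("simulate", "reconstruct", "train",
                                    "calibrate", "evaluate")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  write_run_config(config, file.path(run_dir, "config.yaml"))
  all_stages <- c("simulate", "reconstruct", "train", "calibrate", "evaluate")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  run_stage <- function(stage, fn) {
    if (stage_done(run_dir, stage)) {
      if (stage %in% stages) {
        log_stage(run_dir, paste0(stage, ": already complete, skipping"))
      }
      return(load_stage(run_dir, stage))
    }
    if (!stage %in% stages) {
      stop_mriuq(sprintf(
        "stage '%s' was not requested and has no saved result under %s",
        stage, run_dir
      ), class = "mriuq_stage_error")
    }
    log_stage(run_dir, paste0(stage, ": running"))
    out <- tryCatch(fn(), error = function(e) {
      stop_mriuq(sprintf("pipeline stage '%s' failed: %s", stage,
                         conditionMessage(e)),
                 class = "mriuq_stage_error")
    })
    mark_stage(run_dir, stage, out)
  }

  sim <- run_stage("simulate", function() {
    params <- sim_params(config$height, config$width, config$n_coils,
                         config$n_anomalies, config$noise_sigma)
    data <- make_split_dataset(config$n_train, config$n_val, config$n_cal,
                               config$n_test, params, seed = config$seed)
    mask <- make_cartesian_mask(config$width, config$acceleration,
                                config$acs_fraction)
    list(data = data, mask = mask)
  })

  rec <- run_stage("reconstruct", function() {
    rc <- switch(config$reconstructor,
                 zero_filled = zero_filled_reconstructor(),
                 unrolled = unrolled_reconstructor())
    to_pairs <- function(items) lapply(items, function(it) {
      recon_pair(reconstruct(rc, it$kspace, sim$mask, it$coils),
                 it$image$pixels)
    })
    lapply(sim$data, to_pairs)
  })

  trained <- run_stage("train", function() {
    cfg <- uq_config(alpha_coverage = config$alpha_coverage,
                     mode = config$mode, n_iter = config$train_iters,
                     lr = config$train_lr, seed = config$seed)
    pred <- feature_predictor(mode = config$mode, seed = config$seed)
    p <- train_uq(rec$train, pred, cfg,
                  val_pairs = if (length(rec$val)) rec$val else NULL)
    utils::write.csv(attr(p, "history"),
                     file.path(run_dir, "training_history.csv"),
                     row.names = FALSE)
    write_predictor(p, file.path(run_dir, "predictor.json"))
    p
  })

  calib <- run_stage("calibrate", function() {
    if (length(rec$cal) == 0) {
      stop_mriuq("no calibration slices: cannot calibrate lambda",
                 class = "mriuq_data_error")
    }
    cal_items <- lapply(rec$cal, function(p) {
      list(pair = p, bounds = predict_bounds(trained, p))
    })
    record <- calibrate_lambda(
      cal_items, alpha_miscoverage = 1 - config$alpha_coverage,
      delta = config$delta, lambda_grid = config$lambda_grid,
      aggregate = config$aggregate
    )
    write_calibration_record(record, file.path(run_dir, "calibration.json"))
    record
  })

  eval_out <- run_stage("evaluate", function() {
    if (calib$infeasible) {
      log_stage(run_dir, "evaluate: calibration infeasible; reporting flagged result")
      return(list(reports = list(), report_df = data.frame(), infeasible = TRUE))
    }
    lam <- calib$chosen_lambda
    rows <- list()
    reports <- list()
    for (i in seq_along(rec$test)) {
      p <- rec$test[[i]]
      b <- predict_bounds(trained, p)
      iv <- interval_at_lambda(p$x, b, lam,
                               alpha_miscoverage = 1 - config$alpha_coverage,
                               delta = config$delta)
      q <- uncertainty_map(iv, norm_scale = p$norm_scale)
      e <- error_map(p$x, p$y)
      rep_i <- correlation_report(q, e, blur_sigma = config$blur_sigma)
      su <- normalized_uncertainty_summary(q)
      reports[[i]] <- rep_i
      rows[[i]] <- data.frame(
        slice = i, lambda = lam, coverage = coverage(iv, p$y),
        pearson = rep_i$pearson_r, spearman = rep_i$spearman_rho,
        region_pearson = rep_i$region_pearson,
        region_spearman = rep_i$region_spearman,
        uncertainty_mean_pct = su$mean_pct, uncertainty_sd_pct = su$sd_pct,
        ssim = ssim(p$x, p$y)
      )
    }
    df <- do.call(rbind, rows)
    utils::write.csv(df, file.path(run_dir, "evaluation.csv"),
                     row.names = FALSE)
    list(reports = reports, report_df = df, infeasible = FALSE)
  })

  log_stage(run_dir, "pipeline complete")
  list(pairs_test = rec$test, calibration = calib,
       reports = eval_out$reports, report_df = eval_out$report_df,
       predictor = trained, mask = sim$mask, config = config,
       run_dir = run_dir)
}
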