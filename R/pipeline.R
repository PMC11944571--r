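#' Run the full chlorophyll-calibration study replica
#'
#' Orchestrates every stage on one dataset: simulate (or read) spectra and
#' metadata, preprocess (absorbance + Savitzky-Golay smoothing),
#' Kennard-Stone split into calibration and validation, MSD sweep over
#' nested subset sizes, PLSR and Cubist-lite calibration on the nominated
#' subset, evaluation on the validation set, and report/figure output. The
#' run is fully deterministic given `seed`; every stage derives its random
#' stream from the root seed through named substreams, so toggling one
#' stage does not perturb the others.
#'
#' Artifacts written to `out_dir`: `config.json` (all settings actually
#' used, including derived stage seeds), `preprocessed.csv`, `meta.csv`,
#' `calibration.ids` / `validation.ids`, per-size `subset_<size>.ids`,
#' `msd_sweep.tsv`, `plsr_model.json`, `cubist_model.json`,
#' `evaluation.tsv`, `group_summary.tsv`, and (optionally) figure PDFs
#' analogous to the study's density/scatter/VIP/seasonal plots.
#'
#' @param out_dir output directory (created if needed).
#' @param seed root integer seed.
#' @param cfg a [generator_config()] used when simulating.
#' @param spectra_file,meta_file optional paths to a wide spectra CSV and
#'   metadata CSV; when given, simulation is skipped.
#' @param cal_size calibration set size selected by Kennard-Stone from the
#'   full pool (default 280; the remainder is the validation set).
#' @param sizes nested subset sizes for the MSD sweep.
#' @param k PCs entering the MSD average (default 6).
#' @param var_ks variance retained for Kennard-Stone PC space.
#' @param sg_window,sg_order Savitzky-Golay settings.
#' @param max_lv PLSR latent-variable ceiling.
#' @param committees,neighbors Cubist-lite grid values.
#' @param folds Cubist CV folds; `0` fits a single cell
#'   (`committees[1]`, `neighbors[1]`) without cross-validation.
#' @param skip character vector of stages to skip: any of `"plsr"`,
#'   `"cubist"`, `"plots"`.
#' @param make_plots write figure PDFs (default `TRUE`).
#' @return invisibly, a list with the fitted objects (`sweep`, `plsr`,
#'   `cubist`), evaluation reports, the split indices and `out_dir`.
#' @export
run_pipeline <- function(out_dir, seed = 1, cfg = generator_config(),
                         spectra_file = NULL, meta_file = NULL,
                         cal_size = 280, sizes = seq(60, 260, by = 40),
                         k = 6, var_ks = 0.99, sg_window = 15, sg_order = 1,
                         max_lv = 20, committees = c(2, 4, 6, 8),
                         neighbors = c(10, 20, 30, 40), folds = 10,
                         skip = character(), make_plots = TRUE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if ("plots" %in% skip) make_plots <- FALSE
  seeds <- list(simulate = substream(seed, "simulate"),
                folds = substream(seed, "cubist-folds"))

  ## ingest or simulate
  if (!is.null(spectra_file)) {
    sp <- read_spectra(spectra_file, layout = "wide")
    meta <- read_metadata(meta_file)
  } else {
    meta <- simulate_chlorophyll(cfg, seeds$simulate)
    sp <- simulate_spectra(meta, cfg, seeds$simulate)
  }
  ds <- join_metadata(sp, meta)

  ## preprocess
  pre <- preprocess_spectra(ds$spectra, window = sg_window,
                            polyorder = sg_order)
  write_spectra(pre, file.path(out_dir, "preprocessed.csv"))
  utils::write.csv(ds$meta, file.path(out_dir, "meta.csv"),
                   row.names = FALSE, quote = FALSE)

  ## Kennard-Stone calibration/validation split in PC space
  pool_pca <- fit_pca(pre, var_explained = var_ks)
  cal_idx <- kennard_stone(pool_pca$scores, cal_size)
  val_idx <- setdiff(seq_len(nrow(pre$values)), cal_idx)
  writeLines(pre$sample_ids[cal_idx], file.path(out_dir, "calibration.ids"))
  writeLines(pre$sample_ids[val_idx], file.path(out_dir, "validation.ids"))

  cal <- pre[cal_idx]; val <- pre[val_idx]
  y_cal <- ds$meta$chlorophyll[cal_idx]
  y_val <- ds$meta$chlorophyll[val_idx]

  ## MSD sweep and nomination
  sw <- msd_sweep(cal, val, sizes = sizes, k = k, var_ks = var_ks)
  utils::write.table(sw$table, file.path(out_dir, "msd_sweep.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (s in names(sw$subsets))
    writeLines(cal$sample_ids[sw$subsets[[s]]],
               file.path(out_dir, paste0("subset_", s, ".ids")))
  sub_idx <- sw$subsets[[as.character(sw$nominated)]]
  X_sub <- cal$values[sub_idx, , drop = FALSE]
  y_sub <- y_cal[sub_idx]

  ## models on the nominated subset
  plsr <- cubist <- NULL
  reports <- list()
  if (!"plsr" %in% skip) {
    plsr <- fit_plsr(X_sub, y_sub, max_lv = max_lv,
                     wavelengths = cal$wavelengths)
    write_plsr_json(plsr, file.path(out_dir, "plsr_model.json"))
    reports$plsr <- evaluate(y_val, predict(plsr, val$values),
                             label = "validation/plsr")
  }
  if (!"cubist" %in% skip) {
    cubist <- if (folds > 0) {
      cubist_grid(X_sub, y_sub, committees = committees,
                  neighbors = neighbors, folds = folds,
                  seed = seeds$folds)
    } else {
      cubist_lite(X_sub, y_sub, committees = committees[1],
                  neighbors = neighbors[1])
    }
    write_cubist_json(cubist, file.path(out_dir, "cubist_model.json"))
    reports$cubist <- evaluate(y_val, predict(cubist, val$values),
                               label = "validation/cubist")
  }

  ## evaluation tables
  if (length(reports)) {
    ev <- do.call(rbind, lapply(reports, as.data.frame))
    utils::write.table(format(ev, digits = 10),
                       file.path(out_dir, "evaluation.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    pred_val <- if (!is.null(plsr)) predict(plsr, val$values)
                else predict(cubist, val$values)
    gs <- group_summaries(ds$meta[val_idx, , drop = FALSE], pred_val)
    utils::write.table(format(gs$by_cell, digits = 8),
                       file.path(out_dir, "group_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  ## configuration actually used (design defaults made explicit)
  config <- list(seed = seed, stage_seeds = seeds, cal_size = cal_size,
                 sizes = sizes, k = k, var_ks = var_ks,
                 sg_window = sg_window, sg_order = sg_order,
                 sg_edge = "poly", max_lv = max_lv,
                 committees = committees, neighbors = neighbors,
                 folds = folds, bandwidth_rule = "silverman-on-population",
                 kde_grid_n = sw$grid_n, kde_pad = sw$pad,
                 nomination_tol = sw$tol, nominated = sw$nominated,
                 skip = skip)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ## figures
  if (make_plots) {
    grDevices::pdf(file.path(out_dir, "fig_msd.pdf"), width = 9, height = 4.5)
    plot(sw, validation = val)
    grDevices::dev.off()
    if (!is.null(plsr) || !is.null(cubist)) {
      grDevices::pdf(file.path(out_dir, "fig_pred.pdf"), width = 9,
                     height = 4.5)
      op <- graphics::par(mfrow = c(1, sum(!vapply(
        list(plsr, cubist), is.null, logical(1)))))
      for (m in Filter(Negate(is.null), list(plsr = plsr, cubist = cubist))) {
        pv <- predict(m, val$values)
        graphics::plot(y_val, pv, xlab = "measured chlorophyll (mg/g)",
                       ylab = "predicted (mg/g)", pch = 16,
                       main = class(m)[1])
        graphics::abline(0, 1, lty = 2)
      }
      graphics::par(op)
      grDevices::dev.off()
    }
    if (!is.null(plsr)) {
      grDevices::pdf(file.path(out_dir, "fig_vip.pdf"), width = 9,
                     height = 4.5)
      plot(plsr)
      grDevices::dev.off()
    }
    if (length(reports)) {
      grDevices::pdf(file.path(out_dir, "fig_monthly.pdf"), width = 6,
                     height = 4.5)
      bm <- gs$by_month
      graphics::plot(bm$month, bm$mean, type = "b", pch = 16,
                     xlab = "month", ylab = "predicted chlorophyll (mg/g)")
      graphics::arrows(bm$month, bm$mean - bm$se, bm$month, bm$mean + bm$se,
                       angle = 90, code = 3, length = 0.03)
      grDevices::dev.off()
    }
  }

  invisible(list(out_dir = out_dir, dataset = ds, preprocessed = pre,
                 cal_idx = cal_idx, val_idx = val_idx, sweep = sw,
                 plsr = plsr, cubist = cubist, reports = reports))
}

# derive a deterministic per-stage seed (< 2^31) from the root seed
substream <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131L)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

write_plsr_json <- function(model, path) {
  obj <- list(type = "plsr", n_lv = model$n_lv,
              wavelengths = model$wavelengths,
              intercept = model$intercept,
              coefficients = unname(model$coefficients),
              x_center = unname(model$x_center),
              y_center = model$y_center,
              vip = unname(model$vip),
              cv_rmse = model$cv_rmse)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

write_cubist_json <- function(model, path) {
  obj <- list(type = "cubist_lite", committees = model$committees,
              neighbors = model$neighbors, w_nn = model$w_nn,
              min_leaf = model$min_leaf,
              max_depth = model$max_depth, screen = model$screen,
              leaves_per_tree = vapply(model$trees, count_leaves,
                                       integer(1)),
              fold_seed = model$fold_seed,
              cv_table = model$cv_table)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
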