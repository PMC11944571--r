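#' Model assessment metrics for chlorophyll calibration
#'
#' Computes the standard spectroscopic calibration metrics on a set of
#' observed/predicted pairs:
#' * `r2   = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)`
#' * `rmse = sqrt(mean((pred - obs)^2))` (RMSEP when the split is a
#'   validation set)
#' * `rpiq = IQR(obs) / rmse` with type-7 (linear interpolation) quartiles
#' * `bias = mean(pred - obs)` and `mbe = mean(pred - obs)` -- both emitted
#'   under the single sign convention *predicted minus observed*.
#'
#' Degenerate cases are reported as `NA` with a warning: `r2`/`rpiq` when
#' the observations are constant, `rpiq` when `rmse` is exactly 0.
#'
#' @param obs numeric vector of observed values (mg per g).
#' @param pred numeric vector of predictions, same length.
#' @param label name of the data split (e.g. `"validation"`).
#' @return an `eval_report`: list with `label`, `n`, `r2`, `rmse`, `rpiq`,
#'   `bias`, `mbe`.
#' @examples
#' evaluate(c(1, 2, 3, 4), c(1, 2, 3, 5))  # rmse 0.5, rpiq 3, bias 0.25
#' @export
evaluate <- function(obs, pred, label = "validation") {
  obs <- as.numeric(obs); pred <- as.numeric(pred)
  if (length(obs) != length(pred)) stop("obs and pred lengths differ")
  if (length(obs) < 2) stop("need at least 2 pairs")
  if (anyNA(obs) || anyNA(pred)) stop("missing values in obs or pred")
  rmse <- sqrt(mean((pred - obs) ^ 2))
  bias <- mean(pred - obs)
  sst <- sum((obs - mean(obs)) ^ 2)
  if (sst == 0) {
    warning("constant observations: r2 and rpiq undefined")
    r2 <- NA_real_; rpiq <- NA_real_
  } else {
    r2 <- 1 - sum((obs - pred) ^ 2) / sst
    if (rmse == 0) {
      warning("rmse is 0: rpiq undefined")
      rpiq <- NA_real_
    } else {
      q <- stats::quantile(obs, c(0.25, 0.75), type = 7, names = FALSE)
      rpiq <- (q[2] - q[1]) / rmse
    }
  }
  structure(list(label = label, n = length(obs), r2 = r2, rmse = rmse,
                 rpiq = rpiq, bias = bias, mbe = bias),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %s (n = %d): R2 = %.3f, RMSE = %.3f, RPIQ = %.2f, bias = %.3f\n",
    x$label, x$n, x$r2, x$rmse, x$rpiq, x$bias))
  invisible(x)
}

#' @export
as.data.frame.eval_report <- function(x, ...) {
  data.frame(split = x$label, n = x$n, r2 = x$r2, rmse = x$rmse,
             rpiq = x$rpiq, bias = x$bias, mbe = x$mbe)
}

#' Per-species and per-month prediction summaries
#'
#' Summarises predictions as mean +/- standard error (`sd / sqrt(n)`) by
#' species, by month, and by (species, month) cell -- the per-group view
#' used to inspect seasonal chlorophyll trends. Groups of size 1 get
#' `NA` standard errors.
#'
#' @param meta metadata `data.frame` with `species` and `month` columns,
#'   rows aligned with `pred`.
#' @param pred numeric vector of predictions.
#' @return list of three `data.frame`s: `by_species`, `by_month`,
#'   `by_cell`, each with columns `n`, `mean`, `se`.
#' @export
group_summaries <- function(meta, pred) {
  if (nrow(meta) != length(pred)) stop("meta rows and pred length differ")
  one <- function(key) {
    agg <- do.call(rbind, lapply(split(seq_along(pred), key), function(i) {
      data.frame(n = length(i), mean = mean(pred[i]),
                 se = if (length(i) > 1)
                   stats::sd(pred[i]) / sqrt(length(i)) else NA_real_)
    }))
    cbind(group = rownames(agg), agg, row.names = NULL)
  }
  by_species <- one(meta$species)
  names(by_species)[1] <- "species"
  by_month <- one(meta$month)
  names(by_month)[1] <- "month"
  by_month$month <- as.integer(as.character(by_month$month))
  by_month <- by_month[order(by_month$month), ]
  rownames(by_month) <- NULL
  by_cell <- one(paste(meta$species, meta$month, sep = "|"))
  parts <- strsplit(as.character(by_cell$group), "|", fixed = TRUE)
  by_cell <- data.frame(species = vapply(parts, `[`, "", 1),
                        month = as.integer(vapply(parts, `[`, "", 2)),
                        by_cell[-1])
  by_cell <- by_cell[order(by_cell$species, by_cell$month), ]
  rownames(by_cell) <- NULL
  list(by_species = by_species, by_month = by_month, by_cell = by_cell)
}
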