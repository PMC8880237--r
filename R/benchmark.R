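# Selector x transfer evaluation: one code path serves the GA fitness, the
# per-cell evaluation entry point, and the full benchmark table.

# Build the master model on selected columns, fit the named transfer on the
# calibration standards, transfer the slave eval spectra, and measure.
#
# pair      : preprocessed paired_sets (full sample set)
# cal       : calibration indices (transfer standards = calibration samples)
# eval_idx  : indices whose slave spectra are transferred and predicted
# sel       : selected wavelength columns (NULL = all)
# val_idx   : validation indices, used only by SST's auto factor scan
transfer_eval_core <- function(pair, cal, eval_idx, sel = NULL, method,
                               max_latent = 15L,
                               cv_scheme = "contiguous_blocks",
                               val_idx = NULL, transfer_opts = list()) {
  if (is.null(sel)) sel <- seq_len(ncol(pair$master$spectra))
  m_cal <- subset_samples(pair$master, cal, sel)
  s_cal <- subset_samples(pair$slave, cal, sel)
  s_eval <- subset_samples(pair$slave, eval_idx, sel)
  opts <- transfer_opts

  if (method == "osc") {
    n_osc <- if (is.null(opts$n_osc)) 1L else opts$n_osc
    osc <- fit_osc(m_cal$spectra, m_cal$y, n_osc = n_osc)
    Xm <- apply_transfer(osc, m_cal$spectra)
    nlv <- choose_n_latent(Xm, m_cal$y, max_latent, cv_scheme)
    rmsecv <- cv_rmse(Xm, m_cal$y, nlv, cv_scheme)
    master <- fit_pls(Xm, m_cal$y, nlv)
    pred <- predict(master, apply_transfer(osc, s_eval$spectra))
    tmodel <- osc
  } else {
    nlv <- choose_n_latent(m_cal$spectra, m_cal$y, max_latent, cv_scheme)
    rmsecv <- cv_rmse(m_cal$spectra, m_cal$y, nlv, cv_scheme)
    master <- fit_pls(m_cal$spectra, m_cal$y, nlv)
    if (method == "sbc") {
      tmodel <- fit_sbc(master, s_cal)
      pred <- apply_transfer(tmodel, predict(master, s_eval$spectra))
    } else if (method == "pds") {
      window <- if (is.null(opts$window)) 9L else opts$window
      window <- min(window, 2L * length(sel) - 1L)
      if (window %% 2 == 0) window <- window - 1L
      tmodel <- fit_pds(m_cal, s_cal, window = window,
                        n_latent_local = opts$n_latent_local)
      pred <- predict(master, apply_transfer(tmodel, s_eval$spectra))
    } else if (method == "sst") {
      nf <- if (is.null(opts$n_factors)) "auto" else opts$n_factors
      vp <- if (identical(nf, "auto")) {
        if (is.null(val_idx)) stop("SST auto factor scan needs val_idx")
        subset_pair(pair, val_idx, sel)
      } else NULL
      tmodel <- fit_sst(m_cal, s_cal, n_factors = nf,
                        master_model = master, val_pair = vp)
      pred <- predict(master, apply_transfer(tmodel, s_eval$spectra))
    } else stop("unknown transfer method '", method, "'")
  }
  met <- metric_rmse_r2(pred, s_eval$y)
  list(rmse = met$rmse, r2 = met$r2, pred = pred, n_latent = nlv,
       rmsecv = rmsecv, n_variables = length(sel), transfer_model = tmodel,
       master_model = master)
}

run_selector <- function(selector, pair, splits, transfer_method,
                         opts = list()) {
  p <- ncol(pair$master$spectra)
  max_latent <- if (is.null(opts$max_latent)) 15L else opts$max_latent
  seed <- if (is.null(opts$seed)) 1L else opts$seed
  if (selector == "none") {
    list(selected = seq_len(p), threshold = NA_real_, detail = NULL)
  } else if (selector == "safs") {
    cfg <- if (is.null(opts$ga)) ga_config(seed = seed + 101L) else opts$ga
    K <- if (is.null(opts$K)) 1000L else opts$K
    rate <- if (is.null(opts$rate)) 0.8 else opts$rate
    res <- safs_select(pair, splits, transfer_method, cfg = cfg, K = K,
                       rate = rate, seed = seed, max_latent = max_latent,
                       transfer_opts = opts$transfer_opts %||% list())
    list(selected = res$selected, threshold = res$threshold_best,
         detail = res)
  } else if (selector == "cars") {
    cal <- subset_samples(pair$master, splits$cal)
    res <- cars_select(cal$spectra, cal$y,
                       n_runs = opts$cars_runs %||% 50L,
                       rate = opts$rate %||% 0.8,
                       max_latent = max_latent, seed = seed + 202L)
    list(selected = res$selected, threshold = NA_real_, detail = res)
  } else if (selector == "sipls") {
    cal <- subset_samples(pair$master, splits$cal)
    res <- sipls_select(cal$spectra, cal$y,
                        n_intervals = opts$sipls_intervals %||% 30L,
                        n_joint = opts$sipls_joint %||% 4L,
                        max_latent = max_latent)
    list(selected = res$selected, threshold = NA_real_, detail = res)
  } else stop("unknown selector '", selector, "'")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate one selector x transfer combination
#'
#' Runs the wavelength selector on the calibration data, builds the master
#' model on the selected columns, fits the transfer on the calibration
#' standards, transfers and predicts the slave prediction set, and reports
#' the evaluation row: RMSECV, R^2, RMSEP, latent-variable count, selected
#' variable count, and the stability threshold where applicable.
#'
#' @param pair preprocessed `paired_sets`.
#' @param splits list with `cal`, `val`, `pred` indices (see [spxy_split()]).
#' @param selector `"none"`, `"safs"`, `"cars"` or `"sipls"`.
#' @param transfer_method `"sbc"`, `"pds"`, `"sst"` or `"osc"`.
#' @param opts named list of options: `max_latent`, `seed`, `K`, `rate`,
#'   `ga` (a [ga_config()]), `cars_runs`, `sipls_intervals`, `sipls_joint`,
#'   `transfer_opts` (forwarded to the transfer fit).
#' @return list of class `eval_report` with fields `selector`, `transfer`,
#'   `n_variables`, `rmsecv`, `r2`, `rmsep`, `n_latent`, `threshold`.
#' @export
evaluate_cell <- function(pair, splits, selector, transfer_method,
                          opts = list()) {
  sel <- run_selector(selector, pair, splits, transfer_method, opts)
  core <- transfer_eval_core(pair, splits$cal, splits$pred, sel$selected,
                             transfer_method,
                             max_latent = opts$max_latent %||% 15L,
                             val_idx = splits$val,
                             transfer_opts = opts$transfer_opts %||% list())
  structure(list(selector = selector, transfer = transfer_method,
                 n_variables = core$n_variables, rmsecv = core$rmsecv,
                 r2 = core$r2, rmsep = core$rmse,
                 n_latent = core$n_latent, threshold = sel$threshold,
                 selected = sel$selected, pred = core$pred),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %s x %s: %d vars, RMSECV %.4f, R2 %.4f, RMSEP %.4f, %d LV\n",
    x$transfer, x$selector, x$n_variables, x$rmsecv, x$r2, x$rmsep,
    x$n_latent))
  invisible(x)
}

#' Run the full selector x transfer benchmark grid
#'
#' Produces one evaluation row per combination of wavelength selector and
#' transfer algorithm, mirroring the standard benchmark-table layout for
#' calibration-transfer studies. Cells that error are recorded as failed
#' rather than aborting the grid.
#'
#' @inheritParams evaluate_cell
#' @param selectors,transfers character vectors defining the grid.
#' @return `data.frame` with one row per cell (class `benchmark_table`);
#'   failed cells carry `NA` metrics and the error message.
#' @export
run_benchmark <- function(pair, splits,
                          selectors = c("none", "safs", "cars", "sipls"),
                          transfers = c("sbc", "pds", "sst", "osc"),
                          opts = list()) {
  rows <- list()
  for (tr in transfers) {
    for (se in selectors) {
      cell <- tryCatch(evaluate_cell(pair, splits, se, tr, opts),
                       error = function(e) e)
      rows[[length(rows) + 1L]] <- if (inherits(cell, "error")) {
        data.frame(transfer = tr, selector = se, n_variables = NA_integer_,
                   rmsecv = NA_real_, r2 = NA_real_, rmsep = NA_real_,
                   n_latent = NA_integer_, threshold = NA_real_,
                   error = conditionMessage(cell),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(transfer = tr, selector = se,
                   n_variables = cell$n_variables, rmsecv = cell$rmsecv,
                   r2 = cell$r2, rmsep = cell$rmsep,
                   n_latent = cell$n_latent, threshold = cell$threshold,
                   error = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("benchmark_table", class(out))
  out
}

#' Serialize / restore an evaluation report
#'
#' @param report an `eval_report` or `benchmark_table`.
#' @param path output JSON path.
#' @return `path` invisibly; `read_report` returns the restored object.
#' @export
write_report <- function(report, path) {
  obj <- unclass(report)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$selector) && length(obj$selector) == 1L)
    class(obj) <- "eval_report"
  obj
}
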