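#' Forecast error metrics with accuracy grading
#'
#' Computes the three standard error indices over a (truth, prediction)
#' pairing of equal length:
#' `MAE = mean(|p - t|)`, `MAPE = mean(|p - t| / t) * 100` (%), and
#' `RMSE = sqrt(mean((p - t)^2))`, plus the qualitative MAPE grade.
#'
#' @param truth observed values (`annual_series` or numeric), strictly
#'   positive (MAPE denominator).
#' @param prediction predicted values, same length.
#' @param range optional free-text description of the index span evaluated.
#' @return an object of class `eval_report`: list with `mae`, `mape`,
#'   `rmse`, `grade`, `n`, `range`.
#' @examples
#' compute_metrics(c(100), c(110))   # MAE 10, MAPE 10%, RMSE 10
#' @export
compute_metrics <- function(truth, prediction, range = "") {
  t <- as.numeric(truth)
  p <- as.numeric(prediction)
  if (length(t) != length(p)) stop("compute_metrics: length mismatch")
  if (length(t) == 0L) stop("compute_metrics: empty input")
  if (any(t == 0)) stop("compute_metrics: MAPE undefined (zero truth value)")
  if (any(t < 0)) stop("compute_metrics: truth must be strictly positive")
  e <- p - t
  mape <- mean(abs(e) / t) * 100
  structure(list(mae = mean(abs(e)), mape = mape, rmse = sqrt(mean(e^2)),
                 grade = mape_grade(mape), n = length(t), range = range),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%sMAE %.2f | MAPE %.2f%% | RMSE %.2f | grade: %s (n = %d)\n",
              if (nzchar(x$range)) paste0(x$range, ": ") else "",
              x$mae, x$mape, x$rmse, x$grade, x$n))
  invisible(x)
}

#' Qualitative accuracy grade of a MAPE value
#'
#' Bands (left-closed, right-open): `[0, 10)` excellent, `[10, 20)` good,
#' `[20, 50)` common, `[50, Inf)` poor.
#'
#' @param mape non-negative MAPE percentage.
#' @return one of `"excellent"`, `"good"`, `"common"`, `"poor"`.
#' @examples
#' mape_grade(1.63)   # "excellent"
#' @export
mape_grade <- function(mape) {
  stopifnot(length(mape) == 1L, is.finite(mape))
  if (mape < 0) stop("mape_grade: MAPE cannot be negative")
  if (mape < 10) "excellent" else if (mape < 20) "good"
  else if (mape < 50) "common" else "poor"
}

#' Fit/hold-out benchmark over a set of models
#'
#' Implements the benchmark protocol of the case study: each model is fitted
#' on the contiguous `fit_years` window and predicts the contiguous
#' `test_years` window that immediately follows; error metrics are reported
#' for both blocks. GT-FGM and FGM optimize their accumulation order (and
#' GT-FGM its curvature) on the fitting window only.
#'
#' @param series an [annual_series()] covering both windows.
#' @param fit_years,test_years integer year vectors (`test_years` must start
#'   the year after `fit_years` ends).
#' @param models character vector from
#'   `c("gtfgm", "fgm", "gm11", "verhulst", "logistic", "ses")`.
#' @param include_first include the anchored first fitted point in the
#'   fitting-block metrics (default `TRUE`).
#' @param seed seed for the hyperparameter searches.
#' @param control a [pso_control()].
#' @return an object of class `benchmark_result`: list with `predictions`
#'   (data.frame of year, truth and one column per model over both blocks)
#'   and `metrics` (data.frame with model, block, mae, mape, rmse, grade).
#' @export
run_benchmark <- function(series, fit_years, test_years,
                          models = c("gtfgm", "fgm", "gm11", "verhulst",
                                     "logistic", "ses"),
                          include_first = TRUE, seed = 1L,
                          control = pso_control()) {
  stopifnot(inherits(series, "annual_series"))
  known <- c("gtfgm", "fgm", "gm11", "verhulst", "logistic", "ses")
  bad <- setdiff(models, known)
  if (length(bad))
    stop("run_benchmark: unknown model name(s): ", paste(bad, collapse = ", "))
  fit_years <- as.integer(fit_years)
  test_years <- as.integer(test_years)
  if (any(diff(fit_years) != 1L) || any(diff(test_years) != 1L) ||
      test_years[1L] != fit_years[length(fit_years)] + 1L)
    stop("run_benchmark: fit and test windows must be contiguous, test following fit")
  yr <- years(series)
  if (!all(c(fit_years, test_years) %in% yr))
    stop("run_benchmark: protocol years outside the series range")

  train <- window_years(series, fit_years[1L], fit_years[length(fit_years)])
  truth_test <- window_years(series, test_years[1L], test_years[length(test_years)])
  h <- length(test_years)
  keep_fit <- if (include_first) seq_along(train) else seq_along(train)[-1L]

  fits <- list()
  preds <- list()
  for (m in models) {
    obj <- switch(m,
      gtfgm = gt_fgm(train, control = control, seed = seed),
      fgm = {
        r <- pso_minimize(function(p) fgm_objective(train, p[1L]),
                          lower = control$r_min, upper = control$r_max,
                          control = control, seed = seed)$par[1L]
        fit_fgm(train, r)
      },
      gm11 = fit_gm11(train),
      verhulst = fit_verhulst(train),
      logistic = fit_logistic(train),
      ses = fit_ses(train))
    fits[[m]] <- obj
    preds[[m]] <- as.numeric(predict(obj, horizon = h))
  }

  metrics <- do.call(rbind, lapply(models, function(m) {
    fv <- fitted(fits[[m]])
    fm <- compute_metrics(as.numeric(train)[keep_fit], fv[keep_fit], range = "fit")
    tm <- compute_metrics(truth_test, preds[[m]], range = "test")
    data.frame(model = m, block = c("fit", "test"),
               mae = c(fm$mae, tm$mae), mape = c(fm$mape, tm$mape),
               rmse = c(fm$rmse, tm$rmse), grade = c(fm$grade, tm$grade),
               stringsAsFactors = FALSE)
  }))

  pred_df <- data.frame(year = c(fit_years, test_years),
                        truth = c(as.numeric(train), as.numeric(truth_test)))
  for (m in models) pred_df[[m]] <- c(fitted(fits[[m]]), preds[[m]])

  structure(list(predictions = pred_df, metrics = metrics,
                 fit_years = fit_years, test_years = test_years,
                 fits = fits),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("Benchmark: fit %d-%d, test %d-%d\n",
              x$fit_years[1L], x$fit_years[length(x$fit_years)],
              x$test_years[1L], x$test_years[length(x$test_years)]))
  m <- x$metrics
  m$mae <- round(m$mae, 2)
  m$mape <- round(m$mape, 2)
  m$rmse <- round(m$rmse, 2)
  print(m, row.names = FALSE)
  invisible(x)
}

#' Write a benchmark result as CSV and Markdown tables
#'
#' Emits the year-by-year prediction table with a metric footer per block,
#' mirroring the layout of the case study's comparison tables.
#'
#' @param x a `benchmark_result`.
#' @param csv_path,md_path output paths (either may be `NULL` to skip).
#' @return invisibly, the prediction data.frame.
#' @export
write_benchmark <- function(x, csv_path = NULL, md_path = NULL) {
  stopifnot(inherits(x, "benchmark_result"))
  if (!is.null(csv_path)) {
    utils::write.csv(format_benchmark_df(x), csv_path, row.names = FALSE)
  }
  if (!is.null(md_path)) {
    df <- format_benchmark_df(x)
    hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    writeLines(c(hdr, sep, rows), md_path)
  }
  invisible(x$predictions)
}

format_benchmark_df <- function(x) {
  models <- setdiff(names(x$predictions), c("year", "truth"))
  df <- x$predictions
  for (m in models) df[[m]] <- sprintf("%.2f", df[[m]])
  df$truth <- sprintf("%.2f", df$truth)
  df$year <- as.character(df$year)
  for (blk in c("fit", "test")) {
    mm <- x$metrics[x$metrics$block == blk, ]
    for (metric in c("mae", "mape", "rmse")) {
      row <- c(sprintf("%s %s", blk, toupper(metric)), "")
      for (m in models) {
        v <- mm[mm$model == m, metric]
        row <- c(row, if (metric == "mape") sprintf("%.2f%%", v) else sprintf("%.2f", v))
      }
      df <- rbind(df, stats::setNames(as.list(row), names(df)))
    }
  }
  df
}
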