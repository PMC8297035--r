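#' Stage-one predictor screening by Pearson correlation
#'
#' Ranks candidate predictors by the absolute Pearson correlation of each
#' with the response. Candidates may come in buffer families (e.g. traffic
#' volume extracted in 150/300/600/1200 m buffers, named `traffic_150` etc.);
#' within each base variable only the buffer with the highest |r| is kept —
#' ties go to the smaller buffer, then to the lexicographically smaller
#' name. Zero-variance candidates are excluded with a recorded reason.
#'
#' @param data data frame containing the candidate columns.
#' @param response name of the response column, or a numeric vector.
#' @param candidates character vector of candidate column names; default all
#'   numeric columns except the response and the reserved station-table
#'   columns. A trailing `_<digits>` in a name is parsed as the buffer
#'   radius in meters.
#' @param r_floor optional minimum |r|; candidates below it are dropped
#'   (default 0, i.e. off).
#' @return data frame of class `pearson_screen`, one row per candidate:
#'   `name`, `base`, `buffer`, `r`, `kept` (logical), `reason`, ordered by
#'   decreasing |r| among the kept rows first.
#' @export
pearson_screen <- function(data, response = "y", candidates = NULL,
                           r_floor = 0) {
  yv <- if (is.character(response)) data[[response]] else as.numeric(response)
  if (length(yv) < 3) stop("need at least 3 samples")
  reserved <- c("station_id", "u", "v", "date",
                if (is.character(response)) response)
  if (is.null(candidates)) {
    candidates <- setdiff(names(data)[vapply(data, is.numeric, TRUE)],
                          reserved)
    candidates <- candidates[!grepl("__var$", candidates)]
  }
  base <- sub("_([0-9]+)$", "", candidates)
  buffer <- suppressWarnings(
    as.numeric(ifelse(grepl("_([0-9]+)$", candidates),
                      sub("^.*_([0-9]+)$", "\\1", candidates), NA)))

  r <- vapply(candidates, function(cn) {
    v <- data[[cn]]
    if (stats::sd(v) == 0) NA_real_ else stats::cor(v, yv)
  }, 0)

  out <- data.frame(name = candidates, base = base, buffer = buffer,
                    r = r, kept = FALSE, reason = "", row.names = NULL,
                    stringsAsFactors = FALSE)
  out$reason[is.na(out$r)] <- "zero variance"
  out$reason[!is.na(out$r) & abs(out$r) < r_floor] <-
    sprintf("|r| below floor %.3g", r_floor)

  # within each base variable keep only the best buffer
  for (b in unique(out$base)) {
    rows <- which(out$base == b & out$reason == "")
    if (!length(rows)) next
    ord <- rows[order(-abs(out$r[rows]),
                      ifelse(is.na(out$buffer[rows]), Inf, out$buffer[rows]),
                      out$name[rows])]
    out$kept[ord[1]] <- TRUE
    if (length(ord) > 1)
      out$reason[ord[-1]] <- sprintf(
        "buffer with lower |r| than %s", out$name[ord[1]])
  }
  out <- out[order(-out$kept, -abs(out$r), out$name), ]
  rownames(out) <- NULL
  class(out) <- c("pearson_screen", "data.frame")
  out
}

#' Stage-two exhaustive subset search with a p-value filter
#'
#' Enumerates all subsets (up to `max_size` variables) of the screened
#' candidates, fits each by OLS, discards any subset in which some
#' coefficient has p > `alpha` in that subset's fit, and returns the
#' surviving subset with the highest R². Also reports the best-RMSE-per-size
#' profile over all enumerated subsets, which is non-increasing in subset
#' size. Ties in R² are broken toward the smaller subset, then
#' lexicographically.
#'
#' @param data data frame with the candidate columns and the response.
#' @param response response column name.
#' @param candidates character vector of candidate names (at most 12, so the
#'   enumeration stays exhaustive).
#' @param max_size largest subset considered (default 5).
#' @param alpha per-coefficient significance level (default 0.05).
#' @return list of class `subset_search`: `chosen` (character vector, empty
#'   if nothing survives), `table` (one row per subset: variables, size, r2,
#'   rmse, significant), `rmse_profile` (best RMSE per size), `alpha`.
#' @export
subset_search <- function(data, response = "y", candidates, max_size = 5,
                          alpha = 0.05) {
  if (length(candidates) > 12)
    stop("at most 12 candidates are supported (exhaustive enumeration)")
  yv <- data[[response]]
  max_size <- min(max_size, length(candidates))

  rows <- list()
  for (s in seq_len(max_size)) {
    for (combo in utils::combn(candidates, s, simplify = FALSE)) {
      f <- stats::reformulate(combo, response = response)
      fit <- stats::lm(f, data = data)
      pv <- summary(fit)$coefficients[-1, "Pr(>|t|)"]
      yhat <- stats::fitted(fit)
      rows[[length(rows) + 1L]] <- data.frame(
        variables = paste(sort(combo), collapse = "+"), size = s,
        r2 = r_squared(yv, yhat), rmse = rmse(yv, yhat),
        max_p = max(pv), significant = all(pv <= alpha),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  surv <- tab[tab$significant, , drop = FALSE]
  chosen <- character(0)
  if (nrow(surv)) {
    surv <- surv[order(-surv$r2, surv$size, surv$variables), , drop = FALSE]
    chosen <- strsplit(surv$variables[1], "+", fixed = TRUE)[[1]]
  } else {
    message("no subset survives the p-value filter (alpha = ", alpha, ")")
  }
  profile <- stats::aggregate(rmse ~ size, data = tab, FUN = min)
  structure(list(chosen = chosen, table = tab, rmse_profile = profile,
                 alpha = alpha),
            class = "subset_search")
}

#' Station-wise leave-one-out cross-validation
#'
#' One fold per monitoring station: each fold trains on every other
#' station's samples and tests on all samples of the held-out station, so a
#' model is never judged on data from a location it has seen. Reports RMSE
#' and MAE for test and training data per fold and on average.
#'
#' @param formula,data,coords,method,... as in [gwtls()]; `...` is passed on
#'   (e.g. `variances`, `bandwidth`, `tol`).
#' @param station name of the station-identifier column (default
#'   `"station_id"`).
#' @return list of class `loocv`: `folds` (data frame: station, n_test,
#'   rmse_test, mae_test, rmse_train, mae_train), `mean` (named vector of
#'   the four mean errors), `skipped` (stations whose fold failed, with the
#'   error message).
#' @export
loocv_by_station <- function(formula, data, coords = ~ u + v,
                             method = "gwtlsr", station = "station_id", ...) {
  ids <- unique(data[[station]])
  if (length(ids) < 3) stop("need at least 3 distinct stations")
  folds <- list(); skipped <- list()
  for (id in ids) {
    test <- data[data[[station]] == id, , drop = FALSE]
    train <- data[data[[station]] != id, , drop = FALSE]
    res <- tryCatch({
      fit <- gwtls(formula, train, coords = coords, method = method, ...)
      yhat_test <- predict(fit, test)
      ytest <- stats::model.response(stats::model.frame(formula, test))
      data.frame(station = id, n_test = nrow(test),
                 rmse_test = rmse(ytest, yhat_test),
                 mae_test = mae(ytest, yhat_test),
                 rmse_train = rmse(fit$system$y, fitted(fit)),
                 mae_train = mae(fit$system$y, fitted(fit)),
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("fold for station ", id, " skipped: ", conditionMessage(res))
      skipped[[as.character(id)]] <- conditionMessage(res)
    } else folds[[length(folds) + 1L]] <- res
  }
  folds <- do.call(rbind, folds)
  means <- colMeans(folds[c("rmse_test", "mae_test",
                            "rmse_train", "mae_train")])
  structure(list(folds = folds, mean = means, skipped = skipped,
                 method = method),
            class = "loocv")
}

#' @export
print.loocv <- function(x, ...) {
  cat("Station-wise leave-one-out cross-validation —", toupper(x$method),
      "(", nrow(x$folds), "folds )\n")
  print(x$folds, row.names = FALSE)
  cat("Means:\n"); print(round(x$mean, 4))
  if (length(x$skipped)) cat("Skipped folds:", names(x$skipped), "\n")
  invisible(x)
}
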