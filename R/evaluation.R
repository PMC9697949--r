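# Performance metrics for the quantification model: mean absolute error,
# root mean square error and the coefficient of determination, per analyte
# and per data subset, on the linear concentration (%) scale with log2-scale
# variants as secondary columns.

check_pair <- function(c_exp, c_mod) {
  if (length(c_exp) != length(c_mod))
    stop("metric: input vectors must have equal length")
  if (length(c_exp) == 0) stop("metric: input vectors must be non-empty")
}

#' Mean absolute error
#'
#' `MAE = (1/n) * sum(|C_E - C_M|)` where `C_E` are experimental and `C_M`
#' model-estimated concentrations.
#'
#' @param c_exp,c_mod Equal-length numeric vectors (concentrations in %).
#' @return The mean absolute deviation.
#' @examples
#' mae(c(1, 2, 3), c(2, 2, 2))  # 2/3
#' @export
mae <- function(c_exp, c_mod) {
  check_pair(c_exp, c_mod)
  mean(abs(c_exp - c_mod))
}

#' Root mean square error
#'
#' `RMSE = sqrt(sum((C_E - C_M)^2) / n)`; always at least as large as the
#' MAE on the same pair.
#'
#' @inheritParams mae
#' @return The root mean squared deviation.
#' @examples
#' rmse(c(1, 2, 3), c(2, 2, 2))  # sqrt(2/3)
#' @export
rmse <- function(c_exp, c_mod) {
  check_pair(c_exp, c_mod)
  sqrt(mean((c_exp - c_mod)^2))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot`, with the total sum of squares about the
#' mean of the experimental values. Undefined (NA with a warning) when the
#' experimental vector is constant.
#'
#' @inheritParams mae
#' @return R squared; 1 for perfect prediction, 0 for the mean-only model.
#' @export
r_squared <- function(c_exp, c_mod) {
  check_pair(c_exp, c_mod)
  ss_tot <- sum((c_exp - mean(c_exp))^2)
  if (ss_tot == 0) {
    warning("r_squared: experimental values are constant; R^2 undefined")
    return(NA_real_)
  }
  1 - sum((c_exp - c_mod)^2) / ss_tot
}

#' Evaluate a trained model per analyte and subset
#'
#' Predicts every sample in the feature table, then computes R^2, MAE and
#' RMSE on the linear concentration scale (%) for each analyte within each
#' subset of the split, plus the same metrics on the log2 scale as
#' secondary columns.
#'
#' @param model A trained `mlp_model`.
#' @param features Feature table (data frame with `f1`..`f8`) or n x 8
#'   matrix.
#' @param concentrations n x 2 matrix or data frame of true concentrations
#'   in percent (ethanol, acetone).
#' @param split A [split_dataset()] over the n samples.
#' @return A data frame of class `eval_report`: one row per
#'   (analyte, subset) with columns `analyte`, `subset`, `n`, `r_squared`,
#'   `mae`, `rmse`, `r_squared_log2`, `mae_log2`, `rmse_log2`.
#' @export
evaluate_model <- function(model, features, concentrations, split) {
  conc <- as.matrix(concentrations)
  stopifnot(ncol(conc) == 2)
  pred <- stats::predict(model, features)
  true_log2 <- target_transform(conc[, 1], conc[, 2])
  subsets <- list(learning = split$learning, test = split$test,
                  validation = split$validation)
  pred_pct <- as.matrix(pred[, c("c_ethanol_pct", "c_acetone_pct")])
  pred_log2 <- as.matrix(pred[, c("log2_ethanol", "log2_acetone")])
  rows <- list()
  for (a in 1:2) for (s in names(subsets)) {
    idx <- subsets[[s]]
    analyte <- c("ethanol", "acetone")[a]
    if (length(idx) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        analyte = analyte, subset = s, n = 0L, r_squared = NA_real_,
        mae = NA_real_, rmse = NA_real_, r_squared_log2 = NA_real_,
        mae_log2 = NA_real_, rmse_log2 = NA_real_)
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      analyte = analyte, subset = s, n = length(idx),
      r_squared = r_squared(conc[idx, a], pred_pct[idx, a]),
      mae = mae(conc[idx, a], pred_pct[idx, a]),
      rmse = rmse(conc[idx, a], pred_pct[idx, a]),
      r_squared_log2 = r_squared(true_log2[idx, a], pred_log2[idx, a]),
      mae_log2 = mae(true_log2[idx, a], pred_log2[idx, a]),
      rmse_log2 = rmse(true_log2[idx, a], pred_log2[idx, a]))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("eval_report", "data.frame")
  out
}
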