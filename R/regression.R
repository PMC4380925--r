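#' Per-condition fold changes of shape features and the NF-kB ratio
#'
#' Each treated condition is matched to its control (same line and
#' medium); every feature's fold change is the treated/control ratio of
#' well-average values, so an untreated condition maps to all ones.
#'
#' @param treated data.frame of treated well profiles with columns
#'   \code{condition_id}, \code{line_id}, \code{medium} and the four
#'   features \code{neighbor_fraction}, \code{ruffliness},
#'   \code{area_nuc_cyto}, \code{tf_ratio}.
#' @param control data.frame of control profiles with \code{line_id},
#'   \code{medium} and the same features.
#' @return data.frame with \code{condition_id}, \code{d_nf},
#'   \code{d_ruffliness}, \code{d_anucacyto}, \code{d_tfratio} and a
#'   \code{valid} flag (FALSE when a control mean is zero; such records
#'   are excluded from fitting and a message is logged).
#' @export
compute_fold_changes <- function(treated, control) {
  feats <- c(neighbor_fraction = "d_nf", ruffliness = "d_ruffliness",
             area_nuc_cyto = "d_anucacyto", tf_ratio = "d_tfratio")
  need <- c("condition_id", "line_id", "medium", names(feats))
  if (!all(need %in% names(treated)))
    stop("treated profiles lack columns: ",
         paste(setdiff(need, names(treated)), collapse = ", "))
  key <- function(d) paste(d$line_id, d$medium, sep = "|")
  ck <- key(control)
  out <- NULL
  for (i in seq_len(nrow(treated))) {
    m <- match(key(treated[i, ]), ck)
    if (is.na(m))
      stop(sprintf("missing control for condition '%s'",
                   treated$condition_id[i]))
    fc <- vapply(names(feats), function(f) {
      cc <- control[[f]][m]
      if (cc == 0) NA_real_ else treated[[f]][i] / cc
    }, numeric(1))
    valid <- all(is.finite(fc))
    if (!valid)
      message(sprintf("condition '%s' flagged invalid (zero control mean)",
                      treated$condition_id[i]))
    row <- data.frame(condition_id = treated$condition_id[i],
                      stringsAsFactors = FALSE)
    row[feats] <- as.list(fc)
    row$valid <- valid
    out <- rbind(out, row)
  }
  out
}

#' Fit the three-predictor shape-response regression
#'
#' Ordinary least squares with intercept of the NF-kB ratio fold change on
#' the fold changes of neighbor fraction, ruffliness and the nuclear/
#' cytoplasmic area ratio. Reports R-squared, the residual (error)
#' variance, the overall F-test P value, and a Shapiro-Wilk residual
#' normality check.
#'
#' @param records Fold-change data.frame with columns \code{d_nf},
#'   \code{d_ruffliness}, \code{d_anucacyto}, \code{d_tfratio}
#'   (a \code{valid} column, if present, filters rows).
#' @param cond_threshold Design-matrix condition number above which a
#'   collinearity warning is issued.
#' @return Object of class \code{ShapeResponseModel}: list with
#'   \code{fit} (the lm), \code{coefficients} (c0, c_nf, c_ruffliness,
#'   c_ratio), \code{r_squared}, \code{error_variance},
#'   \code{p_value}, \code{residual_normality_p}, \code{n}.
#' @export
fit_shape_regression <- function(records, cond_threshold = 1e4) {
  if (!is.null(records$valid)) records <- records[records$valid, ]
  need <- c("d_nf", "d_ruffliness", "d_anucacyto", "d_tfratio")
  stopifnot(all(need %in% names(records)))
  if (nrow(records) < 5L) stop("need at least 5 valid fold-change records")
  fit <- stats::lm(d_tfratio ~ d_nf + d_ruffliness + d_anucacyto,
                   data = records)
  X <- stats::model.matrix(fit)
  kappa_x <- kappa(X, exact = TRUE)
  if (kappa_x > cond_threshold)
    warning(sprintf("collinear predictors: condition number %.3g", kappa_x))
  sm <- summary(fit)
  fstat <- sm$fstatistic
  pval <- if (!is.null(fstat))
    unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  else NA_real_
  res <- stats::residuals(fit)
  shap <- if (length(res) >= 3 && length(res) <= 5000)
    tryCatch(stats::shapiro.test(res)$p.value, error = function(e) NA_real_)
  else NA_real_
  structure(list(fit = fit,
                 coefficients = stats::setNames(
                   stats::coef(fit),
                   c("c0", "c_nf", "c_ruffliness", "c_ratio")),
                 r_squared = sm$r.squared,
                 error_variance = sm$sigma^2,
                 p_value = pval,
                 residual_normality_p = shap,
                 n = nrow(records)),
            class = "ShapeResponseModel")
}

#' @export
print.ShapeResponseModel <- function(x, ...) {
  cat(sprintf(
    "ShapeResponseModel (n = %d): R^2 = %.3f, error variance = %.4g, P = %.3g\n",
    x$n, x$r_squared, x$error_variance, x$p_value))
  co <- x$coefficients
  cat(sprintf("  d_tfratio = %.3f %+.3f d_nf %+.3f d_ruffliness %+.3f d_anucacyto\n",
              co[1], co[2], co[3], co[4]))
  invisible(x)
}

#' Tenfold cross-validation and 95%-interval outlier flagging
#'
#' Folds are assigned by seeded simple random permutation; the
#' cross-validation error is the mean absolute held-out prediction error
#' per fold, reported as mean and SD across folds (RMSE per fold is also
#' reported). Outliers are the conditions whose observed NF-kB fold
#' change lies outside the full-fit 95% prediction interval.
#'
#' @param records Fold-change data.frame, as in
#'   \code{\link{fit_shape_regression}}.
#' @param folds Number of folds (<= number of records).
#' @param seed Integer seed for the fold assignment.
#' @param level Prediction-interval coverage for outlier flagging.
#' @return List with \code{cv_mae_mean}, \code{cv_mae_sd},
#'   \code{cv_rmse_mean}, \code{fold_mae}, \code{outliers} (condition
#'   ids), \code{n_outliers}, and the full-fit \code{model}.
#' @export
crossvalidate_and_flag_outliers <- function(records, folds = 10L, seed = 1L,
                                            level = 0.95) {
  if (!is.null(records$valid)) records <- records[records$valid, ]
  n <- nrow(records)
  if (folds > n) stop("folds exceeds the number of records")
  assign_ <- with_seed(seed,
                       sample(rep_len(seq_len(folds), n)))
  fold_mae <- fold_rmse <- numeric(folds)
  for (f in seq_len(folds)) {
    test <- records[assign_ == f, , drop = FALSE]
    train <- records[assign_ != f, , drop = FALSE]
    fit_f <- stats::lm(d_tfratio ~ d_nf + d_ruffliness + d_anucacyto,
                       data = train)
    pred <- stats::predict(fit_f, newdata = test)
    err <- test$d_tfratio - pred
    fold_mae[f] <- mean(abs(err))
    fold_rmse[f] <- sqrt(mean(err^2))
  }
  model <- fit_shape_regression(records)
  pi_ <- stats::predict(model$fit, newdata = records,
                        interval = "prediction", level = level)
  # numerical slack so an exact fit (zero-width interval) flags nothing
  eps <- 1e-8 * max(abs(records$d_tfratio), 1)
  outside <- records$d_tfratio < pi_[, "lwr"] - eps |
    records$d_tfratio > pi_[, "upr"] + eps
  list(cv_mae_mean = mean(fold_mae), cv_mae_sd = stats::sd(fold_mae),
       cv_rmse_mean = mean(fold_rmse), fold_mae = fold_mae,
       outliers = records$condition_id[outside],
       n_outliers = sum(outside), model = model)
}
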