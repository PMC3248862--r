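#' Squared Pearson correlation
#'
#' @param x,y Numeric vectors of equal length (>= 3) with nonzero variance.
#' @return Squared Pearson product-moment correlation coefficient.
#' @export
pearson_r2 <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y) || length(x) < 3L) {
    stop("pearson_r2() needs two equal-length vectors of length >= 3",
         call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate variance: a variable is constant", call. = FALSE)
  }
  stats::cor(x, y)^2
}

#' Two-sided p-value for a squared Pearson correlation
#'
#' Uses the exact t transform of the correlation coefficient:
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` referred to the t distribution with
#' `n - 2` degrees of freedom, two-sided. The published tables report only
#' inequality bounds (P < 0.005, P < 0.05); exact values computed here can be
#' compared against those bounds.
#'
#' @param r2 Squared correlation in `[0, 1]`.
#' @param n Number of paired observations (>= 3).
#' @return Two-sided p-value. An exact fit (`r2 == 1`) returns 0 with
#'   attribute `exact_fit = TRUE`.
#' @export
#' @examples
#' pearson_pvalue(0.74, 9)  # < 0.005
pearson_pvalue <- function(r2, n) {
  stopifnot(is.numeric(r2), length(r2) == 1L, r2 >= 0, r2 <= 1, n >= 3)
  if (r2 >= 1) {
    return(structure(0, exact_fit = TRUE))
  }
  tval <- sqrt(r2) * sqrt(n - 2) / sqrt(1 - r2)
  2 * stats::pt(-abs(tval), df = n - 2)
}

#' Calibrate visceral-fat area on the loss changing rate
#'
#' Ordinary least squares of visceral-fat area (cm^2, response) on the loss
#' changing rate (mV/kHz, predictor). The regression direction follows the
#' units of the reported error measures: the standard error of the estimate
#' (SEE) and the leave-one-out RMSE are both in cm^2, which is only
#' meaningful with area as the response.
#'
#' SEE is `sqrt(RSS / (n - 2))`. The leave-one-out RMSE refits the model with
#' each point held out in turn (see [loocv_rmse()]); it is reported whenever
#' `n_used >= 4`. Exclusions are manual and explicit — supply `exclude` with
#' subject ids, mirroring anatomy-based judgment rather than an automatic
#' rule; [flag_outliers()] offers an advisory flag.
#'
#' @param m_loss Loss changing rates, mV/kHz.
#' @param vf_area Visceral-fat areas, cm^2.
#' @param subject_id Optional ids aligned with the data (needed for
#'   `exclude`).
#' @param exclude Character vector of subject ids to drop before fitting.
#' @param level Optional level label carried into the result.
#' @return Object of class `calibration_fit`: `slope` (cm^2 per mV/kHz),
#'   `intercept` (cm^2), `r2`, `p_value`, `see` (cm^2), `loocv_rmse` (cm^2),
#'   `n_used`, `excluded_ids`, plus the training range and the underlying
#'   `lm` fit.
#' @export
fit_calibration <- function(m_loss, vf_area, subject_id = NULL,
                            exclude = NULL, level = NA_character_) {
  stopifnot(is.numeric(m_loss), is.numeric(vf_area),
            length(m_loss) == length(vf_area))
  if (is.null(subject_id)) {
    subject_id <- as.character(seq_along(m_loss))
  }
  subject_id <- as.character(subject_id)
  if (length(subject_id) != length(m_loss)) {
    stop("subject_id length mismatch", call. = FALSE)
  }
  exclude <- as.character(exclude %||% character())
  unknown <- setdiff(exclude, subject_id)
  if (length(unknown)) {
    stop("exclude lists unknown subject id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- !(subject_id %in% exclude)
  x <- m_loss[keep]
  y <- vf_area[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 points after exclusions", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("degenerate design: loss changing rate is constant", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  rss <- sum(stats::residuals(fit)^2)
  r2 <- if (stats::sd(y) == 0) 0 else pearson_r2(x, y)
  out <- list(
    level = level,
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r2 = r2,
    p_value = as.numeric(pearson_pvalue(min(r2, 1), n)),
    see = sqrt(rss / (n - 2)),
    loocv_rmse = if (n >= 4L) loocv_rmse(x, y) else NA_real_,
    n_used = n,
    excluded_ids = exclude,
    x_range = range(x),
    x_mean = mean(x),
    y_mean = mean(y),
    model = fit
  )
  class(out) <- "calibration_fit"
  out
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("Calibration of VF area on loss changing rate",
      if (!is.na(x$level)) sprintf("(level %s)", x$level) else "", "\n")
  cat(sprintf("  VF[cm^2] = %.1f + %.1f * m_loss[mV/kHz]\n",
              x$intercept, x$slope))
  cat(sprintf("  R^2 = %.2f, p = %.4g, SEE = %.1f cm^2, LOOCV = %.1f cm^2, n = %d\n",
              x$r2, x$p_value, x$see, x$loocv_rmse, x$n_used))
  if (length(x$excluded_ids)) {
    cat("  excluded:", paste(x$excluded_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Leave-one-out cross-validated RMSE of the calibration line
#'
#' Each point is predicted from a straight line refit on the remaining
#' `n - 1` points; the root mean squared prediction error is returned. The
#' refit-per-fold construction is used deliberately (the hat-matrix identity
#' is an independent check, not the implementation).
#'
#' @param m_loss Predictor values, mV/kHz.
#' @param vf_area Response values, cm^2.
#' @return Root mean squared leave-one-out prediction error, cm^2.
#' @export
loocv_rmse <- function(m_loss, vf_area) {
  stopifnot(is.numeric(m_loss), is.numeric(vf_area),
            length(m_loss) == length(vf_area))
  n <- length(m_loss)
  if (n < 4L) stop("leave-one-out needs at least 4 points", call. = FALSE)
  err <- vapply(seq_len(n), function(i) {
    x <- m_loss[-i]
    y <- vf_area[-i]
    if (stats::sd(x) == 0) {
      stop("degenerate leave-one-out design when holding out index ", i,
           call. = FALSE)
    }
    fit <- stats::lm(y ~ x)
    unname(stats::predict(fit, data.frame(x = m_loss[i]))) - vf_area[i]
  }, numeric(1))
  sqrt(mean(err^2))
}

#' Correlation table of the loss rate against fat areas and anthropometrics
#'
#' For each abdominal level, correlates the per-subject loss changing rate
#' with visceral-fat area (VF), subcutaneous-fat area (SF), the VF/SF and
#' SF/VF ratios, BMI and waist circumference (WC), reporting R^2 with a
#' two-sided p-value per cell. This mirrors the study's two results tables.
#' No multiple-testing adjustment is applied, matching the original analysis;
#' downstream reports note this.
#'
#' Subjects with a zero denominator in a ratio are dropped from that column
#' with a warning. Cells with degenerate variance yield `NA` with a note.
#'
#' @param loss_rates Data frame with `subject_id`, `level`, `m_loss`.
#' @param fat_areas Data frame with `subject_id`, `level`, `vf_area_cm2`,
#'   `sf_area_cm2`.
#' @param subjects Data frame with `subject_id`, `bmi`, `wc_cm`.
#' @param pivot `"long"` (default) for one row per level x covariate, or
#'   `"wide"` for one row per level with `r2_*`/`p_*` columns.
#' @return Data frame. Long form has columns `level`, `covariate`, `r2`,
#'   `p_value`, `n_used`, `note`.
#' @export
correlation_table <- function(loss_rates, fat_areas, subjects,
                              pivot = c("long", "wide")) {
  pivot <- match.arg(pivot)
  for (nm in c("subject_id", "level", "m_loss")) {
    if (!nm %in% names(loss_rates)) {
      stop("loss_rates lacks column ", nm, call. = FALSE)
    }
  }
  d <- merge(loss_rates[c("subject_id", "level", "m_loss")],
             fat_areas[c("subject_id", "level", "vf_area_cm2", "sf_area_cm2")],
             by = c("subject_id", "level"))
  d <- merge(d, subjects[c("subject_id", "bmi", "wc_cm")], by = "subject_id")
  if (!nrow(d)) stop("no subjects align across the three inputs", call. = FALSE)
  check_level(d$level)

  covariates <- c("VF", "SF", "VF/SF", "SF/VF", "BMI", "WC")
  # navel+5 first to match the published table ordering (cranial to caudal)
  levels_ord <- rev(bela_levels())
  rows <- list()
  for (lv in levels_ord) {
    dl <- d[d$level == lv, , drop = FALSE]
    for (cv in covariates) {
      val <- switch(cv,
        "VF" = dl$vf_area_cm2,
        "SF" = dl$sf_area_cm2,
        "VF/SF" = ifelse(dl$sf_area_cm2 > 0, dl$vf_area_cm2 / dl$sf_area_cm2, NA),
        "SF/VF" = ifelse(dl$vf_area_cm2 > 0, dl$sf_area_cm2 / dl$vf_area_cm2, NA),
        "BMI" = dl$bmi,
        "WC" = dl$wc_cm)
      drop_n <- sum(is.na(val))
      if (drop_n > 0) {
        warning(sprintf("%s at %s: dropped %d subject(s) with zero ratio denominator",
                        cv, lv, drop_n), call. = FALSE)
      }
      ok <- !is.na(val)
      x <- dl$m_loss[ok]
      y <- val[ok]
      cell <- tryCatch(
        list(r2 = pearson_r2(x, y),
             p = as.numeric(pearson_pvalue(min(pearson_r2(x, y), 1), length(x))),
             note = NA_character_),
        error = function(e) list(r2 = NA_real_, p = NA_real_,
                                 note = conditionMessage(e)))
      rows[[length(rows) + 1L]] <- data.frame(
        level = lv, covariate = cv, r2 = cell$r2, p_value = cell$p,
        n_used = length(x), note = cell$note, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (pivot == "long") return(tab)
  wide <- data.frame(level = levels_ord, stringsAsFactors = FALSE)
  for (cv in covariates) {
    key <- gsub("/", "_over_", tolower(cv))
    sub <- tab[tab$covariate == cv, ]
    wide[[paste0("r2_", key)]] <- sub$r2[match(levels_ord, sub$level)]
    wide[[paste0("p_", key)]] <- sub$p_value[match(levels_ord, sub$level)]
  }
  wide
}

#' Predict visceral-fat area from a calibration fit
#'
#' Applies the calibration line and attaches the half-width of the standard
#' OLS prediction interval at the requested confidence level. Predictions
#' more than 1.5x beyond the span of the training loss rates are flagged as
#' extrapolations.
#'
#' @param fit A [fit_calibration()] result.
#' @param m_loss New loss changing rate(s), mV/kHz.
#' @param level Confidence level of the prediction interval.
#' @return Data frame with `m_loss`, `vf_pred` (cm^2), `half_width` (cm^2),
#'   `extrapolated`.
#' @export
predict_vf <- function(fit, m_loss, level = 0.95) {
  stopifnot(inherits(fit, "calibration_fit"), is.numeric(m_loss))
  pr <- stats::predict(fit$model, data.frame(x = m_loss),
                       interval = "prediction", level = level)
  span <- diff(fit$x_range)
  lo <- fit$x_range[1] - 0.5 * span  # 1.5x training span, centred
  hi <- fit$x_range[2] + 0.5 * span
  extrap <- m_loss < lo | m_loss > hi
  if (any(extrap)) {
    warning("prediction(s) beyond 1.5x the training range of m_loss",
            call. = FALSE)
  }
  data.frame(m_loss = m_loss,
             vf_pred = pr[, "fit"],
             half_width = (pr[, "upr"] - pr[, "lwr"]) / 2,
             extrapolated = extrap)
}

#' Advisory outlier flags for a calibration data set
#'
#' Flags points whose externally studentized residual exceeds a threshold
#' (default 2.5) in the area-on-rate regression. Flags are advisory only:
#' exclusion stays an explicit user decision via the `exclude` argument of
#' [fit_calibration()], matching the study's anatomy-based judgment for its
#' single excluded volunteer.
#'
#' @param m_loss,vf_area Calibration data.
#' @param subject_id Optional ids; defaults to positional indices.
#' @param threshold Absolute studentized-residual cutoff.
#' @return Character vector of flagged subject ids (possibly empty).
#' @export
flag_outliers <- function(m_loss, vf_area, subject_id = NULL, threshold = 2.5) {
  stopifnot(length(m_loss) == length(vf_area), threshold > 0)
  n <- length(m_loss)
  if (n < 5L) stop("outlier flagging needs at least 5 points", call. = FALSE)
  if (is.null(subject_id)) subject_id <- as.character(seq_len(n))
  fit <- stats::lm(vf_area ~ m_loss)
  e <- stats::residuals(fit)
  scale <- max(stats::sd(vf_area), .Machine$double.eps)
  if (sqrt(sum(e^2) / (n - 2)) < 1e-8 * scale) {
    return(character(0))  # numerically exact fit: nothing to flag
  }
  rs <- stats::rstudent(fit)
  # a deleted fit can be exact while the held-out residual is material:
  # that point is wild by construction, not undefined
  rs[!is.finite(rs)] <- ifelse(abs(e[!is.finite(rs)]) > 1e-8 * scale, Inf, 0)
  as.character(subject_id[abs(rs) > threshold])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
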