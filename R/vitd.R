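# Serum 25OHD transformations: natural-log scale, two deseasonalization
# procedures (regression residuals vs a seasonal polynomial fitted in
# controls), and categorical codings (clinical thresholds, quintiles).

.check_serum <- function(serum) {
  need <- c("participant_id", "vitd_25ohd", "draw_date")
  miss <- setdiff(need, names(serum))
  if (length(miss))
    stop("serum table lacks columns: ", paste(miss, collapse = ", "))
  if (any(serum$vitd_25ohd <= 0)) stop("25OHD values must be positive")
  invisible(serum)
}

# April-September indicator from a draw date
draw_season <- function(draw_date) {
  m <- as.POSIXlt(as.Date(draw_date))$mon + 1L
  ifelse(is_summer_month(m), "AprSep", "OctMar")
}

#' Deseasonalize 25OHD by regression residuals
#'
#' Ordinary least squares of log-25OHD on a season-of-draw indicator
#' (April-September vs October-March) and BMI; the deseasonalized value is
#' the residual plus the grand mean of log-25OHD, i.e. it stays on the
#' natural-log nmol/L scale so downstream odds ratios are per log-unit.
#' Residuals are exactly orthogonal to both the season indicator and BMI
#' (OLS normal equations).
#'
#' @param serum data frame with \code{participant_id}, \code{vitd_25ohd}
#'   (nmol/L), \code{draw_date}, and \code{bmi_at_draw}; a \code{season}
#'   column ("AprSep"/"OctMar") is derived from \code{draw_date} when absent.
#' @return data frame: \code{participant_id}, \code{log_vitd},
#'   \code{deseasonalized_log} (log nmol/L), \code{deseasonalized_nmol}
#'   (back-transformed), \code{method = "residual"}.
#' @export
deseasonalize_residual <- function(serum) {
  .check_serum(serum)
  if (nrow(serum) < 3L) stop("need at least 3 serum records")
  if (is.null(serum$bmi_at_draw)) stop("serum table lacks bmi_at_draw")
  season <- serum$season %||% draw_season(serum$draw_date)
  s_ind <- as.numeric(season == "AprSep")
  if (length(unique(s_ind)) < 2L)
    stop("both draw seasons must be represented: season effect unidentifiable")
  logv <- log(serum$vitd_25ohd)
  X <- cbind(1, s_ind, as.numeric(serum$bmi_at_draw))
  fit <- lm.fit(X, logv)
  des <- residuals(fit) + mean(logv)
  data.frame(participant_id = as.character(serum$participant_id),
             log_vitd = logv,
             deseasonalized_log = des,
             deseasonalized_nmol = exp(des),
             method = "residual",
             stringsAsFactors = FALSE)
}

#' Deseasonalize 25OHD by a seasonal polynomial fitted in controls
#'
#' Fits a polynomial in the day of year (rescaled to [0, 1]) to the control
#' log-25OHD values only, and subtracts the fitted seasonal deviation
#' (fitted value minus its control mean) from every record, cases included.
#' Perturbing case values therefore never changes the seasonal curve.
#'
#' @inheritParams deseasonalize_residual
#' @param control_ids participant ids forming the control reference; the fit
#'   uses these records only.
#' @param degree polynomial degree.  The default 3 is the smallest degree
#'   that tracks an annual harmonic well regardless of where its peak falls
#'   in the calendar year; a quadratic leaves a substantial fraction of the
#'   seasonal amplitude when the peak is away from mid-year.
#' @return as \code{\link{deseasonalize_residual}}, with
#'   \code{method = "polynomial"}.
#' @export
deseasonalize_polynomial <- function(serum, control_ids, degree = 3L) {
  .check_serum(serum)
  id <- as.character(serum$participant_id)
  is_ctrl <- id %in% as.character(control_ids)
  if (sum(is_ctrl) < degree + 2L)
    stop(sprintf("need at least %d control records for degree %d",
                 degree + 2L, degree))
  logv <- log(serum$vitd_25ohd)
  lt <- as.POSIXlt(as.Date(serum$draw_date))
  doy <- (lt$yday) / 365
  P <- outer(doy, seq_len(degree), `^`)
  colnames(P) <- paste0("doy", seq_len(degree))
  fit <- lm.fit(cbind(1, P[is_ctrl, , drop = FALSE]), logv[is_ctrl])
  beta <- coef(fit)
  beta[is.na(beta)] <- 0
  fitted_all <- drop(cbind(1, P) %*% beta)
  seasonal_dev <- fitted_all - mean(fitted_all[is_ctrl])
  des <- logv - seasonal_dev
  data.frame(participant_id = id,
             log_vitd = logv,
             deseasonalized_log = des,
             deseasonalized_nmol = exp(des),
             method = "polynomial",
             stringsAsFactors = FALSE)
}

#' Clinical threshold categories for 25OHD
#'
#' Three-bin coding by default: \code{"<50.0"}, \code{"50.0-75.0"},
#' \code{">75.0"} nmol/L, with both 50.0 and 75.0 falling in the middle bin.
#' With \code{include_30 = TRUE} the deficiency cut-point at 30 nmol/L is
#' added (\code{"<30.0"}, \code{"30.0-50.0"}, \code{"50.0-75.0"},
#' \code{">75.0"}; 30.0 falls in \code{"30.0-50.0"}).
#'
#' @param value 25OHD in nmol/L (vectorised), all positive.
#' @param include_30 add the 30 nmol/L cut-point.
#' @return factor of category labels, every positive value in exactly one.
#' @export
categorize_thresholds <- function(value, include_30 = FALSE) {
  if (any(value <= 0)) stop("25OHD values must be positive")
  if (include_30) {
    labs <- c("<30.0", "30.0-50.0", "50.0-75.0", ">75.0")
    out <- ifelse(value < 30, labs[1L],
           ifelse(value < 50, labs[2L],
           ifelse(value <= 75, labs[3L], labs[4L])))
  } else {
    labs <- c("<50.0", "50.0-75.0", ">75.0")
    out <- ifelse(value < 50, labs[1L],
           ifelse(value <= 75, labs[2L], labs[3L]))
  }
  factor(out, levels = labs)
}

#' Quintile categories against a control reference distribution
#'
#' Cut-points are the 20/40/60/80 inclusive linear-interpolation percentiles
#' (\code{quantile} type 7) of the control reference values; a value equal
#' to a cut-point is assigned to the lower quintile.  When reference sizes
#' are multiples of 5 each control quintile holds 20\% of the reference.
#'
#' @param values values to classify.
#' @param reference control values of the same group (>= 5 distinct values).
#' @return integer quintile 1..5 per element of \code{values}.
#' @export
quintile_categories <- function(values, reference) {
  if (length(unique(reference)) < 5L)
    stop("need at least 5 distinct reference values")
  cuts <- quantile(reference, c(.2, .4, .6, .8), names = FALSE, type = 7)
  if (anyDuplicated(cuts)) {
    warning("tied quantile cut-points collapsed; quintiles are unbalanced")
    cuts <- unique(cuts)
  }
  findInterval(values, cuts, left.open = TRUE) + 1L
}
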