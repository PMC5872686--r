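# Study-level analyses: the mutually adjusted unconditional logistic model
# (lifetime UVR + deseasonalized log-25OHD in the same model), the matched
# threshold-category conditional model, and the determinants-of-25OHD
# linear model.

.covariate_design <- function(p) {
  cbind(age = age_years(p$birth_date, p$index_date),
        sex_female = as.numeric(p$sex == "F"),
        smoking_ever = as.numeric(p$smoking == "ever"),
        ancestry_afr = p$ancestry_afr,
        ancestry_amr = p$ancestry_amr,   # European fraction dropped
        hla_carrier = as.numeric(p$hla_carrier))
}

#' Mutually adjusted odds ratios for lifetime UVR and 25OHD
#'
#' One unconditional logistic model per race/ethnicity group containing both
#' cumulative lifetime UVR dose (per 1000 kJ/m^2) and deseasonalized
#' log-25OHD, adjusted for age, sex, smoking, genetic ancestry (two of the
#' three fractions) and HLA-DRB1*15:01 carriage.  The two exposure odds
#' ratios are estimated simultaneously from the same fit.
#'
#' @param participants participant table (see \code{\link{generate_cohort}}).
#' @param exposures output of \code{\link{exposure_summary}}.
#' @param adjusted_vitd output of a deseasonalization function, providing
#'   \code{deseasonalized_log}.
#' @param group group label to analyse; must be present.
#' @param ... passed to \code{\link{fit_logistic}}.
#' @return data frame of \code{\link{wald_or}} records for the two
#'   exposures, with a \code{group} column and the fit attached as
#'   \code{attr(, "fit")}.
#' @export
mutual_adjustment_analysis <- function(participants, exposures, adjusted_vitd,
                                       group, ...) {
  p <- participants[participants$group == group, , drop = FALSE]
  if (nrow(p) == 0L) stop(sprintf("group '%s' absent from cohort", group))
  uvr <- exposures$cumulative_uvr_1000[match(p$id, exposures$participant_id)]
  lvd <- adjusted_vitd$deseasonalized_log[
    match(p$id, adjusted_vitd$participant_id)]
  if (any(is.na(uvr)) || any(is.na(lvd)))
    stop("exposures/adjusted 25OHD not aligned with the participant table")
  x <- cbind("(Intercept)" = 1, uvr_1000 = uvr, log_vitd = lvd,
             .covariate_design(p))
  y <- as.numeric(p$role == "case")
  fit <- fit_logistic(x, y, ...)
  out <- rbind(
    wald_or(fit, "uvr_1000", note = "per 1000 kJ/m^2 lifetime UVR"),
    wald_or(fit, "log_vitd", note = "per log-unit deseasonalized 25OHD"))
  out <- cbind(group = group, out, stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  out
}

#' Matched odds ratios by 25OHD threshold category
#'
#' Conditional logistic regression over matched sets with indicator terms
#' for the upper 25OHD categories (reference \code{"<50.0"}), adjusted for
#' age, smoking and BMI.  Categories empty in the analysed data are dropped
#' from the contrast list with a warning.
#'
#' @param participants participant table with \code{matched_set_id}.
#' @param category factor from \code{\link{categorize_thresholds}}, aligned
#'   with \code{participants} rows.
#' @param group group label to analyse.
#' @param ... passed to \code{\link{fit_conditional_logistic}}.
#' @return data frame of \code{\link{wald_or}} records, one per non-reference
#'   category, with the fit attached as \code{attr(, "fit")}.
#' @export
threshold_or_analysis <- function(participants, category, group, ...) {
  sel <- participants$group == group
  p <- participants[sel, , drop = FALSE]
  if (nrow(p) == 0L) stop(sprintf("group '%s' absent from cohort", group))
  cat_g <- droplevels(factor(category[sel]))
  lv <- levels(cat_g)
  full <- if (is.factor(category)) levels(category)
          else sort(unique(as.character(category)))
  if (length(missing <- setdiff(full, lv)))
    warning(sprintf("category %s empty in group %s: contrast omitted",
                    paste(missing, collapse = ", "), group))
  if (length(lv) < 2L) stop("threshold categories have no variation")
  ref <- lv[1L]
  ind <- sapply(lv[-1L], function(l) as.numeric(cat_g == l))
  colnames(ind) <- paste0("vitd_", lv[-1L])
  x <- cbind(ind,
             age = age_years(p$birth_date, p$index_date),
             smoking_ever = as.numeric(p$smoking == "ever"),
             bmi = p$bmi)
  y <- as.numeric(p$role == "case")
  fit <- fit_conditional_logistic(x, y, p$matched_set_id, ...)
  out <- do.call(rbind, lapply(colnames(ind), function(tm)
    wald_or(fit, tm, note = sprintf("vs %s nmol/L (matched)", ref))))
  out <- cbind(group = group, out, stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  out
}

#' Determinants of serum 25OHD
#'
#' Multivariable linear regression of log-25OHD on recent summer and winter
#' UVR dose (the 12 months before the index date), age, sex, BMI and season
#' of blood draw.
#'
#' @param serum serum table (\code{vitd_25ohd}, \code{bmi_at_draw},
#'   \code{season} or \code{draw_date}).
#' @param recent_exposures output of \code{\link{exposure_summary}}
#'   (\code{recent_summer_uvr}, \code{recent_winter_uvr}).
#' @param participants participant table (age, sex), aligned by id.
#' @return data frame of coefficients with \code{estimate}, \code{se},
#'   \code{t}, \code{p_value}; the \code{lm} fit attached as
#'   \code{attr(, "fit")}.
#' @export
determinants_of_vitd <- function(serum, recent_exposures, participants) {
  i <- match(serum$participant_id, recent_exposures$participant_id)
  j <- match(serum$participant_id, participants$id)
  if (any(is.na(i)) || any(is.na(j)))
    stop("serum, exposures and participants are not aligned on participant id")
  season <- serum$season %||% draw_season(serum$draw_date)
  if (length(unique(season)) < 2L)
    stop("both draw seasons must be present")
  d <- data.frame(
    log_vitd = log(serum$vitd_25ohd),
    summer_uvr = recent_exposures$recent_summer_uvr[i],
    winter_uvr = recent_exposures$recent_winter_uvr[i],
    age = age_years(participants$birth_date[j], participants$index_date[j]),
    sex_female = as.numeric(participants$sex[j] == "F"),
    bmi = serum$bmi_at_draw,
    season_apr_sep = as.numeric(season == "AprSep"))
  fit <- lm(log_vitd ~ summer_uvr + winter_uvr + age + sex_female + bmi +
              season_apr_sep, data = d)
  if (any(is.na(coef(fit))))
    stop("rank-deficient design; collinear columns: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  sm <- summary(fit)$coefficients
  out <- data.frame(term = rownames(sm), estimate = sm[, 1L], se = sm[, 2L],
                    t = sm[, 3L], p_value = sm[, 4L],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  out
}
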