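# Dose reconstruction: for every calendar month overlapping the integration
# window, ambient UVR at the latitude of residence in force that month is
# multiplied by the leisure-time outdoors weight in force and by the fraction
# of the month's days inside the window.  The residence/outdoors interval "in
# force" is the one containing the 15th of the month (clamped into the
# participant's own table coverage so the attribution never depends on the
# window itself -- this keeps dose additivity over window splits exact).

# residences/outdoors are passed internally as lists of aligned vectors with
# half-open [start, end) integer-day intervals, sorted by start.
.prep_intervals <- function(df, who, id) {
  if (is.null(df) || nrow(df) == 0L) return(NULL)
  start <- as_day(df$start_date)
  end <- as_day(df$end_date)
  if (any(start >= end))
    stop(sprintf("%s intervals for participant %s must have start < end", who, id))
  o <- order(start)
  out <- list(start = start[o], end = end[o])
  if (any(out$start[-1L] < out$end[-length(out$end)]))
    stop(sprintf("%s intervals for participant %s overlap", who, id))
  if (!is.null(df$latitude)) out$latitude <- as.numeric(df$latitude)[o]
  if (!is.null(df$weight_apr_sep)) {
    out$w_summer <- as.numeric(df$weight_apr_sep)[o]
    out$w_winter <- as.numeric(df$weight_oct_mar %||% df$weight_apr_sep)[o]
  } else if (!is.null(df$weight)) {
    out$w_summer <- out$w_winter <- as.numeric(df$weight)[o]
  }
  out
}

# locate the interval containing each attribution day; error on a gap
.interval_index <- function(day, iv, who, id) {
  day <- pmin(pmax(day, iv$start[1L]), iv$end[length(iv$end)] - 1L)
  j <- findInterval(day, iv$start)
  bad <- j == 0L | day >= iv$end[pmax(j, 1L)]
  if (any(bad)) {
    b <- which(bad)[1L]
    stop(sprintf(
      "%s history of participant %s has a coverage gap around %s",
      who, id, as.Date(day[b], origin = "1970-01-01")))
  }
  j
}

# per-month doses over the half-open window [win_start, win_end), integer days
.dose_months <- function(win_start, win_end, res, out, clim, id = "?") {
  if (win_end <= win_start)
    return(list(moy = integer(0), dose = numeric(0)))
  mt <- month_table()
  i0 <- findInterval(win_start, mt)
  i1 <- findInterval(win_end - 1L, mt)
  if (i0 < 1L || i1 >= length(mt))
    stop("date outside the supported 1880-2059 calendar range")
  idx <- i0:i1
  firsts <- mt[idx]
  nexts <- mt[idx + 1L]
  frac <- (pmin(nexts, win_end) - pmax(firsts, win_start)) / (nexts - firsts)
  moy <- month_of_index(idx)
  attr_day <- firsts + 14L                      # the 15th of each month
  jr <- .interval_index(attr_day, res, "residence", id)
  amb <- .ambient_interp(clim, res$latitude[jr], moy)
  if (is.null(out)) {
    w <- 1
  } else {
    jo <- .interval_index(attr_day, out, "outdoors", id)
    w <- out$w_winter[jo]
    s <- is_summer_month(moy)
    w[s] <- out$w_summer[jo[s]]
  }
  list(moy = moy, dose = amb * w * frac)
}

#' Cumulative lifetime UVR dose
#'
#' Sums behaviour-weighted monthly ambient UVR at the participant's places of
#' residence from a starting age (default 6 years) to the index date.
#' Boundary months partially inside the window are prorated by day count.
#'
#' @param residences data frame with \code{latitude}, \code{start_date},
#'   \code{end_date} (intervals treated as half-open \code{[start, end)});
#'   they must cover the integration window without gaps.
#' @param outdoors data frame of leisure-time outdoors weights in [0, 1]
#'   with \code{start_date}, \code{end_date} and either a single
#'   \code{weight} column or \code{weight_apr_sep} / \code{weight_oct_mar};
#'   \code{NULL} means unweighted ambient dose (weight 1).
#' @param clim a \code{\link{uvr_climatology}}.
#' @param birth_date,index_date participant dates; the window runs from
#'   \code{birth_date + start_age_years} (exact days / 365.25) to
#'   \code{index_date}.
#' @param start_age_years starting age of the accumulation window, years.
#' @param id participant label used in error messages.
#' @return cumulative dose, kJ/m^2.
#' @export
cumulative_uvr <- function(residences, outdoors, clim, birth_date, index_date,
                           start_age_years = 6, id = "?") {
  res <- .prep_intervals(residences, "residence", id)
  if (is.null(res)) stop(sprintf("participant %s has no residence history", id))
  out <- .prep_intervals(outdoors, "outdoors", id)
  ws <- as_day(birth_date) + as.integer(floor(start_age_years * DAYS_PER_YEAR))
  we <- as_day(index_date)
  sum(.dose_months(ws, we, res, out, clim, id)$dose)
}

#' Recent (12-month) seasonal UVR dose
#'
#' Dose over the 12 calendar months before the index date, split into the
#' April-September ("summer") and October-March ("winter") months of that
#' window.  The two components sum to the total dose of the window.
#'
#' @inheritParams cumulative_uvr
#' @return named numeric vector \code{c(summer =, winter =)}, kJ/m^2.
#' @export
recent_uvr <- function(residences, outdoors, clim, index_date, id = "?") {
  res <- .prep_intervals(residences, "residence", id)
  if (is.null(res)) stop(sprintf("participant %s has no residence history", id))
  out <- .prep_intervals(outdoors, "outdoors", id)
  we <- as_day(index_date)
  ws <- shift_months_day(we, -12L)
  dm <- .dose_months(ws, we, res, out, clim, id)
  s <- is_summer_month(dm$moy)
  c(summer = sum(dm$dose[s]), winter = sum(dm$dose[!s]))
}

#' Per-participant exposure summaries for a cohort
#'
#' Computes cumulative lifetime dose (reported in 1000 kJ/m^2, the scale used
#' by the association models) and the recent summer/winter doses for every
#' participant.
#'
#' @param participants data frame with \code{id}, \code{birth_date},
#'   \code{index_date}.
#' @param residences,outdoors interval tables with a \code{participant_id}
#'   column (see \code{\link{cumulative_uvr}}); \code{outdoors = NULL} for
#'   unweighted ambient dose.
#' @param clim a \code{\link{uvr_climatology}}.
#' @param start_age_years start of the lifetime accumulation window.
#' @param weighted if \code{FALSE}, ignore the outdoors table and use
#'   ambient dose unweighted.
#' @return data frame: \code{participant_id}, \code{cumulative_uvr_1000},
#'   \code{recent_summer_uvr}, \code{recent_winter_uvr}.
#' @export
exposure_summary <- function(participants, residences, outdoors, clim,
                             start_age_years = 6, weighted = TRUE) {
  ids <- as.character(participants$id)
  birth <- as_day(participants$birth_date)
  index <- as_day(participants$index_date)
  rs <- list(start = as_day(residences$start_date),
             end = as_day(residences$end_date),
             latitude = as.numeric(residences$latitude))
  res_idx <- split(seq_len(nrow(residences)),
                   as.character(residences$participant_id))
  od <- out_idx <- NULL
  if (!is.null(outdoors) && weighted && nrow(outdoors) > 0L) {
    wS <- outdoors$weight_apr_sep %||% outdoors$weight
    wW <- outdoors$weight_oct_mar %||% wS
    od <- list(start = as_day(outdoors$start_date),
               end = as_day(outdoors$end_date),
               w_summer = as.numeric(wS), w_winter = as.numeric(wW))
    out_idx <- split(seq_len(nrow(outdoors)),
                     as.character(outdoors$participant_id))
  }
  pick <- function(src, i, o, fields) {
    iv <- lapply(src[fields], function(v) v[i][o])
    iv
  }
  cum <- summer <- winter <- numeric(length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    ri <- res_idx[[id]]
    if (is.null(ri)) stop(sprintf("participant %s has no residence history", id))
    o <- order(rs$start[ri])
    res <- pick(rs, ri, o, c("start", "end", "latitude"))
    out <- NULL
    if (!is.null(od)) {
      oi <- out_idx[[id]]
      if (!is.null(oi)) {
        oo <- order(od$start[oi])
        out <- pick(od, oi, oo, c("start", "end", "w_summer", "w_winter"))
      }
    }
    ws <- birth[k] + as.integer(floor(start_age_years * DAYS_PER_YEAR))
    cum[k] <- sum(.dose_months(ws, index[k], res, out, clim, id)$dose)
    r0 <- shift_months_day(index[k], -12L)
    dm <- .dose_months(r0, index[k], res, out, clim, id)
    sm <- is_summer_month(dm$moy)
    summer[k] <- sum(dm$dose[sm])
    winter[k] <- sum(dm$dose[!sm])
  }
  data.frame(participant_id = ids,
             cumulative_uvr_1000 = cum / 1000,
             recent_summer_uvr = summer,
             recent_winter_uvr = winter,
             stringsAsFactors = FALSE)
}
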