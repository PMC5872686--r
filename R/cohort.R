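# Synthetic matched case-control cohort generator.  An oversized eligible
# pool (pool_factor x the requested cases) is simulated per race/ethnicity
# group; case status is drawn from a logistic model in lifetime UVR dose and
# latent log-25OHD (group-centred, so the scalar baseline_logit fixes the
# case fraction in every group); 1:1 controls are then matched on group, sex,
# facility and a birth-date caliper, inheriting the case's index date.

.per_group <- function(x, groups, what) {
  n <- length(groups)
  if (length(x) == 1L) x <- rep(x, n)
  if (!is.null(names(x))) {
    miss <- setdiff(groups, names(x))
    if (length(miss)) stop(sprintf("%s lacks values for: %s", what,
                                   paste(miss, collapse = ", ")))
    x <- x[groups]
  }
  if (length(x) != n) stop(sprintf("%s must have one value per group", what))
  setNames(as.numeric(x), groups)
}

#' Simulation configuration for a matched case-control cohort
#'
#' Defaults describe a three-group (black / hispanic / white) 1:1 matched
#' design: group-specific true odds ratios for lifetime UVR dose (per 1000
#' kJ/m^2) and latent log-25OHD (per log-unit), group-specific UVR-to-25OHD
#' conversion efficiencies, BMI and draw-season effects on log-25OHD, and
#' Southern-California-like residence histories (latitudes 32-42 N, 1-4
#' residence intervals).  Per-group arguments accept a scalar (recycled), a
#' vector in group order, or a named vector.
#'
#' @param groups race/ethnicity labels.
#' @param n_cases_per_group cases to generate per group (>= 1).
#' @param true_or_uvr true OR per 1000 kJ/m^2 lifetime UVR, per group (> 0).
#' @param true_or_logvd true OR per unit latent log-25OHD, per group (> 0).
#' @param uvr_to_vd_efficiency slope of log-25OHD on recent 12-month UVR
#'   dose (per kJ/m^2), per group.
#' @param vd_mu group intercept of log-25OHD (log nmol/L).
#' @param vd_sigma SD of additive Gaussian noise on log-25OHD.
#' @param season_effect additive log-25OHD shift for April-September draws.
#' @param bmi_effect slope of log-25OHD on BMI (kg/m^2), typically negative.
#' @param baseline_logit intercept of the (group-centred) case model;
#'   \code{qlogis(0.3)} gives a ~30\% case rate in the eligible pool.
#' @param or_hla,or_smoking nuisance ORs for HLA-DRB1*15:01 carriage and
#'   ever-smoking in the case model.
#' @param matching_caliper_years maximum birth-date difference (> 0).
#' @param pool_factor eligible-pool size as a multiple of requested cases.
#' @param n_facilities number of home-facility labels (matching key only).
#' @param female_frac,age_mean,age_sd,bmi_mean,bmi_sd,smoking_frac,hla_freq
#'   per-group covariate distributions.
#' @param supplement_p named probabilities \code{c(case =, control =)} of
#'   vitamin D supplement use (a post-onset behaviour).
#' @param ancestry_alpha list (one numeric triple per group) of Dirichlet
#'   parameters for the African/European/Amerindian ancestry fractions.
#' @param latitude_range residence latitude band, degrees north.
#' @param index_range recruitment window for index dates (coercible to Date).
#' @param outdoors_beta Beta(a, b) parameters of leisure-outdoors weights.
#' @param climatology a \code{\link{uvr_climatology}}; default
#'   \code{\link{default_climatology}()}.
#' @param recruit_on_demand when the simulated pool holds no eligible
#'   control for a case, recruit one by conditional simulation (mirroring
#'   per-case recruitment from a large membership roster).  With
#'   \code{FALSE}, pool exhaustion is a hard error naming the case.
#' @param seed integer random seed.
#' @return a validated list of class \code{sim_config}.
#' @export
sim_config <- function(groups = c("black", "hispanic", "white"),
                       n_cases_per_group = 200L,
                       true_or_uvr = c(black = 0.53, hispanic = 0.66,
                                       white = 0.68),
                       true_or_logvd = c(black = 1, hispanic = 1,
                                         white = 0.52),
                       uvr_to_vd_efficiency = c(black = 0.0013,
                                                hispanic = 0.0022,
                                                white = 0.0025),
                       vd_mu = c(black = 4.07, hispanic = 4.21, white = 4.40),
                       vd_sigma = 0.3,
                       season_effect = 0.10,
                       bmi_effect = -0.01,
                       baseline_logit = qlogis(0.3),
                       or_hla = 2.5, or_smoking = 1.3,
                       matching_caliper_years = 2,
                       pool_factor = 5,
                       n_facilities = 10L,
                       female_frac = c(black = 0.79, hispanic = 0.73,
                                       white = 0.65),
                       age_mean = c(black = 38.5, hispanic = 32.5,
                                    white = 39.8),
                       age_sd = c(black = 13, hispanic = 11, white = 12),
                       bmi_mean = c(black = 31.0, hispanic = 29.8,
                                    white = 28.5),
                       bmi_sd = 7,
                       smoking_frac = c(black = 0.25, hispanic = 0.21,
                                        white = 0.40),
                       hla_freq = c(black = 0.12, hispanic = 0.12,
                                    white = 0.20),
                       supplement_p = c(case = 0.22, control = 0.04),
                       ancestry_alpha = list(black = c(12, 5, 1),
                                             hispanic = c(1, 8, 7),
                                             white = c(0.5, 18, 1)),
                       latitude_range = c(32, 42),
                       index_range = c("2011-12-01", "2015-05-31"),
                       outdoors_beta = c(2, 48),
                       climatology = NULL,
                       recruit_on_demand = TRUE,
                       seed = 1L) {
  groups <- as.character(groups)
  if (anyDuplicated(groups)) stop("group labels must be unique")
  cfg <- list(
    groups = groups,
    n_cases_per_group = round(.per_group(n_cases_per_group, groups,
                                         "n_cases_per_group")),
    true_or_uvr = .per_group(true_or_uvr, groups, "true_or_uvr"),
    true_or_logvd = .per_group(true_or_logvd, groups, "true_or_logvd"),
    uvr_to_vd_efficiency = .per_group(uvr_to_vd_efficiency, groups,
                                      "uvr_to_vd_efficiency"),
    vd_mu = .per_group(vd_mu, groups, "vd_mu"),
    vd_sigma = vd_sigma,
    season_effect = season_effect,
    bmi_effect = bmi_effect,
    baseline_logit = baseline_logit,
    or_hla = or_hla, or_smoking = or_smoking,
    matching_caliper_years = matching_caliper_years,
    pool_factor = pool_factor,
    n_facilities = as.integer(n_facilities),
    female_frac = .per_group(female_frac, groups, "female_frac"),
    age_mean = .per_group(age_mean, groups, "age_mean"),
    age_sd = .per_group(age_sd, groups, "age_sd"),
    bmi_mean = .per_group(bmi_mean, groups, "bmi_mean"),
    bmi_sd = bmi_sd,
    smoking_frac = .per_group(smoking_frac, groups, "smoking_frac"),
    hla_freq = .per_group(hla_freq, groups, "hla_freq"),
    supplement_p = supplement_p,
    ancestry_alpha = if (is.null(names(ancestry_alpha)))
      setNames(ancestry_alpha[seq_along(groups)], groups)
      else ancestry_alpha[groups],
    latitude_range = as.numeric(latitude_range),
    index_range = as.Date(index_range),
    outdoors_beta = as.numeric(outdoors_beta),
    climatology = climatology,
    recruit_on_demand = isTRUE(recruit_on_demand),
    seed = as.integer(seed))
  with(cfg, {
    if (any(n_cases_per_group < 1)) stop("n_cases_per_group must be >= 1")
    if (any(c(true_or_uvr, true_or_logvd, or_hla, or_smoking) <= 0))
      stop("all odds ratios must be > 0")
    if (matching_caliper_years <= 0) stop("matching caliper must be > 0")
    if (pool_factor < 2) stop("pool_factor must be >= 2")
    if (vd_sigma < 0) stop("vd_sigma must be >= 0")
    if (any(female_frac < 0 | female_frac > 1)) stop("female_frac in [0,1]")
    if (diff(as.numeric(index_range)) <= 0) stop("empty index date range")
  })
  structure(cfg, class = "sim_config")
}

# sorted interval break dates strictly inside (lo, hi), integer days
.rand_cuts <- function(k, lo, hi) {
  if (k == 0L) return(integer(0))
  sort(lo + ceiling(runif(k) * (hi - lo - 1)))
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

# simulate n subjects of a group; `fixed` may pin sex, facility, index and
# birth (integer days) for conditional recruitment of matched controls
.sim_subjects <- function(config, g, ids, clim, horizon, fixed = list()) {
  N <- length(ids)
  sex <- fixed$sex %||% ifelse(runif(N) < config$female_frac[[g]], "F", "M")
  facility <- fixed$facility %||%
    sprintf("site%02d", sample.int(config$n_facilities, N, replace = TRUE))
  d0 <- as_day(config$index_range[1L])
  d1 <- as_day(config$index_range[2L])
  index <- fixed$index %||% (d0 + floor(runif(N) * (d1 - d0 + 1L)))
  if (is.null(fixed$birth)) {
    age <- pmin(pmax(rnorm(N, config$age_mean[[g]], config$age_sd[[g]]),
                     18), 70)
    birth <- index - as.integer(round(age * DAYS_PER_YEAR))
  } else {
    birth <- fixed$birth
  }
  bmi <- pmin(pmax(rnorm(N, config$bmi_mean[[g]], config$bmi_sd), 16), 55)
  smoking <- ifelse(runif(N) < config$smoking_frac[[g]], "ever", "never")
  hla <- runif(N) < config$hla_freq[[g]]
  anc <- .rdirichlet(N, config$ancestry_alpha[[g]])

  # residence history: 1-4 intervals from birth to the global horizon
  n_res <- sample.int(4L, N, replace = TRUE, prob = c(.4, .3, .2, .1))
  res_rows <- vector("list", N)
  for (k in seq_len(N)) {
    cuts <- .rand_cuts(n_res[k] - 1L, birth[k], index[k])
    res_rows[[k]] <- list(start = c(birth[k], cuts), end = c(cuts, horizon),
                          lat = runif(n_res[k], config$latitude_range[1L],
                                      config$latitude_range[2L]))
  }
  residences <- data.frame(
    participant_id = rep(ids, n_res),
    latitude = unlist(lapply(res_rows, `[[`, "lat")),
    start_date = as.Date(unlist(lapply(res_rows, `[[`, "start")),
                         origin = "1970-01-01"),
    end_date = as.Date(unlist(lapply(res_rows, `[[`, "end")),
                       origin = "1970-01-01"),
    stringsAsFactors = FALSE)

  # leisure-outdoors behaviour: 1-3 intervals, summer/winter weights
  n_out <- sample.int(3L, N, replace = TRUE, prob = c(.5, .3, .2))
  out_rows <- vector("list", N)
  for (k in seq_len(N)) {
    cuts <- .rand_cuts(n_out[k] - 1L, birth[k], index[k])
    # summer and winter leisure behaviour drawn separately
    w <- rbeta(n_out[k], config$outdoors_beta[1L], config$outdoors_beta[2L])
    w2 <- rbeta(n_out[k], config$outdoors_beta[1L], config$outdoors_beta[2L])
    out_rows[[k]] <- list(start = c(birth[k], cuts), end = c(cuts, horizon),
                          w = w, w2 = w2)
  }
  w_all <- unlist(lapply(out_rows, `[[`, "w"))
  w2_all <- unlist(lapply(out_rows, `[[`, "w2"))
  outdoors <- data.frame(
    participant_id = rep(ids, n_out),
    start_date = as.Date(unlist(lapply(out_rows, `[[`, "start")),
                         origin = "1970-01-01"),
    end_date = as.Date(unlist(lapply(out_rows, `[[`, "end")),
                       origin = "1970-01-01"),
    weight_apr_sep = pmin(1, w_all * 1.25),
    weight_oct_mar = w2_all * 0.75,
    stringsAsFactors = FALSE)

  expo <- exposure_summary(
    data.frame(id = ids, birth_date = as.Date(birth, origin = "1970-01-01"),
               index_date = as.Date(index, origin = "1970-01-01"),
               stringsAsFactors = FALSE),
    residences, outdoors, clim)
  recent <- expo$recent_summer_uvr + expo$recent_winter_uvr
  cum1000 <- expo$cumulative_uvr_1000

  # serum draw shortly after the index date
  draw <- index + pmin(365L, pmax(0L, as.integer(round(rnorm(N, 120, 60)))))
  season <- ifelse(is_summer_month(as.POSIXlt(
    as.Date(draw, origin = "1970-01-01"))$mon + 1L), "AprSep", "OctMar")
  latent_logvd <- config$vd_mu[[g]] +
    config$uvr_to_vd_efficiency[[g]] * recent +
    config$bmi_effect * bmi +
    rnorm(N, 0, config$vd_sigma)
  measured_logvd <- latent_logvd + config$season_effect * (season == "AprSep")

  list(id = ids, sex = sex, facility = facility, index = index,
       birth = birth, bmi = bmi, smoking = smoking, hla = hla, anc = anc,
       residences = residences, outdoors = outdoors, draw = draw,
       season = season, latent = latent_logvd, measured = measured_logvd,
       cum1000 = cum1000)
}

# case probability under the group-centred logistic generating model;
# `centers` are the eligible-pool means the centring refers to
.case_prob <- function(config, g, s, centers) {
  lp <- config$baseline_logit +
    log(config$true_or_uvr[[g]]) * (s$cum1000 - centers$cum) +
    log(config$true_or_logvd[[g]]) * (s$latent - centers$latent) +
    log(config$or_hla) * (s$hla - centers$hla) +
    log(config$or_smoking) * ((s$smoking == "ever") - centers$smk)
  plogis(lp)
}

.sub_subjects <- function(s, i) {
  out <- lapply(s[c("id", "sex", "facility", "index", "birth", "bmi",
                    "smoking", "hla", "draw", "season", "latent",
                    "measured", "cum1000")], `[`, i)
  out$anc <- s$anc[i, , drop = FALSE]
  out$residences <- s$residences[s$residences$participant_id %in% out$id, ,
                                 drop = FALSE]
  out$outdoors <- s$outdoors[s$outdoors$participant_id %in% out$id, ,
                             drop = FALSE]
  out
}

.cat_subjects <- function(a, b) {
  out <- Map(c, a[c("id", "sex", "facility", "index", "birth", "bmi",
                    "smoking", "hla", "draw", "season", "latent",
                    "measured", "cum1000")],
             b[c("id", "sex", "facility", "index", "birth", "bmi",
                 "smoking", "hla", "draw", "season", "latent",
                 "measured", "cum1000")])
  out$anc <- rbind(a$anc, b$anc)
  out$residences <- rbind(a$residences, b$residences)
  out$outdoors <- rbind(a$outdoors, b$outdoors)
  out
}

#' Generate a synthetic matched case-control cohort
#'
#' See \code{\link{sim_config}} for the generative model.  An oversized
#' eligible pool is simulated per group; case status is drawn from the
#' logistic model in lifetime UVR dose and latent log-25OHD; controls are
#' 1:1 matched on sex, facility and the birth-date caliper and inherit the
#' case's index date.  The returned bundle holds the four cohort tables the
#' analysis stages consume: participants, residence intervals (covering
#' birth to beyond every index date), leisure-outdoors weight intervals, and
#' one serum 25OHD draw per participant.  The result is a pure function of
#' the config (seed included).
#'
#' @param config a \code{\link{sim_config}}.
#' @return object of class \code{cohort_bundle}: list with
#'   \code{participants}, \code{residences}, \code{outdoors}, \code{serum},
#'   and the generating \code{config}.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  clim <- config$climatology %||% default_climatology()
  horizon <- as_day(config$index_range[2L]) + 500L
  parts <- res <- outs <- sera <- list()
  for (g in config$groups) {
    n_cases <- config$n_cases_per_group[[g]]
    N <- ceiling(config$pool_factor * n_cases)
    s <- .sim_subjects(config, g, sprintf("%s-%05d", g, seq_len(N)),
                       clim, horizon)
    centers <- list(cum = mean(s$cum1000), latent = mean(s$latent),
                    hla = mean(s$hla), smk = mean(s$smoking == "ever"))
    is_case <- rbinom(N, 1L, .case_prob(config, g, s, centers)) == 1L
    case_idx <- which(is_case)
    if (length(case_idx) < n_cases)
      stop(sprintf(
        "eligible pool produced only %d cases in group %s (%d requested); increase pool_factor",
        length(case_idx), g, n_cases))
    case_idx <- case_idx[seq_len(n_cases)]
    ctrl_pool <- which(!is_case)

    pool_df <- data.frame(
      row = seq_len(N), id = s$id, sex = s$sex, facility = s$facility,
      birth = s$birth, stringsAsFactors = FALSE)
    m <- .match_all(pool_df[case_idx, ], pool_df[ctrl_pool, ],
                    config$matching_caliper_years, g,
                    on_fail = if (config$recruit_on_demand) "na" else "stop")

    subj <- .sub_subjects(s, c(case_idx, m$control_row[!is.na(m$control_row)]))
    case_ids <- s$id[case_idx]
    ctrl_ids <- character(n_cases)
    ctrl_ids[!is.na(m$control_row)] <- s$id[m$control_row[!is.na(m$control_row)]]

    # recruit eligible controls on demand for cases the pool could not serve
    cal <- as.integer(floor(config$matching_caliper_years * DAYS_PER_YEAR))
    n_rec <- 0L
    for (i in which(is.na(m$control_row))) {
      ci <- case_idx[i]
      accepted <- FALSE
      for (try in 1:100) {
        n_rec <- n_rec + 1L
        rid <- sprintf("%s-r%04d", g, n_rec)
        lo <- max(s$birth[ci] - cal,
                  s$index[ci] - as.integer(70 * DAYS_PER_YEAR))
        hi <- min(s$birth[ci] + cal,
                  s$index[ci] - as.integer(18 * DAYS_PER_YEAR))
        rb <- lo + floor(runif(1) * (hi - lo + 1L))
        r <- .sim_subjects(config, g, rid, clim, horizon,
                           fixed = list(sex = s$sex[ci],
                                        facility = s$facility[ci],
                                        index = s$index[ci], birth = rb))
        if (rbinom(1L, 1L, .case_prob(config, g, r, centers)) == 0L) {
          subj <- .cat_subjects(subj, r)
          ctrl_ids[i] <- rid
          accepted <- TRUE
          break
        }
      }
      if (!accepted)
        stop(sprintf("could not recruit an eligible control for case %s",
                     s$id[ci]))
    }

    ord <- match(c(case_ids, ctrl_ids), subj$id)
    role <- rep(c("case", "control"), c(n_cases, n_cases))
    idx_final <- rep(s$index[case_idx], 2L)   # controls inherit case index
    supp_p <- ifelse(role == "case", config$supplement_p[["case"]],
                     config$supplement_p[["control"]])
    participants <- data.frame(
      id = subj$id[ord], group = g, role = role, sex = subj$sex[ord],
      birth_date = as.Date(subj$birth[ord], origin = "1970-01-01"),
      index_date = as.Date(idx_final, origin = "1970-01-01"),
      onset_date = as.Date(ifelse(role == "case", subj$index[ord], NA),
                           origin = "1970-01-01"),
      smoking = subj$smoking[ord], bmi = subj$bmi[ord],
      supplement_user = runif(2L * n_cases) < supp_p,
      hla_carrier = subj$hla[ord],
      ancestry_afr = subj$anc[ord, 1L], ancestry_eur = subj$anc[ord, 2L],
      ancestry_amr = subj$anc[ord, 3L],
      facility = subj$facility[ord],
      matched_set_id = rep(case_ids, 2L),
      stringsAsFactors = FALSE)
    serum <- data.frame(
      participant_id = subj$id[ord],
      vitd_25ohd = exp(subj$measured[ord]),
      draw_date = as.Date(subj$draw[ord], origin = "1970-01-01"),
      season = subj$season[ord],
      bmi_at_draw = subj$bmi[ord],
      stringsAsFactors = FALSE)

    keep_r <- subj$residences$participant_id %in% participants$id
    keep_o <- subj$outdoors$participant_id %in% participants$id
    parts[[g]] <- participants
    res[[g]] <- subj$residences[keep_r, , drop = FALSE]
    outs[[g]] <- subj$outdoors[keep_o, , drop = FALSE]
    sera[[g]] <- serum
  }
  bundle <- list(participants = do.call(rbind, c(parts, make.row.names = FALSE)),
                 residences = do.call(rbind, c(res, make.row.names = FALSE)),
                 outdoors = do.call(rbind, c(outs, make.row.names = FALSE)),
                 serum = do.call(rbind, c(sera, make.row.names = FALSE)),
                 config = config)
  class(bundle) <- "cohort_bundle"
  bundle
}

#' @export
print.cohort_bundle <- function(x, ...) {
  tab <- table(x$participants$group, x$participants$role)
  cat("matched case-control cohort bundle\n")
  print(tab)
  invisible(x)
}

# greedy nearest-birth-date matching without replacement, within exact
# sex x facility cells; on_fail = "na" marks unmatched cases for recruitment
.match_all <- function(cases, pool, caliper_years, group,
                       on_fail = c("stop", "na")) {
  on_fail <- match.arg(on_fail)
  cal <- caliper_years * DAYS_PER_YEAR
  cells <- split(seq_len(nrow(pool)), paste(pool$sex, pool$facility))
  used <- logical(nrow(pool))
  out <- rep(NA_integer_, nrow(cases))
  for (i in seq_len(nrow(cases))) {
    cand <- cells[[paste(cases$sex[i], cases$facility[i])]]
    cand <- cand[!used[cand]]
    gap <- abs(pool$birth[cand] - cases$birth[i])
    cand <- cand[gap <= cal]
    if (length(cand) == 0L) {
      if (on_fail == "stop")
        stop(sprintf(
          paste0("control pool exhausted for case %s (group %s): no unused ",
                 "control with sex=%s, facility=%s and birth date within ",
                 "%g years"),
          cases$id[i], group, cases$sex[i], cases$facility[i], caliper_years))
      next
    }
    gap <- abs(pool$birth[cand] - cases$birth[i])
    pick <- cand[order(gap, pool$id[cand])[1L]]
    used[pick] <- TRUE
    out[i] <- pool$row[pick]
  }
  data.frame(case_row = cases$row, control_row = out)
}

#' Match a single control to a case
#'
#' Selects from \code{pool} a control with the same \code{group}, \code{sex}
#' and \code{facility} as the case and a birth date within
#' \code{caliper_years}; the nearest birth date wins (ties broken by id).
#' The matched control inherits the case's index date and is removed from
#' the returned pool (sampling without replacement).
#'
#' @param case one-row data frame with \code{id}, \code{group}, \code{sex},
#'   \code{facility}, \code{birth_date}, \code{index_date}.
#' @param pool data frame of candidate controls with the same columns.
#' @param caliper_years maximum absolute birth-date difference, years.
#' @return list with \code{control} (one-row data frame, index date set to
#'   the case's) and \code{pool} (the remaining candidates).
#' @export
match_control <- function(case, pool, caliper_years = 2) {
  if (nrow(pool) == 0L) stop("control pool is empty")
  gap_ok <- abs(as_day(pool$birth_date) - as_day(case$birth_date)) <=
    caliper_years * DAYS_PER_YEAR
  ok <- pool$group == case$group & pool$sex == case$sex &
    pool$facility == case$facility & gap_ok
  if (!any(ok)) {
    stop(sprintf(
      paste0("no eligible control for case %s: need group=%s, sex=%s, ",
             "facility=%s, birth date within %g years of %s"),
      case$id, case$group, case$sex, case$facility, caliper_years,
      as.character(as.Date(case$birth_date))))
  }
  cand <- which(ok)
  gap <- abs(as_day(pool$birth_date[cand]) - as_day(case$birth_date))
  pick <- cand[order(gap, pool$id[cand])[1L]]
  control <- pool[pick, , drop = FALSE]
  control$index_date <- case$index_date
  list(control = control, pool = pool[-pick, , drop = FALSE])
}

#' Audit the matching invariants of a cohort
#'
#' Checks every matched set for exact agreement on group, sex and facility,
#' a birth-date gap within the caliper, and a shared index date.
#'
#' @param participants participant table of a \code{cohort_bundle}.
#' @param caliper_years the caliper the cohort was matched under.
#' @return \code{TRUE} invisibly; stops with the first violated set.
#' @export
audit_matching <- function(participants, caliper_years = 2) {
  sets <- split(participants, participants$matched_set_id)
  for (s in sets) {
    if (sum(s$role == "case") != 1L)
      stop(sprintf("set %s does not have exactly one case",
                   s$matched_set_id[1L]))
    ca <- s[s$role == "case", ]
    co <- s[s$role == "control", , drop = FALSE]
    if (nrow(co) == 0L) next
    if (any(co$group != ca$group) || any(co$sex != ca$sex) ||
        any(co$facility != ca$facility))
      stop(sprintf("set %s violates exact matching", ca$id))
    if (any(abs(as_day(co$birth_date) - as_day(ca$birth_date)) >
            caliper_years * DAYS_PER_YEAR))
      stop(sprintf("set %s violates the birth-date caliper", ca$id))
    if (any(as_day(co$index_date) != as_day(ca$index_date)))
      stop(sprintf("set %s controls do not carry the case index date", ca$id))
  }
  invisible(TRUE)
}

# write.csv prints 15 significant digits, which loses the last ulp of a
# double; format numerics with 17 so written cohorts round-trip exactly
.write_csv_lossless <- function(d, path) {
  for (j in seq_along(d))
    if (is.double(d[[j]]) && !inherits(d[[j]], "Date"))
      d[[j]] <- sub("^NA$", NA, sprintf("%.17g", d[[j]]))
  write.csv(d, path, row.names = FALSE)
}

#' Write / read cohort tables as delimited text
#'
#' Four CSV files (participants, residences, outdoors, serum) with ISO-8601
#' dates plus a \code{config.json} sidecar recording the simulation
#' configuration and seed.
#'
#' @param bundle a \code{cohort_bundle}.
#' @param dir output directory (created if needed).
#' @return \code{read_cohort}: a \code{cohort_bundle} (config restored from
#'   the sidecar when present).
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("participants", "residences", "outdoors", "serum"))
    .write_csv_lossless(bundle[[nm]], file.path(dir, paste0(nm, ".csv")))
  cfg <- bundle$config
  if (!is.null(cfg)) {
    cfg$climatology <- NULL
    cfg$index_range <- as.character(cfg$index_range)
    jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' @param dir directory holding the four cohort CSV files.
#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  rd <- function(nm) {
    d <- read.csv(file.path(dir, paste0(nm, ".csv")), stringsAsFactors = FALSE)
    for (cl in intersect(c("birth_date", "index_date", "onset_date",
                           "start_date", "end_date", "draw_date"), names(d)))
      d[[cl]] <- as.Date(d[[cl]])
    d
  }
  bundle <- list(participants = rd("participants"),
                 residences = rd("residences"),
                 outdoors = rd("outdoors"),
                 serum = rd("serum"),
                 config = NULL)
  cfg_path <- file.path(dir, "config.json")
  if (file.exists(cfg_path))
    bundle$config <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  class(bundle) <- "cohort_bundle"
  bundle
}
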