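# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's internal code paths.

# naive per-month dose summation: walks every calendar month between two
# dates with seq.Date, decides proration by counting days, looks up the
# residence/outdoors interval containing the 15th (clamped to the table's
# own coverage) and interpolates the climatology by hand
oracle_dose <- function(residences, outdoors, clim, win_start, win_end) {
  win_start <- as.Date(win_start)
  win_end <- as.Date(win_end)
  if (win_end <= win_start) return(data.frame(month = integer(0),
                                              dose = numeric(0)))
  first_of <- function(d) as.Date(format(d, "%Y-%m-01"))
  months <- seq(first_of(win_start), first_of(win_end - 1), by = "month")
  res <- residences[order(as.Date(residences$start_date)), ]
  out <- if (!is.null(outdoors))
    outdoors[order(as.Date(outdoors$start_date)), ]
  lookup <- function(tab, day) {
    day <- min(max(day, as.Date(min(tab$start_date))),
               as.Date(max(tab$end_date)) - 1)
    hit <- which(as.Date(tab$start_date) <= day & day < as.Date(tab$end_date))
    stopifnot(length(hit) == 1L)
    hit
  }
  interp <- function(lat, m) {
    lats <- clim$latitudes
    lat <- min(max(lat, min(lats)), max(lats))
    if (lat %in% lats) return(clim$values[match(lat, lats), m])
    i <- max(which(lats <= lat))
    v0 <- clim$values[i, m]; v1 <- clim$values[i + 1, m]
    v0 + (lat - lats[i]) / (lats[i + 1] - lats[i]) * (v1 - v0)
  }
  dose <- moy <- numeric(length(months))
  for (k in seq_along(months)) {
    m0 <- months[k]
    m1 <- seq(m0, by = "month", length.out = 2)[2]
    ndays <- as.integer(m1 - m0)
    nin <- as.integer(min(m1, win_end) - max(m0, win_start))
    mid <- m0 + 14
    i <- lookup(res, mid)
    m <- as.integer(format(m0, "%m"))
    amb <- interp(res$latitude[i], m)
    w <- 1
    if (!is.null(out)) {
      j <- lookup(out, mid)
      ws <- if (!is.null(out$weight_apr_sep)) out$weight_apr_sep[j]
            else out$weight[j]
      ww <- if (!is.null(out$weight_oct_mar)) out$weight_oct_mar[j]
            else ws
      w <- if (m >= 4 && m <= 9) ws else ww
    }
    moy[k] <- m
    dose[k] <- amb * w * nin / ndays
  }
  data.frame(month = moy, dose = dose)
}

# random residence/outdoors configuration over a fixed calendar span
random_history <- function(n_res = sample(1:3, 1), n_out = sample(1:3, 1),
                           t0 = as.Date("2000-03-10"),
                           t1 = as.Date("2010-11-20")) {
  span <- as.integer(t1 - t0)
  mk <- function(k) sort(sample(seq_len(span - 1), k - 1))
  rc <- mk(n_res)
  oc <- mk(n_out)
  list(
    residences = data.frame(
      latitude = runif(n_res, 26, 48),
      start_date = t0 + c(0, rc),
      end_date = t0 + c(rc, span)),
    outdoors = data.frame(
      start_date = t0 + c(0, oc),
      end_date = t0 + c(oc, span),
      weight_apr_sep = runif(n_out),
      weight_oct_mar = runif(n_out)))
}

# small sinusoidal climatology used by exposure tests
sin_clim <- function() {
  lats <- seq(25, 50, by = 5)
  vals <- outer(seq_along(lats), 1:12, function(i, m)
    80 - 2 * i + (40 - 3 * i) * cos(2 * pi * (m - 6) / 12))
  uvr_climatology(lats, vals)
}

# 2x2 cross-product (ad/bc) odds-ratio oracle with its logistic data layout
table_2x2_data <- function(a, b, c, d) {
  list(x = cbind("(Intercept)" = 1,
                 expo = c(rep(1, a + c), rep(0, b + d))),
       y = c(rep(1, a), rep(0, c), rep(1, b), rep(0, d)),
       or = (a * d) / (b * c))
}

# full hypergeometric enumeration for the two-sided Fisher exact p
fisher_enum <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  pr <- dhyper(ks, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# tiny single-group cohort config for fast tests
quick_config <- function(n = 80, seed = 1, ...) {
  sim_config(groups = "g", n_cases_per_group = n,
             true_or_uvr = 1, true_or_logvd = 1,
             uvr_to_vd_efficiency = 0.002, vd_mu = 4.2,
             female_frac = 0.7, age_mean = 38, age_sd = 12,
             bmi_mean = 29, smoking_frac = 0.3, hla_freq = 0.15,
             ancestry_alpha = list(c(2, 10, 2)), seed = seed, ...)
}
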