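flat_clim <- function(v) uvr_climatology(c(30, 40),
                                         rbind(rep(v, 12), rep(v, 12)))

test_that("whole-month windows and zero weights give closed-form doses", {
  res <- data.frame(latitude = 34, start_date = as.Date("1980-01-01"),
                    end_date = as.Date("2030-01-01"))
  # exactly 120 whole months at ambient 1, weight 1
  expect_equal(cumulative_uvr(res, NULL, flat_clim(1),
                              as.Date("1990-01-01"), as.Date("2002-01-01"),
                              start_age_years = 6), 72)
  expect_equal(cumulative_uvr(res, NULL, flat_clim(1),
                              as.Date("1986-01-01"), as.Date("2002-01-01"),
                              start_age_years = 6), 120)
  # zero outdoors weight kills the dose entirely
  out0 <- data.frame(start_date = as.Date("1980-01-01"),
                     end_date = as.Date("2030-01-01"), weight = 0)
  expect_equal(cumulative_uvr(res, out0, flat_clim(1),
                              as.Date("1986-01-01"), as.Date("2002-01-01")), 0)
})

test_that("recent dose splits into summer and winter halves", {
  res <- data.frame(latitude = 34, start_date = as.Date("1980-01-01"),
                    end_date = as.Date("2030-01-01"))
  r <- recent_uvr(res, NULL, flat_clim(2), as.Date("2005-03-01"))
  expect_equal(unname(r), c(12, 12))
  # summer-only behaviour: weight 1 Apr-Sep, 0 Oct-Mar
  outS <- data.frame(start_date = as.Date("1980-01-01"),
                     end_date = as.Date("2030-01-01"),
                     weight_apr_sep = 1, weight_oct_mar = 0)
  r2 <- recent_uvr(res, outS, flat_clim(1), as.Date("2005-03-01"))
  expect_equal(unname(r2), c(6, 0))
})

test_that("dose matches the independent per-month oracle on random histories", {
  set.seed(401)
  clim <- sin_clim()
  for (rep in 1:50) {
    h <- random_history()
    ws <- as.Date("2000-03-10") + sample(0:200, 1)
    we <- as.Date("2010-11-20") - sample(0:200, 1)
    want <- sum(oracle_dose(h$residences, h$outdoors, clim, ws, we)$dose)
    birth <- ws - as.integer(floor(6 * 365.25))
    got <- cumulative_uvr(h$residences, h$outdoors, clim, birth, we)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("recent summer/winter split matches the oracle and its partition", {
  set.seed(402)
  clim <- sin_clim()
  for (rep in 1:10) {
    h <- random_history()
    idx <- as.Date("2004-06-01") + sample(0:1000, 1)
    r <- recent_uvr(h$residences, h$outdoors, clim, idx)
    om <- oracle_dose(h$residences, h$outdoors, clim,
                      seq(idx, by = "-12 months", length.out = 2)[2], idx)
    expect_equal(unname(r["summer"]), sum(om$dose[om$month %in% 4:9]),
                 tolerance = 1e-9)
    expect_equal(unname(r["winter"]), sum(om$dose[!om$month %in% 4:9]),
                 tolerance = 1e-9)
    expect_equal(sum(r), sum(om$dose), tolerance = 1e-9)
  }
})

test_that("dose is additive over window splits and homogeneous in weights", {
  set.seed(403)
  clim <- sin_clim()
  h <- random_history(n_res = 3, n_out = 2)
  t0 <- as.Date("2001-02-07")
  t2 <- as.Date("2009-08-23")
  dose_win <- function(a, b, out = h$outdoors) {
    sum(helioepi:::.dose_months(as.integer(a), as.integer(b),
        helioepi:::.prep_intervals(h$residences, "residence", "x"),
        helioepi:::.prep_intervals(out, "outdoors", "x"), clim)$dose)
  }
  whole <- dose_win(t0, t2)
  for (cut in as.integer(t2 - t0) * c(.1, .37, .5, .83)) {
    t1 <- t0 + as.integer(cut)
    expect_equal(dose_win(t0, t1) + dose_win(t1, t2), whole,
                 tolerance = 1e-12)
  }
  # homogeneity: scaling all weights by c scales the dose by c exactly
  out3 <- h$outdoors
  out3$weight_apr_sep <- out3$weight_apr_sep * 0.37
  out3$weight_oct_mar <- out3$weight_oct_mar * 0.37
  expect_equal(dose_win(t0, t2, out3), whole * 0.37, tolerance = 1e-12)
})

test_that("moving poleward under a latitude-monotone climatology never raises dose", {
  clim <- sin_clim()   # values strictly decrease with latitude
  mk_res <- function(lat) data.frame(latitude = lat,
                                     start_date = as.Date("1980-01-01"),
                                     end_date = as.Date("2030-01-01"))
  lats <- seq(26, 48, by = 2)
  doses <- vapply(lats, function(l)
    cumulative_uvr(mk_res(l), NULL, clim, as.Date("1985-04-03"),
                   as.Date("2010-09-17")), numeric(1))
  expect_true(all(diff(doses) < 0))
})

test_that("residence coverage gaps are reported with the participant id", {
  res <- data.frame(latitude = 34,
                    start_date = as.Date(c("1980-01-01", "1995-06-01")),
                    end_date = as.Date(c("1994-01-01", "2030-01-01")))
  expect_error(
    cumulative_uvr(res, NULL, flat_clim(1), as.Date("1980-01-01"),
                   as.Date("2005-01-01"), id = "P77"),
    "P77.*gap|gap.*P77")
})

test_that("exposure_summary reproduces the single-participant functions", {
  set.seed(404)
  h <- random_history()
  clim <- sin_clim()
  parts <- data.frame(id = "A", birth_date = as.Date("1994-03-10"),
                      index_date = as.Date("2010-01-15"))
  h$residences$participant_id <- "A"
  h$outdoors$participant_id <- "A"
  es <- exposure_summary(parts, h$residences, h$outdoors, clim)
  expect_equal(es$cumulative_uvr_1000 * 1000,
               cumulative_uvr(h$residences, h$outdoors, clim,
                              parts$birth_date, parts$index_date))
  r <- recent_uvr(h$residences, h$outdoors, clim, parts$index_date)
  expect_equal(es$recent_summer_uvr, unname(r["summer"]))
  expect_equal(es$recent_winter_uvr, unname(r["winter"]))
  # unweighted flag ignores the outdoors table
  es_u <- exposure_summary(parts, h$residences, h$outdoors, clim,
                           weighted = FALSE)
  expect_equal(es_u$cumulative_uvr_1000 * 1000,
               cumulative_uvr(h$residences, NULL, clim,
                              parts$birth_date, parts$index_date))
})
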