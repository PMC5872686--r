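test_that("percent reproduces published table cells and validates input", {
  expect_identical(percent(92, 116), 79.3)
  expect_identical(percent(62, 247), 25.1)
  expect_identical(percent(214, 267), 80.1)
  expect_identical(percent(0, 50), 0)
  expect_error(percent(5, 0), "total")
  expect_error(percent(-1, 10), "count")
  expect_error(percent(11, 10), "count")
})

test_that("Welch t from summaries matches its closed form and behaves", {
  same <- two_sample_t(10, 2, 30, 10, 2, 30)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # age row comparison from rounded published summaries
  tt <- two_sample_t(38.4, 12.8, 116, 38.5, 13.0, 131)
  expect_lt(abs(abs(tt$t) - 0.061), 0.001)
  expect_equal(tt$p, 0.95, tolerance = 2e-3)
  # doubling both sample sizes at fixed summaries strictly increases |t|
  t2 <- two_sample_t(38.4, 12.8, 232, 38.5, 13.0, 262)
  expect_gt(abs(t2$t), abs(tt$t))
  # pooled variant equals t.test's student flavour on raw data
  set.seed(81)
  x <- rnorm(25, 1); y <- rnorm(35, 0.4)
  ours <- two_sample_t(mean(x), sd(x), 25, mean(y), sd(y), 35, pooled = TRUE)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
})

test_that("chi-square closed form matches observed-vs-expected summation", {
  set.seed(82)
  for (rep in 1:20) {
    tb <- sample(3:80, 4)
    got <- chi_square_2x2(tb[1], tb[2], tb[3], tb[4])
    m <- matrix(tb, 2, byrow = TRUE)
    expd <- outer(rowSums(m), colSums(m)) / sum(m)
    expect_equal(got$statistic, sum((m - expd)^2 / expd), tolerance = 1e-10)
    ref <- suppressWarnings(chisq.test(m, correct = FALSE))
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
  # proportional table carries no signal; swapping rows changes nothing
  expect_equal(chi_square_2x2(10, 20, 30, 60)$statistic, 0)
  expect_equal(chi_square_2x2(10, 20, 30, 60)$p, 1)
  expect_equal(chi_square_2x2(7, 31, 22, 13)$statistic,
               chi_square_2x2(22, 13, 7, 31)$statistic)
})

test_that("Fisher exact p equals full hypergeometric enumeration", {
  cases <- list(c(1, 9, 9, 1), c(3, 7, 5, 5), c(12, 2, 3, 11),
                c(0, 10, 5, 5), c(8, 8, 8, 8))
  for (tb in cases)
    expect_equal(fisher_exact(tb[1], tb[2], tb[3], tb[4]),
                 fisher_enum(tb[1], tb[2], tb[3], tb[4]), tolerance = 1e-10)
  # zero margin: only one table is possible
  expect_identical(fisher_exact(0, 0, 5, 5), 1)
  expect_identical(fisher_exact(3, 0, 7, 0), 1)
  # enumeration probabilities are a proper distribution
  pr <- dhyper(0:10, 10, 10, 10)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  # asymptotic agreement with chi-square on large null-ish tables
  expect_lt(abs(fisher_exact(50, 50, 50, 50) -
                  chi_square_2x2(50, 50, 50, 50)$p), 0.02)
  expect_lt(abs(fisher_exact(520, 480, 490, 510) -
                  chi_square_2x2(520, 480, 490, 510)$p), 0.02)
})

test_that("rank-sum test: exact small-sample enumeration and tie handling", {
  ext <- wilcoxon_mann_whitney(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_identical(unname(ext$U), 0)
  expect_equal(ext$p, 1 / 20)   # 1 of choose(6,3) rank assignments
  two <- wilcoxon_mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(two$p, 2 / 20)
  # identical samples sit at the null centre
  same <- wilcoxon_mann_whitney(1:9, 1:9)
  expect_equal(same$U, 9 * 9 / 2)
  expect_equal(same$p, 1)
  # power under a 1-SD shift at n=100 per arm (normal approximation branch)
  set.seed(83)
  rej <- mean(replicate(100, {
    wilcoxon_mann_whitney(rnorm(100, 1), rnorm(100))$p < 0.05
  }))
  expect_gt(rej, 0.9)
})

test_that("table_one summarises every Table-1-style variable per group", {
  b <- generate_cohort(sim_config(n_cases_per_group = 60, seed = 85))
  t1 <- table_one(b$participants, b$serum)
  vars <- c("age_years", "female", "smoking_ever", "bmi", "vitd_supplement",
            "season_apr_sep", "hla_drb1_carrier")
  for (g in c("black", "hispanic", "white"))
    expect_setequal(t1$variable[t1$group == g], vars)
  expect_true(all(t1$test %in% c("welch-t", "chi-square", "fisher", "none")))
  expect_true(all(is.na(t1$p_value) | (t1$p_value >= 0 & t1$p_value <= 1)))
  # a cohort built from published counts reproduces the printed percent cell
  p <- data.frame(
    id = sprintf("w%03d", 1:247), group = "w", role = "case",
    sex = c(rep("F", 164), rep("M", 83)),
    birth_date = as.Date("1975-01-01"), index_date = as.Date("2013-01-01"),
    smoking = "never", bmi = 28, supplement_user = FALSE,
    hla_carrier = FALSE, facility = "site01", matched_set_id = "s")
  p2 <- p
  p2$id <- sprintf("c%03d", 1:247)
  p2$role <- "control"
  pp <- rbind(p, p2)
  ser <- data.frame(participant_id = pp$id, vitd_25ohd = 50,
                    draw_date = as.Date("2013-05-01"), season = "AprSep",
                    bmi_at_draw = 28)
  tt <- table_one(pp, ser)
  expect_identical(tt$cases[tt$variable == "female"], "164 (66.4)")
})

test_that("shuffled case labels leave descriptive tests mostly non-significant", {
  set.seed(86)
  b <- generate_cohort(quick_config(n = 150, seed = 86))
  p <- b$participants
  frac_sig <- replicate(5, {
    p$role <- sample(p$role)
    t1 <- table_one(p, b$serum)
    mean(t1$p_value < 0.05, na.rm = TRUE)
  })
  expect_lt(mean(frac_sig), 0.15)
})
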