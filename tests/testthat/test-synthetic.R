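test_that("noise-free limit reproduces exp(linear predictor) exactly", {
  cfg <- simulation_config(
    n_provinces_per_category = c(low = 2, middle = 2, high = 2),
    date_range = c("2019-06-01", "2020-06-30"),
    true_coefficients = c(`(Intercept)` = log(100)),
    month_effects = rep(0, 11), dow_effects = rep(0, 6),
    sigma2 = 0, rho = 0, G = matrix(0, 2, 2), seed = 1)
  sim <- simulate_panel(cfg, small_schedule(), small_meta())
  expect_equal(sim$panel$index, rep(100, nrow(sim$panel)))
})

test_that("seeding contract: same seed identical, different seeds differ", {
  a <- small_sim(42)
  b <- small_sim(42)
  c <- small_sim(43)
  expect_identical(a$panel$index, b$panel$index)
  expect_identical(a$truth$random_effects, b$truth$random_effects)
  expect_false(identical(a$panel$index, c$panel$index))
})

test_that("simulated Dec 31 jump matches the low-HDI step within MC error", {
  # 100 low-HDI provinces, no seasonal/trend confounders: the mean
  # log-index jump across Dec 30 -> 31 estimates the step ln(1.41)
  # with SE sqrt(2 * sigma2 * (1 - rho)) / 10 ~ 0.018.
  meta <- province_meta(data.frame(
    province = sprintf("P%03d", 1:100), hdi_category = "low"))
  cfg <- simulation_config(
    n_provinces_per_category = c(low = 100, middle = 0, high = 0),
    date_range = c("2019-12-01", "2020-01-20"),
    true_coefficients = c(`(Intercept)` = log(100),
                          step_covid_low = log(1.41)),
    month_effects = rep(0, 11), dow_effects = rep(0, 6),
    sigma2 = 0.04, rho = 0.6, G = matrix(0, 2, 2), seed = 20)
  sched <- exposure_schedule("covid", "2019-12-31")
  sim <- simulate_panel(cfg, sched, meta)
  pre <- sim$panel$index[sim$panel$date == as.Date("2019-12-30")]
  post <- sim$panel$index[sim$panel$date == as.Date("2019-12-31")]
  expect_lt(abs(mean(log(post) - log(pre)) - log(1.41)), 0.06)
})

test_that("AR(1) recovery: long-series lag-1 autocorrelation approaches rho", {
  meta <- province_meta(data.frame(province = "solo", hdi_category = "low"))
  cfg <- simulation_config(
    n_provinces_per_category = c(low = 1, middle = 0, high = 0),
    date_range = c("1900-01-01", "2064-04-01"),  # 60,000 days
    true_coefficients = c(`(Intercept)` = log(100)),
    month_effects = rep(0, 11), dow_effects = rep(0, 6),
    sigma2 = 0.04, rho = 0.6, G = matrix(0, 2, 2), seed = 9)
  sched <- exposure_schedule("late", "2064-01-01")
  sim <- simulate_panel(cfg, sched, meta)
  # before the late step no effect is active, so log(index) - log(100)
  # is exactly the AR(1) residual series
  e <- log(sim$panel$index) - log(100)
  e <- e[sim$panel$date < as.Date("2064-01-01")]
  r1 <- stats::cor(e[-1], e[-length(e)])
  expect_lt(abs(r1 - 0.6), 0.02)
})

test_that("realized random effects match G in moments across many provinces", {
  # 1000 provinces per draw, pooled over three seeds to damp the
  # Monte-Carlo error of the sample covariance well below the 10% band
  meta <- province_meta(data.frame(
    province = sprintf("P%04d", 1:1000), hdi_category = "low"))
  G <- matrix(c(0.25, 1e-5, 1e-5, 4e-8), 2)
  sched <- exposure_schedule("e", "2020-01-02")
  bs <- NULL
  for (seed in 1:3) {
    cfg <- simulation_config(
      n_provinces_per_category = c(low = 1000, middle = 0, high = 0),
      date_range = c("2020-01-01", "2020-01-03"),
      true_coefficients = c(`(Intercept)` = log(100)),
      month_effects = rep(0, 11), dow_effects = rep(0, 6),
      sigma2 = 0.01, rho = 0, G = G, seed = seed)
    sim <- simulate_panel(cfg, sched, meta)
    bs <- rbind(bs, as.matrix(sim$truth$random_effects[, c("b0", "b1")]))
  }
  S <- stats::cov(bs)
  expect_lt(norm(S - G, "F") / norm(G, "F"), 0.10)
})

test_that("integer rounding clamps at 1", {
  cfg <- simulation_config(
    n_provinces_per_category = c(low = 2, middle = 0, high = 0),
    date_range = c("2020-01-01", "2020-03-01"),
    true_coefficients = c(`(Intercept)` = log(0.2)),  # sub-1 baseline
    month_effects = rep(0, 11), dow_effects = rep(0, 6),
    sigma2 = 0.1, rho = 0, G = matrix(0, 2, 2), seed = 2,
    round_to_integer = TRUE)
  sched <- exposure_schedule("e", "2020-02-01")
  meta <- province_meta(data.frame(province = c("a", "b"),
                                   hdi_category = "low"))
  sim <- simulate_panel(cfg, sched, meta)
  expect_true(all(sim$panel$index >= 1))
  expect_true(all(sim$panel$index == round(sim$panel$index)))
})

test_that("published-table truth map has the stated entries", {
  tr <- default_truth_from_table2()
  expect_equal(unname(tr["step_covid_low"]), log(1.41))
  expect_equal(unname(tr["slope_covid1_low"]), log(0.90) / 7)
  expect_equal(unname(tr["step_covid4_middle"]), log(2.67))
  expect_equal(unname(tr["T"]), log(1.10) / 365)
  # complete: pre-trend (3) + 5 steps x 3 + 4 slopes x 3 + baselines (3)
  expect_equal(sum(grepl("^step_", names(tr))), 15L)
  expect_equal(sum(grepl("^slope_", names(tr))), 12L)
})

test_that("default metadata reproduces the published grouping", {
  m <- make_default_metadata()
  expect_equal(nrow(m), 31L)
  expect_equal(unname(table(m$hdi_category)[c("low", "middle", "high")]),
               c(10L, 13L, 8L), ignore_attr = TRUE)
  expect_equal(m$hdi_category[m$province == "Beijing"], "high")
  expect_equal(m$hdi_category[m$province == "Tibet"], "low")
  expect_equal(m$hdi_category[m$province == "Hubei"], "middle")
  # placeholder continuous values strictly separate the categories
  expect_lt(max(m$hdi[m$hdi_category == "low"]),
            min(m$hdi[m$hdi_category == "middle"]))
  expect_lt(max(m$hdi[m$hdi_category == "middle"]),
            min(m$hdi[m$hdi_category == "high"]))
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(rho = 1.2), class = "its_config_error")
  expect_error(simulation_config(sigma2 = -1), class = "its_config_error")
  expect_error(simulation_config(G = matrix(c(1, 2, 2, 1), 2)),
               class = "its_config_error")
  expect_error(simulation_config(date_range = c("2020-01-02", "2020-01-01")),
               class = "its_config_error")
  cfg <- small_config(1)
  cfg$true_coefficients <- c(step_nope_low = 1)
  expect_error(simulate_panel(cfg, small_schedule(), small_meta()),
               class = "its_config_error")
})

test_that("simulation config round-trips through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_provinces_per_category: {low: 2, middle: 2, high: 2}",
    "date_range: [2019-06-01, 2020-06-30]",
    "true_coefficients: {(Intercept): 4.6}",
    "sigma2: 0.02", "rho: 0.4", "seed: 5",
    "G: [[0.01, 0.0], [0.0, 1.0e-9]]"), f)
  cfg <- read_simulation_config(f)
  expect_equal(cfg$rho, 0.4)
  expect_equal(cfg$G[1, 1], 0.01)
  expect_equal(cfg$n_provinces_per_category[["middle"]], 2)
  expect_equal(unname(cfg$true_coefficients["(Intercept)"]), 4.6)
})
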