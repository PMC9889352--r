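test_that("binomial limits match full pmf enumeration and degenerate cases", {
  lim <- binomial_limits(20, 0.25, 0.05)
  exp <- oracle_limits(20, 0.25, 0.05)
  expect_equal(lim$lower, unname(exp["lower"]))
  expect_equal(lim$upper, unname(exp["upper"]))

  z <- binomial_limits(50, 0, 0.05)
  expect_equal(c(z$lower, z$upper), c(0, 0))
  o <- binomial_limits(50, 1, 0.05)
  expect_equal(c(o$lower, o$upper), c(1, 1))

  withr::with_seed(14, {
    cases <- data.frame(n = sample(1:500, 40, replace = TRUE),
                        p0 = runif(40, 0.01, 0.99),
                        alpha = sample(c(0.05, 1e-3, 1e-6, 1e-12), 40,
                                       replace = TRUE))
  })
  for (i in seq_len(nrow(cases))) {
    got <- binomial_limits(cases$n[i], cases$p0[i], cases$alpha[i])
    exp <- oracle_limits(cases$n[i], cases$p0[i], cases$alpha[i])
    expect_equal(got$lower, unname(exp["lower"]),
                 info = paste(cases[i, ], collapse = "/"))
    expect_equal(got$upper, unname(exp["upper"]),
                 info = paste(cases[i, ], collapse = "/"))
  }
})

test_that("limit bands nest across alpha and tighten with volume", {
  p0 <- 0.243
  for (a in c(0.05, 1e-3, 1e-6)) {
    wide <- binomial_limits(300, p0, a / 100)
    narrow <- binomial_limits(300, p0, a)
    expect_lte(wide$lower, narrow$lower)
    expect_gte(wide$upper, narrow$upper)
  }
  l100 <- binomial_limits(100, p0, 0.05)
  l1000 <- binomial_limits(1000, p0, 0.05)
  expect_gte(l1000$lower, l100$lower)
  expect_lte(l1000$upper, l100$upper)
})

test_that("two-sided binomial P matches the closed form and the summation oracle", {
  expect_equal(two_sided_binomial_p(0, 50, 0.5), 2 * 0.5^50)
  expect_gt(two_sided_binomial_p(round(80 * 0.25), 80, 0.25), 0.8)
  withr::with_seed(21, {
    for (i in 1:25) {
      n <- sample(1:200, 1)
      k <- sample(0:n, 1)
      p0 <- runif(1, 0.05, 0.95)
      expect_equal(two_sided_binomial_p(k, n, p0), oracle_two_sided(k, n, p0))
    }
  })
})

test_that("indirect standardization matches hand computation on a two-station toy", {
  # pooled insufficiency: station A 0.10, station B 0.20
  strat <- c(A = 0.10, B = 0.20)
  # provider samples only station B (double the overall rate of A-heavy peers)
  p0 <- 0.12
  obs <- 30; n <- 200
  expected <- 200 * 0.20
  expect_equal(
    normalize_rate(obs, n, station_counts = c(B = 200), stratum_rates = strat,
                   p0 = p0, mode = "indirect"),
    obs / expected * p0)
  # raw mode is the identity on the crude rate
  expect_equal(normalize_rate(obs, n, mode = "raw"), obs / n)
  # station without pooled data is dropped with a warning
  expect_warning(
    normalize_rate(obs, n, station_counts = c(B = 150, Z = 50),
                   stratum_rates = strat, p0 = p0, mode = "indirect"),
    "excluded")
})

test_that("provider mix equal to the corpus mix makes indirect ~ raw", {
  cfg <- synthetic_config(n_records = 4000, seed = 19,
                          distractor_level = "none")
  withr::with_seed(19, truth <- generate_truth(cfg))
  cls <- truth_as_classified(truth)
  rates <- provider_rates(cls, role = "sps", min_n = 250)
  ch_raw <- build_chart(rates, "insufficient", mode = "raw")
  ch_ind <- build_chart(rates, "insufficient", mode = "indirect",
                        classified = cls)
  # random uniform assignment: every provider's mix ~ corpus mix
  expect_equal(ch_ind$points$normalized_rate, ch_raw$points$normalized_rate,
               tolerance = 0.08)
})

test_that("null charts flag no one when all providers sit at the GMR, and flags nest", {
  cls <- dplyr::bind_rows(lapply(1:6, function(i) {
    s <- classified_stub(c(benign = 300, insufficient = 100),
                         sps = paste0("SPS", i))
    s$specimen_id <- paste0(i, "-", s$specimen_id)
    s
  }))
  rates <- provider_rates(cls, role = "sps", min_n = 250)
  ch <- build_chart(rates, "insufficient", mode = "raw")
  expect_equal(unname(ch$outlier_counts), rep(0L, 4))

  # random provider counts: any 1e-3 flag must also be a 0.05 flag
  withr::with_seed(4, {
    cls2 <- dplyr::bind_rows(lapply(1:8, function(i) {
      k <- rbinom(1, 400, 0.25)
      s <- classified_stub(c(benign = 400 - k, insufficient = k),
                           sps = paste0("P", i))
      s$specimen_id <- paste0(i, "-", s$specimen_id)
      s
    }))
  })
  ch2 <- build_chart(provider_rates(cls2, "sps", min_n = 250),
                     "insufficient", mode = "raw")
  flagged_05 <- ch2$points$flag_0.05 != "in_control"
  flagged_13 <- ch2$points$flag_0.001 != "in_control"
  expect_true(all(!flagged_13 | flagged_05))
})

test_that("an inflated-odds provider is flagged high at alpha 0.001", {
  cfg <- synthetic_config(
    n_records = 8800, seed = 99,
    sps_ids = sprintf("SPS%02d", 1:11),
    sps_effects = list(SPS05 = c(insufficient = log(2.5))),
    distractor_level = "none")
  withr::with_seed(99, truth <- generate_truth(cfg))
  cls <- truth_as_classified(truth)
  ch <- build_chart(provider_rates(cls, "sps", min_n = 250),
                    "insufficient", mode = "raw")
  row <- ch$points[ch$points$provider_id == "SPS05", ]
  expect_equal(row$flag_0.001, "high")
  expect_lt(row$two_sided_p, 1e-3)
})

test_that("chart rendering returns ggplot objects for both kinds", {
  cls <- dplyr::bind_rows(lapply(1:4, function(i) {
    k <- 80 + 10 * i
    s <- classified_stub(c(benign = 400 - k, insufficient = k),
                         sps = paste0("SPS", i))
    s$specimen_id <- paste0(i, "-", s$specimen_id)
    s
  }))
  ch <- build_chart(provider_rates(cls, "sps", min_n = 250),
                    "insufficient", mode = "raw")
  expect_s3_class(render_chart(ch, "control_chart"), "ggplot")
  expect_s3_class(render_chart(ch, "funnel"), "ggplot")
})
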