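make_design_corpus <- function(n = 4000, seed = 55, sps_effects = NULL) {
  cfg <- synthetic_config(n_records = n, seed = seed,
                          sps_effects = sps_effects,
                          distractor_level = "none")
  withr::with_seed(seed, truth <- generate_truth(cfg))
  truth_as_classified(truth)
}

test_that("trimming equals a brute-force filter and relevels by volume", {
  cls <- make_design_corpus(3000, seed = 12)
  # push one SPS and one station below their thresholds
  cls$sps_id[cls$sps_id == "SPS7"][-(1:100)] <- "SPS1"
  cls$station[cls$station == "12R"][-(1:5)] <- "7"
  design <- trim_design(cls, min_n = 250, min_station = 20)
  keep_sps <- names(which(table(cls$sps_id) >= 250))
  keep_path <- names(which(table(cls$pathologist_id) >= 250))
  keep_stn <- setdiff(names(which(table(cls$station) >= 20)), "UNKNOWN")
  brute <- cls[cls$sps_id %in% keep_sps & cls$pathologist_id %in% keep_path &
                 cls$station %in% keep_stn, ]
  expect_equal(design$n, nrow(brute))
  expect_setequal(design$levels$sps, keep_sps)
  expect_false("SPS7" %in% design$levels$sps)
  expect_false("12R" %in% design$levels$station)
  # reference (first) level is the highest-volume one
  expect_equal(design$levels$sps[1],
               names(sort(table(brute$sps_id), decreasing = TRUE))[1])
  expect_error(trim_design(cls, min_n = 10000), "fewer than 2")
})

test_that("factor degrees of freedom and likelihood-ratio bookkeeping are consistent", {
  design <- trim_design(make_design_corpus(4000, seed = 23))
  m <- fit_category_model(design, "insufficient")
  dfs <- setNames(m$factor_tests$df, m$factor_tests$factor)
  expect_equal(unname(dfs), c(length(design$levels$sps) - 1L,
                              length(design$levels$pathologist) - 1L,
                              length(design$levels$station) - 1L))
  # sum of factor dfs + intercept = number of coefficients
  expect_equal(sum(dfs) + 1L, nrow(m$coefficients))
  expect_true(all(m$factor_tests$statistic >= 0))
  expect_true(all(m$factor_tests$p_value >= 0 & m$factor_tests$p_value <= 1))
  expect_true(m$converged)
})

test_that("constant outcomes and unknown outcomes are rejected", {
  design <- trim_design(make_design_corpus(3000, seed = 31))
  expect_error(fit_category_model(design, "melanoma_of_unknown"), "neither")
  d2 <- design
  d2$data$exclusive_group <- "benign"
  expect_error(fit_category_model(d2, "benign"), "constant")
})

test_that("a generated provider effect is recovered and detected by the LR test", {
  cls <- make_design_corpus(6000, seed = 41,
                            sps_effects = list(SPS3 = c(insufficient = log(2.5))))
  design <- trim_design(cls)
  m <- fit_category_model(design, "insufficient")
  # contrast between the inflated SPS and a null SPS estimates log(2.5);
  # one replicate, so allow generous Monte-Carlo slack
  get_beta <- function(id) {
    term <- paste0("sps", id)
    if (term %in% m$coefficients$term)
      m$coefficients$estimate[m$coefficients$term == term] else 0
  }
  est <- unname(get_beta("SPS3") - get_beta("SPS1"))
  expect_equal(est, log(2.5), tolerance = 0.35)
  sps_p <- m$factor_tests$p_value[m$factor_tests$factor == "sps"]
  expect_lt(sps_p, 0.001)
})

test_that("ROC matches hand enumeration, the null, the perfect case, and pROC", {
  # toy 6-record design computed by hand:
  # scores .9 .8 .6 .4 .3 .1 / labels 1 0 1 1 0 0
  # thresholds descending give (fpr,tpr): (0,1/3) (1/3,1/3) (1/3,1) (1,1)
  # AUC = 1/3*2/3 + ... = 2/3*1 - ... = 0.7777...
  d <- data.frame(y = c(1, 0, 1, 1, 0, 0),
                  x = c(.9, .8, .6, .4, .3, .1))
  fit <- glm(y ~ x, family = binomial(), data = d)
  # monotone transform preserves the ROC of the raw scores
  model <- structure(list(fit = fit), class = "mlnqa_model")
  roc <- roc_from_model(model)
  expect_equal(roc$auc, 7 / 9, tolerance = 1e-9)
  expect_equal(roc$points$fpr[1], 0)
  expect_equal(roc$points$tpr[nrow(roc$points)], 1)
  skip_if_not_installed("pROC")
  ref <- suppressMessages(pROC::auc(pROC::roc(d$y, fitted(fit))))
  expect_equal(roc$auc, as.numeric(ref))

  # perfectly separating predictor
  d2 <- data.frame(y = rep(c(0, 1), each = 20), x = rep(c(0, 1), each = 20))
  fit2 <- suppressWarnings(glm(y ~ x, family = binomial(), data = d2))
  expect_equal(roc_from_model(structure(list(fit = fit2),
                                        class = "mlnqa_model"))$auc, 1.0)

  # uninformative predictor: AUC near 1/2
  withr::with_seed(6, {
    d3 <- data.frame(y = rbinom(2000, 1, 0.5), x = runif(2000))
  })
  fit3 <- glm(y ~ x, family = binomial(), data = d3)
  auc3 <- roc_from_model(structure(list(fit = fit3),
                                   class = "mlnqa_model"))$auc
  expect_equal(auc3, 0.5, tolerance = 0.05)
})
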