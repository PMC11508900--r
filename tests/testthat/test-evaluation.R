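test_that("auc reproduces hand-enumerated and degenerate cases", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)
  # presences {0.9, 0.4}, absences {0.6, 0.1}: 3 wins of 4 pairs
  expect_equal(auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_error(auc(c(0.1, 0.9), c(1, 1)), class = "ensdm_metric_error")
})

test_that("auc is invariant to monotone transforms and complement-symmetric", {
  withr::with_seed(21, {
    for (i in 1:20) {
      s <- stats::runif(30)
      l <- stats::rbinom(30, 1, 0.5)
      if (length(unique(l)) < 2) next
      expect_equal(auc(s, l), auc(stats::qlogis(s * 0.98 + 0.01), l))
      expect_equal(auc(s, l) + auc(-s, l), 1)
    }
  })
})

test_that("kappa matches its published formula on canonical tables", {
  expect_equal(kappa_stat(list(TP = 50, FP = 0, TN = 50, FN = 0)), 1)
  expect_equal(kappa_stat(list(TP = 25, FP = 25, TN = 25, FN = 25)), 0)
  expect_equal(kappa_stat(list(TP = 40, FP = 10, TN = 40, FN = 10)), 0.6)
  expect_error(kappa_stat(list(TP = 10, FP = 0, TN = 0, FN = 0)),
               class = "ensdm_metric_error")
})

test_that("tss is sensitivity plus specificity minus one", {
  expect_equal(tss_stat(list(TP = 10, FP = 0, TN = 10, FN = 0)), 1)
  expect_equal(tss_stat(list(TP = 5, FP = 5, TN = 5, FN = 5)), 0)
  expect_equal(tss_stat(list(TP = 40, FN = 10, TN = 30, FP = 20)), 0.4)
  expect_error(tss_stat(list(TP = 0, FN = 0, TN = 5, FP = 5)),
               class = "ensdm_metric_error")
})

test_that("kappa and tss are invariant under class swap", {
  withr::with_seed(3, {
    for (i in 1:20) {
      cc <- as.list(stats::setNames(sample(1:40, 4, replace = TRUE),
                                    c("TP", "FP", "TN", "FN")))
      sw <- list(TP = cc$TN, TN = cc$TP, FP = cc$FN, FN = cc$FP)
      expect_equal(kappa_stat(cc), kappa_stat(sw))
      expect_equal(tss_stat(cc), tss_stat(sw))
    }
  })
})

test_that("max-TSS threshold matches the exhaustive oracle and its tie rule", {
  # separable: smallest candidate inside the gap, TSS = 1
  bt <- best_threshold_by_tss(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(bt$tss, 1)
  expect_equal(bt$threshold, 0.5)
  # single distinct score: threshold from the {0, 1} endpoints, TSS = 0
  bt2 <- best_threshold_by_tss(rep(0.4, 8), rep(c(0, 1), 4))
  expect_true(bt2$threshold %in% c(0, 1))
  expect_equal(bt2$tss, 0)
  # interleaved labels: near-zero max TSS, still matches the oracle
  s <- seq(0.05, 0.95, length.out = 20)
  l <- rep(c(0, 1), 10)
  bt3 <- best_threshold_by_tss(s, l)
  expect_equal(bt3$tss, oracle_max_tss(s, l))
})

test_that("TSS at the chosen threshold dominates any fixed threshold", {
  withr::with_seed(14, {
    for (i in 1:10) {
      s <- round(stats::runif(25), 2)
      l <- stats::rbinom(25, 1, 0.4)
      if (length(unique(l)) < 2) next
      bt <- best_threshold_by_tss(s, l)
      for (th in c(0.25, 0.5, 0.75)) {
        expect_gte(bt$tss + 1e-12, tss_stat(confusion_counts(s, l, th)))
      }
    }
  })
})

test_that("evaluate_models yields one record per model and repeat", {
  d <- monotone_data(n = 60, seed = 31)
  occ <- tibble::tibble(label = d$y, longitude = seq_along(d$y), latitude = 1)
  occ <- make_splits(occ, n_repeats = 4, seed = 2)
  rec <- evaluate_models(list(sdm_spec("GLM", seed = 1), sdm_spec("CTA", seed = 1)),
                         occ, d$X, seed = 3)
  expect_equal(nrow(rec), 8)
  expect_setequal(unique(rec$model), c("GLM", "CTA"))
  expect_false(any(rec$failed))
  expect_true(all(rec$auc >= 0 & rec$auc <= 1))
  preds <- attr(rec, "predictions")
  expect_equal(nrow(preds), 8 * sum(occ$split_1 == "evaluation"))

  # deterministic given fixed splits and seeds
  rec2 <- evaluate_models(list(sdm_spec("GLM", seed = 1), sdm_spec("CTA", seed = 1)),
                          occ, d$X, seed = 3)
  expect_equal(as.data.frame(rec), as.data.frame(rec2))
})

test_that("a failing member is recorded, not fatal", {
  d <- monotone_data(n = 40, seed = 8)
  occ <- make_splits(tibble::tibble(label = d$y, longitude = seq_along(d$y),
                                    latitude = 1), n_repeats = 2, seed = 4)
  # quantile 0.6 is outside [0, 0.5): every SRE fit fails
  specs <- list(sdm_spec("GLM", seed = 1),
                sdm_spec("SRE", hyper = list(quantile = 0.6)))
  rec <- evaluate_models(specs, occ, d$X, seed = 5)
  expect_equal(nrow(rec), 4)
  expect_equal(sum(rec$failed), 2)
  expect_true(all(rec$failed[rec$model == "SRE"]))
  expect_true(all(is.na(rec$auc[rec$failed])))
  expect_match(rec$message[rec$failed][1], "0.5")
})

test_that("permutation importance is zero for ignored variables, high for drivers", {
  d <- monotone_data(n = 150, seed = 12)
  fit <- fit_sdm(sdm_spec("GLM", seed = 1), d$X, d$y)   # knows only x1
  covs <- dplyr::mutate(d$X, unused = stats::rnorm(150))
  imp <- permutation_importance(fit, covs, seed = 6)
  expect_equal(imp$importance[imp$variable == "unused"], 0)
  expect_gt(imp$importance[imp$variable == "x1"], 0.5)
  # reproducible
  expect_identical(imp, permutation_importance(fit, covs, seed = 6))
})

test_that("duplicated informative columns dilute each other's importance", {
  withr::with_seed(19, {
    x <- stats::rnorm(200)
    y <- stats::rbinom(200, 1, stats::plogis(3 * x))
  })
  single <- fit_sdm(sdm_spec("RF", seed = 1), tibble::tibble(a = x), y)
  imp_single <- permutation_importance(single, tibble::tibble(a = x), seed = 2)
  dup <- fit_sdm(sdm_spec("RF", seed = 1), tibble::tibble(a = x, b = x), y)
  imp_dup <- permutation_importance(dup, tibble::tibble(a = x, b = x), seed = 2)
  expect_lt(max(imp_dup$importance), imp_single$importance[1])
})

test_that("response curves recover a constructed optimum and crossing", {
  # suitability logistic in v1, peaked by a quadratic at v* = 0.8
  st <- align_stack(list(
    raster_grid(matrix(seq(-2, 2, length.out = 400), 20, 20), 100, 40, 0.1),
    raster_grid(matrix(stats::rnorm(400, sd = 0.2), 20, 20), 100, 40, 0.1)),
    c("v1", "v2"))
  withr::with_seed(44, {
    v1 <- stats::runif(300, -2, 2)
    v2 <- stats::rnorm(300, sd = 0.2)
    y <- stats::rbinom(300, 1, stats::plogis(4 - 10 * (v1 - 0.8)^2))
  })
  fit <- fit_sdm(sdm_spec("GLM", seed = 1), tibble::tibble(v1 = v1, v2 = v2), y)
  rc <- response_curve(fit, st, "v1", n_steps = 100)
  step <- diff(range(rc$curves$value)) / 99
  expect_lt(abs(rc$optima$optimum - 0.8), 2 * step)
  expect_gt(nrow(rc$favorable), 0)

  # monotone increasing response crossing 0.5 at a known point
  withr::with_seed(45, {
    v1b <- stats::runif(400, -2, 2)
    yb <- stats::rbinom(400, 1, stats::plogis(5 * (v1b - 0.3)))
  })
  fitb <- fit_sdm(sdm_spec("GLM", seed = 1),
                  tibble::tibble(v1 = v1b, v2 = stats::rnorm(400, sd = 0.2)), yb)
  rcb <- response_curve(fitb, st, "v1", n_steps = 200)
  expect_equal(nrow(rcb$favorable), 1)
  expect_lt(abs(rcb$favorable$lower - 0.3), 0.25)
  expect_equal(rcb$favorable$upper, max(rcb$curves$value))
})

test_that("degenerate response inputs are rejected or reported empty", {
  st <- align_stack(list(
    raster_grid(matrix(1, 4, 4), 100, 40, 0.1),
    raster_grid(matrix(seq_len(16), 4, 4), 100, 40, 0.1)), c("flat", "v"))
  d <- monotone_data(n = 50, seed = 2)
  names(d$X) <- "v"
  fit <- fit_sdm(sdm_spec("GLM", seed = 1), d$X, d$y)
  expect_error(response_curve(fit, st, "flat"), class = "ensdm_degenerate_error")

  # all-low suitability: no favourable range but an optimum is still reported
  fit_low <- fit_sdm(sdm_spec("SRE", hyper = list(quantile = 0)),
                     tibble::tibble(v = c(100, 101, 5)), c(1L, 1L, 0L))
  rc <- response_curve(fit_low, st, "v")
  expect_equal(nrow(rc$favorable), 0)
  expect_equal(nrow(rc$optima), 1)
})
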