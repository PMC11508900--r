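fake_records <- function(models, tss_means, n_repeats = 2) {
  dplyr::bind_rows(lapply(seq_along(models), function(i) {
    tibble::tibble(model = models[i], repeat_index = seq_len(n_repeats),
                   auc = tss_means[i] / 2 + 0.5, kappa = tss_means[i],
                   tss = tss_means[i], best_threshold = 0.5,
                   failed = FALSE, message = "")
  }))
}

test_that("weights equal mean metric, floored and cut off", {
  d <- monotone_data(n = 60, seed = 1)
  fits <- list(GLM = fit_sdm(sdm_spec("GLM", seed = 1), d$X, d$y),
               CTA = fit_sdm(sdm_spec("CTA", seed = 1), d$X, d$y))
  rec <- fake_records(c("GLM", "CTA"), c(0.8, 0.4))
  ens <- build_ensemble(rec, fits)
  expect_equal(unname(ens$weights), c(0.8, 0.4))
  expect_equal(unname(ens$weights / sum(ens$weights)), c(2, 1) / 3)

  ens2 <- build_ensemble(rec, fits, inclusion_cutoff = 0.5)
  expect_equal(names(ens2$weights), "GLM")

  expect_error(build_ensemble(rec, fits, inclusion_cutoff = 0.9),
               class = "ensdm_empty_ensemble_error")

  # negative metrics floor at zero
  rec3 <- fake_records(c("GLM", "CTA"), c(0.6, -0.2))
  ens3 <- build_ensemble(rec3, fits)
  expect_equal(names(ens3$weights), "GLM")
})

test_that("the combiner is the weighted mean of member predictions", {
  nd <- tibble::tibble(x1 = 1:5)
  m1 <- stub_model(function(nd) rep(0.2, nrow(nd)))
  m2 <- stub_model(function(nd) rep(0.8, nrow(nd)))
  ens_eq <- stub_ensemble(list(a = m1, b = m2), c(1, 1))
  expect_equal(predict(ens_eq, nd), rep(0.5, 5))

  ens_31 <- stub_ensemble(list(a = m1, b = m2), c(3, 1))
  expect_equal(predict(ens_31, nd), rep(0.35, 5))

  single <- stub_ensemble(list(a = m1), 2)
  expect_equal(predict(single, nd), rep(0.2, 5))
})

test_that("combining is convex and scale invariant on random committees", {
  withr::with_seed(8, {
    for (i in 1:10) {
      k <- sample(2:5, 1)
      preds <- matrix(stats::runif(k * 20), 20, k)
      members <- lapply(seq_len(k), function(j) {
        force(j); stub_model(function(nd) preds[seq_len(nrow(nd)), j])
      })
      names(members) <- paste0("m", seq_len(k))
      w <- stats::runif(k, 0.1, 1)
      ens <- stub_ensemble(members, w)
      nd <- tibble::tibble(x1 = 1:20)
      p <- predict(ens, nd)
      expect_true(all(p >= apply(preds, 1, min) - 1e-12))
      expect_true(all(p <= apply(preds, 1, max) + 1e-12))
      scaled <- stub_ensemble(members, w * 37.5)
      expect_equal(predict(scaled, nd), p)
    }
  })
})

test_that("rows where members cannot predict fall back to the rest, or NA", {
  m_ok <- stub_model(function(nd) rep(0.4, nrow(nd)))
  m_na <- stub_model(function(nd) ifelse(seq_len(nrow(nd)) == 1, NA, 0.8))
  ens <- stub_ensemble(list(a = m_ok, b = m_na), c(1, 1))
  p <- predict(ens, tibble::tibble(x1 = 1:3))
  expect_equal(p, c(0.4, 0.6, 0.6))

  all_na <- stub_ensemble(list(b = stub_model(function(nd) rep(NA_real_, nrow(nd)))), 1)
  expect_true(all(is.na(predict(all_na, tibble::tibble(x1 = 1:2)))))
})

test_that("projection respects the mask and layer-name contract", {
  mask <- cbind(c(1, 3), c(1, 3))
  st <- tiny_stack(2, mask = mask)
  names(st$layers)
  d <- monotone_data(n = 60, seed = 2)
  X <- tibble::tibble(v1 = d$X$x1, v2 = stats::rnorm(60))
  fit <- fit_sdm(sdm_spec("GLM", seed = 1), X, d$y)
  ens <- stub_ensemble(list(GLM = fit), 1)
  pm <- project_map(ens, st)
  expect_identical(is.na(pm$values), st$shared_mask)
  expect_true(all(pm$values[!is.na(pm$values)] >= 0 &
                    pm$values[!is.na(pm$values)] <= 1))
  expect_equal(pm$cell_size, st$layers[[1]]$cell_size)

  st_missing <- align_stack(list(st$layers[[1]]), "v1")
  expect_error(project_map(ens, st_missing), "v2", class = "ensdm_schema_error")

  # constant members give a constant map
  const <- stub_ensemble(list(c = stub_model(function(nd) rep(0.3, nrow(nd)),
                                             variables = c("v1", "v2"))), 1)
  pmc <- project_map(const, st)
  expect_equal(unique(pmc$values[!is.na(pmc$values)]), 0.3)
})

test_that("warming shifted past the optimum lowers mean suitability", {
  scn <- small_scenario(seed = 6)
  land <- simulate_landscape(scn)
  pa <- sample_pseudo_absences(land$stack, land$presences, n = 300, seed = 2)
  occ <- make_splits(build_occurrence_set(land$presences, pa), seed = 3)
  X <- extract_values(land$stack, occ)[, land$stack$layer_names]
  fit <- fit_sdm(sdm_spec("RF", seed = 1), X, occ$label)
  ens <- stub_ensemble(list(RF = fit), 1)
  cur <- project_map(ens, land$stack)
  fut <- project_map(ens, shift_stack(land$stack, c(bio1 = 1.5)))
  # bio1 optimum is +1 sd; a +1.5 sd uniform warming pushes cells already
  # at/above the optimum further away from it
  above <- land$stack$layers$bio1$values >= 1
  expect_lt(mean(fut$values[above]), mean(cur$values[above]))
})

test_that("the committee is at least as good as its median member most of the time", {
  wins <- 0
  n_seeds <- 5
  for (s in seq_len(n_seeds)) {
    scn <- small_scenario(seed = 200 + s)
    land <- simulate_landscape(scn)
    pa <- sample_pseudo_absences(land$stack, land$presences, n = 200,
                                 seed = 300 + s)
    occ <- make_splits(build_occurrence_set(land$presences, pa), n_repeats = 2,
                       seed = 400 + s)
    X <- extract_values(land$stack, occ)[, land$stack$layer_names]
    models <- c("GLM", "CTA", "RF", "SRE", "MARS")
    rec <- evaluate_models(models, occ, X, seed = 500 + s)
    fits <- lapply(stats::setNames(models, models), function(nm) {
      fit_sdm(sdm_spec(nm, seed = 600 + s), X, occ$label)
    })
    ens <- build_ensemble(rec, fits)
    # held-out points from the same truth, fresh draw
    scn_ho <- scn; scn_ho$seed <- scn$seed + 5000L
    ho_p <- sample_occurrences(scn_ho, land$truth)
    ho_a <- sample_pseudo_absences(land$stack, ho_p, n = 100, seed = 700 + s)
    ho <- build_occurrence_set(ho_p, ho_a)
    Xho <- extract_values(land$stack, ho)[, land$stack$layer_names]
    ens_auc <- auc(predict(ens, Xho), ho$label)
    member_aucs <- vapply(fits, function(f) auc(predict(f, Xho), ho$label),
                          numeric(1))
    if (ens_auc >= stats::median(member_aucs) - 1e-9) wins <- wins + 1
  }
  expect_gte(wins, ceiling(0.8 * n_seeds))
})

test_that("tidy and glance summarise an ensemble", {
  d <- monotone_data(n = 60, seed = 1)
  fits <- list(GLM = fit_sdm(sdm_spec("GLM", seed = 1), d$X, d$y),
               CTA = fit_sdm(sdm_spec("CTA", seed = 1), d$X, d$y))
  ens <- build_ensemble(fake_records(c("GLM", "CTA"), c(0.9, 0.3)), fits)
  td <- generics::tidy(ens)
  expect_equal(td$model, c("GLM", "CTA"))
  expect_equal(sum(td$weight_normalized), 1)
  gl <- generics::glance(ens)
  expect_equal(gl$n_members, 2L)
  expect_equal(gl$max_weight_model, "GLM")
})
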