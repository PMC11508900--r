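#' Define a synthetic landscape scenario
#'
#' A fully specified virtual-species study: spatially autocorrelated
#' environmental covariates on a geographic grid, a known (true)
#' suitability surface built from unimodal (Gaussian-bump) or logistic
#' terms on a chosen subset of the covariates, presence records sampled
#' proportionally to that surface, and a categorical land-use layer whose
#' grassland class is probabilistically coupled to suitability. Every
#' pipeline stage can then be exercised, and parameter recovery measured,
#' without any external raster downloads.
#'
#' The defaults emulate a high-plateau study at the standard 2.5-minute
#' resolution: a 100 x 100 grid, two informative bioclimatic covariates
#' with bump-shaped responses plus four uninformative ones, 150 presence
#' records, and a grassland-dominated land-use composition.
#'
#' @param n_rows,n_cols grid size in cells.
#' @param x_min,y_max grid origin (degrees).
#' @param cell_size cell edge in degrees (default 2.5 arc-minutes).
#' @param autocorr_length spatial autocorrelation length of the covariate
#'   fields, in cells (Gaussian smoothing kernel sd; values `<= 1` mean
#'   unsmoothed white noise).
#' @param covariate_names names of all covariate layers.
#' @param informative tibble describing the true response: `variable`,
#'   `shape` (`"bump"` or `"logistic"`), `optimum`, `width`, `gain`.
#' @param intercept intercept of the true logit.
#' @param n_presence number of presence records to sample.
#' @param landuse_base named base probabilities of the nine land-use
#'   classes (must sum to 1).
#' @param landuse_coupling added grassland probability per unit true
#'   suitability (0 = uncoupled).
#' @param seed integer root seed.
#' @return object of class `sdm_scenario`.
#' @export
sdm_scenario <- function(n_rows = 100, n_cols = 100,
                         x_min = 98, y_max = 39, cell_size = 2.5 / 60,
                         autocorr_length = 8,
                         covariate_names = c("bio1", "bio12", "bio4", "bio7", "bio15", "elev"),
                         informative = tibble(
                           variable = c("bio1", "bio12"),
                           shape = c("bump", "bump"),
                           optimum = c(1, -1),
                           width = c(0.3, 0.36),
                           gain = c(10, 10)),
                         intercept = -11,
                         n_presence = 150,
                         landuse_base = c(grassland = 0.40, barren = 0.20,
                                          forest = 0.10, cropland = 0.08,
                                          water = 0.05, shrubs = 0.07,
                                          ice_snow = 0.04, wetland = 0.03,
                                          impervious = 0.03),
                         landuse_coupling = 0.5,
                         seed = 1) {
  if (autocorr_length >= min(n_rows, n_cols)) {
    abort("`autocorr_length` must be smaller than the grid size.",
          class = "ensdm_parameter_error")
  }
  if (!all(informative$variable %in% covariate_names)) {
    abort("informative variables must be among `covariate_names`.",
          class = "ensdm_parameter_error")
  }
  if (abs(sum(landuse_base) - 1) > 1e-8) {
    abort("`landuse_base` must sum to 1.", class = "ensdm_parameter_error")
  }
  if (landuse_coupling < 0) {
    abort("`landuse_coupling` must be >= 0.", class = "ensdm_parameter_error")
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, x_min = x_min, y_max = y_max,
         cell_size = cell_size, autocorr_length = autocorr_length,
         covariate_names = covariate_names, informative = informative,
         intercept = intercept, n_presence = n_presence,
         landuse_base = landuse_base, landuse_coupling = landuse_coupling,
         seed = as.integer(seed)),
    class = "sdm_scenario"
  )
}

# Gaussian random field: white noise smoothed by circular (FFT) convolution
# with a Gaussian kernel of sd `len` cells, then standardised to mean 0 /
# sd 1. Circular convolution avoids edge artefacts without padding.
gaussian_field <- function(n_rows, n_cols, len) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (len <= 1) return((z - mean(z)) / stats::sd(z))
  gr <- stats::dnorm(pmin(0:(n_rows - 1), n_rows - 0:(n_rows - 1)), sd = len)
  gc <- stats::dnorm(pmin(0:(n_cols - 1), n_cols - 0:(n_cols - 1)), sd = len)
  K <- outer(gr, gc)
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(K), inverse = TRUE)) / length(z)
  (sm - mean(sm)) / stats::sd(sm)
}

#' Generate the covariate stack of a scenario
#'
#' Each layer is an independent Gaussian random field with the scenario's
#' autocorrelation length, standardised to mean 0 and sd 1. Bit-identical
#' given the scenario seed.
#'
#' @param scenario an [sdm_scenario].
#' @return an [align_stack] stack with one layer per covariate.
#' @export
generate_covariates <- function(scenario) {
  layers <- with_seed(derive_seed(scenario$seed, "covariates"), {
    lapply(scenario$covariate_names, function(nm) {
      m <- gaussian_field(scenario$n_rows, scenario$n_cols, scenario$autocorr_length)
      raster_grid(m, scenario$x_min, scenario$y_max, scenario$cell_size)
    })
  })
  align_stack(layers, scenario$covariate_names)
}

#' True suitability surface of a scenario
#'
#' Deterministic inverse-logit of the scenario's response: for each
#' informative variable a Gaussian bump
#' `gain * exp(-(v - optimum)^2 / (2 width^2))` or a logistic step
#' `gain * plogis((v - optimum) / width)`, summed with the intercept.
#'
#' @param scenario an [sdm_scenario].
#' @param stack covariate stack containing the informative layers.
#' @return [raster_grid] of true suitability in `(0, 1)`.
#' @export
true_suitability <- function(scenario, stack) {
  miss <- setdiff(scenario$informative$variable, stack$layer_names)
  if (length(miss) > 0) {
    abort(sprintf("stack is missing informative layer(s): %s",
                  paste(miss, collapse = ", ")),
          class = "ensdm_schema_error")
  }
  ref <- stack$layers[[1]]
  eta <- matrix(scenario$intercept, nrow(ref$values), ncol(ref$values))
  for (i in seq_len(nrow(scenario$informative))) {
    tr <- scenario$informative[i, ]
    v <- stack$layers[[tr$variable]]$values
    term <- if (tr$shape == "logistic") {
      tr$gain * stats::plogis((v - tr$optimum) / tr$width)
    } else {
      tr$gain * exp(-(v - tr$optimum)^2 / (2 * tr$width^2))
    }
    eta <- eta + term
  }
  s <- stats::plogis(eta)
  s[stack$shared_mask] <- NA_real_
  raster_grid(s, ref$x_min, ref$y_max, ref$cell_size)
}

#' Sample presence records from a suitability surface
#'
#' Draws `n_presence` distinct cells with probability proportional to true
#' suitability (without replacement) and returns their centres — the
#' presence-only design of a field survey over a known niche.
#'
#' @param scenario an [sdm_scenario].
#' @param truth [raster_grid] of true suitability.
#' @return tibble with `longitude`, `latitude`.
#' @export
sample_occurrences <- function(scenario, truth) {
  tb <- as_tibble(truth)
  tb <- tb[!is.na(tb$value), ]
  if (sum(tb$value) <= 0) {
    abort("true suitability sums to zero; nothing to sample.",
          class = "ensdm_empty_error")
  }
  if (scenario$n_presence > nrow(tb)) {
    abort(sprintf("n_presence (%d) exceeds available cells (%d).",
                  scenario$n_presence, nrow(tb)),
          class = "ensdm_capacity_error")
  }
  idx <- with_seed(derive_seed(scenario$seed, "occurrences"),
                   sample(nrow(tb), scenario$n_presence, prob = tb$value))
  tibble(longitude = tb$longitude[idx], latitude = tb$latitude[idx])
}

#' Generate a land-use layer coupled to suitability
#'
#' Per cell, a category is drawn from the nine-class multinomial whose
#' grassland probability is lifted by `landuse_coupling * truth` (the
#' remaining classes are rescaled proportionally to their base rates).
#' Codes follow [landuse_legend].
#'
#' @param scenario an [sdm_scenario].
#' @param truth [raster_grid] of true suitability.
#' @return [raster_grid] of integer category codes 1-9.
#' @export
generate_landuse <- function(scenario, truth) {
  base <- scenario$landuse_base
  legend <- landuse_legend()
  base <- base[legend$label]  # fixed code order
  s <- as.vector(truth$values)
  ok <- !is.na(s)
  p_grass <- base[["grassland"]] + scenario$landuse_coupling * s[ok]
  if (any(p_grass > 1)) {
    abort("grassland probability exceeds 1 after the coupling lift; reduce `landuse_coupling`.",
          class = "ensdm_parameter_error")
  }
  others <- base[names(base) != "grassland"]
  scale <- (1 - p_grass) / sum(others)
  codes <- with_seed(derive_seed(scenario$seed, "landuse"), {
    u <- stats::runif(length(p_grass))
    # cumulative probabilities: grassland first (code 1), then the rest
    probs <- cbind(p_grass, outer(scale, unname(others)))
    cum <- t(apply(probs, 1, cumsum))
    cum[, ncol(cum)] <- 1  # guard against floating-point undershoot
    max.col(u <= cum, ties.method = "first")
  })
  m <- matrix(NA_real_, nrow(truth$values), ncol(truth$values))
  m[ok] <- codes
  raster_grid(m, truth$x_min, truth$y_max, truth$cell_size)
}

#' Simulate a full synthetic landscape
#'
#' Convenience wrapper: covariates, true suitability, presence records and
#' land use for one scenario.
#'
#' @param scenario an [sdm_scenario].
#' @return list with `stack`, `truth`, `presences`, `landuse`.
#' @export
simulate_landscape <- function(scenario) {
  stack <- generate_covariates(scenario)
  truth <- true_suitability(scenario, stack)
  list(stack = stack, truth = truth,
       presences = sample_occurrences(scenario, truth),
       landuse = generate_landuse(scenario, truth))
}

#' Derive a shifted "future period" stack
#'
#' Adds a uniform offset to selected layers of a stack (e.g. a warming
#' shift applied to the temperature variable), leaving the others
#' untouched — a minimal stand-in for a future-climate projection stack
#' with identical layer names.
#'
#' @param stack an [align_stack] result.
#' @param shifts named numeric vector: offset added to each named layer.
#' @return a new `env_stack`.
#' @export
shift_stack <- function(stack, shifts) {
  layers <- stack$layers
  for (nm in names(shifts)) {
    if (!(nm %in% stack$layer_names)) {
      abort(sprintf("layer '%s' not in stack.", nm), class = "ensdm_schema_error")
    }
    g <- layers[[nm]]
    layers[[nm]] <- raster_grid(g$values + shifts[[nm]], g$x_min, g$y_max, g$cell_size)
  }
  align_stack(layers, stack$layer_names)
}
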