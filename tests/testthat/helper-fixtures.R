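# Shared fixtures built in code.

# small unmasked grid with deterministic values
tiny_grid <- function(nr = 5, nc = 5, x_min = 100, y_max = 40, cell = 0.5,
                      values = NULL) {
  if (is.null(values)) values <- matrix(seq_len(nr * nc), nr, nc)
  raster_grid(values, x_min = x_min, y_max = y_max, cell_size = cell)
}

# stack of k smooth deterministic layers on the tiny grid
tiny_stack <- function(k = 2, nr = 5, nc = 5, mask = NULL) {
  layers <- lapply(seq_len(k), function(j) {
    v <- outer(seq_len(nr), seq_len(nc), function(r, c) r * j + c / j)
    if (!is.null(mask)) v[mask] <- NA
    tiny_grid(nr, nc, values = v)
  })
  align_stack(layers, paste0("v", seq_len(k)))
}

# a small but learnable scenario for fast committee tests
small_scenario <- function(seed = 1, autocorr_length = 5, ...) {
  sdm_scenario(n_rows = 40, n_cols = 40, n_presence = 60,
               autocorr_length = autocorr_length, seed = seed, ...)
}

# 1-D monotone-gradient presence/absence data for learner sanity checks
monotone_data <- function(n = 200, seed = 1, p_extra = 0) {
  withr::with_seed(seed, {
    x <- stats::rnorm(n)
    y <- stats::rbinom(n, 1, stats::plogis(8 * x))
    X <- tibble::tibble(x1 = x)
    if (p_extra > 0) for (j in seq_len(p_extra)) X[[paste0("z", j)]] <- stats::rnorm(n)
    list(X = X, y = y)
  })
}

# register a stub member model whose predictions are a fixed function,
# for exercising the ensemble combiner in isolation
local({
  registerS3method("predict", "stub_model",
                   function(object, newdata, ...) object$fn(newdata),
                   envir = asNamespace("stats"))
})
stub_model <- function(fn, variables = "x1") {
  structure(list(fn = fn, variables = variables), class = "stub_model")
}
stub_ensemble <- function(members, weights) {
  structure(list(members = members,
                 weights = stats::setNames(weights, names(members)),
                 weight_metric = "TSS", inclusion_cutoff = 0,
                 member_metrics = stats::setNames(weights, names(members))),
            class = "sdm_ensemble")
}
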