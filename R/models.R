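#' Names of the available suitability learners
#'
#' The nine-member committee: artificial neural network (ANN),
#' classification tree analysis (CTA), flexible discriminant analysis
#' (FDA), gradient boosted trees (GBM), logistic regression (GLM),
#' multivariate adaptive regression splines (MARS), a MaxEnt-style
#' L1-penalised regression (MAXENT_like), random forest (RF) and the
#' surface range envelope (SRE).
#' @return character vector of learner names.
#' @export
sdm_models <- function() {
  c("ANN", "CTA", "FDA", "GBM", "GLM", "MARS", "MAXENT_like", "RF", "SRE")
}

#' Specify a suitability learner
#'
#' @param name one of [sdm_models()].
#' @param hyper named list of hyperparameter overrides; unset parameters
#'   take the committee defaults (see the methods vignette).
#' @param seed integer seed controlling any randomness in the fit.
#' @return object of class `sdm_spec`.
#' @export
sdm_spec <- function(name, hyper = list(), seed = 1L) {
  if (!(name %in% sdm_models())) {
    abort(sprintf("unknown model '%s'; available: %s", name,
                  paste(sdm_models(), collapse = ", ")),
          class = "ensdm_parameter_error")
  }
  structure(list(name = name, hyper = hyper, seed = as.integer(seed)),
            class = "sdm_spec")
}

hyper_get <- function(spec, key, default) spec$hyper[[key]] %||% default

# ---- feature builders ----------------------------------------------------

# linear + quadratic columns, used by GLM and FDA
features_quad <- function(X) {
  out <- cbind(X, X^2)
  colnames(out) <- c(colnames(X), paste0(colnames(X), "_sq"))
  out
}

# linear + quadratic + pairwise products, used by the MaxEnt-style learner
features_maxent <- function(X) {
  p <- ncol(X)
  out <- features_quad(X)
  if (p >= 2) {
    for (i in seq_len(p - 1)) {
      for (j in (i + 1):p) {
        out <- cbind(out, X[, i] * X[, j])
        colnames(out)[ncol(out)] <- paste0(colnames(X)[i], "_x_", colnames(X)[j])
      }
    }
  }
  out
}

check_fit_inputs <- function(covariates, labels) {
  X <- as.matrix(covariates)
  if (!is.numeric(X) || any(!is.finite(X))) {
    abort("covariates must be finite numeric values (no NA) at fit time.",
          class = "ensdm_data_error")
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(X)) {
    abort("labels length must match covariate rows.", class = "ensdm_data_error")
  }
  if (length(unique(labels)) < 2) {
    abort("both presence and absence labels are required to fit.",
          class = "ensdm_fit_error")
  }
  list(X = X, y = labels)
}

#' Fit a suitability learner
#'
#' Fits the learner named in `spec` to a covariate table and 0/1 labels
#' (1 = presence, 0 = pseudo-absence). Fits are deterministic given
#' `spec$seed`. Predictions of the returned model are probabilities in
#' `[0, 1]` matched to covariate columns by name, in any column order.
#'
#' @param spec an [sdm_spec].
#' @param covariates data frame / matrix of numeric covariates.
#' @param labels integer vector of 0/1 labels.
#' @return object of class `sdm_fit`.
#' @export
fit_sdm <- function(spec, covariates, labels) {
  if (!inherits(spec, "sdm_spec")) abort("`spec` must be an sdm_spec.",
                                         class = "ensdm_parameter_error")
  inp <- check_fit_inputs(covariates, labels)
  X <- inp$X; y <- inp$y
  vars <- colnames(X)
  if (is.null(vars)) abort("covariates must have column names.", class = "ensdm_data_error")

  fitted <- with_seed(spec$seed, switch(
    spec$name,
    GLM = {
      F <- features_quad(X)
      df <- as.data.frame(F)
      suppressWarnings(stats::glm(y ~ ., data = cbind(df, y = y),
                                  family = stats::binomial()))
    },
    CTA = {
      df <- as.data.frame(X)
      rpart::rpart(factor(y) ~ ., data = cbind(df, y = y), method = "class",
                   control = rpart::rpart.control(
                     maxdepth = hyper_get(spec, "maxdepth", 10),
                     minbucket = hyper_get(spec, "minbucket", 5),
                     cp = hyper_get(spec, "cp", 0.001), xval = 0))
    },
    RF = {
      randomForest::randomForest(
        x = as.data.frame(X), y = factor(y, levels = c(0, 1)),
        ntree = hyper_get(spec, "ntree", 500))
    },
    GBM = {
      d <- xgboost::xgb.DMatrix(X, label = y)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      eta = hyper_get(spec, "eta", 0.01),
                      max_depth = hyper_get(spec, "max_depth", 3),
                      nthread = 1),
        data = d, nrounds = hyper_get(spec, "nrounds", 2500), verbose = 0)
    },
    ANN = {
      ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
      scl[scl == 0] <- 1
      Xs <- scale(X, center = ctr, scale = scl)
      m <- nnet::nnet(Xs, y, size = hyper_get(spec, "size", 5),
                      decay = hyper_get(spec, "decay", 0.01),
                      maxit = hyper_get(spec, "maxit", 200),
                      entropy = TRUE, trace = FALSE)
      list(net = m, center = ctr, scale = scl)
    },
    FDA = {
      F <- features_quad(X)
      keep <- apply(F, 2, stats::sd) > 0
      m <- MASS::lda(F[, keep, drop = FALSE], grouping = factor(y, levels = c(0, 1)))
      list(lda = m, keep = colnames(F)[keep])
    },
    MARS = {
      fit_hinge_mars(X, y,
                     max_terms = hyper_get(spec, "max_terms", 15),
                     n_knots = hyper_get(spec, "n_knots", 7),
                     degree = hyper_get(spec, "degree", 2))
    },
    MAXENT_like = {
      F <- features_maxent(X)
      foldid <- sample(rep_len(1:5, nrow(F)))
      cv <- glmnet::cv.glmnet(F, y, family = "binomial", alpha = 1,
                              foldid = foldid, standardize = TRUE)
      list(cv = cv, lambda = cv$lambda.min)
    },
    SRE = {
      sre_fit(X[y == 1, , drop = FALSE], q = hyper_get(spec, "quantile", 0.025))
    }
  ))

  structure(
    list(spec = spec, variables = vars, model = fitted,
         n_presence = sum(y == 1), n_absence = sum(y == 0)),
    class = "sdm_fit"
  )
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf("<sdm_fit> %s on %d variables (%s); %d presences, %d absences\n",
              x$spec$name, length(x$variables),
              paste(x$variables, collapse = ", "), x$n_presence, x$n_absence))
  invisible(x)
}

#' Predict suitability from a fitted learner
#'
#' @param object an [fit_sdm] result.
#' @param newdata data frame with (at least) the variables seen at fit
#'   time; extra columns are ignored, order is irrelevant.
#' @param ... unused.
#' @return numeric suitability in `[0, 1]` per row; rows with missing or
#'   non-finite inputs yield `NA`.
#' @export
predict.sdm_fit <- function(object, newdata, ...) {
  miss <- setdiff(object$variables, colnames(newdata))
  if (length(miss) > 0) {
    abort(sprintf("prediction input is missing variable(s): %s",
                  paste(miss, collapse = ", ")),
          class = "ensdm_schema_error")
  }
  X <- as.matrix(as.data.frame(newdata)[, object$variables, drop = FALSE])
  storage.mode(X) <- "double"
  ok <- stats::complete.cases(X) & apply(is.finite(X), 1, all)
  out <- rep(NA_real_, nrow(X))
  if (!any(ok)) return(out)
  Xok <- X[ok, , drop = FALSE]
  m <- object$model
  p <- switch(
    object$spec$name,
    GLM = suppressWarnings(stats::predict(m, newdata = as.data.frame(features_quad(Xok)),
                                          type = "response")),
    CTA = stats::predict(m, newdata = as.data.frame(Xok), type = "prob")[, "1"],
    RF = stats::predict(m, newdata = as.data.frame(Xok), type = "prob")[, "1"],
    GBM = stats::predict(m, xgboost::xgb.DMatrix(Xok)),
    ANN = as.vector(stats::predict(
      m$net, scale(Xok, center = m$center, scale = m$scale))),
    FDA = {
      F <- features_quad(Xok)
      stats::predict(m$lda, F[, m$keep, drop = FALSE])$posterior[, "1"]
    },
    MARS = predict_hinge_mars(m, Xok),
    MAXENT_like = as.vector(stats::predict(m$cv, features_maxent(Xok),
                                           s = m$lambda, type = "response")),
    SRE = sre_predict(m, Xok)
  )
  out[ok] <- clamp01(as.numeric(p))
  out
}

# ---- surface range envelope (bespoke) ------------------------------------

#' Fit a surface range envelope
#'
#' The classic rectilinear climate envelope: for each variable, the
#' envelope spans the `q` to `1 - q` quantiles (linear-interpolation
#' quantiles) of the presence values. A point is suitable (prediction 1)
#' iff it falls inside the envelope of every variable, else 0.
#'
#' @param presence_covariates matrix/data frame of covariates at presence
#'   points only.
#' @param q tail quantile trimmed from each end (default 0.025).
#' @return object of class `sre_envelope`: per-variable `lo`/`hi` bounds.
#' @export
sre_fit <- function(presence_covariates, q = 0.025) {
  if (!is.numeric(q) || length(q) != 1 || q < 0 || q >= 0.5) {
    abort("`q` must be in [0, 0.5).", class = "ensdm_parameter_error")
  }
  X <- as.matrix(presence_covariates)
  if (nrow(X) < 2) {
    abort("need at least 2 presence rows to fit an envelope.",
          class = "ensdm_fit_error")
  }
  lo <- apply(X, 2, interp_quantile, probs = q)
  hi <- apply(X, 2, interp_quantile, probs = 1 - q)
  structure(list(lo = lo, hi = hi, q = q, variables = colnames(X)),
            class = "sre_envelope")
}

sre_predict <- function(env, X) {
  X <- as.matrix(X)[, env$variables, drop = FALSE]
  inside <- rep(TRUE, nrow(X))
  for (j in seq_along(env$variables)) {
    inside <- inside & X[, j] >= env$lo[j] & X[, j] <= env$hi[j]
  }
  as.numeric(inside)
}

# ---- hinge-basis MARS learner (bespoke) ----------------------------------

# Forward-stagewise selection of reflected hinge-pair basis functions
# (max(0, x - t), max(0, t - x)), with products of up to `degree` hinges,
# by greedy residual-sum-of-squares reduction; final class probabilities
# from a binomial GLM on the selected basis. Knot candidates are interior
# quantiles of each variable.
fit_hinge_mars <- function(X, y, max_terms = 15, n_knots = 7, degree = 2,
                           min_improve = 1e-4) {
  n <- nrow(X); p <- ncol(X)
  knots <- lapply(seq_len(p), function(j) {
    unique(interp_quantile(X[, j], seq(0.05, 0.95, length.out = n_knots)))
  })
  # each term: list of components (var index, knot, dir in {+1,-1});
  # intercept = empty component list
  terms <- list(list())
  B <- matrix(1, n, 1)
  qrB <- qr(B)
  ry <- qr.resid(qrB, y)
  rss <- sum(ry^2)

  term_col <- function(comps) {
    col <- rep(1, n)
    for (cmp in comps) {
      h <- if (cmp$dir > 0) pmax(0, X[, cmp$var] - cmp$knot) else pmax(0, cmp$knot - X[, cmp$var])
      col <- col * h
    }
    col
  }
  term_vars <- function(comps) vapply(comps, function(cmp) cmp$var, integer(1))
  term_degree <- function(comps) length(comps)

  while (ncol(B) + 2 <= max_terms + 1) {
    best <- list(red = 0)
    for (ti in seq_along(terms)) {
      comps <- terms[[ti]]
      if (term_degree(comps) >= degree) next
      parent_col <- if (ti == 1) rep(1, n) else B[, ti]
      used <- if (length(comps)) term_vars(comps) else integer(0)
      for (v in setdiff(seq_len(p), used)) {
        xv <- X[, v]
        for (t in knots[[v]]) {
          c1 <- parent_col * pmax(0, xv - t)
          c2 <- parent_col * pmax(0, t - xv)
          rc <- qr.resid(qrB, cbind(c1, c2))
          # RSS reduction from regressing residual y on residualised pair
          G <- crossprod(rc)
          gy <- crossprod(rc, ry)
          keep <- diag(G) > 1e-8 * n
          if (!any(keep)) next
          Gk <- G[keep, keep, drop = FALSE]
          gyk <- gy[keep, , drop = FALSE]
          sol <- tryCatch(solve(Gk, gyk), error = function(e) NULL)
          if (is.null(sol)) next
          red <- sum(gyk * sol)
          if (red > best$red) {
            best <- list(red = red, parent = ti, var = v, knot = t,
                         cols = cbind(c1, c2)[, keep, drop = FALSE],
                         dirs = c(1, -1)[keep])
          }
        }
      }
    }
    if (best$red <= min_improve * rss) break
    for (k in seq_along(best$dirs)) {
      comps <- c(terms[[best$parent]],
                 list(list(var = best$var, knot = best$knot, dir = best$dirs[k])))
      terms[[length(terms) + 1]] <- comps
    }
    B <- cbind(B, best$cols)
    qrB <- qr(B)
    ry <- qr.resid(qrB, y)
    new_rss <- sum(ry^2)
    if (rss - new_rss <= min_improve * rss) {
      rss <- new_rss
      break
    }
    rss <- new_rss
  }

  coefs <- ridge_logistic(B, y)
  list(terms = terms, coefficients = coefs, variables = colnames(X))
}

# IRLS logistic regression with a light ridge penalty (intercept
# unpenalised); the penalty keeps coefficients finite when the hinge basis
# separates the classes perfectly.
ridge_logistic <- function(B, y, lambda = 1e-2, maxit = 50) {
  p <- ncol(B)
  beta <- numeric(p)
  pen <- diag(lambda, p)
  pen[1, 1] <- 0
  for (it in seq_len(maxit)) {
    eta <- drop(B %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-6)
    z <- eta + (y - mu) / w
    beta_new <- tryCatch(
      drop(solve(crossprod(B, w * B) + pen, crossprod(B, w * z))),
      error = function(e) beta)
    if (max(abs(beta_new - beta)) < 1e-8) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  unname(beta)
}

predict_hinge_mars <- function(fit, X) {
  X <- as.matrix(X)[, fit$variables, drop = FALSE]
  n <- nrow(X)
  eta <- rep(0, n)
  for (ti in seq_along(fit$terms)) {
    comps <- fit$terms[[ti]]
    col <- rep(1, n)
    for (cmp in comps) {
      h <- if (cmp$dir > 0) pmax(0, X[, cmp$var] - cmp$knot) else pmax(0, cmp$knot - X[, cmp$var])
      col <- col * h
    }
    eta <- eta + fit$coefficients[ti] * col
  }
  stats::plogis(eta)
}

# ---- persistence ---------------------------------------------------------

#' Save / load a fitted model
#'
#' Persists an [fit_sdm] result as a small JSON descriptor (spec,
#' variables, training summary, format version) plus an RDS sidecar with
#' the opaque learner internals.
#'
#' @param fit an `sdm_fit`.
#' @param path basename; writes `<path>.json` and `<path>.rds`.
#' @return `path`, invisibly.
#' @export
save_sdm <- function(fit, path) {
  jsonlite::write_json(
    list(format_version = 1L, model = fit$spec$name, seed = fit$spec$seed,
         hyper = fit$spec$hyper, variables = fit$variables,
         n_presence = fit$n_presence, n_absence = fit$n_absence),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(fit, paste0(path, ".rds"))
  invisible(path)
}

#' @rdname save_sdm
#' @export
load_sdm <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  if (!identical(meta$format_version, 1L) && !identical(meta$format_version, 1)) {
    abort("unsupported model format version.", class = "ensdm_format_error")
  }
  readRDS(paste0(path, ".rds"))
}
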