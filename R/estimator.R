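# Six-fold cross-validated two-step stacked regression: four step-1 models
# (linear, random forest, neural network, 1-D convolutional network) whose
# out-of-fold predictions are combined by a step-2 random forest.

#' Build a cross-validation fold plan
#'
#' `by_observation` shuffles observations into folds whose sizes differ by
#' at most one (150 samples over 6 folds gives exactly 125 train / 25 test
#' per fold). `by_participant` keeps every observation of a participant in
#' one fold — the leakage-safe alternative when several vowels per speaker
#' enter the data.
#'
#' @param n Number of observations.
#' @param mode `"by_observation"` or `"by_participant"`.
#' @param seed Integer seed (folds are deterministic given it).
#' @param n_folds Number of folds (default 6).
#' @param participant_ids Required for `by_participant`; length `n`.
#' @return List of class `fold_plan` with `fold` (integer per observation),
#'   `n_folds`, `mode`.
#' @export
make_folds <- function(n, mode = c("by_observation", "by_participant"),
                       seed = 1L, n_folds = 6L, participant_ids = NULL) {
  mode <- match.arg(mode)
  if (n < n_folds) stop("make_folds: need at least ", n_folds, " observations")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(child_seed(seed, "folds"))
  if (mode == "by_observation") {
    fold <- sample(rep(seq_len(n_folds), length.out = n))
  } else {
    if (is.null(participant_ids) || length(participant_ids) != n)
      stop("make_folds: participant_ids required for by_participant mode")
    ids <- unique(participant_ids)
    pf <- setNames(sample(rep(seq_len(n_folds), length.out = length(ids))), ids)
    fold <- unname(pf[as.character(participant_ids)])
  }
  structure(list(fold = as.integer(fold), n_folds = n_folds, mode = mode),
            class = "fold_plan")
}

# Standardize with training-fold statistics; standardized values are
# clipped to +/- 6 so that features nearly constant in the training fold
# (zero-heavy chroma bins, sentinel-imputed formants) cannot blow up
# linear or neural predictions on unseen folds.
.standardizer <- function(x, clip = 6) {
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  sd_[sd_ < 1e-12] <- 1
  list(mu = mu, sd = sd_,
       apply = function(z) {
         z <- sweep(sweep(as.matrix(z), 2, mu), 2, sd_, "/")
         pmin(pmax(z, -clip), clip)
       })
}

# Linear regression by truncated-SVD least squares. With 106 correlated
# features and ~125 training rows, plain least squares near-interpolates
# (the feature set even contains exact dependencies: relative powers and
# chroma fractions sum to one) and its predictions explode on unseen
# folds. Directions with singular values below `tol` of the largest are
# discarded, which keeps the fit well-conditioned; the default retains
# roughly two thirds of the spectrum on cohort-sized data.
.lstsq_fit <- function(x, y, tol = 0.03) {
  X <- cbind(1, x)
  sv <- svd(X)
  keep <- sv$d > tol * sv$d[1]
  coef <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], y)) / sv$d[keep])
  list(coef = as.numeric(coef))
}

.lstsq_predict <- function(model, x) {
  as.numeric(cbind(1, x) %*% model$coef)
}

# median imputation fitted on the training fold only
.imputer <- function(x) {
  med <- apply(x, 2, function(col) stats::median(col, na.rm = TRUE))
  med[!is.finite(med)] <- 0
  function(z) {
    z <- as.matrix(z)
    for (j in seq_len(ncol(z))) z[!is.finite(z[, j]), j] <- med[j]
    z
  }
}

#' Fit the four step-1 regressors
#'
#' Fits (a) linear regression (truncated-SVD least squares, conditioned
#' for the p ~ n regime), (b) a 500-tree random forest, (c) the
#' two-hidden-layer neural network of [fit_mlp()] and (d) the 1-D
#' convolutional network of [fit_cnn()] on one training fold. Features are
#' median-imputed and standardized with training-fold statistics only; the
#' same transform is carried in the returned object for prediction.
#'
#' @param x Training feature matrix (rows = observations, 106 ordered
#'   columns).
#' @param y Training PAP diameters, mm.
#' @param seed Integer seed for the stochastic models.
#' @param config Optional list overriding model settings: `rf_ntree`,
#'   `mlp_epochs`, `cnn_epochs`.
#' @return List of class `step1_models`.
#' @export
fit_step1 <- function(x, y, seed = 1L, config = list()) {
  x <- as.matrix(x)
  if (nrow(x) < 20) stop("fit_step1: need at least 20 training samples")
  cfg <- utils::modifyList(list(rf_ntree = 500, mlp_epochs = 500,
                                cnn_epochs = 500, lin_tol = 0.03), config)
  cn <- if (is.null(colnames(x))) paste0("f", seq_len(ncol(x))) else colnames(x)
  bad <- cn[apply(x, 2, function(col) any(is.infinite(col)) || all(is.na(col)))]
  if (length(bad))
    stop("fit_step1: non-finite feature values in: ", paste(bad, collapse = ", "))
  imp <- .imputer(x)   # NA sentinels are median-imputed, train stats only
  xi <- imp(x)
  std <- .standardizer(xi)
  xs <- std$apply(xi)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  lin <- .lstsq_fit(xs, y, tol = cfg$lin_tol)
  set.seed(child_seed(seed, "forest"))
  rf <- randomForest::randomForest(xs, y, ntree = cfg$rf_ntree)
  set.seed(child_seed(seed, "ann"))
  ann <- fit_mlp(xs, y, epochs = cfg$mlp_epochs)
  set.seed(child_seed(seed, "cnn"))
  cnn <- fit_cnn(xs, y, epochs = cfg$cnn_epochs)
  structure(list(impute = imp, standardize = std, linear = lin, forest = rf,
                 ann = ann, cnn = cnn), class = "step1_models")
}

#' Predict from the four step-1 models
#'
#' @param object A [fit_step1()] result.
#' @param newdata Feature matrix.
#' @param ... Unused.
#' @return Matrix with columns `linear`, `forest`, `ann`, `cnn` (mm).
#' @export
predict.step1_models <- function(object, newdata, ...) {
  xs <- object$standardize$apply(object$impute(as.matrix(newdata)))
  cbind(linear = .lstsq_predict(object$linear, xs),
        forest = unname(stats::predict(object$forest, xs)),
        ann = predict(object$ann, xs),
        cnn = predict(object$cnn, xs))
}

#' Fit the step-2 combiner
#'
#' Random forest regression on the four step-1 out-of-fold prediction
#' columns. Must only ever be given out-of-fold predictions, otherwise the
#' stack leaks.
#'
#' @param step1_oof Matrix with columns `linear`, `forest`, `ann`, `cnn`.
#' @param y Target PAP diameters aligned with the rows.
#' @param seed Integer seed.
#' @param ntree Trees (default 500).
#' @return A `randomForest` combiner.
#' @export
fit_step2 <- function(step1_oof, y, seed = 1L, ntree = 500) {
  step1_oof <- as.matrix(step1_oof)
  if (nrow(step1_oof) != length(y))
    stop("fit_step2: prediction rows and targets misaligned")
  if (is.null(colnames(step1_oof)) ||
      !identical(colnames(step1_oof), c("linear", "forest", "ann", "cnn")))
    stop("fit_step2: expected columns linear, forest, ann, cnn")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(child_seed(seed, "step2"))
  randomForest::randomForest(step1_oof, y, ntree = ntree)
}

#' Cross-validated stacked estimation of PAP diameter
#'
#' Runs the full two-step scheme: per fold, the four step-1 models are fit
#' on the training folds and predict the held-out fold; the step-2 random
#' forest is then trained, per fold, on the out-of-fold step-1 predictions
#' of the other folds and predicts the held-out fold, so no prediction ever
#' sees its own target during training.
#'
#' @param features Feature matrix or the data.frame from
#'   [extract_features()] (feature columns are selected by name).
#' @param pap Numeric PAP targets (mm) aligned with rows, or a PAP table
#'   with `participant_id`, `vowel`, `pap_mm` to be joined.
#' @param folds A [make_folds()] plan, or `NULL` to build one.
#' @param mode,seed,n_folds Passed to [make_folds()] when `folds` is `NULL`.
#' @param config Model settings passed to [fit_step1()].
#' @return List of class `estimation_result`: `predictions` (data.frame
#'   with fold, target and the five prediction columns), `per_fold`
#'   (RMSE and r per model per fold), `overall` (pooled out-of-fold RMSE
#'   and r per model).
#' @export
estimate_pap <- function(features, pap, folds = NULL,
                         mode = "by_observation", seed = 1L, n_folds = 6L,
                         config = list()) {
  if (is.data.frame(features) && "participant_id" %in% names(features)) {
    if (is.data.frame(pap)) {
      m <- merge(features, pap[, c("participant_id", "vowel", "pap_mm")],
                 by = c("participant_id", "vowel"))
      y <- m$pap_mm
      ids <- m$participant_id
      x <- as.matrix(m[, intersect(feature_names(), names(m)), drop = FALSE])
    } else {
      y <- as.numeric(pap)
      ids <- features$participant_id
      x <- as.matrix(features[, intersect(feature_names(), names(features)),
                              drop = FALSE])
    }
  } else {
    x <- as.matrix(features)
    y <- as.numeric(pap)
    ids <- NULL
  }
  stopifnot(nrow(x) == length(y))
  if (is.null(folds))
    folds <- make_folds(nrow(x), mode = mode, seed = seed,
                        n_folds = n_folds, participant_ids = ids)
  k <- folds$n_folds
  oof <- matrix(NA_real_, nrow(x), 4,
                dimnames = list(NULL, c("linear", "forest", "ann", "cnn")))
  for (f in seq_len(k)) {
    tr <- folds$fold != f
    models <- fit_step1(x[tr, , drop = FALSE], y[tr],
                        seed = child_seed(seed, paste0("fold", f)),
                        config = config)
    oof[!tr, ] <- predict(models, x[!tr, , drop = FALSE])
  }
  stacked <- rep(NA_real_, nrow(x))
  for (f in seq_len(k)) {
    tr <- folds$fold != f
    comb <- fit_step2(oof[tr, , drop = FALSE], y[tr],
                      seed = child_seed(seed, paste0("comb", f)),
                      ntree = utils::modifyList(list(rf_ntree = 500),
                                                config)$rf_ntree)
    stacked[!tr] <- stats::predict(comb, oof[!tr, , drop = FALSE])
  }
  preds <- data.frame(fold = folds$fold, pap_mm = y, oof,
                      stacked = stacked)
  evaluate_estimation(preds)
}

#' Evaluate stacked-estimation predictions
#'
#' RMSE (mm) and Pearson r of each model's pooled out-of-fold predictions,
#' plus per-fold values reported as mean and SD across folds. Zero-variance
#' predictions give a missing r with a warning.
#'
#' @param predictions data.frame with `fold`, `pap_mm` and prediction
#'   columns (`linear`, `forest`, `ann`, `cnn`, `stacked`).
#' @return List of class `estimation_result` with `predictions`,
#'   `per_fold`, `overall`.
#' @export
evaluate_estimation <- function(predictions) {
  model_cols <- setdiff(names(predictions), c("fold", "pap_mm"))
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  safe_r <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("evaluate_estimation: zero-variance predictions; r is NA")
      return(NA_real_)
    }
    stats::cor(a, b)
  }
  overall <- do.call(rbind, lapply(model_cols, function(mc)
    data.frame(model = mc,
               rmse = rmse(predictions[[mc]], predictions$pap_mm),
               r = safe_r(predictions[[mc]], predictions$pap_mm))))
  per_fold <- do.call(rbind, lapply(model_cols, function(mc) {
    do.call(rbind, lapply(sort(unique(predictions$fold)), function(f) {
      s <- predictions[predictions$fold == f, ]
      data.frame(model = mc, fold = f,
                 rmse = rmse(s[[mc]], s$pap_mm),
                 r = suppressWarnings(safe_r(s[[mc]], s$pap_mm)))
    }))
  }))
  structure(list(predictions = predictions, per_fold = per_fold,
                 overall = overall),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat("Stacked PAP estimation (pooled out-of-fold):\n")
  agg <- merge(
    stats::aggregate(cbind(rmse, r) ~ model, x$per_fold, mean),
    x$overall, by = "model", suffixes = c("_fold_mean", "_overall"))
  print(agg[match(c("linear", "forest", "ann", "cnn", "stacked"), agg$model), ],
        row.names = FALSE, digits = 3)
  invisible(x)
}
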