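#' Ventilation features always kept in the mortality model
#'
#' @return Character vector of mandatory feature names: mechanical power,
#'   IBW-normalised MP, tidal volume per kg IBW, 48-h SD of MP, PEEP,
#'   respiratory rate, driving pressure.
#' @export
mandatory_features <- function() {
  c("mp", "mp_ibw", "tv_mlkg", "sd48_mp", "peep", "rr", "dp")
}

#' Assemble the modelling feature table
#'
#' Joins 48-hour time-weighted ventilation features (renamed to the canonical
#' model names `mp`, `mp_ibw`, `tv_mlkg`, `sd48_mp`, `peep`, `rr`, `dp`, plus
#' `ve` and `pfr`) with demographics and laboratory values, one row per
#' admission.
#'
#' @param admissions Admission table including labs and `icu_mortality`.
#' @param twa_features Output of [build_twa_features()].
#' @param window_h Which window feeds the model (default 48).
#' @return Data frame with an `admission_id` column, an `icu_mortality`
#'   outcome column, and numeric features.
#' @export
assemble_features <- function(admissions, twa_features, window_h = 48) {
  tf <- twa_features[twa_features$window_h == window_h, , drop = FALSE]
  feat <- data.frame(
    admission_id = tf$admission_id,
    mp = tf$twa_mp,
    mp_ibw = tf$twa_mp_ibw,
    tv_mlkg = tf$twa_tv_mlkg,
    sd48_mp = tf$sd48_mp,
    peep = tf$twa_peep,
    rr = tf$twa_rr,
    dp = tf$twa_dp,
    ve = tf$twa_tv_L * tf$twa_rr,
    pfr = tf$twa_pfr,
    stringsAsFactors = FALSE
  )
  # non-numeric columns and outcome-adjacent times (follow-up, total MV
  # duration) are not predictors
  drop_cols <- c("sex", "specialty", "stratum_true", "followup_days",
                 "mv_duration_h")
  adm <- admissions[, setdiff(names(admissions), drop_cols), drop = FALSE]
  out <- merge(feat, adm, by = "admission_id")
  out
}

#' Drop highly cross-correlated features
#'
#' Greedy scan in column order: for every pair with absolute Pearson
#' correlation above `threshold`, the later column is dropped unless it is
#' mandatory (mandatory columns are never dropped). Constant columns have no
#' defined correlation and are dropped with a note.
#'
#' @param feature_table Numeric feature columns (non-numeric columns are
#'   ignored and retained).
#' @param threshold Absolute correlation above which the later feature is
#'   removed (default 0.9).
#' @param mandatory Protected features, default [mandatory_features()].
#' @return A `feature_spec` list: `mandatory` (present protected features),
#'   `kept` (all surviving feature names, in column order), `pruned` (data
#'   frame `feature`, `partner`; `partner` is `"constant"` for undefined
#'   columns), `selected` (empty until [select_top_features()]).
#' @export
prune_correlated <- function(feature_table, threshold = 0.9,
                             mandatory = mandatory_features()) {
  num <- names(feature_table)[vapply(feature_table, is.numeric, logical(1))]
  num <- setdiff(num, "icu_mortality")
  pruned <- data.frame(feature = character(0), partner = character(0),
                       stringsAsFactors = FALSE)
  # complete-observation correlations; constants are undefined
  keep <- character(0)
  for (v in num) {
    x <- feature_table[[v]]
    if (stats::sd(x, na.rm = TRUE) == 0 || all(is.na(x))) {
      if (!v %in% mandatory) {
        pruned <- rbind(pruned, data.frame(feature = v, partner = "constant",
                                           stringsAsFactors = FALSE))
        next
      }
    }
    partner <- NULL
    for (u in keep) {
      r <- suppressWarnings(stats::cor(feature_table[[u]], x,
                                       use = "pairwise.complete.obs"))
      if (is.finite(r) && abs(r) > threshold) {
        partner <- u
        break
      }
    }
    if (is.null(partner) || v %in% mandatory) {
      keep <- c(keep, v)
    } else {
      pruned <- rbind(pruned, data.frame(feature = v, partner = partner,
                                         stringsAsFactors = FALSE))
    }
  }
  structure(list(mandatory = intersect(mandatory, keep), kept = keep,
                 pruned = pruned, selected = character(0)),
            class = "feature_spec")
}

#' Select top additional features by random-forest importance
#'
#' Ranks the non-mandatory surviving features by impurity-based importance
#' from a seeded random forest and keeps the top `k`, appended to the
#' mandatory ventilation set.
#'
#' @param feature_table Feature table (rows complete for the used columns).
#' @param outcome 0/1 outcome vector aligned with `feature_table` rows.
#' @param spec A `feature_spec` from [prune_correlated()].
#' @param k Number of additional features (default 10).
#' @param seed RNG seed for the forest.
#' @param method `"impurity"` (default) or `"permutation"`.
#' @return The `feature_spec` with `selected` filled (length `min(k,`
#'   candidates`)`; a note attribute marks short selections).
#' @export
select_top_features <- function(feature_table, outcome, spec, k = 10,
                                seed = 1, method = c("impurity", "permutation")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "feature_spec"))
  candidates <- setdiff(spec$kept, spec$mandatory)
  if (length(candidates) == 0) {
    spec$selected <- character(0)
    return(spec)
  }
  X <- feature_table[, candidates, drop = FALSE]
  cc <- stats::complete.cases(X) & !is.na(outcome)
  with_preserved_seed(seed, {
    rf <- randomForest::randomForest(
      x = X[cc, , drop = FALSE], y = factor(outcome[cc]),
      importance = (method == "permutation"))
  })
  imp <- if (method == "permutation") {
    randomForest::importance(rf, type = 1)[, 1]
  } else {
    randomForest::importance(rf, type = 2)[, 1]
  }
  ranked <- names(sort(imp, decreasing = TRUE))
  spec$selected <- utils::head(ranked, k)
  if (length(candidates) < k) {
    attr(spec, "note") <- "fewer candidate features than requested"
  }
  spec
}

#' Features used for model fitting
#'
#' @param spec A `feature_spec`.
#' @return Mandatory plus selected feature names.
#' @export
model_features <- function(spec) {
  unique(c(spec$mandatory, spec$selected))
}

#' Synthetic minority oversampling (SMOTE)
#'
#' Balances a binary training set by adding synthetic minority rows: each new
#' row is a convex combination of a minority row and one of its `k` nearest
#' minority neighbours (Euclidean distance). Apply to training folds only.
#'
#' @param train_X Numeric feature data frame or matrix.
#' @param train_y 0/1 outcome vector.
#' @param seed RNG seed; the result is deterministic per seed.
#' @param k Number of minority neighbours (default 5).
#' @return List `X`, `y` with equal class counts; original rows come first.
#' @export
balance_minority <- function(train_X, train_y, seed = 1, k = 5) {
  X <- as.matrix(train_X)
  y <- as.integer(train_y)
  tab <- table(factor(y, levels = c(0, 1)))
  if (any(tab == 0)) stop("both classes must be present", call. = FALSE)
  minority <- as.integer(names(tab)[which.min(tab)])
  n_needed <- abs(tab[[1]] - tab[[2]])
  if (n_needed == 0) {
    return(list(X = as.data.frame(X), y = y))
  }
  min_idx <- which(y == minority)
  if (length(min_idx) < 2) {
    stop("minority class has fewer than 2 rows; cannot interpolate",
         call. = FALSE)
  }
  M <- X[min_idx, , drop = FALSE]
  d <- as.matrix(stats::dist(M))
  diag(d) <- Inf
  k_eff <- min(k, nrow(M) - 1)
  nn <- apply(d, 1, function(r) order(r)[seq_len(k_eff)], simplify = FALSE)

  with_preserved_seed(seed, {
    base_i <- sample(seq_len(nrow(M)), n_needed, replace = TRUE)
    pick <- vapply(base_i, function(i) nn[[i]][sample.int(k_eff, 1)], integer(1))
    gap <- stats::runif(n_needed)
  })
  synth <- M[base_i, , drop = FALSE] +
    gap * (M[pick, , drop = FALSE] - M[base_i, , drop = FALSE])
  out_X <- rbind(X, synth)
  rownames(out_X) <- NULL
  list(X = as.data.frame(out_X), y = c(y, rep(minority, n_needed)))
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, globalenv())
    }
  })
  eval.parent(substitute(expr))
}

model_names <- function() {
  c("logistic", "random_forest", "svm", "adaboost", "xgboost", "stacking")
}

#' Fit one mortality model
#'
#' Standardises the features (centre/scale learned from the supplied data),
#' optionally balances the classes with [balance_minority()], and fits the
#' requested classifier with library-default settings.
#'
#' @param X Numeric feature data frame.
#' @param y 0/1 outcome (1 = ICU death).
#' @param model One of `"logistic"`, `"random_forest"`, `"svm"`,
#'   `"adaboost"`, `"xgboost"`, `"stacking"`.
#' @param seed RNG seed.
#' @param balance Oversample the minority class before fitting (default
#'   TRUE).
#' @return Object of class `mortality_fit`.
#' @export
fit_mortality_model <- function(X, y, model = model_names(), seed = 1,
                                balance = TRUE) {
  model <- match.arg(model)
  X <- as.data.frame(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  center <- vapply(X, mean, numeric(1))
  scale <- vapply(X, stats::sd, numeric(1))
  scale[!is.finite(scale) | scale == 0] <- 1
  Z <- as.data.frame(scale(X, center = center, scale = scale))
  if (balance) {
    bal <- balance_minority(Z, y, seed = seed)
    Z <- bal$X
    y <- bal$y
  }
  fit <- with_preserved_seed(seed, fit_engine(model, Z, y, seed))
  structure(list(model_name = model, fit = fit, features = names(X),
                 center = center, scale = scale, seed = seed),
            class = "mortality_fit")
}

fit_engine <- function(model, Z, y, seed) {
  switch(model,
    logistic = stats::glm(y ~ ., data = cbind(Z, y = y),
                          family = stats::binomial()),
    random_forest = randomForest::randomForest(x = Z, y = factor(y)),
    svm = e1071::svm(x = as.matrix(Z), y = factor(y), probability = TRUE),
    adaboost = ada_fit(Z, y),
    xgboost = xgboost::xgb.train(
      params = list(objective = "binary:logistic", nthread = 1),
      data = xgboost::xgb.DMatrix(as.matrix(Z), label = y, nthread = 1),
      nrounds = 100, verbose = 0),
    stacking = stack_fit(Z, y, seed)
  )
}

# Discrete AdaBoost (SAMME) over depth-1 rpart stumps.
ada_fit <- function(Z, y, n_rounds = 50) {
  n <- length(y)
  w <- rep(1 / n, n)
  yf <- factor(y, levels = c(0, 1))
  df <- cbind(Z, .y = yf)
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    stump <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                          control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                         minsplit = 2, xval = 0))
    pred <- as.integer(as.character(stats::predict(stump, df, type = "class")))
    miss <- pred != y
    err <- sum(w[miss])
    if (err >= 0.5) break
    if (err == 0) {
      stumps[[length(stumps) + 1L]] <- stump
      alphas <- c(alphas, 10)
      break
    }
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- stump
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * ifelse(miss, 1, -1))
    w <- w / sum(w)
  }
  if (length(stumps) == 0) {
    # no weak learner beats chance; fall back to the prior
    return(list(stumps = list(), alphas = numeric(0), prior = mean(y)))
  }
  list(stumps = stumps, alphas = alphas, prior = mean(y))
}

ada_predict <- function(fit, Z) {
  if (length(fit$stumps) == 0) {
    return(rep(fit$prior, nrow(Z)))
  }
  score <- rep(0, nrow(Z))
  for (m in seq_along(fit$stumps)) {
    pred <- as.integer(as.character(
      stats::predict(fit$stumps[[m]], Z, type = "class")))
    score <- score + fit$alphas[m] * (2 * pred - 1)
  }
  # monotone logistic link on the ensemble margin; ranking- and
  # class-consistent with the vote sign
  stats::plogis(2 * score)
}

# Stacking: base classifiers feed a logistic meta-learner trained on
# out-of-fold base probabilities.
stack_fit <- function(Z, y, seed, base = c("logistic", "random_forest",
                                           "xgboost", "adaboost"),
                      inner_folds = 3) {
  fold <- stratified_folds(y, inner_folds, seed = seed + 17L)
  oof <- matrix(NA_real_, nrow(Z), length(base),
                dimnames = list(NULL, base))
  for (f in seq_len(inner_folds)) {
    tr <- fold != f
    for (b in base) {
      bf <- with_preserved_seed(seed + f, fit_engine(b, Z[tr, , drop = FALSE],
                                                     y[tr], seed + f))
      oof[!tr, b] <- engine_predict(b, bf, Z[!tr, , drop = FALSE])
    }
  }
  meta_df <- as.data.frame(oof)
  meta <- stats::glm(y ~ ., data = cbind(meta_df, y = y),
                     family = stats::binomial())
  full_base <- lapply(stats::setNames(nm = base), function(b) {
    with_preserved_seed(seed, fit_engine(b, Z, y, seed))
  })
  list(base = full_base, meta = meta, base_names = base)
}

stack_predict <- function(fit, Z) {
  probs <- vapply(fit$base_names, function(b) {
    engine_predict(b, fit$base[[b]], Z)
  }, numeric(nrow(Z)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1,
                                           dimnames = list(NULL, fit$base_names))
  nd <- as.data.frame(probs)
  as.numeric(stats::predict(fit$meta, newdata = nd, type = "response"))
}

engine_predict <- function(model, fit, Z) {
  switch(model,
    logistic = as.numeric(stats::predict(fit, newdata = Z, type = "response")),
    random_forest = as.numeric(stats::predict(fit, Z, type = "prob")[, "1"]),
    svm = {
      pr <- stats::predict(fit, as.matrix(Z), probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, "1"])
    },
    adaboost = ada_predict(fit, Z),
    xgboost = as.numeric(stats::predict(fit, as.matrix(Z))),
    stacking = stack_predict(fit, Z)
  )
}

#' Predicted death probability
#'
#' @param object A `mortality_fit`.
#' @param newdata Data frame containing the model's feature columns.
#' @param type `"prob"` (default) for P(death) or `"class"` for the 0/1
#'   prediction at `cut`.
#' @param cut Classification cut-point (default 0.5).
#' @param ... Unused.
#' @return Numeric (prob) or integer (class) vector.
#' @export
predict.mortality_fit <- function(object, newdata, type = c("prob", "class"),
                                  cut = 0.5, ...) {
  type <- match.arg(type)
  missing_cols <- setdiff(object$features, names(newdata))
  if (length(missing_cols) > 0) {
    stop("newdata lacks feature column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  X <- as.data.frame(newdata)[, object$features, drop = FALSE]
  Z <- as.data.frame(scale(X, center = object$center, scale = object$scale))
  p <- engine_predict(object$model_name, object$fit, Z)
  if (type == "prob") p else as.integer(p >= cut)
}

stratified_folds <- function(y, folds, seed) {
  fold <- integer(length(y))
  with_preserved_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  fold
}

#' Cross-validated evaluation of the model suite
#'
#' Stratified k-fold cross-validation of the six-classifier suite. Minority
#' oversampling and feature standardisation are fitted inside each training
#' fold only; metrics (accuracy, precision, recall, AUROC at the 0.5 cut) are
#' computed on the untouched test folds and averaged over folds.
#'
#' @param feature_table Data frame with the model features.
#' @param outcome 0/1 outcome vector.
#' @param features Feature columns to use (default: numeric columns except
#'   the outcome and id).
#' @param folds Number of folds (default 5, >= 2).
#' @param seed RNG seed governing folds, oversampling and every model fit.
#' @param models Which models to run (default all six).
#' @return List of class `model_suite`: `reports` (data frame: model,
#'   accuracy, precision, recall, auroc), `fold_metrics` (per-fold rows),
#'   `folds`, `seed`.
#' @export
run_suite <- function(feature_table, outcome, features = NULL, folds = 5,
                      seed = 1, models = model_names()) {
  stopifnot(folds >= 2)
  y <- as.integer(outcome)
  if (is.null(features)) {
    features <- setdiff(
      names(feature_table)[vapply(feature_table, is.numeric, logical(1))],
      c("icu_mortality", "admission_id"))
  }
  X <- feature_table[, features, drop = FALSE]
  cc <- stats::complete.cases(X) & !is.na(y)
  X <- X[cc, , drop = FALSE]
  y <- y[cc]
  if (min(table(y)) < folds) {
    stop("too few observations in a class for ", folds, "-fold stratification",
         call. = FALSE)
  }
  fold <- stratified_folds(y, folds, seed)

  fold_rows <- list()
  for (model in models) {
    for (f in seq_len(folds)) {
      tr <- fold != f
      fit <- fit_mortality_model(X[tr, , drop = FALSE], y[tr], model = model,
                                 seed = seed + f, balance = TRUE)
      p <- predict(fit, X[!tr, , drop = FALSE], type = "prob")
      m <- classification_metrics(y[!tr], p)
      fold_rows[[length(fold_rows) + 1L]] <- data.frame(
        model = model, fold = f, accuracy = m["accuracy"],
        precision = m["precision"], recall = m["recall"],
        auroc = m["auroc"], stringsAsFactors = FALSE)
    }
  }
  fold_metrics <- do.call(rbind, fold_rows)
  rownames(fold_metrics) <- NULL
  reports <- do.call(rbind, lapply(split(fold_metrics, fold_metrics$model),
    function(d) {
      data.frame(model = d$model[1],
                 accuracy = mean(d$accuracy), precision = mean(d$precision,
                                                               na.rm = TRUE),
                 recall = mean(d$recall), auroc = mean(d$auroc),
                 stringsAsFactors = FALSE)
    }))
  reports <- reports[match(models, reports$model), , drop = FALSE]
  rownames(reports) <- NULL
  structure(list(reports = reports, fold_metrics = fold_metrics,
                 folds = folds, seed = seed, features = features),
            class = "model_suite")
}

classification_metrics <- function(y, p, cut = 0.5) {
  pred <- as.integer(p >= cut)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  auroc <- if (length(unique(y)) < 2) NA_real_ else {
    as.numeric(pROC::auc(pROC::roc(response = y, predictor = p,
                                   quiet = TRUE, direction = "<",
                                   levels = c(0, 1))))
  }
  c(accuracy = mean(pred == y),
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    auroc = auroc)
}

#' Feature-attribution ranking for a fitted model
#'
#' For the boosted-trees model, per-row additive attributions (TreeSHAP) are
#' computed and features are ranked by mean absolute attribution; the
#' attributions per row sum to the margin prediction minus the baseline. For
#' models without attribution support, seeded permutation importance (AUROC
#' drop) is used and flagged.
#'
#' @param fit A `mortality_fit`.
#' @param feature_table Data frame with the model's feature columns.
#' @param outcome 0/1 outcome; required for the permutation fallback.
#' @param seed Seed for the permutation fallback.
#' @return Data frame (`feature`, `score`) sorted decreasing, with attribute
#'   `method` (`"shap"` or `"permutation"`) and, for SHAP, attribute
#'   `max_additivity_residual`.
#' @export
importance_ranking <- function(fit, feature_table, outcome = NULL, seed = 1) {
  stopifnot(inherits(fit, "mortality_fit"))
  X <- as.data.frame(feature_table)[, fit$features, drop = FALSE]
  Z <- as.matrix(as.data.frame(scale(X, center = fit$center, scale = fit$scale)))
  if (fit$model_name == "xgboost") {
    contrib <- stats::predict(fit$fit, Z, predcontrib = TRUE)
    margin <- stats::predict(fit$fit, Z, outputmargin = TRUE)
    resid <- max(abs(rowSums(contrib) - margin))
    score <- colMeans(abs(contrib[, fit$features, drop = FALSE]))
    out <- data.frame(feature = names(score), score = unname(score),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$score), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "method") <- "shap"
    attr(out, "max_additivity_residual") <- resid
    return(out)
  }
  if (is.null(outcome)) {
    stop("permutation importance needs the outcome vector", call. = FALSE)
  }
  y <- as.integer(outcome)
  base_p <- predict(fit, X, type = "prob")
  base_auc <- classification_metrics(y, base_p)[["auroc"]]
  score <- with_preserved_seed(seed, {
    vapply(fit$features, function(v) {
      Xp <- X
      Xp[[v]] <- sample(Xp[[v]])
      base_auc - classification_metrics(y, predict(fit, Xp, type = "prob"))[["auroc"]]
    }, numeric(1))
  })
  out <- data.frame(feature = names(score), score = unname(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "method") <- "permutation"
  out
}
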