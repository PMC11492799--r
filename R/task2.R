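# The mechanism task: PS-Self vs PS-Part classification with a
# gradient-boosted tree model and the three-step feature selection
# pipeline — (1) recursive feature elimination under extra-trees
# importance, (2) a split-count importance sweep in steps of 5, and
# (3) incremental forward selection over the remaining sequence-property
# candidates. The positive class is PS-Self throughout.

# --- boosted-tree primitives ---------------------------------------------

xgb_params_default <- function(...) {
  utils::modifyList(
    list(objective = "binary:logistic", max_depth = 6, eta = 0.3,
         nthread = 1),
    list(...)
  )
}

fit_xgb <- function(x, y, nrounds = 100L, params = xgb_params_default()) {
  if (length(unique(y)) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  d <- xgboost::xgb.DMatrix(as.matrix(x), label = as.numeric(y), nthread = 1)
  xgboost::xgb.train(params = params, data = d, nrounds = nrounds,
                     verbose = 0)
}

predict_xgb <- function(fit, x) {
  as.numeric(predict(fit, xgboost::xgb.DMatrix(as.matrix(x), nthread = 1)))
}

xgb_trainer <- function(nrounds = 100L, params = xgb_params_default()) {
  function(x, y) fit_xgb(x, y, nrounds = nrounds, params = params)
}

#' Split-count feature importance of a boosted-tree model
#'
#' Importance of a feature as the number of times it is selected as a weak
#' classifier, i.e. the count of tree splits using it. Scores are
#' non-negative and sum to the total split count of the model; features
#' never used score 0.
#'
#' @param fit An `xgb.Booster`.
#' @param feature_names All candidate feature names (order preserved).
#' @return Named numeric vector of split counts over `feature_names`.
#' @export
split_count_importance <- function(fit, feature_names) {
  tree <- xgboost::xgb.model.dt.tree(model = fit)
  used <- tree$Feature[tree$Feature != "Leaf"]
  counts <- table(factor(used, levels = feature_names))
  stats::setNames(as.numeric(counts), feature_names)
}

# --- stage 0: per-family baselines ---------------------------------------

#' Baseline evaluation of feature families
#'
#' Scores each feature family (e.g. AAC, PS-related, AAIndex-weighted
#' composition) separately with a boosted-tree classifier under stratified
#' 10-fold cross-validation, seed-pinned so families share folds.
#'
#' @param tables Named list of numeric feature matrices with identical,
#'   aligned row names (sequence ids).
#' @param labels 0/1 labels aligned with the table rows (1 = PS-Self).
#' @param k Folds.
#' @param seed Fold seed.
#' @return Data frame: family, dimension and the seven pooled CV metrics.
#' @export
baseline_eval <- function(tables, labels, k = 10L, seed = 1L) {
  stopifnot(is.list(tables), length(tables) >= 1L, !is.null(names(tables)))
  ids <- rownames(tables[[1]])
  for (nm in names(tables)) {
    if (!identical(rownames(tables[[nm]]), ids)) {
      stop("feature table '", nm, "' rows are not aligned with the others",
           call. = FALSE)
    }
    if (nrow(tables[[nm]]) != length(labels)) {
      stop("feature table '", nm, "' row count does not match labels",
           call. = FALSE)
    }
  }
  rows <- lapply(names(tables), function(nm) {
    cv <- kfold_cv(tables[[nm]], labels, trainer = xgb_trainer(),
                   predictor = predict_xgb, k = k, seed = seed)
    cbind(data.frame(family = nm, dimension = ncol(tables[[nm]])),
          as.data.frame(as.list(round(cv$pooled, 6))))
  })
  do.call(rbind, rows)
}

# --- stage 1: recursive feature elimination ------------------------------

#' Recursive feature elimination under extra-trees importance
#'
#' Repeatedly refits an extremely-randomized-trees ranking model and
#' eliminates the least important ~10% of features per round, pausing at
#' each requested target dimension to score the retained subset by
#' cross-validated boosted-tree AUC. Constant (zero-variance) features are
#' eliminated first and reported. The best dimension is the target with
#' the highest CV AUC.
#'
#' @param x Numeric feature matrix.
#' @param labels 0/1 labels.
#' @param target_dims Dimensions at which to evaluate (values above
#'   `ncol(x)` are clipped).
#' @param k,seed Cross-validation folds and seed.
#' @param drop_fraction Fraction eliminated per round (default 0.1).
#' @param num_trees Trees of the ranking forest.
#' @return List: `selected` (names at the best dimension), `best_dim`,
#'   `curve` (data.frame dim/auc/acc), `constant_dropped`, `per_dim`
#'   (named list of retained names per evaluated dimension).
#' @export
rfe_stage <- function(x, labels, target_dims = c(80L, 60L, 40L, 20L, 10L),
                      k = 10L, seed = 1L, drop_fraction = 0.1,
                      num_trees = 300L) {
  x <- as.matrix(x)
  const <- which(apply(x, 2, stats::sd) == 0)
  constant_dropped <- colnames(x)[const]
  if (length(const)) x <- x[, -const, drop = FALSE]
  dims <- sort(unique(pmin(as.integer(target_dims), ncol(x))),
               decreasing = TRUE)
  if (!length(dims) || ncol(x) < min(dims)) {
    stop("feature dimension must not be below the smallest target dimension",
         call. = FALSE)
  }
  rng <- local_rng(seed)
  current <- colnames(x)
  per_dim <- list(); curve <- list()
  for (target in dims) {
    while (length(current) > target) {
      imp <- rng$with_seed(function() {
        fit <- ranger::ranger(
          x = x[, current, drop = FALSE], y = factor(labels),
          num.trees = num_trees, splitrule = "extratrees",
          importance = "impurity", replace = FALSE, sample.fraction = 1,
          num.threads = 1
        )
        fit$variable.importance
      })
      n_drop <- max(1L, round(drop_fraction * length(current)))
      n_drop <- min(n_drop, length(current) - target)
      # stable order: rank by importance, ties by current name order
      ord <- order(imp, seq_along(imp))
      current <- current[-match(names(imp)[ord[seq_len(n_drop)]], current)]
    }
    cv <- kfold_cv(x[, current, drop = FALSE], labels,
                   trainer = xgb_trainer(), predictor = predict_xgb,
                   k = k, seed = seed)
    per_dim[[as.character(target)]] <- current
    curve[[length(curve) + 1L]] <- data.frame(
      dim = target, auc = cv$pooled[["auc"]], acc = cv$pooled[["acc"]])
  }
  curve <- do.call(rbind, curve)
  best_dim <- curve$dim[which.max(curve$auc)]
  list(selected = per_dim[[as.character(best_dim)]], best_dim = best_dim,
       curve = curve, constant_dropped = constant_dropped,
       per_dim = per_dim)
}

# --- stage 2: split-count importance sweep -------------------------------

#' Importance sweep over nested top-k feature subsets
#'
#' Ranks features by split-count importance of a boosted-tree model fitted
#' on the full table (ties broken by stable column order, which is
#' recorded), then evaluates nested subsets of sizes `step, 2*step, ...`
#' by cross-validation. The best subset is the smallest one attaining the
#' maximum AUC.
#'
#' @param x Numeric feature matrix.
#' @param labels 0/1 labels.
#' @param step Subset-size increment (default 5).
#' @param k,seed Cross-validation controls.
#' @return List: `best_features`, `curve` (data.frame n_features/acc/auc,
#'   `ceiling(ncol(x)/step)` rows), `ranking`, `ties_broken` (logical).
#' @export
importance_sweep <- function(x, labels, step = 5L, k = 10L, seed = 1L) {
  x <- as.matrix(x)
  fit <- fit_xgb(x, labels)
  imp <- split_count_importance(fit, colnames(x))
  ties_broken <- anyDuplicated(imp[imp > 0]) > 0
  ranking <- colnames(x)[order(-imp, seq_along(imp))]
  sizes <- unique(pmin(seq(step, by = step,
                           length.out = ceiling(ncol(x) / step)), ncol(x)))
  curve <- lapply(sizes, function(sz) {
    sub <- ranking[seq_len(sz)]
    cv <- kfold_cv(x[, sub, drop = FALSE], labels, trainer = xgb_trainer(),
                   predictor = predict_xgb, k = k, seed = seed)
    data.frame(n_features = sz, acc = cv$pooled[["acc"]],
               auc = cv$pooled[["auc"]])
  })
  curve <- do.call(rbind, curve)
  best_n <- curve$n_features[which.max(curve$auc)]
  list(best_features = ranking[seq_len(best_n)], curve = curve,
       ranking = ranking, ties_broken = ties_broken)
}

# --- stage 3: incremental forward selection ------------------------------

#' Incremental (increasing) feature selection
#'
#' Greedy forward addition over an ordered candidate list: a candidate is
#' kept if and only if it strictly improves the cross-validated AUC of the
#' running feature set.
#'
#' @param base_features Names of the base subset (retained unconditionally).
#' @param candidates Ordered candidate feature names, disjoint from the
#'   base set.
#' @param x Feature matrix containing base and candidate columns.
#' @param labels 0/1 labels.
#' @param k,seed Cross-validation controls.
#' @return List: `final_features`, `trace` (data.frame candidate / auc /
#'   kept), `base_auc`.
#' @export
ifs_stage <- function(base_features, candidates, x, labels, k = 10L,
                      seed = 1L) {
  x <- as.matrix(x)
  candidates <- setdiff(candidates, base_features)
  cv_auc <- function(feats) {
    kfold_cv(x[, feats, drop = FALSE], labels, trainer = xgb_trainer(),
             predictor = predict_xgb, k = k, seed = seed)$pooled[["auc"]]
  }
  current <- base_features
  best_auc <- cv_auc(current)
  base_auc <- best_auc
  trace <- list()
  for (cand in candidates) {
    auc_try <- cv_auc(c(current, cand))
    kept <- auc_try > best_auc
    if (kept) {
      current <- c(current, cand)
      best_auc <- auc_try
    }
    trace[[length(trace) + 1L]] <- data.frame(candidate = cand,
                                              auc = auc_try, kept = kept)
  }
  list(final_features = current,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(candidate = character(0), auc = numeric(0),
                    kept = logical(0)),
       base_auc = base_auc)
}

# --- full pipeline --------------------------------------------------------

#' Three-step feature selection pipeline
#'
#' Runs recursive feature elimination, the split-count importance sweep and
#' incremental forward selection in sequence over a high-dimensional
#' feature table, sharing one seed-pinned fold assignment so the stage
#' curves are comparable. Returns an auditable report. The pipeline is a
#' pure function of (table, labels, candidates, seed).
#'
#' @param x Numeric feature matrix (the high-dimensional family, e.g. the
#'   AAIndex-weighted composition).
#' @param labels 0/1 labels (1 = PS-Self).
#' @param candidates Ordered candidate features for the forward stage
#'   (columns of `extra`, tried in the given order).
#' @param extra Optional matrix of candidate feature columns aligned with
#'   `x` rows.
#' @param target_dims,step,k,seed Stage controls (see [rfe_stage()],
#'   [importance_sweep()], [ifs_stage()]).
#' @return An object of class `selection_report`: list of stage records
#'   (`stage`, `feature_names`, `dimension`, `cv_metrics`) plus
#'   `final_features`.
#' @export
select_features <- function(x, labels, candidates = character(0),
                            extra = NULL,
                            target_dims = c(80L, 60L, 40L, 20L, 10L),
                            step = 5L, k = 10L, seed = 1L) {
  x <- as.matrix(x)
  full <- if (!is.null(extra)) cbind(x, as.matrix(extra)) else x
  stage_cv <- function(feats) {
    round(kfold_cv(full[, feats, drop = FALSE], labels,
                   trainer = xgb_trainer(), predictor = predict_xgb,
                   k = k, seed = seed)$pooled, 6)
  }
  stages <- list()
  stages$baseline <- list(stage = "baseline", feature_names = colnames(x),
                          dimension = ncol(x),
                          cv_metrics = stage_cv(colnames(x)))
  rfe <- rfe_stage(x, labels, target_dims = target_dims, k = k, seed = seed)
  stages$rfe <- list(stage = "rfe", feature_names = rfe$selected,
                     dimension = length(rfe$selected),
                     cv_metrics = stage_cv(rfe$selected),
                     curve = rfe$curve)
  sweep_res <- importance_sweep(x[, rfe$selected, drop = FALSE], labels,
                                step = step, k = k, seed = seed)
  stages$importance_sweep <- list(stage = "importance_sweep",
                                  feature_names = sweep_res$best_features,
                                  dimension = length(sweep_res$best_features),
                                  cv_metrics = stage_cv(sweep_res$best_features),
                                  curve = sweep_res$curve)
  ifs <- ifs_stage(sweep_res$best_features, candidates, full, labels,
                   k = k, seed = seed)
  stages$ifs <- list(stage = "ifs", feature_names = ifs$final_features,
                     dimension = length(ifs$final_features),
                     cv_metrics = stage_cv(ifs$final_features),
                     trace = ifs$trace)
  structure(list(stages = stages, final_features = ifs$final_features,
                 seed = seed, k = k),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Three-step feature selection report (k =", x$k, ", seed =", x$seed, ")\n")
  for (st in x$stages) {
    cat(sprintf("  %-17s dim %4d  AUC %.3f  Acc %.3f\n", st$stage,
                st$dimension, st$cv_metrics[["auc"]], st$cv_metrics[["acc"]]))
  }
  cat("  final features:", length(x$final_features), "\n")
  invisible(x)
}

#' Serialize a selection report to JSON
#'
#' @param report A `selection_report`.
#' @param path Optional output file.
#' @return JSON string, invisibly if written to `path`.
#' @export
selection_report_json <- function(report, path = NULL) {
  payload <- list(
    seed = report$seed, k = report$k,
    final_features = report$final_features,
    stages = lapply(report$stages, function(st) {
      list(stage = st$stage, dimension = st$dimension,
           feature_names = st$feature_names,
           cv_metrics = as.list(st$cv_metrics))
    })
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Nested cross-validation of the full selection pipeline
#'
#' Treats selection-plus-classifier as one learner: within each outer
#' training fold the three-step selection is re-run from scratch and a
#' boosted-tree model is fitted on its final feature set; the outer test
#' fold is scored by that model. The pooled out-of-fold AUC is an
#' unbiased end-to-end estimate — evaluating the final feature set on the
#' same data that selected it inflates AUC on null data (selection bias),
#' which this design avoids.
#'
#' @param x,labels Feature matrix and 0/1 labels.
#' @param outer_k Outer folds (default 5).
#' @param inner_k Folds used by the selection stages inside each outer
#'   training fold (default 5).
#' @param target_dims,step Stage controls passed to [select_features()].
#' @param seed Seed for outer folds and inner stages.
#' @return List: `auc` (pooled out-of-fold), `oof_scores`, `folds`,
#'   `selected_per_fold`.
#' @export
nested_pipeline_cv <- function(x, labels, outer_k = 5L, inner_k = 5L,
                               target_dims = c(80L, 60L, 40L, 20L, 10L),
                               step = 5L, seed = 1L) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  folds <- stratified_folds(labels, k = outer_k, seed = seed)
  oof <- numeric(length(labels))
  selected <- vector("list", outer_k)
  for (f in seq_len(outer_k)) {
    tr <- folds != f
    rep_f <- select_features(x[tr, , drop = FALSE], labels[tr],
                             target_dims = target_dims, step = step,
                             k = inner_k, seed = seed + f)
    selected[[f]] <- rep_f$final_features
    fit <- ps_mechanism_xgb(x[tr, , drop = FALSE], labels[tr],
                            features = rep_f$final_features)
    oof[!tr] <- predict(fit, x[!tr, , drop = FALSE])
  }
  list(auc = roc_auc(oof, labels), oof_scores = oof, folds = folds,
       selected_per_fold = selected)
}

# --- the mechanism classifier --------------------------------------------

#' Fit the PS-Self vs PS-Part boosted-tree classifier
#'
#' Gradient-boosted trees on the selected feature set. The positive class
#' is PS-Self (label 1); prediction requires exactly the stored feature
#' names.
#'
#' @param x Feature matrix (may contain extra columns; only `features` are
#'   used).
#' @param y 0/1 labels, 1 = PS-Self.
#' @param features Ordered feature names the model expects (default: all
#'   columns of `x`).
#' @param nrounds,params Boosting controls.
#' @return Object of class `ps_xgb` with `fit`, `features`,
#'   `positive_class`.
#' @export
ps_mechanism_xgb <- function(x, y, features = colnames(x), nrounds = 100L,
                             params = xgb_params_default()) {
  x <- as.matrix(x)
  missing <- setdiff(features, colnames(x))
  if (length(missing)) {
    stop("feature table lacks required features: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fit <- fit_xgb(x[, features, drop = FALSE], y, nrounds = nrounds,
                 params = params)
  structure(list(fit = fit, features = features,
                 positive_class = "PS-Self"),
            class = "ps_xgb")
}

#' @export
predict.ps_xgb <- function(object, newdata, type = c("response", "class"),
                           ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing)) {
    stop("prediction input lacks required features: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  p <- predict_xgb(object$fit, newdata[, object$features, drop = FALSE])
  if (type == "class") {
    ifelse(p >= 0.5, object$positive_class, "PS-Part")
  } else p
}

#' @export
print.ps_xgb <- function(x, ...) {
  cat("PS mechanism classifier (gradient-boosted trees)\n")
  cat("  positive class:", x$positive_class, "\n")
  cat("  features (", length(x$features), "): ",
      paste(utils::head(x$features, 6), collapse = ", "),
      if (length(x$features) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Balanced class subsample
#'
#' Seed-pinned random subsample of the majority class down to the minority
#' class size (e.g. drawing 285 of 496 partner-dependent proteins to match
#' 285 self-assembling ones).
#'
#' @param y 0/1 labels.
#' @param seed Integer seed.
#' @return Integer indices of the balanced subset, in original order.
#' @export
balance_classes <- function(y, seed = 1L) {
  y <- as.integer(y)
  rng <- local_rng(seed)
  n_min <- min(table(y))
  keep <- unlist(lapply(sort(unique(y)), function(cls) {
    idx <- which(y == cls)
    if (length(idx) > n_min) {
      sort(idx[rng$sample_int(length(idx), n_min)])
    } else idx
  }))
  sort(keep)
}

# --- classifier comparison harness ---------------------------------------

#' Cross-validated comparison of candidate classifiers
#'
#' Scores gradient-boosted trees, dart-boosted trees, stochastic gradient
#' boosting, random forest, extremely-randomized trees and an RBF support
#' vector machine on one feature table, each tuned over a small grid by
#' cross-validated AUC and reported with the seven-metric panel.
#' Deterministic given the seed.
#'
#' @param x Feature matrix.
#' @param labels 0/1 labels.
#' @param k,seed Cross-validation controls.
#' @return Data frame: classifier, chosen tuning, seven pooled CV metrics.
#' @export
classifier_zoo <- function(x, labels, k = 10L, seed = 1L) {
  x <- as.matrix(x)
  rng <- local_rng(seed)
  zoo <- list(
    xgboost = list(
      grid = list(list(max_depth = 3), list(max_depth = 6)),
      make = function(h) xgb_trainer(params = xgb_params_default(
        max_depth = h$max_depth)),
      pred = predict_xgb
    ),
    dart_boost = list(
      grid = list(list(rate_drop = 0.1)),
      make = function(h) xgb_trainer(params = xgb_params_default(
        booster = "dart", rate_drop = h$rate_drop, seed = 1)),
      pred = predict_xgb
    ),
    stochastic_gbdt = list(
      grid = list(list(eta = 0.1), list(eta = 0.3)),
      make = function(h) function(xx, yy) {
        rng$with_seed(function() fit_xgb(xx, yy, nrounds = 150L,
          params = xgb_params_default(eta = h$eta, subsample = 0.8,
                                      seed = 1)))
      },
      pred = predict_xgb
    ),
    random_forest = list(
      grid = list(list(ntree = 300)),
      make = function(h) function(xx, yy) {
        rng$with_seed(function() randomForest::randomForest(
          x = xx, y = factor(yy, levels = c(0, 1)), ntree = h$ntree))
      },
      pred = function(fit, xx) predict(fit, xx, type = "prob")[, "1"]
    ),
    extra_trees = list(
      grid = list(list(num.trees = 300)),
      make = function(h) function(xx, yy) {
        rng$with_seed(function() ranger::ranger(
          x = xx, y = factor(yy, levels = c(0, 1)),
          num.trees = h$num.trees, splitrule = "extratrees",
          probability = TRUE, num.threads = 1, seed = 1))
      },
      pred = function(fit, xx) predict(fit, xx, num.threads = 1)$predictions[, "1"]
    ),
    svm_rbf = list(
      grid = list(list(cost = 1), list(cost = 10)),
      make = function(h) function(xx, yy) {
        rng$with_seed(function() e1071::svm(
          x = xx, y = factor(yy, levels = c(0, 1)), cost = h$cost,
          kernel = "radial", probability = TRUE))
      },
      pred = function(fit, xx) {
        attr(predict(fit, xx, probability = TRUE), "probabilities")[, "1"]
      }
    )
  )
  rows <- lapply(names(zoo), function(nm) {
    spec <- zoo[[nm]]
    evals <- lapply(spec$grid, function(h) {
      cv <- kfold_cv(x, labels, trainer = spec$make(h), predictor = spec$pred,
                     k = k, seed = seed)
      list(h = h, cv = cv)
    })
    aucs <- vapply(evals, function(e) e$cv$pooled[["auc"]], numeric(1))
    best <- evals[[which.max(aucs)]]
    cbind(data.frame(classifier = nm,
                     tuning = paste(names(best$h), unlist(best$h),
                                    sep = "=", collapse = ",")),
          as.data.frame(as.list(round(best$cv$pooled, 6))))
  })
  do.call(rbind, rows)
}
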