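#' Pearson product-moment correlation
#'
#' Standard correlation between predicted and true angles, the agreement
#' index reported alongside MAE.
#'
#' @param x,y equal-length numeric vectors (n >= 2, nonzero variance).
#' @return correlation in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  cor(x, y, method = "pearson")
}

#' Mean absolute error in degrees
#'
#' @param truth,pred equal-length numeric vectors of angles (degrees).
#' @return mean of `|truth - pred|`.
#' @export
mae <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("length mismatch", call. = FALSE)
  if (length(truth) == 0L) stop("empty input", call. = FALSE)
  mean(abs(truth - pred))
}

#' Per-angle residual summary
#'
#' Residuals are `actual - predicted`. Rows are grouped by the nominal
#' (clip-target) angle and summarized by mean, sample (n-1) standard
#' deviation and count, ordered by ascending angle — the layout of the
#' residual-by-angle tables this package reports. Groups of size 1 get
#' SD 0 and are flagged.
#'
#' @param truth,pred aligned vectors of actual and predicted angles.
#' @param nominal aligned vector of nominal angles used as grouping key.
#' @return data.frame with columns `nominal_angle_deg`, `mean_residual_deg`,
#'   `sd_residual_deg`, `n`, `singleton`.
#' @export
residual_by_angle <- function(truth, pred, nominal) {
  if (length(truth) != length(pred) || length(truth) != length(nominal)) {
    stop("truth, pred and nominal must be aligned", call. = FALSE)
  }
  dt <- data.table(nominal = nominal, resid = truth - pred)
  out <- dt[, .(mean_residual_deg = mean(resid),
                sd_residual_deg = if (.N > 1L) sd(resid) else 0,
                n = .N), by = nominal][order(nominal)]
  setnames(out, "nominal", "nominal_angle_deg")
  out[, singleton := n == 1L]
  setDF(out)
  out
}

#' Correlation matrix of the seven features and the angle
#'
#' Pairwise Pearson correlations among the seven features and
#' `true_angle_deg` — the numbers behind a parameter-correlation heatmap.
#' Constant columns yield NA in their row/column (flagged with a warning).
#'
#' @param rows feature table.
#' @return symmetric 8 x 8 matrix with unit diagonal.
#' @export
feature_correlation_matrix <- function(rows) {
  cols <- c(FEATURE_NAMES, "true_angle_deg")
  missing_cols <- setdiff(cols, names(rows))
  if (length(missing_cols) > 0L) {
    stop("feature table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(rows) < 2L) stop("need at least 2 rows", call. = FALSE)
  m <- as.matrix(rows[, cols, drop = FALSE])
  sds <- apply(m, 2L, sd)
  cm <- suppressWarnings(cor(m))
  diag(cm) <- 1
  if (any(sds == 0)) {
    warning("constant column(s), correlations undefined: ",
            paste(cols[sds == 0], collapse = ", "), call. = FALSE)
  }
  cm
}

#' Tree-ensemble feature importance (per-tree normalized gain shares)
#'
#' For each tree, every feature's split gains are summed and normalized by
#' the tree's total gain; the overall importance of a feature is the mean
#' of its per-tree shares over all trees. The result is nonnegative and
#' sums to 1. Implemented exactly for gradient-boosted models from their
#' per-tree gain tables; random forests report ensemble-total impurity
#' shares normalized to sum 1 (the per-tree decomposition is not exposed
#' by the forest backend).
#'
#' @param model a `fitted_model` of a tree ensemble.
#' @return named numeric vector over the seven features, summing to 1.
#' @export
tree_feature_importance <- function(model) {
  if (!is_tree_model(model)) {
    stop("feature importance is defined for tree ensembles only (random_forest, gradient_boosted_trees)",
         call. = FALSE)
  }
  imp <- setNames(numeric(length(model$feature_names)), model$feature_names)
  if (model$spec$algorithm == "gradient_boosted_trees") {
    fo <- model$forest
    is_split <- fo$feature >= 0L
    if (!any(is_split)) return(imp)      # constant model: all zeros
    splits <- data.table(Tree = fo$tree[is_split],
                         Feature = fo$feature_names[fo$feature[is_split] + 1L],
                         Gain = fo$gain[is_split])
    per_tree <- splits[, .(gain = sum(Gain)), by = .(Tree, Feature)]
    per_tree[, share := gain / sum(gain), by = Tree]
    n_trees <- length(fo$tree_root)
    agg <- per_tree[, .(importance = sum(share) / n_trees), by = Feature]
    imp[agg$Feature] <- agg$importance
    ## trees with no split contribute zero shares; renormalize to sum 1
    if (sum(imp) > 0) imp <- imp / sum(imp)
  } else {
    raw <- model$fit$variable.importance
    if (sum(raw) > 0) imp[names(raw)] <- raw / sum(raw)
  }
  imp
}

#' Shapley additive attributions for a tree-ensemble model
#'
#' For gradient-boosted models, exact tree-path Shapley values are
#' computed in double precision by walking the extracted tree structure
#' (cover-weighted path algorithm). For random forests, an interventional
#' permutation-sampling estimator is used: for each of `n_permutations`
#' random feature orderings, features are switched one at a time from a
#' background sample's values to the explained row's values and the
#' prediction deltas are averaged. Both satisfy local accuracy: per row,
#' `base_value + sum(contributions) = prediction` (exactly for the
#' boosted-tree path, by construction of the telescoping sums for the
#' sampling path).
#'
#' @param model a `fitted_model` of a tree ensemble.
#' @param rows feature rows to explain.
#' @param background background rows for the sampling estimator (defaults
#'   to `rows`, capped at 100 rows).
#' @param n_permutations permutations for the sampling estimator.
#' @return list with `contributions` (rows x 7 matrix, degrees),
#'   `base_value` (scalar), `prediction` (vector).
#' @export
shap_attributions <- function(model, rows, background = NULL,
                              n_permutations = 2000L) {
  if (!is_tree_model(model)) {
    stop("Shapley attributions are provided for tree ensembles only (random_forest, gradient_boosted_trees)",
         call. = FALSE)
  }
  x <- as.matrix(as.data.frame(rows)[, model$feature_names, drop = FALSE])
  if (model$spec$algorithm == "gradient_boosted_trees") {
    return(list(
      contributions = forest_shap(model$forest, x),
      base_value = forest_expected_value(model$forest),
      prediction = as.numeric(forest_predict(model$forest, x))
    ))
  }
  ## sampling estimator (forest path)
  bg <- if (is.null(background)) x else {
    as.matrix(as.data.frame(background)[, model$feature_names, drop = FALSE])
  }
  if (nrow(bg) > 100L) bg <- bg[seq_len(100L), , drop = FALSE]
  p <- ncol(x)
  contrib <- matrix(0, nrow(x), p, dimnames = list(NULL, model$feature_names))
  base_value <- mean(predict(model, bg))
  with_preserved_seed(model$spec$seed, {
    for (i in seq_len(nrow(x))) {
      phi <- numeric(p)
      for (perm in seq_len(n_permutations)) {
        ord <- sample.int(p)
        cur <- bg
        prev <- predict(model, cur)
        for (j in ord) {
          cur[, j] <- x[i, j]
          nxt <- predict(model, cur)
          phi[j] <- phi[j] + mean(nxt - prev)
          prev <- nxt
        }
      }
      contrib[i, ] <- phi / n_permutations
    }
  })
  list(contributions = contrib, base_value = base_value,
       prediction = as.numeric(predict(model, x)))
}

#' Evaluate a fitted model on held-out feature rows
#'
#' Assembles the package's full evaluation battery: Pearson correlation
#' and MAE between predicted and true angles, per-row residuals
#' (`actual - predicted`), a per-nominal-angle residual summary, the
#' feature/angle correlation matrix, and — for tree ensembles — per-tree
#' normalized feature importance and Shapley attributions.
#'
#' @param model a `fitted_model`.
#' @param test feature table rows to evaluate on.
#' @param nominal optional vector of nominal clip-target angles for the
#'   per-angle summary; defaults to [nominal_angle()] of `test` when the
#'   clip ids encode targets, otherwise to rounded true angles.
#' @param compute_shap whether to compute Shapley attributions (tree
#'   models only).
#' @return an `eval_report` list.
#' @export
eval_report <- function(model, test, nominal = NULL, compute_shap = TRUE) {
  pred <- predict(model, test)
  truth <- test$true_angle_deg
  if (is.null(nominal)) {
    nominal <- tryCatch(nominal_angle(test), warning = function(w) NULL)
    if (is.null(nominal) || anyNA(nominal)) {
      nominal <- round(truth / 10) * 10
    }
  }
  rep <- list(
    algorithm = model$spec$algorithm,
    n_test = nrow(test),
    pearson_r = pearson(truth, pred),
    mae_deg = mae(truth, pred),
    residuals = truth - pred,
    per_angle_summary = residual_by_angle(truth, pred, nominal),
    feature_correlations = feature_correlation_matrix(test)
  )
  if (is_tree_model(model)) {
    rep$importance <- tree_feature_importance(model)
    if (compute_shap) {
      shap <- shap_attributions(model, test)
      rep$shap <- shap
      rep$mean_abs_shap <- colMeans(abs(shap$contributions))
    }
  }
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s on %d test rows\n", x$algorithm, x$n_test))
  cat(sprintf("  Pearson r : %.4f\n", x$pearson_r))
  cat(sprintf("  MAE (deg) : %.4f\n", x$mae_deg))
  if (!is.null(x$importance)) {
    top <- names(sort(x$importance, decreasing = TRUE))[1L]
    cat(sprintf("  top feature by importance: %s (%.3f)\n",
                top, max(x$importance)))
  }
  invisible(x)
}

#' Write an evaluation report to a directory
#'
#' Emits `report.json` (scalar metrics, importance, per-angle table),
#' `residuals_by_angle.csv`, `correlations.csv` and, when present,
#' `importance.csv` and `shap_summary.csv` (mean |contribution| per
#' feature plus base value).
#'
#' @param report an `eval_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  payload <- list(
    algorithm = report$algorithm,
    n_test = report$n_test,
    pearson_r = report$pearson_r,
    mae_deg = report$mae_deg,
    per_angle_summary = report$per_angle_summary,
    importance = as.list(report$importance)
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  fwrite(report$per_angle_summary, file.path(dir, "residuals_by_angle.csv"))
  cm <- as.data.table(report$feature_correlations, keep.rownames = "variable")
  fwrite(cm, file.path(dir, "correlations.csv"))
  if (!is.null(report$importance)) {
    fwrite(data.table(feature = names(report$importance),
                      importance = as.numeric(report$importance)),
           file.path(dir, "importance.csv"))
  }
  if (!is.null(report$shap)) {
    fwrite(data.table(feature = names(report$mean_abs_shap),
                      mean_abs_contribution_deg = as.numeric(report$mean_abs_shap),
                      base_value_deg = report$shap$base_value),
           file.path(dir, "shap_summary.csv"))
  }
  invisible(dir)
}
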