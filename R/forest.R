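## Flat-array view of a fitted boosted-tree ensemble, extracted once at fit
## time. All downstream evaluation (prediction, expected value, Shapley
## attribution) walks these arrays in double precision, so additivity
## identities hold to numerical precision rather than to the float32
## precision of the booster's own predictor.

extract_forest <- function(booster, feature_names) {
  dt <- as.data.table(xgboost::xgb.model.dt.tree(model = booster))
  setorder(dt, Tree, Node)
  id2idx <- setNames(seq_len(nrow(dt)) - 1L, dt$ID)
  is_leaf <- dt$Feature == "Leaf"
  feat_idx <- match(dt$Feature, feature_names) - 1L
  feat_idx[is_leaf] <- -1L
  if (any(is.na(feat_idx))) {
    stop("booster splits on features outside the model's feature set",
         call. = FALSE)
  }
  cfg <- xgboost::xgb.config(booster)
  base_score <- as.numeric(cfg$learner$learner_model_param$base_score)
  list(
    tree_root = unname(id2idx[paste0(sort(unique(dt$Tree)), "-0")]),
    feature = as.integer(feat_idx),
    threshold = ifelse(is_leaf, 0, dt$Split),
    yes = as.integer(ifelse(is_leaf, -1L, id2idx[dt$Yes])),
    no = as.integer(ifelse(is_leaf, -1L, id2idx[dt$No])),
    value = ifelse(is_leaf, dt$Gain, 0),
    gain = ifelse(is_leaf, 0, dt$Gain),
    tree = dt$Tree,
    cover = dt$Cover,
    base_score = base_score,
    feature_names = feature_names
  )
}

forest_predict <- function(forest, x) {
  .tree_predict_cpp(x, forest$tree_root, forest$feature, forest$threshold,
                    forest$yes, forest$no, forest$value, forest$base_score)
}

forest_expected_value <- function(forest) {
  .tree_expected_cpp(forest$tree_root, forest$feature, forest$yes, forest$no,
                     forest$value, forest$cover, forest$base_score)
}

forest_shap <- function(forest, x) {
  m <- .treeshap_cpp(x, forest$tree_root, forest$feature, forest$threshold,
                     forest$yes, forest$no, forest$value, forest$cover,
                     length(forest$feature_names))
  colnames(m) <- forest$feature_names
  m
}
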