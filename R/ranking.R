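#' Rank differential edges by boosted-tree information gain
#'
#' Trains a regularized gradient-boosted tree classifier (binary logistic)
#' on a samples x edges weight matrix with shallow trees (depth 2) and
#' early stopping (2 rounds without improvement on a stratified 20%
#' evaluation split), then ranks edges by their information gain — the
#' total improvement in the split criterion attributable to each feature
#' across the ensemble, normalized to sum 1. Because boosting picks one of
#' several correlated features, duplicated columns do not inflate the
#' selected-feature count. The intent is within-data inference of feature
#' importance, so the reported accuracy is over all samples; the accuracy
#' on the held-out evaluation split is reported alongside.
#'
#' @param weights Numeric matrix, samples in rows (rownames = sample ids),
#'   edge features in columns (colnames = edge ids).
#' @param labels Binary labels, one per row: logical, 0/1, or the group
#'   letters "x"/"y" ("x" is coded 1).
#' @param max_depth Maximum tree depth (default 2).
#' @param early_stopping_rounds Rounds without eval improvement before
#'   stopping (default 2).
#' @param nrounds Upper bound on boosting rounds (default 100).
#' @param seed Integer seed controlling the evaluation split and booster.
#' @return A `ccnet_ranking` list: `ranking` (`data.table` of `edge_id`,
#'   `gain`, `rank` for features with nonzero gain), `n_selected`,
#'   `accuracy_all` and `accuracy_eval` (percent), `best_iteration`,
#'   `params`, `seed`, `eval_samples`.
#' @export
rank_edges <- function(weights, labels, max_depth = 2L,
                       early_stopping_rounds = 2L, nrounds = 100L, seed) {
  if (missing(seed)) stop("`seed` is required")
  if (!is.matrix(weights)) weights <- as.matrix(weights)
  if (is.null(colnames(weights)))
    colnames(weights) <- as.character(seq_len(ncol(weights)))
  if (is.character(labels) || is.factor(labels))
    labels <- as.character(labels) == "x"
  y <- as.integer(as.logical(labels))
  if (length(y) != nrow(weights))
    stop("one label per sample row is required")
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  if (min(tabulate(y + 1L, 2L)) < 2L) stop("need >= 2 samples per class")

  # stratified 80/20 split for early-stopping evaluation
  set.seed(as.integer(seed))
  eval_idx <- unlist(lapply(c(0L, 1L), function(cls) {
    idx <- which(y == cls)
    sample(idx, max(1L, floor(0.2 * length(idx))))
  }))
  train_idx <- setdiff(seq_len(nrow(weights)), eval_idx)

  params <- list(objective = "binary:logistic", max_depth = as.integer(max_depth),
                 nthread = 1L, seed = as.integer(seed))
  dtrain <- xgboost::xgb.DMatrix(weights[train_idx, , drop = FALSE],
                                 label = y[train_idx], nthread = 1)
  deval <- xgboost::xgb.DMatrix(weights[eval_idx, , drop = FALSE],
                                label = y[eval_idx], nthread = 1)
  bst <- xgboost::xgb.train(
    params = params, data = dtrain, nrounds = as.integer(nrounds),
    evals = list(eval = deval),
    early_stopping_rounds = as.integer(early_stopping_rounds),
    verbose = 0
  )

  # gain importance from the tree dump: total split-criterion improvement
  # per feature across the ensemble, normalized to sum 1
  tree <- xgboost::xgb.model.dt.tree(model = bst)
  splits <- tree[tree$Feature != "Leaf", ]
  if (nrow(splits)) {
    ranking <- data.table::as.data.table(splits)[
      , .(gain = sum(Gain)), by = .(edge_id = Feature)]
    ranking[, gain := gain / sum(gain)]
    data.table::setorder(ranking, -gain, edge_id)
    ranking[, rank := seq_len(.N)]
  } else {
    ranking <- data.table::data.table(edge_id = character(),
                                      gain = numeric(), rank = integer())
  }

  pred_all <- as.integer(predict(bst, weights) > 0.5)
  acc_all <- 100 * mean(pred_all == y)
  pred_eval <- pred_all[eval_idx]
  acc_eval <- 100 * mean(pred_eval == y[eval_idx])

  structure(list(
    ranking = ranking,
    n_selected = nrow(ranking),
    accuracy_all = acc_all,
    accuracy_eval = acc_eval,
    best_iteration = xgboost::xgb.attr(bst, "best_iteration"),
    params = params,
    nrounds = as.integer(nrounds),
    early_stopping_rounds = as.integer(early_stopping_rounds),
    seed = as.integer(seed),
    eval_samples = rownames(weights)[sort(eval_idx)]
  ), class = "ccnet_ranking")
}

#' @export
print.ccnet_ranking <- function(x, ...) {
  cat(sprintf(paste0("<ccnet_ranking: %d features selected, accuracy %.1f%%",
                     " (all) / %.1f%% (eval split)>\n"),
              x$n_selected, x$accuracy_all, x$accuracy_eval))
  if (nrow(x$ranking)) print(utils::head(x$ranking, 10))
  invisible(x)
}

#' Assemble the samples x DWE-edges feature matrix for ranking
#'
#' @param weights Long weight table from [weight_cohort()].
#' @param dwes Contrast or DWE table holding the `edge_id`s to use.
#' @param groups Group assignment (`sample_id`, `group`).
#' @return List with `x` (matrix, samples x edges) and `labels`
#'   (group letters aligned to rows).
#' @export
dwe_feature_matrix <- function(weights, dwes, groups) {
  weights <- data.table::as.data.table(weights)
  groups <- data.table::as.data.table(groups)
  ids <- unique(data.table::as.data.table(dwes)$edge_id)
  if (!length(ids)) stop("no edges to rank")
  sub <- weights[edge_id %in% ids & sample_id %in% groups$sample_id]
  wide <- data.table::dcast(sub, sample_id ~ edge_id, value.var = "weight")
  x <- as.matrix(wide[, -1])
  rownames(x) <- wide$sample_id
  colnames(x) <- as.character(colnames(x))
  lab <- groups[match(wide$sample_id, sample_id), group]
  list(x = x, labels = lab)
}
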