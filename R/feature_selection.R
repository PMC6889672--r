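## Out-of-bag permutation variable importance and top-k feature selection.
##
## For every tree b of a forest grown on bootstrap sample TSS_b, the
## importance of feature j is the drop in OOB prediction accuracy after
## permuting column j among that tree's OOB rows; S_j averages the drop over
## trees, and the whole computation is repeated over fold resplits and
## averaged. The forest itself comes from randomForest; the per-tree OOB
## bookkeeping and the permutation loop are implemented here because the
## score is accuracy-based (regression predictions thresholded at 0.5
## against the 0/1 labels), which the stock importance measures are not.

## accuracy of thresholded regression predictions against 0/1 labels
.threshold_accuracy <- function(pred, obs) mean((pred >= 0.5) == (obs >= 0.5))

## regression forests on 0/1 targets are the method here, so muffle the
## stock warning about few unique response values
.rf_quiet <- function(...) {
  withCallingHandlers(
    randomForest::randomForest(...),
    warning = function(w) {
      if (grepl("five or fewer unique values", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

## Evaluate one extracted regression tree (randomForest::getTree matrix) on
## a feature matrix: iterative vectorized descent, numeric splits go left
## when x <= split point. Much cheaper than predict() when one tree must be
## applied to many permuted copies of its OOB rows.
.predict_tree <- function(tr, x) {
  node <- rep(1L, nrow(x))
  status <- tr[, "status"]
  repeat {
    live <- which(status[node] != -1L)
    if (!length(live)) break
    cur <- node[live]
    goleft <- x[cbind(live, tr[cur, "split var"])] <= tr[cur, "split point"]
    node[live] <- ifelse(goleft, tr[cur, "left daughter"],
                         tr[cur, "right daughter"])
  }
  tr[node, "prediction"]
}

## One importance computation on a fixed (x, y): grow the forest, recover
## each tree's OOB rows from the recorded in-bag counts, and score each
## feature by the mean per-tree OOB accuracy drop (or MSE increase) under
## within-OOB permutation. Trees with empty OOB sets are skipped.
.importance_once <- function(x, y, ntree, type = "accuracy") {
  p <- ncol(x)
  rf <- .rf_quiet(x, y, ntree = ntree, keep.inbag = TRUE, keep.forest = TRUE)
  oob_rows <- lapply(seq_len(ntree), function(b) which(rf$inbag[, b] == 0L))
  trees <- which(vapply(oob_rows, length, 1L) > 0L)
  if (!length(trees)) stop("every tree has an empty out-of-bag set")
  tree_mats <- lapply(trees, function(b) randomForest::getTree(rf, b))
  oob_x <- lapply(trees, function(b) x[oob_rows[[b]], , drop = FALSE])
  oob_y <- lapply(trees, function(b) y[oob_rows[[b]]])
  tree_score <- function(pred, obs) {
    if (type == "accuracy") .threshold_accuracy(pred, obs)
    else mean((pred - obs)^2)
  }
  base_score <- mapply(function(tr, xo, yo) tree_score(.predict_tree(tr, xo), yo),
                       tree_mats, oob_x, oob_y)
  drops <- matrix(0, length(trees), p)
  for (bi in seq_along(trees)) {
    tr <- tree_mats[[bi]]
    xo <- oob_x[[bi]]
    yo <- oob_y[[bi]]
    m <- nrow(xo)
    ## only features the tree actually splits on can change its predictions
    used <- unique(tr[tr[, "status"] != -1L, "split var"])
    for (j in used) {
      xj <- xo
      xj[, j] <- xo[sample.int(m), j]
      drops[bi, j] <- base_score[bi] - tree_score(.predict_tree(tr, xj), yo)
    }
  }
  scores <- colMeans(drops)
  if (type == "mse") scores <- -scores
  stats::setNames(scores, colnames(x))
}

#' Permutation variable importance scores
#'
#' Grows `folds` forests, one on each training partition of a fold split
#' of the data (all data when `folds = 1`), computes per-feature
#' out-of-bag permutation importance in each, and averages the scores.
#'
#' @param dataset a `labeled_dataset` with both labels present.
#' @param ntree trees per forest (default 500).
#' @param folds number of resplits to average over (default 10); each forest
#'   sees the complement of one fold.
#' @param seed integer seed driving fold assignment, forest growth and
#'   permutations.
#' @param type `"accuracy"` (mean OOB accuracy drop, predictions
#'   thresholded at 0.5) or `"mse"` (mean OOB squared-error increase).
#' @return An `importance_scores` object: numeric vector of per-feature
#'   scores with attributes `ntree`, `folds`, `type`, `seed`.
#' @export
variable_importance <- function(dataset, ntree = 500, folds = 10, seed,
                                type = c("accuracy", "mse")) {
  type <- match.arg(type)
  x <- dataset$features
  y <- dataset$pairs$label
  if (length(unique(y)) < 2L) stop("dataset must contain both labels")
  set.seed(seed)
  n <- nrow(x)
  if (folds > 1) {
    fold_id <- sample(rep_len(seq_len(folds), n))
    per_fold <- lapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      .importance_once(x[tr, , drop = FALSE], y[tr], ntree, type)
    })
  } else {
    per_fold <- list(.importance_once(x, y, ntree, type))
  }
  scores <- Reduce(`+`, per_fold) / length(per_fold)
  structure(scores, ntree = ntree, folds = folds, type = type, seed = seed,
            class = c("importance_scores", "numeric"))
}

#' @export
print.importance_scores <- function(x, ...) {
  cat(sprintf("Permutation importance (%s, ntree = %d, folds = %d): %d features\n",
              attr(x, "type"), attr(x, "ntree"), attr(x, "folds"), length(x)))
  top <- sort(unclass(x), decreasing = TRUE)[seq_len(min(5, length(x)))]
  print(round(top, 4))
  invisible(x)
}

#' Rank features by descending importance score
#'
#' Ties are broken by original feature order (stable sort).
#'
#' @param scores an `importance_scores` vector (or any named numeric).
#' @return Data frame with columns `feature`, `score`, `rank`, ordered by
#'   rank.
#' @export
rank_features <- function(scores) {
  ord <- order(-unclass(scores))   # radix order is stable in ties
  data.frame(feature = names(scores)[ord], score = as.numeric(scores)[ord],
             rank = seq_along(scores), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Restrict a dataset to the top-k ranked features
#'
#' @param dataset a `labeled_dataset`.
#' @param ranking output of [rank_features()].
#' @param k number of features to keep (1..feature count).
#' @return The dataset with `features` reduced to the top-k columns in
#'   ranking order; normalisation stats are subset accordingly.
#' @export
select_top_k <- function(dataset, ranking, k) {
  p <- ncol(dataset$features)
  if (k < 1 || k > p) stop("k must be in 1..", p, ", got ", k)
  keep <- ranking$feature[seq_len(k)]
  dataset$features <- dataset$features[, keep, drop = FALSE]
  if (!is.null(dataset$stats)) {
    dataset$stats <- dataset$stats[match(keep, dataset$stats$feature), ,
                                   drop = FALSE]
  }
  dataset
}

#' Cross-validated accuracy over a grid of feature-set sizes
#'
#' For each k in the grid, a random forest is trained and tested by k-fold
#' cross-validation on the top-k ranked feature columns and the mean
#' thresholded accuracy is recorded — the sweep used to pick the working
#' feature count.
#'
#' @param dataset a `labeled_dataset`.
#' @param ranking output of [rank_features()].
#' @param k_grid integer vector of feature counts to evaluate.
#' @param folds CV folds (default 10).
#' @param ntree trees per CV forest (default 500).
#' @param seed integer seed (fold split shared across the grid).
#' @return Data frame with columns `k`, `accuracy`.
#' @export
sweep_k <- function(dataset, ranking, k_grid, folds = 10, ntree = 500, seed) {
  x_all <- dataset$features
  y <- dataset$pairs$label
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), nrow(x_all)))
  acc <- vapply(k_grid, function(k) {
    keep <- ranking$feature[seq_len(k)]
    x <- x_all[, keep, drop = FALSE]
    fold_acc <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      rf <- .rf_quiet(
        x[tr, , drop = FALSE], y[tr], ntree = ntree,
        mtry = max(1, floor(ncol(x) / 3)))
      .threshold_accuracy(predict(rf, x[!tr, , drop = FALSE]), y[!tr])
    }, 1)
    mean(fold_acc)
  }, 1)
  data.frame(k = k_grid, accuracy = acc)
}
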