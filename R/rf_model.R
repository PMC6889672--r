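## Random-forest regression scorer for disease-miRNA pairs.

#' Train the random-forest regression scorer
#'
#' Fits a regression forest to the 0/1 labels of a (normalised,
#' feature-selected) pair dataset. `mtry` defaults to floor(features / 3) —
#' 33 for the 100-feature working set — and `ntree` to 500.
#'
#' @param dataset a `labeled_dataset` with both labels present.
#' @param ntree number of trees (default 500).
#' @param mtry variables tried per split; default floor(feature count / 3),
#'   at least 1.
#' @param seed integer seed for reproducible forest growth.
#' @return A `trained_scorer`: list with the fitted forest, the feature-name
#'   order, the normalisation stats carried by the dataset, and the config.
#' @export
train_rf <- function(dataset, ntree = 500, mtry = NULL, seed = 1) {
  y <- dataset$pairs$label
  if (length(unique(y)) < 2L) stop("training labels are single-class")
  p <- ncol(dataset$features)
  if (is.null(mtry)) mtry <- max(1, floor(p / 3))
  if (mtry < 1 || mtry > p) stop("mtry must be in 1..", p)
  set.seed(seed)
  forest <- .rf_quiet(dataset$features, as.numeric(y),
                                       ntree = ntree, mtry = mtry)
  structure(
    list(forest = forest, feature_names = colnames(dataset$features),
         stats = dataset$stats,
         config = list(ntree = ntree, mtry = mtry, seed = seed)),
    class = "trained_scorer"
  )
}

#' @export
print.trained_scorer <- function(x, ...) {
  cat(sprintf("Random-forest pair scorer: %d features, ntree = %d, mtry = %d\n",
              length(x$feature_names), x$config$ntree, x$config$mtry))
  invisible(x)
}

## Reconstruct the scorer's feature matrix for arbitrary pairs: raw
## similarity-row features, training-set normalisation, stored column
## selection/order.
.pair_features_for_scorer <- function(model, pairs, idsm, imsm) {
  raw <- build_features(pairs, idsm, imsm)$features
  if (!is.null(model$stats)) {
    cols <- match(model$stats$feature, colnames(raw))
    if (anyNA(cols)) {
      stop("similarity matrices lack feature ",
           model$stats$feature[which(is.na(cols))[1]])
    }
    raw <- apply_normalization_stats(raw[, cols, drop = FALSE],
                                     model$stats$min, model$stats$max)
  } else {
    raw <- raw[, model$feature_names, drop = FALSE]
  }
  raw
}

#' Score disease-miRNA pairs with a trained scorer
#'
#' Pair feature vectors are rebuilt from the integrated similarity matrices,
#' normalised with the training-set stats and reduced to the model's feature
#' set; scores are the forest's regression predictions clipped to [0, 1]. A
#' larger score means a more plausible association.
#'
#' @param model a `trained_scorer` from [train_rf()].
#' @param pairs data frame with columns `disease`, `mirna`.
#' @param idsm,imsm integrated similarity matrices aligned with the entity
#'   index the model was trained under.
#' @return Data frame `disease`, `mirna`, `score`.
#' @export
score_pairs <- function(model, pairs, idsm, imsm) {
  if (nrow(pairs) == 0L) {
    return(data.frame(disease = character(0), mirna = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  feats <- .pair_features_for_scorer(model, pairs, idsm, imsm)
  s <- as.numeric(predict(model$forest, feats))
  s[s < 0] <- 0
  s[s > 1] <- 1
  data.frame(disease = pairs$disease, mirna = pairs$mirna, score = s,
             stringsAsFactors = FALSE)
}
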