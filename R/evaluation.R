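## Ranking-based validation: ROC/AUC, k-fold CV, global/local leave-one-out
## and the novel-disease hold-out protocol.

#' ROC curve and AUC from scores and binary labels
#'
#' Sweeps a threshold over the distinct score values, recording the true-
#' and false-positive rates; the AUC (trapezoidal) equals the
#' Mann-Whitney probability that a random positive outscores a random
#' negative, ties counted one half.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (1 = positive) of the same length.
#' @return A `roc_curve`: list with `points` (data frame `threshold`,
#'   `fpr`, `tpr`, descending thresholds) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("need at least one positive and one negative")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  last <- cumsum(rep(1, length(s)))[!duplicated(s, fromLast = TRUE)]
  ## cumulative counts at each distinct threshold (ties grouped)
  tp <- cumsum(y == 1)[last]
  fp <- cumsum(y == 0)[last]
  points <- data.frame(threshold = s[last], fpr = fp / n_neg, tpr = tp / n_pos)
  points <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), points)
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                 utils::tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

## Descending rank of `score` within {candidates} + itself, mean rank on ties.
.rank_among <- function(score, candidates) {
  1 + sum(candidates > score) + sum(candidates == score) / 2
}

## Fit the full pipeline on a training association table and return a scorer
## bundle. Used by irfmda() and by every CV protocol. `score_fun`, when
## given, short-circuits the pipeline: it receives (train_assoc, pairs) and
## returns scores — the hook the ranking tests use.
.build_similarities <- function(adj, index, dags, mfsm, config) {
  kern <- gipk_from_adjacency(adj, config$alpha_disease, config$alpha_mirna)
  if (is.null(dags) || length(dags) == 0L) {
    idsm <- similarity_matrix(unclass(kern$disease), labels = index$diseases,
                              kind = "integrated", tol = 1e-12)
  } else {
    dss1 <- semantic_similarity(dags, model = 1, delta = config$delta)
    dss2 <- semantic_similarity(dags, model = 2)
    idsm <- integrate_disease_similarity(dss1, dss2, kern$disease)
  }
  if (is.null(mfsm)) {
    imsm <- similarity_matrix(unclass(kern$mirna), labels = index$mirnas,
                              kind = "integrated", tol = 1e-12)
  } else {
    imsm <- integrate_mirna_similarity(mfsm, kern$mirna)
  }
  list(idsm = idsm, imsm = imsm)
}

.fit_pipeline <- function(train_assoc, index, dags, mfsm, config,
                          similarities = NULL) {
  adj <- build_adjacency(train_assoc, index)
  if (is.null(similarities)) {
    similarities <- .build_similarities(adj, index, dags, mfsm, config)
  }
  idsm <- similarities$idsm
  imsm <- similarities$imsm
  n_neg <- if (is.null(config$n_negative)) nrow(train_assoc) else config$n_negative
  dataset <- build_training_dataset(train_assoc, idsm, imsm,
                                    seed = config$seed, adj = adj,
                                    n_negative = n_neg)
  p <- ncol(dataset$features)
  k <- min(config$k, p)
  if (k < p) {
    imp <- variable_importance(dataset, ntree = config$imp_ntree,
                               folds = config$imp_folds, seed = config$seed,
                               type = config$imp_type)
    ranking <- rank_features(imp)
    reduced <- select_top_k(dataset, ranking, k)
  } else {
    imp <- NULL
    ranking <- data.frame(feature = colnames(dataset$features),
                          score = NA_real_,
                          rank = seq_len(p), stringsAsFactors = FALSE)
    reduced <- dataset
  }
  scorer <- train_rf(reduced, ntree = config$rf_ntree, mtry = config$mtry,
                     seed = config$seed)
  list(adj = adj, idsm = idsm, imsm = imsm, dataset = dataset,
       importance = imp, ranking = ranking, scorer = scorer, k = k)
}

.score_with <- function(fit, pairs) {
  score_pairs(fit$scorer, pairs, fit$idsm, fit$imsm)$score
}

#' Pipeline configuration
#'
#' Collects every tunable of the scoring pipeline with the working defaults:
#' semantic decay 0.5, raw kernel bandwidths 1, balanced negatives, top 100
#' features, 500-tree forests, strict leakage (similarities rebuilt from the
#' training-only adjacency in every CV fold).
#'
#' @param delta semantic decay factor.
#' @param alpha_disease,alpha_mirna raw GIPK bandwidths.
#' @param n_negative negatives per training set (NULL = one per positive).
#' @param k features kept after importance ranking (capped at the feature
#'   count; when k covers every feature, selection is skipped).
#' @param imp_ntree,imp_folds,imp_type importance-forest settings, see
#'   [variable_importance()].
#' @param rf_ntree,mtry scorer-forest settings, see [train_rf()].
#' @param leakage `"strict"` (per-fold similarity rebuild) or `"shared"`
#'   (similarities from the full adjacency, the cheaper protocol).
#' @param seed integer seed for every stochastic step.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(delta = 0.5, alpha_disease = 1, alpha_mirna = 1,
                            n_negative = NULL, k = 100,
                            imp_ntree = 500, imp_folds = 10,
                            imp_type = "accuracy",
                            rf_ntree = 500, mtry = NULL,
                            leakage = c("strict", "shared"), seed = 1) {
  structure(list(delta = delta, alpha_disease = alpha_disease,
                 alpha_mirna = alpha_mirna, n_negative = n_negative, k = k,
                 imp_ntree = imp_ntree, imp_folds = imp_folds,
                 imp_type = imp_type, rf_ntree = rf_ntree, mtry = mtry,
                 leakage = match.arg(leakage), seed = seed),
            class = "pipeline_config")
}

## Candidate unlabelled pairs = zero cells of the full adjacency.
.unlabelled_pairs <- function(adj) {
  z <- which(adj == 0)
  data.frame(disease = rownames(adj)[((z - 1) %% nrow(adj)) + 1],
             mirna = colnames(adj)[((z - 1) %/% nrow(adj)) + 1],
             stringsAsFactors = FALSE)
}

#' Repeated k-fold cross-validation with ranking evaluation
#'
#' Positives are split evenly into k folds (per repeat); each fold is held
#' out in turn, the pipeline is refit on the remaining positives and every
#' held-out positive is ranked by score against all unlabelled pairs of the
#' full adjacency. Under the strict leakage policy the kernel similarities,
#' the training set and the feature selection are all rebuilt from the
#' training-only adjacency.
#'
#' @param assoc full `association_table`.
#' @param dags `dag_collection` (NULL = kernel-only disease similarity).
#' @param mfsm functional `similarity_matrix` (NULL = kernel-only).
#' @param k number of folds (default 5).
#' @param repeats number of random re-partitions (default 1).
#' @param config a [pipeline_config()].
#' @param score_fun optional `(train_assoc, pairs) -> scores` replacing the
#'   pipeline fit (for protocol-level testing).
#' @return A `cv_result`: list with `ranks` (data frame: repeat, fold,
#'   disease, mirna, score, rank, candidates), `auc_pooled` (positives
#'   vs unlabelled scores pooled over folds and repeats), `auc_per_repeat`,
#'   and the call settings.
#' @export
kfold_cv <- function(assoc, dags = NULL, mfsm = NULL, k = 5, repeats = 1,
                     config = pipeline_config(), score_fun = NULL) {
  stopifnot(k >= 2)
  index <- attr(assoc, "index")
  adj_full <- build_adjacency(assoc, index)
  unlab <- .unlabelled_pairs(adj_full)
  shared_sims <- if (identical(config$leakage, "shared")) {
    .build_similarities(adj_full, index, dags, mfsm, config)
  } else NULL
  set.seed(config$seed)
  fold_seeds <- sample.int(.Machine$integer.max %/% 2, repeats * k)
  all_ranks <- list()
  pos_scores_all <- c()
  neg_scores_all <- c()
  auc_rep <- numeric(repeats)
  for (r in seq_len(repeats)) {
    fold_id <- sample(rep_len(seq_len(k), nrow(assoc)))
    rep_pos <- c(); rep_neg <- c()
    for (f in seq_len(k)) {
      test <- assoc[fold_id == f, , drop = FALSE]
      train <- association_table(assoc$disease[fold_id != f],
                                 assoc$mirna[fold_id != f], index = index)
      cfg <- config
      cfg$seed <- fold_seeds[(r - 1) * k + f]
      to_score <- rbind(test[c("disease", "mirna")], unlab)
      if (!is.null(score_fun)) {
        scores <- score_fun(train, to_score)
      } else {
        fit <- .fit_pipeline(train, index, dags, mfsm, cfg,
                             similarities = shared_sims)
        scores <- .score_with(fit, to_score)
      }
      s_test <- scores[seq_len(nrow(test))]
      s_unlab <- scores[-seq_len(nrow(test))]
      ranks <- vapply(s_test, .rank_among, 1, candidates = s_unlab)
      all_ranks[[length(all_ranks) + 1L]] <- data.frame(
        repeat_id = r, fold = f, disease = test$disease, mirna = test$mirna,
        score = s_test, rank = ranks, candidates = length(s_unlab) + 1L,
        stringsAsFactors = FALSE)
      rep_pos <- c(rep_pos, s_test); rep_neg <- c(rep_neg, s_unlab)
    }
    auc_rep[r] <- roc_auc(c(rep_pos, rep_neg),
                          rep(c(1, 0), c(length(rep_pos), length(rep_neg))))$auc
    pos_scores_all <- c(pos_scores_all, rep_pos)
    neg_scores_all <- c(neg_scores_all, rep_neg)
  }
  auc_pooled <- roc_auc(
    c(pos_scores_all, neg_scores_all),
    rep(c(1, 0), c(length(pos_scores_all), length(neg_scores_all))))$auc
  structure(list(ranks = do.call(rbind, all_ranks), auc_pooled = auc_pooled,
                 auc_per_repeat = auc_rep, k = k, repeats = repeats,
                 config = config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV (%d repeat%s): pooled AUC = %.4f, mean per-repeat AUC = %.4f\n",
              x$k, x$repeats, if (x$repeats > 1) "s" else "",
              x$auc_pooled, mean(x$auc_per_repeat)))
  invisible(x)
}

#' Global and local leave-one-out cross-validation
#'
#' Each positive is held out in turn and ranked against the unlabelled
#' pairs: against all of them (global) or only those sharing its disease
#' (local). `mode = "exact"` refits the pipeline for every positive;
#' `mode = "grouped"` refits once per disease with all of that disease's
#' positives removed — a cheaper approximation for desk-scale runs.
#'
#' @param assoc full `association_table`.
#' @param dags,mfsm as in [kfold_cv()].
#' @param protocol `"global"` or `"local"` candidate sets.
#' @param mode `"grouped"` (default) or `"exact"`.
#' @param config a [pipeline_config()].
#' @param score_fun optional scorer override, see [kfold_cv()].
#' @return A `cv_result` (see [kfold_cv()]); AUC is computed from the
#'   held-out scores against the unlabelled scores of the corresponding
#'   candidate sets.
#' @export
loocv <- function(assoc, dags = NULL, mfsm = NULL,
                  protocol = c("global", "local"),
                  mode = c("grouped", "exact"),
                  config = pipeline_config(), score_fun = NULL) {
  protocol <- match.arg(protocol)
  mode <- match.arg(mode)
  index <- attr(assoc, "index")
  adj_full <- build_adjacency(assoc, index)
  unlab <- .unlabelled_pairs(adj_full)
  if (nrow(assoc) < 2) stop("need at least two positives for LOOCV")
  shared_sims <- if (identical(config$leakage, "shared")) {
    .build_similarities(adj_full, index, dags, mfsm, config)
  } else NULL
  groups <- if (mode == "grouped") split(seq_len(nrow(assoc)), assoc$disease)
            else as.list(seq_len(nrow(assoc)))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max %/% 2, length(groups))
  out <- list(); pos_s <- c(); neg_s <- c()
  for (g in seq_along(groups)) {
    idx_test <- groups[[g]]
    train <- association_table(assoc$disease[-idx_test],
                               assoc$mirna[-idx_test], index = index)
    cfg <- config; cfg$seed <- seeds[g]
    scorer <- NULL
    score_all <- function(pairs) {
      if (!is.null(score_fun)) return(score_fun(train, pairs))
      if (is.null(scorer)) {
        scorer <<- .fit_pipeline(train, index, dags, mfsm, cfg,
                                 similarities = shared_sims)
      }
      .score_with(scorer, pairs)
    }
    for (i in idx_test) {
      test <- assoc[i, , drop = FALSE]
      cand <- if (protocol == "local")
        unlab[unlab$disease == test$disease, , drop = FALSE] else unlab
      scores <- score_all(rbind(test[c("disease", "mirna")], cand))
      s_test <- scores[1]; s_cand <- scores[-1]
      out[[length(out) + 1L]] <- data.frame(
        disease = test$disease, mirna = test$mirna, score = s_test,
        rank = .rank_among(s_test, s_cand), candidates = length(s_cand) + 1L,
        protocol = protocol, stringsAsFactors = FALSE)
      pos_s <- c(pos_s, s_test); neg_s <- c(neg_s, s_cand)
    }
  }
  auc <- roc_auc(c(pos_s, neg_s),
                 rep(c(1, 0), c(length(pos_s), length(neg_s))))$auc
  structure(list(ranks = do.call(rbind, out), auc_pooled = auc,
                 auc_per_repeat = auc, k = NA_integer_, repeats = 1L,
                 protocol = protocol, mode = mode, config = config),
            class = "cv_result")
}

#' Novel-disease hold-out scoring
#'
#' Removes every known association of one disease before any similarity,
#' feature or model construction, then scores all miRNAs for that disease
#' and returns them sorted by descending score — the protocol for
#' predicting partners of a disease with no usable training associations.
#'
#' @param assoc full `association_table`.
#' @param disease name of the disease to hold out.
#' @param dags,mfsm as in [kfold_cv()].
#' @param config a [pipeline_config()].
#' @param score_fun optional scorer override.
#' @return Data frame `disease`, `mirna`, `score`, sorted by descending
#'   score (one row per miRNA).
#' @export
novel_disease_holdout <- function(assoc, disease, dags = NULL, mfsm = NULL,
                                  config = pipeline_config(),
                                  score_fun = NULL) {
  index <- attr(assoc, "index")
  if (!disease %in% index$diseases) stop("unknown disease: ", disease)
  keep <- assoc$disease != disease
  train <- association_table(assoc$disease[keep], assoc$mirna[keep],
                             index = index)
  pairs <- data.frame(disease = disease, mirna = index$mirnas,
                      stringsAsFactors = FALSE)
  scores <- if (!is.null(score_fun)) score_fun(train, pairs) else
    .score_with(.fit_pipeline(train, index, dags, mfsm, config), pairs)
  out <- data.frame(disease = disease, mirna = index$mirnas, score = scores,
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$mirna), , drop = FALSE]
}
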