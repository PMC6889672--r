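test_that("ROC curve and AUC match hand-enumerated toys", {
  r <- roc_auc(c(0.9, 0.7, 0.8, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 0.75)
  # after the top two scores: TPR = 0.5 (1 of 2 positives), FPR = 0.5
  expect_true(any(r$points$fpr == 0.5 & r$points$tpr == 0.5))
  expect_equal(r$points$fpr[1], 0); expect_equal(r$points$tpr[1], 0)
  expect_equal(utils::tail(r$points$fpr, 1), 1)
  expect_equal(utils::tail(r$points$tpr, 1), 1)

  expect_equal(roc_auc(c(1, 0.9, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(c(0.5, 0.5, 0.5, 0.5), c(1, 0, 1, 0))$auc, 0.5) # ties
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "one positive and one negative")
})

test_that("AUC equals the Mann-Whitney closed form on random score sets", {
  set.seed(53)
  for (rep in 1:30) {
    n <- sample(10:60, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(runif(n), sample(1:3, 1))   # rounding induces ties
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("shuffled labels give a null AUC near one half", {
  set.seed(59)
  scores <- runif(1000)
  labels <- rbinom(1000, 1, 0.4)
  expect_lt(abs(roc_auc(scores, labels)$auc - 0.5), 0.05)
})

test_that("ranks among candidate scores follow the descending-sort rule", {
  expect_equal(irfmda:::.rank_among(0.9, c(0.5, 0.4, 0.3)), 1)
  expect_equal(irfmda:::.rank_among(0.1, c(0.5, 0.4, 0.3)), 4)   # N + 1
  expect_equal(irfmda:::.rank_among(0.5, c(0.5, 0.4)), 1.5)      # mean rank tie
})

# deterministic stub scorer: score depends only on the pair's names, so
# protocol mechanics can be tested independently of the forest
stub_scorer <- function(train, pairs) {
  h <- vapply(paste(pairs$disease, pairs$mirna), function(s) {
    u <- utf8ToInt(s)
    sum(u * seq_along(u))
  }, 1)
  (h %% 97) / 97
}

test_that("k-fold CV partitions evenly and ranks against the oracle", {
  idx <- entity_index(paste0("dd", 1:4), paste0("mm", 1:5))
  cells <- c(1, 2, 6, 8, 11, 15, 18, 20)
  assoc <- association_table(idx$diseases[((cells - 1) %% 4) + 1],
                             idx$mirnas[((cells - 1) %/% 4) + 1], index = idx)
  cv <- kfold_cv(assoc, k = 4, repeats = 2,
                 config = pipeline_config(seed = 11), score_fun = stub_scorer)
  # fold sizes differ by at most one; every positive tested once per repeat
  for (r in 1:2) {
    rk <- cv$ranks[cv$ranks$repeat_id == r, ]
    expect_equal(nrow(rk), nrow(assoc))
    expect_setequal(paste(rk$disease, rk$mirna),
                    paste(assoc$disease, assoc$mirna))
    expect_lte(diff(range(table(rk$fold))), 1)
  }
  # same seed reproduces identical partitions and ranks
  cv2 <- kfold_cv(assoc, k = 4, repeats = 2,
                  config = pipeline_config(seed = 11), score_fun = stub_scorer)
  expect_identical(cv$ranks, cv2$ranks)

  # brute-force re-ranking oracle on the stub scores
  adj <- build_adjacency(assoc)
  unlab <- irfmda:::.unlabelled_pairs(adj)
  s_unlab <- stub_scorer(NULL, unlab)
  for (i in seq_len(nrow(cv$ranks))) {
    row <- cv$ranks[i, ]
    s <- stub_scorer(NULL, row)
    expect_equal(row$rank,
                 1 + sum(s_unlab > s) + sum(s_unlab == s) / 2)
    expect_equal(row$candidates, nrow(unlab) + 1)
  }
})

test_that("global and local LOOCV use the right candidate sets", {
  idx <- entity_index(c("da", "db"), paste0("mm", 1:3))
  assoc <- association_table(c("da", "da", "db"), c("mm1", "mm2", "mm3"),
                             index = idx)
  adj <- build_adjacency(assoc)
  unlab <- irfmda:::.unlabelled_pairs(adj)

  glob <- loocv(assoc, protocol = "global", mode = "exact",
                config = pipeline_config(seed = 3), score_fun = stub_scorer)
  loc <- loocv(assoc, protocol = "local", mode = "exact",
               config = pipeline_config(seed = 3), score_fun = stub_scorer)
  expect_equal(nrow(glob$ranks), nrow(assoc))
  expect_equal(unique(glob$ranks$candidates), nrow(unlab) + 1)
  # local candidate sets are per-disease subsets of the global one
  for (i in seq_len(nrow(loc$ranks))) {
    n_local <- sum(unlab$disease == loc$ranks$disease[i]) + 1
    expect_equal(loc$ranks$candidates[i], n_local)
    expect_lte(loc$ranks$candidates[i], idx$nm)
  }
  # oracle check of every global rank
  s_unlab <- stub_scorer(NULL, unlab)
  for (i in seq_len(nrow(glob$ranks))) {
    s <- stub_scorer(NULL, glob$ranks[i, ])
    expect_equal(glob$ranks$rank[i], 1 + sum(s_unlab > s) + sum(s_unlab == s) / 2)
  }

  # disease with every other miRNA already positive: candidate set size 1
  idx2 <- entity_index(c("dx", "dy"), c("m1", "m2"))
  assoc2 <- association_table(c("dx", "dx", "dy"), c("m1", "m2", "m1"),
                              index = idx2)
  loc2 <- loocv(assoc2, protocol = "local", mode = "exact",
                config = pipeline_config(seed = 4), score_fun = stub_scorer)
  row_dx <- loc2$ranks[loc2$ranks$disease == "dx", ]
  expect_true(all(row_dx$candidates == 1))
  expect_true(all(row_dx$rank == 1))
})

test_that("grouped LOOCV masks all of a disease's positives per refit", {
  seen <- new.env(); seen$trains <- list()
  spy <- function(train, pairs) {
    seen$trains[[length(seen$trains) + 1]] <- train
    stub_scorer(train, pairs)
  }
  idx <- entity_index(c("da", "db"), paste0("mm", 1:3))
  assoc <- association_table(c("da", "da", "db"), c("mm1", "mm2", "mm3"),
                             index = idx)
  res <- loocv(assoc, protocol = "global", mode = "grouped",
               config = pipeline_config(seed = 5), score_fun = spy)
  expect_equal(nrow(res$ranks), 3)
  for (tr in seen$trains) {
    # each training table omits an entire disease
    expect_true(length(setdiff(unique(assoc$disease), unique(tr$disease))) >= 1)
  }
})

test_that("novel-disease holdout scores every miRNA of the masked disease", {
  w <- make_planted_world(nd = 6, nm = 8, groups = 2, seed = 61)
  out <- novel_disease_holdout(w$assoc, w$index$diseases[1],
                               config = pipeline_config(seed = 6),
                               score_fun = stub_scorer)
  expect_equal(nrow(out), w$index$nm)
  expect_equal(sort(out$mirna), sort(w$index$mirnas))
  expect_true(!is.unsorted(rev(out$score)))
  expect_error(novel_disease_holdout(w$assoc, "ghost", score_fun = stub_scorer),
               "unknown disease")
})
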