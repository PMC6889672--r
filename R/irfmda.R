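#' Fit the miRNA-disease association scoring model
#'
#' Runs the four-stage pipeline on an association catalogue: (1) balanced
#' sample selection (all known associations as positives, an equal number of
#' sampled unlabelled pairs as negatives); (2) sample representation by
#' concatenated integrated-similarity rows (miRNA block then disease block),
#' min-max normalised; (3) feature selection by out-of-bag permutation
#' variable importance; (4) random-forest regression on the reduced feature
#' set. The fitted object scores any disease-miRNA pair in [0, 1].
#'
#' @param assoc an `association_table` (see [read_associations()]).
#' @param dags optional `dag_collection` for disease semantic similarity;
#'   without it the disease similarity is the Gaussian kernel alone.
#' @param mfsm optional functional miRNA `similarity_matrix`; without it the
#'   miRNA similarity is the Gaussian kernel alone.
#' @param config a [pipeline_config()].
#' @return An object of class `irfmda` with components `index`, `adj`,
#'   `idsm`, `imsm`, `importance`, `ranking`, `scorer`, `config`, `call`.
#' @seealso [predict.irfmda()], [kfold_cv()], [loocv()]
#' @examples
#' w <- make_planted_world(nd = 12, nm = 16, groups = 2, seed = 7)
#' fit <- irfmda(w$assoc, w$dags, w$mfsm,
#'               config = pipeline_config(k = 10, imp_ntree = 50,
#'                                        imp_folds = 1, rf_ntree = 50))
#' head(predict(fit))
#' @export
irfmda <- function(assoc, dags = NULL, mfsm = NULL,
                   config = pipeline_config()) {
  index <- attr(assoc, "index")
  if (is.null(index)) stop("association table carries no entity index")
  fit <- .fit_pipeline(assoc, index, dags, mfsm, config)
  structure(
    list(index = index, adj = fit$adj, idsm = fit$idsm, imsm = fit$imsm,
         dataset = fit$dataset, importance = fit$importance,
         ranking = fit$ranking, scorer = fit$scorer, k = fit$k,
         config = config, call = match.call()),
    class = "irfmda"
  )
}

#' @export
print.irfmda <- function(x, ...) {
  cat("miRNA-disease association scorer (random-forest regression)\n")
  cat(sprintf("  entities: %d diseases x %d miRNAs, %d known associations\n",
              x$index$nd, x$index$nm, sum(x$adj)))
  cat(sprintf("  features: %d of %d kept by permutation importance\n",
              x$k, x$index$nd + x$index$nm))
  cat(sprintf("  forest: ntree = %d, mtry = %d (seed %d)\n",
              x$scorer$config$ntree, x$scorer$config$mtry, x$config$seed))
  invisible(x)
}

#' @export
summary.irfmda <- function(object, ...) {
  oob <- object$scorer$forest$predicted
  y <- object$dataset$pairs$label
  structure(
    list(nd = object$index$nd, nm = object$index$nm,
         n_positive = sum(y == 1), n_negative = sum(y == 0),
         k = object$k, total_features = object$index$nd + object$index$nm,
         top_features = utils::head(object$ranking, 10),
         oob_accuracy = .threshold_accuracy(oob, y),
         oob_mse = mean((oob - y)^2)),
    class = "summary.irfmda"
  )
}

#' @export
print.summary.irfmda <- function(x, ...) {
  cat("miRNA-disease association scorer\n")
  cat(sprintf("  %d diseases x %d miRNAs; training set %d positives + %d negatives\n",
              x$nd, x$nm, x$n_positive, x$n_negative))
  cat(sprintf("  %d / %d features kept; OOB accuracy %.3f, OOB MSE %.4f\n",
              x$k, x$total_features, x$oob_accuracy, x$oob_mse))
  cat("  top-ranked features:\n")
  print(x$top_features, row.names = FALSE)
  invisible(x)
}

#' Score disease-miRNA pairs with a fitted model
#'
#' @param object an `irfmda` fit.
#' @param pairs data frame with columns `disease`, `mirna`; by default all
#'   unlabelled (adjacency-zero) pairs.
#' @param sort sort the result by disease and descending score (default
#'   TRUE).
#' @param ... unused.
#' @return Data frame `disease`, `mirna`, `score`.
#' @export
predict.irfmda <- function(object, pairs = NULL, sort = TRUE, ...) {
  if (is.null(pairs)) pairs <- .unlabelled_pairs(object$adj)
  out <- score_pairs(object$scorer, pairs, object$idsm, object$imsm)
  if (sort && nrow(out)) {
    out <- out[order(out$disease, -out$score, out$mirna), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Plot the importance ranking of a fitted model
#'
#' Barplot of the top permutation-importance scores (when feature selection
#' ran; otherwise a note is drawn).
#'
#' @param x an `irfmda` fit.
#' @param n number of features to show (default 20).
#' @param ... passed to [graphics::barplot()].
#' @export
plot.irfmda <- function(x, n = 20, ...) {
  if (is.null(x$importance)) {
    graphics::plot.new()
    graphics::text(0.5, 0.5, "no feature selection was run (k covered all features)")
    return(invisible(x))
  }
  top <- utils::head(x$ranking, n)
  graphics::barplot(rev(top$score), names.arg = rev(top$feature), horiz = TRUE,
                    las = 1, xlab = "mean OOB accuracy drop",
                    main = "Permutation variable importance", ...)
  invisible(x)
}

#' Run the full pipeline from input files and write every artifact
#'
#' Reads the three inputs, fits the model, scores all unlabelled pairs and
#' writes the intermediate similarity matrices, the importance ranking, the
#' predictions and a JSON manifest (parameters, seeds, record counts, file
#' hashes). Re-running with the same inputs and config is byte-identical.
#'
#' @param associations path to the association TSV.
#' @param dags optional path to the DAG edge-list TSV.
#' @param functional optional path to the functional similarity TSV.
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @return Invisibly, the fitted `irfmda` object; side effect: artifacts in
#'   `out_dir`.
#' @export
run_pipeline <- function(associations, dags = NULL, functional = NULL,
                         out_dir, config = pipeline_config()) {
  t0 <- Sys.time()
  assoc <- read_associations(associations)
  dag_col <- if (!is.null(dags)) read_dag_collection(dags) else NULL
  mfsm <- if (!is.null(functional)) read_similarity_matrix(functional) else NULL
  index <- attr(assoc, "index")
  if (config$k > index$nd + index$nm) {
    stop("config k = ", config$k, " exceeds the feature count ",
         index$nd + index$nm)
  }
  message(sprintf("[irfmda] %d diseases, %d miRNAs, %d associations",
                  index$nd, index$nm, nrow(assoc)))
  fit <- irfmda(assoc, dag_col, mfsm, config = config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_similarity_matrix(fit$idsm, file.path(out_dir, "integrated_disease_similarity.tsv"))
  write_similarity_matrix(fit$imsm, file.path(out_dir, "integrated_mirna_similarity.tsv"))
  utils::write.table(fit$ranking, file.path(out_dir, "feature_ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  preds <- predict(fit)
  pred_path <- file.path(out_dir, "predictions.tsv")
  writeLines(c("disease\tmirna\tscore",
               sprintf("%s\t%s\t%.10g", preds$disease, preds$mirna,
                       preds$score)),
             pred_path)
  manifest <- list(
    inputs = list(associations = unname(tools::md5sum(associations)),
                  dags = if (!is.null(dags)) unname(tools::md5sum(dags)),
                  functional = if (!is.null(functional)) unname(tools::md5sum(functional))),
    counts = list(diseases = index$nd, mirnas = index$nm,
                  positives = nrow(assoc),
                  negatives = sum(fit$dataset$pairs$label == 0),
                  features_kept = fit$k),
    config = unclass(config),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  message(sprintf("[irfmda] wrote %d predictions to %s", nrow(preds), pred_path))
  invisible(fit)
}
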