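## Labelled training-set construction: balanced negative sampling, pair
## feature vectors (miRNA similarity block then disease similarity block),
## per-column min-max normalisation.

#' Sample unlabelled pairs as negatives
#'
#' Draws `count` distinct (disease, miRNA) pairs uniformly from the zero
#' cells of the adjacency matrix.
#'
#' @param adj binary adjacency matrix.
#' @param count number of negatives; must not exceed the number of zero
#'   cells.
#' @param seed integer seed; required so that the draw is reproducible.
#' @return Data frame with columns `disease`, `mirna`, `label` (all 0).
#' @export
sample_negatives <- function(adj, count, seed) {
  zero_cells <- which(adj == 0)
  if (count > length(zero_cells)) {
    stop("requested ", count, " negatives but only ", length(zero_cells),
         " unlabelled pairs exist")
  }
  set.seed(seed)
  picked <- if (count == 0) integer(0) else
    sample(zero_cells, count, replace = FALSE)
  ri <- ((picked - 1) %% nrow(adj)) + 1
  ci <- ((picked - 1) %/% nrow(adj)) + 1
  data.frame(disease = rownames(adj)[ri], mirna = colnames(adj)[ci],
             label = rep(0, length(ri)), stringsAsFactors = FALSE)
}

#' Build pair feature vectors from the integrated similarity matrices
#'
#' A pair (d, m) is represented by the miRNA m's row of the integrated miRNA
#' similarity matrix (nm values, names `m:<miRNA>`) followed by the disease
#' d's row of the integrated disease similarity matrix (nd values, names
#' `d:<disease>`), giving nm + nd features (878 for the 495-miRNA,
#' 383-disease association catalogue).
#'
#' @param pairs data frame with columns `disease`, `mirna` and optionally
#'   `label`.
#' @param idsm integrated disease `similarity_matrix`.
#' @param imsm integrated miRNA `similarity_matrix`.
#' @return A `labeled_dataset`: list with `pairs` (the input data frame),
#'   `features` (numeric matrix, one row per pair), `normalized` (FALSE) and
#'   `stats` (NULL until [minmax_normalize()]).
#' @export
build_features <- function(pairs, idsm, imsm) {
  di <- match(pairs$disease, rownames(idsm))
  mi <- match(pairs$mirna, rownames(imsm))
  if (anyNA(di)) stop("unknown disease: ", pairs$disease[which(is.na(di))[1]])
  if (anyNA(mi)) stop("unknown miRNA: ", pairs$mirna[which(is.na(mi))[1]])
  feats <- cbind(unclass(imsm)[mi, , drop = FALSE],
                 unclass(idsm)[di, , drop = FALSE])
  colnames(feats) <- c(paste0("m:", rownames(imsm)),
                       paste0("d:", rownames(idsm)))
  rownames(feats) <- NULL
  structure(list(pairs = as.data.frame(pairs), features = feats,
                 normalized = FALSE, stats = NULL),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("Labelled pair dataset: %d samples x %d features%s\n",
              nrow(x$features), ncol(x$features),
              if (isTRUE(x$normalized)) " (min-max normalized)" else ""))
  if (!is.null(x$pairs$label)) {
    cat("  labels:", sum(x$pairs$label == 1), "positive /",
        sum(x$pairs$label == 0), "negative\n")
  }
  invisible(x)
}

#' Min-max normalise a labelled dataset
#'
#' Each feature column is rescaled to [0, 1] with its own minimum and
#' maximum over the dataset's samples; the per-column stats are stored so
#' the identical transform can be applied to prediction-time pairs.
#' Constant columns map to 0.
#'
#' @param dataset a `labeled_dataset` from [build_features()].
#' @return The dataset with normalised `features`, `normalized = TRUE` and
#'   `stats` (data frame of per-feature `min`, `max`).
#' @export
minmax_normalize <- function(dataset) {
  f <- dataset$features
  if (nrow(f) == 0L) stop("empty dataset")
  mins <- apply(f, 2, min)
  maxs <- apply(f, 2, max)
  dataset$features <- apply_normalization_stats(f, mins, maxs)
  dataset$stats <- data.frame(feature = colnames(f), min = mins, max = maxs,
                              row.names = NULL, stringsAsFactors = FALSE)
  dataset$normalized <- TRUE
  dataset
}

#' Apply stored normalisation stats to a feature matrix
#'
#' Used at prediction time: new pair vectors are rescaled with the training
#' set's per-column min/max and clipped to [0, 1].
#'
#' @param features numeric matrix whose columns match `stats$feature`.
#' @param mins,maxs per-column minima and maxima (numeric vectors).
#' @return Normalised matrix with entries in [0, 1].
#' @export
apply_normalization_stats <- function(features, mins, maxs) {
  rng <- maxs - mins
  out <- sweep(features, 2, mins, `-`)
  pos <- rng > 0
  out[, pos] <- sweep(out[, pos, drop = FALSE], 2, rng[pos], `/`)
  out[, !pos] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Assemble the balanced training dataset for an association catalogue
#'
#' Positives are all known associations; negatives are `nrow(assoc)`
#' unlabelled pairs drawn by [sample_negatives()] (balanced 1:1 by default).
#'
#' @param assoc an `association_table`.
#' @param adj adjacency matrix of `assoc` (rebuilt if NULL).
#' @param idsm,imsm integrated similarity matrices.
#' @param seed seed for negative sampling.
#' @param n_negative number of negatives; defaults to the positive count.
#' @return A normalised `labeled_dataset`.
#' @export
build_training_dataset <- function(assoc, idsm, imsm, seed,
                                   adj = NULL, n_negative = nrow(assoc)) {
  if (is.null(adj)) adj <- build_adjacency(assoc)
  pos <- data.frame(disease = assoc$disease, mirna = assoc$mirna, label = 1,
                    stringsAsFactors = FALSE)
  neg <- sample_negatives(adj, n_negative, seed)
  minmax_normalize(build_features(rbind(pos, neg), idsm, imsm))
}
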