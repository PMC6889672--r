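## Disease semantic similarity over MeSH-style ancestor DAGs.
##
## Model 1: exponential-decay contributions down the DAG (decay delta).
## Model 2: information-content contributions, -log of the fraction of DAGs
## in the collection that contain the vertex.

#' Model-1 semantic contributions within one disease DAG
#'
#' The disease itself contributes 1; every ancestor contributes `delta`
#' times the maximum contribution among its children *inside this DAG*, so
#' contributions decay geometrically with distance from the disease.
#'
#' @param dag one element of a [dag_collection()] (fields `disease`,
#'   `vertices`, `edges`).
#' @param delta decay factor in (0, 1); default 0.5.
#' @return Named numeric vector of contributions over the DAG's vertices.
#' @export
contributions_model1 <- function(dag, delta = 0.5) {
  stopifnot(is.numeric(delta), length(delta) == 1L, delta > 0, delta < 1)
  verts <- dag$vertices
  cs <- stats::setNames(rep(NA_real_, length(verts)), verts)
  cs[dag$disease] <- 1
  ## children of v inside DAG(D): edge rows with parent == v
  kids <- split(dag$edges$child, factor(dag$edges$parent, levels = verts))
  remaining <- setdiff(verts, dag$disease)
  while (length(remaining)) {
    progressed <- FALSE
    for (v in remaining) {
      ch <- kids[[v]]
      if (length(ch) == 0L) {
        stop("vertex ", v, " of DAG(", dag$disease,
             ") is not an ancestor of the disease (malformed DAG)")
      }
      vals <- cs[ch]
      if (!anyNA(vals)) {
        cs[v] <- delta * max(vals)
        progressed <- TRUE
      }
    }
    remaining <- names(cs)[is.na(cs)]
    if (length(remaining) && !progressed) {
      stop("unreachable vertices in DAG(", dag$disease, "): ",
           paste(remaining, collapse = ", "))
    }
  }
  cs
}

#' Model-2 semantic contributions across a DAG collection
#'
#' A vertex's contribution is `-log(n_containing / n_diseases)` where
#' `n_containing` counts the DAGs whose vertex set includes it and
#' `n_diseases` is the collection size. A vertex present in every DAG
#' contributes 0; rare vertices contribute more. The score of a vertex is
#' the same in every DAG that contains it.
#'
#' @param dags a [dag_collection()].
#' @param base logarithm base (default natural log; downstream similarity is
#'   invariant to the base since it cancels in the ratio).
#' @return Named numeric vector over all vertices of the collection.
#' @export
contributions_model2 <- function(dags, base = exp(1)) {
  if (length(dags) == 0L) stop("empty DAG collection")
  n_dis <- attr(dags, "n_diseases")
  if (is.null(n_dis)) n_dis <- length(dags)
  counts <- table(unlist(lapply(dags, `[[`, "vertices"), use.names = FALSE))
  stats::setNames(-log(as.numeric(counts) / n_dis, base = base),
                  names(counts))
}

#' Disease semantic similarity matrix (model 1 or 2)
#'
#' The similarity of two diseases is the sum, over the shared vertices of
#' their DAGs, of both diseases' contribution scores, divided by the sum of
#' the two semantic values (the total contribution within each DAG).
#'
#' @param dags a [dag_collection()] covering the diseases of interest.
#' @param model 1 (decay contributions) or 2 (information-content
#'   contributions).
#' @param delta decay for model 1; ignored for model 2.
#' @return A `similarity_matrix` of kind `"semantic1"` or `"semantic2"` over
#'   the collection's diseases. For model 2, a pair whose semantic values are
#'   both zero (every vertex common to all DAGs) gets similarity 1 on the
#'   diagonal and 0 off it.
#' @export
semantic_similarity <- function(dags, model = 1, delta = 0.5) {
  stopifnot(model %in% c(1, 2))
  diseases <- vapply(dags, `[[`, "", "disease")
  n <- length(diseases)
  if (model == 1) {
    contribs <- lapply(dags, contributions_model1, delta = delta)
  } else {
    cs2 <- contributions_model2(dags)
    contribs <- lapply(dags, function(d) cs2[d$vertices])
  }
  dvals <- vapply(contribs, sum, 1)
  sim <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ci <- contribs[[i]]
    for (j in i:n) {
      shared <- intersect(names(ci), names(contribs[[j]]))
      denom <- dvals[i] + dvals[j]
      if (denom == 0) {
        sim[i, j] <- as.numeric(i == j)
      } else {
        sim[i, j] <- sum(ci[shared] + contribs[[j]][shared]) / denom
      }
      sim[j, i] <- sim[i, j]
    }
  }
  similarity_matrix(sim, labels = unname(diseases),
                    kind = if (model == 1) "semantic1" else "semantic2",
                    tol = 1e-12)
}
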