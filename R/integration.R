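## Integration of semantic/functional similarity with the GIPK fallback.

#' Integrated disease similarity
#'
#' Where both diseases have DAGs, the entry is the mean of the two semantic
#' similarity scores; otherwise the Gaussian kernel score is used.
#'
#' @param dss1,dss2 semantic `similarity_matrix` objects (models 1 and 2).
#'   They may cover only a subset of the diseases in `dks`.
#' @param dks GIPK disease `similarity_matrix` over all diseases; fixes the
#'   output labels and order.
#' @param has_dag logical vector over `rownames(dks)` saying which diseases
#'   have DAGs; defaults to membership in `rownames(dss1)`.
#' @return A `similarity_matrix` of kind `"integrated"` with the labels of
#'   `dks`.
#' @export
integrate_disease_similarity <- function(dss1, dss2, dks,
                                         has_dag = rownames(dks) %in% rownames(dss1)) {
  labels <- rownames(dks)
  if (!identical(rownames(dss1), rownames(dss2))) {
    stop("semantic similarity matrices have different labels")
  }
  stopifnot(length(has_dag) == length(labels))
  out <- unclass(dks)[labels, labels]
  covered <- labels[has_dag & labels %in% rownames(dss1)]
  if (length(covered)) {
    sem <- (unclass(dss1)[covered, covered] +
            unclass(dss2)[covered, covered]) / 2
    out[covered, covered] <- sem
  }
  similarity_matrix(out, labels = labels, kind = "integrated", tol = 1e-12)
}

#' Integrated miRNA similarity
#'
#' Where both miRNAs are covered by the functional similarity matrix, the
#' functional score is used as-is; otherwise the Gaussian kernel score.
#'
#' @param mfsm functional `similarity_matrix` (may cover a subset).
#' @param mks GIPK miRNA `similarity_matrix` over all miRNAs; fixes labels.
#' @param has_functional logical over `rownames(mks)`; defaults to
#'   membership in `rownames(mfsm)`.
#' @return A `similarity_matrix` of kind `"integrated"`.
#' @export
integrate_mirna_similarity <- function(mfsm, mks,
                                       has_functional = rownames(mks) %in% rownames(mfsm)) {
  labels <- rownames(mks)
  stopifnot(length(has_functional) == length(labels))
  out <- unclass(mks)[labels, labels]
  ## functional entries for miRNAs outside the catalogue are ignored
  covered <- labels[has_functional & labels %in% rownames(mfsm)]
  if (length(covered)) {
    out[covered, covered] <- unclass(mfsm)[covered, covered]
  }
  similarity_matrix(out, labels = labels, kind = "integrated", tol = 1e-12)
}
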