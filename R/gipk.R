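## Gaussian interaction profile kernel (GIPK) similarity.
##
## Profiles are the rows (diseases) or columns (miRNAs) of the binary
## adjacency matrix; the kernel is exp(-alpha * squared Euclidean distance),
## with alpha the raw bandwidth divided by the mean squared profile norm.

#' GIPK bandwidth from a set of interaction profiles
#'
#' @param profiles numeric matrix, one profile per row (binary 0/1 entries).
#' @param alpha_prime raw bandwidth, default 1.
#' @return Normalised bandwidth `alpha_prime / mean(rowSums(profiles^2))`.
#' @export
gipk_bandwidth <- function(profiles, alpha_prime = 1) {
  stopifnot(is.numeric(alpha_prime), alpha_prime > 0)
  profiles <- as.matrix(profiles)
  mean_sq <- mean(rowSums(profiles^2))
  if (mean_sq == 0) stop("degenerate profiles: all interaction profiles are zero")
  alpha_prime / mean_sq
}

#' GIPK similarity matrix of a profile set
#'
#' `exp(-alpha * ||p_i - p_j||^2)` for every pair of profiles, with `alpha`
#' from [gipk_bandwidth()]. Individual all-zero profiles are allowed (their
#' kernel with another all-zero profile is 1); only a fully zero set errors.
#'
#' @param profiles numeric matrix, one profile per row; rownames label the
#'   output.
#' @param alpha_prime raw bandwidth, default 1.
#' @return A `similarity_matrix` of kind `"gipk"`: symmetric, unit diagonal,
#'   entries in (0, 1].
#' @export
gipk_similarity <- function(profiles, alpha_prime = 1) {
  profiles <- as.matrix(profiles)
  alpha <- gipk_bandwidth(profiles, alpha_prime)
  sq <- rowSums(profiles^2)
  ## ||p_i - p_j||^2 = |p_i|^2 + |p_j|^2 - 2 p_i . p_j
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0
  k <- exp(-alpha * d2)
  diag(k) <- 1
  labels <- rownames(profiles)
  if (is.null(labels)) labels <- paste0("p", seq_len(nrow(profiles)))
  similarity_matrix(k, labels = labels, kind = "gipk", tol = 1e-12)
}

#' Disease- and miRNA-side GIPK similarities of an adjacency matrix
#'
#' Applies the shared kernel routine to the rows (disease profiles) and to
#' the columns (miRNA profiles) of the adjacency matrix.
#'
#' @param adj binary nd x nm adjacency matrix from [build_adjacency()].
#' @param alpha_prime_disease,alpha_prime_mirna raw bandwidths, default 1.
#' @return List with elements `disease` and `mirna`, each a GIPK
#'   `similarity_matrix`.
#' @export
gipk_from_adjacency <- function(adj, alpha_prime_disease = 1,
                                alpha_prime_mirna = 1) {
  list(
    disease = gipk_similarity(adj, alpha_prime_disease),
    mirna = gipk_similarity(t(adj), alpha_prime_mirna)
  )
}
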