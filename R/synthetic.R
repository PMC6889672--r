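## Desk-scale synthetic worlds with planted block structure.
##
## Diseases and miRNAs are partitioned into latent groups; a pair's
## association probability is p_in when their groups match and p_out
## otherwise. The disease DAGs share a per-group ancestor chain (so
## same-group diseases have high semantic similarity) and the miRNA
## functional similarity is base noise plus a within-group boost, giving
## every pipeline stage a signal to find without any external database.

#' Generate a planted-block synthetic world
#'
#' @param nd,nm numbers of diseases and miRNAs (defaults 40 and 60).
#' @param groups number of latent groups (default 4); entities are assigned
#'   to groups in contiguous, near-equal blocks.
#' @param p_in,p_out association probabilities within and across groups
#'   (defaults 0.35 and 0.02); `p_in >= p_out` required, equality giving a
#'   null world with no planted signal.
#' @param seed integer seed; every draw is reproducible from it.
#' @param functional_coverage fraction of miRNAs covered by the functional
#'   similarity matrix (default 1).
#' @return A `planted_world`: list with `index`, `disease_group`,
#'   `mirna_group`, `assoc` (association_table), `adj`, `dags`, `mfsm`,
#'   `params`.
#' @export
make_planted_world <- function(nd = 40, nm = 60, groups = 4,
                               p_in = 0.35, p_out = 0.02, seed = 1,
                               functional_coverage = 1) {
  stopifnot(groups >= 1, nd >= groups, nm >= groups,
            p_out >= 0, p_in <= 1, p_in >= p_out)
  set.seed(seed)
  diseases <- sprintf("disease_%02d", seq_len(nd))
  mirnas <- sprintf("mir-%03d", seq_len(nm))
  dgrp <- sort(rep_len(seq_len(groups), nd))
  mgrp <- sort(rep_len(seq_len(groups), nm))
  prob <- matrix(p_out, nd, nm)
  prob[outer(dgrp, mgrp, `==`)] <- p_in
  adj <- matrix(as.numeric(stats::runif(nd * nm) < prob), nd, nm,
                dimnames = list(diseases, mirnas))
  ## every pipeline stage needs at least one association overall
  if (sum(adj) == 0) adj[1, 1] <- 1
  idx <- entity_index(diseases, mirnas)
  pos <- which(adj == 1)
  assoc <- association_table(diseases[((pos - 1) %% nd) + 1],
                             mirnas[((pos - 1) %/% nd) + 1],
                             index = idx)
  ## DAGs: disease <- groupAncestor1 <- groupAncestor2 <- shared root
  edges <- do.call(rbind, lapply(seq_len(nd), function(i) {
    a1 <- sprintf("grp%d_anc1", dgrp[i])
    a2 <- sprintf("grp%d_anc2", dgrp[i])
    data.frame(disease = diseases[i],
               child = c(diseases[i], a1, a2),
               parent = c(a1, a2, "root"),
               stringsAsFactors = FALSE)
  }))
  dags <- dag_collection(edges)
  ## functional similarity: noise floor + within-group boost
  noise <- matrix(stats::runif(nm * nm, 0, 0.2), nm, nm)
  fsim <- (noise + t(noise)) / 2 + 0.5 * outer(mgrp, mgrp, `==`)
  fsim[fsim > 1] <- 1
  diag(fsim) <- 1
  covered <- sort(sample.int(nm, max(1, round(functional_coverage * nm))))
  mfsm <- similarity_matrix(fsim[covered, covered, drop = FALSE],
                            labels = mirnas[covered], kind = "functional")
  structure(
    list(index = idx, disease_group = stats::setNames(dgrp, diseases),
         mirna_group = stats::setNames(mgrp, mirnas),
         assoc = assoc, adj = adj, dags = dags, mfsm = mfsm,
         params = list(nd = nd, nm = nm, groups = groups, p_in = p_in,
                       p_out = p_out, seed = seed,
                       functional_coverage = functional_coverage)),
    class = "planted_world"
  )
}

#' @export
print.planted_world <- function(x, ...) {
  p <- x$params
  cat(sprintf("Planted world: %d diseases x %d miRNAs, %d groups, p_in = %.2f, p_out = %.2f, %d associations (seed %d)\n",
              p$nd, p$nm, p$groups, p$p_in, p$p_out, nrow(x$assoc), p$seed))
  invisible(x)
}

#' Write a synthetic world's input files
#'
#' Emits the three pipeline inputs (associations, DAG edge list, functional
#' similarity matrix) plus a JSON manifest of the generator parameters.
#'
#' @param world a `planted_world`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    associations = file.path(dir, "associations.tsv"),
    dags = file.path(dir, "dags.tsv"),
    functional = file.path(dir, "mirna_functional_similarity.tsv"),
    manifest = file.path(dir, "world_manifest.json")
  )
  write_associations(world$assoc, paths["associations"])
  write_dag_collection(world$dags, paths["dags"])
  write_similarity_matrix(world$mfsm, paths["functional"])
  jsonlite::write_json(world$params, paths["manifest"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Hand-checkable micro-fixtures
#'
#' Three named toy instances with their analytically derived expected
#' values: a parent/child DAG pair (model-1 similarity 0.6 at decay 0.5),
#' a sibling pair under a shared root (model-1 similarity 1/3; model-2
#' similarity 0 because the only shared vertex occurs in every DAG), and a
#' two-profile Gaussian-kernel toy whose off-diagonal is exp(-1).
#'
#' @return Named list of fixtures; each has the inputs needed to run the
#'   corresponding operation and an `expected` list of derived values.
#' @export
make_toy_instances <- function() {
  parent_child <- dag_collection(data.frame(
    disease = c("P", "D"), child = c("P", "D"), parent = c("-", "P"),
    stringsAsFactors = FALSE
  ))
  sibling <- dag_collection(data.frame(
    disease = c("R", "D1", "D2"), child = c("R", "D1", "D2"),
    parent = c("-", "R", "R"), stringsAsFactors = FALSE
  ))
  gipk_profiles <- matrix(c(1, 0, 1,
                            1, 1, 0), nrow = 2, byrow = TRUE,
                          dimnames = list(c("a", "b"), NULL))
  list(
    parent_child = list(dags = parent_child,
                        expected = list(dss1 = 0.6)),
    sibling = list(dags = sibling,
                   expected = list(dss1 = 1 / 3, dss2 = 0)),
    gipk = list(profiles = gipk_profiles,
                expected = list(alpha = 0.5, offdiag = exp(-1)))
  )
}
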