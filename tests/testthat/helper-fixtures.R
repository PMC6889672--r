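# Shared fixtures built in code at test time.

toys <- make_toy_instances()

# tiny association table: 2 diseases x 3 miRNAs, 3 pairs, row sums (2, 1)
tiny_assoc <- function() {
  association_table(c("dA", "dA", "dB"), c("m1", "m2", "m3"),
                    index = entity_index(c("dA", "dB"), c("m1", "m2", "m3")))
}

# random DAG forest over a small vertex universe, for oracle comparisons.
# Each disease's DAG is built downward-closed: ancestors are drawn from
# vertices with smaller index so acyclicity is guaranteed.
random_dag_forest <- function(n_dis = 4, n_anc = 4, p_edge = 0.5) {
  universe <- c(paste0("anc", seq_len(n_anc)), paste0("dis", seq_len(n_dis)))
  rows <- list()
  for (d in seq_len(n_dis)) {
    dname <- paste0("dis", d)
    verts <- dname
    frontier <- dname
    pool <- paste0("anc", seq_len(n_anc))
    edges <- NULL
    while (length(frontier)) {
      nxt <- c()
      for (v in frontier) {
        vi <- match(v, c(pool, paste0("dis", seq_len(n_dis))))
        cand <- if (v == dname) pool else {
          pi <- match(v, pool)
          if (is.na(pi) || pi <= 1) character(0) else pool[seq_len(pi - 1)]
        }
        parents <- cand[stats::runif(length(cand)) < p_edge]
        for (p in parents) {
          edges <- rbind(edges, data.frame(disease = dname, child = v,
                                           parent = p,
                                           stringsAsFactors = FALSE))
          if (!p %in% verts) { verts <- c(verts, p); nxt <- c(nxt, p) }
        }
      }
      frontier <- unique(nxt)
    }
    if (is.null(edges)) {
      edges <- data.frame(disease = dname, child = dname, parent = "-",
                          stringsAsFactors = FALSE)
    }
    rows[[d]] <- edges
  }
  dag_collection(do.call(rbind, rows))
}

# Brute-force semantic similarity oracle: explicit vertex-set enumeration,
# recursive contribution evaluation, direct ratio of sums. Independent of
# the package's traversal code.
oracle_semantic <- function(dags, model = 1, delta = 0.5) {
  contrib_one <- function(dag) {
    memo <- new.env()
    rec <- function(v) {
      if (v == dag$disease) return(1)
      if (!is.null(memo[[v]])) return(memo[[v]])
      kids <- dag$edges$child[dag$edges$parent == v]
      val <- delta * max(vapply(kids, rec, 1))
      memo[[v]] <- val
      val
    }
    stats::setNames(vapply(dag$vertices, rec, 1), dag$vertices)
  }
  if (model == 2) {
    all_v <- unique(unlist(lapply(dags, `[[`, "vertices")))
    n_in <- vapply(all_v, function(v) {
      sum(vapply(dags, function(d) v %in% d$vertices, TRUE))
    }, 1)
    cs2 <- stats::setNames(-log(n_in / length(dags)), all_v)
    contribs <- lapply(dags, function(d) cs2[d$vertices])
  } else {
    contribs <- lapply(dags, contrib_one)
  }
  n <- length(dags)
  ds <- vapply(contribs, sum, 1)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    sh <- intersect(dags[[i]]$vertices, dags[[j]]$vertices)
    den <- ds[i] + ds[j]
    m[i, j] <- if (den == 0) as.numeric(i == j) else
      sum(contribs[[i]][sh] + contribs[[j]][sh]) / den
  }
  dimnames(m) <- list(vapply(dags, `[[`, "", "disease"),
                      vapply(dags, `[[`, "", "disease"))
  m
}

# Brute-force GIPK oracle: explicit double loop over profile pairs.
oracle_gipk <- function(profiles, alpha_prime = 1) {
  n <- nrow(profiles)
  alpha <- alpha_prime / mean(apply(profiles, 1, function(p) sum(p^2)))
  k <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    k[i, j] <- exp(-alpha * sum((profiles[i, ] - profiles[j, ])^2))
  }
  k
}

# Mann-Whitney closed form for AUC with ties counted one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# simulated pair dataset with named features, first `k_inf` informative
sim_dataset <- function(n, p, k_inf, seed, beta = 4, shuffle_labels = FALSE) {
  set.seed(seed)
  x <- matrix(runif(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  logit <- beta * (rowSums(x[, seq_len(k_inf), drop = FALSE]) - k_inf / 2)
  y <- as.numeric(runif(n) < stats::plogis(logit))
  if (shuffle_labels) y <- sample(y)
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  structure(list(pairs = data.frame(disease = as.character(seq_len(n)),
                                    mirna = "m", label = y),
                 features = x, normalized = TRUE, stats = NULL),
            class = "labeled_dataset")
}
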