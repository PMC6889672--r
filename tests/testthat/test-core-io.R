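test_that("association files are parsed, trimmed and de-duplicated", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("d1\tm1", "d1\tm1", " d2 \tm2"), path)
  assoc <- read_associations(path)
  expect_equal(nrow(assoc), 2)
  expect_equal(assoc$disease, c("d1", "d2"))
  expect_equal(attr(assoc, "index")$nd, 2)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_error(read_associations(empty), "no associations")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("d1\tm1", "lonely"), bad)
  expect_error(read_associations(bad), "line 2")
  expect_error(read_associations(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("adjacency matrix reflects the pair set exactly", {
  idx <- entity_index(c("d1", "d2"), c("m1", "m2"))
  one <- association_table("d1", "m1", index = idx)
  expect_equal(unname(build_adjacency(one)), rbind(c(1, 0), c(0, 0)))

  adj <- build_adjacency(tiny_assoc())
  expect_equal(unname(rowSums(adj)), c(2, 1))
  expect_true(all(adj %in% c(0, 1)))

  expect_error(
    build_adjacency(data.frame(disease = "dX", mirna = "m1"), idx),
    "dX")
})

test_that("adjacency sum equals the number of unique pairs (random tables)", {
  set.seed(11)
  for (i in 1:20) {
    nd <- sample(2:8, 1); nm <- sample(2:8, 1)
    n_pair <- sample(1:(nd * nm), 1)
    cells <- sample(nd * nm, n_pair)
    idx <- entity_index(paste0("d", 1:nd), paste0("m", 1:nm))
    assoc <- association_table(paste0("d", ((cells - 1) %% nd) + 1),
                               paste0("m", ((cells - 1) %/% nd) + 1),
                               index = idx)
    expect_equal(sum(build_adjacency(assoc)), n_pair)
  }
})

test_that("DAG collections load with closure and cycle checks", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("D\tD\tP"), path)
  dags <- read_dag_collection(path)
  expect_setequal(dags$D$vertices, c("D", "P"))
  expect_equal(dags$D$edges$child, "D")
  expect_equal(dags$D$edges$parent, "P")

  cyc <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("D\tD\tP", "D\tP\tD"), cyc)
  expect_error(read_dag_collection(cyc), "cycle")

  # sibling forest: root R, children D1 and D2, root-only row for R
  forest <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("R\tR\t-", "D1\tD1\tR", "D2\tD2\tR"), forest)
  dd <- read_dag_collection(forest)
  expect_setequal(dd$D1$vertices, c("D1", "R"))
  expect_setequal(dd$D2$vertices, c("D2", "R"))
  expect_equal(dd$R$vertices, "R")
  expect_equal(nrow(dd$R$edges), 0)

  # every edge endpoint lies inside the vertex set (closure)
  for (d in dd) {
    expect_true(all(c(d$edges$child, d$edges$parent) %in% d$vertices))
  }
})

test_that("similarity matrices validate and round-trip through TSV", {
  m <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  sim <- similarity_matrix(m, kind = "functional")
  expect_s3_class(sim, "similarity_matrix")

  bad <- m; bad[2, 1] <- 0.5
  expect_error(similarity_matrix(bad), "asymmetric")

  id3 <- diag(3); dimnames(id3) <- list(letters[1:3], letters[1:3])
  expect_silent(similarity_matrix(id3, kind = "functional"))

  set.seed(4)
  r <- matrix(runif(25), 5); r <- (r + t(r)) / 2; diag(r) <- 1
  dimnames(r) <- list(paste0("x", 1:5), paste0("x", 1:5))
  sim <- similarity_matrix(r, kind = "gipk")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_similarity_matrix(sim, path)
  back <- read_similarity_matrix(path, kind = "gipk")
  expect_equal(unclass(back), unclass(sim), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(rownames(back), rownames(sim))
})
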