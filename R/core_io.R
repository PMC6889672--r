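#' @keywords internal
"_PACKAGE"

## Core containers -----------------------------------------------------------

#' Build an entity index from disease and miRNA name vectors
#'
#' The entity index fixes the row (disease) and column (miRNA) order of every
#' matrix in the pipeline. Names are matched case-sensitively after trimming.
#'
#' @param diseases character vector of disease names (duplicates dropped,
#'   first-occurrence order kept).
#' @param mirnas character vector of miRNA names, same treatment.
#' @return An object of class `entity_index` with elements `diseases`,
#'   `mirnas`, `nd`, `nm`.
#' @export
entity_index <- function(diseases, mirnas) {
  diseases <- unique(trimws(as.character(diseases)))
  mirnas <- unique(trimws(as.character(mirnas)))
  if (any(diseases == "")) stop("empty disease name in index")
  if (any(mirnas == "")) stop("empty miRNA name in index")
  structure(
    list(diseases = diseases, mirnas = mirnas,
         nd = length(diseases), nm = length(mirnas)),
    class = "entity_index"
  )
}

#' @export
print.entity_index <- function(x, ...) {
  cat("Entity index:", x$nd, "diseases x", x$nm, "miRNAs\n")
  invisible(x)
}

#' Construct a labelled similarity matrix
#'
#' A thin wrapper around a numeric matrix that records which kind of pairwise
#' similarity it holds and enforces the invariants shared by all kinds:
#' square, symmetric, non-negative entries.
#'
#' @param values square numeric matrix.
#' @param labels entity names for both axes; defaults to existing dimnames.
#' @param kind one of `"semantic1"`, `"semantic2"`, `"gipk"`, `"functional"`,
#'   `"integrated"`.
#' @param tol symmetry tolerance.
#' @return A `similarity_matrix`: the matrix with dimnames set and a `kind`
#'   attribute.
#' @export
similarity_matrix <- function(values,
                              labels = rownames(values),
                              kind = c("functional", "semantic1", "semantic2",
                                       "gipk", "integrated"),
                              tol = 1e-8) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("similarity matrix must be square, got ",
         nrow(values), "x", ncol(values))
  }
  if (is.null(labels) || length(labels) != nrow(values)) {
    stop("labels must match matrix dimension")
  }
  if (anyDuplicated(labels)) stop("duplicate labels in similarity matrix")
  if (any(!is.finite(values))) stop("non-finite similarity value")
  asym <- max(abs(values - t(values)))
  if (asym > tol) {
    stop(sprintf("similarity matrix asymmetric beyond tolerance (max |A - t(A)| = %.3g)",
                 asym))
  }
  values <- (values + t(values)) / 2
  if (any(values < -tol)) stop("negative similarity value")
  values[values < 0] <- 0
  dimnames(values) <- list(labels, labels)
  attr(values, "kind") <- kind
  class(values) <- c("similarity_matrix", class(values))
  values
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("%s similarity matrix over %d entities\n",
              attr(x, "kind"), nrow(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))),
                   drop = FALSE])
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

sim_kind <- function(x) attr(x, "kind")

## File readers ---------------------------------------------------------------

#' Read a disease-miRNA association table
#'
#' Expects a TSV with at least two columns (disease, miRNA); an optional
#' header line `disease<TAB>mirna` is skipped. Duplicate pairs collapse to
#' one; whitespace is trimmed; case is preserved.
#'
#' @param path path to the TSV file.
#' @return An `association_table`: data frame with columns `disease`,
#'   `mirna`, plus an `index` attribute holding the derived [entity_index()].
#' @export
read_associations <- function(path) {
  if (!file.exists(path)) stop("association file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no associations in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad)) {
    stop("malformed association row (need >= 2 tab-separated columns) at line ",
         bad[1], " of ", path)
  }
  d <- trimws(vapply(fields, `[[`, "", 1L))
  m <- trimws(vapply(fields, `[[`, "", 2L))
  if (tolower(d[1]) %in% c("disease", "#disease") &&
      tolower(m[1]) == "mirna") {
    d <- d[-1]; m <- m[-1]
  }
  if (length(d) == 0L) stop("no associations in ", path)
  association_table(d, m)
}

#' Build an association table from paired name vectors
#'
#' @param disease,mirna equal-length character vectors, one association per
#'   element.
#' @param index optional [entity_index()]; derived from the pairs if omitted.
#' @return An `association_table` data frame (unique pairs) with attribute
#'   `index`.
#' @export
association_table <- function(disease, mirna, index = NULL) {
  stopifnot(length(disease) == length(mirna))
  disease <- trimws(as.character(disease))
  mirna <- trimws(as.character(mirna))
  keep <- !duplicated(paste(disease, mirna, sep = "\r"))
  out <- data.frame(disease = disease[keep], mirna = mirna[keep],
                    stringsAsFactors = FALSE)
  if (is.null(index)) index <- entity_index(out$disease, out$mirna)
  unknown_d <- setdiff(out$disease, index$diseases)
  if (length(unknown_d)) stop("disease not in index: ", unknown_d[1])
  unknown_m <- setdiff(out$mirna, index$mirnas)
  if (length(unknown_m)) stop("miRNA not in index: ", unknown_m[1])
  attr(out, "index") <- index
  class(out) <- c("association_table", "data.frame")
  out
}

#' Build the binary disease-miRNA adjacency matrix
#'
#' Rows are diseases, columns miRNAs; entry (i, j) is 1 iff the pair is in
#' the association table. Row i is the interaction profile of disease i and
#' column j the interaction profile of miRNA j.
#'
#' @param assoc an `association_table`.
#' @param index an [entity_index()]; defaults to the table's own.
#' @return nd x nm binary matrix with dimnames from the index.
#' @export
build_adjacency <- function(assoc, index = attr(assoc, "index")) {
  if (is.null(index)) stop("no entity index supplied")
  di <- match(assoc$disease, index$diseases)
  mi <- match(assoc$mirna, index$mirnas)
  if (anyNA(di)) stop("disease not in index: ", assoc$disease[which(is.na(di))[1]])
  if (anyNA(mi)) stop("miRNA not in index: ", assoc$mirna[which(is.na(mi))[1]])
  adj <- matrix(0, index$nd, index$nm,
                dimnames = list(index$diseases, index$mirnas))
  adj[cbind(di, mi)] <- 1
  adj
}

#' Read a per-disease DAG collection
#'
#' The file is a TSV edge list `disease<TAB>child<TAB>parent`: one row per
#' parent-to-child edge of the disease's ancestor DAG. A root disease with no
#' ancestors is encoded as `disease<TAB>disease<TAB>-`. Each DAG's vertex set
#' is the disease itself plus its ancestors and must be closed under the
#' parent relation; cycles are rejected.
#'
#' @param path path to the edge-list TSV.
#' @return A `dag_collection`: named list of per-disease DAGs, each with
#'   elements `disease`, `vertices`, `edges` (data frame child/parent), plus
#'   attribute `n_diseases` (the collection's universe size).
#' @export
read_dag_collection <- function(path) {
  if (!file.exists(path)) stop("DAG file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no DAG rows in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad)) stop("malformed DAG row at line ", bad[1], " of ", path)
  df <- data.frame(
    disease = trimws(vapply(fields, `[[`, "", 1L)),
    child = trimws(vapply(fields, `[[`, "", 2L)),
    parent = trimws(vapply(fields, `[[`, "", 3L)),
    stringsAsFactors = FALSE
  )
  if (tolower(df$disease[1]) == "disease") df <- df[-1, , drop = FALSE]
  dag_collection(df)
}

#' Assemble a DAG collection from an edge-list data frame
#'
#' @param edges data frame with columns `disease`, `child`, `parent`; parent
#'   `"-"` marks a root-only row.
#' @return A `dag_collection` (see [read_dag_collection()]).
#' @export
dag_collection <- function(edges) {
  stopifnot(all(c("disease", "child", "parent") %in% names(edges)))
  dags <- lapply(split(edges, edges$disease, drop = TRUE), function(sub) {
    disease <- sub$disease[1]
    real <- sub[sub$parent != "-", , drop = FALSE]
    verts <- unique(c(disease, real$child, real$parent))
    if (!disease %in% verts) stop("disease ", disease, " absent from its DAG")
    e <- unique(real[c("child", "parent")])
    ## cycle check: Kahn's algorithm on parent -> child edges
    if (nrow(e)) {
      rem <- e
      repeat {
        sinks <- setdiff(unique(c(rem$child, rem$parent)), rem$parent)
        drop <- rem$child %in% sinks
        if (!any(drop)) break
        rem <- rem[!drop, , drop = FALSE]
        if (nrow(rem) == 0L) break
      }
      if (nrow(rem)) stop("cycle detected in DAG of disease ", disease)
    }
    list(disease = disease, vertices = verts, edges = e)
  })
  structure(dags, n_diseases = length(dags), class = "dag_collection")
}

#' @export
print.dag_collection <- function(x, ...) {
  sizes <- vapply(x, function(d) length(d$vertices), 1L)
  cat("DAG collection:", length(x), "diseases, vertex counts",
      min(sizes), "-", max(sizes), "\n")
  invisible(x)
}

#' Read a labelled square similarity matrix
#'
#' TSV with a header row of entity names and the same names in the first
#' column, in the same order. Symmetry is enforced within `tol`.
#'
#' @param path path to the TSV file.
#' @param kind similarity kind tag, see [similarity_matrix()].
#' @param tol symmetry tolerance (default 1e-8).
#' @return A `similarity_matrix`.
#' @export
read_similarity_matrix <- function(path, kind = "functional", tol = 1e-8) {
  if (!file.exists(path)) stop("similarity file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- trimws(as.character(df[[1]]))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cell in ", path)
  if (nrow(m) != ncol(m)) stop("similarity matrix in ", path, " is not square")
  if (!identical(labels, trimws(colnames(m)))) {
    stop("row and column labels disagree in ", path)
  }
  similarity_matrix(m, labels = labels, kind = kind, tol = tol)
}

#' Write a similarity matrix as labelled TSV
#'
#' Values are written with 10 significant digits so that a read/write
#' round-trip is value-stable.
#'
#' @param sim a `similarity_matrix`.
#' @param path output path.
#' @export
write_similarity_matrix <- function(sim, path) {
  labels <- rownames(sim)
  body <- apply(unclass(sim), 1, function(r) {
    paste(formatC(r, digits = 10, format = "g"), collapse = "\t")
  })
  writeLines(c(paste(c("name", labels), collapse = "\t"),
               paste(labels, body, sep = "\t")),
             path)
  invisible(path)
}

#' Write an association table as TSV
#' @param assoc an `association_table`.
#' @param path output path.
#' @export
write_associations <- function(assoc, path) {
  writeLines(paste(assoc$disease, assoc$mirna, sep = "\t"), path)
  invisible(path)
}

#' Write a DAG collection as edge-list TSV
#' @param dags a `dag_collection`.
#' @param path output path.
#' @export
write_dag_collection <- function(dags, path) {
  rows <- unlist(lapply(dags, function(d) {
    if (nrow(d$edges) == 0L) {
      paste(d$disease, d$disease, "-", sep = "\t")
    } else {
      paste(d$disease, d$edges$child, d$edges$parent, sep = "\t")
    }
  }), use.names = FALSE)
  writeLines(rows, path)
  invisible(path)
}
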