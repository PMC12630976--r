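#' Directed acyclic graph over named nodes
#'
#' Lightweight DAG container used throughout the package: a character vector
#' of node names plus a two-column edge matrix (`from`, `to`). Validity
#' (acyclicity, no self-loops, no duplicate edges, endpoints declared) is
#' checked on construction.
#'
#' @param nodes character vector of unique node names.
#' @param edges two-column character matrix (or data.frame) of directed
#'   edges, parent in column 1, child in column 2. May have zero rows.
#' @return an object of class `bn_dag`.
#' @examples
#' dag_structure(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' @export
dag_structure <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- matrix(character(0), ncol = 2)
  } else {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "character"
    if (ncol(edges) != 2) stop("edges must have two columns (from, to)")
  }
  colnames(edges) <- c("from", "to")
  rownames(edges) <- NULL
  if (nrow(edges) > 0) {
    if (!all(edges %in% nodes)) stop("edge endpoint not among declared nodes")
    if (any(edges[, 1] == edges[, 2])) stop("self-loop not allowed")
    key <- paste(edges[, 1], edges[, 2], sep = "\r")
    if (anyDuplicated(key)) stop("duplicate edges not allowed")
  }
  dag <- structure(list(nodes = nodes, edges = edges), class = "bn_dag")
  topological_order(dag)  # errors on a cycle, naming it
  dag
}

#' @export
print.bn_dag <- function(x, ...) {
  cat("DAG:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$edges) > 0) {
    cat(paste0("  ", x$edges[, 1], " -> ", x$edges[, 2], collapse = "\n"), "\n")
  }
  invisible(x)
}

# adjacency matrix, rows = parents, columns = children
amat <- function(dag) {
  p <- length(dag$nodes)
  a <- matrix(0L, p, p, dimnames = list(dag$nodes, dag$nodes))
  if (nrow(dag$edges) > 0) a[dag$edges] <- 1L
  a
}

amat_to_dag <- function(a) {
  idx <- which(a == 1L, arr.ind = TRUE)
  dag_structure(rownames(a),
                cbind(rownames(a)[idx[, 1]], colnames(a)[idx[, 2]]))
}

dag_parents <- function(dag, node) {
  unname(dag$edges[dag$edges[, 2] == node, 1])
}

dag_children <- function(dag, node) {
  unname(dag$edges[dag$edges[, 1] == node, 2])
}

#' Topological order of a DAG
#'
#' Kahn's algorithm with ties broken by node-name order, so the result is
#' deterministic for a fixed graph. Every parent precedes all of its
#' children; a cycle raises an error naming one offending cycle.
#'
#' @param dag a [dag_structure()] (or a bare list with `nodes`/`edges`).
#' @return character vector: the nodes in topological order.
#' @export
topological_order <- function(dag) {
  nodes <- dag$nodes
  edges <- dag$edges
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  if (NROW(edges) > 0) {
    tab <- table(edges[, 2])
    indeg[names(tab)] <- as.integer(tab)
  }
  remaining <- nodes
  out <- character(0)
  while (length(remaining) > 0) {
    ready <- remaining[indeg[remaining] == 0L]
    if (length(ready) == 0) {
      stop("cycle detected involving nodes: ",
           paste(sort(remaining), collapse = ", "))
    }
    nxt <- sort(ready)[1]
    out <- c(out, nxt)
    remaining <- setdiff(remaining, nxt)
    if (NROW(edges) > 0) {
      ch <- edges[edges[, 1] == nxt, 2]
      for (c_ in ch) indeg[c_] <- indeg[c_] - 1L
    }
  }
  out
}

#' Conditional probability table for one node
#'
#' Rows of `prob` index the parent-level configurations (first parent
#' varying fastest, i.e. [expand.grid()] order over `parent_levels`);
#' columns index the child's levels. A node without parents has a single
#' row. Each row must sum to 1.
#'
#' @param child child variable name.
#' @param parents character vector of parent names (possibly empty).
#' @param levels character vector: the child's levels, in declaration order.
#' @param parent_levels named list of level vectors, one per parent, in the
#'   same order as `parents`.
#' @param prob numeric matrix, `prod(lengths(parent_levels))` x
#'   `length(levels)`.
#' @param tol tolerance for the row-sum check.
#' @return an object of class `bn_cpt`.
#' @export
cpt <- function(child, parents, levels, parent_levels, prob, tol = 1e-9) {
  parents <- as.character(parents)
  prob <- as.matrix(prob)
  n_cfg <- if (length(parents) == 0) 1L else prod(lengths(parent_levels))
  if (length(parents) != length(parent_levels))
    stop("parent_levels must match parents")
  if (nrow(prob) != n_cfg || ncol(prob) != length(levels))
    stop("CPT for '", child, "' has wrong dimensions: expected ",
         n_cfg, " x ", length(levels))
  if (any(prob < -tol) || any(prob > 1 + tol))
    stop("CPT for '", child, "' has entries outside [0, 1]")
  bad <- abs(rowSums(prob) - 1) > tol
  if (any(bad))
    stop("CPT row(s) for '", child, "' do not sum to 1: row ",
         paste(which(bad), collapse = ", "))
  colnames(prob) <- levels
  structure(list(child = child, parents = parents, levels = levels,
                 parent_levels = parent_levels, prob = prob),
            class = "bn_cpt")
}

# row index into a CPT's prob matrix from integer parent codes (one column
# per parent, values 1..k); first parent varies fastest.
cpt_config_index <- function(cpt, codes) {
  if (length(cpt$parents) == 0) return(rep.int(1L, NROW(codes)))
  codes <- as.matrix(codes)
  cards <- lengths(cpt$parent_levels)
  idx <- rep.int(0, nrow(codes))
  mult <- 1
  for (j in seq_along(cards)) {
    idx <- idx + (codes[, j] - 1L) * mult
    mult <- mult * cards[j]
  }
  as.integer(idx + 1L)
}

#' Discrete Bayesian network
#'
#' Bundles a DAG, the level declarations of every variable, and one CPT per
#' node. The constructor validates that CPT parents match the graph's
#' in-edges and that all referenced levels are declared.
#'
#' @param dag a [dag_structure()].
#' @param levels named list: for each node, its ordered character levels.
#' @param cpts named list of [cpt()] objects, one per node.
#' @return an object of class `bn_network`.
#' @export
bayesian_network <- function(dag, levels, cpts) {
  if (!setequal(names(levels), dag$nodes))
    stop("levels must be declared for exactly the DAG's nodes")
  if (!setequal(names(cpts), dag$nodes))
    stop("one CPT per node required")
  for (nd in dag$nodes) {
    if (length(levels[[nd]]) < 1) stop("node '", nd, "' has no levels")
    if (anyDuplicated(levels[[nd]])) stop("duplicate levels for '", nd, "'")
    ct <- cpts[[nd]]
    pa <- sort(dag_parents(dag, nd))
    if (!identical(sort(ct$parents), pa))
      stop("CPT parents for '", nd, "' do not match the DAG")
    if (!identical(ct$levels, levels[[nd]]))
      stop("CPT levels for '", nd, "' do not match the declaration")
    for (p in seq_along(ct$parents)) {
      if (!identical(ct$parent_levels[[p]], levels[[ct$parents[p]]]))
        stop("CPT parent levels for '", nd, "' / '", ct$parents[p],
             "' do not match the declaration")
    }
  }
  structure(list(nodes = dag$nodes, levels = levels, dag = dag,
                 cpts = cpts[dag$nodes]),
            class = "bn_network")
}

#' @export
print.bn_network <- function(x, ...) {
  cat("Discrete Bayesian network:", length(x$nodes), "nodes,",
      nrow(x$dag$edges), "edges\n")
  cards <- lengths(x$levels)
  cat("  state space:", format(prod(cards), big.mark = ","),
      "joint configurations\n")
  invisible(x)
}

# equality used by round-trip tests: same structure, levels, probabilities
networks_equal <- function(a, b, tol = 1e-9) {
  if (!setequal(a$nodes, b$nodes)) return(FALSE)
  if (!identical(a$levels[a$nodes], b$levels[a$nodes])) return(FALSE)
  ka <- paste(a$dag$edges[, 1], a$dag$edges[, 2])
  kb <- paste(b$dag$edges[, 1], b$dag$edges[, 2])
  if (!setequal(ka, kb)) return(FALSE)
  for (nd in a$nodes) {
    ca <- a$cpts[[nd]]; cb <- b$cpts[[nd]]
    if (!setequal(ca$parents, cb$parents)) return(FALSE)
    # reorder b's parent dimensions to a's parent order before comparing
    pb <- align_cpt_parents(cb, ca$parents)
    if (max(abs(ca$prob - pb$prob)) > tol) return(FALSE)
  }
  TRUE
}

# permute a CPT's parent order (rows re-indexed accordingly)
align_cpt_parents <- function(ct, new_order) {
  if (identical(ct$parents, new_order)) return(ct)
  stopifnot(setequal(ct$parents, new_order))
  perm <- match(new_order, ct$parents)
  old_cards <- lengths(ct$parent_levels)
  # rows of grid are configurations in the new parent order
  grid <- as.matrix(do.call(expand.grid, lapply(old_cards[perm], seq_len)))
  old_codes <- grid[, match(ct$parents, new_order), drop = FALSE]
  idx <- cpt_config_index(ct, old_codes)
  cpt(ct$child, new_order, ct$levels, ct$parent_levels[perm],
      ct$prob[idx, , drop = FALSE])
}
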