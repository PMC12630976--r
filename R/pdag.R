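# Partially directed graphs: PC-stable output, CPDAGs, consistent
# extensions. Internal representation is a mark matrix m over the nodes:
# m[i, j] == 1 means an edge mark i -> j; an undirected edge has marks in
# both directions, a directed edge only one.

#' Partially directed graph
#'
#' @param nodes character node names.
#' @param directed two-column matrix of directed edges (from, to).
#' @param undirected two-column matrix of undirected pairs (order
#'   irrelevant; stored with the lexicographically smaller name first).
#' @return an object of class `bn_pdag`.
#' @export
pdag <- function(nodes, directed = NULL, undirected = NULL) {
  norm <- function(m) {
    if (is.null(m) || NROW(m) == 0) return(matrix(character(0), ncol = 2))
    m <- as.matrix(m); storage.mode(m) <- "character"
    rownames(m) <- NULL; colnames(m) <- NULL
    m
  }
  directed <- norm(directed)
  undirected <- norm(undirected)
  if (NROW(undirected) > 0) {
    sw <- undirected[, 1] > undirected[, 2]
    undirected[sw, ] <- undirected[sw, 2:1]
  }
  all_e <- rbind(directed, undirected)
  if (NROW(all_e) > 0) {
    if (!all(all_e %in% nodes)) stop("edge endpoint not among nodes")
    if (any(all_e[, 1] == all_e[, 2])) stop("self-loop not allowed")
    du <- c(paste(directed[, 1], directed[, 2]), paste(directed[, 2], directed[, 1]))
    uu <- paste(undirected[, 1], undirected[, 2])
    if (length(intersect(du, c(uu, paste(undirected[, 2], undirected[, 1])))) > 0)
      stop("an edge cannot be both directed and undirected")
  }
  structure(list(nodes = nodes, directed = directed, undirected = undirected),
            class = "bn_pdag")
}

#' @export
print.bn_pdag <- function(x, ...) {
  cat("PDAG:", length(x$nodes), "nodes,", nrow(x$directed), "directed,",
      nrow(x$undirected), "undirected edges\n")
  invisible(x)
}

pdag_marks <- function(g) {
  p <- length(g$nodes)
  m <- matrix(0L, p, p, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$directed) > 0) m[g$directed] <- 1L
  if (nrow(g$undirected) > 0) {
    m[g$undirected] <- 1L
    m[g$undirected[, 2:1, drop = FALSE]] <- 1L
  }
  m
}

marks_to_pdag <- function(m) {
  nodes <- rownames(m)
  und <- which(m == 1L & t(m) == 1L, arr.ind = TRUE)
  und <- und[und[, 1] < und[, 2], , drop = FALSE]
  dir_ <- which(m == 1L & t(m) == 0L, arr.ind = TRUE)
  pdag(nodes,
       directed = cbind(nodes[dir_[, 1]], nodes[dir_[, 2]]),
       undirected = cbind(nodes[und[, 1]], nodes[und[, 2]]))
}

# Meek orientation rules R1-R3 applied to closure. R4 only fires under
# background knowledge, which this pipeline never supplies.
meek_closure <- function(m) {
  adj <- function(i, j) m[i, j] == 1L || m[j, i] == 1L
  p <- nrow(m)
  repeat {
    changed <- FALSE
    und <- which(m == 1L & t(m) == 1L, arr.ind = TRUE)
    for (r in seq_len(nrow(und))) {
      b <- und[r, 1]; c_ <- und[r, 2]  # b - c undirected (both orders appear)
      # R1: a -> b, b - c, a and c nonadjacent  =>  b -> c
      a_in <- which(m[, b] == 1L & m[b, ] == 0L)
      if (any(vapply(a_in, function(a) !adj(a, c_), logical(1)))) {
        m[c_, b] <- 0L; changed <- TRUE; next
      }
      # R2: b -> d -> c with b - c  =>  b -> c
      d_mid <- which(m[b, ] == 1L & m[, b] == 0L)
      if (any(vapply(d_mid, function(d) m[d, c_] == 1L && m[c_, d] == 0L,
                     logical(1)))) {
        m[c_, b] <- 0L; changed <- TRUE; next
      }
      # R3: b - d1, b - d2, d1 -> c, d2 -> c, d1 and d2 nonadjacent => b -> c
      dns <- which(m[b, ] == 1L & m[, b] == 1L)
      dns <- dns[vapply(dns, function(d) m[d, c_] == 1L && m[c_, d] == 0L,
                        logical(1))]
      if (length(dns) >= 2) {
        pair_ok <- FALSE
        for (u in seq_along(dns)) for (v in seq_len(u - 1)) {
          if (!adj(dns[u], dns[v])) pair_ok <- TRUE
        }
        if (pair_ok) { m[c_, b] <- 0L; changed <- TRUE; next }
      }
    }
    if (!changed) break
  }
  m
}

#' PC-stable structure learning
#'
#' Constraint-based learning with the order-independent skeleton phase:
#' at each conditioning-set size the neighbour sets are frozen, and an edge
#' `x - y` is removed when some subset of the frozen neighbours of `x` (or
#' of `y`) of that size renders them conditionally independent. Separating
#' sets are recorded; unshielded triples `x - z - y` with `z` outside
#' `sepset(x, y)` are oriented as v-structures `x -> z <- y`, and Meek
#' rules R1-R3 are applied to closure.
#'
#' @param data a [tabular_dataset()] of factors.
#' @param alpha significance level for [ci_test_g2()], default 0.05.
#' @param max_cond_set cap on conditioning-set size, default 3.
#' @return a [pdag()].
#' @export
pc_stable <- function(data, alpha = 0.05, max_cond_set = 3) {
  nodes <- sort(names(data))
  p <- length(nodes)
  adj <- matrix(TRUE, p, p, dimnames = list(nodes, nodes))
  diag(adj) <- FALSE
  sepset <- list()
  sep_key <- function(x, y) paste(min(x, y), max(x, y))

  l <- 0L
  repeat {
    frozen <- adj
    degrees <- rowSums(frozen)
    if (all(degrees - 1 < l) || l > max_cond_set) break
    for (xi in seq_len(p)) for (yi in seq_len(p)) {
      if (xi == yi || !adj[xi, yi]) next
      x <- nodes[xi]; y <- nodes[yi]
      nbrs <- nodes[frozen[xi, ] & nodes != y]
      if (length(nbrs) < l) next
      subsets <- if (l == 0) list(character(0)) else
        utils::combn(nbrs, l, simplify = FALSE)
      for (S in subsets) {
        if (ci_test_g2(x, y, S, data, alpha)$independent) {
          adj[xi, yi] <- adj[yi, xi] <- FALSE
          sepset[[sep_key(x, y)]] <- S
          break
        }
      }
    }
    l <- l + 1L
  }

  # v-structure orientation on the skeleton
  m <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  m[adj] <- 1L  # all skeleton edges undirected
  for (zi in seq_len(p)) {
    z <- nodes[zi]
    nb <- which(adj[zi, ])
    if (length(nb) < 2) next
    for (u in seq_along(nb)) for (v in seq_len(u - 1)) {
      xi <- nb[u]; yi <- nb[v]
      if (adj[xi, yi]) next  # shielded
      x <- nodes[xi]; y <- nodes[yi]
      S <- sepset[[sep_key(x, y)]]
      if (!is.null(S) && z %in% S) next
      # orient x -> z <- y, never flipping an existing arrowhead
      if (m[zi, xi] == 1L && m[xi, zi] == 1L) m[zi, xi] <- 0L
      if (m[zi, yi] == 1L && m[yi, zi] == 1L) m[zi, yi] <- 0L
    }
  }
  marks_to_pdag(meek_closure(m))
}

#' CPDAG (Markov-equivalence class) of a DAG
#'
#' Keeps the skeleton, directs the compelled edges (those in a v-structure,
#' plus the Meek-rule closure) and leaves the remaining edges undirected.
#'
#' @param dag a [dag_structure()].
#' @return a [pdag()].
#' @export
cpdag_of <- function(dag) {
  a <- amat(dag)
  nodes <- dag$nodes
  p <- length(nodes)
  m <- ((a + t(a)) > 0) * 1L  # undirected skeleton
  for (zi in seq_len(p)) {
    pa <- which(a[, zi] == 1L)
    if (length(pa) < 2) next
    for (u in seq_along(pa)) for (v in seq_len(u - 1)) {
      xi <- pa[u]; yi <- pa[v]
      if (a[xi, yi] == 1L || a[yi, xi] == 1L) next
      m[zi, xi] <- 0L  # x -> z compelled
      m[zi, yi] <- 0L
    }
  }
  marks_to_pdag(meek_closure(m))
}

#' Consistent extension of a partially directed graph to a DAG
#'
#' Dor-Tarsi algorithm: repeatedly locate a node whose undirected
#' neighbours are adjacent to all of its other neighbours and which has no
#' outgoing directed edge, orient its undirected edges towards it, and
#' remove it. When no consistent extension exists the remaining undirected
#' edges are oriented by node-name order, skipping any orientation that
#' would close a cycle, so the procedure always returns an acyclic graph.
#'
#' @param g a [pdag()].
#' @return a [dag_structure()].
#' @export
pdag_to_dag <- function(g) {
  m <- pdag_marks(g)
  nodes <- g$nodes
  p <- length(nodes)
  res <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  dir_ <- m == 1L & t(m) == 0L
  res[dir_] <- 1L
  active <- rep(TRUE, p)
  mm <- m
  repeat {
    if (!any(mm[active, active] == 1L)) break
    found <- FALSE
    # later names become sinks first, so A - B extends to A -> B
    cand_order <- order(nodes, decreasing = TRUE)
    for (xi in cand_order[active[cand_order]]) {
      out_dir <- any(mm[xi, active] == 1L & mm[active, xi] == 0L)
      if (out_dir) next
      und_nb <- which(active & mm[xi, ] == 1L & mm[, xi] == 1L)
      all_nb <- which(active & (mm[xi, ] == 1L | mm[, xi] == 1L))
      ok <- all(vapply(und_nb, function(y) {
        others <- setdiff(all_nb, y)
        all(mm[y, others] == 1L | mm[others, y] == 1L)
      }, logical(1)))
      if (!ok && length(und_nb) > 0) next
      res[und_nb, xi] <- 1L   # orient towards the sink x
      active[xi] <- FALSE
      mm[xi, ] <- 0L; mm[, xi] <- 0L
      found <- TRUE
      break
    }
    if (!found) {
      # no consistent extension: deterministic name-order fallback
      und <- which(mm == 1L & t(mm) == 1L, arr.ind = TRUE)
      und <- und[und[, 1] < und[, 2], , drop = FALSE]
      ord <- order(nodes[und[, 1]], nodes[und[, 2]])
      for (r in ord) {
        i <- und[r, 1]; j <- und[r, 2]
        if (nodes[i] > nodes[j]) { tmp <- i; i <- j; j <- tmp }
        if (!path_exists(res, j, i)) res[i, j] <- 1L else res[j, i] <- 1L
        mm[und[r, 1], und[r, 2]] <- 0L
        mm[und[r, 2], und[r, 1]] <- 0L
      }
      break
    }
  }
  amat_to_dag(res)
}
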