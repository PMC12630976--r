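#' Random DAG fixture generator
#'
#' Draws a DAG that is acyclic by construction: nodes are placed in a random
#' permutation and each candidate edge from an earlier to a later node is
#' included independently with probability `edge_prob`, subject to the
#' in-degree cap. Deterministic for a fixed seed.
#'
#' @param n_nodes number of nodes (named `X1`, `X2`, ...).
#' @param edge_prob edge inclusion probability in `[0, 1]`.
#' @param max_parents in-degree cap (default `Inf`).
#' @param seed integer seed.
#' @return a [dag_structure()].
#' @export
random_dag <- function(n_nodes, edge_prob, max_parents = Inf, seed = 1) {
  stopifnot(n_nodes >= 1, edge_prob >= 0, edge_prob <= 1)
  nodes <- paste0("X", seq_len(n_nodes))
  with_seed(seed, {
    ord <- sample(nodes)
    edges <- NULL
    indeg <- stats::setNames(integer(n_nodes), nodes)
    for (j in seq_len(n_nodes)) {
      for (i in seq_len(j - 1)) {
        if (indeg[ord[j]] >= max_parents) break
        if (stats::runif(1) < edge_prob) {
          edges <- rbind(edges, c(ord[i], ord[j]))
          indeg[ord[j]] <- indeg[ord[j]] + 1L
        }
      }
    }
    dag_structure(nodes, edges)
  })
}

#' Attach Dirichlet-random CPTs to a DAG
#'
#' Each CPT row is drawn from a symmetric Dirichlet with concentration
#' `alpha`: large `alpha` gives near-uniform rows, small `alpha` (e.g. 0.1)
#' gives near-degenerate rows with strong dependencies.
#'
#' @param dag a [dag_structure()].
#' @param n_levels number of levels per node, a single value or a vector
#'   recycled over nodes (default 2, labelled `"l1"`, `"l2"`, ...).
#' @param alpha Dirichlet concentration, > 0.
#' @param seed integer seed.
#' @return a [bayesian_network()].
#' @export
random_cpts <- function(dag, n_levels = 2, alpha = 1, seed = 1) {
  stopifnot(alpha > 0)
  k <- rep_len(n_levels, length(dag$nodes))
  levels <- stats::setNames(
    lapply(k, function(ki) paste0("l", seq_len(ki))), dag$nodes)
  with_seed(seed, {
    cpts <- lapply(dag$nodes, function(nd) {
      pa <- sort(dag_parents(dag, nd))
      plev <- levels[pa]
      kc <- length(levels[[nd]])
      n_cfg <- if (length(pa) == 0) 1L else prod(lengths(plev))
      g <- matrix(stats::rgamma(n_cfg * kc, shape = alpha), n_cfg, kc)
      cpt(nd, pa, levels[[nd]], plev, g / rowSums(g))
    })
    names(cpts) <- dag$nodes
    bayesian_network(dag, levels, cpts)
  })
}

#' Canned toy networks with documented exact marginals
#'
#' Small hand-specified networks used as oracles throughout the test suite:
#'
#' * `chain3` — `A -> B -> C`, binary. `P(A=1) = 0.6`,
#'   `P(B=1|A=0,1) = (0.2, 0.9)`, `P(C=1|B=0,1) = (0.1, 0.8)`, so
#'   `P(B=1) = 0.62` and `P(C=1) = 0.5340`.
#' * `collider3` — `A -> C <- B`, binary, `P(A=1) = P(B=1) = 0.5`, and an
#'   asymmetric collider CPT (`P(C=1|ab) = 0.10, 0.90, 0.60, 0.95`) chosen
#'   so that both parents are also marginally dependent on `C`.
#' * `sprinkler4` — the classic cloudy/sprinkler/rain/wet-grass network:
#'   4 binary nodes, 4 edges, one v-structure at `wet`.
#' * `hub5` — a hub `H` with four children `C1..C4` of graded signal
#'   strength (`P(C=1|H) =` 0.9/0.1, 0.85/0.2, 0.8/0.3, 0.7/0.35); the hub
#'   has the largest Markov boundary and is the natural prediction target.
#'
#' Levels are `"0"`/`"1"` throughout ("1" last).
#'
#' @param name one of `"chain3"`, `"collider3"`, `"sprinkler4"`, `"hub5"`.
#' @return a [bayesian_network()].
#' @export
toy_network <- function(name = c("chain3", "collider3", "sprinkler4", "hub5")) {
  name <- match.arg(name)
  b <- c("0", "1")
  # rows of two-parent CPTs: (first parent fastest) 00, 10, 01, 11
  bin_cpt <- function(child, parents, levels_list, p1) {
    cpt(child, parents, b, levels_list, cbind(1 - p1, p1))
  }
  switch(name,
    chain3 = {
      dag <- dag_structure(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
      lv <- list(A = b, B = b, C = b)
      bayesian_network(dag, lv, list(
        A = bin_cpt("A", character(0), list(), 0.6),
        B = bin_cpt("B", "A", lv["A"], c(0.2, 0.9)),
        C = bin_cpt("C", "B", lv["B"], c(0.1, 0.8))))
    },
    collider3 = {
      dag <- dag_structure(c("A", "B", "C"), rbind(c("A", "C"), c("B", "C")))
      lv <- list(A = b, B = b, C = b)
      bayesian_network(dag, lv, list(
        A = bin_cpt("A", character(0), list(), 0.5),
        B = bin_cpt("B", character(0), list(), 0.5),
        C = bin_cpt("C", c("A", "B"), lv[c("A", "B")],
                    c(0.10, 0.90, 0.60, 0.95))))
    },
    sprinkler4 = {
      dag <- dag_structure(
        c("cloudy", "sprinkler", "rain", "wet"),
        rbind(c("cloudy", "sprinkler"), c("cloudy", "rain"),
              c("sprinkler", "wet"), c("rain", "wet")))
      lv <- list(cloudy = b, sprinkler = b, rain = b, wet = b)
      bayesian_network(dag, lv, list(
        cloudy = bin_cpt("cloudy", character(0), list(), 0.5),
        sprinkler = bin_cpt("sprinkler", "cloudy", lv["cloudy"], c(0.5, 0.1)),
        rain = bin_cpt("rain", "cloudy", lv["cloudy"], c(0.2, 0.8)),
        wet = bin_cpt("wet", c("rain", "sprinkler"), lv[c("rain", "sprinkler")],
                      c(0.01, 0.90, 0.90, 0.99))))
    },
    hub5 = {
      nodes <- c("H", paste0("C", 1:4))
      dag <- dag_structure(nodes, cbind("H", paste0("C", 1:4)))
      lv <- stats::setNames(rep(list(b), 5), nodes)
      p_hi <- c(0.9, 0.85, 0.8, 0.7)
      p_lo <- c(0.1, 0.2, 0.3, 0.35)
      cpts <- c(list(H = bin_cpt("H", character(0), list(), 0.5)),
                lapply(1:4, function(i) {
                  bin_cpt(paste0("C", i), "H", lv["H"], c(p_lo[i], p_hi[i]))
                }))
      names(cpts) <- nodes
      bayesian_network(dag, lv, cpts)
    })
}
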