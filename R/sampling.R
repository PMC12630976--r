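#' Forward (ancestral) sampling from a Bayesian network
#'
#' Draws `n` joint assignments by visiting the nodes in topological order
#' and sampling each variable from its CPT row selected by the already
#' sampled parent values. The same `(bn, n, seed)` triple always yields a
#' bit-identical table.
#'
#' @param bn a [bayesian_network()].
#' @param n number of rows (>= 1).
#' @param seed integer seed for this draw.
#' @return an unsplit [tabular_dataset()] with columns in the network's
#'   declaration order and the full level domains attached.
#' @examples
#' bn <- toy_network("chain3")
#' d <- forward_sample(bn, 100, seed = 1)
#' @export
forward_sample <- function(bn, n, seed) {
  stopifnot(n >= 1)
  ord <- topological_order(bn$dag)
  codes <- matrix(NA_integer_, nrow = n, ncol = length(bn$nodes),
                  dimnames = list(NULL, bn$nodes))
  with_seed(seed, {
    for (nd in ord) {
      ct <- bn$cpts[[nd]]
      cfg <- cpt_config_index(ct, codes[, ct$parents, drop = FALSE])
      cum <- t(apply(ct$prob, 1, cumsum))
      u <- stats::runif(n)
      # index of the first cumulative bin exceeding u
      codes[, nd] <- 1L + as.integer(rowSums(u > cum[cfg, , drop = FALSE] + 1e-15))
    }
  })
  df <- as.data.frame(lapply(bn$nodes, function(nd) {
    factor(bn$levels[[nd]][codes[, nd]], levels = bn$levels[[nd]])
  }), col.names = bn$nodes)
  tabular_dataset(df, levels = bn$levels)
}

#' Maximum-likelihood CPT fitting (optionally smoothed)
#'
#' Estimates one CPT per node of `structure` from categorical data by
#' relative frequencies, with optional Laplace-style smoothing:
#' `(count + pseudo_count) / (config count + pseudo_count * n_levels)`.
#' A parent configuration never observed (with `pseudo_count = 0`) falls
#' back to a uniform distribution over the child's levels.
#'
#' Level domains are taken from the data's factor levels — when the data
#' came from [forward_sample()] these are the ground-truth declarations, so
#' levels unobserved in a small sample keep their place in the state space.
#'
#' @param structure a [dag_structure()] whose nodes are columns of `data`.
#' @param data a [tabular_dataset()] (factors carry the level domains).
#' @param pseudo_count nonnegative smoothing constant, default 0.
#' @return a [bayesian_network()] over `structure`.
#' @export
fit_cpts <- function(structure, data, pseudo_count = 0) {
  stopifnot(pseudo_count >= 0)
  if (!all(structure$nodes %in% names(data)))
    stop("data columns do not cover the structure's nodes")
  levels <- lapply(data, base::levels)[structure$nodes]
  codes <- vapply(structure$nodes, function(j) as.integer(data[[j]]),
                  integer(nrow(data)))
  if (anyNA(codes)) stop("data contain values outside the declared levels")
  cpts <- lapply(structure$nodes, function(nd) {
    pa <- sort(dag_parents(structure, nd))
    kc <- length(levels[[nd]])
    plev <- levels[pa]
    n_cfg <- if (length(pa) == 0) 1L else prod(lengths(plev))
    tmpl <- cpt(nd, pa, levels[[nd]], plev,
                matrix(1 / kc, n_cfg, kc))
    cfg <- cpt_config_index(tmpl, codes[, pa, drop = FALSE])
    cell <- (cfg - 1L) * kc + codes[, nd]
    counts <- matrix(tabulate(cell, nbins = n_cfg * kc),
                     nrow = n_cfg, ncol = kc, byrow = TRUE)
    denom <- rowSums(counts) + pseudo_count * kc
    prob <- (counts + pseudo_count) / ifelse(denom > 0, denom, 1)
    empty <- denom == 0
    if (any(empty)) prob[empty, ] <- 1 / kc
    cpt(nd, pa, levels[[nd]], plev, prob)
  })
  names(cpts) <- structure$nodes
  bayesian_network(structure, levels, cpts)
}

#' Exact marginal distributions by full joint enumeration
#'
#' Test oracle for small networks: builds the exact joint distribution over
#' all configurations (refusing state spaces above `max_states`) and sums it
#' out to one marginal probability vector per variable.
#'
#' @param bn a [bayesian_network()].
#' @param max_states refuse joint state spaces larger than this (default 1e6).
#' @return named list: for each node, a named probability vector over its
#'   levels (each summing to 1 within 1e-9).
#' @examples
#' exact_marginals(toy_network("chain3"))$C
#' @export
exact_marginals <- function(bn, max_states = 1e6) {
  cards <- lengths(bn$levels)
  S <- prod(cards)
  if (S > max_states)
    stop("joint state space has ", S, " configurations; refusing (> ",
         max_states, ")")
  # column j of `grid` holds the level code of node j in each joint state
  grid <- as.matrix(do.call(expand.grid, lapply(cards, seq_len)))
  colnames(grid) <- bn$nodes
  joint <- rep(1, S)
  for (nd in bn$nodes) {
    ct <- bn$cpts[[nd]]
    cfg <- cpt_config_index(ct, grid[, ct$parents, drop = FALSE])
    joint <- joint * ct$prob[cbind(cfg, grid[, nd])]
  }
  out <- lapply(bn$nodes, function(nd) {
    v <- vapply(seq_along(bn$levels[[nd]]),
                function(l) sum(joint[grid[, nd] == l]), numeric(1))
    stats::setNames(v, bn$levels[[nd]])
  })
  stats::setNames(out, bn$nodes)
}
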