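#' Max-min parents-and-children (MMPC) selection for one target
#'
#' Forward phase: repeatedly add the candidate whose weakest association
#' with the target — the maximum [ci_test_g2()] p-value over subsets of the
#' current candidate set (sizes up to `max_cond_set`) — is strongest, until
#' no remaining candidate survives every conditioning subset. Backward
#' phase: drop members that become independent of the target given some
#' subset of the others.
#'
#' @param target target column name.
#' @param data a [tabular_dataset()] of factors.
#' @param alpha significance level, default 0.05.
#' @param max_cond_set conditioning-set size cap, default 3.
#' @return character vector: the estimated parents-and-children set.
#' @export
mmpc <- function(target, data, alpha = 0.05, max_cond_set = 3) {
  others <- sort(setdiff(names(data), target))
  cpc <- character(0)

  # largest p-value of target vs x over conditioning subsets of `set`
  max_pvalue <- function(x, set) {
    worst <- 0
    for (l in 0:min(length(set), max_cond_set)) {
      subsets <- if (l == 0) list(character(0)) else
        utils::combn(set, l, simplify = FALSE)
      for (S in subsets) {
        p <- ci_test_g2(x, target, S, data, alpha)$p_value
        if (p > worst) worst <- p
        if (worst > alpha) return(worst)  # already excluded; stop early
      }
    }
    worst
  }

  repeat {
    cand <- setdiff(others, cpc)
    if (length(cand) == 0) break
    pvals <- vapply(cand, function(x) max_pvalue(x, cpc), numeric(1))
    best <- which.min(pvals)
    if (pvals[best] > alpha) break
    cpc <- c(cpc, cand[best])
  }
  # backward: remove false positives admitted early
  for (x in cpc) {
    if (max_pvalue(x, setdiff(cpc, x)) > alpha) cpc <- setdiff(cpc, x)
  }
  sort(cpc)
}

#' Max-min hill-climbing (MMHC) hybrid structure learning
#'
#' Runs [mmpc()] for every node, keeps only mutually confirmed pairs
#' (`x` in `PC(y)` and `y` in `PC(x)`), and then runs [hill_climb()]
#' restricted to that skeleton.
#'
#' @inheritParams mmpc
#' @inheritParams hill_climb
#' @return a [dag_structure()].
#' @export
mmhc <- function(data, alpha = 0.05, score = family_score_bic,
                 max_cond_set = 3, max_parents = 8, seed = 1) {
  nodes <- names(data)
  pc_sets <- lapply(stats::setNames(nodes, nodes),
                    function(nd) mmpc(nd, data, alpha, max_cond_set))
  allowed <- matrix(FALSE, length(nodes), length(nodes),
                    dimnames = list(nodes, nodes))
  for (x in nodes) for (y in pc_sets[[x]]) {
    if (x %in% pc_sets[[y]]) allowed[x, y] <- allowed[y, x] <- TRUE
  }
  if (!any(allowed)) return(dag_structure(nodes))
  hill_climb(data, score = score, max_parents = max_parents, seed = seed,
             allowed = allowed)
}
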