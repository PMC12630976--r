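#' BIC family score for a discrete node
#'
#' Decomposable score of one node given a candidate parent set: the
#' maximised multinomial log-likelihood of the child within each parent
#' configuration, minus the penalty
#' `(k_child - 1) * prod(k_parents) * log(n) / 2`. The total score of a DAG
#' is the sum of its family scores, and Markov-equivalent DAGs receive
#' identical totals.
#'
#' @param child child column name.
#' @param parents character vector of parent column names (may be empty).
#' @param data a [tabular_dataset()] of factors.
#' @return a finite numeric score (log scale).
#' @export
family_score_bic <- function(child, parents, data) {
  if (child %in% parents) stop("child cannot be its own parent")
  n <- nrow(data)
  stopifnot(n >= 1)
  kc <- nlevels(data[[child]])
  y <- as.integer(data[[child]])
  if (length(parents) == 0) {
    cfg <- rep.int(1L, n)
    n_cfg <- 1L
  } else {
    cards <- vapply(parents, function(p) nlevels(data[[p]]), integer(1))
    n_cfg <- prod(cards)
    cfg <- rep.int(0L, n)
    mult <- 1L
    for (p in seq_along(parents)) {
      cfg <- cfg + (as.integer(data[[parents[p]]]) - 1L) * mult
      mult <- mult * cards[p]
    }
    cfg <- cfg + 1L
  }
  counts <- tabulate((cfg - 1L) * kc + y, nbins = n_cfg * kc)
  cm <- matrix(counts, nrow = n_cfg, byrow = TRUE)
  row_tot <- rowSums(cm)
  nz <- cm > 0
  ll <- sum(cm[nz] * log(cm[nz] / row_tot[row(cm)[nz]]))
  ll - (kc - 1) * n_cfg * log(n) / 2
}

#' Total decomposable score of a DAG
#'
#' @param dag a [dag_structure()].
#' @param data a [tabular_dataset()].
#' @param score family score function with signature
#'   `(child, parents, data)`; default [family_score_bic()].
#' @return list with `total` and named `per_family` components; the total
#'   equals the sum of family scores.
#' @export
score_dag <- function(dag, data, score = family_score_bic) {
  per <- vapply(dag$nodes,
                function(nd) score(nd, dag_parents(dag, nd), data),
                numeric(1))
  list(total = sum(per), per_family = per)
}
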