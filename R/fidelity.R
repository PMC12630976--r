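#' Structural Hamming distance between two DAGs
#'
#' Number of single-edge edits — insertions, deletions, and reversals
#' (a reversal counting one edit) — needed to turn one adjacency matrix
#' into the other. Symmetric in its arguments.
#'
#' With `cpdag = TRUE` the two DAGs are first mapped to their
#' Markov-equivalence classes ([cpdag_of()]) and the distance is computed
#' on the partially directed graphs (a differing edge mark counts one
#' edit). This removes the arbitrary orientation of reversible edges that
#' score-equivalent learners are free to choose, and is the scale on which
#' structure-recovery convergence is meaningfully measured.
#'
#' @param g1,g2 [dag_structure()] objects over the same node set.
#' @param cpdag compare equivalence classes instead of raw adjacency.
#' @return a nonnegative integer count.
#' @export
shd <- function(g1, g2, cpdag = FALSE) {
  if (!setequal(g1$nodes, g2$nodes)) stop("node sets differ")
  if (cpdag) {
    m1 <- pdag_marks(cpdag_of(g1))
    m2 <- pdag_marks(cpdag_of(g2))[g1$nodes, g1$nodes]
    up <- upper.tri(m1)
    return(sum((m1 != m2 | t(m1) != t(m2))[up]))
  }
  a1 <- amat(g1)
  a2 <- amat(g2)[g1$nodes, g1$nodes]
  s1 <- a1 + t(a1)   # skeleton indicators
  s2 <- a2 + t(a2)
  up <- upper.tri(a1)
  both <- up & s1 > 0 & s2 > 0
  # edge present in one graph only: one insertion/deletion each
  d <- sum(up & (s1 > 0) != (s2 > 0))
  # present in both but oriented differently (incl. directed vs opposite)
  d + sum(both & (a1 != a2))
}

#' Mean per-variable Jensen-Shannon divergence between two datasets
#'
#' For every shared column the base-2 Jensen-Shannon divergence between
#' the two empirical marginal distributions is computed over the declared
#' level domain, and the mean across columns is returned. The value lies
#' in `[0, 1]`: 0 iff all marginals coincide, 1 when every column has
#' disjoint support. The joint JS divergence is intractable for networks
#' with dozens of nodes, and per-variable averaging is the scale on which
#' synthetic-data fidelity is reported here.
#'
#' @param data1,data2 [tabular_dataset()] objects with identical columns
#'   and level domains.
#' @return numeric in `[0, 1]`.
#' @export
marginal_js <- function(data1, data2) {
  if (!identical(names(data1), names(data2)))
    stop("datasets must have the same columns")
  js <- vapply(names(data1), function(j) {
    l1 <- base::levels(data1[[j]])
    if (!identical(l1, base::levels(data2[[j]])))
      stop("level domains differ for column '", j, "'")
    p <- tabulate(data1[[j]], nbins = length(l1)) / nrow(data1)
    q <- tabulate(data2[[j]], nbins = length(l1)) / nrow(data2)
    m <- (p + q) / 2
    kl <- function(a, b) {
      nz <- a > 0
      sum(a[nz] * log2(a[nz] / b[nz]))
    }
    (kl(p, m) + kl(q, m)) / 2
  }, numeric(1))
  mean(js)
}

#' Fidelity summary across practitioner repetitions
#'
#' For each learner: the structural Hamming distances of its learned DAGs
#' to the true DAG (one per practitioner repetition), the median SHD, and
#' the mean/variance of the per-repetition Jensen-Shannon divergences
#' between the practitioner's real data and the learner's synthetic data.
#'
#' @param true_bn the ground-truth [bayesian_network()].
#' @param learned named list (by learner id) of lists of
#'   [dag_structure()] objects, one per practitioner repetition.
#' @param js named list (by learner id) of numeric vectors of
#'   per-repetition [marginal_js()] values; optional.
#' @return data.frame with one row per learner: `learner`, `shd_median`,
#'   `js_mean`, `js_variance`, plus a `shd_values` list column.
#' @export
fidelity_report <- function(true_bn, learned, js = NULL) {
  stopifnot(length(learned) >= 1)
  rows <- lapply(sort(names(learned)), function(id) {
    shds <- vapply(learned[[id]], function(g) shd(true_bn$dag, g), numeric(1))
    jsv <- if (!is.null(js)) js[[id]] else numeric(0)
    data.frame(learner = id,
               shd_median = stats::median(shds),
               js_mean = if (length(jsv)) mean(jsv) else NA_real_,
               js_variance = if (length(jsv) > 1) stats::var(jsv) else
                 if (length(jsv) == 1) 0 else NA_real_)
  })
  out <- do.call(rbind, rows)
  out$shd_values <- lapply(sort(names(learned)), function(id)
    vapply(learned[[id]], function(g) shd(true_bn$dag, g), numeric(1)))
  out
}
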