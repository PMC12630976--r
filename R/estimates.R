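#' Strategy estimate container
#'
#' Per-method accuracy summaries for one benchmarking strategy: the
#' asymptotic ground truth (`"true"`), the limited-real practitioner
#' strategy (`"prac"`), or one structure-learner-based strategy (named by
#' the learner id). `mu` holds the per-method mean accuracy;
#' `per_practitioner` (for `prac` and learner strategies) a methods x
#' practitioners matrix of per-practitioner values — raw accuracies for
#' `prac`, inner means over the synthetic repetitions for a learner.
#'
#' @param strategy strategy label.
#' @param mu named numeric vector of per-method mean accuracies.
#' @param records data.frame of the individual accuracy records
#'   (`method`, `strategy`, `practitioner`, `repetition`, `accuracy`).
#' @param per_practitioner optional methods x practitioners matrix.
#' @param n_reps the declared repetition counts, a named list.
#' @return object of class `strategy_estimates`.
#' @export
strategy_estimates <- function(strategy, mu, records,
                               per_practitioner = NULL, n_reps = list()) {
  structure(list(strategy = strategy, mu = mu, records = records,
                 per_practitioner = per_practitioner, n_reps = n_reps),
            class = "strategy_estimates")
}

#' @export
print.strategy_estimates <- function(x, ...) {
  cat("Strategy '", x$strategy, "': mean accuracy per method\n", sep = "")
  print(round(x$mu, 4))
  invisible(x)
}

record_row <- function(method, strategy, practitioner, repetition, accuracy) {
  data.frame(method = method, strategy = strategy,
             practitioner = practitioner, repetition = repetition,
             accuracy = accuracy, stringsAsFactors = FALSE)
}

# evaluate every method on one split dataset; returns named accuracies
# (the one-hot encoding is computed once and shared across methods)
eval_methods <- function(methods, dataset, seed) {
  enc <- encode_split(dataset)
  vapply(methods, function(m) {
    accuracy_on_encoded(m, enc, seed = derive_seed(seed, "fit", m$id))
  }, numeric(1))
}

#' Asymptotic ground-truth performance estimate
#'
#' Draws `n_truth` fresh train/test dataset pairs from the true
#' data-generating process and averages each method's test accuracy:
#' the reference against which both practitioner strategies are judged.
#'
#' @param bn the ground-truth [bayesian_network()].
#' @param target target node name.
#' @param methods named list of [ml_method()] specs.
#' @param n_truth number of repetitions (>= 1).
#' @param n_train,n_test split sizes for each repetition.
#' @param seed stage seed; repetition seeds are derived from it.
#' @return a [strategy_estimates()] with strategy `"true"`.
#' @export
ground_truth_estimate <- function(bn, target, methods, n_truth,
                                  n_train = 200, n_test = 200, seed = 42) {
  stopifnot(n_truth >= 1)
  accs <- matrix(NA_real_, length(methods), n_truth,
                 dimnames = list(names(methods), NULL))
  recs <- vector("list", n_truth)
  for (i in seq_len(n_truth)) {
    s <- derive_seed(seed, "truth", i)
    d <- split_dataset(forward_sample(bn, n_train + n_test, seed = s),
                       n_train, n_test, target = target)
    accs[, i] <- eval_methods(methods, d, s)
    recs[[i]] <- record_row(names(methods), "true", NA_integer_, i, accs[, i])
  }
  strategy_estimates("true", rowMeans(accs), do.call(rbind, recs),
                     n_reps = list(n_truth = n_truth))
}

#' Limited-real (practitioner) performance estimate
#'
#' Benchmarks every method directly on each practitioner's limited
#' dataset and averages across practitioners. Per-practitioner values are
#' retained for variance reporting.
#'
#' @param limited_datasets list of split [tabular_dataset()] objects, one
#'   per practitioner.
#' @param methods named list of [ml_method()] specs.
#' @param seed stage seed.
#' @return a [strategy_estimates()] with strategy `"prac"`.
#' @export
practitioner_estimate <- function(limited_datasets, methods, seed = 42) {
  n_prac <- length(limited_datasets)
  stopifnot(n_prac >= 1)
  accs <- matrix(NA_real_, length(methods), n_prac,
                 dimnames = list(names(methods), NULL))
  recs <- vector("list", n_prac)
  for (i in seq_len(n_prac)) {
    s <- derive_seed(seed, "prac", i)
    accs[, i] <- eval_methods(methods, limited_datasets[[i]], s)
    recs[[i]] <- record_row(names(methods), "prac", i, 1L, accs[, i])
  }
  strategy_estimates("prac", rowMeans(accs), do.call(rbind, recs),
                     per_practitioner = accs,
                     n_reps = list(n_prac = n_prac))
}

#' Structure-learner-based performance estimate
#'
#' For each practitioner's limited dataset: learn a DAG with the named
#' learner, fit CPTs by maximum likelihood, draw `n_sl` fresh synthetic
#' train/test pairs from the fitted network, and average each method's
#' accuracy over them; the outer mean across practitioners is the
#' strategy's estimate. A learner failure on one practitioner's data is
#' logged as a warning and that repetition is skipped (the reported
#' repetition counts reflect the skips).
#'
#' @inheritParams practitioner_estimate
#' @param learner registered learner id (see [learner_names()]).
#' @param n_sl synthetic repetitions per practitioner (>= 1).
#' @param n_train,n_test synthetic split sizes.
#' @param learner_config options forwarded to the learner.
#' @param keep_structures if `TRUE`, the learned DAGs and the
#'   per-repetition [marginal_js()] values are attached (for fidelity
#'   reporting).
#' @return a [strategy_estimates()] whose strategy is the learner id, with
#'   optional `structures` and `js` components.
#' @export
sl_estimate <- function(limited_datasets, learner, methods, n_sl,
                        n_train = 200, n_test = 200, seed = 42,
                        learner_config = list(), keep_structures = TRUE) {
  stopifnot(n_sl >= 1, length(limited_datasets) >= 1)
  n_prac <- length(limited_datasets)
  inner <- matrix(NA_real_, length(methods), n_prac,
                  dimnames = list(names(methods), NULL))
  recs <- list()
  structures <- vector("list", n_prac)
  js <- rep(NA_real_, n_prac)
  for (i in seq_len(n_prac)) {
    d_i <- limited_datasets[[i]]
    target <- attr(d_i, "target")
    g <- tryCatch(
      learn_structure(as.data.frame(d_i), learner, learner_config),
      error = function(e) {
        warning("learner '", learner, "' failed on practitioner ", i, ": ",
                conditionMessage(e))
        NULL
      })
    if (is.null(g)) next
    # DGP calibrated on the practitioner's full data (train + test rows)
    fitted <- fit_cpts(g, d_i)
    acc_j <- matrix(NA_real_, length(methods), n_sl)
    js_j <- numeric(n_sl)
    for (j in seq_len(n_sl)) {
      s <- derive_seed(seed, "sl", learner, i, j)
      synth <- forward_sample(fitted, n_train + n_test, seed = s)
      synth <- tabular_dataset(synth[names(d_i)])  # learner may reorder nodes
      js_j[j] <- marginal_js(d_i, synth)
      d_s <- split_dataset(synth, n_train, n_test, target = target)
      acc_j[, j] <- eval_methods(methods, d_s, s)
      recs[[length(recs) + 1L]] <-
        record_row(names(methods), learner, i, j, acc_j[, j])
    }
    inner[, i] <- rowMeans(acc_j)
    structures[[i]] <- g
    js[i] <- mean(js_j)
  }
  ok <- !is.na(inner[1, ])
  if (!any(ok)) stop("learner '", learner, "' failed on every practitioner")
  est <- strategy_estimates(learner, rowMeans(inner[, ok, drop = FALSE]),
                            do.call(rbind, recs),
                            per_practitioner = inner[, ok, drop = FALSE],
                            n_reps = list(n_prac = sum(ok), n_sl = n_sl))
  if (keep_structures) {
    est$structures <- structures[ok]
    est$js <- js[ok]
  }
  est
}

#' Bias of a strategy relative to the ground truth
#'
#' Per-method difference between a strategy's mean accuracy and the
#' asymptotic ground-truth mean; positive values mean the strategy
#' overestimates accuracy.
#'
#' @param est a [strategy_estimates()] (practitioner or learner strategy).
#' @param truth the `"true"` [strategy_estimates()].
#' @return named numeric vector of per-method biases.
#' @export
delta_bias <- function(est, truth) {
  if (!setequal(names(est$mu), names(truth$mu)))
    stop("method sets differ between the two estimates")
  est$mu - truth$mu[names(est$mu)]
}

#' Centred (relative) performance
#'
#' Subtracts the across-method mean from each method's estimate under the
#' same strategy, isolating relative ordering from absolute bias. The
#' centred values sum to zero.
#'
#' @param est a [strategy_estimates()] with at least two methods.
#' @return named numeric vector summing to 0.
#' @export
centered_estimates <- function(est) {
  stopifnot(length(est$mu) >= 2)
  est$mu - mean(est$mu)
}

#' Method ranks under a strategy
#'
#' Rank 1 is the highest accuracy; ties receive the average rank. With
#' `per_repetition = TRUE` ranks are computed within each practitioner
#' repetition (columns of `per_practitioner`), feeding rank-density
#' summaries; otherwise a single ranking of the strategy means.
#'
#' @param est a [strategy_estimates()].
#' @param per_repetition logical.
#' @return a named vector, or a methods x repetitions matrix.
#' @export
rank_orders <- function(est, per_repetition = FALSE) {
  rk <- function(v) rank(-v, ties.method = "average")
  if (!per_repetition) return(rk(est$mu))
  if (is.null(est$per_practitioner))
    stop("strategy '", est$strategy, "' has no per-practitioner values")
  apply(est$per_practitioner, 2, rk)
}

#' Rank consistency against the ground-truth ranking
#'
#' Compares per-repetition rankings under a strategy with the true
#' ranking: per-method rank-frequency distribution, the fraction of
#' repetitions whose full ranking matches exactly, and the mean absolute
#' rank displacement.
#'
#' @param strategy_ranks methods x repetitions matrix from
#'   [rank_orders()] with `per_repetition = TRUE` (a single ranking vector
#'   is accepted as one repetition).
#' @param truth_ranks named ranking vector of the ground truth.
#' @return list with `rank_frequency` (methods x ranks counts),
#'   `exact_match_fraction`, and `mean_displacement`.
#' @export
rank_consistency <- function(strategy_ranks, truth_ranks) {
  if (is.null(dim(strategy_ranks)))
    strategy_ranks <- matrix(strategy_ranks,
                             dimnames = list(names(strategy_ranks), NULL))
  methods <- rownames(strategy_ranks)
  if (!setequal(methods, names(truth_ranks))) stop("method sets differ")
  truth_ranks <- truth_ranks[methods]
  K <- length(methods)
  n_rep <- ncol(strategy_ranks)
  freq <- matrix(0L, K, K, dimnames = list(methods, paste0("rank", 1:K)))
  for (r in seq_len(n_rep)) {
    rr <- round(strategy_ranks[, r])
    in_range <- rr >= 1 & rr <= K
    freq[cbind(which(in_range), rr[in_range])] <-
      freq[cbind(which(in_range), rr[in_range])] + 1L
  }
  exact <- mean(vapply(seq_len(n_rep), function(r)
    all(strategy_ranks[, r] == truth_ranks), logical(1)))
  disp <- mean(abs(strategy_ranks - matrix(truth_ranks, K, n_rep)))
  list(rank_frequency = freq, exact_match_fraction = exact,
       mean_displacement = disp)
}
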