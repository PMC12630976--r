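#' Experiment configuration for a meta-simulation
#'
#' Validates and normalises the full parameter block of one
#' meta-simulation run. The defaults mirror the standard study
#' configuration: train and test splits of 200 rows, 10 practitioner
#' repetitions, 500 synthetic repetitions per practitioner, 1000
#' ground-truth repetitions, and root seed 42.
#'
#' @param network a [bayesian_network()], or a path to a BIF file.
#' @param target target node name; `NULL` picks the node with the largest
#'   Markov boundary (see [select_target_report()]).
#' @param learners character vector of registered learner ids.
#' @param methods named list of [ml_method()] specs,
#'   default [default_methods()].
#' @param n_train,n_test split sizes.
#' @param n_practitioner,n_sl,n_truth repetition counts (all >= 1).
#' @param seed root seed; every random stream is derived from it.
#' @param learner_config named list of per-learner option lists.
#' @param outdir output directory for [emit_reports()], or `NULL`.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(network, target = NULL,
                              learners = c("hc", "tabu", "mmhc", "pc.stable"),
                              methods = default_methods(),
                              n_train = 200, n_test = 200,
                              n_practitioner = 10, n_sl = 500,
                              n_truth = 1000, seed = 42,
                              learner_config = list(), outdir = NULL) {
  if (is.character(network)) network <- read_bif(network)
  stopifnot(inherits(network, "bn_network"))
  counts <- c(n_train = n_train, n_test = n_test,
              n_practitioner = n_practitioner, n_sl = n_sl, n_truth = n_truth)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (is.null(target)) target <- auto_target(network)
  if (!target %in% network$nodes)
    stop("target node '", target, "' not in the network")
  for (l in learners) get_learner(l)  # errors on unknown ids
  stopifnot(length(methods) >= 1)
  structure(list(network = network, target = target, learners = learners,
                 methods = methods, n_train = n_train, n_test = n_test,
                 n_practitioner = n_practitioner, n_sl = n_sl,
                 n_truth = n_truth, seed = seed,
                 learner_config = learner_config, outdir = outdir),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Schema: `network` (BIF path) or `fixture` (list with `name` for a
#' [toy_network()], or `n_nodes`/`edge_prob`/`n_levels`/`alpha`/`seed` for
#' a random fixture), `target`, `learners`, `methods` (list of
#' `{id, algorithm, params}`), `n_train`, `n_test`, `n_practitioner`,
#' `n_sl`, `n_truth`, `seed`, `outdir`.
#'
#' @param path YAML file path.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  network <- if (!is.null(y$network)) {
    read_bif(y$network)
  } else if (!is.null(y$fixture)) {
    fx <- y$fixture
    if (!is.null(fx$name)) toy_network(fx$name) else
      random_cpts(random_dag(fx$n_nodes, fx$edge_prob,
                             max_parents = if (is.null(fx$max_parents)) Inf
                                           else fx$max_parents,
                             seed = if (is.null(fx$seed)) 1 else fx$seed),
                  n_levels = if (is.null(fx$n_levels)) 2 else fx$n_levels,
                  alpha = if (is.null(fx$alpha)) 1 else fx$alpha,
                  seed = if (is.null(fx$seed)) 1 else fx$seed + 1)
  } else stop("config needs 'network' or 'fixture'")
  methods <- if (!is.null(y$methods)) methods_from_config(y$methods) else
    default_methods()
  args <- y[intersect(names(y),
                      c("target", "learners", "n_train", "n_test",
                        "n_practitioner", "n_sl", "n_truth", "seed",
                        "outdir"))]
  do.call(experiment_config,
          c(list(network = network, methods = methods), args))
}

# node with the largest Markov boundary; name order breaks ties
auto_target <- function(bn) {
  sizes <- vapply(bn$nodes,
                  function(nd) length(markov_boundary(bn$dag, nd)$boundary),
                  numeric(1))
  sort(bn$nodes[sizes == max(sizes)])[1]
}

markov_boundary <- function(dag, node) {
  parents <- sort(dag_parents(dag, node))
  children <- sort(dag_children(dag, node))
  spouses <- sort(setdiff(
    unique(unlist(lapply(children, function(c_) dag_parents(dag, c_)))),
    c(node, parents)))
  list(parents = parents, children = children, spouses = spouses,
       boundary = sort(unique(c(parents, children, spouses))))
}

#' Markov boundary of a candidate target node
#'
#' Reports the parents, children and spouses (other parents of the
#' children) of a node — the minimal set that shields it from the rest of
#' the network — to help choose prediction targets that generate variance
#' among ML methods.
#'
#' @param bn a [bayesian_network()].
#' @param candidate node name.
#' @return list with `node`, `parents`, `children`, `spouses`, `boundary`.
#' @export
select_target_report <- function(bn, candidate) {
  if (!candidate %in% bn$nodes) stop("unknown node '", candidate, "'")
  c(list(node = candidate), markov_boundary(bn$dag, candidate))
}

#' Run the full meta-simulation
#'
#' Executes the three-strategy loop under one configuration:
#' \enumerate{
#'   \item ground-truth reference — [ground_truth_estimate()] with
#'     `n_truth` fresh dataset pairs from the true network;
#'   \item one set of `n_practitioner` limited datasets drawn from the
#'     true network and shared by all remaining strategies (paired
#'     comparison);
#'   \item limited-real strategy — [practitioner_estimate()] on those
#'     datasets;
#'   \item per learner — [sl_estimate()], plus structural (SHD) and
#'     distributional (Jensen-Shannon) fidelity of the inferred
#'     data-generating processes;
#'   \item the comparison report: per-method bias, centred performance,
#'     per-repetition ranks and rank consistency against the truth.
#' }
#' The run is fully reproducible from `(config, seed)`. A failing stage
#' is caught and recorded in the bundle's `failures` manifest; completed
#' stages are kept.
#'
#' @param config an [experiment_config()].
#' @return a `result_bundle`: list with `config`, `truth`, `prac`,
#'   `sl` (named list per learner), `comparison`, `fidelity`, `failures`.
#' @export
run_metasimulation <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  bn <- config$network
  failures <- list()
  note_failure <- function(stage, e) {
    failures[[stage]] <<- conditionMessage(e)
    NULL
  }

  truth <- tryCatch(
    ground_truth_estimate(bn, config$target, config$methods, config$n_truth,
                          config$n_train, config$n_test,
                          seed = derive_seed(config$seed, "stage-truth")),
    error = function(e) note_failure("truth", e))

  limited <- lapply(seq_len(config$n_practitioner), function(i) {
    d <- forward_sample(bn, config$n_train + config$n_test,
                        seed = derive_seed(config$seed, "stage-limited", i))
    split_dataset(d, config$n_train, config$n_test, target = config$target)
  })

  prac <- tryCatch(
    practitioner_estimate(limited, config$methods,
                          seed = derive_seed(config$seed, "stage-prac")),
    error = function(e) note_failure("prac", e))

  sl <- list()
  for (l in config$learners) {
    sl[[l]] <- tryCatch(
      sl_estimate(limited, l, config$methods, config$n_sl,
                  config$n_train, config$n_test,
                  seed = derive_seed(config$seed, "stage-sl", l),
                  learner_config = c(config$learner_config[[l]],
                                     list(seed = derive_seed(config$seed,
                                                             "learn", l)))),
      error = function(e) note_failure(paste0("sl:", l), e))
  }
  sl <- Filter(Negate(is.null), sl)

  comparison <- if (!is.null(truth) && !is.null(prac)) {
    build_comparison(truth, prac, sl)
  } else NULL
  fidelity <- if (length(sl) > 0) {
    fidelity_report(bn,
                    learned = lapply(sl, `[[`, "structures"),
                    js = lapply(sl, `[[`, "js"))
  } else NULL

  bundle <- structure(
    list(config = config, truth = truth, prac = prac, sl = sl,
         comparison = comparison, fidelity = fidelity,
         failures = failures,
         provenance = list(seed = config$seed,
                           package_version =
                             as.character(utils::packageVersion("metasimbn")))),
    class = "result_bundle")
  if (!is.null(config$outdir)) emit_reports(bundle, config$outdir)
  bundle
}

build_comparison <- function(truth, prac, sl) {
  strategies <- c(list(prac = prac), sl)
  delta <- lapply(strategies, delta_bias, truth = truth)
  if (length(truth$mu) < 2) {
    # centred values and ranks are undefined for a single candidate
    return(list(delta = delta))
  }
  truth_rank <- rank_orders(truth)
  centred <- lapply(c(list(true = truth), strategies), centered_estimates)
  ranks <- lapply(strategies, rank_orders, per_repetition = TRUE)
  consistency <- lapply(ranks, rank_consistency, truth_ranks = truth_rank)
  list(truth_rank = truth_rank, delta = delta, centred = centred,
       per_repetition_ranks = ranks, consistency = consistency)
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("Meta-simulation result bundle\n")
  cat("  target:", x$config$target, "| methods:",
      paste(names(x$config$methods), collapse = ", "), "\n")
  if (!is.null(x$truth)) {
    cat("  ground truth (n_truth =", x$config$n_truth, "):\n")
    print(round(x$truth$mu, 4))
  }
  if (!is.null(x$comparison)) {
    cat("  bias (delta) per strategy:\n")
    for (s in names(x$comparison$delta))
      cat(sprintf("    %-10s %s\n", s,
                  paste(sprintf("%+.4f", x$comparison$delta[[s]]),
                        collapse = " ")))
  }
  if (length(x$failures) > 0)
    cat("  FAILURES:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}

#' Write all report tables for a result bundle
#'
#' Emits deterministic CSV tables — `accuracies.csv` (every individual
#' accuracy record), `delta.csv`, `centred.csv`, `ranks.csv`,
#' `fidelity.csv` — plus a `summary.json` with the per-strategy means,
#' rank consistency, fidelity medians and the failure manifest.
#' Re-emitting the same bundle reproduces identical files.
#'
#' @param bundle a `result_bundle` from [run_metasimulation()].
#' @param outdir output directory (created if missing).
#' @return the paths written, invisibly.
#' @export
emit_reports <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  w <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = TRUE)
    paths <<- c(paths, p)
  }

  recs <- do.call(rbind, c(
    if (!is.null(bundle$truth)) list(bundle$truth$records),
    if (!is.null(bundle$prac)) list(bundle$prac$records),
    lapply(bundle$sl, `[[`, "records")))
  if (!is.null(recs)) w(recs, "accuracies.csv")

  cmp <- bundle$comparison
  if (!is.null(cmp)) {
    dd <- do.call(rbind, lapply(names(cmp$delta), function(s)
      data.frame(strategy = s, method = names(cmp$delta[[s]]),
                 delta = unname(cmp$delta[[s]]))))
    w(dd, "delta.csv")
    cc <- do.call(rbind, lapply(names(cmp$centred), function(s)
      data.frame(strategy = s, method = names(cmp$centred[[s]]),
                 centred = unname(cmp$centred[[s]]))))
    w(cc, "centred.csv")
    rr <- do.call(rbind, lapply(names(cmp$per_repetition_ranks), function(s) {
      m <- cmp$per_repetition_ranks[[s]]
      data.frame(strategy = s,
                 method = rep(rownames(m), ncol(m)),
                 practitioner = rep(seq_len(ncol(m)), each = nrow(m)),
                 rank = as.vector(m))
    }))
    w(rr, "ranks.csv")
  }
  if (!is.null(bundle$fidelity)) {
    fid <- bundle$fidelity
    flat <- do.call(rbind, lapply(seq_len(nrow(fid)), function(r)
      data.frame(learner = fid$learner[r],
                 repetition = seq_along(fid$shd_values[[r]]),
                 shd = fid$shd_values[[r]],
                 js_mean = fid$js_mean[r])))
    w(flat, "fidelity.csv")
  }

  summary_list <- list(
    target = bundle$config$target,
    seed = bundle$config$seed,
    mu = c(
      if (!is.null(bundle$truth)) list(true = as.list(bundle$truth$mu)),
      if (!is.null(bundle$prac)) list(prac = as.list(bundle$prac$mu)),
      lapply(bundle$sl, function(s) as.list(s$mu))),
    rank_consistency = if (!is.null(cmp))
      lapply(cmp$consistency, function(x)
        list(exact_match_fraction = x$exact_match_fraction,
             mean_displacement = x$mean_displacement)),
    fidelity = if (!is.null(bundle$fidelity))
      stats::setNames(as.list(bundle$fidelity$shd_median),
                      bundle$fidelity$learner),
    failures = bundle$failures,
    provenance = bundle$provenance)
  jp <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary_list, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, jp)
  invisible(paths)
}
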