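#' Structure-learner registry
#'
#' The meta-simulation addresses learners by the names used in the wider
#' structure-learning literature: `"hc"` (hill-climbing), `"tabu"`,
#' `"mmhc"` and `"pc.stable"`. Each registered learner is a function
#' `(data, config) -> dag_structure`; constraint-based output is extended
#' to a DAG with [pdag_to_dag()] before use as a data-generating process.
#' `config` entries recognised: `alpha`, `max_cond_set`, `max_parents`,
#' `tabu_length`, `max_worsening_moves`, `seed`.
#'
#' `register_learner()` adds or replaces an entry, so further algorithms
#' (e.g. other hybrids) can be plugged in without touching the package.
#'
#' @param name learner id.
#' @param fn function `(data, config)` returning a [dag_structure()].
#' @return `learner_names()` returns the registered ids; `get_learner()`
#'   the learner function.
#' @export
register_learner <- function(name, fn) {
  assign(name, fn, envir = .learner_registry)
  invisible(name)
}

#' @rdname register_learner
#' @export
learner_names <- function() sort(ls(.learner_registry))

#' @rdname register_learner
#' @export
get_learner <- function(name) {
  if (!exists(name, envir = .learner_registry, inherits = FALSE))
    stop("unknown learner '", name, "'; registered: ",
         paste(learner_names(), collapse = ", "))
  get(name, envir = .learner_registry, inherits = FALSE)
}

#' Learn a DAG with a registered learner
#'
#' @param data a [tabular_dataset()] of factors.
#' @param name learner id (see [learner_names()]).
#' @param config named list of learner options.
#' @return a [dag_structure()].
#' @export
learn_structure <- function(data, name, config = list()) {
  get_learner(name)(data, config)
}

.learner_registry <- new.env(parent = emptyenv())

cfg_get <- function(config, key, default) {
  if (!is.null(config[[key]])) config[[key]] else default
}

register_default_learners <- function() {
  register_learner("hc", function(data, config = list()) {
    hill_climb(data,
               max_parents = cfg_get(config, "max_parents", 8),
               restarts = cfg_get(config, "restarts", 0),
               seed = cfg_get(config, "seed", 1))
  })
  register_learner("tabu", function(data, config = list()) {
    tabu_search(data,
                tabu_length = cfg_get(config, "tabu_length", 10),
                max_worsening_moves = cfg_get(config, "max_worsening_moves",
                                              cfg_get(config, "tabu_length", 10)),
                max_parents = cfg_get(config, "max_parents", 8),
                seed = cfg_get(config, "seed", 1))
  })
  register_learner("pc.stable", function(data, config = list()) {
    pdag_to_dag(pc_stable(data,
                          alpha = cfg_get(config, "alpha", 0.05),
                          max_cond_set = cfg_get(config, "max_cond_set", 3)))
  })
  register_learner("mmhc", function(data, config = list()) {
    mmhc(data,
         alpha = cfg_get(config, "alpha", 0.05),
         max_cond_set = cfg_get(config, "max_cond_set", 3),
         max_parents = cfg_get(config, "max_parents", 8),
         seed = cfg_get(config, "seed", 1))
  })
}

#' Export a DAG as edge-list text
#' @param dag a [dag_structure()].
#' @param path output path; one `from<TAB>to` line per edge.
#' @export
write_edge_list <- function(dag, path) {
  utils::write.table(dag$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.onLoad <- function(libname, pkgname) {
  register_default_learners()
}
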