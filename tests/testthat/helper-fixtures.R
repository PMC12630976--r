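# shared helpers: small deterministic datasets and graphs built in code

toy_names <- c("chain3", "collider3", "sprinkler4", "hub5")

# dataset of mutually independent uniform binary columns
independent_data <- function(n, p = 3, seed = 1) {
  withr::with_seed(seed, {
    df <- as.data.frame(replicate(p, sample(c("0", "1"), n, replace = TRUE),
                                  simplify = FALSE))
    names(df) <- LETTERS[seq_len(p)]
    tabular_dataset(df)
  })
}

# enumerate every DAG over the given nodes (2 or 3 nodes is practical):
# all subsets of ordered pairs, filtered for acyclicity and no 2-cycles
all_dags <- function(nodes) {
  pairs <- subset(expand.grid(from = nodes, to = nodes,
                              stringsAsFactors = FALSE), from != to)
  n_e <- nrow(pairs)
  out <- list()
  for (mask in 0:(2^n_e - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n_e) - 1)) > 0)
    e <- pairs[sel, , drop = FALSE]
    g <- tryCatch(dag_structure(nodes, as.matrix(e)), error = function(x) NULL)
    if (!is.null(g)) out[[length(out) + 1L]] <- g
  }
  out
}

# accuracy stub: a strategy_estimates object built from given per-method
# values (vector -> mu only; matrix -> per-practitioner values too)
stub_estimates <- function(strategy, values) {
  if (is.matrix(values)) {
    strategy_estimates(strategy, rowMeans(values),
                       records = data.frame(), per_practitioner = values)
  } else {
    strategy_estimates(strategy, values, records = data.frame())
  }
}
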