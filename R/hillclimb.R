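# Greedy score-based structure search.
#
# Both searchers walk the space of DAGs with single-edge moves
# (add / delete / reverse), keeping family scores cached so a move costs
# only the one or two families it touches. Tie-breaks among equal-score
# improving moves are lexicographic on (operation, parent, child), so runs
# are reproducible without randomness.

# reachability: is there a directed path from `from` to `to` in adjacency a?
path_exists <- function(a, from, to) {
  if (from == to) return(TRUE)
  p <- nrow(a)
  seen <- logical(p)
  stack <- from
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v == to) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, which(a[v, ] == 1L & !seen))
  }
  FALSE
}

# enumerate candidate moves with their score deltas; returns the best
# strictly-improving move (or the best move overall if `best_any`), using
# the lexicographic tie-break. `allowed` is an optional symmetric logical
# matrix whitelisting node pairs (MMHC restriction).
best_move <- function(a, fam, data, score, max_parents, nodes,
                      allowed = NULL, forbidden_keys = character(0),
                      best_any = FALSE) {
  p <- length(nodes)
  best <- NULL
  consider <- function(op, i, j, delta, new_fams) {
    key <- paste(op, nodes[i], nodes[j])
    if (key %in% forbidden_keys) return()
    cand <- list(op = op, i = i, j = j, delta = delta, new_fams = new_fams,
                 key = key)
    if (is.null(best)) { best <<- cand; return() }
    if (delta > best$delta + 1e-12) { best <<- cand; return() }
    if (abs(delta - best$delta) <= 1e-12 &&
        paste(op, nodes[i], nodes[j]) < paste(best$op, nodes[best$i], nodes[best$j]))
      best <<- cand
  }
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    if (a[i, j] == 1L) {
      # delete i -> j
      pa_j <- nodes[a[, j] == 1L]
      d <- score(nodes[j], setdiff(pa_j, nodes[i]), data) - fam[j]
      consider("del", i, j, d, list(j = score(nodes[j], setdiff(pa_j, nodes[i]), data)))
      # reverse i -> j  (becomes j -> i)
      if (sum(a[, i]) < max_parents) {
        a[i, j] <- 0L
        ok <- !path_exists(a, i, j)
        a[i, j] <- 1L
        if (ok) {
          new_j <- score(nodes[j], setdiff(pa_j, nodes[i]), data)
          new_i <- score(nodes[i], c(nodes[a[, i] == 1L], nodes[j]), data)
          consider("rev", i, j, (new_j - fam[j]) + (new_i - fam[i]),
                   list(j = new_j, i = new_i))
        }
      }
    } else if (a[j, i] == 0L) {
      # add i -> j
      if (!is.null(allowed) && !allowed[i, j]) next
      if (sum(a[, j]) >= max_parents) next
      if (path_exists(a, j, i)) next
      new_j <- score(nodes[j], c(nodes[a[, j] == 1L], nodes[i]), data)
      consider("add", i, j, new_j - fam[j], list(j = new_j))
    }
  }
  if (!is.null(best) && !best_any && best$delta <= 1e-12) return(NULL)
  best
}

apply_move <- function(a, fam, mv) {
  if (mv$op == "add") {
    a[mv$i, mv$j] <- 1L
  } else if (mv$op == "del") {
    a[mv$i, mv$j] <- 0L
  } else {
    a[mv$i, mv$j] <- 0L
    a[mv$j, mv$i] <- 1L
  }
  fam[mv$j] <- mv$new_fams$j
  if (!is.null(mv$new_fams$i)) fam[mv$i] <- mv$new_fams$i
  list(a = a, fam = fam)
}

# memoising wrapper around a family score function
make_score_cache <- function(score_fn, data) {
  cache <- new.env(parent = emptyenv())
  function(child, parents, data_ = data) {
    key <- paste(child, paste(sort(parents), collapse = ","), sep = "|")
    v <- cache[[key]]
    if (is.null(v)) {
      v <- score_fn(child, parents, data_)
      cache[[key]] <- v
    }
    v
  }
}

#' Hill-climbing structure search
#'
#' Greedy search over DAGs starting from the empty graph: at each step the
#' single-edge move (add, delete or reverse) with the largest positive score
#' improvement is applied, subject to acyclicity and the in-degree cap,
#' until no move improves. Optional random restarts perturb the local
#' optimum with random edge additions and re-climb, keeping the best
#' optimum found.
#'
#' @param data a [tabular_dataset()] of factors (>= 2 columns).
#' @param score family score function, default [family_score_bic()].
#' @param max_parents in-degree cap, default 8.
#' @param restarts number of random restarts, default 0 (deterministic).
#' @param seed seed for the restart perturbations.
#' @param allowed optional symmetric logical matrix whitelisting pairs.
#' @return a [dag_structure()] that is a verified local optimum.
#' @export
hill_climb <- function(data, score = family_score_bic, max_parents = 8,
                       restarts = 0, seed = 1, allowed = NULL) {
  nodes <- names(data)
  stopifnot(length(nodes) >= 2)
  sc <- make_score_cache(score, data)
  p <- length(nodes)

  climb <- function(a) {
    fam <- vapply(seq_len(p),
                  function(j) sc(nodes[j], nodes[a[, j] == 1L]), numeric(1))
    repeat {
      mv <- best_move(a, fam, data, sc, max_parents, nodes, allowed = allowed)
      if (is.null(mv)) break
      st <- apply_move(a, fam, mv)
      a <- st$a; fam <- st$fam
    }
    list(a = a, total = sum(fam))
  }

  a0 <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  best <- climb(a0)
  if (restarts > 0) {
    with_seed(seed, {
      for (r in seq_len(restarts)) {
        a <- best$a
        for (k in seq_len(min(p, 4))) {
          ij <- sample.int(p, 2)
          if (a[ij[1], ij[2]] == 0L && a[ij[2], ij[1]] == 0L &&
              sum(a[, ij[2]]) < max_parents &&
              !path_exists(a, ij[2], ij[1]) &&
              (is.null(allowed) || allowed[ij[1], ij[2]]))
            a[ij[1], ij[2]] <- 1L
        }
        cand <- climb(a)
        if (cand$total > best$total + 1e-12) best <- cand
      }
    })
  }
  amat_to_dag(best$a)
}

#' Tabu search over DAG structures
#'
#' Extends [hill_climb()] by allowing score-worsening moves: when no
#' improving move exists, the best non-tabu move is taken instead, the
#' inverse move is placed on a fixed-length tabu list, and the search stops
#' after `max_worsening_moves` consecutive non-improving steps. The best
#' DAG visited is returned, so the result never scores below the
#' hill-climbing optimum on the same data.
#'
#' With `tabu_length = 0` and `max_worsening_moves = 0` the procedure
#' reduces exactly to [hill_climb()].
#'
#' @inheritParams hill_climb
#' @param tabu_length number of recent inverse moves kept forbidden.
#' @param max_worsening_moves consecutive non-improving moves tolerated.
#' @return a [dag_structure()].
#' @export
tabu_search <- function(data, score = family_score_bic, tabu_length = 10,
                        max_worsening_moves = tabu_length, max_parents = 8,
                        seed = 1, allowed = NULL) {
  nodes <- names(data)
  stopifnot(length(nodes) >= 2)
  sc <- make_score_cache(score, data)
  p <- length(nodes)
  a <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  fam <- vapply(seq_len(p), function(j) sc(nodes[j], character(0)), numeric(1))
  best_a <- a
  best_total <- sum(fam)
  tabu <- character(0)
  worsening <- 0L

  inverse_key <- function(mv) {
    switch(mv$op,
           add = paste("del", nodes[mv$i], nodes[mv$j]),
           del = paste("add", nodes[mv$i], nodes[mv$j]),
           rev = paste("rev", nodes[mv$j], nodes[mv$i]))
  }

  iter <- 0L
  max_iter <- 100L * p * p  # safety cap; tabu cycling cannot run unbounded
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) break
    mv <- best_move(a, fam, data, sc, max_parents, nodes, allowed = allowed)
    if (is.null(mv)) {
      if (worsening >= max_worsening_moves || tabu_length == 0) break
      mv <- best_move(a, fam, data, sc, max_parents, nodes, allowed = allowed,
                      forbidden_keys = tabu, best_any = TRUE)
      if (is.null(mv)) break
      worsening <- worsening + 1L
    } else {
      worsening <- 0L
    }
    if (tabu_length > 0) {
      tabu <- c(tabu, inverse_key(mv))
      if (length(tabu) > tabu_length) tabu <- tabu[-1]
    }
    st <- apply_move(a, fam, mv)
    a <- st$a; fam <- st$fam
    if (sum(fam) > best_total + 1e-12) {
      best_total <- sum(fam)
      best_a <- a
    }
  }
  amat_to_dag(best_a)
}
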