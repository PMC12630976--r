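test_that("topological order puts every parent before its children", {
  expect_identical(topological_order(dag_structure("A")), "A")
  chain <- dag_structure(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  expect_identical(topological_order(chain), c("A", "B", "C"))

  # brute-force parent-before-child check on random DAGs
  for (s in 1:10) {
    g <- random_dag(8, 0.35, seed = s)
    ord <- topological_order(g)
    pos <- match(g$nodes, ord)
    names(pos) <- g$nodes
    for (r in seq_len(nrow(g$edges)))
      expect_lt(pos[g$edges[r, 1]], pos[g$edges[r, 2]])
  }
})

test_that("cyclic structures are rejected with the cycle named", {
  expect_error(
    dag_structure(c("A", "B"), rbind(c("A", "B"), c("B", "A"))),
    "cycle.*A.*B")
  expect_error(dag_structure("A", rbind(c("A", "A"))), "self-loop")
  expect_error(
    dag_structure(c("A", "B"), rbind(c("A", "B"), c("A", "B"))),
    "duplicate")
})

test_that("CPT validation enforces simplex rows and full coverage", {
  expect_error(cpt("A", character(0), c("0", "1"), list(),
                   matrix(c(0.5, 0.6), 1)), "sum to 1")
  expect_error(cpt("A", character(0), c("0", "1"), list(),
                   matrix(c(1.2, -0.2), 1)), "outside")
  expect_error(cpt("B", "A", c("0", "1"), list(A = c("0", "1")),
                   matrix(c(0.5, 0.5), 1)), "wrong dimensions")
})

test_that("forward sampling from degenerate CPTs is the unique assignment", {
  dag <- dag_structure(c("A", "B"), rbind(c("A", "B")))
  lv <- list(A = c("0", "1"), B = c("0", "1"))
  bn <- bayesian_network(dag, lv, list(
    A = cpt("A", character(0), lv$A, list(), matrix(c(0, 1), 1)),
    B = cpt("B", "A", lv$B, list(A = lv$A), rbind(c(1, 0), c(0, 1)))))
  d <- forward_sample(bn, 200, seed = 9)
  expect_true(all(d$A == "1"))
  expect_true(all(d$B == "1"))
})

test_that("forward sampling is deterministic in (bn, n, seed)", {
  bn <- toy_network("sprinkler4")
  d1 <- forward_sample(bn, 500, seed = 11)
  d2 <- forward_sample(bn, 500, seed = 11)
  expect_identical(d1, d2)
  d3 <- forward_sample(bn, 500, seed = 12)
  expect_false(identical(d1, d3))
})

test_that("exact marginals match hand enumeration", {
  # single node
  dag <- dag_structure("A")
  lv <- list(A = c("0", "1"))
  bn1 <- bayesian_network(dag, lv, list(
    A = cpt("A", character(0), lv$A, list(), matrix(c(0.3, 0.7), 1))))
  expect_equal(unname(exact_marginals(bn1)$A), c(0.3, 0.7))

  # A -> B: P(B=1) = 0.6 * 0.9 + 0.4 * 0.2 = 0.62
  dag2 <- dag_structure(c("A", "B"), rbind(c("A", "B")))
  lv2 <- list(A = c("0", "1"), B = c("0", "1"))
  bn2 <- bayesian_network(dag2, lv2, list(
    A = cpt("A", character(0), lv2$A, list(), matrix(c(0.4, 0.6), 1)),
    B = cpt("B", "A", lv2$B, list(A = lv2$A), rbind(c(0.8, 0.2), c(0.1, 0.9)))))
  expect_equal(unname(exact_marginals(bn2)$B[2]), 0.62)

  # every toy network: marginals are proper distributions
  for (nm in toy_names) {
    m <- exact_marginals(toy_network(nm))
    for (v in m) expect_equal(sum(v), 1, tolerance = 1e-9)
  }
  expect_equal(unname(exact_marginals(toy_network("chain3"))$C[2]), 0.534)
})

test_that("exact marginals refuse oversized state spaces", {
  g <- random_dag(4, 0.3, seed = 1)
  bn <- random_cpts(g, n_levels = 4, seed = 2)
  expect_error(exact_marginals(bn, max_states = 100), "refusing")
})

test_that("empirical marginals agree with enumeration on all toys", {
  n <- 100000
  for (nm in toy_names) {
    bn <- toy_network(nm)
    m <- exact_marginals(bn)
    d <- forward_sample(bn, n, seed = derive_seed(7, nm))
    for (v in bn$nodes) {
      emp <- tabulate(d[[v]], nbins = length(bn$levels[[v]])) / n
      tol <- 4 * sqrt(pmax(m[[v]] * (1 - m[[v]]), 1e-12) / n)
      expect_true(all(abs(emp - m[[v]]) <= tol + 1e-12),
                  label = paste("marginal match for", nm, v))
    }
  }
})

test_that("fitted CPTs recover the generator and improve with n", {
  bn <- toy_network("sprinkler4")
  errs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    d <- forward_sample(bn, n, seed = derive_seed(5, n))
    f <- fit_cpts(bn$dag, d)
    max(vapply(bn$nodes, function(v)
      max(abs(f$cpts[[v]]$prob - bn$cpts[[v]]$prob)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))  # monotone decreasing max-abs error
  expect_lt(errs[3], 0.01)
})

test_that("single-class column fits to a point mass and empty configs to uniform", {
  df <- data.frame(A = rep("yes", 100))
  d <- tabular_dataset(df, levels = list(A = c("no", "yes")))
  f <- fit_cpts(dag_structure("A"), d)
  expect_equal(unname(f$cpts$A$prob[1, ]), c(0, 1))

  # parent configuration absent: uniform fallback at pseudo_count 0
  dag <- dag_structure(c("A", "B"), rbind(c("A", "B")))
  df2 <- tabular_dataset(
    data.frame(A = rep("0", 50), B = rep(c("0", "1"), 25)),
    levels = list(A = c("0", "1"), B = c("0", "1")))
  f2 <- fit_cpts(dag, df2)
  expect_equal(unname(f2$cpts$B$prob[2, ]), c(0.5, 0.5))

  # pseudo-count smoothing pulls towards uniform
  f3 <- fit_cpts(dag_structure("A"), d, pseudo_count = 1)
  expect_equal(unname(f3$cpts$A$prob[1, ]), c(1, 101) / 102)
})

test_that("unknown level in the data is an error", {
  expect_error(
    tabular_dataset(data.frame(A = c("0", "2")), levels = list(A = c("0", "1"))),
    "outside its declared levels")
})
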