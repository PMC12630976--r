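test_that("the default roster holds five distinct candidate methods", {
  m <- default_methods()
  expect_length(m, 5)
  # the two tree criteria are distinct candidates
  expect_equal(m$dt_gini$params$criterion, "gini")
  expect_equal(m$dt_entropy$params$criterion, "entropy")
  expect_error(methods_from_config(list(
    list(id = "a", algorithm = "decision-tree", params = list(criterion = "gini")),
    list(id = "b", algorithm = "decision-tree", params = list(criterion = "gini")))),
    "duplicate \\(algorithm")
})

test_that("every method scores 1.0 on a constant target and is reproducible", {
  bn <- toy_network("hub5")
  d <- forward_sample(bn, 200, seed = 2)
  d$H <- factor(rep("1", 200), levels = c("0", "1"))  # constant target
  d <- split_dataset(tabular_dataset(d), 100, 100, target = "H")
  for (m in default_methods()) {
    expect_equal(evaluate_accuracy(m, d, seed = 1)$accuracy, 1.0,
                 label = m$id)
  }
  # reproducibility of stochastic learners under a fixed seed
  d2 <- split_dataset(forward_sample(bn, 400, seed = 3), 200, 200, target = "H")
  for (m in default_methods()) {
    a1 <- evaluate_accuracy(m, d2, seed = 7)$accuracy
    a2 <- evaluate_accuracy(m, d2, seed = 7)$accuracy
    expect_identical(a1, a2, label = m$id)
  }
})

test_that("accuracy sits at chance when the target is independent of features", {
  withr::with_seed(90, {
    df <- data.frame(
      Y = sample(c("0", "1"), 10400, replace = TRUE),
      F1 = sample(c("0", "1"), 10400, replace = TRUE),
      F2 = sample(c("a", "b", "c"), 10400, replace = TRUE))
  })
  d <- split_dataset(tabular_dataset(df), 400, 10000, target = "Y")
  for (m in default_methods()) {
    acc <- evaluate_accuracy(m, d, seed = 5)$accuracy
    expect_gte(acc, 0.48)
    expect_lte(acc, 0.52)
  }
})

test_that("strategy means are the declared averages of their repetitions", {
  # three ground-truth repetitions: mu is the arithmetic mean
  expect_equal(mean(c(0.5, 0.6, 0.7)), 0.6)
  truth <- stub_estimates("true", c(m1 = 0.75, m2 = 0.60))

  # practitioner: mean over limited datasets, values retained
  prac <- stub_estimates("prac", rbind(m1 = c(0.4, 0.8), m2 = c(0.6, 0.6)))
  expect_equal(unname(prac$mu), c(0.6, 0.6))
  expect_equal(dim(prac$per_practitioner), c(2, 2))

  # SL: outer mean of per-practitioner inner means
  sl <- stub_estimates("hc", rbind(m1 = c(0.55, 0.65), m2 = c(0.70, 0.60)))
  expect_equal(unname(sl$mu), c(0.60, 0.65))

  # bias: elementwise difference, positive = overestimation
  expect_equal(unname(delta_bias(sl, truth)), c(-0.15, 0.05))
  expect_equal(unname(delta_bias(truth, truth)), c(0, 0))
  expect_error(delta_bias(stub_estimates("x", c(zz = 1)), truth),
               "method sets differ")
})

test_that("centred performance sums to zero and reproduces hand values", {
  est <- stub_estimates("true", c(a = 0.5, b = 0.7))
  expect_equal(unname(centered_estimates(est)), c(-0.1, 0.1))
  for (s in 1:5) {
    mu <- withr::with_seed(s, stats::runif(5))
    names(mu) <- paste0("m", 1:5)
    expect_equal(sum(centered_estimates(stub_estimates("x", mu))), 0,
                 tolerance = 1e-9)
  }
  all_equal <- stub_estimates("x", c(a = 0.5, b = 0.5, c = 0.5))
  expect_equal(unname(centered_estimates(all_equal)), c(0, 0, 0))
})

test_that("ranks follow the rank-1-is-best convention with average ties", {
  est <- stub_estimates("true", c(a = 0.9, b = 0.8, c = 0.7))
  expect_equal(unname(rank_orders(est)), c(1, 2, 3))
  tie <- stub_estimates("true", c(a = 0.8, b = 0.8, c = 0.6))
  expect_equal(unname(rank_orders(tie)), c(1.5, 1.5, 3))
  # per-repetition ranks are permutations when values are distinct
  pp <- rbind(a = c(0.9, 0.1), b = c(0.5, 0.5), c = c(0.1, 0.9))
  rks <- rank_orders(stub_estimates("prac", pp), per_repetition = TRUE)
  for (j in 1:2) expect_setequal(rks[, j], 1:3)
})

test_that("rank consistency summarises agreement with the truth", {
  truth <- c(m1 = 1, m2 = 2, m3 = 3, m4 = 4, m5 = 5)
  same <- matrix(rep(1:5, 3), 5, dimnames = list(names(truth), NULL))
  rc <- rank_consistency(same, truth)
  expect_equal(rc$exact_match_fraction, 1.0)
  expect_equal(rc$mean_displacement, 0)
  expect_true(all(rowSums(rc$rank_frequency) == 3))  # conservation

  reversed <- matrix(5:1, 5, 1, dimnames = list(names(truth), NULL))
  rc2 <- rank_consistency(reversed, truth)
  expect_equal(rc2$exact_match_fraction, 0)
  expect_equal(rc2$mean_displacement, (4 + 2 + 0 + 2 + 4) / 5)
})

test_that("estimates computed end-to-end obey the averaging contracts", {
  bn <- toy_network("hub5")
  methods <- default_methods()[c("dt_gini", "adaboost")]
  truth <- ground_truth_estimate(bn, "H", methods, n_truth = 3,
                                 n_train = 80, n_test = 80, seed = 1)
  expect_equal(unname(truth$mu),
               as.numeric(tapply(truth$records$accuracy, truth$records$method,
                                 mean)[names(methods)]))

  limited <- lapply(1:2, function(i)
    split_dataset(forward_sample(bn, 160, seed = i), 80, 80, target = "H"))
  prac <- practitioner_estimate(limited, methods, seed = 2)
  expect_equal(prac$mu, rowMeans(prac$per_practitioner))

  sl <- sl_estimate(limited, "hc", methods, n_sl = 2,
                    n_train = 80, n_test = 80, seed = 3)
  expect_equal(sl$mu, rowMeans(sl$per_practitioner))
  # inner means: each practitioner's column averages its n_sl repetitions
  for (i in 1:2) {
    rec_i <- sl$records[sl$records$practitioner == i, ]
    expect_equal(unname(sl$per_practitioner[, i]),
                 as.numeric(tapply(rec_i$accuracy, rec_i$method,
                                   mean)[names(methods)]))
  }
  expect_length(sl$structures, 2)
  expect_true(all(sl$js >= 0 & sl$js <= 1))
})

test_that("a failing learner skips that practitioner with a warning", {
  register_learner("explodes-on-2", local({
    count <- 0
    function(data, config) {
      count <<- count + 1
      if (count == 2) stop("boom")
      hill_climb(data)
    }
  }))
  bn <- toy_network("chain3")
  limited <- lapply(1:3, function(i)
    split_dataset(forward_sample(bn, 100, seed = i), 50, 50, target = "C"))
  methods <- default_methods()["dt_gini"]
  expect_warning(
    est <- sl_estimate(limited, "explodes-on-2", methods, n_sl = 1,
                       n_train = 50, n_test = 50, seed = 4),
    "failed on practitioner 2")
  expect_equal(est$n_reps$n_prac, 2)  # reported count reflects the skip
  expect_equal(ncol(est$per_practitioner), 2)
})
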