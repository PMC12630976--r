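#' Candidate ML method specifications
#'
#' A method spec names a classifier family plus hyperparameter settings;
#' each `(algorithm, hyperparameters)` combination is a distinct candidate
#' in the benchmark. Supported algorithms: `"random-forest"`,
#' `"decision-tree"` (with a `criterion` hyperparameter, `"gini"` or
#' `"entropy"`), `"multilayer-perceptron"`, and `"adaboost"`.
#'
#' @param id unique method id.
#' @param algorithm algorithm family (see above).
#' @param params named list of hyperparameters.
#' @return an object of class `ml_method`.
#' @export
ml_method <- function(id, algorithm, params = list()) {
  algorithm <- match.arg(algorithm,
    c("random-forest", "decision-tree", "multilayer-perceptron", "adaboost"))
  structure(list(id = id, algorithm = algorithm, params = params),
            class = "ml_method")
}

#' The default candidate roster
#'
#' Five candidate methods: random forest, decision trees with gini and
#' entropy (information-gain) split criteria as two distinct candidates,
#' a single-hidden-layer multilayer perceptron, and multiclass AdaBoost
#' (SAMME) over decision stumps.
#'
#' @return named list of [ml_method()] specs.
#' @export
default_methods <- function() {
  specs <- list(
    ml_method("rf", "random-forest", list(num_trees = 100)),
    ml_method("dt_gini", "decision-tree", list(criterion = "gini")),
    ml_method("dt_entropy", "decision-tree", list(criterion = "entropy")),
    ml_method("mlp", "multilayer-perceptron",
              list(hidden = 8, maxit = 150, decay = 1e-3)),
    ml_method("adaboost", "adaboost", list(n_estimators = 50)))
  stats::setNames(specs, vapply(specs, `[[`, character(1), "id"))
}

#' Build ML method specs from a configuration list
#'
#' Accepts the list form of the YAML schema
#' `methods: [{id, algorithm, params}, ...]`; duplicate
#' `(algorithm, params)` combinations are rejected.
#'
#' @param spec list of lists with `id`, `algorithm`, optional `params`.
#' @return named list of [ml_method()] objects.
#' @export
methods_from_config <- function(spec) {
  out <- lapply(spec, function(s) {
    ml_method(s$id, s$algorithm, if (is.null(s$params)) list() else s$params)
  })
  names(out) <- vapply(out, `[[`, character(1), "id")
  if (anyDuplicated(names(out))) stop("duplicate method ids")
  sig <- vapply(out, function(m) {
    paste(m$algorithm, paste(names(m$params), unlist(m$params),
                             sep = "=", collapse = ","))
  }, character(1))
  if (anyDuplicated(sig))
    stop("duplicate (algorithm, hyperparameters) combination")
  out
}

# One-hot design matrix over the declared level domain: one column per
# (variable, level), in column order then level order, so the encoding is
# deterministic and identical across train/test and real/synthetic data.
one_hot <- function(data, exclude = character(0)) {
  cols <- setdiff(names(data), exclude)
  mats <- lapply(cols, function(j) {
    lv <- base::levels(data[[j]])
    m <- matrix(0L, nrow(data), length(lv),
                dimnames = list(NULL, paste(j, lv, sep = ".")))
    m[cbind(seq_len(nrow(data)), as.integer(data[[j]]))] <- 1L
    m
  })
  do.call(cbind, mats)
}

majority_level <- function(y) {
  tab <- tabulate(y, nbins = nlevels(y))
  base::levels(y)[which.max(tab)]
}

# ---- AdaBoost (SAMME) over depth-1 stumps on one-hot features ------------
# Weak learner: for every binary one-hot column, predict one class on each
# side of the split; pick the column with the lowest weighted error. SAMME
# weights alpha = log((1 - err)/err) + log(K - 1) admit weak learners that
# are only slightly better than chance in the multiclass case.
fit_adaboost <- function(X, y, n_estimators = 50) {
  K <- nlevels(y)
  n <- nrow(X)
  yi <- as.integer(y)
  w <- rep(1 / n, n)
  Xd <- matrix(as.numeric(X), n, ncol(X))
  stumps <- vector("list", n_estimators)
  n_used <- 0L
  for (t in seq_len(n_estimators)) {
    # weighted class tallies per column and side, in two crossproducts
    WK <- matrix(0, n, K)
    WK[cbind(seq_len(n), yi)] <- w
    tot_k <- colSums(WK)
    T_hi <- crossprod(Xd, WK)                  # cols x K
    T_lo <- matrix(tot_k, ncol(X), K, byrow = TRUE) - T_hi
    c_hi <- max.col(T_hi, ties.method = "first")
    c_lo <- max.col(T_lo, ties.method = "first")
    errs <- 1 - (T_hi[cbind(seq_len(ncol(X)), c_hi)] +
                 T_lo[cbind(seq_len(ncol(X)), c_lo)])
    jb <- which.min(errs)
    best <- list(j = jb, c_hi = c_hi[jb], c_lo = c_lo[jb], err = errs[jb])
    if (best$err >= 1 - 1 / K - 1e-10) break     # no better than chance
    err <- max(best$err, 1e-10)
    alpha <- log((1 - err) / err) + log(max(K - 1, 1))
    pred <- ifelse(X[, best$j] == 1L, best$c_hi, best$c_lo)
    w <- w * exp(alpha * (pred != yi))
    w <- w / sum(w)
    n_used <- n_used + 1L
    stumps[[t]] <- c(best[c("j", "c_hi", "c_lo")], alpha = alpha)
    if (best$err <= 1e-10) break                  # perfect stump
  }
  list(stumps = stumps[seq_len(n_used)], K = K, levels = base::levels(y))
}

predict_adaboost <- function(fit, X) {
  votes <- matrix(0, nrow(X), fit$K)
  for (st in fit$stumps) {
    pred <- ifelse(X[, st$j] == 1L, st$c_hi, st$c_lo)
    votes[cbind(seq_len(nrow(X)), pred)] <-
      votes[cbind(seq_len(nrow(X)), pred)] + st$alpha
  }
  factor(fit$levels[max.col(votes, ties.method = "first")],
         levels = fit$levels)
}

#' Train a candidate method and measure test accuracy
#'
#' Trains on the dataset's train split and returns the fraction of correct
#' predictions on the test split. Features are all non-target columns,
#' one-hot encoded over their declared level domains in deterministic
#' order. A degenerate single-class training target yields a constant
#' (majority-class) predictor rather than an error. Stochastic learners
#' are seeded, so the record is reproducible.
#'
#' @param method an [ml_method()].
#' @param dataset a split [tabular_dataset()] with a target column.
#' @param seed integer seed for this fit.
#' @return list with `method`, `accuracy` in `[0, 1]`, `n_train`, `n_test`.
#' @export
evaluate_accuracy <- function(method, dataset, seed = 1) {
  enc <- encode_split(dataset)
  list(method = method$id,
       accuracy = accuracy_on_encoded(method, enc, seed),
       n_train = length(enc$ytr), n_test = length(enc$yte))
}

# one-hot encode a split dataset once; reused across all candidate methods
encode_split <- function(dataset) {
  target <- attr(dataset, "target")
  if (is.null(target)) stop("dataset has no target column")
  tr <- train_rows(dataset)
  te <- test_rows(dataset)
  list(Xtr = one_hot(tr, exclude = target),
       Xte = one_hot(te, exclude = target),
       ytr = tr[[target]], yte = te[[target]])
}

accuracy_on_encoded <- function(method, enc, seed) {
  pred <- if (nlevels(droplevels(enc$ytr)) < 2) {
    rep(majority_level(droplevels(enc$ytr)), length(enc$yte))
  } else {
    with_seed(seed, fit_and_predict(method, enc$Xtr, enc$ytr, enc$Xte))
  }
  mean(as.character(pred) == as.character(enc$yte))
}

fit_and_predict <- function(method, Xtr, ytr, Xte) {
  p <- method$params
  switch(method$algorithm,
    "random-forest" = {
      fit <- ranger::ranger(x = Xtr, y = droplevels(ytr),
                            num.trees = if (is.null(p$num_trees)) 100 else p$num_trees,
                            num.threads = 1,
                            seed = sample.int(.Machine$integer.max, 1))
      stats::predict(fit, data = Xte, num.threads = 1)$predictions
    },
    "decision-tree" = {
      split <- switch(if (is.null(p$criterion)) "gini" else p$criterion,
                      gini = "gini", entropy = "information")
      df_tr <- data.frame(.y = droplevels(ytr), Xtr, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = df_tr, method = "class",
                          parms = list(split = split))
      stats::predict(fit, newdata = data.frame(Xte, check.names = FALSE),
                     type = "class")
    },
    "multilayer-perceptron" = {
      y2 <- droplevels(ytr)
      fit <- withCallsHandlers_quiet(
        nnet::nnet(x = Xtr, y = nnet::class.ind(y2),
                   size = if (is.null(p$hidden)) 8 else p$hidden,
                   maxit = if (is.null(p$maxit)) 150 else p$maxit,
                   decay = if (is.null(p$decay)) 1e-3 else p$decay,
                   softmax = TRUE, trace = FALSE, MaxNWts = 10000))
      pr <- stats::predict(fit, Xte)
      factor(base::levels(y2)[max.col(pr, ties.method = "first")],
             levels = base::levels(y2))
    },
    "adaboost" = {
      fit <- fit_adaboost(Xtr, droplevels(ytr),
                          n_estimators = if (is.null(p$n_estimators)) 50
                                         else p$n_estimators)
      predict_adaboost(fit, Xte)
    })
}

# convergence chatter from nnet is logged, not raised
withCallsHandlers_quiet <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    message("note: ", conditionMessage(w))
    invokeRestart("muffleWarning")
  })
}
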