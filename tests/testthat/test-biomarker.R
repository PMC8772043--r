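# L2-logistic fitting, recursive feature elimination, panel evaluation and
# the random-panel comparison.

make_shifted_data <- function(n = 200, n_inform = 5, n_noise = 5, delta = 1) {
  p <- n_inform + n_noise
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("g%02d", seq_len(p))))
  X[y == 1, seq_len(n_inform)] <- X[y == 1, seq_len(n_inform)] + delta
  list(X = X, y = y,
       informative = sprintf("g%02d", seq_len(n_inform)),
       noise = sprintf("g%02d", n_inform + seq_len(n_noise)))
}

test_that("logistic fit finds the monotone direction and obeys the penalty", {
  x <- matrix(c(-3, -2, -1, -0.5, 0.5, 1, 2, 3), ncol = 1,
              dimnames = list(NULL, "g"))
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  fit <- fit_logistic(x, y, lambda = 0.1)
  expect_gt(fit$coefficients[["g"]], 0)
  expect_true(fit$converged)
  # huge penalty shrinks the slope (but not the intercept) to ~0
  strong <- fit_logistic(x, c(0, 0, 0, 1, 0, 1, 1, 1), lambda = 1e6)
  expect_lt(abs(strong$coefficients[["g"]]), 1e-2)
})

test_that("a symmetric 1-D problem yields a near-zero intercept", {
  x <- matrix(rep(c(-1, 1), each = 10), ncol = 1, dimnames = list(NULL, "g"))
  y <- rep(c(0, 1), each = 10)
  fit <- fit_logistic(x, y, lambda = 1)
  expect_lt(abs(fit$coefficients[["(Intercept)"]]), 1e-6)
  # cross-check the whole solution against a generic numerical minimizer
  obj <- function(th) {
    eta <- th[1] + th[2] * x[, 1]
    sum(log1p(exp(eta)) - y * eta) + 1 * th[2]^2
  }
  ref <- stats::optim(c(0, 0), obj, method = "BFGS",
                      control = list(reltol = 1e-14))$par
  expect_equal(unname(fit$coefficients), ref, tolerance = 1e-5)
})

test_that("the ridge-logistic solution agrees with glmnet", {
  skip_if_not_installed("glmnet")
  set.seed(30)
  d <- make_shifted_data(n = 120, n_inform = 3, n_noise = 2)
  lambda <- 2
  fit <- fit_logistic(d$X, d$y, lambda = lambda)
  # glmnet minimizes (1/n) nll + lam * ||th||^2 / 2  (alpha = 0)
  gn <- glmnet::glmnet(d$X, d$y, family = "binomial", alpha = 0,
                       lambda = 2 * lambda / nrow(d$X), standardize = FALSE,
                       thresh = 1e-14)
  ref <- as.numeric(rbind(gn$a0, gn$beta))
  expect_equal(unname(fit$coefficients), ref, tolerance = 1e-3)
})

test_that("fit rejects degenerate labels", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_logistic(X, rep(1, 10), lambda = 1), "each class")
  expect_error(fit_logistic(X, c(0, rep(1, 9)), lambda = 1), "each class")
})

test_that("RFE on a single-gene module returns that gene", {
  set.seed(31)
  d <- make_shifted_data(n = 60, n_inform = 1, n_noise = 0)
  panel <- rfe_select(d$X[, 1, drop = FALSE], d$y, n_folds = 5, seed = 1)
  expect_equal(panel$genes, "g01")
  expect_equal(nrow(panel$cv_table), 1L)
})

test_that("RFE validates the fold count against the minority class", {
  set.seed(32)
  d <- make_shifted_data(n = 16)
  expect_error(rfe_select(d$X, d$y, n_folds = 10, seed = 1), "lower n_folds")
  expect_error(rfe_select(d$X, d$y, n_folds = 1, seed = 1), ">= 2")
})

test_that("RFE ranks informative genes above noise and selects lean panels", {
  # clear per-gene shift (1.5 noise sd): the elimination ORDER is stable
  # (the 5-gene path point is exactly the informative set); the CV size
  # choice wobbles by a gene or two around it
  res <- lapply(1:10, function(seed) {
    set.seed(seed)
    d <- make_shifted_data(delta = 1.5)
    panel <- rfe_select(d$X, d$y, n_folds = 10, seed = seed)
    path5 <- panel$genes
    if (length(path5) > 5) {
      # walk the recorded elimination path down to 5 genes
      cur <- colnames(d$X)
      while (length(cur) > 5) {
        fit <- fit_logistic(d$X[, cur, drop = FALSE], d$y, 1,
                            standardize = TRUE)
        cur <- setdiff(cur, names(which.min(abs(fit$coefficients[cur]))))
      }
      path5 <- cur
    }
    list(path5_pure = setequal(path5, d$informative) ||
           all(path5 %in% d$informative),
         kept_inform = sum(d$informative %in% panel$genes),
         kept_noise = sum(d$noise %in% panel$genes))
  })
  expect_gte(mean(vapply(res, `[[`, logical(1), "path5_pure")), 0.9)
  panel_ok <- vapply(res, function(r) {
    r$kept_inform >= 4 && r$kept_noise <= 2
  }, logical(1))
  expect_gte(mean(panel_ok), 0.8)
})

test_that("the RFE path is nested and one duplicated gene copy survives", {
  set.seed(33)
  d <- make_shifted_data(n = 150, n_inform = 3, n_noise = 2)
  panel <- rfe_select(d$X, d$y, n_folds = 5, seed = 33)
  expect_equal(panel$cv_table$n_features, seq(ncol(d$X), 1))
  # nestedness: re-run elimination and check set containment along sizes
  survivors <- lapply(seq(ncol(d$X), 1), function(k) {
    X <- d$X; y <- d$y
    cur <- colnames(X)
    while (length(cur) > k) {
      fit <- fit_logistic(X[, cur, drop = FALSE], y, 1, standardize = TRUE)
      cur <- setdiff(cur, names(which.min(abs(fit$coefficients[cur]))))
    }
    cur
  })
  for (i in seq_len(length(survivors) - 1)) {
    expect_true(all(survivors[[i + 1]] %in% survivors[[i]]))
  }

  # L2 splits weight across duplicated columns, so once the path narrows to
  # two genes exactly one copy is still standing
  dup_ok <- vapply(1:25, function(seed) {
    set.seed(seed)
    d <- make_shifted_data(n = 150, n_inform = 2, n_noise = 2, delta = 1.5)
    X <- cbind(d$X, g_dup = d$X[, "g01"])
    cur <- colnames(X)
    while (length(cur) > 2) {
      fit <- fit_logistic(X[, cur, drop = FALSE], d$y, 1, standardize = TRUE)
      cur <- setdiff(cur, names(which.min(abs(fit$coefficients[cur]))))
    }
    sum(c("g01", "g_dup") %in% cur) == 1
  }, logical(1))
  expect_gte(mean(dup_ok), 0.8)
})

test_that("AUC equals brute-force pairwise concordance", {
  expect_equal(auc_score(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.2)), 0.75)
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(10:100, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels <- c(0, 1, labels[-(1:2)])
    scores <- sample(round(runif(n), 2))  # rounded -> ties occur
    expect_equal(auc_score(labels, scores), brute_auc(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC on tied and untied scores", {
  skip_if_not_installed("pROC")
  set.seed(40)
  labels <- rbinom(60, 1, 0.5)
  labels[1:2] <- c(0, 1)
  scores <- round(runif(60), 1)
  expect_equal(auc_score(labels, scores),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("panel evaluation returns perfect and chance-level metrics", {
  set.seed(41)
  d <- make_shifted_data(n = 100, n_inform = 2, n_noise = 1, delta = 8)
  panel <- rfe_select(d$X, d$y, n_folds = 5, seed = 41)
  dd <- make_shifted_data(n = 100, n_inform = 2, n_noise = 1, delta = 8)
  m <- evaluate_panel(panel, dd$X, dd$y)
  expect_gt(m$auc, 0.99)
  expect_gt(m$f1, 0.95)
  expect_true(all(diff(m$roc$fpr) >= 0) && all(diff(m$roc$tpr) >= 0))
  expect_error(evaluate_panel(panel, dd$X, rep(1, 100)), "both classes")
  # label-independent constant probability: all ties -> AUC 1/2
  expect_equal(auc_score(dd$y, rep(0.7, 100)), 0.5)
})

test_that("signed-rank comparison has the exact small-sample tail", {
  expect_equal(dgrn:::signed_rank_p(rep(1, 5), rep(0.5, 5)), 0.03125)
  expect_gte(dgrn:::signed_rank_p(c(0.8, 0.9, 0.7), c(0.8, 0.9, 0.7)), 0.5)
})

test_that("random-panel comparison is seeded and validates its inputs", {
  set.seed(42)
  d <- make_shifted_data(n = 160, n_inform = 4, n_noise = 8)
  tr <- c(1:50, 81:130)  # stratified: half of each class trains
  p1 <- rfe_select(d$X[tr, d$informative], d$y[tr], n_folds = 5, seed = 1,
                   module_id = "M1")
  p2 <- rfe_select(d$X[tr, d$noise[1:4]], d$y[tr], n_folds = 5, seed = 2,
                   module_id = "M2")
  args <- list(panels = list(p1, p2), universe = colnames(d$X),
               X_train = d$X[tr, ], y_train = d$y[tr],
               X_eval = d$X[-tr, ], y_eval = d$y[-tr],
               n_draws = 3, seed = 99)
  r1 <- do.call(random_panel_test, args)
  r2 <- do.call(random_panel_test, args)
  expect_identical(r1, r2)
  expect_true(r1$p_value > 0 && r1$p_value <= 1)
  args_small <- args; args_small$universe <- "g01"
  expect_error(do.call(random_panel_test, args_small),
               "smaller than the largest")
  args_one <- args; args_one$panels <- list(p1)
  expect_error(do.call(random_panel_test, args_one), ">= 2")
})
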