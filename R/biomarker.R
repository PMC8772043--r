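# Per-module biomarker selection: L2-regularized logistic regression with
# recursive feature elimination under cross-validation, plus panel evaluation
# (F1, rank-based AUC, ROC) and the size-matched random-panel comparison.

log1pexp <- function(eta) ifelse(eta > 30, eta, log1p(exp(eta)))

#' Fit an L2-regularized logistic regression
#'
#' Minimizes the penalized cross-entropy
#' `-sum_i [ y_i log pi_i + (1 - y_i) log(1 - pi_i) ] + lambda * sum_j theta_j^2`
#' with `pi_i = 1 / (1 + exp(-x_i' theta))`; the intercept is not penalized.
#' The solver is a damped Newton iteration on the exact gradient/Hessian and
#' stops when the gradient's sup-norm falls below `tol`, so the fit is
#' deterministic given `(X, y, lambda)`.
#'
#' @param X numeric matrix, samples in rows, features (genes) in columns.
#' @param y binary labels (0/1), at least two samples per class.
#' @param lambda positive ridge penalty.
#' @param standardize z-score each column before fitting (centers/scales are
#'   stored in the model and re-applied by `predict`); constant columns get
#'   scale 1.
#' @param max_iter,tol Newton iteration controls.
#' @return object of class `logistic_model` with `coefficients` (named,
#'   including `(Intercept)`, on the possibly standardized scale), `lambda`,
#'   `center`, `scale`, `converged`.
#' @export
fit_logistic <- function(X, y, lambda = 1, standardize = FALSE,
                         max_iter = 100L, tol = 1e-8) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)), lambda > 0)
  if (min(table(factor(y, levels = c(0, 1)))) < 2L)
    stop("need at least two samples in each class")
  center <- scale_ <- NULL
  if (standardize) {
    center <- colMeans(X)
    scale_ <- apply(X, 2L, stats::sd)
    scale_[scale_ == 0] <- 1
    X <- sweep(sweep(X, 2L, center), 2L, scale_, "/")
  }
  Xd <- cbind(`(Intercept)` = 1, X)
  pen <- c(0, rep(lambda, ncol(X)))
  theta <- numeric(ncol(Xd))
  obj <- function(th) {
    eta <- drop(Xd %*% th)
    sum(log1pexp(eta) - y * eta) + sum(pen * th^2)
  }
  f <- obj(theta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% theta)
    p <- stats::plogis(eta)
    g <- drop(crossprod(Xd, p - y)) + 2 * pen * theta
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(Xd * w, Xd) + diag(2 * pen, ncol(Xd))
    step <- solve(H, g)
    s <- 1
    repeat {
      f_new <- obj(theta - s * step)
      if (f_new <= f + 1e-12 || s < 1e-10) break
      s <- s / 2
    }
    theta <- theta - s * step
    f <- f_new
  }
  structure(
    list(coefficients = stats::setNames(theta, colnames(Xd)),
         lambda = lambda, center = center, scale = scale_,
         genes = colnames(X), converged = converged, objective = f),
    class = "logistic_model")
}

#' Predicted disease probabilities from a fitted logistic model
#'
#' @param object a `logistic_model`.
#' @param newdata samples-by-genes matrix containing (at least) the model's
#'   genes as columns.
#' @param ... unused.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict.logistic_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$genes, drop = FALSE]
  if (!is.null(object$center))
    X <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  eta <- drop(cbind(1, X) %*% object$coefficients)
  stats::plogis(eta)
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed from ranks (the Mann-Whitney statistic):
#' ties between a positive and a negative score contribute 1/2.
#'
#' @param labels binary 0/1 labels.
#' @param scores classifier scores (higher = more disease-like).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(labels, scores) {
  labels <- as.numeric(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' F1 score at a probability cutoff
#'
#' @param labels binary 0/1 labels.
#' @param scores probabilities (or any scores compared against `cutoff`).
#' @param cutoff decision threshold, default 0.5.
#' @return F1 = 2TP / (2TP + FP + FN); 0 when the denominator is 0.
#' @export
f1_score <- function(labels, scores, cutoff = 0.5) {
  labels <- as.numeric(labels)
  pred <- as.numeric(scores >= cutoff)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' ROC curve points
#'
#' One point per distinct score threshold (descending), preceded by (0, 0);
#' both coordinates are monotone non-decreasing.
#'
#' @inheritParams auc_score
#' @return data frame with columns `fpr`, `tpr`.
#' @export
roc_curve <- function(labels, scores) {
  labels <- as.numeric(labels)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  # last index of each run of tied scores = one ROC point per threshold
  cut_idx <- which(c(sc[-1] != sc[-length(sc)], TRUE))
  tpr <- cumsum(lab)[cut_idx] / sum(lab == 1)
  fpr <- cumsum(1 - lab)[cut_idx] / sum(lab == 0)
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Select a biomarker panel by recursive feature elimination
#'
#' Backward elimination driven by L2-logistic regression: at each step the
#' model is refit on the full training data (features z-scored) and the gene
#' with the smallest absolute coefficient is removed, one gene per step, down
#' to a single gene. Every candidate panel size is scored by stratified k-fold
#' cross-validation (features z-scored inside each training fold, mean F1
#' across folds). The selected size is the smallest one whose mean CV score is
#' within `tie_tol` of the maximum — features are only removed while removal
#' costs no performance. The default `tie_tol` of 0.005 is the resolution of
#' tenfold-CV mean F1 at typical fold sizes (one flipped sample in one fold
#' moves the mean by about that much), so sub-resolution differences count as
#' "no loss" rather than as signal.
#'
#' @param X training matrix, samples in rows, the module's genes in columns.
#' @param y binary training labels.
#' @param lambda ridge penalty for every fit.
#' @param n_folds number of CV folds (>= 2, at most the minority-class count).
#' @param seed seed for the stratified fold assignment (elimination itself is
#'   deterministic given the data).
#' @param module_id optional identifier carried into the result.
#' @param tie_tol score tolerance for "no performance loss".
#' @return object of class `biomarker_panel`: `module_id`, `genes` (the
#'   selected panel), `cv_table` (data frame `n_features`, `mean_f1`),
#'   `model` (final fit on the selected panel, standardized), plus the
#'   parameters used.
#' @export
rfe_select <- function(X, y, lambda = 1, n_folds = 10L, seed = NULL,
                       module_id = NULL, tie_tol = 0.005) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(ncol(X) >= 1L, length(y) == nrow(X))
  counts <- table(factor(y, levels = c(0, 1)))
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (n_folds > min(counts))
    stop("n_folds (", n_folds, ") exceeds the minority class size (",
         min(counts), "); lower n_folds")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))

  fold <- integer(length(y))
  with_rng(seed, {
    for (cls in c(0, 1)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })

  cv_score <- function(genes) {
    mean(vapply(seq_len(n_folds), function(f) {
      tr <- fold != f
      fit <- fit_logistic(X[tr, genes, drop = FALSE], y[tr], lambda,
                          standardize = TRUE)
      f1_score(y[!tr], predict(fit, X[!tr, , drop = FALSE]))
    }, numeric(1)))
  }

  current <- colnames(X)
  sets <- vector("list", length(current))
  scores <- numeric(length(current))
  for (k in seq(length(current), 1L)) {
    sets[[k]] <- current
    scores[k] <- cv_score(current)
    if (k > 1L) {
      fit <- fit_logistic(X[, current, drop = FALSE], y, lambda,
                          standardize = TRUE)
      imp <- abs(fit$coefficients[current])
      current <- setdiff(current, names(which.min(imp)))
    }
  }
  best <- max(scores)
  chosen <- min(which(scores >= best - tie_tol))
  panel <- sets[[chosen]]
  model <- fit_logistic(X[, panel, drop = FALSE], y, lambda,
                        standardize = TRUE)
  structure(
    list(module_id = module_id, genes = panel,
         cv_table = data.frame(n_features = seq_along(scores),
                               mean_f1 = scores)[rev(seq_along(scores)), ],
         model = model, lambda = lambda, n_folds = as.integer(n_folds),
         seed = seed),
    class = "biomarker_panel")
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat(sprintf("biomarker_panel%s: %d gene(s): %s\n",
              if (!is.null(x$module_id)) paste0(" [", x$module_id, "]") else "",
              length(x$genes), paste(x$genes, collapse = ", ")))
  invisible(x)
}

#' Evaluate a biomarker panel on held-out data
#'
#' Computes F1 (probability cutoff 0.5), the rank-based AUC and the ROC curve
#' of the panel's fitted classifier on an evaluation set, which must be
#' disjoint from the training samples and contain both classes.
#'
#' @param panel a `biomarker_panel` (or a bare `logistic_model`).
#' @param X_eval samples-by-genes evaluation matrix.
#' @param y_eval binary evaluation labels.
#' @return list with `f1`, `auc`, `roc` (data frame), `n`.
#' @export
evaluate_panel <- function(panel, X_eval, y_eval) {
  model <- if (inherits(panel, "biomarker_panel")) panel$model else panel
  stopifnot(inherits(model, "logistic_model"))
  y_eval <- as.numeric(y_eval)
  if (length(unique(y_eval)) < 2L)
    stop("evaluation set must contain both classes")
  p <- predict(model, X_eval)
  list(f1 = f1_score(y_eval, p), auc = auc_score(y_eval, p),
       roc = roc_curve(y_eval, p), n = length(y_eval))
}

# One-sided (greater) Wilcoxon signed-rank p-value for paired differences
# a - b. Zero differences are discarded (standard practice); all-zero input
# gives p = 1 (no evidence of superiority). Exact by sign-flip enumeration for
# n <= 15 (valid under ties, where wilcox.test refuses exactness), normal
# approximation with tie correction otherwise.
signed_rank_p <- function(a, b) {
  d <- a - b
  d <- d[abs(d) > 1e-12]
  n <- length(d)
  if (!n) return(1)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 15L) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vnull <- drop(signs %*% r)
    return(mean(vnull >= v - 1e-9))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  stats::pnorm(v - 0.5, mean = mu, sd = sqrt(sigma2), lower.tail = FALSE)
}

#' Compare module biomarker panels against size-matched random gene panels
#'
#' For each module panel, draws `n_draws` random gene sets of the same size
#' from `universe`, fits the same L2-logistic classifier on the training data
#' and evaluates its AUC on the held-out data, exactly as for the real panels.
#' The per-module random AUC (mean over draws) is paired with the panel's AUC
#' and compared with a one-sided Wilcoxon signed-rank test (panels greater).
#'
#' @param panels list of `biomarker_panel` objects (>= 2).
#' @param universe character vector of candidate gene ids (at least as large
#'   as the largest panel).
#' @param X_train,y_train training data used to fit the random-panel models.
#' @param X_eval,y_eval held-out data used for all AUCs.
#' @param lambda ridge penalty.
#' @param n_draws random panels per module.
#' @param seed RNG seed; the returned p-value is reproducible given it.
#' @return list with `p_value`, `panel_aucs`, `random_aucs` (both per module),
#'   `n_draws`.
#' @export
random_panel_test <- function(panels, universe, X_train, y_train,
                              X_eval, y_eval, lambda = 1, n_draws = 10L,
                              seed = NULL) {
  stopifnot(length(panels) >= 2L)
  sizes <- vapply(panels, function(p) length(p$genes), integer(1))
  if (max(sizes) > length(universe))
    stop("gene universe (", length(universe),
         ") is smaller than the largest panel (", max(sizes), ")")
  panel_aucs <- vapply(panels, function(p)
    evaluate_panel(p, X_eval, y_eval)$auc, numeric(1))
  random_aucs <- with_rng(seed, {
    vapply(sizes, function(s) {
      mean(vapply(seq_len(n_draws), function(d) {
        g <- sample(universe, s)
        fit <- fit_logistic(X_train[, g, drop = FALSE], y_train, lambda,
                            standardize = TRUE)
        auc_score(y_eval, predict(fit, X_eval))
      }, numeric(1)))
    }, numeric(1))
  })
  list(p_value = signed_rank_p(panel_aucs, random_aucs),
       panel_aucs = panel_aucs, random_aucs = random_aucs,
       n_draws = as.integer(n_draws))
}
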