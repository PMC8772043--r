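# Binning, MI/CMI plug-in estimators and path-consistency pruning.

test_that("discretize handles the documented toy cases", {
  ef2 <- binning_scheme(2, "equal_frequency")
  expect_equal(discretize(c(1, 2, 3, 4), ef2), c(0L, 0L, 1L, 1L))
  expect_equal(discretize(c(0, 10), binning_scheme(2, "equal_width")),
               c(0L, 1L))
  expect_equal(discretize(c(5, 5, 5, 5), ef2), rep(0L, 4))
  expect_equal(discretize(c(5, 5, 5, 5), binning_scheme(3, "equal_width")),
               rep(0L, 4))
})

test_that("equal-frequency bins are balanced to within one on tie-free data", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(20:200, 1)
    k <- sample(2:6, 1)
    idx <- discretize(rnorm(n), binning_scheme(k, "equal_frequency"))
    expect_true(all(idx >= 0 & idx < k))
    counts <- tabulate(idx + 1L, k)
    expect_lte(diff(range(counts)), 1)
  }
})

test_that("MI matches brute-force summation on enumerable tables", {
  for (seed in 1:20) {
    set.seed(seed)
    k <- sample(2:4, 1)
    n <- sample(30:100, 1)
    x <- runif(n); y <- runif(n)
    sch <- binning_scheme(k, "equal_frequency")
    expect_equal(mutual_information(x, y, sch),
                 max(0, brute_mi(discretize(x, sch), discretize(y, sch))),
                 tolerance = 1e-12)
  }
})

test_that("CMI matches the brute-force triple sum on enumerable tables", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(30:100, 1)
    x <- runif(n); y <- runif(n); z <- runif(n)
    sch <- binning_scheme(2, "equal_frequency")
    expect_equal(
      conditional_mutual_information(x, y, z, sch),
      max(0, brute_cmi(discretize(x, sch), discretize(y, sch),
                       discretize(z, sch))),
      tolerance = 1e-12)
  }
})

test_that("identical k-binned variables give MI = log k exactly", {
  for (k in 2:5) {
    x <- rep(seq_len(k), each = 12) + 0  # n divisible by k, k distinct levels
    expect_equal(mutual_information(x, x, binning_scheme(k)), log(k),
                 tolerance = 1e-12)
  }
})

test_that("the diagonal 2x2 joint table gives MI = log 2", {
  x <- c(0, 0, 1, 1)
  y <- c(0.1, 0.2, 5, 6)  # same 2-bin pattern: counts [[2,0],[0,2]]
  expect_equal(mutual_information(x, y, binning_scheme(2)), log(2),
               tolerance = 1e-12)
})

test_that("MI is symmetric, non-negative and shrinks under independence", {
  set.seed(42)
  x <- rnorm(300); y <- rnorm(300)
  expect_equal(mutual_information(x, y), mutual_information(y, x),
               tolerance = 1e-12)
  expect_gte(mutual_information(x, y), 0)
  # estimate under independence decreases with n (bias ~ (k-1)^2 / 2n)
  small <- mean(replicate(20, {
    mutual_information(rnorm(50), rnorm(50))
  }))
  large <- mean(replicate(20, {
    mutual_information(rnorm(1000), rnorm(1000))
  }))
  expect_lt(large, small)
})

test_that("MI estimator rejects length mismatches, CMI rejects x/y in z", {
  expect_error(mutual_information(1:5, 1:4), "equal length")
  x <- rnorm(20); y <- rnorm(20)
  expect_error(conditional_mutual_information(x, y, list(x)), "x or y")
  expect_error(conditional_mutual_information(x, y, list()), "at least one")
})

test_that("conditioning on a constant reduces CMI to plain MI", {
  set.seed(3)
  x <- rnorm(100); y <- x + rnorm(100)
  expect_identical(conditional_mutual_information(x, y, rep(1, 100)),
                   mutual_information(x, y))
})

test_that("chain rule I(X;Y|Z) = I(X;YZ) - I(X;Z) holds on binned triples", {
  sch <- binning_scheme(2, "equal_frequency")
  for (seed in 1:100) {
    set.seed(seed)
    n <- 40
    x <- runif(n); y <- runif(n); z <- runif(n)
    ix <- discretize(x, sch); iy <- discretize(y, sch); iz <- discretize(z, sch)
    lhs <- brute_cmi(ix, iy, iz)
    # composite (Y,Z) variable for I(X;(Y,Z))
    iyz <- iy * 2L + iz
    rhs <- brute_mi(ix, iyz) - brute_mi(ix, iz)
    expect_equal(conditional_mutual_information(x, y, z, sch), max(0, lhs),
                 tolerance = 1e-12)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("binned CMI drops below MI along a Markov chain X -> Z -> Y", {
  wins <- vapply(1:20, function(seed) {
    set.seed(seed)
    x <- rnorm(1000)
    z <- 1.2 * x + rnorm(1000, sd = 0.5)
    y <- 1.2 * z + rnorm(1000, sd = 0.5)
    conditional_mutual_information(x, y, z) < mutual_information(x, y)
  }, logical(1))
  expect_true(all(wins))
})

test_that("pruning at threshold 0 keeps the whole background", {
  set.seed(5)
  inst <- make_instance(n_genes = 15, n_edges = 20, n_samples = 30, seed = 5)
  pruned <- pc_prune(inst$background, subset_samples(inst$data, label = 0L),
                     threshold = 0, max_order = 1)
  expect_setequal(dgrn:::undirected_keys(pruned$network),
                  dgrn:::undirected_keys(inst$background))
})

test_that("an edge between independent genes is deleted at order 0", {
  net <- toy_net(list(c("gA", "gB")))
  deleted <- vapply(1:20, function(seed) {
    set.seed(seed)
    vals <- matrix(rnorm(2 * 500), 2, 500,
                   dimnames = list(c("gA", "gB"), paste0("s", 1:500)))
    ds <- expression_dataset(vals, rep(0L, 500))
    nrow(pc_prune(net, ds, threshold = 0.05)$network$edges) == 0L
  }, logical(1))
  expect_gte(mean(deleted), 0.9)
})

test_that("triangle prior over a chain keeps chain edges, cuts the shortcut", {
  prior <- toy_net(list(c("X", "Z"), c("Z", "Y"), c("X", "Y")))
  ok <- vapply(1:20, function(seed) {
    set.seed(seed)
    x <- rnorm(500)
    z <- 1.3 * x + rnorm(500, sd = 0.6)
    y <- 1.3 * z + rnorm(500, sd = 0.6)
    vals <- rbind(X = x, Y = y, Z = z)
    colnames(vals) <- paste0("s", 1:500)
    ds <- expression_dataset(vals, rep(0L, 500))
    keys <- dgrn:::undirected_keys(
      pc_prune(prior, ds, threshold = 0.05, max_order = 1)$network)
    setequal(keys, dgrn:::pair_key(c("X", "Y"), c("Z", "Z")))
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("raising the threshold never adds an edge (monotonicity)", {
  set.seed(11)
  inst <- make_instance(n_genes = 20, n_edges = 30, n_samples = 60, seed = 11)
  ds <- subset_samples(inst$data, label = 0L)
  prev <- NULL
  for (thr in c(0, 0.02, 0.05, 0.1, 0.3)) {
    keys <- dgrn:::undirected_keys(
      pc_prune(inst$background, ds, threshold = thr)$network)
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})

test_that("pruning output is a subset of the background and validates input", {
  set.seed(2)
  inst <- make_instance(n_genes = 12, n_edges = 16, n_samples = 40, seed = 2)
  ds <- subset_samples(inst$data, label = 1L)
  pruned <- pc_prune(inst$background, ds)
  expect_true(all(dgrn:::undirected_keys(pruned$network) %in%
                    dgrn:::undirected_keys(inst$background)))
  expect_error(pc_prune(inst$background, ds, threshold = -1), ">= 0")
  tiny <- subset_samples(ds, samples = names(ds$labels)[1:2])
  expect_error(pc_prune(inst$background, tiny), "3 samples")
})

test_that("background genes missing from the data are dropped with a message", {
  set.seed(8)
  vals <- matrix(rnorm(3 * 50), 3, 50,
                 dimnames = list(c("A", "B", "C"), paste0("s", 1:50)))
  ds <- expression_dataset(vals, rep(0L, 50))
  prior <- toy_net(list(c("A", "B"), c("B", "C"), c("C", "MISSING")))
  expect_message(pruned <- pc_prune(prior, ds, threshold = 0), "1 background")
  expect_false("MISSING" %in% pruned$network$nodes)
  expect_equal(pruned$dropped_genes, "MISSING")
})
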