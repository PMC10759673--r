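test_that("entropy weights match hand computation and handle degeneracy", {
  # hand-computed 2x2 case: columns (1,3) and (2,4)
  dm <- decision_matrix(matrix(c(1, 3, 2, 4), 2, 2),
                        impacts = c("benefit", "benefit"))
  w <- entropy_weights(dm)
  expect_equal(unname(w), c(0.698, 0.302), tolerance = 1e-3)
  expect_equal(sum(w), 1, tolerance = 1e-12)

  # identical constant columns: fatal, nothing discriminates
  dmc <- decision_matrix(matrix(1, 3, 2), impacts = c("benefit", "benefit"))
  expect_error(entropy_weights(dmc), "no discriminating")

  # a constant column among varying ones gets zero weight
  dm2 <- decision_matrix(cbind(c(1, 2, 4), c(5, 5, 5)),
                         impacts = c("benefit", "benefit"))
  w2 <- entropy_weights(dm2)
  expect_equal(unname(w2[2]), 0)
  expect_equal(unname(w2[1]), 1)

  # cost inversion changes the weights only through the cost column
  dm3 <- decision_matrix(cbind(c(1, 2, 4), c(0.1, 0.2, 0.9)),
                         impacts = c("benefit", "cost"))
  expect_false(isTRUE(all.equal(entropy_weights(dm3),
                                entropy_weights(dm3, on = "cost_inverted"))))
})

test_that("TOPSIS degenerate and dominance cases behave as defined", {
  dm <- decision_matrix(matrix(c(2, 1), 2, 1), impacts = "benefit")
  r <- topsis(dm, w = 1)
  expect_equal(unname(r$scores), c(1, 0))
  expect_equal(unname(r$ranks), c(1L, 2L))

  # identical alternatives: closeness defined as 0.5 with degeneracy flag
  dmi <- decision_matrix(matrix(c(1, 1, 2, 2), 2, 2),
                         impacts = c("benefit", "cost"))
  ri <- topsis(dmi, w = c(0.5, 0.5))
  expect_equal(unname(ri$scores), c(0.5, 0.5))
  expect_true(isTRUE(attr(ri, "degenerate")))
})

test_that("COPRAS awards exactly one utility of 100 and respects dominance", {
  vals <- rbind(a = c(5, 4, 3), b = c(4, 3, 2), c = c(3, 2, 1))
  dm <- decision_matrix(vals, impacts = rep("benefit", 3))
  r <- copras(dm, w = rep(1 / 3, 3), normalization = "sum")
  expect_equal(unname(r$scores["a"]), 100)
  expect_equal(unname(r$ranks["a"]), 1L)
  expect_equal(sum(r$scores == 100), 1)

  set.seed(8)
  for (k in 1:10) {
    m <- sample(3:6, 1)
    dm2 <- decision_matrix(random_decision_values(m, 3, seed = 100 + k),
                           impacts = c("benefit", "benefit", "cost"))
    r2 <- copras(dm2, rep(1 / 3, 3))
    expect_equal(sum(r2$scores == 100), 1)
  }
})

test_that("TOPSIS and COPRAS agree with independent step-by-step oracles", {
  cases <- 0
  seed <- 0
  while (cases < 100) {
    seed <- seed + 1
    m <- 2 + (seed %% 4)          # 2..5 alternatives
    n <- 1 + (seed %% 4)          # 1..4 criteria
    X <- random_decision_values(m, n, seed = 2000 + seed)
    set.seed(3000 + seed)
    impacts <- sample(c("benefit", "cost"), n, replace = TRUE)
    w <- runif(n); w <- w / sum(w)
    dm <- decision_matrix(X, impacts)
    expect_equal(unname(topsis(dm, w)$scores),
                 oracle_topsis(X, impacts, w), tolerance = 1e-12,
                 label = paste("topsis case", seed))
    expect_equal(unname(copras(dm, w, normalization = "sum")$scores),
                 oracle_copras(X, impacts, w, "sum"), tolerance = 1e-12,
                 label = paste("copras sum case", seed))
    expect_equal(unname(copras(dm, w, normalization = "none")$scores),
                 oracle_copras(X, impacts, w, "none"), tolerance = 1e-12,
                 label = paste("copras raw case", seed))
    cases <- cases + 1
  }
})

test_that("SECA matches a nested-grid oracle on small instances", {
  for (seed in 1:12) {
    m <- 3 + (seed %% 3)           # 3..5 alternatives
    n <- 2 + (seed %% 2)           # 2..3 criteria
    X <- random_decision_values(m, n, seed = 4000 + seed)
    set.seed(5000 + seed)
    impacts <- sample(c("benefit", "cost"), n, replace = TRUE)
    beta <- sample(c(0.5, 1, 3), 1)
    dm <- decision_matrix(X, impacts)
    r <- seca(dm, beta = beta)
    oracle <- oracle_seca_grid(X, impacts, beta)
    expect_equal(r$intermediates$objective, oracle$obj, tolerance = 1e-4,
                 label = paste("seca objective case", seed))
    f <- oracle_seca_objective(X, impacts, beta)
    # the solver's weights must be at least as good as the grid's
    expect_gte(f(r$intermediates$weights) + 1e-6, oracle$obj)
  }
})

test_that("SECA is deterministic and symmetric under identical criteria", {
  X <- random_decision_values(5, 3, seed = 77)
  dm <- decision_matrix(X, impacts = c("benefit", "benefit", "cost"))
  r1 <- seca(dm, beta = 2, seed = 9, restarts = 3)
  r2 <- seca(dm, beta = 2, seed = 9, restarts = 3)
  expect_identical(r1$intermediates$weights, r2$intermediates$weights)
  expect_identical(r1$scores, r2$scores)

  # identical columns: equal weights, alternatives ranked by the column
  col <- c(0.9, 0.3, 0.6)
  dmi <- decision_matrix(cbind(col, col, col), impacts = rep("benefit", 3))
  ri <- seca(dmi, beta = 3)
  expect_equal(unname(ri$intermediates$weights), rep(1 / 3, 3),
               tolerance = 1e-9)
  expect_equal(unname(ri$ranks), c(1L, 3L, 2L))

  expect_error(seca(dm, beta = -1), "non-negative")
})

test_that("column rescaling and row permutation leave rankings invariant", {
  X <- random_decision_values(5, 4, seed = 55)
  impacts <- c("benefit", "cost", "benefit", "cost")
  dm <- decision_matrix(X, impacts)
  w <- entropy_weights(dm)

  # scale invariance: multiply one column by a positive constant
  for (j in 1:4) {
    X2 <- X; X2[, j] <- X2[, j] * 37.5
    dm2 <- decision_matrix(X2, impacts)
    expect_equal(unname(topsis(dm2, w)$scores), unname(topsis(dm, w)$scores),
                 tolerance = 1e-12)
    expect_equal(unname(copras(dm2, w, "sum")$scores),
                 unname(copras(dm, w, "sum")$scores), tolerance = 1e-10)
    # entropy weights themselves are scale-invariant
    expect_equal(unname(entropy_weights(dm2)), unname(w), tolerance = 1e-12)
  }

  # permutation equivariance: permuting rows permutes scores identically
  perm <- c(3, 1, 5, 2, 4)
  dmp <- decision_matrix(X[perm, ], impacts)
  expect_equal(unname(topsis(dmp, w)$scores),
               unname(topsis(dm, w)$scores)[perm], tolerance = 1e-12)
  expect_equal(unname(copras(dmp, w, "sum")$scores),
               unname(copras(dm, w, "sum")$scores)[perm], tolerance = 1e-12)
  rs <- seca(dm, beta = 3); rsp <- seca(dmp, beta = 3)
  expect_equal(unname(rsp$scores), unname(rs$scores)[perm], tolerance = 1e-6)
})

test_that("spearman_rho matches the hand formula", {
  expect_equal(spearman_rho(1:6, 1:6), 1)
  expect_equal(spearman_rho(1:6, 6:1), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_error(spearman_rho(1:3, 1:4), "length")
})

test_that("decision matrices reject bad input and round-trip through CSV", {
  expect_error(decision_matrix(matrix(1, 1, 2), c("benefit", "cost")),
               "2 alternatives")
  expect_error(decision_matrix(matrix(c(1, -1, 2, 3), 2, 2),
                               c("benefit", "cost")), "positive")
  expect_error(decision_matrix(matrix(1:4, 2, 2), c("up", "down")),
               "benefit")

  dm <- decision_matrix(random_decision_values(4, 3, seed = 9),
                        impacts = c("benefit", "cost", "benefit"))
  path <- tempfile(fileext = ".csv")
  write_decision_matrix(dm, path)
  back <- read_decision_matrix(path)
  expect_equal(back$values, dm$values, tolerance = 1e-12)
  expect_equal(back$impacts, dm$impacts)
})
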