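test_that("weight training reproduces pairwise correlations exactly", {
  x <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8), g3 = c(4, 3, 2, 1))
  colnames(x) <- paste0("s", 1:4)
  W <- train_weights(x)
  expect_equal(W["g1", "g2"], 1)
  expect_equal(W["g1", "g3"], -1)
  expect_equal(diag(W), c(g1 = 0, g2 = 0, g3 = 0))

  y <- random_expr(6, 10, seed = 21)
  Wy <- train_weights(y)
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(Wy[i, j], cor(y[i, ], y[j, ]), tolerance = 1e-12)
  expect_identical(Wy, t(Wy))
})

test_that("weight training rejects degenerate input", {
  x <- rbind(g1 = c(1, 2, 3, 4), bad = c(7, 7, 7, 7))
  colnames(x) <- paste0("s", 1:4)
  expect_error(train_weights(x), "bad")
  expect_error(train_weights(x[, 1:2]), "3 samples")
})

test_that("the sign update follows hand-computed dynamics and tie rules", {
  W <- rbind(c(0, -1), c(-1, 0))
  expect_equal(recall_step(c(1, -1), W), c(1, -1))     # fixed point
  expect_equal(recall_step(c(1, 1), W), c(-1, -1))     # half of a 2-cycle
  expect_equal(recall_step(c(-1, -1), W), c(1, 1))
  # zero weight matrix: tie rule makes the update an identity on signs
  W0 <- matrix(0, 3, 3)
  expect_equal(recall_step(c(1, -1, 1), W0), c(1, -1, 1))
  expect_equal(recall_step(c(0.5, -2, 0), W0), c(1, -1, 1))  # sgn(0) -> +1
  expect_error(recall_step(c(1, 1, 1), W), "match")
})

test_that("the update is invariant to positive rescaling of the state", {
  set.seed(4)
  x <- random_expr(8, 6)
  W <- train_weights(x)
  for (c in c(0.01, 1, 250)) {
    p <- rnorm(8)
    expect_identical(recall_step(c * p, W), recall_step(p, W))
  }
})

test_that("energy matches the quadratic form on hand cases", {
  W <- matrix(0, 2, 2); W[1, 2] <- W[2, 1] <- 0.8
  expect_equal(hopfield_energy(c(1, 1), W), -0.8)
  expect_equal(hopfield_energy(c(1, -1), W), 0.8)
  expect_equal(hopfield_energy(rnorm(2), matrix(0, 2, 2)), 0)
  expect_error(hopfield_energy(c(1, 1, 1), W), "match")
})

test_that("recall terminates with correct status bookkeeping", {
  W <- rbind(c(0, -1), c(-1, 0))
  # a bipolar fixed point is recognised after one confirming update
  tr <- run_recall(c(1, -1), W)
  expect_equal(tr$status, "fixed_point")
  expect_equal(tr$n_iterations, 1L)
  expect_equal(tr$terminal, c(1, -1))
  # the antiferromagnetic pair cycles; both cycle states have E = +1,
  # so the tie sends the later state out as terminal
  tc <- run_recall(c(1, 1), W)
  expect_equal(tc$status, "two_cycle")
  expect_equal(tc$energies[2], 1)
  expect_equal(tc$energies[3], 1)
  expect_equal(tc$terminal, tc$states[[length(tc$states)]])
  # max_iter is honoured and reported
  expect_equal(run_recall(c(1, 1), W, max_iter = 1)$status, "max_iter")
  expect_error(run_recall(c(1, 1), W, max_iter = 0), "max_iter")
})

test_that("recall respects spin-flip symmetry", {
  set.seed(31)
  x <- random_expr(10, 8)
  W <- train_weights(x)
  for (j in 1:4) {
    a <- run_recall(x[, j], W)
    b <- run_recall(-x[, j], W)
    expect_equal(b$status, a$status)
    expect_equal(b$energies, a$energies)
    expect_equal(b$terminal, -a$terminal)
  }
})

test_that("the bilinear Lyapunov function descends on random weights", {
  # synchronous sign dynamics guarantee descent of -P(t) W P(t+1)^T
  set.seed(42)
  for (rep in 1:20) {
    d <- sample(4:10, 1)
    x <- random_expr(d, 8)
    W <- train_weights(x)
    for (j in 1:8) {
      ss <- run_recall(x[, j], W)$states
      if (length(ss) < 4) next
      b <- vapply(2:(length(ss) - 1), function(t)
        -as.numeric(ss[[t]] %*% W %*% ss[[t + 1]]), 0)
      expect_lte(max(diff(b)), 1e-9)
    }
  }
})

test_that("quadratic energy descends on correlation-structured data", {
  sim <- simulate_progression(seed = 17)
  fit <- hopfield_fit(sim$data, features = "all")
  for (tr in fit$trajectories) {
    e <- tr$energies[-1]                       # bipolar states only
    n <- if (tr$status == "two_cycle") length(e) - 2 else length(e)
    if (n >= 2) expect_lte(max(diff(e[seq_len(n)])), 1e-9)
  }
})
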