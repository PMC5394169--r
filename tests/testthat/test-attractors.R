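make_W <- function(d) {
  W <- matrix(0.5, d, d)
  diag(W) <- 0
  W
}

test_that("samples sharing a terminal pattern share an attractor", {
  W <- make_W(3)
  p <- c(1, 1, 1)
  tr <- list(a = traj_stub(p, -2), b = traj_stub(p, -3),
             c = traj_stub(-p, -1))
  stages <- factor(c(a = "normal", b = "normal", c = "disease"),
                   levels = c("normal", "disease"))
  aset <- collect_attractors(tr, W, stages)
  expect_length(aset$attractors, 2)
  n <- vapply(aset$attractors, function(a) length(a$members), 0L)
  expect_setequal(n, c(2L, 1L))
})

test_that("patterns differing in one gene are distinct attractors", {
  W <- make_W(4)
  tr <- list(a = traj_stub(c(1, 1, 1, 1), -2),
             b = traj_stub(c(1, 1, 1, -1), -2))
  stages <- factor(c(a = "x", b = "x"))
  expect_length(collect_attractors(tr, W, stages)$attractors, 2)
})

test_that("unconverged samples are excluded but accounted for", {
  W <- make_W(2)
  tr <- list(a = traj_stub(c(1, 1), -2),
             b = traj_stub(c(1, 1), -2, status = "max_iter"),
             c = traj_stub(c(-1, -1), -2))
  stages <- factor(c(a = "s1", b = "s1", c = "s2"))
  aset <- collect_attractors(tr, W, stages)
  expect_equal(aset$unconverged, "b")
  total <- sum(vapply(aset$attractors,
                      function(a) sum(a$stage_composition), 0)) +
    length(aset$unconverged)
  expect_equal(total, length(tr))
})

test_that("attractor labels follow plurality with stage-order tie-break", {
  W <- make_W(2)
  p <- c(1, 1)
  tr <- list(a = traj_stub(p, -1), b = traj_stub(p, -1),
             c = traj_stub(p, -1), d = traj_stub(p, -1))
  stages <- factor(c(a = "mid", b = "mid", c = "normal", d = "normal"),
                   levels = c("normal", "mid"))
  aset <- collect_attractors(tr, W, stages)
  expect_equal(aset$attractors[[1]]$label, "normal")  # 2-2 tie -> earliest
  stages2 <- factor(c(a = "mid", b = "mid", c = "mid", d = "normal"),
                    levels = c("normal", "mid"))
  expect_equal(collect_attractors(tr, W, stages2)$attractors[[1]]$label,
               "mid")
})

test_that("width matches hand computation and its invariances", {
  x <- cbind(s1 = c(1, 1, 1, 1), s2 = c(-1, 1, 1, 1))
  rownames(x) <- paste0("g", 1:4)
  attr <- list(members = c("s1", "s2"))
  expect_equal(attractor_width(attr, x), 1.0)  # ||diff|| = 2, / sqrt(4)
  expect_equal(attractor_width(list(members = "s1"), x), 0)
  x2 <- cbind(x, s3 = c(1, 1, 1, 1))
  expect_equal(attractor_width(list(members = c("s3", "s1")), x2), 0)
  # permutation of member order leaves the width unchanged
  set.seed(2)
  y <- random_expr(6, 5)
  m <- colnames(y)
  expect_equal(attractor_width(list(members = m), y),
               attractor_width(list(members = rev(m)), y))
  expect_error(attractor_width(list(members = c("s1", "zz")), x), "zz")
})

test_that("depth is the energy drop from original states to the attractor", {
  W <- make_W(2)
  tr <- list(a = traj_stub(c(1, 1), -120), b = traj_stub(c(1, 1), -122),
             c = traj_stub(c(1, 1), -278))
  stages <- factor(c(a = "normal", b = "normal", c = "pd"),
                   levels = c("normal", "pd"))
  aset <- collect_attractors(tr, W, stages)
  a <- aset$attractors[[1]]
  d <- attractor_depth(a, tr, stages)
  expect_equal(d$overall, abs(mean(c(-120, -122, -278)) - a$energy),
               tolerance = 1e-12)
  expect_equal(unname(d$by_group["normal"]), abs(-121 - a$energy),
               tolerance = 1e-12)
  # a member starting exactly at the attractor pattern contributes zero drop
  tr0 <- list(z = traj_stub(c(1, 1), hopfield_energy(c(1, 1), W)))
  aset0 <- collect_attractors(tr0, W, factor(c(z = "s")))
  expect_equal(attractor_depth(aset0$attractors[[1]], tr0)$overall, 0)
})

test_that("width grows with within-stage noise", {
  widths <- vapply(c(0.2, 0.5, 1.0), function(ns) {
    mean(vapply(1:20, function(s) {
      sim <- simulate_progression(n_genes = 60, samples_per_stage = 6,
                                  noise_sd = ns, seed = s)
      fit <- hopfield_fit(sim$data, features = "all")
      mean(fit$metrics$width)
    }, 0))
  }, 0)
  expect_true(all(diff(widths) > 0))
})
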