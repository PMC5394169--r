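test_that("z-scoring centers and scales every gene row", {
  x <- rbind(g1 = c(1, 2, 3), g2 = c(10, 0, 5))
  colnames(x) <- paste0("s", 1:3)
  z <- zscore_genes(x)
  expect_equal(z["g1", ], c(s1 = -1, s2 = 0, s3 = 1))
  expect_true(all(abs(rowMeans(z)) < 1e-9))
  expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-9))
  # idempotence: z-scoring an already z-scored matrix is a no-op
  expect_equal(zscore_genes(z), z, tolerance = 1e-6)
})

test_that("constant rows are dropped with a warning; all-constant errors", {
  x <- rbind(g1 = c(1, 2, 3, 4), flat = c(5, 5, 5, 5))
  colnames(x) <- paste0("s", 1:4)
  expect_warning(z <- zscore_genes(x), "zero-variance")
  expect_equal(rownames(z), "g1")
  expect_error(zscore_genes(rbind(a = rep(1, 4), b = rep(2, 4))),
               "constant")
})

test_that("variance ranking is descending with lexicographic tie-break", {
  x <- rbind(g1 = c(0, 0.1, 0.2, 0.55), g2 = c(0, 3, 6, 9),
             g3 = c(0, 1.5, 3, 4))
  colnames(x) <- paste0("s", 1:4)
  fr <- rank_by_variance(x)
  expect_equal(fr$gene, c("g2", "g3", "g1"))
  # equal variance -> smaller ID first
  y <- rbind(b = c(0, 1, 2), a = c(2, 1, 0), c = c(0, 10, 20))
  colnames(y) <- paste0("s", 1:3)
  expect_equal(rank_by_variance(y)$gene, c("c", "a", "b"))
})

test_that("ranking agrees with an independent per-row variance oracle", {
  x <- random_expr(50, 10, seed = 11)
  fr <- rank_by_variance(x)
  oracle <- apply(x, 1, var)
  expect_equal(fr$variance, unname(sort(oracle, decreasing = TRUE)),
               tolerance = 1e-12)
  expect_equal(unname(oracle[fr$gene]), fr$variance, tolerance = 1e-12)
})

test_that("elbow sits at the max-perpendicular-distance point of the curve", {
  # steep descent (100,80,60,40,20) then a flat tail of 50 genes at 1.0
  v <- c(100, 80, 60, 40, 20, rep(1, 50))
  u <- scale(rnorm(20))[, 1]
  x <- t(sapply(sqrt(v), function(s) s * u))
  dimnames(x) <- list(sprintf("g%02d", seq_along(v)), paste0("s", 1:20))
  fr <- select_elbow(rank_by_variance(x))
  # independent oracle: explicit point-to-chord distance on the
  # min-max-normalised curve
  n <- length(v)
  px <- (seq_len(n) - 1) / (n - 1)
  py <- (sort(v, decreasing = TRUE) - min(v)) / diff(range(v))
  a <- c(px[1], py[1]); b <- c(px[n], py[n])
  dd <- abs((b[1] - a[1]) * (a[2] - py) - (a[1] - px) * (b[2] - a[2])) /
    sqrt(sum((b - a)^2))
  expect_equal(fr$k, which.max(dd))
  expect_equal(fr$k, 6L)
  expect_equal(fr$method, "elbow")
})

test_that("flat and degenerate variance curves are handled", {
  u <- scale(rnorm(12))[, 1]
  x <- t(sapply(rep(2, 5), function(s) s * u))
  dimnames(x) <- list(paste0("g", 1:5), paste0("s", 1:12))
  expect_warning(fr <- select_elbow(rank_by_variance(x)), "flat")
  expect_equal(fr$k, 5L)
})

test_that("an explicit k override keeps exactly the top-k genes", {
  x <- random_expr(30, 8, seed = 3)
  fr <- select_elbow(rank_by_variance(x), k = 7)
  expect_equal(fr$method, "fixed")
  genes <- selected_genes(fr)
  expect_length(genes, 7)
  oracle <- names(sort(apply(x, 1, var), decreasing = TRUE))[1:7]
  expect_setequal(genes, oracle)
  expect_error(select_elbow(rank_by_variance(x), k = 31), "k must be")
})

test_that("feature subsetting commutes with z-scoring", {
  x <- random_expr(20, 9, seed = 5)
  genes <- selected_genes(select_elbow(rank_by_variance(x), k = 8))
  expect_equal(zscore_genes(x)[genes, ], zscore_genes(x[genes, ]))
})

test_that("expression loader validates and round-trips", {
  sim <- simulate_progression(n_genes = 12, samples_per_stage = 4, seed = 9)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  es <- read_expression(paths[1], paths[2],
                        stage_order = levels(sim$data$stages))
  expect_equal(es$values, sim$data$values)
  expect_equal(es$stages, sim$data$stages)
  expect_error(read_expression(file.path(dir, "nope.tsv"), paths[2]),
               "nope.tsv")
})

test_that("missing values are rejected unless imputation is requested", {
  dir <- withr::local_tempdir()
  ef <- file.path(dir, "e.tsv"); sf <- file.path(dir, "s.tsv")
  writeLines(c("id\ts1\ts2\ts3", "g1\t1\tNA\t3", "g2\t4\t5\t6"), ef)
  writeLines(c("s1\ta", "s2\ta", "s3\tb"), sf)
  expect_error(read_expression(ef, sf), "impute")
  es <- read_expression(ef, sf, impute = TRUE)
  expect_equal(es$values["g1", "s2"], 2)  # row mean of 1 and 3
})
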