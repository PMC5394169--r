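test_that("correlation p-values match the t-distribution route", {
  expect_equal(correlation_pvalue(0, 10), 1)
  expect_equal(correlation_pvalue(1, 10), 0)
  expect_equal(correlation_pvalue(-1, 10), 0)
  expect_lt(correlation_pvalue(0.9, 15), 1e-4)   # clearly significant
  expect_gt(correlation_pvalue(0.5, 15), 0.05)   # clearly not
  expect_error(correlation_pvalue(0.5, 2), "n >= 3")
  # independent oracle: cor.test on actual paired data
  set.seed(12)
  for (n in c(5, 10, 15, 40)) {
    for (rep in 1:5) {
      a <- rnorm(n); b <- 0.5 * a + rnorm(n)
      ct <- cor.test(a, b)
      expect_equal(correlation_pvalue(cor(a, b), n), ct$p.value,
                   tolerance = 1e-9)
    }
  }
})

test_that("stage networks keep only significant canonical edges", {
  set.seed(20)
  x <- random_expr(6, 18)
  x["g002", 1:9] <- x["g001", 1:9]          # identical within stage A
  stages <- rep(c("A", "B"), each = 9)
  net <- stage_network(x, "A", alpha = 1e-4, stages = stages)
  hit <- net$edges[net$edges$gene_a == "g001" & net$edges$gene_b == "g002", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$r, 1)
  expect_equal(hit$sign, "+")
  expect_true(all(net$edges$gene_a < net$edges$gene_b))
  expect_setequal(net$nodes, unique(c(net$edges$gene_a, net$edges$gene_b)))
  expect_error(stage_network(x, "C", stages = stages), "unknown stage")
  expect_error(stage_network(x[, 1:2], "A", stages = stages[1:2]),
               "fewer than 3")
})

test_that("a pure-noise stage yields almost no edges at alpha 1e-4", {
  set.seed(7)
  x <- random_expr(100, 15)
  net <- stage_network(x, "only", stages = rep("only", 15), alpha = 1e-4)
  expect_lte(nrow(net$edges), 3)   # null expectation ~0.5 of 4,950 pairs
})

test_that("edge filtering is monotone in alpha and permutation-invariant", {
  set.seed(14)
  x <- random_expr(20, 12)
  stages <- rep("S", 12)
  loose <- stage_network(x, "S", alpha = 1e-2, stages = stages)
  strict <- stage_network(x, "S", alpha = 1e-4, stages = stages)
  keys <- function(net) paste(net$edges$gene_a, net$edges$gene_b)
  expect_true(all(keys(strict) %in% keys(loose)))
  # shuffling samples and genes leaves the edge set unchanged
  perm <- stage_network(x[sample(20), sample(12)], "S", alpha = 1e-2,
                        stages = stages)
  expect_setequal(keys(perm), keys(loose))
})

test_that("common/unique decomposition obeys the subtraction identity", {
  sim <- simulate_progression(seed = 6)
  fit <- hopfield_fit(sim$data, features = "all")
  nets <- lapply(levels(fit$stages), function(s)
    stage_network(fit$X, s, alpha = 1e-3, stages = fit$stages))
  cu <- common_and_unique(nets)
  for (net in nets) {
    u <- cu$unique[[net$stage]]
    expect_equal(nrow(u$edges), nrow(net$edges) - nrow(cu$common))
    expect_setequal(u$nodes, unique(c(u$edges$gene_a, u$edges$gene_b)))
  }
  tab <- network_summary(nets, cu)
  expect_equal(tab$pos + tab$neg, tab$edges)
  expect_equal(tab$unique_edges, tab$edges - tab$common_edges)
  expect_error(common_and_unique(nets[1]), "at least 2")
})

test_that("two identical networks share everything and keep nothing unique", {
  set.seed(33)
  x <- random_expr(15, 10)
  n1 <- stage_network(x, "S", alpha = 0.05, stages = rep("S", 10))
  n2 <- n1; n2$stage <- "T"
  cu <- common_and_unique(list(n1, n2))
  expect_equal(nrow(cu$common), nrow(n1$edges))
  expect_equal(nrow(cu$unique$S$edges), 0)
  expect_length(cu$unique$S$nodes, 0)
})

test_that("networks export to SIF and GraphML", {
  set.seed(40)
  x <- random_expr(10, 10)
  net <- stage_network(x, "S", alpha = 0.05, stages = rep("S", 10))
  sif <- withr::local_tempfile(fileext = ".sif")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_sif(net, sif)
  expect_length(readLines(sif), nrow(net$edges))
  write_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(net$edges))
})
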