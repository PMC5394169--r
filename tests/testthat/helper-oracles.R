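# Independent oracles, kept free of the package's own code paths.

# Exhaustively enumerate the bipolar fixed points of the synchronous sign
# update (same tie rule: a zero field keeps the previous sign).
enumerate_fixed_points <- function(W) {
  d <- nrow(W)
  S <- as.matrix(expand.grid(rep(list(c(-1, 1)), d)))
  H <- S %*% W
  Snew <- sign(H)
  Snew[H == 0] <- S[H == 0]
  S[rowSums(Snew == S) == d, , drop = FALSE]
}

pat_key <- function(p) paste(ifelse(p > 0, "+", "-"), collapse = "")

# random expression-like matrix with gene/sample names
random_expr <- function(d, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(d * n), d, n,
         dimnames = list(sprintf("g%03d", seq_len(d)),
                         sprintf("s%03d", seq_len(n))))
}

# minimal trajectory stub for unit-testing the grouping layer
traj_stub <- function(terminal, e0, status = "fixed_point") {
  list(states = list(terminal), energies = e0, status = status,
       n_iterations = 1L, terminal = terminal)
}
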