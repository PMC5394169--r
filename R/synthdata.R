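#' Simulate staged expression data with planted attractor structure
#'
#' Generates a genes-by-samples matrix organised in contiguous blocks of
#' co-expressed genes. Each *program* assigns one sign per block; a sample
#' carrying program p expresses gene g of block b as
#' `baseline + sign_b(p) * A_b + jitter_{b,s} + noise_{g,s}`, where `A_b`
#' is the block amplitude, the per-sample block jitter is shared by all
#' genes of the block (within-stage co-expression) and the noise is i.i.d.
#' Gaussian.
#'
#' `within_block_r` is the target pooled within-block Pearson correlation
#' *at unit noise*: amplitude and jitter are solved from it at
#' `noise_sd = 1` (95% of the signal variance from program sign flips
#' across samples, 5% from jitter) and then held fixed, so `noise_sd` is
#' an independent dial — raising it genuinely degrades correlations and
#' widens attractors rather than being rescaled away.
#'
#' Stages map onto programs as a progression: the first stage carries
#' program 1 ("normal"), all later stages program 2 ("disease") unless
#' `stage_programs` says otherwise. `mixing` reassigns that fraction of
#' each interior stage's samples to the preceding stage's program,
#' emulating heterogeneous mid-stages whose samples split between the
#' normal and disease attractors.
#'
#' Correlation-weight Hopfield recall stabilises block-sign patterns, so
#' each program's gene-level sign vector is the attractor its samples
#' should reach — this is the ground truth end-to-end tests check. For
#' that to hold the programs must differ on every block (the default
#' does): a block whose sign is constant across all samples carries no
#' program signal once genes are mean-centered, and its relaxed sign is
#' then jitter-driven.
#'
#' @param n_genes number of signal genes (default 100).
#' @param n_stages number of ordered stages (default 3).
#' @param samples_per_stage samples per stage (default 15; >= 3).
#' @param n_blocks number of co-expression blocks (default 2).
#' @param within_block_r target within-block Pearson correlation in (0, 1)
#'   (default 0.8).
#' @param noise_sd standard deviation of the i.i.d. gene-level noise
#'   (default 1).
#' @param mixing fraction of each interior stage's samples planted with
#'   the preceding stage's program (default 0).
#' @param seed RNG seed; same seed gives a bit-identical dataset.
#' @param programs optional programs x blocks sign matrix (entries +-1).
#'   Default: program 1 all +1, program 2 all -1 (opposed expression
#'   programs, so every block is informative).
#' @param stage_programs optional integer vector (length `n_stages`)
#'   mapping each stage to a program row. Default `c(1, 2, 2, ...)`.
#' @param n_null_genes additional inert genes with low-variance noise
#'   (default 0); gives the variance elbow a breakpoint to find.
#' @param baseline additive constant emulating log-intensity scale
#'   (default 8; removed again by z-scoring).
#' @return List with `data` (an [expression_set()]), `truth` (data.frame:
#'   `sample`, `stage`, `program`), `programs` (the sign matrix),
#'   `program_patterns` (genes x programs matrix of planted gene-level
#'   sign vectors over the signal genes) and `blocks` (gene -> block map).
#' @examples
#' sim <- simulate_progression(n_genes = 40, samples_per_stage = 5, seed = 1)
#' sim$data
#' @export
simulate_progression <- function(n_genes = 100, n_stages = 3,
                                 samples_per_stage = 15, n_blocks = 2,
                                 within_block_r = 0.8, noise_sd = 1,
                                 mixing = 0, seed = 1,
                                 programs = NULL, stage_programs = NULL,
                                 n_null_genes = 0, baseline = 8) {
  if (samples_per_stage < 3) stop("need >= 3 samples per stage")
  if (n_stages < 2) stop("need >= 2 stages")
  if (within_block_r <= 0 || within_block_r >= 1)
    stop("within_block_r must be in (0, 1)")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (mixing < 0 || mixing > 1) stop("mixing must be in [0, 1]")

  if (is.null(programs))
    programs <- rbind(rep(1, n_blocks), rep(-1, n_blocks))
  programs <- as.matrix(programs)
  if (!all(programs %in% c(-1, 1))) stop("programs must be +-1 signs")
  if (ncol(programs) != n_blocks) stop("programs must have n_blocks columns")
  stage_programs <- stage_programs %||% c(1, rep(2, n_stages - 1))
  if (length(stage_programs) != n_stages ||
      any(!stage_programs %in% seq_len(nrow(programs))))
    stop("stage_programs must map each stage to a program row")

  stage_names <- if (n_stages == 2) c("normal", "disease")
    else c("normal", paste0("mid", seq_len(n_stages - 2)), "disease")
  blocks <- rep(seq_len(n_blocks), length.out = n_genes)
  blocks <- sort(blocks)                       # contiguous blocks

  n_samples <- n_stages * samples_per_stage
  sample_ids <- sprintf("s%03d", seq_len(n_samples))
  stage_of <- rep(stage_names, each = samples_per_stage)

  with_seed(seed, {
    prog_of <- rep(stage_programs, each = samples_per_stage)
    if (mixing > 0 && n_stages > 2) {
      for (s in 2:(n_stages - 1)) {
        idx <- which(stage_of == stage_names[s])
        flip <- sample(idx, round(mixing * length(idx)))
        prog_of[flip] <- stage_programs[s - 1]
      }
    }
    # pooled signal variance achieving within_block_r at unit noise;
    # 95% from sign flips across samples, 5% from per-sample jitter
    v <- within_block_r / (1 - within_block_r)
    tau <- sqrt(0.05 * v)
    sgn_of <- programs[prog_of, , drop = FALSE]     # samples x blocks
    q <- colMeans(sgn_of == -1)                     # flip rate per block
    spread <- pmax(4 * q * (1 - q), 0.04)           # guard degenerate mixes
    A <- sqrt(0.95 * v / spread)
    vals <- matrix(0, n_genes, n_samples)
    for (j in seq_len(n_samples)) {
      jit <- stats::rnorm(n_blocks, 0, tau)
      vals[, j] <- (sgn_of[j, ] * A + jit)[blocks]
    }
    vals <- vals + matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd),
                          n_genes, n_samples)
    if (n_null_genes > 0) {
      nulls <- matrix(stats::rnorm(n_null_genes * n_samples,
                                   0, 0.2 * noise_sd),
                      n_null_genes, n_samples)
      vals <- rbind(vals, nulls)
    }
  })
  vals <- vals + baseline
  gene_ids <- c(sprintf("g%04d", seq_len(n_genes)),
                if (n_null_genes > 0) sprintf("null%04d",
                                              seq_len(n_null_genes)))
  dimnames(vals) <- list(gene_ids, sample_ids)

  patterns <- apply(programs, 1, function(p) p[blocks])
  rownames(patterns) <- gene_ids[seq_len(n_genes)]
  colnames(patterns) <- paste0("program", seq_len(nrow(programs)))

  list(data = expression_set(vals, stats::setNames(stage_of, sample_ids),
                             stage_order = stage_names),
       truth = data.frame(sample = sample_ids, stage = stage_of,
                          program = prog_of, row.names = NULL),
       programs = programs,
       program_patterns = patterns,
       blocks = stats::setNames(blocks, gene_ids[seq_len(n_genes)]))
}

#' Write a simulated dataset to disk
#'
#' Emits the expression/stage TSV pair [read_expression()] reads plus a
#' sidecar TSV with the planted per-sample program (the ground truth).
#'
#' @param sim result of [simulate_progression()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- file.path(dir, "expression.tsv")
  stages <- file.path(dir, "stages.tsv")
  truth <- file.path(dir, "truth.tsv")
  write_expression(sim$data, expr, stages)
  utils::write.table(sim$truth, truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expr, stages, truth))
}
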