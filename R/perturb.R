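#' Randomly perturb weight-matrix edges
#'
#' Replaces a fixed fraction of the unordered off-diagonal gene pairs
#' ("edges") of `W` with i.i.d. draws from Uniform(-1, 1), keeping entries
#' on the correlation scale. Exactly `round(fraction * d(d-1)/2)` pairs are
#' chosen uniformly without replacement; one draw per pair is mirrored to
#' both triangles so symmetry and the zero diagonal are preserved, and
#' untouched entries are bit-identical to the input. Fully reproducible
#' from `seed` (the caller's RNG stream is left undisturbed).
#'
#' @param W symmetric zero-diagonal weight matrix.
#' @param fraction fraction of edges to randomise, in \[0, 1\].
#' @param seed integer seed for the perturbation draw.
#' @return Perturbed weight matrix of the same shape.
#' @export
perturb_weights <- function(W, fraction, seed) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  d <- nrow(W)
  ut <- which(upper.tri(W))
  k <- round(fraction * length(ut))
  if (k == 0) return(W)
  Wp <- W
  with_seed(seed, {
    idx <- sample.int(length(ut), k)
    Wp[ut[idx]] <- stats::runif(k, -1, 1)
  })
  Wp[lower.tri(Wp)] <- t(Wp)[lower.tri(Wp)]
  Wp
}

#' Hamming distance between bipolar patterns
#'
#' Fraction of components on which two bipolar strings disagree: 0 means
#' identical, 1 fully complementary.
#'
#' @param a,b bipolar vectors of equal length (entries in \{-1, +1\}).
#' @return Number in \[0, 1\].
#' @export
hamming_distance <- function(a, b) {
  if (length(a) != length(b)) stop("patterns differ in length")
  if (!is_bipolar(a) || !is_bipolar(b)) stop("patterns must be bipolar (+-1)")
  mean(a != b)
}

#' Attractor robustness under edge perturbation
#'
#' Repeatedly perturbs a fraction of the weight edges
#' ([perturb_weights()]), relaxes every converged sample on the perturbed
#' landscape, and counts a sample as *failed* when it no longer reaches its
#' original attractor pattern exactly (or no longer reaches a fixed point at
#' all; plain non-convergence is also reported separately). Per attractor
#' the mean fail fraction over replicates measures how much random rewiring
#' the phenotype tolerates. The last replicate's per-iteration Hamming
#' distances to the original attractor are kept for plotting, and the mean
#' energy shift of each attractor pattern on the perturbed landscape is
#' reported (the difference bracketed between original and perturbed
#' surfaces).
#'
#' @param x z-scored feature-selected genes-by-samples matrix.
#' @param W unperturbed weight matrix.
#' @param aset `"attractor_set"` computed on the unperturbed `W`.
#' @param fraction fraction of edges perturbed per replicate (default 0.5).
#' @param n_replicates number of independent perturbation draws
#'   (default 100).
#' @param seed base seed; replicate r uses `seed + r`.
#' @param max_iter recall iteration cap.
#' @return An object of class `"perturbation_result"`: list with `fraction`,
#'   `n_replicates`, `seed`, `fail_fraction` (named per attractor id, mean
#'   over replicates), `fail_sd`, `nonconvergence_fraction`,
#'   `per_replicate` (replicates x attractors matrix), `energy_shift`
#'   (named, mean E_perturbed - E_original of each attractor pattern),
#'   `hd_traces` (long data.frame: sample, attractor, iteration, hd, from
#'   the final replicate) and `labels` (attractor id -> stage label).
#' @export
robustness_analysis <- function(x, W, aset, fraction = 0.5,
                                n_replicates = 100, seed = 0,
                                max_iter = 100) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  atts <- aset$attractors
  ids <- vapply(atts, `[[`, "", "id")
  labels <- stats::setNames(vapply(atts, `[[`, "", "label"), ids)
  # sample -> home attractor
  home <- list()
  for (a in atts) for (m in a$members) home[[m]] <- a
  samples <- intersect(colnames(x), names(home))

  fails <- matrix(NA_real_, n_replicates, length(ids),
                  dimnames = list(NULL, ids))
  nonconv <- numeric(n_replicates)
  shift <- matrix(NA_real_, n_replicates, length(ids),
                  dimnames = list(NULL, ids))
  hd_traces <- NULL
  for (r in seq_len(n_replicates)) {
    Wp <- perturb_weights(W, fraction, seed = seed + r)
    failed <- stats::setNames(logical(length(samples)), samples)
    nc <- 0L
    traces <- list()
    for (s in samples) {
      tr <- run_recall(x[, s], Wp, max_iter)
      pat <- home[[s]]$pattern
      failed[s] <- tr$status != "fixed_point" || any(tr$terminal != pat)
      if (tr$status == "max_iter") nc <- nc + 1L
      if (r == n_replicates) {
        hd <- vapply(tr$states[-1], hamming_distance, 0, b = pat)
        traces[[s]] <- data.frame(sample = s, attractor = home[[s]]$id,
                                  iteration = seq_along(hd), hd = hd,
                                  row.names = NULL)
      }
    }
    for (i in seq_along(atts)) {
      mem <- intersect(atts[[i]]$members, samples)
      fails[r, i] <- mean(failed[mem])
      shift[r, i] <- hopfield_energy(atts[[i]]$pattern, Wp) -
        atts[[i]]$energy
    }
    nonconv[r] <- nc / length(samples)
    if (r == n_replicates) hd_traces <- do.call(rbind, traces)
  }
  structure(list(fraction = fraction, n_replicates = n_replicates,
                 seed = seed,
                 fail_fraction = colMeans(fails),
                 fail_sd = apply(fails, 2, stats::sd),
                 nonconvergence_fraction = mean(nonconv),
                 per_replicate = fails,
                 energy_shift = colMeans(shift),
                 hd_traces = hd_traces,
                 labels = labels),
            class = "perturbation_result")
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(sprintf("Edge perturbation: fraction %.2f, %d replicate(s)\n",
              x$fraction, x$n_replicates))
  for (id in names(x$fail_fraction))
    cat(sprintf("  %s [%s]: fail fraction %.3f (sd %.3f), energy shift %.4g\n",
                id, x$labels[[id]], x$fail_fraction[[id]],
                if (x$n_replicates > 1) x$fail_sd[[id]] else NA,
                x$energy_shift[[id]]))
  invisible(x)
}
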