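#' Train the correlation weight matrix
#'
#' The Hopfield weight between genes i and j is their Pearson correlation
#' across all samples (stages pooled); the diagonal is zero and symmetry is
#' enforced exactly. This is the non-parametric "training phase": no sample
#' labels enter the weights.
#'
#' @param x numeric genes-by-samples matrix (typically z-scored and
#'   feature-selected); at least 3 samples, no constant rows.
#' @return A symmetric zero-diagonal d x d matrix with dimnames = gene IDs,
#'   entries in \[-1, 1\].
#' @examples
#' x <- rbind(g1 = c(1, 2, 3, 5), g2 = c(2, 4, 6, 10), g3 = c(4, 3, 2, 0))
#' train_weights(x)
#' @export
train_weights <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 3) stop("need at least 3 samples to train weights")
  s <- row_sds(x)
  if (any(bad <- s < .Machine$double.eps^0.5))
    stop("zero-variance gene(s) cannot enter the weight matrix: ",
         paste(rownames(x)[bad], collapse = ", "))
  W <- stats::cor(t(x))
  W <- (W + t(W)) / 2        # exact symmetry
  diag(W) <- 0
  W
}

# sign update with the tie rule: a zero local field keeps the previous
# component's sign (+1 if the previous component was itself 0)
sgn_update <- function(h, prev) {
  s <- sign(h)
  z <- s == 0
  if (any(z)) {
    ps <- sign(prev)
    ps[ps == 0] <- 1
    s[z] <- ps[z]
  }
  s
}

#' One synchronous recall update
#'
#' Applies `P(t+1) = sgn(P(t) %*% W)` to the whole state vector at once.
#' Components whose local field is exactly zero retain the previous state's
#' sign (+1 if that was zero), so a null weight matrix is an identity map
#' and no fixed bias is injected. The update only uses signs of the field,
#' so it is invariant to positive rescaling of `p`.
#'
#' @param p numeric state vector (continuous original sample state or a
#'   bipolar pattern).
#' @param W weight matrix from [train_weights()] (or a perturbed one).
#' @return Bipolar vector in \{-1, +1\}^d.
#' @export
recall_step <- function(p, W) {
  if (length(p) != nrow(W)) stop("state length does not match weight matrix")
  sgn_update(as.vector(p %*% W), p)
}

#' Hopfield (Lyapunov) energy of a state
#'
#' `E(P) = -1/2 * P W P^T`. For bipolar states this is the Lyapunov function
#' of the recall dynamics; for the continuous original sample states it
#' measures how tightly the sample's expression aligns with the correlation
#' structure (more coherent = lower energy).
#'
#' @inheritParams recall_step
#' @return A single number.
#' @export
hopfield_energy <- function(p, W) {
  if (length(p) != nrow(W)) stop("state length does not match weight matrix")
  -0.5 * as.numeric(p %*% W %*% p)
}

#' Relax a state to its attractor
#'
#' Iterates [recall_step()] from `p0` until a fixed point, a 2-cycle
#' (synchronous dynamics can oscillate between two states), or `max_iter`
#' updates. Every visited state and its energy are recorded; the energy at
#' index 1 is computed on `p0` itself, which may be continuous.
#'
#' For a 2-cycle the member of the oscillating pair with the lower energy is
#' designated the terminal state (on a tie, the later one).
#'
#' @param p0 numeric start state.
#' @param W weight matrix.
#' @param max_iter maximum number of synchronous updates (default 100; fixed
#'   points are typically reached within ten).
#' @return An object of class `"recall_trajectory"`: list with `states`
#'   (list, `[[1]]` = `p0`), `energies`, `status` (`"fixed_point"`,
#'   `"two_cycle"` or `"max_iter"`), `n_iterations` and `terminal` (the
#'   terminal bipolar pattern).
#' @examples
#' W <- rbind(c(0, -1), c(-1, 0))
#' run_recall(c(1, 1), W)$status   # "two_cycle"
#' @export
run_recall <- function(p0, W, max_iter = 100) {
  if (max_iter < 1) stop("max_iter must be >= 1")
  p0 <- as.numeric(p0)
  states <- vector("list", max_iter + 1)
  energies <- numeric(max_iter + 1)
  states[[1]] <- p0
  energies[1] <- hopfield_energy(p0, W)
  status <- "max_iter"
  last <- max_iter + 1
  for (i in seq_len(max_iter)) {
    p <- recall_step(states[[i]], W)
    states[[i + 1]] <- p
    energies[i + 1] <- hopfield_energy(p, W)
    if (all(p == states[[i]])) {
      status <- "fixed_point"; last <- i + 1; break
    }
    if (i >= 2 && all(p == states[[i - 1]])) {
      status <- "two_cycle"; last <- i + 1; break
    }
  }
  states <- states[seq_len(last)]
  energies <- energies[seq_len(last)]
  terminal <- if (status == "two_cycle") {
    a <- states[[last - 1]]; b <- states[[last]]
    if (energies[last - 1] < energies[last]) a else b
  } else {
    states[[last]]
  }
  structure(list(states = states, energies = energies, status = status,
                 n_iterations = as.integer(last) - 1L, terminal = terminal),
            class = "recall_trajectory")
}

#' @export
print.recall_trajectory <- function(x, ...) {
  cat(sprintf("Recall trajectory: %s after %d iteration(s); E %g -> %g\n",
              x$status, x$n_iterations, x$energies[1],
              x$energies[length(x$energies)]))
  invisible(x)
}

# relax every column of a (continuous) matrix; returns a named list
recall_samples <- function(x, W, max_iter = 100) {
  res <- lapply(seq_len(ncol(x)), function(j) run_recall(x[, j], W, max_iter))
  names(res) <- colnames(x)
  res
}
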