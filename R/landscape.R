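#' Project samples onto the first two principal components
#'
#' Deterministic 2-component PCA of the samples (rows = samples after
#' transposition). The sign of each component is fixed so that its
#' largest-magnitude gene loading is positive, removing the arbitrary sign
#' flip of eigenvector routines.
#'
#' @param x z-scored, feature-selected genes-by-samples matrix with at
#'   least 3 samples.
#' @return An object of class `"hn_projection"`: list with `scores`
#'   (samples x 2, columns PC1/PC2), `rotation` (genes x 2), `center`
#'   (per-gene means) and `sdev` (the component standard deviations).
#' @export
project_pca <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 3) stop("need at least 3 samples for PCA")
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE, rank. = 2)
  rot <- pc$rotation[, 1:2, drop = FALSE]
  sc <- pc$x[, 1:2, drop = FALSE]
  for (j in 1:2) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sc[, j] <- -sc[, j]
    }
  }
  colnames(sc) <- colnames(rot) <- c("PC1", "PC2")
  structure(list(scores = sc, rotation = rot, center = pc$center,
                 sdev = pc$sdev[1:2]),
            class = "hn_projection")
}

#' Project additional states through an existing PCA
#'
#' Used to place bipolar trajectory states and attractor patterns on the
#' same PC1/PC2 plane as the samples they relax from.
#'
#' @param proj an `"hn_projection"` from [project_pca()].
#' @param states numeric matrix of states as columns (genes x k), or a
#'   single vector.
#' @return k x 2 matrix of (PC1, PC2) coordinates.
#' @export
project_points <- function(proj, states) {
  if (is.null(dim(states))) states <- matrix(states, ncol = 1)
  sc <- crossprod(states - proj$center, proj$rotation)
  colnames(sc) <- c("PC1", "PC2")
  sc
}

# thin-plate radial basis: phi(r) = r^2 log r, phi(0) = 0
tps_phi <- function(r) ifelse(r > 0, r^2 * log(r), 0)

# exact scattered interpolator: TPS RBF + affine term
tps_fit <- function(coords, values) {
  key <- paste(signif(coords[, 1], 12), signif(coords[, 2], 12))
  if (anyDuplicated(key)) {           # average energies at coincident sites
    values <- as.vector(tapply(values, key, mean)[unique(key)])
    coords <- coords[!duplicated(key), , drop = FALSE]
  }
  n <- nrow(coords)
  K <- tps_phi(as.matrix(stats::dist(coords)))
  P <- cbind(1, coords)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  sol <- tryCatch(solve(A, c(values, 0, 0, 0)),
                  error = function(e) {
                    diag(K) <- diag(K) + 1e-8 * mean(abs(K))
                    A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
                    solve(A, c(values, 0, 0, 0))
                  })
  list(coords = coords, values = values,
       w = sol[seq_len(n)], a = sol[n + 1:3])
}

tps_eval <- function(fit, pts) {
  D <- sqrt(outer(pts[, 1], fit$coords[, 1], "-")^2 +
            outer(pts[, 2], fit$coords[, 2], "-")^2)
  as.vector(tps_phi(D) %*% fit$w + cbind(1, pts) %*% fit$a)
}

#' Interpolate the energy landscape over a PC grid
#'
#' Builds a regular grid over the bounding box of the projected points
#' (plus a margin) and interpolates the scattered (PC1, PC2, energy)
#' observations onto it with an exact thin-plate-spline interpolator: the
#' surface passes through every data site. Outside the convex hull of the
#' data there is no support for interpolation, so the surface is filled
#' with the maximum observed energy — a high plateau against which
#' attractors read as basins.
#'
#' @param coords numeric matrix/data.frame with two columns (PC1, PC2), one
#'   row per scattered point (samples, and typically their intermediate
#'   trajectory states and attractor patterns projected through the same
#'   PCA). At least 3 non-collinear points.
#' @param energies energy value per row of `coords`.
#' @param grid_resolution number of lattice points per axis (default 100,
#'   minimum 10).
#' @param margin fractional bounding-box padding (default 0.05).
#' @return An object of class `"hn_surface"`: list with `x`, `y` (axis
#'   vectors), `z` (energy matrix, `length(x)` x `length(y)`), `coords`,
#'   `energies`, `hull` (hull vertex indices) and the fitted interpolator.
#' @export
build_surface <- function(coords, energies, grid_resolution = 100,
                          margin = 0.05) {
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  if (nrow(coords) < 3) stop("need at least 3 scattered points")
  if (nrow(coords) != length(energies))
    stop("coords and energies lengths differ")
  if (grid_resolution < 10) stop("grid_resolution must be >= 10")
  fit <- tps_fit(coords, energies)
  rx <- range(fit$coords[, 1]); ry <- range(fit$coords[, 2])
  mx <- margin * max(diff(rx), .Machine$double.eps)
  my <- margin * max(diff(ry), .Machine$double.eps)
  gx <- seq(rx[1] - mx, rx[2] + mx, length.out = grid_resolution)
  gy <- seq(ry[1] - my, ry[2] + my, length.out = grid_resolution)
  pts <- cbind(rep(gx, times = grid_resolution),
               rep(gy, each = grid_resolution))
  z <- tps_eval(fit, pts)
  hull <- grDevices::chull(fit$coords)
  boundary <- fit$coords[c(hull, hull[1]), , drop = FALSE]
  inside <- mgcv::in.out(boundary, pts)
  plateau <- max(fit$values)
  z[!inside] <- plateau
  structure(list(x = gx, y = gy,
                 z = matrix(z, grid_resolution, grid_resolution),
                 coords = fit$coords, energies = fit$values,
                 hull = hull, plateau = plateau, tps = fit),
            class = "hn_surface")
}

#' Evaluate a landscape surface at arbitrary points
#'
#' Uses the exact interpolator inside the data hull and the plateau value
#' outside; a point coinciding with a data site returns that site's energy
#' exactly.
#'
#' @param object an `"hn_surface"`.
#' @param newdata two-column matrix of (PC1, PC2) coordinates.
#' @param ... unused.
#' @return Numeric vector of surface energies.
#' @export
predict.hn_surface <- function(object, newdata, ...) {
  pts <- as.matrix(newdata)[, 1:2, drop = FALSE]
  z <- tps_eval(object$tps, pts)
  boundary <- object$coords[c(object$hull, object$hull[1]), , drop = FALSE]
  inside <- mgcv::in.out(boundary, pts)
  # exact at data sites regardless of hull-boundary classification
  D <- sqrt(outer(pts[, 1], object$coords[, 1], "-")^2 +
            outer(pts[, 2], object$coords[, 2], "-")^2)
  hit <- apply(D, 1, function(r) {
    i <- which.min(r)
    if (r[i] < 1e-10) i else NA_integer_
  })
  z[!inside] <- object$plateau
  z[!is.na(hit)] <- object$energies[hit[!is.na(hit)]]
  z
}

#' Export the surface grid as TSV
#'
#' Long format (`pc1`, `pc2`, `energy`), one row per lattice point, for
#' external plotting tools.
#'
#' @param surface an `"hn_surface"`.
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
write_surface <- function(surface, file) {
  g <- expand.grid(pc1 = surface$x, pc2 = surface$y)
  g$energy <- as.vector(surface$z)
  utils::write.table(g, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Plot an energy landscape surface
#'
#' `type = "contour"` draws a filled image with contour lines in the PC
#' plane, optionally overlaying sample points and convergence trajectories;
#' `type = "persp"` draws the 3D surface.
#'
#' @param x an `"hn_surface"`.
#' @param type `"contour"` or `"persp"`.
#' @param points optional samples x 2 coordinate matrix to overlay.
#' @param point_col colors for `points`.
#' @param trajectories optional list of polylines (each a k x 2 matrix) to
#'   overlay in the contour view.
#' @param attractor_coords optional attractors x 2 coordinate matrix, drawn
#'   as filled green points.
#' @param ... passed to the underlying graphics call.
#' @return Invisibly, `x`.
#' @export
plot.hn_surface <- function(x, type = c("contour", "persp"), points = NULL,
                            point_col = "black", trajectories = NULL,
                            attractor_coords = NULL, ...) {
  type <- match.arg(type)
  if (type == "persp") {
    graphics::persp(x$x, x$y, x$z, xlab = "PC1", ylab = "PC2",
                    zlab = "energy", theta = 35, phi = 25,
                    col = "lightsteelblue", border = NA, shade = 0.6, ...)
  } else {
    graphics::image(x$x, x$y, x$z, xlab = "PC1", ylab = "PC2",
                    col = grDevices::hcl.colors(64, "Blue-Red 3",
                                                rev = TRUE), ...)
    graphics::contour(x$x, x$y, x$z, add = TRUE, col = "grey30",
                      drawlabels = FALSE)
    if (!is.null(trajectories))
      for (tr in trajectories)
        graphics::lines(tr[, 1], tr[, 2], col = "grey15", lwd = 0.7)
    if (!is.null(points))
      graphics::points(points[, 1], points[, 2], pch = 19, cex = 0.8,
                       col = point_col)
    if (!is.null(attractor_coords))
      graphics::points(attractor_coords[, 1], attractor_coords[, 2],
                       pch = 21, cex = 1.6, bg = "green3")
  }
  invisible(x)
}
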