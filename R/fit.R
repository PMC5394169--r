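#' Fit a Hopfield attractor-landscape model
#'
#' The main entry point. Starting from a staged expression set the fit
#' (1) ranks genes by raw-value variance and keeps those up to the
#' variance elbow (or a fixed `k`), (2) z-scores the retained genes,
#' (3) trains the correlation weight matrix on all samples pooled,
#' (4) relaxes every sample's continuous z-scored profile to a bipolar
#' fixed point under synchronous sign-update recall, and (5) groups the
#' terminal patterns into attractors with width and depth estimates.
#' Stage labels never enter steps 3-4; they only name attractors and
#' structure the reporting.
#'
#' @param x an [expression_set()], or a raw genes-by-samples matrix (then
#'   `stages` is required).
#' @param stages stage factor/labels when `x` is a plain matrix.
#' @param stage_order ordered stage names when `x` is a plain matrix.
#' @param features `"elbow"` (default) selects at the variance elbow;
#'   `"all"` keeps every gene; `"fixed"` keeps the top `k`.
#' @param k number of genes for `features = "fixed"` (also accepted with
#'   `features = "elbow"` as an explicit override).
#' @param max_iter recall iteration cap per sample (default 100).
#' @return An object of class `"hopfield_fit"` with components `X` (the
#'   z-scored selected matrix the dynamics ran on), `stages`, `selection`
#'   (the `"feature_rank"`), `W`, `trajectories`, `attractors` (an
#'   `"attractor_set"`), `metrics` ([attractor_metrics()] table),
#'   `stage_table` ([stage_energy_table()]), `center`/`scale` (the
#'   training z-score transform, used by [predict.hopfield_fit()]) and
#'   `call`.
#' @seealso [robustness_analysis()], [stage_network()], [plot.hopfield_fit()]
#' @examples
#' sim <- simulate_progression(n_genes = 40, samples_per_stage = 5, seed = 1)
#' fit <- hopfield_fit(sim$data, features = "all")
#' fit
#' summary(fit)
#' @export
hopfield_fit <- function(x, stages = NULL, stage_order = NULL,
                         features = c("elbow", "all", "fixed"), k = NULL,
                         max_iter = 100) {
  features <- match.arg(features)
  if (!inherits(x, "expr_set"))
    x <- expression_set(x, stages, stage_order)
  raw <- x$values
  stages <- x$stages

  # constant rows can neither be z-scored nor correlated; drop them first
  s <- row_sds(raw)
  if (any(zero <- s < .Machine$double.eps^0.5)) {
    warning("dropping ", sum(zero), " zero-variance gene row(s)")
    raw <- raw[!zero, , drop = FALSE]
  }
  fs <- rank_by_variance(raw)
  fs <- switch(features,
               elbow = select_elbow(fs, k = k),
               all = select_elbow(fs, k = length(fs$gene)),
               fixed = {
                 if (is.null(k)) stop("features = 'fixed' needs k")
                 select_elbow(fs, k = k)
               })
  genes <- selected_genes(fs)
  sub <- raw[genes, , drop = FALSE]
  center <- rowMeans(sub)
  scale <- row_sds(sub)
  X <- (sub - center) / scale

  W <- train_weights(X)
  traj <- recall_samples(X, W, max_iter)
  aset <- collect_attractors(traj, W, stages)
  structure(list(call = match.call(), X = X, stages = stages,
                 selection = fs, W = W, trajectories = traj,
                 attractors = aset,
                 metrics = attractor_metrics(aset, X, traj),
                 stage_table = stage_energy_table(aset, traj, stages),
                 center = center, scale = scale, max_iter = max_iter),
            class = "hopfield_fit")
}

#' @export
print.hopfield_fit <- function(x, ...) {
  cat("Hopfield attractor-landscape fit\n")
  cat(sprintf("  %d genes kept (%s) of %d; %d samples in %d stage(s)\n",
              x$selection$k, x$selection$method, length(x$selection$gene),
              ncol(x$X), nlevels(x$stages)))
  print(x$attractors)
  invisible(x)
}

#' Summarise a Hopfield landscape fit
#'
#' Prints the stage-by-attractor energy table (mean original-state energy
#' and energy distance to the attractor per stage group) and the
#' per-attractor metrics (members, energy, width, depth).
#'
#' @param object a `"hopfield_fit"`.
#' @param ... unused.
#' @return An object of class `"summary.hopfield_fit"` (list with the two
#'   tables), printed with rounded display.
#' @export
summary.hopfield_fit <- function(object, ...) {
  structure(list(stage_table = object$stage_table,
                 metrics = object$metrics,
                 unconverged = object$attractors$unconverged),
            class = "summary.hopfield_fit")
}

#' @export
print.summary.hopfield_fit <- function(x, ...) {
  cat("Stage energies (original state vs attractor):\n")
  st <- x$stage_table
  st$mean_energy <- signif(st$mean_energy, 5)
  st$attractor_energy <- signif(st$attractor_energy, 5)
  st$delta_e <- signif(st$delta_e, 5)
  print(st, row.names = FALSE)
  cat("\nAttractors:\n")
  m <- x$metrics
  m$energy <- signif(m$energy, 5)
  m$width <- round(m$width, 3)
  m$depth <- signif(m$depth, 5)
  print(m, row.names = FALSE)
  if (length(x$unconverged))
    cat("\nUnconverged samples:", paste(x$unconverged, collapse = ", "),
        "\n")
  invisible(x)
}

#' @describeIn hopfield_fit the trained weight matrix.
#' @param object,... method arguments.
#' @export
coef.hopfield_fit <- function(object, ...) object$W

#' Assign samples to attractors
#'
#' With `newdata = NULL`, returns the training samples' attractor
#' assignments. New samples are transformed with the training per-gene
#' z-score (center/scale learned at fit time), relaxed on the fitted
#' weight matrix, and matched against the fitted attractors; a terminal
#' pattern equal to no fitted attractor is labelled `NA`.
#'
#' @param object a `"hopfield_fit"`.
#' @param newdata optional genes-by-samples matrix of raw values covering
#'   the fit's selected genes.
#' @param ... unused.
#' @return data.frame: `sample`, `attractor` (id or `NA`), `label`,
#'   `status`, `n_iterations`, `energy0`.
#' @export
predict.hopfield_fit <- function(object, newdata = NULL, ...) {
  aset <- object$attractors
  keys <- vapply(aset$attractors, function(a) pattern_key(a$pattern), "")
  ids <- vapply(aset$attractors, `[[`, "", "id")
  labels <- vapply(aset$attractors, `[[`, "", "label")
  if (is.null(newdata)) {
    traj <- object$trajectories
  } else {
    newdata <- as.matrix(newdata)
    genes <- rownames(object$X)
    missing <- setdiff(genes, rownames(newdata))
    if (length(missing))
      stop("newdata lacks fitted gene(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    Xn <- (newdata[genes, , drop = FALSE] - object$center) / object$scale
    traj <- recall_samples(Xn, object$W, object$max_iter)
  }
  hit <- vapply(traj, function(t) {
    i <- match(pattern_key(t$terminal), keys)
    if (t$status == "max_iter") NA_integer_ else i
  }, integer(1))
  data.frame(sample = names(traj),
             attractor = ids[hit],
             label = labels[hit],
             status = vapply(traj, `[[`, "", "status"),
             n_iterations = vapply(traj, `[[`, 0L, "n_iterations"),
             energy0 = vapply(traj, function(t) t$energies[1], 0),
             row.names = NULL)
}

#' Build the energy landscape of a fit
#'
#' Projects the samples onto PC1/PC2, optionally adds the intermediate
#' bipolar trajectory states and the attractor patterns as interpolation
#' anchors (their much lower energies carve the basins), and interpolates
#' the energy surface over a regular grid with [build_surface()].
#'
#' @param fit a `"hopfield_fit"`.
#' @param grid_resolution lattice points per axis (default 100).
#' @param include_trajectories include intermediate recall states as
#'   anchors (default `TRUE`).
#' @param margin bounding-box padding passed to [build_surface()].
#' @return List of class `"hopfield_landscape"`: `surface`
#'   (`"hn_surface"`), `projection`, `sample_coords`,
#'   `attractor_coords`, `trajectories` (polylines in PC space) and
#'   `stages`.
#' @export
fit_landscape <- function(fit, grid_resolution = 100,
                          include_trajectories = TRUE, margin = 0.05) {
  proj <- project_pca(fit$X)
  sample_coords <- proj$scores
  e0 <- vapply(fit$trajectories, function(t) t$energies[1], 0)
  coords <- sample_coords
  energies <- e0
  polylines <- list()
  for (s in names(fit$trajectories)) {
    tr <- fit$trajectories[[s]]
    pts <- project_points(proj, do.call(cbind, tr$states))
    polylines[[s]] <- pts
    if (include_trajectories && length(tr$states) > 1) {
      coords <- rbind(coords, pts[-1, , drop = FALSE])
      energies <- c(energies, tr$energies[-1])
    }
  }
  apat <- do.call(cbind, lapply(fit$attractors$attractors, `[[`, "pattern"))
  acoords <- NULL
  if (!is.null(apat)) {
    acoords <- project_points(proj, apat)
    rownames(acoords) <- vapply(fit$attractors$attractors, `[[`, "", "id")
    coords <- rbind(coords, acoords)
    energies <- c(energies,
                  vapply(fit$attractors$attractors, `[[`, 0, "energy"))
  }
  surface <- build_surface(coords, energies,
                           grid_resolution = grid_resolution,
                           margin = margin)
  structure(list(surface = surface, projection = proj,
                 sample_coords = sample_coords,
                 attractor_coords = acoords,
                 trajectories = polylines, stages = fit$stages),
            class = "hopfield_landscape")
}

#' @export
plot.hopfield_landscape <- function(x, type = c("contour", "persp"),
                                    trajectories = TRUE, ...) {
  type <- match.arg(type)
  cols <- grDevices::palette.colors(nlevels(x$stages), "Okabe-Ito")
  plot(x$surface, type = type,
       points = if (type == "contour") x$sample_coords,
       point_col = cols[as.integer(x$stages)],
       trajectories = if (trajectories && type == "contour") x$trajectories,
       attractor_coords = if (type == "contour") x$attractor_coords, ...)
  if (type == "contour")
    graphics::legend("topright", legend = levels(x$stages), col = cols,
                     pch = 19, bty = "n", cex = 0.8)
  invisible(x)
}

#' Plot a Hopfield landscape fit
#'
#' Convenience wrapper: builds the landscape ([fit_landscape()]) and plots
#' it, contour view by default with samples coloured by stage, attractors
#' in green and convergence trajectories as lines.
#'
#' @param x a `"hopfield_fit"`.
#' @param type `"contour"` or `"persp"`.
#' @param grid_resolution lattice points per axis (default 60 for quick
#'   interactive use).
#' @param ... passed on to the surface plot.
#' @return Invisibly, the `"hopfield_landscape"`.
#' @export
plot.hopfield_fit <- function(x, type = c("contour", "persp"),
                              grid_resolution = 60, ...) {
  ls <- fit_landscape(x, grid_resolution = grid_resolution)
  plot(ls, type = match.arg(type), ...)
  invisible(ls)
}
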