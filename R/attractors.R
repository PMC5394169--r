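#' Group relaxed samples into attractors
#'
#' Samples whose recall trajectories terminate in exactly the same bipolar
#' pattern share an attractor. Patterns differing in even one gene are
#' distinct attractors; stage labels play no role in the grouping and are
#' used only afterwards to name each attractor by its plurality stage
#' (ties broken by the configured stage order, earliest first). Samples
#' whose trajectories hit `max_iter` are listed as unconverged and excluded
#' from membership.
#'
#' @param trajectories named list of [run_recall()] results, one per sample,
#'   all produced against the same `W`.
#' @param W the weight matrix the trajectories were run against.
#' @param stages factor of stage labels named by (or aligned with) the
#'   trajectory names; its levels define the stage order.
#' @return An object of class `"attractor_set"`: list with `attractors`
#'   (each: `id`, `pattern`, `energy`, `members`, `stage_composition`,
#'   `label`), `unconverged` (sample IDs) and `stage_order`.
#' @export
collect_attractors <- function(trajectories, W, stages) {
  if (is.null(names(trajectories)))
    stop("trajectories must be named by sample ID")
  stages <- as.factor(stages)
  if (!is.null(names(stages))) {
    stages <- stages[names(trajectories)]
  } else if (length(stages) == length(trajectories)) {
    names(stages) <- names(trajectories)
  } else {
    stop("stages must match trajectories")
  }
  stage_order <- levels(stages)

  conv <- vapply(trajectories, function(t) t$status != "max_iter", logical(1))
  unconverged <- names(trajectories)[!conv]
  keys <- vapply(trajectories[conv], function(t) pattern_key(t$terminal), "")
  groups <- split(names(trajectories)[conv], keys)

  attractors <- lapply(groups, function(members) {
    pattern <- trajectories[[members[1]]]$terminal
    comp <- table(factor(as.character(stages[members]), levels = stage_order))
    top <- max(comp)
    label <- stage_order[which(comp == top)[1]]   # earliest stage on ties
    list(pattern = pattern,
         energy = hopfield_energy(pattern, W),
         members = members,
         stage_composition = comp,
         label = label)
  })
  # deterministic order: by stage-order position of the label, then energy
  ord <- order(match(vapply(attractors, `[[`, "", "label"), stage_order),
               vapply(attractors, `[[`, 0, "energy"))
  attractors <- attractors[ord]
  for (i in seq_along(attractors)) attractors[[i]]$id <- paste0("A", i)
  structure(list(attractors = attractors, unconverged = unconverged,
                 stage_order = stage_order),
            class = "attractor_set")
}

#' @export
print.attractor_set <- function(x, ...) {
  cat(length(x$attractors), "attractor(s);",
      length(x$unconverged), "unconverged sample(s)\n")
  for (a in x$attractors)
    cat(sprintf("  %s [%s] E = %.4g, %d member(s): %s\n", a$id, a$label,
                a$energy, length(a$members),
                paste(names(a$stage_composition), a$stage_composition,
                      sep = "=", collapse = " ")))
  invisible(x)
}

#' Attractor width
#'
#' The width of an attractor is the mean standardized pairwise Euclidean
#' distance among the *original* (continuous, z-scored) expression vectors
#' of its member samples: `mean ||x_i - x_j|| / sqrt(d)`. Division by
#' `sqrt(d)` makes widths comparable across dimensionalities (two
#' independent standard-normal vectors have expected width about
#' `sqrt(2)`). A wider attractor drains a more heterogeneous set of
#' samples. Singletons have width 0.
#'
#' @param attractor one element of `collect_attractors()$attractors`.
#' @param x the z-scored, feature-selected genes-by-samples matrix the
#'   recall was started from.
#' @return A non-negative number.
#' @export
attractor_width <- function(attractor, x) {
  members <- attractor$members
  missing <- setdiff(members, colnames(x))
  if (length(missing))
    stop("member sample(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  if (length(members) < 2) return(0)
  d <- stats::dist(t(x[, members, drop = FALSE]))
  mean(d) / sqrt(nrow(x))
}

#' Attractor depth
#'
#' Depth is the magnitude of the energy drop from samples' original states
#' to the attractor: `|mean(E0 of members) - E(attractor)|`, overall and per
#' stage group among the members. A deep attractor sits far below the
#' states it captures.
#'
#' @param attractor one element of `collect_attractors()$attractors`.
#' @param trajectories the same named trajectory list the attractor set was
#'   built from (iteration-0 energies are read from it).
#' @param stages factor of stage labels named by sample (optional; needed
#'   for the per-group map).
#' @return List with `overall` (number) and `by_group` (named numeric,
#'   empty groups omitted).
#' @export
attractor_depth <- function(attractor, trajectories, stages = NULL) {
  members <- attractor$members
  e0 <- vapply(trajectories[members], function(t) t$energies[1], 0)
  out <- list(overall = abs(mean(e0) - attractor$energy))
  if (!is.null(stages)) {
    stages <- as.factor(stages)
    if (!is.null(names(stages))) stages <- stages[members] else
      stop("stages must be named by sample for depth by group")
    grp <- split(e0, droplevels(stages))
    out$by_group <- vapply(grp, function(e) abs(mean(e) - attractor$energy), 0)
  }
  out
}

#' Per-attractor summary metrics
#'
#' Convenience table combining membership, energy, [attractor_width()] and
#' [attractor_depth()] for every attractor in a set.
#'
#' @param aset an `"attractor_set"`.
#' @param x z-scored feature-selected expression matrix.
#' @param trajectories the trajectory list the set was built from.
#' @return data.frame with one row per attractor: `id`, `label`,
#'   `n_members`, `energy`, `width`, `depth`.
#' @export
attractor_metrics <- function(aset, x, trajectories) {
  do.call(rbind, lapply(aset$attractors, function(a) {
    data.frame(id = a$id, label = a$label, n_members = length(a$members),
               energy = a$energy,
               width = attractor_width(a, x),
               depth = attractor_depth(a, trajectories)$overall,
               row.names = NULL)
  }))
}

#' Stage-by-attractor energy table
#'
#' For every (stage, attractor) pair with converging members: the number of
#' samples, their mean original-state energy, the attractor energy, and the
#' energy distance `delta_e = |mean E0 - E(attractor)|`. When a stage splits
#' across attractors each destination gets its own row, so the table stays
#' faithful to heterogeneous mid-stages.
#'
#' @param aset an `"attractor_set"`.
#' @param trajectories named trajectory list.
#' @param stages factor of stage labels named by sample.
#' @return data.frame: `stage`, `attractor`, `attractor_label`, `n`,
#'   `mean_energy`, `attractor_energy`, `delta_e`.
#' @export
stage_energy_table <- function(aset, trajectories, stages) {
  stages <- as.factor(stages)
  rows <- list()
  for (a in aset$attractors) {
    st <- droplevels(factor(as.character(stages[a$members]),
                            levels = levels(stages)))
    e0 <- vapply(trajectories[a$members], function(t) t$energies[1], 0)
    for (g in levels(st)) {
      sel <- st == g
      rows[[length(rows) + 1]] <- data.frame(
        stage = g, attractor = a$id, attractor_label = a$label,
        n = sum(sel), mean_energy = mean(e0[sel]),
        attractor_energy = a$energy,
        delta_e = abs(mean(e0[sel]) - a$energy), row.names = NULL)
    }
  }
  if (!length(rows)) stop("no converged members to tabulate")
  out <- do.call(rbind, rows)
  out <- out[order(match(out$stage, levels(stages)), out$attractor), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
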