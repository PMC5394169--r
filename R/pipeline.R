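#' Run the full attractor-landscape pipeline
#'
#' End-to-end orchestration: load (or accept) a staged expression set, fit
#' the Hopfield landscape model ([hopfield_fit()]), run the edge
#' perturbation robustness analysis, build per-stage significance-filtered
#' correlation networks with their common/unique decomposition, assemble
#' the energy surface, and write a result bundle to `outdir`:
#'
#' * `summary.json` — versioned machine-readable summary (settings incl.
#'   seed, stage energy table, attractors with width/depth, robustness,
#'   network counts);
#' * `stage_energy.tsv`, `network_summary.tsv` — the two report tables;
#' * `networks/<stage>.sif|.graphml` and `networks/unique_<stage>.*`;
#' * `surface.tsv`, `hd_traces.tsv`; and
#' * `landscape.png` (contour + trajectories) unless `figures = FALSE`.
#'
#' Reruns with the same inputs and seed produce byte-identical summaries.
#'
#' @param data an [expression_set()]; alternatively give `expr_file` +
#'   `stage_file`.
#' @param expr_file,stage_file,stage_order passed to [read_expression()].
#' @param outdir output directory (created).
#' @param features,k feature selection mode, as in [hopfield_fit()].
#' @param n_network_genes gene-universe size for the stage networks
#'   (default 100, capped at the number of selected genes).
#' @param alpha raw p-value threshold for network edges (default 1e-4).
#' @param perturb_fraction fraction of edges perturbed (default 0.5).
#' @param n_replicates perturbation replicates (default 100).
#' @param seed base seed for all randomness in the run (default 0).
#' @param grid_resolution landscape lattice points per axis (default 100).
#' @param max_iter recall iteration cap.
#' @param figures write the PNG figure (default `TRUE`).
#' @return Invisibly, a list with `fit`, `robustness`, `networks`,
#'   `common_unique`, `network_table`, `landscape` and `paths`.
#' @export
run_pipeline <- function(data = NULL, expr_file = NULL, stage_file = NULL,
                         stage_order = NULL, outdir,
                         features = c("elbow", "all", "fixed"), k = NULL,
                         n_network_genes = 100, alpha = 1e-4,
                         perturb_fraction = 0.5, n_replicates = 100,
                         seed = 0, grid_resolution = 100, max_iter = 100,
                         figures = TRUE) {
  features <- match.arg(features)
  if (is.null(data)) {
    if (is.null(expr_file) || is.null(stage_file))
      stop("provide either `data` or both `expr_file` and `stage_file`")
    data <- read_expression(expr_file, stage_file, stage_order)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  netdir <- file.path(outdir, "networks")
  dir.create(netdir, showWarnings = FALSE)

  fit <- hopfield_fit(data, features = features, k = k, max_iter = max_iter)
  rob <- robustness_analysis(fit$X, fit$W, fit$attractors,
                             fraction = perturb_fraction,
                             n_replicates = n_replicates, seed = seed,
                             max_iter = max_iter)

  universe <- utils::head(selected_genes(fit$selection), n_network_genes)
  networks <- lapply(levels(fit$stages), function(st)
    stage_network(fit$X, stage = st, genes = universe, alpha = alpha,
                  stages = fit$stages))
  names(networks) <- levels(fit$stages)
  cu <- common_and_unique(networks)
  net_table <- network_summary(networks, cu)

  ls <- fit_landscape(fit, grid_resolution = grid_resolution)

  paths <- list(summary = file.path(outdir, "summary.json"),
                stage_energy = file.path(outdir, "stage_energy.tsv"),
                network_summary = file.path(outdir, "network_summary.tsv"),
                surface = file.path(outdir, "surface.tsv"),
                hd_traces = file.path(outdir, "hd_traces.tsv"))
  utils::write.table(fit$stage_table, paths$stage_energy, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(net_table, paths$network_summary, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(rob$hd_traces, paths$hd_traces, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_surface(ls$surface, paths$surface)
  for (st in names(networks)) {
    write_sif(networks[[st]], file.path(netdir, paste0(st, ".sif")))
    write_graphml(networks[[st]], file.path(netdir, paste0(st, ".graphml")))
    write_sif(cu$unique[[st]], file.path(netdir,
                                         paste0("unique_", st, ".sif")))
    write_graphml(cu$unique[[st]],
                  file.path(netdir, paste0("unique_", st, ".graphml")))
  }
  if (figures) {
    fig <- file.path(outdir, "landscape.png")
    grDevices::png(fig, width = 900, height = 800, res = 120)
    plot(ls)
    grDevices::dev.off()
    paths$figure <- fig
  }

  aset <- fit$attractors
  summary <- list(
    schema_version = "1.0",
    package = as.character(utils::packageVersion("hopscape")),
    settings = list(features = features,
                    k = fit$selection$k,
                    selection_method = fit$selection$method,
                    n_network_genes = length(universe),
                    alpha = alpha,
                    perturb_fraction = perturb_fraction,
                    n_replicates = n_replicates,
                    seed = seed,
                    grid_resolution = grid_resolution,
                    max_iter = max_iter,
                    stage_order = levels(fit$stages)),
    stage_table = fit$stage_table,
    attractors = lapply(aset$attractors, function(a) {
      list(id = a$id, label = a$label,
           pattern = pattern_key(a$pattern),
           energy = a$energy,
           members = a$members,
           stage_composition = as.list(a$stage_composition),
           width = attractor_width(a, fit$X),
           depth = attractor_depth(a, fit$trajectories,
                                   fit$stages)[c("overall", "by_group")])
    }),
    unconverged = aset$unconverged,
    robustness = list(fraction = rob$fraction,
                      fail_fraction = as.list(rob$fail_fraction),
                      fail_sd = as.list(rob$fail_sd),
                      nonconvergence_fraction = rob$nonconvergence_fraction,
                      energy_shift = as.list(rob$energy_shift)),
    networks = net_table)
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  message("pipeline complete; summary at ", paths$summary)
  invisible(list(fit = fit, robustness = rob, networks = networks,
                 common_unique = cu, network_table = net_table,
                 landscape = ls, paths = paths))
}
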