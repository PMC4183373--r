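# End-to-end orchestration: sequence -> Langevin ensemble -> PCA ->
# Conformational Markov Network -> basins -> free energy landscape ->
# promoter report.

#' Full promoter analysis
#'
#' Runs the complete pipeline on one promoter sequence: encode with clamps,
#' simulate the Langevin ensemble of chain + sliding particle, reduce the
#' opening trajectories with PCA, discretize into microstates, build the
#' Conformational Markov Network, split it into basins of attraction, pool
#' nonspecific basins, build the disconnectivity dendrogram, cluster
#' macrostates, and report each detected site's occupancy, free energy
#' relative to the nonspecific background and entropy.
#'
#' Deterministic given `config$seed`: rerunning with the same inputs yields
#' an identical report.
#'
#' @param seq A [promoter_sequence()].
#' @param params A [model_params()] object (`A_p` must be > 0 so the
#'   particle is coupled).
#' @param config A [sim_config()] object.
#' @param clamp_len G-C clamp pairs per end (default 10).
#' @param n_pc Principal components kept (default 5).
#' @param n_bins Bins per principal component (default 10).
#' @param barrier_cut Macrostate clustering barrier in kB*T (default 1).
#' @param ns_threshold Nonspecific basin occupancy threshold (default 0.005).
#' @param known_tss Optional TSS positions (label coordinates) to annotate.
#' @param verbose Print one progress line per stage.
#' @return An object of class `breath_analysis`: list with `report`,
#'   `profile`, `pca`, `network`, `basins`, `specific`, `P_NS`,
#'   `dendrogram`, `macrostates`, `chain`, `config`, `params`,
#'   `bin_ranges`.
#' @export
analyze_promoter <- function(seq, params = model_params(),
                             config = sim_config(), clamp_len = 10L,
                             n_pc = 5L, n_bins = 10L, barrier_cut = 1,
                             ns_threshold = 0.005, known_tss = NULL,
                             verbose = FALSE) {
  stopifnot(inherits(seq, "promoter_sequence"))
  if (params$A_p <= 0)
    stop("analyze_promoter requires a coupled particle (A_p > 0); ",
         "use analyze_gene_chain_only for chain-only runs")
  say <- function(...) if (verbose) message(sprintf(...))
  chain <- encode_chain(seq, clamp_len)
  say("simulate: %d sites, %d realizations x %d steps", chain$N,
      config$n_realizations, config$n_steps)
  ens <- run_ensemble(chain, params, config)
  say("pca: pooling %d frames",
      sum(vapply(ens$trajectories, function(t) nrow(t$Y), 0L)))
  pca <- fit_pca(ens$trajectories, chain = chain)
  projs <- lapply(ens$trajectories, project_trajectory, pca = pca,
                  n_pc = n_pc)
  ranges <- pooled_bin_ranges(projs, n_bins)
  keys <- lapply(projs, discretize_projection, N = chain$N,
                 ranges = ranges, n_bins = n_bins)
  net <- build_network(keys)
  say("cmn: %d microstates, %d edges", nrow(net$nodes), nrow(net$edges))
  basins <- find_basins(net)
  sp <- split_nonspecific(basins, ns_threshold)
  say("fel: %d basins (%d nonspecific, P_NS = %.3f)", nrow(basins$basins),
      sp$n_nonspecific, sp$P_NS)
  links <- basin_network_links(net, sp$specific)
  dend <- build_dendrogram(sp$specific, links)
  macro <- cluster_macrostates(dend, sp$specific, barrier_cut)
  report <- promoter_report(macro, sp$specific, sp$P_NS, chain, known_tss)
  say("report: %d macrostates, heaviest at site %s", nrow(report),
      if (nrow(report)) report$seq_position[1] else NA)
  structure(list(report = report, profile = ens$profile, pca = pca,
                 network = net, basins = basins, specific = sp$specific,
                 P_NS = sp$P_NS, dendrogram = dend, macrostates = macro,
                 chain = chain, config = config, params = params,
                 bin_ranges = ranges),
            class = "breath_analysis")
}

#' @export
print.breath_analysis <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Chain-only PCA localization analysis of a whole gene
#'
#' Simulates the bare breathing dynamics (the particle coupling is forced
#' off regardless of `params$A_p`) and reports where the leading PCA
#' eigenvectors localize over user-labeled regions (e.g. promoter vs coding
#' body). This is the whole-gene workflow that justifies restricting the
#' full particle analysis to promoter regions: breathing fluctuations
#' concentrate in the soft promoter while the body stays closed.
#'
#' @param seq A [promoter_sequence()].
#' @param regions Named list of sequence-coordinate ranges, each
#'   `c(start, end)` (1-based, inclusive), jointly covering the sequence
#'   without overlap.
#' @param params,config,clamp_len As in [analyze_promoter()].
#' @param n_components Leading components to report (default 4).
#' @return A list with `localization` (an [eigenvector_localization()]
#'   table), `pca`, `profile`, `chain`.
#' @export
analyze_gene_chain_only <- function(seq, regions, params = model_params(),
                                    config = sim_config(), clamp_len = 10L,
                                    n_components = 4L) {
  stopifnot(inherits(seq, "promoter_sequence"))
  if (is.null(regions) || length(regions) == 0L || is.null(names(regions)))
    stop("named region labels are required (e.g. promoter / body)")
  params_chain <- params
  params_chain$A_p <- 0  # chain-only by contract
  chain <- encode_chain(seq, clamp_len)
  ens <- run_ensemble(chain, params_chain, config)
  pca <- fit_pca(ens$trajectories, chain = chain)
  # convert sequence-coordinate ranges to masked-site indices
  reg_idx <- lapply(regions, function(r) {
    stopifnot(length(r) == 2L)
    which(chain$seq_position[chain$mask] >= r[1] &
            chain$seq_position[chain$mask] <= r[2])
  })
  loc <- eigenvector_localization(pca, reg_idx, n_components)
  list(localization = loc, pca = pca, profile = ens$profile, chain = chain)
}
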