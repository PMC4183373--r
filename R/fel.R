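# Free energy landscape analysis of the Conformational Markov Network:
# steepest-descent basins of attraction, per-basin free energies, the
# disconnectivity dendrogram, macrostate clustering and thermo-statistical
# characterization (occupancy, free energy vs nonspecific states, entropy).

#' Split a Conformational Markov Network into basins of attraction
#'
#' Every microstate is assigned to an attractor by iteratively hopping to
#' the linked neighbor with the largest occupancy among neighbors heavier
#' than the current node (steepest ascent on the stationary weight; links
#' are taken as undirected, self-loops ignored). Nodes with no heavier
#' linked neighbor are attractors. Because each hop strictly increases the
#' occupancy, the walk terminates and the basins partition all nodes.
#'
#' The default assignment is deterministic (ties broken toward the
#' lexicographically lowest key). `method = "stochastic"` instead hops to a
#' heavier neighbor with probability proportional to the observed transition
#' flux on the connecting link, which is the randomized variant of the
#' steepest-descent construction; it requires a `seed`.
#'
#' @param net A [build_network()] result.
#' @param method "deterministic" (default) or "stochastic".
#' @param seed Seed for the stochastic variant.
#' @return An object of class `breath_basins`: `basins` (data.frame
#'   `basin_id`, `attractor`, `P_b`, `n_members`, ordered by decreasing
#'   `P_b`) and `membership` (data.frame `key`, `P`, `basin_id`).
#' @export
find_basins <- function(net, method = c("deterministic", "stochastic"),
                        seed = NULL) {
  stopifnot(inherits(net, "breath_cmn"))
  method <- match.arg(method)
  keys <- net$nodes$key
  P <- net$nodes$P
  n <- length(keys)
  idx <- seq_len(n)
  names(idx) <- keys
  e <- net$edges[net$edges$from != net$edges$to, , drop = FALSE]
  nb <- vector("list", n)
  wt <- vector("list", n)
  if (nrow(e) > 0L) {
    fi <- idx[e$from]; ti <- idx[e$to]
    # undirected neighbor sets with summed link flux
    pair_lo <- pmin(fi, ti); pair_hi <- pmax(fi, ti)
    agg <- tapply(e$count, paste0(pair_lo, "_", pair_hi), sum)
    sp <- strsplit(names(agg), "_", fixed = TRUE)
    lo <- as.integer(vapply(sp, `[`, "", 1))
    hi <- as.integer(vapply(sp, `[`, "", 2))
    cnt <- as.numeric(agg)
    for (k in seq_along(lo)) {
      nb[[lo[k]]] <- c(nb[[lo[k]]], hi[k]); wt[[lo[k]]] <- c(wt[[lo[k]]], cnt[k])
      nb[[hi[k]]] <- c(nb[[hi[k]]], lo[k]); wt[[hi[k]]] <- c(wt[[hi[k]]], cnt[k])
    }
  }
  step_to <- integer(n)
  pick <- function(i) {
    js <- nb[[i]]
    if (is.null(js)) return(0L)
    heavier <- js[P[js] > P[i]]
    if (length(heavier) == 0L) return(0L)
    if (method == "deterministic") {
      best <- heavier[P[heavier] == max(P[heavier])]
      if (length(best) > 1L) best <- best[order(keys[best])][1]
      best
    } else {
      w <- wt[[i]][match(heavier, js)]
      heavier[sample.int(length(heavier), 1L, prob = w)]
    }
  }
  assign_steps <- function() {
    for (i in seq_len(n)) step_to[i] <<- pick(i)
  }
  if (method == "stochastic") {
    if (is.null(seed)) stop("the stochastic variant requires a seed")
    withr::with_seed(as.integer(seed), assign_steps())
  } else assign_steps()
  # path-compress to attractors (each hop strictly increases P: terminates)
  attractor_of <- integer(n)
  for (i in seq_len(n)) {
    j <- i
    while (step_to[j] != 0L) j <- step_to[j]
    attractor_of[i] <- j
  }
  atts <- sort(unique(attractor_of))
  P_b <- vapply(atts, function(a) sum(P[attractor_of == a]), 0)
  o <- order(-P_b, keys[atts])
  atts <- atts[o]; P_b <- P_b[o]
  basin_id <- match(attractor_of, atts)
  basins <- data.frame(basin_id = seq_along(atts), attractor = keys[atts],
                       P_b = P_b,
                       n_members = as.integer(table(factor(basin_id,
                         levels = seq_along(atts)))))
  membership <- data.frame(key = keys, P = P, basin_id = basin_id,
                           stringsAsFactors = FALSE)
  structure(list(basins = basins, membership = membership),
            class = "breath_basins")
}

#' @export
print.breath_basins <- function(x, ...) {
  cat(sprintf("breath_basins: %d basins over %d microstates (heaviest P = %.3f)\n",
              nrow(x$basins), nrow(x$membership), max(x$basins$P_b)))
  invisible(x)
}

#' Free energy of basins from their statistical weights
#'
#' `F_b = -kBT * ln(P_b / P_max)` where `P_max` is the weight of the
#' heaviest basin, which therefore sits at `F = 0`.
#'
#' @param P_b Vector of basin weights (> 0).
#' @param kT Thermal energy unit (default 1, i.e. F in kB*T units).
#' @return Free energies, same length as `P_b`.
#' @export
basin_free_energy <- function(P_b, kT = 1) {
  if (any(P_b <= 0)) stop("basin weights must be > 0")
  -kT * log(P_b / max(P_b))
}

#' Pool low-occupancy basins into the nonspecific background
#'
#' Basins lighter than `ns_threshold` are interpreted as short-lived
#' transitional states in which the particle diffuses between targets; their
#' pooled weight `P_NS` is the reference for specific-state free energy
#' differences and they are excluded from macrostate clustering.
#'
#' @param basins A `breath_basins` object.
#' @param ns_threshold Occupancy threshold in `[0, 1)`.
#' @return List with `specific` (a filtered `breath_basins`), `P_NS`, and
#'   `n_nonspecific`.
#' @export
split_nonspecific <- function(basins, ns_threshold = 0.005) {
  stopifnot(inherits(basins, "breath_basins"))
  if (ns_threshold < 0 || ns_threshold >= 1)
    stop("ns_threshold must be in [0, 1)")
  ns <- basins$basins$P_b < ns_threshold
  if (all(ns))
    stop("all basins fall below the nonspecific threshold: landscape unresolved")
  keep_ids <- basins$basins$basin_id[!ns]
  b <- basins$basins[!ns, , drop = FALSE]
  m <- basins$membership[basins$membership$basin_id %in% keep_ids, ,
                         drop = FALSE]
  # renumber kept basins 1..k preserving order
  remap <- stats::setNames(seq_along(keep_ids), keep_ids)
  b$basin_id <- as.integer(remap[as.character(b$basin_id)])
  m$basin_id <- as.integer(remap[as.character(m$basin_id)])
  rownames(b) <- rownames(m) <- NULL
  list(specific = structure(list(basins = b, membership = m),
                            class = "breath_basins"),
       P_NS = sum(basins$basins$P_b[ns]),
       n_nonspecific = sum(ns))
}

#' Free energy difference between a specific state and the nonspecific
#' background
#'
#' `dF = ln(P_state / P_NS)` in kB*T units: the reversible work gained by
#' the particle binding at the specific site rather than diffusing among
#' nonspecific states.
#'
#' @param P_state Occupancy of the specific macrostate, in (0, 1].
#' @param P_NS Pooled occupancy of the nonspecific states, in (0, 1].
#' @return Free energy difference in kB*T (vectorized).
#' @examples
#' free_energy_difference(0.220, 0.027)  # ~2.10 kB T
#' @export
free_energy_difference <- function(P_state, P_NS) {
  if (any(P_state <= 0) || any(P_NS <= 0))
    stop("occupancies must be > 0")
  if (any(P_state > 1) || any(P_NS > 1))
    stop("occupancies must be <= 1")
  log(P_state / P_NS)
}

#' Entropy of a macrostate over its member basins
#'
#' Shannon multiplicity `S = -sum_b q_b ln q_b` with `q_b = P_b / P_alpha`:
#' zero when the macrostate is a single basin (a localized, narrow bubble),
#' `ln m` when it is spread evenly over `m` basins.
#'
#' @param weights Member basin weights (> 0, need not be normalized).
#' @return Entropy in nats.
#' @export
macrostate_entropy <- function(weights) {
  if (length(weights) == 0L) stop("empty member set")
  if (any(weights <= 0)) stop("weights must be > 0")
  q <- weights / sum(weights)
  -sum(q * log(q))
}

# undirected basin-level links inherited from microstate transitions
basin_links <- function(net, basins) {
  e <- net$edges[net$edges$from != net$edges$to, , drop = FALSE]
  if (nrow(e) == 0L)
    return(data.frame(b1 = integer(0), b2 = integer(0), count = numeric(0)))
  bid <- stats::setNames(basins$membership$basin_id, basins$membership$key)
  bf <- bid[e$from]; bt <- bid[e$to]
  keep <- !is.na(bf) & !is.na(bt) & bf != bt
  if (!any(keep))
    return(data.frame(b1 = integer(0), b2 = integer(0), count = numeric(0)))
  lo <- pmin(bf[keep], bt[keep]); hi <- pmax(bf[keep], bt[keep])
  agg <- tapply(e$count[keep], paste0(lo, "_", hi), sum)
  sp <- strsplit(names(agg), "_", fixed = TRUE)
  data.frame(b1 = as.integer(vapply(sp, `[`, "", 1)),
             b2 = as.integer(vapply(sp, `[`, "", 2)),
             count = as.numeric(agg))
}

#' Disconnectivity dendrogram of the basin network
#'
#' Sweeps a free energy threshold upward through the sorted basin free
#' energies, activating basins (and the inherited links between active
#' basins) as the threshold passes their `F_b`. Whenever two previously
#' disconnected active groups become linked, a merge event is recorded at a
#' barrier equal to the current threshold. Merge barriers are therefore
#' non-decreasing toward the root; if the basin network is disconnected the
#' result is a forest.
#'
#' @param basins A `breath_basins` (typically the specific basins after
#'   [split_nonspecific()]).
#' @param links Basin-level links, either from [basin_network_links()] or a
#'   data.frame with integer columns `b1`, `b2`.
#' @param kT Thermal energy unit for the free energies (default 1: kB*T).
#' @return An object of class `breath_dendrogram`: `leaves` (data.frame
#'   `basin_id`, `P_b`, `F`) and `merges` (list of merge events, each with
#'   `left`, `right` (member basin_id vectors) and `barrier`), in sweep
#'   order.
#' @export
build_dendrogram <- function(basins, links, kT = 1) {
  stopifnot(inherits(basins, "breath_basins"))
  b <- basins$basins
  Fb <- basin_free_energy(b$P_b, kT)
  leaves <- data.frame(basin_id = b$basin_id, P_b = b$P_b, F = Fb)
  ord <- order(Fb, b$basin_id)
  parent <- stats::setNames(b$basin_id, b$basin_id)  # union-find
  find_root <- function(i) {
    r <- as.character(i)
    while (parent[[r]] != as.numeric(r)) r <- as.character(parent[[r]])
    as.integer(r)
  }
  active <- logical(max(b$basin_id))
  merges <- list()
  for (i in b$basin_id[ord]) {
    active[i] <- TRUE
    thr <- Fb[match(i, b$basin_id)]
    nbrs <- unique(c(links$b2[links$b1 == i], links$b1[links$b2 == i]))
    nbrs <- nbrs[nbrs <= length(active) & active[nbrs]]
    for (j in nbrs) {
      ri <- find_root(i); rj <- find_root(j)
      if (ri != rj) {
        grp_i <- b$basin_id[vapply(b$basin_id, find_root, 0L) == ri &
                              active[b$basin_id]]
        grp_j <- b$basin_id[vapply(b$basin_id, find_root, 0L) == rj &
                              active[b$basin_id]]
        merges[[length(merges) + 1L]] <-
          list(left = sort(grp_i), right = sort(grp_j), barrier = thr)
        parent[[as.character(rj)]] <- ri
      }
    }
  }
  structure(list(leaves = leaves, merges = merges, kT = kT),
            class = "breath_dendrogram")
}

#' @rdname build_dendrogram
#' @param net The microstate network the basins came from.
#' @export
basin_network_links <- function(net, basins) basin_links(net, basins)

#' @export
print.breath_dendrogram <- function(x, ...) {
  cat(sprintf("breath_dendrogram: %d basins, %d merges (max barrier %.3g kT)\n",
              nrow(x$leaves), length(x$merges),
              if (length(x$merges)) max(vapply(x$merges, `[[`, 0, "barrier"))
              else NA_real_))
  invisible(x)
}

#' Cluster basins into macrostates below a barrier cut
#'
#' Basins separated by free energy barriers lower than `barrier_cut` are
#' clustered into a single macrostate: the system transits among them within
#' short waiting times, so they act as one thermodynamic state. For each
#' dendrogram merge the effective barrier is measured relative to the
#' shallower merging group's minimum free energy (the standard
#' disconnectivity convention); if it is below the cut, the deep clusters of
#' the two groups are united.
#'
#' @param dend A [build_dendrogram()] result.
#' @param basins The matching `breath_basins`.
#' @param barrier_cut Barrier threshold in kB*T (default 1).
#' @return A list of macrostates, each a list with `member_ids`, `P_alpha`,
#'   `entropy`, `heaviest_basin`, ordered by decreasing `P_alpha`.
#' @export
cluster_macrostates <- function(dend, basins, barrier_cut = 1) {
  stopifnot(inherits(dend, "breath_dendrogram"),
            inherits(basins, "breath_basins"))
  ids <- dend$leaves$basin_id
  Fb <- stats::setNames(dend$leaves$F, ids)
  Pb <- stats::setNames(dend$leaves$P_b, ids)
  parent <- stats::setNames(ids, ids)
  find_root <- function(i) {
    r <- as.character(i)
    while (parent[[r]] != as.numeric(r)) r <- as.character(parent[[r]])
    as.integer(r)
  }
  deepest <- function(grp) grp[which.min(Fb[as.character(grp)])]
  for (m in dend$merges) {
    shallow_min <- max(min(Fb[as.character(m$left)]),
                       min(Fb[as.character(m$right)]))
    if (m$barrier - shallow_min < barrier_cut) {
      ra <- find_root(deepest(m$left))
      rb <- find_root(deepest(m$right))
      if (ra != rb) parent[[as.character(rb)]] <- ra
    }
  }
  roots <- vapply(ids, find_root, 0L)
  out <- lapply(unique(roots), function(r) {
    mem <- ids[roots == r]
    w <- Pb[as.character(mem)]
    list(member_ids = sort(mem), P_alpha = sum(w),
         entropy = macrostate_entropy(w),
         heaviest_basin = mem[which.max(w)])
  })
  out[order(-vapply(out, `[[`, 0, "P_alpha"))]
}

#' Modal particle site of a basin
#'
#' The chain site at which the particle spends the most weight within the
#' basin's member microstates (1-based site index on the full chain).
#'
#' @param basins A `breath_basins`.
#' @param basin_id Basin id.
#' @return Integer site index.
#' @export
basin_modal_site <- function(basins, basin_id) {
  m <- basins$membership[basins$membership$basin_id == basin_id, ,
                         drop = FALSE]
  site <- key_particle_site(m$key)
  w <- tapply(m$P, site, sum)
  as.integer(names(w)[which.max(w)])
}

#' Assemble the promoter report
#'
#' One row per macrostate (sorted by occupancy), located at the modal
#' particle site of its heaviest basin and mapped to sequence coordinates
#' and, when an ATG anchor is known, signed genomic labels. Known TSS
#' positions (in label coordinates) are matched within +/- 10 bp.
#'
#' @param macrostates [cluster_macrostates()] output.
#' @param basins The specific `breath_basins`.
#' @param P_NS Pooled nonspecific weight.
#' @param chain The [encode_chain()] analyzed.
#' @param known_tss Optional integer vector of TSS positions in label
#'   coordinates (or sequence coordinates when no ATG anchor is present).
#' @return An object of class `breath_report`: data.frame with columns
#'   `state`, `site`, `seq_position`, `label`, `P`, `dF_kBT`, `S`,
#'   `n_basins`, `tss_match`, plus attributes `P_NS` and `id`.
#' @export
promoter_report <- function(macrostates, basins, P_NS, chain,
                            known_tss = NULL) {
  rows <- lapply(seq_along(macrostates), function(i) {
    ms <- macrostates[[i]]
    site <- basin_modal_site(basins, ms$heaviest_basin)
    pos <- chain$seq_position[site]
    lab <- chain$position_labels[site]
    data.frame(state = paste0("M", i), site = site,
               seq_position = pos, label = lab, P = ms$P_alpha,
               dF_kBT = free_energy_difference(ms$P_alpha, P_NS),
               S = ms$entropy, n_basins = length(ms$member_ids))
  })
  rep <- if (length(rows)) do.call(rbind, rows) else
    data.frame(state = character(0), site = integer(0),
               seq_position = integer(0), label = integer(0),
               P = numeric(0), dF_kBT = numeric(0), S = numeric(0),
               n_basins = integer(0))
  rep <- rep[order(-rep$P), , drop = FALSE]
  rownames(rep) <- NULL
  rep$tss_match <- rep(NA_integer_, nrow(rep))
  if (!is.null(known_tss) && nrow(rep) > 0L) {
    coord <- if (all(is.na(rep$label))) rep$seq_position else rep$label
    for (i in seq_len(nrow(rep))) {
      d <- abs(known_tss - coord[i])
      if (length(d) && min(d, na.rm = TRUE) <= 10)
        rep$tss_match[i] <- known_tss[which.min(d)]
    }
  }
  structure(rep, P_NS = P_NS, id = chain$id,
            class = c("breath_report", "data.frame"))
}

#' @export
print.breath_report <- function(x, ...) {
  cat(sprintf("Promoter report for '%s' (P_NS = %.3f)\n",
              attr(x, "id"), attr(x, "P_NS")))
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Write a promoter report as TSV and/or JSON
#'
#' @param report A `breath_report`.
#' @param tsv,json Output paths (NULL = skip).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, tsv = NULL, json = NULL) {
  written <- character(0)
  if (!is.null(tsv)) {
    utils::write.table(as.data.frame(report), tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, tsv)
  }
  if (!is.null(json)) {
    jsonlite::write_json(list(id = attr(report, "id"),
                              P_NS = attr(report, "P_NS"),
                              states = as.data.frame(report)),
                         json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, json)
  }
  invisible(written)
}

#' Export a dendrogram as Newick with branch lengths
#'
#' Leaves are basins (named `B<id>`); node heights are merge barriers, so a
#' branch length is the barrier minus the child's own height (its free
#' energy for a leaf). A forest yields one Newick tree per component.
#'
#' @param dend A `breath_dendrogram`.
#' @return Character vector of Newick strings.
#' @export
dendrogram_newick <- function(dend) {
  stopifnot(inherits(dend, "breath_dendrogram"))
  height <- stats::setNames(dend$leaves$F, dend$leaves$basin_id)
  node <- stats::setNames(paste0("B", dend$leaves$basin_id),
                          dend$leaves$basin_id)
  root_of <- stats::setNames(dend$leaves$basin_id, dend$leaves$basin_id)
  for (m in dend$merges) {
    ra <- as.character(root_of[[as.character(m$left[1])]])
    rb <- as.character(root_of[[as.character(m$right[1])]])
    sub <- sprintf("(%s:%.6g,%s:%.6g)",
                   node[[ra]], m$barrier - height[[ra]],
                   node[[rb]], m$barrier - height[[rb]])
    node[[ra]] <- sub
    height[[ra]] <- m$barrier
    for (k in names(root_of))
      if (root_of[[k]] == as.numeric(rb)) root_of[[k]] <- as.numeric(ra)
  }
  roots <- unique(unlist(root_of))
  vapply(as.character(roots), function(r) paste0(node[[r]], ";"), "")
}
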