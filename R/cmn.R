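# Conformational Markov Network: discretize projected trajectories into
# microstates (particle site x binned principal components) and collect
# visit weights and frame-to-frame transitions.

#' Pooled bin edges for a set of projected trajectories
#'
#' Equal-width bins per principal component spanning the pooled min/max over
#' all realizations (extreme values are clipped into the end bins during
#' discretization). Recorded alongside the network for reproducibility.
#'
#' @param projections List of `breath_projection` objects.
#' @param n_bins Number of bins per component (>= 2).
#' @return A matrix with rows `min`/`max`, one column per component.
#' @export
pooled_bin_ranges <- function(projections, n_bins = 10L) {
  if (inherits(projections, "breath_projection"))
    projections <- list(projections)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  S <- do.call(rbind, lapply(projections, function(p) p$scores))
  rbind(min = apply(S, 2, min), max = apply(S, 2, max))
}

#' Discretize a projected trajectory into microstate keys
#'
#' Each frame is mapped to a microstate key combining the particle's nearest
#' site (periodic wrap, 1-based) with the bin index of each principal
#' component. Bin `b` of component `j` covers
#' `[min_j + (b-1) w_j, min_j + b w_j)` with `w_j = (max_j - min_j)/n_bins`;
#' values at or beyond the pooled extremes are clipped into the end bins, so
#' the pooled maximum falls in bin `n_bins`.
#'
#' @param proj A `breath_projection`.
#' @param N Chain length (number of particle sites).
#' @param ranges Bin ranges from [pooled_bin_ranges()].
#' @param n_bins Number of bins per component.
#' @return Character vector of keys, one per frame, formatted
#'   `"site|b1,b2,..."`.
#' @export
discretize_projection <- function(proj, N, ranges, n_bins = 10L) {
  stopifnot(inherits(proj, "breath_projection"))
  if (nrow(proj$scores) == 0L) stop("empty trajectory")
  if (n_bins < 2L) stop("n_bins must be >= 2")
  n_pc <- ncol(proj$scores)
  if (ncol(ranges) != n_pc) stop("ranges do not match the projection width")
  bins <- matrix(0L, nrow(proj$scores), n_pc)
  for (j in seq_len(n_pc)) {
    lo <- ranges["min", j]
    hi <- ranges["max", j]
    w <- (hi - lo) / n_bins
    b <- if (w > 0) floor((proj$scores[, j] - lo) / w) + 1 else 1
    bins[, j] <- pmin(pmax(as.integer(b), 1L), as.integer(n_bins))
  }
  site <- particle_site(proj$x, N)
  paste0(site, "|", apply(bins, 1, paste, collapse = ","))
}

#' Build the Conformational Markov Network from microstate key sequences
#'
#' Nodes are the visited microstates, weighted by the fraction of all frames
#' spent in them. Directed edges count the observed frame-to-frame
#' transitions within each realization (self-loops retained; no transition
#' is counted across the seam between realizations).
#'
#' @param key_sequences List of character vectors, one per realization
#'   ([discretize_projection()] output).
#' @return An object of class `breath_cmn`: `nodes` (data.frame `key`, `count`,
#'   `P`), `edges` (data.frame `from`, `to`, `count`, `prob` with `prob`
#'   normalized per source node), `frame_total`.
#' @export
build_network <- function(key_sequences) {
  if (is.character(key_sequences)) key_sequences <- list(key_sequences)
  key_sequences <- key_sequences[lengths(key_sequences) > 0L]
  if (length(key_sequences) == 0L) stop("no nonempty key sequences")
  all_keys <- unlist(key_sequences, use.names = FALSE)
  tb <- table(all_keys)
  nodes <- data.frame(key = names(tb), count = as.integer(tb),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$key), , drop = FALSE]
  nodes$P <- nodes$count / length(all_keys)
  ef <- character(0); et <- character(0)
  for (ks in key_sequences) {
    if (length(ks) >= 2L) {
      ef <- c(ef, ks[-length(ks)])
      et <- c(et, ks[-1])
    }
  }
  if (length(ef) > 0L) {
    pair <- paste0(ef, "->", et)
    tbp <- table(pair)
    sp <- strsplit(names(tbp), "->", fixed = TRUE)
    edges <- data.frame(from = vapply(sp, `[`, "", 1),
                        to = vapply(sp, `[`, "", 2),
                        count = as.integer(tbp), stringsAsFactors = FALSE)
    out_tot <- tapply(edges$count, edges$from, sum)
    edges$prob <- edges$count / as.numeric(out_tot[edges$from])
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        count = integer(0), prob = numeric(0))
  }
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 frame_total = length(all_keys)),
            class = "breath_cmn")
}

#' @export
print.breath_cmn <- function(x, ...) {
  cat(sprintf("breath_cmn: %d microstates, %d directed edges, %d frames\n",
              nrow(x$nodes), nrow(x$edges), x$frame_total))
  invisible(x)
}

#' Particle site encoded in a microstate key
#'
#' @param keys Character vector of microstate keys.
#' @return Integer vector of 1-based particle sites.
#' @export
key_particle_site <- function(keys) {
  as.integer(sub("\\|.*$", "", keys))
}

#' Convert a Conformational Markov Network to an igraph object
#'
#' @param net A `breath_cmn`.
#' @param drop_self Drop self-loops (default FALSE).
#' @return A directed `igraph` graph with vertex attribute `P` and edge
#'   attributes `count`, `prob`.
#' @export
cmn_graph <- function(net, drop_self = FALSE) {
  stopifnot(inherits(net, "breath_cmn"))
  e <- net$edges
  if (drop_self) e <- e[e$from != e$to, , drop = FALSE]
  g <- igraph::graph_from_data_frame(e, directed = TRUE,
                                     vertices = net$nodes)
  g
}

#' Export a network as GraphML and TSV tables
#'
#' @param net A `breath_cmn`.
#' @param graphml,nodes_tsv,edges_tsv Output paths (NULL = skip).
#' @return Invisibly, the paths written.
#' @export
write_network <- function(net, graphml = NULL, nodes_tsv = NULL,
                          edges_tsv = NULL) {
  stopifnot(inherits(net, "breath_cmn"))
  written <- character(0)
  if (!is.null(graphml)) {
    igraph::write_graph(cmn_graph(net), graphml, format = "graphml")
    written <- c(written, graphml)
  }
  if (!is.null(nodes_tsv)) {
    utils::write.table(net$nodes, nodes_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, nodes_tsv)
  }
  if (!is.null(edges_tsv)) {
    utils::write.table(net$edges, edges_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, edges_tsv)
  }
  invisible(written)
}
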