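# Shared fixtures: small chains and scaled-down configurations.

fixture_params <- function(...) model_params(...)

# short homogeneous chains
fixture_chain <- function(bases, clamp_len = 0L, id = "fix", atg_pos = NULL) {
  encode_chain(promoter_sequence(id, bases, atg_pos = atg_pos), clamp_len)
}

# write a small FASTA file and return its path
fixture_fasta <- function(records, dir = withr::local_tempdir(.local_envir =
                                                               parent.frame())) {
  path <- file.path(dir, "fixture.fa")
  writeLines(as.character(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]])))), path)
  path
}

# tiny trajectory object with prescribed frames (for analysis-module tests)
fixture_trajectory <- function(Y, x = rep(0, nrow(Y)), realization_id = 1L) {
  structure(list(Y = Y, x = x, kinetic = rep(0, nrow(Y)),
                 times = seq_len(nrow(Y)), realization_id = realization_id,
                 seed_used = 0L, dt = 1, stride = 1L),
            class = "breath_trajectory")
}

# hand-built Markov network from explicit node weights and undirected links
fixture_network <- function(P, links) {
  keys <- sprintf("%d|1", seq_along(P))
  nodes <- data.frame(key = keys, count = as.integer(round(P * 1000)),
                      P = P, stringsAsFactors = FALSE)
  edges <- if (nrow(links) > 0L)
    data.frame(from = keys[links[, 1]], to = keys[links[, 2]],
               count = 1L, prob = 1, stringsAsFactors = FALSE)
  else data.frame(from = character(0), to = character(0),
                  count = integer(0), prob = numeric(0))
  structure(list(nodes = nodes, edges = edges, frame_total = 1000L),
            class = "breath_cmn")
}

# independent brute-force hill climb used as the basin-finding oracle:
# follows max-occupancy heavier neighbors step by step, no path compression
oracle_basins <- function(P, links) {
  n <- length(P)
  adj <- lapply(seq_len(n), function(i)
    sort(unique(c(links[links[, 1] == i, 2], links[links[, 2] == i, 1]))))
  climb <- function(i) {
    repeat {
      nb <- adj[[i]]
      heavier <- nb[P[nb] > P[i]]
      if (length(heavier) == 0L) return(i)
      best <- heavier[P[heavier] == max(P[heavier])]
      i <- min(best)  # lowest node index == lowest key for "%d|1" keys < 10
    }
  }
  vapply(seq_len(n), climb, 0L)
}

# scaled-down simulation config for pipeline tests; any sim_config()
# argument may be overridden through ...
fixture_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(dt = 0.5, n_steps = 4e4, preheat_steps = 5e3,
         n_realizations = 2, sample_stride = 40, seed = seed),
    list(...))
  do.call(sim_config, args)
}
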