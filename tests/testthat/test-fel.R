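test_that("steepest-ascent basins match simple hand cases", {
  # monotone 3-node chain: one basin with the heaviest node as attractor
  net <- fixture_network(c(0.5, 0.3, 0.2), rbind(c(1, 2), c(2, 3)))
  b <- find_basins(net)
  expect_equal(nrow(b$basins), 1L)
  expect_equal(b$basins$attractor, "1|1")
  expect_equal(b$basins$P_b, 1)

  # two peaks separated by a light node
  net2 <- fixture_network(c(0.4, 0.05, 0.35, 0.2),
                          rbind(c(1, 2), c(2, 3), c(3, 4)))
  b2 <- find_basins(net2)
  expect_equal(nrow(b2$basins), 2L)
  expect_setequal(b2$basins$attractor, c("1|1", "3|1"))

  # isolated node forms its own basin
  net3 <- fixture_network(c(0.9, 0.1), matrix(numeric(0), 0, 2))
  expect_equal(nrow(find_basins(net3)$basins), 2L)
})

test_that("basin finding equals the brute-force hill-climb oracle", {
  set.seed(99)
  for (trial in 1:300) {
    n <- sample(2:8, 1)
    P <- runif(n)
    P <- P / sum(P)
    m <- sample(1:(n * (n - 1) / 2), 1)
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    links <- pairs[sample(nrow(pairs), min(m, nrow(pairs))), , drop = FALSE]
    net <- fixture_network(P, links)
    got <- find_basins(net)
    want <- oracle_basins(P, links)
    # same partition: attractor of each node agrees
    got_attr <- got$basins$attractor[got$membership$basin_id]
    expect_equal(got_attr, sprintf("%d|1", want))
  }
})

test_that("the stochastic steepest-descent variant is seeded and valid", {
  net <- fixture_network(c(0.4, 0.05, 0.35, 0.2),
                         rbind(c(1, 2), c(2, 3), c(3, 4)))
  expect_error(find_basins(net, method = "stochastic"), "seed")
  b1 <- find_basins(net, method = "stochastic", seed = 5)
  b2 <- find_basins(net, method = "stochastic", seed = 5)
  expect_identical(b1, b2)
  # partitions still converge to local maxima of the weight
  expect_setequal(b1$basins$attractor, c("1|1", "3|1"))
})

test_that("basin free energies are weight ratios to the heaviest basin", {
  expect_equal(basin_free_energy(c(0.5, 0.5 / exp(1), 0.25)),
               c(0, 1, log(2)))
  expect_equal(basin_free_energy(c(0.2, 0.1), kT = 2), c(0, 2 * log(2)))
  expect_error(basin_free_energy(c(0.5, 0)), "> 0")
})

test_that("nonspecific pooling sums sub-threshold basins", {
  net <- fixture_network(c(0.5, 0.3, 0.15, 0.05),
                         rbind(c(1, 2), c(2, 3), c(3, 4)))
  # make each node its own basin: no links between them
  net0 <- fixture_network(c(0.5, 0.3, 0.15, 0.05), matrix(numeric(0), 0, 2))
  b <- find_basins(net0)
  sp <- split_nonspecific(b, 0.1)
  expect_equal(sp$P_NS, 0.05)
  expect_equal(nrow(sp$specific$basins), 3L)
  expect_equal(split_nonspecific(b, 0)$P_NS, 0)
  expect_error(split_nonspecific(b, 0.9), "unresolved")
  expect_error(split_nonspecific(b, 1.2), "ns_threshold")
  rm(net)
})

test_that("free energy differences reproduce the published promoter table", {
  occ <- anabaena_occupancies()
  dF <- free_energy_difference(occ$P, occ$P_NS)
  expect_true(all(abs(dF - occ$dF_kBT) <= 0.05))
  expect_equal(free_energy_difference(0.2, 0.2), 0)
  expect_error(free_energy_difference(0, 0.1), "> 0")
  expect_error(free_energy_difference(0.5, 1.2), "<= 1")
})

test_that("macrostate entropy is the Shannon multiplicity of member basins", {
  expect_equal(macrostate_entropy(0.3), 0)
  expect_equal(macrostate_entropy(rep(0.2, 5)), log(5))
  expect_equal(macrostate_entropy(c(0.9, 0.1)),
               -(0.9 * log(0.9) + 0.1 * log(0.1)))
  # invariant to normalization
  expect_equal(macrostate_entropy(c(9, 1)), macrostate_entropy(c(0.9, 0.1)))
  # bounds
  set.seed(2)
  for (i in 1:20) {
    w <- runif(sample(1:6, 1))
    s <- macrostate_entropy(w)
    expect_gte(s, 0)
    expect_lte(s, log(length(w)) + 1e-12)
  }
  expect_error(macrostate_entropy(numeric(0)), "empty")
})

# basins fixture for dendrogram tests: explicit weights, one node per basin
basins_from_weights <- function(P) {
  net <- fixture_network(P, matrix(numeric(0), 0, 2))
  find_basins(net)
}

test_that("dendrogram merges appear at the threshold sweep barriers", {
  # single basin: empty merge list
  d1 <- build_dendrogram(basins_from_weights(0.9),
                         data.frame(b1 = integer(0), b2 = integer(0)))
  expect_length(d1$merges, 0L)

  # two linked basins F = {0, 1.2}: one merge at barrier 1.2
  P <- c(0.6, 0.6 * exp(-1.2))
  d2 <- build_dendrogram(basins_from_weights(P), data.frame(b1 = 1, b2 = 2))
  expect_length(d2$merges, 1L)
  expect_equal(d2$merges[[1]]$barrier, 1.2, tolerance = 1e-12)

  # three basins in a line F = {0, 0.4, 2.0}: merges at 0.4 then 2.0
  P3 <- 0.5 * exp(-c(0, 0.4, 2.0))
  d3 <- build_dendrogram(basins_from_weights(P3),
                         data.frame(b1 = c(1, 2), b2 = c(2, 3)))
  expect_equal(vapply(d3$merges, `[[`, 0, "barrier"), c(0.4, 2.0),
               tolerance = 1e-12)
  # barriers non-decreasing toward the root
  expect_true(!is.unsorted(vapply(d3$merges, `[[`, 0, "barrier")))
})

test_that("macrostate clustering respects the barrier cut", {
  # barriers between deep basins are mediated by shallow transition basins:
  # deep A (F = 0) and B (F = 0.2) both link only to transition basin C.

  # C high (F = 2.5): A and B separated by 2.3 kT >= cut -> two macrostates
  Ph <- 0.5 * exp(-c(0, 0.2, 2.5))
  bh <- basins_from_weights(Ph)
  dh <- build_dendrogram(bh, data.frame(b1 = c(1, 2), b2 = c(3, 3)))
  mh <- cluster_macrostates(dh, bh, barrier_cut = 1)
  expect_length(mh, 2L)
  groups <- lapply(mh, `[[`, "member_ids")
  # the transition basin is absorbed into the deeper branch
  expect_true(any(vapply(groups, function(g) setequal(g, c(1, 3)), TRUE)))
  expect_true(any(vapply(groups, function(g) setequal(g, 2), TRUE)))

  # C low (F = 0.9): barrier 0.7 kT < cut -> one macrostate
  Pl <- 0.5 * exp(-c(0, 0.2, 0.9))
  bl <- basins_from_weights(Pl)
  dl <- build_dendrogram(bl, data.frame(b1 = c(1, 2), b2 = c(3, 3)))
  ml <- cluster_macrostates(dl, bl, barrier_cut = 1)
  expect_length(ml, 1L)
  expect_equal(ml[[1]]$P_alpha, sum(Pl))

  # directly linked basins have no barrier above the shallower attractor
  # and always cluster together, whatever their free energy gap
  Pd <- 0.5 * exp(-c(0, 3))
  bd <- basins_from_weights(Pd)
  dd <- build_dendrogram(bd, data.frame(b1 = 1, b2 = 2))
  expect_length(cluster_macrostates(dd, bd, barrier_cut = 0.1), 1L)

  # 4-basin toy (F = 0, 0.1, 0.3, 1.4; basin ids follow decreasing weight):
  # basin 2 joins basin 1 directly; the high transition basin 4 bridges
  # {1,2} and basin 3, leaving basin 3 behind a 1.1 kT barrier >= the cut
  P4 <- 0.5 * exp(-c(0, 0.1, 0.3, 1.4))
  b4 <- basins_from_weights(P4)
  expect_equal(b4$basins$attractor, sprintf("%d|1", 1:4))  # id = node here
  d4 <- build_dendrogram(b4, data.frame(b1 = c(1, 2, 4), b2 = c(2, 4, 3)))
  m4 <- cluster_macrostates(d4, b4, barrier_cut = 1)
  g4 <- lapply(m4, `[[`, "member_ids")
  expect_length(g4, 2L)
  # the deep basins 1+2 stay together, basin 3 is in the other macrostate;
  # the transition basin 4 may be absorbed into either group
  in_group <- function(id) which(vapply(g4, function(g) id %in% g, TRUE))
  expect_equal(in_group(1), in_group(2))
  expect_true(in_group(3) != in_group(1))
  expect_equal(sum(vapply(m4, `[[`, 0, "P_alpha")), sum(P4),
               tolerance = 1e-12)
  # the same landscape with a generous cut collapses to one macrostate
  m1 <- cluster_macrostates(d4, b4, barrier_cut = 1.2)
  expect_length(m1, 1L)
  expect_equal(m1[[1]]$P_alpha, sum(P4), tolerance = 1e-12)
})

test_that("promoter report composes the landscape quantities", {
  # two specific basins far apart plus nonspecific background
  net <- fixture_network(c(0.45, 0.35, 0.004),
                         matrix(numeric(0), 0, 2))
  # build keys encoding distinct particle sites
  net$nodes$key <- c("12|1", "30|1", "5|1")
  net$edges$from <- character(0); net$edges$to <- character(0)
  b <- find_basins(net)
  sp <- split_nonspecific(b, 0.01)
  d <- build_dendrogram(sp$specific, data.frame(b1 = integer(0),
                                                b2 = integer(0)))
  mac <- cluster_macrostates(d, sp$specific, 1)
  ch <- fixture_chain(strrep("A", 40), clamp_len = 2, atg_pos = 35)
  rep <- promoter_report(mac, sp$specific, sp$P_NS, ch, known_tss = NULL)
  expect_equal(nrow(rep), 2L)
  expect_equal(rep$P, c(0.45, 0.35))
  expect_equal(rep$dF_kBT, log(c(0.45, 0.35) / sp$P_NS))
  expect_equal(rep$S, c(0, 0))
  # site 12 on the clamped chain is sequence position 10
  expect_equal(rep$seq_position, c(10L, 28L))
  # labels: sequence positions 10 and 28 relative to the anchor at 35
  expect_equal(rep$label, c(-25L, -7L))
  # TSS annotation within +-10 bp, in label coordinates: -20 is within 5 bp
  # of the first state's label (-25) but 13 bp from the second (-7)
  rep2 <- promoter_report(mac, sp$specific, sp$P_NS, ch,
                          known_tss = c(-20L))
  expect_equal(rep2$tss_match, c(-20L, NA_integer_))

  # empty macrostate list: NS-only report
  rep0 <- promoter_report(list(), sp$specific, sp$P_NS, ch)
  expect_equal(nrow(rep0), 0L)
  expect_equal(attr(rep0, "P_NS"), sp$P_NS)
})

test_that("dendrogram exports valid Newick trees", {
  P3 <- 0.5 * exp(-c(0, 0.4, 2.0))
  b3 <- basins_from_weights(P3)
  d3 <- build_dendrogram(b3, data.frame(b1 = c(1, 2), b2 = c(2, 3)))
  nwk <- dendrogram_newick(d3)
  expect_length(nwk, 1L)
  tr <- ape::read.tree(text = nwk)
  expect_equal(sort(tr$tip.label), c("B1", "B2", "B3"))
  # leaf depths from the root recover barrier minus leaf free energy
  depths <- ape::node.depth.edgelength(tr)[1:3]
  names(depths) <- tr$tip.label
  expect_equal(unname(depths["B1"] - depths["B2"]), 0.4, tolerance = 1e-6)
})
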