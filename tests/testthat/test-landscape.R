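test_that("state free energies follow -kT log(pi) with the minimum at zero", {
  expect_equal(unname(state_free_energies(rep(0.25, 4))), rep(0, 4))
  f <- state_free_energies(c(1, 2) / 3, kT = 1)
  expect_equal(unname(f), c(log(2), 0), tolerance = 1e-12)
  expect_error(state_free_energies(c(0, 1)), "zero or negative")
  # generated network: recovers the generating energies up to a constant
  net <- psii_network(seed = 5)
  f <- state_free_energies(net)
  e <- net$states$energy[transient_states(net)]
  d <- f - (e - min(e))
  expect_lt(max(d) - min(d), 1e-10)
})

test_that("transition-state free energies reproduce the rates exactly", {
  net <- psii_network(seed = 8, states_per_subunit = 2)
  fel <- free_energy_landscape(net, kT = 1, nu = 1)
  expect_lt(fel$asymmetry_residual, 1e-10)
  Khat <- reconstruct_rates(fel)
  K <- transient_rates(net)
  nz <- K > 0
  expect_lt(max(abs(Khat[nz] - K[nz]) / K[nz]), 1e-12)
  # nu shifts barriers but cancels in the round trip
  fel2 <- free_energy_landscape(net, nu = 10)
  expect_equal(fel2$edges$F_ts, fel$edges$F_ts + log(10), tolerance = 1e-10)
  expect_lt(max(abs(reconstruct_rates(fel2)[nz] - K[nz]) / K[nz]), 1e-12)
  # k = nu on an edge means zero barrier above the departing state
  K2 <- matrix(c(0, 1, 1, 0), 2, 2)
  twin <- make_net(K2, is_trap = c(FALSE, FALSE))
  fel3 <- free_energy_landscape(twin, nu = 1)
  expect_equal(fel3$edges$F_ts, fel3$F_state[[1]], tolerance = 1e-12)
})

test_that("one-way edges are rejected in the free-energy translation", {
  c3 <- toy_network("chain3")
  expect_error(free_energy_landscape(c3))  # irreversible (and no equilibrium)
  K <- matrix(0, 2, 2); K[1, 2] <- 1; K[2, 1] <- 1
  net <- make_net(K, is_trap = c(FALSE, FALSE))
  net$rates[2, 1] <- 0; net$rates[2, 2] <- 0
  f <- c(s1 = 0, s2 = 0)
  expect_error(ts_free_energies(net, f), "one-way edge")
})

test_that("hand-built disconnectivity trees merge at the right thresholds", {
  # 2 states, one TS at 1.0: single merge at the first level >= 1.0
  fel <- list(F_state = c(a = 0, b = 0.2),
              edges = data.frame(i = 1, j = 2, label_i = "a", label_j = "b",
                                 F_ts = 1.0, asymmetry = 0),
              kT = 1, nu = 1, labels = c("a", "b"))
  class(fel) <- "free_energy_landscape"
  tree <- build_disconnectivity(fel, levels = seq(0, 2, by = 0.1))
  expect_equal(length(tree$heights), 3)
  expect_equal(tree$heights[3], 1.0, tolerance = 1e-12)  # tie merges at level

  # 3 states, TS(A,B)=1.0, TS(B,C)=2.0: at 1.5 the partition is {A,B},{C}
  fel3 <- list(F_state = c(A = 0, B = 0.1, C = 0.2),
               edges = data.frame(i = c(1, 2), j = c(2, 3),
                                  label_i = c("A", "B"), label_j = c("B", "C"),
                                  F_ts = c(1.0, 2.0), asymmetry = c(0, 0)),
               kT = 1, nu = 1, labels = c("A", "B", "C"))
  class(fel3) <- "free_energy_landscape"
  tr3 <- build_disconnectivity(fel3, levels = seq(0, 2.5, by = 0.5))
  expect_equal(merge_height(tr3, 1, 2), 1.0)
  expect_equal(merge_height(tr3, 2, 3), 2.0)
  expect_equal(merge_height(tr3, 1, 3), 2.0)
  # grid not covering the TS range is an explicit error
  expect_error(build_disconnectivity(fel3, levels = seq(0, 1.5, by = 0.5)),
               "forest")
})

test_that("merge heights are ultrametric and match minimax barriers", {
  net <- psii_network(seed = 3, states_per_subunit = 2)
  fel <- free_energy_landscape(net)
  tree <- build_disconnectivity(fel)
  n <- tree$n_leaves
  set.seed(1)
  trips <- replicate(40, sample.int(n, 3))
  for (k in seq_len(ncol(trips))) {
    a <- trips[1, k]; b <- trips[2, k]; c <- trips[3, k]
    expect_lte(merge_height(tree, a, c),
               max(merge_height(tree, a, b), merge_height(tree, b, c)) + 1e-12)
  }
})

test_that("zero disorder yields mirror-symmetric monomer subtrees", {
  net <- psii_network(seed = 4, energy_disorder_sigma = 0,
                      states_per_subunit = 2)
  fel <- free_energy_landscape(net)
  tree <- build_disconnectivity(fel)
  st <- net$states[transient_states(net), ]
  key <- sub("\\.m[12]\\.", ".", st$label)
  m1 <- which(st$monomer == 1)
  for (i in m1) for (j in m1) {
    if (j <= i) next
    i2 <- which(st$monomer == 2 & key == key[i])
    j2 <- which(st$monomer == 2 & key == key[j])
    expect_equal(merge_height(tree, i, j), merge_height(tree, i2, j2),
                 tolerance = 1e-9)
  }
})

test_that("MFPT annotations colour trap-adjacent branches fastest", {
  net <- psii_network(seed = 6, states_per_subunit = 2)
  fel <- free_energy_landscape(net)
  tree <- annotate_mfpt(build_disconnectivity(fel), net, trap_states(net))
  ann <- tree$annotations
  expect_true(all(ann > 0))
  st <- net$states[transient_states(net), ]
  core <- ann[st$subunit %in% c("RC", "CP43")]
  distal <- ann[st$subunit %in% c("M-B")]
  expect_lt(min(core), min(distal))
  # annotation equals a point-mass MFPT
  lab <- names(ann)[5]
  p0 <- initial_distribution(net, state = lab)
  expect_equal(unname(ann[lab]), mfpt(net, p0, trap_states(net)),
               tolerance = 1e-10)
})

test_that("landscape files and Newick trees round-trip through ape", {
  md <- withr::local_tempdir()
  net <- psii_network(seed = 2, states_per_subunit = 2)
  fel <- free_energy_landscape(net)
  tree <- annotate_mfpt(build_disconnectivity(fel), net, trap_states(net))
  minp <- file.path(md, "min.data"); tsp <- file.path(md, "ts.data")
  nwk <- file.path(md, "tree.nwk")
  write_landscape(fel, tree, min_path = minp, ts_path = tsp,
                  newick_path = nwk)
  mins <- utils::read.table(minp)
  expect_equal(nrow(mins), length(fel$F_state))
  expect_equal(mins$V1, unname(fel$F_state), tolerance = 1e-10)
  tss <- utils::read.table(tsp)
  expect_equal(nrow(tss), nrow(fel$edges))
  phy <- ape::read.tree(nwk)
  expect_equal(ape::Ntip(phy), tree$n_leaves)
  # merge heights survive the phylo conversion: root-to-tip depths equal
  # root height minus leaf free energy
  phy0 <- as_phylo(tree)
  depths <- ape::node.depth.edgelength(phy0)[seq_len(tree$n_leaves)]
  expect_equal(depths, max(tree$heights) - fel$F_state[phy0$tip.label],
               ignore_attr = TRUE, tolerance = 1e-9)
})
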