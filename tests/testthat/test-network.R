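test_that("a minimal 2-state network loads from files with correct rates", {
  md <- withr::local_tempdir()
  mat <- file.path(md, "m.csv"); sts <- file.path(md, "s.csv")
  writeLines(c(",A,B", "A,-1.0,1.0", "B,1.0,-1.0"), mat)
  writeLines(c("state_label,subunit,monomer,is_trap",
               "A,X,1,FALSE", "B,Y,1,FALSE"), sts)
  net <- read_network(mat, sts)
  expect_equal(nrow(net$states), 2)
  expect_equal(-diag(net$rates), c(A = 1, B = 1))  # escape rate 1 ps^-1 each
})

test_that("contract violations raise distinct, described errors", {
  md <- withr::local_tempdir()
  mat <- file.path(md, "m.csv"); sts <- file.path(md, "s.csv")
  writeLines(c("state_label,subunit,monomer,is_trap",
               "A,X,1,FALSE", "B,Y,1,FALSE"), sts)
  # negative off-diagonal names the offending pair
  writeLines(c(",A,B", "A,0.3,-0.3", "B,1.0,-1.0"), mat)
  expect_error(read_network(mat, sts), "negative rate k\\(A -> B\\)")
  # non-square
  writeLines(c(",A,B,C", "A,0,1,0", "B,1,0,0"), mat)
  expect_error(read_network(mat, sts), "square|labels")
  # label mismatch between the two files
  writeLines(c(",A,Z", "A,0,1", "Z,1,0"), mat)
  expect_error(read_network(mat, sts), "do not match")
  # unparseable numeric field
  writeLines(c(",A,B", "A,0,oops", "B,1,0"), mat)
  expect_error(read_network(mat, sts), "unparseable numeric field 'oops'")
})

test_that("write_network / read_network round-trips rates and metadata", {
  net <- psii_network(seed = 3, states_per_subunit = 2)
  md <- withr::local_tempdir()
  mat <- file.path(md, "m.csv"); sts <- file.path(md, "s.csv")
  write_network(net, mat, sts)
  net2 <- read_network(mat, sts)
  expect_identical(net2$rates, net$rates)
  expect_identical(net2$states$label, net$states$label)
  expect_identical(net2$states$is_trap, net$states$is_trap)
  expect_equal(net2$states$energy, net$states$energy)
})

test_that("equilibrium distribution matches closed forms", {
  # pi2/pi1 = k(1->2)/k(2->1) under detailed balance
  K <- matrix(c(0, 2, 1, 0), 2, 2, byrow = TRUE)
  net <- make_net(K, is_trap = c(FALSE, FALSE))
  expect_equal(unname(equilibrium_distribution(net)), c(1/3, 2/3),
               tolerance = 1e-12)
  # fully symmetric 3-state network: uniform
  K3 <- matrix(1, 3, 3); diag(K3) <- 0
  net3 <- make_net(K3, is_trap = rep(FALSE, 3))
  expect_equal(unname(equilibrium_distribution(net3)), rep(1/3, 3),
               tolerance = 1e-12)
})

test_that("equilibrium of a detailed-balanced network is Boltzmann", {
  e <- c(0.2, 1.1, 0.5, 0.9, 0.0, 0.7)
  pairs <- cbind(c(1, 2, 3, 4, 5, 1), c(2, 3, 4, 5, 6, 6))
  net <- net_from_energies(e, pairs)
  pi <- equilibrium_distribution(net)
  boltz <- exp(-e) / sum(exp(-e))
  expect_rel_equal(unname(pi), boltz, 1e-10)
})

test_that("disconnected transient subnetwork is rejected with components", {
  K <- matrix(0, 4, 4)
  K[1, 2] <- 1; K[2, 1] <- 1; K[3, 4] <- 1; K[4, 3] <- 1
  net <- make_net(K, is_trap = rep(FALSE, 4))
  expect_error(equilibrium_distribution(net), "2 components")
})

test_that("validation reports injected defects without mutating the network", {
  net <- psii_network(seed = 5, states_per_subunit = 2)
  expect_lt(validate_network(net)$db_residual, 1e-10)

  # perturb one row sum by 1e-3
  net2 <- net
  net2$rates[1, 1] <- net2$rates[1, 1] + 1e-3
  rep <- validate_network(net2, tol = 1e-6)
  expect_equal(rep$row_sum_max_error, 1e-3, tolerance = 1e-6)
  expect_true(rep$row_sum_flagged)

  # two disjoint 2-state blocks -> exactly 2 components
  K <- matrix(0, 4, 4)
  K[1, 2] <- 1; K[2, 1] <- 1; K[3, 4] <- 1; K[4, 3] <- 1
  blocks <- make_net(K, is_trap = rep(FALSE, 4))
  expect_length(validate_network(blocks)$connected_components, 2)

  # traps reachable from every transient state of a generated network
  net3 <- psii_network(seed = 6, states_per_subunit = 2)
  expect_setequal(validate_network(net3)$traps_reachable_from,
                  transient_states(net3))
})

test_that("generator rows sum to zero for every state", {
  for (seed in c(1, 2)) {
    net <- psii_network(seed = seed, states_per_subunit = 2)
    expect_lt(max(abs(rowSums(net$rates))), 1e-12)
  }
})

test_that("detailed balance is equivalent to symmetry of the similarity transform", {
  net <- psii_network(seed = 9, states_per_subunit = 2)
  pi <- equilibrium_distribution(net)
  K <- transient_rates(net)
  S <- diag(sqrt(pi)) %*% K %*% diag(1 / sqrt(pi))
  expect_lt(max(abs(S - t(S))), 1e-10)

  # a driven 3-cycle violates detailed balance and the symmetry alike
  K3 <- matrix(0, 3, 3)
  K3[1, 2] <- 1; K3[2, 3] <- 1; K3[3, 1] <- 1
  K3[2, 1] <- 0.2; K3[3, 2] <- 0.2; K3[1, 3] <- 0.2
  cyc <- make_net(K3, is_trap = rep(FALSE, 3))
  pic <- equilibrium_distribution(cyc)
  Sc <- diag(sqrt(pic)) %*% transient_rates(cyc) %*% diag(1 / sqrt(pic))
  expect_gt(max(abs(Sc - t(Sc))), 1e-3)
  expect_gt(validate_network(cyc)$db_residual, 1e-3)
})

test_that("initial distributions are Boltzmann over the subunit", {
  net <- psii_network(seed = 4)
  p0 <- initial_distribution(net, "CP43", monomer = 1)
  idx <- subunit_states(net, "CP43", monomer = 1)
  expect_equal(sum(p0), 1)
  expect_setequal(which(p0 > 0), idx)
  e <- net$states$energy[idx]
  expect_equal(p0[idx], exp(-(e - min(e))) / sum(exp(-(e - min(e)))),
               tolerance = 1e-12)
  # uniform and point-mass variants
  pu <- initial_distribution(net, "CP43", monomer = 1, kind = "uniform")
  expect_true(all(abs(pu[idx] - 1 / length(idx)) < 1e-15))
  pp <- initial_distribution(net, state = idx[2])
  expect_equal(which(pp == 1), idx[2])
})
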