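test_that("knockout deletes states without touching surviving rates", {
  net <- psii_network(seed = 1, states_per_subunit = 2)
  expect_identical(knockout(net, character(0)), net)

  ko <- knockout(net, "CP26")
  expect_false(any(ko$states$subunit == "CP26"))
  expect_equal(nrow(ko$states), nrow(net$states) - 4)
  keep <- which(net$states$subunit != "CP26")
  off_old <- net$rates; diag(off_old) <- 0
  off_new <- ko$rates; diag(off_new) <- 0
  expect_identical(unname(off_new), unname(off_old[keep, keep]))
  expect_equal(attr(ko, "knockout")$subunits, "CP26")
})

test_that("removing a dead-end detour strictly shortens the MFPT", {
  net <- toy_network("dead_end")
  p0 <- c(1, 0, 0)
  m_full <- mfpt(net, p0, 3)
  ko <- knockout(net, "D")
  m_ko <- mfpt(ko, c(1, 0), 2)
  expect_lt(m_ko, m_full)
  expect_equal(m_ko, 1 / 0.2, tolerance = 1e-12)  # single exponential escape
})

test_that("knockout that disconnects the start reports infinite MFPT", {
  # start -> bridge -> trap; removing the bridge strands the start
  K <- matrix(0, 3, 3)
  K[1, 2] <- 1; K[2, 1] <- 1; K[2, 3] <- 1
  net <- make_net(K, labels = c("S", "B", "T"), is_trap = c(FALSE, FALSE, TRUE))
  ko <- knockout(net, "B")
  expect_error(knockout(net, c("S", "B")), "every transient state")
  expect_equal(mfpt(ko, c(1, 0), 2), Inf)
  fd <- fpt_distribution(ko, c(1, 0), 2, time_grid = c(1, 10))
  expect_equal(fd$absorption_probability, 0)
})

test_that("a zero-rate quencher is a null perturbation", {
  net <- psii_network(seed = 7, states_per_subunit = 2)
  hosts <- subunit_states(net, "CP29")
  netq <- add_quencher(net, hosts, k_capture = 0)
  rc <- state_ids(netq, net$states$label[trap_states(net)])
  p0n <- initial_distribution(net, "CP43", monomer = 1)
  p0q <- initial_distribution(netq, "CP43", monomer = 1)
  tg <- fpt_time_grid(0.1, 1e4, 100)
  f1 <- fpt_distribution(net, p0n, trap_states(net), time_grid = tg)
  f2 <- fpt_distribution(netq, p0q, rc, time_grid = tg)
  expect_lt(max(abs(f1$density - f2$density)), 1e-10)
  expect_lt(abs(f1$mfpt - f2$mfpt), 1e-10)
  # sinks are absorbing, one per monomer, and hosts must be transient
  sinks <- attr(netq, "quencher")$sinks
  expect_length(sinks, 2)
  expect_true(all(rowSums(excitonet:::off_diagonal(netq))[sinks] == 0))
  expect_error(add_quencher(net, trap_states(net), 1), "already absorbing")
})

test_that("mirror-symmetric quencher and trap split probability equally", {
  sc <- toy_network("symmetric_committor")
  p0 <- c(0, 1, 0, 0, 0)
  expect_equal(first_hit_probability(sc, p0, 4, 5), 0.5, tolerance = 1e-12)
  expect_equal(first_hit_probability(sc, p0, 5, 4), 0.5, tolerance = 1e-12)
})

test_that("committor boundary conditions, bounds and harmonicity hold", {
  net <- psii_network(seed = 23, states_per_subunit = 2)
  A <- subunit_states(net, "RC1-CT")
  B <- subunit_states(net, "RC2-CT")
  q <- first_hit_probability(net, NULL, A, B)
  expect_equal(unname(q[A]), 1)
  expect_equal(unname(q[B]), 0)
  expect_true(all(q >= -1e-12 & q <= 1 + 1e-12))
  # harmonic: q_i equals the jump-chain average over successors
  off <- excitonet:::off_diagonal(net)
  tr <- setdiff(seq_len(nrow(off)), c(A, B))
  jump_avg <- (off[tr, ] %*% q) / rowSums(off[tr, ])
  expect_lt(max(abs(q[tr] - jump_avg)), 1e-10)
  # p0 on A gives 1
  p0 <- numeric(nrow(net$states)); p0[A] <- 1
  expect_equal(first_hit_probability(net, p0, A, B), 1)
  expect_error(first_hit_probability(net, NULL, A, A), "overlap")
})

test_that("committor matches kMC first-hit fractions", {
  # 4-state chain with unequal rates, traps at both ends
  K <- matrix(0, 4, 4)
  K[2, 1] <- 0.7; K[2, 3] <- 1.3
  K[3, 2] <- 0.4; K[3, 4] <- 2.1
  net <- make_net(K, labels = c("TA", "x", "y", "TB"),
                  is_trap = c(TRUE, FALSE, FALSE, TRUE))
  p0 <- c(0, 1, 0, 0)
  q <- first_hit_probability(net, p0, 1, 4)
  n <- 1e5
  sm <- sample_fpt(net, p0, c(1, 4), n, seed = 11)
  phat <- mean(sm$terminal == 1)
  se <- sqrt(q * (1 - q) / n)
  expect_lt(abs(phat - q), 3 * se)
  # complement property
  expect_equal(q + first_hit_probability(net, p0, 4, 1), 1, tolerance = 1e-10)
})

test_that("quench maps obey probability conservation and domain equivalence", {
  placements <- c("CP26", "S-B", "CP24", "CP29", "M-C")
  inits <- c("CP43", "CP47", "S-B", "M-B")
  # strong timescale separation so shared-domain states pre-equilibrate
  net <- psii_network(seed = 12, intra_rate = 50, inter_rate = 0.05,
                      shared_domains = list(c("CP29", "M-C")))
  qm <- quench_map(net, placements, inits, k_capture = 1)
  expect_true(all(qm >= 0 & qm <= 1))
  # entry + P(RC first) = 1
  hosts <- subunit_states(net, "S-B")
  netq <- add_quencher(net, hosts, 1, sink_label = "Q:S-B")
  sinks <- attr(netq, "quencher")$sinks
  rcq <- state_ids(netq, net$states$label[trap_states(net)])
  p0 <- initial_distribution(netq, "CP43", monomer = 1)
  expect_equal(first_hit_probability(netq, p0, sinks, rcq) +
                 first_hit_probability(netq, p0, rcq, sinks), 1,
               tolerance = 1e-10)
  expect_equal(qm["CP43", "S-B"], first_hit_probability(netq, p0, sinks, rcq),
               tolerance = 1e-12)
  # quencher in CP29 ~ quencher in M-C when their chlorophylls share a domain
  expect_lt(max(abs(qm[, "CP29"] - qm[, "M-C"])), 0.05)
  # an isolated edge subunit quenches least
  expect_equal(unname(which.min(colSums(qm))), which(placements == "CP24"))
})
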