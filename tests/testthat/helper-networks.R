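# compact constructor for hand-built fixtures
make_net <- function(K, labels = NULL, is_trap = NULL, subunit = NULL,
                     monomer = 1L, energy = NA_real_) {
  n <- nrow(K)
  if (is.null(labels)) labels <- paste0("s", seq_len(n))
  if (is.null(subunit)) subunit <- labels
  kinetic_network(K, data.frame(label = labels, subunit = subunit,
                                monomer = monomer, energy = energy,
                                is_trap = is_trap))
}

# detailed-balanced network from explicit energies over a connected pair
# list, independent of the package generator (barrier = max energy + 0.4)
net_from_energies <- function(e, pairs, trap_from = NULL, trap_rate = 1) {
  n <- length(e)
  nt <- n + as.integer(!is.null(trap_from))
  K <- matrix(0, nt, nt)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    B <- max(e[i], e[j]) + 0.4
    K[i, j] <- exp(-(B - e[i]))
    K[j, i] <- exp(-(B - e[j]))
  }
  if (!is.null(trap_from)) K[trap_from, nt] <- trap_rate
  make_net(K,
           labels = c(paste0("s", seq_len(n)), if (nt > n) "trap"),
           is_trap = c(rep(FALSE, n), if (nt > n) TRUE),
           energy = c(e, if (nt > n) NA))
}

# transient off-diagonal rate block, for bitwise comparisons
transient_rates <- function(net) {
  tr <- transient_states(net)
  off <- net$rates
  diag(off) <- 0
  off[tr, tr, drop = FALSE]
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), .Machine$double.xmin)), tol)
}
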