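#' Synthetic dimeric antenna network with a flat, trap-terminated landscape
#'
#' Generates a kinetic transition network with the statistical structure of
#' the C2S2M2-type photosystem II supercomplex: two mirror-image monomers,
#' each containing the subunit instances RC, CP43, CP47, CP26, CP29, CP24
#' and the strongly/moderately bound LHCII trimers (S-A, S-B, S-C and M-A,
#' M-B, M-C), connected by the supercomplex adjacency (core antennae bridge
#' the reaction centre and the periphery; the trimers form rings; S-B links
#' to M-A; the two monomers touch through the CP47 pair and the cross
#' S-C/CP29 contacts). Site energies are spread over a narrow range of order
#' kT (a "flat" landscape) with Gaussian static disorder, inter-state rates
#' are constructed to satisfy detailed balance exactly, and each reaction
#' centre feeds an absorbing charge-transfer trap from its lowest exciton
#' state.
#'
#' Rates follow a barrier model: for a connected pair of states i, j a
#' symmetric barrier \code{B >= max(E_i, E_j)} is drawn and
#' \code{k(i -> j) = nu * exp(-(B - E_i) / kT)}, with the attempt prefactor
#' \code{nu} equal to \code{intra_rate} for pairs in the same domain (fast
#' local equilibration) and \code{inter_rate} otherwise (slow inter-domain
#' transfer). This guarantees \code{pi_i k(i->j) = pi_j k(j->i)} exactly and
#' gives the free-energy translation an exact round-trip target.
#'
#' By default every subunit instance is one domain. \code{shared_domains}
#' merges named subunit pairs within each monomer into a single domain
#' (e.g. \code{list(c("CP29", "M-C"))} to emulate fast equilibration between
#' the CP29 and M-LHCII (C) chlorophylls).
#'
#' @param states_per_subunit exciton states per subunit instance.
#' @param landscape_span span of subunit base energies, in kT units.
#' @param energy_disorder_sigma s.d. of Gaussian static disorder added per
#'   state after mirroring monomer 1 into monomer 2, in kT units.
#' @param intra_rate attempt prefactor for intra-domain transitions, ps^-1.
#' @param inter_rate attempt prefactor for inter-domain transitions, ps^-1;
#'   must be smaller than \code{intra_rate}.
#' @param trap_rate rate from each RC's lowest exciton state into its
#'   absorbing charge-transfer state, ps^-1.
#' @param barrier_sigma scale (kT) of the half-normal barrier excess above
#'   \code{max(E_i, E_j)}.
#' @param kT thermal energy (energies are in kT units, so 1).
#' @param seed integer seed; the same seed reproduces the network exactly.
#' @param shared_domains list of character vectors of subunit names merged
#'   into one domain per monomer.
#' @return a \code{kinetic_network} whose states carry the generating
#'   energies, with two absorbing charge-transfer states \code{RC1-CT},
#'   \code{RC2-CT}.
#' @export
psii_network <- function(states_per_subunit = 3,
                         landscape_span = 1.0,
                         energy_disorder_sigma = 0.3,
                         intra_rate = 10,
                         inter_rate = 0.2,
                         trap_rate = 2,
                         barrier_sigma = 0.2,
                         kT = 1,
                         seed = 1,
                         shared_domains = NULL) {
  stopifnot(states_per_subunit >= 1,
            energy_disorder_sigma >= 0, landscape_span >= 0,
            intra_rate > 0, inter_rate > 0, trap_rate > 0, barrier_sigma >= 0)
  if (!(intra_rate > inter_rate))
    stop("intra_rate must exceed inter_rate (fast local equilibration, ",
         "slow inter-domain transfer)")

  subunits <- c("RC", "CP43", "CP47", "CP26", "CP29", "CP24",
                "S-A", "S-B", "S-C", "M-A", "M-B", "M-C")
  edges <- psii_adjacency()

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  nss <- states_per_subunit
  # state bookkeeping: one instance per (subunit, monomer)
  st <- expand.grid(k = seq_len(nss), subunit = subunits, monomer = 1:2,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  st <- st[order(st$monomer, match(st$subunit, subunits), st$k), ]
  st$label <- sprintf("%s.m%d.%d", st$subunit, st$monomer, st$k)
  n <- nrow(st)

  # energies: monomer 1 drawn, mirrored into monomer 2, then disordered
  base <- stats::runif(length(subunits), 0, landscape_span)
  names(base) <- subunits
  e1 <- base[st$subunit[st$monomer == 1]] +
    stats::runif(sum(st$monomer == 1), -0.1, 0.1) * landscape_span
  energy <- c(e1, e1)  # mirror
  energy <- energy + stats::rnorm(n, 0, energy_disorder_sigma)
  st$energy <- energy

  # domains: one per subunit instance, optionally merged pairs
  dom_key <- paste(st$subunit, st$monomer)
  if (!is.null(shared_domains)) {
    for (grp in shared_domains) {
      for (m in 1:2) {
        keys <- paste(grp, m)
        dom_key[dom_key %in% keys] <- paste(paste(grp, collapse = "+"), m)
      }
    }
  }
  st$domain_id <- as.integer(factor(dom_key, levels = unique(dom_key)))

  # connected state pairs: all pairs within a domain, plus all cross pairs
  # between states of adjacent subunit instances
  K <- matrix(0, n, n)
  idx_of <- function(subunit, monomer) which(st$subunit == subunit & st$monomer == monomer)
  pair_list <- list()
  for (m in 1:2) {
    for (e in seq_len(nrow(edges$intra))) {
      pair_list[[length(pair_list) + 1]] <-
        cbind(rep(idx_of(edges$intra$a[e], m), each = nss),
              idx_of(edges$intra$b[e], m))
    }
  }
  for (e in seq_len(nrow(edges$inter))) {
    pair_list[[length(pair_list) + 1]] <-
      cbind(rep(idx_of(edges$inter$a[e], 1), each = nss),
            idx_of(edges$inter$b[e], 2))
    pair_list[[length(pair_list) + 1]] <-
      cbind(rep(idx_of(edges$inter$a[e], 2), each = nss),
            idx_of(edges$inter$b[e], 1))
  }
  # intra-domain pairs (within subunit instance or merged domain)
  for (d in unique(st$domain_id)) {
    ids <- which(st$domain_id == d)
    if (length(ids) > 1) {
      cmb <- t(utils::combn(ids, 2))
      pair_list[[length(pair_list) + 1]] <- cmb
    }
  }
  pairs <- unique(do.call(rbind, lapply(pair_list, function(p)
    cbind(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2])))))

  # barrier excesses are drawn once per mirror-equivalence class of pairs,
  # so with zero disorder the two monomers' rate blocks are exact mirror
  # images (the dimer's approximate two-fold symmetry becomes exact)
  strip <- sub("\\.m[12]\\.", ".", st$label)
  excess_cache <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    same_dom <- st$domain_id[i] == st$domain_id[j]
    nu <- if (same_dom) intra_rate else inter_rate
    key <- paste(c(sort(c(strip[i], strip[j])),
                   if (st$monomer[i] == st$monomer[j]) "intra" else "cross"),
                 collapse = "|")
    if (is.null(excess_cache[[key]]))
      excess_cache[[key]] <- abs(stats::rnorm(1, 0, barrier_sigma))
    B <- max(st$energy[i], st$energy[j]) + excess_cache[[key]]
    K[i, j] <- nu * exp(-(B - st$energy[i]) / kT)
    K[j, i] <- nu * exp(-(B - st$energy[j]) / kT)
  }

  # absorbing charge-transfer state per RC, fed from that RC's lowest state
  ct_labels <- c("RC1-CT", "RC2-CT")
  Kfull <- rbind(cbind(K, matrix(0, n, 2)), matrix(0, 2, n + 2))
  for (m in 1:2) {
    rc <- idx_of("RC", m)
    low <- rc[which.min(st$energy[rc])]
    Kfull[low, n + m] <- trap_rate
  }
  states <- data.frame(
    label = c(st$label, ct_labels),
    subunit = c(st$subunit, "RC1-CT", "RC2-CT"),
    monomer = c(st$monomer, 1L, 2L),
    domain_id = c(st$domain_id, max(st$domain_id) + 1:2),
    energy = c(st$energy, NA, NA),
    is_trap = c(rep(FALSE, n), TRUE, TRUE),
    stringsAsFactors = FALSE)

  net <- kinetic_network(Kfull, states, kT = kT)
  attr(net, "seed") <- as.integer(seed)
  net
}

# Subunit adjacency of the dimeric supercomplex: intra-monomer contacts and
# the two inter-monomer contacts (CP47 pair, cross S-C/CP29).
psii_adjacency <- function() {
  intra <- data.frame(
    a = c("CP43", "CP43", "CP43", "CP26", "S-A", "S-B", "S-C",
          "S-B", "M-A", "M-B", "M-C", "M-C", "CP24", "CP29", "CP47"),
    b = c("RC", "CP26", "S-C", "S-A", "S-B", "S-C", "S-A",
          "M-A", "M-B", "M-C", "M-A", "CP29", "CP29", "CP47", "RC"),
    stringsAsFactors = FALSE)
  inter <- data.frame(a = c("CP47", "S-C"), b = c("CP47", "CP29"),
                      stringsAsFactors = FALSE)
  list(intra = intra, inter = inter)
}

#' Small analytic fixture networks
#'
#' Canonical toy networks with closed-form first-passage properties, used
#' as oracles throughout the package:
#' \describe{
#'   \item{two_state}{one transient state escaping to a trap at
#'     0.5 ps^-1: MFPT = 2 ps, FPT density 0.5 exp(-0.5 t).}
#'   \item{chain3}{A -> B -> trap, both rates 1 ps^-1: FPT density
#'     t exp(-t) (Gamma(2, 1)), mode at 1 ps, MFPT 2 ps.}
#'   \item{dead_end}{start with a direct slow route to the trap plus a
#'     reversible dead-end detour; deleting the detour shortens the MFPT.}
#'   \item{funnel}{4-state detailed-balanced chain with decreasing energies
#'     ending at a trap.}
#'   \item{dimer_mini}{two mirror-image 2-state monomers, each with its own
#'     trap, weakly coupled.}
#'   \item{symmetric_committor}{mirror-symmetric 3-state chain with traps at
#'     both ends; from the centre each trap is hit first with probability
#'     1/2.}
#' }
#'
#' @param name fixture name.
#' @return a \code{kinetic_network}.
#' @export
toy_network <- function(name = c("two_state", "chain3", "dead_end", "funnel",
                                 "dimer_mini", "symmetric_committor")) {
  name <- match.arg(name)
  mk <- function(K, labels, subunit = labels, is_trap = NULL, energy = NA) {
    kinetic_network(K, data.frame(label = labels, subunit = subunit,
                                  monomer = 1L, energy = energy,
                                  is_trap = is_trap))
  }
  switch(name,
    two_state = {
      K <- matrix(c(0, 0.5, 0, 0), 2, 2, byrow = TRUE)
      mk(K, c("A", "trap"), is_trap = c(FALSE, TRUE))
    },
    chain3 = {
      K <- matrix(0, 3, 3)
      K[1, 2] <- 1; K[2, 3] <- 1
      mk(K, c("A", "B", "trap"), is_trap = c(FALSE, FALSE, TRUE))
    },
    dead_end = {
      # start S: slow direct route to trap (0.2 ps^-1); fast reversible
      # detour to dead-end D (2 ps^-1 each way)
      K <- matrix(0, 3, 3)
      K[1, 2] <- 2; K[2, 1] <- 2; K[1, 3] <- 0.2
      mk(K, c("S", "D", "trap"), is_trap = c(FALSE, FALSE, TRUE))
    },
    funnel = {
      e <- c(1.5, 1.0, 0.5, 0.0)
      n <- 4
      K <- matrix(0, n + 1, n + 1)
      for (i in seq_len(n - 1)) {
        B <- max(e[i], e[i + 1]) + 0.5
        K[i, i + 1] <- exp(-(B - e[i]))
        K[i + 1, i] <- exp(-(B - e[i + 1]))
      }
      K[n, n + 1] <- 1
      mk(K, c(paste0("S", 1:n), "trap"), is_trap = c(rep(FALSE, n), TRUE),
         energy = c(e, NA))
    },
    dimer_mini = {
      # per monomer: antenna A <-> core C, C -> trap; monomers coupled A1<->A2
      K <- matrix(0, 6, 6)
      lab <- c("A.m1", "C.m1", "A.m2", "C.m2", "CT1", "CT2")
      K[1, 2] <- 1; K[2, 1] <- 0.5; K[2, 5] <- 0.8
      K[3, 4] <- 1; K[4, 3] <- 0.5; K[4, 6] <- 0.8
      K[1, 3] <- 0.3; K[3, 1] <- 0.3
      kinetic_network(K, data.frame(
        label = lab, subunit = c("A", "C", "A", "C", "CT", "CT"),
        monomer = c(1L, 1L, 2L, 2L, 1L, 2L),
        is_trap = c(rep(FALSE, 4), TRUE, TRUE)))
    },
    symmetric_committor = {
      # trapL <- x <- c -> y -> trapR, mirror symmetric
      K <- matrix(0, 5, 5)
      lab <- c("x", "c", "y", "trapL", "trapR")
      K[2, 1] <- 1; K[2, 3] <- 1      # centre out
      K[1, 2] <- 0.5; K[3, 2] <- 0.5  # back to centre
      K[1, 4] <- 2; K[3, 5] <- 2      # into traps
      mk(K, lab, is_trap = c(FALSE, FALSE, FALSE, TRUE, TRUE))
    })
}
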