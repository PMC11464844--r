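#' In-silico knockout of subunit instances
#'
#' Deletes every state of the named subunits from the network (rows and
#' columns of the rate matrix removed, metadata re-indexed). Surviving
#' rates are untouched: no renormalisation is applied, exactly as in
#' "deleting the corresponding sites" from the original network.
#'
#' @param net a \code{kinetic_network}.
#' @param subunits character vector of subunit names to remove (both
#'   monomers unless restricted); empty vector returns the network
#'   unchanged.
#' @param monomer optional monomer restriction (1 or 2).
#' @return a \code{kinetic_network} with provenance in
#'   \code{attr(, "knockout")}.
#' @export
knockout <- function(net, subunits, monomer = NULL) {
  if (length(subunits) == 0) return(net)
  drop <- subunit_states(net, subunits, monomer)
  keep <- setdiff(seq_len(nrow(net$states)), drop)
  if (!any(!net$states$is_trap[keep]))
    stop("knockout removes every transient state")
  off <- off_diagonal(net)[keep, keep, drop = FALSE]
  st <- net$states[keep, , drop = FALSE]
  st$state_id <- NULL
  out <- kinetic_network(off, st, kT = net$kT)
  attr(out, "knockout") <- list(subunits = subunits, monomer = monomer,
                                removed = net$states$label[drop])
  out
}

#' Attach a phenomenological quencher sink
#'
#' Models active non-photochemical quenching by appending one absorbing
#' sink state per monomer represented in \code{host_states}, with rate
#' \code{k_capture} from each host state into its monomer's sink. Original
#' rates are untouched and sinks have no outgoing rates. Host states must
#' be transient.
#'
#' @param net a \code{kinetic_network}.
#' @param host_states state ids or labels coupled to the quencher
#'   (typically all states of one peripheral antenna subunit, both
#'   monomers).
#' @param k_capture capture rate into the sink, ps^-1.
#' @param sink_label base label for the sink states (suffixed by monomer).
#' @return a \code{kinetic_network} with the added sink state(s); their ids
#'   are in \code{attr(, "quencher")$sinks}.
#' @export
add_quencher <- function(net, host_states, k_capture, sink_label = "Q") {
  host <- state_ids(net, host_states)
  if (any(net$states$is_trap[host]))
    stop("host state(s) already absorbing: ",
         paste(net$states$label[host[net$states$is_trap[host]]], collapse = ", "))
  if (k_capture < 0) stop("k_capture must be >= 0")
  mons <- sort(unique(net$states$monomer[host]))
  n <- nrow(net$states)
  m <- length(mons)
  off <- off_diagonal(net)
  K <- rbind(cbind(off, matrix(0, n, m)), matrix(0, m, n + m))
  for (i in seq_along(mons)) {
    h <- host[net$states$monomer[host] == mons[i]]
    K[h, n + i] <- k_capture
  }
  sink_labels <- paste0(sink_label, mons)
  st <- rbind(net$states[, c("label", "subunit", "monomer", "domain_id",
                             "energy", "is_trap")],
              data.frame(label = sink_labels, subunit = sink_label,
                         monomer = mons,
                         domain_id = max(net$states$domain_id) + seq_len(m),
                         energy = NA_real_, is_trap = TRUE))
  out <- kinetic_network(K, st, kT = net$kT)
  attr(out, "quencher") <- list(sinks = n + seq_len(m),
                                sink_labels = sink_labels,
                                hosts = net$states$label[host],
                                k_capture = k_capture)
  out
}

#' Committor: probability of reaching A before B
#'
#' Splitting probability of first reaching the absorbing set A before the
#' absorbing set B, computed by a linear solve on the transient generator
#' with boundary values 1 on A and 0 on B. Absorbing states outside A and
#' B (if any) also carry committor 0 (the excitation never arrives at A).
#' When A and B together absorb all probability,
#' \code{P(A first) + P(B first) = 1}.
#'
#' @param net a \code{kinetic_network}.
#' @param p0 initial probability vector over all states, or \code{NULL} to
#'   return the full per-state committor vector.
#' @param set_A,set_B disjoint non-empty state sets (ids or labels).
#' @return p0-weighted committor (scalar), or the per-state vector when
#'   \code{p0} is \code{NULL} (1 on A, 0 on B).
#' @export
first_hit_probability <- function(net, p0, set_A, set_B) {
  A <- state_ids(net, set_A)
  B <- state_ids(net, set_B)
  if (length(A) == 0 || length(B) == 0) stop("A and B must be non-empty")
  if (length(intersect(A, B)) > 0)
    stop("A and B overlap: ",
         paste(net$states$label[intersect(A, B)], collapse = ", "))
  n <- nrow(net$states)
  other_traps <- setdiff(trap_states(net), union(A, B))
  transient <- setdiff(seq_len(n), Reduce(union, list(A, B, other_traps)))
  q <- numeric(n)
  q[A] <- 1
  if (length(transient) > 0) {
    g <- generator(net)
    off <- off_diagonal(net)
    Tc <- g[transient, transient, drop = FALSE]
    rA <- rowSums(off[transient, A, drop = FALSE])
    # states that cannot reach any absorbing state keep q = 0 (the solve
    # would otherwise be singular)
    r_any <- rowSums(off[transient, c(A, B, other_traps), drop = FALSE])
    can <- r_any > 0
    adj <- Tc; diag(adj) <- 0
    repeat {
      newly <- which(!can & rowSums(adj[, can, drop = FALSE]) > 0)
      if (length(newly) == 0) break
      can[newly] <- TRUE
    }
    if (any(can))
      q[transient[can]] <- solve(-Tc[can, can, drop = FALSE], rA[can])
  }
  if (is.null(p0)) return(stats::setNames(q, net$states$label))
  if (length(p0) != n) stop("p0 must have one entry per state")
  if (abs(sum(p0) - 1) > 1e-8) stop("p0 must sum to 1")
  sum(p0 * q)
}

#' Quenching-probability map over quencher placements
#'
#' For each candidate quencher placement (a peripheral antenna subunit,
#' quenching in both monomers at once) and each initial-excitation subunit,
#' computes the probability that the excitation reaches the quencher sinks
#' before any reaction-centre charge-transfer state. Initial excitations
#' are Boltzmann-weighted over the subunit's states in monomer 1 by
#' default, mirroring an excitation on one side of the dimer.
#'
#' @param net a \code{kinetic_network} whose traps are the RC
#'   charge-transfer states.
#' @param placements character vector of subunit names to host the
#'   quencher, one placement at a time.
#' @param initial_subunits character vector of subunits for the initial
#'   excitation.
#' @param k_capture capture rate into the sink, ps^-1 (no canonical
#'   default; always reported with the output).
#' @param initial_monomer monomer for the initial excitation (default 1).
#' @return matrix of quench probabilities, rows = initial subunits,
#'   columns = placements, with \code{attr(, "k_capture")}.
#' @export
quench_map <- function(net, placements, initial_subunits, k_capture,
                       initial_monomer = 1) {
  rc <- trap_states(net)
  if (length(rc) == 0) stop("network has no RC trap states")
  out <- matrix(NA_real_, length(initial_subunits), length(placements),
                dimnames = list(initial_subunits, placements))
  for (j in seq_along(placements)) {
    hosts <- subunit_states(net, placements[j])
    netq <- add_quencher(net, hosts, k_capture,
                         sink_label = paste0("Q:", placements[j]))
    sinks <- attr(netq, "quencher")$sinks
    rcq <- state_ids(netq, net$states$label[rc])
    for (i in seq_along(initial_subunits)) {
      p0 <- initial_distribution(netq, initial_subunits[i],
                                 monomer = initial_monomer)
      out[i, j] <- first_hit_probability(netq, p0, sinks, rcq)
    }
  }
  attr(out, "k_capture") <- k_capture
  out
}
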