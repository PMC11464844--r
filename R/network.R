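#' Labelled kinetic transition network
#'
#' Constructs the central container for a continuous-time Markov (master
#' equation) model of excitation energy transfer: a square rate matrix over
#' exciton states together with per-state metadata (subunit, monomer, domain,
#' optional site energy, trap flag).
#'
#' The stored matrix is the full generator: entry \code{(i, j)}, for
#' \code{i != j}, is the rate \code{k(i -> j)} in 1/ps from row-state to
#' column-state, and each diagonal entry is minus the row's off-diagonal sum.
#' If \code{rates} is supplied with a zero diagonal the diagonal is filled in.
#' Trap states (absorbing sinks such as reaction-centre charge-transfer
#' states, where charge separation is taken to be effectively instantaneous)
#' must have zero outgoing rate.
#'
#' @param rates square numeric matrix of rates in 1/ps; off-diagonals are
#'   \code{k(i -> j)} (row = from, column = to).
#' @param states data frame with one row per state. Recognised columns:
#'   \code{label} (required, unique), \code{subunit} (required),
#'   \code{monomer} (integer, default 1), \code{domain_id} (integer, default:
#'   one domain per subunit instance), \code{energy} (numeric, optional,
#'   in units of \code{kT}; \code{NA} allowed) and \code{is_trap} (logical,
#'   default: states with zero escape rate).
#' @param kT thermal energy in the same units as \code{states$energy}.
#'   Energies are conventionally expressed in units of kT at 298 K
#'   (about 207 cm^-1), so the default is 1.
#' @return an object of class \code{kinetic_network}.
#' @export
kinetic_network <- function(rates, states, kT = 1) {
  rates <- as.matrix(rates)
  if (nrow(rates) != ncol(rates))
    stop("rate matrix must be square, got ", nrow(rates), " x ", ncol(rates))
  n <- nrow(rates)
  states <- as.data.frame(states, stringsAsFactors = FALSE)
  if (nrow(states) != n)
    stop("state table has ", nrow(states), " rows but rate matrix has ",
         n, " states")
  if (is.null(states$label)) stop("state table needs a 'label' column")
  states$label <- as.character(states$label)
  if (anyDuplicated(states$label))
    stop("duplicated state labels: ",
         paste(unique(states$label[duplicated(states$label)]), collapse = ", "))
  if (is.null(states$subunit)) stop("state table needs a 'subunit' column")
  if (is.null(states$monomer)) states$monomer <- 1L
  states$monomer <- as.integer(states$monomer)
  if (is.null(states$domain_id))
    states$domain_id <- as.integer(factor(paste(states$subunit, states$monomer)))
  if (is.null(states$energy)) states$energy <- NA_real_
  off <- rates; diag(off) <- 0
  neg <- which(off < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    i <- neg[1, 1]; j <- neg[1, 2]
    stop(sprintf("negative rate k(%s -> %s) = %g",
                 states$label[i], states$label[j], off[i, j]))
  }
  if (is.null(states$is_trap)) states$is_trap <- rowSums(off) == 0
  states$is_trap <- as.logical(states$is_trap)
  esc <- rowSums(off)
  if (any(states$is_trap & esc > 0)) {
    k <- which(states$is_trap & esc > 0)[1]
    stop("trap state '", states$label[k], "' has nonzero escape rate ",
         esc[k], " ps^-1; traps must be absorbing")
  }
  diag(off) <- -esc
  dimnames(off) <- list(states$label, states$label)
  states$state_id <- seq_len(n)
  rownames(states) <- NULL
  structure(list(rates = off, states = states, kT = kT),
            class = "kinetic_network")
}

#' @export
print.kinetic_network <- function(x, ...) {
  n <- nrow(x$states)
  nt <- sum(x$states$is_trap)
  cat("Kinetic transition network: ", n, " states (", n - nt,
      " transient, ", nt, " absorbing), ",
      sum(off_diagonal(x) > 0), " directed transitions\n", sep = "")
  cat("Subunits:", paste(unique(x$states$subunit), collapse = ", "), "\n")
  cat("kT =", x$kT, "(energy units)\n")
  invisible(x)
}

#' @export
summary.kinetic_network <- function(object, ...) {
  off <- off_diagonal(object)
  rts <- off[off > 0]
  res <- list(
    n_states = nrow(object$states),
    n_traps = sum(object$states$is_trap),
    n_transitions = length(rts),
    rate_range = if (length(rts)) range(rts) else c(NA_real_, NA_real_),
    validation = validate_network(object)
  )
  class(res) <- "summary.kinetic_network"
  res
}

#' @export
print.summary.kinetic_network <- function(x, ...) {
  cat("Kinetic network:", x$n_states, "states,", x$n_traps, "traps,",
      x$n_transitions, "transitions\n")
  if (!is.na(x$rate_range[1]))
    cat(sprintf("Rate range: %.4g .. %.4g ps^-1\n",
                x$rate_range[1], x$rate_range[2]))
  print(x$validation)
  invisible(x)
}

# off-diagonal rates with diagonal zeroed
off_diagonal <- function(net) {
  off <- net$rates
  diag(off) <- 0
  off
}

# full generator (diagonal = -row escape rate), recomputed from off-diagonals
generator <- function(net) {
  off <- off_diagonal(net)
  diag(off) <- -rowSums(off)
  off
}

#' @rdname state_ids
#' @export
trap_states <- function(net) which(net$states$is_trap)

#' @rdname state_ids
#' @export
transient_states <- function(net) which(!net$states$is_trap)

#' Resolve states by id, label or subunit
#'
#' \code{state_ids} turns labels or indices into validated integer state
#' indices; \code{subunit_states} selects every state of a subunit
#' (optionally restricted to one monomer); \code{trap_states} and
#' \code{transient_states} partition the network into absorbing and
#' non-absorbing states.
#'
#' @param net a \code{kinetic_network}.
#' @param x integer indices or character labels.
#' @param subunit subunit name, e.g. \code{"CP43"}.
#' @param monomer optional monomer (1 or 2) to restrict to one instance.
#' @return integer vector of state indices.
#' @export
state_ids <- function(net, x) {
  if (is.character(x)) {
    idx <- match(x, net$states$label)
    if (anyNA(idx))
      stop("unknown state label(s): ", paste(x[is.na(idx)], collapse = ", "))
    return(idx)
  }
  x <- as.integer(x)
  if (any(x < 1 | x > nrow(net$states)))
    stop("state index out of range 1..", nrow(net$states))
  x
}

#' @rdname state_ids
#' @export
subunit_states <- function(net, subunit, monomer = NULL) {
  sel <- net$states$subunit %in% subunit
  if (!is.null(monomer)) sel <- sel & net$states$monomer %in% monomer
  idx <- which(sel)
  if (length(idx) == 0)
    stop("no states for subunit '", paste(subunit, collapse = ","),
         "'", if (!is.null(monomer)) paste0(" in monomer ", monomer))
  idx
}

#' Stationary distribution of the trap-free subnetwork
#'
#' Solves for the equilibrium occupation probabilities of the transient
#' (non-trap) states with all absorbing states removed, i.e. the null space
#' of the transposed generator of the closed transient subnetwork,
#' normalised to sum to one. For a detailed-balanced network built from site
#' energies \code{E_i} this is the Boltzmann distribution
#' \code{pi_i ~ exp(-E_i / kT)}.
#'
#' @param net a \code{kinetic_network}.
#' @return numeric vector named by state label, one entry per transient
#'   state, all positive, summing to 1.
#' @export
equilibrium_distribution <- function(net) {
  tr <- transient_states(net)
  if (length(tr) == 0) stop("network has no transient states")
  off <- off_diagonal(net)[tr, tr, drop = FALSE]
  comp <- strong_components(off)
  if (max(comp) > 1) {
    stop("transient subnetwork is not strongly connected (",
         max(comp), " components: sizes ",
         paste(tabulate(comp), collapse = ", "),
         "); stationary distribution is not unique")
  }
  n <- length(tr)
  if (n == 1) {
    pi <- 1
  } else {
    Q <- off
    diag(Q) <- -rowSums(Q)
    A <- t(Q)
    A[n, ] <- 1
    b <- c(rep(0, n - 1), 1)
    pi <- solve(A, b)
  }
  if (any(pi <= 0))
    stop("stationary distribution has non-positive entries; network may be ",
         "nearly reducible")
  pi <- pi / sum(pi)
  names(pi) <- net$states$label[tr]
  pi
}

# strongly connected components of the directed graph with adjacency adj > 0,
# by repeated forward/backward reachability (Kosaraju-style; n is small)
strong_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    fwd <- reach(adj, s)
    bwd <- reach(t(adj), s)
    comp[fwd & bwd & comp == 0L] <- cur
  }
  comp
}

# states reachable from s along edges adj > 0 (including s)
reach <- function(adj, s) {
  n <- nrow(adj)
  seen <- logical(n)
  seen[s] <- TRUE
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE] > 0) > 0)
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen
}

#' Structural and numerical diagnostics for a kinetic network
#'
#' Pure diagnostic pass over a network: generator row-sum conservation,
#' negative rates, detailed-balance residual against the equilibrium
#' distribution, weak connectivity, and reachability of the absorbing traps
#' from each transient state. Nothing is mutated.
#'
#' The detailed-balance residual is the maximum over connected pairs of
#' \code{|pi_i k(i->j) - pi_j k(j->i)|} relative to the larger of the two
#' fluxes. Averaged rate matrices (e.g. over inhomogeneous realisations) may
#' carry a small residual; it is reported, not fatal.
#'
#' @param net a \code{kinetic_network}.
#' @param tol tolerance for flagging row-sum violations (must be > 0).
#' @return object of class \code{network_validation} with fields
#'   \code{row_sum_max_error}, \code{row_sum_flagged},
#'   \code{negative_rate_count}, \code{db_residual},
#'   \code{connected_components} (list of state-id vectors) and
#'   \code{traps_reachable_from} (transient states from which at least one
#'   trap is reachable).
#' @export
validate_network <- function(net, tol = 1e-8) {
  stopifnot(tol > 0)
  n <- nrow(net$states)
  if (n == 0) stop("empty network")
  off <- net$rates
  diag(off) <- 0
  row_err <- max(abs(rowSums(net$rates)))
  neg <- sum(off < 0)

  sym <- (off + t(off)) > 0
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    comp[reach(sym * 1, s) & comp == 0L] <- cur
  }
  components <- split(seq_len(n), comp)

  db <- NA_real_
  pi_full <- rep(NA_real_, n)
  tr <- transient_states(net)
  pi_try <- try(equilibrium_distribution(net), silent = TRUE)
  if (!inherits(pi_try, "try-error")) {
    pi_full[tr] <- pi_try
    db <- 0
    offt <- pmax(off, 0)
    for (i in tr) for (j in tr) {
      if (j <= i) next
      f1 <- pi_full[i] * offt[i, j]; f2 <- pi_full[j] * offt[j, i]
      m <- max(f1, f2)
      if (m > 0) db <- max(db, abs(f1 - f2) / m)
    }
  }

  traps <- trap_states(net)
  reach_ok <- integer(0)
  if (length(traps) > 0) {
    # transient states that can reach >= 1 trap: backward reachability
    back <- logical(n)
    radj <- t(off)
    for (tp in traps) back <- back | reach(radj, tp)
    reach_ok <- intersect(which(back), tr)
  }

  structure(list(
    row_sum_max_error = row_err,
    row_sum_flagged = row_err > tol,
    negative_rate_count = neg,
    db_residual = db,
    connected_components = components,
    traps_reachable_from = reach_ok,
    tol = tol
  ), class = "network_validation")
}

#' @export
print.network_validation <- function(x, ...) {
  cat("Network validation\n")
  cat(sprintf("  row-sum max error : %.3g%s\n", x$row_sum_max_error,
              if (x$row_sum_flagged) "  ** exceeds tol **" else ""))
  cat("  negative rates    :", x$negative_rate_count, "\n")
  cat(sprintf("  detailed-balance residual : %.3g\n", x$db_residual))
  cat("  connected components      :", length(x$connected_components), "\n")
  cat("  transient states reaching a trap :",
      length(x$traps_reachable_from), "\n")
  invisible(x)
}

#' Read / write a kinetic network as delimited text
#'
#' The rate matrix file is square delimited text (comma or tab, inferred
#' from the extension: \code{.tsv}/\code{.tab} means tab) with a header row
#' of state labels and the same labels in the first column; entry (i, j) is
#' the rate from row-state i to column-state j in 1/ps, with the diagonal
#' carrying the negative row sum (a zero diagonal is also accepted). The
#' state metadata file has columns \code{state_label}, \code{subunit},
#' \code{monomer}, \code{domain_id}, \code{energy} (may be blank) and
#' \code{is_trap}. State ordering follows the metadata file.
#'
#' @param matrix_path path to the rate-matrix file.
#' @param states_path path to the state-metadata file.
#' @param kT thermal energy, passed to \code{\link{kinetic_network}}.
#' @return a \code{kinetic_network}.
#' @export
read_network <- function(matrix_path, states_path, kT = 1) {
  sep <- delim_for(matrix_path)
  raw <- utils::read.table(matrix_path, header = TRUE, sep = sep,
                           row.names = 1, check.names = FALSE,
                           colClasses = "character")
  m <- as.matrix(raw)
  num <- suppressWarnings(array(as.numeric(m), dim(m), dimnames(m)))
  bad <- which(is.na(num) & !(m %in% c("", "NA")), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("unparseable numeric field '%s' at (%s, %s) in %s",
                 m[bad[1, 1], bad[1, 2]], rownames(m)[bad[1, 1]],
                 colnames(m)[bad[1, 2]], matrix_path))
  num[is.na(num)] <- 0  # missing entries are zero rate
  if (nrow(num) != ncol(num))
    stop("rate matrix in ", matrix_path, " is not square: ",
         nrow(num), " x ", ncol(num))
  if (!identical(rownames(num), colnames(num)))
    stop("row and column labels disagree in ", matrix_path)

  st <- utils::read.table(states_path, header = TRUE, sep = delim_for(states_path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(st$state_label))
    stop("state metadata ", states_path, " needs a 'state_label' column")
  if (!setequal(st$state_label, rownames(num)) ||
      nrow(st) != nrow(num))
    stop("state labels in ", states_path, " do not match matrix labels in ",
         matrix_path)
  ord <- st$state_label
  num <- num[ord, ord, drop = FALSE]
  states <- data.frame(label = st$state_label,
                       subunit = st$subunit,
                       monomer = if (is.null(st$monomer)) 1L else st$monomer,
                       stringsAsFactors = FALSE)
  if (!is.null(st$domain_id)) states$domain_id <- as.integer(st$domain_id)
  if (!is.null(st$energy)) states$energy <- as.numeric(st$energy)
  if (!is.null(st$is_trap))
    states$is_trap <- as.logical(st$is_trap) |
      tolower(as.character(st$is_trap)) %in% c("true", "1", "yes")
  kinetic_network(num, states, kT = kT)
}

delim_for <- function(path) {
  if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
}

#' @rdname read_network
#' @param net a \code{kinetic_network} to write.
#' @export
write_network <- function(net, matrix_path, states_path) {
  sep <- delim_for(matrix_path)
  g <- generator(net)
  lab <- net$states$label
  lines <- c(paste(c("", lab), collapse = sep),
             vapply(seq_along(lab), function(i)
               paste(c(lab[i], sprintf("%.17g", g[i, ])), collapse = sep),
               character(1)))
  writeLines(lines, matrix_path)
  st <- net$states
  out <- data.frame(state_label = st$label, subunit = st$subunit,
                    monomer = st$monomer, domain_id = st$domain_id,
                    energy = ifelse(is.na(st$energy), "",
                                    sprintf("%.17g", st$energy)),
                    is_trap = st$is_trap)
  utils::write.table(out, states_path, sep = delim_for(states_path),
                     row.names = FALSE, quote = FALSE)
  invisible(net)
}

#' Initial excitation distribution over a subunit
#'
#' Builds a probability vector over all states for an initial excitation
#' "located in" a subunit. The default spreads the excitation over the
#' subunit's transient states with Boltzmann weights at temperature
#' \code{kT} (uniform if the network carries no energies); alternatives are
#' a uniform spread or a point mass on one state.
#'
#' @param net a \code{kinetic_network}.
#' @param subunit subunit name(s); ignored when \code{state} is given.
#' @param monomer optional monomer restriction.
#' @param kind one of \code{"boltzmann"}, \code{"uniform"}.
#' @param state optional single state (id or label) for a point mass.
#' @param kT thermal energy; defaults to the network's.
#' @return numeric vector of length \code{n_states}, summing to 1, supported
#'   on transient states.
#' @export
initial_distribution <- function(net, subunit = NULL, monomer = NULL,
                                 kind = c("boltzmann", "uniform"),
                                 state = NULL, kT = net$kT) {
  n <- nrow(net$states)
  p0 <- numeric(n)
  if (!is.null(state)) {
    i <- state_ids(net, state)
    stopifnot(length(i) == 1)
    if (net$states$is_trap[i]) stop("initial state is a trap")
    p0[i] <- 1
    return(p0)
  }
  kind <- match.arg(kind)
  idx <- subunit_states(net, subunit, monomer)
  idx <- idx[!net$states$is_trap[idx]]
  if (length(idx) == 0) stop("subunit has no transient states")
  if (kind == "boltzmann" && !anyNA(net$states$energy[idx])) {
    e <- net$states$energy[idx]
    w <- exp(-(e - min(e)) / kT)
  } else {
    w <- rep(1, length(idx))
  }
  p0[idx] <- w / sum(w)
  p0
}
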