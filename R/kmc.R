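#' Simulate a single kinetic Monte Carlo trajectory
#'
#' Rejection-free continuous-time Markov simulation of one excitation:
#' waiting times are exponential with the state's total escape rate and the
#' successor is drawn proportionally to the outgoing rates, until the
#' trajectory enters the target set, is absorbed by a competing trap, or
#' exceeds \code{max_time} (censored). Each trajectory uses its own RNG
#' stream derived from \code{(seed, traj_index)}, so a given pair always
#' reproduces the identical visit sequence.
#'
#' @param net a \code{kinetic_network}.
#' @param start starting state (id or label).
#' @param targets target state ids or labels (termination set).
#' @param seed integer master seed.
#' @param traj_index index selecting the per-trajectory stream.
#' @param max_time censoring horizon in ps.
#' @return object of class \code{kmc_trajectory}: data frame \code{visits}
#'   (state, label, dwell_ps), \code{terminal_state}, \code{fpt},
#'   \code{censored}, \code{seed}, \code{draws}.
#' @export
simulate_trajectory <- function(net, start, targets, seed = 1,
                                traj_index = 1, max_time = 1e6) {
  stopifnot(max_time > 0)
  start <- state_ids(net, start)
  stopifnot(length(start) == 1)
  targets <- state_ids(net, targets)
  esc <- -diag(generator(net))
  if (esc[start] <= 0 && !(start %in% targets) && !net$states$is_trap[start])
    stop("start state '", net$states$label[start],
         "' has zero escape rate but is not a declared trap or target")
  is_target <- seq_len(nrow(net$states)) %in% targets
  res <- kmc_trajectory(off_diagonal(net), start, is_target, max_time,
                        as.double(seed), as.integer(traj_index))
  visits <- data.frame(state = res$states,
                       label = net$states$label[res$states],
                       dwell_ps = res$dwells)
  structure(list(visits = visits,
                 terminal_state = res$terminal,
                 fpt = res$fpt,
                 censored = res$censored,
                 reached_target = !res$censored && res$terminal %in% targets,
                 seed = c(seed = as.integer(seed), traj_index = as.integer(traj_index)),
                 draws = res$draws),
            class = "kmc_trajectory")
}

#' @export
print.kmc_trajectory <- function(x, ...) {
  cat("kMC trajectory: ", nrow(x$visits), " visits, FPT = ",
      format(x$fpt), " ps, terminal state ", x$terminal_state,
      if (x$censored) " (censored)" else "", "\n", sep = "")
  invisible(x)
}

#' Sample first-passage times by kinetic Monte Carlo
#'
#' Runs \code{n_traj} independent trajectories with initial states drawn
#' from \code{p0} and returns the first-passage samples together with
#' per-trajectory dwell times aggregated at the requested level. Censored
#' trajectories (horizon exceeded) and trajectories absorbed by competing
#' traps outside \code{targets} are counted and excluded from the FPT
#' sample.
#'
#' @param net a \code{kinetic_network}.
#' @param p0 initial probability vector over all states.
#' @param targets target state ids or labels.
#' @param n_traj number of trajectories.
#' @param seed integer master seed (one RNG stream per trajectory).
#' @param max_time censoring horizon in ps.
#' @param record dwell aggregation: \code{"subunit"} (per subunit instance,
#'   i.e. subunit x monomer), \code{"state"}, or \code{"none"}.
#' @return object of class \code{fpt_sample}: \code{fpt} (per trajectory),
#'   \code{reached} (logical: absorbed in targets), \code{censored},
#'   \code{terminal}, \code{dwell} (matrix n_traj x groups or NULL),
#'   \code{groups} (data frame describing dwell columns), \code{seed}.
#' @export
sample_fpt <- function(net, p0, targets, n_traj, seed = 1, max_time = 1e6,
                       record = c("subunit", "state", "none")) {
  stopifnot(n_traj >= 1, max_time > 0)
  record <- match.arg(record)
  targets <- state_ids(net, targets)
  ab <- make_absorbing(net, targets)   # validates p0 support below
  check_p0(net, p0, ab)
  n <- nrow(net$states)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  starts <- sample.int(n, n_traj, replace = TRUE, prob = p0)

  if (record == "subunit") {
    key <- paste(net$states$subunit, net$states$monomer, sep = ".m")
    groups <- data.frame(group = unique(key))
    gid <- match(key, groups$group)
    groups$subunit <- net$states$subunit[match(groups$group, key)]
    groups$monomer <- net$states$monomer[match(groups$group, key)]
    n_groups <- nrow(groups)
  } else if (record == "state") {
    gid <- seq_len(n)
    groups <- data.frame(group = net$states$label,
                         subunit = net$states$subunit,
                         monomer = net$states$monomer)
    n_groups <- n
  } else {
    gid <- integer(n); groups <- NULL; n_groups <- 0L
  }

  is_target <- seq_len(n) %in% targets
  res <- kmc_batch(off_diagonal(net), starts, is_target, max_time,
                   as.double(seed), as.integer(gid), as.integer(n_groups))
  reached <- !res$censored & res$terminal %in% targets
  dw <- if (n_groups > 0) res$dwell else NULL
  if (!is.null(dw)) colnames(dw) <- groups$group
  structure(list(fpt = res$fpt, reached = reached,
                 censored = res$censored, terminal = res$terminal,
                 steps = res$steps, dwell = dw, groups = groups,
                 starts = starts, targets = targets,
                 seed = as.integer(seed), max_time = max_time,
                 labels = net$states$label),
            class = "fpt_sample")
}

#' @export
print.fpt_sample <- function(x, ...) {
  n <- length(x$fpt)
  cat("kMC first-passage sample: ", n, " trajectories (",
      sum(x$reached), " reached targets, ", sum(x$censored),
      " censored)\n", sep = "")
  if (any(x$reached)) {
    q <- stats::quantile(x$fpt[x$reached], c(0.01, 0.5, 0.99))
    cat(sprintf("  FPT quantiles 1/50/99%%: %.3g / %.3g / %.3g ps\n",
                q[1], q[2], q[3]))
    cat(sprintf("  mean FPT: %.6g ps\n", mean(x$fpt[x$reached])))
  }
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Long-run state occupation fractions by kinetic Monte Carlo
#'
#' Simulates trajectories of fixed duration on a trapless (reflecting)
#' network, starting from the equilibrium distribution unless \code{p0} is
#' given, and returns per-trajectory occupation fractions of each state.
#' On an ergodic network the column means converge to the equilibrium
#' distribution, which makes this a Monte Carlo parameter-recovery check
#' for the energies underlying a generated landscape.
#'
#' @param net a \code{kinetic_network} without absorbing states (e.g. a
#'   generated network with its charge-transfer sinks knocked out).
#' @param t_total trajectory duration in ps.
#' @param n_traj number of independent trajectories.
#' @param seed integer master seed.
#' @param p0 optional initial distribution; default equilibrium.
#' @return matrix (n_traj x n_states) of occupation fractions; columns
#'   named by state label.
#' @export
sample_occupation <- function(net, t_total, n_traj, seed = 1, p0 = NULL) {
  if (length(trap_states(net)) > 0)
    stop("network has absorbing states; occupation fractions require a ",
         "reflecting (trapless) network")
  n <- nrow(net$states)
  if (is.null(p0)) {
    p0 <- numeric(n)
    p0[transient_states(net)] <- equilibrium_distribution(net)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  starts <- sample.int(n, n_traj, replace = TRUE, prob = p0)
  res <- kmc_batch(off_diagonal(net), starts, rep(FALSE, n), t_total,
                   as.double(seed), seq_len(n), n)
  occ <- res$dwell / rowSums(res$dwell)
  colnames(occ) <- net$states$label
  occ
}

#' First-passage samples that reached the targets
#'
#' @param x an \code{fpt_sample}.
#' @return numeric vector of uncensored FPTs (ps).
#' @export
fpt_samples <- function(x) {
  stopifnot(inherits(x, "fpt_sample"))
  x$fpt[x$reached]
}

#' Write trajectories and FPT samples as delimited text
#'
#' Streams a set of trajectories to a long-format file
#' (trajectory_id, step, state_label, dwell_ps) and an \code{fpt_sample}
#' to a single-column CSV plus a key-value sidecar (seed, n, censoring).
#'
#' @param x an \code{fpt_sample} or list of \code{kmc_trajectory}.
#' @param path output file path.
#' @export
write_fpt_samples <- function(x, path) {
  stopifnot(inherits(x, "fpt_sample"))
  utils::write.table(data.frame(fpt_ps = fpt_samples(x)), path,
                     sep = ",", row.names = FALSE, quote = FALSE)
  side <- sub("(\\.[^.]+)?$", ".meta.txt", path)
  writeLines(c(paste0("seed: ", x$seed),
               paste0("n_traj: ", length(x$fpt)),
               paste0("n_reached: ", sum(x$reached)),
               paste0("n_censored: ", sum(x$censored)),
               paste0("max_time_ps: ", x$max_time)), side)
  invisible(path)
}

#' @rdname write_fpt_samples
#' @param trajectories list of \code{kmc_trajectory} objects.
#' @export
write_trajectories <- function(trajectories, path) {
  rows <- lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    if (nrow(tr$visits) == 0) return(NULL)
    data.frame(trajectory_id = i, step = seq_len(nrow(tr$visits)),
               state_label = tr$visits$label, dwell_ps = tr$visits$dwell_ps)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
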