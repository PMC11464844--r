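#' Substochastic transient generator for a target set
#'
#' Restricts the master-equation generator to the transient states, treating
#' the given target set as absorbing (escape rates out of targets are
#' irrelevant and dropped). States that are traps but not targets remain
#' absorbing competitors: probability reaching them never arrives at the
#' targets. Returns the transient generator \code{T} (diagonal includes the
#' full escape rate, so \code{T} is substochastic), the per-state flux into
#' the targets, and the index maps.
#'
#' @param net a \code{kinetic_network}.
#' @param targets state ids or labels of the absorbing target set.
#' @return list with \code{T} (transient generator), \code{flux} (rate from
#'   each transient state directly into the targets), \code{transient}
#'   (state ids), \code{targets} (state ids).
#' @export
make_absorbing <- function(net, targets) {
  targets <- state_ids(net, targets)
  if (length(targets) == 0) stop("target set is empty")
  n <- nrow(net$states)
  absorbing <- union(targets, trap_states(net))
  transient <- setdiff(seq_len(n), absorbing)
  if (length(transient) == 0)
    stop("target set plus traps covers all states; no transient states left")
  g <- generator(net)
  list(T = g[transient, transient, drop = FALSE],
       flux = rowSums(off_diagonal(net)[transient, targets, drop = FALSE]),
       transient = transient,
       targets = targets)
}

# spectral pieces for an initial distribution p0 (full-length): amplitudes
# c_k with f(t) = sum_k c_k exp(lambda_k t). Returns NULL if the eigenvector
# matrix is too ill-conditioned (defective generator), signalling the dense
# fallback path.
spectral_components <- function(ab, p0) {
  Tm <- ab$T
  eg <- eigen(Tm)
  V <- eg$vectors
  Vinv <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vinv)) return(NULL)
  inorm <- function(M) max(rowSums(Mod(M)))
  rc <- 1 / (inorm(V) * inorm(Vinv))
  if (!is.finite(rc) || rc < 1e-12) return(NULL)
  p <- p0[ab$transient]
  c_k <- as.vector(p %*% V) * as.vector(Vinv %*% ab$flux)
  list(lambda = eg$values, c_k = c_k)
}

# absorption probability b and conditional-mean numerator u = (-T)^-1 b by
# linear solve, restricted to the transient states that can actually reach
# the targets (the full system is singular when some states cannot)
absorb_solve <- function(ab) {
  n <- nrow(ab$T)
  adj <- ab$T; diag(adj) <- 0
  can <- ab$flux > 0
  repeat {
    newly <- which(!can & rowSums(adj[, can, drop = FALSE]) > 0)
    if (length(newly) == 0) break
    can[newly] <- TRUE
  }
  b <- numeric(n); u <- numeric(n)
  if (any(can)) {
    Tc <- ab$T[can, can, drop = FALSE]
    b[can] <- solve(-Tc, ab$flux[can])
    u[can] <- solve(-Tc, b[can])
  }
  list(b = b, u = u, can = can)
}

check_p0 <- function(net, p0, ab) {
  if (length(p0) != nrow(net$states))
    stop("p0 must have one entry per state (", nrow(net$states), ")")
  if (any(p0 < 0)) stop("p0 has negative entries")
  if (abs(sum(p0) - 1) > 1e-8) stop("p0 must sum to 1, got ", sum(p0))
  off_support <- sum(p0[-ab$transient])
  if (off_support > 1e-12)
    stop("p0 places mass ", off_support, " outside the transient states")
  invisible(TRUE)
}

#' Default logarithmic time grid
#'
#' Log-spaced grid covering the full span of first-passage timescales in a
#' flat antenna landscape (sub-picosecond direct transfer to the
#' multi-hundred-ps peripheral detours).
#'
#' @param from,to grid limits in ps.
#' @param n number of points.
#' @export
fpt_time_grid <- function(from = 1e-2, to = 1e4, n = 400) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Analytic first-passage-time distribution
#'
#' Computes the distribution of the time for an excitation started from
#' \code{p0} to first reach the target set, from the eigendecomposition of
#' the substochastic transient generator: the density is
#' \code{f(t) = sum_k c_k exp(lambda_k t)} with all \code{Re(lambda_k) < 0}.
#' Complex conjugate eigenpairs combine to a real density; a residual
#' imaginary part above \code{1e-8} of the density scale is an error. For
#' defective (non-diagonalisable) generators, e.g. an irreversible chain
#' with equal rates, the density falls back to a dense matrix-exponential
#' evaluation and moments to linear solves.
#'
#' When part of the probability is absorbed elsewhere (competing traps),
#' \code{absorption_probability < 1} and the reported \code{mfpt} is
#' conditional on reaching the targets.
#'
#' @param net a \code{kinetic_network}.
#' @param p0 initial probability vector over all states (see
#'   \code{\link{initial_distribution}}).
#' @param targets target state ids or labels.
#' @param time_grid evaluation grid in ps.
#' @return object of class \code{fpt_distribution} with fields \code{time},
#'   \code{density}, \code{eigenvalues}, \code{amplitudes},
#'   \code{absorption_probability}, \code{mfpt}, \code{method}.
#' @export
fpt_distribution <- function(net, p0, targets, time_grid = fpt_time_grid()) {
  ab <- make_absorbing(net, targets)
  check_p0(net, p0, ab)
  sp <- spectral_components(ab, p0)
  p <- p0[ab$transient]

  # absorption probability and conditional MFPT by direct linear solve
  sol <- absorb_solve(ab)
  absp <- sum(p * sol$b)
  m1 <- if (absp > 1e-12) sum(p * sol$u) / absp else Inf

  if (!is.null(sp)) {
    E <- exp(outer(time_grid, sp$lambda))
    dens <- as.vector(E %*% sp$c_k)
    scale <- max(abs(dens), 1e-300)
    if (max(abs(Im(dens))) > 1e-8 * scale)
      stop("imaginary residue ", max(abs(Im(dens))),
           " in FPT density exceeds tolerance")
    dens <- Re(dens)
    method <- "spectral"
  } else {
    dens <- vapply(time_grid, function(t)
      sum(p * (expm_dense(ab$T * t) %*% ab$flux)), numeric(1))
    sp <- list(lambda = eigen(ab$T, only.values = TRUE)$values,
               c_k = rep(NA_real_, length(ab$transient)))
    method <- "dense"
  }
  dens[dens < 0 & dens > -1e-12 * max(abs(dens))] <- 0
  structure(list(time = time_grid, density = dens,
                 eigenvalues = sp$lambda, amplitudes = sp$c_k,
                 absorption_probability = absp, mfpt = m1,
                 method = method, p0 = p, flux = ab$flux, T = ab$T, b = sol$b,
                 transient = ab$transient, targets = ab$targets),
            class = "fpt_distribution")
}

# matrix exponential by scaling and squaring with a Pade-free Taylor core;
# adequate for the small dense generators used here
expm_dense <- function(A) {
  n <- nrow(A)
  nrm <- max(rowSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  As <- A / 2^s
  E <- diag(n); term <- diag(n)
  for (k in 1:30) {
    term <- term %*% As / k
    E <- E + term
    if (max(abs(term)) < 1e-18) break
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

#' @export
print.fpt_distribution <- function(x, ...) {
  cat("First-passage-time distribution (", x$method, " method)\n", sep = "")
  cat(sprintf("  absorption probability : %.6f\n", x$absorption_probability))
  cat(sprintf("  MFPT                   : %.6g ps\n", x$mfpt))
  cat(sprintf("  slowest eigenvalue     : %.6g ps^-1\n",
              max(Re(x$eigenvalues))))
  cat("  grid: ", length(x$time), " points, ",
      format(min(x$time)), " .. ", format(max(x$time)), " ps\n", sep = "")
  invisible(x)
}

#' @export
plot.fpt_distribution <- function(x, ..., log = "x") {
  graphics::plot(x$time, x$density, type = "l", log = log,
                 xlab = "first passage time (ps)",
                 ylab = expression(f(t) ~ (ps^-1)), ...)
  invisible(x)
}

#' Analytic first-passage CDF
#'
#' Cumulative probability of having reached the targets by time \code{t},
#' conditional on absorption in the targets (so it tends to 1), matching
#' the empirical CDF of first-passage samples.
#'
#' @param fd an \code{fpt_distribution}.
#' @param t times (ps).
#' @export
fpt_cdf <- function(fd, t) {
  if (fd$method == "spectral" && !anyNA(fd$amplitudes)) {
    cdf <- vapply(t, function(tt)
      Re(sum(fd$amplitudes / (-fd$eigenvalues) *
               (1 - exp(fd$eigenvalues * tt)))), numeric(1))
    return(cdf / fd$absorption_probability)
  }
  # dense fallback: F(t) = p' (I - e^{Tt}) (-T)^{-1} r
  v <- vapply(t, function(tt)
    sum(fd$p0 * (fd$b - expm_dense(fd$T * tt) %*% fd$b)), numeric(1))
  v / fd$absorption_probability
}

#' Mean first passage time
#'
#' Mean time to first reach the target set, by either of two independent
#' algorithms: \code{"spectral"} assembles the first moment from the
#' eigendecomposition of the transient generator; \code{"linear_solve"}
#' solves the transposed-generator linear system directly (the standard
#' absorbing-Markov-chain route) and serves as the independent oracle.
#' With competing absorbing states the value is conditional on absorption
#' in \code{targets}; unreachable targets give \code{Inf}.
#'
#' @param net a \code{kinetic_network}.
#' @param p0 initial probability vector over all states.
#' @param targets target state ids or labels.
#' @param method \code{"spectral"} or \code{"linear_solve"}.
#' @return time in ps (possibly \code{Inf}).
#' @export
mfpt <- function(net, p0, targets, method = c("linear_solve", "spectral")) {
  method <- match.arg(method)
  ab <- make_absorbing(net, targets)
  check_p0(net, p0, ab)
  p <- p0[ab$transient]
  if (method == "linear_solve") {
    sol <- absorb_solve(ab)
    absp <- sum(p * sol$b)
    if (absp < 1e-12) return(Inf)
    return(sum(p * sol$u) / absp)
  }
  sp <- spectral_components(ab, p0)
  if (is.null(sp) || any(Mod(sp$lambda) < 1e-14)) {
    # defective or singular generator: fall back to the solve route
    sol <- absorb_solve(ab)
    absp <- sum(p * sol$b)
    if (absp < 1e-12) return(Inf)
    return(sum(p * sol$u) / absp)
  }
  absp <- Re(sum(-sp$c_k / sp$lambda))
  if (absp < 1e-12) return(Inf)
  Re(sum(sp$c_k / sp$lambda^2)) / absp
}

#' Raw moments of the first-passage time
#'
#' n-th raw moment of the FPT to the targets, conditional on absorption
#' there. Computed spectrally when the transient generator is
#' diagonalisable (moment n = n! sum_k c_k / (-lambda_k)^(n+1), divided by
#' the absorption probability), otherwise by repeated linear solves.
#'
#' @inheritParams mfpt
#' @param order moment order, integer >= 1.
#' @param method computation route.
#' @return scalar moment in ps^order.
#' @export
fpt_moments <- function(net, p0, targets, order = 1,
                        method = c("spectral", "linear_solve")) {
  if (order < 1 || order != round(order)) stop("order must be an integer >= 1")
  method <- match.arg(method)
  ab <- make_absorbing(net, targets)
  check_p0(net, p0, ab)
  p <- p0[ab$transient]
  sp <- if (method == "spectral") spectral_components(ab, p0) else NULL
  if (!is.null(sp) && all(Mod(sp$lambda) > 1e-14)) {
    absp <- Re(sum(-sp$c_k / sp$lambda))
    if (absp < 1e-12) return(Inf)
    return(Re(sum(factorial(order) * sp$c_k / (-sp$lambda)^(order + 1))) / absp)
  }
  sol <- absorb_solve(ab)
  absp <- sum(p * sol$b)
  if (absp < 1e-12) return(Inf)
  v <- sol$b
  Tc <- ab$T[sol$can, sol$can, drop = FALSE]
  for (k in seq_len(order)) v[sol$can] <- solve(-Tc, v[sol$can])
  factorial(order) * sum(p * v) / absp
}
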