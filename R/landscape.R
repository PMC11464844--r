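#' Effective free energies of network states
#'
#' Translates equilibrium occupation probabilities into effective state
#' free energies, \code{F_i = -kT log(pi_i)}, shifted so the minimum is
#' exactly 0. For a detailed-balanced network generated from site energies
#' this recovers those energies up to an additive constant.
#'
#' @param x a \code{kinetic_network} (equilibrium computed over the
#'   trap-free transient subnetwork) or a probability vector.
#' @param kT thermal energy.
#' @return named numeric vector of free energies, min 0.
#' @export
state_free_energies <- function(x, kT = 1) {
  pi <- if (inherits(x, "kinetic_network")) equilibrium_distribution(x) else x
  if (any(pi <= 0)) stop("zero or negative probability state; free energy undefined")
  f <- -kT * log(pi)
  f - min(f)
}

#' Transition-state free energies reproducing the rates
#'
#' For each connected pair of transient states the transition-state free
#' energy is defined so the rate is recovered from the barrier:
#' \code{k(i -> j) = nu * exp(-(F_ts - F_i) / kT)}, i.e.
#' \code{F_ts(i, j) = F_i + kT log(nu / k(i -> j))}. Under detailed balance
#' the two directions give the same value; the stored \code{F_ts} is their
#' mean and the maximum directional disagreement is reported as
#' \code{asymmetry_residual} (rate matrices averaged over inhomogeneous
#' realisations may carry a mild asymmetry).
#'
#' @param net a \code{kinetic_network}.
#' @param F_state per-transient-state free energies (default: from the
#'   equilibrium distribution).
#' @param kT thermal energy.
#' @param nu attempt prefactor in ps^-1; shifts all F_ts uniformly and
#'   cancels in the rate round trip.
#' @param strict if \code{TRUE}, fail when \code{asymmetry_residual}
#'   exceeds \code{strict_tol}.
#' @param strict_tol threshold for strict mode.
#' @return data frame with columns \code{i}, \code{j} (transient state
#'   ids), \code{label_i}, \code{label_j}, \code{F_ts}, \code{asymmetry};
#'   attribute \code{asymmetry_residual}.
#' @export
ts_free_energies <- function(net, F_state = state_free_energies(net, kT),
                             kT = 1, nu = 1, strict = FALSE,
                             strict_tol = 1e-6) {
  tr <- transient_states(net)
  off <- off_diagonal(net)[tr, tr, drop = FALSE]
  n <- length(tr)
  rows <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    kij <- off[i, j]; kji <- off[j, i]
    if (kij == 0 && kji == 0) next
    if (kij == 0 || kji == 0)
      stop(sprintf("one-way edge between '%s' and '%s': zero rate in one %s",
                   names(F_state)[i], names(F_state)[j],
                   "direction; free-energy translation undefined"))
    f1 <- F_state[i] + kT * log(nu / kij)
    f2 <- F_state[j] + kT * log(nu / kji)
    rows[[length(rows) + 1]] <- data.frame(
      i = i, j = j, label_i = names(F_state)[i], label_j = names(F_state)[j],
      F_ts = (f1 + f2) / 2, asymmetry = abs(f1 - f2))
  }
  edges <- do.call(rbind, rows)
  rownames(edges) <- NULL
  resid <- if (is.null(edges)) 0 else max(edges$asymmetry)
  if (strict && resid > strict_tol)
    stop("transition-state asymmetry residual ", resid,
         " exceeds strict tolerance ", strict_tol)
  attr(edges, "asymmetry_residual") <- resid
  edges
}

#' Free-energy landscape of a kinetic network
#'
#' Bundles the state free energies (reproducing the equilibrium
#' distribution) and the transition-state free energies (reproducing the
#' rates) into one object, the exact free-energy representation of the
#' network.
#'
#' @inheritParams ts_free_energies
#' @return object of class \code{free_energy_landscape} with fields
#'   \code{F_state}, \code{edges}, \code{kT}, \code{nu},
#'   \code{asymmetry_residual}.
#' @export
free_energy_landscape <- function(net, kT = 1, nu = 1, strict = FALSE) {
  F_state <- state_free_energies(net, kT)
  edges <- ts_free_energies(net, F_state, kT = kT, nu = nu, strict = strict)
  structure(list(F_state = F_state, edges = edges, kT = kT, nu = nu,
                 asymmetry_residual = attr(edges, "asymmetry_residual"),
                 labels = names(F_state)),
            class = "free_energy_landscape")
}

#' @export
print.free_energy_landscape <- function(x, ...) {
  cat("Free-energy landscape: ", length(x$F_state), " states, ",
      nrow(x$edges), " transition states\n", sep = "")
  cat(sprintf("  F_state range: 0 .. %.4g kT units\n", max(x$F_state)))
  cat(sprintf("  F_ts range   : %.4g .. %.4g\n",
              min(x$edges$F_ts), max(x$edges$F_ts)))
  cat(sprintf("  asymmetry residual: %.3g (nu = %g ps^-1)\n",
              x$asymmetry_residual, x$nu))
  invisible(x)
}

#' Reconstruct the rate matrix from a free-energy landscape
#'
#' Inverts the defining barrier relation,
#' \code{k(i -> j) = nu * exp(-(F_ts(i,j) - F_i) / kT)}; on a
#' detailed-balanced network this is the exact inverse of
#' \code{\link{free_energy_landscape}} (round trip is the identity).
#'
#' @param fel a \code{free_energy_landscape}.
#' @return matrix of off-diagonal rates over the transient states.
#' @export
reconstruct_rates <- function(fel) {
  n <- length(fel$F_state)
  K <- matrix(0, n, n, dimnames = list(fel$labels, fel$labels))
  for (r in seq_len(nrow(fel$edges))) {
    i <- fel$edges$i[r]; j <- fel$edges$j[r]; fts <- fel$edges$F_ts[r]
    K[i, j] <- fel$nu * exp(-(fts - fel$F_state[i]) / fel$kT)
    K[j, i] <- fel$nu * exp(-(fts - fel$F_state[j]) / fel$kT)
  }
  K
}

#' Free-energy disconnectivity tree
#'
#' Builds the disconnectivity graph of the landscape: leaves are states at
#' their free energies; sweeping a free-energy threshold upward over a
#' regular level grid, states merge (union-find over edges with
#' \code{F_ts <= threshold}) when the threshold reaches the highest
#' transition state on the lowest-energy path connecting them. Merge
#' heights are therefore the minimax path barriers, quantised to the level
#' grid (a transition state falling exactly on a level merges at that
#' level), and the merge structure is ultrametric.
#'
#' @param fel a \code{free_energy_landscape}.
#' @param levels either a numeric vector of thresholds, or a list
#'   \code{list(first =, spacing =, count =)}; default: 60 levels spanning
#'   \code{[min F_state, max F_ts]}.
#' @return object of class \code{disconnectivity_tree}: \code{heights}
#'   (per node; first n = leaves at F_state), \code{parent} (node index of
#'   each node's parent, 0 at the root), \code{children} (list per node),
#'   \code{labels}, \code{levels}, \code{annotations} (optional, see
#'   \code{\link{annotate_mfpt}}).
#' @export
build_disconnectivity <- function(fel, levels = NULL) {
  n <- length(fel$F_state)
  if (is.null(levels)) {
    lo <- min(fel$F_state); hi <- max(fel$edges$F_ts)
    levels <- seq(lo, hi, length.out = 60)
  } else if (is.list(levels)) {
    levels <- levels$first + levels$spacing * (seq_len(levels$count) - 1)
  }
  levels <- sort(levels)
  if (max(levels) < max(fel$edges$F_ts))
    stop("level grid top ", max(levels), " does not cover the highest ",
         "transition state ", max(fel$edges$F_ts), "; tree would be a forest")

  # union-find over states; each component tracks its current tree node
  parent_uf <- seq_len(n)
  find <- function(i) {
    i <- as.integer(i)
    while (parent_uf[i] != i) i <- as.integer(parent_uf[i])
    i
  }
  comp_node <- seq_len(n)              # tree node representing component
  heights <- fel$F_state
  labels <- fel$labels
  parent <- integer(n)                 # 0 = currently a root
  children <- vector("list", n)
  edges <- fel$edges[order(fel$edges$F_ts), ]
  e <- 1L
  for (lev in levels) {
    # components connected by edges up to this level
    merged_any <- FALSE
    while (e <= nrow(edges) && edges$F_ts[e] <= lev) {
      a <- find(edges$i[e]); b <- find(edges$j[e])
      if (a != b) { parent_uf[a] <- b; merged_any <- TRUE }
      e <- e + 1L
    }
    if (!merged_any) next
    # group current roots that have fused at this level into new nodes
    roots <- unique(vapply(seq_len(n), find, integer(1)))
    for (r in roots) {
      members <- which(vapply(seq_len(n), find, integer(1)) == r)
      nodes <- unique(comp_node[members])
      if (length(nodes) > 1) {
        new_id <- length(heights) + 1L
        heights <- c(heights, lev)
        labels <- c(labels, NA_character_)
        parent <- c(parent, 0L)
        children[[new_id]] <- nodes
        parent[nodes] <- new_id
        comp_node[members] <- new_id
      }
    }
  }
  if (length(unique(comp_node)) > 1)
    stop("states do not all merge below the top level; check connectivity")
  structure(list(heights = unname(heights), parent = parent,
                 children = children, labels = labels,
                 n_leaves = n, levels = levels, annotations = NULL),
            class = "disconnectivity_tree")
}

#' @export
print.disconnectivity_tree <- function(x, ...) {
  cat("Disconnectivity tree: ", x$n_leaves, " leaves, ",
      length(x$heights) - x$n_leaves, " merge nodes\n", sep = "")
  cat(sprintf("  leaf free energies: 0 .. %.4g\n",
              max(x$heights[seq_len(x$n_leaves)])))
  cat(sprintf("  root merge height : %.4g\n", max(x$heights)))
  if (!is.null(x$annotations))
    cat(sprintf("  leaf annotations (MFPT): %.4g .. %.4g ps\n",
                min(x$annotations), max(x$annotations)))
  invisible(x)
}

#' Merge height of two leaves
#'
#' Free-energy threshold at which two states join the same branch of the
#' disconnectivity tree (the grid-resolved minimax barrier between them).
#'
#' @param tree a \code{disconnectivity_tree}.
#' @param i,j leaf indices.
#' @export
merge_height <- function(tree, i, j) {
  anc <- function(k) {
    path <- k
    while (tree$parent[k] != 0L) { k <- tree$parent[k]; path <- c(path, k) }
    path
  }
  common <- intersect(anc(i), anc(j))
  tree$heights[common[1]]
}

#' Annotate disconnectivity leaves with single-state MFPTs
#'
#' Colours the tree by kinetics: each leaf carries the mean first passage
#' time from that state alone to the target set (e.g. both RC
#' charge-transfer states), computed by linear solve.
#'
#' @param tree a \code{disconnectivity_tree} built from \code{net}.
#' @param net the underlying \code{kinetic_network}.
#' @param targets target state ids or labels.
#' @return the tree with \code{annotations} set (named by leaf label).
#' @export
annotate_mfpt <- function(tree, net, targets) {
  ab <- make_absorbing(net, targets)
  b <- solve(-ab$T, ab$flux)
  m <- solve(-ab$T, b)
  ann <- ifelse(b > 1e-12, m / b, Inf)
  names(ann) <- net$states$label[ab$transient]
  leaf_labels <- tree$labels[seq_len(tree$n_leaves)]
  if (!all(leaf_labels %in% names(ann)))
    stop("tree leaves are not a subset of the network's transient states")
  tree$annotations <- ann[leaf_labels]
  tree
}

#' Convert a disconnectivity tree to an ape phylogeny
#'
#' Internal merge nodes become (possibly multifurcating) nodes with branch
#' lengths equal to merge-height differences, so standard tree tooling
#' (plotting, Newick export) applies. Leaf annotations, when present, are
#' appended to tip labels as comments on export.
#'
#' @param tree a \code{disconnectivity_tree}.
#' @return an object of class \code{phylo}.
#' @export
as_phylo <- function(tree) {
  n <- tree$n_leaves
  n_all <- length(tree$heights)
  internal <- setdiff(seq_len(n_all), seq_len(n))
  # ape numbering: tips 1..n, internals n+1..; root must be first internal
  root <- which(tree$parent == 0L)
  ord <- c(root, setdiff(internal, root))
  node_id <- integer(n_all)
  node_id[seq_len(n)] <- seq_len(n)
  node_id[ord] <- n + seq_along(ord)
  edge <- cbind(node_id[tree$parent[tree$parent != 0L]],
                node_id[which(tree$parent != 0L)])
  lens <- tree$heights[tree$parent[tree$parent != 0L]] -
    tree$heights[which(tree$parent != 0L)]
  phy <- list(edge = edge, tip.label = tree$labels[seq_len(n)],
              edge.length = lens, Nnode = length(internal))
  class(phy) <- "phylo"
  stats::reorder(phy)
}

#' Serialise a landscape and tree to plain-text landscape files
#'
#' Writes the two-file dialect used by disconnectivity plotting tools: a
#' minima file with one line per state (free energy, label) and a
#' transition-state file with one line per connected pair (free energy,
#' state-index pair), plus a Newick string for the merged tree with
#' internal-node heights encoded as branch lengths.
#'
#' @param fel a \code{free_energy_landscape}.
#' @param tree optional \code{disconnectivity_tree} for the Newick file.
#' @param min_path,ts_path,newick_path output paths (\code{NULL} to skip).
#' @export
write_landscape <- function(fel, tree = NULL, min_path = NULL,
                            ts_path = NULL, newick_path = NULL) {
  if (!is.null(min_path))
    writeLines(sprintf("%.12f %s", fel$F_state, fel$labels), min_path)
  if (!is.null(ts_path))
    writeLines(sprintf("%.12f %d %d", fel$edges$F_ts, fel$edges$i,
                       fel$edges$j), ts_path)
  if (!is.null(newick_path)) {
    if (is.null(tree)) stop("a disconnectivity tree is required for Newick output")
    phy <- as_phylo(tree)
    if (!is.null(tree$annotations)) {
      phy$tip.label <- sprintf("%s_mfpt%.4g", phy$tip.label,
                               tree$annotations[phy$tip.label])
    }
    ape::write.tree(phy, file = newick_path)
  }
  invisible(NULL)
}
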