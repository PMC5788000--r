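#' Build the hydraulic network of a tree
#'
#' Each axis (directed from the collar outward) gets a hydraulic conductivity
#' from its diameter through the power law k = a_k d^b_k (m4 s-1 MPa-1). The
#' axes must form a single tree rooted at the collar (parent id 0).
#'
#' @param tree an \code{orchard_tree}.
#' @param params parameter set (hydraulics block used).
#' @return list with the axis table (plus conductivity \code{k} and
#'   resistance \code{r} = length / k, MPa s m-3), topological order, and the
#'   FU-to-axis map; class \code{hydraulic_network}.
#' @export
hydraulic_network <- function(tree, params = default_params()) {
  ax <- tree$axes
  if (!identical(as.integer(ax$id), seq_len(nrow(ax))))
    stop("axis ids must be 1..n in row order")
  hp <- params$hydraulics
  ax$k <- hp$a_k * ax$diameter^hp$b_k
  if (any(ax$k <= 0)) stop("non-positive axis conductivity")
  ax$r <- ax$length / ax$k
  # topological order from the root outward
  ord <- integer(0)
  frontier <- ax$id[ax$parent == 0L]
  if (length(frontier) == 0) stop("no axis attached to the collar")
  while (length(frontier)) {
    ord <- c(ord, frontier)
    frontier <- ax$id[ax$parent %in% frontier]
  }
  if (length(ord) != nrow(ax)) stop("axis table is not a connected tree")
  fu_axis <- ax$id[match(tree$fu$id, ax$fu_id)]
  if (any(is.na(fu_axis))) stop("fruiting unit without an axis")
  out <- list(axes = ax, order = ord, fu_axis = fu_axis, n_fu = nrow(tree$fu),
              parent = as.integer(ax$parent), r = as.numeric(ax$r))
  class(out) <- c("hydraulic_network", "list")
  out
}

#' Steady-state water potentials along the hydraulic network
#'
#' Flow through each axis equals the summed transpiration of all downstream
#' fruiting units (steady state, no capacitance); the water potential drops
#' by flow x resistance along each axis. Mass is conserved exactly at every
#' node by construction.
#'
#' @param network a \code{hydraulic_network}.
#' @param psi_collar collar water potential, MPa.
#' @param E_fu per-unit transpiration, mol s-1 (>= 0), in tree FU order.
#' @return list with \code{psi_stem} (MPa per FU, at the FU's axis distal
#'   node), \code{psi_node} (MPa per axis distal node), \code{flow} (m3 s-1
#'   per axis) and \code{balance} (node-wise conservation residual, m3 s-1).
#' @export
solve_hydraulic_network <- function(network, psi_collar, E_fu) {
  if (any(E_fu < 0)) stop("transpiration must be >= 0")
  pc <- physical_constants()
  parent <- network$parent
  r <- network$r
  nax <- length(parent)
  q <- numeric(nax)                       # m3 s-1 through each axis
  extract <- numeric(nax)
  extract[network$fu_axis] <- E_fu * pc$water_molar_volume
  q <- extract
  for (id in rev(network$order)) {        # accumulate toward the collar
    p <- parent[id]
    if (p > 0L) q[p] <- q[p] + q[id]
  }
  psi <- numeric(nax)
  for (id in network$order) {
    p <- parent[id]
    psi[id] <- (if (p == 0L) psi_collar else psi[p]) - q[id] * r[id]
  }
  # node conservation: axis inflow minus child outflows minus extraction
  child_sum <- numeric(nax)
  for (id in seq_len(nax)) {
    p <- parent[id]
    if (p > 0L) child_sum[p] <- child_sum[p] + q[id]
  }
  balance <- q - child_sum - extract
  list(psi_stem = psi[network$fu_axis], psi_node = psi, flow = q,
       balance = balance)
}

#' Leaf water potential from stem potential and transpiration
#'
#' The stem-to-leaf drop scales linearly with transpiration up to the
#' maximum drop at (and above) a reference transpiration rate.
#'
#' @param psi_stem stem water potential, MPa.
#' @param E transpiration, mol s-1 (>= 0).
#' @param E_ref reference transpiration at which the drop saturates (> 0),
#'   mol s-1 on the same per-unit basis as \code{E}.
#' @param dpsi_max maximum stem-to-leaf potential difference, MPa.
#' @return leaf water potential, MPa (vectorized).
#' @export
leaf_potential <- function(psi_stem, E, E_ref,
                           dpsi_max = default_params()$hydraulics$dpsi_max) {
  if (any(E_ref <= 0)) stop("E_ref must be positive")
  if (any(E < 0)) stop("transpiration must be >= 0")
  psi_stem - dpsi_max * pmin(1, E / E_ref)
}

#' Reference transpiration per unit leaf area
#'
#' Transpiration rate (mol m-2 s-1) of a fully sunlit leaf under saturating
#' PAR, a reference VPD of 30 hPa, unstressed water status and warm air: the
#' normalization used by \code{leaf_potential} (multiplied by each unit's
#' leaf area). Computed once per simulation.
#'
#' @param params parameter set.
#' @return mol m-2 s-1.
#' @export
reference_transpiration <- function(params = default_params()) {
  hp <- params$hydraulics
  gs <- stomatal_conductance(2000, hp$e_ref_vpd, 30, -0.3, params$stomatal)
  gtot <- 1 / (1 / gs + 1 / hp$e_ref_gb)
  gtot * hp$e_ref_vpd / physical_constants()$p_atm
}
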