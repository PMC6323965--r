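#' Allosteric potential parameters
#'
#' For each internal (non-rigid) mode mu and residue i, the stiffness the
#' residue feels from its contact neighbours when the structure moves along
#' that mode:
#' \deqn{\epsilon_{\mu,i} = \sum_{j \in nb(i)} |e_{\mu,i} - e_{\mu,j}|^2}
#' where `e_{mu,i}` is the per-residue 3-vector block of the orthonormal
#' eigenvector. These parameters fully determine the allosteric free
#' energy: the amplitude of mode mu felt at residue i is a zero-mean
#' Gaussian of variance `1/epsilon_{mu,i}`, and integrating the quadratic
#' allosteric potential over the mode amplitudes turns ratios of epsilon
#' between perturbed and unperturbed ensembles into free energies.
#'
#' The sum runs over contact-network neighbours of i (not over all
#' residues, which would erase the topology); a residue's epsilon is exactly
#' zero for a pure translation, where all per-residue blocks are equal.
#'
#' @param modes A `mode_set` from [normal_modes()].
#' @param network A `contact_network` supplying the neighbour topology.
#' @param n_modes `"all"` (default) or an integer: number of lowest-frequency
#'   internal modes to retain.
#' @return Matrix of epsilon values (retained modes x residues), with the
#'   retained mode ranks as attribute `mode_rank`.
#' @export
epsilon_parameters <- function(modes, network, n_modes = "all") {
  stopifnot(inherits(modes, "mode_set"), inherits(network, "contact_network"),
            modes$n == network$n)
  n <- network$n
  deg <- tabulate(c(network$edges$i, network$edges$j), nbins = n)
  if (any(deg == 0))
    stop("disconnected structure: residue(s) with no contact neighbours: ",
         paste(which(deg == 0), collapse = ", "))
  adj <- matrix(0, n, n)
  adj[cbind(network$edges$i, network$edges$j)] <- 1
  adj[cbind(network$edges$j, network$edges$i)] <- 1

  keep <- which(!modes$rigid)
  if (!identical(n_modes, "all")) {
    stopifnot(is.numeric(n_modes), n_modes >= 1)
    keep <- keep[seq_len(min(n_modes, length(keep)))]
  }
  eps <- matrix(0, length(keep), n)
  for (m in seq_along(keep)) {
    E <- matrix(modes$vectors[, keep[m]], nrow = n, ncol = 3, byrow = TRUE)
    s <- rowSums(E * E)
    # sum_j A_ij (|e_i|^2 + |e_j|^2 - 2 e_i.e_j)
    eps[m, ] <- deg * s + as.vector(adj %*% s) -
      2 * rowSums(E * (adj %*% E))
  }
  eps[eps < 0] <- 0          # guard against roundoff
  attr(eps, "mode_rank") <- keep
  eps
}

#' Per-residue allosteric free energy
#'
#' The free energy difference between the perturbed and unperturbed
#' ensembles felt at each residue:
#' \deqn{\Delta g_i = \frac{1}{2} k_B T \sum_\mu
#'       \ln\frac{\epsilon^{(P)}_{\mu,i}}{\epsilon^{(0)}_{\mu,i}}}
#' with modes paired by ascending-eigenvalue rank. Modes whose epsilon
#' falls below `floor` relative to the residue's largest epsilon (in either
#' state) are skipped for that residue, symmetrically in both states, to
#' avoid logarithms of numerically-zero stiffness.
#'
#' @param eps0,epsP Epsilon matrices (modes x residues) for the unperturbed
#'   and perturbed states, same dimensions.
#' @param kT Thermal energy unit the result is expressed in (default 1,
#'   i.e. units of kB*T).
#' @param floor Relative epsilon floor (default 1e-12).
#' @return Numeric vector of per-residue free energies, with the number of
#'   skipped modes per residue as attribute `skipped`.
#' @export
free_energy_profile <- function(eps0, epsP, kT = 1, floor = 1e-12) {
  if (!all(dim(eps0) == dim(epsP)))
    stop("mode-count mismatch between unperturbed (", nrow(eps0),
         ") and perturbed (", nrow(epsP), ") parameter sets")
  n <- ncol(eps0)
  dg <- numeric(n)
  skipped <- integer(n)
  for (i in seq_len(n)) {
    a <- eps0[, i]; b <- epsP[, i]
    ok <- a > 0 & b > 0 & a >= floor * max(a) & b >= floor * max(b)
    skipped[i] <- sum(!ok)
    dg[i] <- 0.5 * kT * sum(log(b[ok] / a[ok]))
  }
  attr(dg, "skipped") <- skipped
  dg
}

#' Allosteric modulation profile
#'
#' The background-free allosteric effect: the deviation of the per-residue
#' free energy from its mean over the residue's chain (default) or over the
#' whole structure. By construction the per-chain (resp. global) mean of
#' the result is zero.
#'
#' @param delta_g Per-residue free energy vector.
#' @param chains Chain assignment, one value per residue.
#' @param scope `"chain"` (default) or `"global"`.
#' @return Per-residue modulation vector.
#' @export
modulation_profile <- function(delta_g, chains, scope = c("chain", "global")) {
  scope <- match.arg(scope)
  stopifnot(length(delta_g) == length(chains), all(is.finite(delta_g)))
  if (scope == "global") return(delta_g - mean(delta_g))
  delta_g - stats::ave(delta_g, chains)
}

#' Allosteric modulation of a site
#'
#' The modulation a perturbation exerts on a functional site: the
#' arithmetic mean of the member residues' modulation values.
#'
#' @param delta_h Per-residue modulation vector.
#' @param structure The `ca_structure` the vector is indexed against.
#' @param site A `site_definition` (or residue identifiers).
#' @return Scalar site modulation.
#' @export
site_modulation <- function(delta_h, structure, site) {
  members <- if (inherits(site, "site_definition")) site$members else site
  if (length(members) == 0) stop("empty site")
  idx <- resolve_residues(structure, members)
  mean(delta_h[idx])
}

#' Modulation range
#'
#' The generic allosteric effect of a sequence position: the difference
#' between the responses to the stabilizing (UP, bulkiest substitution) and
#' destabilizing (DOWN, Ala/Gly-like) mutation at the same position,
#' `delta_h(UP) - delta_h(DOWN)`. Inherits per-chain zero mean.
#'
#' @param up,down Per-residue modulation vectors for the UP and DOWN
#'   mutation of the same position.
#' @return Elementwise difference.
#' @export
modulation_range <- function(up, down) {
  if (length(up) != length(down))
    stop("length mismatch between UP (", length(up), ") and DOWN (",
         length(down), ") profiles")
  up - down
}

#' Flag strongly modulated residues
#'
#' Splits residues into those under stronger-than-average positive
#' modulation (high) and stronger-than-average negative modulation (low).
#' The default threshold is one standard deviation of the modulation over
#' the residue's chain; an absolute threshold or a quantile can be given
#' instead.
#'
#' @param delta_h Per-residue modulation vector.
#' @param structure The `ca_structure` (for chain assignment and labels).
#' @param tau Threshold value: with `type = "sd"` a multiplier of the
#'   per-chain standard deviation (default 1), with `"absolute"` an energy,
#'   with `"quantile"` an upper-tail probability (e.g. 0.1 flags the top
#'   and bottom deciles).
#' @param type Threshold rule.
#' @return List with character vectors `high` and `low` of residue labels
#'   (always disjoint for positive thresholds).
#' @export
flag_extreme_residues <- function(delta_h, structure, tau = 1,
                                  type = c("sd", "absolute", "quantile")) {
  type <- match.arg(type)
  stopifnot(length(delta_h) == structure$n, all(is.finite(delta_h)), tau >= 0)
  chains <- structure$residues$chain
  thr <- switch(type,
    sd = {
      s <- tau * stats::ave(delta_h, chains, FUN = stats::sd)
      s[is.na(s)] <- Inf   # single-residue chain: nothing flagged
      s
    },
    absolute = rep(tau, length(delta_h)),
    quantile = {
      hi <- stats::ave(delta_h, chains, FUN = function(v)
        stats::quantile(v, 1 - tau, names = FALSE))
      lo <- stats::ave(delta_h, chains, FUN = function(v)
        stats::quantile(v, tau, names = FALSE))
      list(hi = hi, lo = lo)
    })
  if (type == "quantile") {
    high <- delta_h > thr$hi & delta_h > 0
    low <- delta_h < thr$lo & delta_h < 0
  } else {
    high <- delta_h > thr
    low <- delta_h < -thr
  }
  list(high = structure$labels[high], low = structure$labels[low])
}
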