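kB_KCAL <- 0.0019872041   # Boltzmann constant, kcal/mol/K

#' Fit the structure-based statistical mechanical model of allostery
#'
#' The central fitting function. Given a C-alpha structure and a
#' perturbation (ligand binding, UP/DOWN mutations, or any combination),
#' it builds the unperturbed and perturbed elastic networks, decomposes
#' both into normal modes, computes the allosteric potential parameters
#' epsilon for each mode/residue pair, and evaluates the per-residue
#' allosteric free energy
#' \deqn{\Delta g_i = \frac{1}{2} k_B T \sum_\mu
#'       \ln\frac{\epsilon^{(P)}_{\mu,i}}{\epsilon^{(0)}_{\mu,i}}}
#' and the allosteric modulation `delta_h` (the deviation of `delta_g`
#' from its chain mean). Positive modulation at a residue means the
#' perturbation increases the elastic work its neighbours exert on it —
#' the residue is pushed towards a conformational change; negative
#' modulation means it is relatively rigidified.
#'
#' Modes of the two ensembles are paired by ascending-eigenvalue rank over
#' the internal (non-rigid) modes. By default the epsilon sums of both
#' states use the unperturbed contact topology, so binding-created springs
#' act only through the modes; set `topology = "respective"` to let each
#' state use its own neighbour set.
#'
#' @param structure A `ca_structure` from [read_structure()] or
#'   [generate_fixture()].
#' @param perturbation A `perturbation` (see [binding()], [mutation_up()],
#'   [mutation_down()]); `NULL` or [no_perturbation()] gives the null
#'   perturbation, for which `delta_g` is identically zero.
#' @param cutoff Contact cutoff, Angstrom.
#' @param base_k Uniform spring constant.
#' @param binding_pair_cutoff Maximum pair distance bridged by binding.
#' @param temperature Temperature in Kelvin used to express energies in
#'   kcal/mol (kB*T at 300 K is about 0.596 kcal/mol).
#' @param n_modes `"all"` or number of lowest-frequency internal modes.
#' @param epsilon_floor Relative floor below which a mode is skipped in a
#'   residue's free-energy sum.
#' @param scope Chain-wise (default) or global mean removal for `delta_h`.
#' @param topology Neighbour topology for the perturbed-state epsilon.
#' @param rigid_tol Relative eigenvalue threshold for rigid-body modes.
#' @return An object of class `sbsmma` with components `delta_g`
#'   (kB*T units), `delta_h` (kB*T units), `kT_kcal` (conversion factor),
#'   the two networks and mode sets, the epsilon matrices, and the call.
#'   Use [coef()], [summary()], [plot()], [profile_table()] to inspect it.
#' @examples
#' fix <- generate_fixture("ideal_helix", n = 20)
#' fit <- sbsmma(fix, mutation_up("A:10"))
#' head(coef(fit))          # per-residue modulation, kcal/mol
#' @seealso [asm_scan()] for exhaustive per-position scanning.
#' @export
sbsmma <- function(structure, perturbation = NULL, cutoff = 11, base_k = 1,
                   binding_pair_cutoff = 15, temperature = 300,
                   n_modes = "all", epsilon_floor = 1e-12,
                   scope = c("chain", "global"),
                   topology = c("unperturbed", "respective"),
                   rigid_tol = 1e-12) {
  scope <- match.arg(scope)
  topology <- match.arg(topology)
  stopifnot(inherits(structure, "ca_structure"), temperature > 0)
  if (is.null(perturbation)) perturbation <- no_perturbation()

  net0 <- contact_network(structure, cutoff = cutoff, base_k = base_k)
  netP <- apply_perturbation(net0, perturbation, structure,
                             binding_pair_cutoff = binding_pair_cutoff)
  modes0 <- normal_modes(build_hessian(net0, structure), rigid_tol, net0)
  modesP <- normal_modes(build_hessian(netP, structure), rigid_tol, netP)

  eps0 <- epsilon_parameters(modes0, net0, n_modes = n_modes)
  epsP <- epsilon_parameters(modesP,
                             if (topology == "unperturbed") net0 else netP,
                             n_modes = n_modes)
  dg <- free_energy_profile(eps0, epsP, kT = 1, floor = epsilon_floor)
  dh <- modulation_profile(as.vector(dg), structure$residues$chain,
                           scope = scope)
  fit <- list(structure = structure, perturbation = perturbation,
              network0 = net0, networkP = netP,
              modes0 = modes0, modesP = modesP,
              eps0 = eps0, epsP = epsP,
              delta_g = as.vector(dg), delta_h = dh,
              skipped_modes = attr(dg, "skipped"),
              temperature = temperature,
              kT_kcal = kB_KCAL * temperature,
              scope = scope, topology = topology,
              cutoff = cutoff, base_k = base_k,
              binding_pair_cutoff = binding_pair_cutoff,
              n_modes = n_modes, epsilon_floor = epsilon_floor,
              call = match.call())
  class(fit) <- "sbsmma"
  fit
}

#' Extract per-residue profiles from a fitted allostery model
#'
#' @param object A `sbsmma` fit.
#' @param which `"delta_h"` (allosteric modulation, default) or
#'   `"delta_g"` (allosteric free energy).
#' @param units `"kcal"` (kcal/mol, default) or `"kT"` (units of kB*T).
#' @param ... Unused.
#' @return Named numeric vector, one value per residue.
#' @export
coef.sbsmma <- function(object, which = c("delta_h", "delta_g"),
                        units = c("kcal", "kT"), ...) {
  which <- match.arg(which)
  units <- match.arg(units)
  v <- object[[which]]
  if (units == "kcal") v <- v * object$kT_kcal
  names(v) <- object$structure$labels
  v
}

#' @export
print.sbsmma <- function(x, ...) {
  cat("Structure-based statistical mechanical model of allostery\n")
  print(x$structure)
  print(x$perturbation)
  dh <- x$delta_h * x$kT_kcal
  cat(sprintf("Allosteric modulation (kcal/mol): min %.3f, max %.3f\n",
              min(dh), max(dh)))
  invisible(x)
}

#' @export
summary.sbsmma <- function(object, tau = 1, ...) {
  dh_kcal <- coef(object)
  flags <- flag_extreme_residues(object$delta_h, object$structure, tau = tau)
  out <- list(n = object$structure$n,
              n_modes_used = nrow(object$eps0),
              n_springs0 = nrow(object$network0$edges),
              n_springsP = nrow(object$networkP$edges),
              perturbation = object$perturbation,
              temperature = object$temperature,
              delta_h_kcal = dh_kcal,
              high = flags$high, low = flags$low,
              skipped_modes = sum(object$skipped_modes))
  class(out) <- "summary.sbsmma"
  out
}

#' @export
print.summary.sbsmma <- function(x, ...) {
  cat(sprintf("SBSMMA fit: %d residues, %d internal modes, T = %g K\n",
              x$n, x$n_modes_used, x$temperature))
  print(x$perturbation)
  cat(sprintf("Springs: %d unperturbed, %d perturbed\n",
              x$n_springs0, x$n_springsP))
  qs <- stats::quantile(x$delta_h_kcal, c(0, .25, .5, .75, 1))
  cat("Allosteric modulation, kcal/mol:\n")
  print(signif(qs, 4))
  cat(sprintf("High-modulation residues (> +1 sd): %s\n",
              if (length(x$high)) paste(x$high, collapse = ", ") else "none"))
  cat(sprintf("Low-modulation residues (< -1 sd): %s\n",
              if (length(x$low)) paste(x$low, collapse = ", ") else "none"))
  if (x$skipped_modes > 0)
    cat(sprintf("Note: %d mode/residue terms skipped by the epsilon floor\n",
                x$skipped_modes))
  invisible(x)
}

#' @export
plot.sbsmma <- function(x, which = c("delta_h", "delta_g"),
                        units = c("kcal", "kT"), ...) {
  which <- match.arg(which)
  units <- match.arg(units)
  v <- coef(x, which = which, units = units)
  chains <- factor(x$structure$residues$chain)
  ylab <- paste0(if (which == "delta_h") "allosteric modulation"
                 else "allosteric free energy",
                 if (units == "kcal") " (kcal/mol)" else " (kT)")
  graphics::plot(seq_along(v), v, type = "h", col = as.integer(chains),
                 xlab = "residue index", ylab = ylab, ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Per-residue result table of a fitted allostery model
#'
#' @param fit A `sbsmma` fit.
#' @return Data frame with residue identity and `delta_g` / `delta_h` in
#'   kcal/mol, in model order.
#' @export
profile_table <- function(fit) {
  stopifnot(inherits(fit, "sbsmma"))
  df <- fit$structure$residues
  df$delta_g_kcal <- fit$delta_g * fit$kT_kcal
  df$delta_h_kcal <- fit$delta_h * fit$kT_kcal
  df
}
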