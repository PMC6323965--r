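#' Exhaustive mutation scan: Allosteric Signaling Map
#'
#' Mutates every position in turn (UP = stabilizing, DOWN = destabilizing),
#' refits the perturbed elastic network and records the full modulation
#' profile, giving the N x N Allosteric Signaling Map: entry `[m, i]` is
#' the modulation `delta_h_i` (kcal/mol) caused at residue i by mutating
#' position m — rows are the perturbing positions, columns the responding
#' residues. Rows are independent and the scan is deterministic.
#'
#' @inheritParams sbsmma
#' @param kind `"UP"` or `"DOWN"`.
#' @param alpha Mutation strength; defaults to 2 for UP, 0.1 for DOWN.
#' @return An `asm` object: list with `values` (N x N matrix, kcal/mol,
#'   dimnames = residue labels), `kind`, `alpha`, `labels`, `chains`,
#'   `distances` (the inter-residue distance matrix, always carried
#'   alongside the map) and the model parameters.
#' @examples
#' fix <- generate_fixture("ideal_helix", n = 12)
#' m <- asm_scan(fix, "UP")
#' dim(m$values)
#' @export
asm_scan <- function(structure, kind = c("UP", "DOWN"), alpha = NULL,
                     cutoff = 11, base_k = 1, temperature = 300,
                     n_modes = "all", epsilon_floor = 1e-12,
                     scope = c("chain", "global"), rigid_tol = 1e-12) {
  kind <- match.arg(kind)
  scope <- match.arg(scope)
  stopifnot(inherits(structure, "ca_structure"))
  if (is.null(alpha)) alpha <- if (kind == "UP") 2 else 0.1

  net0 <- contact_network(structure, cutoff = cutoff, base_k = base_k)
  modes0 <- normal_modes(build_hessian(net0, structure), rigid_tol, net0)
  eps0 <- epsilon_parameters(modes0, net0, n_modes = n_modes)
  kT_kcal <- kB_KCAL * temperature
  chains <- structure$residues$chain

  n <- structure$n
  values <- matrix(0, n, n, dimnames = list(structure$labels, structure$labels))
  make_mut <- if (kind == "UP") mutation_up else mutation_down
  for (m in seq_len(n)) {
    row <- tryCatch({
      netP <- apply_perturbation(net0, make_mut(m, alpha = alpha), structure)
      modesP <- normal_modes(build_hessian(netP, structure), rigid_tol, netP)
      epsP <- epsilon_parameters(modesP, net0, n_modes = n_modes)
      dg <- free_energy_profile(eps0, epsP, kT = 1, floor = epsilon_floor)
      modulation_profile(as.vector(dg), chains, scope = scope) * kT_kcal
    }, error = function(e) {
      stop("scan failed at position ", structure$labels[m], ": ",
           conditionMessage(e), call. = FALSE)
    })
    values[m, ] <- row
  }
  out <- list(values = values, kind = kind, alpha = alpha,
              labels = structure$labels, chains = chains,
              distances = distance_matrix(structure),
              cutoff = cutoff, base_k = base_k, temperature = temperature,
              n_modes = n_modes, epsilon_floor = epsilon_floor, scope = scope)
  class(out) <- "asm"
  out
}

#' Modulation-range map
#'
#' Combines matched UP and DOWN scans into the map of modulation ranges:
#' the generic allosteric effect of substituting each position from the
#' smallest to the bulkiest residue, `UP - DOWN` elementwise.
#'
#' @param up,down `asm` objects of kind UP and DOWN over the same model.
#' @return An `asm` of kind `"RANGE"`; `alpha` records both scan strengths.
#' @export
modulation_range_map <- function(up, down) {
  stopifnot(inherits(up, "asm"), inherits(down, "asm"))
  if (up$kind != "UP" || down$kind != "DOWN")
    stop("arguments must be an UP map and a DOWN map, in that order")
  if (!all(dim(up$values) == dim(down$values)) ||
      !identical(up$labels, down$labels))
    stop("UP and DOWN maps were not computed over the same model")
  out <- up
  out$values <- up$values - down$values
  out$kind <- "RANGE"
  out$alpha <- c(up = up$alpha, down = down$alpha)
  out
}

#' @export
print.asm <- function(x, ...) {
  cat(sprintf(
    "Allosteric Signaling Map (%s, alpha = %s): %d x %d, kcal/mol\n",
    x$kind, paste(signif(x$alpha, 3), collapse = "/"),
    nrow(x$values), ncol(x$values)))
  cat("rows = mutated position, columns = responding residue\n")
  invisible(x)
}

#' @export
as.matrix.asm <- function(x, ...) x$values

#' @export
plot.asm <- function(x, what = c("map", "distances"), ...) {
  what <- match.arg(what)
  v <- if (what == "map") x$values else x$distances
  n <- nrow(v)
  main <- if (what == "map") paste0("ASM (", x$kind, "), kcal/mol")
          else "C-alpha distances (A)"
  pal <- if (what == "map")
    grDevices::hcl.colors(101, "Blue-Red 3") else grDevices::hcl.colors(101)
  graphics::image(seq_len(n), seq_len(n), t(v[n:1, , drop = FALSE]),
                  col = pal, xlab = "responding residue",
                  ylab = "mutated position", main = main, useRaster = TRUE, ...)
  invisible(x)
}

#' Effect of every mutation on a site
#'
#' Aggregates an Allosteric Signaling Map over a site: for each sequence
#' position m, the mean modulation its mutation causes over the site's
#' member residues — the allosteric signaling from all positions to the
#' site.
#'
#' @param map An `asm`.
#' @param site A `site_definition` or residue identifiers.
#' @return Named vector, one value per mutated position (kcal/mol).
#' @export
mutations_effect_on_site <- function(map, site) {
  stopifnot(inherits(map, "asm"))
  members <- if (inherits(site, "site_definition")) site$members else site
  if (length(members) == 0) stop("empty site")
  idx <- match(members, map$labels)
  if (anyNA(idx)) stop("unknown residue identifier(s): ",
                       paste(members[is.na(idx)], collapse = ", "))
  v <- rowMeans(map$values[, idx, drop = FALSE])
  names(v) <- map$labels
  v
}

#' Site-to-site allosteric signaling
#'
#' Binds ligands at a chosen subset of sites and reports the modulation
#' each remaining site experiences. With `choose` set, the liganded group
#' is expanded into all combinations of that many copies (sequential
#' binding to an oligomer's subunits), one table row per combination and
#' target site, so cooperativity can be read off directly.
#'
#' @inheritParams sbsmma
#' @param sites List of `site_definition` objects.
#' @param liganded Character vector of site labels to bind (subset of
#'   `sites`); may be empty, in which case all modulations are zero.
#' @param alpha Binding strength.
#' @param choose Optional: bind every combination of `choose` sites from
#'   `liganded` instead of all of them at once.
#' @return Data frame with columns `bound` (combination label), `site`
#'   (target site label) and `delta_h_site_kcal`.
#' @export
site_to_site_signaling <- function(structure, sites, liganded,
                                   alpha = 10, choose = NULL,
                                   cutoff = 11, base_k = 1,
                                   binding_pair_cutoff = 15,
                                   temperature = 300, n_modes = "all",
                                   epsilon_floor = 1e-12,
                                   scope = c("chain", "global")) {
  scope <- match.arg(scope)
  stopifnot(is.list(sites),
            all(vapply(sites, inherits, TRUE, "site_definition")))
  labels <- vapply(sites, `[[`, "", "label")
  names(sites) <- labels
  unknown <- setdiff(liganded, labels)
  if (length(unknown) > 0)
    .validation_error("unknown site label(s): ", paste(unknown, collapse = ", "))

  if (length(liganded) == 0) {
    specs <- list("(none)" = no_perturbation())
  } else if (!is.null(choose)) {
    specs <- site_combinations(sites[liganded], choose, alpha = alpha)
  } else {
    members <- unique(unlist(lapply(sites[liganded], `[[`, "members")))
    lab <- paste(sort(liganded), collapse = " & ")
    specs <- stats::setNames(list(binding(site(lab, members), alpha = alpha)),
                             lab)
  }

  rows <- list()
  for (sname in names(specs)) {
    fit <- sbsmma(structure, specs[[sname]], cutoff = cutoff, base_k = base_k,
                  binding_pair_cutoff = binding_pair_cutoff,
                  temperature = temperature, n_modes = n_modes,
                  epsilon_floor = epsilon_floor, scope = scope)
    bound_idx <- unique(unlist(lapply(specs[[sname]]$actions, function(a)
      if (a$kind == "BINDING") resolve_residues(structure, a$site$members))))
    targets <- setdiff(labels, unlist(strsplit(sname, " & ", fixed = TRUE)))
    for (t in targets) {
      t_idx <- resolve_residues(structure, sites[[t]]$members)
      if (length(intersect(t_idx, bound_idx)) > 0)
        warning("site ", t, " overlaps the liganded residue set")
      rows[[length(rows) + 1]] <- data.frame(
        bound = sname, site = t,
        delta_h_site_kcal = site_modulation(fit$delta_h, structure,
                                            sites[[t]]) * fit$kT_kcal,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write an Allosteric Signaling Map to CSV and JSON
#'
#' The CSV carries residue labels as header row and first column; the JSON
#' bundle records the kind, alphas, labels, the map (row-major) and the
#' inter-residue distance matrix that complements it.
#'
#' @param map An `asm`.
#' @param csv,json,distances_csv Optional output paths (skipped when NULL).
#' @return Invisibly, the list written to JSON.
#' @export
write_asm <- function(map, csv = NULL, json = NULL, distances_csv = NULL) {
  stopifnot(inherits(map, "asm"))
  if (!is.null(csv)) {
    df <- data.frame(position = map$labels, map$values, check.names = FALSE)
    utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(distances_csv)) {
    df <- data.frame(position = map$labels, map$distances, check.names = FALSE)
    utils::write.csv(df, distances_csv, row.names = FALSE, quote = FALSE)
  }
  payload <- list(kind = map$kind, alpha = map$alpha,
                  rows = "mutated position", columns = "responding residue",
                  units = "kcal/mol", labels = map$labels,
                  values = map$values, distance_matrix = map$distances)
  if (!is.null(json))
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor")
  invisible(payload)
}
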