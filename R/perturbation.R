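#' Define a binding site
#'
#' A site is a labelled set of residues (e.g. the residues lining a ligand
#' pocket). Symmetry-related copies of the same site in different subunits
#' of an oligomer can share a `symmetry_group`, which enables combinatorial
#' binding scans over the copies.
#'
#' @param label Site label, e.g. `"ADP.1"`.
#' @param members Character vector of residue identifiers (`"A:12"`) or
#'   integer indices.
#' @param symmetry_group Optional group name shared by symmetry-related
#'   copies.
#' @return A `site_definition`.
#' @export
site <- function(label, members, symmetry_group = NULL) {
  stopifnot(is.character(label), length(label) == 1, length(members) > 0)
  out <- list(label = label, members = members, symmetry_group = symmetry_group)
  class(out) <- "site_definition"
  out
}

#' @export
print.site_definition <- function(x, ...) {
  cat(sprintf("Site %s: %d residue(s)%s\n", x$label, length(x$members),
              if (is.null(x$symmetry_group)) ""
              else paste0(" [group ", x$symmetry_group, "]")))
  invisible(x)
}

.new_perturbation <- function(actions) {
  out <- list(actions = actions)
  class(out) <- "perturbation"
  out
}

.validation_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("sbsmma_validation", "error")))
}

#' Perturbations: ligand binding and point mutations
#'
#' The model knows three perturbation classes, all acting on the spring
#' constants of the contact network:
#' * `binding(site, alpha)` mimics ligand binding by introducing strong
#'   interactions between the residues of the binding site: every pair of
#'   site members closer than `binding_pair_cutoff` gets spring constant
#'   `alpha * base_k`, with new springs created where the pair was beyond
#'   the network cutoff.
#' * `mutation_up(residues, alpha)` models a stabilizing substitution to a
#'   bulky residue: every existing spring incident to the mutated position
#'   is stiffened by `alpha > 1`.
#' * `mutation_down(residues, alpha)` models a destabilizing Ala/Gly-like
#'   substitution: incident springs are softened by `0 < alpha < 1`.
#'
#' Mutations never create or remove springs. Perturbations are combined
#' with [c()] and compose multiplicatively on shared springs.
#'
#' @param site A `site_definition` (or vector of residue identifiers) to
#'   bind.
#' @param residues Residue identifiers to mutate (one action per residue).
#' @param alpha Positive scale factor; `> 1` for binding and UP mutations,
#'   in `(0, 1)` for DOWN mutations.
#' @return A `perturbation` object.
#' @examples
#' p <- c(binding(site("lig", c("A:1", "A:5"))), mutation_down("A:9"))
#' @name perturbations
NULL

#' @rdname perturbations
#' @export
binding <- function(site, alpha = 10) {
  if (!inherits(site, "site_definition")) {
    site <- list(label = "site", members = site, symmetry_group = NULL)
    class(site) <- "site_definition"
  }
  if (!(alpha > 1)) .validation_error("binding requires alpha > 1, got ", alpha)
  .new_perturbation(list(list(kind = "BINDING", site = site, alpha = alpha)))
}

#' @rdname perturbations
#' @export
mutation_up <- function(residues, alpha = 2) {
  if (!(alpha > 1)) .validation_error("UP mutation requires alpha > 1, got ", alpha)
  .new_perturbation(lapply(residues, function(r)
    list(kind = "UP", residue = r, alpha = alpha)))
}

#' @rdname perturbations
#' @export
mutation_down <- function(residues, alpha = 0.1) {
  if (!(alpha > 0 && alpha < 1))
    .validation_error("DOWN mutation requires 0 < alpha < 1, got ", alpha)
  .new_perturbation(lapply(residues, function(r)
    list(kind = "DOWN", residue = r, alpha = alpha)))
}

#' @export
c.perturbation <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, TRUE, "perturbation")))
  .new_perturbation(do.call(c, lapply(parts, `[[`, "actions")))
}

#' An empty perturbation (the unperturbed state)
#' @return A `perturbation` with no actions.
#' @export
no_perturbation <- function() .new_perturbation(list())

#' @export
print.perturbation <- function(x, ...) {
  if (length(x$actions) == 0) {
    cat("Perturbation: none (unperturbed state)\n")
    return(invisible(x))
  }
  for (a in x$actions) {
    if (a$kind == "BINDING")
      cat(sprintf("  BINDING %s (%d residues), alpha = %g\n",
                  a$site$label, length(a$site$members), a$alpha))
    else
      cat(sprintf("  %s mutation at %s, alpha = %g\n", a$kind,
                  as.character(a$residue), a$alpha))
  }
  invisible(x)
}

# validate a perturbation against a structure; returns actions with
# resolved residue indices
.resolve_perturbation <- function(spec, structure) {
  stopifnot(inherits(spec, "perturbation"))
  mut_seen <- integer(0)
  lapply(spec$actions, function(a) {
    if (a$kind == "BINDING") {
      a$idx <- resolve_residues(structure, a$site$members)
    } else {
      a$idx <- resolve_residues(structure, a$residue)
      if (a$idx %in% mut_seen)
        .validation_error("residue ", structure$labels[a$idx],
                          " appears in more than one mutation action")
      mut_seen <<- c(mut_seen, a$idx)
    }
    a
  })
}

#' Apply a perturbation to a contact network
#'
#' Pure function: returns a new network, the input is never modified.
#' Binding stiffens (and, within `binding_pair_cutoff`, creates) springs
#' among the site residues; UP/DOWN mutations rescale every existing spring
#' incident to the mutated position. The perturbed edge set is always a
#' superset of the input's.
#'
#' @param network A `contact_network`.
#' @param spec A `perturbation`.
#' @param structure The `ca_structure` (resolves residue identifiers and
#'   supplies rest lengths for created springs).
#' @param binding_pair_cutoff Maximum distance (Angstrom) at which binding
#'   couples two site residues (default 15).
#' @return A new `contact_network`.
#' @export
apply_perturbation <- function(network, spec, structure,
                               binding_pair_cutoff = 15) {
  stopifnot(inherits(network, "contact_network"),
            inherits(structure, "ca_structure"),
            network$n == structure$n)
  actions <- .resolve_perturbation(spec, structure)
  out <- network
  if (length(actions) == 0) return(out)
  edges <- network$edges
  ekey <- paste(edges$i, edges$j)
  xyz <- structure$xyz
  for (a in actions) {
    if (a$kind == "BINDING") {
      idx <- sort(unique(a$idx))
      if (length(idx) >= 2) {
        pairs <- utils::combn(idx, 2)
        for (p in seq_len(ncol(pairs))) {
          i <- pairs[1, p]; j <- pairs[2, p]
          r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
          if (r > binding_pair_cutoff) next
          at <- match(paste(i, j), ekey)
          if (is.na(at)) {
            edges <- rbind(edges, data.frame(i = i, j = j,
                                             k = a$alpha * network$base_k,
                                             r0 = r))
            ekey <- c(ekey, paste(i, j))
          } else {
            edges$k[at] <- edges$k[at] * a$alpha
          }
        }
      }
    } else {
      inc <- edges$i == a$idx | edges$j == a$idx
      edges$k[inc] <- edges$k[inc] * a$alpha
    }
  }
  out$edges <- edges
  out
}

#' Enumerate binding combinations over symmetry-related sites
#'
#' For an oligomer with `n` symmetry-related copies of a binding site,
#' returns one binding perturbation for every unordered combination of
#' `choose` copies (e.g. 2 of 4 copies gives the 6 pairings), supporting
#' sequential-binding and cooperativity analyses.
#'
#' @param sites List of `site_definition` objects (one symmetry group).
#' @param choose Number of copies to bind simultaneously (1..length(sites)).
#' @param alpha Binding strength passed to [binding()].
#' @return Named list of `perturbation` objects in lexicographic order of
#'   site labels; names are combination labels like `"ADP.1 & ADP.2"`.
#' @export
site_combinations <- function(sites, choose, alpha = 10) {
  stopifnot(is.list(sites), length(sites) > 0,
            all(vapply(sites, inherits, TRUE, "site_definition")))
  if (!(choose >= 1 && choose <= length(sites)))
    .validation_error("choose must be between 1 and ", length(sites),
                      ", got ", choose)
  labels <- vapply(sites, `[[`, "", "label")
  sites <- sites[order(labels)]
  labels <- sort(labels)
  combos <- utils::combn(seq_along(sites), choose, simplify = FALSE)
  out <- lapply(combos, function(ix) {
    members <- unique(unlist(lapply(sites[ix], `[[`, "members")))
    lab <- paste(labels[ix], collapse = " & ")
    binding(site(lab, members), alpha = alpha)
  })
  names(out) <- vapply(combos, function(ix) paste(labels[ix], collapse = " & "), "")
  out
}
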