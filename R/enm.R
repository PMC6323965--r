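#' Build the C-alpha contact network
#'
#' The harmonic model connects every pair of C-alpha atoms closer than
#' `cutoff` by a spring of stiffness `base_k` whose rest length is the
#' observed distance, so the crystal structure is the energy minimum.
#'
#' @param structure A `ca_structure`.
#' @param cutoff Contact cutoff in Angstrom (default 11).
#' @param base_k Uniform spring constant (arbitrary energy/A^2 units).
#' @return A `contact_network`: list with `n`, `edges` (data frame `i`, `j`,
#'   `k`, `r0`, with `i < j`), `cutoff`, `base_k`.
#' @export
contact_network <- function(structure, cutoff = 11, base_k = 1) {
  stopifnot(inherits(structure, "ca_structure"), cutoff > 0, base_k > 0)
  d <- distance_matrix(structure)
  sel <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  edges <- data.frame(i = sel[, 1], j = sel[, 2],
                      k = rep(base_k, nrow(sel)),
                      r0 = d[sel])
  net <- list(n = structure$n, edges = edges, cutoff = cutoff,
              base_k = base_k)
  class(net) <- "contact_network"
  net
}

#' @export
print.contact_network <- function(x, ...) {
  cat(sprintf("Contact network: %d residues, %d springs (cutoff %.1f A)\n",
              x$n, nrow(x$edges), x$cutoff))
  invisible(x)
}

#' Anisotropic network Hessian
#'
#' Assembles the 3N x 3N second-derivative matrix of the pairwise harmonic
#' potential at its minimum: each spring (i, j) contributes the block
#' `k * d d^T / |d|^2` with `d` the equilibrium inter-C-alpha vector.
#' By construction the matrix is symmetric and annihilates uniform
#' translations (and infinitesimal rotations) of the whole structure.
#'
#' @param network A `contact_network`.
#' @param structure The `ca_structure` it was built from.
#' @return Symmetric 3N x 3N matrix.
#' @export
build_hessian <- function(network, structure) {
  stopifnot(inherits(network, "contact_network"),
            inherits(structure, "ca_structure"),
            network$n == structure$n)
  n <- network$n
  H <- matrix(0, 3 * n, 3 * n)
  e <- network$edges
  xyz <- structure$xyz
  for (row in seq_len(nrow(e))) {
    i <- e$i[row]; j <- e$j[row]
    d <- xyz[j, ] - xyz[i, ]
    B <- (e$k[row] / sum(d * d)) * tcrossprod(d)
    bi <- (3 * i - 2):(3 * i); bj <- (3 * j - 2):(3 * j)
    H[bi, bi] <- H[bi, bi] + B
    H[bj, bj] <- H[bj, bj] + B
    H[bi, bj] <- H[bi, bj] - B
    H[bj, bi] <- H[bj, bi] - B
  }
  H
}

#' Normal modes of the elastic network
#'
#' Dense eigendecomposition of the Hessian. Modes whose eigenvalue is below
#' `rigid_tol` relative to the largest eigenvalue are flagged as rigid-body
#' modes: a connected, non-collinear 3-D structure has exactly six (three
#' translations, three rotations). More than six signals a disconnected or
#' geometrically degenerate network and is an error, except for the
#' two-bead system whose single internal (stretch) mode leaves five
#' zero-frequency modes.
#'
#' @param hessian Symmetric 3N x 3N matrix from [build_hessian()].
#' @param rigid_tol Relative eigenvalue threshold for rigid modes.
#' @param network Optional `contact_network`; used to report connected
#'   components when the rigid-mode count is wrong.
#' @return A `mode_set`: list with `values` (eigenvalues, ascending),
#'   `vectors` (orthonormal 3N x 3N matrix, columns are modes), `rigid`
#'   (logical mask) and `n` (residue count).
#' @export
normal_modes <- function(hessian, rigid_tol = 1e-12, network = NULL) {
  stopifnot(is.matrix(hessian), nrow(hessian) == ncol(hessian),
            nrow(hessian) %% 3 == 0)
  n <- nrow(hessian) / 3
  eig <- eigen(hessian, symmetric = TRUE)
  ord <- rev(seq_along(eig$values))     # ascending eigenvalues
  values <- eig$values[ord]
  vectors <- eig$vectors[, ord, drop = FALSE]
  lmax <- max(values)
  if (!(lmax > 0)) stop("elastic network has no internal stiffness")
  rigid <- values <= rigid_tol * lmax
  n_rigid <- sum(rigid)
  expected <- if (n == 2) 5L else 6L
  if (n_rigid > expected) {
    msg <- sprintf(
      "disconnected or degenerate structure: %d rigid (zero-frequency) modes, expected %d",
      n_rigid, expected)
    if (!is.null(network)) {
      comp <- .components(network)
      if (max(comp) > 1) {
        sizes <- table(comp)
        msg <- paste0(msg, sprintf("; %d connected components of sizes %s",
                                   max(comp), paste(sizes, collapse = ", ")))
      }
    }
    stop(msg)
  }
  structure(list(values = values, vectors = vectors, rigid = rigid, n = n),
            class = "mode_set")
}

# connected components of the contact graph (label vector, 1-based)
.components <- function(network) {
  n <- network$n
  adj <- vector("list", n)
  for (r in seq_len(nrow(network$edges))) {
    i <- network$edges$i[r]; j <- network$edges$j[r]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

#' Fit an elastic network model to a structure
#'
#' Convenience wrapper building the contact network, the Hessian and the
#' normal-mode set in one call.
#'
#' @inheritParams contact_network
#' @inheritParams normal_modes
#' @return An `enm` object: list with `structure`, `network`, `hessian`,
#'   `modes`.
#' @examples
#' fix <- generate_fixture("cubic_cluster", n = 8)
#' fit <- enm(fix)
#' sum(fit$modes$rigid)   # 6 rigid-body modes
#' @export
enm <- function(structure, cutoff = 11, base_k = 1, rigid_tol = 1e-12) {
  network <- contact_network(structure, cutoff = cutoff, base_k = base_k)
  hessian <- build_hessian(network, structure)
  modes <- normal_modes(hessian, rigid_tol = rigid_tol, network = network)
  fit <- list(structure = structure, network = network,
              hessian = hessian, modes = modes)
  class(fit) <- "enm"
  fit
}

#' @export
print.enm <- function(x, ...) {
  cat(sprintf("Elastic network model: %d residues, %d springs, %d internal modes\n",
              x$network$n, nrow(x$network$edges), sum(!x$modes$rigid)))
  invisible(x)
}
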