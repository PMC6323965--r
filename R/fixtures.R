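#' Deterministic synthetic structures for testing and demonstration
#'
#' Generates poly-alanine, C-alpha-only toy structures with known geometry:
#' * `linear_chain` — beads on a line (`spacing` apart); note that a
#'   perfectly straight chain is degenerate under an anisotropic network
#'   (transverse motions cost nothing), so analytic tests jitter it.
#' * `ideal_helix` — standard alpha-helix C-alpha geometry: rise 1.5 A and
#'   100 degrees of twist per residue at radius 2.3 A.
#' * `cubic_cluster` — beads filling a cubic lattice, a compact non-
#'   degenerate 3-D blob.
#' * `two_domain_dumbbell` — two cubic clusters joined by a short linker
#'   chain, a minimal two-domain architecture.
#' * `symmetric_dimer` — a helical chain A and its exact two-fold copy
#'   (chain B, C2 rotation about z); the jitter is applied to chain A
#'   before mirroring, so the dimer symmetry is exact at any jitter.
#'
#' Coordinates are deterministic given the arguments and `seed`; jitter is
#' drawn from a seeded uniform cube without touching the global RNG state.
#'
#' @param kind Fixture kind (see above).
#' @param n Total residue count (>= 2; even for `symmetric_dimer`).
#' @param spacing Bead spacing for chains/lattices, Angstrom.
#' @param rise,twist,radius Helix geometry (Angstrom, degrees, Angstrom).
#' @param linker Number of linker residues in the dumbbell.
#' @param jitter Uniform jitter half-width, Angstrom (default 0).
#' @param seed Seed for the jitter.
#' @return A `ca_structure`; render to PDB text with [as_pdb()].
#' @examples
#' dim2 <- generate_fixture("symmetric_dimer", n = 20, jitter = 0.1)
#' table(dim2$residues$chain)
#' @export
generate_fixture <- function(kind = c("linear_chain", "ideal_helix",
                                      "cubic_cluster", "two_domain_dumbbell",
                                      "symmetric_dimer"),
                             n, spacing = 3.8, rise = 1.5, twist = 100,
                             radius = 2.3, linker = 3, jitter = 0, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(n >= 2, spacing > 0, rise > 0, radius > 0, jitter >= 0)
  if (kind == "symmetric_dimer" && n %% 2 != 0)
    stop("symmetric_dimer needs an even residue count")

  helix_xyz <- function(m, offset = c(0, 0, 0)) {
    t <- (seq_len(m) - 1) * twist * pi / 180
    cbind(radius * cos(t) + offset[1],
          radius * sin(t) + offset[2],
          rise * (seq_len(m) - 1) + offset[3])
  }
  cube_xyz <- function(m, offset = c(0, 0, 0)) {
    side <- ceiling(m^(1 / 3))
    g <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                               z = seq_len(side)))
    # fill the lattice diagonal-shell first so even tiny clusters (n = 4:
    # a tetrahedron) span three dimensions instead of a degenerate plane
    g <- g[order(rowSums(g), g[, 1], g[, 2], g[, 3]), , drop = FALSE]
    sweep((g[seq_len(m), , drop = FALSE] - 1) * spacing, 2, offset, `+`)
  }
  add_jitter <- function(xyz) {
    if (jitter == 0) return(xyz)
    xyz + matrix(.fixture_runif(3 * nrow(xyz), seed) * 2 - 1,
                 ncol = 3) * jitter
  }

  chain <- rep("A", n)
  resnum <- seq_len(n)
  xyz <- switch(kind,
    linear_chain = add_jitter(cbind((seq_len(n) - 1) * spacing, 0, 0)),
    ideal_helix = add_jitter(helix_xyz(n)),
    cubic_cluster = add_jitter(cube_xyz(n)),
    two_domain_dumbbell = {
      if (n < linker + 4) stop("dumbbell needs at least linker + 4 residues")
      nd <- (n - linker) %/% 2
      d1 <- cube_xyz(nd)
      gap <- max(d1[, 1]) + spacing
      # the linker coils off the inter-domain axis at compressed spacing:
      # a straight on-axis linker would leave a zero-energy inter-domain
      # torsion, and each domain must reach three non-collinear linker
      # beads or it can still pivot about a two-anchor axis
      k <- seq_len(linker)
      step <- 0.66 * spacing
      link <- cbind(gap + (k - 1) * step,
                    1.5 * cos(2 * k), 1.5 * sin(2 * k))
      d2 <- cube_xyz(n - nd - linker,
                     offset = c(gap + linker * step, 0, 0))
      add_jitter(rbind(d1, link, d2))
    },
    symmetric_dimer = {
      h <- n %/% 2
      # a 4.5 A axis offset keeps a broad inter-chain contact interface
      # (a thin interface under-constrains the relative chain motion)
      a <- add_jitter(helix_xyz(h, offset = c(4.5, 0, 0)))
      b <- cbind(-a[, 1], -a[, 2], a[, 3])   # C2 about the z axis
      chain <- rep(c("A", "B"), each = h)
      resnum <- c(seq_len(h), seq_len(h))
      rbind(a, b)
    })

  res <- data.frame(chain = chain, resnum = resnum, icode = "",
                    resname = "ALA", stringsAsFactors = FALSE)
  labels <- paste0(res$chain, ":", res$resnum)
  dimnames(xyz) <- list(labels, c("x", "y", "z"))
  out <- list(residues = res, xyz = xyz, labels = labels, n = n)
  class(out) <- "ca_structure"
  out
}

# seeded uniforms that leave the caller's RNG state untouched
.fixture_runif <- function(n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::runif(n)
}

#' Render a C-alpha structure as PDB text
#'
#' Fixed-column ATOM records, one CA atom per residue, suitable for any
#' PDB reader (and for [read_structure()] round-trips).
#'
#' @param structure A `ca_structure`.
#' @param file Optional path to write to.
#' @return PDB text as a single string (invisibly when `file` is given).
#' @export
as_pdb <- function(structure, file = NULL) {
  stopifnot(inherits(structure, "ca_structure"))
  r <- structure$residues
  xyz <- structure$xyz
  lines <- sprintf(
    "ATOM  %5d  CA  %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(structure$n), r$resname, r$chain, r$resnum,
    ifelse(r$icode == "", " ", r$icode),
    xyz[, 1], xyz[, 2], xyz[, 3], 1, 0)
  lines <- c(lines, "END")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(txt))
  }
  txt
}
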