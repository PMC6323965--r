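# Hand-built structures and PDB snippets used across tests.

make_structure <- function(xyz, chain = "A", resnum = seq_len(nrow(xyz)),
                           icode = "", resname = "ALA") {
  xyz <- as.matrix(xyz)
  res <- data.frame(chain = rep_len(chain, nrow(xyz)),
                    resnum = resnum,
                    icode = rep_len(icode, nrow(xyz)),
                    resname = rep_len(resname, nrow(xyz)),
                    stringsAsFactors = FALSE)
  labels <- paste0(res$chain, ":", res$resnum, res$icode)
  dimnames(xyz) <- list(labels, c("x", "y", "z"))
  out <- list(residues = res, xyz = xyz, labels = labels, n = nrow(xyz))
  class(out) <- "ca_structure"
  out
}

# a short, non-collinear bead chain with deterministic jitter; spacing 3.0
# keeps i,i+3 contacts inside the cutoff so the network has at least 3n-6
# springs (straight or sparsely connected chains are degenerate under the
# anisotropic network)
jittered_chain <- function(n, spacing = 3.0, jitter = 0.3, seed = 2) {
  generate_fixture("linear_chain", n = n, spacing = spacing,
                   jitter = jitter, seed = seed)
}

pdb_atom_line <- function(serial, elety, resname, chain, resnum, xyz,
                          icode = " ", alt = " ", b = 0, record = "ATOM  ") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          record, serial, paste0(" ", elety), alt, resname, chain, resnum,
          icode, xyz[1], xyz[2], xyz[3], 1, b)
}

# all-atom-ish 3-residue PDB text (N + CA per residue)
three_residue_pdb <- function() {
  paste(c(
    pdb_atom_line(1, "N ", "GLY", "A", 1, c(0, 1, 0)),
    pdb_atom_line(2, "CA ", "GLY", "A", 1, c(0, 0, 0)),
    pdb_atom_line(3, "N ", "ALA", "A", 2, c(3, 4.5, 0)),
    pdb_atom_line(4, "CA ", "ALA", "A", 2, c(3, 4, 0)),
    pdb_atom_line(5, "N ", "SER", "A", 3, c(6, 0.5, 0)),
    pdb_atom_line(6, "CA ", "SER", "A", 3, c(6, 0, 0)),
    "END"), collapse = "\n")
}

rotation_matrix <- function(seed = 1) {
  set.seed(seed)
  qr_out <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_out)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

transform_structure <- function(structure, R, t = c(0, 0, 0)) {
  xyz <- structure$xyz %*% t(R)
  xyz <- sweep(xyz, 2, t, `+`)
  dimnames(xyz) <- dimnames(structure$xyz)
  structure$xyz <- xyz
  structure
}
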