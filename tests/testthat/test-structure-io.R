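test_that("PDB parsing keeps file order, skips CA-less residues, takes first altLoc and first MODEL", {
  s <- read_structure(three_residue_pdb())
  expect_s3_class(s, "ca_structure")
  expect_equal(s$n, 3)
  expect_equal(s$labels, c("A:1", "A:2", "A:3"))
  expect_equal(s$residues$resname, c("GLY", "ALA", "SER"))
  expect_equal(unname(s$xyz[2, ]), c(3, 4, 0))

  # residue 2 loses its CA -> skipped, with a warning naming it
  lines <- strsplit(three_residue_pdb(), "\n")[[1]]
  expect_warning(s2 <- read_structure(paste(lines[-4], collapse = "\n")),
                 "A:2")
  expect_equal(s2$n, 2)
  expect_equal(s2$labels, c("A:1", "A:3"))

  # two altLocs for one CA -> one record with the first-listed coordinates
  alt <- paste(c(
    pdb_atom_line(1, "CA ", "ALA", "A", 1, c(0, 0, 0), alt = "A"),
    pdb_atom_line(2, "CA ", "ALA", "A", 1, c(9, 9, 9), alt = "B"),
    pdb_atom_line(3, "CA ", "ALA", "A", 2, c(3.8, 0, 0)),
    "END"), collapse = "\n")
  s3 <- read_structure(alt)
  expect_equal(s3$n, 2)
  expect_equal(unname(s3$xyz[1, ]), c(0, 0, 0))

  # only the first MODEL of a multi-model file is read
  multi <- paste(c(
    "MODEL        1",
    pdb_atom_line(1, "CA ", "ALA", "A", 1, c(0, 0, 0)),
    pdb_atom_line(2, "CA ", "ALA", "A", 2, c(3.8, 0, 0)),
    "ENDMDL",
    "MODEL        2",
    pdb_atom_line(1, "CA ", "ALA", "A", 1, c(50, 0, 0)),
    pdb_atom_line(2, "CA ", "ALA", "A", 2, c(53.8, 0, 0)),
    "ENDMDL", "END"), collapse = "\n")
  s4 <- read_structure(multi)
  expect_equal(s4$n, 2)
  expect_equal(unname(s4$xyz[1, 1]), 0)
})

test_that("parsing errors: no CA atoms, too few residues, HETATM ignored", {
  no_ca <- paste(pdb_atom_line(1, "N ", "GLY", "A", 1, c(0, 0, 0)),
                 collapse = "\n")
  expect_error(read_structure(no_ca), "C-alpha")

  one_res <- pdb_atom_line(1, "CA ", "GLY", "A", 1, c(0, 0, 0))
  expect_error(read_structure(one_res), "fewer than 2")

  het <- paste(c(
    pdb_atom_line(1, "CA ", "ALA", "A", 1, c(0, 0, 0)),
    pdb_atom_line(2, "CA ", "ALA", "A", 2, c(3.8, 0, 0)),
    pdb_atom_line(3, "CA ", "LIG", "A", 99, c(1, 1, 1), record = "HETATM"),
    "END"), collapse = "\n")
  expect_equal(read_structure(het)$n, 2)

  # chain filter narrows the model
  two_chain <- paste(c(
    pdb_atom_line(1, "CA ", "ALA", "A", 1, c(0, 0, 0)),
    pdb_atom_line(2, "CA ", "ALA", "A", 2, c(3.8, 0, 0)),
    pdb_atom_line(3, "CA ", "ALA", "B", 1, c(20, 0, 0)),
    pdb_atom_line(4, "CA ", "ALA", "B", 2, c(23.8, 0, 0)),
    "END"), collapse = "\n")
  sb <- read_structure(two_chain, chains = "B")
  expect_equal(sb$labels, c("B:1", "B:2"))
})

test_that("distance matrix is Euclidean, symmetric, zero-diagonal", {
  s <- make_structure(rbind(c(0, 0, 0), c(3, 4, 0)))
  d <- distance_matrix(s)
  expect_equal(unname(d[1, 2]), 5)
  expect_equal(unname(d[2, 1]), 5)
  expect_equal(diag(d), stats::setNames(c(0, 0), s$labels))

  fix <- generate_fixture("cubic_cluster", n = 9, jitter = 0.2, seed = 3)
  dd <- distance_matrix(fix)
  expect_identical(dd, t(dd))
  expect_true(all(diag(dd) == 0))
  expect_true(all(dd >= 0))
})

test_that("B-factor profile writing round-trips, clamps, and validates lengths", {
  fix <- generate_fixture("ideal_helix", n = 5)
  txt <- as_pdb(fix)

  zero <- write_profile_pdb(fix, rep(0, 5), txt)
  blines <- grep("^ATOM", strsplit(zero, "\n")[[1]], value = TRUE)
  expect_true(all(substr(blines, 61, 66) == "  0.00"))

  vals <- c(-1.25, 0, 2.5, 1234567, -55555)
  out <- write_profile_pdb(fix, vals, txt)
  olines <- grep("^ATOM", strsplit(out, "\n")[[1]], value = TRUE)
  # fixed-width alignment intact: every B-factor field is exactly 6 chars
  expect_true(all(nchar(olines) == nchar(blines)))
  expect_equal(substr(olines[1], 61, 66), " -1.25")
  expect_equal(substr(olines[4], 61, 66), "999.99")
  expect_equal(substr(olines[5], 61, 66), "-99.99")

  # round-trip: re-parse and read the B column back
  reparsed <- read_structure(out)
  expect_equal(reparsed$labels, fix$labels)
  b <- as.numeric(substr(olines, 61, 66))
  expect_equal(b[1:3], vals[1:3], tolerance = 1e-9)

  expect_error(write_profile_pdb(fix, rep(0, 4), txt), "does not match")
  expect_error(write_profile_pdb(fix, c(0, 0, NA, 0, 0), txt), "finite")
})

test_that("CSV profile table has the documented shape and full precision", {
  s <- make_structure(rbind(c(0, 0, 0), c(3.8, 0, 0)),
                      resname = c("GLY", "ALA"))
  vals <- c(0.123456789, -2.7182818)
  txt <- write_profile_table(s, vals)
  lines <- strsplit(txt, "\n")[[1]]
  expect_length(lines, 3)
  expect_equal(lines[1], "chain,resnum,icode,resname,value")
  # empty insertion code is an empty field, not whitespace
  expect_match(lines[2], "^A,1,,GLY,")
  parsed <- utils::read.csv(text = txt, colClasses = c(icode = "character"))
  expect_equal(parsed$value, vals, tolerance = 1e-9)
  expect_error(write_profile_table(s, 1), "does not match")
})

test_that("parse -> annotate -> parse round-trip preserves residue count and order", {
  for (kind in c("ideal_helix", "symmetric_dimer")) {
    fix <- generate_fixture(kind, n = 10, jitter = 0.1, seed = 4)
    s <- read_structure(as_pdb(fix))
    out <- write_profile_pdb(s, seq_len(s$n) / 7, as_pdb(fix))
    s2 <- read_structure(out)
    expect_identical(s2$labels, s$labels)
    expect_equal(s2$n, fix$n)
  }
})
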