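#' Read the C-alpha representation of a protein structure
#'
#' Parses ATOM records of a PDB file (or PDB-formatted text) into the
#' coarse-grained, C-alpha-only residue model that the elastic network and
#' all downstream allostery calculations operate on.
#'
#' Parsing rules: only `ATOM` records are considered (HETATM ligands are not
#' part of the C-alpha network); for alternate locations the first-listed
#' altLoc is kept; only the first MODEL of a multi-model file is read;
#' residues lacking a C-alpha atom are skipped with a warning. Residues are
#' identified externally by PDB author numbering (`chain:resnum` plus
#' insertion code, e.g. `"A:272"`), and internally by a contiguous index in
#' file order.
#'
#' @param pdb Path to a PDB file, or a character string containing
#'   PDB-formatted text (recognised by embedded newlines), or a character
#'   vector of PDB lines.
#' @param chains Optional character vector of chain identifiers to keep.
#' @return An object of class `ca_structure`: a list with components
#'   `residues` (data frame with columns `chain`, `resnum`, `icode`,
#'   `resname`), `xyz` (N x 3 coordinate matrix, Angstrom), `labels`
#'   (residue identifiers `chain:resnum[icode]`) and `n`.
#' @examples
#' helix <- generate_fixture("ideal_helix", n = 10)
#' s <- read_structure(as_pdb(helix))
#' s$n
#' @export
read_structure <- function(pdb, chains = NULL) {
  lines <- .pdb_lines(pdb)
  # first MODEL only
  end <- grep("^ENDMDL", lines)
  if (length(end) > 0) lines <- lines[seq_len(end[1])]

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdbobj <- suppressWarnings(bio3d::read.pdb(tmp, multi = FALSE, verbose = FALSE))

  at <- pdbobj$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records found in input")
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- ""
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records left after chain filtering")

  key <- paste(at$chain, at$resno, at$insert, sep = "\r")
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0) stop("no C-alpha atoms found in input")
  # first-listed altLoc wins
  ca_key <- paste(ca$chain, ca$resno, ca$insert, sep = "\r")
  ca <- ca[!duplicated(ca_key), , drop = FALSE]
  ca_key <- ca_key[!duplicated(ca_key)]

  missing_ca <- setdiff(unique(key), ca_key)
  if (length(missing_ca) > 0) {
    lab <- vapply(strsplit(missing_ca, "\r"), function(p)
      paste0(p[1], ":", p[2], if (length(p) > 2) p[3] else ""), "")
    warning(sprintf("skipped %d residue(s) without a C-alpha atom: %s",
                    length(lab), paste(lab, collapse = ", ")))
  }
  if (nrow(ca) < 2) stop("fewer than 2 residues with C-alpha atoms after filtering")

  res <- data.frame(chain = ca$chain, resnum = ca$resno, icode = ca$insert,
                    resname = ca$resid, stringsAsFactors = FALSE)
  xyz <- cbind(x = ca$x, y = ca$y, z = ca$z)
  if (!all(is.finite(xyz))) stop("non-finite C-alpha coordinates in input")
  labels <- paste0(res$chain, ":", res$resnum, res$icode)
  if (anyDuplicated(labels)) stop("duplicate residue identifiers: ",
                                  paste(labels[duplicated(labels)], collapse = ", "))
  rownames(xyz) <- labels
  out <- list(residues = res, xyz = xyz, labels = labels, n = nrow(res))
  class(out) <- "ca_structure"
  out
}

# Accepts a path, a string of PDB text, or a vector of lines.
.pdb_lines <- function(pdb) {
  looks_like_record <- grepl(
    "^(ATOM|HETATM|MODEL|HEADER|TITLE|REMARK|CRYST1|SEQRES|TER|END)", pdb[1])
  if (length(pdb) == 1 && !grepl("\n", pdb) && !looks_like_record) {
    if (!file.exists(pdb)) stop("PDB file not found: ", pdb)
    return(readLines(pdb, warn = FALSE))
  }
  unlist(strsplit(pdb, "\n", fixed = TRUE), use.names = FALSE)
}

#' @export
print.ca_structure <- function(x, ...) {
  ch <- table(x$residues$chain)
  cat(sprintf("C-alpha structure: %d residues, %d chain(s) (%s)\n",
              x$n, length(ch),
              paste(sprintf("%s: %d", names(ch), as.integer(ch)), collapse = ", ")))
  invisible(x)
}

#' Inter-residue C-alpha distance matrix
#'
#' @param structure A [read_structure()] / [generate_fixture()] object.
#' @return N x N symmetric matrix of Euclidean C-alpha distances (Angstrom),
#'   zero diagonal, dimnames set to residue labels.
#' @export
distance_matrix <- function(structure) {
  stopifnot(inherits(structure, "ca_structure"))
  d <- as.matrix(stats::dist(structure$xyz))
  dimnames(d) <- list(structure$labels, structure$labels)
  d
}

# Resolve user residue identifiers ("A:12", "A:12B") or integer indices
# to internal indices; errors name any unknown identifier.
resolve_residues <- function(structure, ids) {
  if (is.numeric(ids)) {
    bad <- ids[ids < 1 | ids > structure$n | ids != round(ids)]
    if (length(bad) > 0) stop("residue index out of range: ",
                              paste(bad, collapse = ", "), call. = FALSE)
    return(as.integer(ids))
  }
  idx <- match(ids, structure$labels)
  if (anyNA(idx)) {
    stop("unknown residue identifier(s): ",
         paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

#' Write a per-residue profile into the B-factor column of a PDB
#'
#' Annotates a structure with a per-residue score (e.g. allosteric
#' modulation) by replacing the B-factor column of every atom of residue i
#' with `values[i]`, so the profile can be rendered as a colour gradient in
#' any molecular viewer. Atoms belonging to residues outside `structure`
#' (e.g. HETATM ligands or filtered chains) are left untouched.
#'
#' @param structure A `ca_structure` the values are indexed against.
#' @param values Numeric vector, one finite value per residue; values are
#'   formatted to 2 decimals and clamped to the fixed-width B-factor
#'   column (61-66).
#' @param pdb The PDB source (path, text or lines) to annotate; defaults to
#'   a C-alpha-only rendering of `structure` itself.
#' @param file Optional path to write the annotated text to.
#' @return The annotated PDB text as a single string (invisibly when `file`
#'   is given).
#' @export
write_profile_pdb <- function(structure, values, pdb = as_pdb(structure),
                              file = NULL) {
  stopifnot(inherits(structure, "ca_structure"))
  if (length(values) != structure$n)
    stop("length of values (", length(values), ") does not match residue count (",
         structure$n, ")")
  if (!all(is.finite(values))) stop("values must be finite")

  lines <- .pdb_lines(pdb)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(is_atom)
  if (length(idx) > 0) {
    ln <- lines[idx]
    chain <- substr(ln, 22, 22)
    resno <- suppressWarnings(as.integer(substr(ln, 23, 26)))
    icode <- sub(" ", "", substr(ln, 27, 27), fixed = TRUE)
    lab <- paste0(sub(" ", "", chain, fixed = TRUE), ":", resno, icode)
    m <- match(lab, structure$labels)
    hit <- which(!is.na(m))
    if (length(hit) > 0) {
      # clamp to what fits in 6 columns at 2 decimals
      v <- pmin(pmax(values[m[hit]], -99.99), 999.99)
      bcol <- sprintf("%6.2f", v)
      ln[hit] <- paste0(formatC(substr(ln[hit], 1, 60), width = -60),
                        bcol, substring(ln[hit], 67))
      lines[idx] <- ln
    }
  }
  out <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(out))
  }
  out
}

#' Write a per-residue profile as a CSV table
#'
#' @param structure A `ca_structure`.
#' @param values Numeric vector, one value per residue (written with full
#'   precision so re-parsing recovers them).
#' @param file Optional path; when `NULL` the CSV text is returned.
#' @param value_name Column name for the value column.
#' @return CSV text with header `chain,resnum,icode,resname,value` and one
#'   row per residue in model order (invisibly when `file` is given).
#' @export
write_profile_table <- function(structure, values, file = NULL,
                                value_name = "value") {
  stopifnot(inherits(structure, "ca_structure"))
  if (length(values) != structure$n)
    stop("length of values (", length(values), ") does not match residue count (",
         structure$n, ")")
  df <- structure$residues
  df[[value_name]] <- values
  txt <- utils::capture.output(
    utils::write.csv(df, row.names = FALSE, quote = FALSE))
  txt <- paste(txt, collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
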