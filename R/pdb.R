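## structure_io: PDB parsing, reference-ligand selection, pocket extraction
## by distance cutoff, and residue-contact edges.
##
## Internal length unit is Angstrom; cutoffs exposed in nm (multiplied by 10
## at the API boundary) because that is how pocket sizes are conventionally
## quoted. Boundaries are inclusive: distance == cutoff keeps the residue or
## edge.

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

#' Parse a PDB-format string into a structure object
#'
#' Reads `ATOM`/`HETATM` records from fixed PDB columns (coordinates in
#' Angstrom). Alternate locations are resolved to the first-listed
#' conformer. Parsing is delegated to [bio3d::read.pdb()].
#'
#' @param text A single string of PDB-format text (may contain newlines),
#'   or a character vector of lines.
#' @param id Free-text label attached to the returned structure.
#' @return An object of class `pg_structure`: a list with `atoms` (a
#'   data.frame with one row per atom: `serial`, `name`, `element`,
#'   `resname`, `chain`, `resno`, `insert`, `x`, `y`, `z`, `is_hetero`)
#'   and `id`.
#' @examples
#' s <- parse_pdb(paste0(
#'   "ATOM      1  CA  ALA A   1       1.000   2.000   3.000",
#'   "  1.00  0.00           C"))
#' s$atoms$x
#' @export
parse_pdb <- function(text, id = "structure") {
  stopifnot(is.character(text), length(text) >= 1)
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  rec <- substr(lines, 1, 6)
  is_atom <- grepl("^ATOM", rec) | grepl("^HETATM", rec)
  if (!any(is_atom)) {
    bad <- if (length(lines)) lines[1] else "<empty>"
    stop("no ATOM/HETATM records found; first line was: ", sQuote(bad))
  }
  short <- is_atom & nchar(lines) < 54  # need at least through the z column
  if (any(short)) {
    stop("malformed ATOM/HETATM record (fewer than 54 columns): ",
         sQuote(lines[which(short)[1]]))
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- tryCatch(
    bio3d::read.pdb(tf, rm.alt = TRUE, verbose = FALSE),
    error = function(e) stop("PDB parse failed: ", conditionMessage(e))
  )
  a <- pdb$atom
  atoms <- data.frame(
    serial   = as.integer(a$eleno),
    name     = trimws(a$elety),
    element  = toupper(trimws(ifelse(is.na(a$elesy) | trimws(a$elesy) == "",
                                     substr(trimws(a$elety), 1, 1), a$elesy))),
    resname  = trimws(a$resid),
    chain    = ifelse(is.na(a$chain), " ", a$chain),
    resno    = as.integer(a$resno),
    insert   = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    is_hetero = a$type == "HETATM",
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in PDB input")
  structure(list(atoms = atoms, id = id), class = "pg_structure")
}

#' Read a structure from a PDB file
#'
#' @param path Path to a PDB file.
#' @param id Label for the structure; defaults to the file name.
#' @return A `pg_structure` (see [parse_pdb()]).
#' @export
read_structure <- function(path, id = basename(path)) {
  parse_pdb(readLines(path, warn = FALSE), id = id)
}

#' @exportS3Method base::print
print.pg_structure <- function(x, ...) {
  n_het <- sum(x$atoms$is_hetero)
  cat("<pg_structure>", x$id, "\n",
      " atoms: ", nrow(x$atoms), " (", n_het, " HETATM)\n", sep = "")
  invisible(x)
}

## residue key used for grouping/sorting: chain, resno, insertion code
.res_key <- function(atoms) paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")

#' Coordinates of a reference ligand
#'
#' Selects one hetero residue (the bound reference ligand that anchors
#' pocket extraction) by residue name and/or chain + residue number, and
#' returns its atom coordinates.
#'
#' @param s A `pg_structure`.
#' @param resname 3-letter (or up to 3-character) HETATM residue name,
#'   e.g. `"LIG"`. Optional if `chain` and `resno` are given.
#' @param chain Chain identifier to disambiguate multiple copies.
#' @param resno Residue sequence number to disambiguate.
#' @return A numeric matrix (n x 3) of coordinates in Angstrom.
#' @export
ligand_coordinates <- function(s, resname = NULL, chain = NULL, resno = NULL) {
  stopifnot(inherits(s, "pg_structure"))
  het <- s$atoms[s$atoms$is_hetero, , drop = FALSE]
  if (nrow(het) == 0)
    stop("structure has no HETATM records to select a ligand from")
  keep <- rep(TRUE, nrow(het))
  if (!is.null(resname)) keep <- keep & het$resname == resname
  if (!is.null(chain))   keep <- keep & het$chain == chain
  if (!is.null(resno))   keep <- keep & het$resno == as.integer(resno)
  sel <- het[keep, , drop = FALSE]
  if (nrow(sel) == 0) {
    avail <- unique(paste0(het$resname, " (chain ", het$chain, ", resno ",
                           het$resno, ")"))
    stop("no hetero residue matches the selector; available: ",
         paste(avail, collapse = "; "))
  }
  copies <- unique(.res_key(sel))
  if (length(copies) > 1) {
    avail <- unique(paste0(sel$resname, " chain ", sel$chain, " resno ", sel$resno))
    stop("selector matches ", length(copies),
         " residue copies; disambiguate with chain/resno. Matches: ",
         paste(avail, collapse = "; "))
  }
  as.matrix(sel[, c("x", "y", "z")])
}

#' Extract the binding pocket around a reference ligand
#'
#' A residue is kept iff any of its heavy atoms lies within `cutoff_nm` of
#' any reference-ligand atom (minimum Euclidean distance, inclusive
#' boundary). Hydrogens, waters, ions and other hetero residues are never
#' pocket candidates; non-standard amino acids are dropped with a warning.
#'
#' @param s A `pg_structure`.
#' @param lig Ligand coordinates, an (n x 3) matrix in Angstrom (see
#'   [ligand_coordinates()]).
#' @param cutoff_nm Pocket cutoff in nm; 0.6 and 0.8 are the values used
#'   throughout this package's workflows.
#' @return An object of class `pg_pocket`: list with `residues` (list of
#'   `list(id, name, xyz)`, sorted by chain then residue number),
#'   `ligand` (the reference coordinates) and `cutoff_nm`.
#' @export
extract_pocket <- function(s, lig, cutoff_nm = 0.6) {
  stopifnot(inherits(s, "pg_structure"), cutoff_nm > 0)
  lig <- as.matrix(lig)
  stopifnot(ncol(lig) == 3, nrow(lig) >= 1)
  cutoff_A <- cutoff_nm * 10

  a <- s$atoms
  cand <- !a$is_hetero & a$element != "H" & a$element != "D"
  nonstd <- cand & !(a$resname %in% STANDARD_AA)
  if (any(nonstd)) {
    warning("dropping non-standard residue(s): ",
            paste(unique(a$resname[nonstd]), collapse = ", "))
    cand <- cand & !nonstd
  }
  a <- a[cand, , drop = FALSE]
  if (nrow(a) == 0) {
    warning("no standard protein heavy atoms; returning empty pocket")
    return(structure(list(residues = list(), ligand = lig,
                          cutoff_nm = cutoff_nm), class = "pg_pocket"))
  }
  P <- as.matrix(a[, c("x", "y", "z")])
  ## min distance from each protein atom to any ligand atom
  d2min <- .min_cross_dist2(P, lig)
  keyvec <- .res_key(a)
  keep_key <- unique(keyvec[d2min <= cutoff_A^2 + 1e-12])
  if (length(keep_key) == 0) {
    warning("no residues within ", cutoff_nm, " nm of the reference ligand")
    return(structure(list(residues = list(), ligand = lig,
                          cutoff_nm = cutoff_nm), class = "pg_pocket"))
  }
  a <- a[keyvec %in% keep_key, , drop = FALSE]
  keyvec <- .res_key(a)
  ord_keys <- unique(keyvec[order(a$chain, a$resno, a$insert)])
  residues <- lapply(ord_keys, function(k) {
    sub <- a[keyvec == k, , drop = FALSE]
    list(id = c(chain = sub$chain[1], resno = as.character(sub$resno[1]),
                insert = sub$insert[1]),
         name = sub$resname[1],
         xyz = as.matrix(sub[, c("x", "y", "z")]))
  })
  structure(list(residues = residues, ligand = lig, cutoff_nm = cutoff_nm),
            class = "pg_pocket")
}

## squared min distance from each row of A to the rows of B
.min_cross_dist2 <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  D2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  D2[D2 < 0] <- 0
  apply(D2, 1, min)
}

#' @exportS3Method base::print
print.pg_pocket <- function(x, ...) {
  cat("<pg_pocket> ", length(x$residues), " residues at cutoff ",
      x$cutoff_nm, " nm\n", sep = "")
  if (length(x$residues)) {
    lab <- vapply(x$residues, function(r)
      paste0(r$name, " ", r$id[["chain"]], r$id[["resno"]]), "")
    cat(" ", paste(head(lab, 12), collapse = ", "),
        if (length(lab) > 12) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Residue-contact edges of a pocket
#'
#' Two residues are connected iff their minimum heavy-atom pair distance is
#' at most `edge_cutoff_nm` (inclusive). Edges are stored symmetrically
#' (both directions); there are no self-edges.
#'
#' @param p A `pg_pocket`.
#' @param edge_cutoff_nm Contact cutoff in nm (default 0.5).
#' @return An integer matrix with columns `i`, `j` (1-based residue
#'   indices), one row per direction. Zero rows for pockets with fewer
#'   than two residues or no contacts.
#' @export
contact_edges <- function(p, edge_cutoff_nm = 0.5) {
  stopifnot(inherits(p, "pg_pocket"))
  n <- length(p$residues)
  empty <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  if (n < 2) return(empty)
  cut2 <- (edge_cutoff_nm * 10)^2 + 1e-12
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  hit <- vapply(seq_len(nrow(pairs)), function(r) {
    A <- p$residues[[pairs[r, 1]]]$xyz
    B <- p$residues[[pairs[r, 2]]]$xyz
    min(.min_cross_dist2(A, B)) <= cut2
  }, logical(1))
  if (!any(hit)) return(empty)
  ij <- pairs[hit, , drop = FALSE]
  out <- rbind(ij, ij[, 2:1, drop = FALSE])
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  colnames(out) <- c("i", "j")
  storage.mode(out) <- "integer"
  out
}

#' Write a pocket back out as a PDB fragment
#'
#' Emits column-conformant `ATOM` records for the pocket residues (atom
#' names are generic since only coordinates and residue identity are
#' retained in a pocket).
#'
#' @param p A `pg_pocket`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pocket_pdb <- function(p, path) {
  stopifnot(inherits(p, "pg_pocket"))
  lines <- character(0)
  serial <- 0L
  for (r in p$residues) {
    for (k in seq_len(nrow(r$xyz))) {
      serial <- serial + 1L
      nm <- if (k == 1) "CA" else paste0("C", k)
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nm, " ", r$name, r$id[["chain"]],
        as.integer(r$id[["resno"]]), ifelse(r$id[["insert"]] == "", " ", r$id[["insert"]]),
        r$xyz[k, 1], r$xyz[k, 2], r$xyz[k, 3], 1, 0, "C"))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
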