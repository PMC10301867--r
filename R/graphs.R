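## graph_build: ligand graphs with the five GraphDTA-style atom features
## and pocket graphs with embedding or one-hot residue features.

#' Atom symbol vocabulary for ligand featurization
#'
#' 43 elements plus a trailing `"other"` slot; fixed so that the ligand
#' feature width is constant across datasets.
#' @format Character vector of length 44.
#' @export
ATOM_VOCAB <- c("C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg",
                "Na", "Ca", "Fe", "As", "Al", "I", "B", "V", "K", "Tl",
                "Yb", "Sb", "Sn", "Ag", "Pd", "Co", "Se", "Ti", "Zn", "H",
                "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn", "Zr", "Cr",
                "Pt", "Hg", "Pb", "other")

#' Ligand feature width
#' @return Integer: `length(ATOM_VOCAB) + 4` (symbol one-hot plus heavy
#'   neighbour count, attached hydrogens, implicit valence, aromatic flag).
#' @export
ligand_feature_dim <- function() length(ATOM_VOCAB) + 4L

#' Per-atom feature vector
#'
#' Concatenates: atom-symbol one-hot over [ATOM_VOCAB] (unknown elements
#' map to the `"other"` slot), the number of adjacent heavy atoms, the
#' number of attached hydrogens, the implicit valence, and an aromatic
#' flag. "Implicit valence" is taken as the number of hydrogens supplied
#' by the valence model (`mode = "hydrogens"`, default); a
#' `"valence_gap"` mode instead reports typical valence minus heavy-atom
#' bond count, clamped at zero.
#'
#' @param mol A `pg_mol` (see [parse_smiles()]).
#' @param i Atom index (canonical order).
#' @param implicit_mode `"hydrogens"` or `"valence_gap"`.
#' @return Numeric vector of length [ligand_feature_dim()].
#' @export
atom_features <- function(mol, i, implicit_mode = c("hydrogens", "valence_gap")) {
  implicit_mode <- match.arg(implicit_mode)
  stopifnot(inherits(mol, "pg_mol"), i >= 1, i <= mol$n)
  sym <- mol$element[i]
  slot <- match(sym, ATOM_VOCAB)
  if (is.na(slot)) slot <- length(ATOM_VOCAB)
  oh <- numeric(length(ATOM_VOCAB))
  oh[slot] <- 1
  impl <- if (implicit_mode == "hydrogens") {
    mol$h_count[i]
  } else {
    typ <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1,
             I = 1, B = 3)[sym]
    if (is.na(typ)) typ <- mol$degree[i] + mol$h_count[i]
    max(0, typ - mol$degree[i])
  }
  c(oh, mol$degree[i], mol$h_count[i], impl, as.numeric(mol$aromatic[i]))
}

#' Ligand graph from a SMILES string
#'
#' Heavy atoms are nodes in canonical atom order; each bond contributes
#' one symmetric edge pair. Single-atom molecules yield zero edges and
#' are valid inputs everywhere downstream.
#'
#' @param smiles SMILES string.
#' @param implicit_mode Passed to [atom_features()].
#' @return An object of class `pg_graph` with fields `x` (node-feature
#'   matrix, n x F), `edges` (integer matrix, both directions), `n`,
#'   `kind = "ligand"` and `smiles`.
#' @export
ligand_graph <- function(smiles, implicit_mode = "hydrogens") {
  mol <- parse_smiles(smiles)
  X <- t(vapply(seq_len(mol$n), function(i)
    atom_features(mol, i, implicit_mode), numeric(ligand_feature_dim())))
  edges <- if (nrow(mol$bonds)) {
    ij <- cbind(mol$bonds$a1, mol$bonds$a2)
    ij <- t(apply(ij, 1, sort))
    out <- rbind(ij, ij[, 2:1, drop = FALSE])
    out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
    storage.mode(out) <- "integer"
    colnames(out) <- c("i", "j")
    out
  } else {
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  }
  structure(list(x = X, edges = edges, n = mol$n, kind = "ligand",
                 smiles = mol$smiles),
            class = "pg_graph")
}

#' Pocket graph from an extracted pocket
#'
#' Node i carries either the 30-dimensional molecular vector or the
#' 20-dimensional one-hot encoding of residue i; edges come from
#' [contact_edges()] at the given contact cutoff.
#'
#' @param p A `pg_pocket`.
#' @param features A `pg_residue_table` for embedding features, or the
#'   string `"onehot"`.
#' @param edge_cutoff_nm Residue-contact cutoff in nm (default 0.5).
#' @return A `pg_graph` with `kind = "pocket"` and `residue_ids` labels.
#' @export
pocket_graph <- function(p, features = "onehot", edge_cutoff_nm = 0.5) {
  stopifnot(inherits(p, "pg_pocket"))
  n <- length(p$residues)
  if (n == 0)
    stop("empty pocket: no residues within ", p$cutoff_nm,
         " nm of the reference ligand; widen the pocket cutoff")
  names_ <- vapply(p$residues, function(r) r$name, "")
  if (identical(features, "onehot")) {
    X <- t(vapply(names_, one_hot_residue, numeric(20)))
  } else if (inherits(features, "pg_residue_table")) {
    X <- features$vectors[names_, , drop = FALSE]
  } else {
    stop("features must be a pg_residue_table or \"onehot\"")
  }
  dimnames(X) <- NULL
  ids <- vapply(p$residues, function(r)
    paste0(r$id[["chain"]], ":", r$id[["resno"]], r$id[["insert"]]), "")
  structure(list(x = X, edges = contact_edges(p, edge_cutoff_nm), n = n,
                 kind = "pocket", residue_ids = ids),
            class = "pg_graph")
}

#' @exportS3Method base::print
print.pg_graph <- function(x, ...) {
  cat("<pg_graph:", x$kind, "> ", x$n, " nodes x ", ncol(x$x),
      " features, ", nrow(x$edges), " directed edges\n", sep = "")
  invisible(x)
}

## Symmetric-normalized adjacency with self loops (Kipf convention),
## cached on the graph object by callers.
graph_ahat <- function(g) {
  n <- g$n
  i <- c(g$edges[, 1], seq_len(n))
  j <- c(g$edges[, 2], seq_len(n))
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  d <- Matrix::rowSums(A)
  Dm <- Matrix::Diagonal(n, 1 / sqrt(d))
  Dm %*% A %*% Dm
}
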