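## Molecule handling. SMILES are canonicalized and perceived (aromaticity,
## hydrogen counts) through Open Babel (ChemmineOB); the light MOL2 text
## emitted by the converter carries exactly the per-atom information the
## featurizers need (SYBYL atom types mark aromaticity, explicit H fill-in
## gives hydrogen counts). Circular substructure identifiers (ECFP-style,
## used both for mol2vec-style sentences and for folded fingerprints) are
## computed here.

## Deterministic string hash: polynomial rolling hash modulo a prime below
## 2^29 so every intermediate stays exactly representable in a double.
.HASH_P <- 536870909
hash_string <- function(s) {
  b <- utf8ToInt(s)
  h <- 17
  for (x in b) h <- (h * 31 + x) %% .HASH_P
  h
}

.mol_cache <- new.env(parent = emptyenv())

.ob_convert <- function(from, to, src, add_h = FALSE) {
  if (add_h) {
    suppressWarnings(ChemmineOB::convertFormat(
      from, to, source = src, options = data.frame(names = "h", args = "")))
  } else {
    suppressWarnings(ChemmineOB::convertFormat(from, to, source = src))
  }
}

#' Parse a SMILES string into an internal molecule object
#'
#' The SMILES is canonicalized first so that atom order (and hence graph
#' node order) is deterministic for all inputs denoting the same molecule.
#' Hydrogens are implicit: nodes are heavy atoms only.
#'
#' @param smiles A single SMILES string.
#' @return An object of class `pg_mol`: list with `smiles` (canonical),
#'   `element`, `aromatic`, `h_count`, `degree` (heavy-atom degree) per
#'   atom, and `bonds` (data.frame `a1`, `a2`, `type` with SYBYL bond
#'   types: "1", "2", "3", "am", "ar").
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  if (!nzchar(trimws(smiles))) stop("empty SMILES string")
  key <- smiles
  hit <- get0(key, envir = .mol_cache)
  if (!is.null(hit)) return(hit)
  can <- trimws(.ob_convert("SMI", "CAN", smiles))
  if (!nzchar(can))
    stop("unparsable SMILES: ", sQuote(smiles))
  can <- strsplit(can, "[ \t]")[[1]][1]
  m2 <- .ob_convert("SMI", "MOL2", can, add_h = TRUE)
  if (!nzchar(m2)) stop("unparsable SMILES: ", sQuote(smiles))
  mol <- .parse_mol2(m2, can)
  if (mol$n == 0) stop("SMILES has no heavy atoms: ", sQuote(smiles))
  assign(key, mol, envir = .mol_cache)
  mol
}

.parse_mol2 <- function(text, can) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  ia <- grep("^@<TRIPOS>ATOM", lines)[1]
  ib <- grep("^@<TRIPOS>BOND", lines)[1]
  sect_end <- c(grep("^@<TRIPOS>", lines), length(lines) + 1L)
  atom_lines <- lines[(ia + 1):(min(sect_end[sect_end > ia]) - 1L)]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  bond_lines <- if (is.na(ib) || ib >= length(lines)) character(0) else {
    bl <- lines[(ib + 1):(min(sect_end[sect_end > ib], length(lines) + 1L) - 1L)]
    bl <- bl[!is.na(bl)]
    bl[nzchar(trimws(bl))]
  }
  af <- do.call(rbind, strsplit(trimws(atom_lines), "[ \t]+"))
  typ <- af[, 6]
  elem <- toupper(sub("\\..*$", "", typ))
  elem <- paste0(substr(elem, 1, 1), tolower(substr(elem, 2, 2)))
  aromatic <- grepl("\\.ar$", typ)
  nb <- length(bond_lines)
  b1 <- integer(nb); b2 <- integer(nb); bt <- character(nb)
  if (nb) {
    bf <- do.call(rbind, strsplit(trimws(bond_lines), "[ \t]+"))
    b1 <- as.integer(bf[, 2]); b2 <- as.integer(bf[, 3]); bt <- bf[, 4]
  }
  heavy <- elem != "H"
  idx <- cumsum(heavy)           # old index -> new heavy index
  n <- sum(heavy)
  h_count <- integer(n); degree <- integer(n)
  keep <- logical(nb)
  for (k in seq_len(nb)) {
    u <- b1[k]; v <- b2[k]
    if (heavy[u] && heavy[v]) {
      keep[k] <- TRUE
      degree[idx[u]] <- degree[idx[u]] + 1L
      degree[idx[v]] <- degree[idx[v]] + 1L
    } else if (heavy[u] && !heavy[v]) {
      h_count[idx[u]] <- h_count[idx[u]] + 1L
    } else if (!heavy[u] && heavy[v]) {
      h_count[idx[v]] <- h_count[idx[v]] + 1L
    }
  }
  bonds <- data.frame(a1 = idx[b1[keep]], a2 = idx[b2[keep]],
                      type = bt[keep], stringsAsFactors = FALSE)
  structure(list(smiles = can, n = n, element = elem[heavy],
                 aromatic = aromatic[heavy], h_count = h_count,
                 degree = degree, bonds = bonds),
            class = "pg_mol")
}

#' @exportS3Method base::print
print.pg_mol <- function(x, ...) {
  cat("<pg_mol> ", x$smiles, " (", x$n, " heavy atoms, ",
      nrow(x$bonds), " bonds)\n", sep = "")
  invisible(x)
}

#' Circular substructure identifiers per atom
#'
#' ECFP-style (Morgan) identifiers: the radius-0 identifier hashes the
#' atom's element, heavy degree, hydrogen count and aromaticity; the
#' radius-r identifier hashes the atom's radius-(r-1) identifier together
#' with the sorted (bond type, neighbour radius-(r-1) identifier) pairs.
#'
#' @param mol A `pg_mol` (or a SMILES string).
#' @param radius Maximum neighbourhood radius.
#' @return Integer-valued numeric matrix (n_atoms x (radius + 1)); column
#'   r + 1 holds the radius-r identifiers.
#' @export
morgan_identifiers <- function(mol, radius = 1) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  stopifnot(inherits(mol, "pg_mol"), radius >= 0)
  n <- mol$n
  ids <- matrix(0, n, radius + 1)
  for (i in seq_len(n)) {
    ids[i, 1] <- hash_string(paste(mol$element[i], mol$degree[i],
                                   mol$h_count[i], as.integer(mol$aromatic[i]),
                                   sep = "|"))
  }
  if (radius >= 1 && n > 0) {
    nbr <- vector("list", n); btype <- vector("list", n)
    for (k in seq_len(nrow(mol$bonds))) {
      u <- mol$bonds$a1[k]; v <- mol$bonds$a2[k]; t <- mol$bonds$type[k]
      nbr[[u]] <- c(nbr[[u]], v); btype[[u]] <- c(btype[[u]], t)
      nbr[[v]] <- c(nbr[[v]], u); btype[[v]] <- c(btype[[v]], t)
    }
    for (r in seq_len(radius)) {
      for (i in seq_len(n)) {
        if (length(nbr[[i]])) {
          env <- sort(paste0(btype[[i]], ":", ids[nbr[[i]], r]))
          ids[i, r + 1] <- hash_string(paste(ids[i, r],
                                             paste(env, collapse = ","),
                                             sep = "!"))
        } else {
          ids[i, r + 1] <- hash_string(paste(ids[i, r], "!", sep = ""))
        }
      }
    }
  }
  ids
}

#' Substructure sentence of a molecule
#'
#' The mol2vec sentence convention: for each atom in (canonical) atom
#' order, its circular substructure identifiers for radii 0..`radius` are
#' emitted consecutively, so the sentence length is
#' `n_atoms * (radius + 1)`.
#'
#' @param smiles SMILES string (or a `pg_mol`).
#' @param radius Maximum substructure radius (default 1, the published
#'   mol2vec convention).
#' @return Character vector of substructure identifiers.
#' @export
substructure_sentence <- function(smiles, radius = 1) {
  ids <- morgan_identifiers(smiles, radius)
  as.character(as.vector(t(ids)))
}

#' Folded circular fingerprint
#'
#' Binary fingerprint obtained by folding all substructure identifiers up
#' to `radius` into `nbits` buckets.
#'
#' @param smiles SMILES string (or a `pg_mol`).
#' @param radius Substructure radius (default 2, ECFP4-like).
#' @param nbits Fingerprint length (default 2048).
#' @return Integer vector of 0/1 of length `nbits`.
#' @export
morgan_fingerprint <- function(smiles, radius = 2, nbits = 2048) {
  ids <- morgan_identifiers(smiles, radius)
  fp <- integer(nbits)
  fp[(as.vector(ids) %% nbits) + 1] <- 1L
  fp
}
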