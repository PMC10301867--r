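## Pair examples and lossless dataset serialization.
##
## A dataset is a plain list of pair examples. Serialization writes a
## single JSON file with a versioned manifest; unique pockets and ligands
## are stored once and referenced from the pair table. Doubles are
## formatted with 17 significant digits so matrices round-trip bit-exactly
## through plain text.

DATASET_FORMAT_VERSION <- "1"

#' Construct a protein-ligand pair example
#'
#' @param pocket_graph A `pg_graph` of kind `"pocket"`.
#' @param ligand_graph A `pg_graph` of kind `"ligand"`.
#' @param label Numeric: 0/1 for the binder-classification head, a pKa for
#'   the affinity head.
#' @param provenance Free-text tag, e.g. `"positive"`, `"cross-negative"`,
#'   `"affinity:Kd"`.
#' @param pocket_id,ligand_id Identifiers forming the pair key.
#' @return An object of class `pg_pair`.
#' @export
pair_example <- function(pocket_graph, ligand_graph, label,
                         provenance = "positive",
                         pocket_id = "pocket", ligand_id = "ligand") {
  stopifnot(is.numeric(label), length(label) == 1, is.finite(label))
  structure(list(pocket_graph = pocket_graph, ligand_graph = ligand_graph,
                 label = label, provenance = provenance,
                 pair_key = paste(pocket_id, ligand_id, sep = "::"),
                 pocket_id = pocket_id, ligand_id = ligand_id),
            class = "pg_pair")
}

#' @exportS3Method base::print
print.pg_pair <- function(x, ...) {
  cat("<pg_pair> ", x$pair_key, " label=", x$label,
      " (", x$provenance, ")\n", sep = "")
  invisible(x)
}

.graph_to_json <- function(g) {
  list(kind = g$kind, n = g$n,
       x = apply(g$x, 1, function(r) paste(fmt_dbl(r), collapse = " ")),
       ncol = ncol(g$x),
       edges_i = as.integer(g$edges[, 1]), edges_j = as.integer(g$edges[, 2]),
       smiles = if (!is.null(g$smiles)) g$smiles else NULL,
       residue_ids = if (!is.null(g$residue_ids)) g$residue_ids else NULL)
}

.graph_from_json <- function(j) {
  X <- t(vapply(as.character(j$x),
                function(r) as.numeric(strsplit(r, " ", fixed = TRUE)[[1]]),
                numeric(j$ncol)))
  dimnames(X) <- NULL
  if (j$n == 1 && nrow(X) != 1) X <- matrix(as.vector(X), 1, j$ncol)
  edges <- cbind(i = as.integer(j$edges_i), j = as.integer(j$edges_j))
  g <- list(x = X, edges = edges, n = as.integer(j$n), kind = j$kind)
  if (!is.null(j$smiles)) g$smiles <- j$smiles
  if (!is.null(j$residue_ids)) g$residue_ids <- as.character(j$residue_ids)
  structure(g, class = "pg_graph")
}

#' Serialize a dataset of pair examples
#'
#' Lossless, versioned plain-text (JSON) serialization. Pockets and
#' ligands shared by many pairs are stored once.
#'
#' @param examples List of `pg_pair` objects.
#' @param path Output file path (.json).
#' @return The manifest (list), invisibly.
#' @export
serialize_dataset <- function(examples, path) {
  stopifnot(is.list(examples), all(vapply(examples, inherits, TRUE, "pg_pair")))
  pocket_ids <- vapply(examples, function(e) e$pocket_id, "")
  ligand_ids <- vapply(examples, function(e) e$ligand_id, "")
  upo <- !duplicated(pocket_ids)
  uli <- !duplicated(ligand_ids)
  pockets <- setNames(lapply(examples[upo], function(e)
    .graph_to_json(e$pocket_graph)), pocket_ids[upo])
  ligands <- setNames(lapply(examples[uli], function(e)
    .graph_to_json(e$ligand_graph)), ligand_ids[uli])
  pairs <- data.frame(
    pocket_id = pocket_ids, ligand_id = ligand_ids,
    label = vapply(examples, function(e) fmt_dbl(e$label), ""),
    provenance = vapply(examples, function(e) e$provenance, ""),
    stringsAsFactors = FALSE)
  manifest <- list(format = "pocketgcn-dataset",
                   version = DATASET_FORMAT_VERSION,
                   n_pairs = length(examples),
                   n_pockets = sum(upo), n_ligands = sum(uli),
                   pocket_dim = ncol(examples[[1]]$pocket_graph$x),
                   ligand_dim = ncol(examples[[1]]$ligand_graph$x))
  obj <- list(manifest = manifest, pockets = pockets, ligands = ligands,
              pairs = pairs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Load a serialized dataset
#'
#' @param path Path written by [serialize_dataset()].
#' @return List of `pg_pair` objects with the manifest as attribute
#'   `"manifest"`.
#' @export
load_dataset <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("cannot read dataset (truncated or not JSON): ",
                         conditionMessage(e)))
  man <- obj$manifest
  if (is.null(man$format) || man$format != "pocketgcn-dataset")
    stop("not a pocketgcn dataset file: ", path)
  if (!identical(as.character(man$version), DATASET_FORMAT_VERSION))
    stop("dataset format version ", man$version,
         " does not match supported version ", DATASET_FORMAT_VERSION)
  pockets <- lapply(obj$pockets, .graph_from_json)
  ligands <- lapply(obj$ligands, .graph_from_json)
  pairs <- obj$pairs
  if (length(pairs) != man$n_pairs)
    stop("dataset truncated: manifest promises ", man$n_pairs,
         " pairs, found ", length(pairs))
  out <- lapply(pairs, function(p) {
    pair_example(pockets[[p$pocket_id]], ligands[[p$ligand_id]],
                 as.numeric(p$label), p$provenance,
                 p$pocket_id, p$ligand_id)
  })
  attr(out, "manifest") <- man
  out
}
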