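## screening: BC-filter -> RG-rank virtual screening of a SMILES library
## against one pocket, with fingerprint Ward clustering of the
## candidates and medoid representatives.

#' Screening configuration
#'
#' @param bc_threshold Minimum binder probability to pass (default
#'   0.99; the screening convention is that candidates score
#'   essentially 1 on the classifier).
#' @param rg_threshold Minimum predicted pKa to pass (default 8.6, the
#'   candidate rule used in the screening workflow).
#' @param k_clusters Number of Ward clusters for candidate grouping
#'   (default 6).
#' @param fp_radius,fp_bits Fingerprint parameters (default radius 2,
#'   2048 bits).
#' @param seed Recorded in run manifests.
#' @return An object of class `pg_screen_config`.
#' @export
screen_config <- function(bc_threshold = 0.99, rg_threshold = 8.6,
                          k_clusters = 6, fp_radius = 2, fp_bits = 2048,
                          seed = 1) {
  stopifnot(bc_threshold >= 0, bc_threshold <= 1, k_clusters >= 1)
  structure(list(bc_threshold = bc_threshold, rg_threshold = rg_threshold,
                 k_clusters = as.integer(k_clusters),
                 fp_radius = as.integer(fp_radius),
                 fp_bits = as.integer(fp_bits), seed = as.integer(seed)),
            class = "pg_screen_config")
}

#' Screen a SMILES library against one pocket
#'
#' Scores every parseable compound with the bc model (binding
#' probability) and the rg model (predicted pKa); a compound passes iff
#' its scores reach both thresholds (or the rg threshold alone when no
#' bc model is supplied). Unparsable SMILES are skipped and counted.
#' Processing is chunked so memory is constant in library size.
#'
#' @param bc_model A `pg_gcn` with bc head, or `NULL` for rg-only
#'   screening.
#' @param rg_model A `pg_gcn` with rg head, or `NULL`.
#' @param pocket A `pg_graph` of kind `"pocket"`.
#' @param library Character vector of SMILES, or data.frame with
#'   `smiles` and optional `id` columns.
#' @param cfg A `pg_screen_config`.
#' @param chunk Compounds per scoring chunk (default 256).
#' @return data.frame of class `pg_screen`: `compound_id`, `smiles`,
#'   `bc_score`, `rg_score`, `passed`, sorted by `rg_score` (then
#'   `bc_score`) descending; the number of skipped compounds is in
#'   `attr(x, "n_skipped")`.
#' @export
screen_library <- function(bc_model, rg_model, pocket, library,
                           cfg = screen_config(), chunk = 256L) {
  stopifnot(inherits(cfg, "pg_screen_config"))
  if (is.null(bc_model) && is.null(rg_model))
    stop("at least one of bc_model, rg_model is required")
  if (is.character(library))
    library <- data.frame(smiles = library, stringsAsFactors = FALSE)
  if (is.null(library$id))
    library$id <- sprintf("CPD%05d", seq_len(nrow(library)))
  if (nrow(library) == 0) {
    warning("empty library")
    out <- data.frame(compound_id = character(0), smiles = character(0),
                      bc_score = numeric(0), rg_score = numeric(0),
                      passed = logical(0))
    attr(out, "n_skipped") <- 0L
    class(out) <- c("pg_screen", class(out))
    return(out)
  }
  res <- vector("list", ceiling(nrow(library) / chunk))
  n_skipped <- 0L
  for (ci in seq_along(res)) {
    i1 <- (ci - 1L) * chunk + 1L
    i2 <- min(ci * chunk, nrow(library))
    sub <- library[i1:i2, , drop = FALSE]
    graphs <- lapply(sub$smiles, function(s)
      tryCatch(ligand_graph(s), error = function(e) NULL))
    ok <- !vapply(graphs, is.null, TRUE)
    n_skipped <- n_skipped + sum(!ok)
    if (!any(ok)) next
    pairs <- lapply(graphs[ok], function(g) pair_example(pocket, g, 0))
    bc <- if (!is.null(bc_model)) predict_pairs(bc_model, pairs)
          else rep(NA_real_, sum(ok))
    rg <- if (!is.null(rg_model)) predict_pairs(rg_model, pairs)
          else rep(NA_real_, sum(ok))
    res[[ci]] <- data.frame(compound_id = sub$id[ok],
                            smiles = sub$smiles[ok],
                            bc_score = bc, rg_score = rg,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(out)) {
    warning("no parseable compounds in library")
    out <- data.frame(compound_id = character(0), smiles = character(0),
                      bc_score = numeric(0), rg_score = numeric(0))
  }
  pass_bc <- if (is.null(bc_model)) TRUE else out$bc_score >= cfg$bc_threshold
  pass_rg <- if (is.null(rg_model)) TRUE else out$rg_score >= cfg$rg_threshold
  out$passed <- pass_bc & pass_rg
  key <- if (!is.null(rg_model)) out$rg_score else out$bc_score
  tie <- if (!is.null(bc_model)) out$bc_score else rep(0, nrow(out))
  out <- out[order(-key, -tie, out$compound_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("pg_screen", class(out))
  out
}

#' Cluster candidate compounds and pick representatives
#'
#' Ward agglomerative clustering (on the Euclidean embedding of the
#' binary circular fingerprints, since Ward's criterion requires
#' Euclidean geometry) cut at `k` clusters; each cluster's
#' representative is its medoid under Tanimoto distance (minimum summed
#' distance to the other members, lowest index on ties).
#'
#' @param smiles Character vector of candidate SMILES.
#' @param k Number of clusters (default 6; reduced with a warning when
#'   there are fewer candidates).
#' @param cfg A `pg_screen_config` (fingerprint parameters).
#' @return data.frame with `smiles`, `cluster`, `is_medoid`.
#' @export
cluster_candidates <- function(smiles, k = 6, cfg = screen_config()) {
  n <- length(smiles)
  stopifnot(n >= 1)
  if (n < k) {
    warning("only ", n, " candidates; reducing k from ", k, " to ", n)
    k <- n
  }
  FP <- do.call(rbind, lapply(smiles, morgan_fingerprint,
                              radius = cfg$fp_radius, nbits = cfg$fp_bits))
  ## cluster in a canonical row order so the partition (and medoids) do
  ## not depend on input order, then map assignments back
  canon <- order(vapply(seq_len(n), function(i)
    paste(c(FP[i, ], utf8ToInt(smiles[i])), collapse = ""), ""))
  cl <- integer(n)
  if (k == n) {
    cl <- seq_len(n)
  } else if (k == 1) {
    cl[] <- 1L
  } else {
    hc <- hclust(dist(FP[canon, , drop = FALSE]), method = "ward.D2")
    cl[canon] <- unname(cutree(hc, k = k))
  }
  ## Tanimoto distance for medoid selection
  inter <- tcrossprod(FP)
  ones <- rowSums(FP)
  union <- outer(ones, ones, "+") - inter
  TD <- 1 - ifelse(union > 0, inter / union, 1)
  crank <- integer(n); crank[canon] <- seq_len(n)
  is_medoid <- logical(n)
  for (g in unique(cl)) {
    idx <- which(cl == g)
    ssum <- rowSums(TD[idx, idx, drop = FALSE])
    best <- idx[abs(ssum - min(ssum)) < 1e-12]
    is_medoid[best[which.min(crank[best])]] <- TRUE  # canonical tie-break
  }
  data.frame(smiles = smiles, cluster = cl, is_medoid = is_medoid,
             stringsAsFactors = FALSE)
}

#' Run the screening workflow end to end
#'
#' [extract_pocket()] -> [pocket_graph()] -> [screen_library()] ->
#' [cluster_candidates()] on the passed compounds; writes a ranked TSV,
#' a cluster report and a JSON run manifest (thresholds, seed, counts).
#' Downstream docking/simulation stages are represented by the exported
#' candidate list (`candidates.smi`), the hand-off point for external
#' tools.
#'
#' @param receptor_path PDB file of the receptor with its reference
#'   ligand.
#' @param ligand_resname HETATM residue name selecting the reference
#'   ligand (alternatively give `ligand_chain` + `ligand_resno`).
#' @param ligand_chain,ligand_resno Optional selector components.
#' @param library data.frame with `smiles` (and optional `id`), or a
#'   path to a .smi file (SMILES first token, optional id second).
#' @param bc_model,rg_model `pg_gcn` models (either may be `NULL`).
#' @param features Pocket features: `pg_residue_table` or `"onehot"`.
#' @param cutoff_nm Pocket cutoff (default 0.8, the screening
#'   convention).
#' @param cfg A `pg_screen_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `records`, `clusters`, `manifest`.
#' @export
run_screen <- function(receptor_path, ligand_resname = NULL,
                       ligand_chain = NULL, ligand_resno = NULL,
                       library, bc_model = NULL, rg_model = NULL,
                       features = "onehot", cutoff_nm = 0.8,
                       cfg = screen_config(), out_dir = ".") {
  s <- read_structure(receptor_path)
  lig <- ligand_coordinates(s, resname = ligand_resname,
                            chain = ligand_chain, resno = ligand_resno)
  pk <- extract_pocket(s, lig, cutoff_nm = cutoff_nm)
  pg <- pocket_graph(pk, features = features)
  if (is.character(library) && length(library) == 1 && file.exists(library))
    library <- read_smi(library)
  rec <- screen_library(bc_model, rg_model, pg, library, cfg = cfg)
  cand <- rec[rec$passed, , drop = FALSE]
  clusters <- NULL
  if (nrow(cand) > 0) {
    clusters <- cluster_candidates(cand$smiles, k = cfg$k_clusters, cfg = cfg)
    clusters <- cbind(compound_id = cand$compound_id, clusters)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.table(format_screen(rec), file.path(out_dir, "ranked.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(clusters))
    write.table(clusters, file.path(out_dir, "clusters.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(cand) > 0)
    writeLines(paste(cand$smiles, cand$compound_id),
               file.path(out_dir, "candidates.smi"))
  manifest <- list(receptor = basename(receptor_path),
                   pocket_residues = pg$n, cutoff_nm = cutoff_nm,
                   n_library = nrow(rec) + attr(rec, "n_skipped"),
                   n_scored = nrow(rec),
                   n_skipped = attr(rec, "n_skipped"),
                   n_passed = nrow(cand),
                   bc_threshold = cfg$bc_threshold,
                   rg_threshold = cfg$rg_threshold,
                   k_clusters = cfg$k_clusters, seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("pocketgcn")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(records = rec, clusters = clusters, manifest = manifest))
}

## fixed-precision screen table so re-runs are byte-identical
format_screen <- function(rec) {
  data.frame(compound_id = rec$compound_id, smiles = rec$smiles,
             bc_score = sprintf("%.6f", rec$bc_score),
             rg_score = sprintf("%.6f", rec$rg_score),
             passed = rec$passed, stringsAsFactors = FALSE)
}

#' Read a .smi file
#'
#' One compound per line: SMILES first token, optional id second token.
#'
#' @param path File path.
#' @return data.frame with `smiles` and `id`.
#' @export
read_smi <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln))]
  parts <- strsplit(trimws(ln), "[ \t]+")
  data.frame(smiles = vapply(parts, `[`, "", 1),
             id = vapply(seq_along(parts), function(i)
               if (length(parts[[i]]) > 1) parts[[i]][2]
               else sprintf("CPD%05d", i), ""),
             stringsAsFactors = FALSE)
}
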