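## synthetic_fixtures: desk-scale toy complexes, SMILES libraries and
## planted affinity labels. The planted signal rides on features the
## network actually sees -- pocket residue composition (hydrophobicity
## latent h) and ligand aromatic content (latent a) -- so that learning it
## demonstrates use of the representations, not of graph size.

.HYDROPHOBIC_AA <- c("PHE", "TRP", "TYR", "LEU", "ILE", "VAL", "MET", "ALA")
.POLAR_AA <- c("SER", "THR", "ASN", "GLN", "ASP", "GLU", "LYS", "ARG",
               "HIS", "GLY", "PRO", "CYS")

.unit_vec <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

.pdb_atom_line <- function(serial, name, resname, chain, resno, xyz,
                           hetero = FALSE, element = "C") {
  sprintf("%-6s%5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (hetero) "HETATM" else "ATOM", serial, name, " ", resname,
          chain, resno, " ", xyz[1], xyz[2], xyz[3], 1, 0, element)
}

#' Generate a toy receptor-ligand complex
#'
#' Residues are placed on jittered shells around a planted ligand at the
#' origin with safe margins so that pocket extraction at 0.6 nm recovers
#' exactly the inner shell and extraction at 0.8 nm the inner plus
#' middle shells: inner-shell atoms lie within 6 A of the ligand, middle
#' shell within (6, 8], outer shell beyond 8 A. Residue identities are
#' drawn with hydrophobic probability `h` (the planted pocket latent).
#' The same seed reproduces the file byte-identically.
#'
#' @param seed RNG seed.
#' @param n_residues Total residues (>= 3); split across the three
#'   shells as evenly as possible.
#' @param h Hydrophobicity bias in `[0, 1]`; probability that each
#'   residue is drawn from the hydrophobic set.
#' @param ligand_smiles Optional SMILES recorded for the complex (the
#'   toy HETATM ligand in the file is a 5-atom anchor; the SMILES is the
#'   chemistry the complex is paired with downstream).
#' @return List with `pdb` (PDB text), `smiles`, and `ledger`: seed,
#'   latents, per-shell residue ids (`chain:resno`), atom and residue
#'   counts.
#' @export
make_toy_complex <- function(seed, n_residues = 12, h = 0.5,
                             ligand_smiles = "c1ccccc1") {
  stopifnot(n_residues >= 3, h >= 0, h <= 1)
  with_seed(seed, {
    n_in <- ceiling(n_residues / 3)
    n_mid <- ceiling((n_residues - n_in) / 2)
    n_out <- n_residues - n_in - n_mid
    shells <- rep(c("inner", "middle", "outer"), c(n_in, n_mid, n_out))
    ## CA radius ranges per shell; atom jitter <= 0.4 A and ligand atoms
    ## within 0.3 A of the origin keep min distances strictly inside
    ## (<= 5.9), (6.2, 7.9) and (>= 8.3) respectively.
    r_rng <- list(inner = c(4.8, 5.4), middle = c(6.9, 7.2),
                  outer = c(9.2, 10.0))
    lig_xyz <- t(vapply(1:5, function(i) .unit_vec() * runif(1, 0, 0.3),
                        numeric(3)))
    lines <- character(0)
    serial <- 0L
    res_names <- character(n_residues)
    for (i in seq_len(n_residues)) {
      res_names[i] <- if (runif(1) < h) sample(.HYDROPHOBIC_AA, 1)
                      else sample(.POLAR_AA, 1)
      rr <- r_rng[[shells[i]]]
      ca <- .unit_vec() * runif(1, rr[1], rr[2])
      for (k in 1:3) {
        serial <- serial + 1L
        at <- if (k == 1) ca else ca + .unit_vec() * runif(1, 0, 0.4)
        lines <- c(lines, .pdb_atom_line(serial, c("CA", "CB", "CG")[k],
                                         res_names[i], "A", i, at))
      }
    }
    for (k in 1:5) {
      serial <- serial + 1L
      lines <- c(lines, .pdb_atom_line(serial, paste0("C", k), "LIG", "L",
                                       1L, lig_xyz[k, ], hetero = TRUE))
    }
    pdb <- paste(c(lines, "END"), collapse = "\n")
    ids <- paste0("A:", seq_len(n_residues))
    ledger <- list(seed = seed, n_residues = n_residues, h = h,
                   n_atoms = serial,
                   residue_names = res_names,
                   inner_ids = ids[shells == "inner"],
                   middle_ids = ids[shells == "middle"],
                   outer_ids = ids[shells == "outer"])
    list(pdb = pdb, smiles = ligand_smiles, ledger = ledger)
  })
}

#' Generate a toy SMILES library
#'
#' Compounds are assembled from a small fragment grammar restricted to
#' drug-like valences, so every emitted SMILES parses. Each compound
#' carries a latent aromatic bias `a` in `[0, 1]`: of its fragments, a
#' `round(a * n_units)` share are benzene rings (the rest drawn from an
#' aliphatic set), so the realized aromatic-atom fraction correlates
#' strongly with `a`.
#'
#' @param n Number of compounds.
#' @param seed RNG seed.
#' @return data.frame with columns `id`, `smiles`, `aromatic_latent`.
#' @export
make_toy_library <- function(n, seed = 1) {
  stopifnot(n >= 1)
  aliphatic <- c("C", "CC", "CCC", "CO", "CN", "C(C)C")
  with_seed(seed, {
    a <- runif(n)
    smiles <- vapply(seq_len(n), function(i) {
      n_units <- sample(3:6, 1)
      n_arom <- round(a[i] * n_units)
      units <- c(rep("c1ccccc1", n_arom),
                 sample(aliphatic, n_units - n_arom, replace = TRUE))
      paste(sample(units), collapse = "")
    }, "")
    data.frame(id = sprintf("CPD%05d", seq_len(n)), smiles = smiles,
               aromatic_latent = a, stringsAsFactors = FALSE)
  })
}

#' Planted affinity labels
#'
#' `pKa = 3 + 8 * h * a + eps`, `eps ~ Normal(0, noise_sd)`; the binary
#' binder label is `pKa >= 7`. Both latents are recoverable from the
#' observable graphs (pocket residue composition, ligand aromatic
#' fraction), so a graph network can learn the signal.
#'
#' @param h Pocket hydrophobicity latent(s) in `[0, 1]`.
#' @param a Ligand aromatic latent(s) in `[0, 1]`.
#' @param noise_sd Gaussian noise standard deviation (default 0.3).
#' @param seed RNG seed (optional; when `NULL` the current RNG stream is
#'   used).
#' @return data.frame with columns `pka` and `label`.
#' @export
planted_affinity <- function(h, a, noise_sd = 0.3, seed = NULL) {
  stopifnot(length(h) == length(a) || length(h) == 1 || length(a) == 1)
  n <- max(length(h), length(a))
  f <- function() {
    pka <- 3 + 8 * h * a + (if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0)
    data.frame(pka = pka, label = as.integer(pka >= 7))
  }
  if (is.null(seed)) f() else with_seed(seed, f())
}

#' Build a planted-signal benchmark through the real featurization path
#'
#' Generates `n_complexes` toy complexes (pocket latent h ~ U(0,1)) and a
#' toy ligand library (latent a ~ U(0,1)); assigns each complex a native
#' ligand; featurizes every pocket via [parse_pdb()], [extract_pocket()]
#' and [pocket_graph()] and every ligand via [ligand_graph()]; adds
#' cross-combination negatives at the given ratio; labels every pair by
#' [planted_affinity()]; and splits pairs train/test disjointly.
#'
#' @param n_complexes Number of complexes (= positive pairs).
#' @param library_size Size of the ligand library.
#' @param seed Master seed; every sub-step derives its seed from it.
#' @param noise_sd Label noise (default 0.3).
#' @param cutoff_nm Pocket cutoff used in featurization (default 0.6).
#' @param features Pocket node features: a `pg_residue_table` or
#'   `"onehot"` (default).
#' @param neg_ratio Cross-negatives per positive (default 3).
#' @param fractions Split fractions (default 0.8/0.2).
#' @return List with `train`, `test` (lists of `pg_pair` whose `label`
#'   is the planted pKa; binary labels in `attr(pair, "label_bc")` via
#'   the `label_bc` field of each pair), and `ledger` (a
#'   `pg_fixture_ledger` recording seeds, counts and latents).
#' @export
make_benchmark <- function(n_complexes = 500, library_size = 300, seed = 1,
                           noise_sd = 0.3, cutoff_nm = 0.6,
                           features = "onehot", neg_ratio = 3,
                           fractions = c(train = 0.8, test = 0.2)) {
  stopifnot(n_complexes >= 2, library_size >= 2)
  lib <- make_toy_library(library_size, seed = seed)
  comp <- with_seed(seed, {
    data.frame(pocket_id = sprintf("PKT%05d", seq_len(n_complexes)),
               h = runif(n_complexes),
               sub_seed = sample.int(2^30, n_complexes),
               native = sample(lib$id, n_complexes, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  ## featurize unique ligands
  lig_graphs <- setNames(lapply(lib$smiles, ligand_graph), lib$id)
  a_of <- setNames(lib$aromatic_latent, lib$id)
  ## featurize pockets through the real path
  pkt_graphs <- setNames(vector("list", n_complexes), comp$pocket_id)
  for (i in seq_len(n_complexes)) {
    tc <- make_toy_complex(comp$sub_seed[i], n_residues = 12, h = comp$h[i])
    s <- parse_pdb(tc$pdb, id = comp$pocket_id[i])
    pk <- extract_pocket(s, ligand_coordinates(s, resname = "LIG"),
                         cutoff_nm = cutoff_nm)
    pkt_graphs[[i]] <- pocket_graph(pk, features = features)
  }
  positives <- data.frame(pocket_id = comp$pocket_id,
                          ligand_id = comp$native, stringsAsFactors = FALSE)
  negatives <- make_negative_pairs(positives, ratio = neg_ratio,
                                   seed = seed + 1L)
  all_pairs <- rbind(cbind(positives, provenance = "positive"), negatives)
  h_of <- setNames(comp$h, comp$pocket_id)
  labs <- planted_affinity(h_of[all_pairs$pocket_id],
                           a_of[all_pairs$ligand_id],
                           noise_sd = noise_sd, seed = seed + 2L)
  examples <- lapply(seq_len(nrow(all_pairs)), function(r) {
    ex <- pair_example(pkt_graphs[[all_pairs$pocket_id[r]]],
                       lig_graphs[[all_pairs$ligand_id[r]]],
                       label = labs$pka[r],
                       provenance = all_pairs$provenance[r],
                       pocket_id = all_pairs$pocket_id[r],
                       ligand_id = all_pairs$ligand_id[r])
    ex$label_bc <- labs$label[r]
    ex
  })
  sp <- split_pairs(examples, fractions = fractions, seed = seed + 3L)
  ledger <- structure(
    list(seed = seed, n_complexes = n_complexes,
         library_size = library_size, noise_sd = noise_sd,
         cutoff_nm = cutoff_nm, neg_ratio = neg_ratio,
         n_positive = nrow(positives), n_negative = nrow(negatives),
         n_pairs = length(examples),
         split = sp$ledger$counts,
         pocket_latents = h_of, ligand_latents = a_of,
         signal = "pka = 3 + 8*h*a + N(0, sd)"),
    class = "pg_fixture_ledger")
  list(train = sp$train, test = sp$test, ledger = ledger)
}

#' @exportS3Method base::print
print.pg_fixture_ledger <- function(x, ...) {
  cat("<pg_fixture_ledger> seed=", x$seed, ", ", x$n_complexes,
      " complexes x ", x$library_size, " ligands; ", x$n_positive,
      " positive + ", x$n_negative, " cross-negative pairs (split ",
      paste(names(x$split), x$split, sep = "=", collapse = ", "),
      "); noise sd ", x$noise_sd, "\n", sep = "")
  invisible(x)
}

#' Relabel benchmark pairs for the binder-classification head
#'
#' Returns the same pairs with `label` set to the planted binary label
#' (`pKa >= 7`), as required by a bc-head model.
#'
#' @param pairs List of `pg_pair` from [make_benchmark()].
#' @return List of `pg_pair` with 0/1 labels.
#' @export
bc_labels <- function(pairs) {
  lapply(pairs, function(p) {
    p$label <- as.numeric(p$label_bc)
    p
  })
}
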