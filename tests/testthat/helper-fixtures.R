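## Shared fixtures, built in code and cached for the test session.

.fix_env <- new.env(parent = emptyenv())

fix_cached <- function(name, builder) {
  hit <- get0(name, envir = .fix_env)
  if (!is.null(hit)) return(hit)
  val <- builder()
  assign(name, val, envir = .fix_env)
  val
}

## A hand-placed structure: one ligand atom at the origin, four residues
## whose nearest atoms lie at exactly 5.9, 6.1, 7.9 and 8.1 A.
boundary_structure <- function() {
  mk <- function(serial, resname, resno, d) {
    sprintf("ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            serial, resname, resno, d, 0, 0)
  }
  txt <- paste(c(
    mk(1, "ALA", 1, 5.9), mk(2, "GLY", 2, 6.1),
    mk(3, "SER", 3, 7.9), mk(4, "LEU", 4, 8.1),
    "HETATM    5  C1  LIG L   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"), collapse = "\n")
  parse_pdb(txt, id = "boundary")
}

## Random multi-atom pocket for oracle comparisons: n residues of 3 atoms
## placed uniformly in a box.
random_pocket <- function(n, seed, box = 14) {
  set.seed(seed)
  residues <- lapply(seq_len(n), function(i) {
    ctr <- runif(3, 0, box)
    xyz <- t(vapply(1:3, function(k) ctr + rnorm(3, 0, 0.5), numeric(3)))
    list(id = c(chain = "A", resno = as.character(i), insert = ""),
         name = "ALA", xyz = xyz)
  })
  structure(list(residues = residues,
                 ligand = matrix(0, 1, 3), cutoff_nm = 1),
            class = "pg_pocket")
}

## Brute-force O(n^2 m^2) contact-edge oracle.
oracle_edges <- function(p, cutoff_nm = 0.5) {
  n <- length(p$residues)
  out <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    A <- p$residues[[i]]$xyz; B <- p$residues[[j]]$xyz
    dmin <- Inf
    for (a in seq_len(nrow(A))) for (b in seq_len(nrow(B)))
      dmin <- min(dmin, sqrt(sum((A[a, ] - B[b, ])^2)))
    if (dmin <= cutoff_nm * 10) out <- rbind(out, c(i, j))
  }
  if (is.null(out)) matrix(integer(0), ncol = 2)
  else out[order(out[, 1], out[, 2]), , drop = FALSE]
}

## Small shared graphs/pairs for model tests.
tiny_pair_set <- function(n = 16, seed = 5) {
  fix_cached(paste0("tiny_pairs_", n, "_", seed), function() {
    lib <- make_toy_library(max(4, ceiling(n / 2)), seed = seed)
    pairs <- list()
    for (i in seq_len(n)) {
      tc <- make_toy_complex(seed * 100 + i, n_residues = 9,
                             h = (i - 1) / max(1, n - 1))
      s <- parse_pdb(tc$pdb)
      pk <- extract_pocket(s, ligand_coordinates(s, resname = "LIG"), 0.8)
      pgr <- pocket_graph(pk, "onehot")
      li <- ((i - 1) %% nrow(lib)) + 1
      lg <- ligand_graph(lib$smiles[li])
      lab <- planted_affinity(tc$ledger$h, lib$aromatic_latent[li],
                              noise_sd = 0, seed = 1)
      ex <- pair_example(pgr, lg, lab$pka,
                         pocket_id = paste0("P", i),
                         ligand_id = lib$id[li])
      ex$label_bc <- lab$label
      pairs[[i]] <- ex
    }
    pairs
  })
}

default_table <- function() fix_cached("residue_table", default_residue_table)
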