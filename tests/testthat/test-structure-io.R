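test_that("parse_pdb reads coordinates back identically", {
  s <- parse_pdb(paste0(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000",
    "  1.00  0.00           C"))
  expect_equal(nrow(s$atoms), 1)
  expect_equal(unlist(s$atoms[1, c("x", "y", "z")], use.names = FALSE),
               c(1, 2, 3))
  expect_false(s$atoms$is_hetero[1])
})

test_that("parse_pdb flags HETATM-only files and rejects bad input", {
  s <- parse_pdb(paste0(
    "HETATM    1  C1  LIG A   1       0.000   0.000   0.000",
    "  1.00  0.00           C"))
  expect_true(all(s$atoms$is_hetero))
  expect_error(parse_pdb("REMARK nothing here"), "first line")
  expect_error(parse_pdb("ATOM      1  CA  ALA A   1   1.0"), "malformed")
})

test_that("fixture complexes re-parse to the generator's ledger counts", {
  for (seed in c(3, 17)) {
    tc <- make_toy_complex(seed, n_residues = 10, h = 0.4)
    s <- parse_pdb(tc$pdb)
    expect_equal(nrow(s$atoms), tc$ledger$n_atoms)
    expect_equal(length(unique(paste(s$atoms$chain, s$atoms$resno)[
      !s$atoms$is_hetero])), tc$ledger$n_residues)
  }
})

test_that("ligand_coordinates selects, errors on miss and on ambiguity", {
  tc <- make_toy_complex(8, n_residues = 6)
  s <- parse_pdb(tc$pdb)
  xyz <- ligand_coordinates(s, resname = "LIG")
  expect_equal(nrow(xyz), 5)
  expect_error(ligand_coordinates(s, resname = "XYZ"), "available")
  ## duplicate the ligand on another chain -> ambiguous by name alone
  body <- strsplit(tc$pdb, "\n")[[1]]
  body <- body[body != "END"]
  dup <- gsub("LIG L", "LIG M", body[grepl("LIG", body)])
  substr(dup, 7, 11) <- sprintf("%5d", 900 + seq_along(dup))
  s2 <- parse_pdb(c(body, dup, "END"))
  expect_error(ligand_coordinates(s2, resname = "LIG"), "disambiguate")
  expect_equal(nrow(ligand_coordinates(s2, resname = "LIG", chain = "M")), 5)
})

test_that("pocket cutoff boundary is inclusive and ordered by distance rule", {
  s <- boundary_structure()
  lig <- ligand_coordinates(s, resname = "LIG")
  p06 <- extract_pocket(s, lig, 0.6)
  expect_equal(vapply(p06$residues, function(r) r$name, ""), "ALA")
  p08 <- extract_pocket(s, lig, 0.8)
  expect_equal(vapply(p08$residues, function(r) r$name, ""),
               c("ALA", "GLY", "SER"))
  ## exact boundary: residue at 6.1 kept at cutoff 0.61
  p061 <- extract_pocket(s, lig, 0.61)
  expect_true("GLY" %in% vapply(p061$residues, function(r) r$name, ""))
})

test_that("smaller pocket cutoffs give subsets (monotonicity)", {
  for (seed in c(2, 9, 23)) {
    tc <- make_toy_complex(seed, n_residues = 12, h = 0.5)
    s <- parse_pdb(tc$pdb)
    lig <- ligand_coordinates(s, resname = "LIG")
    ids <- function(p) vapply(p$residues, function(r)
      paste0(r$id[["chain"]], ":", r$id[["resno"]]), "")
    r6 <- ids(extract_pocket(s, lig, 0.6))
    r8 <- ids(extract_pocket(s, lig, 0.8))
    expect_true(all(r6 %in% r8))
    ## and the generator's planted shells are recovered exactly
    expect_setequal(r6, tc$ledger$inner_ids)
    expect_setequal(r8, c(tc$ledger$inner_ids, tc$ledger$middle_ids))
  }
})

test_that("hydrogens and hetero records are never pocket candidates", {
  txt <- paste(c(
    "ATOM      1  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  H   GLY A   2       0.500   0.000   0.000  1.00  0.00           H",
    "HETATM    3  O   HOH A 101       0.200   0.000   0.000  1.00  0.00           O",
    "HETATM    4  C1  LIG L   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"), collapse = "\n")
  s <- parse_pdb(txt)
  p <- extract_pocket(s, ligand_coordinates(s, resname = "LIG"), 0.3)
  ## GLY has only an H within 3 A, HOH is hetero -> only ALA qualifies via CA
  expect_equal(vapply(p$residues, function(r) r$name, ""), "ALA")
})

test_that("non-standard residues are dropped with a warning", {
  txt <- paste(c(
    "ATOM      1  CA  MSE A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       2.000   0.000   0.000  1.00  0.00           C",
    "HETATM    3  C1  LIG L   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"), collapse = "\n")
  s <- parse_pdb(txt)
  expect_warning(p <- extract_pocket(s, ligand_coordinates(s, resname = "LIG"),
                                     0.6), "MSE")
  expect_equal(vapply(p$residues, function(r) r$name, ""), "ALA")
})

test_that("empty pocket is a warning, not an error", {
  txt <- paste(c(
    "ATOM      1  CA  ALA A   1      99.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  C1  LIG L   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"), collapse = "\n")
  s <- parse_pdb(txt)
  expect_warning(p <- extract_pocket(s, ligand_coordinates(s, resname = "LIG"),
                                     0.6), "no residues")
  expect_length(p$residues, 0)
  expect_equal(nrow(contact_edges(p)), 0)
})

test_that("contact edges match the hand-placed boundary example", {
  ## residues with min inter-residue distances A-B 4, A-C 9, B-C 5
  mkres <- function(resno, x) sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    resno, resno, x, 0, 0)
  txt <- paste(c(mkres(1, 0), mkres(2, 4), mkres(3, 9),
    "HETATM    4  C1  LIG L   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"), collapse = "\n")
  s <- parse_pdb(txt)
  p <- extract_pocket(s, ligand_coordinates(s, resname = "LIG"), 2)
  e <- contact_edges(p, 0.5)   # B-C at exactly 5 A is kept (inclusive)
  expect_equal(unname(e), rbind(c(1L, 2L), c(2L, 1L), c(2L, 3L), c(3L, 2L)))
})

test_that("single-residue pockets yield empty edge lists", {
  p <- random_pocket(1, seed = 4)
  expect_equal(nrow(contact_edges(p)), 0)
})

test_that("contact_edges agrees with the brute-force oracle up to n = 50", {
  for (cfg in list(c(10, 31), c(25, 32), c(50, 33))) {
    p <- random_pocket(cfg[1], seed = cfg[2])
    e <- contact_edges(p, 0.5)
    o <- oracle_edges(p, 0.5)
    expect_equal(unname(e), unname(o))
    ## symmetry + irreflexivity
    if (nrow(e)) {
      expect_true(all(e[, 1] != e[, 2]))
      key <- paste(e[, 1], e[, 2]); rev <- paste(e[, 2], e[, 1])
      expect_setequal(key, rev)
    }
  }
})

test_that("pocket membership and edges are rigid-motion invariant", {
  tc <- make_toy_complex(12, n_residues = 12, h = 0.5)
  s <- parse_pdb(tc$pdb)
  lig <- ligand_coordinates(s, resname = "LIG")
  p1 <- extract_pocket(s, lig, 0.8)
  e1 <- contact_edges(p1)
  ## rotate + translate every coordinate
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  tr <- c(5, -3, 11)
  s2 <- s
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% R
  s2$atoms$x <- xyz[, 1] + tr[1]
  s2$atoms$y <- xyz[, 2] + tr[2]
  s2$atoms$z <- xyz[, 3] + tr[3]
  lig2 <- ligand_coordinates(s2, resname = "LIG")
  p2 <- extract_pocket(s2, lig2, 0.8)
  expect_equal(vapply(p1$residues, function(r) r$id[["resno"]], ""),
               vapply(p2$residues, function(r) r$id[["resno"]], ""))
  expect_equal(unname(contact_edges(p2)), unname(e1))
})

test_that("pockets write back as parseable PDB fragments", {
  tc <- make_toy_complex(5, n_residues = 8)
  s <- parse_pdb(tc$pdb)
  p <- extract_pocket(s, ligand_coordinates(s, resname = "LIG"), 0.8)
  tf <- tempfile(fileext = ".pdb")
  write_pocket_pdb(p, tf)
  s2 <- read_structure(tf)
  expect_equal(length(unique(paste(s2$atoms$chain, s2$atoms$resno))),
               length(p$residues))
})
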