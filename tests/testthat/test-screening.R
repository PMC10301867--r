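screen_models <- function() {
  fix_cached("screen_models", function() {
    list(bc = build_gcn(gcn_config(20, head = "bc", seed = 21)),
         rg = build_gcn(gcn_config(20, head = "rg", seed = 22)))
  })
}

screen_pocket <- function() {
  fix_cached("screen_pocket", function() {
    tc <- make_toy_complex(77, n_residues = 10, h = 0.6)
    s <- parse_pdb(tc$pdb)
    pocket_graph(extract_pocket(s, ligand_coordinates(s, resname = "LIG"),
                                0.8), "onehot")
  })
}

test_that("screening applies the pass rule to both scores by hand", {
  m <- screen_models()
  lib <- make_toy_library(12, seed = 41)
  rec <- screen_library(m$bc, m$rg, screen_pocket(), lib,
                        cfg = screen_config(bc_threshold = 0,
                                            rg_threshold = -Inf))
  expect_equal(nrow(rec), 12)
  expect_true(all(rec$passed))
  ## recompute the filter by hand at interior thresholds
  thr_bc <- median(rec$bc_score); thr_rg <- median(rec$rg_score)
  rec2 <- screen_library(m$bc, m$rg, screen_pocket(), lib,
                         cfg = screen_config(bc_threshold = thr_bc,
                                             rg_threshold = thr_rg))
  expect_equal(rec2$passed,
               rec2$bc_score >= thr_bc & rec2$rg_score >= thr_rg)
  ## ranking is a permutation sorted by rg score
  expect_equal(rec2$rg_score, sort(rec2$rg_score, decreasing = TRUE))
  expect_setequal(rec2$compound_id, lib$id)
})

test_that("raising a threshold never adds a passed compound", {
  m <- screen_models()
  lib <- make_toy_library(20, seed = 42)
  base <- screen_library(m$bc, m$rg, screen_pocket(), lib,
                         cfg = screen_config(bc_threshold = 0.2,
                                             rg_threshold = -1))
  for (d in c(0.1, 0.3)) {
    up <- screen_library(m$bc, m$rg, screen_pocket(), lib,
                         cfg = screen_config(bc_threshold = 0.2 + d,
                                             rg_threshold = -1))
    expect_true(all(up$compound_id[up$passed] %in%
                      base$compound_id[base$passed]))
  }
})

test_that("unparsable library entries are skipped and counted", {
  m <- screen_models()
  lib <- data.frame(smiles = c(make_toy_library(9, seed = 43)$smiles,
                               "thisisnotasmiles"),
                    id = sprintf("X%02d", 1:10))
  expect_no_error(rec <- screen_library(m$bc, m$rg, screen_pocket(), lib))
  expect_equal(nrow(rec), 9)
  expect_equal(attr(rec, "n_skipped"), 1)
  expect_false("X10" %in% rec$compound_id)
})

test_that("empty libraries warn and rg-only screening works", {
  m <- screen_models()
  expect_warning(rec <- screen_library(m$bc, m$rg, screen_pocket(),
                                       character(0)), "empty")
  expect_equal(nrow(rec), 0)
  lib <- make_toy_library(5, seed = 44)
  rec2 <- screen_library(NULL, m$rg, screen_pocket(), lib,
                         cfg = screen_config(rg_threshold = -Inf))
  expect_true(all(is.na(rec2$bc_score)))
  expect_true(all(rec2$passed))
})

test_that("clustering yields k non-empty groups with stable medoids", {
  lib <- make_toy_library(40, seed = 45)
  cl <- cluster_candidates(lib$smiles, k = 6)
  expect_equal(length(unique(cl$cluster)), 6)
  expect_equal(sum(cl$is_medoid), 6)
  expect_true(all(table(cl$cluster) >= 1))
  ## k = 1 puts everything together
  cl1 <- cluster_candidates(lib$smiles[1:8], k = 1)
  expect_equal(unique(cl1$cluster), 1)
  expect_equal(sum(cl1$is_medoid), 1)
  ## fewer candidates than k reduces k with a warning
  expect_warning(clr <- cluster_candidates(lib$smiles[1:3], k = 6), "reducing")
  expect_equal(length(unique(clr$cluster)), 3)
})

test_that("clustering is invariant to input order and groups duplicates", {
  lib <- make_toy_library(30, seed = 46)
  smiles <- c(lib$smiles, lib$smiles[1])   # duplicate
  cl <- cluster_candidates(smiles, k = 5)
  expect_equal(cl$cluster[31], cl$cluster[1])
  set.seed(2)
  perm <- sample(length(smiles))
  cl2 <- cluster_candidates(smiles[perm], k = 5)
  ## same partition up to label renaming
  part1 <- split(seq_along(smiles), cl$cluster)
  part2 <- split(perm, cl2$cluster)
  canon <- function(part) {
    s <- lapply(part, sort)
    s[order(vapply(s, `[`, 0, 1))]
  }
  expect_equal(unname(canon(part1)), unname(canon(part2)))
  expect_setequal(smiles[cl$is_medoid], smiles[perm][cl2$is_medoid])
})

test_that("the end-to-end screen writes ranked output deterministically", {
  m <- screen_models()
  tc <- make_toy_complex(78, n_residues = 10, h = 0.5)
  rec_pdb <- tempfile(fileext = ".pdb")
  writeLines(tc$pdb, rec_pdb)
  lib <- make_toy_library(25, seed = 47)
  d1 <- tempfile(); d2 <- tempfile()
  r1 <- run_screen(rec_pdb, ligand_resname = "LIG", library = lib,
                   bc_model = m$bc, rg_model = m$rg,
                   cfg = screen_config(bc_threshold = 0, rg_threshold = -Inf),
                   out_dir = d1)
  r2 <- run_screen(rec_pdb, ligand_resname = "LIG", library = lib,
                   bc_model = m$bc, rg_model = m$rg,
                   cfg = screen_config(bc_threshold = 0, rg_threshold = -Inf),
                   out_dir = d2)
  expect_identical(readLines(file.path(d1, "ranked.tsv")),
                   readLines(file.path(d2, "ranked.tsv")))
  expect_equal(nrow(r1$records), 25)
  expect_true(file.exists(file.path(d1, "clusters.tsv")))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$n_scored, 25)
  expect_equal(man$n_passed, 25)
  ## rg-only screen (no bc model)
  d3 <- tempfile()
  r3 <- run_screen(rec_pdb, ligand_resname = "LIG", library = lib,
                   rg_model = m$rg,
                   cfg = screen_config(rg_threshold = -Inf), out_dir = d3)
  expect_true(all(r3$records$passed))
})
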