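#!/usr/bin/env Rscript

## Virtual-screening command line: BC-filter -> RG-rank a SMILES library
## against one receptor pocket, cluster the candidates and write reports.
##
##   Rscript scripts/screen.R --receptor x.pdb --ligand-resname LIG \
##     --library lib.smi --bc-model bc.json --rg-model rg.json \
##     [--residue-table table.tsv] [--bc-threshold 0.99] \
##     [--rg-threshold 8.6] [--clusters 6] [--cutoff-nm 0.8] [--no-bc] \
##     [--seed 1] --out dir

suppressMessages({
  library(optparse)
  library(pocketgcn)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--receptor", type = "character"),
  make_option("--ligand-resname", type = "character", default = NULL,
              dest = "ligand_resname"),
  make_option("--ligand-chain", type = "character", default = NULL,
              dest = "ligand_chain"),
  make_option("--ligand-resid", type = "integer", default = NULL,
              dest = "ligand_resid"),
  make_option("--library", type = "character"),
  make_option("--bc-model", type = "character", default = NULL,
              dest = "bc_model"),
  make_option("--rg-model", type = "character", default = NULL,
              dest = "rg_model"),
  make_option("--residue-table", type = "character", default = NULL,
              dest = "residue_table",
              help = "TSV residue embedding table; one-hot features if absent"),
  make_option("--bc-threshold", type = "double", default = 0.99,
              dest = "bc_threshold"),
  make_option("--rg-threshold", type = "double", default = 8.6,
              dest = "rg_threshold"),
  make_option("--clusters", type = "integer", default = 6),
  make_option("--cutoff-nm", type = "double", default = 0.8,
              dest = "cutoff_nm"),
  make_option("--no-bc", action = "store_true", default = FALSE,
              dest = "no_bc", help = "rank by RG alone"),
  make_option("--seed", type = "integer", default = 1),
  make_option("--out", type = "character", default = "screen_out")
)))

if (is.null(opts$receptor) || is.null(opts$library))
  stop("--receptor and --library are required")
if (is.null(opts$ligand_resname) &&
    (is.null(opts$ligand_chain) || is.null(opts$ligand_resid)))
  stop("give --ligand-resname or --ligand-chain plus --ligand-resid")
if (is.null(opts$bc_model) && is.null(opts$rg_model))
  stop("at least one of --bc-model / --rg-model is required")

bc <- if (!opts$no_bc && !is.null(opts$bc_model)) load_gcn(opts$bc_model)
rg <- if (!is.null(opts$rg_model)) load_gcn(opts$rg_model)
features <- if (!is.null(opts$residue_table))
  read_residue_table(opts$residue_table) else "onehot"

res <- run_screen(
  opts$receptor,
  ligand_resname = opts$ligand_resname,
  ligand_chain = opts$ligand_chain,
  ligand_resno = opts$ligand_resid,
  library = opts$library,
  bc_model = bc, rg_model = rg,
  features = features, cutoff_nm = opts$cutoff_nm,
  cfg = screen_config(bc_threshold = opts$bc_threshold,
                      rg_threshold = opts$rg_threshold,
                      k_clusters = opts$clusters, seed = opts$seed),
  out_dir = opts$out)

cat(sprintf("scored %d compounds (%d skipped), %d passed; reports in %s\n",
            res$manifest$n_scored, res$manifest$n_skipped,
            res$manifest$n_passed, opts$out))
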