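## data_pipeline: affinity conversion, cross-combination negatives,
## pair-disjoint splits and class balancing.

#' pKa from a molar affinity
#'
#' `pKa = -log10(Kx)` where Kx is a Ki, Kd or IC50 in molar units;
#' sub-molar affinities give positive pKa.
#'
#' @param Kx Molar concentration(s), must be positive.
#' @return Numeric pKa value(s).
#' @export
pka_from_affinity <- function(Kx) {
  if (any(!is.finite(Kx)) || any(Kx <= 0))
    stop("Kx must be positive and finite (molar concentration)")
  -log10(Kx)
}

#' Binding free energy from pKa
#'
#' `dG = R * T * ln(10) * pKa` with R = 1.987e-3 kcal/(mol K). The
#' default reports the magnitude (the printed convention for binding
#' strength); `sign = "thermodynamic"` negates it so that favourable
#' binding is negative.
#'
#' @param pKa Unitless affinity value(s).
#' @param T Temperature in kelvin (default 298.15).
#' @param sign `"magnitude"` (default) or `"thermodynamic"`.
#' @return Energy in kcal/mol.
#' @export
delta_g_from_pka <- function(pKa, T = 298.15,
                             sign = c("magnitude", "thermodynamic")) {
  sign <- match.arg(sign)
  stopifnot(T > 0)
  R <- 1.987e-3  # kcal / (mol K)
  dg <- R * T * log(10) * pKa
  if (sign == "thermodynamic") -dg else dg
}

#' Parse an affinity table into pKa records
#'
#' Accepts a data.frame (or TSV/CSV path) with columns `id`, `measure`
#' (Ki/Kd/IC50), `value` and `unit` (M, mM, uM, nM, pM) and returns the
#' table with a derived `pKa` column.
#'
#' @param x data.frame or file path.
#' @return data.frame with an added `Kx_molar` and `pKa` column.
#' @export
affinity_records <- function(x) {
  if (is.character(x)) {
    sep <- if (grepl("\\.csv$", x)) "," else "\t"
    x <- read.table(x, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  }
  need <- c("id", "measure", "value", "unit")
  if (!all(need %in% names(x)))
    stop("affinity table needs columns: ", paste(need, collapse = ", "))
  if (!all(x$measure %in% c("Ki", "Kd", "IC50")))
    stop("measure must be one of Ki, Kd, IC50")
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)
  if (!all(x$unit %in% names(scale)))
    stop("unit must be one of ", paste(names(scale), collapse = ", "))
  x$Kx_molar <- x$value * scale[x$unit]
  x$pKa <- pka_from_affinity(x$Kx_molar)
  x
}

#' Cross-combination negative pairs
#'
#' Pairs each pocket with ligands drawn from other complexes to form
#' presumed non-binders. No generated pair key ever collides with a
#' positive pair key, and generated keys are unique. Sampling is uniform
#' over foreign ligands, seeded.
#'
#' @param positives data.frame with columns `pocket_id` and `ligand_id`
#'   (one row per positive complex), or a list of `pg_pair` objects.
#' @param ratio Negatives per positive (default 3).
#' @param seed RNG seed.
#' @return data.frame with columns `pocket_id`, `ligand_id`,
#'   `provenance = "cross-negative"`. If the ratio is unattainable after
#'   exclusions a warning is given and a smaller set returned.
#' @export
make_negative_pairs <- function(positives, ratio = 3, seed = 1) {
  if (is.list(positives) && !is.data.frame(positives) &&
      all(vapply(positives, inherits, TRUE, "pg_pair"))) {
    positives <- data.frame(
      pocket_id = vapply(positives, function(p) p$pocket_id, ""),
      ligand_id = vapply(positives, function(p) p$ligand_id, ""),
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(positives),
            all(c("pocket_id", "ligand_id") %in% names(positives)))
  if (length(unique(positives$pocket_id)) < 2 ||
      length(unique(positives$ligand_id)) < 2)
    stop("need at least 2 distinct pockets and ligands for cross-combination")
  pos_key <- paste(positives$pocket_id, positives$ligand_id, sep = "::")
  ligands <- unique(positives$ligand_id)
  ## ligands native to each pocket (a pocket may appear multiple times)
  native <- split(positives$ligand_id, positives$pocket_id)
  with_seed(seed, {
    taken <- new.env(parent = emptyenv(), size = 4L * nrow(positives))
    for (k in pos_key) assign(k, TRUE, envir = taken)
    n_lig <- length(ligands)
    out <- vector("list", nrow(positives))
    for (r in seq_len(nrow(positives))) {
      po <- positives$pocket_id[r]
      excl <- native[[po]]
      ## rejection sampling over the ligand pool (fast path), falling back
      ## to full enumeration when the pool is nearly exhausted
      pick <- character(0)
      cand <- sample(ligands, min(n_lig, 4L * ratio + 8L))
      for (lg in cand) {
        if (lg %in% excl) next
        key <- paste(po, lg, sep = "::")
        if (exists(key, envir = taken, inherits = FALSE)) next
        assign(key, TRUE, envir = taken)
        pick <- c(pick, lg)
        if (length(pick) == ratio) break
      }
      if (length(pick) < ratio) {
        foreign <- setdiff(ligands, c(excl, pick))
        if (length(foreign))
          foreign <- foreign[!vapply(paste(po, foreign, sep = "::"),
                                     exists, TRUE, envir = taken,
                                     inherits = FALSE)]
        extra <- min(ratio - length(pick), length(foreign))
        if (extra > 0) {
          more <- if (length(foreign) == 1) foreign
                  else sample(foreign, extra)
          for (lg in more) assign(paste(po, lg, sep = "::"), TRUE,
                                  envir = taken)
          pick <- c(pick, more)
        }
      }
      out[[r]] <- pick
    }
    lens <- lengths(out)
    target <- ratio * nrow(positives)
    if (sum(lens) < target)
      warning("only ", sum(lens), " negatives achievable (target ",
              target, ") after exclusions")
    data.frame(pocket_id = rep(positives$pocket_id, lens),
               ligand_id = unlist(out, use.names = FALSE),
               provenance = "cross-negative", stringsAsFactors = FALSE)
  })
}

#' Pair-disjoint dataset split
#'
#' Splits examples into partitions by shuffled pair keys so no pair key
#' appears in two partitions; returns the partitions plus a ledger of
#' counts and the seed.
#'
#' @param pairs List of `pg_pair` objects (or anything with a
#'   `pair_key`-like identity; a data.frame with a `pair_key` column is
#'   also accepted).
#' @param fractions Named numeric vector summing to 1, e.g.
#'   `c(train = 0.8, test = 0.2)`.
#' @param seed RNG seed.
#' @return List with one element per partition plus `ledger` (class
#'   `pg_split_ledger`).
#' @export
split_pairs <- function(pairs, fractions = c(train = 0.8, test = 0.2),
                        seed = 1) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, length(fractions) >= 2)
  n <- if (is.data.frame(pairs)) nrow(pairs) else length(pairs)
  with_seed(seed, {
    ord <- sample.int(n)
    sizes <- floor(fractions * n)
    rem <- n - sum(sizes)
    if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
    idx <- split(ord, rep(seq_along(sizes), sizes))
    parts <- lapply(idx, function(i) {
      if (is.data.frame(pairs)) pairs[sort(i), , drop = FALSE]
      else pairs[sort(i)]
    })
    names(parts) <- names(fractions)
    counts <- vapply(parts, function(p)
      if (is.data.frame(p)) nrow(p) else length(p), 0L)
    ledger <- structure(list(counts = counts, total = n, seed = seed,
                             fractions = fractions),
                        class = "pg_split_ledger")
    c(parts, list(ledger = ledger))
  })
}

#' @exportS3Method base::print
print.pg_split_ledger <- function(x, ...) {
  cat("<pg_split_ledger> total=", x$total, ", seed=", x$seed, ": ",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Balance classes by replicating positives
#'
#' Replicates the positive examples `factor` times, concatenates the
#' negatives and shuffles (seeded). With 15,000 positives, factor 3 and
#' 45,000 negatives the result is exactly 1:1.
#'
#' @param positives,negatives Lists (or data.frames) of examples.
#' @param factor Replication factor (default 3).
#' @param seed RNG seed for the shuffle.
#' @return Combined, shuffled sequence of the same type as the inputs.
#' @export
balance_classes <- function(positives, negatives, factor = 3, seed = 1) {
  stopifnot(factor >= 1)
  if (is.data.frame(positives)) {
    combined <- rbind(positives[rep(seq_len(nrow(positives)), factor), ,
                                drop = FALSE], negatives)
    with_seed(seed, combined[sample.int(nrow(combined)), , drop = FALSE])
  } else {
    combined <- c(rep(positives, factor), negatives)
    with_seed(seed, combined[sample.int(length(combined))])
  }
}
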