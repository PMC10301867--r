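## residue_embedding: desk-scale mol2vec-style substructure vectors and
## per-residue 30-dimensional vectors obtained by summing chemical-group
## vectors over each free amino acid, plus the one-hot alternative.

#' Canonical free amino-acid SMILES
#'
#' Neutral free amino acids (backbone included, no capping); these define
#' the "chemical groups" summed into each residue vector.
#' @format Named character vector, names are the 20 standard 3-letter codes.
#' @export
AA_SMILES <- c(
  ALA = "CC(N)C(=O)O",
  ARG = "NC(CCCNC(N)=N)C(=O)O",
  ASN = "NC(CC(N)=O)C(=O)O",
  ASP = "NC(CC(O)=O)C(=O)O",
  CYS = "NC(CS)C(=O)O",
  GLN = "NC(CCC(N)=O)C(=O)O",
  GLU = "NC(CCC(O)=O)C(=O)O",
  GLY = "NCC(=O)O",
  HIS = "NC(Cc1c[nH]cn1)C(=O)O",
  ILE = "CCC(C)C(N)C(=O)O",
  LEU = "CC(C)CC(N)C(=O)O",
  LYS = "NCCCCC(N)C(=O)O",
  MET = "CSCCC(N)C(=O)O",
  PHE = "NC(Cc1ccccc1)C(=O)O",
  PRO = "OC(=O)C1CCCN1",
  SER = "NC(CO)C(=O)O",
  THR = "CC(O)C(N)C(=O)O",
  TRP = "NC(Cc1c[nH]c2ccccc12)C(=O)O",
  TYR = "NC(Cc1ccc(O)cc1)C(=O)O",
  VAL = "CC(C)C(N)C(=O)O"
)

#' Train substructure vectors on a SMILES corpus
#'
#' Skip-gram with negative sampling over substructure sentences (the
#' word2vec formulation mol2vec applies to molecules). Desk-scale: meant
#' for corpora of hundreds to thousands of molecules; vectors are
#' reproducible for a fixed seed.
#'
#' @param corpus Character vector of SMILES strings.
#' @param dim Embedding dimension (default 30).
#' @param radius Substructure radius for sentences (default 1).
#' @param window Skip-gram context window (default 5).
#' @param epochs Training passes over the corpus (default 5).
#' @param negative Negative samples per positive pair (default 5).
#' @param lr Initial learning rate, decayed linearly (default 0.025).
#' @param min_count Minimum token frequency to enter the vocabulary.
#' @param seed RNG seed; fixes initialization and sampling.
#' @return An object of class `pg_subst_table`: list with `vectors`
#'   (matrix, one row per substructure identifier plus a reserved
#'   all-zero `"UNK"` row), `dim`, and `meta` (corpus size, radius,
#'   window, epochs, seed).
#' @export
train_substructure_vectors <- function(corpus, dim = 30, radius = 1,
                                       window = 5, epochs = 5, negative = 5,
                                       lr = 0.025, min_count = 1, seed = 1) {
  stopifnot(is.character(corpus))
  if (length(corpus) == 0) stop("empty corpus")
  if (length(corpus) < 100)
    warning("corpus has fewer than 100 molecules; vectors will be weak")
  sentences <- lapply(corpus, function(s) {
    tryCatch(substructure_sentence(s, radius), error = function(e) NULL)
  })
  bad <- vapply(sentences, is.null, logical(1))
  if (any(bad)) warning(sum(bad), " unparsable SMILES skipped")
  sentences <- sentences[!bad]
  if (length(sentences) == 0) stop("no parseable molecules in corpus")

  tok <- unlist(sentences)
  tab <- table(tok)
  vocab <- names(tab)[tab >= min_count]
  if (length(vocab) == 0) stop("empty vocabulary after min_count filter")
  vidx <- seq_along(vocab); names(vidx) <- vocab
  V <- length(vocab)

  ## (center, context) pairs with a fixed window, all sentences
  centers <- integer(0); contexts <- integer(0)
  for (s in sentences) {
    si <- unname(vidx[s]); si <- si[!is.na(si)]
    L <- length(si)
    if (L < 2) next
    for (off in seq_len(window)) {
      if (L > off) {
        centers  <- c(centers,  si[seq_len(L - off)], si[(off + 1):L])
        contexts <- c(contexts, si[(off + 1):L], si[seq_len(L - off)])
      }
    }
  }
  n_pairs <- length(centers)
  if (n_pairs == 0) stop("corpus sentences too short to form skip-gram pairs")

  freq <- as.numeric(tab[vocab])
  neg_prob <- freq^0.75 / sum(freq^0.75)

  with_seed(seed, {
    W <- matrix(runif(V * dim, -0.5 / dim, 0.5 / dim), V, dim)  # input vectors
    C <- matrix(0, V, dim)                                      # output vectors
    ord <- sample.int(n_pairs)
    centers <- centers[ord]; contexts <- contexts[ord]
    chunk <- 2048L
    n_chunks <- ceiling(n_pairs / chunk)
    total_steps <- epochs * n_chunks
    step <- 0L
    for (ep in seq_len(epochs)) {
      for (ch in seq_len(n_chunks)) {
        step <- step + 1L
        eta <- lr * max(1e-4, 1 - (step - 1) / total_steps)
        i1 <- (ch - 1L) * chunk + 1L
        i2 <- min(ch * chunk, n_pairs)
        ce <- centers[i1:i2]; co <- contexts[i1:i2]
        m <- length(ce)
        ## positive + negative targets, label vector
        neg <- sample.int(V, m * negative, replace = TRUE, prob = neg_prob)
        tgt <- c(co, neg)
        ctr <- c(ce, rep(ce, negative))
        lab <- c(rep(1, m), rep(0, m * negative))
        Wc <- W[ctr, , drop = FALSE]
        Ct <- C[tgt, , drop = FALSE]
        p <- 1 / (1 + exp(-rowSums(Wc * Ct)))
        g <- (lab - p) * eta
        ## per-token mean gradient within the chunk keeps hot tokens from
        ## accumulating runaway summed updates
        dW <- rowsum(g * Ct, ctr) / as.vector(table(ctr))
        dC <- rowsum(g * Wc, tgt) / as.vector(table(tgt))
        iw <- as.integer(rownames(dW)); ic <- as.integer(rownames(dC))
        W[iw, ] <- W[iw, ] + dW
        C[ic, ] <- C[ic, ] + dC
      }
    }
    rownames(W) <- vocab
    W <- rbind(W, UNK = rep(0, dim))
    structure(list(vectors = W, dim = dim,
                   meta = list(corpus_size = length(sentences),
                               vocab_size = V, radius = radius,
                               window = window, epochs = epochs,
                               negative = negative, min_count = min_count,
                               seed = seed)),
              class = "pg_subst_table")
  })
}

#' @exportS3Method base::print
print.pg_subst_table <- function(x, ...) {
  cat("<pg_subst_table> ", x$meta$vocab_size, " substructures, dim ", x$dim,
      " (corpus ", x$meta$corpus_size, ", radius ", x$meta$radius,
      ", seed ", x$meta$seed, ")\n", sep = "")
  invisible(x)
}

#' Molecular vector of one amino-acid residue
#'
#' Sums the substructure (chemical-group) vectors over the residue's
#' substructure sentence, computed from the bundled free amino-acid
#' SMILES. Identifiers absent from the table contribute the zero UNK
#' vector.
#'
#' @param aa 3-letter amino-acid code (one of the 20 standard codes).
#' @param table A `pg_subst_table` from [train_substructure_vectors()].
#' @return Numeric vector of length `table$dim`.
#' @export
residue_vector <- function(aa, table) {
  stopifnot(inherits(table, "pg_subst_table"))
  aa <- toupper(aa)
  if (!aa %in% names(AA_SMILES))
    stop("unknown residue code ", sQuote(aa), "; valid codes: ",
         paste(names(AA_SMILES), collapse = ", "))
  sent <- substructure_sentence(AA_SMILES[[aa]], radius = table$meta$radius)
  v <- numeric(table$dim)
  known <- rownames(table$vectors)
  for (tk in sent) {
    if (tk %in% known) v <- v + table$vectors[tk, ]
  }
  unname(v)
}

#' Residue embedding table for all 20 standard amino acids
#'
#' @param table A `pg_subst_table`.
#' @return An object of class `pg_residue_table`: list with `vectors`
#'   (20 x dim matrix, rows named by 3-letter code in alphabetical
#'   order) and `source` metadata.
#' @export
residue_embedding_table <- function(table) {
  stopifnot(inherits(table, "pg_subst_table"))
  codes <- names(AA_SMILES)
  M <- t(vapply(codes, function(a) residue_vector(a, table),
                numeric(table$dim)))
  rownames(M) <- codes
  if (any(!is.finite(M))) stop("non-finite residue vectors")
  structure(list(vectors = M, source = table$meta),
            class = "pg_residue_table")
}

#' @exportS3Method base::print
print.pg_residue_table <- function(x, ...) {
  cat("<pg_residue_table> 20 residues x ", ncol(x$vectors),
      " dims (corpus ", x$source$corpus_size, ", seed ", x$source$seed,
      ")\n", sep = "")
  invisible(x)
}

#' One-hot residue encoding
#'
#' Unit basis vector under the fixed alphabetical ordering of the 20
#' standard 3-letter codes (ALA first, VAL last).
#'
#' @param aa 3-letter amino-acid code.
#' @return Numeric 0/1 vector of length 20.
#' @export
one_hot_residue <- function(aa) {
  aa <- toupper(aa)
  i <- match(aa, names(AA_SMILES))
  if (is.na(i))
    stop("unknown residue code ", sQuote(aa), "; valid codes: ",
         paste(names(AA_SMILES), collapse = ", "))
  v <- numeric(20)
  v[i] <- 1
  v
}

#' Write / read a residue embedding table
#'
#' Plain TSV with `#`-prefixed metadata header lines; doubles are stored
#' with 17 significant digits so the round trip is bit-exact.
#'
#' @param x A `pg_residue_table`.
#' @param path File path.
#' @return `write_residue_table`: `path` invisibly.
#'   `read_residue_table`: a `pg_residue_table`.
#' @export
write_residue_table <- function(x, path) {
  stopifnot(inherits(x, "pg_residue_table"))
  meta <- x$source
  hdr <- c(
    paste0("# pocketgcn residue embedding table v1"),
    paste0("# dim=", ncol(x$vectors)),
    paste0("# corpus_size=", meta$corpus_size),
    paste0("# vocab_size=", meta$vocab_size),
    paste0("# radius=", meta$radius),
    paste0("# window=", meta$window),
    paste0("# epochs=", meta$epochs),
    paste0("# seed=", meta$seed)
  )
  body <- vapply(seq_len(nrow(x$vectors)), function(i) {
    paste(c(rownames(x$vectors)[i], fmt_dbl(x$vectors[i, ])), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_residue_table
#' @export
read_residue_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  if (!length(hdr) || !grepl("residue embedding table v1", hdr[1]))
    stop("not a pocketgcn residue embedding table: ", path)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  codes <- vapply(parts, `[`, "", 1)
  M <- t(vapply(parts, function(p) as.numeric(p[-1]),
                numeric(length(parts[[1]]) - 1L)))
  rownames(M) <- codes
  if (!identical(sort(codes), sort(names(AA_SMILES))))
    stop("table must contain exactly the 20 standard residue codes")
  M <- M[names(AA_SMILES), , drop = FALSE]
  gv <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, "="), hdr)]
    if (length(ln)) as.numeric(sub(paste0("# ", key, "="), "", ln[1])) else NA
  }
  structure(list(vectors = M,
                 source = list(corpus_size = gv("corpus_size"),
                               vocab_size = gv("vocab_size"),
                               radius = gv("radius"), window = gv("window"),
                               epochs = gv("epochs"), seed = gv("seed"))),
            class = "pg_residue_table")
}

#' Bundled pre-trained residue table (synthetic corpus)
#'
#' Loads the residue embedding table shipped with the package. It was
#' trained on a small synthetic SMILES corpus (see
#' [make_toy_library()]) and stands in for a table trained on a large
#' compound collection, so downstream modules are usable without any
#' training step.
#'
#' @return A `pg_residue_table`.
#' @export
default_residue_table <- function() {
  read_residue_table(system.file("extdata", "residue_vectors_synthetic.tsv",
                                 package = "pocketgcn", mustWork = TRUE))
}
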