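## gcn_model: two-branch graph convolutional network.
##
## Each branch applies two Kipf-style graph convolutions
## H' = ReLU(Ahat H W + b), Ahat = D^-1/2 (A + I) D^-1/2, followed by a
## global pooling over nodes; the pooled pocket and ligand vectors are
## concatenated and passed through a fully connected stack to a single
## output. The binder-classification (bc) head applies a sigmoid; the
## affinity-regression (rg) head is linear. Gradients are computed
## analytically and optimized with Adam. Batches stack graphs
## block-diagonally so one sparse product handles a whole batch.

#' Model configuration
#'
#' @param pocket_dim Pocket node-feature width (20 for one-hot, 30 for
#'   molecular-vector features).
#' @param ligand_dim Ligand node-feature width (default
#'   [ligand_feature_dim()]).
#' @param head `"bc"` (sigmoid output, binary cross-entropy) or `"rg"`
#'   (linear output, mean squared error).
#' @param gcn_widths Two graph-convolution layer widths, shared by both
#'   branches (default `c(64, 128)`).
#' @param fc_widths Hidden widths of the fully connected stack
#'   (default `c(256, 64)`; the output layer of width 1 is implicit).
#' @param pooling `"max"` or `"mean"` global node pooling.
#' @param dropout Dropout rate applied after each hidden FC layer during
#'   training (default 0.2).
#' @param seed Seed for parameter initialization.
#' @return An object of class `pg_gcn_config`.
#' @export
gcn_config <- function(pocket_dim, ligand_dim = ligand_feature_dim(),
                       head = c("bc", "rg"), gcn_widths = c(64, 128),
                       fc_widths = c(256, 64), pooling = c("max", "mean"),
                       dropout = 0.2, seed = 1) {
  head <- match.arg(head)
  pooling <- match.arg(pooling)
  stopifnot(pocket_dim >= 1, ligand_dim >= 1,
            length(gcn_widths) == 2, all(gcn_widths >= 1),
            length(fc_widths) == 2, all(fc_widths >= 1),
            dropout >= 0, dropout < 1)
  structure(list(pocket_dim = as.integer(pocket_dim),
                 ligand_dim = as.integer(ligand_dim), head = head,
                 gcn_widths = as.integer(gcn_widths),
                 fc_widths = as.integer(fc_widths), pooling = pooling,
                 dropout = dropout, seed = as.integer(seed)),
            class = "pg_gcn_config")
}

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

#' Build an untrained model
#'
#' @param cfg A `pg_gcn_config`.
#' @return An object of class `pg_gcn` (configuration + parameter list).
#'   Building twice with the same config (and seed) gives identical
#'   initial parameters.
#' @export
build_gcn <- function(cfg) {
  stopifnot(inherits(cfg, "pg_gcn_config"))
  g1 <- cfg$gcn_widths[1]; g2 <- cfg$gcn_widths[2]
  f1 <- cfg$fc_widths[1]; f2 <- cfg$fc_widths[2]
  with_seed(cfg$seed, {
    params <- list(
      pW1 = .glorot(cfg$pocket_dim, g1), pb1 = numeric(g1),
      pW2 = .glorot(g1, g2),             pb2 = numeric(g2),
      lW1 = .glorot(cfg$ligand_dim, g1), lb1 = numeric(g1),
      lW2 = .glorot(g1, g2),             lb2 = numeric(g2),
      fW1 = .glorot(2 * g2, f1), fb1 = numeric(f1),
      fW2 = .glorot(f1, f2),     fb2 = numeric(f2),
      fW3 = .glorot(f2, 1),      fb3 = numeric(1)
    )
    structure(list(cfg = cfg, params = params), class = "pg_gcn")
  })
}

#' @exportS3Method base::print
print.pg_gcn <- function(x, ...) {
  cfg <- x$cfg
  np <- sum(vapply(x$params, length, 0L))
  cat("<pg_gcn> head=", cfg$head, ", pocket_dim=", cfg$pocket_dim,
      ", ligand_dim=", cfg$ligand_dim, "\n",
      " gcn widths (", paste(cfg$gcn_widths, collapse = ", "),
      ") x 2 branches, ", cfg$pooling, " pooling, fc (",
      paste(cfg$fc_widths, collapse = ", "), ", 1), dropout ",
      cfg$dropout, "\n  parameters: ", np, "\n", sep = "")
  invisible(x)
}

## ---- batching -------------------------------------------------------------

.stack_graphs <- function(graphs, expect_dim, what) {
  dims <- vapply(graphs, function(g) ncol(g$x), 0L)
  if (any(dims != expect_dim))
    stop(what, " feature dim mismatch: model expects ", expect_dim,
         ", got ", dims[which(dims != expect_dim)[1]],
         " (pair index ", which(dims != expect_dim)[1], ")")
  ns <- vapply(graphs, function(g) g$n, 0L)
  X <- do.call(rbind, lapply(graphs, function(g) g$x))
  Ahat <- Matrix::bdiag(lapply(graphs, graph_ahat))
  groups <- rep(seq_along(graphs), ns)
  list(X = X, Ahat = Ahat, groups = groups, ns = ns,
       offsets = c(0L, cumsum(ns))[seq_along(ns)], G = length(graphs))
}

prepare_batch <- function(model, pairs) {
  pb <- .stack_graphs(lapply(pairs, function(p) p$pocket_graph),
                      model$cfg$pocket_dim, "pocket")
  lb <- .stack_graphs(lapply(pairs, function(p) p$ligand_graph),
                      model$cfg$ligand_dim, "ligand")
  y <- vapply(pairs, function(p) p$label, 0)
  list(pocket = pb, ligand = lb, y = y, G = pb$G)
}

## ---- forward / backward ---------------------------------------------------

.branch_forward <- function(W1, b1, W2, b2, bat, pooling) {
  S1 <- as.matrix(bat$Ahat %*% bat$X)
  Z1 <- sweep(S1 %*% W1, 2, b1, "+")
  H1 <- pmax(Z1, 0)
  S2 <- as.matrix(bat$Ahat %*% H1)
  Z2 <- sweep(S2 %*% W2, 2, b2, "+")
  H2 <- pmax(Z2, 0)
  K <- ncol(H2); G <- bat$G
  P <- matrix(0, G, K)
  M <- matrix(0L, G, K)    # argmax node rows (max pooling only)
  if (pooling == "max") {
    for (g in seq_len(G)) {
      rows <- (bat$offsets[g] + 1L):(bat$offsets[g] + bat$ns[g])
      sub <- H2[rows, , drop = FALSE]
      am <- max.col(t(sub), ties.method = "first")
      P[g, ] <- sub[cbind(am, seq_len(K))]
      M[g, ] <- rows[am]
    }
  } else {
    P <- rowsum(H2, bat$groups) / bat$ns
  }
  list(S1 = S1, Z1 = Z1, H1 = H1, S2 = S2, Z2 = Z2, H2 = H2, P = P, M = M)
}

.branch_backward <- function(dP, fw, W1, W2, bat, pooling) {
  N <- nrow(fw$H2); K <- ncol(fw$H2); G <- bat$G
  dH2 <- matrix(0, N, K)
  if (pooling == "max") {
    dH2[cbind(as.vector(fw$M), rep(seq_len(K), each = G))] <- as.vector(dP)
  } else {
    dH2 <- (dP / bat$ns)[bat$groups, , drop = FALSE]
  }
  dZ2 <- dH2 * (fw$Z2 > 0)
  dW2 <- crossprod(fw$S2, dZ2)
  db2 <- colSums(dZ2)
  dH1 <- as.matrix(bat$Ahat %*% (dZ2 %*% t(W2)))  # Ahat is symmetric
  dZ1 <- dH1 * (fw$Z1 > 0)
  dW1 <- crossprod(fw$S1, dZ1)
  db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

.forward <- function(model, batch, train = FALSE) {
  p <- model$params; cfg <- model$cfg
  fp <- .branch_forward(p$pW1, p$pb1, p$pW2, p$pb2, batch$pocket, cfg$pooling)
  fl <- .branch_forward(p$lW1, p$lb1, p$lW2, p$lb2, batch$ligand, cfg$pooling)
  C <- cbind(fp$P, fl$P)
  G <- batch$G
  Z3 <- sweep(C %*% p$fW1, 2, p$fb1, "+"); A3 <- pmax(Z3, 0)
  keep <- 1 - cfg$dropout
  m3 <- if (train && cfg$dropout > 0)
    matrix((runif(length(A3)) < keep) / keep, nrow(A3)) else NULL
  A3d <- if (is.null(m3)) A3 else A3 * m3
  Z4 <- sweep(A3d %*% p$fW2, 2, p$fb2, "+"); A4 <- pmax(Z4, 0)
  m4 <- if (train && cfg$dropout > 0)
    matrix((runif(length(A4)) < keep) / keep, nrow(A4)) else NULL
  A4d <- if (is.null(m4)) A4 else A4 * m4
  out <- as.vector(A4d %*% p$fW3 + p$fb3)
  score <- if (cfg$head == "bc") 1 / (1 + exp(-out)) else out
  list(fp = fp, fl = fl, C = C, Z3 = Z3, A3d = A3d, m3 = m3,
       Z4 = Z4, A4d = A4d, m4 = m4, out = out, score = score)
}

.loss <- function(head, score, y) {
  if (head == "bc") {
    p <- pmin(pmax(score, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  } else {
    mean((score - y)^2)
  }
}

.backward <- function(model, batch, fw) {
  p <- model$params; cfg <- model$cfg
  G <- batch$G
  dout <- if (cfg$head == "bc") (fw$score - batch$y) / G
          else 2 * (fw$score - batch$y) / G
  dout <- matrix(dout, ncol = 1)
  gr <- list()
  gr$fW3 <- crossprod(fw$A4d, dout); gr$fb3 <- colSums(dout)
  dA4d <- dout %*% t(p$fW3)
  if (!is.null(fw$m4)) dA4d <- dA4d * fw$m4
  dZ4 <- dA4d * (fw$Z4 > 0)
  gr$fW2 <- crossprod(fw$A3d, dZ4); gr$fb2 <- colSums(dZ4)
  dA3d <- dZ4 %*% t(p$fW2)
  if (!is.null(fw$m3)) dA3d <- dA3d * fw$m3
  dZ3 <- dA3d * (fw$Z3 > 0)
  gr$fW1 <- crossprod(fw$C, dZ3); gr$fb1 <- colSums(dZ3)
  dC <- dZ3 %*% t(p$fW1)
  g2 <- cfg$gcn_widths[2]
  bp <- .branch_backward(dC[, seq_len(g2), drop = FALSE], fw$fp,
                         p$pW1, p$pW2, batch$pocket, cfg$pooling)
  bl <- .branch_backward(dC[, g2 + seq_len(g2), drop = FALSE], fw$fl,
                         p$lW1, p$lW2, batch$ligand, cfg$pooling)
  gr$pW1 <- bp$W1; gr$pb1 <- bp$b1; gr$pW2 <- bp$W2; gr$pb2 <- bp$b2
  gr$lW1 <- bl$W1; gr$lb1 <- bl$b1; gr$lW2 <- bl$W2; gr$lb2 <- bl$b2
  gr
}

## ---- training -------------------------------------------------------------

#' Training configuration
#'
#' @param epochs Number of passes over the training set.
#' @param batch_size Minibatch size (default 128).
#' @param lr Adam learning rate (default 5e-4).
#' @param eval_every Evaluate on the test set every this many epochs
#'   (default 5).
#' @param seed Seed controlling shuffling and dropout.
#' @return An object of class `pg_train_config`.
#' @export
train_config <- function(epochs = 200, batch_size = 128, lr = 5e-4,
                         eval_every = 5, seed = 1) {
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0, eval_every >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 eval_every = as.integer(eval_every),
                 seed = as.integer(seed)),
            class = "pg_train_config")
}

#' Train a model
#'
#' Minibatch Adam on binary cross-entropy (bc head) or mean squared
#' error (rg head). If a test set is given, the test loss and the head's
#' headline metric (AUC for bc, Pearson r for rg) are recorded on the
#' evaluation cadence and the best-on-test parameters are returned;
#' otherwise the final parameters are returned. Fully reproducible for
#' fixed seeds.
#'
#' @param model A `pg_gcn` from [build_gcn()].
#' @param train List of `pg_pair` training examples.
#' @param test Optional list of `pg_pair` test examples.
#' @param tc A `pg_train_config`.
#' @param verbose Print progress lines.
#' @return List with `model` (trained `pg_gcn`) and `history`
#'   (data.frame: epoch, train_loss, test_loss, test_metric).
#' @export
train_gcn <- function(model, train, test = NULL, tc = train_config(),
                      verbose = FALSE) {
  stopifnot(inherits(model, "pg_gcn"), inherits(tc, "pg_train_config"),
            length(train) >= 1)
  if (model$cfg$head == "bc") {
    labs <- vapply(train, function(p) p$label, 0)
    if (!all(labs %in% c(0, 1)))
      stop("bc head requires 0/1 labels")
  }
  with_seed(tc$seed, {
    ord <- sample.int(length(train))
    train <- train[ord]
    nb <- ceiling(length(train) / tc$batch_size)
    batches <- lapply(seq_len(nb), function(b) {
      i1 <- (b - 1L) * tc$batch_size + 1L
      i2 <- min(b * tc$batch_size, length(train))
      prepare_batch(model, train[i1:i2])
    })
    test_batches <- if (!is.null(test) && length(test))
      .chunk_batches(model, test) else NULL
    test_y <- if (!is.null(test_batches))
      vapply(test, function(p) p$label, 0) else NULL

    opt <- .adam_init(model$params, tc$lr)
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       test_loss = numeric(0), test_metric = numeric(0))
    best <- list(metric = -Inf, params = model$params)
    for (ep in seq_len(tc$epochs)) {
      ep_loss <- 0
      for (b in sample.int(nb)) {
        bat <- batches[[b]]
        fw <- .forward(model, bat, train = TRUE)
        l <- .loss(model$cfg$head, fw$score, bat$y)
        if (!is.finite(l))
          stop("training diverged (non-finite loss at epoch ", ep,
               "); try a lower learning rate")
        ep_loss <- ep_loss + l * bat$G
        gr <- .backward(model, bat, fw)
        upd <- .adam_step(opt, model$params, gr)
        model$params <- upd$params; opt <- upd$opt
      }
      ep_loss <- ep_loss / length(train)
      te_loss <- NA_real_; te_metric <- NA_real_
      if (!is.null(test_batches) &&
          (ep %% tc$eval_every == 0 || ep == tc$epochs)) {
        sc <- unlist(lapply(test_batches, function(b)
          .forward(model, b, train = FALSE)$score))
        te_loss <- .loss(model$cfg$head, sc, test_y)
        te_metric <- if (model$cfg$head == "bc") {
          if (length(unique(test_y)) > 1) roc_auc(test_y, sc) else NA_real_
        } else {
          if (sd(test_y) > 0 && sd(sc) > 0) cor(test_y, sc) else NA_real_
        }
        if (is.finite(te_metric) && te_metric > best$metric)
          best <- list(metric = te_metric, params = model$params)
      }
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss,
                                     test_loss = te_loss,
                                     test_metric = te_metric))
      if (verbose && (ep %% tc$eval_every == 0 || ep == 1))
        message(sprintf("epoch %4d  train %.4f  test %.4f  metric %.4f",
                        ep, ep_loss, te_loss, te_metric))
    }
    if (!is.null(test_batches) && is.finite(best$metric))
      model$params <- best$params
    list(model = model, history = hist)
  })
}

.chunk_batches <- function(model, pairs, chunk = 256L) {
  nb <- ceiling(length(pairs) / chunk)
  lapply(seq_len(nb), function(b) {
    i1 <- (b - 1L) * chunk + 1L
    i2 <- min(b * chunk, length(pairs))
    prepare_batch(model, pairs[i1:i2])
  })
}

.adam_init <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

.adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    g <- as.matrix(g)
    if (is.null(dim(params[[nm]]))) g <- as.vector(g)
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] -
      opt$lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + opt$eps)
  }
  list(opt = opt, params = params)
}

## ---- prediction -----------------------------------------------------------

#' Score one pocket-ligand pair
#'
#' @param model A `pg_gcn`.
#' @param pocket_graph,ligand_graph `pg_graph` objects.
#' @return A single score: binding probability in (0, 1) for the bc
#'   head, predicted pKa for the rg head.
#' @export
gcn_forward <- function(model, pocket_graph, ligand_graph) {
  bat <- prepare_batch(model, list(pair_example(pocket_graph, ligand_graph, 0)))
  .forward(model, bat, train = FALSE)$score
}

#' Batch prediction
#'
#' Scores a sequence of pairs in fixed-size chunks (constant memory in
#' the number of pairs), preserving input order.
#'
#' @param model A `pg_gcn`.
#' @param pairs List of `pg_pair` objects (labels ignored).
#' @param chunk Chunk size (default 256).
#' @return Numeric vector of scores, one per pair.
#' @export
predict_pairs <- function(model, pairs, chunk = 256L) {
  stopifnot(inherits(model, "pg_gcn"))
  if (length(pairs) == 0) return(numeric(0))
  unlist(lapply(.chunk_batches(model, pairs, chunk), function(b)
    .forward(model, b, train = FALSE)$score))
}

## ---- checkpoints ----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Plain-text (JSON) checkpoint carrying the configuration and all
#' parameters at full precision; feature-width drift is detected at
#' load time against the stored dims.
#'
#' @param model A `pg_gcn`.
#' @param path File path (.json).
#' @return `save_gcn`: `path` invisibly. `load_gcn`: a `pg_gcn`.
#' @export
save_gcn <- function(model, path) {
  stopifnot(inherits(model, "pg_gcn"))
  obj <- list(
    format = "pocketgcn-checkpoint", version = "1",
    cfg = unclass(model$cfg),
    params = lapply(model$params, function(p) {
      list(dim = if (is.matrix(p)) dim(p) else length(p),
           data = fmt_dbl(as.vector(p)))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_gcn
#' @export
load_gcn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "pocketgcn-checkpoint")
    stop("not a pocketgcn checkpoint: ", path)
  cfg <- do.call(gcn_config, obj$cfg[c("pocket_dim", "ligand_dim", "head",
                                       "gcn_widths", "fc_widths", "pooling",
                                       "dropout", "seed")])
  params <- lapply(obj$params, function(p) {
    v <- as.numeric(p$data)
    if (length(p$dim) == 2) matrix(v, p$dim[1], p$dim[2]) else v
  })
  structure(list(cfg = cfg, params = params), class = "pg_gcn")
}
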