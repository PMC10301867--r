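## High-level modelling interface in the classic R idiom: one fitting
## function returning a classed object with the usual methods. Wraps
## build_gcn()/train_gcn() so interactive use looks like any other R
## model fit, while the lower-level functions remain available.

#' Fit a pocket-ligand graph convolutional network
#'
#' Trains a two-branch GCN on a list of pocket-ligand pair examples.
#' With `head = "bc"` the model is a binder classifier (sigmoid output,
#' binary cross-entropy); with `head = "rg"` an affinity regressor
#' (linear output, predicting pKa, mean squared error).
#'
#' @param train List of `pg_pair` training examples (see
#'   [pair_example()] and [make_benchmark()]).
#' @param test Optional held-out examples used for the per-epoch metric
#'   trace and best-checkpoint selection.
#' @param head `"bc"` or `"rg"`.
#' @param epochs,batch_size,lr,eval_every Training controls (see
#'   [train_config()]).
#' @param gcn_widths,fc_widths,pooling,dropout Architecture controls
#'   (see [gcn_config()]).
#' @param seed One seed for initialization, shuffling and dropout.
#' @param verbose Print a progress line per evaluation.
#' @return An object of class `pocket_gcn`: list with `model`
#'   (`pg_gcn`), `history`, `head`, sizes and the call.
#' @seealso [predict.pocket_gcn()], [plot.pocket_gcn()]
#' @examples
#' \donttest{
#' bench <- make_benchmark(n_complexes = 20, library_size = 10, seed = 1)
#' fit <- pocket_gcn(bench$train, bench$test, head = "rg", epochs = 5)
#' print(fit)
#' pred <- predict(fit, bench$test)
#' }
#' @export
pocket_gcn <- function(train, test = NULL, head = c("bc", "rg"),
                       epochs = 200, batch_size = 128, lr = 5e-4,
                       eval_every = 5, gcn_widths = c(64, 128),
                       fc_widths = c(256, 64), pooling = "max",
                       dropout = 0.2, seed = 1, verbose = FALSE) {
  head <- match.arg(head)
  stopifnot(length(train) >= 1)
  pdim <- ncol(train[[1]]$pocket_graph$x)
  ldim <- ncol(train[[1]]$ligand_graph$x)
  cfg <- gcn_config(pocket_dim = pdim, ligand_dim = ldim, head = head,
                    gcn_widths = gcn_widths, fc_widths = fc_widths,
                    pooling = pooling, dropout = dropout, seed = seed)
  model <- build_gcn(cfg)
  tc <- train_config(epochs = epochs, batch_size = batch_size, lr = lr,
                     eval_every = eval_every, seed = seed)
  fit <- train_gcn(model, train, test, tc, verbose = verbose)
  structure(list(model = fit$model, history = fit$history, head = head,
                 n_train = length(train),
                 n_test = if (is.null(test)) 0L else length(test),
                 train_labels = vapply(train, function(p) p$label, 0),
                 train_pairs = train,
                 call = match.call()),
            class = "pocket_gcn")
}

#' @exportS3Method base::print
print.pocket_gcn <- function(x, ...) {
  cat("Pocket-ligand GCN (", if (x$head == "bc")
    "binder classification" else "pKa regression", " head)\n", sep = "")
  cat("  trained on ", x$n_train, " pairs",
      if (x$n_test) paste0(", evaluated on ", x$n_test) else "",
      ", ", max(x$history$epoch), " epochs\n", sep = "")
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final train loss %.4f", last$train_loss))
  m <- x$history$test_metric[!is.na(x$history$test_metric)]
  if (length(m))
    cat(sprintf("; best test %s %.4f",
                if (x$head == "bc") "AUC" else "Pearson r", max(m)))
  cat("\n")
  invisible(x)
}

#' @export
summary.pocket_gcn <- function(object, ...) {
  h <- object$history
  ev <- h[!is.na(object$history$test_metric), , drop = FALSE]
  out <- list(head = object$head, epochs = max(h$epoch),
              final_train_loss = h$train_loss[nrow(h)],
              best_test_metric = if (nrow(ev)) max(ev$test_metric) else NA,
              best_epoch = if (nrow(ev))
                ev$epoch[which.max(ev$test_metric)] else NA,
              config = object$model$cfg)
  class(out) <- "summary.pocket_gcn"
  out
}

#' @exportS3Method base::print
print.summary.pocket_gcn <- function(x, ...) {
  cat("Two-branch GCN, head:", x$head, "\n")
  print(x$config)
  cat(sprintf("epochs %d; final train loss %.4f", x$epochs,
              x$final_train_loss), "\n")
  if (!is.na(x$best_test_metric))
    cat(sprintf("best test %s: %.4f at epoch %d\n",
                if (x$head == "bc") "AUC" else "Pearson r",
                x$best_test_metric, x$best_epoch))
  invisible(x)
}

#' @export
coef.pocket_gcn <- function(object, ...) object$model$params

#' Predict binding scores for new pairs
#'
#' @param object A fitted `pocket_gcn`.
#' @param newdata List of `pg_pair` objects (labels ignored), or a
#'   single `pg_pair`.
#' @param ... Unused.
#' @return Numeric vector of scores (probabilities for bc, pKa for rg).
#' @export
predict.pocket_gcn <- function(object, newdata, ...) {
  if (inherits(newdata, "pg_pair")) newdata <- list(newdata)
  predict_pairs(object$model, newdata)
}

#' @export
fitted.pocket_gcn <- function(object, ...) {
  predict_pairs(object$model, object$train_pairs)
}

#' @export
residuals.pocket_gcn <- function(object, ...) {
  if (object$head != "rg")
    stop("residuals are defined for the rg (regression) head")
  object$train_labels - fitted(object)
}

#' Plot training history
#'
#' Training loss per epoch and, when a test set was supplied, the test
#' metric (AUC or Pearson r) on the evaluation cadence.
#'
#' @param x A `pocket_gcn`.
#' @param ... Passed to [plot()].
#' @export
plot.pocket_gcn <- function(x, ...) {
  h <- x$history
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
       ylab = if (x$head == "bc") "BCE" else "MSE",
       main = "training loss", ...)
  ev <- h[!is.na(h$test_metric), , drop = FALSE]
  if (nrow(ev)) {
    plot(ev$epoch, ev$test_metric, type = "b", xlab = "epoch",
         ylab = if (x$head == "bc") "test AUC" else "test Pearson r",
         main = "held-out metric", ...)
  } else {
    plot.new(); title("no test set")
  }
  invisible(x)
}

#' @importFrom graphics par plot.new title
#' @importFrom stats fitted residuals coef
NULL
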