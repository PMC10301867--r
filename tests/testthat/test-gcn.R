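test_that("bc scores sit strictly inside (0,1), rg scores are finite", {
  pairs <- tiny_pair_set(8)
  bc <- build_gcn(gcn_config(20, head = "bc", seed = 2))
  rg <- build_gcn(gcn_config(20, head = "rg", seed = 2))
  sb <- predict_pairs(bc, pairs)
  sr <- predict_pairs(rg, pairs)
  expect_true(all(sb > 0 & sb < 1))
  expect_true(all(is.finite(sr)))
})

test_that("seeded builds are identical, different seeds differ", {
  a <- build_gcn(gcn_config(20, head = "bc", seed = 11))
  b <- build_gcn(gcn_config(20, head = "bc", seed = 11))
  c <- build_gcn(gcn_config(20, head = "bc", seed = 12))
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, c$params))
})

test_that("single-atom ligands pass through the network", {
  pairs <- tiny_pair_set(2)
  g <- ligand_graph("C")
  m <- build_gcn(gcn_config(20, head = "rg", seed = 1))
  s <- gcn_forward(m, pairs[[1]]$pocket_graph, g)
  expect_true(is.finite(s))
})

test_that("scores are invariant to node permutation", {
  pairs <- tiny_pair_set(6)
  m <- build_gcn(gcn_config(20, head = "rg", seed = 4))
  for (p in pairs[1:3]) {
    g <- p$ligand_graph
    s0 <- gcn_forward(m, p$pocket_graph, g)
    set.seed(1)
    perm <- sample(g$n)
    inv <- order(perm)
    g2 <- g
    g2$x <- g$x[perm, , drop = FALSE]
    if (nrow(g$edges)) {
      e <- cbind(inv[g$edges[, 1]], inv[g$edges[, 2]])
      g2$edges <- e[order(e[, 1], e[, 2]), , drop = FALSE]
    }
    s1 <- gcn_forward(m, p$pocket_graph, g2)
    expect_equal(s1, s0, tolerance = 1e-5)
  }
})

test_that("batched scores match per-item scores", {
  pairs <- tiny_pair_set(16)
  m <- build_gcn(gcn_config(20, head = "bc", seed = 9))
  batched <- predict_pairs(m, pairs)
  single <- vapply(pairs, function(p)
    gcn_forward(m, p$pocket_graph, p$ligand_graph), 0)
  expect_equal(batched, single, tolerance = 1e-5)
  ## repeats give identical scores; empty input gives empty output
  expect_equal(predict_pairs(m, pairs[c(1, 1, 1)]),
               rep(single[1], 3), tolerance = 1e-12)
  expect_length(predict_pairs(m, list()), 0)
})

test_that("analytic gradients match numerical differentiation", {
  pairs <- tiny_pair_set(4)
  cfg <- gcn_config(20, head = "rg", gcn_widths = c(5, 6),
                    fc_widths = c(7, 4), dropout = 0, seed = 3)
  m <- build_gcn(cfg)
  ## jitter all parameters away from zero so no pre-activation sits
  ## exactly on a ReLU kink (where the one-sided numerical derivative
  ## and the subgradient legitimately disagree)
  set.seed(30)
  m$params <- lapply(m$params, function(p) p + rnorm(length(p), 0, 0.05))
  bat <- pocketgcn:::prepare_batch(m, pairs)
  fw <- pocketgcn:::.forward(m, bat, train = TRUE)   # dropout 0 => det.
  gr <- pocketgcn:::.backward(m, bat, fw)
  lossfn <- function(model) {
    f <- pocketgcn:::.forward(model, bat, train = FALSE)
    pocketgcn:::.loss("rg", f$score, bat$y)
  }
  eps <- 1e-6
  set.seed(42)
  for (nm in c("pW1", "lW2", "fW1", "fW3", "pb2", "fb3")) {
    k <- sample(length(m$params[[nm]]), min(3, length(m$params[[nm]])))
    for (i in k) {
      mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
      num <- (lossfn(mp) - lossfn(mm)) / (2 * eps)
      expect_equal(as.vector(gr[[nm]])[i], num, tolerance = 1e-4)
    }
  }
})

test_that("the network can overfit a small set (capacity sanity)", {
  pairs <- bc_labels(tiny_pair_set(32, seed = 8))
  fit <- train_gcn(build_gcn(gcn_config(20, head = "bc", dropout = 0,
                                        seed = 5)),
                   pairs, tc = train_config(epochs = 200, batch_size = 32,
                                            lr = 2e-3, seed = 5))
  expect_lt(fit$history$train_loss[200], 0.05)
})

test_that("training histories are reproducible for a fixed seed", {
  pairs <- tiny_pair_set(20)
  run <- function() {
    train_gcn(build_gcn(gcn_config(20, head = "rg", seed = 6)),
              pairs[1:16], pairs[17:20],
              tc = train_config(epochs = 5, batch_size = 8, eval_every = 2,
                                seed = 6))
  }
  h1 <- run(); h2 <- run()
  expect_equal(h1$history$train_loss, h2$history$train_loss,
               tolerance = 1e-6)
  expect_identical(h1$model$params, h2$model$params)
})

test_that("feature-dim mismatches raise configuration errors", {
  pairs <- tiny_pair_set(2)
  m <- build_gcn(gcn_config(30, head = "bc", seed = 1))  # expects 30, gets 20
  expect_error(predict_pairs(m, pairs), "dim mismatch")
})

test_that("checkpoints restore models exactly", {
  pairs <- tiny_pair_set(6)
  fit <- train_gcn(build_gcn(gcn_config(20, head = "rg", seed = 2)),
                   pairs, tc = train_config(epochs = 3, batch_size = 4,
                                            seed = 2))
  tf <- tempfile(fileext = ".json")
  save_gcn(fit$model, tf)
  m2 <- load_gcn(tf)
  expect_identical(m2$params, fit$model$params)
  expect_equal(predict_pairs(m2, pairs), predict_pairs(fit$model, pairs))
})

test_that("the pocket_gcn fit interface exposes the standard methods", {
  pairs <- tiny_pair_set(20)
  fit <- pocket_gcn(pairs[1:16], pairs[17:20], head = "rg", epochs = 4,
                    batch_size = 8, eval_every = 2, seed = 3)
  expect_s3_class(fit, "pocket_gcn")
  expect_output(print(fit), "pKa regression")
  s <- summary(fit)
  expect_s3_class(s, "summary.pocket_gcn")
  expect_named(coef(fit), c("pW1", "pb1", "pW2", "pb2", "lW1", "lb1",
                            "lW2", "lb2", "fW1", "fb1", "fW2", "fb2",
                            "fW3", "fb3"))
  pred <- predict(fit, pairs[17:20])
  expect_length(pred, 4)
  r <- residuals(fit)
  expect_length(r, 16)
  expect_equal(r, fit$train_labels - fitted(fit))
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tf))
})
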