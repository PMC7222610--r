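blob_table <- function(n_half = 100, sep = 10, seed = 1,
                       labels = c("liver", "other")) {
  generate_blobs(n_half, 2, rbind(c(0, 0), c(sep, sep)), sd = 1,
                 seed = seed, labels = labels)
}

test_that("binary training separates distant blobs and is deterministic", {
  tab <- blob_table(100, sep = 10, seed = 2)
  cfg <- train_config(lambda = 10, mu = 0.05, seed = 5)
  m <- train_binary(tab, cfg)
  expect_equal(accuracy(predict_binary(m, tab), tab$labels), 1.0)

  m2 <- train_binary(tab, cfg)
  expect_identical(m$expansion, m2$expansion)
  expect_identical(m$support_Xtilde, m2$support_Xtilde)

  one_class <- feature_table(tab$X, labels = rep("liver", nrow(tab$X)))
  expect_error(train_binary(one_class, cfg), "2 label")
})

test_that("core-set and direct solvers yield near-identical classifiers", {
  tab <- blob_table(100, sep = 10, seed = 3)
  grid <- generate_blobs(150, 2, rbind(c(0, 0), c(10, 10)), sd = 2.5,
                         seed = 99, labels = c("a", "b"))
  cfg_d <- train_config(lambda = 10, mu = 0.05, seed = 5, solver = "direct")
  cfg_c <- train_config(lambda = 10, mu = 0.05, seed = 5, solver = "coreset",
                        sample_size = 0L)
  md <- train_binary(tab, cfg_d)
  mc <- train_binary(tab, cfg_c)
  agree <- mean(predict_binary(md, grid$X) == predict_binary(mc, grid$X))
  expect_gte(agree, 0.99)
  # train-set accuracies of the two routes within one percentage point
  expect_lte(abs(accuracy(predict_binary(md, tab), tab$labels) -
                   accuracy(predict_binary(mc, tab), tab$labels)), 0.01)
})

test_that("decision values follow the kernel expansion and the sign rule", {
  tab <- blob_table(50, sep = 8, seed = 4)
  m <- train_binary(tab, train_config(lambda = 10, mu = 0.05, seed = 1))

  # manual re-computation of the expansion sum (independent code path)
  Xs <- sweep(sweep(tab$X, 2, m$scaler$center), 2, m$scaler$scale, "/")
  Xt <- hidden_map(m$hidden, Xs)
  D2 <- as.matrix(stats::dist(rbind(Xt, m$support_Xtilde)))^2
  cross <- D2[seq_len(nrow(Xt)),
              nrow(Xt) + seq_len(nrow(m$support_Xtilde)), drop = FALSE]
  manual <- as.numeric(exp(-cross / (2 * m$sigma2)) %*% m$expansion)
  expect_equal(decision_value(m, tab), manual, tolerance = 1e-10)

  # zero expansion gives identically zero decisions
  m0 <- m; m0$expansion <- m$expansion * 0
  expect_equal(decision_value(m0, tab), rep(0, nrow(tab$X)))

  # deep-positive training point has a positive decision value
  pos_idx <- which(tab$labels == m$pos_label)[1]
  expect_gt(decision_value(m, tab$X[pos_idx, , drop = FALSE]), 0)

  # sign rule with the zero-goes-positive tie
  expect_identical(predict_binary(m0, tab$X[1:3, ]), rep(m$pos_label, 3))
  expect_error(decision_value(m, tab$X[, 1, drop = FALSE]), "dimension")
})

test_that("one-vs-one training covers the three pairs with derived seeds", {
  tab <- generate_blobs(60, 2, rbind(c(0, 0), c(8, 0), c(0, 8)), sd = 1,
                        seed = 6, labels = c("liver", "kidney", "other"))
  cfg <- train_config(lambda = 10, mu = 0.05, seed = 2)
  m <- train_ovo(tab, cfg)
  expect_s3_class(m, "fast_rbf_ovo")
  expect_identical(c(m$clf_AB$pos_label, m$clf_AB$neg_label), c("liver", "kidney"))
  expect_identical(c(m$clf_AC$pos_label, m$clf_AC$neg_label), c("liver", "other"))
  expect_identical(c(m$clf_BC$pos_label, m$clf_BC$neg_label), c("kidney", "other"))
  expect_equal(m$clf_AB$n_train, 120)

  m2 <- train_ovo(tab, cfg)
  expect_identical(m$clf_BC$expansion, m2$clf_BC$expansion)
  expect_equal(accuracy(predict_ovo(m, tab), tab$labels), 1.0)

  two <- feature_table(tab$X, labels = sub("kidney", "liver", tab$labels))
  expect_error(train_ovo(two, cfg), "missing class: kidney")
})

test_that("one-vs-one voting matches hand enumeration over all 8 outcomes", {
  # synthesize an OvO model whose three decision values we control
  mk_const <- function(v, pos, neg) {
    structure(list(kind = "linear",
                   scaler = list(center = c(0, 0), scale = c(1, 1)),
                   hidden = structure(list(centers = matrix(0, 1, 2),
                                           widths = 1, M = 1L),
                                      class = "hidden_layer"),
                   sigma2 = 1, lambda = 1, mu = 1, weights = v,
                   pos_label = pos, neg_label = neg, n_train = 1,
                   info = list()), class = "fast_rbf_binary")
  }
  # hidden activation at x = (0,0) is exp(0) = 1, so decision = weight
  cases <- expand.grid(ab = c(1, -1), ac = c(1, -1), bc = c(1, -1))
  hand <- character(8)
  for (i in seq_len(8)) {
    votes <- c(liver = 0, kidney = 0, other = 0)
    if (cases$ab[i] > 0) votes["liver"] <- votes["liver"] + 1 else
      votes["kidney"] <- votes["kidney"] + 1
    if (cases$ac[i] > 0) votes["liver"] <- votes["liver"] + 1 else
      votes["other"] <- votes["other"] + 1
    if (cases$bc[i] > 0) votes["kidney"] <- votes["kidney"] + 1 else
      votes["other"] <- votes["other"] + 1
    top <- names(votes)[votes == max(votes)]
    hand[i] <- top[1]  # unique except in cyclic cases handled below
  }
  for (i in seq_len(8)) {
    model <- structure(list(
      clf_AB = mk_const(cases$ab[i] * 0.5, "liver", "kidney"),
      clf_AC = mk_const(cases$ac[i] * 0.4, "liver", "other"),
      clf_BC = mk_const(cases$bc[i] * 0.3, "kidney", "other"),
      tie_break = "winning-margin-sum"), class = "fast_rbf_ovo")
    got <- predict_ovo(model, matrix(0, 1, 2))
    votes <- c(liver = 0, kidney = 0, other = 0)
    votes["liver"] <- (cases$ab[i] > 0) + (cases$ac[i] > 0)
    votes["kidney"] <- (cases$ab[i] < 0) + (cases$bc[i] > 0)
    votes["other"] <- (cases$ac[i] < 0) + (cases$bc[i] < 0)
    if (max(votes) == 2) {
      expect_identical(got, names(votes)[which.max(votes)])
    } else {
      # cyclic 1-1-1 tie: largest summed winning margin
      wins <- c(liver = 0, kidney = 0, other = 0)
      if (cases$ab[i] > 0) wins["liver"] <- wins["liver"] + 0.5 else
        wins["kidney"] <- wins["kidney"] + 0.5
      if (cases$ac[i] > 0) wins["liver"] <- wins["liver"] + 0.4 else
        wins["other"] <- wins["other"] + 0.4
      if (cases$bc[i] > 0) wins["kidney"] <- wins["kidney"] + 0.3 else
        wins["other"] <- wins["other"] + 0.3
      expect_identical(got, names(wins)[which.max(wins)])
    }
  }
})

test_that("accuracy is the exact fraction of correct labels", {
  expect_equal(accuracy(c("a", "b"), c("a", "b")), 1.0)
  expect_equal(accuracy(c("a", "b", "a", "b"), c("a", "b", "a", "a")), 0.75)
  withr::with_seed(31, {
    for (r in 1:5) {
      n <- sample(5:50, 1)
      p <- sample(letters[1:3], n, TRUE); t <- sample(letters[1:3], n, TRUE)
      count <- 0
      for (i in seq_len(n)) if (p[i] == t[i]) count <- count + 1
      expect_equal(accuracy(p, t), count / n)
    }
  })
  expect_error(accuracy(character(0), character(0)), "empty")
  expect_error(accuracy("a", c("a", "b")), "mismatch")
})

test_that("the gradient-descent RBF baseline solves the normal equations", {
  tab <- blob_table(60, sep = 8, seed = 7)
  cfg <- train_config(seed = 3, solver = "baseline", ridge = 0)
  m <- train_rbf_baseline(tab, cfg)
  expect_equal(accuracy(predict_binary(m, tab), tab$labels), 1.0)

  # residuals orthogonal to the hidden features at zero regularization
  Xs <- sweep(sweep(tab$X, 2, m$scaler$center), 2, m$scaler$scale, "/")
  Xt <- hidden_map(m$hidden, Xs)
  y <- ifelse(tab$labels == m$pos_label, 1, -1)
  res <- y - as.numeric(Xt %*% m$weights)
  expect_equal(max(abs(crossprod(Xt, res))), 0, tolerance = 1e-6)

  # agrees with explicit gradient-descent iterations run to convergence
  cfg_r <- train_config(seed = 3, solver = "baseline", ridge = 0.1)
  mr <- train_rbf_baseline(tab, cfg_r)
  w_gd <- gd_ridge_weights(Xt, y, ridge = 0.1)
  expect_equal(mr$weights, w_gd, tolerance = 1e-4)

  # solver = "baseline" through train_binary dispatches here
  mb <- train_binary(tab, cfg_r)
  expect_identical(mb$weights, mr$weights)
})

test_that("models round-trip through the JSON archive", {
  tab <- blob_table(40, sep = 8, seed = 8)
  m <- train_binary(tab, train_config(lambda = 10, mu = 0.05, seed = 1))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "model.json")
  save_model(m, p)
  back <- load_model(p)
  expect_equal(decision_value(back, tab), decision_value(m, tab),
               tolerance = 1e-12)

  tab3 <- generate_blobs(40, 2, rbind(c(0, 0), c(8, 0), c(0, 8)), sd = 1,
                         seed = 6, labels = c("liver", "kidney", "other"))
  mo <- train_ovo(tab3, train_config(lambda = 10, mu = 0.05, seed = 2))
  save_model(mo, p)
  back3 <- load_model(p)
  expect_identical(predict_ovo(back3, tab3), predict_ovo(mo, tab3))
})
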