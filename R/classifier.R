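#' Training configuration
#'
#' Collects the hyperparameters of the Fast-RBF pipeline. `sigma2 = NULL`
#' selects the median heuristic (median pairwise squared distance of the
#' hidden features, estimated on a subsample) at training time.
#'
#' @param M Number of hidden nodes (FCM clusters).
#' @param fuzzifier FCM fuzziness exponent (> 1).
#' @param lambda Weight of the epsilon term in the training objective.
#' @param mu Balance factor (mean slack); `mu * n / lambda` regularizes
#'   the augmented kernel diagonal.
#' @param sigma2 Base-kernel bandwidth, or `NULL` for the median
#'   heuristic.
#' @param eps_tol Core-set MEB approximation factor.
#' @param sample_size Core-set probe-sample size (0 = exhaustive scans).
#' @param seed Integer seed; all randomness in training flows from it.
#' @param solver One of `"coreset"`, `"direct"`, `"baseline"`.
#' @param ridge Ridge regularization for the `"baseline"` least-squares
#'   output weights.
#' @return An object of class `train_config`.
#' @export
train_config <- function(M = 10L, fuzzifier = 2, lambda = 1000, mu = 0.001,
                         sigma2 = NULL, eps_tol = 1e-6, sample_size = 59L,
                         seed = 1L, solver = c("coreset", "direct", "baseline"),
                         ridge = 1e-8) {
  solver <- match.arg(solver)
  for (nm in c("M", "fuzzifier", "lambda", "mu", "eps_tol")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(nm, " must be a single strictly positive number")
    }
  }
  if (!is.null(sigma2) && (!is.numeric(sigma2) || sigma2 <= 0)) {
    stop("sigma2 must be NULL or strictly positive")
  }
  structure(list(M = as.integer(M), fuzzifier = fuzzifier, lambda = lambda,
                 mu = mu, sigma2 = sigma2, eps_tol = eps_tol,
                 sample_size = as.integer(sample_size), seed = as.integer(seed),
                 solver = solver, ridge = ridge),
            class = "train_config")
}

scaler_fit <- function(X) {
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[!is.finite(sd_) | sd_ < 1e-12] <- 1
  list(center = mu, scale = sd_)
}

scaler_apply <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

median_heuristic_sigma2 <- function(Xtilde, seed, max_n = 2000L) {
  n <- nrow(Xtilde)
  idx <- if (n > max_n) withr::with_seed(seed, sample.int(n, max_n)) else seq_len(n)
  D <- pdist2(Xtilde[idx, , drop = FALSE], Xtilde[idx, , drop = FALSE])
  m <- stats::median(D[upper.tri(D)])
  if (!is.finite(m) || m <= 0) m <- 1
  m
}

table_xy <- function(table) {
  if (inherits(table, "feature_table")) list(X = table$X, labels = table$labels)
  else stop("expected a feature_table")
}

# Order labels by the fixed tissue priority, unknown labels after.
order_pair_labels <- function(labs) {
  pri <- match(labs, TISSUE_LEVELS)
  pri[is.na(pri)] <- length(TISSUE_LEVELS) + rank(labs[is.na(pri)])
  labs[order(pri)]
}

fit_hidden_pipeline <- function(X, cfg) {
  scaler <- scaler_fit(X)
  Xs <- scaler_apply(scaler, X)
  fcm <- fcm_cluster(Xs, M = cfg$M, fuzzifier = cfg$fuzzifier, seed = cfg$seed)
  hidden <- build_hidden_layer(fcm, Xs)
  Xtilde <- hidden_map(hidden, Xs)
  sigma2 <- if (is.null(cfg$sigma2)) {
    median_heuristic_sigma2(Xtilde, cfg$seed)
  } else cfg$sigma2
  list(scaler = scaler, hidden = hidden, Xtilde = Xtilde, sigma2 = sigma2)
}

#' Train a binary Fast-RBF classifier
#'
#' Pipeline: z-score the features with training statistics, estimate the
#' Gaussian hidden layer by FCM, map to hidden space, and solve the
#' epsilon-insensitive dual with the configured solver (`"coreset"` for
#' the core-set MEB iteration, `"direct"` for the dense QP,
#' `"baseline"` delegates to [train_rbf_baseline()]). Deterministic for
#' a fixed `cfg$seed`.
#'
#' @param table A [feature_table()] whose labels take exactly two values.
#' @param cfg A [train_config()].
#' @return An object of class `fast_rbf_binary`.
#' @export
train_binary <- function(table, cfg = train_config()) {
  if (cfg$solver == "baseline") return(train_rbf_baseline(table, cfg))
  tx <- table_xy(table)
  if (is.null(tx$labels)) stop("training requires labels")
  labs <- order_pair_labels(unique(tx$labels))
  if (length(labs) != 2L) {
    stop("binary training requires exactly 2 label values, got ",
         length(labs))
  }
  pos_label <- labs[1]; neg_label <- labs[2]
  y <- ifelse(tx$labels == pos_label, 1, -1)
  if (nrow(tx$X) < cfg$M) stop("fewer samples than hidden nodes")

  pipe <- fit_hidden_pipeline(tx$X, cfg)
  n <- nrow(pipe$Xtilde)
  if (cfg$solver == "direct") {
    prob <- eps_qp_problem(pipe$Xtilde, y, cfg$lambda, cfg$mu, pipe$sigma2)
    sol <- solve_dual_direct(prob)
    alpha <- sol$alpha; alpha_star <- sol$alpha_star
    info <- list(solver = "direct", objective = sol$objective)
  } else {
    prob <- ccmeb_problem(pipe$Xtilde, y, cfg$lambda, cfg$mu, pipe$sigma2)
    cs <- solve_coreset(prob, eps_tol = cfg$eps_tol,
                        sample_size = cfg$sample_size, seed = cfg$seed)
    ab <- coreset_to_alpha(cs, n)
    alpha <- ab$alpha; alpha_star <- ab$alpha_star
    info <- list(solver = "coreset", objective = cs$objective,
                 coreset_size = length(cs$indices), n_iter = cs$n_iter,
                 radius = cs$radius)
  }
  expansion <- cfg$lambda * (alpha - alpha_star)
  nz <- which(expansion != 0)
  if (length(nz) == 0L) nz <- which.max(abs(alpha + alpha_star))
  structure(list(kind = "kernel", scaler = pipe$scaler, hidden = pipe$hidden,
                 sigma2 = pipe$sigma2, lambda = cfg$lambda, mu = cfg$mu,
                 support_Xtilde = pipe$Xtilde[nz, , drop = FALSE],
                 expansion = expansion[nz],
                 pos_label = pos_label, neg_label = neg_label,
                 n_train = n, info = info, cfg = cfg),
            class = "fast_rbf_binary")
}

#' Traditional RBF baseline
#'
#' Same FCM hidden layer as [train_binary()], but the output weights are
#' the ridge-regularized least-squares fit of the +/-1 labels on the
#' hidden activations -- the fixed point of gradient-descent training of
#' the classical RBF output layer.
#'
#' @inheritParams train_binary
#' @return A `fast_rbf_binary` with `kind = "linear"`.
#' @export
train_rbf_baseline <- function(table, cfg = train_config(solver = "baseline")) {
  tx <- table_xy(table)
  if (is.null(tx$labels)) stop("training requires labels")
  labs <- order_pair_labels(unique(tx$labels))
  if (length(labs) != 2L) {
    stop("binary training requires exactly 2 label values, got ", length(labs))
  }
  pos_label <- labs[1]; neg_label <- labs[2]
  y <- ifelse(tx$labels == pos_label, 1, -1)
  if (nrow(tx$X) < cfg$M) stop("fewer samples than hidden nodes")
  pipe <- fit_hidden_pipeline(tx$X, cfg)
  Xt <- pipe$Xtilde
  G <- crossprod(Xt) + diag(cfg$ridge, ncol(Xt))
  w <- solve(G, crossprod(Xt, y))
  structure(list(kind = "linear", scaler = pipe$scaler, hidden = pipe$hidden,
                 sigma2 = pipe$sigma2, lambda = cfg$lambda, mu = cfg$mu,
                 weights = as.numeric(w),
                 pos_label = pos_label, neg_label = neg_label,
                 n_train = nrow(Xt), info = list(solver = "baseline"),
                 cfg = cfg),
            class = "fast_rbf_binary")
}

#' @export
print.fast_rbf_binary <- function(x, ...) {
  cat(sprintf("<fast_rbf_binary %s vs %s: %s solver, M = %d%s>\n",
              x$pos_label, x$neg_label, x$info$solver, x$hidden$M,
              if (!is.null(x$info$coreset_size))
                sprintf(", core set %d", x$info$coreset_size) else ""))
  invisible(x)
}

#' Decision values of a binary model
#'
#' For the kernel models, `f(x) = sum_i expansion_i k(xtilde_i,
#' xtilde_test)` with `k` the base Gaussian kernel (the diagonal
#' regularizer of the augmented training kernel never applies to test
#' points); for the baseline, the linear output `xtilde' w`.
#'
#' @param model A `fast_rbf_binary`.
#' @param X Raw feature matrix (or [feature_table()]) with the training
#'   feature dimension.
#' @return Numeric vector of decision values.
#' @export
decision_value <- function(model, X) {
  stopifnot(inherits(model, "fast_rbf_binary"))
  if (inherits(X, "feature_table")) X <- X$X
  X <- as.matrix(X)
  if (ncol(X) != length(model$scaler$center)) {
    stop("feature dimension (", ncol(X), ") does not match model (",
         length(model$scaler$center), ")")
  }
  Xt <- hidden_map(model$hidden, scaler_apply(model$scaler, X))
  if (model$kind == "linear") {
    return(as.numeric(Xt %*% model$weights))
  }
  K <- base_kernel(Xt, model$support_Xtilde, model$sigma2)
  as.numeric(K %*% model$expansion)
}

#' Predict binary labels by the sign rule
#'
#' Positive decision values (including exactly zero) map to the positive
#' label, negative values to the negative label.
#'
#' @inheritParams decision_value
#' @return Character vector of labels.
#' @export
predict_binary <- function(model, X) {
  f <- decision_value(model, X)
  ifelse(f >= 0, model$pos_label, model$neg_label)
}

#' Train the one-vs-one three-class organ model
#'
#' Trains the pairwise classifiers liver-kidney, liver-other and
#' kidney-other on the label-restricted subsets of the table.
#'
#' @param table A [feature_table()] containing all three tissue labels.
#' @param cfg A [train_config()]; pairwise seeds are derived from
#'   `cfg$seed`.
#' @return An object of class `fast_rbf_ovo`.
#' @export
train_ovo <- function(table, cfg = train_config()) {
  tx <- table_xy(table)
  if (is.null(tx$labels)) stop("training requires labels")
  missing <- setdiff(TISSUE_LEVELS, unique(tx$labels))
  if (length(missing) > 0L) {
    stop("missing class: ", paste(missing, collapse = ", "))
  }
  pairs <- list(c("liver", "kidney"), c("liver", "other"), c("kidney", "other"))
  clfs <- vector("list", 3L)
  for (k in seq_along(pairs)) {
    pr <- pairs[[k]]
    sel <- tx$labels %in% pr
    sub <- feature_table(tx$X[sel, , drop = FALSE], labels = tx$labels[sel],
                         case_id = table$case_id, roi = table$roi)
    cfg_k <- cfg
    cfg_k$seed <- cfg$seed + k - 1L
    clfs[[k]] <- train_binary(sub, cfg_k)
  }
  structure(list(clf_AB = clfs[[1]], clf_AC = clfs[[2]], clf_BC = clfs[[3]],
                 tie_break = "winning-margin-sum", cfg = cfg),
            class = "fast_rbf_ovo")
}

#' @export
print.fast_rbf_ovo <- function(x, ...) {
  cat("<fast_rbf_ovo: liver-kidney, liver-other, kidney-other>\n")
  invisible(x)
}

# Votes and tie-break from the three pairwise decision values.
# f_AB > 0 means liver over kidney, f_AC > 0 liver over other,
# f_BC > 0 kidney over other (zero counts as the positive side).
ovo_vote <- function(f_AB, f_AC, f_BC) {
  m <- length(f_AB)
  votes <- matrix(0L, m, 3L, dimnames = list(NULL, TISSUE_LEVELS))
  wins <- matrix(0, m, 3L, dimnames = list(NULL, TISSUE_LEVELS))
  add <- function(f, pos, neg) {
    p <- f >= 0
    j <- ifelse(p, match(pos, TISSUE_LEVELS), match(neg, TISSUE_LEVELS))
    ij <- cbind(seq_len(m), j)
    votes[ij] <<- votes[ij] + 1L
    wins[ij] <<- wins[ij] + abs(f)
  }
  add(f_AB, "liver", "kidney")
  add(f_AC, "liver", "other")
  add(f_BC, "kidney", "other")
  out <- character(m)
  for (j in seq_len(m)) {
    v <- votes[j, ]
    top <- which(v == max(v))
    if (length(top) > 1L) {
      # cyclic 1-1-1 tie (or equal-vote pair): largest summed winning
      # margin, residual ties by fixed priority liver > kidney > other
      w <- wins[j, top]
      top <- top[w == max(w)]
    }
    out[j] <- TISSUE_LEVELS[min(top)]
  }
  out
}

#' Predict tissue labels by one-vs-one voting
#'
#' Each pairwise classifier casts one vote; the class with the most
#' votes wins. A cyclic tie is broken by the largest sum of winning
#' decision-value margins, and any residual tie by the fixed priority
#' liver > kidney > other.
#'
#' @param model A `fast_rbf_ovo`.
#' @param X Raw feature matrix or [feature_table()].
#' @return Character vector over `{liver, kidney, other}`.
#' @export
predict_ovo <- function(model, X) {
  stopifnot(inherits(model, "fast_rbf_ovo"))
  ovo_vote(decision_value(model$clf_AB, X),
           decision_value(model$clf_AC, X),
           decision_value(model$clf_BC, X))
}

#' Classification accuracy
#'
#' Fraction of test samples classified correctly.
#'
#' @param pred,truth Equal-length label vectors.
#' @return A number in `[0, 1]`.
#' @export
accuracy <- function(pred, truth) {
  if (length(pred) == 0L) stop("empty input")
  if (length(pred) != length(truth)) stop("length mismatch")
  mean(as.character(pred) == as.character(truth))
}
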