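# Shared fixtures: all inputs are generated in code at test time.

# Four-channel volume with deterministic, channel-distinct intensities.
make_test_volume <- function(h = 12, w = 12, spacing = c(1, 1), seed = 42) {
  withr::with_seed(seed, {
    channels <- lapply(1:4, function(k) {
      matrix(k * 10 + rnorm(h * w), h, w)
    })
  })
  names(channels) <- c("fat", "water", "ip", "op")
  mr_volume_set(channels, spacing, case_id = "test")
}

# Two well-separated Gaussian blobs as a +/-1 training problem.
make_blob_problem <- function(n_half, d = 2, sep = 4, seed = 1) {
  tab <- generate_blobs(n_half, d, rbind(rep(0, d), rep(sep, d)),
                        sd = 1, seed = seed, labels = c("pos", "neg"))
  list(X = tab$X, y = ifelse(tab$labels == "pos", 1, -1), table = tab)
}

# Exhaustive simplex-grid maximization of the n = 2 dual objective
# 2*lambda*[y, -y]'a - a' Ktilde a at resolution `step` (independent
# brute-force oracle; vectorized over the two inner coordinates).
brute_force_dual_n2 <- function(Ktilde, y, lambda, step = 1e-3) {
  stopifnot(length(y) == 2, all(dim(Ktilde) == 4))
  m <- round(1 / step)
  d <- 2 * lambda * c(y, -y)
  best <- -Inf
  for (i in 0:m) {
    rem <- m - i
    jj <- rep.int(0:rem, rem:0 + 1L)
    kk <- sequence(rem:0 + 1L) - 1L
    ll <- rem - jj - kk
    V <- cbind(i, jj, kk, ll) / m
    quad <- rowSums((V %*% Ktilde) * V)
    val <- as.numeric(V %*% d) - quad
    best <- max(best, max(val))
  }
  best
}

# Textbook-FCM oracle: let e1071::cmeans converge from the same centers,
# then evaluate the standard fuzzy within-cluster objective
# sum_ji u_ji^m ||x_j - c_i||^2 on its solution.
fcm_oracle_objective <- function(X, centers, m = 2) {
  ref <- e1071::cmeans(X, centers = centers, m = m, iter.max = 1000,
                       method = "cmeans")
  D <- outer(rowSums(X^2), rowSums(ref$centers^2), "+") -
    2 * tcrossprod(X, ref$centers)
  sum(ref$membership^m * pmax(D, 0))
}

# Plain gradient-descent iterations for the ridge least-squares output
# weights of the baseline RBF (independent iterative oracle).
gd_ridge_weights <- function(Xt, y, ridge, iters = 50000, lr = NULL) {
  M <- ncol(Xt)
  w <- numeric(M)
  G <- crossprod(Xt)
  if (is.null(lr)) lr <- 1 / (2 * (max(eigen(G, symmetric = TRUE,
                                             only.values = TRUE)$values) + ridge))
  b <- crossprod(Xt, y)
  for (i in seq_len(iters)) {
    grad <- G %*% w - b + ridge * w
    w <- w - lr * grad
    if (max(abs(grad)) < 1e-10) break
  }
  as.numeric(w)
}
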