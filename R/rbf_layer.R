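# Squared Euclidean distances between rows of A (n x d) and B (m x d).
pdist2 <- function(A, B) {
  an <- rowSums(A * A)
  bn <- rowSums(B * B)
  D <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  D[D < 0] <- 0
  D
}

# E||x - x'||^2 for independent draws = 2 * sum of column variances;
# used to set a scale-aware width floor without forming all pairs.
mean_pairwise_sq_dist <- function(X) {
  if (nrow(X) < 2L) return(0)
  2 * sum(apply(X, 2, stats::var))
}

#' Fuzzy C-means clustering
#'
#' Standard FCM alternating updates: memberships from current centers,
#' then centers from fuzzified memberships, until the largest membership
#' change drops below `tol` or `max_iter` is reached. Initial centers are
#' `M` distinct rows of `X` drawn under `seed`.
#'
#' @param X Numeric matrix, n x d.
#' @param M Number of clusters, `1 <= M <= n`.
#' @param fuzzifier Fuzziness exponent m > 1 (default 2).
#' @param tol Convergence tolerance on the max membership change.
#' @param max_iter Iteration cap.
#' @param seed Integer seed for center initialization.
#' @return An object of class `fcm_result` with elements `memberships`
#'   (n x M, rows sum to 1), `centers` (M x d), `objective_trace`
#'   (per-iteration objective, non-increasing), `n_iter`, `converged`.
#' @export
fcm_cluster <- function(X, M, fuzzifier = 2, tol = 1e-5, max_iter = 300L,
                        seed = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); d <- ncol(X)
  if (M < 1L) stop("M must be at least 1")
  if (M > n) stop("M (", M, ") exceeds the number of samples (", n, ")")
  if (fuzzifier <= 1) stop("fuzzifier must be > 1")

  uniq <- unique(X)
  if (nrow(uniq) < M) {
    stop("degenerate data: only ", nrow(uniq), " distinct samples for M = ", M)
  }
  centers <- withr::with_seed(seed, uniq[sample.int(nrow(uniq), M), , drop = FALSE])

  pw <- 1 / (fuzzifier - 1)
  U_old <- matrix(0, n, M)
  obj <- numeric(0)
  converged <- FALSE
  it <- 0L
  U <- NULL
  repeat {
    it <- it + 1L
    D <- pdist2(X, centers)
    # membership update; crisp assignment where a distance is exactly 0
    zero <- D <= 0
    inv <- (1 / pmax(D, .Machine$double.xmin))^pw
    U <- inv / rowSums(inv)
    hit <- rowSums(zero) > 0
    if (any(hit)) {
      U[hit, ] <- 0
      U[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
    }
    Um <- U^fuzzifier
    centers <- crossprod(Um, X) / colSums(Um)
    obj <- c(obj, sum(Um * pdist2(X, centers)))
    delta <- max(abs(U - U_old))
    U_old <- U
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  structure(list(memberships = U, centers = centers,
                 objective_trace = obj, n_iter = it, converged = converged,
                 fuzzifier = fuzzifier),
            class = "fcm_result")
}

#' Build the Gaussian hidden layer from an FCM fit
#'
#' Centers are membership-weighted means of the data and widths are
#' membership-weighted mean squared distances to the center (so each
#' width carries squared-distance units). Widths are floored at
#' `1e-8 * mean pairwise squared distance` of `X` to keep the Gaussian
#' map well defined for singleton clusters.
#'
#' @param fcm An `fcm_result` from [fcm_cluster()].
#' @param X The matrix the FCM was fitted to.
#' @return An object of class `hidden_layer` with `centers` (M x d),
#'   `widths` (length M, positive) and `M`.
#' @export
build_hidden_layer <- function(fcm, X) {
  stopifnot(inherits(fcm, "fcm_result"))
  X <- as.matrix(X)
  U <- fcm$memberships
  if (nrow(U) != nrow(X)) stop("FCM result is inconsistent with X")
  mass <- colSums(U)
  if (any(mass <= 0)) {
    stop("zero membership mass for cluster ", which(mass <= 0)[1])
  }
  centers <- crossprod(U, X) / mass
  D <- pdist2(X, centers)
  widths <- colSums(U * D) / mass
  floor_ <- 1e-8 * mean_pairwise_sq_dist(X)
  if (floor_ <= 0) floor_ <- 1e-12
  widths <- pmax(widths, floor_)
  structure(list(centers = centers, widths = widths, M = nrow(centers)),
            class = "hidden_layer")
}

#' Map features into the hidden-layer representation
#'
#' Entry (j, i) is `exp(-||x_j - c_i||^2 / delta_i)`: the width (a mean
#' squared distance) divides the squared distance directly, so all
#' outputs lie in (0, 1] and equal 1 exactly when the input coincides
#' with a center.
#'
#' @param layer A `hidden_layer`.
#' @param X Numeric matrix, n x d with d matching the centers.
#' @return n x M matrix of hidden activations.
#' @export
hidden_map <- function(layer, X) {
  stopifnot(inherits(layer, "hidden_layer"))
  X <- as.matrix(X)
  if (ncol(X) != ncol(layer$centers)) {
    stop("feature dimension (", ncol(X), ") does not match hidden layer (",
         ncol(layer$centers), ")")
  }
  D <- pdist2(X, layer$centers)
  exp(-sweep(D, 2, layer$widths, "/"))
}
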