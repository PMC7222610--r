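# ---------------------------------------------------------------------
# Center-constrained minimum enclosing ball (CC-MEB) reformulation of the
# epsilon-insensitive dual, and its (1+xi)-approximation core-set solver.
#
# The 2n augmented points are the hidden-space training points and their
# negated copies; index i <= n carries sign +1 and base point i, index
# n + i carries sign -1 and base point i. The augmented kernel is
#   Ktilde[i, j] = s_i s_j K(b_i, b_j) + (mu n / lambda) [i == j]
# and each point gets an extra squared augmentation distance Delta_i
# chosen so the MEB dual coincides with the training dual.
# ---------------------------------------------------------------------

aug_sign <- function(idx, n) ifelse(idx <= n, 1, -1)
aug_base <- function(idx, n) ((idx - 1L) %% n) + 1L

#' Recast the dual QP as a center-constrained MEB problem
#'
#' Builds the per-point augmentation distances
#' `Delta_i = -Ktilde_ii + eta + 2 lambda ytilde_i` with
#' `ytilde = (y, -y)` and `eta` chosen as the smallest value making
#' `Delta >= 0` (the MEB dual weights are invariant to `eta`).
#'
#' @param Ktilde Dense 2n x 2n augmented kernel from
#'   [build_augmented_kernel()].
#' @param y Length-n labels in `{+1, -1}`.
#' @param lambda Positive epsilon trade-off weight.
#' @return An object of class `ccmeb_problem` (dense form).
#' @export
build_delta <- function(Ktilde, y, lambda) {
  Ktilde <- as.matrix(Ktilde)
  n <- length(y)
  if (nrow(Ktilde) != 2L * n || ncol(Ktilde) != 2L * n) {
    stop("Ktilde must be 2n x 2n for n = length(y)")
  }
  ytilde <- c(y, -y)
  dK <- diag(Ktilde)
  eta <- max(dK - 2 * lambda * ytilde)
  Delta <- -dK + eta + 2 * lambda * ytilde
  structure(list(form = "dense", Ktilde = Ktilde, Delta = Delta, eta = eta,
                 ytilde = ytilde, lambda = lambda, n = n, n2 = 2L * n),
            class = "ccmeb_problem")
}

#' Implicit CC-MEB problem over hidden features
#'
#' Equivalent to [build_delta()] applied to the dense augmented kernel,
#' but kernel rows are computed lazily on demand, so the 2n x 2n matrix
#' is never materialized; this is the path used for large training sets.
#'
#' @param Xtilde n x M hidden-feature matrix.
#' @param y Length-n labels in `{+1, -1}`.
#' @param lambda,mu,sigma2 Training hyperparameters as in
#'   [eps_qp_problem()].
#' @return An object of class `ccmeb_problem` (implicit form).
#' @export
ccmeb_problem <- function(Xtilde, y, lambda, mu, sigma2) {
  p <- eps_qp_problem(Xtilde, y, lambda, mu, sigma2)  # validates
  n <- p$n
  creg <- mu * n / lambda
  ytilde <- c(p$y, -p$y)
  dK <- rep(1 + creg, 2L * n)      # unit-diagonal Gaussian base kernel
  eta <- max(dK - 2 * lambda * ytilde)
  Delta <- -dK + eta + 2 * lambda * ytilde
  structure(list(form = "implicit", Xtilde = p$Xtilde, sigma2 = sigma2,
                 creg = creg, Delta = Delta, eta = eta, ytilde = ytilde,
                 lambda = lambda, n = n, n2 = 2L * n, diag_value = 1 + creg),
            class = "ccmeb_problem")
}

# Diagonal entries Ktilde_ii for augmented indices.
ccmeb_diag <- function(prob, idx) {
  if (prob$form == "dense") diag(prob$Ktilde)[idx] else
    rep(prob$diag_value, length(idx))
}

# Submatrix Ktilde[I, J] for augmented index vectors.
ccmeb_kmat <- function(prob, I, J) {
  if (prob$form == "dense") {
    return(prob$Ktilde[I, J, drop = FALSE])
  }
  n <- prob$n
  sI <- aug_sign(I, n); sJ <- aug_sign(J, n)
  bI <- aug_base(I, n); bJ <- aug_base(J, n)
  K <- base_kernel(prob$Xtilde[bI, , drop = FALSE],
                   prob$Xtilde[bJ, , drop = FALSE], prob$sigma2)
  K <- K * outer(sI, sJ)
  same <- outer(I, J, "==")
  if (any(same)) K[same] <- K[same] + prob$creg
  K
}

new_coreset <- function(indices, beta, radius, center_norm2, n_iter, trace,
                        converged, objective, n) {
  structure(list(indices = indices, beta = beta, radius = radius,
                 center_norm2 = center_norm2, n_iter = n_iter, trace = trace,
                 converged = converged, objective = objective, n = n),
            class = "coreset")
}

#' @export
print.coreset <- function(x, ...) {
  cat(sprintf(
    "<coreset: %d of %d augmented points, R = %.6g, %d iterations%s>\n",
    length(x$indices), 2L * x$n, x$radius, x$n_iter,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Radius of a core-set ball
#'
#' `R = sqrt(beta' (diag(Ktilde_SS) + Delta_S) - beta' Ktilde_SS beta)`;
#' radicands in `[-1e-10, 0)` are clamped to zero, anything lower is a
#' numerical failure.
#'
#' @param coreset A `coreset` (or any list with `indices` and `beta`).
#' @param problem The `ccmeb_problem` it refers to.
#' @return The radius R.
#' @export
ccmeb_radius <- function(coreset, problem) {
  S <- coreset$indices; beta <- coreset$beta
  KSS <- ccmeb_kmat(problem, S, S)
  rad2 <- sum(beta * (ccmeb_diag(problem, S) + problem$Delta[S])) -
    as.numeric(crossprod(beta, KSS %*% beta))
  if (rad2 < -1e-10) stop("negative squared radius (", rad2, "): numerical failure")
  sqrt(max(rad2, 0))
}

#' Squared distance from augmented points to the ball center
#'
#' `||c - phi(x_l)||^2 + delta_l^2 = ||c||^2 - 2 (Ktilde beta)_l +
#' ktilde_ll + Delta_l`, with the center expanded on the core set.
#'
#' @param coreset A `coreset`.
#' @param problem The `ccmeb_problem`.
#' @param l Augmented index (vectorized) in `1..2n`.
#' @return Squared distances, same length as `l`.
#' @export
ccmeb_distance2 <- function(coreset, problem, l) {
  S <- coreset$indices; beta <- coreset$beta
  cnorm2 <- coreset$center_norm2
  if (is.null(cnorm2)) {
    KSS <- ccmeb_kmat(problem, S, S)
    cnorm2 <- as.numeric(crossprod(beta, KSS %*% beta))
  }
  q <- as.numeric(ccmeb_kmat(problem, l, S) %*% beta)
  cnorm2 - 2 * q + ccmeb_diag(problem, l) + problem$Delta[l]
}

# Squared distances of ALL 2n augmented points, chunked so that the
# implicit form computes each base-kernel row once (both signed copies
# of a base point share one kernel evaluation).
ccmeb_dist2_all <- function(prob, S, beta, cnorm2, chunk = 8192L) {
  n <- prob$n
  if (prob$form == "dense") {
    q <- as.numeric(prob$Ktilde[, S, drop = FALSE] %*% beta)
    return(cnorm2 - 2 * q + diag(prob$Ktilde) + prob$Delta)
  }
  sS <- aug_sign(S, n); bS <- aug_base(S, n)
  w <- beta * sS
  XS <- prob$Xtilde[bS, , drop = FALSE]
  qbase <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    qbase[i:j] <- as.numeric(
      base_kernel(prob$Xtilde[i:j, , drop = FALSE], XS, prob$sigma2) %*% w)
    i <- j + 1L
  }
  q <- c(qbase, -qbase)
  q[S] <- q[S] + prob$creg * beta
  cnorm2 - 2 * q + prob$diag_value + prob$Delta
}

restricted_qp <- function(prob, S) {
  KSS <- ccmeb_kmat(prob, S, S)
  dS <- ccmeb_diag(prob, S) + prob$Delta[S] - prob$eta
  sol <- solve_simplex_qp(KSS, dS)
  cnorm2 <- as.numeric(crossprod(sol$beta, KSS %*% sol$beta))
  rad2 <- sum(sol$beta * (ccmeb_diag(prob, S) + prob$Delta[S])) - cnorm2
  if (rad2 < -1e-10) stop("negative squared radius (", rad2, "): numerical failure")
  # Objective on the scale of the training dual: d' beta - beta' K beta
  # with d = diag + Delta - eta = 2 lambda ytilde.
  list(beta = sol$beta, cnorm2 = cnorm2, rad2 = max(rad2, 0),
       objective = sol$value)
}

#' Core-set solver for the CC-MEB dual
#'
#' Badoiu-Clarkson style (1+xi)-approximation: starting from a seeded
#' two-point core set, repeatedly (a) solve the MEB dual restricted to
#' the current core set exactly, (b) look for an augmented point whose
#' distance to the center exceeds `(1 + eps_tol) R` -- first among
#' violators remembered from the last full scan, then in a random sample
#' of `sample_size` points, finally by an exhaustive scan -- and (c) add
#' the farthest violator. Terminates only when a full exhaustive scan
#' certifies the (1 + eps_tol)-cover.
#'
#' @param problem A `ccmeb_problem` (dense or implicit).
#' @param eps_tol MEB approximation factor xi (> 0); default `1e-6`.
#' @param sample_size Size of the random probe sample; `0` forces an
#'   exhaustive scan every iteration.
#' @param seed Integer seed driving initialization and sampling.
#' @param max_iter Iteration cap; default
#'   `min(5000, ceiling(10 / sqrt(eps_tol)))`.
#' @return A `coreset` with fields `indices`, `beta`, `radius`,
#'   `center_norm2`, `n_iter`, `trace` (per-iteration size and radius),
#'   `converged` and the attained dual `objective`.
#' @export
solve_coreset <- function(problem, eps_tol = 1e-6, sample_size = 59L,
                          seed = 1L, max_iter = NULL) {
  stopifnot(inherits(problem, "ccmeb_problem"))
  if (!is.numeric(eps_tol) || eps_tol <= 0) stop("eps_tol must be > 0")
  n2 <- problem$n2
  if (n2 < 1L) stop("empty problem")
  if (is.null(max_iter)) max_iter <- min(5000L, as.integer(ceiling(10 / sqrt(eps_tol))))

  rng <- withr::with_seed(seed, {
    # initialization: farthest pair among up to 100 random candidates
    cand <- sample.int(n2, min(100L, n2))
    list(cand = cand, sampler_seed = sample.int(.Machine$integer.max, 1L))
  })
  cand <- rng$cand
  if (n2 == 1L) {
    S <- 1L
  } else {
    Kc <- ccmeb_kmat(problem, cand, cand)
    sq <- ccmeb_diag(problem, cand) + problem$Delta[cand]
    Dc <- outer(sq, sq, "+") - 2 * Kc
    pick <- arrayInd(which.max(Dc), dim(Dc))
    S <- unique(cand[c(pick[1], pick[2])])
  }

  sizes <- integer(0); radii <- numeric(0)
  pending <- integer(0)   # violators remembered from the last full scan
  fit <- NULL
  it <- 0L
  converged <- FALSE
  withr::with_seed(rng$sampler_seed, {
    repeat {
      it <- it + 1L
      fit <- restricted_qp(problem, S)
      R2 <- fit$rad2
      thr <- (1 + eps_tol)^2 * R2
      sizes <- c(sizes, length(S)); radii <- c(radii, sqrt(R2))

      cs <- list(indices = S, beta = fit$beta, center_norm2 = fit$cnorm2)
      violator <- NA_integer_
      # 1) re-check remembered violators against the current ball
      if (length(pending) > 0L) {
        d2 <- ccmeb_distance2(cs, problem, pending)
        keep <- d2 > thr
        pending <- pending[keep]; d2 <- d2[keep]
        if (length(pending) > 0L) {
          k <- which.max(d2)
          violator <- pending[k]
          pending <- pending[-k]
        }
      }
      # 2) random probe sample
      if (is.na(violator) && sample_size > 0L) {
        probe <- setdiff(sample.int(n2, min(sample_size, n2)), S)
        if (length(probe) > 0L) {
          d2 <- ccmeb_distance2(cs, problem, probe)
          if (any(d2 > thr)) violator <- probe[which.max(d2)]
        }
      }
      # 3) certification scan (always reached when 1-2 fail)
      if (is.na(violator)) {
        d2 <- ccmeb_dist2_all(problem, S, fit$beta, fit$cnorm2)
        viol <- setdiff(which(d2 > thr), S)
        if (length(viol) == 0L) { converged <- TRUE; break }
        violator <- viol[which.max(d2[viol])]
        ord <- viol[order(d2[viol], decreasing = TRUE)]
        pending <- setdiff(ord, violator)
        if (length(pending) > 2048L) pending <- pending[seq_len(2048L)]
      }
      S <- c(S, violator)
      pending <- setdiff(pending, violator)
      if (it >= max_iter) {
        err <- simpleError(sprintf(
          "core-set iteration cap (%d) exceeded at |S| = %d", max_iter, length(S)))
        err$trace <- data.frame(size = sizes, radius = radii)
        stop(err)
      }
    }
  })
  new_coreset(indices = S, beta = fit$beta, radius = sqrt(fit$rad2),
              center_norm2 = fit$cnorm2, n_iter = it,
              trace = data.frame(size = sizes, radius = radii),
              converged = converged, objective = fit$objective,
              n = problem$n)
}

#' Scatter core-set MEB weights back to dual multipliers
#'
#' Augmented index `i <= n` maps to `alpha_i`, index `n + i` to
#' `alpha*_i`; all other entries are zero. The expansion coefficients
#' `lambda (alpha - alpha*)` recover the primal weight vector
#' `p = lambda c`.
#'
#' @param coreset A `coreset`.
#' @param n Number of training samples.
#' @return List with `alpha` and `alpha_star`, each length n.
#' @export
coreset_to_alpha <- function(coreset, n) {
  alpha <- numeric(n); alpha_star <- numeric(n)
  idx <- coreset$indices
  pos <- idx <= n
  alpha[idx[pos]] <- coreset$beta[pos]
  alpha_star[idx[!pos] - n] <- coreset$beta[!pos]
  list(alpha = alpha, alpha_star = alpha_star)
}
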