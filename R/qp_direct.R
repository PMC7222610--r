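#' Gaussian base kernel between hidden representations
#'
#' `K_ij = exp(-||a_i - b_j||^2 / (2 sigma2))`.
#'
#' @param Xtilde_a,Xtilde_b Hidden-feature matrices with matching
#'   column dimension.
#' @param sigma2 Kernel bandwidth (variance-scale), strictly positive.
#' @return Kernel matrix `nrow(Xtilde_a) x nrow(Xtilde_b)`.
#' @export
base_kernel <- function(Xtilde_a, Xtilde_b, sigma2) {
  if (!is.numeric(sigma2) || length(sigma2) != 1L || sigma2 <= 0) {
    stop("sigma2 must be a single strictly positive number")
  }
  A <- as.matrix(Xtilde_a); B <- as.matrix(Xtilde_b)
  if (ncol(A) != ncol(B)) stop("hidden dimensions do not match")
  exp(-pdist2(A, B) / (2 * sigma2))
}

#' Define an epsilon-insensitive QP training problem
#'
#' Holds the hidden features, the +/-1 labels and the three
#' hyperparameters of the structural-risk regularized epsilon-insensitive
#' objective: `lambda` (weight of the epsilon term), `mu` (balance factor
#' controlling the mean slack) and `sigma2` (base-kernel bandwidth).
#'
#' @param Xtilde n x M hidden-feature matrix.
#' @param y Length-n labels in `{+1, -1}`.
#' @param lambda,mu,sigma2 Strictly positive hyperparameters.
#' @return An object of class `eps_qp_problem`.
#' @export
eps_qp_problem <- function(Xtilde, y, lambda, mu, sigma2) {
  Xtilde <- as.matrix(Xtilde)
  y <- as.numeric(y)
  if (length(y) != nrow(Xtilde)) stop("labels do not match rows of Xtilde")
  if (!all(y %in% c(-1, 1))) stop("labels must be +1/-1")
  for (nm in c("lambda", "mu", "sigma2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(nm, " must be a single strictly positive number")
    }
  }
  structure(list(Xtilde = Xtilde, y = y, lambda = lambda, mu = mu,
                 sigma2 = sigma2, n = nrow(Xtilde)),
            class = "eps_qp_problem")
}

#' Build the 2n x 2n augmented kernel
#'
#' Block form `[[K + (mu n / lambda) I, -K], [-K, K + (mu n / lambda) I]]`
#' over the base Gaussian kernel `K`; symmetric and positive
#' semidefinite.
#'
#' @param problem An [eps_qp_problem()].
#' @return 2n x 2n matrix.
#' @export
build_augmented_kernel <- function(problem) {
  stopifnot(inherits(problem, "eps_qp_problem"))
  K <- base_kernel(problem$Xtilde, problem$Xtilde, problem$sigma2)
  creg <- problem$mu * problem$n / problem$lambda
  Kr <- K + diag(creg, problem$n)
  rbind(cbind(Kr, -K), cbind(-K, Kr))
}

# Maximize d'b - b'Hb over the probability simplex {b >= 0, sum(b) = 1}.
# Exact Goldfarb-Idnani active-set solve; a small diagonal jitter is
# retried if H is numerically indefinite.
solve_simplex_qp <- function(H, d) {
  m <- length(d)
  if (m == 1L) {
    return(list(beta = 1, value = as.numeric(d - H[1, 1])))
  }
  Amat <- cbind(rep(1, m), diag(m))
  bvec <- c(1, rep(0, m))
  jitter <- 0
  base <- mean(abs(diag(H)))
  for (attempt in 1:6) {
    sol <- tryCatch(
      quadprog::solve.QP(Dmat = 2 * H + diag(jitter, m), dvec = d,
                         Amat = Amat, bvec = bvec, meq = 1),
      error = function(e) e)
    if (!inherits(sol, "error")) {
      beta <- pmax(sol$solution, 0)
      beta <- beta / sum(beta)
      return(list(beta = beta,
                  value = as.numeric(crossprod(d, beta) -
                                       crossprod(beta, H %*% beta))))
    }
    jitter <- if (jitter == 0) 1e-12 * max(base, 1) else jitter * 100
  }
  stop("simplex QP solver failed: ", conditionMessage(sol))
}

#' Solve the epsilon-insensitive dual QP exactly
#'
#' Maximizes `2 lambda [y', -y'] a - a' Ktilde a` over the probability
#' simplex on the stacked multipliers `a = (alpha, alpha*)`, using a
#' dense augmented kernel and an exact active-set QP solve. Serves both
#' as the full-data trainer and as the correctness oracle for the
#' core-set solver; guarded to `n <= 5000`.
#'
#' @param problem An [eps_qp_problem()].
#' @return An object of class `dual_solution` with `alpha`, `alpha_star`,
#'   `objective`, slacks `xi = alpha * mu * n`, `xi_star`, and
#'   `expansion = lambda * (alpha - alpha_star)`.
#' @export
solve_dual_direct <- function(problem) {
  stopifnot(inherits(problem, "eps_qp_problem"))
  n <- problem$n
  if (n > 5000L) {
    stop("direct dual solve refused for n = ", n,
         " (> 5000); use the core-set solver")
  }
  Ktilde <- build_augmented_kernel(problem)
  d <- 2 * problem$lambda * c(problem$y, -problem$y)
  sol <- solve_simplex_qp(Ktilde, d)
  alpha <- sol$beta[seq_len(n)]
  alpha_star <- sol$beta[n + seq_len(n)]
  structure(list(alpha = alpha, alpha_star = alpha_star,
                 objective = sol$value,
                 xi = alpha * problem$mu * n,
                 xi_star = alpha_star * problem$mu * n,
                 expansion = problem$lambda * (alpha - alpha_star)),
            class = "dual_solution")
}
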