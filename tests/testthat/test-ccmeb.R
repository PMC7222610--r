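test_that("Delta construction matches hand computation and is minimally shifted", {
  # constant-diagonal kernel with lambda -> 0: Delta = 0, eta = diagonal
  Kc <- diag(3, 4) + 0.1 - diag(0.1, 4)
  pr <- build_delta(Kc, c(1, -1), lambda = 1e-12)
  expect_equal(pr$eta, 3, tolerance = 1e-9)
  expect_equal(pr$Delta, rep(0, 4), tolerance = 1e-9)

  # n = 1: Ktilde = [[3,-1],[-1,3]], y = +1, lambda = 1
  pr1 <- build_delta(rbind(c(3, -1), c(-1, 3)), 1, 1)
  expect_equal(pr1$ytilde, c(1, -1))
  expect_equal(pr1$eta, 5)
  expect_equal(pr1$Delta, c(4, 0))

  withr::with_seed(17, {
    for (r in 1:5) {
      pb <- make_blob_problem(6, seed = r)
      prob <- eps_qp_problem(pb$X, pb$y, 1, 0.1, 1)
      pr2 <- build_delta(build_augmented_kernel(prob), pb$y, prob$lambda)
      expect_true(all(pr2$Delta >= 0))
      expect_equal(min(pr2$Delta), 0)
      # implicit form agrees with the dense construction
      pi2 <- ccmeb_problem(pb$X, pb$y, 1, 0.1, 1)
      expect_equal(pi2$Delta, pr2$Delta, tolerance = 1e-12)
      expect_equal(pi2$eta, pr2$eta, tolerance = 1e-12)
    }
  })
})

test_that("ball radius matches closed forms and an independent QP solve", {
  # single-point core set, Delta = 0: R = 0
  one <- build_delta(matrix(1, 2, 2), 1, 0)
  cs1 <- list(indices = 1L, beta = 1)
  expect_equal(ccmeb_radius(cs1, one), 0)

  # two orthonormal points, Delta = 0, beta = (1/2, 1/2): R = sqrt(1/2)
  two <- build_delta(diag(1, 2), c(1), 1e-12)
  expect_equal(ccmeb_radius(list(indices = 1:2, beta = c(.5, .5)), two),
               sqrt(0.5), tolerance = 1e-9)

  # random instance: radius from the core-set solver equals the radius of
  # an independent dense QP solve of the MEB dual
  pb <- make_blob_problem(8, seed = 2)
  prob <- eps_qp_problem(pb$X, pb$y, 1, 0.1, 1)
  Kt <- build_augmented_kernel(prob)
  pr <- build_delta(Kt, pb$y, prob$lambda)
  cs <- solve_coreset(pr, eps_tol = 1e-7, sample_size = 0, seed = 1)

  m <- pr$n2
  ref <- quadprog::solve.QP(
    Dmat = 2 * Kt + diag(1e-10, m), dvec = diag(Kt) + pr$Delta,
    Amat = cbind(rep(1, m), diag(m)), bvec = c(1, rep(0, m)), meq = 1)
  R_ref <- sqrt(sum(ref$solution * (diag(Kt) + pr$Delta)) -
                  as.numeric(crossprod(ref$solution, Kt %*% ref$solution)))
  expect_equal(cs$radius, R_ref, tolerance = 1e-6)
  expect_equal(ccmeb_radius(cs, pr), cs$radius, tolerance = 1e-12)
})

test_that("distances to the center match an explicit-coordinates oracle", {
  pb <- make_blob_problem(6, seed = 9)
  prob <- eps_qp_problem(pb$X, pb$y, 1, 0.2, 1)
  Kt <- build_augmented_kernel(prob)
  pr <- build_delta(Kt, pb$y, prob$lambda)
  cs <- solve_coreset(pr, eps_tol = 1e-6, sample_size = 0, seed = 2)

  # materialize feature-space coordinates from the kernel's eigensystem
  ei <- eigen(Kt, symmetric = TRUE)
  Phi <- ei$vectors %*% diag(sqrt(pmax(ei$values, 0)))
  ctr <- colSums(cs$beta * Phi[cs$indices, , drop = FALSE])
  for (l in c(1, 3, pr$n2)) {
    explicit <- sum((ctr - Phi[l, ])^2) + pr$Delta[l]
    expect_equal(ccmeb_distance2(cs, pr, l), explicit, tolerance = 1e-8)
  }
  # every point of the solved instance is inside the certified ball
  d2 <- ccmeb_distance2(cs, pr, seq_len(pr$n2))
  expect_true(all(d2 <= (1 + 1e-6)^2 * cs$radius^2 + 1e-9))
  # core point of a single-point ball sits at distance zero
  expect_equal(ccmeb_distance2(list(indices = 1L, beta = 1),
                               build_delta(matrix(1, 2, 2), 1, 0), 1),
               0)
})

test_that("core-set iteration certifies a cover with a monotone radius trace", {
  # degenerate ball: all augmented points identical
  deg <- build_delta(matrix(1, 6, 6), rep(1, 3), 0)
  csd <- solve_coreset(deg, eps_tol = 1e-6, sample_size = 0, seed = 1)
  expect_equal(length(csd$indices), 1L)
  expect_equal(csd$radius, 0, tolerance = 1e-9)
  expect_equal(csd$n_iter, 1L)

  withr::with_seed(19, {
    for (r in 1:5) {
      pb <- make_blob_problem(sample(5:20, 1), seed = r)
      prob <- eps_qp_problem(pb$X, pb$y, 1, 0.05, 1)
      direct <- solve_dual_direct(prob)
      cp <- ccmeb_problem(pb$X, pb$y, 1, 0.05, 1)
      cs <- solve_coreset(cp, eps_tol = 1e-6, sample_size = 0, seed = r)
      expect_true(cs$converged)
      # dual objective within 1% of the dense oracle
      expect_lt(abs(cs$objective - direct$objective) / abs(direct$objective),
                0.01)
      # certified (1+eps) cover and monotone radius growth
      d2 <- ccmeb_distance2(cs, cp, seq_len(cp$n2))
      expect_true(all(d2 <= (1 + 1e-6)^2 * cs$radius^2 + 1e-9))
      expect_true(all(diff(cs$trace$radius) >= -1e-8))
      expect_true(all(cs$beta >= 0))
      expect_equal(sum(cs$beta), 1, tolerance = 1e-10)
    }
  })
})

test_that("core-set failure modes raise informative errors", {
  pb <- make_blob_problem(30, seed = 3)
  cp <- ccmeb_problem(pb$X, pb$y, 1, 0.05, 1)
  err <- tryCatch(solve_coreset(cp, eps_tol = 1e-9, sample_size = 0, seed = 1,
                                max_iter = 3),
                  error = function(e) e)
  expect_match(conditionMessage(err), "iteration cap")
  expect_s3_class(err$trace, "data.frame")
  expect_equal(nrow(err$trace), 3)
  expect_error(solve_coreset(structure(list(n2 = 0L), class = "ccmeb_problem")),
               "empty")
})

test_that("MEB weights scatter back to simplex-feasible dual multipliers", {
  cs <- list(indices = 1L, beta = 1)
  ab <- coreset_to_alpha(cs, 3)
  expect_equal(ab$alpha, c(1, 0, 0))
  expect_equal(ab$alpha_star, c(0, 0, 0))

  withr::with_seed(23, {
    for (r in 1:5) {
      pb <- make_blob_problem(10, seed = r)
      cp <- ccmeb_problem(pb$X, pb$y, 1, 0.05, 1)
      cs <- solve_coreset(cp, eps_tol = 1e-6, sample_size = 0, seed = r)
      ab <- coreset_to_alpha(cs, cp$n)
      expect_equal(sum(ab$alpha + ab$alpha_star), 1, tolerance = 1e-10)
      expect_true(all(ab$alpha >= 0) && all(ab$alpha_star >= 0))
    }
  })
})
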