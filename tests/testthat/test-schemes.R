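test_that("the position-1 forward subnetwork equilibrates to the scaled forward row", {
  crn <- build_bw_network(2, 2, 2)
  state <- initial_state(crn, toy3(), seq_ab())
  eq <- subnetwork_equilibrium(crn, "R1alpha", state)
  expect_false(eq$boundary)
  expect_equal(unname(eq$values[order(eq$ids)]), c(0.75, 0.25), tolerance = 1e-12)
  expect_equal(eq$total, 1)
})

test_that("closed-form subnetwork equilibria agree with long-time integration", {
  crn <- build_bw_network(2, 2, 3)
  p <- random_hmm(2, 2)
  s <- hmm_seq(c(1L, 2L, 1L), p$alphabet)
  state <- initial_state(crn, p, s, trellis_init = "random", seed = 12)
  for (lab in c("R1alpha", "R2alpha", "R1gamma")) {
    eq <- subnetwork_equilibrium(crn, lab, state)
    rx <- crn$reactions[crn$reactions$subnetwork == lab, ]
    comp <- bwcrn:::compile_reactions(crn, rx)
    out <- bwcrn:::integrate_compiled(comp, state, c(0, 500), rtol = 1e-10, atol = 1e-12)
    expect_equal(unname(out[2, -1][eq$ids]), unname(eq$values), tolerance = 1e-6)
    state[eq$ids] <- eq$values
  }
})

test_that("sequential equilibration reproduces the discrete iterates exactly", {
  set.seed(61)
  for (k in 1:8) {
    nh <- sample(2:3, 1); nv <- sample(2:3, 1); L <- sample(3:10, 1)
    inst <- random_instance(nh, nv, L, seed = 800 + k)
    p0 <- random_hmm(nh, nv)
    n_it <- 4
    s1 <- run_bw1(p0, inst$seq, scheme_config(max_outer = n_it, outer_tol = 1e-15))
    fc <- bw_fit(p0, inst$seq, tol = 1e-15, max_iter = n_it)
    for (i in seq_len(n_it))
      expect_lt(bwcrn:::param_distance(s1$iterates[[i + 1]], fc$iterates[[i + 1]]),
                1e-7)
  }
})

test_that("the learned parameters are invariant to the conserved totals", {
  inst <- random_instance(2, 2, 6, seed = 71)
  p0 <- random_hmm(2, 2)
  a <- run_bw1(p0, inst$seq, scheme_config(max_outer = 3, outer_tol = 1e-15))
  b <- run_bw1(p0, inst$seq, scheme_config(max_outer = 3, outer_tol = 1e-15,
                                           totals_alpha = c(2, 7, 0.1, 1, 3, 9),
                                           totals_beta = 5))
  expect_lt(bwcrn:::param_distance(a$params, b$params), 1e-9)
})

test_that("the learned parameters are invariant to the reference states", {
  inst <- random_instance(2, 2, 5, seed = 72)
  p0 <- random_hmm(2, 2)
  runs <- list(
    run_bw1(p0, inst$seq, scheme_config(max_outer = 3, h_star = 1, v_star = 1)),
    run_bw1(p0, inst$seq, scheme_config(max_outer = 3, h_star = 2, v_star = 1)),
    run_bw1(p0, inst$seq, scheme_config(max_outer = 3, h_star = 2, v_star = 2)))
  expect_lt(bwcrn:::param_distance(runs[[1]]$params, runs[[2]]$params), 1e-6)
  expect_lt(bwcrn:::param_distance(runs[[1]]$params, runs[[3]]$params), 1e-6)
  # the BW3 flow shares the invariance at positive equilibria
  cfgs <- list(scheme_config(h_star = 1, v_star = 1, t_max = 400),
               scheme_config(h_star = 2, v_star = 2, t_max = 400))
  s <- hmm_seq(sample(rep(1:2, c(4, 4))), c("v1", "v2"))
  u0 <- hmm(pi = c(0.5, 0.5), theta = matrix(0.5, 2, 2), psi = matrix(0.5, 2, 2),
            alphabet = c("v1", "v2"))
  lim <- lapply(cfgs, function(cf) run_bw3(u0, s, cf)$params)
  expect_lt(bwcrn:::param_distance(lim[[1]], lim[[2]]), 1e-6)
})

test_that("module alternation matches sequential equilibration and decays exponentially", {
  set.seed(62)
  for (k in 1:3) {
    L <- sample(4:6, 1)
    s <- hmm_seq(sample(rep(1:2, c(ceiling(L / 2), floor(L / 2)))), c("v1", "v2"))
    p0 <- random_hmm(2, 2, alphabet = c("v1", "v2"))
    cfg2 <- scheme_config(equilibration = "integrate", max_outer = 3,
                          t_max = 1e7, equil_tol = 1e-11,
                          rtol = 1e-10, atol = 1e-13)
    s2 <- run_bw2(p0, s, cfg2)
    s1 <- run_bw1(p0, s, scheme_config(max_outer = 3, outer_tol = 1e-15))
    for (i in 2:min(length(s1$iterates), length(s2$iterates)))
      expect_lt(bwcrn:::param_distance(s2$iterates[[i]], s1$iterates[[i]]), 1e-7)
    # intra-sweep approach of the learning module is exponential
    expect_lt(s2$report$convergence_rate, 0)
  }
})

test_that("integrate-mode sequential equilibration agrees with closed form", {
  inst <- random_instance(2, 2, 4, seed = 73)
  p0 <- random_hmm(2, 2)
  ci <- scheme_config(equilibration = "integrate", max_outer = 2,
                      t_max = 400, equil_tol = 1e-10)
  s_int <- run_bw1(p0, inst$seq, ci)
  s_cf <- run_bw1(p0, inst$seq, scheme_config(max_outer = 2, outer_tol = 1e-15))
  expect_lt(bwcrn:::param_distance(s_int$params, s_cf$params), 1e-6)
})

test_that("positive limits of the coupled ODE are discrete fixed points and vice versa", {
  # symmetric starts give positive limits; check the fixed-point residual
  set.seed(63)
  for (k in 1:3) {
    counts <- c(sample(3:6, 1), sample(3:6, 1))
    s <- hmm_seq(sample(rep(1:2, counts)), c("v1", "v2"))
    u0 <- hmm(pi = c(0.5, 0.5), theta = matrix(0.5, 2, 2),
              psi = matrix(0.5, 2, 2), alphabet = c("v1", "v2"))
    s3 <- run_bw3(u0, s, scheme_config(t_max = 600, equil_tol = 1e-10))
    expect_true(s3$report$converged)
    expect_true(is_positive_hmm(s3$params))
    expect_lt(s3$report$bw_residual, 1e-5)
  }
  # conversely, started at a positive discrete fixed point the flow stays put
  s <- hmm_seq(sample(rep(1:2, c(4, 6))), c("v1", "v2"))
  u0 <- hmm(pi = c(0.5, 0.5), theta = matrix(0.5, 2, 2), psi = matrix(0.5, 2, 2),
            alphabet = c("v1", "v2"))
  fp <- bw_fit(u0, s, tol = 1e-13, max_iter = 50)$params
  expect_lt(fixed_point_residual(fp, s), 1e-9)
  s3 <- run_bw3(fp, s, scheme_config(t_max = 300, equil_tol = 1e-12,
                                     trellis_init = "equilibrium"))
  expect_lt(bwcrn:::param_distance(s3$params, fp), 1e-6)
})

test_that("trajectories stay bounded and conserve row sums from any simplex start", {
  # boundary initialization: global existence, conserved totals, flagged boundary
  p0 <- hmm(pi = c(0.5, 0.5), theta = matrix(c(1, 0, 0, 1), 2),
            psi = matrix(c(0, 1, 1, 0), 2, byrow = TRUE), alphabet = c("v1", "v2"))
  s <- hmm_seq(c("v2", "v1", "v2"), c("v1", "v2"))
  expect_warning(res <- run_bw1(p0, s, scheme_config(max_outer = 2)), "boundary")
  expect_true(res$report$boundary)
  s3 <- run_bw3(p0, s, scheme_config(t_max = 50))
  tr <- s3$trajectory
  th_rows <- cbind(tr$theta_11 + tr$theta_12, tr$theta_21 + tr$theta_22)
  expect_true(all(abs(th_rows - 1) < 1e-6))
  ps_rows <- cbind(tr$psi_11 + tr$psi_12, tr$psi_21 + tr$psi_22)
  expect_true(all(abs(ps_rows - 1) < 1e-6))
  vals <- as.matrix(tr[, setdiff(names(tr), c("time", "loglik"))])
  expect_true(all(vals > -1e-9 & vals < 1 + 1e-9))
})

test_that("fixed-point residual separates fixed points from ordinary points", {
  inst <- random_instance(2, 2, 8, seed = 74)
  p <- random_hmm(2, 2)
  expect_gt(fixed_point_residual(p, inst$seq), 0)
  # out-of-domain points report infinite residual
  bad <- hmm(pi = c(1, 0), theta = matrix(c(1, 0, 1, 0), 2, byrow = TRUE),
             psi = matrix(c(1, 0, 0, 1), 2, byrow = TRUE), alphabet = p$alphabet)
  expect_identical(fixed_point_residual(bad, hmm_seq(c(1L, 1L), p$alphabet)), Inf)
})

test_that("decay-rate estimation recovers a constructed exponential", {
  t <- seq(0, 5, by = 0.1)
  expect_equal(estimate_convergence_rate(exp(-2 * t), t), -2, tolerance = 0.01)
  expect_identical(estimate_convergence_rate(rep(1e-15, 20), t[1:20]), -Inf)
  expect_error(estimate_convergence_rate(1:3, 1:4), "length")
})
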