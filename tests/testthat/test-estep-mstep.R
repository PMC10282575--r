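test_that("E-step posteriors match hand evaluation on the toy models", {
  es <- e_step(toy3(), seq_ab())
  expect_equal(unname(es$gamma[1, ]), c(0.75, 0.25))
  expect_equal(unname(es$gamma[2, ]), c(0.25, 0.75))
  expect_equal(unname(es$xi[1, , ]),
               matrix(c(0.1875, 0.5625, 0.0625, 0.1875), 2, byrow = TRUE))
  es2 <- e_step(toy2(), seq_ab())
  expect_equal(unname(es2$gamma[1, ]), c(1, 0))
  expect_equal(unname(es2$xi[1, , ]), matrix(c(0, 1, 0, 0), 2, byrow = TRUE))
})

test_that("posteriors are invariant to rescaling the alpha/beta tables", {
  p <- toy3(); s <- seq_ab()
  fw <- forward_algorithm(p, s, scaled = FALSE)
  bw <- backward_algorithm(p, s)
  base <- e_step(p, s, alpha = fw$alpha, beta = bw)
  resc <- e_step(p, s, alpha = 3.7 * fw$alpha, beta = 0.2 * bw)
  expect_equal(resc$gamma, base$gamma, tolerance = 1e-12)
  expect_equal(resc$xi, base$xi, tolerance = 1e-12)
})

test_that("E-step invariants hold across random instances", {
  set.seed(21)
  for (k in 1:15) {
    inst <- random_instance(sample(2:3, 1), sample(2:3, 1), sample(3:8, 1),
                            seed = 300 + k)
    es <- e_step(inst$params, inst$seq)
    L <- length(inst$seq)
    expect_equal(rowSums(es$gamma), rep(1, L), tolerance = 1e-9)
    for (l in seq_len(L - 1)) {
      expect_equal(sum(es$xi[l, , ]), 1, tolerance = 1e-9)
      expect_equal(unname(rowSums(es$xi[l, , ])), unname(es$gamma[l, ]),
                   tolerance = 1e-9)
    }
  }
})

test_that("M-step reproduces hand ratios and normalizes rows exactly", {
  es <- e_step(toy3(), seq_ab())
  ms <- m_step(es$gamma, es$xi, seq_ab())
  expect_equal(unname(ms$theta), matrix(c(0.25, 0.75, 0.25, 0.75), 2, byrow = TRUE))
  expect_equal(unname(ms$psi), matrix(c(0.75, 0.25, 0.25, 0.75), 2, byrow = TRUE))
  # a single transition slice is normalized row-wise
  xi1 <- array(c(0.2, 0.1, 0.3, 0.4), c(1, 2, 2))
  g <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, byrow = TRUE)
  ms2 <- m_step(g, xi1, hmm_seq(c(1L, 2L), c("a", "b")))
  expect_equal(unname(ms2$theta), matrix(c(0.4, 0.6, 0.2, 0.8), 2, byrow = TRUE))
  expect_equal(unname(rowSums(ms2$theta)), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(rowSums(ms2$psi)), c(1, 1), tolerance = 1e-12)
})

test_that("a zero transition-count row raises an out-of-domain error", {
  # toy2 on (a,b): state 2 is never left, so row 2 of xi sums to zero
  es <- e_step(toy2(), seq_ab())
  err <- expect_error(m_step(es$gamma, es$xi, seq_ab()),
                      class = "bwcrn_out_of_domain")
  expect_match(conditionMessage(err), "theta row 2")
})

test_that("pooled M-step reduces to the single-sequence update", {
  p <- toy3(); s <- seq_ab()
  es <- e_step(p, s)
  single <- m_step(es$gamma, es$xi, s)
  pooled <- m_step_multi(list(es), list(s), p, update_pi = FALSE)
  expect_equal(unname(pooled$theta), unname(single$theta))
  expect_equal(unname(pooled$psi), unname(single$psi))
  expect_equal(unname(pooled$pi), unname(p$pi))  # pi untouched
  # duplicating a sequence leaves the ratio estimators unchanged
  dup <- m_step_multi(list(es, es), list(s, s), p)
  expect_equal(dup$theta, pooled$theta, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(dup$psi, pooled$psi, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the initial-distribution update averages the position-1 posteriors", {
  p <- toy3()
  g1 <- matrix(c(1, 0, 0.5, 0.5), 2, byrow = TRUE)
  g2 <- matrix(c(0, 1, 0.5, 0.5), 2, byrow = TRUE)
  xi <- array(0.25, c(1, 2, 2))
  out <- m_step_multi(list(list(gamma = g1, xi = xi), list(gamma = g2, xi = xi)),
                      list(seq_ab(), seq_ab()), p, update_pi = TRUE)
  expect_equal(unname(out$pi), c(0.5, 0.5))
})

test_that("the no-division-by-zero region check reports failing states", {
  expect_true(check_theta_region(toy2(), seq_ab())$in_theta)
  inst <- random_instance(2, 2, 5, seed = 9)
  expect_true(check_theta_region(inst$params, inst$seq)$in_theta)
  # state 2 unreachable and silent: its alpha*beta sums vanish
  p <- hmm(pi = c(1, 0), theta = matrix(c(1, 0, 1, 0), 2, byrow = TRUE),
           psi = matrix(c(1, 0, 0, 1), 2, byrow = TRUE), alphabet = c("a", "b"))
  chk <- check_theta_region(p, hmm_seq(c("a", "a"), c("a", "b")))
  expect_false(chk$in_theta)
  expect_identical(chk$failing_states, "H2")
  expect_true(check_theta_region(toy3(), seq_ab())$positivity_precondition)
})
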