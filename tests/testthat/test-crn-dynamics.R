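test_that("mass-action rates follow reactant x catalysts and conserve mass", {
  crn <- build_bw_network(2, 2, 3)
  state <- initial_state(crn, toy3(), hmm_seq(c("a", "b", "a"), c("a", "b")))
  dx <- mass_action_rhs(crn, state)
  # catalyst-only species never move
  expect_equal(unname(dx[species_ids(crn, "E")]), rep(0, 6))
  expect_equal(unname(dx[species_ids(crn, "theta")]), rep(0, 4))
  expect_equal(unname(dx[species_ids(crn, "pi")]), rep(0, 2))
  # each conserved class has zero net derivative at any state
  cl <- conserved_classes(crn)
  for (k in seq_len(nrow(cl))) expect_equal(sum(dx[cl$species[[k]]]), 0,
                                            tolerance = 1e-14)
  # hand check of one reaction's contribution on a restricted part:
  # the gamma subnetwork at position 1 has rates alpha_1_h * beta_1_h
  dg <- mass_action_rhs(crn, state, parts = "gamma")
  g <- crn$species$id[crn$species$name %in% c("gamma_1_1", "gamma_1_2")]
  a <- state[crn$species$name == "alpha_1_1"] * state[crn$species$name == "beta_1_1"]
  b <- state[crn$species$name == "alpha_1_2"] * state[crn$species$name == "beta_1_2"]
  g1 <- state[crn$species$name == "gamma_1_1"]
  g2 <- state[crn$species$name == "gamma_1_2"]
  expect_equal(unname(dx[g[1]]), unname(g2 * a - g1 * b), tolerance = 1e-14)
  expect_equal(unname(dg[g[1]]), unname(dx[g[1]]))
  expect_error(mass_action_rhs(crn, state[-1]), "does not match")
})

test_that("finite differences of an integrated trajectory match the vector field", {
  crn <- build_bw_network(2, 2, 3)
  p <- toy3()
  s <- hmm_seq(c("a", "b", "b"), c("a", "b"))
  x0 <- initial_state(crn, p, s, trellis_init = "random", seed = 4)
  comp <- bwcrn:::compile_reactions(crn, encoding = encode_observations(crn, s))
  h <- 1e-5
  out <- bwcrn:::integrate_compiled(comp, x0, c(0, h, 2 * h, 0.5),
                                    rtol = 1e-11, atol = 1e-13)
  fd <- (out[3, -1] - out[1, -1]) / (2 * h)
  mid <- out[2, -1]
  expect_equal(unname(fd), unname(bwcrn:::compiled_rhs(comp, mid)),
               tolerance = 1e-5)
})

test_that("conserved class totals stay constant along trajectories", {
  crn <- build_bw_network(2, 2, 4)
  p <- random_hmm(2, 2)
  s <- hmm_seq(c(1L, 2L, 2L, 1L), p$alphabet)
  x0 <- initial_state(crn, p, s, totals_alpha = c(1, 2, 3, 4), totals_beta = 0.5,
                      trellis_init = "random", seed = 2)
  comp <- bwcrn:::compile_reactions(crn, encoding = encode_observations(crn, s))
  out <- bwcrn:::integrate_compiled(comp, x0, seq(0, 50, length.out = 6))
  cl <- conserved_classes(crn)
  t0 <- vapply(cl$species, function(ids) sum(x0[ids]), numeric(1))
  for (r in 2:nrow(out)) {
    tr <- vapply(cl$species, function(ids) sum(out[r, -1][ids]), numeric(1))
    expect_equal(tr, t0, tolerance = 1e-6)
  }
  # alpha position totals honour the configured A_l
  expect_equal(unname(t0[cl$role == "alpha"][order(cl$l[cl$role == "alpha"])]),
               c(1, 2, 3, 4))
})

test_that("frozen-catalyst equilibria satisfy the pairwise balance equations", {
  # position-1 balance: alpha_1h pi_h* psi_h*v1 = alpha_1h* pi_h psi_hv1
  p <- toy3()
  s <- seq_ab()
  crn <- build_bw_network(2, 2, 2)
  state <- initial_state(crn, p, s)
  eq <- subnetwork_equilibrium(crn, "R1alpha", state)
  state[eq$ids] <- eq$values
  a1 <- state[crn$species$name %in% c("alpha_1_1", "alpha_1_2")]
  v1 <- 1  # first symbol is "a"
  lhs <- a1[2] * p$pi[1] * p$psi[1, v1]
  rhs <- a1[1] * p$pi[2] * p$psi[2, v1]
  expect_lt(abs(lhs - rhs), 1e-10)
  # recursion balance at position 2 after equilibrating R2alpha
  eq2 <- subnetwork_equilibrium(crn, "R2alpha", state)
  state[eq2$ids] <- eq2$values
  a2 <- state[crn$species$name %in% c("alpha_2_1", "alpha_2_2")]
  v2 <- 2
  lhs2 <- a2[2] * sum(a1 * p$theta[, 1] * p$psi[1, v2])
  rhs2 <- a2[1] * sum(a1 * p$theta[, 2] * p$psi[2, v2])
  expect_lt(abs(lhs2 - rhs2), 1e-10)
  # and the normalized equilibrium reproduces the forward quantities
  fw <- forward_algorithm(p, s, scaled = FALSE)
  expect_equal(unname(a1), unname(fw$alpha[1, ] / sum(fw$alpha[1, ])),
               tolerance = 1e-10)
  expect_equal(unname(a2), unname(fw$alpha[2, ] / sum(fw$alpha[2, ])),
               tolerance = 1e-10)
})

test_that("text export round-trips to an identical network", {
  crn <- build_bw_network(2, 2, 3, h_star = 2, v_star = 2, learn_pi = TRUE)
  f <- withr::local_tempfile(fileext = ".rxn")
  export_network(crn, f, format = "text")
  back <- import_network(f)
  expect_identical(back$species, crn$species)
  expect_equal(back$reactions$from, crn$reactions$from)
  expect_equal(back$reactions$to, crn$reactions$to)
  expect_equal(back$reactions$catalysts, crn$reactions$catalysts)
  expect_identical(back$reactions$subnetwork, crn$reactions$subnetwork)
  expect_identical(back$h_star, crn$h_star)
  expect_identical(back$v_star, crn$v_star)
})

test_that("SBML export lists every species and reaction with kinetic laws", {
  crn <- build_bw_network(2, 2, 2)
  s <- seq_ab()
  state <- initial_state(crn, toy3(), s)
  f <- withr::local_tempfile(fileext = ".xml")
  export_network(crn, f, format = "sbml", state = state)
  doc <- xml2::read_xml(f)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "sbml")
  spn <- xml2::xml_find_all(doc, ".//sbml:species", ns)
  expect_equal(length(spn), nrow(crn$species))
  rxn <- xml2::xml_find_all(doc, ".//sbml:reaction", ns)
  expect_equal(length(rxn), nrow(crn$reactions))
  kl <- xml2::xml_find_all(doc, ".//sbml:kineticLaw", ns)
  expect_equal(length(kl), nrow(crn$reactions))
  # E species are flagged as boundary-condition species
  eflag <- xml2::xml_attr(spn, "boundaryCondition")
  expect_equal(sum(eflag == "true"), sum(crn$species$role == "E"))
})
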