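test_that("species enumeration has the prescribed counts and no collisions", {
  sp <- enumerate_species(2, 2, 100)
  expect_equal(sum(sp$role == "alpha"), 200)
  expect_equal(sum(sp$role == "E"), 200)
  expect_equal(anyDuplicated(sp$name), 0)
  expect_equal(sp$id, seq_len(nrow(sp)))
  sp5 <- enumerate_species(2, 2, 5)
  expect_equal(sum(sp5$role == "xi"), 16)  # (L-1)|H|^2
  expect_equal(sum(sp5$role == "beta"), 10)
  expect_equal(sum(sp5$role == "gamma"), 10)
})

test_that("multi-sequence networks duplicate trellis species but share parameters", {
  sp <- enumerate_species(2, 2, c(4, 4))
  expect_equal(sum(sp$role == "alpha" & sp$i == 1), 8)
  expect_equal(sum(sp$role == "alpha" & sp$i == 2), 8)
  expect_equal(sum(sp$role == "theta"), 4)
  expect_equal(sum(sp$role == "psi_p"), 4)
  expect_equal(sum(sp$role == "E"), 16)
})

test_that("every reaction transforms exactly one molecule and keeps its catalysts", {
  crn <- build_bw_network(2, 3, 4, learn_pi = TRUE)
  expect_true(all(crn$reactions$from != crn$reactions$to))
  expect_true(all(crn$reactions$rate == 1))
  # catalysts are untouched: the stoichiometry of every reaction is -1/+1
  comp <- bwcrn:::compile_reactions(crn)
  expect_true(all(Matrix::colSums(abs(comp$S)) == 2))
  expect_true(all(Matrix::colSums(comp$S) == 0))
})

test_that("the initialization subnetwork routes position 1 through the h* hub", {
  crn <- build_bw_network(2, 2, 3, h_star = 1)
  nm <- crn$species$name
  r1a <- crn$reactions[crn$reactions$subnetwork == "R1alpha", ]
  lab <- vapply(seq_len(nrow(r1a)), function(j)
    paste(nm[r1a$from[j]], "->", nm[r1a$to[j]], "|",
          paste(sort(nm[r1a$catalysts[[j]]]), collapse = ",")), character(1))
  # alpha_1_2 + pi_1 + psi_1_w + E_1_w -> alpha_1_1 + (same catalysts)
  expect_true("alpha_1_2 -> alpha_1_1 | E_1_1,pi_1,psi_1_1" %in% lab)
  expect_true("alpha_1_2 -> alpha_1_1 | E_1_2,pi_1,psi_1_2" %in% lab)
  expect_true("alpha_1_1 -> alpha_1_2 | E_1_1,pi_2,psi_2_1" %in% lab)
  expect_equal(nrow(r1a), 4)  # (|H|-1) x |V| x 2 directions
})

test_that("transformed pairs stay inside one conserved class", {
  crn <- build_bw_network(3, 2, 4, learn_pi = TRUE)
  cl <- conserved_classes(crn)
  class_of <- integer(nrow(crn$species))
  for (k in seq_len(nrow(cl))) class_of[cl$species[[k]]] <- k
  for (j in seq_len(nrow(crn$reactions))) {
    expect_gt(class_of[crn$reactions$from[j]], 0)
    expect_equal(class_of[crn$reactions$from[j]], class_of[crn$reactions$to[j]])
  }
  # alpha classes are the position rows
  a1 <- cl[cl$role == "alpha" & cl$l == 1, ]
  expect_equal(lengths(a1$species), 3)
})

test_that("with positive concentrations each subnetwork graph is strongly connected", {
  crn <- build_bw_network(2, 2, 4, learn_pi = TRUE)
  state <- initial_state(crn, random_hmm(2, 2),
                         hmm_seq(c(1L, 2L, 1L, 1L), c("v1", "v2")))
  # E species include zeros; connectivity must hold through the observed ones
  for (s in unique(crn$reactions$subnetwork)) {
    rx <- crn$reactions[crn$reactions$subnetwork == s, ]
    comp <- bwcrn:::compile_reactions(crn, rx)
    xx <- c(state, 1)
    rates <- rx$rate
    for (k in seq_len(ncol(comp$catmat))) rates <- rates * xx[comp$catmat[, k]]
    for (cid in bwcrn:::components_over(rx$from, rx$to)) {
      for (sp in cid) {
        expect_gt(sum(rates[rx$from == sp]), 0)  # can leave every node
        expect_gt(sum(rates[rx$to == sp]), 0)    # can reach every node
      }
    }
  }
})

test_that("observation encoding is an indicator per position", {
  crn <- build_bw_network(2, 2, 3)
  enc <- encode_observations(crn, hmm_seq(c("b", "a", "b"), c("a", "b")))
  expect_equal(unname(enc[c("E_1_1", "E_1_2", "E_2_1", "E_2_2", "E_3_1", "E_3_2")]),
               c(0, 1, 1, 0, 0, 1))
  expect_equal(sum(enc), 3)
  crn2 <- build_bw_network(2, 2, c(2, 2))
  enc2 <- encode_observations(crn2, list(hmm_seq(c("a", "b"), c("a", "b")),
                                         hmm_seq(c("b", "b"), c("a", "b"))))
  expect_equal(unname(enc2[c("s1_E_1_1", "s2_E_1_2")]), c(1, 1))
  expect_error(encode_observations(crn, hmm_seq(c("a", "b"), c("a", "b"))),
               "length")
})

test_that("network construction depends only on dimensions, not the sequence", {
  a <- build_bw_network(2, 2, 4)
  b <- build_bw_network(2, 2, 4)
  expect_identical(a$reactions, b$reactions)
  # different sequences only change the encoding
  e1 <- encode_observations(a, hmm_seq(c(1L, 1L, 2L, 2L), c("x", "y")))
  e2 <- encode_observations(a, hmm_seq(c(2L, 1L, 1L, 1L), c("x", "y")))
  expect_false(identical(e1, e2))
})
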