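# two-state models small enough for hand evaluation
# toy2: deterministic emissions, uniform transitions
toy2 <- function() {
  hmm(pi = c(0.5, 0.5),
      theta = matrix(0.5, 2, 2),
      psi = matrix(c(1, 0, 0, 1), 2, byrow = TRUE),
      alphabet = c("a", "b"))
}

# toy3: noisy emissions (0.75 / 0.25), uniform transitions
toy3 <- function() {
  hmm(pi = c(0.5, 0.5),
      theta = matrix(0.5, 2, 2),
      psi = matrix(c(0.75, 0.25, 0.25, 0.75), 2, byrow = TRUE),
      alphabet = c("a", "b"))
}

seq_ab <- function() hmm_seq(c("a", "b"), c("a", "b"))

# a strictly positive random instance together with a sampled sequence
random_instance <- function(n_hidden, n_visible, L, seed) {
  set.seed(seed)
  params <- random_hmm(n_hidden, n_visible, concentration = 2)
  seq <- as_hmm_seq(sample_hmm(params, L))
  list(params = params, seq = seq)
}
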