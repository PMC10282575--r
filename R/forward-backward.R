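#' Likelihood by exhaustive hidden-path enumeration
#'
#' Computes the observation likelihood as the explicit sum over all `|H|^L`
#' hidden paths of `pi[h1] psi[h1,v1] prod_l theta[h(l-1),h(l)] psi[h(l),v(l)]`.
#' This is the definition of the likelihood and serves as the independent
#' oracle for the forward/backward recursions; it is only feasible for tiny
#' instances and refuses anything with more than `10^6` paths.
#'
#' @param params An [hmm()] object.
#' @param seq An observed sequence ([as_hmm_seq()] input).
#' @return The likelihood as a plain probability.
#' @export
brute_force_likelihood <- function(params, seq) {
  validate_hmm(params)
  v <- as_hmm_seq(seq, params$alphabet)
  L <- length(v)
  nh <- length(params$pi)
  if (nh^L > 1e6)
    stop("|H|^L exceeds 1e6 paths; use forward_algorithm() instead", call. = FALSE)
  paths <- as.matrix(expand.grid(rep(list(seq_len(nh)), L)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    h <- paths[r, ]
    p <- params$pi[h[1]] * params$psi[h[1], v[1]]
    if (L > 1) for (l in 2:L)
      p <- p * params$theta[h[l - 1], h[l]] * params$psi[h[l], v[l]]
    total <- total + p
  }
  unname(total)
}

#' Forward recursion
#'
#' Computes the forward table `alpha[l, h]`, the joint probability of the
#' first `l` observations and hidden state `h` at position `l`:
#' `alpha[1, h] = pi[h] psi[h, v1]`,
#' `alpha[l+1, h] = sum_g alpha[l, g] theta[g, h] psi[h, v(l+1)]`.
#' With `scaled = TRUE` each row is renormalized to sum 1 and the normalizers
#' are returned, so the raw values (`alpha_raw[l, ] = alpha[l, ] *
#' prod(scale[1:l])`) and the log-likelihood (`sum(log(scale))`) remain
#' recoverable without underflow even for long sequences.
#'
#' @param params An [hmm()] object.
#' @param seq Observed sequence.
#' @param scaled Use per-position rescaling (recommended; default).
#' @return A list with `alpha` (L x |H| matrix), `scale` (length-L vector;
#'   all 1 when `scaled = FALSE`) and `loglik`.
#' @export
forward_algorithm <- function(params, seq, scaled = TRUE) {
  validate_hmm(params)
  v <- unclass(as_hmm_seq(seq, params$alphabet))
  L <- length(v)
  nh <- length(params$pi)
  alpha <- matrix(0, L, nh, dimnames = list(NULL, params$hidden))
  scale <- rep(1, L)
  alpha[1, ] <- params$pi * params$psi[, v[1]]
  if (scaled) {
    s <- sum(alpha[1, ])
    if (s > 0) { alpha[1, ] <- alpha[1, ] / s; scale[1] <- s }
  }
  if (L > 1) for (l in seq_len(L - 1)) {
    alpha[l + 1, ] <- as.vector(alpha[l, ] %*% params$theta) * params$psi[, v[l + 1]]
    if (scaled) {
      s <- sum(alpha[l + 1, ])
      if (s > 0) { alpha[l + 1, ] <- alpha[l + 1, ] / s; scale[l + 1] <- s }
    }
  }
  ll <- if (scaled) {
    if (all(scale > 0) && sum(alpha[L, ]) > 0) sum(log(scale)) else -Inf
  } else {
    p <- sum(alpha[L, ]); if (p > 0) log(p) else -Inf
  }
  list(alpha = alpha, scale = scale, loglik = ll)
}

#' Backward recursion
#'
#' Computes the backward table `beta[l, h]`, the probability of observations
#' `l+1, ..., L` given hidden state `h` at position `l`:
#' `beta[L, h] = 1`,
#' `beta[l, h] = sum_g theta[h, g] psi[g, v(l+1)] beta[l+1, g]`.
#' When the `scale` vector from a scaled forward pass is supplied, each row
#' `l` is divided by `prod(scale[(l+1):L])` incrementally, which keeps the
#' scaled products `alpha[l, h] * beta[l, h]` summing to 1 at every position.
#'
#' @param params An [hmm()] object.
#' @param seq Observed sequence.
#' @param scale Optional per-position normalizers from [forward_algorithm()].
#' @return L x |H| matrix `beta`.
#' @export
backward_algorithm <- function(params, seq, scale = NULL) {
  validate_hmm(params)
  v <- unclass(as_hmm_seq(seq, params$alphabet))
  L <- length(v)
  nh <- length(params$pi)
  beta <- matrix(0, L, nh, dimnames = list(NULL, params$hidden))
  beta[L, ] <- 1
  if (L > 1) for (l in (L - 1):1) {
    beta[l, ] <- as.vector(params$theta %*% (params$psi[, v[l + 1]] * beta[l + 1, ]))
    if (!is.null(scale) && scale[l + 1] > 0) beta[l, ] <- beta[l, ] / scale[l + 1]
  }
  beta
}

#' E-step: posterior state and transition probabilities
#'
#' Computes `gamma[l, h] = alpha[l, h] beta[l, h] / sum_f alpha[l, f] beta[l, f]`
#' and `xi[l, g, h] = alpha[l, g] theta[g, h] psi[h, v(l+1)] beta[l+1, h] /
#' sum_f alpha[l, f] beta[l, f]`. Both are invariant to any positive
#' rescaling of `alpha` and `beta` rows, so scaled tables may be passed.
#'
#' @param params An [hmm()] object.
#' @param seq Observed sequence.
#' @param alpha,beta,scale Optional precomputed tables from
#'   [forward_algorithm()] / [backward_algorithm()]; computed here otherwise.
#' @return A list with `gamma` (L x |H|) and `xi` ((L-1) x |H| x |H| array).
#' @export
e_step <- function(params, seq, alpha = NULL, beta = NULL, scale = NULL) {
  validate_hmm(params)
  v <- unclass(as_hmm_seq(seq, params$alphabet))
  L <- length(v)
  nh <- length(params$pi)
  if (is.null(alpha)) {
    fw <- forward_algorithm(params, seq, scaled = TRUE)
    alpha <- fw$alpha; scale <- fw$scale
  }
  if (is.null(beta)) beta <- backward_algorithm(params, seq, scale = scale)
  if (is.null(scale)) scale <- rep(1, L)
  ab <- alpha * beta
  den <- rowSums(ab)
  bad <- which(den <= 0)
  if (length(bad))
    stop_out_of_domain("zero E-step denominator sum_f alpha*beta at position ",
                       bad[1])
  gamma <- ab / den
  xi <- array(0, c(max(L - 1, 0), nh, nh),
              dimnames = list(NULL, params$hidden, params$hidden))
  if (L > 1) for (l in seq_len(L - 1)) {
    m <- params$theta * outer(alpha[l, ], params$psi[, v[l + 1]] * beta[l + 1, ])
    # with scaled tables, beta[l+1,] lacks one factor 1/scale[l+1] relative
    # to the position-l denominator
    xi[l, , ] <- m / (den[l] * scale[l + 1])
  }
  list(gamma = gamma, xi = xi)
}

#' M-step: re-estimate transition and emission matrices
#'
#' `theta'[g, h] = sum_{l<=L-1} xi[l, g, h] / sum_{l<=L-1} sum_f xi[l, g, f]`,
#' `psi'[h, w] = sum_l gamma[l, h] [v_l = w] / sum_l gamma[l, h]`.
#' Rows of the update sum to 1 by construction. Zero denominators are
#' reported as out-of-domain errors naming the offending row.
#'
#' @param gamma,xi E-step output (see [e_step()]).
#' @param seq Observed sequence (supplies the emission indicators).
#' @param alphabet Optional alphabet when `seq` is given as raw indices.
#' @return A list with matrices `theta` and `psi`.
#' @export
m_step <- function(gamma, xi, seq, alphabet = NULL) {
  v <- as_hmm_seq(seq, alphabet)
  ab <- seq_alphabet(v)
  v <- unclass(v)
  nh <- ncol(gamma)
  num_t <- apply(xi, c(2, 3), sum)
  den_t <- rowSums(num_t)
  if (any(den_t <= 0))
    stop_out_of_domain("zero M-step denominator for theta row ", which(den_t <= 0)[1])
  theta <- num_t / den_t
  den_p <- colSums(gamma)
  if (any(den_p <= 0))
    stop_out_of_domain("zero M-step denominator for psi row ", which(den_p <= 0)[1])
  psi <- matrix(0, nh, length(ab))
  for (w in seq_along(ab)) psi[, w] <- colSums(gamma[v == w, , drop = FALSE])
  psi <- psi / den_p
  list(theta = theta, psi = psi)
}

#' Pooled M-step over multiple sequences
#'
#' Pools expected counts over `R` sequences:
#' `pi'[g] = mean_i gamma_i[1, g]` (when `update_pi`),
#' `theta'` and `psi'` as in [m_step()] with numerators and denominators
#' summed over sequences. With a single sequence and `update_pi = FALSE`
#' this reduces exactly to [m_step()].
#'
#' @param e_steps List of [e_step()] outputs, one per sequence.
#' @param seqs List of observed sequences (same order).
#' @param params The current [hmm()] object (supplies labels and the current
#'   `pi` when it is not updated).
#' @param update_pi Update the initial distribution?
#' @return An [hmm()] object holding the updated parameters.
#' @export
m_step_multi <- function(e_steps, seqs, params, update_pi = FALSE) {
  seqs <- as_seq_list(seqs, params$alphabet)
  stopifnot(length(e_steps) == length(seqs), length(seqs) >= 1)
  nh <- length(params$pi)
  nv <- length(params$alphabet)
  num_t <- matrix(0, nh, nh); num_p <- matrix(0, nh, nv)
  den_p <- rep(0, nh); pi_acc <- rep(0, nh)
  for (i in seq_along(seqs)) {
    es <- e_steps[[i]]
    v <- unclass(seqs[[i]])
    num_t <- num_t + apply(es$xi, c(2, 3), sum)
    den_p <- den_p + colSums(es$gamma)
    for (w in seq_len(nv))
      num_p[, w] <- num_p[, w] + colSums(es$gamma[v == w, , drop = FALSE])
    pi_acc <- pi_acc + es$gamma[1, ]
  }
  den_t <- rowSums(num_t)
  if (any(den_t <= 0))
    stop_out_of_domain("zero M-step denominator for theta row ", which(den_t <= 0)[1])
  if (any(den_p <= 0))
    stop_out_of_domain("zero M-step denominator for psi row ", which(den_p <= 0)[1])
  pi_new <- if (update_pi) pi_acc / length(seqs) else unname(params$pi)
  hmm(pi = pi_new, theta = num_t / den_t, psi = num_p / den_p,
      hidden = params$hidden, alphabet = params$alphabet)
}

#' Log-likelihood of one or more observed sequences
#'
#' Computed with the scaled forward recursion and summed over sequences.
#' A likelihood of exactly zero returns `-Inf` rather than raising, so
#' boundary experiments can proceed.
#'
#' @param params An [hmm()] object.
#' @param seqs A sequence or list of sequences.
#' @return Log-likelihood (scalar).
#' @export
log_likelihood <- function(params, seqs) {
  seqs <- as_seq_list(seqs, params$alphabet)
  sum(vapply(seqs, function(v) forward_algorithm(params, v)$loglik, numeric(1)))
}

#' Check membership of the no-division-by-zero region
#'
#' The region where every Baum-Welch step is well defined requires
#' `sum_l alpha[l, h] beta[l, h] > 0` for every hidden state `h`. Also
#' reports whether the positivity-preservation preconditions hold: every
#' symbol of the alphabet observed with `pi > 0` and `L >= 2`, or every
#' symbol observed within positions `2..L` with `L >= 3`.
#'
#' @param params An [hmm()] object.
#' @param seq Observed sequence.
#' @return A list with `in_theta` (flag), `state_sums` (per-state
#'   `sum_l alpha*beta`), `failing_states`, and `positivity_precondition`
#'   (the condition under which strictly positive parameters stay positive).
#' @export
check_theta_region <- function(params, seq) {
  v <- as_hmm_seq(seq, params$alphabet)
  fw <- forward_algorithm(params, v, scaled = TRUE)
  bw <- backward_algorithm(params, v, scale = fw$scale)
  sums <- colSums(fw$alpha * bw)
  # scaled tables only differ from raw ones by positive factors unless the
  # whole likelihood is zero, in which case raw sums vanish too
  if (!is.finite(fw$loglik)) sums <- colSums(matrix(0, 1, length(sums)))
  names(sums) <- params$hidden
  nv <- length(params$alphabet)
  idx <- unclass(v)
  pre <- (all(seq_len(nv) %in% idx) && all(params$pi > 0) && length(v) >= 2) ||
    (length(v) >= 3 && all(seq_len(nv) %in% idx[-1]))
  list(in_theta = all(sums > 0),
       state_sums = sums,
       failing_states = params$hidden[sums <= 0],
       positivity_precondition = pre)
}

stop_out_of_domain <- function(...) {
  stop(structure(class = c("bwcrn_out_of_domain", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
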