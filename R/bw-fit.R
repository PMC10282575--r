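#' Fit an HMM by the classical Baum-Welch (EM) algorithm
#'
#' Iterates forward, backward, E-step and M-step until the maximum absolute
#' parameter change drops below `tol` or `max_iter` is reached. The
#' log-likelihood at the current parameters is recorded every iteration; EM
#' guarantees it is non-decreasing.
#'
#' @param params0 Initial [hmm()] parameters. Strictly positive values are
#'   recommended: the equivalence guarantees with the reaction network
#'   semantics hold on the positive interior.
#' @param seqs A sequence or list of sequences ([as_hmm_seq()] inputs).
#' @param tol Convergence tolerance on the max-abs parameter change.
#' @param max_iter Iteration cap.
#' @param update_pi Also update the initial distribution (multi-sequence
#'   pooled estimator; with one sequence it sets `pi` to `gamma[1, ]`).
#' @return An object of class `"bw_fit"`: a list with `params` (fitted
#'   [hmm()]), `loglik_history`, `n_iter`, `converged`, `in_theta_region`,
#'   `iterates` (list of per-iteration parameter objects, starting at
#'   `params0`).
#' @seealso [run_bw1()], [run_bw2()], [run_bw3()] for the reaction network
#'   executions of the same computation.
#' @export
bw_fit <- function(params0, seqs, tol = 1e-10, max_iter = 10000, update_pi = FALSE) {
  validate_hmm(params0)
  seqs <- as_seq_list(seqs, params0$alphabet)
  lapply(seqs, check_seq_for_hmm, params = params0)
  params <- params0
  ll_hist <- numeric(0)
  iterates <- list(params0)
  converged <- FALSE
  n <- 0L
  while (n < max_iter) {
    n <- n + 1L
    ll_hist[n] <- log_likelihood(params, seqs)
    upd <- tryCatch(
      bw_update(params, seqs, update_pi = update_pi),
      bwcrn_out_of_domain = function(e)
        stop_out_of_domain(conditionMessage(e), " (iteration ", n, ")"))
    iterates[[n + 1L]] <- upd
    delta <- param_distance(upd, params)
    params <- upd
    if (delta < tol) { converged <- TRUE; break }
  }
  theta_flags <- vapply(seqs, function(v) check_theta_region(params, v)$in_theta,
                        logical(1))
  structure(list(params = params,
                 loglik_history = ll_hist,
                 n_iter = n,
                 converged = converged,
                 in_theta_region = all(theta_flags),
                 iterates = iterates,
                 update_pi = update_pi),
            class = "bw_fit")
}

# one full BW iteration (forward, backward, E, M) on a list of sequences
bw_update <- function(params, seqs, update_pi = FALSE) {
  es <- lapply(seqs, function(v) e_step(params, v))
  m_step_multi(es, seqs, params, update_pi = update_pi)
}

#' @export
print.bw_fit <- function(x, ...) {
  cat("Baum-Welch fit: ", x$n_iter, " iterations, ",
      if (x$converged) "converged" else "not converged",
      if (x$in_theta_region) "" else " (limit outside the valid region)",
      "\n", sep = "")
  cat("final log-likelihood: ",
      format(x$loglik_history[length(x$loglik_history)]), "\n", sep = "")
  print(x$params, ...)
  invisible(x)
}

#' Tidy a Baum-Welch fit into per-iteration rows
#'
#' @param x A `"bw_fit"` object.
#' @param ... Unused.
#' @return A tibble with columns `iteration`, `loglik`, and the max-abs
#'   parameter change `delta` from the previous iterate.
#' @export
tidy.bw_fit <- function(x, ...) {
  n <- length(x$loglik_history)
  delta <- vapply(seq_len(n), function(i)
    param_distance(x$iterates[[i + 1]], x$iterates[[i]]), numeric(1))
  tibble::tibble(iteration = seq_len(n), loglik = x$loglik_history, delta = delta)
}

#' One-row summary of a Baum-Welch fit
#'
#' @param x A `"bw_fit"` object.
#' @param ... Unused.
#' @return A one-row tibble with `n_iter`, `converged`, `in_theta_region`,
#'   `loglik`.
#' @export
glance.bw_fit <- function(x, ...) {
  tibble::tibble(n_iter = x$n_iter,
                 converged = x$converged,
                 in_theta_region = x$in_theta_region,
                 loglik = x$loglik_history[length(x$loglik_history)])
}

#' @export
autoplot.bw_fit <- function(object, ...) {
  df <- tidy.bw_fit(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$loglik)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "iteration", y = "log-likelihood",
                  title = "Baum-Welch log-likelihood per iteration")
}

#' Tidy generic (re-exported interface)
#'
#' Minimal broom-style generics so fitted objects can be turned into tibbles
#' without depending on broom itself.
#' @param x Object to tidy or summarize.
#' @param ... Method-specific arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")
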