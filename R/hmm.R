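#' Construct a hidden Markov model parameter set
#'
#' Bundles an initial distribution `pi`, a transition matrix `theta` and an
#' emission matrix `psi` into a validated parameter object. `theta` and `psi`
#' must be row-stochastic (each row a probability distribution); zero entries
#' are allowed, so boundary parameter values can be represented.
#'
#' @param pi Numeric probability vector over the hidden states.
#' @param theta Row-stochastic transition matrix, hidden x hidden.
#' @param psi Row-stochastic emission matrix, hidden x visible.
#' @param hidden Optional character vector of hidden-state labels.
#' @param alphabet Optional character vector of visible-symbol labels. Symbol
#'   order fixes the column order of `psi`.
#' @return An object of class `"hmm"`: a list with elements `pi`, `theta`,
#'   `psi`, `hidden`, `alphabet`.
#' @examples
#' hmm(pi = c(0.5, 0.5),
#'     theta = matrix(0.5, 2, 2),
#'     psi = matrix(c(0.75, 0.25, 0.25, 0.75), 2, byrow = TRUE),
#'     alphabet = c("a", "b"))
#' @export
hmm <- function(pi, theta, psi, hidden = NULL, alphabet = NULL) {
  theta <- as.matrix(theta)
  psi <- as.matrix(psi)
  pi <- as.numeric(pi)
  nh <- length(pi)
  if (!all(dim(theta) == c(nh, nh)) || nrow(psi) != nh)
    stop("inconsistent dimensions between pi, theta and psi", call. = FALSE)
  if (is.null(hidden)) hidden <- paste0("H", seq_len(nh))
  if (is.null(alphabet)) alphabet <- paste0("v", seq_len(ncol(psi)))
  obj <- structure(
    list(pi = stats::setNames(pi, hidden),
         theta = `dimnames<-`(theta, list(hidden, hidden)),
         psi = `dimnames<-`(psi, list(hidden, alphabet)),
         hidden = hidden, alphabet = alphabet),
    class = "hmm")
  validate_hmm(obj)
  obj
}

validate_hmm <- function(x, tol = 1e-9) {
  nh <- length(x$pi)
  if (nh < 1L || length(x$alphabet) < 1L)
    stop("an HMM needs at least one hidden state and one visible symbol", call. = FALSE)
  if (!all(dim(x$theta) == c(nh, nh)) || nrow(x$psi) != nh)
    stop("inconsistent dimensions between pi, theta and psi", call. = FALSE)
  vals <- c(x$pi, x$theta, x$psi)
  if (any(!is.finite(vals)) || any(vals < -tol))
    stop("HMM parameters must be finite and non-negative", call. = FALSE)
  if (abs(sum(x$pi) - 1) > tol)
    stop("pi must sum to 1", call. = FALSE)
  bad_t <- which(abs(rowSums(x$theta) - 1) > tol)
  if (length(bad_t))
    stop("theta row(s) ", paste(bad_t, collapse = ", "), " do not sum to 1", call. = FALSE)
  bad_p <- which(abs(rowSums(x$psi) - 1) > tol)
  if (length(bad_p))
    stop("psi row(s) ", paste(bad_p, collapse = ", "), " do not sum to 1", call. = FALSE)
  invisible(x)
}

#' @export
print.hmm <- function(x, digits = 4, ...) {
  cat("Hidden Markov model: ", length(x$hidden), " hidden states, ",
      length(x$alphabet), " visible symbols\n", sep = "")
  cat("pi:\n"); print(round(x$pi, digits))
  cat("theta (transition):\n"); print(round(x$theta, digits))
  cat("psi (emission):\n"); print(round(x$psi, digits))
  invisible(x)
}

#' Test whether all HMM parameters are strictly positive
#'
#' Strict positivity (the interior of the parameter simplex) is the
#' hypothesis under which the discrete algorithm and all three reaction
#' network semantics provably agree.
#'
#' @param params An [hmm()] object.
#' @param eps Positivity threshold.
#' @return Logical scalar.
#' @export
is_positive_hmm <- function(params, eps = 0) {
  all(params$pi > eps) && all(params$theta > eps) && all(params$psi > eps)
}

#' Draw a random HMM with Dirichlet-distributed rows
#'
#' Each row of `theta` and `psi` (and `pi`) is drawn from a flat Dirichlet
#' distribution, giving strictly positive parameters almost surely.
#'
#' @param n_hidden,n_visible State-space sizes.
#' @param alphabet Optional symbol labels.
#' @param concentration Dirichlet concentration parameter (1 = flat).
#' @return An [hmm()] object.
#' @export
random_hmm <- function(n_hidden, n_visible, alphabet = NULL, concentration = 1) {
  rdir <- function(n) {
    z <- stats::rgamma(n, shape = concentration)
    z / sum(z)
  }
  hmm(pi = rdir(n_hidden),
      theta = t(vapply(seq_len(n_hidden), function(i) rdir(n_hidden), numeric(n_hidden))),
      psi = t(vapply(seq_len(n_hidden), function(i) rdir(n_visible), numeric(n_visible))),
      alphabet = alphabet)
}

#' Read or write HMM parameters as JSON
#'
#' The JSON document has fields `alphabet`, `hidden`, `pi`, `theta`, `psi`,
#' with `theta` and `psi` stored row-wise.
#'
#' @param path File path.
#' @param params An [hmm()] object (for writing).
#' @return `read_hmm()` returns an [hmm()] object; `write_hmm()` returns
#'   `path` invisibly.
#' @export
read_hmm <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  for (f in c("pi", "theta", "psi"))
    if (is.null(doc[[f]])) stop("HMM JSON is missing field '", f, "': ", path, call. = FALSE)
  hmm(pi = doc$pi, theta = doc$theta, psi = doc$psi,
      hidden = doc$hidden, alphabet = doc$alphabet)
}

#' @rdname read_hmm
#' @export
write_hmm <- function(params, path) {
  doc <- list(alphabet = params$alphabet, hidden = params$hidden,
              pi = unname(params$pi), theta = unname(params$theta),
              psi = unname(params$psi))
  jsonlite::write_json(doc, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a row-stochastic matrix from a TSV file with a header row
#'
#' The header names the columns (e.g. the visible alphabet); row names go in
#' the first column.
#'
#' @param path File path.
#' @return A numeric matrix with dimnames.
#' @export
read_stochastic_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

# max-abs difference between two parameter sets, used for convergence checks
param_distance <- function(a, b) {
  max(abs(a$pi - b$pi), abs(a$theta - b$theta), abs(a$psi - b$psi))
}
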