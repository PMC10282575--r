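# Compiled form of a reaction set: index vectors for vectorized mass-action
# rate evaluation plus a sparse stoichiometry matrix. A dummy species with
# concentration fixed at 1 pads the catalyst matrix to rectangular shape.
compile_reactions <- function(crn, reactions = NULL, identify_primed = FALSE,
                              encoding = NULL) {
  rx <- if (is.null(reactions)) crn$reactions else reactions
  n_sp <- nrow(crn$species)
  if (identify_primed) {
    sp <- crn$species
    map <- seq_len(n_sp)
    remap_role <- function(role_from, role_to) {
      a <- sp[sp$role == role_from, ]
      b <- sp[sp$role == role_to, ]
      key_b <- paste(b$g, b$h, b$w, sep = "|")
      key_a <- paste(a$g, a$h, a$w, sep = "|")
      map[a$id] <<- b$id[match(key_a, key_b)]
    }
    remap_role("theta", "theta_p")
    remap_role("psi", "psi_p")
    if (crn$learn_pi) {
      a <- sp[sp$role == "pi", ]; b <- sp[sp$role == "pi_p", ]
      map[a$id] <- b$id[match(a$h, b$h)]
    }
    rx$catalysts <- lapply(rx$catalysts, function(z) map[z])
  }
  if (!is.null(encoding)) {
    # reactions with an always-zero E catalyst never fire; drop them
    e_ids <- species_ids(crn, "E")
    zero_e <- e_ids[encoding[match(e_ids, e_ids)] == 0]
    zero_e <- e_ids[encoding == 0]
    keep <- !vapply(rx$catalysts, function(z) any(z %in% zero_e), logical(1))
    rx <- rx[keep, ]
  }
  m <- nrow(rx)
  maxc <- if (m) max(lengths(rx$catalysts)) else 0L
  dummy <- n_sp + 1L
  catmat <- matrix(dummy, m, maxc)
  for (j in seq_len(m)) {
    z <- rx$catalysts[[j]]
    if (length(z)) catmat[j, seq_along(z)] <- z
  }
  S <- Matrix::sparseMatrix(i = c(rx$from, rx$to), j = rep(seq_len(m), 2),
                            x = rep(c(-1, 1), each = m), dims = c(n_sp, m))
  list(from = rx$from, to = rx$to, catmat = catmat, rate = rx$rate,
       S = S, n_species = n_sp, reactions = rx)
}

compiled_rhs <- function(comp, x) {
  xx <- c(x, 1)
  r <- comp$rate * xx[comp$from]
  for (k in seq_len(ncol(comp$catmat))) r <- r * xx[comp$catmat[, k]]
  as.vector(comp$S %*% r)
}

#' Mass-action right-hand side of the network ODE
#'
#' Each reaction fires at rate `k * [reactant] * prod([catalysts])`; the rate
#' is subtracted from the reactant coordinate and added to the product
#' coordinate, so catalysts receive zero net contribution.
#'
#' @param crn A [build_bw_network()] object.
#' @param state Concentration vector over all species (length
#'   `nrow(crn$species)`), non-negative.
#' @param parts Optional subset of parts
#'   (`"alpha","beta","gamma","xi","theta","psi","pi"`) to include.
#' @param identify_primed Substitute primed parameter species for unprimed
#'   ones wherever they act as catalysts (the fully coupled semantics).
#' @return The derivative vector, one entry per species.
#' @export
mass_action_rhs <- function(crn, state, parts = NULL, identify_primed = FALSE) {
  if (length(state) != nrow(crn$species))
    stop("state length ", length(state), " does not match the ",
         nrow(crn$species), " network species", call. = FALSE)
  rx <- crn$reactions
  if (!is.null(parts)) rx <- rx[rx$part %in% parts, ]
  comp <- compile_reactions(crn, rx, identify_primed = identify_primed)
  stats::setNames(compiled_rhs(comp, state), crn$species$name)
}

# integrate a compiled reaction set with deSolve; returns the deSolve matrix
integrate_compiled <- function(comp, x0, times, rtol = 1e-8, atol = 1e-10) {
  f <- function(t, x, p) list(compiled_rhs(comp, x))
  deSolve::ode(y = x0, times = times, func = f, parms = NULL,
               method = "lsoda", rtol = rtol, atol = atol, maxsteps = 5e5)
}

# integrate until the max-abs vector field component on `watch_ids` (or all
# species) drops below tol, in geometrically growing time chunks
integrate_to_equilibrium <- function(comp, x0, t_max = 1e4, tol = 1e-8,
                                     rtol = 1e-8, atol = 1e-10,
                                     watch_ids = NULL, snapshot_times = 25,
                                     state_tol = NULL) {
  t0 <- 0
  chunk <- 1
  x <- x0
  x_prev <- x0
  traj_t <- 0
  traj_x <- matrix(x0, nrow = 1)
  converged <- FALSE
  wid <- if (is.null(watch_ids)) seq_along(x0) else watch_ids
  while (t0 < t_max) {
    t1 <- min(t0 + chunk, t_max)
    times <- seq(t0, t1, length.out = max(3, ceiling(snapshot_times * (t1 - t0) / t_max) + 2))
    out <- integrate_compiled(comp, x, times, rtol = rtol, atol = atol)
    x <- out[nrow(out), -1]
    traj_t <- c(traj_t, out[-1, 1])
    traj_x <- rbind(traj_x, out[-1, -1, drop = FALSE])
    dx <- compiled_rhs(comp, x)
    resid <- max(abs(dx[wid]))
    # slow near-boundary modes can leave a small vector field long before the
    # state settles; when state_tol is given, additionally require successive
    # (doubling) chunk ends to agree
    settled <- is.null(state_tol) || max(abs(x[wid] - x_prev[wid])) < state_tol
    if (resid < tol && settled) { converged <- TRUE; break }
    x_prev <- x
    t0 <- t1
    chunk <- chunk * 2
  }
  list(state = x, times = traj_t, states = traj_x,
       residual = resid, converged = converged)
}

#' Assemble a full initial concentration vector for the network
#'
#' Parameter species are set from `params` (primed copies from
#' `params_primed`, defaulting to `params`); the `E` species from the
#' observation encoding; trellis species within each conserved class are
#' initialized either uniformly or from a flat Dirichlet draw, scaled to the
#' class totals (`A_l` for `alpha` rows, `B_l` for `beta` rows, 1 for
#' `gamma`/`xi`/primed rows). The last `beta` row, which no reaction
#' transforms, is always uniform, mirroring the `beta[L, h] = 1` terminal
#' condition up to scale.
#'
#' @param crn A [build_bw_network()] object.
#' @param params An [hmm()] object for the (unprimed) parameter species.
#' @param seqs Observed sequence(s) for the encoding.
#' @param params_primed Optional [hmm()] for the primed species.
#' @param totals_alpha,totals_beta Positive totals for the `alpha`/`beta`
#'   position rows (recycled over positions).
#' @param trellis_init `"uniform"` or `"random"` (flat Dirichlet per class).
#' @param seed Seed used when `trellis_init = "random"`.
#' @return Named numeric state vector over all species.
#' @export
initial_state <- function(crn, params, seqs, params_primed = params,
                          totals_alpha = 1, totals_beta = 1,
                          trellis_init = c("uniform", "random", "equilibrium"),
                          seed = NULL) {
  # "equilibrium" is resolved by the caller (the trellis is swept to its
  # conditional equilibrium afterwards); here it starts uniform
  trellis_init <- match.arg(trellis_init)
  if (trellis_init == "equilibrium") trellis_init <- "uniform"
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(totals_alpha > 0), all(totals_beta > 0))
  sp <- crn$species
  x <- stats::setNames(numeric(nrow(sp)), sp$name)
  x[species_ids(crn, "E")] <- encode_observations(crn, seqs, params$alphabet)
  set_mat <- function(role, m) {
    rows <- sp[sp$role == role, ]
    idx <- if (role %in% c("pi", "pi_p")) cbind(rows$h, 1) else
      if (role %in% c("theta", "theta_p")) cbind(rows$g, rows$h) else
        cbind(rows$h, rows$w)
    x[rows$id] <<- m[idx]
  }
  set_mat("theta", params$theta); set_mat("psi", params$psi)
  set_mat("pi", as.matrix(params$pi))
  set_mat("theta_p", params_primed$theta); set_mat("psi_p", params_primed$psi)
  if (crn$learn_pi) set_mat("pi_p", as.matrix(params_primed$pi))
  cl <- conserved_classes(crn)
  n_a <- max(vapply(crn$seq_lengths, length, integer(1)))
  ta <- rep(totals_alpha, length.out = max(crn$seq_lengths))
  tb <- rep(totals_beta, length.out = max(crn$seq_lengths))
  for (k in seq_len(nrow(cl))) {
    ids <- cl$species[[k]]
    role <- cl$role[k]
    if (role %in% c("theta_p", "psi_p", "pi_p")) next  # set from params above
    total <- switch(role, alpha = ta[cl$l[k]], beta = tb[cl$l[k]], 1)
    m <- length(ids)
    w <- if (trellis_init == "uniform" ||
             (role == "beta" && cl$l[k] == crn$seq_lengths[cl$i[k]]))
      rep(1, m) else stats::rexp(m)
    x[ids] <- total * w / sum(w)
  }
  x
}

# read the (primed or unprimed) parameter species out of a state vector
state_params <- function(crn, state, primed = TRUE, hidden = NULL,
                         alphabet = NULL, normalize = FALSE) {
  sp <- crn$species
  get_mat <- function(role, nr, nc, rix, cix) {
    rows <- sp[sp$role == role, ]
    m <- matrix(0, nr, nc)
    m[cbind(rows[[rix]], if (is.null(cix)) 1L else rows[[cix]])] <- state[rows$id]
    m
  }
  nh <- crn$n_hidden; nv <- crn$n_visible
  theta <- get_mat(if (primed) "theta_p" else "theta", nh, nh, "g", "h")
  psi <- get_mat(if (primed) "psi_p" else "psi", nh, nv, "h", "w")
  pi_role <- if (primed && crn$learn_pi) "pi_p" else "pi"
  pi <- as.vector(get_mat(pi_role, nh, 1, "h", NULL))
  if (normalize) {
    theta <- pmax(theta, 0); psi <- pmax(psi, 0); pi <- pmax(pi, 0)
    theta <- theta / rowSums(theta); psi <- psi / rowSums(psi); pi <- pi / sum(pi)
  }
  hmm(pi = pi, theta = theta, psi = psi, hidden = hidden, alphabet = alphabet)
}
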