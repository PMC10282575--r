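#' Scheme configuration
#'
#' Collects the tunable settings of the reaction network executions.
#'
#' @param totals_alpha,totals_beta Conserved totals `A_l`, `B_l` of the
#'   `alpha`/`beta` position rows (positive; the learned parameters are
#'   invariant to them).
#' @param h_star,v_star Reference (hub) states. `v_star = NULL` picks the
#'   first alphabet symbol occurring in the data, so the emission hub is
#'   never starved.
#' @param equilibration `"closed_form"` solves each subnetwork's balance
#'   equations exactly; `"integrate"` runs its ODE to numerical equilibrium.
#' @param equil_tol Equilibrium threshold on the max-abs vector-field
#'   component (integrate mode and BW3 stopping rule).
#' @param rtol,atol ODE integrator tolerances.
#' @param t_max Integration horizon per equilibration / for BW3.
#' @param outer_tol,max_outer Stopping rule on the parameter iterates of
#'   BW1/BW2.
#' @param trellis_init,seed Initialization of the trellis species (see
#'   [initial_state()]).
#' @return A list of class `"bw_scheme_config"`.
#' @export
scheme_config <- function(totals_alpha = 1, totals_beta = 1,
                          h_star = 1L, v_star = NULL,
                          equilibration = c("closed_form", "integrate"),
                          equil_tol = 1e-8, rtol = 1e-8, atol = 1e-10,
                          t_max = 1e4, outer_tol = 1e-10, max_outer = 10000,
                          trellis_init = "uniform", seed = NULL) {
  stopifnot(all(totals_alpha > 0), all(totals_beta > 0),
            equil_tol > 0, rtol > 0, atol > 0, t_max > 0, outer_tol > 0)
  structure(list(totals_alpha = totals_alpha, totals_beta = totals_beta,
                 h_star = as.integer(h_star), v_star = v_star,
                 equilibration = match.arg(equilibration),
                 equil_tol = equil_tol, rtol = rtol, atol = atol,
                 t_max = t_max, outer_tol = outer_tol, max_outer = max_outer,
                 trellis_init = trellis_init, seed = seed),
            class = "bw_scheme_config")
}

# resolve v*: first alphabet symbol that occurs in the data
resolve_v_star <- function(config, seqs) {
  if (!is.null(config$v_star)) return(as.integer(config$v_star))
  present <- sort(unique(unlist(lapply(seqs, unclass))))
  present[1]
}

#' Equilibrium of one mono-molecular subnetwork
#'
#' Each subnetwork is a star graph of single-molecule interconversions
#' through its hub species, with rates given by the frozen catalyst
#' concentrations. When every rate is positive the graph is strongly
#' connected and the unique equilibrium balances each leaf against the hub
#' (`x_leaf * rate_out = x_hub * rate_in`), reproducing the corresponding
#' Baum-Welch quantity scaled to the conserved class total. When some rates
#' vanish the limit implied by the linear dynamics is returned instead
#' (mass drains from cut-off nodes and accumulates in dead ends) and the
#' `boundary` flag is set.
#'
#' @param crn A [build_bw_network()] object.
#' @param subnetwork Subnetwork label (e.g. `"R2alpha"`, `"Rtheta"`; see
#'   `crn$reactions$subnetwork`).
#' @param state Full concentration vector supplying catalyst concentrations
#'   and the current (initial) transformed-species values.
#' @param rate_cache Optional precomputed [compile_reactions()] subset.
#' @return A list with `ids` (transformed species), `values` (their
#'   equilibrium concentrations), `boundary` flag, and `total`.
#' @export
subnetwork_equilibrium <- function(crn, subnetwork, state, rate_cache = NULL) {
  rx <- if (is.null(rate_cache)) {
    compile_reactions(crn, crn$reactions[crn$reactions$subnetwork == subnetwork, ])
  } else rate_cache
  if (!length(rx$from)) stop("unknown or empty subnetwork: ", subnetwork, call. = FALSE)
  xx <- c(state, 1)
  rates <- rx$rate
  for (k in seq_len(ncol(rx$catmat))) rates <- rates * xx[rx$catmat[, k]]
  # the M-step subnetworks are one star per parameter row; split the reaction
  # set into connected components over the transformed species and solve each
  comp_of <- components_over(rx$from, rx$to)
  ids_all <- integer(0); vals_all <- numeric(0); boundary <- FALSE
  for (cids in comp_of) {
    res <- star_component_limit(cids, rx, rates, state, subnetwork)
    ids_all <- c(ids_all, res$ids); vals_all <- c(vals_all, res$values)
    boundary <- boundary || res$boundary
  }
  list(ids = ids_all, values = vals_all, boundary = boundary,
       total = sum(state[ids_all]))
}

# weakly connected components of the transformation graph; returns a list of
# species-id vectors
components_over <- function(from, to) {
  ids <- sort(unique(c(from, to)))
  parent <- stats::setNames(seq_along(ids), ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (j in seq_along(from)) {
    a <- find(match(from[j], ids)); b <- find(match(to[j], ids))
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_along(ids), find, integer(1))
  unname(split(ids, roots))
}

# equilibrium (or boundary limit) of one star component through its hub
star_component_limit <- function(ids, rx, rates, state, subnetwork) {
  sel <- rx$from %in% ids
  deg <- vapply(ids, function(s) sum(rx$from[sel] == s | rx$to[sel] == s),
                numeric(1))
  hub <- ids[which.max(deg)]
  leaves <- setdiff(ids, hub)
  total <- sum(state[ids])
  if (total <= 0) stop("zero conserved total in subnetwork ", subnetwork, call. = FALSE)
  r_in <- vapply(leaves, function(s) sum(rates[rx$from == hub & rx$to == s]), numeric(1))
  r_out <- vapply(leaves, function(s) sum(rates[rx$from == s & rx$to == hub]), numeric(1))
  if (all(r_in > 0) && all(r_out > 0)) {
    w <- c(1, r_in / r_out)
    return(list(ids = c(hub, leaves), values = total * w / sum(w),
                boundary = FALSE))
  }
  # boundary: limit of the frozen-rate linear star dynamics, computed from the
  # graph structure. Leaves with neither in- nor out-rate are frozen at their
  # initial mass; leaves with an in-rate but no out-rate are dead ends.
  x_hub <- state[hub]; x_leaf <- state[leaves]
  frozen <- r_in == 0 & r_out == 0
  dead <- r_out == 0 & r_in > 0
  drain <- r_out > 0
  vals_leaf <- x_leaf
  if (!any(dead)) {
    # unique equilibrium on the non-frozen part: x_leaf r_out = x_hub r_in
    active_total <- total - sum(x_leaf[frozen])
    w <- c(1, ifelse(drain, r_in / r_out, 0))
    scaled <- active_total * w / sum(w)
    hub_val <- scaled[1]
    vals_leaf[!frozen] <- scaled[-1][!frozen]
  } else {
    # everything feeding the hub empties into the dead ends; the split among
    # dead ends is r_in[d] * integral of the hub trajectory, obtained from
    # the absorbing linear subsystem of the hub and the draining leaves
    nd <- sum(drain)
    B <- matrix(0, 1 + nd, 1 + nd)
    B[1, 1] <- -sum(r_in)
    if (nd) {
      B[1, 1 + seq_len(nd)] <- r_out[drain]
      B[1 + seq_len(nd), 1] <- r_in[drain]
      diag(B)[1 + seq_len(nd)] <- -r_out[drain]
    }
    z0 <- c(x_hub, x_leaf[drain])
    J <- solve(B, -z0)  # time-integrals of hub and draining leaves
    hub_val <- 0
    vals_leaf[drain] <- 0
    vals_leaf[dead] <- x_leaf[dead] + r_in[dead] * J[1]
  }
  list(ids = c(hub, leaves), values = pmax(c(hub_val, vals_leaf), 0),
       boundary = TRUE)
}

# the subnetwork execution order: forward sweeps, backward sweep, E-step
# rows, then the learning reactions
subnetwork_order <- function(crn) {
  multi <- length(crn$seq_lengths) > 1
  pre <- function(i) if (multi) sprintf("s%d:", i) else ""
  out <- character(0)
  for (i in seq_along(crn$seq_lengths)) {
    L <- crn$seq_lengths[i]
    out <- c(out,
             sprintf("%sR%dalpha", pre(i), 1:L),
             sprintf("%sR%dbeta", pre(i), (L - 1):1),
             sprintf("%sR%dgamma", pre(i), 1:L),
             sprintf("%sR%dxi", pre(i), 1:(L - 1)))
  }
  c(out, "Rtheta", "Rpsi", if (crn$learn_pi) "Rpi")
}

# copy the primed parameter species onto the unprimed ones
promote_primed <- function(crn, state) {
  sp <- crn$species
  copy <- function(role_p, role_u) {
    a <- sp[sp$role == role_p, ]; b <- sp[sp$role == role_u, ]
    key <- function(d) paste(d$g, d$h, d$w, sep = "|")
    state[b$id[match(key(a), key(b))]] <<- state[a$id]
  }
  copy("theta_p", "theta"); copy("psi_p", "psi")
  if (crn$learn_pi) copy("pi_p", "pi")
  state
}

run_scheme_iterative <- function(mode, params0, seqs, config, crn = NULL) {
  validate_hmm(params0)
  seqs <- as_seq_list(seqs, params0$alphabet)
  lapply(seqs, check_seq_for_hmm, params = params0)
  vs <- resolve_v_star(config, seqs)
  if (is.null(crn))
    crn <- build_bw_network(length(params0$pi), length(params0$alphabet),
                            vapply(seqs, length, integer(1)),
                            h_star = config$h_star, v_star = vs,
                            learn_pi = config$learn_pi %||% FALSE)
  state <- initial_state(crn, params0, seqs,
                         totals_alpha = config$totals_alpha,
                         totals_beta = config$totals_beta,
                         trellis_init = config$trellis_init, seed = config$seed)
  if (!is_positive_hmm(params0))
    warning("initial parameters on the boundary: the scheme equilibria may ",
            "differ from the discrete algorithm's", call. = FALSE)
  order <- subnetwork_order(crn)
  caches <- lapply(order, function(s)
    compile_reactions(crn, crn$reactions[crn$reactions$subnetwork == s, ]))
  names(caches) <- order
  # for BW2, subnetworks of the inference module are grouped and integrated
  # jointly; closed form evaluates them in cascade, which shares the same
  # equilibrium because the dependency structure is acyclic
  inference_sets <- order[!order %in% c("Rtheta", "Rpsi", "Rpi")]
  learning_sets <- intersect(c("Rtheta", "Rpsi", "Rpi"), order)
  iterates <- list(params0)
  boundary <- FALSE
  learn_traj <- NULL
  params <- params0
  for (n in seq_len(config$max_outer)) {
    if (config$equilibration == "closed_form") {
      for (s in order) {
        eq <- subnetwork_equilibrium(crn, s, state, rate_cache = caches[[s]])
        state[eq$ids] <- eq$values
        boundary <- boundary || eq$boundary
      }
    } else {
      grp <- if (mode == "bw1") as.list(order) else
        list(inference_sets, learning_sets)
      for (g in grp) {
        rxg <- crn$reactions[crn$reactions$subnetwork %in% g, ]
        comp <- compile_reactions(crn, rxg)
        watch <- sort(unique(c(comp$from, comp$to)))
        res <- integrate_to_equilibrium(comp, state, t_max = config$t_max,
                                        tol = config$equil_tol,
                                        rtol = config$rtol, atol = config$atol,
                                        watch_ids = watch, state_tol = 1e-9)
        state <- res$state
        boundary <- boundary || !res$converged
        if (mode == "bw2" && identical(g, learning_sets) && is.null(learn_traj)) {
          pids <- c(species_ids(crn, "theta_p"), species_ids(crn, "psi_p"))
          learn_traj <- list(times = res$times,
                             values = res$states[, pids, drop = FALSE])
        }
      }
    }
    upd <- state_params(crn, state, primed = TRUE,
                        hidden = params0$hidden, alphabet = params0$alphabet)
    iterates[[n + 1L]] <- upd
    delta <- param_distance(upd, params)
    params <- upd
    state <- promote_primed(crn, state)
    if (delta < config$outer_tol) break
  }
  converged <- delta < config$outer_tol
  make_scheme_result(mode, crn, params, iterates, seqs, config,
                     boundary = boundary || !is_positive_hmm(params, eps = 0),
                     converged = converged, learn_traj = learn_traj,
                     state = state)
}

#' Run the network by sequential subnetwork equilibration (BW1)
#'
#' Executes the subnetworks one at a time in the forward, backward, E-step,
#' M-step order, freezing every catalyst at its previously obtained value
#' and running each subnetwork to equilibrium. After each full sweep the
#' primed parameter species are promoted to the unprimed ones and the sweep
#' is repeated until the parameter iterates settle. From a strictly positive
#' start the n-th sweep reproduces the n-th iterate of the classical
#' discrete algorithm exactly.
#'
#' @param params0 Initial [hmm()] parameters (strictly positive recommended).
#' @param seqs Observed sequence(s).
#' @param config A [scheme_config()].
#' @param learn_pi Update the initial distribution via the extra reactions.
#' @return A `"bw_scheme"` object; see [glance.bw_scheme()], [tidy.bw_scheme()].
#' @export
run_bw1 <- function(params0, seqs, config = scheme_config(), learn_pi = FALSE) {
  config$learn_pi <- learn_pi
  run_scheme_iterative("bw1", params0, seqs, config)
}

#' Run the network by inference/learning module alternation (BW2)
#'
#' The inference module (all `alpha`, `beta`, `gamma`, `xi` subnetworks) and
#' the learning module (`theta'`, `psi'`, and optionally `pi'`) are each run
#' jointly to equilibrium, alternating, with the unprimed parameters frozen
#' during a sweep. Per-sweep equilibria coincide with [run_bw1()]'s; within
#' a sweep the modules converge exponentially fast, which
#' [estimate_convergence_rate()] quantifies from the recorded learning-module
#' trajectory (integrate mode).
#'
#' @inheritParams run_bw1
#' @return A `"bw_scheme"` object.
#' @export
run_bw2 <- function(params0, seqs, config = scheme_config(), learn_pi = FALSE) {
  config$learn_pi <- learn_pi
  run_scheme_iterative("bw2", params0, seqs, config)
}

#' Run the fully coupled autonomous ODE (BW3)
#'
#' Identifies the primed and unprimed parameter species and integrates the
#' complete mass-action system simultaneously, with no frozen
#' concentrations. Any initialization in the closed simplex is admitted
#' (solutions exist globally); positive equilibria coincide with the fixed
#' points of the discrete algorithm, while boundary limits may differ.
#' Integration stops when the max-abs vector-field component on the
#' parameter species falls below `config$equil_tol`, or at `config$t_max`.
#'
#' @inheritParams run_bw1
#' @param record Number of trajectory snapshots to keep (log-spaced in time).
#' @return A `"bw_scheme"` object whose `trajectory` element is a tibble
#'   with the parameter concentrations and the log-likelihood over time.
#' @export
run_bw3 <- function(params0, seqs, config = scheme_config(), learn_pi = FALSE,
                    record = 200) {
  validate_hmm(params0)
  seqs <- as_seq_list(seqs, params0$alphabet)
  lapply(seqs, check_seq_for_hmm, params = params0)
  vs <- resolve_v_star(config, seqs)
  crn <- build_bw_network(length(params0$pi), length(params0$alphabet),
                          vapply(seqs, length, integer(1)),
                          h_star = config$h_star, v_star = vs,
                          learn_pi = learn_pi)
  state <- initial_state(crn, params0, seqs,
                         totals_alpha = config$totals_alpha,
                         totals_beta = config$totals_beta,
                         trellis_init = config$trellis_init, seed = config$seed)
  if (identical(config$trellis_init, "equilibrium")) {
    # sweep the inference subnetworks once so the trellis species start at
    # their conditional equilibrium given params0
    for (s in setdiff(subnetwork_order(crn), c("Rtheta", "Rpsi", "Rpi"))) {
      eq <- subnetwork_equilibrium(crn, s, state)
      state[eq$ids] <- eq$values
    }
  }
  enc <- encode_observations(crn, seqs, params0$alphabet)
  comp <- compile_reactions(crn, identify_primed = TRUE, encoding = enc)
  pids <- c(species_ids(crn, "theta_p"), species_ids(crn, "psi_p"),
            if (learn_pi) species_ids(crn, "pi_p"))
  res <- integrate_to_equilibrium(comp, state, t_max = config$t_max,
                                  tol = config$equil_tol,
                                  rtol = config$rtol, atol = config$atol,
                                  watch_ids = pids,
                                  snapshot_times = record)
  params <- state_params(crn, res$state, primed = TRUE,
                         hidden = params0$hidden, alphabet = params0$alphabet,
                         normalize = TRUE)
  make_scheme_result("bw3", crn, params, iterates = NULL, seqs, config,
                     boundary = !is_positive_hmm(params, eps = 1e-6),
                     converged = res$converged,
                     trajectory = bw3_trajectory(crn, res, params0, seqs, learn_pi),
                     scheme_residual = res$residual,
                     state = res$state)
}

bw3_trajectory <- function(crn, res, params0, seqs, learn_pi) {
  sp <- crn$species
  keep <- sp[sp$role %in% c("theta_p", "psi_p", if (learn_pi) "pi_p"), ]
  lab <- ifelse(keep$role == "theta_p", sprintf("theta_%d%d", keep$g, keep$h),
                ifelse(keep$role == "psi_p", sprintf("psi_%d%d", keep$h, keep$w),
                       sprintf("pi_%d", keep$h)))
  vals <- res$states[, keep$id, drop = FALSE]
  colnames(vals) <- lab
  ll <- vapply(seq_along(res$times), function(r) {
    p <- tryCatch(state_params(crn, res$states[r, ], primed = TRUE,
                               alphabet = params0$alphabet, normalize = TRUE),
                  error = function(e) NULL)
    if (is.null(p)) NA_real_ else log_likelihood(p, seqs)
  }, numeric(1))
  tibble::as_tibble(cbind(tibble::tibble(time = res$times),
                          tibble::as_tibble(vals),
                          tibble::tibble(loglik = ll)))
}

make_scheme_result <- function(mode, crn, params, iterates, seqs, config,
                               boundary, converged, trajectory = NULL,
                               learn_traj = NULL, scheme_residual = NA_real_,
                               state = NULL) {
  bw_res <- fixed_point_residual(params, seqs)
  rate <- NA_real_
  if (!is.null(learn_traj) && length(learn_traj$times) >= 5) {
    lim <- learn_traj$values[nrow(learn_traj$values), ]
    resid <- apply(learn_traj$values, 1, function(z) max(abs(z - lim)))
    rate <- estimate_convergence_rate(resid, learn_traj$times)
  }
  if (!is.null(trajectory) && nrow(trajectory) >= 5) {
    pm <- as.matrix(trajectory[, setdiff(names(trajectory), c("time", "loglik"))])
    lim <- pm[nrow(pm), ]
    resid <- apply(pm, 1, function(z) max(abs(z - lim)))
    rate <- estimate_convergence_rate(resid, trajectory$time)
  }
  structure(list(mode = mode, params = params, iterates = iterates,
                 trajectory = trajectory, config = config, crn = crn,
                 state = state,
                 report = list(bw_residual = bw_res,
                               scheme_residual = scheme_residual,
                               convergence_rate = rate,
                               boundary = boundary,
                               converged = converged)),
            class = "bw_scheme")
}

#' @export
print.bw_scheme <- function(x, ...) {
  cat("Reaction network scheme ", toupper(x$mode), ": ",
      if (x$report$converged) "converged" else "stopped before convergence",
      if (x$report$boundary) " (boundary)" else "", "\n", sep = "")
  cat("residual under one discrete update: ", format(x$report$bw_residual), "\n",
      sep = "")
  print(x$params, ...)
  invisible(x)
}

#' Distance of a parameter point from being a Baum-Welch fixed point
#'
#' Applies one full discrete update (forward, backward, E, M) and returns
#' the max-abs difference to the input; zero iff the point is a fixed point.
#' Points outside the valid (no-division-by-zero) region give `Inf`.
#'
#' @param params An [hmm()] object.
#' @param seqs Observed sequence(s).
#' @param update_pi Include the initial distribution in the update.
#' @return Non-negative scalar (possibly `Inf`).
#' @export
fixed_point_residual <- function(params, seqs, update_pi = FALSE) {
  seqs <- as_seq_list(seqs, params$alphabet)
  upd <- tryCatch(bw_update(params, seqs, update_pi = update_pi),
                  error = function(e) NULL)
  if (is.null(upd)) return(Inf)
  param_distance(upd, params)
}

#' Exponential decay rate of a residual series
#'
#' Least-squares slope of `log(residual)` against time over the tail of the
#' series (the asymptotic regime). A converging exponential approach gives a
#' strictly negative rate; an (effectively) already-converged series returns
#' the sentinel `-Inf`.
#'
#' @param residuals Non-negative residual values.
#' @param times Matching time points.
#' @param tail_fraction Fraction of the series (from the end) used in the fit.
#' @param floor Residuals at or below this value count as converged.
#' @return The fitted decay rate (per unit time).
#' @export
estimate_convergence_rate <- function(residuals, times, tail_fraction = 0.5,
                                      floor = 1e-13) {
  stopifnot(length(residuals) == length(times))
  keep <- residuals > floor
  if (sum(keep) < 5) return(-Inf)
  r <- residuals[keep]; t <- times[keep]
  n <- length(r)
  from <- max(1L, ceiling(n * (1 - tail_fraction)))
  r <- r[from:n]; t <- t[from:n]
  if (length(unique(t)) < 2 || stats::sd(log(r)) == 0) return(-Inf)
  unname(stats::coef(stats::lm(log(r) ~ t))[2])
}

#' @export
glance.bw_scheme <- function(x, ...) {
  tibble::tibble(mode = x$mode,
                 converged = x$report$converged,
                 boundary = x$report$boundary,
                 bw_residual = x$report$bw_residual,
                 scheme_residual = x$report$scheme_residual,
                 convergence_rate = x$report$convergence_rate,
                 n_iter = if (is.null(x$iterates)) NA_integer_
                          else length(x$iterates) - 1L)
}

#' @export
tidy.bw_scheme <- function(x, ...) {
  if (!is.null(x$trajectory)) {
    return(tidyr::pivot_longer(x$trajectory, -"time",
                               names_to = "species", values_to = "concentration"))
  }
  purrr::imap_dfr(x$iterates, function(p, n) {
    tibble::tibble(iteration = n - 1L,
                   matrix = rep(c("theta", "psi"),
                                c(length(p$theta), length(p$psi))),
                   entry = c(sprintf("theta_%d%d", row(p$theta), col(p$theta)),
                             sprintf("psi_%d%d", row(p$psi), col(p$psi))),
                   value = c(as.vector(p$theta), as.vector(p$psi)))
  })
}

#' @export
autoplot.bw_scheme <- function(object, ...) {
  df <- tidy.bw_scheme(object)
  if (!is.null(object$trajectory)) {
    df <- df[df$species != "loglik", ]
    ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$concentration,
                                     colour = .data$species)) +
      ggplot2::geom_line() +
      ggplot2::labs(title = paste("Parameter species along the",
                                  toupper(object$mode), "trajectory"),
                    x = "time", y = "concentration")
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value,
                                     colour = .data$entry)) +
      ggplot2::geom_line() +
      ggplot2::labs(title = paste("Parameter iterates of", toupper(object$mode)),
                    x = "sweep", y = "value")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
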