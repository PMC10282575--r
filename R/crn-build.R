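#' Enumerate the species of the Baum-Welch reaction network
#'
#' Every quantity of the Baum-Welch algorithm is represented by its own
#' chemical species: `alpha[l,h]`, `beta[l,h]`, `gamma[l,h]`, `xi[l,g,h]`,
#' the parameter species `theta[g,h]`, `psi[h,w]`, `pi[h]`, their primed
#' (updated) copies, and the observation-encoding catalysts `E[l,w]`.
#' With several sequences, trellis and `E` species are duplicated per
#' sequence (prefix `s<i>_`) while parameter species are shared.
#'
#' @param n_hidden,n_visible State-space sizes (`n_hidden >= 2`).
#' @param seq_lengths Integer vector of sequence lengths (length = number of
#'   sequences), each `>= 2`.
#' @param learn_pi Include primed `pi` species (initial-distribution update)?
#' @return A tibble with one row per species: `id`, `name`, `role`, `i`
#'   (sequence), `l`, `g`, `h`, `w`.
#' @export
enumerate_species <- function(n_hidden, n_visible, seq_lengths, learn_pi = FALSE) {
  if (n_hidden < 2) stop("the network needs at least 2 hidden states", call. = FALSE)
  if (n_visible < 1) stop("the network needs at least 1 visible symbol", call. = FALSE)
  if (any(seq_lengths < 2)) stop("sequence lengths must be >= 2", call. = FALSE)
  multi <- length(seq_lengths) > 1
  pre <- function(i) if (multi) sprintf("s%d_", i) else ""
  rows <- list()
  add <- function(name, role, i = NA, l = NA, g = NA, h = NA, w = NA)
    rows[[length(rows) + 1L]] <<- list(name = name, role = role, i = i,
                                       l = l, g = g, h = h, w = w)
  for (i in seq_along(seq_lengths)) {
    L <- seq_lengths[i]
    for (l in 1:L) for (h in 1:n_hidden)
      add(sprintf("%salpha_%d_%d", pre(i), l, h), "alpha", i, l, h = h)
    for (l in 1:L) for (h in 1:n_hidden)
      add(sprintf("%sbeta_%d_%d", pre(i), l, h), "beta", i, l, h = h)
    for (l in 1:L) for (h in 1:n_hidden)
      add(sprintf("%sgamma_%d_%d", pre(i), l, h), "gamma", i, l, h = h)
    for (l in 1:(L - 1)) for (g in 1:n_hidden) for (h in 1:n_hidden)
      add(sprintf("%sxi_%d_%d_%d", pre(i), l, g, h), "xi", i, l, g, h)
    for (l in 1:L) for (w in 1:n_visible)
      add(sprintf("%sE_%d_%d", pre(i), l, w), "E", i, l, w = w)
  }
  for (g in 1:n_hidden) for (h in 1:n_hidden) {
    add(sprintf("theta_%d_%d", g, h), "theta", g = g, h = h)
  }
  for (g in 1:n_hidden) for (h in 1:n_hidden) {
    add(sprintf("thetap_%d_%d", g, h), "theta_p", g = g, h = h)
  }
  for (h in 1:n_hidden) for (w in 1:n_visible)
    add(sprintf("psi_%d_%d", h, w), "psi", h = h, w = w)
  for (h in 1:n_hidden) for (w in 1:n_visible)
    add(sprintf("psip_%d_%d", h, w), "psi_p", h = h, w = w)
  for (h in 1:n_hidden) add(sprintf("pi_%d", h), "pi", h = h)
  if (learn_pi) for (h in 1:n_hidden) add(sprintf("pip_%d", h), "pi_p", h = h)
  sp <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  sp$id <- seq_len(nrow(sp))
  dplyr::relocate(sp, "id")
}

#' Build the Baum-Welch reaction network
#'
#' Constructs the full catalytic mono-molecular network whose mass-action
#' equilibria reproduce the Baum-Welch quantities. Every reaction transforms
#' exactly one molecule of one species into one molecule of another; all
#' other participants are catalysts, repeated unchanged on both sides. Flow
#' within each subnetwork is routed through a hub species indexed by the
#' reference states `h_star` (hidden) and `v_star` (visible) - an arbitrary
#' symmetry-breaking choice that does not affect positive equilibria.
#' No-op reactions (transformed species equal to its own hub) are omitted,
#' as they have zero net effect.
#'
#' @param n_hidden,n_visible State-space sizes.
#' @param seq_lengths Integer vector of sequence lengths (one per sequence).
#' @param h_star Reference hidden state (hub index), in `1:n_hidden`.
#' @param v_star Reference visible symbol (emission hub), in `1:n_visible`.
#'   Pick a symbol that occurs in the observed data: all emission flow runs
#'   through the `v_star` hub, and an unobserved `v_star` freezes it.
#' @param learn_pi Emit the initial-distribution update reactions?
#' @return An object of class `"bw_crn"`: a list with `species` (tibble),
#'   `reactions` (tibble with `from`, `to`, `catalysts` list-column, `rate`,
#'   `part`, `l`, `i`, `subnetwork`), the dimensions, and the reference
#'   states.
#' @examples
#' net <- build_bw_network(2, 2, seq_lengths = 5)
#' net
#' @export
build_bw_network <- function(n_hidden, n_visible, seq_lengths,
                             h_star = 1L, v_star = 1L, learn_pi = FALSE) {
  h_star <- as.integer(h_star); v_star <- as.integer(v_star)
  if (!h_star %in% seq_len(n_hidden)) stop("h_star out of range", call. = FALSE)
  if (!v_star %in% seq_len(n_visible)) stop("v_star out of range", call. = FALSE)
  species <- enumerate_species(n_hidden, n_visible, seq_lengths, learn_pi)
  id_map <- stats::setNames(species$id, species$name)
  multi <- length(seq_lengths) > 1
  pre <- function(i) if (multi) sprintf("s%d_", i) else ""
  sid <- function(fmt, ...) id_map[[sprintf(fmt, ...)]]

  from <- integer(0); to <- integer(0); cats <- list()
  part <- character(0); lvec <- integer(0); ivec <- integer(0)
  emit <- function(f, t, cat_ids, p, l = NA_integer_, i = NA_integer_) {
    k <- length(from) + 1L
    from[k] <<- f; to[k] <<- t; cats[[k]] <<- as.integer(cat_ids)
    part[k] <<- p; lvec[k] <<- l; ivec[k] <<- i
  }
  hs <- h_star; vs <- v_star
  others <- setdiff(seq_len(n_hidden), hs)

  for (i in seq_along(seq_lengths)) {
    L <- seq_lengths[i]; P <- pre(i)
    # forward part: initialization subnetwork (l = 1) ...
    for (h in others) for (w in 1:n_visible) {
      emit(sid("%salpha_1_%d", P, h), sid("%salpha_1_%d", P, hs),
           c(sid("pi_%d", hs), sid("psi_%d_%d", hs, w), sid("%sE_1_%d", P, w)),
           "alpha", 1L, i)
      emit(sid("%salpha_1_%d", P, hs), sid("%salpha_1_%d", P, h),
           c(sid("pi_%d", h), sid("psi_%d_%d", h, w), sid("%sE_1_%d", P, w)),
           "alpha", 1L, i)
    }
    # ... and recursion subnetworks (producing position l+1)
    for (l in 1:(L - 1)) for (h in others) for (g in 1:n_hidden) for (w in 1:n_visible) {
      emit(sid("%salpha_%d_%d", P, l + 1, h), sid("%salpha_%d_%d", P, l + 1, hs),
           c(sid("%salpha_%d_%d", P, l, g), sid("theta_%d_%d", g, hs),
             sid("psi_%d_%d", hs, w), sid("%sE_%d_%d", P, l + 1, w)),
           "alpha", l + 1L, i)
      emit(sid("%salpha_%d_%d", P, l + 1, hs), sid("%salpha_%d_%d", P, l + 1, h),
           c(sid("%salpha_%d_%d", P, l, g), sid("theta_%d_%d", g, h),
             sid("psi_%d_%d", h, w), sid("%sE_%d_%d", P, l + 1, w)),
           "alpha", l + 1L, i)
    }
    # backward part
    for (l in 1:(L - 1)) for (h in others) for (g in 1:n_hidden) for (w in 1:n_visible) {
      emit(sid("%sbeta_%d_%d", P, l, h), sid("%sbeta_%d_%d", P, l, hs),
           c(sid("%sbeta_%d_%d", P, l + 1, g), sid("theta_%d_%d", hs, g),
             sid("psi_%d_%d", g, w), sid("%sE_%d_%d", P, l + 1, w)),
           "beta", l, i)
      emit(sid("%sbeta_%d_%d", P, l, hs), sid("%sbeta_%d_%d", P, l, h),
           c(sid("%sbeta_%d_%d", P, l + 1, g), sid("theta_%d_%d", h, g),
             sid("psi_%d_%d", g, w), sid("%sE_%d_%d", P, l + 1, w)),
           "beta", l, i)
    }
    # E-step, state posteriors (l up to L)
    for (l in 1:L) for (h in others) {
      emit(sid("%sgamma_%d_%d", P, l, h), sid("%sgamma_%d_%d", P, l, hs),
           c(sid("%salpha_%d_%d", P, l, hs), sid("%sbeta_%d_%d", P, l, hs)),
           "gamma", l, i)
      emit(sid("%sgamma_%d_%d", P, l, hs), sid("%sgamma_%d_%d", P, l, h),
           c(sid("%salpha_%d_%d", P, l, h), sid("%sbeta_%d_%d", P, l, h)),
           "gamma", l, i)
    }
    # E-step, transition posteriors, routed through the (h*, h*) hub
    for (l in 1:(L - 1)) for (g in 1:n_hidden) for (h in 1:n_hidden) {
      if (g == hs && h == hs) next
      for (w in 1:n_visible) {
        emit(sid("%sxi_%d_%d_%d", P, l, g, h), sid("%sxi_%d_%d_%d", P, l, hs, hs),
             c(sid("%salpha_%d_%d", P, l, hs), sid("theta_%d_%d", hs, hs),
               sid("%sbeta_%d_%d", P, l + 1, hs), sid("psi_%d_%d", hs, w),
               sid("%sE_%d_%d", P, l + 1, w)),
             "xi", l, i)
        emit(sid("%sxi_%d_%d_%d", P, l, hs, hs), sid("%sxi_%d_%d_%d", P, l, g, h),
             c(sid("%salpha_%d_%d", P, l, g), sid("theta_%d_%d", g, h),
               sid("%sbeta_%d_%d", P, l + 1, h), sid("psi_%d_%d", h, w),
               sid("%sE_%d_%d", P, l + 1, w)),
             "xi", l, i)
      }
    }
  }
  # M-step: transition update, catalysed by the xi species of every sequence
  for (i in seq_along(seq_lengths)) {
    L <- seq_lengths[i]; P <- pre(i)
    for (g in 1:n_hidden) for (h in others) for (l in 1:(L - 1)) {
      emit(sid("thetap_%d_%d", g, h), sid("thetap_%d_%d", g, hs),
           sid("%sxi_%d_%d_%d", P, l, g, hs), "theta", NA_integer_, i)
      emit(sid("thetap_%d_%d", g, hs), sid("thetap_%d_%d", g, h),
           sid("%sxi_%d_%d_%d", P, l, g, h), "theta", NA_integer_, i)
    }
  }
  # M-step: emission update through the v* hub
  for (i in seq_along(seq_lengths)) {
    L <- seq_lengths[i]; P <- pre(i)
    for (h in 1:n_hidden) for (w in setdiff(seq_len(n_visible), vs)) for (l in 1:L) {
      emit(sid("psip_%d_%d", h, w), sid("psip_%d_%d", h, vs),
           c(sid("%sgamma_%d_%d", P, l, h), sid("%sE_%d_%d", P, l, vs)),
           "psi", NA_integer_, i)
      emit(sid("psip_%d_%d", h, vs), sid("psip_%d_%d", h, w),
           c(sid("%sgamma_%d_%d", P, l, h), sid("%sE_%d_%d", P, l, w)),
           "psi", NA_integer_, i)
    }
  }
  # M-step: initial-distribution update from the position-1 posteriors
  if (learn_pi) for (i in seq_along(seq_lengths)) {
    P <- pre(i)
    for (g in others) {
      emit(sid("pip_%d", g), sid("pip_%d", hs), sid("%sgamma_1_%d", P, hs),
           "pi", NA_integer_, i)
      emit(sid("pip_%d", hs), sid("pip_%d", g), sid("%sgamma_1_%d", P, g),
           "pi", NA_integer_, i)
    }
  }

  reactions <- tibble::tibble(
    from = from, to = to, catalysts = cats, rate = 1,
    part = part, l = lvec, i = ivec,
    subnetwork = ifelse(part %in% c("theta", "psi", "pi"),
                        paste0("R", part),
                        paste0(ifelse(rep(multi, length(part)),
                                      sprintf("s%d:", ivec), ""),
                               "R", lvec, part)))
  structure(list(species = species,
                 reactions = reactions,
                 n_hidden = n_hidden, n_visible = n_visible,
                 seq_lengths = as.integer(seq_lengths),
                 h_star = hs, v_star = vs, learn_pi = learn_pi),
            class = "bw_crn")
}

#' @export
print.bw_crn <- function(x, ...) {
  cat("Baum-Welch reaction network: |H| = ", x$n_hidden, ", |V| = ", x$n_visible,
      ", L = ", paste(x$seq_lengths, collapse = ", "),
      if (x$learn_pi) ", learning pi" else "", "\n", sep = "")
  cat(nrow(x$species), " species, ", nrow(x$reactions), " reactions, ",
      length(unique(x$reactions$subnetwork)), " subnetworks\n", sep = "")
  cat("reference states: h* = H", x$h_star, ", v* = v", x$v_star, "\n", sep = "")
  invisible(x)
}

#' Species ids of a given role
#'
#' @param crn A [build_bw_network()] object.
#' @param role One of `"alpha"`, `"beta"`, `"gamma"`, `"xi"`, `"theta"`,
#'   `"theta_p"`, `"psi"`, `"psi_p"`, `"pi"`, `"pi_p"`, `"E"`.
#' @param i Optional sequence index filter.
#' @return Integer vector of species ids.
#' @export
species_ids <- function(crn, role, i = NULL) {
  sp <- crn$species
  keep <- sp$role == role
  if (!is.null(i)) keep <- keep & sp$i %in% i
  sp$id[keep]
}

#' Observation-encoding concentrations
#'
#' The indicator catalysts `E[l,w]` carry the observed sequence into the
#' network: `E[l,w] = 1` when symbol `w` is observed at position `l` and 0
#' otherwise. They take part in reactions only as catalysts, so these
#' concentrations stay fixed for all time, and one network serves every
#' sequence of the same length.
#'
#' @param crn A [build_bw_network()] object.
#' @param seqs A sequence or list of sequences, lengths matching the network.
#' @param alphabet Optional alphabet for character input.
#' @return A named numeric vector over the `E` species.
#' @export
encode_observations <- function(crn, seqs, alphabet = NULL) {
  seqs <- as_seq_list(seqs, alphabet)
  if (length(seqs) != length(crn$seq_lengths))
    stop("expected ", length(crn$seq_lengths), " sequence(s)", call. = FALSE)
  sp <- crn$species[crn$species$role == "E", ]
  out <- stats::setNames(numeric(nrow(sp)), sp$name)
  for (k in seq_len(nrow(sp))) {
    i <- sp$i[k]
    v <- unclass(seqs[[i]])
    if (length(v) != crn$seq_lengths[i])
      stop("sequence ", i, " has length ", length(v), ", network expects ",
           crn$seq_lengths[i], call. = FALSE)
    if (max(v) > crn$n_visible)
      stop("sequence symbols exceed the network alphabet", call. = FALSE)
    out[k] <- as.numeric(v[sp$l[k]] == sp$w[k])
  }
  out
}

#' Conserved classes of the network
#'
#' The one-molecule-in, one-molecule-out design conserves the total
#' concentration within each position row of the trellis species
#' (`alpha[l,]`, `beta[l,]`, `gamma[l,]`, the `xi[l,,]` slice) and within
#' each row of the primed parameter matrices. Catalyst-only species
#' (`theta`, `psi`, `pi`, `E`) are constant individually.
#'
#' @param crn A [build_bw_network()] object.
#' @return A tibble with one row per class: `class` (label), `role`, `i`,
#'   `l`, `row`, and a `species` list-column of member ids.
#' @export
conserved_classes <- function(crn) {
  sp <- crn$species
  dyn <- sp[!sp$role %in% c("theta", "psi", "pi", "E"), ]
  key <- character(nrow(dyn)); row <- rep(NA_integer_, nrow(dyn))
  trellis <- dyn$role %in% c("alpha", "beta", "gamma", "xi")
  key[trellis] <- sprintf("s%d_%s_%d", dyn$i[trellis], dyn$role[trellis], dyn$l[trellis])
  key[dyn$role == "theta_p"] <- sprintf("thetap_row%d", dyn$g[dyn$role == "theta_p"])
  row[dyn$role == "theta_p"] <- dyn$g[dyn$role == "theta_p"]
  key[dyn$role == "psi_p"] <- sprintf("psip_row%d", dyn$h[dyn$role == "psi_p"])
  row[dyn$role == "psi_p"] <- dyn$h[dyn$role == "psi_p"]
  key[dyn$role == "pi_p"] <- "pip"
  out <- dyn |>
    dplyr::mutate(class = key, row = row) |>
    dplyr::group_by(.data$class, .data$role, .data$i, .data$l, .data$row) |>
    dplyr::summarise(species = list(.data$id), .groups = "drop")
  out[order(vapply(out$species, min, integer(1))), ]
}

#' Totals of the conserved classes at a given state
#'
#' @param crn A [build_bw_network()] object.
#' @param state Full concentration vector over `crn$species`.
#' @return The [conserved_classes()] tibble with a `total` column added.
#' @export
class_totals <- function(crn, state) {
  cl <- conserved_classes(crn)
  cl$total <- vapply(cl$species, function(ids) sum(state[ids]), numeric(1))
  cl
}
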