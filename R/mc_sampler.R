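#' Annealing schedule
#'
#' One inner cycle of simulated annealing: `n_low` steps at `beta_low`,
#' `n_ramp` steps of linear beta increase, `n_high` steps at `beta_high`.
#' The defaults (50/100/250) make the canonical 400-step inner cycle.
#'
#' @param n_low,n_ramp,n_high step counts (must sum to the inner-cycle
#'   length).
#' @param beta_low,beta_high inverse temperatures (`beta_low < beta_high`).
#' @return object of class `annealing_schedule`.
#' @export
annealing_schedule <- function(n_low = 50, n_ramp = 100, n_high = 250,
                               beta_low = 0.2, beta_high = 1.0) {
  stopifnot(n_low >= 0, n_ramp >= 0, n_high >= 0, beta_low < beta_high)
  structure(list(n_low = n_low, n_ramp = n_ramp, n_high = n_high,
                 beta_low = beta_low, beta_high = beta_high),
            class = "annealing_schedule")
}

#' Beta sequence of one inner cycle
#'
#' @param schedule an [annealing_schedule()].
#' @return numeric vector of length `n_low + n_ramp + n_high`.
#' @export
beta_cycle <- function(schedule) {
  ramp <- if (schedule$n_ramp > 0)
    seq(schedule$beta_low, schedule$beta_high,
        length.out = schedule$n_ramp + 2)[-c(1, schedule$n_ramp + 2)]
  else numeric(0)
  c(rep(schedule$beta_low, schedule$n_low), ramp,
    rep(schedule$beta_high, schedule$n_high))
}

#' Monte Carlo configuration
#'
#' @param seed integer RNG seed; one seed reproduces an entire ensemble.
#' @param relaxation_steps initial relaxation length in the full potential
#'   (default 12000).
#' @param inner_cycle_steps annealing steps per decoy (default 400).
#' @param schedule an [annealing_schedule()]; its lengths must sum to
#'   `inner_cycle_steps`.
#' @param move_weights proposal probabilities for crankshaft/bond/angle
#'   moves (must sum to 1).
#' @param max_rot maximum rotation per move, radians.
#' @param max_trans maximum translation per bond move, Angstrom.
#' @param crank_span allowed crankshaft segment spans `j - i` (inclusive
#'   range, default 2 to 4).
#' @return object of class `mc_config`.
#' @export
mc_config <- function(seed = 1, relaxation_steps = 12000,
                      inner_cycle_steps = 400,
                      schedule = annealing_schedule(),
                      move_weights = c(crankshaft = 0.5, bond = 0.25,
                                       angle = 0.25),
                      max_rot = 0.5, max_trans = 0.2,
                      crank_span = c(2, 4)) {
  stopifnot(abs(sum(move_weights) - 1) < 1e-9, length(move_weights) == 3)
  if (schedule$n_low + schedule$n_ramp + schedule$n_high != inner_cycle_steps)
    stop("annealing schedule lengths must sum to inner_cycle_steps")
  structure(list(seed = seed, relaxation_steps = relaxation_steps,
                 inner_cycle_steps = inner_cycle_steps, schedule = schedule,
                 move_weights = move_weights, max_rot = max_rot,
                 max_trans = max_trans, crank_span = crank_span),
            class = "mc_config")
}

## flatten params + alphabet for the C++ kernel
.pack_params <- function(chain, alphabet, params) {
  P <- params$letters
  list(letters = cbind(P$theta0_1, P$theta0_2, P$tau0, P$k_theta, P$k_tau,
                       P$e_ref),
       e_ref2 = params$e_ref2,
       prototypes = alphabet$prototypes,
       bond_r0 = .bond_r0(chain, params),
       bond_k = params$bond$k,
       r_rep = params$steric$r_rep,
       k_rep = params$steric$k_rep,
       min_sep = as.integer(params$steric$min_sep),
       hb_edges = params$hbond$edges,
       hb_values = params$hbond$values,
       pn_offset = params$pseudo$n_offset,
       po_offset = params$pseudo$o_offset,
       mix_angle = params$pseudo$mix_angle)
}

## enumerate eligible moves given the mobility mask
.move_tables <- function(chain, crank_span = c(2, 4)) {
  n <- length(chain)
  mob <- chain$mobile
  cranks <- NULL
  for (s in crank_span[1]:crank_span[2]) {
    i <- seq_len(max(0, n - s))
    if (!length(i)) next
    ok <- vapply(i, function(a) all(mob[(a + 1):(a + s - 1)]), TRUE)
    if (any(ok)) cranks <- rbind(cranks, cbind(i[ok], i[ok] + s))
  }
  if (is.null(cranks)) cranks <- matrix(0L, 0, 2)
  storage.mode(cranks) <- "integer"
  bonds <- which(mob[-n] & mob[-1])
  centres <- if (n >= 3) {
    i <- 2:(n - 1)
    i[mob[i - 1] & mob[i + 1]]
  } else integer(0)
  list(cranks = cranks, bonds = as.integer(bonds),
       angles = as.integer(centres))
}

#' Crankshaft move
#'
#' Rotates the interior atoms `i+1 .. j-1` about the axis through
#' `Ca_i -> Ca_j`; the endpoint atoms do not move, so the bonds entering
#' the segment are preserved exactly and loop closure is maintained by
#' construction.
#'
#' @param chain a [ca_chain()].
#' @param i,j segment endpoints (`i < j`; interior residues must all be
#'   mobile).
#' @param angle rotation angle in radians.
#' @return proposal list `chain`, `moved` (indices), `log_jacobian` (0:
#'   rigid rotations preserve Cartesian volume), or NULL when the axis is
#'   degenerate (move invalid).
#' @export
crankshaft_move <- function(chain, i, j, angle) {
  stopifnot(i < j, j <= length(chain))
  interior <- (i + 1):(j - 1)
  if (!all(chain$mobile[interior]))
    stop("crankshaft interior atoms must all be mobile")
  axis <- chain$xyz[j, ] - chain$xyz[i, ]
  if (vnorm(axis) < 1e-6) return(NULL)
  chain$xyz[interior, ] <- rotate_about_axis(
    chain$xyz[interior, , drop = FALSE], chain$xyz[i, ], axis, angle)
  list(chain = chain, moved = interior, log_jacobian = 0)
}

#' Bond move
#'
#' Moves `Ca_i` and `Ca_(i+1)` by equal amounts in opposite directions
#' along their bond vector, changing the bond length by exactly
#' `2 * delta` and leaving the midpoint untouched.
#'
#' @param chain a [ca_chain()].
#' @param i bond index (residues i and i+1 must be mobile).
#' @param delta displacement per atom, Angstrom.
#' @return proposal list as in [crankshaft_move()]; `log_jacobian` is
#'   `2 log(r'/r)`, the Cartesian volume factor of the radial map. NULL
#'   when the bond has (near-)zero length.
#' @export
bond_move <- function(chain, i, delta) {
  stopifnot(i >= 1, i < length(chain))
  if (!all(chain$mobile[c(i, i + 1)]))
    stop("bond move requires both residues mobile")
  bv <- chain$xyz[i + 1, ] - chain$xyz[i, ]
  r <- vnorm(bv)
  rnew <- r + 2 * delta
  if (r < 1e-9 || rnew <= 1e-3) return(NULL)
  u <- bv / r
  chain$xyz[i, ] <- chain$xyz[i, ] - delta * u
  chain$xyz[i + 1, ] <- chain$xyz[i + 1, ] + delta * u
  list(chain = chain, moved = c(i, i + 1), log_jacobian = 2 * log(rnew / r))
}

#' Angle move
#'
#' Rotates `Ca_(i-1)` and `Ca_(i+1)` about the axis through `Ca_i` normal
#' to the plane of the three atoms, by `+angle` and `-angle`: both bond
#' lengths are preserved and the pseudo bond angle at i changes by
#' `2 * angle` (up to range clamping at 0 and pi).
#'
#' @param chain a [ca_chain()].
#' @param i centre residue (`i-1` and `i+1` must be mobile; the centre may
#'   be an anchor since it does not move).
#' @param angle half-change of the bond angle, radians.
#' @return proposal list as in [crankshaft_move()]; `log_jacobian` is
#'   `log(sin(theta')/sin(theta))`, the angular volume factor. NULL when
#'   the triple is collinear (axis undefined).
#' @export
angle_move <- function(chain, i, angle) {
  n <- length(chain)
  stopifnot(i >= 2, i <= n - 1)
  if (!all(chain$mobile[c(i - 1, i + 1)]))
    stop("angle move requires residues i-1 and i+1 mobile")
  u1 <- chain$xyz[i - 1, ] - chain$xyz[i, ]
  u2 <- chain$xyz[i + 1, ] - chain$xyz[i, ]
  nrm <- vcross(u1, u2)
  if (vnorm(nrm) < 1e-9) return(NULL)
  th0 <- angle_points(chain$xyz[i - 1, ], chain$xyz[i, ], chain$xyz[i + 1, ])
  chain$xyz[i - 1, ] <- rotate_about_axis(rbind(chain$xyz[i - 1, ]),
                                          chain$xyz[i, ], nrm, angle)
  chain$xyz[i + 1, ] <- rotate_about_axis(rbind(chain$xyz[i + 1, ]),
                                          chain$xyz[i, ], nrm, -angle)
  th1 <- angle_points(chain$xyz[i - 1, ], chain$xyz[i, ], chain$xyz[i + 1, ])
  list(chain = chain, moved = c(i - 1, i + 1),
       log_jacobian = log(max(sin(th1), 1e-12)) - log(max(sin(th0), 1e-12)))
}

#' Monte Carlo state
#'
#' Bundles the chain, its current (mobile-relevant) energy and the
#' per-move-type acceptance counters.
#'
#' @param chain a [ca_chain()].
#' @param alphabet an [alphabet_model()].
#' @param params a [cg_params()].
#' @return object of class `mc_state`.
#' @export
mc_state <- function(chain, alphabet = default_alphabet(),
                     params = default_cg_params()) {
  packed <- .pack_params(chain, alphabet, params)
  e <- .pd2_energy_cpp(chain$xyz, chain$mobile, packed)
  structure(list(chain = chain, alphabet = alphabet, params = params,
                 packed = packed, energy = e,
                 accepted = c(crankshaft = 0, bond = 0, angle = 0),
                 rejected = c(crankshaft = 0, bond = 0, angle = 0),
                 steps = 0),
            class = "mc_state")
}

#' One Metropolis step
#'
#' Evaluates the proposal's energy change incrementally (only the terms
#' touched by the moved atoms are recomputed) and accepts with probability
#' `min(1, exp(-beta dE + log_jacobian))`. Non-finite energy changes are
#' rejected and logged.
#'
#' @param state an [mc_state()].
#' @param beta inverse temperature.
#' @param proposal a proposal from [crankshaft_move()], [bond_move()] or
#'   [angle_move()] (NULL proposals — invalid moves — are rejected).
#' @param type move-type label for the counters.
#' @return list `state` (updated) and `accept` (logical).
#' @export
metropolis_step <- function(state, beta, proposal, type = "crankshaft") {
  state$steps <- state$steps + 1
  if (is.null(proposal)) {
    state$rejected[type] <- state$rejected[type] + 1
    return(list(state = state, accept = FALSE))
  }
  de <- .pd2_delta_energy_cpp(state$chain$xyz, as.integer(proposal$moved),
                              proposal$chain$xyz[proposal$moved, , drop = FALSE],
                              state$chain$mobile, state$packed)
  if (!is.finite(de)) {
    warning("non-finite energy change: move rejected")
    state$rejected[type] <- state$rejected[type] + 1
    return(list(state = state, accept = FALSE))
  }
  logr <- -beta * de + proposal$log_jacobian
  accept <- logr >= 0 || stats::runif(1) < exp(logr)
  if (accept) {
    state$chain <- proposal$chain
    state$energy$total <- state$energy$total + de
    state$accepted[type] <- state$accepted[type] + 1
  } else {
    state$rejected[type] <- state$rejected[type] + 1
  }
  list(state = state, accept = accept)
}

#' Initialise a loop on the anchor-anchor segment
#'
#' Places the mobile C-alpha atoms at equal spacing on the straight
#' segment between the two anchors, displaces each by a uniform random
#' vector in a ball, then minimises under the pseudo-bond + steric terms
#' until the gradient norm drops below `tol`.
#'
#' @param chain a [ca_chain()] whose mobility mask marks the loop.
#' @param params a [cg_params()].
#' @param displacement radius of the random displacement ball (Angstrom,
#'   default 0.5; 0 gives the deterministic interpolation).
#' @param tol gradient-norm tolerance of the initial minimisation.
#' @param max_iter minimiser iteration cap.
#' @return the chain with the loop initialised (anchors untouched).
#' @export
init_loop <- function(chain, params = default_cg_params(),
                      displacement = 0.5, tol = 1e-3, max_iter = 1000) {
  mob <- which(chain$mobile)
  if (!length(mob)) stop("no mobile residues to initialise")
  if (any(diff(mob) != 1)) stop("mobile region must be contiguous")
  a1 <- min(mob) - 1
  a2 <- max(mob) + 1
  if (a1 < 1 || a2 > length(chain)) stop("loop lacks a flanking anchor")
  p1 <- chain$xyz[a1, ]; p2 <- chain$xyz[a2, ]
  if (vnorm(p2 - p1) < 1e-6) stop("anchor residues coincide")
  m <- length(mob)
  t <- seq_len(m) / (m + 1)
  pos <- outer(1 - t, p1) + outer(t, p2)
  if (displacement > 0) {
    dir <- matrix(stats::rnorm(3 * m), m, 3)
    dir <- dir / rownorm(dir)
    rad <- displacement * stats::runif(m)^(1 / 3)
    pos <- pos + rad * dir
  }
  chain$xyz[mob, ] <- pos
  minimize_ca(chain, params, terms = c("bond", "steric"),
              tol = tol, max_iter = max_iter)
}

#' Run Monte Carlo simulated annealing
#'
#' Executes `n_steps` Metropolis steps with the inverse temperature
#' following the repeating annealing schedule of `config`. Anchors and
#' scaffold never move (they are never proposed as displaced atoms).
#' The move set, energies and acceptance rule run in compiled code; the
#' stored energy is drift-checked against a full recomputation every 1000
#' steps.
#'
#' @param chain a [ca_chain()] with its mobility mask set.
#' @param config an [mc_config()].
#' @param alphabet an [alphabet_model()].
#' @param params a [cg_params()].
#' @param n_steps total steps (default: one inner cycle).
#' @param record_stride if > 0, record mobile coordinates every this many
#'   steps (matrix `samples`).
#' @param trace_stride if > 0, record (step, beta, total energy) every
#'   this many steps.
#' @param beta_override optional explicit beta vector (overrides the
#'   schedule; length defines `n_steps`).
#' @return list `chain` (final), `energy` (breakdown over mobile-relevant
#'   terms), `accepted`, `proposed`, `invalid`, `drift_max`, `samples`,
#'   `trace`.
#' @export
anneal <- function(chain, config = mc_config(),
                   alphabet = default_alphabet(),
                   params = default_cg_params(),
                   n_steps = NULL, record_stride = 0, trace_stride = 0,
                   beta_override = NULL) {
  beta <- if (!is.null(beta_override)) beta_override else {
    if (is.null(n_steps)) n_steps <- config$inner_cycle_steps
    cyc <- beta_cycle(config$schedule)
    rep(cyc, length.out = n_steps)
  }
  tabs <- .move_tables(chain, config$crank_span)
  packed <- .pack_params(chain, alphabet, params)
  res <- .pd2_run_mc_cpp(chain$xyz, chain$mobile, tabs$cranks, tabs$bonds,
                         tabs$angles, as.numeric(config$move_weights),
                         config$max_rot, config$max_trans, beta, packed,
                         as.integer(record_stride), as.integer(trace_stride),
                         1000L)
  out_chain <- chain
  out_chain$xyz <- res$coords
  list(chain = out_chain, energy = res$energy,
       accepted = stats::setNames(res$accepted, c("crankshaft", "bond", "angle")),
       proposed = stats::setNames(res$proposed, c("crankshaft", "bond", "angle")),
       invalid = res$invalid, drift_max = res$drift_max,
       samples = res$samples, trace = res$trace)
}
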