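toy_loop <- function(D = 7.6, mobile = c(FALSE, TRUE, TRUE, FALSE)) {
  dx <- D / 3; dy <- sqrt(3.8^2 - dx^2)
  chain_from(rbind(c(0, 0, 0), c(dx, dy, 0), c(2 * dx, 0, 0), c(D, 0, 0)),
             mobile = mobile)
}

test_that("annealing schedule and config enforce their invariants", {
  s <- annealing_schedule()
  b <- beta_cycle(s)
  expect_length(b, 400)
  expect_equal(sum(b == s$beta_low), 50)
  expect_equal(sum(b == s$beta_high), 250)
  ramp <- b[51:150]
  expect_true(all(diff(ramp) > 0))
  expect_error(annealing_schedule(beta_low = 2, beta_high = 1), "beta_low")
  expect_error(mc_config(inner_cycle_steps = 300), "must sum")
  expect_error(mc_config(move_weights = c(0.5, 0.5, 0.5)), "sum")
})

test_that("crankshaft moves rotate only the interior and preserve end distances", {
  ch <- random_chain(8, seed = 1)
  p <- crankshaft_move(ch, 2, 6, 0.7)
  expect_identical(p$moved, 3:5)
  ## atoms outside [i, j] untouched, endpoints untouched
  expect_identical(p$chain$xyz[c(1, 2, 6, 7, 8), ], ch$xyz[c(1, 2, 6, 7, 8), ])
  ## distances from rotated atoms to both axis endpoints preserved
  for (k in 3:5) {
    expect_equal(sqrt(sum((p$chain$xyz[k, ] - ch$xyz[2, ])^2)),
                 sqrt(sum((ch$xyz[k, ] - ch$xyz[2, ])^2)), tolerance = 1e-9)
    expect_equal(sqrt(sum((p$chain$xyz[k, ] - ch$xyz[6, ])^2)),
                 sqrt(sum((ch$xyz[k, ] - ch$xyz[6, ])^2)), tolerance = 1e-9)
  }
  ## identity and 2*pi periodicity
  expect_equal(crankshaft_move(ch, 2, 6, 0)$chain$xyz, ch$xyz)
  expect_equal(crankshaft_move(ch, 2, 6, 2 * pi)$chain$xyz, ch$xyz,
               tolerance = 1e-9)
  ## degenerate axis is an invalid (NULL) proposal
  dg <- ch; dg$xyz[6, ] <- dg$xyz[2, ]
  expect_null(crankshaft_move(dg, 2, 6, 0.5))
  ## inverse under negated angle
  p2 <- crankshaft_move(p$chain, 2, 6, -0.7)
  expect_equal(p2$chain$xyz, ch$xyz, tolerance = 1e-12)
})

test_that("bond moves change one bond by exactly 2 delta about a fixed midpoint", {
  ch <- random_chain(6, seed = 2)
  r0 <- sqrt(sum((ch$xyz[4, ] - ch$xyz[3, ])^2))
  p <- bond_move(ch, 3, 0.1)
  expect_identical(p$moved, c(3, 4))
  expect_equal(sqrt(sum((p$chain$xyz[4, ] - p$chain$xyz[3, ])^2)), r0 + 0.2,
               tolerance = 1e-12)
  expect_identical(p$chain$xyz[c(1, 2, 5, 6), ], ch$xyz[c(1, 2, 5, 6), ])
  expect_equal((p$chain$xyz[3, ] + p$chain$xyz[4, ]) / 2,
               (ch$xyz[3, ] + ch$xyz[4, ]) / 2, tolerance = 1e-12)
  expect_equal(bond_move(ch, 3, 0)$chain$xyz, ch$xyz)
  expect_equal(p$log_jacobian, 2 * log((r0 + 0.2) / r0), tolerance = 1e-12)
  ## inverse under negated delta
  p2 <- bond_move(p$chain, 3, -0.1)
  expect_equal(p2$chain$xyz, ch$xyz, tolerance = 1e-12)
})

test_that("angle moves preserve bond lengths and change the angle by 2a", {
  ch <- chain_from(rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 3.8)))
  th0 <- pseudo_bond_angle(ch, 2)
  p <- angle_move(ch, 2, 0.1)
  expect_identical(sort(p$moved), c(1, 3))
  expect_equal(sqrt(sum((p$chain$xyz[1, ] - p$chain$xyz[2, ])^2)), 1,
               tolerance = 1e-9)
  expect_equal(sqrt(sum((p$chain$xyz[3, ] - p$chain$xyz[2, ])^2)), 1,
               tolerance = 1e-9)
  expect_equal(pseudo_bond_angle(p$chain, 2), th0 + 0.2, tolerance = 1e-9)
  ## locality: other atoms unchanged
  expect_identical(p$chain$xyz[c(2, 4), ], ch$xyz[c(2, 4), ])
  expect_equal(angle_move(ch, 2, 0)$chain$xyz, ch$xyz)
  ## collinear triple has no defined rotation plane
  coll <- chain_from(rbind(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_null(angle_move(coll, 2, 0.1))
  ## inverse under negated angle
  p2 <- angle_move(p$chain, 2, -0.1)
  expect_equal(p2$chain$xyz, ch$xyz, tolerance = 1e-12)
})

test_that("metropolis always accepts downhill and tracks counters", {
  ch <- toy_loop()
  A <- random_alphabet(2, seed = 3)
  P <- bond_only_params()
  st <- mc_state(ch, A, P)
  ## a proposal that relaxes a stretched bond is always accepted
  stretch <- bond_move(ch, 2, 0.3)  # raises energy
  relax <- bond_move(stretch$chain, 2, -0.3)
  st2 <- mc_state(stretch$chain, A, P)
  out <- metropolis_step(st2, beta = 5, relax, type = "bond")
  expect_true(out$accept)
  expect_equal(out$state$accepted[["bond"]], 1)
  ## NULL proposals are rejected and counted
  out2 <- metropolis_step(st, 1, NULL, type = "crankshaft")
  expect_false(out2$accept)
  expect_equal(out2$state$rejected[["crankshaft"]], 1)
})

test_that("acceptance probability is exactly exp(-beta dE) for uphill moves", {
  ## two-atom system, bond term only: craft a proposal with dE = ln 2 / beta
  beta <- 1
  P <- bond_only_params()
  A <- random_alphabet(2, seed = 4)
  delta <- sqrt(2 * log(2) / (beta * P$bond$k))
  ch <- chain_from(rbind(c(0, 0, 0), c(P$bond$r0, 0, 0)))
  prop_chain <- ch
  prop_chain$xyz[2, 1] <- prop_chain$xyz[2, 1] + delta
  proposal <- list(chain = prop_chain, moved = 2L, log_jacobian = 0)
  st <- mc_state(ch, A, P)
  set.seed(99)
  n <- 1e5
  acc <- 0L
  for (i in seq_len(n)) {
    out <- metropolis_step(st, beta, proposal)
    acc <- acc + out$accept
  }
  ## dE = k/2 delta^2 = ln 2, so P(accept) = 1/2; 3 sigma binomial window
  expect_lt(abs(acc / n - 0.5), 3 * sqrt(0.25 / n))
})

test_that("incremental energy differences equal full recomputation", {
  A <- random_alphabet(5, seed = 5)
  P <- random_params(5, seed = 5)
  ch <- random_chain(12, seed = 6)
  st <- mc_state(ch, A, P)
  set.seed(7)
  maxd <- 0
  for (t in 1:1000) {
    type <- sample(3, 1)
    p <- switch(type,
                crankshaft_move(st$chain, 3, 6, runif(1, -0.5, 0.5)),
                bond_move(st$chain, sample(11, 1), runif(1, -0.2, 0.2)),
                angle_move(st$chain, sample(2:11, 1), runif(1, -0.3, 0.3)))
    if (is.null(p)) next
    de <- pd2loop:::.pd2_delta_energy_cpp(
      st$chain$xyz, as.integer(p$moved),
      p$chain$xyz[p$moved, , drop = FALSE], st$chain$mobile, st$packed)
    de_full <- total_cg_energy(p$chain, A, P)$total -
      total_cg_energy(st$chain, A, P)$total
    maxd <- max(maxd, abs(de - de_full))
    out <- metropolis_step(st, 0.5, p)
    st <- out$state
  }
  expect_lt(maxd, 1e-8)
  ## stored energy has not drifted from a full recomputation
  fresh <- pd2loop:::.pd2_energy_cpp(st$chain$xyz, st$chain$mobile, st$packed)
  expect_equal(st$energy$total, fresh$total, tolerance = 1e-6)
})

test_that("init_loop spaces mobile atoms and never moves anchors", {
  fx <- hth_fixture(6, seed = 8)
  ch <- set_mobile_region(fx$ca, fx$regions[[1]])
  P <- bond_only_params()
  set.seed(1)
  out <- init_loop(ch, P, displacement = 0)
  idx <- which(ch$mobile)
  expect_identical(out$xyz[!ch$mobile, ], ch$xyz[!ch$mobile, ])
  ## bond-term-only minimisation from the symmetric start: uniform bonds
  seg <- c(min(idx) - 1, idx, max(idx) + 1)
  bonds <- sqrt(rowSums(diff(out$xyz[seg, ])^2))
  expect_lt(max(bonds) - min(bonds), 1e-3)
  ## anchors exactly (m + 1) r0 apart: interpolation is already optimal
  m <- 4
  ids <- res_ids(m + 2)
  straight <- ca_chain(ids, cbind(seq(0, by = 3.8, length.out = m + 2), 0, 0),
                       mobile = c(FALSE, rep(TRUE, m), FALSE))
  init0 <- straight
  init0$xyz[2:(m + 1), ] <- 0  # scramble the loop; init_loop must restore
  res <- init_loop(init0, P, displacement = 0)
  expect_lt(max(abs(res$xyz - straight$xyz)), 1e-3)
  ## same seed, same initial loop
  set.seed(42); a <- init_loop(ch, P)
  set.seed(42); b <- init_loop(ch, P)
  expect_identical(a$xyz, b$xyz)
  ## coincident anchors are an error
  bad <- ch; bad$xyz[max(idx) + 1, ] <- bad$xyz[min(idx) - 1, ]
  expect_error(init_loop(bad, P), "coincide")
})

test_that("anneal keeps immobile atoms bit-identical over long mixed-move runs", {
  fx <- hth_fixture(8, seed = 9)
  ch <- set_mobile_region(fx$ca, fx$regions[[1]])
  set.seed(2)
  ch <- init_loop(ch)
  run <- anneal(ch, mc_config(seed = 3), n_steps = 1e5)
  fixed <- !ch$mobile
  expect_identical(run$chain$xyz[fixed, ], ch$xyz[fixed, ])
  expect_true(all(run$proposed > 0))
  expect_lt(run$drift_max, 1e-6)
})

test_that("default inner cycle is 400 steps partitioned 50/100/250", {
  cfg <- mc_config()
  expect_equal(cfg$relaxation_steps, 12000)
  expect_equal(cfg$inner_cycle_steps, 400)
  expect_equal(cfg$schedule$n_low + cfg$schedule$n_ramp + cfg$schedule$n_high,
               400)
  fx <- hth_fixture(4, seed = 10)
  ch <- set_mobile_region(fx$ca, fx$regions[[1]])
  set.seed(4)
  run <- anneal(ch, cfg, trace_stride = 1)
  expect_equal(nrow(run$trace), 400)
  expect_equal(sum(run$trace[, 2] == cfg$schedule$beta_low), 50)
  expect_equal(sum(run$trace[, 2] == cfg$schedule$beta_high), 250)
})
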