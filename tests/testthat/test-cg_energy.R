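test_that("each term matches closed forms on constructed inputs", {
  P <- bond_only_params()
  ## all bonds at r0: zero; one bond stretched 1 A: k/2
  straight <- chain_from(cbind(seq(0, by = 3.8, length.out = 5), 0, 0))
  expect_equal(e_bond(straight, P), 0)
  stretched <- straight
  stretched$xyz[5, 1] <- stretched$xyz[5, 1] + 1
  expect_equal(e_bond(stretched, P), 0.5 * P$bond$k)
  ## steric: pair at r_rep - 0.5
  P2 <- random_params()
  far <- chain_from(cbind(seq(0, by = 6, length.out = 5), 0, 0))
  expect_equal(e_steric(far, P2), 0)
  sq <- chain_from(rbind(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0),
                         c(0, 3.8, 0), c(P2$steric$r_rep - 0.5, 3.8, 3.8)))
  d15 <- sqrt(sum((sq$xyz[5, ] - sq$xyz[1, ])^2))
  manual <- if (d15 < P2$steric$r_rep)
    0.5 * P2$steric$k_rep * (P2$steric$r_rep - d15)^2 else 0
  d25 <- sqrt(sum((sq$xyz[5, ] - sq$xyz[2, ])^2))
  if (d25 < P2$steric$r_rep) manual <- manual + 0.5 * P2$steric$k_rep * (P2$steric$r_rep - d25)^2
  d14 <- sqrt(sum((sq$xyz[4, ] - sq$xyz[1, ])^2))
  if (d14 < P2$steric$r_rep) manual <- manual + 0.5 * P2$steric$k_rep * (P2$steric$r_rep - d14)^2
  expect_equal(e_steric(sq, P2), manual, tolerance = 1e-12)
  ## hbond: all pairs beyond cutoff -> 0
  expect_equal(e_hbond(far, P2), 0)
})

test_that("harmonic minimum of the alphabet term is exactly zero", {
  A <- random_alphabet(3, seed = 21)
  P <- random_params(3, seed = 21)
  P$letters$theta0_1 <- A$prototypes[, 1]
  P$letters$theta0_2 <- A$prototypes[, 2]
  P$letters$tau0 <- A$prototypes[, 3]
  P$letters$e_ref <- 0
  P$e_ref2[] <- 0
  ## helix chain: every fragment has the same descriptor; centre one letter
  ## on it so the harmonic part vanishes
  h <- helix_chain(8)
  d <- fragment_descriptor(h, 1)
  A$prototypes[2, ] <- d
  P$letters$theta0_1[2] <- d[1]; P$letters$theta0_2[2] <- d[2]
  P$letters$tau0[2] <- d[3]
  out <- e_sa_local(h, A, P)
  expect_equal(out$e_harmonic, 0, tolerance = 1e-18)
  ## displacing theta1 by delta adds exactly k/2 delta^2 + refs
  P$letters$e_ref <- c(0.3, 0.7, -0.1)
  single <- chain_from(h$xyz[1:4, ])
  out1 <- e_sa_local(single, A, P)
  expect_equal(out1$energy, P$letters$e_ref[out1$letters])
})

test_that("every term matches its brute-force oracle on random chains", {
  A <- random_alphabet(5, seed = 30)
  P <- random_params(5, seed = 30)
  for (s in 1:5) {
    ch <- random_chain(10, seed = 40 + s)
    expect_equal(e_bond(ch, P), oracle_bond(ch, P), tolerance = 1e-10)
    expect_equal(e_steric(ch, P), oracle_steric(ch, P), tolerance = 1e-10)
    expect_equal(e_hbond(ch, P), oracle_hbond(ch, P), tolerance = 1e-10)
    sa <- e_sa_local(ch, A, P)
    or <- oracle_sa(ch, A, P)
    expect_equal(sa$e_harmonic, or$e_h, tolerance = 1e-10)
    expect_equal(sa$e_ref, or$e_r, tolerance = 1e-10)
  }
})

test_that("total energy is the sum of its components and rigid-motion invariant", {
  A <- random_alphabet(5, seed = 31)
  P <- random_params(5, seed = 31)
  ch <- random_chain(12, seed = 50)
  eb <- total_cg_energy(ch, A, P)
  expect_equal(eb$total,
               eb$e_sa_local + eb$e_bond + eb$e_steric + eb$e_hbond +
                 eb$e_ref_total, tolerance = 1e-10)
  expect_equal(eb$e_bond, e_bond(ch, P))
  expect_equal(eb$e_steric, e_steric(ch, P))
  expect_equal(eb$e_hbond, e_hbond(ch, P))
  ch2 <- ch; ch2$xyz <- apply_rigid(ch$xyz, random_rotation(51), c(2, -3, 1))
  expect_equal(total_cg_energy(ch2, A, P)$total, eb$total, tolerance = 1e-9)
  ## all force constants zero and empty tables: zero energy
  P0 <- bond_only_params(5); P0$bond$k <- 0
  expect_equal(total_cg_energy(ch, A, P0)$total, 0)
})

test_that("control-mode parameters leave only bond and steric terms", {
  A <- random_alphabet(5, seed = 32)
  P <- random_params(5, seed = 32)
  ctl <- control_cg_params(P)
  ch <- random_chain(10, seed = 52)
  eb <- total_cg_energy(ch, A, ctl)
  expect_equal(eb$e_sa_local, 0)
  expect_equal(eb$e_hbond, 0)
  expect_equal(eb$e_ref_total, 0)
  expect_equal(eb$total, e_bond(ch, ctl) + e_steric(ch, ctl))
})

test_that("analytic gradient agrees with central finite differences", {
  A <- random_alphabet(5, seed = 33)
  P <- random_params(5, seed = 33)
  h <- 1e-5
  worst <- 0
  for (s in 1:20) {
    ch <- random_chain(8, seed = 60 + s)
    g <- cg_gradient(ch, A, P)
    for (t in 1:4) {
      i <- sample(8, 1); dd <- sample(3, 1)
      cp <- ch; cp$xyz[i, dd] <- cp$xyz[i, dd] + h
      cm <- ch; cm$xyz[i, dd] <- cm$xyz[i, dd] - h
      fd <- (total_cg_energy(cp, A, P)$total -
               total_cg_energy(cm, A, P)$total) / (2 * h)
      worst <- max(worst, abs(fd - g[i, dd]) / max(1, abs(fd)))
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("gradient respects the mobility mask and stationarity", {
  A <- random_alphabet(5, seed = 34)
  P <- random_params(5, seed = 34)
  ch <- random_chain(10, seed = 70)
  ch$mobile <- rep(c(FALSE, TRUE), 5)
  g <- cg_gradient(ch, A, P)
  expect_true(all(g[!ch$mobile, ] == 0))
  ## constructed minimum of the bond term: straight chain at r0
  Pb <- bond_only_params(5)
  straight <- chain_from(cbind(seq(0, by = Pb$bond$r0, length.out = 6), 0, 0))
  expect_lt(max(abs(cg_gradient(straight, A, Pb))), 1e-8)
})

test_that("compiled energy kernel agrees with the R implementation", {
  A <- random_alphabet(5, seed = 35)
  P <- random_params(5, seed = 35)
  for (s in 1:10) {
    ch <- random_chain(11, seed = 80 + s)
    eb <- total_cg_energy(ch, A, P)
    ec <- pd2loop:::.pd2_energy_cpp(ch$xyz, ch$mobile,
                                    pd2loop:::.pack_params(ch, A, P))
    for (k in c("e_sa_local", "e_bond", "e_steric", "e_hbond",
                "e_ref_total", "total"))
      expect_equal(ec[[k]], eb[[k]], tolerance = 1e-10)
  }
})

test_that("cg_params validates invariants and round-trips via YAML", {
  P <- random_params(4, seed = 36)
  expect_error(cg_params(P$letters,
                         hbond = list(edges = c(3, 2.5, 4), values = c(0, 0))),
               "edges")
  expect_error(cg_params(P$letters,
                         hbond = list(edges = c(3, 3.5, 4), values = c(1, 1))),
               "cutoff")
  bad <- P$letters; bad$k_theta[1] <- -1
  expect_error(cg_params(bad), "force constants")
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_cg_params(P, f)
  P2 <- read_cg_params(f)
  expect_equal(P2$letters, P$letters, tolerance = 1e-9)
  expect_equal(P2$e_ref2, P$e_ref2, tolerance = 1e-9)
  expect_equal(P2$hbond$values, P$hbond$values, tolerance = 1e-9)
})
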