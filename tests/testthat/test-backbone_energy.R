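test_that("bonded terms vanish at ideal geometry and follow closed forms", {
  ff <- default_backbone_ff()
  ## a generated dipeptide has exactly the ideal internal coordinates the
  ## generator uses; with matching ff equilibria the bonded terms are ~0
  bb <- backbone_from_torsions(c(-57, -57), c(-47, -47))
  e <- backbone_energy(bb, ff)
  expect_lt(e[["bond"]], 1e-6)
  expect_lt(abs(e[["improper"]]), 1e-4)
  ## angle terms: near zero; O-C-N is not an independent coordinate of the
  ## generator (it is implied by CA-C-O and CA-C-N), so allow a small
  ## residual there
  expect_lt(e[["angle"]], 1e-3)
  ## one bond stretched by 0.1 A raises the bond energy by k/2 * 0.01
  bb2 <- bb
  u <- (bb2$O[1, ] - bb2$C[1, ]) / sqrt(sum((bb2$O[1, ] - bb2$C[1, ])^2))
  bb2$O[1, ] <- bb2$O[1, ] + 0.1 * u
  e2 <- backbone_energy(bb2, ff)
  expect_equal(e2[["bond"]] - e[["bond"]], 0.5 * ff$bonds[["C-O"]][2] * 0.01,
               tolerance = 1e-6)
})

test_that("bonded energies match the enumeration oracle on perturbed loops", {
  ff <- default_backbone_ff()
  ## silence the nonbonded pieces so the oracle covers the whole sum
  ff$lj <- lapply(ff$lj, function(v) c(v[1], 1e-12))
  ff$steric$k_rep <- 0
  ff$hbond$values[] <- 0
  for (s in 1:3) {
    p <- bb_perturbed(seed = 40 + s)
    e <- backbone_energy(p$bb, ff)
    expect_equal(e[["total"]] - e[["lj14"]] - e[["lj15"]],
                 oracle_backbone(p$bb, ff), tolerance = 1e-6)
  }
})

test_that("LJ pairs are exactly the 1-4 and 1-5 graph distances", {
  ff <- default_backbone_ff()
  p <- bb_perturbed(seed = 50)
  sys <- pd2loop:::.bb_system(p$bb, ff)
  ## verify a known 1-4 pair: N(i) to N(i+1) is 3 bonds (N-CA-C-N)
  i <- p$idx[2]
  ai <- pd2loop:::.ai
  pair_in <- function(pairs, a, b)
    any((pairs[, 1] == a & pairs[, 2] == b) | (pairs[, 1] == b & pairs[, 2] == a))
  expect_true(pair_in(sys$lj14$idx, ai(i, 1L), ai(i + 1L, 1L)))
  ## O(i) to O(i+1): O-C-N-CA-C-O is 5 bonds -> not 1-4, not 1-5
  expect_false(pair_in(sys$lj14$idx, ai(i, 4L), ai(i + 1L, 4L)))
  ## CA(i) to CA(i+1): CA-C-N-CA = 3 bonds -> 1-4
  expect_true(pair_in(sys$lj14$idx, ai(i, 2L), ai(i + 1L, 2L)))
  ## N(i) to CA(i+1): 4 bonds -> 1-5
  expect_true(pair_in(sys$lj15$idx, ai(i, 1L), ai(i + 1L, 2L)))
})

test_that("backbone gradient matches finite differences and the mask", {
  ff <- default_backbone_ff()
  h <- 1e-6
  worst <- 0
  for (s in 1:6) {
    p <- bb_perturbed(seed = 60 + s, sigma = 0.08)
    sys <- pd2loop:::.bb_system(p$bb, ff)
    X <- sys$X
    g <- pd2loop:::.bb_gradient_sys(X, sys)
    f <- function(X) sum(pd2loop:::.bb_energy_sys(X, sys))
    mob <- which(sys$mob_atom)
    set.seed(s)
    for (t in 1:8) {
      i <- sample(mob, 1); dd <- sample(3, 1)
      Xp <- X; Xp[i, dd] <- Xp[i, dd] + h
      Xm <- X; Xm[i, dd] <- Xm[i, dd] - h
      fd <- (f(Xp) - f(Xm)) / (2 * h)
      worst <- max(worst, abs(fd - g[i, dd]) / max(1, abs(fd)))
    }
    expect_true(all(g[!sys$mob_atom, ] == 0))
  }
  expect_lt(worst, 1e-5)
})

test_that("torsion-term forces have zero net force and torque", {
  ff <- default_backbone_ff()
  ## isolate one torsion by zeroing everything else
  ff$bonds <- lapply(ff$bonds, function(v) c(v[1], 0))
  ff$angles <- lapply(ff$angles, function(v) c(v[1], 0))
  ff$impropers <- lapply(ff$impropers, function(v) c(v[1], 0))
  ff$torsions$phi <- c(ff$torsions$phi[1:2], 0)
  ff$torsions$psi <- c(ff$torsions$psi[1:2], 0)
  ff$lj <- lapply(ff$lj, function(v) c(v[1], 1e-12))
  ff$steric$k_rep <- 0
  ff$hbond$values[] <- 0
  p <- bb_perturbed(seed = 70)
  p$bb$mobile[] <- TRUE  # all atoms get gradients
  sys <- pd2loop:::.bb_system(p$bb, ff)
  g <- pd2loop:::.bb_gradient_sys(sys$X, sys)
  ## net force zero
  expect_lt(max(abs(colSums(g))), 1e-8)
  ## net torque zero about the origin
  torque <- colSums(pd2loop:::rowcross(sys$X[is.finite(sys$X[, 1]), ],
                                       g[is.finite(sys$X[, 1]), ]))
  expect_lt(max(abs(torque)), 1e-7)
})

test_that("backbone hydrogen bonds: cutoff, bin lookup, helix vs extended", {
  ff <- default_backbone_ff()
  ## widely separated donors/acceptors score zero
  ext <- make_fixtures(list(list(type = "strand", len = 8)), seed = 80)
  expect_equal(hbond_bb(ext$backbone, ff), 0, tolerance = 1e-12)
  ## an ideal helix scores lower (more favourable) than an extended chain
  hel <- make_fixtures(list(list(type = "helix", len = 14)), seed = 81)
  ex2 <- make_fixtures(list(list(type = "strand", len = 14)), seed = 82)
  expect_lt(hbond_bb(hel$backbone, ff), hbond_bb(ex2$backbone, ff))
})

test_that("minimisation decreases energy monotonically and fixes geometry", {
  ff <- default_backbone_ff()
  fx <- hth_fixture(5, seed = 90)
  bb <- fx$backbone
  ## stationary start: a native structure barely moves
  bb$mobile <- seq_len(length(bb)) %in% region_indices(bb$ids, fx$regions[[1]])
  m0 <- minimize_cg(bb, ff, max_iter = 100)
  disp <- max(abs(m0$CA - bb$CA))
  expect_lt(disp, 0.2)
  expect_true(all(diff(attr(m0, "trace")) <= 1e-8))
  ## a stretched bond recovers to within 0.01 A of r0
  idx <- which(bb$mobile)
  st <- bb
  i <- idx[3]
  u <- (st$C[i, ] - st$CA[i, ]) / sqrt(sum((st$C[i, ] - st$CA[i, ])^2))
  st$C[i, ] <- st$C[i, ] + 0.3 * u
  m1 <- minimize_cg(st, ff, max_iter = 200)
  r <- sqrt(sum((m1$C[i, ] - m1$CA[i, ])^2))
  expect_lt(abs(r - ff$bonds[["CA-C"]][1]), 0.01)
  expect_true(all(diff(attr(m1, "trace")) <= 1e-8))
  ## fixed atoms never move
  sc <- setdiff(seq_len(length(bb)), idx)
  for (at in c("N", "CA", "C", "O"))
    expect_identical(m1[[at]][sc, ], bb[[at]][sc, ])
})

test_that("force-field files round-trip and validate", {
  ff <- default_backbone_ff()
  f <- tempfile(fileext = ".yaml"); on.exit(unlink(f))
  write_backbone_ff(ff, f)
  f2 <- read_backbone_ff(f)
  expect_equal(f2$bonds, lapply(ff$bonds, as.numeric), tolerance = 1e-9)
  expect_equal(unname(f2$hbond$values), unname(ff$hbond$values), tolerance = 1e-9)
  bad <- ff; bad$lj$N <- c(-1, 0.1)
  expect_error(do.call(backbone_ff, bad), "positive")
})
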