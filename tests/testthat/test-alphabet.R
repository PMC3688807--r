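test_that("fragment descriptors compose the chain-model operations", {
  h <- helix_chain(10)
  d <- fragment_descriptor(h, 1:7)
  ## helical symmetry: identical descriptor at every position
  expect_lt(max(abs(sweep(d, 2, d[1, ]))), 1e-9)
  ## planar zigzag: tau = +/- pi
  zig <- chain_from(cbind(seq(0, 10, length.out = 6), rep(c(0, 2), 3), 0))
  expect_equal(abs(fragment_descriptor(zig, 1:3)[, "tau"]), rep(pi, 3))
  ## arbitrary points: equals recomputation via the public operations
  ch <- random_chain(9, seed = 8)
  d <- fragment_descriptor(ch, 2)
  expect_equal(unname(d[1, "theta1"]), pseudo_bond_angle(ch, 3))
  expect_equal(unname(d[1, "theta2"]), pseudo_bond_angle(ch, 4))
  expect_equal(unname(d[1, "tau"]), pseudo_dihedral(ch, 2))
  expect_error(fragment_descriptor(ch, 7), "out of range")
})

test_that("assign_letter is a periodic nearest-prototype rule", {
  model <- random_alphabet(7, seed = 2)
  ## prototype maps to itself
  expect_identical(assign_letter(model$prototypes, model), 1:7)
  ## tie goes to the lowest index
  tie <- alphabet_model(rbind(c(1.5, 1.5, 1.0), c(1.5, 1.5, 2.0),
                              c(2.5, 2.5, 0)))
  expect_identical(assign_letter(c(1.5, 1.5, 1.5), tie), 1L)
  ## periodic wrap: tau near -pi is close to a prototype near +pi
  wrapm <- alphabet_model(rbind(c(1.5, 1.5, 3.1), c(1.5, 1.5, 0)))
  expect_identical(assign_letter(c(1.5, 1.5, -3.1), wrapm), 1L)
  ## brute-force nearest-neighbour oracle on 100 random descriptors
  set.seed(9)
  d <- cbind(runif(100, 0, pi), runif(100, 0, pi), runif(100, -pi, pi))
  got <- assign_letter(d, model)
  wrap <- function(x) atan2(sin(x), cos(x))
  want <- apply(d, 1, function(v) {
    dist <- apply(model$prototypes, 1, function(p)
      sqrt((v[1] - p[1])^2 + (v[2] - p[2])^2 + wrap(v[3] - p[3])^2))
    which.min(dist)
  })
  expect_identical(got, as.integer(want))
})

test_that("assign_letter is invariant under rigid motion of the fragment", {
  model <- random_alphabet(6, seed = 3)
  ch <- random_chain(10, seed = 4)
  l1 <- chain_letters(ch, model)
  ch2 <- ch; ch2$xyz <- apply_rigid(ch$xyz, random_rotation(5), c(3, 1, -2))
  expect_identical(chain_letters(ch2, model), l1)
})

test_that("train_alphabet recovers well-separated clusters", {
  ## three tight descriptor clusters realised as noisy chains is hard to
  ## construct directly; instead build synthetic chains from three letter
  ## geometries via torsion-space generation
  set.seed(10)
  mk <- function(type, n) switch(type,
    h = make_fixtures(list(list(type = "helix", len = n)), seed = n)$ca,
    s = make_fixtures(list(list(type = "strand", len = n)), seed = n)$ca)
  chains <- c(lapply(8:17, function(n) mk("h", n)),
              lapply(8:17, function(n) mk("s", n)))
  m <- train_alphabet(chains, n_letters = 2, seed = 1, n_restart = 5)
  ## recovered prototypes match the empirical cluster centres (label
  ## permutation allowed) within 0.05 rad
  d <- do.call(rbind, lapply(chains, function(ch)
    fragment_descriptor(ch, seq_len(length(ch) - 3))))
  km <- m$prototypes
  for (i in 1:2) {
    lab <- assign_letter(d, m)
    expect_lt(max(abs(km[i, 1:2] - colMeans(d[lab == i, 1:2, drop = FALSE]))),
              0.05)
  }
  ## objective is non-increasing across Lloyd iterations
  expect_true(all(diff(attr(m, "history")) <= 1e-9))
  ## determinism
  m2 <- train_alphabet(chains, n_letters = 2, seed = 1, n_restart = 5)
  expect_identical(m$prototypes, m2$prototypes)
  ## degenerate k = 1: prototype is the (circular) mean descriptor
  m1 <- train_alphabet(chains, n_letters = 1, seed = 1, n_restart = 2)
  expect_equal(unname(m1$prototypes[1, 1]), mean(d[, 1]), tolerance = 1e-8)
  expect_equal(unname(m1$prototypes[1, 3]), circ_mean(d[, 3]), tolerance = 1e-8)
  ## too few fragments is an informative error
  expect_error(train_alphabet(chains[1], n_letters = 27), "need at least")
})

test_that("letter frequencies are normalised counting statistics", {
  model <- random_alphabet(4, seed = 6)
  ch <- random_chain(12, seed = 7)
  fr <- letter_frequencies(list(ch), model)
  expect_equal(sum(fr$unigram), 1, tolerance = 1e-12)
  expect_equal(sum(fr$bigram), 1, tolerance = 1e-12)
  ## counting oracle
  lab <- chain_letters(ch, model)
  expect_equal(fr$unigram, tabulate(lab, 4) / length(lab))
  bi <- matrix(0, 4, 4)
  for (f in seq_len(length(lab) - 1)) bi[lab[f], lab[f + 1]] <- bi[lab[f], lab[f + 1]] + 1
  expect_equal(fr$bigram, bi / sum(bi))
  ## degenerate input: helix maps every fragment to one letter
  h <- helix_chain(15)
  lab_h <- chain_letters(h, model)[1]
  fr_h <- letter_frequencies(list(h), model)
  expect_equal(fr_h$unigram[lab_h], 1)
  expect_equal(fr_h$bigram[lab_h, lab_h], 1)
  ## bigram marginals reproduce the unigram up to edge effects
  chains <- lapply(1:5, function(s) random_chain(20, seed = 20 + s))
  fr2 <- letter_frequencies(chains, model)
  tot <- sum(vapply(chains, function(c) length(c) - 3, 0))
  expect_lt(max(abs(rowSums(fr2$bigram) - fr2$unigram)), 5 / tot)
  expect_lt(max(abs(colSums(fr2$bigram) - fr2$unigram)), 5 / tot)
})

test_that("alphabet files round-trip with version header", {
  m <- random_alphabet(5, seed = 11)
  m$metadata <- list(trained_on = "unit test", seed = 11)
  f <- tempfile()
  on.exit(unlink(f))
  write_alphabet(m, f)
  m2 <- read_alphabet(f)
  expect_equal(m2$prototypes, m$prototypes, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_identical(m2$metadata$trained_on, "unit test")
  writeLines("not an alphabet", f)
  expect_error(read_alphabet(f), "version header")
})
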