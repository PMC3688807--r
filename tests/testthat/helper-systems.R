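## shared builders for small test systems (built in code, no stored data)

res_ids <- function(n, chain = "A") {
  data.frame(chain_id = chain, resnum = seq_len(n), icode = "",
             resname = "GLY", stringsAsFactors = FALSE)
}

## chain from an explicit coordinate matrix
chain_from <- function(xyz, mobile = NULL) {
  ca_chain(res_ids(nrow(xyz)), xyz, mobile)
}

## random walk chain with steps ~ 3.8 A (self-avoiding enough for tests)
random_chain <- function(n, seed = NULL, step = 3.8) {
  if (!is.null(seed)) set.seed(seed)
  d <- matrix(stats::rnorm(3 * (n - 1)), n - 1, 3)
  d <- step * d / sqrt(rowSums(d^2))
  chain_from(rbind(0, apply(d, 2, cumsum)))
}

## ideal alpha-helix C-alpha trace: radius 2.3 A, rise 1.5 A, 100 deg/res
helix_chain <- function(n, radius = 2.3, rise = 1.5, twist = 100) {
  t <- (seq_len(n) - 1) * twist * pi / 180
  chain_from(cbind(radius * cos(t), radius * sin(t), (seq_len(n) - 1) * rise))
}

## small random alphabet + parameter set exercising every term
random_alphabet <- function(k = 5, seed = 1) {
  set.seed(seed)
  alphabet_model(cbind(stats::runif(k, 0.8, 3.0), stats::runif(k, 0.8, 3.0),
                       stats::runif(k, -3, 3)))
}

random_params <- function(k = 5, seed = 1) {
  set.seed(seed + 1000)
  cg_params(
    letters = data.frame(theta0_1 = stats::runif(k, 0.8, 3.0),
                         theta0_2 = stats::runif(k, 0.8, 3.0),
                         tau0 = stats::runif(k, -3, 3),
                         k_theta = stats::runif(k, 0.5, 5),
                         k_tau = stats::runif(k, 0.5, 5),
                         e_ref = stats::rnorm(k)),
    e_ref2 = matrix(stats::rnorm(k * k), k),
    hbond = list(edges = seq(3, 6.5, 0.25),
                 values = c(stats::rnorm(13), 0)))
}

## parameters with only the bond term active (plus optional steric)
bond_only_params <- function(k = 2, steric = FALSE) {
  cg_params(
    letters = data.frame(theta0_1 = seq(1.2, 2.8, length.out = k),
                         theta0_2 = seq(1.2, 2.8, length.out = k),
                         tau0 = seq(-2, 2, length.out = k),
                         k_theta = 0, k_tau = 0, e_ref = 0),
    e_ref2 = matrix(0, k, k),
    steric = list(r_rep = if (steric) 4.5 else 0,
                  k_rep = if (steric) 10 else 0, min_sep = 3))
}

## rigid motion helpers
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(xyz, R, t) sweep(xyz %*% t(R), 2, t, `+`)

## independent brute-force angle/torsion oracles (vector arithmetic only)
oracle_angle <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
}

oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  m1 <- cr(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

## helix-turn-helix fixture shared by pipeline tests
hth_fixture <- function(loop_len = 8, seed = 101) {
  make_fixtures(list(list(type = "helix", len = 9),
                     list(type = "loop", len = loop_len),
                     list(type = "helix", len = 9)), seed = seed)
}

## perturbed-loop backbone used by the energy tests
bb_perturbed <- function(loop_len = 5, seed = 21, sigma = 0.1) {
  fx <- hth_fixture(loop_len, seed = seed)
  reg <- fx$regions[[1]]
  bb <- fx$backbone
  idx <- region_indices(bb$ids, reg)
  bb$mobile <- seq_len(length(bb)) %in% idx
  set.seed(seed)
  for (at in c("N", "CA", "C", "O"))
    bb[[at]][idx, ] <- bb[[at]][idx, ] +
      matrix(stats::rnorm(3 * length(idx), 0, sigma), ncol = 3)
  list(bb = bb, idx = idx, reg = reg)
}

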