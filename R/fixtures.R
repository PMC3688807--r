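#' Synthetic structure generation
#'
#' Builds full-backbone structures from phi/psi/omega sequences with ideal
#' bond lengths and angles (natural extension reference frame / internal-
#' coordinate chain growth), so every pipeline stage can be exercised on
#' structures whose native loop conformations are known exactly.
#'
#' @name fixtures
NULL

## ideal backbone internal coordinates used by the generator
.ideal <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
               a_n_ca_c = 110.1, a_ca_c_n = 116.6, a_c_n_ca = 121.9,
               a_ca_c_o = 120.4)

## place atom D given A, B, C and internal coordinates (angles in radians);
## torsion(A, B, C, D) equals phi in the IUPAC convention
.nerf_place <- function(A, B, C, r, theta, phi) {
  bc <- vunit(C - B)
  nrm <- vunit(vcross(B - A, bc))
  m <- vcross(nrm, bc)
  d <- c(-r * cos(theta), r * sin(theta) * cos(phi), -r * sin(theta) * sin(phi))
  C + d[1] * bc + d[2] * m + d[3] * nrm
}

#' Build a backbone from torsion angles
#'
#' @param phi,psi numeric vectors (degrees) of length n; `phi[1]` and
#'   `psi[n]` are not used for chain growth (`psi[n]` still orients the
#'   final carbonyl; NA falls back to 140).
#' @param omega peptide torsions (degrees), length n-1 (default all 180,
#'   trans).
#' @param chain_id,start_resnum residue labelling.
#' @return a [backbone_model()] with residue names `GLY`.
#' @export
backbone_from_torsions <- function(phi, psi, omega = NULL, chain_id = "A",
                                   start_resnum = 1) {
  n <- length(phi)
  stopifnot(length(psi) == n)
  if (is.null(omega)) omega <- rep(180, max(0, n - 1))
  rad <- function(x) x * pi / 180
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.ideal$b_n_ca, 0, 0)
  th <- rad(.ideal$a_n_ca_c)
  C[1, ] <- CA[1, ] + .ideal$b_ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)[-1]) {
    N[i, ] <- .nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                          .ideal$b_c_n, rad(.ideal$a_ca_c_n),
                          rad(psi[i - 1]))
    CA[i, ] <- .nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                           .ideal$b_n_ca, rad(.ideal$a_c_n_ca),
                           rad(omega[i - 1]))
    C[i, ] <- .nerf_place(C[i - 1, ], N[i, ], CA[i, ],
                          .ideal$b_ca_c, rad(.ideal$a_n_ca_c),
                          rad(phi[i]))
  }
  for (i in seq_len(n)) {
    psi_i <- if (i < n) psi[i] else if (is.finite(psi[n])) psi[n] else 140
    O[i, ] <- .nerf_place(N[i, ], CA[i, ], C[i, ],
                          .ideal$b_c_o, rad(.ideal$a_ca_c_o),
                          rad(psi_i - 180))
  }
  ids <- data.frame(chain_id = chain_id,
                    resnum = as.integer(start_resnum + seq_len(n) - 1),
                    icode = "", resname = "GLY", stringsAsFactors = FALSE)
  backbone_model(ids, N, CA, C, O)
}

## small library of coil/turn (phi, psi) basins sampled by random-coil loops
.coil_library <- rbind(c(-75, 145),   # polyproline II
                       c(-140, 150),  # beta
                       c(-120, 130),  # extended
                       c(-60, -35),   # alpha-R turn
                       c(-90, -10),   # bridge/turn
                       c(60, 45))     # alpha-L (common in turns)

#' Generate a synthetic structure from a segment specification
#'
#' `spec` is a list of segments, each a list with `type` one of `helix`
#' (phi/psi -57/-47), `strand` (-120/135), `loop` (random-coil from a
#' small basin library with 10-degree jitter, or an explicit `phi_psi`
#' matrix) and `len`. Optional Gaussian coordinate noise of `noise`
#' Angstrom is added to every atom. Seeded and deterministic.
#'
#' @param spec list of segment lists; e.g.
#'   `list(list(type = "helix", len = 10), list(type = "loop", len = 8),
#'   list(type = "helix", len = 10))`.
#' @param seed integer seed.
#' @param noise coordinate noise sigma in Angstrom (default 0).
#' @param chain_id chain label.
#' @return list `backbone` (a [backbone_model()]), `ca` (its trace),
#'   `regions` (a [loop_region()] per loop segment), `phi_psi` (the
#'   generating angles).
#' @export
make_fixtures <- function(spec, seed = 1, noise = 0, chain_id = "A") {
  if (!length(spec) || !all(vapply(spec, function(s)
    is.list(s) && s$type %in% c("helix", "strand", "loop") && s$len >= 1,
    TRUE)))
    stop("spec must be a list of segments with type helix/strand/loop and len >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  phi <- psi <- numeric(0)
  seg_id <- integer(0)
  for (k in seq_along(spec)) {
    s <- spec[[k]]
    ang <- switch(s$type,
      helix = matrix(rep(c(-57, -47), each = s$len), ncol = 2),
      strand = matrix(rep(c(-120, 135), each = s$len), ncol = 2),
      loop = if (!is.null(s$phi_psi)) {
        stopifnot(nrow(s$phi_psi) == s$len)
        as.matrix(s$phi_psi)
      } else {
        pick <- sample.int(nrow(.coil_library), s$len, replace = TRUE)
        .coil_library[pick, , drop = FALSE] +
          matrix(stats::rnorm(2 * s$len, 0, 10), ncol = 2)
      })
    phi <- c(phi, ang[, 1])
    psi <- c(psi, ang[, 2])
    seg_id <- c(seg_id, rep(k, s$len))
  }
  bb <- backbone_from_torsions(phi, psi, chain_id = chain_id)
  if (noise > 0) {
    n <- length(bb)
    for (at in c("N", "CA", "C", "O"))
      bb[[at]] <- bb[[at]] + matrix(stats::rnorm(3 * n, 0, noise), n, 3)
  }
  regions <- list()
  for (k in seq_along(spec)) {
    if (spec[[k]]$type != "loop") next
    idx <- which(seg_id == k)
    regions[[length(regions) + 1]] <-
      loop_region(chain_id, bb$ids$resnum[min(idx)], bb$ids$resnum[max(idx)])
  }
  list(backbone = bb, ca = ca_trace(bb), regions = regions,
       phi_psi = cbind(phi = phi, psi = psi))
}

#' The synthetic training family used for the shipped defaults
#'
#' A deterministic mixture of helices, strands, helix/strand-loop-helix
#' motifs with loop lengths 2-12 and varied random-coil runs; used to
#' train the shipped alphabet, CG parameters, Ramachandran map and
#' backbone look-up table.
#'
#' @param n_sets repeats of the motif battery (default 3).
#' @param seed integer seed.
#' @param noise coordinate noise sigma (default 0.08 Angstrom, roughly
#'   crystallographic precision).
#' @return list of fixture lists (see [make_fixtures()]).
#' @export
fixture_family <- function(n_sets = 3, seed = 42, noise = 0.08) {
  out <- list()
  s <- 0
  for (rep_i in seq_len(n_sets)) {
    for (ll in 2:12) {
      s <- s + 1
      out[[length(out) + 1]] <- make_fixtures(
        list(list(type = "helix", len = 9), list(type = "loop", len = ll),
             list(type = "helix", len = 9)),
        seed = seed + s, noise = noise)
      s <- s + 1
      out[[length(out) + 1]] <- make_fixtures(
        list(list(type = "strand", len = 6), list(type = "loop", len = ll),
             list(type = "strand", len = 6)),
        seed = seed + s, noise = noise)
    }
    s <- s + 1
    out[[length(out) + 1]] <- make_fixtures(
      list(list(type = "helix", len = 18)), seed = seed + s, noise = noise)
    s <- s + 1
    out[[length(out) + 1]] <- make_fixtures(
      list(list(type = "strand", len = 12)), seed = seed + s, noise = noise)
    s <- s + 1
    out[[length(out) + 1]] <- make_fixtures(
      list(list(type = "loop", len = 16)), seed = seed + s, noise = noise)
  }
  out
}
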