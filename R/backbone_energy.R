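#' Backbone potential energy and regularisation
#'
#' Energy over the mobile backbone region and its interactions with the
#' fixed surroundings: bonded terms (bond, angle, torsion, improper),
#' Lennard-Jones on 1-4/1-5 intra-backbone pairs, a soft steric clash
#' penalty against everything else (including the fixed scaffold) and the
#' backbone-backbone hydrogen-bond statistical potential. Used to
#' regularise rebuilt backbones by conjugate-gradient minimisation.
#'
#' @name backbone_energy
NULL

## atom index of residue i, atom t (1=N, 2=CA, 3=C, 4=O)
.ai <- function(i, t) 4L * (i - 1L) + t

## assemble the interaction lists of a backbone model once; terms with a
## missing atom are dropped, terms with no mobile atom are dropped
.bb_system <- function(model, ff, mobile_res = NULL) {
  n <- length(model)
  if (is.null(mobile_res)) mobile_res <- which(model$mobile)
  X <- matrix(NA_real_, 4 * n, 3)
  X[.ai(1:n, 1L), ] <- model$N
  X[.ai(1:n, 2L), ] <- model$CA
  X[.ai(1:n, 3L), ] <- model$C
  X[.ai(1:n, 4L), ] <- model$O
  mob_atom <- rep(FALSE, 4 * n)
  mob_atom[as.vector(vapply(mobile_res, .ai, integer(4), t = 1:4))] <- TRUE
  finite <- is.finite(X[, 1])
  keep <- function(idx) {
    ok <- matrix(finite[idx], nrow(idx), ncol(idx))
    m <- matrix(mob_atom[idx], nrow(idx), ncol(idx))
    rowSums(!ok) == 0 & rowSums(m) > 0
  }
  i <- 1:n
  ## bonds
  bidx <- rbind(cbind(.ai(i, 1L), .ai(i, 2L)),
                cbind(.ai(i, 2L), .ai(i, 3L)),
                cbind(.ai(i, 3L), .ai(i, 4L)),
                if (n > 1) cbind(.ai(1:(n - 1), 3L), .ai(2:n, 1L)))
  bcls <- c(rep("N-CA", n), rep("CA-C", n), rep("C-O", n),
            rep("C-N", max(0, n - 1)))
  sel <- keep(bidx)
  bonds <- list(idx = bidx[sel, , drop = FALSE],
                r0 = vapply(ff$bonds[bcls[sel]], `[`, 0, 1),
                k = vapply(ff$bonds[bcls[sel]], `[`, 0, 2))
  ## angles
  aidx <- rbind(cbind(.ai(i, 1L), .ai(i, 2L), .ai(i, 3L)),
                cbind(.ai(i, 2L), .ai(i, 3L), .ai(i, 4L)),
                if (n > 1) cbind(.ai(1:(n - 1), 2L), .ai(1:(n - 1), 3L), .ai(2:n, 1L)),
                if (n > 1) cbind(.ai(1:(n - 1), 4L), .ai(1:(n - 1), 3L), .ai(2:n, 1L)),
                if (n > 1) cbind(.ai(1:(n - 1), 3L), .ai(2:n, 1L), .ai(2:n, 2L)))
  acls <- c(rep("N-CA-C", n), rep("CA-C-O", n), rep("CA-C-N", max(0, n - 1)),
            rep("O-C-N", max(0, n - 1)), rep("C-N-CA", max(0, n - 1)))
  sel <- keep(aidx)
  angles <- list(idx = aidx[sel, , drop = FALSE],
                 th0 = vapply(ff$angles[acls[sel]], `[`, 0, 1) * pi / 180,
                 k = vapply(ff$angles[acls[sel]], `[`, 0, 2))
  ## torsions: phi (C-, N, CA, C), psi (N, CA, C, N+), omega (CA, C, N+, CA+)
  tidx <- rbind(if (n > 1) cbind(.ai(1:(n - 1), 3L), .ai(2:n, 1L), .ai(2:n, 2L), .ai(2:n, 3L)),
                if (n > 1) cbind(.ai(1:(n - 1), 1L), .ai(1:(n - 1), 2L), .ai(1:(n - 1), 3L), .ai(2:n, 1L)),
                if (n > 1) cbind(.ai(1:(n - 1), 2L), .ai(1:(n - 1), 3L), .ai(2:n, 1L), .ai(2:n, 2L)))
  tcls <- c(rep("phi", max(0, n - 1)), rep("psi", max(0, n - 1)),
            rep("omega", max(0, n - 1)))
  sel <- keep(tidx)
  torsions <- list(idx = tidx[sel, , drop = FALSE],
                   n = vapply(ff$torsions[tcls[sel]], `[`, 0, 1),
                   phase = vapply(ff$torsions[tcls[sel]], `[`, 0, 2) * pi / 180,
                   V = vapply(ff$torsions[tcls[sel]], `[`, 0, 3))
  ## improper at C(i): dihedral CA(i) - N(i+1) - C(i) - O(i), target trans
  iidx <- if (n > 1) cbind(.ai(1:(n - 1), 2L), .ai(2:n, 1L),
                           .ai(1:(n - 1), 3L), .ai(1:(n - 1), 4L))
          else matrix(0L, 0, 4)
  sel <- if (nrow(iidx)) keep(iidx) else logical(0)
  imp <- ff$impropers[["C-planar"]]
  impropers <- list(idx = iidx[sel, , drop = FALSE],
                    target = rep(imp[1] * pi / 180, sum(sel)),
                    k = rep(imp[2], sum(sel)))
  ## bond graph distances (BFS to depth 4) for LJ / steric classification
  nat <- 4 * n
  adj <- vector("list", nat)
  for (r in seq_len(nrow(bidx))) {
    a <- bidx[r, 1]; b <- bidx[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  atom_class <- rep(c("N", "CA", "C", "O"), n)
  lj_pairs <- list()
  near <- vector("list", nat)  # atoms within graph distance 4
  for (a in seq_len(nat)) {
    frontier <- a
    dvec <- integer(0); dat <- integer(0)
    seen <- c(a)
    for (d in 1:4) {
      frontier <- setdiff(unique(unlist(adj[frontier])), seen)
      if (!length(frontier)) break
      seen <- c(seen, frontier)
      dvec <- c(dvec, rep(d, length(frontier)))
      dat <- c(dat, frontier)
    }
    near[[a]] <- seen
    sel14 <- dat[dvec == 3 & dat > a]
    sel15 <- dat[dvec == 4 & dat > a]
    lj_pairs[[a]] <- list(p14 = sel14, p15 = sel15)
  }
  mk_lj <- function(field) {
    pr <- do.call(rbind, lapply(seq_len(nat), function(a) {
      js <- lj_pairs[[a]][[field]]
      if (length(js)) cbind(a, js) else NULL
    }))
    if (is.null(pr)) pr <- matrix(0L, 0, 2)
    sel <- if (nrow(pr)) keep(pr) else logical(0)
    pr <- pr[sel, , drop = FALSE]
    sig <- sqrt(vapply(ff$lj[atom_class[pr[, 1]]], `[`, 0, 1) *
                vapply(ff$lj[atom_class[pr[, 2]]], `[`, 0, 1))
    eps <- sqrt(vapply(ff$lj[atom_class[pr[, 1]]], `[`, 0, 2) *
                vapply(ff$lj[atom_class[pr[, 2]]], `[`, 0, 2))
    list(idx = pr, sigma = sig, eps = eps)
  }
  lj14 <- mk_lj("p14")
  lj15 <- mk_lj("p15")
  ## soft steric: mobile atom vs anything beyond graph distance 4
  mob_atoms <- which(mob_atom & finite)
  st <- do.call(rbind, lapply(mob_atoms, function(a) {
    js <- setdiff(which(finite), near[[a]])
    js <- js[js > a | !mob_atom[js]]
    if (length(js)) cbind(a, js) else NULL
  }))
  if (is.null(st)) st <- matrix(0L, 0, 2)
  ## hydrogen bonds: donor N(i) (H inferred from C(i-1), N, CA), acceptor O(j)
  don <- if (n >= 2) {
    cand <- 2:n
    cand[finite[.ai(cand, 1L)] & finite[.ai(cand - 1L, 3L)] &
           finite[.ai(cand, 2L)]]
  } else integer(0)
  accp <- (1:n)[finite[.ai(1:n, 4L)]]
  hb <- expand.grid(i = don, j = accp)
  hb <- hb[abs(hb$i - hb$j) >= 2, , drop = FALSE]
  hb <- hb[mob_atom[.ai(hb$i, 1L)] | mob_atom[.ai(hb$j, 4L)], , drop = FALSE]
  list(n = n, X = X, mob_atom = mob_atom,
       bonds = bonds, angles = angles, torsions = torsions,
       impropers = impropers, lj14 = lj14, lj15 = lj15,
       steric = list(idx = st, r_rep = ff$steric$r_rep,
                     k_rep = ff$steric$k_rep),
       hb = list(i = hb$i, j = hb$j, r_edges = ff$hbond$r_edges,
                 a_edges = ff$hbond$a_edges, values = ff$hbond$values))
}

.bb_hb_energy <- function(X, hb) {
  if (!length(hb$i) || !length(hb$values)) return(0)
  Ni <- X[.ai(hb$i, 1L), , drop = FALSE]
  Ci <- X[.ai(hb$i - 1L, 3L), , drop = FALSE]
  CAi <- X[.ai(hb$i, 2L), , drop = FALSE]
  u1 <- (Ci - Ni) / rownorm(Ci - Ni)
  u2 <- (CAi - Ni) / rownorm(CAi - Ni)
  hd <- -(u1 + u2)
  hd <- hd / rownorm(hd)
  H <- Ni + hd  # N-H length 1.0
  O <- X[.ai(hb$j, 4L), , drop = FALSE]
  r <- rownorm(H - O)
  ang <- angle_points(Ni, H, O) * 180 / pi
  rb <- findInterval(r, hb$r_edges)
  ab <- findInterval(ang, hb$a_edges)
  ok <- rb >= 1 & rb <= nrow(hb$values) & ab >= 1 & ab <= ncol(hb$values)
  sum(hb$values[cbind(rb[ok], ab[ok])])
}

.bb_energy_sys <- function(X, sys) {
  e <- c(bond = 0, angle = 0, torsion = 0, improper = 0, lj14 = 0,
         lj15 = 0, steric = 0, hbond = 0)
  b <- sys$bonds
  if (nrow(b$idx)) {
    r <- rownorm(X[b$idx[, 1], , drop = FALSE] - X[b$idx[, 2], , drop = FALSE])
    e["bond"] <- sum(0.5 * b$k * (r - b$r0)^2)
  }
  a <- sys$angles
  if (nrow(a$idx)) {
    th <- angle_points(X[a$idx[, 1], , drop = FALSE],
                       X[a$idx[, 2], , drop = FALSE],
                       X[a$idx[, 3], , drop = FALSE])
    e["angle"] <- sum(0.5 * a$k * (th - a$th0)^2)
  }
  t <- sys$torsions
  if (nrow(t$idx)) {
    ph <- dihedral_points(X[t$idx[, 1], , drop = FALSE],
                          X[t$idx[, 2], , drop = FALSE],
                          X[t$idx[, 3], , drop = FALSE],
                          X[t$idx[, 4], , drop = FALSE])
    e["torsion"] <- sum(t$V * (1 + cos(t$n * ph - t$phase)))
  }
  im <- sys$impropers
  if (nrow(im$idx)) {
    ph <- dihedral_points(X[im$idx[, 1], , drop = FALSE],
                          X[im$idx[, 2], , drop = FALSE],
                          X[im$idx[, 3], , drop = FALSE],
                          X[im$idx[, 4], , drop = FALSE])
    e["improper"] <- sum(0.5 * im$k * wrap_angle(ph - im$target)^2)
  }
  for (nm in c("lj14", "lj15")) {
    lj <- sys[[nm]]
    if (nrow(lj$idx)) {
      r <- rownorm(X[lj$idx[, 1], , drop = FALSE] - X[lj$idx[, 2], , drop = FALSE])
      sr6 <- (lj$sigma / r)^6
      e[nm] <- sum(4 * lj$eps * (sr6^2 - sr6))
    }
  }
  st <- sys$steric
  if (nrow(st$idx)) {
    r <- rownorm(X[st$idx[, 1], , drop = FALSE] - X[st$idx[, 2], , drop = FALSE])
    v <- r < st$r_rep
    e["steric"] <- sum(0.5 * st$k_rep * (st$r_rep - r[v])^2)
  }
  e["hbond"] <- .bb_hb_energy(X, sys$hb)
  e
}

.bb_gradient_sys <- function(X, sys) {
  G <- matrix(0, nrow(X), 3)
  addg <- function(G, idx, contrib) {
    ## indices may repeat across terms: accumulate per column block
    for (r in seq_len(nrow(idx))) G[idx[r], ] <- G[idx[r], ] + contrib[r, ]
    G
  }
  b <- sys$bonds
  if (nrow(b$idx)) {
    d <- X[b$idx[, 2], , drop = FALSE] - X[b$idx[, 1], , drop = FALSE]
    r <- rownorm(d)
    coef <- b$k * (r - b$r0) / r
    G <- addg(G, b$idx[, 1, drop = FALSE], -coef * d)
    G <- addg(G, b$idx[, 2, drop = FALSE], coef * d)
  }
  a <- sys$angles
  if (nrow(a$idx)) {
    th <- angle_points(X[a$idx[, 1], , drop = FALSE],
                       X[a$idx[, 2], , drop = FALSE],
                       X[a$idx[, 3], , drop = FALSE])
    ga <- angle_gradient(X[a$idx[, 1], , drop = FALSE],
                         X[a$idx[, 2], , drop = FALSE],
                         X[a$idx[, 3], , drop = FALSE])
    coef <- a$k * (th - a$th0)
    G <- addg(G, a$idx[, 1, drop = FALSE], coef * ga$g1)
    G <- addg(G, a$idx[, 2, drop = FALSE], coef * ga$g2)
    G <- addg(G, a$idx[, 3, drop = FALSE], coef * ga$g3)
  }
  tors <- function(G, idx, dEdphi) {
    gd <- dihedral_gradient(X[idx[, 1], , drop = FALSE],
                            X[idx[, 2], , drop = FALSE],
                            X[idx[, 3], , drop = FALSE],
                            X[idx[, 4], , drop = FALSE])
    G <- addg(G, idx[, 1, drop = FALSE], dEdphi * gd$g1)
    G <- addg(G, idx[, 2, drop = FALSE], dEdphi * gd$g2)
    G <- addg(G, idx[, 3, drop = FALSE], dEdphi * gd$g3)
    addg(G, idx[, 4, drop = FALSE], dEdphi * gd$g4)
  }
  t <- sys$torsions
  if (nrow(t$idx)) {
    ph <- dihedral_points(X[t$idx[, 1], , drop = FALSE],
                          X[t$idx[, 2], , drop = FALSE],
                          X[t$idx[, 3], , drop = FALSE],
                          X[t$idx[, 4], , drop = FALSE])
    G <- tors(G, t$idx, -t$V * t$n * sin(t$n * ph - t$phase))
  }
  im <- sys$impropers
  if (nrow(im$idx)) {
    ph <- dihedral_points(X[im$idx[, 1], , drop = FALSE],
                          X[im$idx[, 2], , drop = FALSE],
                          X[im$idx[, 3], , drop = FALSE],
                          X[im$idx[, 4], , drop = FALSE])
    G <- tors(G, im$idx, im$k * wrap_angle(ph - im$target))
  }
  for (nm in c("lj14", "lj15")) {
    lj <- sys[[nm]]
    if (nrow(lj$idx)) {
      d <- X[lj$idx[, 2], , drop = FALSE] - X[lj$idx[, 1], , drop = FALSE]
      r <- rownorm(d)
      sr6 <- (lj$sigma / r)^6
      dEdr <- 4 * lj$eps * (-12 * sr6^2 + 6 * sr6) / r
      coef <- dEdr / r
      G <- addg(G, lj$idx[, 1, drop = FALSE], -coef * d)
      G <- addg(G, lj$idx[, 2, drop = FALSE], coef * d)
    }
  }
  st <- sys$steric
  if (nrow(st$idx)) {
    d <- X[st$idx[, 2], , drop = FALSE] - X[st$idx[, 1], , drop = FALSE]
    r <- rownorm(d)
    v <- which(r < st$r_rep)
    if (length(v)) {
      coef <- -st$k_rep * (st$r_rep - r[v]) / r[v]
      G <- addg(G, st$idx[v, 1, drop = FALSE], -coef * d[v, , drop = FALSE])
      G <- addg(G, st$idx[v, 2, drop = FALSE], coef * d[v, , drop = FALSE])
    }
  }
  ## hbond: binned table, zero gradient almost everywhere
  G[!sys$mob_atom, ] <- 0
  G
}

#' Backbone energy with per-term breakdown
#'
#' @param model a [backbone_model()] whose mobility mask marks the loop;
#'   fixed residues act as scaffold context (soft steric and hydrogen-bond
#'   interactions only, plus shared bonded terms at the loop boundary).
#' @param ff a [backbone_ff()] (default: shipped united-atom values).
#' @return named numeric vector of term energies plus `total`.
#' @export
backbone_energy <- function(model, ff = default_backbone_ff()) {
  sys <- .bb_system(model, ff)
  e <- .bb_energy_sys(sys$X, sys)
  c(e, total = sum(e))
}

#' Analytic gradient of the backbone energy
#'
#' Gradient with respect to mobile backbone atoms, as an (4n) x 3 matrix
#' ordered (N, CA, C, O) per residue; fixed atoms receive zero.
#'
#' @inheritParams backbone_energy
#' @return gradient matrix.
#' @export
backbone_gradient <- function(model, ff = default_backbone_ff()) {
  sys <- .bb_system(model, ff)
  .bb_gradient_sys(sys$X, sys)
}

#' Backbone-backbone hydrogen-bond energy
#'
#' Statistical potential over inferred amide H...O distance and N-H...O
#' angle bins for donor-acceptor pairs with `|i - j| >= 2`; zero beyond
#' the table, floor-capped values come from the parameter file. The amide
#' H is placed geometrically on the bisector opposite C(i-1) and CA.
#'
#' @inheritParams backbone_energy
#' @return energy.
#' @export
hbond_bb <- function(model, ff = default_backbone_ff()) {
  sys <- .bb_system(model, ff)
  .bb_hb_energy(sys$X, sys$hb)
}

#' Conjugate-gradient minimisation of a backbone model
#'
#' Polak-Ribiere conjugate gradients with a line search guaranteeing a
#' non-increasing energy trace; fixed atoms never move. Regularises the
#' stereochemistry of rebuilt backbones.
#'
#' @param model a [backbone_model()] with its mobility mask set.
#' @param ff a [backbone_ff()].
#' @param tol gradient-norm stopping tolerance.
#' @param max_iter iteration cap.
#' @return the minimised model; attributes `value`, `grad_norm`, `trace`,
#'   `converged`.
#' @export
minimize_cg <- function(model, ff = default_backbone_ff(), tol = 1e-2,
                        max_iter = 200) {
  sys <- .bb_system(model, ff)
  mob <- which(sys$mob_atom & is.finite(sys$X[, 1]))
  if (!length(mob)) return(model)
  X <- sys$X
  fn <- function(v) {
    X[mob, ] <- matrix(v, ncol = 3)
    sum(.bb_energy_sys(X, sys))
  }
  gr <- function(v) {
    X[mob, ] <- matrix(v, ncol = 3)
    as.numeric(.bb_gradient_sys(X, sys)[mob, , drop = FALSE])
  }
  res <- cg_minimize(fn, gr, as.numeric(X[mob, ]), tol, max_iter)
  X[mob, ] <- matrix(res$x, ncol = 3)
  n <- sys$n
  out <- model
  out$N <- X[.ai(1:n, 1L), , drop = FALSE]
  out$CA <- X[.ai(1:n, 2L), , drop = FALSE]
  out$C <- X[.ai(1:n, 3L), , drop = FALSE]
  out$O <- X[.ai(1:n, 4L), , drop = FALSE]
  attr(out, "value") <- res$value
  attr(out, "grad_norm") <- res$grad_norm
  attr(out, "trace") <- res$trace
  attr(out, "converged") <- res$converged
  out
}
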