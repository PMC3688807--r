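#' The five-term coarse-grained C-alpha potential
#'
#' Total energy = structural-alphabet local term (harmonic pseudo bond
#' angle and pseudo dihedral wells whose centres, force constants and
#' reference energies vary with the fragment's alphabet letter) +
#' pseudo-bond term + soft steric repulsion + pseudo hydrogen-bond
#' statistical potential + unigram/bigram reference energies. All terms
#' are rigid-motion invariant and additive over their interaction sets.
#'
#' @name cg_energy
NULL

## per-bond equilibrium lengths; chains may carry a logical `cis` flag per
## bond (set at load time from native geometry) selecting r0_cis
.bond_r0 <- function(chain, params) {
  nb <- length(chain) - 1
  r0 <- rep(params$bond$r0, nb)
  if (!is.null(chain$cis) && !is.null(params$r0_cis))
    r0[which(chain$cis[seq_len(nb)])] <- params$r0_cis
  r0
}

#' Pseudo-bond energy
#'
#' Harmonic restraint on consecutive C-alpha distances:
#' `sum 0.5 k (r - r0)^2`.
#'
#' @param chain a [ca_chain()].
#' @param params a [cg_params()].
#' @return energy (dimensionless statistical units).
#' @export
e_bond <- function(chain, params = default_cg_params()) {
  if (length(chain) < 2) return(0)
  r <- rownorm(diff(chain$xyz))
  sum(0.5 * params$bond$k * (r - .bond_r0(chain, params))^2)
}

#' Soft steric repulsion
#'
#' Half-harmonic clash penalty `0.5 k_rep (r_rep - r)^2` for every
#' C-alpha pair with sequence separation >= `min_sep` (default 3; closer
#' pairs are governed by the bond and angle terms) and `r < r_rep`.
#' Mobile-fixed pairs (loop vs. scaffold) are included.
#'
#' @inheritParams e_bond
#' @return energy.
#' @export
e_steric <- function(chain, params = default_cg_params()) {
  n <- length(chain)
  ms <- params$steric$min_sep
  if (n <= ms) return(0)
  d <- as.matrix(stats::dist(chain$xyz))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  idx <- idx[idx[, 2] - idx[, 1] >= ms, , drop = FALSE]
  r <- d[idx]
  viol <- r < params$steric$r_rep
  sum(0.5 * params$steric$k_rep * (params$steric$r_rep - r[viol])^2)
}

## pseudo atoms for every interior residue; returns NULL when n < 3
.all_pseudo_atoms <- function(chain, params) {
  n <- length(chain)
  if (n < 3) return(NULL)
  i <- 2:(n - 1)
  pa <- levitt_pseudo_atoms(chain, i, params)
  list(idx = i, n = pa$n, o = pa$o)
}

## binned table lookup: below the first edge clamps to the first bin,
## beyond the last edge the energy is zero
.hbond_lookup <- function(r, hbond) {
  b <- findInterval(r, hbond$edges)
  e <- numeric(length(r))
  inside <- b >= 1 & b <= length(hbond$values)
  e[inside] <- hbond$values[b[inside]]
  e[b == 0] <- hbond$values[1]
  e
}

#' Pseudo hydrogen-bond statistical potential
#'
#' Binned distance energy over every pseudo-N(i)...pseudo-O(j) pair with
#' `|i - j| >= 2` (pseudo atoms exist only at interior residues); zero
#' beyond the last bin edge.
#'
#' @inheritParams e_bond
#' @return energy.
#' @export
e_hbond <- function(chain, params = default_cg_params()) {
  pa <- .all_pseudo_atoms(chain, params)
  if (is.null(pa)) return(0)
  m <- length(pa$idx)
  ii <- rep(seq_len(m), each = m)
  jj <- rep(seq_len(m), m)
  keep <- abs(pa$idx[ii] - pa$idx[jj]) >= 2
  ii <- ii[keep]; jj <- jj[keep]
  r <- rownorm(pa$n[ii, , drop = FALSE] - pa$o[jj, , drop = FALSE])
  sum(.hbond_lookup(r[is.finite(r)], params$hbond))
}

#' Structural-alphabet local term
#'
#' For each 4-residue fragment with letter L:
#' `0.5 k_theta(L) [(theta1 - theta0_1(L))^2 + (theta2 - theta0_2(L))^2]
#'  + 0.5 k_tau(L) wrap(tau - tau0(L))^2 + e_ref(L)`, plus the bigram
#' reference `e_ref2(L_f, L_f+1)` for consecutive fragments. Only
#' fragments containing at least one mobile residue contribute (fully
#' fixed fragments add a constant that cancels from every energy
#' difference).
#'
#' @param chain a [ca_chain()] (length >= 4; shorter chains return zero
#'   with a warning).
#' @param alphabet an [alphabet_model()].
#' @param params a [cg_params()].
#' @return list with `e_harmonic`, `e_ref` (unigram + bigram reference
#'   part), `energy` (their sum) and `letters` (per-fragment letters).
#' @export
e_sa_local <- function(chain, alphabet = default_alphabet(),
                       params = default_cg_params()) {
  n <- length(chain)
  if (n < 4) {
    warning("chain shorter than 4 residues: structural-alphabet term is zero")
    return(list(e_harmonic = 0, e_ref = 0, energy = 0, letters = integer(0)))
  }
  f <- seq_len(n - 3)
  d <- fragment_descriptor(chain, f)
  lab <- assign_letter(d, alphabet)
  P <- params$letters
  touch <- vapply(f, function(s) any(chain$mobile[s:(s + 3)]), TRUE)
  eh <- 0.5 * P$k_theta[lab] * ((d[, 1] - P$theta0_1[lab])^2 +
                                (d[, 2] - P$theta0_2[lab])^2) +
        0.5 * P$k_tau[lab] * wrap_angle(d[, 3] - P$tau0[lab])^2
  er <- P$e_ref[lab]
  e_harm <- sum(eh[touch])
  e_ref <- sum(er[touch])
  if (length(f) >= 2) {
    pf <- seq_len(length(f) - 1)
    touch2 <- vapply(pf, function(s) any(chain$mobile[s:(s + 4)]), TRUE)
    e_ref <- e_ref + sum(params$e_ref2[cbind(lab[pf], lab[pf + 1])][touch2])
  }
  list(e_harmonic = e_harm, e_ref = e_ref, energy = e_harm + e_ref,
       letters = lab)
}

#' Total coarse-grained energy with per-term breakdown
#'
#' @inheritParams e_sa_local
#' @return object of class `cg_energy_breakdown`: list with `e_sa_local`
#'   (harmonic part), `e_bond`, `e_steric`, `e_hbond`, `e_ref_total`
#'   (unigram + bigram references) and `total` (their sum).
#' @export
total_cg_energy <- function(chain, alphabet = default_alphabet(),
                            params = default_cg_params()) {
  sa <- if (length(chain) >= 4)
    e_sa_local(chain, alphabet, params)
  else list(e_harmonic = 0, e_ref = 0, energy = 0, letters = integer(0))
  out <- list(e_sa_local = sa$e_harmonic,
              e_bond = e_bond(chain, params),
              e_steric = e_steric(chain, params),
              e_hbond = e_hbond(chain, params),
              e_ref_total = sa$e_ref)
  out$total <- out$e_sa_local + out$e_bond + out$e_steric +
    out$e_hbond + out$e_ref_total
  structure(out, class = "cg_energy_breakdown")
}

#' @export
print.cg_energy_breakdown <- function(x, ...) {
  cat(sprintf("CG energy: total=%.4f (sa=%.4f bond=%.4f steric=%.4f hbond=%.4f ref=%.4f)\n",
              x$total, x$e_sa_local, x$e_bond, x$e_steric, x$e_hbond,
              x$e_ref_total))
  invisible(x)
}

#' Analytic gradient of the coarse-grained energy
#'
#' Gradient of [total_cg_energy()] with respect to mobile C-alpha
#' coordinates, holding the (piecewise-constant) letter assignment fixed.
#' The binned hydrogen-bond table and the reference energies are
#' piecewise constant in the coordinates, so their gradient is zero
#' almost everywhere; the bond, steric and alphabet-harmonic terms are
#' differentiated analytically. Rows of fixed residues are zero.
#'
#' @inheritParams e_sa_local
#' @return n x 3 gradient matrix (energy / Angstrom).
#' @export
cg_gradient <- function(chain, alphabet = default_alphabet(),
                        params = default_cg_params()) {
  n <- length(chain)
  x <- chain$xyz
  g <- matrix(0, n, 3)
  ## bond term
  if (n >= 2) {
    dvec <- diff(x)
    r <- rownorm(dvec)
    u <- dvec / r
    coef <- params$bond$k * (r - .bond_r0(chain, params))
    gi <- coef * u
    i <- seq_len(n - 1)
    g[i, ] <- g[i, ] - gi
    g[i + 1, ] <- g[i + 1, ] + gi
  }
  ## steric term
  ms <- params$steric$min_sep
  if (n > ms) {
    d <- as.matrix(stats::dist(x))
    idx <- which(upper.tri(d), arr.ind = TRUE)
    idx <- idx[idx[, 2] - idx[, 1] >= ms, , drop = FALSE]
    r <- d[idx]
    sel <- which(r < params$steric$r_rep)
    if (length(sel)) {
      i <- idx[sel, 1]; j <- idx[sel, 2]
      rv <- r[sel]
      u <- (x[j, , drop = FALSE] - x[i, , drop = FALSE]) / rv
      coef <- -params$steric$k_rep * (params$steric$r_rep - rv)
      ## accumulate with possible repeated indices
      for (k in seq_along(sel)) {
        g[i[k], ] <- g[i[k], ] - coef[k] * u[k, ]
        g[j[k], ] <- g[j[k], ] + coef[k] * u[k, ]
      }
    }
  }
  ## alphabet harmonic term
  if (n >= 4) {
    f <- seq_len(n - 3)
    d <- fragment_descriptor(chain, f)
    lab <- assign_letter(d, alphabet)
    P <- params$letters
    ct <- P$k_theta[lab] * (d[, 1] - P$theta0_1[lab])
    ct2 <- P$k_theta[lab] * (d[, 2] - P$theta0_2[lab])
    cta <- P$k_tau[lab] * wrap_angle(d[, 3] - P$tau0[lab])
    add <- function(g, idx, contrib) {
      ## idx entries are unique within a slot (one per fragment)
      g[idx, ] <- g[idx, ] + contrib
      g
    }
    ga <- angle_gradient(x[f, , drop = FALSE], x[f + 1, , drop = FALSE],
                         x[f + 2, , drop = FALSE])
    g <- add(g, f, ct * ga$g1)
    g <- add(g, f + 1, ct * ga$g2)
    g <- add(g, f + 2, ct * ga$g3)
    ga <- angle_gradient(x[f + 1, , drop = FALSE], x[f + 2, , drop = FALSE],
                         x[f + 3, , drop = FALSE])
    g <- add(g, f + 1, ct2 * ga$g1)
    g <- add(g, f + 2, ct2 * ga$g2)
    g <- add(g, f + 3, ct2 * ga$g3)
    gd <- dihedral_gradient(x[f, , drop = FALSE], x[f + 1, , drop = FALSE],
                            x[f + 2, , drop = FALSE], x[f + 3, , drop = FALSE])
    g <- add(g, f, cta * gd$g1)
    g <- add(g, f + 1, cta * gd$g2)
    g <- add(g, f + 2, cta * gd$g3)
    g <- add(g, f + 3, cta * gd$g4)
  }
  g[!chain$mobile, ] <- 0
  g
}
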