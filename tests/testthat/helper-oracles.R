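## independent brute-force oracles for every term, written against the
## published definitions rather than the implementation

oracle_bond <- function(ch, P) {
  e <- 0
  for (i in seq_len(length(ch) - 1)) {
    r <- sqrt(sum((ch$xyz[i + 1, ] - ch$xyz[i, ])^2))
    e <- e + 0.5 * P$bond$k * (r - P$bond$r0)^2
  }
  e
}

oracle_steric <- function(ch, P) {
  e <- 0
  n <- length(ch)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i < P$steric$min_sep) next
    r <- sqrt(sum((ch$xyz[j, ] - ch$xyz[i, ])^2))
    if (r < P$steric$r_rep) e <- e + 0.5 * P$steric$k_rep * (P$steric$r_rep - r)^2
  }
  e
}

oracle_hbond <- function(ch, P) {
  n <- length(ch)
  e <- 0
  for (i in 2:(n - 1)) for (j in 2:(n - 1)) {
    if (abs(i - j) < 2) next
    pn <- levitt_pseudo_atoms(ch, i, P)$n
    po <- levitt_pseudo_atoms(ch, j, P)$o
    r <- sqrt(sum((pn - po)^2))
    b <- findInterval(r, P$hbond$edges)
    if (b == 0) e <- e + P$hbond$values[1]
    else if (b <= length(P$hbond$values)) e <- e + P$hbond$values[b]
  }
  e
}

oracle_sa <- function(ch, A, P) {
  wrap <- function(x) atan2(sin(x), cos(x))
  n <- length(ch)
  e_h <- e_r <- 0
  lab <- integer(n - 3)
  for (f in seq_len(n - 3)) {
    t1 <- oracle_angle(ch$xyz[f, ], ch$xyz[f + 1, ], ch$xyz[f + 2, ])
    t2 <- oracle_angle(ch$xyz[f + 1, ], ch$xyz[f + 2, ], ch$xyz[f + 3, ])
    ta <- oracle_dihedral(ch$xyz[f, ], ch$xyz[f + 1, ], ch$xyz[f + 2, ],
                          ch$xyz[f + 3, ])
    dst <- apply(A$prototypes, 1, function(p)
      (t1 - p[1])^2 + (t2 - p[2])^2 + wrap(ta - p[3])^2)
    L <- which.min(dst)
    lab[f] <- L
    e_h <- e_h + 0.5 * P$letters$k_theta[L] *
      ((t1 - P$letters$theta0_1[L])^2 + (t2 - P$letters$theta0_2[L])^2) +
      0.5 * P$letters$k_tau[L] * wrap(ta - P$letters$tau0[L])^2
    e_r <- e_r + P$letters$e_ref[L]
  }
  for (f in seq_len(n - 4)) e_r <- e_r + P$e_ref2[lab[f], lab[f + 1]]
  list(e_h = e_h, e_r = e_r)
}


## independent enumeration oracle: rebuild interaction lists by hand from
## the force-field definitions and sum term by term
oracle_backbone <- function(model, ff) {
  n <- length(model)
  at <- function(i, t) switch(t, N = model$N[i, ], CA = model$CA[i, ],
                              C = model$C[i, ], O = model$O[i, ])
  mobile <- model$mobile
  touch <- function(spec) any(vapply(spec, function(s) mobile[s[[1]]], TRUE))
  dist <- function(a, b) sqrt(sum((a - b)^2))
  e <- 0
  ## bonds
  for (i in 1:n) {
    for (b in list(list("N-CA", list(i, "N"), list(i, "CA")),
                   list("CA-C", list(i, "CA"), list(i, "C")),
                   list("C-O", list(i, "C"), list(i, "O")))) {
      if (!mobile[i]) next
      p <- ff$bonds[[b[[1]]]]
      e <- e + 0.5 * p[2] * (dist(at(i, b[[2]][[2]]), at(i, b[[3]][[2]])) - p[1])^2
    }
    if (i < n && (mobile[i] || mobile[i + 1])) {
      p <- ff$bonds[["C-N"]]
      e <- e + 0.5 * p[2] * (dist(at(i, "C"), at(i + 1, "N")) - p[1])^2
    }
  }
  ## angles
  ang <- function(a, b, c) oracle_angle(a, b, c)
  for (i in 1:n) {
    if (mobile[i]) {
      p <- ff$angles[["N-CA-C"]]
      e <- e + 0.5 * p[2] * (ang(at(i, "N"), at(i, "CA"), at(i, "C")) - p[1] * pi / 180)^2
      p <- ff$angles[["CA-C-O"]]
      e <- e + 0.5 * p[2] * (ang(at(i, "CA"), at(i, "C"), at(i, "O")) - p[1] * pi / 180)^2
    }
    if (i < n && (mobile[i] || mobile[i + 1])) {
      for (cls in list(c("CA-C-N", "CA"), c("O-C-N", "O"))) {
        p <- ff$angles[[cls[1]]]
        e <- e + 0.5 * p[2] * (ang(at(i, cls[2]), at(i, "C"), at(i + 1, "N")) - p[1] * pi / 180)^2
      }
      p <- ff$angles[["C-N-CA"]]
      e <- e + 0.5 * p[2] * (ang(at(i, "C"), at(i + 1, "N"), at(i + 1, "CA")) - p[1] * pi / 180)^2
    }
  }
  ## torsions and impropers
  tor <- function(a, b, c, d) oracle_dihedral(a, b, c, d)
  for (i in 1:(n - 1)) {
    if (mobile[i] || mobile[i + 1]) {
      p <- ff$torsions[["phi"]]
      e <- e + p[3] * (1 + cos(p[1] * tor(at(i, "C"), at(i + 1, "N"),
                                          at(i + 1, "CA"), at(i + 1, "C")) - p[2] * pi / 180))
      p <- ff$torsions[["psi"]]
      e <- e + p[3] * (1 + cos(p[1] * tor(at(i, "N"), at(i, "CA"),
                                          at(i, "C"), at(i + 1, "N")) - p[2] * pi / 180))
      p <- ff$torsions[["omega"]]
      e <- e + p[3] * (1 + cos(p[1] * tor(at(i, "CA"), at(i, "C"),
                                          at(i + 1, "N"), at(i + 1, "CA")) - p[2] * pi / 180))
      p <- ff$impropers[["C-planar"]]
      w <- tor(at(i, "CA"), at(i + 1, "N"), at(i, "C"), at(i, "O")) - p[1] * pi / 180
      e <- e + 0.5 * p[2] * atan2(sin(w), cos(w))^2
    }
  }
  e
}

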