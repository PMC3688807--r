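#' Backbone model objects
#'
#' A `backbone_model` stores the four backbone heavy atoms N, CA, C and O
#' per residue (rows may contain NA where an atom is absent, e.g. termini
#' of partially built models) plus the residue identifier table shared
#' with [ca_chain()].
#'
#' @param ids residue id data.frame (columns `chain_id`, `resnum`,
#'   `icode`, `resname`).
#' @param N,CA,C,O numeric n x 3 coordinate matrices in Angstrom.
#' @param mobile optional logical mobility mask per residue.
#' @return object of class `backbone_model`.
#' @export
backbone_model <- function(ids, N, CA, C, O, mobile = NULL) {
  n <- nrow(ids)
  fix <- function(m) { m <- as.matrix(m); storage.mode(m) <- "double"; m }
  N <- fix(N); CA <- fix(CA); C <- fix(C); O <- fix(O)
  stopifnot(nrow(N) == n, nrow(CA) == n, nrow(C) == n, nrow(O) == n,
            ncol(N) == 3, ncol(CA) == 3, ncol(C) == 3, ncol(O) == 3)
  if (is.null(mobile)) mobile <- rep(TRUE, n)
  ids$icode <- as.character(ids$icode)
  structure(list(ids = ids, N = N, CA = CA, C = C, O = O,
                 mobile = as.logical(mobile)),
            class = "backbone_model")
}

#' @export
length.backbone_model <- function(x) nrow(x$ids)

#' @export
print.backbone_model <- function(x, ...) {
  cat(sprintf("<backbone_model> %d residues, %d complete backbones\n",
              length(x),
              sum(stats::complete.cases(cbind(x$N, x$CA, x$C, x$O)))))
  invisible(x)
}

#' Extract the C-alpha trace of a backbone model
#'
#' @param model a `backbone_model`.
#' @return a [ca_chain()] with the same ids and mobility mask.
#' @export
ca_trace <- function(model) {
  ca_chain(model$ids, model$CA, model$mobile)
}

#' Backbone torsion angles phi, psi, omega
#'
#' Standard IUPAC backbone torsions in degrees. phi is undefined at the
#' first residue, psi and omega at the last; any torsion whose atoms are
#' missing is NA rather than an error.
#'
#' @param model a `backbone_model`.
#' @return data.frame with columns `phi`, `psi`, `omega` (degrees).
#' @export
phi_psi <- function(model) {
  n <- length(model)
  phi <- psi <- omega <- rep(NA_real_, n)
  if (n >= 2) {
    i <- 2:n
    ok <- stats::complete.cases(cbind(model$C[i - 1, , drop = FALSE],
                                      model$N[i, , drop = FALSE],
                                      model$CA[i, , drop = FALSE],
                                      model$C[i, , drop = FALSE]))
    if (any(ok))
      phi[i[ok]] <- dihedral_points(model$C[i[ok] - 1, , drop = FALSE],
                                    model$N[i[ok], , drop = FALSE],
                                    model$CA[i[ok], , drop = FALSE],
                                    model$C[i[ok], , drop = FALSE]) * 180 / pi
    j <- 1:(n - 1)
    ok <- stats::complete.cases(cbind(model$N[j, , drop = FALSE],
                                      model$CA[j, , drop = FALSE],
                                      model$C[j, , drop = FALSE],
                                      model$N[j + 1, , drop = FALSE]))
    if (any(ok))
      psi[j[ok]] <- dihedral_points(model$N[j[ok], , drop = FALSE],
                                    model$CA[j[ok], , drop = FALSE],
                                    model$C[j[ok], , drop = FALSE],
                                    model$N[j[ok] + 1, , drop = FALSE]) * 180 / pi
    ok <- stats::complete.cases(cbind(model$CA[j, , drop = FALSE],
                                      model$C[j, , drop = FALSE],
                                      model$N[j + 1, , drop = FALSE],
                                      model$CA[j + 1, , drop = FALSE]))
    if (any(ok))
      omega[j[ok]] <- dihedral_points(model$CA[j[ok], , drop = FALSE],
                                      model$C[j[ok], , drop = FALSE],
                                      model$N[j[ok] + 1, , drop = FALSE],
                                      model$CA[j[ok] + 1, , drop = FALSE]) * 180 / pi
  }
  data.frame(phi = phi, psi = psi, omega = omega)
}

#' Stereochemistry check of a backbone model
#'
#' Flags residues whose bond lengths (N-CA, CA-C, C-N(+1), C=O) deviate
#' more than `tol_bond` from standard values (1.458, 1.525, 1.329,
#' 1.231 Angstrom) or whose omega deviates more than `tol_omega` degrees
#' from 180 (trans).
#'
#' @param model a `backbone_model`.
#' @param tol_bond bond-length tolerance in Angstrom (default 0.25).
#' @param tol_omega omega tolerance in degrees (default 30).
#' @return logical vector, TRUE where the residue passes all checks that
#'   apply to it (checks with missing atoms are skipped).
#' @export
check_stereochemistry <- function(model, tol_bond = 0.25, tol_omega = 30) {
  n <- length(model)
  ok <- rep(TRUE, n)
  chk <- function(a, b, r0) {
    pass <- abs(rownorm(a - b) - r0) <= tol_bond
    pass[is.na(pass)] <- TRUE  # missing atoms: check skipped
    pass
  }
  ok <- ok & chk(model$N, model$CA, 1.458)
  ok <- ok & chk(model$CA, model$C, 1.525)
  ok <- ok & chk(model$C, model$O, 1.231)
  if (n >= 2) {
    i <- 1:(n - 1)
    pass <- chk(model$C[i, , drop = FALSE], model$N[i + 1, , drop = FALSE], 1.329)
    ok[i] <- ok[i] & pass
    om <- phi_psi(model)$omega[i]
    pass <- abs(wrap_angle((om - 180) * pi / 180)) * 180 / pi <= tol_omega
    pass[is.na(pass)] <- TRUE
    ok[i] <- ok[i] & pass
  }
  ok
}
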