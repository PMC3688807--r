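#' C-alpha chain objects
#'
#' A `ca_chain` is the sole structural state of the coarse-grained model:
#' an ordered set of residues, their C-alpha coordinates and a mobility
#' mask (anchors and scaffold are immobile, loop residues mobile).
#'
#' @param ids data.frame with columns `chain_id`, `resnum`, `icode`,
#'   `resname` (3-letter code), one row per residue, strictly ordered and
#'   unique within each chain.
#' @param xyz numeric n x 3 matrix of C-alpha coordinates in Angstrom.
#' @param mobile logical vector of length n; defaults to all mobile.
#' @return object of class `ca_chain`.
#' @export
ca_chain <- function(ids, xyz, mobile = NULL) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  n <- nrow(xyz)
  stopifnot(ncol(xyz) == 3, nrow(ids) == n)
  if (!all(is.finite(xyz))) stop("ca_chain: coordinates must be finite")
  if (is.null(mobile)) mobile <- rep(TRUE, n)
  stopifnot(length(mobile) == n)
  ids$icode <- as.character(ids$icode)
  key <- paste(ids$chain_id, ids$resnum, ids$icode)
  dup <- key[duplicated(key)]
  if (length(dup)) stop("ca_chain: duplicate residue identifier(s): ",
                        paste(unique(dup), collapse = ", "))
  structure(list(ids = ids, xyz = xyz, mobile = as.logical(mobile)),
            class = "ca_chain")
}

#' @export
length.ca_chain <- function(x) nrow(x$xyz)

#' @export
print.ca_chain <- function(x, ...) {
  cat(sprintf("<ca_chain> %d residues (%d mobile), chains: %s\n",
              length(x), sum(x$mobile),
              paste(unique(x$ids$chain_id), collapse = ",")))
  invisible(x)
}

#' Diagnostic check of consecutive C-alpha distances
#'
#' A physically valid trace has consecutive C-alpha distances inside
#' (2.0, 4.6) Angstrom. The sampler may transiently violate this, so the
#' check is a diagnostic flag, never a hard error.
#'
#' @param chain a `ca_chain`.
#' @return logical vector (length n-1), TRUE where the bond is in range.
#' @export
ca_bond_ok <- function(chain) {
  d <- rownorm(diff(chain$xyz))
  d > 2.0 & d < 4.6
}

#' Loop region definition
#'
#' Identifies a contiguous stretch of mobile residues; the residues
#' immediately flanking it are the fixed anchors.
#'
#' @param chain_id chain identifier (single character string).
#' @param first,last residue numbers of the first and last mobile residue.
#' @param icode_first,icode_last insertion codes (default `""`).
#' @return object of class `loop_region`.
#' @export
loop_region <- function(chain_id, first, last,
                        icode_first = "", icode_last = "") {
  stopifnot(is.character(chain_id), length(chain_id) == 1)
  structure(list(chain_id = chain_id, first = first, last = last,
                 icode_first = icode_first, icode_last = icode_last),
            class = "loop_region")
}

#' Residue indices of a loop region within a structure
#'
#' Maps PDB-style residue labels to 0-free internal 1-based indices and
#' verifies that both anchors (the residues flanking the region) exist.
#'
#' @param ids residue id data.frame (as in [ca_chain()]).
#' @param region a [loop_region()].
#' @return integer vector of region residue indices.
#' @export
region_indices <- function(ids, region) {
  key <- paste(ids$chain_id, ids$resnum, ids$icode)
  i1 <- match(paste(region$chain_id, region$first, region$icode_first), key)
  i2 <- match(paste(region$chain_id, region$last, region$icode_last), key)
  if (is.na(i1) || is.na(i2) || i2 < i1)
    stop("loop region not found in structure: ",
         region$chain_id, ":", region$first, "-", region$last)
  if (i1 == 1 || i2 == nrow(ids))
    stop("loop region has no flanking anchor residue on one side")
  if (!all(ids$chain_id[c(i1 - 1, i2 + 1)] == region$chain_id))
    stop("anchor residues are not on chain ", region$chain_id)
  i1:i2
}

#' Set the mobility mask of a chain from a loop region
#'
#' Mobile residues are exactly those inside the region; anchors and the
#' rest of the scaffold become immobile.
#'
#' @inheritParams region_indices
#' @param chain a `ca_chain`.
#' @return the chain with its `mobile` mask replaced.
#' @export
set_mobile_region <- function(chain, region) {
  idx <- region_indices(chain$ids, region)
  chain$mobile <- seq_len(length(chain)) %in% idx
  chain
}

#' Pseudo bond angle at an interior residue
#'
#' The angle at `Ca_i` subtended by `Ca_(i-1)` and `Ca_(i+1)`, one of the
#' internal coordinates on which the structural-alphabet local term of the
#' coarse-grained potential acts.
#'
#' @param chain a `ca_chain`.
#' @param i interior residue index (1-based; `2 <= i <= n-1`).
#' @return angle in radians, in `[0, pi]`.
#' @export
pseudo_bond_angle <- function(chain, i) {
  n <- length(chain)
  if (any(i < 2 | i > n - 1)) stop("pseudo bond angle undefined at terminal residue")
  angle_points(chain$xyz[i - 1, , drop = FALSE],
               chain$xyz[i, , drop = FALSE],
               chain$xyz[i + 1, , drop = FALSE])
}

#' Pseudo dihedral of four consecutive C-alpha atoms
#'
#' Signed torsion of `Ca_i .. Ca_(i+3)` (right-handed, IUPAC convention).
#'
#' @param chain a `ca_chain`.
#' @param i index of the first residue of the tetrad (`1 <= i <= n-3`).
#' @return angle in radians in `(-pi, pi]`.
#' @export
pseudo_dihedral <- function(chain, i) {
  n <- length(chain)
  if (any(i < 1 | i > n - 3)) stop("pseudo dihedral undefined: tetrad exceeds chain")
  dihedral_points(chain$xyz[i, , drop = FALSE],
                  chain$xyz[i + 1, , drop = FALSE],
                  chain$xyz[i + 2, , drop = FALSE],
                  chain$xyz[i + 3, , drop = FALSE])
}

#' Pseudo N and O atoms at an interior residue
#'
#' Places hydrogen-bonding pseudo atoms in the local frame spanned by the
#' two pseudo-bonds at residue i: with bisector b of the unit vectors to
#' the two neighbours and plane normal m = u1 x u2, the pseudo atoms sit at
#' `Ca_i + off * (cos(g) b +/- sin(g) m)` on opposite sides of the C-alpha
#' plane. Offsets `off` and mixing angle `g` are entries of [cg_params()].
#' The construction is an approximation: the original geometric recipe is
#' defined in cited prior work and not reproduced here, so the offsets are
#' trainable parameters rather than fixed constants.
#'
#' @param chain a `ca_chain`.
#' @param i interior residue index (vectorised).
#' @param params a [cg_params()] (only the `pseudo` block is used).
#' @return list with matrices `n` and `o` (one row per requested residue;
#'   NA rows where the three C-alpha atoms are collinear and no frame
#'   exists — such residues are excluded from hydrogen-bond sums).
#' @export
levitt_pseudo_atoms <- function(chain, i, params = default_cg_params()) {
  nres <- length(chain)
  if (any(i < 2 | i > nres - 1)) stop("pseudo atoms undefined at terminal residues")
  p0 <- chain$xyz[i - 1, , drop = FALSE]
  p1 <- chain$xyz[i, , drop = FALSE]
  p2 <- chain$xyz[i + 1, , drop = FALSE]
  u1 <- p0 - p1; u1 <- u1 / rownorm(u1)
  u2 <- p2 - p1; u2 <- u2 / rownorm(u2)
  b <- u1 + u2
  nb <- rownorm(b)
  bad <- nb < 1e-9  # collinear triple: no defined frame, pseudo atoms NA
  b <- b / ifelse(bad, 1, nb)
  m <- rowcross(u1, u2)
  nm <- rownorm(m)
  bad <- bad | nm < 1e-12
  m <- m / ifelse(bad, 1, nm)
  b[bad, ] <- NA_real_
  g <- params$pseudo$mix_angle
  dirN <- cos(g) * b + sin(g) * m
  dirO <- cos(g) * b - sin(g) * m
  list(n = p1 + params$pseudo$n_offset * dirN,
       o = p1 + params$pseudo$o_offset * dirO)
}

#' Global-frame backbone RMSD (RMSD-G)
#'
#' Root-mean-square deviation over the backbone heavy atoms N, CA, C and O
#' of the region residues, computed in the fixed frame with no
#' superposition. This is the loop-accuracy metric used throughout the
#' decoy statistics.
#'
#' @param model,reference `backbone_model` objects with identical residue
#'   sets over the region.
#' @param region a [loop_region()].
#' @return RMSD in Angstrom.
#' @export
rmsd_g <- function(model, reference, region) {
  idx <- region_indices(model$ids, region)
  ridx <- region_indices(reference$ids, region)
  if (length(idx) != length(ridx))
    stop("model and reference disagree over the region")
  dev2 <- 0
  for (at in c("N", "CA", "C", "O")) {
    a <- model[[at]][idx, , drop = FALSE]
    b <- reference[[at]][ridx, , drop = FALSE]
    bad <- !stats::complete.cases(a) | !stats::complete.cases(b)
    if (any(bad)) {
      r <- model$ids[idx[which(bad)[1]], ]
      stop(sprintf("missing %s atom at residue %s%d%s", at,
                   r$chain_id, r$resnum, r$icode))
    }
    dev2 <- dev2 + sum((a - b)^2)
  }
  sqrt(dev2 / (4 * length(idx)))
}
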