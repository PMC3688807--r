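#' Backbone force-field parameters
#'
#' United-atom style backbone potential: harmonic bond and angle terms,
#' periodic torsions, a harmonic improper keeping the carbonyl planar,
#' Lennard-Jones on 1-4 and 1-5 intra-backbone pairs, a soft steric
#' repulsion for all other non-bonded pairs (including loop vs. fixed
#' scaffold) and a binned backbone-backbone hydrogen-bond statistical
#' potential over H...O distance and N-H...O angle. The shipped parameter
#' file carries standard united-atom backbone values; nothing is
#' hard-coded in the package functions.
#'
#' @param bonds named list of `c(r0, k)` per bond class (`N-CA`, `CA-C`,
#'   `C-O`, `C-N`); energy `0.5 k (r - r0)^2`.
#' @param angles named list of `c(theta0_deg, k)` per angle class;
#'   energy `0.5 k (theta - theta0)^2` in radians.
#' @param torsions named list of `c(n, phase_deg, V)` per torsion class
#'   (`phi`, `psi`, `omega`); energy `V (1 + cos(n x - phase))`.
#' @param impropers named list of `c(target_deg, k)`; harmonic in the
#'   wrapped improper dihedral.
#' @param lj named list of `c(sigma, epsilon)` per atom class (N, CA, C,
#'   O); geometric-mean combination, applied to 1-4 and 1-5 pairs.
#' @param steric list `r_rep`, `k_rep` for the soft clash penalty.
#' @param hbond list `r_edges`, `a_edges` (degrees), `values` (matrix
#'   r-bins x angle-bins, floor-capped), applied to N-H...O pairs with
#'   `|i - j| >= 2`.
#' @return object of class `backbone_ff`.
#' @export
backbone_ff <- function(bonds, angles, torsions, impropers, lj, steric,
                        hbond) {
  stopifnot(all(c("N-CA", "CA-C", "C-O", "C-N") %in% names(bonds)),
            all(c("N-CA-C", "CA-C-O", "CA-C-N", "O-C-N", "C-N-CA") %in%
                  names(angles)),
            all(c("phi", "psi", "omega") %in% names(torsions)),
            all(c("N", "CA", "C", "O") %in% names(lj)))
  if (any(vapply(lj, function(v) any(v <= 0), TRUE)))
    stop("LJ sigma and epsilon must be positive")
  structure(list(bonds = bonds, angles = angles, torsions = torsions,
                 impropers = impropers, lj = lj, steric = steric,
                 hbond = hbond),
            class = "backbone_ff")
}

#' Write backbone force-field parameters as YAML
#'
#' @param ff a [backbone_ff()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_backbone_ff <- function(ff, file) {
  obj <- list(format = "pd2loop backbone_ff v1",
              bonds = lapply(ff$bonds, as.numeric),
              angles = lapply(ff$angles, as.numeric),
              torsions = lapply(ff$torsions, as.numeric),
              impropers = lapply(ff$impropers, as.numeric),
              lj = lapply(ff$lj, as.numeric),
              steric = ff$steric,
              hbond = list(r_edges = ff$hbond$r_edges,
                           a_edges = ff$hbond$a_edges,
                           values = apply(ff$hbond$values, 1, as.numeric,
                                          simplify = FALSE)))
  yaml::write_yaml(obj, file, precision = 12)
  invisible(file)
}

#' Read backbone force-field parameters written by [write_backbone_ff()]
#'
#' @param file path.
#' @return a [backbone_ff()].
#' @export
read_backbone_ff <- function(file) {
  obj <- yaml::read_yaml(file)
  if (!identical(obj$format, "pd2loop backbone_ff v1"))
    stop("not a pd2loop backbone_ff file")
  backbone_ff(bonds = obj$bonds, angles = obj$angles,
              torsions = obj$torsions, impropers = obj$impropers,
              lj = obj$lj, steric = obj$steric,
              hbond = list(r_edges = as.numeric(obj$hbond$r_edges),
                           a_edges = as.numeric(obj$hbond$a_edges),
                           values = do.call(rbind, obj$hbond$values)))
}

#' Shipped default backbone force field
#' @return a [backbone_ff()].
#' @export
default_backbone_ff <- function() .load_default("backbone_ff.yaml",
                                                read_backbone_ff)
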