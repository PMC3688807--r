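#' Coarse-grained potential parameters
#'
#' Container for every parameter of the five-term C-alpha potential:
#' per-letter harmonic centres and force constants plus unigram reference
#' energies, bigram reference energies, the pseudo-bond term, the soft
#' steric repulsion, the binned pseudo hydrogen-bond table and the
#' pseudo-atom construction offsets. Energies are dimensionless
#' "statistical energy" (kT at beta = 1); beta carries all temperature
#' dependence.
#'
#' @param letters data.frame with one row per alphabet letter and columns
#'   `theta0_1`, `theta0_2`, `tau0` (radians), `k_theta`, `k_tau`
#'   (energy/rad^2) and `e_ref` (unigram reference energy).
#' @param e_ref2 k x k matrix of bigram reference energies for consecutive
#'   fragment letter pairs.
#' @param bond list `r0` (Angstrom, default 3.8) and `k` (energy/A^2).
#' @param steric list `r_rep` (clash onset, default 4.5 A), `k_rep`
#'   (energy/A^2, default 10) and `min_sep` (minimum sequence separation,
#'   default 3).
#' @param hbond list `edges` (strictly increasing bin edges, Angstrom) and
#'   `values` (one per bin; the last must be 0 for cutoff continuity).
#' @param pseudo list `n_offset`, `o_offset` (Angstrom) and `mix_angle`
#'   (radians) of the pseudo N/O construction.
#' @param r0_cis optional cis-proline pseudo-bond length (default 2.95 A).
#' @return object of class `cg_params`.
#' @export
cg_params <- function(letters, e_ref2 = NULL,
                      bond = list(r0 = 3.8, k = 100),
                      steric = list(r_rep = 4.5, k_rep = 10, min_sep = 3),
                      hbond = list(edges = seq(3.0, 6.5, by = 0.25),
                                   values = rep(0, 14)),
                      pseudo = list(n_offset = 1.0, o_offset = 1.0,
                                    mix_angle = pi / 4),
                      r0_cis = 2.95) {
  letters <- as.data.frame(letters)
  need <- c("theta0_1", "theta0_2", "tau0", "k_theta", "k_tau", "e_ref")
  stopifnot(all(need %in% names(letters)))
  k <- nrow(letters)
  if (is.null(e_ref2)) e_ref2 <- matrix(0, k, k)
  e_ref2 <- as.matrix(e_ref2)
  stopifnot(nrow(e_ref2) == k, ncol(e_ref2) == k)
  if (any(c(letters$k_theta, letters$k_tau, bond$k, steric$k_rep) < 0))
    stop("force constants must be >= 0")
  if (is.null(steric$min_sep)) steric$min_sep <- 3
  stopifnot(all(diff(hbond$edges) > 0),
            length(hbond$values) == length(hbond$edges) - 1)
  if (abs(hbond$values[length(hbond$values)]) > 1e-12)
    stop("hbond table must reach 0 in the last bin (cutoff continuity)")
  structure(list(letters = letters, e_ref2 = e_ref2, bond = bond,
                 steric = steric, hbond = hbond, pseudo = pseudo,
                 r0_cis = r0_cis),
            class = "cg_params")
}

#' @export
print.cg_params <- function(x, ...) {
  cat(sprintf(paste0("<cg_params> %d letters; bond r0=%.2f k=%.3g; steric ",
                     "r_rep=%.2f k=%.3g; hbond %d bins\n"),
              nrow(x$letters), x$bond$r0, x$bond$k, x$steric$r_rep,
              x$steric$k_rep, length(x$hbond$values)))
  invisible(x)
}

#' Minimal control-mode parameters
#'
#' Only the pseudo-bond and soft steric terms are active: all alphabet
#' harmonics, reference energies and hydrogen-bond values are zero. Used
#' as the sampling control against the full potential.
#'
#' @param params a [cg_params()] to strip (default: shipped defaults).
#' @return a [cg_params()] with only bond + steric terms active.
#' @export
control_cg_params <- function(params = default_cg_params()) {
  params$letters$k_theta <- 0
  params$letters$k_tau <- 0
  params$letters$e_ref <- 0
  params$e_ref2[] <- 0
  params$hbond$values[] <- 0
  params
}

#' Write CG parameters as a structured text (YAML) file
#'
#' @param params a [cg_params()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_cg_params <- function(params, file) {
  obj <- list(format = "pd2loop cg_params v1",
              letters = as.list(as.data.frame(params$letters)),
              e_ref2 = apply(params$e_ref2, 1, as.numeric, simplify = FALSE),
              bond = params$bond, steric = params$steric,
              hbond = params$hbond, pseudo = params$pseudo,
              r0_cis = params$r0_cis)
  yaml::write_yaml(obj, file, precision = 12)
  invisible(file)
}

#' Read CG parameters written by [write_cg_params()]
#'
#' @param file path to the parameter file.
#' @return a [cg_params()].
#' @export
read_cg_params <- function(file) {
  obj <- yaml::read_yaml(file)
  if (!identical(obj$format, "pd2loop cg_params v1"))
    stop("not a pd2loop cg_params file (missing version header)")
  cg_params(letters = as.data.frame(obj$letters),
            e_ref2 = do.call(rbind, obj$e_ref2),
            bond = obj$bond, steric = obj$steric,
            hbond = list(edges = as.numeric(obj$hbond$edges),
                         values = as.numeric(obj$hbond$values)),
            pseudo = obj$pseudo, r0_cis = obj$r0_cis)
}

## cache for shipped defaults
.pd2_defaults <- new.env(parent = emptyenv())

.load_default <- function(name, loader) {
  if (!is.null(.pd2_defaults[[name]])) return(.pd2_defaults[[name]])
  path <- system.file("extdata", name, package = "pd2loop")
  if (path == "") stop("shipped default '", name, "' not found")
  .pd2_defaults[[name]] <- loader(path)
  .pd2_defaults[[name]]
}

#' Shipped default CG parameters
#'
#' Trained on the package's synthetic structure family (see the methods
#' vignette); these are not the published parameters of the original
#' potential, which live in cited prior work.
#'
#' @return a [cg_params()].
#' @export
default_cg_params <- function() .load_default("cg_params.yaml", read_cg_params)

#' Shipped default structural alphabet
#'
#' 27 letters fitted on the synthetic structure family; not the published
#' alphabet.
#'
#' @return an [alphabet_model()].
#' @export
default_alphabet <- function() .load_default("alphabet.txt", read_alphabet)
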