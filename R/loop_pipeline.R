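#' Loop decoy ensemble generation and statistics
#'
#' End-to-end orchestration: initialise the loop, relax it in the full
#' C-alpha potential, generate decoys by repeated annealing inner cycles,
#' rebuild and filter backbones, minimise each accepted decoy in the
#' backbone potential and score the ensemble against the native loop by
#' global-frame backbone RMSD with bootstrap confidence intervals.
#'
#' @name loop_pipeline
NULL

## normalise structure input: fixture list, backbone_model or PDB path/text
.as_structure <- function(x) {
  if (is.list(x) && !is.null(x$ca)) return(list(ca = x$ca, backbone = x$backbone))
  if (inherits(x, "backbone_model")) return(list(ca = ca_trace(x), backbone = x))
  if (inherits(x, "ca_chain")) return(list(ca = x, backbone = NULL))
  if (is.character(x)) return(read_structure(x))
  stop("unsupported structure input")
}

.md5_of <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(obj, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

## replace the loop residues of the native backbone with rebuilt atoms;
## the two junction peptide units are re-seeded from the native anchors'
## internal coordinates so minimisation starts from a trans peptide
.splice_backbone <- function(native, rebuilt, idx) {
  out <- if (is.null(native)) rebuilt else native
  for (at in c("N", "CA", "C", "O"))
    out[[at]][idx, ] <- rebuilt[[at]][idx, ]
  out$mobile <- seq_len(length(out)) %in% idx
  if (!is.null(native)) {
    rad <- pi / 180
    first <- min(idx); last <- max(idx); n <- length(out)
    a0 <- first - 1; a1 <- last + 1
    tor <- phi_psi(native)
    ## N(first) continues the native psi of the N-terminal anchor
    if (a0 >= 1 && is.finite(tor$psi[a0]))
      out$N[first, ] <- .nerf_place(native$N[a0, ], native$CA[a0, ],
                                    native$C[a0, ], 1.329, 116.6 * rad,
                                    tor$psi[a0] * rad)
    ## C(last) closes a trans peptide onto the native phi of the
    ## C-terminal anchor; O(last) then follows the local psi
    if (a1 <= n && is.finite(tor$phi[a1])) {
      out$C[last, ] <- .nerf_place(native$C[a1, ], native$CA[a1, ],
                                   native$N[a1, ], 1.329, 121.9 * rad,
                                   tor$phi[a1] * rad)
      psi_l <- dihedral_points(out$N[last, ], out$CA[last, ],
                               out$C[last, ], native$N[a1, ])
      out$O[last, ] <- .nerf_place(out$N[last, ], out$CA[last, ],
                                   out$C[last, ], 1.231, 120.4 * rad,
                                   psi_l - pi)
    }
  }
  out
}

## rotate twisted peptide units (|omega| far from 180) about their
## CA(i)-CA(i+1) axis to the most trans-like orientation, so conjugate-
## gradient minimisation starts inside the trans basin; deterministic
.fix_omega <- function(model, idx, tol_deg = 25) {
  n <- length(model)
  for (i in idx) {
    if (i + 1 > n) next
    atoms <- rbind(model$CA[i, ], model$C[i, ], model$N[i + 1, ],
                   model$CA[i + 1, ])
    if (!all(is.finite(atoms))) next
    om <- dihedral_points(atoms[1, ], atoms[2, ], atoms[3, ], atoms[4, ])
    if (abs(wrap_angle(om - pi)) <= tol_deg * pi / 180) next
    axis <- model$CA[i + 1, ] - model$CA[i, ]
    if (vnorm(axis) < 1e-6) next
    ## only mobile atoms may be rotated; the scaffold never moves
    movable <- c(C = model$mobile[i], O = model$mobile[i],
                 N = model$mobile[i + 1])
    if (!any(movable)) next
    unit <- rbind(model$C[i, ], model$O[i, ], model$N[i + 1, ])
    best <- NULL; best_dev <- Inf
    for (alpha in seq(-pi, pi, length.out = 73)) {
      cand <- unit
      cand[movable, ] <- rotate_about_axis(unit[movable, , drop = FALSE],
                                           model$CA[i, ], axis, alpha)
      om_c <- dihedral_points(model$CA[i, ], cand[1, ], cand[3, ],
                              model$CA[i + 1, ])
      dev <- abs(wrap_angle(om_c - pi))
      if (dev < best_dev) { best_dev <- dev; best <- cand }
    }
    model$C[i, ] <- best[1, ]
    model$O[i, ] <- best[2, ]
    model$N[i + 1, ] <- best[3, ]
  }
  model
}

#' Generate a loop decoy ensemble
#'
#' Runs the full sampling protocol: the native loop C-alpha positions are
#' discarded and re-initialised by anchor-anchor interpolation plus a
#' small random displacement and bond/steric minimisation; the loop is
#' relaxed in the sampling potential (`relaxation_steps` of simulated
#' annealing); then decoys are drawn by repeated annealing inner cycles,
#' each followed by backbone reconstruction and the adaptive
#' forbidden-phi/psi filter. Accepted conformations are minimised in the
#' backbone potential. Rejected conformations trigger another inner cycle
#' from the current state, so exactly `n_decoys` accepted decoys are
#' returned. Control mode strips the potential to pseudo-bond + steric
#' terms. Deterministic given `config$seed`.
#'
#' @param structure a fixture list, [backbone_model()], [ca_chain()] or
#'   PDB path/text.
#' @param region a [loop_region()].
#' @param n_decoys number of accepted decoys to generate.
#' @param config an [mc_config()].
#' @param mode `"pd2"` (full potential) or `"control"` (bond + steric
#'   only).
#' @param alphabet,params,ff,lookup,rama model components (shipped
#'   defaults).
#' @param margin adaptive-filter margin (default 1; see the methods
#'   vignette for why a zero margin over-rejects with a conservative
#'   fixture-trained Ramachandran map).
#' @param minimize_backbone minimise each accepted decoy (default TRUE).
#' @param minimize_iter iteration cap of the per-decoy backbone
#'   minimisation.
#' @param max_rejects abort after this many consecutive filter rejections
#'   (default 500; the adaptive filter is designed to make this
#'   unreachable).
#' @return object of class `decoy_ensemble`.
#' @export
generate_ensemble <- function(structure, region, n_decoys = 100,
                              config = mc_config(),
                              mode = c("pd2", "control"),
                              alphabet = default_alphabet(),
                              params = default_cg_params(),
                              ff = default_backbone_ff(),
                              lookup = default_lookup_table(),
                              rama = default_rama_map(),
                              margin = 1, minimize_backbone = TRUE,
                              minimize_iter = 150, max_rejects = 2000) {
  mode <- match.arg(mode)
  s <- .as_structure(structure)
  ca <- set_mobile_region(s$ca, region)
  idx <- region_indices(ca$ids, region)
  native <- s$backbone
  params_use <- if (mode == "control") control_cg_params(params) else params
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  ca <- init_loop(ca, params_use)
  if (config$relaxation_steps > 0)
    ca <- anneal(ca, config, alphabet, params_use,
                 n_steps = config$relaxation_steps)$chain
  fstate <- filter_state(length(idx), margin)
  decoys <- vector("list", n_decoys)
  got <- 0L
  n_rejected <- 0L
  consec <- 0L
  while (got < n_decoys) {
    run <- anneal(ca, config, alphabet, params_use,
                  n_steps = config$inner_cycle_steps)
    ca <- run$chain
    rebuilt <- build_backbone(ca, lookup)
    decoy_bb <- .splice_backbone(native, rebuilt, idx)
    nf <- count_forbidden(decoy_bb, region, rama)
    res <- adaptive_filter(nf, fstate)
    fstate <- res$state
    if (!res$accept) {
      n_rejected <- n_rejected + 1L
      consec <- consec + 1L
      if (consec > max_rejects)
        stop("acceptance stalled: ", consec,
             " consecutive filter rejections (n_best = ", fstate$n_best, ")")
      next
    }
    consec <- 0L
    if (minimize_backbone) {
      decoy_bb <- .fix_omega(decoy_bb, c(min(idx) - 1L, idx))
      decoy_bb <- minimize_cg(decoy_bb, ff, max_iter = minimize_iter)
    }
    got <- got + 1L
    decoys[[got]] <- list(
      backbone = decoy_bb,
      cg_energy = suppressWarnings(total_cg_energy(ca, alphabet, params_use)),
      backbone_energy = if (minimize_backbone) attr(decoy_bb, "value")
                        else backbone_energy(decoy_bb, ff)[["total"]],
      n_forbidden = nf,
      rmsd_g = if (!is.null(native)) rmsd_g(decoy_bb, native, region) else NA_real_)
  }
  structure(list(decoys = decoys, region = region, mode = mode,
                 config = config, n_rejected = n_rejected,
                 filter_state = fstate,
                 provenance = list(seed = config$seed,
                                   params_hash = .md5_of(params_use),
                                   alphabet_hash = .md5_of(alphabet),
                                   ff_hash = .md5_of(ff))),
            class = "decoy_ensemble")
}

#' @export
print.decoy_ensemble <- function(x, ...) {
  r <- vapply(x$decoys, `[[`, 0, "rmsd_g")
  cat(sprintf(paste0("<decoy_ensemble> %d decoys (%s mode), %d filter ",
                     "rejections; RMSD-G best %.2f mean %.2f\n"),
              length(x$decoys), x$mode, x$n_rejected,
              suppressWarnings(min(r)), mean(r)))
  invisible(x)
}

#' Per-decoy table of an ensemble
#'
#' @param x a `decoy_ensemble`.
#' @param ... unused.
#' @return data.frame with one row per decoy (energies, forbidden counts,
#'   RMSD-G).
#' @export
as.data.frame.decoy_ensemble <- function(x, ...) {
  data.frame(decoy = seq_along(x$decoys),
             cg_total = vapply(x$decoys, function(d) d$cg_energy$total, 0),
             cg_sa = vapply(x$decoys, function(d) d$cg_energy$e_sa_local, 0),
             cg_bond = vapply(x$decoys, function(d) d$cg_energy$e_bond, 0),
             cg_steric = vapply(x$decoys, function(d) d$cg_energy$e_steric, 0),
             cg_hbond = vapply(x$decoys, function(d) d$cg_energy$e_hbond, 0),
             cg_ref = vapply(x$decoys, function(d) d$cg_energy$e_ref_total, 0),
             backbone_energy = vapply(x$decoys, `[[`, 0, "backbone_energy"),
             n_forbidden = vapply(x$decoys, `[[`, 0, "n_forbidden"),
             rmsd_g = vapply(x$decoys, `[[`, 0, "rmsd_g"))
}

#' Select the prediction from an ensemble
#'
#' The decoy with the lowest ranking (backbone) energy; ties broken by the
#' lowest decoy index.
#'
#' @param ensemble a `decoy_ensemble`.
#' @return the selected decoy (list); attribute `index` gives its
#'   position.
#' @export
select_prediction <- function(ensemble) {
  if (!length(ensemble$decoys)) stop("empty ensemble")
  e <- vapply(ensemble$decoys, `[[`, 0, "backbone_energy")
  i <- which.min(e)  # which.min returns the first minimum: lowest index
  out <- ensemble$decoys[[i]]
  attr(out, "index") <- i
  out
}

#' Ensemble accuracy statistics with bootstrap confidence intervals
#'
#' Best and mean RMSD-G plus the fractions of decoys below 1 and 2
#' Angstrom; 95% percentile confidence intervals from an m-out-of-n
#' bootstrap (resample `m` decoys with replacement per replicate).
#'
#' @param ensemble a `decoy_ensemble` scored against a native loop.
#' @param n_boot bootstrap replicates (default 1000).
#' @param m decoys resampled per replicate (default 1000, matching
#'   comparisons against 1000-decoy ensembles).
#' @param seed RNG seed for the resampling.
#' @return object of class `ensemble_stats`: list with `best_rmsd`,
#'   `mean_rmsd`, `frac_sub1`, `frac_sub2` and a `ci` matrix (2.5/97.5
#'   percentiles per statistic).
#' @export
ensemble_stats <- function(ensemble, n_boot = 1000, m = 1000, seed = 1) {
  r <- vapply(ensemble$decoys, `[[`, 0, "rmsd_g")
  if (any(is.na(r))) stop("ensemble has no native RMSD-G values")
  stat <- function(x) c(best_rmsd = min(x), mean_rmsd = mean(x),
                        frac_sub1 = mean(x < 1), frac_sub2 = mean(x < 2))
  est <- stat(r)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  boots <- t(vapply(seq_len(n_boot), function(b)
    stat(r[sample.int(length(r), m, replace = TRUE)]), est))
  ci <- apply(boots, 2, stats::quantile, probs = c(0.025, 0.975))
  structure(list(best_rmsd = est[["best_rmsd"]],
                 mean_rmsd = est[["mean_rmsd"]],
                 frac_sub1 = est[["frac_sub1"]],
                 frac_sub2 = est[["frac_sub2"]],
                 ci = ci, n_boot = n_boot, m = m),
            class = "ensemble_stats")
}

#' @export
print.ensemble_stats <- function(x, ...) {
  cat(sprintf(paste0("best RMSD-G %.2f A [%.2f, %.2f]; mean %.2f A ",
                     "[%.2f, %.2f]; frac <1A %.2f; frac <2A %.2f\n"),
              x$best_rmsd, x$ci[1, "best_rmsd"], x$ci[2, "best_rmsd"],
              x$mean_rmsd, x$ci[1, "mean_rmsd"], x$ci[2, "mean_rmsd"],
              x$frac_sub1, x$frac_sub2))
  invisible(x)
}

## phi/psi-window secondary-structure assignment (internal substitute for
## an external assignment program)
.ss_assign <- function(model) {
  tor <- phi_psi(model)
  n <- length(model)
  h_ok <- !is.na(tor$phi) & !is.na(tor$psi) &
    tor$phi >= -100 & tor$phi <= -30 & tor$psi >= -80 & tor$psi <= -5
  s_ok <- !is.na(tor$phi) & !is.na(tor$psi) &
    tor$phi >= -180 & tor$phi <= -40 &
    ((tor$psi >= 90 & tor$psi <= 180) | (tor$psi >= -180 & tor$psi <= -170))
  ss <- rep("C", n)
  mark_runs <- function(ok, min_run, label, ss) {
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$lengths))
      if (r$values[k] && r$lengths[k] >= min_run && all(ss[starts[k]:ends[k]] == "C"))
        ss[starts[k]:ends[k]] <- label
    ss
  }
  ss <- mark_runs(h_ok, 4, "H", ss)
  ss <- mark_runs(s_ok & ss == "C", 3, "E", ss)
  ss
}

#' Find candidate loops in a structure
#'
#' Residues are assigned helix/strand/coil from phi/psi windows (helix:
#' phi in [-100, -30] and psi in [-80, -5] over at least 4 consecutive
#' residues; strand: phi in [-180, -40] and psi in [90, 180] or
#' [-180, -170] over at least 3; everything else coil). Maximal coil runs
#' with length in `[min_len, max_len]` and an anchor on both sides are
#' returned.
#'
#' @param structure a [backbone_model()] (or anything [read_structure()]
#'   accepts that yields a full backbone).
#' @param min_len,max_len loop length range (defaults 2 and 12).
#' @return list of [loop_region()] objects.
#' @export
find_loops <- function(structure, min_len = 2, max_len = 12) {
  s <- .as_structure(structure)
  if (is.null(s$backbone)) stop("find_loops needs a full backbone")
  bb <- s$backbone
  ss <- .ss_assign(bb)
  r <- rle(ss == "C")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- list()
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    len <- r$lengths[k]
    if (len < min_len || len > max_len) next
    if (starts[k] == 1 || ends[k] == length(bb)) next  # no anchor
    out[[length(out) + 1]] <- loop_region(bb$ids$chain_id[starts[k]],
                                          bb$ids$resnum[starts[k]],
                                          bb$ids$resnum[ends[k]],
                                          bb$ids$icode[starts[k]],
                                          bb$ids$icode[ends[k]])
  }
  out
}
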