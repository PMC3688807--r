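#!/usr/bin/env Rscript
## Regenerates the shipped default parameter files in inst/extdata from the
## package's synthetic training family. Run from the repository root with
## the package installed:  Rscript scripts/make_defaults.R
suppressMessages(library(pd2loop))

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

message("training family ...")
fam <- fixture_family(n_sets = 3, seed = 42, noise = 0.08)
chains <- lapply(fam, `[[`, "ca")
bbs <- lapply(fam, `[[`, "backbone")

## ---- structural alphabet -------------------------------------------------
message("alphabet ...")
alpha <- train_alphabet(chains, n_letters = 27, seed = 7, n_restart = 20)
alpha$metadata$trained_on <- "pd2loop synthetic fixture family v1"
write_alphabet(alpha, "inst/extdata/alphabet.txt")

## ---- per-letter harmonics from cluster spread ----------------------------
desc <- do.call(rbind, lapply(chains, function(ch)
  fragment_descriptor(ch, seq_len(length(ch) - 3))))
lab <- assign_letter(desc, alpha)
k <- alpha$n_letters
k_theta <- k_tau <- numeric(k)
for (L in seq_len(k)) {
  m <- lab == L
  vt <- mean(c(stats::var(desc[m, 1]), stats::var(desc[m, 2])))
  dtau <- wrap_angle(desc[m, 3] - alpha$prototypes[L, 3])
  vtau <- mean(dtau^2)
  ## harmonic force constant = 1/var (kT units), kept in a sane range so
  ## sampling stays diverse
  k_theta[L] <- min(max(1 / max(vt, 1e-3), 2), 50)
  k_tau[L] <- min(max(1 / max(vtau, 1e-3), 2), 50)
}
freq <- letter_frequencies(chains, alpha)

## ---- CG pseudo hydrogen-bond table ---------------------------------------
message("cg hbond table ...")
edges <- seq(3.0, 6.5, by = 0.25)
pseudo <- list(n_offset = 1.0, o_offset = 1.0, mix_angle = pi / 4)
tmp_params <- cg_params(
  letters = data.frame(theta0_1 = alpha$prototypes[, 1],
                       theta0_2 = alpha$prototypes[, 2],
                       tau0 = alpha$prototypes[, 3],
                       k_theta = k_theta, k_tau = k_tau, e_ref = 0),
  pseudo = pseudo)
dists <- unlist(lapply(chains, function(ch) {
  n <- length(ch)
  if (n < 5) return(NULL)
  pa <- levitt_pseudo_atoms(ch, 2:(n - 1), tmp_params)
  idx <- 2:(n - 1)
  m <- length(idx)
  ii <- rep(seq_len(m), each = m); jj <- rep(seq_len(m), m)
  keep <- abs(idx[ii] - idx[jj]) >= 2
  sqrt(rowSums((pa$n[ii[keep], ] - pa$o[jj[keep], ])^2))
}))
cnt <- hist(dists[dists >= 3 & dists < 6.5], breaks = edges, plot = FALSE)$counts
shell <- diff(edges^3)
p_obs <- (cnt + 1) / sum(cnt + 1)
p_ref <- shell / sum(shell)
hb_val <- -log(p_obs / p_ref)
hb_val <- pmin(pmax(hb_val, -3), 3)
hb_val <- hb_val - hb_val[length(hb_val)]  # zero at the cutoff bin

params <- cg_params(
  letters = data.frame(theta0_1 = alpha$prototypes[, 1],
                       theta0_2 = alpha$prototypes[, 2],
                       tau0 = alpha$prototypes[, 3],
                       k_theta = k_theta, k_tau = k_tau,
                       e_ref = 0),
  e_ref2 = matrix(0, k, k),
  hbond = list(edges = edges, values = hb_val),
  pseudo = pseudo)

## ---- reference energies by iterative Boltzmann fitting -------------------
message("reference energies ...")
train_chains <- lapply(fam[seq(1, length(fam), by = 18)][1:4], `[[`, "ca")
params <- fit_reference_energies(alpha, params, freq, train_chains,
                                 beta = 1, n_chunks = 4,
                                 steps_per_chunk = 6000,
                                 record_stride = 25, lambda = 0.5,
                                 tol = 0.10, max_iter = 40, seed = 11)
message("  converged: ", attr(params, "converged"),
        "  final dev: ", round(tail(attr(params, "history"), 1), 3))
write_cg_params(params, "inst/extdata/cg_params.yaml")

## ---- Ramachandran map ----------------------------------------------------
message("rama map ...")
rama <- build_rama_map(bbs)
write_rama_map(rama, "inst/extdata/rama_map.txt")
message("  forbidden fraction: ", round(mean(rama$forbidden), 3))

## ---- backbone look-up table ----------------------------------------------
message("lookup table ...")
lk <- build_lookup_table(bbs)
write_lookup_table(lk, "inst/extdata/backbone_lookup.txt")
print(lk)

## ---- backbone force field ------------------------------------------------
## Standard united-atom backbone values (bond/angle equilibria from
## peptide geometry, force constants and LJ in kcal/mol-style units).
message("backbone ff ...")
bb_hb_fit <- local({
  r_edges <- seq(1.4, 3.0, by = 0.1)
  a_edges <- seq(90, 180, by = 10)
  cnt <- matrix(0, length(r_edges) - 1, length(a_edges) - 1)
  for (bb in bbs) {
    n <- length(bb)
    don <- 2:n
    for (i in don) {
      u1 <- bb$C[i - 1, ] - bb$N[i, ]; u1 <- u1 / sqrt(sum(u1^2))
      u2 <- bb$CA[i, ] - bb$N[i, ]; u2 <- u2 / sqrt(sum(u2^2))
      hd <- -(u1 + u2); hd <- hd / sqrt(sum(hd^2))
      H <- bb$N[i, ] + hd
      js <- which(abs(seq_len(n) - i) >= 2)
      r <- sqrt(rowSums(sweep(bb$O[js, , drop = FALSE], 2, H)^2))
      sel <- r >= 1.4 & r < 3.0
      if (!any(sel)) next
      for (j in which(sel)) {
        v1 <- bb$N[i, ] - H
        v2 <- bb$O[js[j], ] - H
        ang <- acos(min(1, max(-1, sum(v1 * v2) /
                                 sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        rb <- findInterval(r[j], r_edges)
        ab <- findInterval(ang, a_edges)
        if (ab >= 1 && ab <= ncol(cnt)) cnt[rb, ab] <- cnt[rb, ab] + 1
      }
    }
  }
  shell_r <- diff(r_edges^3)
  shell_a <- abs(diff(cos(a_edges * pi / 180)))
  ref <- outer(shell_r, shell_a)
  p_obs <- (cnt + 0.5) / sum(cnt + 0.5)
  p_ref <- ref / sum(ref)
  v <- -log(p_obs / p_ref)
  v <- pmin(pmax(v, -3), 3)
  v[cnt == 0] <- 0  # no signal: neutral
  list(r_edges = r_edges, a_edges = a_edges, values = v)
})
ff <- backbone_ff(
  bonds = list(`N-CA` = c(1.458, 600), `CA-C` = c(1.525, 600),
               `C-O` = c(1.231, 1100), `C-N` = c(1.329, 900)),
  angles = list(`N-CA-C` = c(110.1, 120), `CA-C-O` = c(120.4, 160),
                `CA-C-N` = c(116.6, 140), `O-C-N` = c(122.9, 160),
                `C-N-CA` = c(121.9, 100)),
  ## omega is a single-minimum (trans-only) restraint: cis peptides are
  ## out of the model's scope, so the regulariser must not trap units there
  torsions = list(phi = c(3, 0, 0.3), psi = c(1, 180, 0.4),
                  omega = c(1, 0, 80)),
  impropers = list(`C-planar` = c(180, 40)),
  lj = list(N = c(3.25, 0.17), CA = c(3.80, 0.08), C = c(3.75, 0.105),
            O = c(2.96, 0.21)),
  steric = list(r_rep = 2.8, k_rep = 25),
  hbond = bb_hb_fit)
write_backbone_ff(ff, "inst/extdata/backbone_ff.yaml")

message("done; files: ", paste(dir("inst/extdata"), collapse = ", "))
for (f in dir("inst/extdata", full.names = TRUE))
  message(sprintf("  %-30s %6.1f KB", basename(f), file.size(f) / 1024))
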