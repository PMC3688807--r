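#' Backbone reconstruction and Ramachandran filtering
#'
#' Backbone N, C and O atoms are rebuilt from the C-alpha trace by a fast
#' look-up: local C-alpha geometry (two skip distances and the chirality
#' of the 4-residue tetrad) indexes a table of mean peptide-unit
#' placements expressed in each residue's local frame. Rebuilt loops are
#' screened by counting residues whose phi/psi fall in strictly forbidden
#' cells of a non-residue-specific Ramachandran map, with an adaptive
#' acceptance threshold that cannot get stuck.
#'
#' @name backbone_builder
NULL

## local frame of residue i: origin CA_i, x towards CA_(i+1), y the
## orthogonalised direction of `ref` (usually CA_(i-1) - CA_i), z = x X y
.residue_frame <- function(origin, nxt, ref) {
  ex <- vunit(nxt - origin)
  ey <- ref - sum(ref * ex) * ex
  if (vnorm(ey) < 1e-8) {
    ## collinear reference: fall back to a deterministic perpendicular
    ey <- vcross(ex, c(0, 0, 1))
    if (vnorm(ey) < 1e-8) ey <- vcross(ex, c(0, 1, 0))
  }
  ey <- vunit(ey)
  list(origin = origin, R = cbind(ex, ey, vcross(ex, ey)))
}

.frame_local <- function(frame, p) as.numeric(t(frame$R) %*% (p - frame$origin))
.frame_global <- function(frame, v) as.numeric(frame$R %*% v + frame$origin)

## geometry key of residue i (needs CA_(i-1) .. CA_(i+2)):
## d13 = d(i-1, i+1), d24 = d(i, i+2), chirality of the tetrad
.lookup_key <- function(xyz, i, bin = 0.2, d_min = 4.0, n_bins = 18) {
  d13 <- vnorm(xyz[i + 1, ] - xyz[i - 1, ])
  d24 <- vnorm(xyz[i + 2, ] - xyz[i, ])
  v1 <- xyz[i, ] - xyz[i - 1, ]
  v2 <- xyz[i + 1, ] - xyz[i, ]
  v3 <- xyz[i + 2, ] - xyz[i + 1, ]
  chir <- if (sum(vcross(v1, v2) * v3) >= 0) 1L else -1L
  b13 <- min(max(floor((d13 - d_min) / bin), 0), n_bins - 1)
  b24 <- min(max(floor((d24 - d_min) / bin), 0), n_bins - 1)
  c(b13 = b13, b24 = b24, chir = chir)
}

#' Build the backbone look-up table from full-backbone structures
#'
#' For every interior residue of the training structures the peptide-unit
#' atoms C(i), O(i) and N(i+1) are expressed in the residue's local
#' C-alpha frame and averaged per discretised geometry key (0.2 Angstrom
#' distance bins, binary chirality). Sparse keys fall back to the nearest
#' populated key at query time, so every key in the discretisation range
#' resolves to a payload. Deterministic.
#'
#' @param structures list of [backbone_model()] objects with complete
#'   backbones.
#' @param bin distance bin width (Angstrom).
#' @param d_min lower edge of the distance discretisation.
#' @param n_bins number of distance bins per axis.
#' @return object of class `backbone_lookup`.
#' @export
build_lookup_table <- function(structures, bin = 0.2, d_min = 4.0,
                               n_bins = 18) {
  if (!length(structures)) stop("empty training set")
  acc <- new.env(parent = emptyenv())
  for (bb in structures) {
    n <- length(bb)
    if (n < 4) next
    xyz <- bb$CA
    for (i in 2:(n - 2)) {
      atoms <- rbind(bb$C[i, ], bb$O[i, ], bb$N[i + 1, ])
      if (!all(is.finite(atoms))) next
      fr <- .residue_frame(xyz[i, ], xyz[i + 1, ], xyz[i - 1, ] - xyz[i, ])
      key <- .lookup_key(xyz, i, bin, d_min, n_bins)
      id <- paste(key, collapse = "_")
      pay <- c(.frame_local(fr, atoms[1, ]), .frame_local(fr, atoms[2, ]),
               .frame_local(fr, atoms[3, ]))
      if (is.null(acc[[id]])) acc[[id]] <- list(s = pay, n = 1, key = key)
      else acc[[id]] <- list(s = acc[[id]]$s + pay, n = acc[[id]]$n + 1,
                             key = key)
    }
  }
  ids <- ls(acc)
  if (!length(ids)) stop("no usable peptide units in training set")
  keys <- t(vapply(ids, function(k) acc[[k]]$key, numeric(3)))
  pays <- t(vapply(ids, function(k) acc[[k]]$s / acc[[k]]$n, numeric(9)))
  counts <- vapply(ids, function(k) acc[[k]]$n, numeric(1))
  ord <- order(keys[, 3], keys[, 1], keys[, 2])
  structure(list(keys = keys[ord, , drop = FALSE],
                 payloads = pays[ord, , drop = FALSE],
                 counts = counts[ord],
                 bin = bin, d_min = d_min, n_bins = n_bins),
            class = "backbone_lookup")
}

#' @export
print.backbone_lookup <- function(x, ...) {
  cat(sprintf("<backbone_lookup> %d populated keys of %d (%.0f peptide units)\n",
              nrow(x$keys), 2 * x$n_bins^2, sum(x$counts)))
  invisible(x)
}

## payload for a key with nearest-populated fallback (same chirality
## preferred; distance in bin units)
.lookup_payload <- function(table, key) {
  hit <- which(table$keys[, 1] == key[1] & table$keys[, 2] == key[2] &
               table$keys[, 3] == key[3])
  if (length(hit)) return(table$payloads[hit[1], ])
  same <- table$keys[, 3] == key[3]
  cand <- if (any(same)) which(same) else seq_len(nrow(table$keys))
  d2 <- (table$keys[cand, 1] - key[1])^2 + (table$keys[cand, 2] - key[2])^2
  table$payloads[cand[which.min(d2)], ]
}

#' Rebuild backbone N, C, O atoms from a C-alpha trace
#'
#' CA coordinates are copied unchanged; C(i), O(i) and N(i+1) are placed
#' from the look-up payload expressed in residue i's local frame.
#' Terminal residues use borrowed keys and reversed/extrapolated frames
#' and are approximate; they are regularised by the subsequent backbone
#' minimisation.
#'
#' @param ca a [ca_chain()] of length >= 4 with finite coordinates.
#' @param table a [build_lookup_table()] result (default: shipped table).
#' @return a [backbone_model()] carrying the chain's mobility mask.
#' @export
build_backbone <- function(ca, table = default_lookup_table()) {
  n <- length(ca)
  if (n < 4) stop("backbone reconstruction needs at least 4 residues")
  xyz <- ca$xyz
  if (!all(is.finite(xyz))) stop("non-finite C-alpha coordinates")
  N <- C <- O <- matrix(NA_real_, n, 3)
  place <- function(fr, pay) list(C = .frame_global(fr, pay[1:3]),
                                  O = .frame_global(fr, pay[4:6]),
                                  N = .frame_global(fr, pay[7:9]))
  for (i in 2:(n - 2)) {
    fr <- .residue_frame(xyz[i, ], xyz[i + 1, ], xyz[i - 1, ] - xyz[i, ])
    pay <- .lookup_payload(table, .lookup_key(xyz, i, table$bin,
                                              table$d_min, table$n_bins))
    pl <- place(fr, pay)
    C[i, ] <- pl$C; O[i, ] <- pl$O; N[i + 1, ] <- pl$N
  }
  ## residue 1: frame reference borrowed from the forward direction
  fr <- .residue_frame(xyz[1, ], xyz[2, ], xyz[3, ] - xyz[1, ])
  pay <- .lookup_payload(table, .lookup_key(xyz, 2, table$bin, table$d_min,
                                            table$n_bins))
  pl <- place(fr, pay)
  C[1, ] <- pl$C; O[1, ] <- pl$O; N[2, ] <- pl$N
  ## residue n-1: key borrowed from n-2
  fr <- .residue_frame(xyz[n - 1, ], xyz[n, ], xyz[n - 2, ] - xyz[n - 1, ])
  pay <- .lookup_payload(table, .lookup_key(xyz, n - 2, table$bin,
                                            table$d_min, table$n_bins))
  pl <- place(fr, pay)
  C[n - 1, ] <- pl$C; O[n - 1, ] <- pl$O; N[n, ] <- pl$N
  ## residue n: extrapolated frame continuing the chain direction
  virt <- xyz[n, ] + (xyz[n, ] - xyz[n - 1, ])
  fr <- .residue_frame(xyz[n, ], virt, xyz[n - 2, ] - xyz[n, ])
  pl <- place(fr, pay)
  C[n, ] <- pl$C; O[n, ] <- pl$O
  ## residue 1 N: reversed frame at residue 1 (approximate)
  fr <- .residue_frame(xyz[1, ], xyz[1, ] + (xyz[1, ] - xyz[2, ]),
                       xyz[2, ] - xyz[1, ] + (xyz[3, ] - xyz[1, ]) * 0.01)
  N[1, ] <- .frame_global(fr, pay[7:9])
  backbone_model(ca$ids, N, xyz, C, O, mobile = ca$mobile)
}

#' Ramachandran map of strictly forbidden regions
#'
#' 10-degree phi/psi cells over `[-180, 180)^2`. A cell is allowed when
#' the training structures populate it or lie within `dilate` cells of a
#' populated cell (dilation closes isolated holes and keeps the map
#' conservative only about regions far from anything ever observed);
#' everything else is strictly forbidden. Non-residue-specific.
#'
#' @param structures list of [backbone_model()] training structures.
#' @param cell cell size in degrees (default 10).
#' @param dilate dilation steps around observed cells (default 2).
#' @return object of class `rama_map` (logical `forbidden` matrix).
#' @export
build_rama_map <- function(structures, cell = 10, dilate = 2) {
  nc <- as.integer(360 / cell)
  obs <- matrix(FALSE, nc, nc)
  for (bb in structures) {
    tor <- phi_psi(bb)
    ok <- !is.na(tor$phi) & !is.na(tor$psi)
    if (!any(ok)) next
    ip <- .rama_cell(tor$phi[ok], cell)
    is <- .rama_cell(tor$psi[ok], cell)
    obs[cbind(ip, is)] <- TRUE
  }
  allowed <- obs
  sh <- function(m, di, dj) {
    i <- ((seq_len(nc) - 1 + di) %% nc) + 1
    j <- ((seq_len(nc) - 1 + dj) %% nc) + 1
    m[i, j, drop = FALSE]
  }
  for (step in seq_len(dilate)) {
    prev <- allowed
    for (di in -1:1) for (dj in -1:1)
      allowed <- allowed | sh(prev, di, dj)
  }
  map <- structure(list(forbidden = !allowed, cell = cell,
                        provenance = sprintf("%d training structures",
                                             length(structures))),
                   class = "rama_map")
  if (mean(map$forbidden) < 0.5)
    warning("Ramachandran map is not conservative: < 50% of cells forbidden")
  map
}

.rama_cell <- function(deg, cell) {
  d <- ((deg + 180) %% 360)
  pmin(pmax(floor(d / cell), 0), as.integer(360 / cell) - 1) + 1L
}

#' @export
print.rama_map <- function(x, ...) {
  cat(sprintf("<rama_map> %d-degree cells, %.0f%% forbidden (%s)\n",
              x$cell, 100 * mean(x$forbidden), x$provenance))
  invisible(x)
}

#' Count loop residues with forbidden phi/psi
#'
#' @param model a [backbone_model()].
#' @param region a [loop_region()].
#' @param map a `rama_map` (default: shipped map).
#' @return integer count; residues with undefined torsions never count.
#' @export
count_forbidden <- function(model, region, map = default_rama_map()) {
  idx <- region_indices(model$ids, region)
  tor <- phi_psi(model)[idx, ]
  ok <- !is.na(tor$phi) & !is.na(tor$psi)
  if (!any(ok)) return(0L)
  sum(map$forbidden[cbind(.rama_cell(tor$phi[ok], map$cell),
                          .rama_cell(tor$psi[ok], map$cell))])
}

#' Adaptive Ramachandran filter state
#'
#' `n_best` starts at the region length, so the first conformation is
#' always accepted; thereafter a conformation is accepted iff its
#' forbidden count is at most `n_best + margin`, and `n_best` tracks the
#' lowest accepted count. Designed so the generator can never get stuck
#' with no acceptable loops.
#'
#' @param region_length number of loop residues.
#' @param margin slack above the best previously accepted count
#'   (default 0).
#' @return filter state list.
#' @export
filter_state <- function(region_length, margin = 0) {
  list(n_best = region_length, margin = margin)
}

#' Apply the adaptive forbidden-phi/psi filter
#'
#' @param n_forbidden forbidden-residue count of the candidate.
#' @param state a [filter_state()].
#' @return list `accept` (logical) and `state` (updated; `n_best` is
#'   non-increasing over a run).
#' @export
adaptive_filter <- function(n_forbidden, state) {
  accept <- n_forbidden <= state$n_best + state$margin
  if (accept) state$n_best <- min(state$n_best, n_forbidden)
  list(accept = accept, state = state)
}

#' Serialise / read a Ramachandran map
#'
#' Versioned text grid: one row per phi cell, `F` forbidden / `A`
#' allowed.
#'
#' @param map a `rama_map`.
#' @param file path.
#' @return the path (write) or a `rama_map` (read).
#' @export
write_rama_map <- function(map, file) {
  nc <- nrow(map$forbidden)
  lines <- c(sprintf("# pd2loop rama_map v1 cell=%d provenance=%s",
                     map$cell, map$provenance),
             vapply(seq_len(nc), function(i)
               paste(ifelse(map$forbidden[i, ], "F", "A"), collapse = ""), ""))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_rama_map
#' @export
read_rama_map <- function(file) {
  lines <- readLines(file)
  if (!grepl("^# pd2loop rama_map v1", lines[1]))
    stop("not a pd2loop rama_map file")
  cell <- as.numeric(sub(".*cell=(\\d+).*", "\\1", lines[1]))
  prov <- sub(".*provenance=", "", lines[1])
  grid <- do.call(rbind, lapply(lines[-1], function(l)
    strsplit(l, "")[[1]] == "F"))
  structure(list(forbidden = grid, cell = cell, provenance = prov),
            class = "rama_map")
}

#' Serialise / read a backbone look-up table
#'
#' @param table a `backbone_lookup`.
#' @param file path.
#' @return the path (write) or a `backbone_lookup` (read).
#' @export
write_lookup_table <- function(table, file) {
  hdr <- sprintf("# pd2loop backbone_lookup v1 bin=%g d_min=%g n_bins=%d",
                 table$bin, table$d_min, table$n_bins)
  rows <- vapply(seq_len(nrow(table$keys)), function(i)
    paste(c(table$keys[i, ], table$counts[i],
            sprintf("%.4f", table$payloads[i, ])), collapse = "\t"), "")
  writeLines(c(hdr, rows), file)
  invisible(file)
}

#' @rdname write_lookup_table
#' @export
read_lookup_table <- function(file) {
  lines <- readLines(file)
  if (!grepl("^# pd2loop backbone_lookup v1", lines[1]))
    stop("not a pd2loop backbone_lookup file")
  gethdr <- function(k) as.numeric(sub(paste0(".*", k, "=([-0-9.]+).*"), "\\1",
                                       lines[1]))
  m <- do.call(rbind, lapply(strsplit(lines[-1], "\t"), as.numeric))
  structure(list(keys = m[, 1:3, drop = FALSE],
                 payloads = m[, 5:13, drop = FALSE],
                 counts = m[, 4],
                 bin = gethdr("bin"), d_min = gethdr("d_min"),
                 n_bins = as.integer(gethdr("n_bins"))),
            class = "backbone_lookup")
}

#' Shipped default Ramachandran map
#' @return a `rama_map`.
#' @export
default_rama_map <- function() .load_default("rama_map.txt", read_rama_map)

#' Shipped default backbone look-up table
#' @return a `backbone_lookup`.
#' @export
default_lookup_table <- function() .load_default("backbone_lookup.txt",
                                                 read_lookup_table)
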