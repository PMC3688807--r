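#' Read a protein structure from PDB format
#'
#' Parses ATOM records via bio3d and assembles the C-alpha chain plus, where
#' backbone atoms are present, a [backbone_model()]. Only the first MODEL of
#' multi-model files is used; alternate locations are resolved by highest
#' occupancy then first-seen; residues lacking a CA atom are dropped with a
#' warning. Hydrogens and hetero atoms are ignored.
#'
#' @param pdb path to a PDB file, or a character string/vector of PDB-format
#'   text (anything containing a newline or an ATOM record is treated as
#'   text).
#' @return list with elements `ca` (a [ca_chain()]) and `backbone` (a
#'   [backbone_model()], or NULL when no N/C/O atoms are present).
#' @export
read_structure <- function(pdb) {
  path <- pdb
  if (length(pdb) > 1 || grepl("\n", pdb[1]) || grepl("^(ATOM|HETATM|MODEL|REMARK|HEADER)", pdb[1])) {
    path <- tempfile(fileext = ".pdb")
    writeLines(if (length(pdb) > 1) pdb else strsplit(pdb, "\n")[[1]], path)
    on.exit(unlink(path))
  }
  p <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                        verbose = FALSE))
  at <- p$atom[p$atom$type == "ATOM", , drop = FALSE]
  at <- at[at$elety %in% c("N", "CA", "C", "O"), , drop = FALSE]
  if (nrow(at) == 0 || !any(at$elety == "CA"))
    stop("no CA atoms found: cannot build a C-alpha chain")
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  ## altloc resolution: highest occupancy, ties by first appearance
  grp <- paste(at$chain, at$resno, at$insert, at$elety)
  ord <- order(match(grp, unique(grp)), -at$o, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  dup_alt <- duplicated(paste(at$chain, at$resno, at$insert, at$elety))
  kept <- at[!dup_alt, , drop = FALSE]
  dropped <- at[dup_alt, , drop = FALSE]
  if (any(dropped$alt == "" | dropped$alt == kept$alt[match(
        paste(dropped$chain, dropped$resno, dropped$insert, dropped$elety),
        paste(kept$chain, kept$resno, kept$insert, kept$elety))]))
    stop("duplicate atom records (not altlocs) for residue ",
         with(dropped[1, ], paste0(chain, resno, insert)))
  at <- kept[order(match(paste(kept$chain, kept$resno, kept$insert),
                         unique(paste(at$chain, at$resno, at$insert)))), ,
             drop = FALSE]
  rk <- paste(at$chain, at$resno, at$insert)
  res <- at[!duplicated(rk), c("chain", "resno", "insert", "resid"), drop = FALSE]
  rownames(res) <- NULL
  has_ca <- paste(res$chain, res$resno, res$insert) %in%
    rk[at$elety == "CA"]
  if (any(!has_ca)) {
    warning("dropping ", sum(!has_ca), " residue(s) lacking a CA atom: ",
            paste(paste0(res$chain, res$resno, res$insert)[!has_ca],
                  collapse = ", "))
    res <- res[has_ca, , drop = FALSE]
  }
  ids <- data.frame(chain_id = res$chain, resnum = res$resno,
                    icode = res$insert, resname = res$resid,
                    stringsAsFactors = FALSE)
  getm <- function(elety) {
    m <- matrix(NA_real_, nrow(ids), 3)
    sel <- at$elety == elety
    j <- match(paste(at$chain, at$resno, at$insert)[sel],
               paste(ids$chain_id, ids$resnum, ids$icode))
    keep <- !is.na(j)
    m[j[keep], ] <- as.matrix(at[sel, c("x", "y", "z")])[keep, , drop = FALSE]
    m
  }
  CA <- getm("CA")
  ca <- ca_chain(ids, CA)
  N <- getm("N"); C <- getm("C"); O <- getm("O")
  bb <- NULL
  if (any(stats::complete.cases(N)) || any(stats::complete.cases(C)))
    bb <- backbone_model(ids, N, CA, C, O)
  list(ca = ca, backbone = bb)
}

#' Write a structure in PDB format
#'
#' Fixed-column PDB writer (via bio3d) emitting occupancy 1.00 and
#' B-factor 0.00. Accepts a C-alpha chain (CA records only) or a backbone
#' model (N, CA, C, O records; residues with missing atoms are written with
#' the atoms they have).
#'
#' @param x a [ca_chain()] or [backbone_model()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_structure <- function(x, file) {
  if (inherits(x, "ca_chain")) {
    ids <- x$ids
    xyz <- x$xyz
    elety <- rep("CA", nrow(xyz))
    resmap <- seq_len(nrow(xyz))
  } else if (inherits(x, "backbone_model")) {
    ids <- x$ids
    n <- nrow(ids)
    xyz <- NULL; elety <- character(0); resmap <- integer(0)
    for (i in seq_len(n)) {
      for (at in c("N", "CA", "C", "O")) {
        v <- x[[at]][i, ]
        if (all(is.finite(v))) {
          xyz <- rbind(xyz, v)
          elety <- c(elety, at)
          resmap <- c(resmap, i)
        }
      }
    }
  } else stop("write_structure: unsupported object")
  na <- length(elety)
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(xyz)),
                   resno = ids$resnum[resmap],
                   resid = ids$resname[resmap],
                   chain = ids$chain_id[resmap],
                   insert = ifelse(ids$icode[resmap] == "", NA,
                                   ids$icode[resmap]),
                   elety = elety,
                   eleno = seq_len(na),
                   o = rep(1, na), b = rep(0, na))
  invisible(file)
}
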