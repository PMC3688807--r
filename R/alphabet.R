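#' Structural alphabet model
#'
#' A set of prototype local conformations ("letters", 27 by default) for
#' 4-residue C-alpha fragments. Each fragment is summarised by the minimal
#' rigid-motion-invariant descriptor (theta1, theta2, tau): the pseudo bond
#' angles at the two interior residues and the pseudo dihedral of the
#' tetrad. Letters are assigned by nearest prototype under the periodic
#' metric `sqrt(dtheta1^2 + dtheta2^2 + wrap(dtau)^2)`.
#'
#' @param prototypes numeric k x 3 matrix, columns `theta1`, `theta2`
#'   (radians, in `[0, pi]`) and `tau` (radians, in `(-pi, pi]`).
#' @param metadata named list (training-set identifier, date, ...).
#' @return object of class `alphabet_model`.
#' @export
alphabet_model <- function(prototypes, metadata = list()) {
  prototypes <- as.matrix(prototypes)
  stopifnot(ncol(prototypes) == 3)
  colnames(prototypes) <- c("theta1", "theta2", "tau")
  if (any(prototypes[, 1:2] < 0 | prototypes[, 1:2] > pi))
    stop("prototype theta out of [0, pi]")
  if (anyDuplicated(round(prototypes, 10)))
    stop("two prototypes are identical")
  structure(list(n_letters = nrow(prototypes), prototypes = prototypes,
                 metadata = metadata),
            class = "alphabet_model")
}

#' @export
print.alphabet_model <- function(x, ...) {
  cat(sprintf("<alphabet_model> %d letters (%s)\n", x$n_letters,
              if (!is.null(x$metadata$trained_on)) x$metadata$trained_on else "untrained"))
  invisible(x)
}

#' Descriptor of a 4-residue C-alpha fragment
#'
#' @param chain a [ca_chain()].
#' @param i start index of the fragment (vectorised; `1 <= i <= n-3`).
#' @return matrix with columns `theta1`, `theta2`, `tau` (radians).
#' @export
fragment_descriptor <- function(chain, i) {
  n <- length(chain)
  if (n < 4) stop("fragment descriptor needs at least 4 residues")
  if (any(i < 1 | i > n - 3)) stop("fragment start index out of range")
  cbind(theta1 = pseudo_bond_angle(chain, i + 1),
        theta2 = pseudo_bond_angle(chain, i + 2),
        tau = pseudo_dihedral(chain, i))
}

## squared periodic descriptor distance between rows of d and each prototype
.alpha_dist2 <- function(d, prototypes) {
  k <- nrow(prototypes)
  out <- matrix(0, nrow(d), k)
  for (j in seq_len(k)) {
    out[, j] <- (d[, 1] - prototypes[j, 1])^2 +
      (d[, 2] - prototypes[j, 2])^2 +
      wrap_angle(d[, 3] - prototypes[j, 3])^2
  }
  out
}

#' Assign structural-alphabet letters to descriptors
#'
#' Nearest prototype under the periodic metric; ties broken by lowest
#' letter index.
#'
#' @param d descriptor matrix (columns theta1, theta2, tau) or a single
#'   descriptor vector.
#' @param model an [alphabet_model()].
#' @return integer letter indices in `[1, n_letters]`.
#' @export
assign_letter <- function(d, model) {
  if (is.null(dim(d))) d <- rbind(d)
  max.col(-.alpha_dist2(d, model$prototypes), ties.method = "first")
}

#' Letters of every fragment of a chain
#'
#' @param chain a [ca_chain()] of length >= 4.
#' @param model an [alphabet_model()].
#' @return integer vector of length `n - 3`.
#' @export
chain_letters <- function(chain, model) {
  n <- length(chain)
  if (n < 4) return(integer(0))
  assign_letter(fragment_descriptor(chain, seq_len(n - 3)), model)
}

## collect fragment descriptors from a list of ca_chain objects
.collect_descriptors <- function(structures) {
  do.call(rbind, lapply(structures, function(ch) {
    if (length(ch) < 4) return(NULL)
    fragment_descriptor(ch, seq_len(length(ch) - 3))
  }))
}

#' Train a structural alphabet by periodic k-means
#'
#' Lloyd-style clustering of all fragment descriptors under the periodic
#' metric (tau differences wrapped; cluster tau centres are circular
#' means). Runs `n_restart` seeded random initialisations and keeps the
#' lowest within-cluster sum of squared periodic distances. Deterministic
#' given the seed.
#'
#' @param structures list of [ca_chain()] objects.
#' @param n_letters number of letters (default 27).
#' @param seed integer RNG seed.
#' @param n_restart random restarts (default 20).
#' @param max_iter Lloyd iteration cap per restart.
#' @return an [alphabet_model()]; attribute `objective` holds the final
#'   within-cluster sum of squares.
#' @export
train_alphabet <- function(structures, n_letters = 27, seed = 1,
                           n_restart = 20, max_iter = 100) {
  d <- .collect_descriptors(structures)
  need <- 10 * n_letters
  if (is.null(d) || nrow(d) < need)
    stop("too few fragments for training: need at least ", need,
         ", got ", if (is.null(d)) 0 else nrow(d))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  best <- NULL
  best_obj <- Inf
  best_hist <- NULL
  for (r in seq_len(n_restart)) {
    centres <- d[sample.int(nrow(d), n_letters), , drop = FALSE]
    obj_prev <- Inf
    hist <- numeric(0)
    for (it in seq_len(max_iter)) {
      d2 <- .alpha_dist2(d, centres)
      lab <- max.col(-d2, ties.method = "first")
      obj <- sum(d2[cbind(seq_len(nrow(d)), lab)])
      hist <- c(hist, obj)
      for (k in seq_len(n_letters)) {
        m <- lab == k
        if (!any(m)) {  # re-seed an empty cluster at the worst-fit point
          centres[k, ] <- d[which.max(d2[cbind(seq_len(nrow(d)), lab)]), ]
        } else {
          centres[k, 1] <- mean(d[m, 1])
          centres[k, 2] <- mean(d[m, 2])
          centres[k, 3] <- circ_mean(d[m, 3])
        }
      }
      if (obj_prev - obj < 1e-10) break
      obj_prev <- obj
    }
    if (obj < best_obj) { best_obj <- obj; best <- centres; best_hist <- hist }
  }
  ord <- order(best[, 1], best[, 2], best[, 3])
  model <- alphabet_model(best[ord, , drop = FALSE],
                          metadata = list(trained_on = sprintf("%d fragments", nrow(d)),
                                          seed = seed))
  attr(model, "objective") <- best_obj
  attr(model, "history") <- best_hist
  model
}

#' Letter and letter-pair frequencies of a structure set
#'
#' Unigram frequencies over all fragments and bigram frequencies over
#' pairs of fragments starting at consecutive residues.
#'
#' @param structures list of [ca_chain()] objects.
#' @param model an [alphabet_model()].
#' @return list with `unigram` (length k, sums to 1) and `bigram`
#'   (k x k matrix, sums to 1; all-zero when no chain has >= 5 residues).
#' @export
letter_frequencies <- function(structures, model) {
  k <- model$n_letters
  uni <- numeric(k)
  bi <- matrix(0, k, k)
  for (ch in structures) {
    if (length(ch) < 4) next
    lab <- chain_letters(ch, model)
    t1 <- tabulate(lab, k)
    uni <- uni + t1
    if (length(lab) >= 2)
      for (f in seq_len(length(lab) - 1))
        bi[lab[f], lab[f + 1]] <- bi[lab[f], lab[f + 1]] + 1
  }
  if (sum(uni) == 0) stop("no fragments in structure set")
  list(unigram = uni / sum(uni),
       bigram = if (sum(bi) > 0) bi / sum(bi) else bi)
}

#' Write an alphabet model to a flat key-value text file
#'
#' @param model an [alphabet_model()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_alphabet <- function(model, file) {
  lines <- c("# pd2loop alphabet v1",
             paste0("n_letters\t", model$n_letters),
             vapply(names(model$metadata), function(k)
               paste0("meta_", k, "\t", model$metadata[[k]]), ""),
             vapply(seq_len(model$n_letters), function(i)
               sprintf("letter\t%d\t%.12g\t%.12g\t%.12g", i,
                       model$prototypes[i, 1], model$prototypes[i, 2],
                       model$prototypes[i, 3]), ""))
  writeLines(lines, file)
  invisible(file)
}

#' Read an alphabet model written by [write_alphabet()]
#'
#' @param file path to the alphabet file.
#' @return an [alphabet_model()].
#' @export
read_alphabet <- function(file) {
  lines <- readLines(file)
  if (!grepl("^# pd2loop alphabet v1", lines[1]))
    stop("not a pd2loop alphabet file (missing version header)")
  fields <- strsplit(lines[-1], "\t")
  lets <- fields[vapply(fields, function(f) f[1] == "letter", TRUE)]
  proto <- t(vapply(lets, function(f) as.numeric(f[3:5]), numeric(3)))
  meta <- fields[vapply(fields, function(f) startsWith(f[1], "meta_"), TRUE)]
  md <- stats::setNames(lapply(meta, `[`, 2),
                        sub("^meta_", "", vapply(meta, `[`, "", 1)))
  alphabet_model(proto, md)
}
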