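#' Fit reference energies by iterative Boltzmann correction
#'
#' Tunes the unigram and bigram reference energies so that the equilibrium
#' distribution of structural-alphabet letters (and consecutive-letter
#' pairs) sampled from the potential matches a target distribution
#' (typically letter frequencies observed in a structure database; here,
#' in the training family). Each iteration runs fixed-beta Monte Carlo on
#' the training chains, measures simulated letter frequencies `p_sim` and
#' updates `e_ref <- e_ref + lambda * log(p_sim / p_target)` (same for
#' bigrams), gauged to zero mean and capped, until the largest absolute
#' log-deviation of the unigram frequencies drops below `tol` or the
#' iteration cap is reached.
#'
#' @param alphabet an [alphabet_model()].
#' @param params_init starting [cg_params()].
#' @param target list with `unigram` (strictly positive after flooring)
#'   and optionally `bigram`, as from [letter_frequencies()].
#' @param structures training chains (list of [ca_chain()], all residues
#'   mobile).
#' @param beta inverse temperature of the equilibrium sampling.
#' @param n_chunks,steps_per_chunk,record_stride sampling effort per
#'   iteration (samples = n_chunks * steps_per_chunk / record_stride per
#'   chain).
#' @param lambda update damping (default 0.5).
#' @param tol convergence tolerance on `max |log(p_sim / p_target)|`
#'   (default 0.05).
#' @param max_iter iteration cap (default 50).
#' @param e_cap reference-energy cap; also applied to letters with
#'   (floored) zero target frequency.
#' @param floor_freq floor applied to target frequencies (default 1e-4).
#' @param seed integer seed.
#' @return a [cg_params()] with fitted `e_ref` and `e_ref2`; attributes
#'   `history` (per-iteration max log deviation) and `converged`.
#' @export
fit_reference_energies <- function(alphabet, params_init, target,
                                   structures,
                                   beta = 1, n_chunks = 5,
                                   steps_per_chunk = 4000,
                                   record_stride = 25, lambda = 0.5,
                                   tol = 0.05, max_iter = 50, e_cap = 4,
                                   floor_freq = 1e-3, seed = 1) {
  k <- alphabet$n_letters
  p_t <- pmax(target$unigram, floor_freq)
  p_t <- p_t / sum(p_t)
  p2_t <- if (!is.null(target$bigram)) {
    m <- pmax(target$bigram, floor_freq / k)
    m / sum(m)
  } else NULL
  params <- params_init
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  chains <- structures
  cfg <- mc_config(seed = seed)
  history <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    cnt <- numeric(k)
    cnt2 <- matrix(0, k, k)
    for (ci in seq_along(chains)) {
      ch <- chains[[ci]]
      nres <- length(ch)
      for (chunk in seq_len(n_chunks)) {
        run <- anneal(ch, cfg, alphabet, params,
                      beta_override = rep(beta, steps_per_chunk),
                      record_stride = record_stride)
        ch <- run$chain
        for (si in seq_len(nrow(run$samples))) {
          ch$xyz[ch$mobile, ] <- matrix(run$samples[si, ], ncol = 3,
                                        byrow = TRUE)
          lab <- chain_letters(ch, alphabet)
          cnt <- cnt + tabulate(lab, k)
          if (length(lab) >= 2) {
            pr <- cbind(lab[-length(lab)], lab[-1])
            for (r in seq_len(nrow(pr)))
              cnt2[pr[r, 1], pr[r, 2]] <- cnt2[pr[r, 1], pr[r, 2]] + 1
          }
        }
      }
      chains[[ci]] <- ch  # warm start for the next iteration
    }
    p_sim <- (cnt + 0.5) / sum(cnt + 0.5)
    dev <- log(p_sim / p_t)
    history <- c(history, max(abs(dev)))
    if (max(abs(dev)) < tol) { converged <- TRUE; break }
    er <- params$letters$e_ref + lambda * dev
    er <- er - mean(er)  # gauge: equilibrium is invariant to a constant shift
    params$letters$e_ref <- pmin(pmax(er, -e_cap), e_cap)
    if (!is.null(p2_t)) {
      p2_sim <- (cnt2 + 0.5) / sum(cnt2 + 0.5)
      er2 <- params$e_ref2 + lambda * log(p2_sim / p2_t)
      er2 <- er2 - mean(er2)
      params$e_ref2 <- pmin(pmax(er2, -e_cap), e_cap)
    }
  }
  attr(params, "history") <- history
  attr(params, "converged") <- converged
  params
}
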