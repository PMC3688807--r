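#' Nonlinear conjugate-gradient engine
#'
#' Polak-Ribiere conjugate gradients with restarts (the `type = 2`
#' conjugate-gradient method of [stats::optim()]), run in chunks so the
#' energy trace and a gradient-norm stopping rule can be enforced. The
#' line search guarantees the recorded energy trace is non-increasing.
#' Used by loop initialisation (C-alpha level) and by backbone
#' regularisation.
#'
#' @param fn energy function of a flat coordinate vector.
#' @param gr gradient function of a flat coordinate vector.
#' @param x0 starting coordinates (flat vector).
#' @param tol stopping threshold on the Euclidean gradient norm.
#' @param max_iter iteration cap.
#' @param chunk iterations per convergence check.
#' @return list `x` (final coordinates), `value`, `grad_norm`,
#'   `converged`, `trace` (energy per recorded iterate, non-increasing),
#'   `iterations`.
#' @keywords internal
cg_minimize <- function(fn, gr, x0, tol = 1e-3, max_iter = 500, chunk = 50) {
  x <- x0
  f <- fn(x)
  if (!is.finite(f)) stop("non-finite starting energy in conjugate-gradient minimisation")
  g <- gr(x)
  trace <- f
  it <- 0
  while (it < max_iter && sqrt(sum(g * g)) > tol) {
    steps <- min(chunk, max_iter - it)
    o <- stats::optim(x, fn, gr, method = "CG",
                      control = list(type = 2, maxit = steps))
    it <- it + steps
    if (o$value > f + 1e-10) break  # safeguard: never accept an increase
    no_progress <- f - o$value < 1e-10
    x <- o$par
    f <- o$value
    g <- gr(x)
    trace <- c(trace, f)
    if (no_progress) break  # converged to line-search precision
  }
  list(x = x, value = f, grad_norm = sqrt(sum(g * g)),
       converged = sqrt(sum(g * g)) <= tol, trace = trace, iterations = it)
}

#' Minimise a C-alpha chain in selected CG terms
#'
#' Conjugate-gradient minimisation of the mobile C-alpha coordinates.
#' With `terms = c("bond", "steric")` this is the regulariser used on
#' freshly interpolated loops before annealing.
#'
#' @param chain a [ca_chain()].
#' @param params a [cg_params()].
#' @param alphabet an [alphabet_model()] (needed only when the alphabet
#'   term is included).
#' @param terms character subset of `c("bond", "steric", "sa")`.
#' @param tol gradient-norm tolerance (energy/Angstrom).
#' @param max_iter iteration cap.
#' @return the minimised [ca_chain()]; attributes `value`, `grad_norm`,
#'   `trace`.
#' @export
minimize_ca <- function(chain, params = default_cg_params(),
                        alphabet = default_alphabet(),
                        terms = c("bond", "steric"),
                        tol = 1e-3, max_iter = 500) {
  mob <- which(chain$mobile)
  if (!length(mob)) return(chain)
  p2 <- params
  if (!"sa" %in% terms) {
    ## drop the alphabet term entirely (a one-letter dummy keeps letter
    ## assignment well-defined whatever alphabet the caller holds)
    alphabet <- alphabet_model(matrix(c(1.9, 1.9, 0), 1))
    p2$letters <- data.frame(theta0_1 = 1.9, theta0_2 = 1.9, tau0 = 0,
                             k_theta = 0, k_tau = 0, e_ref = 0)
    p2$e_ref2 <- matrix(0, 1, 1)
  }
  if (!"bond" %in% terms) p2$bond$k <- 0
  if (!"steric" %in% terms) p2$steric$k_rep <- 0
  p2$hbond$values[] <- 0  # binned table: no gradient contribution anyway
  base <- chain
  fn <- function(v) {
    base$xyz[mob, ] <- matrix(v, ncol = 3)
    eb <- suppressWarnings(total_cg_energy(base, alphabet, p2))
    eb$total
  }
  gr <- function(v) {
    base$xyz[mob, ] <- matrix(v, ncol = 3)
    as.numeric(suppressWarnings(cg_gradient(base, alphabet, p2))[mob, ])
  }
  res <- cg_minimize(fn, gr, as.numeric(chain$xyz[mob, ]), tol, max_iter)
  chain$xyz[mob, ] <- matrix(res$x, ncol = 3)
  attr(chain, "value") <- res$value
  attr(chain, "grad_norm") <- res$grad_norm
  attr(chain, "trace") <- res$trace
  chain
}
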