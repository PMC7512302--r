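# Stochastic complexity c_M = log \int dg sqrt(det J(g)): the log volume of
# the model under Jeffreys' prior, i.e. the parameter-geometry part of the
# MDL penalty.  Closed forms exist for loopless models, (sub-)complete models
# and models whose loop structure splits into independent sub-complete
# components; everything else is integrated by Monte Carlo.

.M_CAP_MC <- 15L   # operator-count cap for Monte Carlo integration

#' Construct a complexity estimate
#'
#' @param value complexity in nats.
#' @param std_error standard error (0 for closed forms).
#' @param method one of \code{"closed_loopless"}, \code{"closed_complete"},
#'   \code{"closed_subcomplete"}, \code{"closed_nonoverlapping"},
#'   \code{"monte_carlo"}.
#' @param n_samples,n_reps,seed Monte Carlo metadata (0/0/NA for closed
#'   forms).
#' @return object of class \code{complexity_estimate}.
#' @export
complexity_estimate <- function(value, std_error, method,
                                n_samples = 0L, n_reps = 0L, seed = NA_integer_) {
  method <- match.arg(method, c("closed_loopless", "closed_complete",
                                "closed_subcomplete", "closed_nonoverlapping",
                                "monte_carlo"))
  closed <- method != "monte_carlo"
  if (closed && std_error != 0)
    stop("closed-form estimates have zero standard error")
  if (!closed && std_error < 0) stop("std_error must be >= 0")
  structure(list(value = value, std_error = std_error, method = method,
                 n_samples = as.integer(n_samples),
                 n_reps = as.integer(n_reps), seed = seed),
            class = "complexity_estimate")
}

#' @export
print.complexity_estimate <- function(x, digits = 4, ...) {
  cat("<complexity_estimate> ", format(x$value, digits = digits), " nats",
      if (x$method == "monte_carlo")
        paste0(" (se ", format(x$std_error, digits = 3), ")"),
      "  [", x$method, "]\n", sep = "")
  invisible(x)
}

#' Convert a complexity estimate to bits
#' @param x a \code{complexity_estimate}.
#' @return the same estimate with value and standard error divided by
#'   \eqn{\log 2}.
#' @export
in_bits <- function(x) {
  stopifnot(inherits(x, "complexity_estimate"))
  x$value <- x$value / log(2)
  x$std_error <- x$std_error / log(2)
  x
}

#' Stochastic complexity of the complete model
#'
#' The complete model on \code{n} spins contains all \eqn{2^n - 1} operators;
#' its couplings are in bijection with the \eqn{2^n} state probabilities, and
#' the Jeffreys volume reduces to a Dirichlet integral, giving the closed
#' form \deqn{c_{\bar M} = 2^{n-1} \log \pi - \log \Gamma(2^{n-1}).}
#' The value turns negative for \eqn{n > 4}: complete models are, by this
#' measure, the simplest models of all.
#'
#' @param n number of spins.
#' @return a \code{complexity_estimate} with method \code{closed_complete}.
#' @examples
#' complexity_complete(6)  # about -41.46 nats
#' @export
complexity_complete <- function(n) {
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1")
  half <- 2^(n - 1)
  complexity_estimate(half * log(pi) - lgamma(half), 0,
                      if (n == 1L) "closed_loopless" else "closed_complete")
}

# decompose the model's loop structure into independent components:
# free operators (in no loop) plus connected components of the fundamental
# circuits.  Returns NULL components if lambda = 0.
.loop_components <- function(model) {
  el <- .gf2_eliminate(model$masks)
  m <- length(model$masks)
  gens <- el$generators
  if (length(gens) == 0L)
    return(list(components = list(), free = seq_len(m), lambda = 0L))
  # union-find over operator positions, merging along each circuit
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (gen in gens) {
    r <- find(gen[1L])
    for (i in gen[-1L]) parent[find(i)] <- r
  }
  # path-compress lazily via repeated find
  roots <- vapply(seq_len(m), find, integer(1))
  looped <- unique(unlist(gens))
  comps <- split(looped, roots[looped])
  free <- setdiff(seq_len(m), looped)
  list(components = unname(comps), free = free, lambda = length(gens))
}

#' Closed-form stochastic complexity, where available
#'
#' Closed forms cover the models whose loop structure factorizes into
#' independent pieces:
#' \itemize{
#'   \item loopless models (\eqn{\lambda = 0}): \eqn{c_M = |M| \log \pi};
#'   \item models gauge-equivalent to a complete model on \eqn{k} spins plus
#'     free operators: \eqn{c_M = 2^{k-1}\log\pi - \log\Gamma(2^{k-1})
#'     + (|M| - (2^k - 1)) \log\pi};
#'   \item models whose looped operators split into several such independent
#'     sub-complete components (in particular, non-overlapping 3-loops, each
#'     contributing \eqn{2\log\pi}).
#' }
#' A component of looped operators is sub-complete iff it consists of all
#' \eqn{2^k - 1} non-zero vectors of the \eqn{k}-dimensional GF(2) span of
#' its masks; this test is gauge-invariant.  For models with overlapping
#' loops that are not sub-complete no closed form is known and \code{NULL}
#' is returned (use \code{\link{complexity_mc}}).
#'
#' @param model a \code{spin_model}.
#' @return a \code{complexity_estimate}, or \code{NULL} if no closed form
#'   applies.
#' @export
complexity_closed <- function(model) {
  stopifnot(inherits(model, "spin_model"))
  m <- length(model$masks)
  dec <- .loop_components(model)
  if (dec$lambda == 0L)
    return(complexity_estimate(m * log(pi), 0, "closed_loopless"))
  value <- length(dec$free) * log(pi)
  for (comp in dec$components) {
    k <- .gf2_eliminate(model$masks[comp])$rank
    if (length(comp) != 2^k - 1) return(NULL)  # not sub-complete
    value <- value + 2^(k - 1) * log(pi) - lgamma(2^(k - 1))
  }
  method <- if (length(dec$components) > 1L) "closed_nonoverlapping"
            else if (length(dec$free) == 0L && m == 2^model$n - 1L)
              "closed_complete"
            else "closed_subcomplete"
  complexity_estimate(value, 0, method)
}

#' Monte Carlo estimate of the stochastic complexity
#'
#' Estimates \eqn{c_M = \log \int dg \sqrt{\det J(g)}} by importance
#' sampling under the substitution \eqn{g_\mu = \mathrm{atanh}(\sin
#' \theta_\mu)} with \eqn{\theta_\mu} uniform on \eqn{(-\pi/2, \pi/2)}.  This
#' substitution makes the integrand of a loopless model identically 1
#' (\eqn{\mathrm{sech}(\mathrm{atanh}(\sin\theta)) = \cos\theta}), so the
#' estimator is exact there and low-variance nearby; it also keeps the
#' integrand bounded, unlike a plain \eqn{\tanh} substitution whose tails
#' have infinite variance.  Each of \code{n_reps} repetitions averages the
#' integrand over \code{n_samples} draws; the estimate is the mean of the
#' per-rep log values and the standard error their standard deviation over
#' \eqn{\sqrt{n_{reps}}}.  Per-rep seeds are \code{seed + rep - 1}, so
#' extending \code{n_reps} never reshuffles earlier repetitions.
#'
#' @param model a \code{spin_model} with \code{n <= 12} and
#'   \eqn{|M| \le 15}.
#' @param n_samples Monte Carlo samples per repetition (default \code{1e5}).
#' @param n_reps number of repetitions (default 100).
#' @param seed master integer seed.
#' @return a \code{complexity_estimate} with method \code{monte_carlo}.
#' @export
complexity_mc <- function(model, n_samples = 1e5, n_reps = 100, seed = 1L) {
  stopifnot(inherits(model, "spin_model"))
  m <- length(model$masks)
  if (m == 0L)  # empty model: a single distribution, zero parameter volume
    return(complexity_estimate(0, 0, "closed_loopless"))
  if (m > .M_CAP_MC) stop("Monte Carlo capped at |M| = ", .M_CAP_MC)
  if (model$n > .N_CAP_FISHER)
    stop("Monte Carlo capped at n = ", .N_CAP_FISHER)
  n_samples <- as.integer(n_samples)
  n_reps <- as.integer(n_reps)
  if (n_samples < 1L || n_reps < 1L) stop("positive MC budgets required")
  phi <- operator_matrix(model)
  rep_vals <- vapply(seq_len(n_reps), function(r) {
    theta <- withr_seed(as.integer(seed) + r - 1L,
                        matrix(runif(m * n_samples, -pi / 2, pi / 2),
                               nrow = m))
    m * log(pi) + log(.jeffreys_integrand_mean(phi, theta))
  }, numeric(1))
  se <- if (n_reps > 1L) sd(rep_vals) / sqrt(n_reps) else 0
  complexity_estimate(mean(rep_vals), se, "monte_carlo",
                      n_samples = n_samples, n_reps = n_reps,
                      seed = as.integer(seed))
}

#' Stochastic complexity of a model, by the best available route
#'
#' Uses the closed form when one applies, otherwise Monte Carlo.
#'
#' @inheritParams complexity_mc
#' @return a \code{complexity_estimate}.
#' @export
model_complexity <- function(model, n_samples = 1e5, n_reps = 100, seed = 1L) {
  cc <- complexity_closed(model)
  if (!is.null(cc)) cc else complexity_mc(model, n_samples, n_reps, seed)
}

#' Complexity of the canonical single-loop model
#'
#' Builds the model with one loop of length \code{k} (operators
#' \eqn{s_1, \ldots, s_{k-1}} and their product \eqn{s_1 \cdots s_{k-1}})
#' plus \code{m_total - k} free single-spin operators on fresh spins, and
#' returns its stochastic complexity.  For \code{k = 3} the loop is a
#' complete model on 2 spins and the closed form
#' \eqn{c_M = (|M| - 1)\log\pi} applies; longer loops are integrated by
#' Monte Carlo.  The complexity increases with the loop length and saturates
#' at the independent-operator value \eqn{|M| \log \pi}.
#'
#' @param k loop length, \code{k >= 3}.
#' @param m_total total number of operators \eqn{|M|}, \code{m_total >= k}.
#' @param n_samples,n_reps,seed Monte Carlo settings (used when
#'   \code{k > 3}).
#' @return a \code{complexity_estimate}; attribute \code{model} carries the
#'   constructed model.
#' @export
complexity_single_loop <- function(k, m_total = k, n_samples = 1e5,
                                   n_reps = 100, seed = 1L) {
  k <- as.integer(k)
  m_total <- as.integer(m_total)
  if (k < 3L) stop("a loop has length at least 3")
  if (m_total < k) stop("m_total must be >= k")
  model <- single_loop_model(k, m_total)
  est <- if (k == 3L) complexity_closed(model)
         else complexity_mc(model, n_samples, n_reps, seed)
  attr(est, "model") <- model
  est
}

#' Canonical single-loop model
#' @inheritParams complexity_single_loop
#' @return a \code{spin_model} on \eqn{m_{total} - 1} spins whose only loop
#'   has length \code{k}.
#' @export
single_loop_model <- function(k, m_total = k) {
  k <- as.integer(k)
  m_total <- as.integer(m_total)
  if (k < 3L) stop("a loop has length at least 3")
  if (m_total < k) stop("m_total must be >= k")
  n <- m_total - 1L
  masks <- c(bitwShiftL(1L, seq_len(k - 1L) - 1L),      # s_1 .. s_{k-1}
             bitwShiftL(1L, k - 1L) - 1L,               # s_1 s_2 ... s_{k-1}
             if (m_total > k) bitwShiftL(1L, (k:n) - 1L)) # fresh single spins
  spin_model(masks, n)
}

#' Marginal-polytope membership for the 3-loop model
#'
#' For the model \eqn{\{s_1, s_2, s_1 s_2\}} the attainable expectation
#' vectors \eqn{\varphi = (\varphi_1, \varphi_2, \varphi_3)} form the
#' polytope \eqn{|\varphi_1 + \varphi_2| - 1 \le \varphi_3 \le
#' 1 - |\varphi_1 - \varphi_2|}, a strict subset of \eqn{[-1,1]^3}: the loop
#' constrains the moments, which is what lowers the complexity below
#' \eqn{3\log\pi}.
#'
#' @param phi numeric vector of length 3 with entries in \eqn{[-1, 1]}.
#' @return \code{TRUE} iff \code{phi} lies in the marginal polytope
#'   (boundary included).
#' @export
polytope_contains_3loop <- function(phi) {
  phi <- as.numeric(phi)
  if (length(phi) != 3L) stop("phi must have length 3")
  if (any(abs(phi) > 1)) stop("entries must lie in [-1, 1]")
  (abs(phi[1] + phi[2]) - 1 <= phi[3]) && (phi[3] <= 1 - abs(phi[1] - phi[2]))
}

#' Upper bound on the complexity spread at fixed parameter count
#'
#' The complexity of any model with \eqn{m} parameters is at most
#' \eqn{m \log \pi} (all operators independent) and at least the complete
#' model value at \eqn{m = 2^n - 1}.  The spread
#' \deqn{\Delta c = \frac{m-1}{2}\log\pi + \log\Gamma\!\left(\frac{m+1}{2}\right)}
#' bounds how much the complexity term can move a model comparison; when
#' \eqn{\Delta c} is much smaller than the BIC term the stochastic complexity
#' can be neglected, which for large \eqn{m} requires \eqn{N \gg m}.
#'
#' @param m number of parameters (\code{m >= 1}).
#' @return \eqn{\Delta c} in nats.
#' @export
complexity_gap_bound <- function(m) {
  if (any(m < 1)) stop("`m` must be >= 1")
  (m - 1) / 2 * log(pi) + lgamma((m + 1) / 2)
}
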