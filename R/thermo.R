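# Exact thermodynamics by 2^n state enumeration.  The regime of interest is
# small n, where enumeration is both feasible and the right oracle: no MCMC
# anywhere.

.N_CAP_Z <- 20L        # 2^n enumeration cap for partition functions
.N_CAP_FISHER <- 12L   # cap for Fisher matrices / fitting / sampling

#' All spin configurations of n spins
#'
#' @param n number of spins (\code{n <= 20}).
#' @return a \code{2^n x n} matrix of \code{-1/+1}; row \code{k} encodes the
#'   binary expansion of \code{k - 1} (bit \code{i-1} set means \eqn{s_i = -1}),
#'   so the first row is all \code{+1}.
#' @export
state_matrix <- function(n) {
  n <- as.integer(n)
  if (n < 1L || n > .N_CAP_Z) stop("state enumeration capped at n = ", .N_CAP_Z)
  k <- 0:(bitwShiftL(1L, n) - 1L)
  m <- vapply(seq_len(n), function(i)
    1L - 2L * bitwAnd(bitwShiftR(k, i - 1L), 1L), integer(length(k)))
  if (n == 1L) m <- matrix(m, ncol = 1L)
  m
}

#' Operator values on every state
#'
#' @param model a \code{spin_model}.
#' @return a \code{2^n x |M|} matrix \eqn{\Phi} with
#'   \eqn{\Phi_{s\mu} = \phi_\mu(s)}, states ordered as in
#'   \code{\link{state_matrix}}.
#' @export
operator_matrix <- function(model) {
  stopifnot(inherits(model, "spin_model"))
  n <- model$n
  if (n > .N_CAP_Z) stop("state enumeration capped at n = ", .N_CAP_Z)
  k <- 0:(bitwShiftL(1L, n) - 1L)
  m <- length(model$masks)
  out <- matrix(1, nrow = length(k), ncol = m)
  for (j in seq_len(m)) {
    # phi_mu(s) = (-1)^{popcount(state_bits & mask)} in the row-k encoding
    out[, j] <- 1 - 2 * (.popcount(bitwAnd(k, model$masks[j])) %% 2L)
  }
  out
}

.check_g <- function(model, g) {
  g <- as.numeric(g)
  if (length(g) != length(model$masks))
    stop("parameter vector must have length |M| = ", length(model$masks))
  if (any(!is.finite(g))) stop("parameters must be finite")
  g
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Log partition function by state enumeration
#'
#' \eqn{\log Z_M(g) = \log \sum_s \exp(\sum_\mu g_\mu \phi_\mu(s))}, computed
#' in the log domain (log-sum-exp) so that couplings up to \eqn{|g| \approx 30}
#' do not overflow.
#'
#' @param model a \code{spin_model} with \code{n <= 20}.
#' @param g numeric parameter vector of length \eqn{|M|}.
#' @return \eqn{\log Z} as a single numeric.
#' @export
log_partition_brute <- function(model, g) {
  g <- .check_g(model, g)
  phi <- operator_matrix(model)
  .logsumexp(as.numeric(phi %*% g))
}

#' Partition function by state enumeration
#' @inheritParams log_partition_brute
#' @return \eqn{Z_M(g)} (may overflow to \code{Inf} for extreme couplings;
#'   use \code{\link{log_partition_brute}} in that regime).
#' @export
partition_brute <- function(model, g) exp(log_partition_brute(model, g))

#' Partition function via the loop expansion
#'
#' Evaluates the high-temperature (cluster) expansion
#' \deqn{Z_M(g) = 2^n \prod_{\mu} \cosh(g_\mu)
#'       \sum_{\ell \in L} \prod_{\mu \in \ell} \tanh(g_\mu),}
#' where the sum runs over the full loop group \eqn{L}: all \eqn{2^\lambda}
#' XOR-combinations of the loop-basis generators, including the empty loop.
#'
#' @inheritParams log_partition_brute
#' @param max_lambda refuse models with more than this many loop generators
#'   (default 20).
#' @return \eqn{Z_M(g)}.
#' @export
partition_loops <- function(model, g, max_lambda = 20L) {
  exp(log_partition_loops(model, g, max_lambda))
}

#' @rdname partition_loops
#' @export
log_partition_loops <- function(model, g, max_lambda = 20L) {
  g <- .check_g(model, g)
  lb <- loop_basis(model)
  if (lb$lam > max_lambda)
    stop("loop group too large: lambda = ", lb$lam, " > cap ", max_lambda)
  m <- length(model$masks)
  t <- tanh(g)
  loop_sum <- 1  # empty loop
  if (lb$lam > 0L) {
    # membership matrix of all 2^lambda loops over the m operators, built by
    # doubling: combinations with/without each successive generator
    memb <- matrix(0L, nrow = 1L, ncol = m)
    for (gen in lb$generators) {
      add <- memb
      add[, gen] <- 1L - add[, gen, drop = FALSE]
      memb <- rbind(memb, add)
    }
    lt <- ifelse(t == 0, -Inf, log(abs(t)))
    sgn <- (-1)^(memb %*% (t < 0))
    loop_sum <- sum(sgn * exp(memb %*% lt))
  }
  if (loop_sum <= 0)
    stop("loop-expansion sum is non-positive; cannot take log (use ",
         "partition_brute)")
  model$n * log(2) + sum(log(cosh(g))) + log(loop_sum)
}

#' State probabilities under a model
#' @inheritParams log_partition_brute
#' @return numeric vector of length \code{2^n}: \eqn{P(s \mid g, M)} in the
#'   state order of \code{\link{state_matrix}}.
#' @export
state_probabilities <- function(model, g) {
  g <- .check_g(model, g)
  phi <- operator_matrix(model)
  e <- as.numeric(phi %*% g)
  e <- e - .logsumexp(e)
  exp(e)
}

#' Fisher information matrix
#'
#' \eqn{J_{\mu\nu}(g) = \partial^2 \log Z / \partial g_\mu \partial g_\nu
#' = \langle \phi_\mu \phi_\nu \rangle - \langle \phi_\mu \rangle
#'   \langle \phi_\nu \rangle}, the covariance of the operator values under
#' \eqn{P(s \mid g, M)}, computed by exact state enumeration.  (Note
#' \eqn{\phi_\mu \phi_\nu = \phi_{\mu \oplus \nu}}: products of operators are
#' operators.)
#'
#' @param model a \code{spin_model} with \code{n <= 12}.
#' @param g numeric parameter vector of length \eqn{|M|}.
#' @return symmetric positive semi-definite \eqn{|M| \times |M|} matrix.
#' @export
fisher_matrix <- function(model, g) {
  if (model$n > .N_CAP_FISHER)
    stop("Fisher matrix capped at n = ", .N_CAP_FISHER)
  g <- .check_g(model, g)
  phi <- operator_matrix(model)
  p <- state_probabilities(model, g)
  mu <- as.numeric(crossprod(phi, p))
  J <- crossprod(phi, p * phi) - tcrossprod(mu)
  (J + t(J)) / 2
}

#' Model expectations of the operators
#' @inheritParams fisher_matrix
#' @return numeric vector \eqn{\langle \phi_\mu \rangle} of length \eqn{|M|}.
#' @export
operator_means <- function(model, g) {
  phi <- operator_matrix(model)
  as.numeric(crossprod(phi, state_probabilities(model, g)))
}

# -- datasets -----------------------------------------------------------------

#' Construct a spin dataset
#' @param samples an \code{N x n} matrix with entries in \code{c(-1, 1)}.
#' @return object of class \code{spin_dataset}.
#' @export
spin_dataset <- function(samples) {
  m <- as.matrix(samples)
  storage.mode(m) <- "integer"
  if (nrow(m) < 1L) stop("dataset must contain at least one sample")
  if (!all(m %in% c(-1L, 1L))) stop("dataset entries must be -1 or +1")
  dimnames(m) <- NULL
  structure(list(samples = m, N = nrow(m), n = ncol(m)),
            class = "spin_dataset")
}

#' @export
print.spin_dataset <- function(x, ...) {
  cat("<spin_dataset> N = ", x$N, " samples of n = ", x$n, " spins\n", sep = "")
  invisible(x)
}

#' Draw i.i.d. samples from a spin model
#'
#' Exact sampling: all \code{2^n} state probabilities are enumerated and
#' states are drawn categorically.  Reproducible given \code{seed}.
#'
#' @inheritParams fisher_matrix
#' @param N number of samples.
#' @param seed integer seed (the RNG state is restored on exit).
#' @return a \code{spin_dataset}.
#' @export
sample_states <- function(model, g, N, seed) {
  if (model$n > .N_CAP_FISHER)
    stop("exact sampling capped at n = ", .N_CAP_FISHER)
  p <- state_probabilities(model, g)
  st <- state_matrix(model$n)
  idx <- withr_seed(seed, sample.int(length(p), size = N, replace = TRUE,
                                     prob = p))
  spin_dataset(st[idx, , drop = FALSE])
}

# evaluate expr under a temporary RNG seed, restoring any prior RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  expr
}

#' Empirical means of a model's operators in a dataset
#' @param model a \code{spin_model}.
#' @param dataset a \code{spin_dataset} with matching \code{n}.
#' @return numeric vector of length \eqn{|M|}: the sufficient statistics
#'   \eqn{\bar\phi_\mu = N^{-1} \sum_t \phi_\mu(s^{(t)})}.
#' @export
empirical_means <- function(model, dataset) {
  stopifnot(inherits(model, "spin_model"), inherits(dataset, "spin_dataset"))
  if (dataset$n != model$n) stop("dataset and model dimensions differ")
  vapply(model$masks, function(mask) {
    idx <- .indices_from_mask(mask, model$n)
    res <- dataset$samples[, idx[1L]]
    for (j in idx[-1L]) res <- res * dataset$samples[, j]
    mean(res)
  }, numeric(1))
}

#' Log-likelihood of a dataset under a model
#'
#' \eqn{\sum_t [\sum_\mu g_\mu \phi_\mu(s^{(t)})] - N \log Z_M(g)
#'  = N [g \cdot \bar\phi - \log Z_M(g)]}.
#'
#' @inheritParams empirical_means
#' @param g numeric parameter vector of length \eqn{|M|}.
#' @return the log-likelihood in nats.
#' @export
loglikelihood <- function(model, g, dataset) {
  g <- .check_g(model, g)
  phibar <- empirical_means(model, dataset)
  dataset$N * (sum(g * phibar) - log_partition_brute(model, g))
}

# -- maximum-likelihood fitting ----------------------------------------------

#' Maximum-likelihood couplings for the complete model
#'
#' For the complete model (all \eqn{2^n - 1} operators) the ML couplings have
#' the closed form \eqn{\hat g_\mu = 2^{-n} \sum_s \phi_\mu(s) \log \hat p(s)}
#' with \eqn{\hat p} the empirical state distribution.  Any state with
#' \eqn{\hat p(s) = 0} makes the log undefined, so \eqn{\hat p} is smoothed
#' with an additive pseudocount per state (Jeffreys-style 0.5 by default);
#' \code{pseudocount = 0} is allowed only when every state was observed.
#'
#' @param dataset a \code{spin_dataset} with \code{n <= 12}.
#' @param pseudocount non-negative additive count per state (default 0.5).
#' @return numeric vector of length \eqn{2^n - 1} named by operator mask, with
#'   attributes \code{model} (the complete \code{spin_model}) and
#'   \code{pseudocount}.
#' @export
fit_complete <- function(dataset, pseudocount = 0.5) {
  stopifnot(inherits(dataset, "spin_dataset"))
  n <- dataset$n
  if (n > .N_CAP_FISHER) stop("fit_complete capped at n = ", .N_CAP_FISHER)
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  n_states <- bitwShiftL(1L, n)
  # state index of each sample under the state_matrix encoding (s_i = -1 <=> bit set)
  bits <- (1L - dataset$samples) / 2L
  idx <- as.integer(bits %*% bitwShiftL(1L, seq_len(n) - 1L)) + 1L
  counts <- tabulate(idx, nbins = n_states)
  if (pseudocount == 0 && any(counts == 0L))
    stop("empirical distribution has unobserved states; log p(s) undefined ",
         "with pseudocount = 0")
  p_hat <- (counts + pseudocount) / (dataset$N + n_states * pseudocount)
  model <- spin_model(seq_len(n_states - 1L), n)
  phi <- operator_matrix(model)
  g <- as.numeric(crossprod(phi, log(p_hat))) / n_states
  names(g) <- model$masks
  attr(g, "model") <- model
  attr(g, "pseudocount") <- pseudocount
  g
}

#' Maximum-likelihood fit of an arbitrary model
#'
#' Maximizes the exact log-likelihood by damped Newton ascent, using the
#' exact Fisher matrix as the Hessian of the concave objective.  At the
#' optimum the model expectations match the empirical operator means.
#'
#' @inheritParams empirical_means
#' @param tol convergence tolerance on
#'   \eqn{\max_\mu |\langle \phi_\mu \rangle_{g} - \bar\phi_\mu|}
#'   (default \code{1e-8}).
#' @param max_iter iteration cap (default 500); exceeding it is an error.
#' @return numeric vector \eqn{\hat g} of length \eqn{|M|}, with attribute
#'   \code{iterations}.
#' @export
fit_ml <- function(model, dataset, tol = 1e-8, max_iter = 500L) {
  stopifnot(inherits(model, "spin_model"))
  if (model$n > .N_CAP_FISHER) stop("fit_ml capped at n = ", .N_CAP_FISHER)
  m <- length(model$masks)
  if (m == 0L) {
    g <- numeric(0)
    attr(g, "iterations") <- 0L
    return(g)
  }
  phibar <- empirical_means(model, dataset)
  at_boundary <- abs(phibar) >= 1 - .Machine$double.eps
  if (any(at_boundary)) {
    bad <- operator_indices(model)[at_boundary]
    stop("sufficient statistic at boundary (|mean| = 1) for operator(s) ",
         paste(vapply(bad, function(ix) paste0("s", ix, collapse = ""),
                      character(1)), collapse = ", "),
         ": maximum-likelihood couplings diverge")
  }
  phi <- operator_matrix(model)
  g <- numeric(m)
  obj <- function(g) sum(g * phibar) - .logsumexp(as.numeric(phi %*% g))
  f <- obj(g)
  for (it in seq_len(max_iter)) {
    p <- state_probabilities(model, g)
    mu <- as.numeric(crossprod(phi, p))
    grad <- phibar - mu
    if (max(abs(grad)) < tol) {
      attr(g, "iterations") <- it - 1L
      return(g)
    }
    J <- crossprod(phi, p * phi) - tcrossprod(mu)
    step <- tryCatch(solve(J + diag(1e-10, m), grad),
                     error = function(e) grad)
    # backtracking line search on the concave objective
    alpha <- 1
    repeat {
      g_new <- g + alpha * step
      f_new <- obj(g_new)
      if (is.finite(f_new) && f_new >= f - 1e-14) break
      alpha <- alpha / 2
      if (alpha < 1e-12) stop("line search failed in fit_ml")
    }
    g <- g_new
    f <- f_new
  }
  stop("fit_ml did not converge in ", max_iter, " iterations")
}
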