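#' @useDynLib spinsc, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rnorm sd setNames
NULL

# -- bit-mask helpers ---------------------------------------------------------
# An interaction operator on n spins is an n-bit mask: bit i-1 set <=> spin i
# participates.  Masks are plain R integers, so n is capped at 30.

.mask_from_indices <- function(indices, n) {
  sum(bitwShiftL(1L, as.integer(indices) - 1L))
}

.indices_from_mask <- function(mask, n) {
  which(bitwAnd(bitwShiftR(mask, 0L:(n - 1L)), 1L) == 1L)
}

.popcount <- function(x) {
  # vectorized bit population count for 30-bit integers
  cnt <- integer(length(x))
  while (any(x > 0L)) {
    cnt <- cnt + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  cnt
}

#' Create an interaction operator
#'
#' An operator \eqn{\phi_\mu(s) = \prod_{i \in \mu} s_i} is the product of the
#' spins in a non-empty subset \eqn{\mu} of \code{1..n}.  Internally it is an
#' n-bit mask (bit \code{i-1} set iff spin \code{i} participates); the identity
#' operator (empty subset) is excluded because it carries no interaction.
#'
#' @param indices integer vector of 1-based spin indices (non-empty, distinct).
#' @param n number of spins in the system.
#' @return An object of class \code{spin_op} with fields \code{mask} and
#'   \code{n}.
#' @examples
#' make_operator(c(1, 2, 3), n = 4)
#' @export
make_operator <- function(indices, n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L || n > 30L)
    stop("`n` must be a single integer in 1..30")
  if (length(indices) == 0L)
    stop("empty index set: the identity operator is not a valid interaction")
  indices <- as.integer(indices)
  if (anyNA(indices) || any(indices < 1L) || any(indices > n))
    stop("spin indices must lie in 1..", n)
  if (anyDuplicated(indices))
    stop("duplicate spin index in operator")
  structure(list(mask = .mask_from_indices(indices, n), n = n),
            class = "spin_op")
}

#' @export
print.spin_op <- function(x, ...) {
  idx <- .indices_from_mask(x$mask, x$n)
  cat("<spin_op> ", paste0("s", idx, collapse = ""), "  (n = ", x$n,
      ", mask = ", x$mask, ")\n", sep = "")
  invisible(x)
}

#' Evaluate an operator on a spin configuration
#'
#' @param op a \code{spin_op}.
#' @param state numeric vector of length \code{n} with entries in
#'   \code{c(-1, 1)}.
#' @return \code{+1} or \code{-1}, the product of the participating spins.
#' @export
evaluate_operator <- function(op, state) {
  stopifnot(inherits(op, "spin_op"))
  if (length(state) != op$n)
    stop("state must have length n = ", op$n)
  if (!all(state %in% c(-1, 1)))
    stop("state entries must be -1 or +1")
  prod(state[.indices_from_mask(op$mask, op$n)])
}

# -- spin models --------------------------------------------------------------

#' Construct a spin model
#'
#' A spin model is identified by the set of product operators it contains.
#' Operators are kept in the order supplied; the empty model (no operators)
#' is valid and represents the uniform distribution.
#'
#' @param operators either a list of \code{spin_op} objects, a list of index
#'   vectors, or an integer vector of operator masks.
#' @param n number of spins.
#' @return An object of class \code{spin_model} with fields \code{n} and
#'   \code{masks} (integer vector of distinct non-zero operator masks).
#' @examples
#' spin_model(list(1, 2, c(1, 2)), n = 2)  # fields on s1, s2 plus coupling
#' @export
spin_model <- function(operators, n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L || n > 30L)
    stop("`n` must be a single integer in 1..30")
  if (is.list(operators)) {
    masks <- vapply(operators, function(o) {
      if (inherits(o, "spin_op")) {
        if (o$n != n) stop("operator defined for a different n")
        o$mask
      } else {
        make_operator(o, n)$mask
      }
    }, integer(1))
  } else {
    masks <- as.integer(operators)
    if (any(masks < 1L) || any(masks >= bitwShiftL(1L, n)))
      stop("operator masks must lie in 1..2^n-1")
  }
  if (anyDuplicated(masks))
    stop("duplicate operator in model")
  structure(list(n = n, masks = as.integer(masks)), class = "spin_model")
}

#' @export
print.spin_model <- function(x, ...) {
  lab <- vapply(x$masks, function(m)
    paste0("s", .indices_from_mask(m, x$n), collapse = ""), character(1))
  cat("<spin_model> n = ", x$n, ", |M| = ", length(x$masks), "\n", sep = "")
  if (length(lab)) cat("  {", paste(lab, collapse = ", "), "}\n", sep = "")
  inv <- model_invariants(x)
  cat("  n_M = ", inv[["n_M"]], ", lambda = ", inv[["lambda"]], "\n", sep = "")
  invisible(x)
}

#' Number of operators in a model
#' @param model a \code{spin_model}.
#' @return integer \eqn{|M|}.
#' @export
n_operators <- function(model) length(model$masks)

#' Operators of a model as index sets
#' @param model a \code{spin_model}.
#' @return list of integer vectors of 1-based spin indices, in stored order.
#' @export
operator_indices <- function(model) {
  lapply(model$masks, .indices_from_mask, n = model$n)
}

# canonical key used for deduplication: sorted mask tuple ("m" for the
# empty model, which would otherwise key on the empty string)
.model_key <- function(masks) paste0("m", paste(sort(masks), collapse = ","))

# -- GF(2) rank and loop structure --------------------------------------------

# Gaussian elimination over GF(2) on the |M| x n matrix of operator masks,
# processing operators in stored order.  Tracks, for each eliminated row, the
# combination of original operators it came from, so that rows reducing to
# zero yield fundamental circuits (loop generators) directly.
.gf2_eliminate <- function(masks) {
  pivot_mask <- integer(0)       # reduced masks with distinct leading bits
  pivot_hb <- integer(0)         # the leading bit of each pivot
  pivot_combo <- list()          # operator index sets composing each pivot
  generators <- list()           # loops: index sets whose masks XOR to zero
  for (i in seq_along(masks)) {
    m <- masks[i]
    combo <- i
    # reduce against pivots in descending leading-bit order: XORing a pivot
    # only introduces bits strictly below its leading bit, so one pass suffices
    for (j in order(pivot_hb, decreasing = TRUE)) {
      if (bitwAnd(m, pivot_hb[j]) != 0L) {
        m <- bitwXor(m, pivot_mask[j])
        combo <- .symdiff(combo, pivot_combo[[j]])
      }
    }
    if (m == 0L) {
      generators[[length(generators) + 1L]] <- sort(combo)
    } else {
      pivot_mask <- c(pivot_mask, m)
      pivot_hb <- c(pivot_hb, .high_bit(m))
      pivot_combo[[length(pivot_combo) + 1L]] <- combo
    }
  }
  list(rank = length(pivot_mask), generators = generators)
}

.high_bit <- function(x) {
  b <- 1L
  while (bitwShiftR(x, 1L) != 0L) {
    x <- bitwShiftR(x, 1L)
    b <- bitwShiftL(b, 1L)
  }
  b
}

.symdiff <- function(a, b) sort(c(setdiff(a, b), setdiff(b, a)))

#' Number of independent operators of a model
#'
#' The maximal number of operators that can be chosen without forming a loop:
#' the GF(2) rank of the \eqn{|M| \times n} binary matrix of operator masks.
#'
#' @param model a \code{spin_model}.
#' @return integer \eqn{n_M}, with \eqn{0 \le n_M \le \min(|M|, n)}.
#' @export
independent_rank <- function(model) {
  stopifnot(inherits(model, "spin_model"))
  .gf2_eliminate(model$masks)$rank
}

#' Minimal generating set of the loop group
#'
#' A loop is a subset of the model's operators whose masks XOR to zero, i.e.
#' whose operator product is identically 1.  All loops form an Abelian group
#' under symmetric difference, of size \eqn{2^\lambda}, with
#' \eqn{\lambda = |M| - n_M}.  The basis is computed as the GF(2) null space
#' of the mask matrix by Gaussian elimination with pivots taken in stored
#' operator order, which makes the (non-unique) generating set deterministic.
#' Each generator is a fundamental circuit: one dependent operator plus the
#' independent operators that express it.
#'
#' @param model a \code{spin_model}.
#' @return An object of class \code{loop_basis}: list with \code{generators}
#'   (list of sorted integer vectors of operator positions in the model) and
#'   \code{lam} (the number \eqn{\lambda} of generators).  The empty loop is
#'   the group identity and is never stored.
#' @export
loop_basis <- function(model) {
  stopifnot(inherits(model, "spin_model"))
  el <- .gf2_eliminate(model$masks)
  structure(list(generators = el$generators,
                 lam = length(el$generators)),
            class = "loop_basis")
}

#' @export
print.loop_basis <- function(x, ...) {
  cat("<loop_basis> lambda = ", x$lam, "\n", sep = "")
  for (g in x$generators)
    cat("  {", paste(g, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Test whether a subset of operators is a loop
#'
#' @param model a \code{spin_model}.
#' @param subset integer vector of operator positions (indices into the
#'   model's operator list).  The empty subset is the empty loop, which is a
#'   loop by convention.
#' @return \code{TRUE} iff the masks of the subset XOR to zero, equivalently
#'   \eqn{\prod_{\mu \in \ell} \phi_\mu(s) = 1} for every state \eqn{s}.
#' @export
is_loop <- function(model, subset) {
  stopifnot(inherits(model, "spin_model"))
  subset <- as.integer(subset)
  if (length(subset) == 0L) return(TRUE)
  if (anyDuplicated(subset) || any(subset < 1L) ||
      any(subset > length(model$masks)))
    stop("subset must be distinct operator positions within the model")
  Reduce(bitwXor, model$masks[subset], 0L) == 0L
}

#' Enumerate all loops of a model
#'
#' Expands the loop basis into the full loop group: all \eqn{2^\lambda}
#' XOR-combinations of the generators, including the empty loop.
#'
#' @param model a \code{spin_model}.
#' @param max_lambda refuse enumeration beyond this many generators
#'   (default 20).
#' @return list of sorted integer vectors of operator positions; the first
#'   element is the empty loop \code{integer(0)}.
#' @export
enumerate_loops <- function(model, max_lambda = 20L) {
  lb <- loop_basis(model)
  if (lb$lam > max_lambda)
    stop("loop group too large: lambda = ", lb$lam, " > cap ", max_lambda)
  loops <- list(integer(0))
  for (g in lb$generators) {
    loops <- c(loops, lapply(loops, .symdiff, b = g))
  }
  loops
}
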