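# Gauge transformations: invertible GF(2) changes of the spin basis.  A gauge
# map acts on operator masks (as binary column vectors) by left multiplication,
# inducing a bijection of the set of all 2^n - 1 operators onto itself.  It
# preserves |M|, n_M and lambda, hence the stochastic complexity; its orbits
# are the complexity classes.

#' Create a gauge map
#'
#' @param matrix an \code{n x n} 0/1 matrix, invertible over GF(2).
#' @return An object of class \code{gauge_map}.
#' @export
gauge_map <- function(matrix) {
  m <- as.matrix(matrix)
  storage.mode(m) <- "integer"
  if (nrow(m) != ncol(m) || !all(m %in% c(0L, 1L)))
    stop("a gauge map must be a square 0/1 matrix")
  if (!.gf2_invertible(m))
    stop("matrix is not invertible over GF(2)")
  structure(list(matrix = m, n = nrow(m)), class = "gauge_map")
}

#' @export
print.gauge_map <- function(x, ...) {
  cat("<gauge_map> n = ", x$n, "\n", sep = "")
  print(x$matrix)
  invisible(x)
}

# columns of a 0/1 matrix as mask integers (column j = image of basis spin j)
.col_masks <- function(m) {
  as.integer(colSums(m * bitwShiftL(1L, seq_len(nrow(m)) - 1L)))
}

.gf2_invertible <- function(m) {
  .gf2_eliminate(.col_masks(m))$rank == ncol(m)
}

# image of a mask under left multiplication by the matrix with column masks cm
.transform_mask <- function(mask, col_masks) {
  out <- 0L
  j <- 1L
  while (mask != 0L) {
    if (bitwAnd(mask, 1L) == 1L) out <- bitwXor(out, col_masks[j])
    mask <- bitwShiftR(mask, 1L)
    j <- j + 1L
  }
  out
}

#' Number of gauge transformations
#'
#' The number of invertible \code{n x n} binary matrices,
#' \eqn{N_{GT}(n) = 2^{n^2} \prod_{k=1}^{n} (1 - 2^{-k})}, i.e. the order of
#' the general linear group over GF(2).
#'
#' @param n number of spins (\code{n >= 1}).
#' @return the count as a numeric; exact for \code{n <= 7} (beyond that the
#'   value exceeds the integers representable in a double).
#' @examples
#' count_gauge_maps(3)  # 168
#' @export
count_gauge_maps <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) stop("`n` must be >= 1")
  prod(2^n - 2^(0:(n - 1)))
}

#' Enumerate all gauge transformations
#'
#' Yields every invertible \code{n x n} binary matrix exactly once, by
#' enumerating all \eqn{2^{n^2}} binary matrices and keeping the invertible
#' ones.  Intended for small systems; the count matches
#' \code{count_gauge_maps(n)}.
#'
#' @param n number of spins.
#' @param cap refuse enumeration for \code{n > cap} (default 4;
#'   \eqn{2^{25}} candidate matrices at \code{n = 5} are impractical here).
#' @return list of \code{gauge_map} objects.
#' @export
enumerate_gauge_maps <- function(n, cap = 4L) {
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1")
  if (n > cap) stop("full enumeration capped at n = ", cap)
  # enumerate column tuples: each column is a mask in 1..2^n-1; build up
  # columns left to right, pruning tuples whose columns are already dependent
  res <- list()
  recurse <- function(cols) {
    if (length(cols) == n) {
      m <- vapply(cols, function(cm)
        as.integer(bitwAnd(bitwShiftR(cm, 0:(n - 1L)), 1L)),
        integer(n))
      res[[length(res) + 1L]] <<- gauge_map(m)
      return(invisible())
    }
    for (cm in seq_len(bitwShiftL(1L, n) - 1L)) {
      if (.gf2_eliminate(c(cols, cm))$rank == length(cols) + 1L)
        recurse(c(cols, cm))
    }
  }
  recurse(integer(0))
  res
}

#' Apply a gauge transformation to a model
#'
#' Each operator mask \code{m}, viewed as a binary column vector, is replaced
#' by \code{(A m) mod 2}.  Invertibility guarantees the transformed operators
#' are distinct and non-zero; \eqn{|M|}, \eqn{n_M} and \eqn{\lambda} are
#' preserved.
#'
#' @param model a \code{spin_model}.
#' @param map a \code{gauge_map} with matching \code{n}.
#' @return the transformed \code{spin_model} (operators in the image order of
#'   the originals).
#' @export
apply_gauge <- function(model, map) {
  stopifnot(inherits(model, "spin_model"), inherits(map, "gauge_map"))
  if (map$n != model$n) stop("gauge map and model dimensions differ")
  cm <- .col_masks(map$matrix)
  new_masks <- vapply(model$masks, .transform_mask, integer(1), col_masks = cm)
  spin_model(new_masks, model$n)
}

# -- complexity classes (gauge orbits) ---------------------------------------

#' Construct a complexity-class record
#' @param representative lexicographically minimal member (a \code{spin_model}).
#' @param members list of member models (each an integer mask vector, sorted).
#' @param n spin count.
#' @return object of class \code{complexity_class} with the class invariants
#'   \code{size}, \code{n_ops} (\eqn{|M|}), \code{n_indep} (\eqn{n_M}) and
#'   \code{lambda}.
#' @keywords internal
.complexity_class <- function(representative, members, n) {
  inv <- model_invariants(representative)
  structure(list(representative = representative,
                 members = members,
                 n = n,
                 size = length(members),
                 n_ops = inv[["n_ops"]],
                 n_indep = inv[["n_M"]],
                 lambda = inv[["lambda"]]),
            class = "complexity_class")
}

#' @export
print.complexity_class <- function(x, ...) {
  cat("<complexity_class> n = ", x$n, ": ", x$size, " model(s) with |M| = ",
      x$n_ops, ", n_M = ", x$n_indep, ", lambda = ", x$lambda, "\n", sep = "")
  invisible(x)
}

#' Class invariants of a model
#' @param model a \code{spin_model}.
#' @return named numeric vector with \code{n_ops} (\eqn{|M|}), \code{n_M}
#'   (GF(2) rank) and \code{lambda} (\eqn{|M| - n_M}).
#' @export
model_invariants <- function(model) {
  r <- independent_rank(model)
  c(n_ops = length(model$masks), n_M = r, lambda = length(model$masks) - r)
}

# lexicographically minimal sorted mask tuple among a list of equal-length
# tuples (all members of one gauge orbit share |M|)
.lex_min_masks <- function(members) {
  if (length(members) == 1L) return(members[[1L]])
  mat <- do.call(rbind, members)
  ord <- do.call(order, lapply(seq_len(ncol(mat)), function(j) mat[, j]))
  members[[ord[1L]]]
}

# generators of GL(n, 2): the elementary transvections I + E_ij (i != j),
# i.e. "add spin j's row to spin i's row".  They generate the full group,
# so breadth-first closure under them reaches the whole gauge orbit.
.transvection_col_masks <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    cm <- bitwShiftL(1L, seq_len(n) - 1L)   # identity columns
    cm[j] <- bitwXor(cm[j], bitwShiftL(1L, i - 1L))
    out[[length(out) + 1L]] <- as.integer(cm)
  }
  out
}

#' Gauge orbit (complexity class) of a model
#'
#' Computes the set of all models reachable from \code{model} by gauge
#' transformations, by breadth-first closure under the elementary
#' transvections that generate the gauge group.  All members share the class
#' invariants \eqn{(|M|, n_M, \lambda)} and the stochastic complexity.
#'
#' @param model a \code{spin_model} with \code{n <= 6} (the orbit itself is
#'   small; the bound keeps closure cheap).
#' @return a \code{complexity_class}; the representative is the
#'   lexicographically minimal member (by sorted mask tuple).
#' @export
orbit <- function(model) {
  stopifnot(inherits(model, "spin_model"))
  n <- model$n
  if (n > 6L) stop("orbit closure supported for n <= 6")
  gens <- .transvection_col_masks(n)
  start <- sort(model$masks)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  assign(.model_key(start), TRUE, envir = seen)
  members <- list(start)
  queue <- list(start)
  while (length(queue)) {
    cur <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (cm in gens) {
      nxt <- sort(vapply(cur, .transform_mask, integer(1), col_masks = cm))
      key <- .model_key(nxt)
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        members[[length(members) + 1L]] <- nxt
        queue[[length(queue) + 1L]] <- nxt
      }
    }
  }
  rep_masks <- .lex_min_masks(members)
  .complexity_class(structure(list(n = n, masks = rep_masks),
                              class = "spin_model"),
                    members, n)
}

#' Partition all models on n spins into complexity classes
#'
#' Enumerates every subset of the \eqn{2^n - 1} operators (including the
#' empty model) and groups them into gauge orbits by breadth-first closure.
#' Class sizes sum to \eqn{2^{2^n - 1}}.
#'
#' @param n number of spins, \code{n <= 4}.
#' @param keep_members if \code{FALSE} (default) member lists are dropped to
#'   save memory; the representative, size and invariants are always kept.
#' @return list of \code{complexity_class} objects, ordered by
#'   (\eqn{|M|}, \eqn{n_M}, representative).
#' @export
classify_models <- function(n, keep_members = FALSE) {
  n <- as.integer(n)
  if (n < 1L || n > 4L) stop("classification supported for 1 <= n <= 4")
  n_ops_all <- bitwShiftL(1L, n) - 1L          # 2^n - 1 possible operators
  n_models <- bitwShiftL(1L, n_ops_all)        # subsets of operators
  gens <- .transvection_col_masks(n)
  # each generator permutes the non-zero masks 1..2^n-1; precompute
  perms <- lapply(gens, function(cm)
    vapply(seq_len(n_ops_all), .transform_mask, integer(1), col_masks = cm))
  # a model is a subset code in 0..n_models-1: bit m-1 set <=> mask m present
  bit_of <- bitwShiftL(1L, seq_len(n_ops_all) - 1L)
  transform_code <- function(code, perm) {
    present <- which(bitwAnd(code, bit_of) != 0L)
    sum(bit_of[perm[present]])
  }
  visited <- logical(n_models)
  classes <- list()
  for (code0 in 0:(n_models - 1L)) {
    if (visited[code0 + 1L]) next
    comp <- code0
    visited[code0 + 1L] <- TRUE
    queue <- code0
    while (length(queue)) {
      cur <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      for (perm in perms) {
        nxt <- transform_code(cur, perm)
        if (!visited[nxt + 1L]) {
          visited[nxt + 1L] <- TRUE
          comp <- c(comp, nxt)
          queue <- c(queue, nxt)
        }
      }
    }
    decode <- function(code) which(bitwAnd(code, bit_of) != 0L)
    all_members <- lapply(sort(comp), decode)
    rep_model <- structure(list(n = n, masks = .lex_min_masks(all_members)),
                           class = "spin_model")
    cl <- .complexity_class(rep_model,
                            if (keep_members) all_members else vector("list", 0L),
                            n)
    cl$size <- length(comp)
    classes[[length(classes) + 1L]] <- cl
  }
  ord <- order(vapply(classes, `[[`, numeric(1), "n_ops"),
               vapply(classes, `[[`, numeric(1), "n_indep"),
               vapply(classes, function(cl) .model_key(cl$representative$masks),
                      character(1)))
  classes[ord]
}

#' Dual model: the complementary operator set
#'
#' Gauge transformations induce a duality pairing each class of models with
#' \eqn{|M|} operators with the class of the \eqn{2^n - 1 - |M|} complementary
#' operators.  This returns the member-level complement.
#'
#' @param model a \code{spin_model}.
#' @return the \code{spin_model} whose operators are exactly those not in
#'   \code{model}, in increasing mask order.
#' @export
dual_model <- function(model) {
  stopifnot(inherits(model, "spin_model"))
  all_masks <- seq_len(bitwShiftL(1L, model$n) - 1L)
  comp <- setdiff(all_masks, model$masks)
  structure(list(n = model$n, masks = as.integer(comp)), class = "spin_model")
}

#' Canonical class representative of a model
#'
#' The lexicographically minimal member of the model's gauge orbit (by sorted
#' mask tuple).  Two models are gauge-equivalent iff their canonical
#' representatives coincide.
#'
#' @param model a \code{spin_model} with \code{n <= 6}.
#' @return a \code{spin_model}.
#' @export
canonical_representative <- function(model) {
  orbit(model)$representative
}
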