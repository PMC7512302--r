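# Plain-text formats.
#
# Model spec: a header line "n=<int>", then one operator per line as
# space-separated 1-based spin indices; '#' starts a comment line.  The
# writer emits operators in stored order, so read/write round-trips are
# bit-exact.
#
# Dataset: whitespace-delimited, one sample per row, entries +1/-1 (or 0/1
# with `zero_one = TRUE`, 0 mapping to -1).

#' Read a spin model from a text file
#'
#' @param path file path.
#' @return a \code{spin_model}.
#' @export
read_model <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L || !grepl("^n\\s*=\\s*[0-9]+$", lines[1L]))
    stop("model file must start with a header line 'n=<int>'")
  n <- as.integer(sub("^n\\s*=\\s*", "", lines[1L]))
  body <- lines[-1L]
  ops <- lapply(body, function(line) {
    toks <- strsplit(line, "\\s+")[[1L]]
    idx <- suppressWarnings(as.integer(toks))
    if (anyNA(idx)) stop("malformed operator line: '", line, "'")
    idx
  })
  masks <- vapply(ops, function(ix) make_operator(ix, n)$mask, integer(1))
  if (anyDuplicated(masks))
    stop("duplicate operator in model file (line ",
         which(duplicated(masks))[1L] + 1L, ")")
  spin_model(masks, n)
}

#' Write a spin model to a text file
#' @param model a \code{spin_model}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "spin_model"))
  lines <- c(paste0("n=", model$n),
             vapply(operator_indices(model), paste, character(1),
                    collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read a spin dataset from a delimited text file
#'
#' @param path file path.
#' @param zero_one if \code{TRUE}, entries are 0/1 with 0 mapped to -1;
#'   otherwise entries must be -1/+1.
#' @return a \code{spin_dataset}.
#' @export
read_dataset <- function(path, zero_one = FALSE) {
  m <- tryCatch(as.matrix(utils::read.table(path, header = FALSE,
                                            colClasses = "integer")),
                error = function(e) stop("cannot parse dataset: ",
                                         conditionMessage(e)))
  if (zero_one) {
    if (!all(m %in% c(0L, 1L))) stop("entries must be 0 or 1")
    m <- 2L * m - 1L
  } else if (!all(m %in% c(-1L, 1L))) {
    stop("entries must be -1 or +1")
  }
  spin_dataset(m)
}

#' Write a spin dataset to a text file
#' @param dataset a \code{spin_dataset}.
#' @param path file path.
#' @param zero_one write 0/1 instead of -1/+1.
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(dataset, path, zero_one = FALSE) {
  stopifnot(inherits(dataset, "spin_dataset"))
  m <- dataset$samples
  if (zero_one) m <- (m + 1L) / 2L
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# -- named model families and fixtures ---------------------------------------

#' The complete model on n spins
#' @param n number of spins.
#' @return the \code{spin_model} containing all \eqn{2^n - 1} operators.
#' @export
complete_model <- function(n) {
  n <- as.integer(n)
  spin_model(seq_len(bitwShiftL(1L, n) - 1L), n)
}

#' The four models of the reference 4-spin complexity class
#'
#' Four gauge-equivalent models on \code{n = 4} spins with \eqn{|M| = 7},
#' \eqn{n_M = 3}, \eqn{\lambda = 4}, spanning very different-looking
#' structures: (a) the complete model on spins 1-3, (b)-(c) mixed-order
#' models, (d) the permutation-symmetric model of all six pair couplings
#' plus the 4-spin interaction.  Their gauge orbit contains 15 models in
#' total and is the least complex class at \eqn{|M| = 7}.
#'
#' @param which one of \code{"a"}, \code{"b"}, \code{"c"}, \code{"d"}.
#' @return a \code{spin_model} on 4 spins.
#' @export
reference_class_model <- function(which = c("a", "b", "c", "d")) {
  which <- match.arg(which)
  ops <- switch(which,
    a = list(1, 2, 3, c(1, 2), c(1, 3), c(2, 3), c(1, 2, 3)),
    b = list(1, c(2, 3), c(3, 4), c(4, 2), c(1, 2, 3), c(1, 3, 4),
             c(1, 2, 4)),
    c = list(2, 4, c(2, 4), c(1, 3), c(1, 2, 3), c(1, 3, 4), c(1, 2, 3, 4)),
    d = list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4),
             c(1, 2, 3, 4)))
  spin_model(ops, 4L)
}

#' Fully connected pairwise model
#' @param n number of spins.
#' @param fields include the n single-spin operators as well.
#' @return a \code{spin_model} with all \eqn{n(n-1)/2} pair couplings (plus
#'   fields if requested).
#' @export
pairwise_model <- function(n, fields = FALSE) {
  n <- as.integer(n)
  ops <- list()
  if (fields) ops <- as.list(seq_len(n))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    ops[[length(ops) + 1L]] <- c(i, j)
  spin_model(ops, n)
}

#' Generate a reproducible model/parameter/dataset fixture
#'
#' Instantiates one of the named model families, draws couplings, and
#' samples a dataset from the exact distribution.
#'
#' @param kind one of \code{"loopless"} (the first \code{m} of: single-spin
#'   operators then nested pair chains), \code{"single_loop"},
#'   \code{"subcomplete"} (complete on \code{k} spins embedded in \code{n}),
#'   \code{"pairwise_full"}, \code{"figure_class"} (one of the four
#'   reference 4-spin models).
#' @param n number of spins.
#' @param params list of family parameters: \code{m} (operator count),
#'   \code{k} (loop length / sub-complete size), \code{fields} (logical),
#'   \code{which} (reference model letter), \code{g_scale} (coupling scale,
#'   default 0.5: couplings are \code{g_scale} in magnitude with random
#'   sign), \code{N} (sample count, default 1000).
#' @param seed integer seed controlling both couplings and samples.
#' @return list with elements \code{model}, \code{g}, \code{dataset}.
#' @export
make_fixture <- function(kind = c("loopless", "single_loop", "subcomplete",
                                  "pairwise_full", "figure_class"),
                         n, params = list(), seed = 1L) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  p <- function(name, default) if (!is.null(params[[name]]))
    params[[name]] else default
  model <- switch(kind,
    loopless = {
      m <- p("m", n)
      if (m > n) stop("a loopless model has at most n operators")
      spin_model(as.list(seq_len(m)), n)
    },
    single_loop = {
      k <- p("k", 3L)
      mod <- single_loop_model(k, p("m", k))
      if (mod$n != n) stop("single_loop with these params needs n = ", mod$n)
      mod
    },
    subcomplete = {
      k <- p("k", 2L)
      if (k > n) stop("sub-complete block larger than n")
      spin_model(seq_len(bitwShiftL(1L, k) - 1L), n)
    },
    pairwise_full = pairwise_model(n, fields = p("fields", FALSE)),
    figure_class = {
      if (n != 4L) stop("the reference class lives on n = 4 spins")
      reference_class_model(p("which", "a"))
    })
  g_scale <- p("g_scale", 0.5)
  N <- p("N", 1000L)
  g <- withr_seed(seed, g_scale * sample(c(-1, 1), length(model$masks),
                                         replace = TRUE))
  dataset <- sample_states(model, g, N, seed = seed + 1L)
  list(model = model, g = g, dataset = dataset)
}
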