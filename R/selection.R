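# MDL-penalized model scoring.  The asymptotic description length of a model
# M on N samples is
#   max log-likelihood - (|M|/2) log(N / 2 pi) - c_M :
# a BIC term counting parameters and the stochastic complexity c_M counting
# how the parameters constrain each other.  Higher total = preferred model.

#' Score a model on a dataset by penalized maximum likelihood
#'
#' @param model a \code{spin_model}.
#' @param dataset a \code{spin_dataset} with matching \code{n}.
#' @param complexity a \code{complexity_estimate} for the model (e.g. from
#'   \code{\link{model_complexity}}); computed automatically if omitted.
#' @param ... Monte Carlo settings passed to \code{\link{model_complexity}}
#'   when \code{complexity} is missing.
#' @return object of class \code{model_score}: list with \code{model},
#'   \code{max_loglik}, \code{bic_term} (\eqn{(|M|/2)\log(N/2\pi)}),
#'   \code{complexity_term} (\eqn{c_M}, nats), \code{complexity} (the full
#'   estimate), \code{score_se} (MC uncertainty propagated from \eqn{c_M})
#'   and \code{total = max_loglik - bic_term - complexity_term}.
#' @export
mdl_score <- function(model, dataset, complexity = NULL, ...) {
  stopifnot(inherits(model, "spin_model"), inherits(dataset, "spin_dataset"))
  if (is.null(complexity)) complexity <- model_complexity(model, ...)
  stopifnot(inherits(complexity, "complexity_estimate"))
  m <- length(model$masks)
  g_hat <- fit_ml(model, dataset)
  ll <- loglikelihood(model, g_hat, dataset)
  bic <- m / 2 * log(dataset$N / (2 * pi))
  structure(list(model = model,
                 g_hat = g_hat,
                 max_loglik = ll,
                 bic_term = bic,
                 complexity_term = complexity$value,
                 complexity = complexity,
                 score_se = complexity$std_error,
                 total = ll - bic - complexity$value),
            class = "model_score")
}

#' @export
print.model_score <- function(x, digits = 4, ...) {
  cat("<model_score> total = ", format(x$total, digits = digits),
      "  (max loglik ", format(x$max_loglik, digits = digits),
      " - BIC ", format(x$bic_term, digits = digits),
      " - c_M ", format(x$complexity_term, digits = digits), ")\n", sep = "")
  invisible(x)
}

# model spec string used for deterministic tie-breaking
.model_spec_string <- function(model) {
  paste(vapply(operator_indices(model), paste, character(1), collapse = " "),
        collapse = "; ")
}

#' Rank candidate models by MDL score
#'
#' Scores every candidate (closed-form complexity where available, Monte
#' Carlo otherwise) and ranks by descending total; ties are broken by smaller
#' \eqn{|M|}, then by the lexicographic model specification.  Gauge-equivalent
#' candidates have equal complexity, so for small systems (\code{n <= 4}) the
#' complexity of each gauge class is computed once, at its canonical
#' representative, and cached.  Ranking uses point estimates; the propagated
#' MC uncertainty is reported in each score's \code{score_se}.
#'
#' @param candidates list of \code{spin_model}s, all with the dataset's
#'   \code{n}.
#' @param dataset a \code{spin_dataset}.
#' @param n_samples,n_reps,seed Monte Carlo settings for complexities without
#'   closed form.
#' @return list of \code{model_score} in rank order.  Candidates whose fit
#'   fails (e.g. boundary sufficient statistics) are not fatal: they are
#'   returned at the end as records with a \code{fit_error} field and
#'   \code{total = -Inf}.
#' @export
select_model <- function(candidates, dataset, n_samples = 1e5, n_reps = 100,
                         seed = 1L) {
  stopifnot(is.list(candidates), length(candidates) >= 1L,
            inherits(dataset, "spin_dataset"))
  for (cand in candidates) {
    stopifnot(inherits(cand, "spin_model"))
    if (cand$n != dataset$n) stop("candidate n differs from dataset n")
  }
  cache <- new.env(hash = TRUE, parent = emptyenv())
  complexity_of <- function(model) {
    cc <- complexity_closed(model)
    if (!is.null(cc)) return(cc)
    key <- if (model$n <= 4L)
      .model_key(canonical_representative(model)$masks)
    else .model_key(sort(model$masks))
    if (!exists(key, envir = cache, inherits = FALSE)) {
      assign(key, complexity_mc(model, n_samples, n_reps, seed), envir = cache)
    }
    get(key, envir = cache)
  }
  scores <- lapply(candidates, function(model) {
    tryCatch(mdl_score(model, dataset, complexity_of(model)),
             error = function(e) {
               structure(list(model = model, g_hat = NULL,
                              max_loglik = NA_real_, bic_term = NA_real_,
                              complexity_term = NA_real_, complexity = NULL,
                              score_se = NA_real_, total = -Inf,
                              fit_error = conditionMessage(e)),
                         class = "model_score")
             })
  })
  totals <- vapply(scores, `[[`, numeric(1), "total")
  sizes <- vapply(scores, function(s) length(s$model$masks), numeric(1))
  specs <- vapply(scores, function(s) .model_spec_string(s$model), character(1))
  scores[order(-totals, sizes, specs)]
}
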