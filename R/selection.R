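#' Akaike weights from AIC differences
#'
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)}, computed with
#' a log-sum-exp normalization so that very large differences (\eqn{\Delta}
#' of several hundred) yield tiny but nonzero weights instead of
#' underflowing to zero.
#'
#' @param delta_aic numeric vector of AIC differences
#'   (\eqn{\Delta_i = \mathrm{AIC}_i - \min_j \mathrm{AIC}_j}); a raw AIC
#'   vector is accepted and re-centred.
#' @return numeric vector of weights summing to 1.
#' @export
akaike_weights <- function(delta_aic) {
  d <- delta_aic - min(delta_aic)
  lw <- -d / 2
  exp(lw - (max(lw) + log(sum(exp(lw - max(lw))))))
}

#' Rank candidate fits by AIC
#'
#' Builds the model-selection table: AIC, \eqn{\Delta}AIC and Akaike
#' weight per candidate, sorted by ascending AIC. All fits must be for the
#' same response on the same records.
#'
#' @param fits list of [fit_nb()] results.
#' @return data frame of class \code{selection_table} with columns
#'   \code{model, covariates, k, aic, delta_aic, weight}.
#' @export
model_selection <- function(fits) {
  if (length(fits) < 2)
    stop("model selection needs at least two fitted candidates",
         call. = FALSE)
  for (f in fits) stopifnot(inherits(f, "nb_fit"))
  fp <- vapply(fits, function(f) paste(f$fingerprint, collapse = "/"), "")
  resp <- vapply(fits, function(f) f$spec$response, "")
  if (length(unique(fp)) != 1 || length(unique(resp)) != 1)
    stop("all candidate fits must use the same records and response",
         call. = FALSE)
  tab <- data.frame(
    model = vapply(fits, function(f) f$spec$name, ""),
    covariates = vapply(fits, function(f)
      paste(f$spec$covariates, collapse = "+"), ""),
    k = vapply(fits, function(f) f$k, 0L),
    aic = vapply(fits, function(f) f$aic, 0))
  tab <- tab[order(tab$aic), , drop = FALSE]
  tab$delta_aic <- tab$aic - tab$aic[1]
  tab$weight <- akaike_weights(tab$delta_aic)
  rownames(tab) <- NULL
  class(tab) <- c("selection_table", "data.frame")
  tab
}

#' Evidence ratio of two Akaike weights
#'
#' How many times more plausible model \eqn{i} is than model \eqn{j}:
#' \eqn{w_i / w_j}. A zero denominator returns \code{Inf} (flagged, not an
#' error), which arises only when a weight has underflowed.
#'
#' @param w_i,w_j Akaike weights.
#' @return the ratio, with attribute \code{infinite = TRUE} when
#'   \code{w_j} is zero.
#' @export
evidence_ratio <- function(w_i, w_j) {
  if (w_j == 0) return(structure(Inf, infinite = TRUE))
  w_i / w_j
}

#' Fit all candidate models for one or more responses
#'
#' Fits the four candidates of [candidate_models()] for each requested
#' response and ranks them by AIC. Per-model fit failures are captured and
#' reported rather than aborting the whole analysis; selection proceeds
#' over the candidates that converged.
#'
#' @param records contig table.
#' @param responses character vector among \code{c("snp", "ti", "tv")}.
#' @return named list (one element per response), each a list with
#'   \code{fits} (successful fits), \code{selection}
#'   ([model_selection()] table, or \code{NULL} if fewer than two fits
#'   succeeded), \code{best} (lowest-AIC fit) and \code{errors} (named
#'   character vector of per-model failure messages).
#' @export
run_full_selection <- function(records, responses = c("snp", "ti", "tv")) {
  responses <- match.arg(responses, several.ok = TRUE)
  out <- list()
  for (resp in responses) {
    specs <- candidate_models(resp)
    fits <- list(); errors <- character(0)
    for (nm in names(specs)) {
      f <- tryCatch(fit_nb(records, specs[[nm]]), error = function(e) e)
      if (inherits(f, "error")) {
        errors[[paste(resp, nm, sep = ":")]] <- conditionMessage(f)
      } else fits[[nm]] <- f
    }
    sel <- if (length(fits) >= 2) model_selection(fits) else NULL
    best <- if (length(fits)) {
      fits[[which.min(vapply(fits, function(f) f$aic, 0))]]
    } else NULL
    out[[resp]] <- list(fits = fits, selection = sel, best = best,
                        errors = errors)
  }
  structure(out, class = "full_selection")
}

#' @export
print.selection_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$weight <- format_weight(y$weight)
  print(y)
  invisible(x)
}

#' @export
print.full_selection <- function(x, ...) {
  for (resp in names(x)) {
    cat(sprintf("== response: %s ==\n", resp))
    if (!is.null(x[[resp]]$selection)) print(x[[resp]]$selection)
    if (length(x[[resp]]$errors))
      cat("fit errors:\n",
          paste(" ", names(x[[resp]]$errors), x[[resp]]$errors,
                collapse = "\n"), "\n")
  }
  invisible(x)
}
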