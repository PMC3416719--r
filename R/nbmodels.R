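#' Candidate model specification
#'
#' A candidate negative-binomial regression for one response (SNP,
#' transition or transversion counts) on a subset of the covariates
#' \code{length}, \code{depth}, \code{cnc}. The intercept is always
#' included.
#'
#' @param response one of \code{"snp"}, \code{"ti"}, \code{"tv"}.
#' @param covariates character subset of
#'   \code{c("length", "depth", "cnc")}.
#' @param name optional label (e.g. \code{"M1"}).
#' @return an object of class \code{model_spec}.
#' @export
model_spec <- function(response = c("snp", "ti", "tv"),
                       covariates = c("length", "depth", "cnc"),
                       name = NULL) {
  response <- match.arg(response)
  bad <- setdiff(covariates, c("length", "depth", "cnc"))
  if (length(bad))
    stop("unknown covariate(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  covariates <- intersect(c("length", "depth", "cnc"), covariates)
  if (is.null(name))
    name <- if (length(covariates)) paste(covariates, collapse = "+")
            else "intercept-only"
  structure(list(response = response, covariates = covariates, name = name),
            class = "model_spec")
}

#' The four standard candidate models
#'
#' M1 (global): length + depth + coding class; M2: depth + coding class;
#' M3: length + coding class; M4: coding class only. The coding-class
#' indicator appears in every candidate so coding/non-coding contrasts are
#' always estimable.
#'
#' @param response one of \code{"snp"}, \code{"ti"}, \code{"tv"}.
#' @return named list of four [model_spec()] objects.
#' @export
candidate_models <- function(response = c("snp", "ti", "tv")) {
  response <- match.arg(response)
  list(
    M1 = model_spec(response, c("length", "depth", "cnc"), "M1"),
    M2 = model_spec(response, c("depth", "cnc"), "M2"),
    M3 = model_spec(response, c("length", "cnc"), "M3"),
    M4 = model_spec(response, "cnc", "M4"))
}

response_column <- function(response)
  c(snp = "n_snp", ti = "n_ti", tv = "n_tv")[[response]]

#' Fit one negative-binomial count regression
#'
#' Maximum-likelihood NB2 fit with log link,
#' \eqn{\log\mu_i = \beta x_i}, \eqn{\mathrm{Var} = \mu + \alpha\mu^2},
#' via [MASS::glm.nb()] (which alternates IWLS for \eqn{\beta} with ML
#' estimation of the shape \eqn{\theta = 1/\alpha}). Wald 95\% confidence
#' limits (\eqn{\hat\beta \pm 1.96\,\mathrm{se}}) and two-sided normal
#' p-values are attached per coefficient. The reported AIC counts the
#' dispersion as a parameter: \eqn{\mathrm{AIC} = -2\log L + 2(p + 1)}.
#'
#' If the data are equidispersed the shape estimate diverges; the
#' dispersion is then floored at \code{1e-8} and the fit flagged
#' \code{poisson_limit}.
#'
#' @param records contig table from [build_table()] or
#'   [simulate_count_table()].
#' @param spec a [model_spec()].
#' @return an object of class \code{nb_fit}: coefficients \code{beta},
#'   \code{se}, \code{ci95}, \code{wald_p}, dispersion \code{alpha},
#'   \code{loglik}, \code{aic}, sample size \code{n}, coefficient
#'   covariance \code{vcov}.
#' @export
fit_nb <- function(records, spec) {
  stopifnot(inherits(spec, "model_spec"))
  ycol <- response_column(spec$response)
  y <- records[[ycol]]
  if (is.null(y)) stop("records lack column ", ycol, call. = FALSE)
  if (any(y < 0) || any(y != floor(y)))
    stop("response must be nonnegative integer counts", call. = FALSE)
  if (all(y == 0))
    stop("all-zero response: no dispersion is identifiable; ",
         "consider a Poisson model", call. = FALSE)
  p <- length(spec$covariates) + 1L
  if (nrow(records) <= p + 1L)
    stop("too few records for the requested model", call. = FALSE)
  form <- stats::as.formula(paste(
    ycol, "~", paste(c("1", spec$covariates), collapse = " + ")))
  warn <- character(0)
  fit <- withCallingHandlers(
    tryCatch(
      MASS::glm.nb(form, data = records,
                   control = stats::glm.control(epsilon = 1e-10,
                                                maxit = 200)),
      error = function(e) e),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (inherits(fit, "error") || 1 / fit$theta < 1e-8) {
    # shape estimate diverged (equidispersed data): Poisson limit of NB2.
    # The dispersion is floored at 1e-8 and the coefficients taken from the
    # Poisson fit, whose likelihood the NB2 approaches as alpha -> 0.
    pf <- tryCatch(
      stats::glm(form, data = records, family = stats::poisson(),
                 control = stats::glm.control(epsilon = 1e-10, maxit = 200)),
      error = function(e)
        stop(sprintf("NB fit failed for model %s (%s): %s",
                     spec$name, spec$response, conditionMessage(e)),
             call. = FALSE))
    theta_chk <- suppressWarnings(
      tryCatch(MASS::theta.ml(records[[ycol]], stats::fitted(pf),
                              limit = 50),
               error = function(e) Inf))
    if (inherits(fit, "error") && is.finite(theta_chk) && theta_chk < 1e4)
      stop(sprintf("NB fit failed for model %s (%s): %s",
                   spec$name, spec$response, conditionMessage(fit)),
           call. = FALSE)
    fit <- pf
    fit$theta <- 1e8
    warn <- c(warn, "dispersion at Poisson limit; alpha floored at 1e-8")
  }
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  se <- sqrt(diag(V))
  alpha <- 1 / fit$theta
  poisson_limit <- alpha <= 1e-8
  if (poisson_limit) alpha <- 1e-8
  ll <- if (poisson_limit) {
    mu_hat <- stats::fitted(fit)
    sum(stats::dnbinom(records[[ycol]], size = 1 / alpha, mu = mu_hat,
                       log = TRUE))
  } else as.numeric(stats::logLik(fit))
  k <- length(beta) + 1L
  z <- beta / se
  structure(list(
    spec = spec, beta = beta, se = se,
    ci95 = cbind(lower = beta - 1.96 * se, upper = beta + 1.96 * se),
    wald_p = 2 * stats::pnorm(-abs(z)),
    alpha = alpha, theta = fit$theta, loglik = ll,
    aic = -2 * ll + 2 * k, k = k, n = nrow(records),
    vcov = V, poisson_limit = poisson_limit,
    warnings = warn,
    fingerprint = c(n = nrow(records), ysum = sum(y))),
    class = "nb_fit")
}

#' Construct an \code{nb_fit} from known coefficients
#'
#' Builds a minimal fit object from published or externally estimated
#' coefficients so [predict_count()] can be used without refitting (no
#' covariance, so prediction intervals are unavailable).
#'
#' @param beta named coefficient vector; names from
#'   \code{c("(Intercept)", "length", "depth", "cnc")}.
#' @param response response label.
#' @return an object of class \code{nb_fit}.
#' @export
nb_fit_from_coefs <- function(beta, response = "snp") {
  if (is.null(names(beta)))
    names(beta) <- c("(Intercept)", "length", "depth", "cnc")[
      seq_along(beta)]
  covs <- setdiff(names(beta), "(Intercept)")
  structure(list(spec = model_spec(response, covs),
                 beta = beta, se = NULL, ci95 = NULL, wald_p = NULL,
                 alpha = NA_real_, loglik = NA_real_, aic = NA_real_,
                 k = length(beta) + 1L, n = NA_integer_, vcov = NULL,
                 poisson_limit = FALSE, warnings = character(0),
                 fingerprint = c(n = NA, ysum = NA)),
            class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf("<nb_fit> %s ~ %s  (NB2, log link)\n", x$spec$response,
              paste(c("1", x$spec$covariates), collapse = " + ")))
  if (!is.null(x$se)) {
    tab <- data.frame(estimate = x$beta, se = x$se,
                      lower = x$ci95[, "lower"], upper = x$ci95[, "upper"],
                      p = signif(x$wald_p, 3))
    print(tab)
    cat(sprintf("alpha = %.4g   logLik = %.2f   AIC = %.1f   n = %d\n",
                x$alpha, x$loglik, x$aic, x$n))
    if (x$poisson_limit) cat("note: dispersion at Poisson limit\n")
  } else {
    print(x$beta)
  }
  invisible(x)
}

#' Predict the standardized SNP count at given contig length and depth
#'
#' Evaluates \eqn{\hat\mu = \exp(\hat\beta x)} at user-supplied covariate
#' values — the "standardized number of SNPs for a given contig length and
#' depth" that replaces per-kb SNP densities. When the coefficient
#' covariance is available a Wald 95\% interval on the mean is computed by
#' the delta method on the log scale:
#' \eqn{\exp(\hat\beta x \pm 1.96\sqrt{x^\top \Sigma x})}.
#'
#' Inputs are vectorized (recycled to a common length). Every covariate
#' present in the fit's specification must be supplied.
#'
#' @param fit an [fit_nb()] result (or [nb_fit_from_coefs()]).
#' @param length contig length in bp.
#' @param depth contig depth in reads.
#' @param cnc coding class (1 = protein-coding, 0 = non-coding).
#' @return data frame with columns \code{length, depth, cnc, estimate,
#'   lower, upper} (bounds \code{NA} without a covariance).
#' @export
predict_count <- function(fit, length = NULL, depth = NULL, cnc = NULL) {
  stopifnot(inherits(fit, "nb_fit"))
  covs <- fit$spec$covariates
  supplied <- list(length = length, depth = depth, cnc = cnc)
  for (cv in covs)
    if (is.null(supplied[[cv]]))
      stop(sprintf("covariate '%s' is in the model but was not supplied",
                   cv), call. = FALSE)
  n <- max(1L, lengths(supplied))
  vals <- lapply(supplied, function(v) if (is.null(v)) rep(NA, n)
                 else rep_len(v, n))
  X <- cbind(`(Intercept)` = rep(1, n))
  for (cv in covs) X <- cbind(X, vals[[cv]])
  colnames(X) <- c("(Intercept)", covs)
  b <- fit$beta[colnames(X)]
  eta <- drop(X %*% b)
  if (!is.null(fit$vcov)) {
    V <- fit$vcov[colnames(X), colnames(X)]
    se_eta <- sqrt(rowSums((X %*% V) * X))
    lower <- exp(eta - 1.96 * se_eta)
    upper <- exp(eta + 1.96 * se_eta)
  } else {
    lower <- upper <- rep(NA_real_, n)
  }
  data.frame(length = vals$length, depth = vals$depth, cnc = vals$cnc,
             estimate = exp(eta), lower = lower, upper = upper)
}
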