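#' Simulate a per-contig SNP count table from a known NB2 model
#'
#' Draws contig lengths, depths and coding classes from the configured
#' distributions and then SNP counts from a negative-binomial (NB2)
#' regression with log link,
#' \eqn{\mu_i = \exp(\beta_0 + \beta_L \ell_i + \beta_D d_i + \beta_C c_i)},
#' \eqn{\mathrm{Var} = \mu + \alpha\mu^2}. With \code{dispersion_alpha = 0}
#' counts are Poisson. Transitions are split from each SNP count as
#' \code{Binomial(n_snp, ti_prop)}; transversions are the remainder.
#'
#' @param config a [count_sim_config()].
#' @return a data frame with columns \code{contig_id, length, depth, cnc,
#'   n_snp, n_ti, n_tv} (\code{cnc} = 1 for protein-coding, 0 for
#'   non-coding).
#' @export
simulate_count_table <- function(config) {
  stopifnot(inherits(config, "count_sim_config"))
  set.seed(config$seed)
  n <- config$n_contigs
  len <- round(draw_dist(config$length_dist, n))
  dep <- round(draw_dist(config$depth_dist, n))
  cnc <- stats::rbinom(n, 1, config$prop_coding)
  b <- config$true_beta
  mu <- exp(b[1] + b[2] * len + b[3] * dep + b[4] * cnc)
  if (any(!is.finite(mu)))
    stop_config("true_beta", "yields non-finite means for simulated covariates")
  a <- config$dispersion_alpha
  n_snp <- if (a < 1e-12) stats::rpois(n, mu)
           else stats::rnbinom(n, size = 1 / a, mu = mu)
  n_ti <- stats::rbinom(n, n_snp, config$ti_prop)
  data.frame(contig_id = sprintf("contig%05d", seq_len(n)),
             length = as.integer(len), depth = as.integer(dep),
             cnc = as.integer(cnc), n_snp = as.integer(n_snp),
             n_ti = as.integer(n_ti),
             n_tv = as.integer(n_snp - n_ti))
}
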