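#' Configuration for the contig-alignment simulator
#'
#' Describes a set of synthetic transcriptome contigs: consensus sequences
#' with per-base quality scores and the full-length reads aligned over them,
#' with biallelic SNPs planted at known positions and minor-allele counts,
#' plus "decoy" events, each of which violates exactly one rule of the SNP
#' filter cascade and must therefore be rejected by a correct caller.
#'
#' Contig lengths default to a lognormal truncated to 100--5,400 bp and
#' depths to a shifted lognormal truncated to 10--315 reads, bracketing the
#' ranges typical of a 454 transcriptome assembly. Decoy and SNP rates are
#' expected events per kb of contig (Poisson-distributed counts).
#'
#' Base-call errors are injected at \code{base_error_rate} per read base and
#' carry quality scores drawn from \code{error_quality_dist} (default
#' uniform 5--15, i.e. below the default quality filter), while correct
#' bases draw from \code{quality_dist} (default uniform 30--40): the
#' simulator idealizes the case where the basecaller's quality scores are
#' informative about its errors.
#'
#' @param n_contigs number of contigs to simulate.
#' @param length_dist,depth_dist,quality_dist,error_quality_dist,minor_freq_dist
#'   named distribution specs: \code{list(dist = "lognormal", meanlog=,
#'   sdlog=, shift=, min=, max=)}, \code{list(dist = "uniform", min=, max=)}
#'   or \code{list(dist = "constant", value=)}.
#' @param prop_coding fraction of contigs labelled protein-coding.
#' @param snp_rate_per_kb expected planted SNPs per kb.
#' @param base_error_rate per-base probability of a sequencing error.
#' @param homopolymer_decoy_rate,indel_decoy_rate,triallelic_decoy_rate,low_minor_decoy_rate,edge_decoy_rate,lowqual_flank_decoy_rate
#'   expected decoys per kb for each filter-rule class. Low-minor decoys
#'   (one minor read at minor-allele frequency below 1\%) require depth
#'   > 100 and are only placed on contigs deep enough to express them.
#' @param partial_span_reads if \code{TRUE}, reads cover a random
#'   sub-interval of the contig instead of its full length (stress-test
#'   mode; planted event counts are then guaranteed only among spanning
#'   reads).
#' @param seed root RNG seed; per-contig substreams are derived from it by
#'   counter so contig \code{i} does not depend on \code{n_contigs}.
#' @return an object of class \code{alignment_sim_config}.
#' @seealso [simulate_alignments()]
#' @export
alignment_sim_config <- function(
    n_contigs = 100,
    length_dist = list(dist = "lognormal", meanlog = log(650), sdlog = 0.75,
                       min = 100, max = 5400),
    depth_dist = list(dist = "lognormal", meanlog = log(16), sdlog = 0.85,
                      shift = 8, min = 10, max = 315),
    prop_coding = 0.5,
    snp_rate_per_kb = 1.0,
    minor_freq_dist = list(dist = "uniform", min = 0.05, max = 0.5),
    base_error_rate = 0.001,
    quality_dist = list(dist = "uniform", min = 30, max = 40),
    error_quality_dist = list(dist = "uniform", min = 5, max = 15),
    homopolymer_decoy_rate = 0,
    indel_decoy_rate = 0,
    triallelic_decoy_rate = 0,
    low_minor_decoy_rate = 0,
    edge_decoy_rate = 0,
    lowqual_flank_decoy_rate = 0,
    partial_span_reads = FALSE,
    seed = 1L) {
  if (!is.numeric(n_contigs) || n_contigs < 1)
    stop_config("n_contigs", "must be >= 1")
  check_prob(prop_coding, "prop_coding")
  check_prob(base_error_rate, "base_error_rate")
  check_nonneg(snp_rate_per_kb, "snp_rate_per_kb")
  for (f in c("homopolymer_decoy_rate", "indel_decoy_rate",
              "triallelic_decoy_rate", "low_minor_decoy_rate",
              "edge_decoy_rate", "lowqual_flank_decoy_rate"))
    check_nonneg(get(f), f)
  structure(list(
    n_contigs = as.integer(n_contigs), length_dist = length_dist,
    depth_dist = depth_dist, prop_coding = prop_coding,
    snp_rate_per_kb = snp_rate_per_kb, minor_freq_dist = minor_freq_dist,
    base_error_rate = base_error_rate, quality_dist = quality_dist,
    error_quality_dist = error_quality_dist,
    homopolymer_decoy_rate = homopolymer_decoy_rate,
    indel_decoy_rate = indel_decoy_rate,
    triallelic_decoy_rate = triallelic_decoy_rate,
    low_minor_decoy_rate = low_minor_decoy_rate,
    edge_decoy_rate = edge_decoy_rate,
    lowqual_flank_decoy_rate = lowqual_flank_decoy_rate,
    partial_span_reads = isTRUE(partial_span_reads),
    seed = as.integer(seed)),
    class = "alignment_sim_config")
}

#' Configuration for the per-contig SNP-count simulator
#'
#' Describes a table of contigs whose SNP counts are drawn from a
#' negative-binomial (NB2) regression with log link:
#' \deqn{\log \mu_i = \beta_0 + \beta_L \cdot \mathrm{length}_i +
#'       \beta_D \cdot \mathrm{depth}_i + \beta_C \cdot \mathrm{cnc}_i,
#'       \quad \mathrm{Var} = \mu + \alpha \mu^2.}
#' Transition counts are split from the SNP count binomially with
#' probability \code{ti_prop} (default 0.64, the transition share typical of
#' transcriptome SNP sets with Ti/Tv near 1.8).
#'
#' Length and depth distributions default to the "long contig" regime:
#' lengths lognormal truncated to 501--5,354 bp (mean near 1,000) and depths
#' a shifted lognormal truncated to 10--315 reads (mean near 32).
#'
#' @param n_contigs number of rows to simulate.
#' @param true_beta numeric length-4 vector
#'   (intercept, length, depth, coding-class) on the log-link scale.
#' @param dispersion_alpha NB2 dispersion \eqn{\alpha \ge 0}; \code{0}
#'   gives the Poisson limit.
#' @param length_dist,depth_dist distribution specs as in
#'   [alignment_sim_config()].
#' @param prop_coding fraction of protein-coding contigs.
#' @param ti_prop probability a SNP is a transition.
#' @param seed RNG seed.
#' @return an object of class \code{count_sim_config}.
#' @seealso [simulate_count_table()]
#' @export
count_sim_config <- function(
    n_contigs = 1000,
    true_beta = c(-0.9828, 0.0002, 0.0146, -0.0999),
    dispersion_alpha = 0.5,
    length_dist = list(dist = "lognormal", meanlog = log(900), sdlog = 0.45,
                       min = 501, max = 5354),
    depth_dist = list(dist = "lognormal", meanlog = log(20), sdlog = 0.8,
                      shift = 8, min = 10, max = 315),
    prop_coding = 0.55,
    ti_prop = 0.64,
    seed = 1L) {
  if (!is.numeric(n_contigs) || n_contigs < 1)
    stop_config("n_contigs", "must be >= 1")
  if (!is.numeric(true_beta) || length(true_beta) != 4)
    stop_config("true_beta", "must be a numeric 4-vector")
  check_nonneg(dispersion_alpha, "dispersion_alpha")
  check_prob(prop_coding, "prop_coding")
  check_prob(ti_prop, "ti_prop")
  structure(list(
    n_contigs = as.integer(n_contigs), true_beta = as.numeric(true_beta),
    dispersion_alpha = dispersion_alpha, length_dist = length_dist,
    depth_dist = depth_dist, prop_coding = prop_coding, ti_prop = ti_prop,
    seed = as.integer(seed)),
    class = "count_sim_config")
}

#' Read a simulator configuration from a flat key-value file
#'
#' The file holds one \code{key = value} pair per line (\code{#} comments
#' allowed). Scalar fields use their name directly; distribution fields use
#' dotted keys, e.g. \code{length_dist.dist = lognormal},
#' \code{length_dist.meanlog = 6.5}. \code{type} must be \code{alignment}
#' or \code{count} and selects the config class. Unknown keys are an error.
#'
#' @param path file to read.
#' @return an \code{alignment_sim_config} or \code{count_sim_config}.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3
  if (any(bad))
    stop_config("file", sprintf("unparseable line: '%s'", lines[bad][1]))
  keys <- vapply(kv, `[`, "", 2)
  vals <- vapply(kv, `[`, "", 3)
  type <- vals[keys == "type"]
  if (length(type) != 1 || !type %in% c("alignment", "count"))
    stop_config("type", "must be 'alignment' or 'count'")
  keep <- keys != "type"
  keys <- keys[keep]; vals <- vals[keep]

  ctor <- if (type == "alignment") alignment_sim_config else count_sim_config
  known <- names(formals(ctor))
  args <- list()
  for (i in seq_along(keys)) {
    parts <- strsplit(keys[i], ".", fixed = TRUE)[[1]]
    v <- utils::type.convert(vals[i], as.is = TRUE)
    if (length(parts) == 1) {
      if (!parts %in% known) stop_config(parts, "is not a recognized key")
      if (parts == "true_beta")
        v <- as.numeric(strsplit(vals[i], "[, ]+")[[1]])
      args[[parts]] <- v
    } else if (length(parts) == 2) {
      if (!parts[1] %in% known || !grepl("_dist$", parts[1]))
        stop_config(keys[i], "is not a recognized key")
      if (is.null(args[[parts[1]]])) args[[parts[1]]] <- list()
      args[[parts[1]]][[parts[2]]] <- v
    } else stop_config(keys[i], "is not a recognized key")
  }
  do.call(ctor, args)
}
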