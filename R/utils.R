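#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")

# Derive a per-contig RNG seed from the root seed and a contig counter, so
# contig i is reproducible regardless of how many contigs are simulated.
# Kept strictly below 2^31 (R integer range).
contig_seed <- function(root_seed, i) {
  as.integer((as.numeric(root_seed) %% 1e6L * 1009 + i * 7919) %% 2147483647)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

# Draw n values from a named distribution spec: list(dist = "...", <params>).
# Supported: lognormal (meanlog, sdlog, optional min/max truncation by
# rejection), uniform (min, max), constant (value). Integer-valued draws are
# rounded by the caller where required.
draw_dist <- function(spec, n) {
  if (!is.list(spec) || is.null(spec$dist))
    stop_config("distribution", "must be a list with a 'dist' name")
  d <- spec$dist
  if (d == "constant") {
    if (is.null(spec$value)) stop_config("value", "required for constant")
    return(rep(spec$value, n))
  }
  if (d == "uniform") {
    if (is.null(spec$min) || is.null(spec$max) || spec$min > spec$max)
      stop_config("min/max", "must satisfy min <= max for uniform")
    return(stats::runif(n, spec$min, spec$max))
  }
  if (d == "lognormal") {
    if (is.null(spec$meanlog) || is.null(spec$sdlog) || spec$sdlog < 0)
      stop_config("meanlog/sdlog", "required, sdlog >= 0")
    shift <- if (is.null(spec$shift)) 0 else spec$shift
    lo <- if (is.null(spec$min)) -Inf else spec$min
    hi <- if (is.null(spec$max)) Inf else spec$max
    out <- numeric(0)
    for (it in 1:1000) {
      x <- shift + stats::rlnorm(max(n * 2L, 16L), spec$meanlog, spec$sdlog)
      out <- c(out, x[x >= lo & x <= hi])
      if (length(out) >= n) return(out[seq_len(n)])
    }
    stop_config("distribution", "truncation bounds reject nearly all draws")
  }
  stop_config("dist", sprintf("unknown distribution '%s'", d))
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop_config(field, "must be a single probability in [0, 1]")
  x
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0)
    stop_config(field, "must be a single nonnegative number")
  x
}
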