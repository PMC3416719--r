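#' Simulate contig alignments with planted SNPs and filter-rule decoys
#'
#' Generates a set of synthetic contig alignments (full-length reads over a
#' random consensus by default) together with a truth table of every
#' planted event. Planted SNPs are constructed to pass every rule of the
#' SNP filter cascade: at least two high-quality minor reads, clean
#' high-quality flanks, no homopolymer run at or adjacent to the site, and
#' an interior position. Each decoy class violates exactly one rule:
#' \describe{
#'   \item{homopolymer}{a well-supported variant placed inside an injected
#'     run of 6 identical consensus bases;}
#'   \item{indel}{a column carrying both a substitution (2 reads) and read
#'     gaps (2 reads);}
#'   \item{triallelic}{a column with two distinct minor alleles, each on 2
#'     high-quality reads;}
#'   \item{low_minor}{a single minor read on a contig deeper than 100
#'     reads, so the minor-allele frequency is below 1\% and the read count
#'     below 2;}
#'   \item{edge}{a well-supported variant within 20 bp of a contig end;}
#'   \item{lowqual_flank}{a well-supported variant with one flanking
#'     consensus base forced to quality 10.}
#' }
#' Events on the same contig are spaced at least 45 bp apart so no decoy's
#' side effects (injected runs, degraded flank quality) can leak into a
#' planted SNP's acceptance region. The natural consensus is generated
#' homopolymer-free above run length 4.
#'
#' @param config an [alignment_sim_config()].
#' @return a list with elements \code{alignments} (named list of
#'   [contig_alignment()] objects), \code{truth} (list of data frames
#'   \code{snps} with columns \code{contig_id, pos, major, minor,
#'   minor_count} and \code{decoys} with columns \code{contig_id, kind,
#'   pos}), and \code{labels} (data frame \code{contig_id, class} with
#'   class \code{coding}/\code{noncoding}).
#' @export
simulate_alignments <- function(config) {
  stopifnot(inherits(config, "alignment_sim_config"))
  alns <- vector("list", config$n_contigs)
  snps <- list(); decoys <- list()
  labels <- data.frame(contig_id = character(0), class = character(0))
  for (i in seq_len(config$n_contigs)) {
    res <- sim_one_contig(config, i)
    alns[[i]] <- res$aln
    snps[[i]] <- res$snps
    decoys[[i]] <- res$decoys
    labels <- rbind(labels,
                    data.frame(contig_id = res$aln$contig_id,
                               class = res$class))
  }
  names(alns) <- vapply(alns, function(a) a$contig_id, "")
  list(alignments = alns,
       truth = list(snps = do.call(rbind, snps),
                    decoys = do.call(rbind, decoys)),
       labels = labels)
}

# Consensus with no homopolymer run longer than 4: regenerate the offending
# base of every run of 5+ until none remain.
sim_consensus <- function(L) {
  s <- sample(BASES, L, replace = TRUE)
  repeat {
    r <- rle(s)
    long <- which(r$lengths > 4)
    if (!length(long)) break
    ends <- cumsum(r$lengths)
    for (k in long) {
      pos <- ends[k] - r$lengths[k] + 5L  # 5th base of the run
      s[pos] <- sample(setdiff(BASES, s[pos]), 1)
    }
  }
  s
}

sim_one_contig <- function(config, i) {
  set.seed(contig_seed(config$seed, i))
  cid <- sprintf("contig%05d", i)
  L <- as.integer(round(draw_dist(config$length_dist, 1)))
  D <- as.integer(round(draw_dist(config$depth_dist, 1)))
  class <- if (stats::runif(1) < config$prop_coding) "coding" else "noncoding"
  cons <- sim_consensus(L)
  cqual <- as.integer(round(draw_dist(config$quality_dist, L)))

  kb <- L / 1000
  n_ev <- c(
    snp          = stats::rpois(1, config$snp_rate_per_kb * kb),
    homopolymer  = stats::rpois(1, config$homopolymer_decoy_rate * kb),
    indel        = stats::rpois(1, config$indel_decoy_rate * kb),
    triallelic   = stats::rpois(1, config$triallelic_decoy_rate * kb),
    low_minor    = if (D > 100)
                     stats::rpois(1, config$low_minor_decoy_rate * kb) else 0L,
    lowqual_flank = stats::rpois(1, config$lowqual_flank_decoy_rate * kb))
  n_edge <- stats::rpois(1, config$edge_decoy_rate * kb)

  # interior slots, spaced 45 bp, clear of both contig ends
  lo <- 31L; hi <- L - 30L
  slots <- if (hi >= lo) seq.int(lo, hi, by = 45L) else integer(0)
  slots <- slots[sample.int(length(slots))]
  n_int <- sum(n_ev)
  if (n_int > length(slots)) {
    # shed events proportionally, SNPs last
    for (k in rev(names(n_ev))) {
      drop <- min(n_ev[[k]], n_int - length(slots))
      n_ev[[k]] <- n_ev[[k]] - drop
      n_int <- n_int - drop
      if (n_int <= length(slots)) break
    }
  }
  kinds <- rep(names(n_ev), times = n_ev)
  pos_int <- slots[seq_along(kinds)]

  edge_pool <- unique(c(1:min(20L, L), max(1L, L - 19L):L))
  n_edge <- min(n_edge, length(edge_pool))
  pos_edge <- edge_pool[sample.int(length(edge_pool), n_edge)]

  # homopolymer decoys rewrite the consensus before reads are laid down
  for (k in which(kinds == "homopolymer")) {
    p <- pos_int[k]
    run_base <- cons[p]
    cons[(p - 2L):(p + 3L)] <- run_base
  }

  M <- matrix(rep(cons, each = D), nrow = D, ncol = L)
  Q <- matrix(as.integer(round(draw_dist(config$quality_dist, D * L))),
              nrow = D, ncol = L)

  # sequencing errors: random substitutions carrying low quality scores
  n_err <- stats::rbinom(1, D * L, config$base_error_rate)
  if (n_err > 0) {
    cells <- sample.int(D * L, n_err)
    M[cells] <- vapply(M[cells],
                       function(b) sample(setdiff(BASES, b), 1), "")
    Q[cells] <- as.integer(round(draw_dist(config$error_quality_dist, n_err)))
  }

  minor_count_for <- function() {
    f <- draw_dist(config$minor_freq_dist, 1)
    max(2L, min(D %/% 2L, as.integer(round(f * D))))
  }
  snp_rows <- list(); decoy_rows <- list()
  # planting overwrites any earlier error at the same cell, quality included
  plant <- function(p, base, rows) {
    M[rows, p] <<- base
    Q[rows, p] <<- as.integer(round(draw_dist(config$quality_dist,
                                              length(rows))))
  }

  for (k in seq_along(kinds)) {
    p <- pos_int[k]; kind <- kinds[k]
    major <- cons[p]
    minor <- sample(setdiff(BASES, major), 1)
    if (kind == "snp") {
      m <- minor_count_for()
      plant(p, minor, sample.int(D, m))
      snp_rows[[length(snp_rows) + 1L]] <-
        data.frame(contig_id = cid, pos = p, major = major, minor = minor,
                   minor_count = m)
      next
    }
    if (kind == "homopolymer") {
      plant(p, minor, sample.int(D, minor_count_for()))
    } else if (kind == "indel") {
      rows <- sample.int(D, 4L)
      plant(p, minor, rows[1:2])
      M[rows[3:4], p] <- "-"
      Q[rows[3:4], p] <- 0L
    } else if (kind == "triallelic") {
      minors <- sample(setdiff(BASES, major), 2)
      rows <- sample.int(D, 4L)
      plant(p, minors[1], rows[1:2])
      plant(p, minors[2], rows[3:4])
    } else if (kind == "low_minor") {
      # the column must stay clean: a single minor read out of >100
      # quality-passing reads keeps the MAF strictly below 1%
      plant(p, major, seq_len(D))
      plant(p, minor, sample.int(D, 1L))
    } else if (kind == "lowqual_flank") {
      plant(p, minor, sample.int(D, minor_count_for()))
      off <- sample(c(-(1:20), 1:20), 1)
      cqual[p + off] <- 10L
    }
    decoy_rows[[length(decoy_rows) + 1L]] <-
      data.frame(contig_id = cid, kind = kind, pos = p)
  }
  for (p in pos_edge) {
    major <- cons[p]
    minor <- sample(setdiff(BASES, major), 1)
    plant(p, minor, sample.int(D, max(2L, min(D %/% 2L, 3L))))
    decoy_rows[[length(decoy_rows) + 1L]] <-
      data.frame(contig_id = cid, kind = "edge", pos = p)
  }

  if (config$partial_span_reads) {
    starts <- sample.int(max(1L, L - 30L), D, replace = TRUE)
    ends <- pmin(L, starts + 29L +
                   as.integer(round(draw_dist(config$length_dist, D) / 2)))
  } else {
    starts <- rep(1L, D); ends <- rep(L, D)
  }
  reads <- vector("list", D)
  for (j in seq_len(D)) {
    idx <- starts[j]:ends[j]
    reads[[j]] <- list(read_id = sprintf("%s_r%04d", cid, j),
                       start = starts[j],
                       seq = paste0(M[j, idx], collapse = ""),
                       qual = Q[j, idx])
  }
  aln <- contig_alignment(cid, paste0(cons, collapse = ""), cqual, reads)
  empty_snps <- data.frame(contig_id = character(0), pos = integer(0),
                           major = character(0), minor = character(0),
                           minor_count = integer(0))
  empty_dec <- data.frame(contig_id = character(0), kind = character(0),
                          pos = integer(0))
  list(aln = aln, class = class,
       snps = if (length(snp_rows)) do.call(rbind, snp_rows) else empty_snps,
       decoys = if (length(decoy_rows)) do.call(rbind, decoy_rows)
                else empty_dec)
}
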