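#' SNP filter configuration
#'
#' Thresholds of the SNP-calling filter cascade. Defaults follow a
#' conservative 454-transcriptome scoring scheme: contigs must be at least
#' 100 bp long with 10 or more aligned reads; a variant site needs a minor
#' allele frequency of at least 0.01 \emph{or} at least two minor-allele
#' reads; 20 bp of high-quality consensus sequence must flank the site on
#' both sides; sites in (or immediately adjacent to) consensus homopolymer
#' runs longer than 4 bases are discarded; and only read bases with quality
#' strictly above 20 count. Only biallelic substitutions are scored: any
#' gap observation or third allele at a column disqualifies it.
#'
#' @param min_contig_length minimum contig length in bp (set 501 for a
#'   long-contig analysis).
#' @param min_depth minimum number of aligned reads.
#' @param min_maf minimum minor allele frequency, in (0, 0.5].
#' @param min_minor_reads minimum minor-allele read count (OR-combined with
#'   \code{min_maf}).
#' @param flank_len required high-quality flank, bp, each side.
#' @param min_base_quality exclusive quality threshold: a base counts only
#'   if its score is strictly greater.
#' @param max_homopolymer exclusive homopolymer run threshold: runs
#'   strictly longer are excluded.
#' @return an object of class \code{filter_config}.
#' @export
filter_config <- function(min_contig_length = 100, min_depth = 10,
                          min_maf = 0.01, min_minor_reads = 2,
                          flank_len = 20, min_base_quality = 20,
                          max_homopolymer = 4) {
  vals <- c(min_contig_length = min_contig_length, min_depth = min_depth,
            min_maf = min_maf, min_minor_reads = min_minor_reads,
            flank_len = flank_len, min_base_quality = min_base_quality,
            max_homopolymer = max_homopolymer)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all filter thresholds must be positive", call. = FALSE)
  if (min_maf > 0.5)
    stop("min_maf must lie in (0, 0.5]", call. = FALSE)
  structure(as.list(vals), class = "filter_config")
}

#' Is a contig eligible for SNP scoring?
#'
#' A contig enters the analysis only if its consensus is at least
#' \code{min_contig_length} bp and at least \code{min_depth} reads are
#' aligned to it.
#'
#' @param alignment a [contig_alignment()].
#' @param cfg a [filter_config()].
#' @return logical scalar.
#' @export
eligible_contig <- function(alignment, cfg = filter_config()) {
  nchar(alignment$consensus) >= cfg$min_contig_length &&
    length(alignment$reads) >= cfg$min_depth
}

#' Quality-filtered allele counts at one alignment column
#'
#' Tallies read bases at a 1-based consensus position. Bases count only if
#' their quality is strictly above \code{min_base_quality}; gap characters
#' (\code{-}) are tallied unconditionally (they carry no quality and are
#' needed for indel exclusion); read \code{N}s are ignored; reads not
#' covering the column contribute nothing.
#'
#' @inheritParams eligible_contig
#' @param position 1-based position on the consensus.
#' @return named integer vector of nonzero counts over
#'   \code{A,C,G,T,gap}.
#' @export
column_alleles <- function(alignment, position, cfg = filter_config()) {
  L <- nchar(alignment$consensus)
  if (position < 1 || position > L)
    stop(sprintf("position %d outside contig '%s' (1..%d)",
                 position, alignment$contig_id, L), call. = FALSE)
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L, gap = 0L)
  for (rd in alignment$reads) {
    off <- position - rd$start + 1L
    if (off < 1L || off > nchar(rd$seq)) next
    b <- substr(rd$seq, off, off)
    if (b == "-") counts["gap"] <- counts["gap"] + 1L
    else if (b %in% BASES && rd$qual[off] > cfg$min_base_quality)
      counts[b] <- counts[b] + 1L
  }
  counts[counts > 0L]
}

#' Homopolymer exclusion test
#'
#' A position is excluded if it lies inside, or immediately adjacent to, a
#' maximal run of identical consensus bases strictly longer than
#' \code{max_homopolymer} (default: runs of 5 or more). Adjacency is
#' included because pyrosequencing homopolymer miscalls concentrate at run
#' boundaries.
#'
#' @param consensus consensus sequence (single string).
#' @param position 1-based position.
#' @param cfg a [filter_config()].
#' @return logical scalar.
#' @export
homopolymer_excluded <- function(consensus, position, cfg = filter_config()) {
  s <- strsplit(consensus, "")[[1]]
  if (position < 1 || position > length(s))
    stop("position outside consensus", call. = FALSE)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  long <- which(r$lengths > cfg$max_homopolymer)
  for (k in long) {
    if (position >= starts[k] - 1L && position <= ends[k] + 1L) return(TRUE)
  }
  FALSE
}

#' High-quality flank test
#'
#' TRUE iff the \code{flank_len} consensus positions immediately upstream
#' and downstream of the site all exist, all have consensus quality
#' strictly above \code{min_base_quality}, and none is an \code{N}.
#'
#' @inheritParams eligible_contig
#' @param position 1-based position on the consensus.
#' @return logical scalar.
#' @export
flank_ok <- function(alignment, position, cfg = filter_config()) {
  L <- nchar(alignment$consensus)
  if (position < 1 || position > L)
    stop("position outside consensus", call. = FALSE)
  f <- cfg$flank_len
  if (position - f < 1 || position + f > L) return(FALSE)
  idx <- c((position - f):(position - 1L), (position + 1L):(position + f))
  if (any(alignment$consensus_quality[idx] <= cfg$min_base_quality))
    return(FALSE)
  flanks <- substring(alignment$consensus, idx, idx)
  !any(flanks == "N")
}

#' Classify a substitution as transition or transversion
#'
#' Transitions are the purine--purine (A/G) and pyrimidine--pyrimidine
#' (C/T) exchanges; the four other unordered pairs are transversions.
#'
#' @param a,b distinct bases in \code{A,C,G,T}.
#' @return \code{"Ti"} or \code{"Tv"}.
#' @export
classify_substitution <- function(a, b) {
  if (!a %in% BASES || !b %in% BASES)
    stop("alleles must be in {A,C,G,T}", call. = FALSE)
  if (a == b) stop("alleles must differ", call. = FALSE)
  pair <- paste(sort(c(a, b)), collapse = "")
  if (pair %in% c("AG", "CT")) "Ti" else "Tv"
}

#' Call SNPs on a contig alignment
#'
#' Applies the full filter cascade to every consensus column and returns
#' the accepted biallelic substitution sites. A column yields a call iff:
#' \enumerate{
#'   \item the contig is eligible ([eligible_contig()]); an ineligible
#'     contig returns an empty call set;
#'   \item the quality-passing allele counts contain exactly two distinct
#'     bases and no gap observation (strict indel/triallelic exclusion);
#'   \item the minor fraction among quality-passing bases is at least
#'     \code{min_maf} \emph{or} the minor count is at least
#'     \code{min_minor_reads};
#'   \item [flank_ok()] holds and [homopolymer_excluded()] does not;
#'   \item the consensus base at the column is not \code{N}.
#' }
#' The minor allele is the lower-count base; on an exact tie the
#' lexicographically later base is taken as minor. MAF is the minor count
#' over the quality-passing reads at that column.
#'
#' @inheritParams eligible_contig
#' @return data frame with one row per call, sorted by position: columns
#'   \code{contig_id, position, major_allele, minor_allele, major_count,
#'   minor_count, maf, substitution_class}.
#' @export
call_snps <- function(alignment, cfg = filter_config()) {
  if (!inherits(alignment, "contig_alignment"))
    stop("alignment must be a contig_alignment", call. = FALSE)
  empty <- data.frame(contig_id = character(0), position = integer(0),
                      major_allele = character(0), minor_allele = character(0),
                      major_count = integer(0), minor_count = integer(0),
                      maf = numeric(0), substitution_class = character(0))
  if (!eligible_contig(alignment, cfg)) return(empty)

  mats <- alignment_matrices(alignment)
  M <- mats$bases; Q <- mats$quals
  cons <- strsplit(alignment$consensus, "")[[1]]
  L <- length(cons)

  hq <- !is.na(M) & M != "-" & M != "N" & Q > cfg$min_base_quality
  mism <- hq & (M != rep(cons, each = nrow(M)))
  has_gap <- colSums(M == "-", na.rm = TRUE) > 0L
  # candidate columns: any high-quality mismatch or any gap
  cand <- which(colSums(mism) > 0L | has_gap)

  # homopolymer-excluded positions, precomputed once per contig
  r <- rle(cons)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  hp_bad <- rep(FALSE, L)
  for (k in which(r$lengths > cfg$max_homopolymer))
    hp_bad[max(1L, starts[k] - 1L):min(L, ends[k] + 1L)] <- TRUE

  rows <- list()
  for (p in cand) {
    if (has_gap[p] || cons[p] == "N" || hp_bad[p]) next
    keep <- hq[, p]
    tab <- table(M[keep, p])
    if (length(tab) != 2L) next
    cnt <- as.integer(tab); names(cnt) <- names(tab)
    ord <- order(cnt, names(cnt))  # minor first; tie -> later base is minor
    minor_i <- if (cnt[ord[1]] == cnt[ord[2]]) {
      which(names(cnt) == max(names(cnt)))
    } else ord[1]
    major_i <- setdiff(1:2, minor_i)
    minor_n <- cnt[minor_i]; major_n <- cnt[major_i]
    maf <- minor_n / (minor_n + major_n)
    if (maf < cfg$min_maf && minor_n < cfg$min_minor_reads) next
    if (!flank_ok(alignment, p, cfg)) next
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = alignment$contig_id, position = p,
      major_allele = names(cnt)[major_i], minor_allele = names(cnt)[minor_i],
      major_count = unname(major_n), minor_count = unname(minor_n),
      maf = unname(maf),
      substitution_class = classify_substitution(names(cnt)[major_i],
                                                 names(cnt)[minor_i]))
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$position), , drop = FALSE]
}

#' Call SNPs across a set of contig alignments
#'
#' @param alignments list of [contig_alignment()] objects.
#' @param cfg a [filter_config()].
#' @return row-bound data frame of [call_snps()] results.
#' @export
call_snps_all <- function(alignments, cfg = filter_config()) {
  do.call(rbind, c(lapply(alignments, call_snps, cfg = cfg),
                   make.row.names = FALSE))
}
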