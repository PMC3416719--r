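#' Contig alignment container
#'
#' Holds one contig: its consensus sequence, per-base consensus quality
#' scores, and the reads aligned over it. Reads are stored in alignment
#' coordinates on the consensus: a 1-based start offset and an aligned
#' string over \code{A,C,G,T,N,-} (\code{-} marks a deleted base relative
#' to the consensus), with one integer quality per aligned character (gap
#' characters carry quality 0, which is never consulted).
#'
#' @param contig_id contig identifier.
#' @param consensus consensus sequence, a single string over
#'   \code{A,C,G,T,N}.
#' @param consensus_quality integer vector of per-base consensus quality
#'   scores, one per consensus base.
#' @param reads list of reads, each a list with elements \code{read_id},
#'   \code{start} (1-based offset on the consensus), \code{seq} (aligned
#'   string) and \code{qual} (integer vector, one per aligned character).
#' @return an object of class \code{contig_alignment}.
#' @export
contig_alignment <- function(contig_id, consensus, consensus_quality, reads) {
  if (!is.character(consensus) || length(consensus) != 1 ||
      nchar(consensus) < 1)
    stop("consensus must be a single nonempty string", call. = FALSE)
  L <- nchar(consensus)
  if (length(consensus_quality) != L)
    stop("consensus_quality length must equal consensus length",
         call. = FALSE)
  if (grepl("[^ACGTN]", consensus))
    stop("consensus contains characters outside {A,C,G,T,N}", call. = FALSE)
  for (rd in reads) {
    w <- nchar(rd$seq)
    if (rd$start < 1 || rd$start + w - 1 > L)
      stop(sprintf("read '%s' extends outside the consensus (start %d, width %d, contig %d bp)",
                   rd$read_id, rd$start, w, L), call. = FALSE)
    if (length(rd$qual) != w)
      stop(sprintf("read '%s': quality length differs from aligned length",
                   rd$read_id), call. = FALSE)
  }
  structure(list(contig_id = contig_id, consensus = consensus,
                 consensus_quality = as.integer(consensus_quality),
                 reads = reads),
            class = "contig_alignment")
}

#' @export
print.contig_alignment <- function(x, ...) {
  cat(sprintf("<contig_alignment> %s: %d bp, %d reads\n",
              x$contig_id, nchar(x$consensus), length(x$reads)))
  invisible(x)
}

# Expand an alignment into a depth x length character matrix of read bases
# (NA where a read does not cover a column) and a matching integer quality
# matrix. Used by the caller; cheap at transcriptome-contig scale.
alignment_matrices <- function(aln) {
  L <- nchar(aln$consensus)
  D <- length(aln$reads)
  M <- matrix(NA_character_, nrow = D, ncol = L)
  Q <- matrix(NA_integer_, nrow = D, ncol = L)
  for (j in seq_len(D)) {
    rd <- aln$reads[[j]]
    idx <- rd$start:(rd$start + nchar(rd$seq) - 1L)
    M[j, idx] <- strsplit(rd$seq, "")[[1]]
    Q[j, idx] <- rd$qual
  }
  list(bases = M, quals = Q)
}
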