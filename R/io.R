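#' Write contig alignments to FASTA + quality + SAM
#'
#' Writes the consensus sequences as FASTA (one reference per contig), the
#' consensus qualities as a FASTA-quality file (same ids, space-separated
#' integer scores), and the reads as SAM with per-base qualities in QUAL
#' (Phred+33). Read gaps relative to the consensus become CIGAR \code{D}
#' operations.
#'
#' @param alignments list of [contig_alignment()] objects.
#' @param fasta,qual,sam output paths (\code{NULL} skips that file).
#' @return invisibly, the paths written.
#' @export
write_alignments <- function(alignments, fasta = NULL, qual = NULL,
                             sam = NULL) {
  if (!is.null(fasta)) {
    seqs <- Biostrings::DNAStringSet(
      vapply(alignments, function(a) a$consensus, ""))
    names(seqs) <- vapply(alignments, function(a) a$contig_id, "")
    Biostrings::writeXStringSet(seqs, fasta)
  }
  if (!is.null(qual)) {
    con <- file(qual, "w"); on.exit(close(con), add = TRUE)
    for (a in alignments) {
      writeLines(paste0(">", a$contig_id), con)
      writeLines(paste(a$consensus_quality, collapse = " "), con)
    }
  }
  if (!is.null(sam)) {
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             vapply(alignments, function(a)
               sprintf("@SQ\tSN:%s\tLN:%d", a$contig_id,
                       nchar(a$consensus)), ""))
    recs <- unlist(lapply(alignments, function(a) {
      vapply(a$reads, function(rd) {
        chars <- strsplit(rd$seq, "")[[1]]
        isgap <- chars == "-"
        cigar <- paste0(rle(ifelse(isgap, "D", "M"))$lengths,
                        rle(ifelse(isgap, "D", "M"))$values,
                        collapse = "")
        paste(rd$read_id, 0L, a$contig_id, rd$start, 60L, cigar, "*", 0L,
              0L, paste(chars[!isgap], collapse = ""),
              intToUtf8(pmin(rd$qual[!isgap], 93L) + 33L),
              sep = "\t")
      }, "")
    }))
    writeLines(c(hdr, recs), sam)
  }
  invisible(c(fasta = fasta, qual = qual, sam = sam))
}

parse_cigar <- function(cigar) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[A-Z=]$", "", ops)),
       op = sub("^[0-9]+", "", ops))
}

#' Read contig alignments from SAM + FASTA (+ optional quality file)
#'
#' Rebuilds [contig_alignment()] objects from files produced by
#' [write_alignments()] or any aligner emitting reads against per-contig
#' references. The SAM is converted via [Rsamtools::asBam()] and parsed
#' with [Rsamtools::scanBam()]. CIGAR \code{M/=/X} bases are placed on the
#' consensus, \code{D/N} become gap characters, inserted (\code{I/S})
#' bases are dropped (insertions relative to the consensus are not scored).
#' Without a quality file, consensus qualities default to 40.
#'
#' @param sam SAM file of reads.
#' @param fasta consensus FASTA.
#' @param qual optional FASTA-quality file of consensus scores.
#' @return named list of [contig_alignment()] objects.
#' @export
read_alignments <- function(sam, fasta, qual = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  quals <- if (!is.null(qual)) read_fasta_qual(qual) else NULL

  tmp <- tempfile()
  bam <- Rsamtools::asBam(sam, tmp, overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, tmp)), add = TRUE)
  b <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "cigar", "seq", "qual")))[[1]]

  out <- list()
  for (cid in names(seqs)) {
    cons <- as.character(seqs[[cid]])
    cq <- if (!is.null(quals)) quals[[cid]] else rep(40L, nchar(cons))
    idx <- which(as.character(b$rname) == cid & !is.na(b$pos))
    reads <- lapply(idx, function(i) {
      cg <- parse_cigar(b$cigar[i])
      rseq <- strsplit(as.character(b$seq[i]), "")[[1]]
      rq <- as.integer(charToRaw(as.character(b$qual[i]))) - 33L
      aligned <- character(0); aq <- integer(0); rpos <- 1L
      for (k in seq_along(cg$op)) {
        n <- cg$len[k]
        if (cg$op[k] %in% c("M", "=", "X")) {
          aligned <- c(aligned, rseq[rpos:(rpos + n - 1L)])
          aq <- c(aq, rq[rpos:(rpos + n - 1L)])
          rpos <- rpos + n
        } else if (cg$op[k] %in% c("D", "N")) {
          aligned <- c(aligned, rep("-", n))
          aq <- c(aq, rep(0L, n))
        } else if (cg$op[k] %in% c("I", "S")) {
          rpos <- rpos + n
        }
      }
      list(read_id = b$qname[i], start = b$pos[i],
           seq = paste(aligned, collapse = ""), qual = aq)
    })
    out[[cid]] <- contig_alignment(cid, cons, cq, reads)
  }
  out
}

read_fasta_qual <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  ends <- c(hdr[-1] - 1L, length(lines))
  out <- lapply(seq_along(hdr), function(i) {
    as.integer(strsplit(trimws(paste(lines[(hdr[i] + 1L):ends[i]],
                                     collapse = " ")), "\\s+")[[1]])
  })
  stats::setNames(out, ids)
}

#' Write / read the per-column pileup dialect
#'
#' A plain TSV with columns \code{contig_id pos consensus_base
#' consensus_qual read_bases read_quals}: \code{read_bases} holds one
#' character per read (in a fixed read order, \code{-} for a deleted
#' base), \code{read_quals} the matching comma-separated integer scores.
#' This dialect assumes full-length reads (every read covers every
#' column), which is how contig depth is defined for assembled contigs.
#'
#' @param alignments list of [contig_alignment()] objects (full-span
#'   reads).
#' @param path file path.
#' @return \code{write_pileup}: invisibly, \code{path};
#'   \code{read_pileup}: named list of [contig_alignment()] objects.
#' @export
write_pileup <- function(alignments, path) {
  con <- file(path, "w"); on.exit(close(con), add = TRUE)
  writeLines(paste("contig_id", "pos", "consensus_base", "consensus_qual",
                   "read_bases", "read_quals", sep = "\t"), con)
  for (a in alignments) {
    L <- nchar(a$consensus)
    for (rd in a$reads)
      if (rd$start != 1L || nchar(rd$seq) != L)
        stop("pileup output requires full-span reads", call. = FALSE)
    mats <- alignment_matrices(a)
    cons <- strsplit(a$consensus, "")[[1]]
    lines <- vapply(seq_len(L), function(p) {
      paste(a$contig_id, p, cons[p], a$consensus_quality[p],
            paste(mats$bases[, p], collapse = ""),
            paste(mats$quals[, p], collapse = ","), sep = "\t")
    }, "")
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_pileup
#' @export
read_pileup <- function(path) {
  df <- utils::read.delim(path, colClasses = c(
    contig_id = "character", pos = "integer", consensus_base = "character",
    consensus_qual = "integer", read_bases = "character",
    read_quals = "character"))
  out <- list()
  for (cid in unique(df$contig_id)) {
    d <- df[df$contig_id == cid, , drop = FALSE]
    d <- d[order(d$pos), , drop = FALSE]
    if (!identical(d$pos, seq_len(nrow(d))))
      stop(sprintf("pileup for '%s' does not cover positions 1..L", cid),
           call. = FALSE)
    B <- do.call(rbind, strsplit(d$read_bases, ""))       # L x D
    Qc <- lapply(strsplit(d$read_quals, ","), as.integer)
    D <- ncol(B)
    if (any(lengths(Qc) != D))
      stop(sprintf("pileup for '%s': read_quals width mismatch", cid),
           call. = FALSE)
    Q <- do.call(rbind, Qc)
    reads <- lapply(seq_len(D), function(j)
      list(read_id = sprintf("%s_r%04d", cid, j), start = 1L,
           seq = paste(B[, j], collapse = ""), qual = Q[, j]))
    out[[cid]] <- contig_alignment(cid, paste(d$consensus_base,
                                              collapse = ""),
                                   d$consensus_qual, reads)
  }
  out
}

#' Write SNP calls as minimal VCF 4.2 (plus a TSV mirror)
#'
#' One record per call: \code{CHROM} = contig id, \code{POS} 1-based,
#' \code{REF} = major allele, \code{ALT} = minor allele; \code{INFO}
#' carries the major/minor read counts (\code{MAJC}, \code{MINC}), minor
#' allele frequency (\code{MAF}) and substitution class (\code{TITV}).
#'
#' @param calls data frame from [call_snps_all()].
#' @param path output VCF path.
#' @param contig_lengths optional named vector for \code{##contig} header
#'   lines.
#' @return invisibly, \code{path}.
#' @export
write_vcf <- function(calls, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=snpdepth",
           '##INFO=<ID=MAJC,Number=1,Type=Integer,Description="Major allele read count">',
           '##INFO=<ID=MINC,Number=1,Type=Integer,Description="Minor allele read count">',
           '##INFO=<ID=MAF,Number=1,Type=Float,Description="Minor allele frequency">',
           '##INFO=<ID=TITV,Number=1,Type=String,Description="Substitution class (Ti or Tv)">')
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), contig_lengths))
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", sep = "\t"))
  recs <- if (!is.null(calls) && nrow(calls)) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tMAJC=%d;MINC=%d;MAF=%.4f;TITV=%s",
            calls$contig_id, calls$position, calls$major_allele,
            calls$minor_allele, calls$major_count, calls$minor_count,
            calls$maf, calls$substitution_class)
  } else character(0)
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read / write contig tables and labels as TSV
#'
#' Plain tab-separated files with a header row; the contig table uses the
#' columns \code{contig_id length depth cnc n_snp n_ti n_tv}, the label
#' table \code{contig_id class} (optional \code{score} column tolerated).
#'
#' @param records,path contig table and file path.
#' @return \code{read_contig_table} / \code{read_labels}: a data frame.
#' @export
write_contig_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_contig_table
#' @export
read_contig_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname write_contig_table
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("contig_id", "class") %in% names(df)))
    stop("labels TSV needs columns contig_id and class", call. = FALSE)
  df
}
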