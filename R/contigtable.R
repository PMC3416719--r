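#' Build the per-contig regression table
#'
#' Joins SNP calls with contig metadata and coding/non-coding labels into
#' one row per eligible contig: length (bp), depth (number of aligned
#' reads), coding class (\code{cnc}: 1 = protein-coding, 0 = non-coding)
#' and the SNP, transition and transversion counts aggregated from the
#' calls. Contigs with no calls get zero counts; contigs failing the
#' eligibility gate (length, depth) never enter the table.
#'
#' @param calls data frame of SNP calls as returned by [call_snps_all()].
#' @param metadata data frame with columns \code{contig_id, length, depth}
#'   for every contig (see [alignment_metadata()]).
#' @param labels data frame with columns \code{contig_id, class}, class in
#'   \code{coding}/\code{noncoding} (or already-numeric \code{cnc}).
#' @param cfg a [filter_config()] supplying the eligibility gate.
#' @return data frame with columns \code{contig_id, length, depth, cnc,
#'   n_snp, n_ti, n_tv}.
#' @export
build_table <- function(calls, metadata, labels, cfg = filter_config()) {
  stopifnot(all(c("contig_id", "length", "depth") %in% names(metadata)))
  keep <- metadata$length >= cfg$min_contig_length &
    metadata$depth >= cfg$min_depth
  meta <- metadata[keep, , drop = FALSE]
  missing <- setdiff(meta$contig_id, labels$contig_id)
  if (length(missing))
    stop(sprintf("no coding/non-coding label for contig(s): %s",
                 paste(utils::head(missing, 10), collapse = ", ")),
         call. = FALSE)
  cnc <- if ("cnc" %in% names(labels)) {
    stats::setNames(as.integer(labels$cnc), labels$contig_id)
  } else {
    stats::setNames(as.integer(labels$class == "coding"), labels$contig_id)
  }
  n_snp <- n_ti <- stats::setNames(integer(nrow(meta)), meta$contig_id)
  if (!is.null(calls) && nrow(calls)) {
    calls <- calls[calls$contig_id %in% meta$contig_id, , drop = FALSE]
    tot <- table(factor(calls$contig_id, levels = meta$contig_id))
    ti <- table(factor(calls$contig_id[calls$substitution_class == "Ti"],
                       levels = meta$contig_id))
    n_snp[] <- as.integer(tot)
    n_ti[] <- as.integer(ti)
  }
  data.frame(contig_id = meta$contig_id,
             length = as.integer(meta$length),
             depth = as.integer(meta$depth),
             cnc = unname(cnc[meta$contig_id]),
             n_snp = unname(n_snp), n_ti = unname(n_ti),
             n_tv = unname(n_snp - n_ti))
}

#' Extract contig metadata from a set of alignments
#'
#' @param alignments list of [contig_alignment()] objects.
#' @return data frame \code{contig_id, length, depth}.
#' @export
alignment_metadata <- function(alignments) {
  data.frame(
    contig_id = vapply(alignments, function(a) a$contig_id, ""),
    length = vapply(alignments, function(a) nchar(a$consensus), 0L),
    depth = vapply(alignments, function(a) length(a$reads), 0L),
    row.names = NULL)
}

#' Restrict a contig table to long contigs
#'
#' @param records contig table from [build_table()].
#' @param min_length minimum length in bp (default 501, the conventional
#'   long-contig cut).
#' @return the subset of records with \code{length >= min_length}.
#' @export
subset_long <- function(records, min_length = 501) {
  records[records$length >= min_length, , drop = FALSE]
}

#' Summary statistics of a contig table
#'
#' Computes, overall and within each coding class, the number of contigs,
#' mean length, mean depth and the total SNP, transition and transversion
#' counts.
#'
#' @param records contig table from [build_table()].
#' @return data frame with rows \code{total}, \code{coding},
#'   \code{noncoding} and columns \code{n_contigs, mean_length, mean_depth,
#'   total_snp, total_ti, total_tv}.
#' @export
summarize_contigs <- function(records) {
  if (is.null(records) || nrow(records) == 0)
    stop("cannot summarize an empty contig table", call. = FALSE)
  one <- function(r) data.frame(
    n_contigs = nrow(r),
    mean_length = if (nrow(r)) mean(r$length) else NA_real_,
    mean_depth = if (nrow(r)) mean(r$depth) else NA_real_,
    total_snp = sum(r$n_snp), total_ti = sum(r$n_ti), total_tv = sum(r$n_tv))
  out <- rbind(one(records),
               one(records[records$cnc == 1, , drop = FALSE]),
               one(records[records$cnc == 0, , drop = FALSE]))
  out$group <- c("total", "coding", "noncoding")
  out[, c("group", "n_contigs", "mean_length", "mean_depth",
          "total_snp", "total_ti", "total_tv")]
}

#' Transition/transversion ratio
#'
#' @param n_ti,n_tv transition and transversion counts.
#' @return \code{n_ti / n_tv}.
#' @export
titv_ratio <- function(n_ti, n_tv) {
  if (n_tv <= 0)
    stop("Ti/Tv ratio undefined: transversion count is zero", call. = FALSE)
  n_ti / n_tv
}

#' Pearson correlation between a contig covariate and a count column
#'
#' Sample Pearson correlation with the usual t-distribution two-sided
#' p-value (via [stats::cor.test()]), computed on raw per-contig values,
#' optionally within one coding class.
#'
#' @param records contig table from [build_table()].
#' @param x covariate column, \code{"length"} or \code{"depth"}.
#' @param y count column, one of \code{"n_snp"}, \code{"n_ti"},
#'   \code{"n_tv"}.
#' @param cnc optional class filter (1 = coding, 0 = non-coding).
#' @return list with elements \code{r}, \code{p}, \code{n}.
#' @export
snp_cor <- function(records, x = c("length", "depth"),
                    y = c("n_snp", "n_ti", "n_tv"), cnc = NULL) {
  x <- match.arg(x); y <- match.arg(y)
  if (!is.null(cnc)) records <- records[records$cnc == cnc, , drop = FALSE]
  if (nrow(records) < 3)
    stop("need at least 3 records for a correlation", call. = FALSE)
  xv <- records[[x]]; yv <- records[[y]]
  if (stats::var(xv) == 0 || stats::var(yv) == 0)
    stop("degenerate (zero-variance) column in correlation", call. = FALSE)
  ct <- stats::cor.test(xv, yv, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(records))
}
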