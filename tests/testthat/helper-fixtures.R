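# Hand-built alignment fixtures.

# Build a contig_alignment from read strings (full-span unless `starts`
# given). Scalar qualities are recycled per base; a matrix of qualities
# (reads x bases) overrides per read.
make_aln <- function(consensus, reads, read_qual = 30, cons_qual = 40,
                     starts = NULL, contig_id = "ctg1") {
  L <- nchar(consensus)
  if (is.null(starts)) starts <- rep(1L, length(reads))
  qmat <- if (is.matrix(read_qual)) read_qual else NULL
  rl <- lapply(seq_along(reads), function(j) {
    w <- nchar(reads[j])
    q <- if (!is.null(qmat)) qmat[j, seq_len(w)]
         else rep_len(read_qual, w)
    list(read_id = sprintf("r%03d", j), start = starts[j],
         seq = reads[j], qual = as.integer(q))
  })
  contig_alignment(contig_id, consensus,
                   rep_len(as.integer(cons_qual), L), rl)
}

# Random consensus of length L with natural homopolymers allowed.
rand_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L,
                                     replace = TRUE), collapse = "")

# A 1000 bp contig, 30 reads, one planted SNP (minor count 3) mid-contig.
single_snp_fixture <- function(pos = 500, minor_count = 3, depth = 30,
                               L = 1000, qual = 30) {
  set.seed(4242)
  cons <- rand_seq(L)
  # keep the neighbourhood homopolymer-free so only the planted site matters
  while (any(rle(strsplit(cons, "")[[1]])$lengths > 4)) cons <- rand_seq(L)
  major <- substr(cons, pos, pos)
  minor <- setdiff(c("A", "C", "G", "T"), major)[1]
  reads <- rep(cons, depth)
  for (j in seq_len(minor_count))
    substr(reads[j], pos, pos) <- minor
  list(aln = make_aln(cons, reads, read_qual = qual),
       pos = pos, major = major, minor = minor)
}
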