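# Independent oracles, written as literal transcriptions of the scoring
# rules with no code shared with the package implementation.

# Brute-force SNP scorer: plain loops over columns and reads.
oracle_call_snps <- function(aln, min_len = 100, min_depth = 10,
                             min_maf = 0.01, min_minor = 2, flank = 20,
                             minq = 20, maxhp = 4) {
  out <- data.frame(contig_id = character(0), position = integer(0),
                    major_allele = character(0), minor_allele = character(0),
                    major_count = integer(0), minor_count = integer(0),
                    maf = numeric(0), substitution_class = character(0))
  cons <- strsplit(aln$consensus, "")[[1]]
  L <- length(cons)
  if (L < min_len) return(out)
  if (length(aln$reads) < min_depth) return(out)
  for (p in seq_len(L)) {
    if (cons[p] == "N") next
    # tally this column read by read
    counts <- c(A = 0, C = 0, G = 0, T = 0)
    gaps <- 0
    for (rd in aln$reads) {
      off <- p - rd$start + 1
      if (off < 1 || off > nchar(rd$seq)) next
      b <- substr(rd$seq, off, off)
      if (b == "-") gaps <- gaps + 1
      else if (b %in% c("A", "C", "G", "T") && rd$qual[off] > minq)
        counts[b] <- counts[b] + 1
    }
    if (gaps > 0) next
    present <- names(counts)[counts > 0]
    if (length(present) != 2) next
    c1 <- counts[present[1]]; c2 <- counts[present[2]]
    if (c1 < c2) { minor <- present[1]; major <- present[2] }
    else if (c2 < c1) { minor <- present[2]; major <- present[1] }
    else { # tie: the lexicographically later base is the minor allele
      minor <- max(present); major <- min(present)
    }
    mn <- counts[minor]; mj <- counts[major]
    maf <- mn / (mn + mj)
    if (!(maf >= min_maf || mn >= min_minor)) next
    # 20 bp of high-quality consensus on both sides
    if (p - flank < 1 || p + flank > L) next
    ok <- TRUE
    for (q in c((p - flank):(p - 1), (p + 1):(p + flank))) {
      if (aln$consensus_quality[q] <= minq || cons[q] == "N") ok <- FALSE
    }
    if (!ok) next
    # homopolymer runs > maxhp: excluded inside and immediately adjacent
    inrun <- FALSE
    i <- 1
    while (i <= L) {
      j <- i
      while (j < L && cons[j + 1] == cons[i]) j <- j + 1
      if (j - i + 1 > maxhp && p >= i - 1 && p <= j + 1) inrun <- TRUE
      i <- j + 1
    }
    if (inrun) next
    ti <- (major == "A" && minor == "G") || (major == "G" && minor == "A") ||
      (major == "C" && minor == "T") || (major == "T" && minor == "C")
    out <- rbind(out, data.frame(
      contig_id = aln$contig_id, position = p, major_allele = major,
      minor_allele = minor, major_count = as.integer(mj),
      minor_count = as.integer(mn), maf = as.numeric(maf),
      substitution_class = if (ti) "Ti" else "Tv"))
  }
  rownames(out) <- NULL
  out
}

# Textbook Pearson correlation.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Direct NB2 log-likelihood at given coefficients/dispersion.
oracle_nb2_loglik <- function(records, response_col, beta, covariates,
                              alpha) {
  X <- cbind(1, as.matrix(records[, covariates, drop = FALSE]))
  mu <- exp(drop(X %*% beta))
  y <- records[[response_col]]
  size <- 1 / alpha
  sum(lgamma(y + size) - lgamma(size) - lgamma(y + 1) +
        size * log(size / (size + mu)) + y * log(mu / (size + mu)))
}

# Random small adversarial alignment for caller-vs-oracle equivalence:
# short contigs, partial-span reads, gaps, mixed qualities, occasional
# consensus Ns and natural homopolymer runs.
rand_alignment <- function(id) {
  L <- sample(42:50, 1)
  D <- sample(10:16, 1)
  cons_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  # encourage homopolymers and an occasional N
  if (runif(1) < 0.5) {
    s <- sample(3:(L - 7), 1)
    cons_chars[s:(s + sample(3:6, 1))] <- cons_chars[s]
  }
  if (runif(1) < 0.2) cons_chars[sample(L, 1)] <- "N"
  cq <- sample(15:40, L, replace = TRUE)
  reads <- lapply(seq_len(D), function(j) {
    full <- runif(1) < 0.7
    st <- if (full) 1L else sample.int(L - 20L, 1)
    en <- if (full) L else min(L, st + sample(20:40, 1))
    seg <- cons_chars[st:en]
    qual <- sample(10:40, length(seg), replace = TRUE)
    nmut <- rpois(1, 1.2)
    if (nmut > 0) {
      at <- sample(length(seg), min(nmut, length(seg)))
      seg[at] <- sample(c("A", "C", "G", "T", "-"), length(at),
                        replace = TRUE, prob = c(.22, .22, .22, .22, .12))
    }
    list(read_id = sprintf("%s_r%02d", id, j), start = st,
         seq = paste(seg, collapse = ""), qual = as.integer(qual))
  })
  contig_alignment(id, paste(cons_chars, collapse = ""), cq, reads)
}
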