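# Independent oracles for property tests. These deliberately avoid the
# package's code paths: plain string/arithmetic re-derivations.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

ORACLE_STOPS <- c("TAA", "TAG", "TGA")

# 0-based nt offset of the first stop codon read in frame from `from`
oracle_first_stop <- function(nt, from = 0L) {
  n <- nchar(nt)
  pos <- seq(from + 1L, n - 2L, by = 3L)
  if (from + 3L > n) return(NA_integer_)
  for (p in pos) {
    if (substr(nt, p, p + 2L) %in% ORACLE_STOPS) return(p - 1L)
  }
  NA_integer_
}

# introns as gaps between sorted exon intervals (genomic order)
oracle_intron_gaps <- function(exons) {
  m <- exons[order(exons[, 1L]), , drop = FALSE]
  if (nrow(m) < 2L) return(matrix(integer(0), ncol = 2L))
  cbind(m[-nrow(m), 2L], m[-1L, 1L])
}

# BH step-up, re-derived from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  running <- 1
  for (k in n:1) {
    running <- min(running, p[o[k]] * n / k)
    q[o[k]] <- running
  }
  q
}

# G statistic of a 2x2 table, written out longhand
oracle_g_p <- function(tab) {
  tot <- sum(tab)
  g <- 0
  for (i in 1:2) for (j in 1:2) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / tot
    if (tab[i, j] > 0) g <- g + 2 * tab[i, j] * log(tab[i, j] / e)
  }
  stats::pchisq(g, df = 1, lower.tail = FALSE)
}
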