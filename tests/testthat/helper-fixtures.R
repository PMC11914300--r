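# In-code fixtures: random transcripts with retained-intron ground truth
# computed by a brute-force oracle (full retained-transcript translation).

SENSE_CODONS <- setdiff(
  as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0),
                  c("A", "C", "G", "T"), paste0)),
  c("TAA", "TAG", "TGA"))

rand_codons <- function(n) {
  paste(sample(SENSE_CODONS, n, replace = TRUE), collapse = "")
}
rand_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# one random single-transcript gene; introns at arbitrary mRNA positions
# (5' UTR, CDS at any codon phase, or 3' UTR), random strand
random_retention_fixture <- function(id = "FX", coding = TRUE) {
  u5 <- rand_nt(sample(6:20, 1L))
  cds <- paste0("ATG", rand_codons(sample(20:60, 1L)), "TAA")
  u3 <- rand_nt(sample(10:30, 1L))
  mrna <- paste0(u5, cds, u3)
  mlen <- nchar(mrna)
  n_int <- sample(1:4, 1L)
  cuts <- sort(sample(2:(mlen - 2L), n_int))
  introns <- vapply(seq_len(n_int), function(k) {
    if (stats::runif(1) < 0.4) {
      # pyrimidine-body intron, frame-preserving: no stop in any frame
      len <- sample(2:20, 1L) * 3L
      paste0("GT", paste(sample(c("C", "T"), len - 5L, replace = TRUE),
                         collapse = ""), "CAG")
    } else {
      rand_nt(sample(6:60, 1L))
    }
  }, character(1))
  strand <- sample(c("+", "-"), 1L)

  pieces <- character(0)
  prev <- 0L
  for (k in seq_len(n_int)) {
    pieces <- c(pieces, substr(mrna, prev + 1L, cuts[[k]]), introns[[k]])
    prev <- cuts[[k]]
  }
  pieces <- c(pieces, substr(mrna, prev + 1L, mlen))
  full <- paste(pieces, collapse = "")
  glen <- nchar(full)

  # transcript-oriented exon intervals, then genomic flip on minus strand
  plen <- nchar(pieces)
  pend <- cumsum(plen)
  pstart <- pend - plen
  exon_ids <- seq(1L, length(pieces), by = 2L)
  ex <- cbind(pstart[exon_ids], pend[exon_ids])
  cds_span <- c(nchar(u5), nchar(u5) + nchar(cds))   # mRNA coords
  # map mRNA coords to transcript-oriented genomic coords per exon
  mrna_off <- cumsum(c(0L, plen[exon_ids]))[seq_along(exon_ids)]
  cds_iv <- NULL
  for (j in seq_along(exon_ids)) {
    lo <- max(cds_span[[1L]], mrna_off[[j]])
    hi <- min(cds_span[[2L]], mrna_off[[j]] + plen[exon_ids[[j]]])
    if (hi > lo) {
      cds_iv <- rbind(cds_iv, c(ex[j, 1L] + lo - mrna_off[[j]],
                                ex[j, 1L] + hi - mrna_off[[j]]))
    }
  }
  if (!coding) cds_iv <- matrix(integer(0), ncol = 2L)
  if (strand == "+") {
    contig <- full
  } else {
    contig <- oracle_revcomp(full)
    flip <- function(m) if (nrow(m) == 0L) m else
      cbind(glen - m[, 2L], glen - m[, 1L])
    ex <- flip(ex); cds_iv <- flip(cds_iv)
  }
  genome <- iesplice::as_genome(stats::setNames(contig, paste0("ctg_", id)))
  t <- iesplice:::new_transcript_model(
    paste0("TX_", id), paste0("G_", id),
    if (coding) "protein_coding" else "lncRNA",
    paste0("ctg_", id), strand,
    iesplice:::orient_intervals(ex, strand),
    iesplice:::orient_intervals(cds_iv, strand))
  list(t = t, genome = genome, u5 = u5, cds = cds, u3 = u3,
       cuts = cuts, introns = introns, coding = coding)
}

# brute-force consequence of retaining intron k: translate the retained
# transcript end to end and locate the first stop, independent of the
# package's insertion-point bookkeeping
oracle_consequence <- function(fx, k) {
  if (!fx$coding) return(list(category = "NONCODING_GENE"))
  L <- nchar(fx$cds)
  u5n <- nchar(fx$u5)
  mlen <- u5n + L + nchar(fx$u3)
  cuts_all <- c(0L, fx$cuts, mlen)
  up_ex <- c(cuts_all[[k]], cuts_all[[k + 1L]])        # mRNA coords
  down_ex <- c(cuts_all[[k + 1L]], cuts_all[[k + 2L]])
  cds_span <- c(u5n, u5n + L)
  overlaps <- function(iv) iv[1L] < cds_span[2L] && cds_span[1L] < iv[2L]
  if (!overlaps(up_ex) || !overlaps(down_ex)) {
    return(list(category = "NONCODING_REGION"))
  }
  within <- vapply(seq_along(fx$introns), function(j) {
    u <- c(cuts_all[[j]], cuts_all[[j + 1L]])
    d <- c(cuts_all[[j + 1L]], cuts_all[[j + 2L]])
    overlaps(u) && overlaps(d)
  }, logical(1))
  is_last <- k == max(which(within))
  ilen <- nchar(fx$introns[[k]])
  d <- fx$cuts[[k]] - u5n                              # CDS nt upstream
  retained <- paste0(substr(fx$cds, 1L, d), fx$introns[[k]],
                     substr(fx$cds, d + 1L, L), fx$u3)
  o <- oracle_first_stop(retained)
  annotated <- L - 3L + ilen
  # the annotated stop only survives if the intron did not split it
  if (d > L - 3L) annotated <- NA_integer_
  if (!is.na(o) && !is.na(annotated) && o == annotated) {
    return(list(category = "CODING_INFRAME", extra_aa = ilen %/% 3L))
  }
  if (is.na(o)) return(list(category = "PTC", no_stop_found = TRUE))
  list(category = if (is_last) "LAST_INTRON_PTC" else "PTC",
       ptc_offset = o %/% 3L - d %/% 3L)
}

# junction counts for a hand-specified PSI trajectory table
make_truth <- function(n, psi0, psi30, psi150) {
  data.frame(event_id = sprintf("E%05d", seq_len(n)),
             psi_t0 = psi0, psi_t30 = psi30, psi_t150 = psi150,
             stringsAsFactors = FALSE)
}
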