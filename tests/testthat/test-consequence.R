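# deterministic hand-built transcript: 2 exons + 1 intron, plus strand
two_exon_fixture <- function(intron_seq, cds1_codons = 10L,
                             cds2_codons = 10L, biotype = "protein_coding") {
  u5 <- "GGGGG"
  cds1 <- paste0("ATG", rand_codons(cds1_codons))
  cds2 <- paste0(rand_codons(cds2_codons), "TAA")
  u3 <- "TAACTAACTAACCTT"
  contig <- paste0(u5, cds1, intron_seq, cds2, u3)
  e1 <- c(0L, nchar(u5) + nchar(cds1))
  e2s <- e1[[2L]] + nchar(intron_seq)
  t <- iesplice:::new_transcript_model(
    "T", "G", biotype, "c", "+",
    rbind(e1, c(e2s, nchar(contig))),
    rbind(c(nchar(u5), e1[[2L]]), c(e2s, e2s + nchar(cds2))))
  list(t = t, genome = as_genome(c(c = contig)))
}

test_that("coding-consequence categories follow the frame and stop rules", {
  set.seed(71)
  # 96-nt stop-free, frame-preserving: 32 extra amino acids
  fx <- two_exon_fixture(paste0("GT", strrep("C", 91), "CAG"))
  ir <- extract_introns(fx$t)
  expect_equal(ir$length, 96L)
  cc <- classify_retained_intron(fx$t, ir[1, ], fx$genome)
  expect_equal(cc$category, "CODING_INFRAME")
  expect_equal(cc$extra_aa, 32L)
  expect_true(cc$frame_preserving)

  # length 100: frameshift, stop met downstream, not the last CDS intron
  # (build 3 exons so the frameshifted intron is the first of two)
  u5 <- "GGGGG"
  cds1 <- paste0("ATG", rand_codons(8))
  cds2 <- rand_codons(8)
  cds3 <- paste0(rand_codons(8), "TAA")
  i1 <- paste0("GT", strrep("C", 95), "CAG")  # 100 nt
  i2 <- paste0("GT", strrep("T", 55), "CAG")  # 60 nt
  u3 <- "TAACTAACTAACCT"
  contig <- paste0(u5, cds1, i1, cds2, i2, cds3, u3)
  p <- cumsum(nchar(c(u5, cds1, i1, cds2, i2, cds3, u3)))
  t3 <- iesplice:::new_transcript_model(
    "T", "G", "protein_coding", "c", "+",
    rbind(c(0L, p[2]), c(p[3], p[4]), c(p[5], nchar(contig))),
    rbind(c(nchar(u5), p[2]), c(p[3], p[4]), c(p[5], p[6])))
  g3 <- as_genome(c(c = contig))
  ir3 <- extract_introns(t3)
  cc1 <- classify_retained_intron(t3, ir3[1, ], g3)
  expect_equal(cc1$category, "PTC")
  expect_false(cc1$frame_preserving)
  expect_false(cc1$no_stop_found)

  # frame-preserving intron carrying an aligned TAA in the last CDS intron
  i2_stop <- paste0("GT", strrep("C", 10),
                    "TAA", strrep("C", 45), "CAG")  # 63 nt, phase-0 cut
  # place at codon boundary: cds1+cds2 length is 5+27+24? ensure %%3
  cdsA <- paste0("ATG", rand_codons(10))
  cdsB <- paste0(rand_codons(10), "TAA")
  contig2 <- paste0(u5, cdsA, i2_stop, cdsB, u3)
  e1 <- c(0L, nchar(u5) + nchar(cdsA))
  e2s <- e1[[2L]] + nchar(i2_stop)
  t2 <- iesplice:::new_transcript_model(
    "T", "G", "protein_coding", "c", "+",
    rbind(e1, c(e2s, nchar(contig2))),
    rbind(c(nchar(u5), e1[[2L]]), c(e2s, e2s + nchar(cdsB))))
  g2 <- as_genome(c(c = contig2))
  ir2 <- extract_introns(t2)
  cc2 <- classify_retained_intron(t2, ir2[1, ], g2)
  expect_equal(cc2$category, "LAST_INTRON_PTC")
  expect_true(cc2$frame_preserving)
  # the aligned TAA sits 4 codons into the intron (12 nt of C/GT before it)
  expect_equal(cc2$ptc_offset, 4L)
})

test_that("noncoding genes and non-ORF introns short-circuit the classifier", {
  set.seed(73)
  fx <- two_exon_fixture(paste0("GT", strrep("C", 55), "CAG"),
                         biotype = "lncRNA")
  ir <- extract_introns(fx$t)
  expect_equal(classify_retained_intron(fx$t, ir[1, ], fx$genome)$category,
               "NONCODING_GENE")

  # intron between exons that are entirely UTR on one side
  fx2 <- random_retention_fixture("utr")
  # force: pick fixtures until one has a NONCODING_REGION intron
  found <- FALSE
  for (i in 1:200) {
    fy <- random_retention_fixture(paste0("u", i))
    irs <- extract_introns(fy$t)
    ncr <- which(!irs$within_cds)
    if (length(ncr) > 0L) {
      cc <- classify_retained_intron(fy$t, irs[ncr[[1L]], ], fy$genome)
      expect_equal(cc$category, "NONCODING_REGION")
      found <- TRUE
      break
    }
  }
  expect_true(found)

  # unknown intron coordinates are an error
  bad <- extract_introns(fx$t)[1, ]
  bad$start <- bad$start + 1L
  expect_error(classify_retained_intron(fx$t, bad, fx$genome), "not found")
})

test_that("classifier agrees with the brute-force translation oracle", {
  set.seed(79)
  checked <- 0L
  for (i in 1:250) {
    fx <- random_retention_fixture(paste0("r", i),
                                   coding = stats::runif(1) < 0.9)
    irs <- extract_introns(fx$t)
    for (k in seq_len(nrow(irs))) {
      got <- classify_retained_intron(fx$t, irs[k, ], fx$genome)
      want <- oracle_consequence(fx, k)
      expect_equal(got$category, want$category,
                   info = sprintf("fixture %d intron %d", i, k))
      if (want$category == "CODING_INFRAME") {
        expect_equal(got$extra_aa, want$extra_aa)
        expect_equal(got$extra_aa * 3L, irs$length[[k]])
      }
      if (!is.null(want$ptc_offset)) {
        expect_equal(got$ptc_offset, want$ptc_offset)
      }
      if (isTRUE(want$no_stop_found)) expect_true(got$no_stop_found)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 250L)
})

test_that("splice-site windows cover -3..+6 and -20..+3 across the junctions", {
  set.seed(83)
  contig <- rand_nt(400)
  g <- as_genome(c(c = contig))
  intr <- list(contig = "c", start = 100L, end = 200L, strand = "+",
               length = 100L)
  w <- extract_splice_site_windows(intr, g)
  expect_equal(w$donor_seq, substr(contig, 98, 106))    # [97,106) 0-based
  expect_equal(w$acceptor_seq, substr(contig, 181, 203))  # [180,203)
  expect_equal(nchar(w$donor_seq), 9L)
  expect_equal(nchar(w$acceptor_seq), 23L)
  expect_false(w$overlapping)

  # minus strand is the reverse complement of the mirrored plus windows
  intr_m <- within(as.data.frame(intr), strand <- "-")
  wm <- extract_splice_site_windows(intr_m, g)
  expect_equal(wm$donor_seq, oracle_revcomp(substr(contig, 195, 203)))
  expect_equal(wm$acceptor_seq, oracle_revcomp(substr(contig, 98, 120)))

  short <- list(contig = "c", start = 100L, end = 120L, strand = "+",
                length = 20L)
  expect_true(extract_splice_site_windows(short, g)$overlapping)
  edge <- list(contig = "c", start = 1L, end = 30L, strand = "+",
               length = 29L)
  expect_error(extract_splice_site_windows(edge, g), "bounds")
})

test_that("donor and acceptor windows flank the intron's terminal dinucleotides", {
  set.seed(89)
  for (i in 1:300) {
    contig <- rand_nt(300)
    g <- as_genome(c(c = contig))
    s <- sample(30:120, 1L); e <- s + sample(40:120, 1L)
    strand <- sample(c("+", "-"), 1L)
    intr <- list(contig = "c", start = s, end = e, strand = strand,
                 length = e - s)
    w <- extract_splice_site_windows(intr, g)
    iseq <- if (strand == "+") substr(contig, s + 1L, e) else
      oracle_revcomp(substr(contig, s + 1L, e))
    expect_equal(substr(w$donor_seq, 4L, 5L), substr(iseq, 1L, 2L))
    expect_equal(substr(w$acceptor_seq, 19L, 20L),
                 substr(iseq, nchar(iseq) - 1L, nchar(iseq)))
  }
})

test_that("PWM scoring is log-odds in bits against a uniform background", {
  uniform <- build_pwm(c("ACGTACGTA", "TGCATGCAT", "CATGCATGC",
                         "GTACGTACG"), pseudocount = 0)
  # a model trained on all four bases equally is uniform: score 0
  expect_equal(score_pwm("AAAAAAAAA", uniform), 0)

  one_hot <- build_pwm("GTAAGTATC", pseudocount = 0)
  expect_equal(score_pwm("GTAAGTATC", one_hot), 18)   # 9 * log2(4)
  expect_true(is.na(score_pwm("GTAAGTATA", one_hot))) # zero frequency
  expect_true(is.na(score_pwm("GTAAGTATN", one_hot))) # N: undefined
  expect_error(score_pwm("GTAAG", one_hot), "length")

  pwm <- build_pwm(c("GTAAGT", "GTGAGT", "GTAAGA"))
  expect_true(all(abs(rowSums(unclass(pwm)) - 1) < 1e-12))
})

test_that("window FASTA export pairs donor and acceptor per event", {
  set.seed(97)
  fx <- two_exon_fixture(paste0("GT", strrep("C", 55), "CAG"))
  tab <- splice_site_table(extract_introns(fx$t), fx$genome)
  tf <- withr::local_tempfile(fileext = ".fa")
  write_windows_fasta(tab, tf)
  lines <- readLines(tf)
  expect_equal(lines[[1L]], sprintf(">%s|donor", tab$event_id[[1L]]))
  expect_equal(nchar(lines[[2L]]), 9L)
  expect_equal(lines[[3L]], sprintf(">%s|acceptor", tab$event_id[[1L]]))
  expect_equal(nchar(lines[[4L]]), 23L)
})
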