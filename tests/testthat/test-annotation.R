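mini_genome <- function() {
  as_genome(c(chrA = paste(rep("ACGT", 200), collapse = ""),
              chrB = "AACGT"))
}

gtf_lines <- function(rows) {
  vapply(rows, function(r) {
    sprintf('%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
            r$c, r$type, r$s, r$e, r$strand, r$g, r$t, r$b)
  }, character(1))
}

test_that("GTF coordinates convert to 0-based half-open and structure is kept", {
  lines <- gtf_lines(list(
    list(c = "chrA", type = "exon", s = 100, e = 199, strand = "+",
         g = "G1", t = "T1", b = "protein_coding"),
    list(c = "chrA", type = "exon", s = 300, e = 399, strand = "+",
         g = "G1", t = "T1", b = "protein_coding"),
    list(c = "chrA", type = "CDS", s = 110, e = 199, strand = "+",
         g = "G1", t = "T1", b = "protein_coding"),
    list(c = "chrA", type = "CDS", s = 300, e = 320, strand = "+",
         g = "G1", t = "T1", b = "protein_coding")))
  tx <- parse_annotation(lines, mini_genome())
  expect_length(tx, 1L)
  t <- tx$T1
  expect_equal(t$exons, rbind(c(99L, 199L), c(299L, 399L)))
  expect_equal(t$exons[1, 2] - t$exons[1, 1], 100L)
  expect_equal(nrow(t$cds), 2L)
  expect_equal(t$gene_biotype, "protein_coding")
})

test_that("minus-strand exons are ordered 5'->3' in transcript orientation", {
  lines <- gtf_lines(list(
    list(c = "chrA", type = "exon", s = 100, e = 150, strand = "-",
         g = "G1", t = "T1", b = "lncRNA"),
    list(c = "chrA", type = "exon", s = 300, e = 350, strand = "-",
         g = "G1", t = "T1", b = "lncRNA")))
  t <- parse_annotation(lines, mini_genome())$T1
  expect_equal(t$exons[1, ], c(299L, 350L))  # genomically last exon first
})

test_that("malformed GTF lines are rejected with a line number", {
  bad_fields <- c("chrA\ttest\texon\t1\t50\t.\t+\t.")
  expect_error(parse_annotation(bad_fields, mini_genome()),
               "line 1")
  bad_attr <- gtf_lines(list(
    list(c = "chrA", type = "exon", s = 1, e = 50, strand = "+",
         g = "G1", t = "T1", b = "x")))
  bad_attr <- c(bad_attr, "chrA\ttest\texon\t60\t90\t.\t+\t.\tfoo bar")
  expect_error(parse_annotation(bad_attr, mini_genome()), "line 2")
})

test_that("unknown contigs are skipped with a warning, out-of-bounds exons error", {
  lines <- gtf_lines(list(
    list(c = "chrZ", type = "exon", s = 1, e = 50, strand = "+",
         g = "G1", t = "T1", b = "x"),
    list(c = "chrA", type = "exon", s = 1, e = 50, strand = "+",
         g = "G2", t = "T2", b = "x")))
  expect_warning(tx <- parse_annotation(lines, mini_genome()), "skipped")
  expect_named(tx, "T2")
  oob <- gtf_lines(list(
    list(c = "chrB", type = "exon", s = 1, e = 50, strand = "+",
         g = "G1", t = "T1", b = "x")))
  expect_error(parse_annotation(oob, mini_genome()), "bounds")
})

test_that("GTF round-trip reproduces the parsed models", {
  cfg <- simulation_config(n_genes = 6L, seed = 42L)
  sim <- simulate_genome_annotation(cfg)
  tx1 <- parse_annotation(sim$gtf, sim$genome)
  tx2 <- parse_annotation(write_gtf(tx1), sim$genome)
  expect_equal(tx2, tx1)
})

test_that("intron records are the gaps between exons", {
  g <- mini_genome()
  lines <- gtf_lines(list(
    list(c = "chrA", type = "exon", s = 1, e = 100, strand = "+",
         g = "G1", t = "T1", b = "x"),
    list(c = "chrA", type = "exon", s = 201, e = 300, strand = "+",
         g = "G1", t = "T1", b = "x")))
  ir <- extract_introns(parse_annotation(lines, g)$T1)
  expect_equal(nrow(ir), 1L)
  expect_equal(c(ir$start, ir$end, ir$length), c(100L, 200L, 100L))

  single <- gtf_lines(list(
    list(c = "chrA", type = "exon", s = 1, e = 100, strand = "+",
         g = "G1", t = "T1", b = "x")))
  expect_equal(nrow(extract_introns(parse_annotation(single, g)$T1)), 0L)
})

test_that("CDS flags mark introns inside and outside the ORF", {
  # CDS confined to exons 1-2: intron 1 is in the ORF (and its last
  # intron), intron 2 is not
  lines <- gtf_lines(list(
    list(c = "chrA", type = "exon", s = 1, e = 100, strand = "+",
         g = "G1", t = "T1", b = "protein_coding"),
    list(c = "chrA", type = "exon", s = 201, e = 300, strand = "+",
         g = "G1", t = "T1", b = "protein_coding"),
    list(c = "chrA", type = "exon", s = 401, e = 500, strand = "+",
         g = "G1", t = "T1", b = "protein_coding"),
    list(c = "chrA", type = "CDS", s = 50, e = 100, strand = "+",
         g = "G1", t = "T1", b = "protein_coding"),
    list(c = "chrA", type = "CDS", s = 201, e = 250, strand = "+",
         g = "G1", t = "T1", b = "protein_coding")))
  ir <- extract_introns(parse_annotation(lines, mini_genome())$T1)
  expect_equal(ir$within_cds, c(TRUE, FALSE))
  expect_equal(ir$is_last_cds_intron, c(TRUE, FALSE))
})

test_that("extract_introns matches the gap oracle on random transcripts", {
  set.seed(101)
  for (i in 1:1000) {
    n_ex <- sample(1:6, 1L)
    starts <- sort(sample(seq(0L, 760L, by = 40L), n_ex))
    exons <- cbind(starts, starts + sample(10:39, n_ex, replace = TRUE))
    strand <- sample(c("+", "-"), 1L)
    t <- iesplice:::new_transcript_model(
      "T", "G", "x", "chrA", strand,
      iesplice:::orient_intervals(exons, strand),
      matrix(integer(0), ncol = 2L))
    ir <- extract_introns(t)
    gaps <- oracle_intron_gaps(exons)
    got <- if (nrow(ir) == 0L) gaps[0, , drop = FALSE] else {
      m <- cbind(ir$start, ir$end)
      m[order(m[, 1L]), , drop = FALSE]
    }
    expect_equal(unname(got), unname(gaps))
    # conservation: exon + intron lengths tile the genomic span
    span <- max(exons[, 2L]) - min(exons[, 1L])
    expect_equal(sum(exons[, 2L] - exons[, 1L]) + sum(ir$length), span)
  }
})

test_that("fetch_sequence slices and reverse-complements", {
  g <- mini_genome()
  expect_equal(fetch_sequence(g, "chrB", 0L, 4L, "+"), "AACG")
  expect_equal(fetch_sequence(g, "chrB", 0L, 4L, "-"), oracle_revcomp("AACG"))
  expect_equal(fetch_sequence(g, "chrB", 0L, 4L, "-"), "CGTT")
  expect_error(fetch_sequence(g, "chrB", 0L, 6L, "+"), "bounds")
  expect_error(fetch_sequence(g, "nope", 0L, 2L, "+"), "contig")
})

test_that("build_orf translates, flags malformed ORFs, and is strand-symmetric", {
  seq_plus <- paste0("GG", "ATGAAATAG", "CC")
  g <- as_genome(c(p = seq_plus, m = oracle_revcomp(seq_plus)))
  mk <- function(contig, strand, len) {
    s <- if (strand == "+") 2L else 2L
    iesplice:::new_transcript_model(
      "T", "G", "protein_coding", contig, strand,
      matrix(c(0L, len), ncol = 2L), matrix(c(s, s + 9L), ncol = 2L))
  }
  o <- build_orf(mk("p", "+", 13L), g)
  expect_equal(o$protein, "MK")
  expect_true(is.na(o$malformed))
  om <- build_orf(mk("m", "-", 13L), g)
  expect_equal(om$protein, "MK")  # minus-strand mirror gives same protein

  # CDS length 10: malformed
  t10 <- iesplice:::new_transcript_model(
    "T", "G", "protein_coding", "p", "+",
    matrix(c(0L, 13L), ncol = 2L), matrix(c(2L, 12L), ncol = 2L))
  expect_match(build_orf(t10, g)$malformed, "multiple of 3")

  # internal stop is flagged, not truncated
  seq_int <- paste0("ATG", "TAA", "AAA", "TAG")
  gi <- as_genome(c(i = seq_int))
  ti <- iesplice:::new_transcript_model(
    "T", "G", "protein_coding", "i", "+",
    matrix(c(0L, 12L), ncol = 2L), matrix(c(0L, 12L), ncol = 2L))
  expect_match(build_orf(ti, gi)$malformed, "internal stop")

  # N inside a codon translates to X
  gn <- as_genome(c(n = "ATGANATAG"))
  tn <- iesplice:::new_transcript_model(
    "T", "G", "protein_coding", "n", "+",
    matrix(c(0L, 9L), ncol = 2L), matrix(c(0L, 9L), ncol = 2L))
  expect_equal(build_orf(tn, gn)$protein, "MX")
})

test_that("canonical transcript per gene is the longest CDS, ties lexicographic", {
  cfg <- simulation_config(n_genes = 3L, seed = 9L)
  sim <- simulate_genome_annotation(cfg)
  can <- canonical_transcripts(sim$transcripts)
  expect_equal(sort(unname(can)), sort(names(sim$transcripts)))
  # tie case
  tx <- sim$transcripts
  dup <- tx[[1]]
  dup$transcript_id <- "AAA"
  tx[["AAA"]] <- dup
  can2 <- canonical_transcripts(tx)
  expect_equal(unname(can2[[dup$gene_id]]), "AAA")
})
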