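#' @title Transcript models from Ensembl-style GTF
#' @description Internal coordinates are 0-based half-open (BED-compatible
#'   arithmetic); the GTF boundary converts from/to 1-based inclusive. Exon
#'   and CDS intervals are stored 5' to 3' in transcript orientation, i.e.
#'   reversed genomic order on the minus strand.
#' @name annotation
NULL

new_transcript_model <- function(transcript_id, gene_id, gene_biotype,
                                 contig, strand, exons, cds) {
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id,
         gene_biotype = gene_biotype, contig = contig, strand = strand,
         exons = exons, cds = cds),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s, %s) %s:%s  exons=%d cds=%d\n",
              x$transcript_id, x$gene_id, x$gene_biotype, x$contig,
              x$strand, nrow(x$exons), nrow(x$cds)))
  invisible(x)
}

# order a 2-column (start,end) matrix 5'->3' in transcript orientation
orient_intervals <- function(m, strand) {
  if (nrow(m) == 0L) return(m)
  m <- m[order(m[, 1L]), , drop = FALSE]
  if (strand == "-") m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  m
}

validate_transcript_model <- function(t) {
  ex <- t$exons[order(t$exons[, 1L]), , drop = FALSE]
  if (any(ex[, 2L] <= ex[, 1L])) {
    stop(sprintf("transcript %s: empty or inverted exon", t$transcript_id))
  }
  if (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L])) {
    stop(sprintf("transcript %s: overlapping exons", t$transcript_id))
  }
  if (nrow(t$cds) > 0L) {
    for (i in seq_len(nrow(t$cds))) {
      contained <- any(ex[, 1L] <= t$cds[i, 1L] & t$cds[i, 2L] <= ex[, 2L])
      if (!contained) {
        stop(sprintf("transcript %s: CDS interval outside exons",
                     t$transcript_id))
      }
    }
    if (sum(t$cds[, 2L] - t$cds[, 1L]) < 3L) {
      stop(sprintf("transcript %s: CDS shorter than one codon",
                   t$transcript_id))
    }
  }
  invisible(t)
}

# quick structural scan so parse failures carry a line number, which
# rtracklayer's parser does not report
prescan_gtf_lines <- function(lines) {
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L) {
      stop(sprintf("GTF parse error at line %d: expected 9 tab-separated fields", i))
    }
    if (f[3L] %in% c("exon", "CDS", "stop_codon")) {
      if (!grepl("gene_id \"[^\"]+\"", f[9L]) ||
          !grepl("transcript_id \"[^\"]+\"", f[9L])) {
        stop(sprintf(
          "GTF parse error at line %d: attribute field lacks gene_id/transcript_id", i))
      }
    }
  }
  invisible(TRUE)
}

#' Parse an Ensembl-style GTF into transcript models
#'
#' Reads `exon`, `CDS` and `stop_codon` features and assembles one
#' [transcript model][annotation] per `transcript_id`. `stop_codon`
#' intervals are merged into the CDS so the open reading frame ends with
#' its termination codon (Ensembl GTFs exclude the stop from `CDS` rows).
#' Transcripts on contigs absent from `genome` are skipped with a warning;
#' exons outside contig bounds are an error.
#'
#' @param gtf Path to a GTF file, or a character vector of GTF lines.
#' @param genome A `genome_sequence` from [read_genome_fasta()]/[as_genome()].
#' @return Named list of `transcript_model` objects (class `transcript_set`).
#' @export
parse_annotation <- function(gtf, genome) {
  if (length(gtf) == 1L && file.exists(gtf)) {
    lines <- readLines(gtf)
  } else {
    lines <- as.character(gtf)
  }
  prescan_gtf_lines(lines)
  tf <- tempfile(fileext = ".gtf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  gr <- rtracklayer::import(tf, format = "gtf")

  keep <- gr$type %in% c("exon", "CDS", "stop_codon")
  gr <- gr[keep]
  if (length(gr) == 0L) return(structure(list(), class = "transcript_set"))

  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    gene_biotype = if (!is.null(gr$gene_biotype)) gr$gene_biotype else NA_character_,
    stringsAsFactors = FALSE)

  out <- list()
  skipped <- character(0)
  for (tid in unique(df$transcript_id)) {
    rows <- df[df$transcript_id == tid, , drop = FALSE]
    contig <- rows$contig[[1L]]
    if (!contig %in% names(genome)) {
      skipped <- c(skipped, tid)
      next
    }
    clen <- length(genome[[contig]])
    ex <- rows[rows$type == "exon", , drop = FALSE]
    if (any(ex$start < 0L) || any(ex$end > clen)) {
      stop(sprintf("transcript %s: exon outside bounds of contig %s", tid, contig))
    }
    strand <- rows$strand[[1L]]
    cds_rows <- rows[rows$type %in% c("CDS", "stop_codon"), , drop = FALSE]
    exons <- orient_intervals(cbind(ex$start, ex$end), strand)
    cds <- if (nrow(cds_rows) > 0L) {
      merge_adjacent(cbind(cds_rows$start, cds_rows$end))
    } else {
      matrix(integer(0), ncol = 2L)
    }
    cds <- orient_intervals(cds, strand)
    bt <- rows$gene_biotype[[1L]]
    if (is.na(bt)) bt <- if (nrow(cds) > 0L) "protein_coding" else "unknown"
    t <- new_transcript_model(tid, rows$gene_id[[1L]], bt, contig, strand,
                              exons, cds)
    validate_transcript_model(t)
    out[[tid]] <- t
  }
  if (length(skipped) > 0L) {
    warning(sprintf("skipped %d transcript(s) on contigs absent from genome: %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  }
  structure(out, class = "transcript_set")
}

# merge book-ended/overlapping intervals (genomic order)
merge_adjacent <- function(m) {
  if (nrow(m) <= 1L) return(m)
  m <- m[order(m[, 1L]), , drop = FALSE]
  out <- m[1L, , drop = FALSE]
  for (i in 2L:nrow(m)) {
    if (m[i, 1L] <= out[nrow(out), 2L]) {
      out[nrow(out), 2L] <- max(out[nrow(out), 2L], m[i, 2L])
    } else {
      out <- rbind(out, m[i, , drop = FALSE])
    }
  }
  out
}

#' Write transcript models back to GTF
#'
#' Emits `exon` and `CDS` rows (1-based inclusive coordinates) with
#' Ensembl-style attributes. Because the in-memory CDS already contains the
#' termination codon, no separate `stop_codon` rows are written; re-parsing
#' the output reproduces the same models.
#'
#' @param transcripts A `transcript_set`.
#' @param path Output file path (or `NULL` to return the lines).
#' @return Invisibly, the GTF lines.
#' @export
write_gtf <- function(transcripts, path = NULL) {
  lines <- character(0)
  for (t in transcripts) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                     t$gene_id, t$transcript_id, t$gene_biotype)
    fmt <- function(type, m) {
      m <- m[order(m[, 1L]), , drop = FALSE]
      sprintf("%s\tiesplice\t%s\t%d\t%d\t.\t%s\t.\t%s",
              t$contig, type, m[, 1L] + 1L, m[, 2L], t$strand, attrs)
    }
    lines <- c(lines, fmt("exon", t$exons))
    if (nrow(t$cds) > 0L) lines <- c(lines, fmt("CDS", t$cds))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Derive introns from a transcript model
#'
#' One record per adjacent exon pair, ordered 5' to 3' in transcript
#' orientation. `within_cds` is true when both flanking exons overlap the
#' CDS; `is_last_cds_intron` marks the 3'-most such intron (the last intron
#' of the open reading frame).
#'
#' @param t A `transcript_model`.
#' @return A data.frame with columns `event_id`, `contig`, `start`, `end`,
#'   `strand`, `transcript_id`, `ordinal`, `length`, `within_cds`,
#'   `is_last_cds_intron` (0 rows for a single-exon transcript).
#' @export
extract_introns <- function(t) {
  n <- nrow(t$exons)
  empty <- data.frame(event_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), transcript_id = character(0),
                      ordinal = integer(0), length = integer(0),
                      within_cds = logical(0), is_last_cds_intron = logical(0),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  ex <- t$exons  # transcript orientation
  overlaps_cds <- function(iv) {
    nrow(t$cds) > 0L && any(t$cds[, 1L] < iv[2L] & iv[1L] < t$cds[, 2L])
  }
  rows <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    up <- ex[k, ]; down <- ex[k + 1L, ]
    if (t$strand == "+") {
      s <- up[2L]; e <- down[1L]
    } else {
      s <- down[2L]; e <- up[1L]
    }
    rows[[k]] <- data.frame(
      event_id = sprintf("%s.I%d", t$transcript_id, k),
      contig = t$contig, start = s, end = e, strand = t$strand,
      transcript_id = t$transcript_id, ordinal = k, length = e - s,
      within_cds = overlaps_cds(up) && overlaps_cds(down),
      is_last_cds_intron = FALSE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (any(out$within_cds)) {
    out$is_last_cds_intron[max(which(out$within_cds))] <- TRUE
  }
  out
}

#' Derive introns for every transcript in a set
#'
#' @param transcripts A `transcript_set`.
#' @return Row-bound intron table (see [extract_introns()]).
#' @export
extract_all_introns <- function(transcripts) {
  do.call(rbind, c(lapply(unname(transcripts), extract_introns),
                   list(make.row.names = FALSE)))
}

#' Reconstruct and translate the open reading frame of a transcript
#'
#' Concatenates CDS pieces in transcript orientation and translates with
#' the standard genetic code. The terminal stop codon is excluded from the
#' protein. A CDS whose length is not a multiple of three, or that carries
#' an in-frame stop before the annotated end, is flagged rather than
#' silently truncated; codons containing `N` translate to `X`.
#'
#' @param t A `transcript_model` with non-empty CDS.
#' @param genome A `genome_sequence`.
#' @return List with `cds_seq`, `protein`, `protein_length`,
#'   `malformed` (`NA` or a reason string).
#' @export
build_orf <- function(t, genome) {
  if (nrow(t$cds) == 0L) stop(sprintf("transcript %s has no CDS", t$transcript_id))
  pieces <- vapply(seq_len(nrow(t$cds)), function(i) {
    fetch_sequence(genome, t$contig, t$cds[i, 1L], t$cds[i, 2L], t$strand)
  }, character(1))
  cds_seq <- paste(pieces, collapse = "")
  malformed <- NA_character_
  if (nchar(cds_seq) %% 3L != 0L) {
    malformed <- sprintf("CDS length %d not a multiple of 3", nchar(cds_seq))
  }
  aa <- translate_codons(cds_seq)
  n_cod <- nchar(aa)
  stops <- which(strsplit(aa, "", fixed = TRUE)[[1L]] == "*")
  protein <- aa
  if (length(stops) > 0L) {
    if (any(stops < n_cod)) {
      malformed <- if (is.na(malformed)) {
        sprintf("internal stop at codon %d of %d", min(stops), n_cod)
      } else malformed
    }
    if (stops[length(stops)] == n_cod) {
      protein <- substr(aa, 1L, n_cod - 1L)
    }
  }
  list(cds_seq = cds_seq, protein = protein,
       protein_length = nchar(protein), malformed = malformed)
}

#' Pick one canonical transcript per gene
#'
#' The transcript with the longest total CDS represents the gene; ties go
#' to the lexicographically smallest `transcript_id`.
#'
#' @param transcripts A `transcript_set`.
#' @return Character vector of canonical transcript ids, named by gene id.
#' @export
canonical_transcripts <- function(transcripts) {
  if (length(transcripts) == 0L) return(character(0))
  info <- data.frame(
    gene_id = vapply(transcripts, `[[`, character(1), "gene_id"),
    transcript_id = vapply(transcripts, `[[`, character(1), "transcript_id"),
    cds_len = vapply(transcripts, function(t) {
      if (nrow(t$cds) == 0L) 0L else sum(t$cds[, 2L] - t$cds[, 1L])
    }, integer(1)),
    stringsAsFactors = FALSE)
  info <- info[order(info$gene_id, -info$cds_len, info$transcript_id), ]
  picked <- info[!duplicated(info$gene_id), ]
  stats::setNames(picked$transcript_id, picked$gene_id)
}
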