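#' Classify the protein-coding consequence of retaining one intron
#'
#' Decision sequence: a non-protein-coding gene gives `NONCODING_GENE`;
#' an intron outside the open reading frame gives `NONCODING_REGION`.
#' Otherwise the intron sequence is inserted at its position in the
#' spliced CDS and the result translated from the annotated start. A
#' frame-preserving intron (length divisible by 3) with no stop codon in
#' the inserted region is `CODING_INFRAME`, adding `length/3` amino acids.
#' A novel stop -- harboured directly by an in-frame intron, or met in the
#' shifted frame of a frameshifting intron (searched through to the
#' annotated transcript 3' end) -- gives `LAST_INTRON_PTC` when the intron
#' is the last intron of the ORF (a potentially stable mRNA with an
#' alternative C-terminus), else `PTC`.
#'
#' @param t A `transcript_model`.
#' @param intron One row of [extract_introns()] output (data.frame or
#'   list with `event_id`, `start`, `end`, `length`, `within_cds`,
#'   `is_last_cds_intron`, `ordinal`).
#' @param genome A `genome_sequence`.
#' @return One-row data.frame: `event_id`, `transcript_id`, `category`,
#'   `frame_preserving`, `extra_aa`, `ptc_offset` (codon index of the
#'   first novel stop relative to the insertion point; NA when no stop
#'   was found before the transcript end, with `no_stop_found` set),
#'   `no_stop_found`, `unclassifiable`.
#' @export
classify_retained_intron <- function(t, intron, genome) {
  intron <- as.list(intron)
  known <- extract_introns(t)
  hit <- which(known$start == intron$start & known$end == intron$end)
  if (length(hit) != 1L) {
    stop(sprintf("intron [%s,%s) not found in transcript %s",
                 intron$start, intron$end, t$transcript_id))
  }
  info <- known[hit, ]
  call <- function(category, frame_preserving = NA, extra_aa = NA_integer_,
                   ptc_offset = NA_integer_, no_stop_found = FALSE,
                   unclassifiable = FALSE) {
    data.frame(event_id = info$event_id, transcript_id = t$transcript_id,
               category = category, frame_preserving = frame_preserving,
               extra_aa = extra_aa, ptc_offset = ptc_offset,
               no_stop_found = no_stop_found, unclassifiable = unclassifiable,
               stringsAsFactors = FALSE)
  }
  if (t$gene_biotype != "protein_coding") return(call("NONCODING_GENE"))
  if (!info$within_cds) return(call("NONCODING_REGION"))

  orf <- build_orf(t, genome)
  if (!is.na(orf$malformed)) {
    return(call(NA_character_, unclassifiable = TRUE))
  }
  ilen <- info$length
  frame_preserving <- ilen %% 3L == 0L
  d <- cds_offset_of_intron(t, info)       # nt of CDS 5' of the insertion
  insert_codon <- d %/% 3L
  intron_seq <- fetch_sequence(genome, t$contig, info$start, info$end,
                               t$strand)
  cds <- orf$cds_seq

  # translate the retained coding sequence from the insertion point through
  # to the annotated transcript 3' end; the termination codon is "novel"
  # unless it is the annotated stop at its intron-shifted position (which
  # requires an intact terminal codon: a rare intron inserted inside the
  # stop codon itself destroys it, and any stop met then is novel)
  retained <- paste0(substr(cds, 1L, d), intron_seq,
                     substr(cds, d + 1L, nchar(cds)),
                     utr3_sequence(t, genome))
  aa <- strsplit(translate_codons(retained), "", fixed = TRUE)[[1L]]
  idx <- which(aa == "*")
  idx <- idx[idx - 1L >= insert_codon]              # codons from insertion on
  expected_idx <- if (frame_preserving && d <= nchar(cds) - 3L) {
    (nchar(cds) - 3L + ilen) %/% 3L + 1L            # annotated stop, shifted
  } else NA_integer_
  if (length(idx) == 0L) {
    # ran off the transcript end without terminating: still a disrupted ORF
    return(call("PTC", frame_preserving, no_stop_found = TRUE))
  }
  if (!is.na(expected_idx) && idx[[1L]] == expected_idx) {
    return(call("CODING_INFRAME", TRUE, extra_aa = ilen %/% 3L))
  }
  category <- if (info$is_last_cds_intron) "LAST_INTRON_PTC" else "PTC"
  call(category, frame_preserving,
       ptc_offset = idx[[1L]] - 1L - insert_codon)
}

# nucleotides of CDS lying 5' of an intron's insertion point
cds_offset_of_intron <- function(t, intron) {
  if (nrow(t$cds) == 0L) stop("transcript has no CDS")
  upstream <- if (t$strand == "+") {
    t$cds[, 2L] <= intron$start
  } else {
    t$cds[, 1L] >= intron$end
  }
  sum((t$cds[, 2L] - t$cds[, 1L])[upstream])
}

# spliced exonic sequence 3' of the CDS end (the 3' UTR)
utr3_sequence <- function(t, genome) {
  pieces <- character(0)
  for (i in seq_len(nrow(t$exons))) {
    ex <- t$exons[i, ]
    if (t$strand == "+") {
      cds_end <- max(t$cds[, 2L])
      s <- max(ex[1L], cds_end); e <- ex[2L]
    } else {
      cds_end <- min(t$cds[, 1L])
      s <- ex[1L]; e <- min(ex[2L], cds_end)
    }
    if (e > s) {
      pieces <- c(pieces, fetch_sequence(genome, t$contig, s, e, t$strand))
    }
  }
  paste(pieces, collapse = "")
}

#' Classify the consequence of every intron in a table
#'
#' @param introns Intron table (rows from [extract_introns()] /
#'   [extract_all_introns()]).
#' @param transcripts A `transcript_set`.
#' @param genome A `genome_sequence`.
#' @return Row-bound consequence table (see [classify_retained_intron()]).
#' @export
classify_all_introns <- function(introns, transcripts, genome) {
  rows <- lapply(seq_len(nrow(introns)), function(i) {
    t <- transcripts[[introns$transcript_id[[i]]]]
    classify_retained_intron(t, introns[i, ], genome)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Extract donor and acceptor splice-site windows for one intron
#'
#' The donor window spans positions -3 to +6 across the 5' splice site
#' (3 exonic + 6 intronic bases, 9 nt); the acceptor window spans -20 to
#' +3 across the 3' splice site (20 intronic + 3 exonic bases, 23 nt).
#' On the minus strand the mirrored genomic slices are reverse
#' complemented so both windows read 5' to 3' in transcript orientation.
#'
#' @param intron One intron record (list/row with `contig`, `start`,
#'   `end`, `strand`, `length`).
#' @param genome A `genome_sequence`.
#' @return List: `donor_seq` (9 nt), `acceptor_seq` (23 nt),
#'   `overlapping` (TRUE when the intron is shorter than 26 nt and the
#'   windows overlap).
#' @export
extract_splice_site_windows <- function(intron, genome) {
  intron <- as.list(intron)
  s <- intron$start; e <- intron$end
  if (intron$strand == "+") {
    donor <- fetch_sequence(genome, intron$contig, s - 3L, s + 6L, "+")
    acceptor <- fetch_sequence(genome, intron$contig, e - 20L, e + 3L, "+")
  } else {
    donor <- fetch_sequence(genome, intron$contig, e - 6L, e + 3L, "-")
    acceptor <- fetch_sequence(genome, intron$contig, s - 3L, s + 20L, "-")
  }
  list(donor_seq = donor, acceptor_seq = acceptor,
       overlapping = (e - s) < 26L)
}

#' Extract splice-site windows for an intron table
#'
#' @param introns Intron table.
#' @param genome A `genome_sequence`.
#' @return Data.frame: `event_id`, `donor_seq`, `acceptor_seq`,
#'   `overlapping`.
#' @export
splice_site_table <- function(introns, genome) {
  rows <- lapply(seq_len(nrow(introns)), function(i) {
    w <- extract_splice_site_windows(introns[i, ], genome)
    data.frame(event_id = introns$event_id[[i]], donor_seq = w$donor_seq,
               acceptor_seq = w$acceptor_seq, overlapping = w$overlapping,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write splice-site windows as FASTA for external scoring
#'
#' Headers are `event_id|donor` and `event_id|acceptor`, the layout
#' expected by maximum-entropy splice-site scorers run outside this
#' package.
#'
#' @param windows Data.frame from [splice_site_table()].
#' @param path Output FASTA path.
#' @export
write_windows_fasta <- function(windows, path) {
  lines <- character(0)
  for (i in seq_len(nrow(windows))) {
    lines <- c(lines,
               sprintf(">%s|donor", windows$event_id[[i]]),
               windows$donor_seq[[i]],
               sprintf(">%s|acceptor", windows$event_id[[i]]),
               windows$acceptor_seq[[i]])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Train a position weight matrix from aligned site sequences
#'
#' Per-position base frequencies with a pseudocount, against a uniform
#' background; a built-in stand-in scorer for splice-site strength when an
#' external maximum-entropy model is not in play.
#'
#' @param sites Character vector of equal-length A/C/G/T sequences.
#' @param pseudocount Added to each base count per position (default 0.5).
#' @return A `pwm_model`: positions x 4 frequency matrix (columns
#'   A, C, G, T), rows summing to 1.
#' @export
build_pwm <- function(sites, pseudocount = 0.5) {
  stopifnot(length(sites) >= 1L)
  if (length(unique(nchar(sites))) != 1L) stop("sites must share one length")
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(sites))
  counts <- t(cm[c("A", "C", "G", "T"), , drop = FALSE])
  freq <- (counts + pseudocount) / (length(sites) + 4 * pseudocount)
  structure(freq, class = "pwm_model", pseudocount = pseudocount)
}

#' Score a window against a position weight matrix
#'
#' Log-odds in bits against a uniform background:
#' `sum_i log2(f_i(base_i) / 0.25)`. A window containing `N` (or any
#' non-ACGT base), or hitting a zero frequency (possible only with
#' pseudocount 0), has no defined score and returns `NA`.
#'
#' @param window A/C/G/T string of the model's length.
#' @param model A `pwm_model` from [build_pwm()].
#' @return Log-odds score in bits, or `NA`.
#' @export
score_pwm <- function(window, model) {
  stopifnot(inherits(model, "pwm_model"))
  bases <- strsplit(toupper(window), "", fixed = TRUE)[[1L]]
  if (length(bases) != nrow(model)) {
    stop(sprintf("window length %d does not match model length %d",
                 length(bases), nrow(model)))
  }
  if (!all(bases %in% c("A", "C", "G", "T"))) return(NA_real_)
  f <- model[cbind(seq_len(nrow(model)), match(bases, colnames(model)))]
  score <- sum(log2(f / 0.25))
  if (!is.finite(score)) return(NA_real_)
  score
}
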