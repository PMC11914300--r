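#' Simulation settings for the synthetic time-course fixture
#'
#' Defaults describe the data regime the pipeline is designed for:
#' chromatin-associated RNA junction counts at 0/30/150 min in biological
#' duplicates, with a minority of introns showing transient retention
#' (PSI up at 30 min, back to baseline at 150 min). Effect size defaults
#' sit in the 0.15--0.30 PSI range typical of these transient events, on a
#' low retention baseline, and most planted introns disrupt the reading
#' frame or carry a stop, with in-frame stop-free introns the rare class.
#'
#' @param n_genes Number of simulated genes (one transcript each).
#' @param introns_per_gene Introns per transcript.
#' @param frame_class_mix Named proportions over the three coding classes
#'   `inframe_nostop`, `inframe_stop`, `frameshift`; must sum to 1.
#' @param ies_fraction Fraction of introns given a transient trajectory.
#' @param baseline_psi Retention level at 0 min, in `[0,1]`.
#' @param delta30 Planted PSI increase at 30 min.
#' @param delta150 Residual PSI offset at 150 min (0 = full reversion).
#' @param depth Expected junction reads per event per sample.
#' @param rho Beta-binomial intra-class correlation in `[0,1)`; 0 gives
#'   pure binomial counts.
#' @param replicates Biological replicates per condition.
#' @param seed Integer seed; every random draw derives from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 60L, introns_per_gene = 5L,
                              frame_class_mix = c(inframe_nostop = 0.10,
                                                  inframe_stop = 0.30,
                                                  frameshift = 0.60),
                              ies_fraction = 0.2, baseline_psi = 0.10,
                              delta30 = 0.25, delta150 = 0.0,
                              depth = 200, rho = 0.02, replicates = 2L,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              introns_per_gene = as.integer(introns_per_gene),
              frame_class_mix = frame_class_mix,
              ies_fraction = ies_fraction, baseline_psi = baseline_psi,
              delta30 = delta30, delta150 = delta150, depth = depth,
              rho = rho, replicates = as.integer(replicates),
              seed = as.integer(seed))
  if (cfg$n_genes < 1L || cfg$introns_per_gene < 0L) stop("invalid gene/intron counts")
  if (abs(sum(frame_class_mix) - 1) > 1e-8) stop("frame_class_mix must sum to 1")
  if (is.null(names(frame_class_mix)) ||
      !setequal(names(frame_class_mix),
                c("inframe_nostop", "inframe_stop", "frameshift"))) {
    stop("frame_class_mix must be named inframe_nostop/inframe_stop/frameshift")
  }
  if (cfg$baseline_psi < 0 || cfg$baseline_psi + cfg$delta30 > 1) {
    stop("baseline_psi + delta30 must lie in [0,1]")
  }
  if (cfg$baseline_psi + cfg$delta150 > 1 || cfg$baseline_psi + cfg$delta150 < 0) {
    stop("baseline_psi + delta150 must lie in [0,1]")
  }
  if (cfg$rho < 0 || cfg$rho >= 1) stop("rho must be in [0,1)")
  if (cfg$replicates < 1L) stop("need >= 1 replicate")
  if (cfg$ies_fraction < 0 || cfg$ies_fraction > 1) stop("ies_fraction in [0,1]")
  structure(cfg, class = "simulation_config")
}

# deterministic per-unit substream: fixed affine map of the master seed, so
# adding genes/events never perturbs earlier units' draws
substream_seed <- function(seed, unit, tag) {
  ((as.double(seed) * 48271 + unit * 65599 + tag * 7919) %% 2147483562) + 1
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# random sense codons (no stops)
random_codons <- function(n) {
  all <- as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"), paste0),
                         c("A","C","G","T"), paste0))
  sense <- setdiff(all, STOP_CODONS)
  paste(sample(sense, n, replace = TRUE), collapse = "")
}

# intron whose body is pyrimidine-only so it cannot harbour a stop codon in
# any frame; canonical GT...AG ends with a C before the terminal AG
pyrimidine_intron <- function(len) {
  stopifnot(len >= 6L)
  body <- paste(sample(c("C", "T"), len - 5L, replace = TRUE), collapse = "")
  paste0("GT", body, "CAG")
}

# plant an in-frame TAA inside the intron, aligned to the reading frame the
# intron lands in (phase = CDS offset of the insertion point mod 3)
plant_stop <- function(intron, phase) {
  len <- nchar(intron)
  j0 <- ((3L - phase) %% 3L) + 3L  # smallest aligned 0-based offset >= 3
  while (j0 + 3L > len - 3L) j0 <- j0 - 3L
  stopifnot(j0 >= 3L)
  paste0(substr(intron, 1L, j0), "TAA", substr(intron, j0 + 4L, len))
}

#' Simulate a genome, annotation and ground truth for the pipeline
#'
#' Builds one protein-coding transcript per gene on its own contig (random
#' strand), with a valid ATG...stop open reading frame split across exons at
#' random codon phases. Each intron is assigned a coding class from
#' `frame_class_mix` and constructed so that retaining it realises that
#' class: in-frame stop-free introns have length divisible by 3 and a
#' pyrimidine body free of stop codons in every frame; in-frame stop
#' introns additionally carry an aligned TAA; frameshift introns have
#' length not divisible by 3. The 3' UTR opens with a stop codon in every
#' frame so a frameshift always meets a termination codon before the
#' transcript end. A subset of introns (`ies_fraction`) is planted with the
#' transient trajectory (baseline, baseline + delta30, baseline + delta150);
#' all other introns stay at baseline. Fully deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @return List with `genome` (a `genome_sequence`), `gtf` (character
#'   lines), `transcripts` (`transcript_set`), and `truth` (data.frame:
#'   `event_id`, `transcript_id`, `psi_t0`, `psi_t30`, `psi_t150`,
#'   `is_ies`, `frame_class`, `expected_category`, `intron_length`).
#' @export
simulate_genome_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  classes <- names(cfg$frame_class_mix)
  contigs <- character(cfg$n_genes)
  names(contigs) <- sprintf("chr_g%03d", seq_len(cfg$n_genes))
  transcripts <- list()
  truth_rows <- list()
  n_introns_total <- cfg$n_genes * cfg$introns_per_gene

  # global assignments drawn from their own substreams
  set.seed(substream_seed(cfg$seed, 0, 1))
  class_of <- if (n_introns_total > 0L) {
    sample(rep(classes, diff(round(cumsum(c(0, cfg$frame_class_mix)) *
                                   n_introns_total))))
  } else character(0)
  set.seed(substream_seed(cfg$seed, 0, 2))
  n_ies <- round(cfg$ies_fraction * n_introns_total)
  ies_idx <- if (n_ies > 0L) sample.int(n_introns_total, n_ies) else integer(0)

  intron_counter <- 0L
  for (g in seq_len(cfg$n_genes)) {
    set.seed(substream_seed(cfg$seed, g, 3))
    gene_id <- sprintf("GENE%03d", g)
    tid <- sprintf("TX%03d", g)
    strand <- sample(c("+", "-"), 1L)
    n_int <- cfg$introns_per_gene

    n_codons <- sample(120:220, 1L)                      # ORF body size
    cds_seq <- paste0("ATG", random_codons(n_codons), "TAA")
    cds_len <- nchar(cds_seq)
    # intron insertion points as CDS offsets (not at the very ends); exclude
    # offsets where the preceding exonic "TA" would meet the intron's leading
    # G and forge a TAG stop across the 5' junction (phase-2 insertions)
    cand <- 6:(cds_len - 6L)
    junction_tag <- cand %% 3L == 2L &
      substring(cds_seq, cand - 1L, cand) == "TA"
    cand <- cand[!junction_tag]
    cuts <- if (n_int > 0L) sort(sample(cand, n_int)) else integer(0)

    utr5 <- paste(sample(c("A","C","G","T"), 15L, replace = TRUE), collapse = "")
    # TAA at offsets 0, 4 and 8: a stop codon in each of the three frames
    # right after the ORF, so a frameshifted read-through always terminates
    utr3 <- paste0("TAACTAACTAA",
                   paste(sample(c("C","T"), 12L, replace = TRUE), collapse = ""))

    intron_seqs <- character(n_int)
    gene_truth <- vector("list", n_int)
    for (k in seq_len(n_int)) {
      intron_counter <- intron_counter + 1L
      cls <- class_of[[intron_counter]]
      phase <- cuts[[k]] %% 3L
      len <- sample(20:100, 1L) * 3L                     # 60..300, %%3 == 0
      if (cls == "frameshift") len <- len + sample(1:2, 1L)
      intr <- pyrimidine_intron(len)
      if (cls == "inframe_stop") intr <- plant_stop(intr, phase)
      intron_seqs[[k]] <- intr
      is_last <- k == n_int
      expected <- switch(cls,
        inframe_nostop = "CODING_INFRAME",
        inframe_stop = if (is_last) "LAST_INTRON_PTC" else "PTC",
        frameshift = if (is_last) "LAST_INTRON_PTC" else "PTC")
      is_ies <- intron_counter %in% ies_idx
      gene_truth[[k]] <- data.frame(
        event_id = sprintf("%s.I%d", tid, k), transcript_id = tid,
        psi_t0 = cfg$baseline_psi,
        psi_t30 = if (is_ies) cfg$baseline_psi + cfg$delta30 else cfg$baseline_psi,
        psi_t150 = if (is_ies) cfg$baseline_psi + cfg$delta150 else cfg$baseline_psi,
        is_ies = is_ies, frame_class = cls, expected_category = expected,
        intron_length = len, stringsAsFactors = FALSE)
    }

    # assemble the transcript-oriented genomic sequence and coordinates
    pieces <- c(list(utr5), {
      out <- list(); prev <- 0L
      for (k in seq_len(n_int)) {
        out[[length(out) + 1L]] <- substr(cds_seq, prev + 1L, cuts[[k]])
        out[[length(out) + 1L]] <- intron_seqs[[k]]
        prev <- cuts[[k]]
      }
      out[[length(out) + 1L]] <- substr(cds_seq, prev + 1L, cds_len)
      out
    }, list(utr3))
    pieces <- unlist(pieces)
    full <- paste(pieces, collapse = "")
    glen <- nchar(full)

    # exon/CDS intervals in transcript-oriented coordinates
    piece_len <- nchar(pieces)
    piece_end <- cumsum(piece_len)
    piece_start <- piece_end - piece_len
    # pieces: 1 = utr5, then alternating cds-chunk/intron, last = utr3
    exon_iv <- matrix(integer(0), ncol = 2L)
    cds_iv <- matrix(integer(0), ncol = 2L)
    exon_open <- 0L
    for (p in seq_along(pieces)) {
      is_intron <- p > 1L && p < length(pieces) && (p %% 2L == 1L)
      if (is_intron) {
        exon_iv <- rbind(exon_iv, c(exon_open, piece_start[[p]]))
        exon_open <- piece_end[[p]]
      }
    }
    exon_iv <- rbind(exon_iv, c(exon_open, glen))
    cds_chunk_ids <- setdiff(seq(2L, length(pieces) - 1L), seq_along(pieces)[
      seq_along(pieces) > 1L & seq_along(pieces) < length(pieces) &
        seq_along(pieces) %% 2L == 1L])
    for (p in cds_chunk_ids) {
      if (piece_len[[p]] > 0L) {
        cds_iv <- rbind(cds_iv, c(piece_start[[p]], piece_end[[p]]))
      }
    }

    if (strand == "+") {
      contig_seq <- full
      ex <- exon_iv; cd <- cds_iv
    } else {
      contig_seq <- revcomp_chr(full)
      flip <- function(m) cbind(glen - m[, 2L], glen - m[, 1L])
      ex <- flip(exon_iv); cd <- flip(cds_iv)
    }
    contigs[[g]] <- contig_seq
    transcripts[[tid]] <- new_transcript_model(
      tid, gene_id, "protein_coding", names(contigs)[[g]], strand,
      orient_intervals(ex, strand), orient_intervals(cd, strand))
    validate_transcript_model(transcripts[[tid]])
    truth_rows[[g]] <- do.call(rbind, gene_truth)
  }

  transcripts <- structure(transcripts, class = "transcript_set")
  truth <- do.call(rbind, c(truth_rows, list(make.row.names = FALSE)))
  genome <- as_genome(contigs)
  list(genome = genome, gtf = write_gtf(transcripts),
       transcripts = transcripts, truth = truth)
}

# one beta-binomial draw vector: n trials each, mean p, ICC rho
rbetabinom <- function(k, n, p, rho) {
  if (rho <= 0) return(stats::rbinom(k, n, p))
  if (p <= 0) return(integer(k))
  if (p >= 1) return(n)
  theta <- (1 - rho) / rho
  pi <- stats::rbeta(k, theta * p, theta * (1 - p))
  stats::rbinom(k, n, pi)
}

#' Simulate a junction-count table from ground-truth PSI trajectories
#'
#' For each event and sample, a total junction depth is drawn as
#' Poisson(`depth`); the inclusion-supporting fraction follows a
#' beta-binomial with mean equal to the read-level inclusion fraction
#' implied by the true PSI, `p = 2*psi/(1 + psi)` (a retained transcript
#' presents two exon-intron junctions against one spliced exon-exon
#' junction, inverting the effective-length normalisation used by
#' [estimate_psi()] so the estimator is unbiased at `rho = 0`). Inclusion
#' reads are split evenly between the 5' and 3' boundaries; the remainder
#' are spliced reads. Deterministic given `cfg$seed`.
#'
#' @param truth Ground-truth data.frame from [simulate_genome_annotation()]
#'   (only `event_id`, `psi_t0`, `psi_t30`, `psi_t150` are used).
#' @param cfg A [simulation_config()].
#' @return Junction-count data.frame with columns `event_id`, `sample_id`,
#'   `condition` (`t0`/`t30`/`t150`), `replicate`, `I_up`, `I_down`, `S`.
#' @export
simulate_junction_counts <- function(truth, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  conds <- c("t0", "t30", "t150")
  psi_cols <- c("psi_t0", "psi_t30", "psi_t150")
  reps <- seq_len(cfg$replicates)
  grid <- expand.grid(condition = conds, replicate = reps,
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    set.seed(substream_seed(cfg$seed, i, 11))
    m <- nrow(grid)
    psi <- unlist(truth[i, psi_cols])[match(grid$condition, conds)]
    p <- 2 * psi / (1 + psi)
    n <- stats::rpois(m, cfg$depth)
    incl <- integer(m)
    for (j in seq_len(m)) incl[[j]] <- rbetabinom(1L, n[[j]], p[[j]], cfg$rho)
    i_up <- stats::rbinom(m, incl, 0.5)
    out[[i]] <- data.frame(
      event_id = truth$event_id[[i]],
      sample_id = sprintf("%s_r%d", grid$condition, grid$replicate),
      condition = grid$condition, replicate = grid$replicate,
      I_up = i_up, I_down = incl - i_up, S = n - incl,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write a complete simulated dataset to disk
#'
#' Writes `genome.fa`, `annotation.gtf`, `junction_counts.tsv` and
#' `ground_truth.tsv` under `dir`.
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list from [simulate_genome_annotation()] plus
#'   `counts`.
#' @export
write_simulation <- function(cfg, dir) {
  sim <- simulate_genome_annotation(cfg)
  counts <- simulate_junction_counts(sim$truth, cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  writeLines(sim$gtf, file.path(dir, "annotation.gtf"))
  utils::write.table(counts, file.path(dir, "junction_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(sim, list(counts = counts)))
}
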