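#' Configuration for an end-to-end pipeline run
#'
#' Exactly one input mode must be given: paths to a genome FASTA, GTF and
#' junction-count TSV, or a [simulation_config()] that generates all three.
#'
#' @param genome,gtf,counts Input file paths (file mode).
#' @param simulate A [simulation_config()] (simulation mode).
#' @param delta_min,fdr_max,min_reads Significance filters (defaults
#'   0.15, 0.01, 100), see [filter_significant()].
#' @param reversion_max Transience criterion, see [classify_trajectory()].
#' @param out_dir Output directory, or `NULL` for no file output.
#' @param seed Integer seed (used in simulation mode).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genome = NULL, gtf = NULL, counts = NULL,
                            simulate = NULL, delta_min = 0.15,
                            fdr_max = 0.01, min_reads = 100,
                            reversion_max = 0.5, out_dir = NULL,
                            seed = 1L) {
  file_mode <- !is.null(counts)
  sim_mode <- !is.null(simulate)
  if (file_mode == sim_mode) {
    stop("give exactly one of a counts path or a simulate block")
  }
  if (file_mode && (is.null(genome) || is.null(gtf))) {
    stop("file mode needs genome and gtf paths")
  }
  if (sim_mode && !inherits(simulate, "simulation_config")) {
    stop("simulate must be a simulation_config")
  }
  stopifnot(delta_min >= 0, delta_min <= 1, fdr_max > 0, fdr_max <= 1,
            min_reads >= 0, reversion_max >= 0)
  structure(list(genome = genome, gtf = gtf, counts = counts,
                 simulate = simulate, delta_min = delta_min,
                 fdr_max = fdr_max, min_reads = min_reads,
                 reversion_max = reversion_max, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat `thresholds` block plus either `inputs` paths or a `simulate`
#' block of [simulation_config()] fields.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  th <- y$thresholds
  sim <- if (!is.null(y$simulate)) {
    sim_args <- y$simulate
    if (!is.null(sim_args$frame_class_mix)) {
      sim_args$frame_class_mix <- unlist(sim_args$frame_class_mix)
    }
    do.call(simulation_config, sim_args)
  }
  pipeline_config(
    genome = y$inputs$genome, gtf = y$inputs$gtf, counts = y$inputs$counts,
    simulate = sim,
    delta_min = th$delta_min %||% 0.15, fdr_max = th$fdr_max %||% 0.01,
    min_reads = th$min_reads %||% 100,
    reversion_max = th$reversion_max %||% 0.5,
    out_dir = y$out_dir, seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full immediate-early-splicing pipeline
#'
#' Stages, in order: annotation parsing (or simulation), per-sample PSI,
#' differential retention for 0-vs-30 and 30-vs-150 min with BH
#' adjustment per comparison, significance filtering, trajectory
#' classification, coding-consequence classification and splice-site
#' window extraction for all annotated events, magnitude histogram and
#' intron-length comparison over the transient classes, PCA and heatmap
#' matrix over the significant 0-vs-30 events. Identical config and seed
#' give identical results (and identical output files when `out_dir` is
#' set).
#'
#' @param cfg A [pipeline_config()].
#' @return A results bundle: `differential_0v30`, `differential_30v150`,
#'   `trajectory`, `consequence`, `windows`, `histogram`,
#'   `length_comparison`, `pca`, `heatmap`, `gene_lists`, `manifest`
#'   (plus `truth` in simulation mode).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  truth <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- stage("simulate", {
      s <- simulate_genome_annotation(cfg$simulate)
      s$counts <- simulate_junction_counts(s$truth, cfg$simulate)
      s
    })
    genome <- sim$genome; transcripts <- sim$transcripts
    counts <- sim$counts; truth <- sim$truth
  } else {
    genome <- stage("genome", read_genome_fasta(cfg$genome))
    transcripts <- stage("annotation", parse_annotation(cfg$gtf, genome))
    counts <- stage("counts", read_junction_counts(cfg$counts))
  }

  introns <- stage("introns", extract_all_introns(transcripts))
  d1 <- stage("differential_0v30", filter_significant(
    differential_table(counts, "t0", "t30"),
    cfg$delta_min, cfg$fdr_max, cfg$min_reads))
  d2 <- stage("differential_30v150", filter_significant(
    differential_table(counts, "t30", "t150"),
    cfg$delta_min, cfg$fdr_max, cfg$min_reads))
  trajectory <- stage("trajectory", detect_ies(
    counts, cfg$delta_min, cfg$fdr_max, cfg$min_reads, cfg$reversion_max))

  known <- !is.null(introns) && nrow(introns) > 0L
  ann_events <- if (known) {
    introns[introns$event_id %in% trajectory$event_id, , drop = FALSE]
  } else introns
  consequence <- if (known && nrow(ann_events) > 0L) {
    stage("consequence", classify_all_introns(ann_events, transcripts, genome))
  } else NULL
  windows <- if (known && nrow(ann_events) > 0L) {
    stage("windows", splice_site_table(ann_events, genome))
  } else NULL

  up <- trajectory[trajectory$class == "IES_UP", , drop = FALSE]
  down <- trajectory[trajectory$class == "IES_DOWN", , drop = FALSE]
  histogram <- stage("histogram", bin_magnitudes(up$delta_max))
  length_comparison <- if (known && nrow(up) > 0L && nrow(down) > 0L) {
    stage("length_comparison", compare_intron_lengths(
      introns$length[match(up$event_id, introns$event_id)],
      introns$length[match(down$event_id, introns$event_id)]))
  } else NULL

  sig1 <- d1$event_id[d1$significant]
  pca <- heatmap <- NULL
  if (length(sig1) > 0L) {
    sub <- counts[counts$event_id %in% sig1, , drop = FALSE]
    heatmap <- stage("heatmap", heatmap_matrix(sub))
    complete <- heatmap[stats::complete.cases(heatmap), , drop = FALSE]
    if (nrow(complete) > 0L && ncol(complete) >= 2L) {
      pca <- stage("pca", pca_psi(complete))
    }
  }

  gene_lists <- if (known) {
    gid <- vapply(transcripts, `[[`, character(1), "gene_id")
    tid_of <- introns$transcript_id[match(trajectory$event_id,
                                          introns$event_id)]
    lapply(split(gid[tid_of], trajectory$class), unique_na)
  } else NULL

  manifest <- list(
    package = "iesplice",
    version = as.character(utils::packageVersion("iesplice")),
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    thresholds = list(delta_min = cfg$delta_min, fdr_max = cfg$fdr_max,
                      min_reads = cfg$min_reads,
                      reversion_max = cfg$reversion_max))

  bundle <- list(differential_0v30 = d1, differential_30v150 = d2,
                 trajectory = trajectory, consequence = consequence,
                 windows = windows, histogram = histogram,
                 length_comparison = length_comparison, pca = pca,
                 heatmap = heatmap, gene_lists = gene_lists,
                 truth = truth, introns = introns, manifest = manifest)
  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg$out_dir)
  bundle
}

unique_na <- function(x) unique(x[!is.na(x)])

# reproducible digest of the scientific configuration (output location
# excluded: where results land must not change what they are)
config_hash <- function(cfg) {
  plain <- cfg
  plain$out_dir <- NULL
  plain$simulate <- if (!is.null(cfg$simulate)) unclass(cfg$simulate)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(plain), auto_unbox = TRUE,
                              null = "null", digits = NA), tf)
  unname(tools::md5sum(tf))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(bundle$differential_0v30, file.path(dir, "differential_0v30.tsv"))
  write_tsv(bundle$differential_30v150,
            file.path(dir, "differential_30v150.tsv"))
  write_tsv(bundle$trajectory, file.path(dir, "trajectory.tsv"))
  if (!is.null(bundle$consequence)) {
    write_tsv(bundle$consequence, file.path(dir, "consequence.tsv"))
  }
  if (!is.null(bundle$windows)) {
    write_tsv(bundle$windows, file.path(dir, "splice_site_windows.tsv"))
    write_windows_fasta(bundle$windows,
                        file.path(dir, "splice_site_windows.fa"))
  }
  write_tsv(data.frame(center = bundle$histogram$centers,
                       count = bundle$histogram$counts),
            file.path(dir, "magnitude_histogram.tsv"))
  if (!is.null(bundle$pca)) {
    co <- as.data.frame(bundle$pca$coordinates)
    co <- cbind(sample_id = rownames(co), co)
    write_tsv(co, file.path(dir, "pca_coordinates.tsv"))
  }
  if (!is.null(bundle$heatmap)) {
    hm <- as.data.frame(bundle$heatmap)
    hm <- cbind(event_id = rownames(hm), hm)
    write_tsv(hm, file.path(dir, "heatmap_matrix.tsv"))
  }
  if (!is.null(bundle$introns)) {
    up <- bundle$trajectory[bundle$trajectory$class == "IES_UP", ,
                            drop = FALSE]
    write_ies_bed(up, bundle$introns, file.path(dir, "ies_up.bed"))
  }
  for (cls in names(bundle$gene_lists)) {
    writeLines(sort(bundle$gene_lists[[cls]]),
               file.path(dir, sprintf("genes_%s.txt", cls)))
  }
  writeLines(jsonlite::toJSON(bundle$manifest, auto_unbox = TRUE,
                              pretty = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

# BED6 of transient retained introns; score = 1000*|delta_max| capped
write_ies_bed <- function(up, introns, path) {
  m <- introns[match(up$event_id, introns$event_id), , drop = FALSE]
  keep <- !is.na(m$event_id)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   m$contig[keep], m$start[keep], m$end[keep],
                   m$event_id[keep],
                   pmin(1000L, as.integer(round(1000 * abs(up$delta_max[keep])))),
                   m$strand[keep])
  writeLines(lines, path)
  invisible(path)
}

#' Fraction of phosphorylated protein from band intensities
#'
#' The western-blot readout for the phosphorylated isoform:
#' `100 * C2P / (C2P + C2)`.
#'
#' @param C2P Intensity of the phosphorylated band.
#' @param C2 Intensity of the unphosphorylated band.
#' @return Percentage in `[0, 100]`.
#' @export
phospho_fraction <- function(C2P, C2) {
  if (any(C2P < 0) || any(C2 < 0)) stop("band intensities must be >= 0")
  if (any(C2P + C2 == 0)) stop("undefined: both band intensities are zero")
  100 * C2P / (C2P + C2)
}

#' Load an RNA probe table
#'
#' Reads a TSV of gel-shift probe sequences (columns `name`, `sequence`
#' over A/C/G/U) and annotates each probe with its length and whether it
#' ends with the 3' splice-site AG. With no argument, the packaged probe
#' set (30-nt probes spanning the polypyrimidine tract and 3' splice site
#' of the regulated RPL10, eIF5A and TRAF4 introns) is loaded.
#'
#' @param path TSV path; default the packaged probe table.
#' @return Data.frame: `name`, `sequence`, `length`, `ends_with_AG`.
#' @export
load_probe_table <- function(path = system.file("extdata",
                                                "emsa_probes.tsv",
                                                package = "iesplice")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "sequence") %in% names(df)))
  if (any(nchar(df$sequence) == 0L)) stop("empty probe sequence")
  if (any(grepl("[^ACGU]", df$sequence))) {
    stop("probe sequences must be RNA (A/C/G/U only)")
  }
  df$length <- nchar(df$sequence)
  df$ends_with_AG <- endsWith(df$sequence, "AG")
  df
}
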