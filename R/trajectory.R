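#' Classify one event's time-course trajectory
#'
#' An immediate-early splicing (IES) event changes between 0 and 30 min
#' and returns towards baseline by 150 min. `IES_UP` requires a passing
#' comparison consistent with increased retention at 30 min (0-vs-30
#' significant with `psi_t30 > psi_t0`, or 30-vs-150 significant with
#' `psi_t30 > psi_t150`) and a 150-min residual no more than
#' `reversion_max` of the 30-min excursion; `IES_DOWN` is the mirrored
#' case. A significant but non-reverting event is `NON_TRANSIENT`;
#' otherwise `UNCHANGED`. Events with an undefined PSI at any time point
#' are `UNCLASSIFIABLE`.
#'
#' @param psi Numeric triple `c(psi_t0, psi_t30, psi_t150)`.
#' @param sig_0v30,sig_30v150 Logical: did the comparison pass the
#'   significance filters (see [filter_significant()])?
#' @param reversion_max Maximum allowed `|psi_t150 - psi_t0| /
#'   |psi_t30 - psi_t0|` for a transient call (default 0.5).
#' @return List: `class`, `delta_max` (see [max_delta_psi()]),
#'   `reversion_ratio`.
#' @export
classify_trajectory <- function(psi, sig_0v30, sig_30v150,
                                reversion_max = 0.5) {
  if (length(psi) != 3L || anyNA(psi)) {
    return(list(class = "UNCLASSIFIABLE", delta_max = NA_real_,
                reversion_ratio = NA_real_))
  }
  p0 <- psi[[1L]]; p30 <- psi[[2L]]; p150 <- psi[[3L]]
  excursion <- p30 - p0
  reversion_ratio <- if (excursion == 0) NA_real_ else {
    abs(p150 - p0) / abs(excursion)
  }
  up_sig <- (isTRUE(sig_0v30) && p30 > p0) ||
    (isTRUE(sig_30v150) && p30 > p150)
  down_sig <- (isTRUE(sig_0v30) && p30 < p0) ||
    (isTRUE(sig_30v150) && p30 < p150)
  reverted <- !is.na(reversion_ratio) && reversion_ratio <= reversion_max
  cls <- if (up_sig && reverted) "IES_UP"
  else if (down_sig && reverted) "IES_DOWN"
  else if (up_sig || down_sig) "NON_TRANSIENT"
  else "UNCHANGED"
  list(class = cls, delta_max = max_delta_psi(psi),
       reversion_ratio = reversion_ratio)
}

#' Maximal PSI change of a 0/30/150-min trajectory
#'
#' The magnitude of a transient event is the larger (in absolute value) of
#' the 0-vs-30 and 150-vs-30 changes, signed as earlier-minus-30: for an
#' event retained at 30 min both candidates are negative, matching the
#' negative magnitude bins of [bin_magnitudes()]. Ties go to the 0-vs-30
#' value.
#'
#' @param psi Numeric triple `c(psi_t0, psi_t30, psi_t150)`.
#' @return Signed delta.
#' @export
max_delta_psi <- function(psi) {
  if (length(psi) != 3L || anyNA(psi)) stop("need a complete PSI triple")
  d1 <- psi[[1L]] - psi[[2L]]   # 0 vs 30
  d2 <- psi[[3L]] - psi[[2L]]   # 150 vs 30
  if (abs(d1) >= abs(d2)) d1 else d2
}

#' Histogram of transient-event magnitudes
#'
#' Bin centres run from -0.15 to -0.65 in 0.05 steps. Bins are half-open
#' on the magnitude scale: bin k covers magnitudes
#' `[|centre| - 0.025, |centre| + 0.025)`, i.e. signed values
#' `(centre - 0.025, centre + 0.025]`, so an edge value like -0.175 goes
#' to the -0.20 bin. Values outside `(-0.675, -0.125]` are counted as
#' out-of-range.
#'
#' @param deltas Numeric vector of signed maximal PSI changes.
#' @return List: `centers`, `counts`, `out_of_range`.
#' @export
bin_magnitudes <- function(deltas) {
  stopifnot(all(is.finite(deltas)))
  centers <- seq(-0.15, -0.65, by = -0.05)
  breaks_lo <- round(centers - 0.025, 10)
  breaks_hi <- round(centers + 0.025, 10)
  counts <- vapply(seq_along(centers), function(k) {
    sum(deltas > breaks_lo[[k]] & deltas <= breaks_hi[[k]])
  }, integer(1))
  list(centers = centers, counts = counts,
       out_of_range = length(deltas) - sum(counts))
}

#' Compare intron lengths between direction classes
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test with tie correction,
#' asking whether introns spliced more efficiently at 30 min differ in
#' length from introns retained at 30 min.
#'
#' @param up_lengths,down_lengths Non-empty numeric vectors of intron
#'   lengths (nt) for the retained-up and spliced-down classes.
#' @return List: `statistic` (U for the first group), `p_value`,
#'   `median_up`, `median_down`.
#' @export
compare_intron_lengths <- function(up_lengths, down_lengths) {
  if (length(up_lengths) == 0L || length(down_lengths) == 0L) {
    stop("both length groups must be non-empty")
  }
  has_ties <- anyDuplicated(c(up_lengths, down_lengths)) > 0L
  wt <- stats::wilcox.test(up_lengths, down_lengths, correct = FALSE,
                           exact = if (has_ties) FALSE else NULL)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_up = stats::median(up_lengths),
       median_down = stats::median(down_lengths))
}

#' PCA of samples on percent-intron-retention values
#'
#' Samples are observations, events are variables; the matrix is centred
#' per event and decomposed on the covariance (no per-event scaling).
#' Percent variance over all components sums to 100.
#'
#' @param psi_matrix Numeric matrix, events x samples (%IR or PSI),
#'   complete (drop events with undefined values first).
#' @param n_components Components to return coordinates for.
#' @return List: `coordinates` (samples x components), `percent_variance`
#'   (all components).
#' @export
pca_psi <- function(psi_matrix, n_components = 2L) {
  if (ncol(psi_matrix) < 2L) stop("PCA needs at least 2 samples")
  if (anyNA(psi_matrix)) stop("psi_matrix must be complete")
  pc <- stats::prcomp(t(psi_matrix), center = TRUE, scale. = FALSE)
  pv <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components, ncol(pc$x))
  list(coordinates = pc$x[, seq_len(k), drop = FALSE],
       percent_variance = pv)
}

#' Heatmap matrix of significant events
#'
#' Rows are events sorted by descending 0-to-30-min PSI change
#' (strongest retention gain first); columns are samples. Values are %IR
#' (`100 * psi`).
#'
#' @param counts Junction-count data.frame restricted to the events of
#'   interest.
#' @return Numeric matrix events x samples, row-sorted as above.
#' @export
heatmap_matrix <- function(counts) {
  pt <- psi_table(counts)
  samples <- unique(pt$sample_id)
  ids <- unique(pt$event_id)
  if (length(ids) == 0L) return(matrix(numeric(0), nrow = 0L, ncol = 0L))
  m <- matrix(NA_real_, nrow = length(ids), ncol = length(samples),
              dimnames = list(ids, samples))
  m[cbind(match(pt$event_id, ids), match(pt$sample_id, samples))] <-
    100 * pt$psi
  bc <- psi_by_condition(counts)
  ord <- order(-(bc$psi_t30 - bc$psi_t0)[match(ids, bc$event_id)])
  m[ord, , drop = FALSE]
}

#' Classify trajectories for all events of a time course
#'
#' Runs both pairwise comparisons (0 vs 30, 30 vs 150), applies the
#' significance filters per comparison, and classifies every event.
#'
#' @param counts Junction-count data.frame.
#' @param delta_min,fdr_max,min_reads Filters, see [filter_significant()].
#' @param reversion_max See [classify_trajectory()].
#' @return Data.frame: `event_id`, `class`, `psi_t0`, `psi_t30`,
#'   `psi_t150`, `delta_max`, `reversion_ratio`, `sig_0v30`, `sig_30v150`.
#' @export
detect_ies <- function(counts, delta_min = 0.15, fdr_max = 0.01,
                       min_reads = 100, reversion_max = 0.5) {
  d1 <- filter_significant(differential_table(counts, "t0", "t30"),
                           delta_min, fdr_max, min_reads)
  d2 <- filter_significant(differential_table(counts, "t30", "t150"),
                           delta_min, fdr_max, min_reads)
  psis <- psi_by_condition(counts)
  ids <- psis$event_id
  if (length(ids) == 0L) {
    return(data.frame(event_id = character(0), class = character(0),
                      psi_t0 = numeric(0), psi_t30 = numeric(0),
                      psi_t150 = numeric(0), delta_max = numeric(0),
                      reversion_ratio = numeric(0), sig_0v30 = logical(0),
                      sig_30v150 = logical(0), stringsAsFactors = FALSE))
  }
  s1 <- d1$significant[match(ids, d1$event_id)]
  s2 <- d2$significant[match(ids, d2$event_id)]
  rows <- lapply(seq_along(ids), function(i) {
    tri <- c(psis$psi_t0[[i]], psis$psi_t30[[i]], psis$psi_t150[[i]])
    cl <- classify_trajectory(tri, s1[[i]], s2[[i]], reversion_max)
    data.frame(event_id = ids[[i]], class = cl$class,
               psi_t0 = tri[[1L]], psi_t30 = tri[[2L]], psi_t150 = tri[[3L]],
               delta_max = cl$delta_max, reversion_ratio = cl$reversion_ratio,
               sig_0v30 = isTRUE(s1[[i]]), sig_30v150 = isTRUE(s2[[i]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
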