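#' Percent spliced in (PSI) from junction counts
#'
#' Junction-only estimator with effective inclusion length 2: a retained
#' intron contributes reads at two exon-intron boundaries (`I_up`, `I_down`)
#' while the spliced form contributes one exon-exon junction (`S`), so the
#' inclusion evidence is halved before forming the fraction:
#' `psi = ((I_up + I_down)/2) / ((I_up + I_down)/2 + S)`. Percent intron
#' retention is `100 * psi`.
#'
#' @param I_up,I_down,S Non-negative integer counts (vectorised).
#' @return PSI in `[0,1]`; `NA` where all three counts are zero.
#' @export
estimate_psi <- function(I_up, I_down, S) {
  if (any(c(I_up, I_down, S) < 0, na.rm = TRUE)) {
    stop("junction counts must be non-negative")
  }
  incl <- (I_up + I_down) / 2
  denom <- incl + S
  ifelse(denom == 0, NA_real_, incl / denom)
}

# G-test (likelihood-ratio) of equal binomial proportions on a pooled
# 2x2 table: rows = group, cols = (effective inclusion, spliced)
lrt_2x2 <- function(x) {
  if (any(rowSums(x) == 0)) return(NA_real_)
  e <- outer(rowSums(x), colSums(x)) / sum(x)
  terms <- x * log(x / e)
  terms[x == 0] <- 0
  g <- 2 * sum(terms)
  stats::pchisq(max(g, 0), df = 1L, lower.tail = FALSE)
}

#' Test for differential intron retention between two conditions
#'
#' Replicates are pooled within each group to a 2x2 table of
#' inclusion-supporting junction reads (`I_up + I_down`) versus spliced
#' reads (`S`) by group, tested with a likelihood-ratio test of equal
#' binomial proportions (chi-squared, 1 df). The read-level inclusion
#' fraction is a monotone function of PSI, so equal inclusion fractions
#' and equal PSI are the same null hypothesis; testing the raw read
#' counts keeps the test calibrated (the halved effective-inclusion
#' quantity enters only the PSI estimate, where it corrects the two-fold
#' junction advantage of the retained form -- halving the counts before a
#' chi-squared test would understate their sampling variance and make the
#' test conservative). `delta_psi` is the difference of mean
#' per-replicate PSI (B minus A), excluding replicates where PSI is
#' undefined.
#'
#' @param groupA,groupB Data.frames with one row per replicate and columns
#'   `I_up`, `I_down`, `S`.
#' @return List: `delta_psi`, `p_value`, `combined_junction_reads`
#'   (sum of all counts over both groups), `untestable` (TRUE when either
#'   group has no reads at all).
#' @export
test_differential <- function(groupA, groupB) {
  stopifnot(nrow(groupA) >= 1L, nrow(groupB) >= 1L)
  pool <- function(g) c(incl = sum(g$I_up) + sum(g$I_down),
                        S = sum(g$S))
  a <- pool(groupA); b <- pool(groupB)
  tab <- rbind(a, b)
  combined <- sum(groupA$I_up + groupA$I_down + groupA$S) +
    sum(groupB$I_up + groupB$I_down + groupB$S)
  psiA <- estimate_psi(groupA$I_up, groupA$I_down, groupA$S)
  psiB <- estimate_psi(groupB$I_up, groupB$I_down, groupB$S)
  untestable <- sum(a) == 0 || sum(b) == 0
  if (untestable) {
    return(list(delta_psi = NA_real_, p_value = NA_real_,
                combined_junction_reads = combined, untestable = TRUE))
  }
  list(delta_psi = mean(psiB, na.rm = TRUE) - mean(psiA, na.rm = TRUE),
       p_value = lrt_2x2(tab),
       combined_junction_reads = combined,
       untestable = FALSE)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Input order is preserved. Untestable events (NA p-values) must be
#' excluded by the caller before adjustment.
#'
#' @param p Numeric vector of p-values in `[0,1]`.
#' @return q-values in input order.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Run the differential test for every event between two conditions
#'
#' @param counts Junction-count data.frame (columns `event_id`,
#'   `sample_id`, `condition`, `replicate`, `I_up`, `I_down`, `S`).
#' @param cond_a,cond_b Condition labels for groups A and B.
#' @return Data.frame: `event_id`, `delta_psi`, `p_value`, `q_value`,
#'   `combined_junction_reads`, `untestable`. q-values are BH-adjusted
#'   over the testable events of this comparison only.
#' @export
differential_table <- function(counts, cond_a, cond_b) {
  validate_counts(counts)
  ids <- unique(counts$event_id)
  if (length(ids) == 0L) {
    return(data.frame(event_id = character(0), delta_psi = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      combined_junction_reads = numeric(0),
                      untestable = logical(0), stringsAsFactors = FALSE))
  }
  idx <- split(seq_len(nrow(counts)),
               factor(counts$event_id, levels = ids))
  res <- lapply(idx, function(i) {
    sub <- counts[i, , drop = FALSE]
    test_differential(sub[sub$condition == cond_a, , drop = FALSE],
                      sub[sub$condition == cond_b, , drop = FALSE])
  })
  out <- data.frame(
    event_id = ids,
    delta_psi = vapply(res, `[[`, numeric(1), "delta_psi"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    q_value = NA_real_,
    combined_junction_reads = vapply(res, `[[`, numeric(1),
                                     "combined_junction_reads"),
    untestable = vapply(res, `[[`, logical(1), "untestable"),
    stringsAsFactors = FALSE)
  ok <- !out$untestable & !is.na(out$p_value)
  out$q_value[ok] <- adjust_bh(out$p_value[ok])
  out
}

#' Apply the significance filters for one comparison
#'
#' An event passes when `|delta_psi| > delta_min`, `q_value < fdr_max`
#' and it has at least `min_reads` combined junction reads across the
#' tested samples.
#'
#' @param results Data.frame from [differential_table()].
#' @param delta_min Minimum absolute PSI difference (default 0.15).
#' @param fdr_max FDR ceiling (default 0.01).
#' @param min_reads Minimum combined junction reads (default 100).
#' @return `results` with a logical `significant` column.
#' @export
filter_significant <- function(results, delta_min = 0.15, fdr_max = 0.01,
                               min_reads = 100) {
  results$significant <- !results$untestable &
    !is.na(results$q_value) &
    abs(results$delta_psi) > delta_min &
    results$q_value < fdr_max &
    results$combined_junction_reads >= min_reads
  results
}

#' Per-sample PSI table from junction counts
#'
#' @param counts Junction-count data.frame.
#' @return `counts` with `inclusion_effective` and `psi` columns added.
#' @export
psi_table <- function(counts) {
  validate_counts(counts)
  counts$inclusion_effective <- (counts$I_up + counts$I_down) / 2
  counts$psi <- estimate_psi(counts$I_up, counts$I_down, counts$S)
  counts
}

#' Mean PSI per event and condition
#'
#' @param counts Junction-count data.frame.
#' @return Data.frame `event_id`, `psi_t0`, `psi_t30`, `psi_t150`
#'   (replicate means; NA replicates dropped).
#' @export
psi_by_condition <- function(counts) {
  pt <- psi_table(counts)
  if (nrow(pt) == 0L) {
    return(data.frame(event_id = character(0), psi_t0 = numeric(0),
                      psi_t30 = numeric(0), psi_t150 = numeric(0),
                      stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(psi ~ event_id + condition, data = pt,
                          FUN = mean, na.rm = TRUE, na.action = NULL)
  wide <- stats::reshape(agg, idvar = "event_id", timevar = "condition",
                         direction = "wide")
  names(wide) <- sub("^psi\\.", "psi_", names(wide))
  for (col in c("psi_t0", "psi_t30", "psi_t150")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
    wide[[col]][is.nan(wide[[col]])] <- NA_real_
  }
  rownames(wide) <- NULL
  wide[, c("event_id", "psi_t0", "psi_t30", "psi_t150")]
}

validate_counts <- function(counts) {
  need <- c("event_id", "sample_id", "condition", "replicate",
            "I_up", "I_down", "S")
  miss <- setdiff(need, names(counts))
  if (length(miss) > 0L) {
    stop("counts table lacks columns: ", paste(miss, collapse = ", "))
  }
  if (any(counts$I_up < 0 | counts$I_down < 0 | counts$S < 0)) {
    stop("junction counts must be non-negative")
  }
  invisible(counts)
}

#' Read a junction-count TSV
#'
#' Expected header: `event_id, sample_id, condition, replicate, I_up,
#' I_down, S`.
#'
#' @param path TSV path.
#' @return Validated junction-count data.frame.
#' @export
read_junction_counts <- function(path) {
  counts <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_counts(counts)
  counts
}
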