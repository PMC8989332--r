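#' Classify scanned marker pairs against the true architecture
#'
#' Labels each pair of a [pairwise_scan()] result as `"dmi_pair"` (exactly
#' the two loci of a simulated DMI), `"dmi_chrom"` (at least one marker on
#' a chromosome carrying a DMI locus, but not a true pair) or `"neutral"`
#' (both markers on DMI-free chromosomes). Used by the evaluation harness
#' to compute true- and false-positive rates.
#'
#' @param scan A [pairwise_scan()] result whose marker indices refer to
#'   `arch$markers`.
#' @param arch The [genome_architecture] the data were simulated from.
#' @param dmis The true [dmi_architecture] (or `NULL` for a neutral
#'   genome).
#' @return `scan` with an added `class` column.
#' @export
classify_pairs <- function(scan, arch, dmis) {
  cls <- rep("neutral", nrow(scan))
  if (!is.null(dmis) && nrow(dmis) > 0) {
    dmi_chroms <- unique(arch$markers$chrom[c(dmis$locus_A, dmis$locus_B)])
    on_dmi <- scan$chrom1 %in% dmi_chroms | scan$chrom2 %in% dmi_chroms
    cls[on_dmi] <- "dmi_chrom"
    key <- paste(pmin(scan$marker1, scan$marker2),
                 pmax(scan$marker1, scan$marker2))
    true_key <- paste(pmin(dmis$locus_A, dmis$locus_B),
                      pmax(dmis$locus_A, dmis$locus_B))
    cls[key %in% true_key] <- "dmi_pair"
  }
  scan$class <- cls
  scan
}

# Wald binomial CI clipped to [0, 1]
.wald_ci <- function(p, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(p * (1 - p) / n)
  c(lower = max(0, p - z * se), upper = min(1, p + z * se))
}

#' Sensitivity and specificity of DMI detection across replicates
#'
#' Sensitivity is the fraction of replicate simulations in which the true
#' DMI pair is flagged; specificity is one minus the fraction in which a
#' designated neutral pair is flagged. 95% confidence intervals are Wald
#' intervals \eqn{\hat p \pm 1.96 \sqrt{\hat p (1-\hat p)/n}}, clipped to
#' \[0, 1\].
#'
#' @param true_detected Logical vector over replicates: was the true DMI
#'   pair flagged?
#' @param neutral_detected Optional logical vector over replicates: was a
#'   neutral pair flagged?
#' @param conf Confidence level (default 0.95).
#' @return A data frame with one row per metric: `metric`, `estimate`,
#'   `lower`, `upper`, `n`.
#' @export
sensitivity_specificity <- function(true_detected, neutral_detected = NULL,
                                    conf = 0.95) {
  rows <- list()
  if (!is.null(true_detected)) {
    n <- length(true_detected)
    if (n == 0) stop("no replicates")
    p <- mean(true_detected)
    ci <- .wald_ci(p, n, conf)
    rows$sensitivity <- data.frame(metric = "sensitivity", estimate = p,
                                   lower = ci[1], upper = ci[2], n = n)
  }
  if (!is.null(neutral_detected)) {
    n <- length(neutral_detected)
    p <- 1 - mean(neutral_detected)
    ci <- .wald_ci(p, n, conf)
    rows$specificity <- data.frame(metric = "specificity", estimate = p,
                                   lower = ci[1], upper = ci[2], n = n)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' False- and true-positive rates with resampled confidence intervals
#'
#' Pools classified pair statistics across replicate scans (see
#' [classify_pairs()]) and computes, per X(2) threshold, the flagged
#' fraction of true DMI pairs (true-positive rate) and of non-DMI pairs on
#' DMI-bearing and neutral chromosomes (false-positive rates). Confidence
#' intervals come from resampling `resample_size` pairs `n_resample` times
#' and taking the 2.5/97.5 percentiles.
#'
#' @param pairs A data frame of pooled classified pairs (rbind of
#'   [classify_pairs()] outputs) with columns `X2`, `Dprime`, `usable`,
#'   `class`.
#' @param thresholds X(2) thresholds to evaluate (default -0.005).
#' @param n_resample Number of resampling rounds (default 1000).
#' @param resample_size Pairs per resampling round (default 2000).
#' @param conf Confidence level (default 0.95).
#' @return A data frame: `threshold`, `class`, `rate`, `lower`, `upper`,
#'   `n_pairs`.
#' @export
fp_tp_rates <- function(pairs, thresholds = -0.005, n_resample = 1000,
                        resample_size = 2000, conf = 0.95) {
  out <- list()
  for (thr in thresholds) {
    flag <- pairs$usable & !is.na(pairs$X2) & pairs$X2 < thr &
      !is.na(pairs$Dprime) & pairs$Dprime < 0
    for (cl in intersect(c("dmi_pair", "dmi_chrom", "neutral"),
                         unique(pairs$class))) {
      sel <- pairs$class == cl & pairs$usable
      n <- sum(sel)
      if (n == 0) next
      rate <- mean(flag[sel])
      f <- flag[sel]
      bs <- vapply(seq_len(n_resample), function(i)
        mean(f[sample.int(n, min(resample_size, n), replace = TRUE)]),
        numeric(1))
      qs <- stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2))
      out[[length(out) + 1L]] <- data.frame(
        threshold = thr, class = cl, rate = rate,
        lower = qs[1], upper = qs[2], n_pairs = n)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Signal decay with distance to the true DMI loci
#'
#' For increasingly large genetic windows around the true interacting
#' loci, computes the fraction of flagged pairs among pairs whose two
#' markers fall within the window of the two partner loci (either
#' orientation, any DMI), and the median of that fraction across
#' replicates. The whole-genome window reproduces the global flagged
#' fraction.
#'
#' @param scans A list of classified scan results (one per replicate) that
#'   carry `cM1`/`cM2` columns.
#' @param arch The [genome_architecture].
#' @param dmis The true [dmi_architecture].
#' @param windows_cM Window half-widths in cM (default
#'   `c(1, 2, 5, 10, 20, 50, Inf)`).
#' @return A data frame: `window_cM`, `median_fraction`, `global_fraction`
#'   (median across replicates of the genome-wide flagged fraction).
#' @export
distance_profile <- function(scans, arch, dmis,
                             windows_cM = c(1, 2, 5, 10, 20, 50, Inf)) {
  stopifnot(!is.null(dmis), nrow(dmis) > 0)
  mk <- arch$markers
  per_rep <- lapply(scans, function(sc) {
    flag <- sc$usable & sc$candidate
    glob <- mean(flag[sc$usable])
    frac <- vapply(windows_cM, function(w) {
      inwin <- rep(FALSE, nrow(sc))
      for (r in seq_len(nrow(dmis))) {
        la <- dmis$locus_A[r]; lb <- dmis$locus_B[r]
        near <- function(midx, locus) {
          same <- mk$chrom[midx] == mk$chrom[locus]
          if (is.infinite(w)) rep(TRUE, length(midx))
          else same & abs(mk$cM[midx] - mk$cM[locus]) <= w
        }
        inwin <- inwin |
          (near(sc$marker1, la) & near(sc$marker2, lb)) |
          (near(sc$marker1, lb) & near(sc$marker2, la))
      }
      sel <- inwin & sc$usable
      if (!any(sel)) NA_real_ else mean(flag[sel])
    }, numeric(1))
    list(frac = frac, glob = glob)
  })
  fr <- do.call(rbind, lapply(per_rep, `[[`, "frac"))
  data.frame(window_cM = windows_cM,
             median_fraction = apply(fr, 2, stats::median, na.rm = TRUE),
             global_fraction = stats::median(
               vapply(per_rep, `[[`, numeric(1), "glob"), na.rm = TRUE))
}
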