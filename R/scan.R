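#' Ancestry hard-call matrix
#'
#' Container for the genome scan's input: per-individual, per-marker
#' ancestry dosage (0, 1 or 2 copies of parent-1 ancestry, `NA` for
#' missing) plus marker metadata. Markers are stored in rows, sorted by
#' chromosome then position; duplicate (chromosome, position) entries are
#' rejected.
#'
#' @param dosage Marker-by-individual matrix with entries in
#'   \{0, 1, 2, NA\}.
#' @param chrom,pos Chromosome and 1-based bp position per marker.
#' @param cM Optional genetic position per marker.
#' @return A list of class `"ancestry_matrix"` with `dosage` and `markers`.
#' @export
ancestry_matrix <- function(dosage, chrom, pos, cM = NULL) {
  dosage <- as.matrix(dosage)
  bad <- !(dosage %in% c(0L, 1L, 2L, NA))
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("invalid dosage %s at marker row %d, individual %d",
                 format(dosage[i]), (i - 1) %% nrow(dosage) + 1,
                 (i - 1) %/% nrow(dosage) + 1))
  }
  if (length(chrom) != nrow(dosage) || length(pos) != nrow(dosage))
    stop("chrom and pos must have one entry per marker row")
  markers <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos))
  if (!is.null(cM)) markers$cM <- as.numeric(cM)
  if (anyDuplicated(markers[c("chrom", "pos")]))
    stop("duplicate (chrom, pos) marker entries")
  o <- order(markers$chrom, markers$pos)
  if (is.unsorted(o)) warning("markers were not sorted; sorting now")
  markers <- markers[o, , drop = FALSE]
  rownames(markers) <- NULL
  structure(list(dosage = dosage[o, , drop = FALSE], markers = markers),
            class = "ancestry_matrix")
}

#' @export
print.ancestry_matrix <- function(x, ...) {
  cat(sprintf("Ancestry matrix: %d markers x %d individuals (%d chromosomes)\n",
              nrow(x$dosage), ncol(x$dosage),
              length(unique(x$markers$chrom))))
  invisible(x)
}

# Normalize scan input: ancestry_matrix or ancestry_sample.
# Returns list(dosage, markers, h1, h2) with h1/h2 NULL when unphased.
.scan_input <- function(x) {
  if (inherits(x, "ancestry_sample"))
    list(dosage = x$dosage,
         markers = data.frame(chrom = x$markers$chrom, pos = x$markers$bp,
                              cM = x$markers$cM),
         h1 = x$h1, h2 = x$h2)
  else if (inherits(x, "ancestry_matrix"))
    list(dosage = x$dosage, markers = x$markers, h1 = NULL, h2 = NULL)
  else stop("expected an ancestry_matrix or ancestry_sample")
}

# Subset markers (rows) of either input type, preserving class.
.subset_markers <- function(x, keep) {
  if (inherits(x, "ancestry_sample")) {
    x$h1 <- x$h1[keep, , drop = FALSE]
    x$h2 <- x$h2[keep, , drop = FALSE]
    x$dosage <- x$dosage[keep, , drop = FALSE]
    x$markers <- x$markers[keep, , drop = FALSE]
    rownames(x$markers) <- NULL
  } else {
    x$dosage <- x$dosage[keep, , drop = FALSE]
    x$markers <- x$markers[keep, , drop = FALSE]
    rownames(x$markers) <- NULL
  }
  x
}

#' Locus quality filter for the genome scan
#'
#' Retains a marker if the frequency of each homozygous ancestry genotype
#' exceeds `hom_min` (both `> 0.05` by default) and the combined fraction
#' of heterozygous-or-missing individuals is below `het_miss_max` (60%).
#' Frequencies are computed over all individuals in the matrix, which is
#' assumed to already exclude nearly-pure parental individuals.
#'
#' @param x An [ancestry_matrix] or [sample_ancestry()] result.
#' @param hom_min Minimum frequency of each homozygous genotype.
#' @param het_miss_max Maximum combined heterozygous-or-missing fraction.
#' @return `x` with failing markers removed; warns if none survive.
#' @export
filter_loci <- function(x, hom_min = 0.05, het_miss_max = 0.60) {
  inp <- .scan_input(x)
  n <- ncol(inp$dosage)
  f0 <- rowSums(inp$dosage == 0, na.rm = TRUE) / n
  f2 <- rowSums(inp$dosage == 2, na.rm = TRUE) / n
  fh <- (rowSums(inp$dosage == 1, na.rm = TRUE) +
           rowSums(is.na(inp$dosage))) / n
  keep <- f0 > hom_min & f2 > hom_min & fh < het_miss_max
  if (!any(keep)) warning("no markers pass the locus filters")
  .subset_markers(x, keep)
}

#' Thin markers by ancestry-dosage linkage disequilibrium
#'
#' Single deterministic forward pass in genomic order: for each retained
#' marker, the squared Pearson correlation of dosages (pairwise-complete
#' individuals) is computed against every downstream marker within
#' `window_bp`; the later marker of any pair with \eqn{r^2} above the
#' threshold is dropped. The earlier marker is always kept.
#'
#' @inheritParams filter_loci
#' @param r2_threshold Squared-correlation threshold (default 0.9).
#' @param window_bp Window size in bases (default 10 kb).
#' @return `x` with thinned markers.
#' @export
ld_thin <- function(x, r2_threshold = 0.9, window_bp = 10000) {
  inp <- .scan_input(x)
  mk <- inp$markers
  keep <- rep(TRUE, nrow(mk))
  for (ch in unique(mk$chrom)) {
    idx <- which(mk$chrom == ch)          # already sorted by pos
    for (a in seq_along(idx)) {
      i <- idx[a]
      if (!keep[i]) next
      b <- a + 1L
      while (b <= length(idx) && mk$pos[idx[b]] - mk$pos[i] <= window_bp) {
        j <- idx[b]
        if (keep[j]) {
          r <- suppressWarnings(
            stats::cor(inp$dosage[i, ], inp$dosage[j, ],
                       use = "pairwise.complete.obs"))
          if (!is.na(r) && r^2 > r2_threshold) keep[j] <- FALSE
        }
        b <- b + 1L
      }
    }
  }
  .subset_markers(x, keep)
}

# All-pairs two-locus statistics from per-class haplotype count matrices.
# n_ab, n_Ab, n_aB, n_AB: m x m matrices of haplotype counts for each
# ordered pair (row marker = first locus). Returns a list of m x m
# matrices of statistics.
.pairwise_stats <- function(n_ab, n_Ab, n_aB, n_AB) {
  tot <- n_ab + n_Ab + n_aB + n_AB
  safe_tot <- ifelse(tot > 0, tot, NA_real_)
  g_ab <- n_ab / safe_tot; g_Ab <- n_Ab / safe_tot
  g_aB <- n_aB / safe_tot; g_AB <- n_AB / safe_tot
  p_a <- g_ab + g_aB; p_A <- 1 - p_a
  p_b <- g_ab + g_Ab; p_B <- 1 - p_b
  h_A <- 1 - p_a^2 - p_A^2
  h_B <- 1 - p_b^2 - p_B^2
  var_expected <- h_A + h_B - h_A^2 - h_B^2
  pp_ab <- p_a * p_b; pp_Ab <- p_A * p_b
  pp_aB <- p_a * p_B; pp_AB <- p_A * p_B
  delta2 <- 2 * ((g_ab^2 - pp_ab^2) + (g_Ab^2 - pp_Ab^2) +
                   (g_aB^2 - pp_aB^2) + (g_AB^2 - pp_AB^2))
  X2 <- ifelse(!is.na(var_expected) & var_expected > 0,
               delta2 / var_expected, NA_real_)
  D <- g_AB * g_ab - g_aB * g_Ab
  absDmax <- ifelse(D < 0, pmin(pp_AB, pp_ab), pmin(pp_Ab, pp_aB))
  Dprime <- ifelse(is.na(D) | D == 0, ifelse(is.na(D), NA_real_, 0),
                   D / absDmax)
  deltaD2 <- (g_ab^2 - pp_ab^2) - (g_AB^2 - pp_AB^2)
  list(tot = tot, X2 = X2, D = D, Dprime = Dprime, deltaD2 = deltaD2,
       g_ab = g_ab, g_Ab = g_Ab, g_aB = g_aB, g_AB = g_AB)
}

# G test on the allele-by-allele table for all pairs at once.
.pairwise_g <- function(n_ab, n_Ab, n_aB, n_AB) {
  tot <- n_ab + n_Ab + n_aB + n_AB
  ra <- n_ab + n_aB; rA <- n_Ab + n_AB     # allele margins at first locus
  cb <- n_ab + n_Ab; cB <- n_aB + n_AB
  gterm <- function(O, E) ifelse(O > 0, O * log(O / E), 0)
  E_ab <- ra * cb / tot; E_Ab <- rA * cb / tot
  E_aB <- ra * cB / tot; E_AB <- rA * cB / tot
  G <- 2 * (gterm(n_ab, E_ab) + gterm(n_Ab, E_Ab) +
              gterm(n_aB, E_aB) + gterm(n_AB, E_AB))
  mono <- ra == 0 | rA == 0 | cb == 0 | cB == 0 | tot == 0
  G[mono] <- NA_real_
  p <- stats::pchisq(G, df = 1, lower.tail = FALSE)
  list(G = G, p = p)
}

#' Pairwise DMI genome scan
#'
#' Computes the two-locus statistics of [two_locus_stats()] for every
#' unordered pair of (up to `max_markers` uniformly sampled) markers and
#' flags candidate DMI pairs by the joint rule \eqn{X^{(2)} <} `x2_threshold`
#' and \eqn{D' < 0}. In `"phased"` mode haplotype frequencies come from the
#' phased ancestry haplotypes; in `"pseudo_phased"` mode only individuals
#' homozygous at both loci contribute (two identical haplotypes each), and
#' a pair is usable only if at least `min_haplotypes` haplotypes are
#' recovered.
#'
#' For each pair the first (genomically earlier) marker plays the role of
#' the locus carrying allele `a/A` and the second that of `b/B`; ancestry 1
#' (parent 1) maps to the lowercase allele at the first locus and to the
#' capital allele at the second, so the parental haplotypes are the
#' same-ancestry classes and the recombinants the mixed-ancestry classes.
#' `X2` and `Dprime` do not depend on this labelling; the sign of `deltaD2`
#' does (it flips under parent relabelling).
#'
#' @param x An [ancestry_matrix] or [sample_ancestry()] result (phased mode
#'   requires the latter, or phased data loaded with
#'   [read_phased_table()]).
#' @param mode `"phased"` or `"pseudo_phased"`.
#' @param max_markers Markers to sample for the scan (default 700; `Inf`
#'   scans all markers).
#' @param x2_threshold Candidate threshold on X(2) (default -0.005).
#' @param min_haplotypes Minimum recovered haplotypes for a pseudo-phased
#'   pair to be usable (default 50).
#' @param g_test Also compute the G test of allelic independence per pair.
#' @param seed Optional seed for the marker subsample.
#' @return A data frame of class `"dmi_scan"` with one row per pair:
#'   marker indices and coordinates, `n_hap`, `X2`, `Dprime`, `deltaD2`,
#'   optional `G` and `p_G`, `usable` and `candidate`. Attributes record
#'   the mode, thresholds, and sampled marker indices.
#' @export
pairwise_scan <- function(x, mode = c("phased", "pseudo_phased"),
                          max_markers = 700, x2_threshold = -0.005,
                          min_haplotypes = 50, g_test = FALSE,
                          seed = NULL) {
  mode <- match.arg(mode)
  inp <- .scan_input(x)
  L <- nrow(inp$markers)
  if (L < 2) stop("need at least two markers")
  if (!is.null(seed)) set.seed(seed)
  idx <- if (is.finite(max_markers) && L > max_markers)
    sort(sample.int(L, max_markers)) else seq_len(L)
  m <- length(idx)
  mk <- inp$markers[idx, , drop = FALSE]

  if (mode == "phased") {
    if (is.null(inp$h1))
      stop("phased mode requires phased ancestry haplotypes")
    H <- cbind(inp$h1[idx, , drop = FALSE], inp$h2[idx, , drop = FALSE])
    storage.mode(H) <- "double"
    nh <- ncol(H)
    C11 <- H %*% t(H)
    r <- rowSums(H)
    n11 <- C11
    n10 <- matrix(r, m, m) - C11
    n01 <- matrix(r, m, m, byrow = TRUE) - C11
    n00 <- nh - n11 - n10 - n01
    # ancestry (1,1) = parental aB; (0,0) = parental Ab;
    # (1,0) = recombinant ab; (0,1) = recombinant AB
    n_ab <- n10; n_Ab <- n00; n_aB <- n11; n_AB <- n01
  } else {
    dos <- inp$dosage[idx, , drop = FALSE]
    H1 <- matrix(0, m, ncol(dos)); H1[which(dos == 2)] <- 1
    H0 <- matrix(0, m, ncol(dos)); H0[which(dos == 0)] <- 1
    C11 <- 2 * (H1 %*% t(H1)); C10 <- 2 * (H1 %*% t(H0))
    C01 <- 2 * (H0 %*% t(H1)); C00 <- 2 * (H0 %*% t(H0))
    n_ab <- C10; n_Ab <- C00; n_aB <- C11; n_AB <- C01
  }

  st <- .pairwise_stats(n_ab, n_Ab, n_aB, n_AB)
  usable <- if (mode == "pseudo_phased") st$tot >= min_haplotypes
            else st$tot > 0
  ut <- upper.tri(st$X2)
  ij <- which(ut, arr.ind = TRUE)
  out <- data.frame(
    marker1 = idx[ij[, 1]], marker2 = idx[ij[, 2]],
    chrom1 = mk$chrom[ij[, 1]], pos1 = mk$pos[ij[, 1]],
    chrom2 = mk$chrom[ij[, 2]], pos2 = mk$pos[ij[, 2]],
    n_hap = st$tot[ut], X2 = st$X2[ut], Dprime = st$Dprime[ut],
    deltaD2 = st$deltaD2[ut], usable = usable[ut] & !is.na(st$X2[ut]),
    stringsAsFactors = FALSE)
  if (!is.null(mk$cM)) { out$cM1 <- mk$cM[ij[, 1]]; out$cM2 <- mk$cM[ij[, 2]] }
  if (g_test) {
    gt <- .pairwise_g(n_ab, n_Ab, n_aB, n_AB)
    out$G <- gt$G[ut]; out$p_G <- gt$p[ut]
  }
  out$candidate <- out$usable & !is.na(out$X2) & out$X2 < x2_threshold &
    !is.na(out$Dprime) & out$Dprime < 0
  attr(out, "mode") <- mode
  attr(out, "x2_threshold") <- x2_threshold
  attr(out, "min_haplotypes") <- min_haplotypes
  attr(out, "marker_index") <- idx
  class(out) <- c("dmi_scan", "data.frame")
  out
}

#' @export
print.dmi_scan <- function(x, ...) {
  cat(sprintf(
    "DMI scan (%s): %d marker pairs, %d usable, %d candidate(s) at X(2) < %g & D' < 0\n",
    attr(x, "mode"), nrow(x), sum(x$usable), sum(x$candidate),
    attr(x, "x2_threshold")))
  invisible(x)
}

#' @export
summary.dmi_scan <- function(object, ...) {
  list(n_pairs = nrow(object), n_usable = sum(object$usable),
       n_candidates = sum(object$candidate),
       min_X2 = suppressWarnings(min(object$X2[object$usable],
                                     na.rm = TRUE)),
       mode = attr(object, "mode"),
       x2_threshold = attr(object, "x2_threshold"))
}

#' G-test genome scan
#'
#' Applies the G test of allelic independence to the same haplotype
#' estimates as [pairwise_scan()], the comparison baseline for X(2). By
#' default only interchromosomal pairs are returned, since the test assumes
#' unlinked loci.
#'
#' @inheritParams pairwise_scan
#' @param interchromosomal_only Drop within-chromosome pairs (default TRUE).
#' @param ... Passed to [pairwise_scan()].
#' @return A `"dmi_scan"` data frame including `G` and `p_G` columns.
#' @export
g_test_scan <- function(x, mode = c("phased", "pseudo_phased"),
                        interchromosomal_only = TRUE, ...) {
  sc <- pairwise_scan(x, mode = mode, g_test = TRUE, ...)
  if (interchromosomal_only) {
    keep <- sc$chrom1 != sc$chrom2
    at <- attributes(sc)
    sc <- sc[keep, , drop = FALSE]
    for (a in setdiff(names(at), c("names", "row.names", "class")))
      attr(sc, a) <- at[[a]]
    class(sc) <- c("dmi_scan", "data.frame")
  }
  sc
}

#' Assign candidate marker pairs to megabase bin pairs
#'
#' Maps each marker to the half-open physical window
#' \eqn{[k \cdot binsize, (k+1) \cdot binsize)} on its chromosome
#' (`bin = floor(pos / bin_size)`, 0-based) and aggregates marker pairs
#' into bin pairs. A bin pair is a putative DMI if it contains at least one
#' candidate marker pair; pairs whose two markers fall in the same bin are
#' excluded.
#'
#' @param scan A [pairwise_scan()] result.
#' @param bin_size_bp Bin width in bases (default 1 Mb).
#' @return A data frame of class `"dmi_bins"`: `chrom1`, `bin1`, `chrom2`,
#'   `bin2`, `n_pairs` (tested marker pairs), `n_candidates`, `candidate`.
#' @export
bin_pairs <- function(scan, bin_size_bp = 1e6) {
  b1 <- floor(scan$pos1 / bin_size_bp)
  b2 <- floor(scan$pos2 / bin_size_bp)
  # canonical bin-pair order
  k1 <- paste(scan$chrom1, b1, sep = ":")
  k2 <- paste(scan$chrom2, b2, sep = ":")
  swap <- k2 < k1
  a <- ifelse(swap, k2, k1); b <- ifelse(swap, k1, k2)
  keep <- a != b
  key <- paste(a[keep], b[keep], sep = "|")
  usable <- scan$usable[keep]
  cand <- scan$candidate[keep]
  if (length(key) == 0L) {
    out <- data.frame(chrom1 = character(0), bin1 = integer(0),
                      chrom2 = character(0), bin2 = integer(0),
                      n_pairs = integer(0), n_candidates = integer(0),
                      candidate = logical(0))
    attr(out, "bin_size_bp") <- bin_size_bp
    class(out) <- c("dmi_bins", "data.frame")
    return(out)
  }
  agg <- data.frame(key = key, usable = usable, cand = cand)
  n_pairs <- tapply(agg$usable, agg$key, sum)
  n_cand <- tapply(agg$cand, agg$key, sum)
  keys <- names(n_pairs)
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  p1 <- do.call(rbind, strsplit(parts[, 1], ":", fixed = TRUE))
  p2 <- do.call(rbind, strsplit(parts[, 2], ":", fixed = TRUE))
  out <- data.frame(chrom1 = p1[, 1], bin1 = as.integer(p1[, 2]),
                    chrom2 = p2[, 1], bin2 = as.integer(p2[, 2]),
                    n_pairs = as.integer(n_pairs),
                    n_candidates = as.integer(n_cand),
                    candidate = as.integer(n_cand) > 0,
                    stringsAsFactors = FALSE)
  out <- out[out$n_pairs > 0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "bin_size_bp") <- bin_size_bp
  class(out) <- c("dmi_bins", "data.frame")
  out
}

#' Bootstrap support for candidate bin pairs
#'
#' Repeats the marker-subsampling scan `n_bootstrap` times, bins the
#' candidates, and calibrates a minimum occurrence count `k` by a binomial
#' test: with `p_bin` the median (over bootstraps) fraction of tested bin
#' pairs that are candidates, the probability of observing the same
#' candidate bin pair in at least `x` of `n_bootstrap` samples by chance is
#' the upper binomial tail at `p_bin`. `k` is the smallest count whose tail
#' p-value passes the Benjamini-Hochberg-style criterion
#' `p < (number of bin pairs with count >= k) / (total candidate bin-pair
#' occurrences across bootstraps) * fdr`. Bin pairs observed at least `k`
#' times are reported as supported putative DMIs.
#'
#' @inheritParams pairwise_scan
#' @param n_bootstrap Number of marker resamples (default 20).
#' @param markers_per_bootstrap Markers per resample (default 700).
#' @param fdr Target false discovery rate (default 0.001).
#' @param bin_size_bp Bin width in bases (default 1 Mb).
#' @param seed Optional master seed for the bootstrap streams.
#' @return A list of class `"dmi_support"`: `bins` (bin pairs with
#'   occurrence `count`, binomial `p`, `supported`), `k`, `p_bin`,
#'   `n_bootstrap` and `total_candidates`.
#' @export
bootstrap_support <- function(x, mode = c("phased", "pseudo_phased"),
                              n_bootstrap = 20, markers_per_bootstrap = 700,
                              x2_threshold = -0.005, min_haplotypes = 50,
                              fdr = 0.001, bin_size_bp = 1e6, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  counts <- integer(0)
  p_b <- numeric(n_bootstrap)
  total_sig <- 0L
  for (b in seq_len(n_bootstrap)) {
    sc <- pairwise_scan(x, mode = mode,
                        max_markers = markers_per_bootstrap,
                        x2_threshold = x2_threshold,
                        min_haplotypes = min_haplotypes)
    bins <- bin_pairs(sc, bin_size_bp)
    p_b[b] <- if (nrow(bins) > 0) mean(bins$candidate) else 0
    ck <- paste(bins$chrom1, bins$bin1, bins$chrom2,
                bins$bin2, sep = "|")[bins$candidate]
    total_sig <- total_sig + length(ck)
    for (k in ck) counts[k] <- if (k %in% names(counts)) counts[[k]] + 1L else 1L
  }
  p_bin <- stats::median(p_b)
  if (p_bin == 0) {
    warning("median candidate fraction is 0; using k = 1")
    k_min <- 1L
  } else {
    k_min <- NA_integer_
    for (kk in seq_len(n_bootstrap)) {
      pval <- stats::pbinom(kk - 1, n_bootstrap, p_bin, lower.tail = FALSE)
      n_at <- sum(counts >= kk)
      crit <- if (total_sig > 0) n_at / total_sig * fdr else 0
      if (!is.na(pval) && pval < crit) { k_min <- kk; break }
    }
    if (is.na(k_min)) k_min <- n_bootstrap + 1L
  }
  bins_df <- if (length(counts) > 0) {
    parts <- do.call(rbind, strsplit(names(counts), "|", fixed = TRUE))
    data.frame(chrom1 = parts[, 1], bin1 = as.integer(parts[, 2]),
               chrom2 = parts[, 3], bin2 = as.integer(parts[, 4]),
               count = as.integer(counts),
               p = stats::pbinom(as.integer(counts) - 1, n_bootstrap,
                                 p_bin, lower.tail = FALSE),
               supported = as.integer(counts) >= k_min,
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom1 = character(0), bin1 = integer(0),
               chrom2 = character(0), bin2 = integer(0),
               count = integer(0), p = numeric(0), supported = logical(0))
  }
  structure(list(bins = bins_df[order(-bins_df$count), , drop = FALSE],
                 k = k_min, p_bin = p_bin, n_bootstrap = n_bootstrap,
                 total_candidates = total_sig),
            class = "dmi_support")
}

#' @export
print.dmi_support <- function(x, ...) {
  cat(sprintf(
    "Bootstrap support over %d resamples: p_bin = %.4g, k = %d\n",
    x$n_bootstrap, x$p_bin, x$k))
  cat(sprintf("  %d candidate bin pair(s); %d supported (count >= k)\n",
              nrow(x$bins), sum(x$bins$supported)))
  invisible(x)
}
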