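#' Two-locus haplotype frequency distribution
#'
#' Constructs a validated frequency vector for the four two-locus haplotypes
#' of a hybrid population. The two loci carry alleles \eqn{a/A} and
#' \eqn{b/B}; in the admixture setting the parental haplotypes are `Ab` and
#' `aB` and the recombinant haplotypes are `ab` and `AB`.
#'
#' @param ab,Ab,aB,AB Haplotype frequencies, each in \[0, 1\]. Alternatively
#'   `ab` may be a numeric vector of length 4 in the order
#'   (`ab`, `Ab`, `aB`, `AB`).
#' @param tol Tolerance for the sum-to-one check; frequencies within `tol`
#'   of a valid simplex are renormalized.
#' @return A named numeric vector of class `"haplotype_freqs"` with
#'   components `ab`, `Ab`, `aB`, `AB` summing to exactly 1.
#' @examples
#' haplotype_freqs(0.5, 0.2, 0.3, 0)
#' @export
haplotype_freqs <- function(ab, Ab = NULL, aB = NULL, AB = NULL,
                            tol = 1e-12) {
  g <- if (is.null(Ab) && length(ab) == 4L) as.numeric(ab)
       else c(ab, Ab, aB, AB)
  if (length(g) != 4L || !is.numeric(g) || anyNA(g))
    stop("need four non-missing haplotype frequencies")
  if (any(g < -tol) || any(g > 1 + tol))
    stop("haplotype frequencies must lie in [0, 1]")
  s <- sum(g)
  if (abs(s - 1) > 1e-6)
    stop("haplotype frequencies must sum to 1 (got ", format(s), ")")
  g <- pmin(pmax(g, 0), 1)
  g <- g / sum(g)
  names(g) <- c("ab", "Ab", "aB", "AB")
  class(g) <- "haplotype_freqs"
  g
}

#' @export
print.haplotype_freqs <- function(x, digits = 6, ...) {
  cat("Two-locus haplotype frequencies:\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

# Internal fast path: stats from an unclassed length-4 vector (ab, Ab, aB, AB).
# Returns a plain list; no validation.
.two_locus_core <- function(g) {
  g <- unname(g)
  p_A <- g[2] + g[4]; p_a <- 1 - p_A
  p_B <- g[3] + g[4]; p_b <- 1 - p_B
  h_A <- 1 - p_a^2 - p_A^2
  h_B <- 1 - p_b^2 - p_B^2
  var_expected <- h_A + h_B - h_A^2 - h_B^2
  pp <- c(p_a * p_b, p_A * p_b, p_a * p_B, p_A * p_B)
  D2 <- g^2 - pp^2
  delta2 <- 2 * sum(D2)
  D <- g[4] * g[1] - g[3] * g[2]
  if (D < 0) {
    Dmax <- max(-p_A * p_B, -p_a * p_b)
    Dprime <- D / abs(Dmax)
  } else if (D > 0) {
    Dmax <- min(p_A * p_b, p_a * p_B)
    Dprime <- D / abs(Dmax)
  } else Dprime <- 0
  X2 <- if (var_expected > 0) delta2 / var_expected else NA_real_
  list(p_a = p_a, p_A = p_A, p_b = p_b, p_B = p_B,
       h_A = h_A, h_B = h_B,
       var_expected = var_expected, delta2 = delta2, X2 = X2,
       D = D, Dprime = Dprime,
       D2_ab = D2[1], D2_Ab = D2[2], D2_aB = D2[3], D2_AB = D2[4],
       deltaD2 = D2[1] - D2[4])
}

#' Summary statistics for one locus pair
#'
#' Computes, from a two-locus haplotype distribution, all derived statistics
#' used for DMI detection: allele frequencies, single-locus heterozygosities
#' \eqn{h_A = 1 - p_a^2 - p_A^2} (and analogously \eqn{h_B}), the expected
#' variance of the number of heterozygous loci \eqn{K} under independence
#' \eqn{\sigma^2_{exp} = h_A + h_B - h_A^2 - h_B^2}, its deviation
#' \eqn{\Delta_2 = 2\sum_{ik}(g_{ik}^2 - p_i^2 p_k^2)}, the focal statistic
#' \eqn{X^{(2)} = \Delta_2 / \sigma^2_{exp}}, linkage disequilibrium
#' \eqn{D = g_{AB} g_{ab} - g_{aB} g_{Ab}} and its range-normalized form
#' \eqn{D'}, the per-haplotype squared-frequency deviations
#' \eqn{D2_{ik} = g_{ik}^2 - p_i^2 p_k^2}, and the recombinant imbalance
#' \eqn{\Delta D2 = D2_{ab} - D2_{AB}}.
#'
#' A negative \eqn{X^{(2)}} together with \eqn{D' < 0} indicates a deficit of
#' one recombinant haplotype relative to the other, the footprint of a
#' Dobzhansky-Muller incompatibility. When either locus is monomorphic
#' (\eqn{\sigma^2_{exp} = 0}) `X2` is `NA` and `defined` is `FALSE`. By
#' convention `Dprime = 0` when `D = 0`.
#'
#' @param g A [haplotype_freqs] vector (or anything it accepts).
#' @return A list of class `"two_locus_stats"`.
#' @examples
#' two_locus_stats(haplotype_freqs(0.5, 0.2, 0.3, 0))
#' @export
two_locus_stats <- function(g) {
  g <- haplotype_freqs(g)
  out <- .two_locus_core(unclass(g))
  out$g <- g
  out$defined <- !is.na(out$X2)
  class(out) <- "two_locus_stats"
  out
}

#' @export
print.two_locus_stats <- function(x, digits = 6, ...) {
  cat("Two-locus summary\n")
  cat(sprintf("  p_A = %.*g, p_B = %.*g\n", digits, x$p_A, digits, x$p_B))
  cat(sprintf("  D = %.*g, D' = %.*g\n", digits, x$D, digits, x$Dprime))
  if (x$defined)
    cat(sprintf("  X(2) = %.*g  (delta2 = %.*g, expected var = %.*g)\n",
                digits, x$X2, digits, x$delta2, digits, x$var_expected))
  else
    cat("  X(2) undefined: a locus is monomorphic\n")
  cat(sprintf("  deltaD2 = %.*g\n", digits, x$deltaD2))
  invisible(x)
}

#' Variance of two-locus heterozygosity by pair enumeration
#'
#' Brute-force oracle for the closed-form variance of \eqn{K}, the number of
#' heterozygous loci observed when two haplotypes are drawn at random from
#' the population. Enumerates the 10 unordered haplotype pairs, counts the
#' heterozygous loci \eqn{K \in \{0, 1, 2\}} for each, and returns
#' \eqn{\sum \mathrm{pr}(pair) (K - h)^2} where \eqn{h = h_A + h_B}.
#' Equals `var_expected + delta2` of [two_locus_stats()].
#'
#' @inheritParams two_locus_stats
#' @return The variance of \eqn{K} (a single number).
#' @export
var_K_enumeration <- function(g) {
  g <- unclass(haplotype_freqs(g))
  st <- .two_locus_core(g)
  h <- st$h_A + st$h_B
  # allele composition of each haplotype: columns A-allele, B-allele (0/1)
  hap <- rbind(ab = c(0, 0), Ab = c(1, 0), aB = c(0, 1), AB = c(1, 1))
  v <- 0
  for (i in 1:4) for (j in i:4) {
    pr <- if (i == j) g[i]^2 else 2 * g[i] * g[j]
    K <- sum(hap[i, ] != hap[j, ])
    v <- v + pr * (K - h)^2
  }
  unname(v)
}

#' Haplotype frequencies from phased counts
#'
#' @param counts Non-negative counts of the four haplotypes, in the order
#'   (`ab`, `Ab`, `aB`, `AB`); a named vector is reordered by name.
#' @return A [haplotype_freqs] vector.
#' @export
phased_haplotype_freqs <- function(counts) {
  nm <- c("ab", "Ab", "aB", "AB")
  if (!is.null(names(counts)) && all(nm %in% names(counts)))
    counts <- counts[nm]
  counts <- as.numeric(counts)
  if (length(counts) != 4L || any(counts < 0) || anyNA(counts))
    stop("need four non-negative haplotype counts")
  if (sum(counts) == 0) stop("no observations")
  haplotype_freqs(counts / sum(counts))
}

#' Pseudo-phased haplotype frequencies from homozygous genotypes
#'
#' In unphased ancestry-call data, phase is only known for individuals that
#' are homozygous at both loci: such an individual carries two identical
#' two-locus haplotypes. This estimator uses only the four
#' homozygous-homozygous cells of the 3x3 diploid genotype table, counting
#' two haplotypes per individual, and flags the pair unusable when fewer
#' than `min_haplotypes` haplotypes are recovered.
#'
#' @param counts A 3x3 matrix of genotype counts; rows index the first-locus
#'   ancestry dosage (0, 1, 2 copies of the allele labelled `A`... see
#'   Details) and columns the second-locus dosage. Dosage here counts copies
#'   of the *capital* allele at each locus, so cell \[3, 3\] (dosage 2, 2) is
#'   the `AB/AB` genotype and cell \[1, 1\] is `ab/ab`.
#' @param min_haplotypes Minimum number of recovered haplotypes for the pair
#'   to be usable (default 50).
#' @return A list with components `g` (a [haplotype_freqs] vector or `NULL`),
#'   `n_haplotypes` (effective haplotype count) and `usable` (logical).
#' @export
homozygote_haplotype_freqs <- function(counts, min_haplotypes = 50) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3L, 3L)) || any(counts < 0) || anyNA(counts))
    stop("counts must be a non-negative 3x3 genotype table")
  # homo-homo cells: (dose A, dose B) -> haplotype
  n <- 2 * c(ab = counts[1, 1], Ab = counts[3, 1],
             aB = counts[1, 3], AB = counts[3, 3])
  tot <- sum(n)
  if (tot == 0 || tot < min_haplotypes)
    return(list(g = NULL, n_haplotypes = tot, usable = FALSE))
  list(g = haplotype_freqs(n / tot), n_haplotypes = tot, usable = TRUE)
}

#' G test of two-locus allelic independence
#'
#' Log-likelihood-ratio test of independence on the 2x2 allele-by-allele
#' table implied by the four haplotype counts, the classical screen for
#' interchromosomal DMIs. \eqn{G = 2 \sum O \ln(O/E)} with expectations from
#' the marginal products, 1 degree of freedom, and the convention
#' \eqn{0 \ln 0 = 0}.
#'
#' @inheritParams phased_haplotype_freqs
#' @return A list with `G`, `df` and `p`; `p` is `NA` when a margin is
#'   monomorphic.
#' @export
g_test_haplotypes <- function(counts) {
  nm <- c("ab", "Ab", "aB", "AB")
  if (!is.null(names(counts)) && all(nm %in% names(counts)))
    counts <- counts[nm]
  counts <- as.numeric(counts)
  if (length(counts) != 4L || any(counts < 0) || anyNA(counts))
    stop("need four non-negative haplotype counts")
  N <- sum(counts)
  if (N == 0) stop("no observations")
  O <- matrix(counts, 2, 2)            # rows: a, A; cols: b, B
  rs <- rowSums(O); cs <- colSums(O)
  if (any(rs == 0) || any(cs == 0))
    return(list(G = NA_real_, df = 1L, p = NA_real_))
  E <- outer(rs, cs) / N
  term <- ifelse(O > 0, O * log(O / E), 0)
  G <- 2 * sum(term)
  list(G = G, df = 1L, p = stats::pchisq(G, df = 1, lower.tail = FALSE))
}
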