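#' Marker map of a simulated genome
#'
#' Builds the genome architecture used by the forward simulator: an ordered
#' marker table with genetic (cM) and physical (bp) positions, and the
#' per-interval recombination probabilities derived from the genetic map.
#' The interval probability between adjacent markers is
#' `min(interval cM / 100, 0.5)` (no crossover interference, independent
#' intervals); chromosomes recombine freely (probability 0.5). Two markers
#' 10 cM apart therefore recombine with probability 0.1.
#'
#' @param chrom Chromosome identifier per marker (coerced to character).
#' @param cM Genetic position per marker, strictly increasing within a
#'   chromosome.
#' @param bp Physical position per marker (1-based), strictly increasing
#'   within a chromosome.
#' @return A list of class `"genome_architecture"` with `markers` (a data
#'   frame `chrom`, `cM`, `bp`) and `rec` (per-marker recombination
#'   probability with the preceding marker; 0.5 at chromosome starts).
#' @seealso [uniform_genome()] for the standard equally-spaced layout.
#' @export
genome_architecture <- function(chrom, cM, bp) {
  markers <- data.frame(chrom = as.character(chrom), cM = as.numeric(cM),
                        bp = as.numeric(bp))
  o <- order(markers$chrom, markers$bp)
  markers <- markers[o, , drop = FALSE]
  rownames(markers) <- NULL
  newchrom <- c(TRUE, markers$chrom[-1] != markers$chrom[-nrow(markers)])
  dcM <- c(0, diff(markers$cM))
  dbp <- c(0, diff(markers$bp))
  if (any(!newchrom & (dcM <= 0 | dbp <= 0)))
    stop("marker positions must be strictly increasing within a chromosome")
  rec <- ifelse(newchrom, 0.5, pmin(dcM / 100, 0.5))
  structure(list(markers = markers, rec = rec),
            class = "genome_architecture")
}

#' Equally spaced multi-chromosome marker map
#'
#' Standard layout for simulation studies: `n_chromosomes` chromosomes of
#' `markers_per_chrom` markers at 1 cM spacing (positions 1..markers cM),
#' with physical positions at `bp_per_cM` bases per cM.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param markers_per_chrom Markers per chromosome (default 100).
#' @param bp_per_cM Physical bases per centimorgan (default 3e5, giving
#'   30-Mb chromosomes of 100 cM, a teleost-like scale).
#' @return A [genome_architecture] object.
#' @export
uniform_genome <- function(n_chromosomes, markers_per_chrom = 100,
                           bp_per_cM = 3e5) {
  chrom <- rep(sprintf("chr%d", seq_len(n_chromosomes)),
               each = markers_per_chrom)
  cM <- rep(seq_len(markers_per_chrom), n_chromosomes)
  genome_architecture(chrom, cM, bp = cM * bp_per_cM)
}

#' Pairwise DMI architecture
#'
#' Declares the incompatibilities segregating in a simulation. Each row is
#' one pairwise DMI between a locus carrying incompatible allele `A`
#' (derived in the parent-2 background) and a locus carrying allele `B`
#' (derived in the parent-1 background), with its selection coefficients.
#' Interaction hubs are expressed as two rows sharing a locus in the `B`
#' role; fitness is multiplicative across rows.
#'
#' @param locus_A,locus_B Row indices into `arch$markers` of the two
#'   interacting loci.
#' @param alpha,beta,gamma Selection coefficients per DMI (recycled).
#' @param dominance Dominance mode per DMI (recycled); see
#'   [selection_params()].
#' @return A data frame of class `"dmi_architecture"`.
#' @export
dmi_architecture <- function(locus_A, locus_B, alpha = 0.001, beta = 0.002,
                             gamma = -0.5, dominance = "recessive") {
  if (any(gamma > 0)) stop("gamma must be <= 0 for a DMI")
  out <- data.frame(locus_A = as.integer(locus_A),
                    locus_B = as.integer(locus_B),
                    alpha = alpha, beta = beta, gamma = gamma,
                    dominance = dominance, stringsAsFactors = FALSE)
  if (any(out$locus_A == out$locus_B))
    stop("a DMI needs two distinct loci")
  class(out) <- c("dmi_architecture", "data.frame")
  out
}

#' Random multi-chromosome DMI study design
#'
#' Draws the genome-scan study architecture: DMI-bearing chromosomes plus
#' neutral chromosomes (100 markers each), with DMI loci placed uniformly
#' at random on the DMI chromosomes (so incompatibilities may be intra- or
#' interchromosomal), direct selection coefficients
#' \eqn{\alpha, \beta \sim Exp(mean)} and epistasis
#' \eqn{\gamma \sim U[\gamma_{min}, \gamma_{max}]}. With `hub = TRUE`, a
#' three-locus two-DMI model is drawn instead: alleles at two loci each
#' interact with a shared third locus.
#'
#' @param n_dmi_pairs Number of pairwise DMIs (ignored when `hub = TRUE`,
#'   which always has two).
#' @param n_dmi_chromosomes,n_neutral_chromosomes Chromosome counts.
#' @param markers_per_chrom Markers per chromosome.
#' @param alpha_mean Mean of the exponential draw for `alpha` and `beta`.
#' @param gamma_range Interval for the uniform epistasis draw
#'   (default `c(-1, -0.001)`).
#' @param hub Draw the three-locus hub model instead of independent pairs.
#' @param dominance Dominance mode for all drawn DMIs.
#' @param bp_per_cM Passed to [uniform_genome()].
#' @return A list with `arch` ([genome_architecture]) and `dmis`
#'   ([dmi_architecture]); uses the current RNG state.
#' @export
random_architecture <- function(n_dmi_pairs = 2, n_dmi_chromosomes = 4,
                                n_neutral_chromosomes = 2,
                                markers_per_chrom = 100,
                                alpha_mean = 0.001,
                                gamma_range = c(-1, -0.001),
                                hub = FALSE, dominance = "recessive",
                                bp_per_cM = 3e5) {
  arch <- uniform_genome(n_dmi_chromosomes + n_neutral_chromosomes,
                         markers_per_chrom, bp_per_cM)
  n_dmi_markers <- n_dmi_chromosomes * markers_per_chrom
  if (hub) {
    loci <- sample.int(n_dmi_markers, 3)
    dmis <- dmi_architecture(
      locus_A = loci[1:2], locus_B = c(loci[3], loci[3]),
      alpha = stats::rexp(2, rate = 1 / alpha_mean),
      beta  = stats::rexp(2, rate = 1 / alpha_mean),
      gamma = stats::runif(2, min(gamma_range), max(gamma_range)),
      dominance = dominance)
  } else if (n_dmi_pairs > 0) {
    loci <- sample.int(n_dmi_markers, 2 * n_dmi_pairs)
    dmis <- dmi_architecture(
      locus_A = loci[seq_len(n_dmi_pairs)],
      locus_B = loci[n_dmi_pairs + seq_len(n_dmi_pairs)],
      alpha = stats::rexp(n_dmi_pairs, rate = 1 / alpha_mean),
      beta  = stats::rexp(n_dmi_pairs, rate = 1 / alpha_mean),
      gamma = stats::runif(n_dmi_pairs, min(gamma_range), max(gamma_range)),
      dominance = dominance)
  } else {
    dmis <- NULL
  }
  list(arch = arch, dmis = dmis)
}

# Diploid fitness of every individual given the DMI architecture.
# h1, h2: L x N matrices of parent-1 ancestry labels (0/1).
# Allele A = parent-2 ancestry at locus_A; allele B = parent-1 at locus_B.
.dmi_fitness <- function(h1, h2, dmis) {
  N <- ncol(h1)
  w <- rep(1, N)
  if (is.null(dmis) || nrow(dmis) == 0L) return(w)
  for (r in seq_len(nrow(dmis))) {
    nA <- 2L - (h1[dmis$locus_A[r], ] + h2[dmis$locus_A[r], ])
    nB <- h1[dmis$locus_B[r], ] + h2[dmis$locus_B[r], ]
    e <- .epistasis_exponent(nA, nB, dmis$dominance[r])
    w <- w * (1 + dmis$alpha[r])^nA * (1 + dmis$beta[r])^nB *
      (1 + dmis$gamma[r])^e
  }
  unname(w)
}

# Draw n gametes from the individuals indexed by `parents`.
# rec: per-marker recombination probability with the preceding marker.
.meiosis <- function(h1, h2, rec, parents) {
  L <- nrow(h1); n <- length(parents)
  E <- matrix(stats::runif(L * n) < rec, L, n)   # rec recycled down columns
  S <- E
  if (L > 1) for (l in 2:L) S[l, ] <- xor(S[l - 1, ], E[l, ])
  G <- h1[, parents, drop = FALSE]
  B <- h2[, parents, drop = FALSE]
  G[S] <- B[S]
  G
}

# Replace random juveniles with pure parental migrants (after selection).
# Returns the modified haplotype matrices.
.migrate <- function(h1, h2, m1, m2) {
  n <- ncol(h1)
  if (m1 <= 0 && m2 <= 0) return(list(h1 = h1, h2 = h2))
  nm1 <- stats::rbinom(1, n, m1)
  nm2 <- stats::rbinom(1, n, min(m2, 1 - m1))
  k <- nm1 + nm2
  if (k == 0) return(list(h1 = h1, h2 = h2))
  idx <- sample.int(n, min(k, n))
  i1 <- idx[seq_len(min(nm1, length(idx)))]
  i2 <- setdiff(idx, i1)
  h1[, i1] <- 1L; h2[, i1] <- 1L     # parent 1 (aB background)
  h1[, i2] <- 0L; h2[, i2] <- 0L     # parent 2 (Ab background)
  list(h1 = h1, h2 = h2)
}

#' Forward-time simulation of an admixed hybrid population
#'
#' Individual-based Wright-Fisher or Moran simulation of a diploid hybrid
#' population carrying ancestry-labelled chromosomes and one or more DMIs.
#' Founding adults (generation 1) are pure parental individuals: parent 1
#' (the `aB` background) with probability `f`, else parent 2. Each
#' Wright-Fisher generation, parents are drawn with probability
#' proportional to fitness (fecundity weighting, equivalent to
#' juvenile-stage viability selection), meiosis draws an independent
#' crossover per marker interval, the whole generation is replaced, and
#' migrants then replace random juveniles with pure parental individuals.
#' Under the Moran model, individuals die according to the age-specific
#' mortality schedule and are replaced by juveniles bred from the
#' survivors; one time step counts as one generation.
#'
#' @param arch A [genome_architecture].
#' @param dmis A [dmi_architecture] or `NULL` for neutral evolution.
#' @param N Founding diploid population size (default 5000).
#' @param f Founding admixture proportion of parent 1.
#' @param m1,m2 Per-generation migrant fractions from parent 1 / parent 2.
#' @param generations Final generation index (founders are generation 1).
#' @param model `"WF"` (non-overlapping) or `"Moran"` (overlapping
#'   generations).
#' @param growth_rate,growth_duration Optional early expansion: the
#'   population grows by `growth_rate` per generation for
#'   `growth_duration` generations, then stays constant (WF only).
#' @param mortality Moran age-specific death probabilities from age 0
#'   upwards; ages beyond the schedule die with probability 1. Default is
#'   the 10-age schedule `c(0.2, 0.2, 0, 0, 0, 0, 0.25, 0.5, 0.75, 1)`.
#' @param checkpoints Generations at which to take an ancestry sample.
#' @param sample_size Individuals per checkpoint sample (see
#'   [sample_ancestry()]).
#' @param exclude_threshold Minimum minor-parent genome fraction for a
#'   sampled individual (default 0.10).
#' @param seed Optional integer seed (set once at the start).
#' @return A list of class `"hybrid_sim"`: `h1`, `h2` (marker-by-individual
#'   ancestry matrices of the final generation), `ages`, `generation`,
#'   `arch`, `dmis`, `config` and `samples` (a list of [sample_ancestry()]
#'   results named by generation).
#' @export
sim_hybrid <- function(arch, dmis = NULL, N = 5000, f = 0.5,
                       m1 = 0, m2 = 0, generations = 50,
                       model = c("WF", "Moran"),
                       growth_rate = 0, growth_duration = 0,
                       mortality = c(0.2, 0.2, 0, 0, 0, 0,
                                     0.25, 0.5, 0.75, 1),
                       checkpoints = NULL, sample_size = NULL,
                       exclude_threshold = 0.10, seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  if (N < 2) stop("N must be at least 2")
  L <- nrow(arch$markers)
  founder_p1 <- stats::runif(N) < f
  h1 <- matrix(0L, L, N); h1[, founder_p1] <- 1L
  h2 <- h1
  ages <- integer(N)
  samples <- list()
  take <- function(gen, h1, h2) {
    if (!is.null(checkpoints) && gen %in% checkpoints &&
        !is.null(sample_size)) {
      samples[[as.character(gen)]] <<- sample_ancestry(
        list(h1 = h1, h2 = h2, arch = arch, generation = gen),
        sample_size, exclude_threshold)
    }
  }
  take(1L, h1, h2)
  if (generations >= 2) for (gen in 2:generations) {
    if (model == "WF") {
      w <- .dmi_fitness(h1, h2, dmis)
      n_off <- round(N * (1 + growth_rate)^min(gen - 1, growth_duration))
      p1 <- sample.int(ncol(h1), n_off, replace = TRUE, prob = w)
      p2 <- sample.int(ncol(h1), n_off, replace = TRUE, prob = w)
      nh1 <- .meiosis(h1, h2, arch$rec, p1)
      nh2 <- .meiosis(h1, h2, arch$rec, p2)
      mig <- .migrate(nh1, nh2, m1, m2)
      h1 <- mig$h1; h2 <- mig$h2
      ages <- integer(n_off)
    } else {
      n <- ncol(h1)
      pd <- ifelse(ages >= length(mortality), 1, mortality[ages + 1L])
      dead <- stats::runif(n) < pd
      if (any(dead)) {
        surv <- which(!dead)
        pool <- if (length(surv) >= 2) surv else seq_len(n)
        w <- .dmi_fitness(h1, h2, dmis)[pool]
        nd <- sum(dead)
        p1 <- pool[sample.int(length(pool), nd, replace = TRUE, prob = w)]
        p2 <- pool[sample.int(length(pool), nd, replace = TRUE, prob = w)]
        j1 <- .meiosis(h1, h2, arch$rec, p1)
        j2 <- .meiosis(h1, h2, arch$rec, p2)
        mig <- .migrate(j1, j2, m1, m2)
        h1[, dead] <- mig$h1; h2[, dead] <- mig$h2
      }
      ages[!dead] <- ages[!dead] + 1L
      ages[dead] <- 0L
    }
    take(gen, h1, h2)
  }
  structure(list(h1 = h1, h2 = h2, ages = ages,
                 generation = as.integer(generations),
                 arch = arch, dmis = dmis,
                 config = list(N = N, f = f, m1 = m1, m2 = m2,
                               model = model, growth_rate = growth_rate,
                               growth_duration = growth_duration,
                               exclude_threshold = exclude_threshold,
                               seed = seed),
                 samples = samples),
            class = "hybrid_sim")
}

#' @export
print.hybrid_sim <- function(x, ...) {
  cat(sprintf(
    "Hybrid population (%s model): %d individuals, %d markers, generation %d\n",
    x$config$model, ncol(x$h1), nrow(x$h1), x$generation))
  cat(sprintf("  %d DMI pair(s); %d checkpoint sample(s)\n",
              if (is.null(x$dmis)) 0L else nrow(x$dmis), length(x$samples)))
  invisible(x)
}

#' Sample individuals and derive ancestry calls
#'
#' Draws a uniform sample without replacement from the population,
#' excluding individuals that are nearly purely parental (minor-parent
#' genome fraction below `exclude_threshold`, default 10%), and returns the
#' phased ancestry haplotypes along with the diploid dosage matrix (0/1/2
#' copies of parent-1 ancestry per marker).
#'
#' @param pop A [sim_hybrid()] result (or any list with `h1`, `h2`, `arch`,
#'   `generation`).
#' @param sample_size Number of individuals to draw. If fewer individuals
#'   are eligible, all eligible individuals are returned and `short_sample`
#'   is set with a warning.
#' @param exclude_threshold Minimum minor-parent genome fraction.
#' @return A list of class `"ancestry_sample"`: `h1`, `h2` (marker-by-
#'   individual phased ancestry), `dosage`, `markers`, `generation`,
#'   `ancestry_fraction` and `short_sample`.
#' @export
sample_ancestry <- function(pop, sample_size, exclude_threshold = 0.10) {
  frac <- colMeans(pop$h1 + pop$h2) / 2
  eligible <- which(pmin(frac, 1 - frac) >= exclude_threshold)
  short <- length(eligible) < sample_size
  if (short)
    warning("only ", length(eligible),
            " eligible hybrids for a sample of ", sample_size)
  idx <- if (short) eligible
         else sort(sample(eligible, sample_size))
  structure(list(h1 = pop$h1[, idx, drop = FALSE],
                 h2 = pop$h2[, idx, drop = FALSE],
                 dosage = pop$h1[, idx, drop = FALSE] +
                   pop$h2[, idx, drop = FALSE],
                 markers = pop$arch$markers,
                 generation = pop$generation,
                 ancestry_fraction = frac[idx],
                 short_sample = short),
            class = "ancestry_sample")
}

#' @export
print.ancestry_sample <- function(x, ...) {
  cat(sprintf(
    "Ancestry sample: %d individuals x %d markers (generation %d)%s\n",
    ncol(x$dosage), nrow(x$dosage), x$generation,
    if (x$short_sample) " [short sample]" else ""))
  invisible(x)
}
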