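#' Selection parameters of a two-locus DMI
#'
#' The fitness scheme of the incompatibility: haplotype fitnesses are
#' \eqn{w_{ab} = 1}, \eqn{w_{Ab} = 1 + \alpha}, \eqn{w_{aB} = 1 + \beta},
#' \eqn{w_{AB} = (1+\alpha)(1+\beta)(1+\gamma)}, with \eqn{\gamma \le 0} for
#' a DMI. In diploids the genotype fitness is
#' \eqn{(1+\alpha)^{n_A} (1+\beta)^{n_B} (1+\gamma)^{e(n_A, n_B)}} where
#' \eqn{n_A, n_B} count allele copies and the epistasis exponent \eqn{e}
#' depends on the dominance of the incompatibility:
#' \describe{
#'   \item{`codominant`}{\eqn{e = n_A n_B}: heterozygous carriers of both
#'     alleles already suffer.}
#'   \item{`recessive`}{\eqn{e = n_A n_B} except \eqn{e(1,1) = 0}: the
#'     double heterozygote is unaffected, so e.g.
#'     \eqn{w_{AB/AB} = (1+\alpha)^2 (1+\beta)^2 (1+\gamma)^4} and
#'     \eqn{w_{AB/aB} = (1+\alpha)(1+\beta)^2 (1+\gamma)^2}.}
#'   \item{`homo_homo`}{\eqn{e = 4} only for the double homozygote
#'     \eqn{n_A = n_B = 2}, else 0.}
#' }
#'
#' @param alpha,beta Direct selection coefficients of alleles `A` and `B`.
#' @param gamma Epistasis coefficient (non-positive for a DMI; 0 switches
#'   epistasis off).
#' @param dominance One of `"haploid"`, `"recessive"`, `"homo_homo"`,
#'   `"codominant"`.
#' @return A list of class `"selection_params"`.
#' @export
selection_params <- function(alpha = 0.001, beta = 0.002, gamma = -0.5,
                             dominance = c("haploid", "recessive",
                                           "homo_homo", "codominant")) {
  dominance <- match.arg(dominance)
  if (1 + alpha <= 0 || 1 + beta <= 0 || 1 + gamma < 0)
    stop("need 1+alpha > 0, 1+beta > 0 and 1+gamma >= 0")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 dominance = dominance),
            class = "selection_params")
}

#' Demography of the hybrid population
#'
#' @param f Founding admixture proportion of the `aB` parental population
#'   (the `Ab` parent contributes `1 - f`).
#' @param c Recombination probability per generation between the two loci,
#'   in \[0, 0.5\].
#' @param m1 Per-generation migrant fraction from the `aB` parent.
#' @param m2 Per-generation migrant fraction from the `Ab` parent.
#' @return A list of class `"dmi_demography"`.
#' @export
demography <- function(f = 0.5, c = 0.1, m1 = 0, m2 = 0) {
  if (f < 0 || f > 1) stop("f must lie in [0, 1]")
  if (c < 0 || c > 0.5) stop("c must lie in [0, 0.5]")
  if (m1 < 0 || m2 < 0 || m1 + m2 > 1) stop("need m1, m2 >= 0 and m1+m2 <= 1")
  structure(list(f = f, c = c, m1 = m1, m2 = m2), class = "dmi_demography")
}

# epistasis exponent e(nA, nB) for a dominance mode; vectorized over nA, nB
.epistasis_exponent <- function(nA, nB, dominance) {
  e <- switch(dominance,
    codominant = nA * nB,
    recessive  = ifelse(nA == 1 & nB == 1, 0, nA * nB),
    homo_homo  = ifelse(nA == 2 & nB == 2, 4, 0),
    stop("unknown dominance mode: ", dominance))
  e
}

#' One generation of the deterministic haploid recursion
#'
#' Applies, in order, selection (haplotype fitnesses of
#' [selection_params()]), recombination
#' (\eqn{g''_{AB} = g'_{AB} - c D_{sel}} etc., with
#' \eqn{D_{sel} = g'_{AB} g'_{ab} - g'_{Ab} g'_{aB}}), and migration
#' (\eqn{g''' = (1 - m_1 - m_2) g'' + m_1 [aB] + m_2 [Ab]}). Migrants enter
#' after selection, mirroring juvenile-stage immigration.
#'
#' @param g A [haplotype_freqs] vector.
#' @param sel A [selection_params] object with `dominance = "haploid"`.
#' @param dem A [demography] object.
#' @return The next generation's [haplotype_freqs].
#' @export
haploid_step <- function(g, sel, dem) {
  g <- unclass(haplotype_freqs(g))
  w <- c(1, 1 + sel$alpha, 1 + sel$beta,
         (1 + sel$alpha) * (1 + sel$beta) * (1 + sel$gamma))
  gp <- w * g
  gp <- gp / sum(gp)
  D <- gp[4] * gp[1] - gp[3] * gp[2]
  gpp <- gp + dem$c * D * c(-1, 1, 1, -1)
  out <- (1 - dem$m1 - dem$m2) * gpp +
    dem$m1 * c(0, 0, 1, 0) + dem$m2 * c(0, 1, 0, 0)
  haplotype_freqs(out)
}

#' One generation of the deterministic diploid recursion
#'
#' The gamete pool `g` forms diploids by random union of gametes; genotypes
#' are reweighted by the dominance-aware fitness of [selection_params()];
#' meiosis with recombination probability `c` yields the next gamete pool;
#' migration then injects pure parental gametes as in [haploid_step()].
#'
#' @param g Gamete-pool [haplotype_freqs].
#' @inheritParams haploid_step
#' @return The next gamete pool as a [haplotype_freqs] vector.
#' @export
diploid_step <- function(g, sel, dem) {
  g <- unclass(haplotype_freqs(g))
  if (sel$dominance == "haploid")
    stop("diploid_step requires a diploid dominance mode")
  # allele content per haplotype (A copies, B copies)
  hapA <- c(0, 1, 0, 1); hapB <- c(0, 0, 1, 1)
  G <- outer(g, g)                       # ordered genotype frequencies
  nA <- outer(hapA, hapA, `+`)
  nB <- outer(hapB, hapB, `+`)
  e <- .epistasis_exponent(nA, nB, sel$dominance)
  w <- (1 + sel$alpha)^nA * (1 + sel$beta)^nB * (1 + sel$gamma)^e
  G <- G * w
  G <- G / sum(G)
  # meiosis: parental transmission (1-c), recombinant combination c
  out <- numeric(4)
  for (i in 1:4) for (j in 1:4) {
    pr <- G[i, j]
    if (pr == 0) next
    out[i] <- out[i] + pr * (1 - dem$c) / 2
    out[j] <- out[j] + pr * (1 - dem$c) / 2
    r1 <- 1L + hapA[i] + 2L * hapB[j]   # A-allele from i, B-allele from j
    r2 <- 1L + hapA[j] + 2L * hapB[i]
    out[r1] <- out[r1] + pr * dem$c / 2
    out[r2] <- out[r2] + pr * dem$c / 2
  }
  out <- (1 - dem$m1 - dem$m2) * out +
    dem$m1 * c(0, 0, 1, 0) + dem$m2 * c(0, 1, 0, 0)
  haplotype_freqs(out)
}

#' Deterministic two-locus DMI trajectory
#'
#' Iterates [haploid_step()] (or [diploid_step()] for diploid dominance
#' modes) from the founding admixed distribution
#' \eqn{g_{aB} = f, g_{Ab} = 1 - f}, recording the full two-locus summary
#' each generation. Founders are generation 1, so recombinant haplotypes
#' first appear at generation 2. The recursion stops when the minor allele
#' frequency at either locus drops below `maf_stop` (that near-fixation
#' state is not recorded) or when `max_generations` is reached.
#'
#' @inheritParams haploid_step
#' @param maf_stop Minor-allele-frequency stopping threshold (default 0.005).
#' @param max_generations Generation cap (default 10000).
#' @return A data frame of class `"dmi_trajectory"` with columns
#'   `generation`, `g_ab`, `g_Ab`, `g_aB`, `g_AB`, `p_A`, `p_B`, `D`,
#'   `Dprime`, `X2`, `deltaD2`, and attributes `sel`, `dem`, `termination`.
#' @examples
#' tr <- run_trajectory(selection_params(0.001, 0.002, -0.5),
#'                      demography(f = 0.5, c = 0.1))
#' detection_window(tr)
#' @export
run_trajectory <- function(sel = selection_params(),
                           dem = demography(),
                           maf_stop = 0.005, max_generations = 10000) {
  stepfun <- if (sel$dominance == "haploid") haploid_step else diploid_step
  g <- haplotype_freqs(c(0, 1 - dem$f, dem$f, 0))
  rows <- vector("list", 256)
  n <- 0L
  record <- function(gen, g) {
    st <- .two_locus_core(unclass(g))
    c(generation = gen, g_ab = g[[1]], g_Ab = g[[2]], g_aB = g[[3]],
      g_AB = g[[4]], p_A = st$p_A, p_B = st$p_B, D = st$D,
      Dprime = st$Dprime, X2 = st$X2, deltaD2 = st$deltaD2)
  }
  maf <- function(g) {
    p_A <- g[[2]] + g[[4]]; p_B <- g[[3]] + g[[4]]
    min(p_A, 1 - p_A, p_B, 1 - p_B)
  }
  n <- n + 1L; rows[[n]] <- record(1L, g)
  termination <- "generation cap"
  if (maf(g) < maf_stop) {
    termination <- "near-fixation"
  } else if (max_generations >= 2) {
    for (gen in 2:max_generations) {
      g <- stepfun(g, sel, dem)
      if (maf(g) < maf_stop) { termination <- "near-fixation"; break }
      if (n == length(rows)) rows <- c(rows, vector("list", length(rows)))
      n <- n + 1L; rows[[n]] <- record(gen, g)
    }
  }
  out <- as.data.frame(do.call(rbind, rows[seq_len(n)]))
  out$generation <- as.integer(out$generation)
  attr(out, "sel") <- sel
  attr(out, "dem") <- dem
  attr(out, "termination") <- termination
  class(out) <- c("dmi_trajectory", "data.frame")
  out
}

#' Detection window of negative X(2)
#'
#' The span of generations during which \eqn{X^{(2)}} falls below
#' `threshold` (default 0), i.e. during which the DMI is detectable, plus
#' the generation of the most negative value.
#'
#' @param trajectory A [run_trajectory()] result.
#' @param threshold X(2) threshold defining the window (default 0).
#' @return A list of class `"detection_window"` with `first`, `last`,
#'   `argmin`, `min_X2` and `empty`.
#' @export
detection_window <- function(trajectory, threshold = 0) {
  x2 <- trajectory$X2
  gen <- trajectory$generation
  neg <- which(!is.na(x2) & x2 < threshold)
  if (length(neg) == 0L)
    return(structure(list(first = NA_integer_, last = NA_integer_,
                          argmin = NA_integer_, min_X2 = NA_real_,
                          empty = TRUE), class = "detection_window"))
  i <- neg[which.min(x2[neg])]
  structure(list(first = gen[min(neg)], last = gen[max(neg)],
                 argmin = gen[i], min_X2 = x2[i], empty = FALSE),
            class = "detection_window")
}

#' @export
print.detection_window <- function(x, ...) {
  if (x$empty) cat("Detection window: empty (X(2) never below threshold)\n")
  else cat(sprintf(
    "Detection window: generations %d-%d, strongest signal at %d (X(2) = %.4g)\n",
    x$first, x$last, x$argmin, x$min_X2))
  invisible(x)
}

#' @export
print.dmi_trajectory <- function(x, ...) {
  sel <- attr(x, "sel"); dem <- attr(x, "dem")
  cat(sprintf(
    "Deterministic %s DMI trajectory: %d generations (%s)\n",
    sel$dominance, nrow(x), attr(x, "termination")))
  cat(sprintf("  alpha = %g, beta = %g, gamma = %g; f = %g, c = %g, m1 = %g, m2 = %g\n",
              sel$alpha, sel$beta, sel$gamma, dem$f, dem$c, dem$m1, dem$m2))
  print(detection_window(x))
  invisible(x)
}

#' @export
summary.dmi_trajectory <- function(object, threshold = 0, ...) {
  w <- detection_window(object, threshold)
  list(window = w,
       generations = nrow(object),
       termination = attr(object, "termination"),
       min_X2 = suppressWarnings(min(object$X2, na.rm = TRUE)),
       min_deltaD2 = suppressWarnings(min(object$deltaD2, na.rm = TRUE)))
}

#' @export
plot.dmi_trajectory <- function(x, which = c("X2", "haplotypes"), ...) {
  which <- match.arg(which)
  if (which == "X2") {
    graphics::plot(x$generation, x$X2, type = "l", xlab = "generation",
                   ylab = expression(X^(2)), ...)
    graphics::abline(h = 0, lty = 3)
  } else {
    graphics::matplot(x$generation, x[, c("g_ab", "g_Ab", "g_aB", "g_AB")],
                      type = "l", lty = 1, xlab = "generation",
                      ylab = "haplotype frequency", ...)
    graphics::legend("topright", legend = c("ab", "Ab", "aB", "AB"),
                     col = 1:4, lty = 1, bty = "n")
  }
  invisible(x)
}

#' Export a trajectory as tidy TSV
#'
#' @param trajectory A [run_trajectory()] result.
#' @param path Output file path.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.table(as.data.frame(trajectory), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Detection windows over a parameter grid
#'
#' Runs one deterministic trajectory per cell of the grid spanned by the
#' supplied parameter values and tabulates the detection window and the
#' extreme X(2) and deltaD2 values, supporting recombination-rate and
#' admixture-proportion surfaces of the detectability landscape.
#'
#' @param c_values,f_values,gamma_values,m1_values,m2_values Numeric vectors
#'   of parameter values; the grid is their Cartesian product.
#' @param alpha,beta Direct selection coefficients (fixed across the grid).
#' @param dominance Dominance mode passed to [selection_params()].
#' @param threshold X(2) threshold for [detection_window()].
#' @param ... Passed to [run_trajectory()] (e.g. `maf_stop`).
#' @return A data frame with one row per grid cell: the parameters, the
#'   window bounds, `argmin_generation`, `min_X2`, `min_deltaD2` and
#'   `deltaD2_argmin_generation`.
#' @export
parameter_grid <- function(c_values = 0.1, f_values = 0.5,
                           gamma_values = -0.5, m1_values = 0, m2_values = 0,
                           alpha = 0.001, beta = 0.002,
                           dominance = "haploid", threshold = 0, ...) {
  grid <- expand.grid(c = c_values, f = f_values, gamma = gamma_values,
                      m1 = m1_values, m2 = m2_values)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- selection_params(alpha, beta, grid$gamma[i], dominance)
    dem <- demography(grid$f[i], grid$c[i], grid$m1[i], grid$m2[i])
    tr <- run_trajectory(sel, dem, ...)
    w <- detection_window(tr, threshold)
    i_dd2 <- which.min(tr$deltaD2)
    data.frame(first = w$first, last = w$last,
               argmin_generation = w$argmin, min_X2 = w$min_X2,
               empty = w$empty,
               min_deltaD2 = tr$deltaD2[i_dd2],
               deltaD2_argmin_generation = tr$generation[i_dd2])
  })
  cbind(grid, do.call(rbind, res))
}
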