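test_that("ancestry_matrix validates, sorts and rejects duplicates", {
  dos <- matrix(c(0L, 1L, 2L, NA, 2L, 0L), 3, 2)
  am <- ancestry_matrix(dos, chrom = c("chr1", "chr1", "chr1"),
                        pos = c(100, 200, 300))
  expect_equal(nrow(am$dosage), 3L)
  expect_error(ancestry_matrix(matrix(3L, 1, 1), "chr1", 1),
               "invalid dosage")
  expect_error(ancestry_matrix(matrix(0L, 2, 1), c("chr1", "chr1"),
                               c(5, 5)), "duplicate")
})

test_that("locus filters apply the homozygote and heterozygous-or-missing rules", {
  n <- 100
  mk_dos <- function(n0, n1, n2, nNA = 0) {
    c(rep(0L, n0), rep(1L, n1), rep(2L, n2), rep(NA, nNA))
  }
  dos <- rbind(
    mk_dos(4, 26, 70),          # hom-0 freq 0.04: dropped
    mk_dos(20, 61, 15, 4),      # 65% het-or-missing: dropped
    mk_dos(20, 50, 30),         # retained
    mk_dos(10, 55, 30, 5))      # 60% het-or-missing: dropped (not < 0.60)
  am <- ancestry_matrix(dos, rep("chr1", 4), c(10, 20, 30, 40) * 1e3)
  kept <- filter_loci(am)
  expect_equal(kept$markers$pos, 30e3)
})

test_that("LD thinning drops later near-duplicate markers within the window", {
  set.seed(4)
  base <- sample(0:2, 300, replace = TRUE)
  indep <- sample(0:2, 300, replace = TRUE)
  dos <- rbind(base, base, base, indep)
  am <- ancestry_matrix(dos, rep("chr1", 4),
                        pos = c(1000, 6000, 60000, 65000))
  thinned <- ld_thin(am)
  # second copy 5 kb away dropped; identical marker 50+ kb away kept;
  # independent marker kept
  expect_equal(thinned$markers$pos, c(1000, 60000, 65000))
})

test_that("the scan flags a strong interchromosomal DMI and is seed-deterministic", {
  d <- strong_dmi_design()
  sim <- sim_hybrid(d$arch, d$dmis, N = 5000, f = 0.5, generations = 30,
                    checkpoints = 30, sample_size = 300, seed = 17)
  sam <- sim$samples[["30"]]
  sc <- pairwise_scan(sam, "phased", max_markers = Inf)
  dmi_row <- sc$marker1 == 50 & sc$marker2 == 150
  expect_true(sc$candidate[dmi_row])
  expect_lt(sc$X2[dmi_row], -0.005)
  expect_lt(sc$Dprime[dmi_row], 0)

  # candidate rule is a conjunction: X2 < threshold alone is not enough
  expect_true(all(sc$Dprime[sc$candidate] < 0))
  expect_true(all(sc$X2[sc$candidate] < -0.005))

  # identical input and seed give the identical candidate set
  s1 <- pairwise_scan(sam, "phased", max_markers = 100, seed = 99)
  s2 <- pairwise_scan(sam, "phased", max_markers = 100, seed = 99)
  expect_identical(s1, s2)
})

test_that("the candidate set is invariant under parent relabelling", {
  d <- strong_dmi_design()
  sim <- sim_hybrid(d$arch, d$dmis, N = 500, f = 0.5, generations = 25,
                    checkpoints = 25, sample_size = 200, seed = 23)
  sam <- sim$samples[["25"]]
  flip <- sam
  flip$h1 <- 1L - sam$h1; flip$h2 <- 1L - sam$h2
  flip$dosage <- 2L - sam$dosage
  a <- pairwise_scan(sam, "phased", max_markers = Inf)
  b <- pairwise_scan(flip, "phased", max_markers = Inf)
  expect_equal(b$X2, a$X2, tolerance = 1e-12)
  expect_equal(b$Dprime, a$Dprime, tolerance = 1e-12)
  expect_equal(b$deltaD2, -a$deltaD2, tolerance = 1e-12)
  expect_identical(b$candidate, a$candidate)
})

test_that("pseudo-phased mode enforces the 50-haplotype usability rule", {
  # 30 individuals, all heterozygous at marker 2: no phase information there
  dos <- rbind(rep(c(0L, 2L), 15), rep(1L, 30), rep(c(2L, 0L), 15))
  am <- ancestry_matrix(dos, rep("chr1", 3), c(1, 2, 3) * 1e6)
  sc <- pairwise_scan(am, "pseudo_phased", max_markers = Inf)
  het_pairs <- sc$marker1 == 2 | sc$marker2 == 2
  expect_true(all(!sc$usable[het_pairs]))
  # markers 1 and 3: all 30 individuals homo at both = 60 haplotypes
  expect_equal(sc$n_hap[sc$marker1 == 1 & sc$marker2 == 3], 60)
  expect_true(sc$usable[sc$marker1 == 1 & sc$marker2 == 3])
})

test_that("pseudo-phased and phased agree on complete homozygote data", {
  # individuals homozygous everywhere: pseudo-phasing recovers the
  # haplotype table exactly
  set.seed(6)
  h <- matrix(sample(0:1, 5 * 40, replace = TRUE), 5, 40)
  sam <- structure(list(h1 = h, h2 = h, dosage = 2L * h,
                        markers = data.frame(chrom = "chr1",
                                             bp = (1:5) * 1e6,
                                             cM = 1:5),
                        generation = 1L,
                        ancestry_fraction = colMeans(h),
                        short_sample = FALSE),
                   class = "ancestry_sample")
  a <- pairwise_scan(sam, "phased", max_markers = Inf)
  b <- pairwise_scan(sam, "pseudo_phased", max_markers = Inf,
                     min_haplotypes = 50)
  expect_equal(b$X2, a$X2, tolerance = 1e-12)
  expect_equal(b$deltaD2, a$deltaD2, tolerance = 1e-12)
})

test_that("bin assignment uses half-open megabase windows and drops self pairs", {
  sc <- data.frame(
    marker1 = 1:3, marker2 = 4:6,
    chrom1 = c("chr1", "chr1", "chr2"), pos1 = c(5e5, 1.2e6, 3e5),
    chrom2 = c("chr2", "chr1", "chr2"), pos2 = c(1.5e6, 1.4e6, 9e5),
    n_hap = 100, X2 = -0.01, Dprime = -0.5, deltaD2 = 0,
    usable = TRUE, candidate = c(TRUE, TRUE, TRUE))
  b <- bin_pairs(sc)
  # pair 2 (chr1:1 x chr1:1) and pair 3 (chr2:0 x chr2:0) are self pairs
  expect_equal(nrow(b), 1L)
  expect_equal(b$chrom1, "chr1"); expect_equal(b$bin1, 0L)
  expect_equal(b$chrom2, "chr2"); expect_equal(b$bin2, 1L)
  # two candidate marker pairs in one bin pair collapse to one putative DMI
  sc2 <- sc; sc2$chrom2 <- "chr2"; sc2$pos2 <- c(1.5e6, 1.6e6, 9e5)
  sc2$pos1 <- c(5e5, 6e5, 3e5); sc2$chrom1 <- "chr1"
  b2 <- bin_pairs(sc2)
  expect_equal(sum(b2$candidate), 2L)
  expect_equal(b2$n_candidates[b2$bin1 == 0 & b2$bin2 == 1], 2L)
})

test_that("bootstrap support calibrates k by the binomial tail", {
  d <- strong_dmi_design()
  sim <- sim_hybrid(d$arch, d$dmis, N = 1000, f = 0.5, generations = 30,
                    checkpoints = 30, sample_size = 300, seed = 41)
  sam <- sim$samples[["30"]]
  bs <- bootstrap_support(sam, "phased", n_bootstrap = 20,
                          markers_per_bootstrap = 120, seed = 1)
  expect_true(bs$k >= 1)
  # every reported p is the upper binomial tail at p_bin
  expect_equal(bs$bins$p,
               stats::pbinom(bs$bins$count - 1, 20, bs$p_bin,
                             lower.tail = FALSE), tolerance = 1e-12)
  # supported set is exactly the count >= k rule
  expect_identical(bs$bins$supported, bs$bins$count >= bs$k)
  # the true DMI bin pair is recovered with strong support
  hit <- bs$bins$chrom1 == "chr1" & bs$bins$chrom2 == "chr2" &
    bs$bins$bin1 == floor(d$arch$markers$bp[50] / 1e6) &
    bs$bins$bin2 == floor(d$arch$markers$bp[150] / 1e6)
  expect_true(any(hit))
  expect_true(bs$bins$supported[hit])

  # k is stable (within 1) across master seeds
  ks <- vapply(2:4, function(s)
    bootstrap_support(sam, "phased", n_bootstrap = 20,
                      markers_per_bootstrap = 120, seed = s)$k,
    numeric(1))
  expect_lte(max(abs(ks - bs$k)), 1)
})

test_that("bootstrap support falls back to k = 1 when nothing is ever flagged", {
  set.seed(8)
  dos <- matrix(sample(c(0L, 1L, 2L), 6 * 200, replace = TRUE), 6, 200)
  am <- ancestry_matrix(dos, rep(c("chr1", "chr2"), each = 3),
                        pos = rep((1:3) * 1e6, 2))
  expect_warning(bs <- bootstrap_support(am, "pseudo_phased",
                                         n_bootstrap = 5,
                                         markers_per_bootstrap = 6),
                 "k = 1")
  expect_equal(bs$k, 1L)
})

test_that("the G test flags a strong DMI early after admixture", {
  d <- strong_dmi_design()
  sim <- sim_hybrid(d$arch, d$dmis, N = 1000, f = 0.5, generations = 5,
                    checkpoints = 5, sample_size = 300, seed = 53)
  gt <- g_test_scan(sim$samples[["5"]], "phased", max_markers = Inf)
  row <- gt$marker1 == 50 & gt$marker2 == 150
  expect_lt(gt$p_G[row], 0.05)
})
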