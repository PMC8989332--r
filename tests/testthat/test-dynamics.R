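test_that("haploid step reproduces hand-computed one-generation updates", {
  neutral <- selection_params(0, 0, 0, "haploid")
  dem <- demography(f = 0.5, c = 0.1)
  # linkage equilibrium is a fixed point of the neutral model
  g <- haploid_step(haplotype_freqs(0.25, 0.25, 0.25, 0.25), neutral, dem)
  expect_equal(unclass(g), c(ab = 0.25, Ab = 0.25, aB = 0.25, AB = 0.25))

  # founding parental mix: recombinants appear at frequency c|D| = 0.025
  g <- haploid_step(haplotype_freqs(0, 0.5, 0.5, 0), neutral, dem)
  expect_equal(unclass(g), c(ab = 0.025, Ab = 0.475, aB = 0.475, AB = 0.025))

  # no recombination: recombinants can never arise
  sel <- selection_params(0.001, 0.002, -0.5, "haploid")
  g <- haploid_step(haplotype_freqs(0, 0.4, 0.6, 0), sel,
                    demography(f = 0.5, c = 0))
  expect_identical(g[["ab"]], 0)
  expect_identical(g[["AB"]], 0)
})

test_that("neutral haploid dynamics: constant allele frequencies, exact D decay, X2 >= 0", {
  tr <- run_trajectory(selection_params(0, 0, 0, "haploid"),
                       demography(f = 0.4, c = 0.1),
                       max_generations = 300)
  expect_equal(tr$p_A, rep(0.6, nrow(tr)), tolerance = 1e-12)
  expect_equal(tr$D, tr$D[1] * (1 - 0.1)^(tr$generation - 1),
               tolerance = 1e-12)
  expect_true(all(tr$X2 > -1e-12, na.rm = TRUE))
})

test_that("trajectories keep valid frequencies and recombinants appear at generation 2", {
  tr <- run_trajectory(selection_params(0.001, 0.002, -0.5, "haploid"),
                       demography(f = 0.3, c = 0.2, m1 = 0.004, m2 = 0.001),
                       max_generations = 500)
  gs <- as.matrix(tr[, c("g_ab", "g_Ab", "g_aB", "g_AB")])
  expect_true(all(gs >= -1e-12 & gs <= 1 + 1e-12))
  expect_equal(rowSums(gs), rep(1, nrow(tr)), tolerance = 1e-12)
  expect_equal(gs[1, c(1, 4)], c(g_ab = 0, g_AB = 0))
  expect_true(all(gs[2, ] > 0))
})

test_that("trajectory terminates immediately for a monomorphic founding state", {
  tr <- run_trajectory(selection_params(), demography(f = 0, c = 0.1))
  expect_equal(nrow(tr), 1L)
  expect_equal(attr(tr, "termination"), "near-fixation")
  expect_true(detection_window(tr)$empty)
})

test_that("highly skewed admixture yields no negative X2", {
  tr <- run_trajectory(selection_params(0.001, 0.002, -0.5, "haploid"),
                       demography(f = 0.1, c = 0.1))
  expect_true(detection_window(tr)$empty)
})

test_that("mirrored parameters give the mirrored trajectory", {
  t1 <- run_trajectory(selection_params(0.001, 0.002, -0.5, "haploid"),
                       demography(f = 0.35, c = 0.1, m1 = 0.003, m2 = 0.001),
                       max_generations = 200)
  t2 <- run_trajectory(selection_params(0.002, 0.001, -0.5, "haploid"),
                       demography(f = 0.65, c = 0.1, m1 = 0.001, m2 = 0.003),
                       max_generations = 200)
  expect_equal(t2$g_Ab, t1$g_aB, tolerance = 1e-12)
  expect_equal(t2$g_aB, t1$g_Ab, tolerance = 1e-12)
  expect_equal(t2$g_ab, t1$g_ab, tolerance = 1e-12)
  expect_equal(t2$X2, t1$X2, tolerance = 1e-12)
})

test_that("diploid recursion honours dominance of the epistasis", {
  dem0 <- demography(f = 0.5, c = 0)
  # with c = 0 the founders form only double heterozygotes, which are
  # unaffected under the recessive DMI: gamma must not matter
  g0 <- haplotype_freqs(0, 0.5, 0.5, 0)
  g_dmi <- diploid_step(g0, selection_params(0.001, 0.002, -0.5, "recessive"),
                        dem0)
  g_null <- diploid_step(g0, selection_params(0.001, 0.002, 0, "recessive"),
                         dem0)
  expect_equal(unclass(g_dmi), unclass(g_null), tolerance = 1e-14)
  # ...but the codominant DMI does punish the double heterozygote
  g_codom <- diploid_step(g0, selection_params(0.001, 0.002, -0.5,
                                               "codominant"), dem0)
  expect_false(isTRUE(all.equal(unclass(g_codom), unclass(g_null))))

  # gamma = 0 makes every dominance mode collapse to direct selection
  dem <- demography(f = 0.5, c = 0.1)
  gs <- lapply(c("recessive", "homo_homo", "codominant"), function(d)
    unclass(diploid_step(g0, selection_params(0.001, 0.002, 0, d), dem)))
  expect_equal(gs[[1]], gs[[2]], tolerance = 1e-14)
  expect_equal(gs[[1]], gs[[3]], tolerance = 1e-14)
})

test_that("stronger dominance shortens and advances the detection window", {
  wins <- lapply(c("codominant", "recessive", "homo_homo"), function(d)
    detection_window(run_trajectory(
      selection_params(0.001, 0.002, -0.5, d), demography(0.5, 0.1))))
  names(wins) <- c("codominant", "recessive", "homo_homo")
  expect_lt(wins$codominant$first, wins$recessive$first)
  expect_lt(wins$recessive$first, wins$homo_homo$first)
  len <- vapply(wins, function(w) w$last - w$first, numeric(1))
  expect_lt(len["codominant"], len["recessive"])
  expect_lt(len["recessive"], len["homo_homo"])
})

test_that("parameter_grid tabulates windows over the parameter surface", {
  pg <- parameter_grid(c_values = c(0.05, 0.1), f_values = c(0.2, 0.5))
  expect_equal(nrow(pg), 4L)
  # strongly skewed admixture yields empty windows, even admixture does not
  expect_true(all(pg$empty[pg$f == 0.2]))
  expect_true(all(!pg$empty[pg$f == 0.5]))
  ok <- !pg$empty
  expect_true(all(pg$first[ok] <= pg$argmin_generation[ok] &
                    pg$argmin_generation[ok] <= pg$last[ok]))
})
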