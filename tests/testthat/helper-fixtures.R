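# Random valid haplotype frequency vectors (Dirichlet-like via exponentials)
random_simplices <- function(n, seed = 1) {
  set.seed(seed)
  t(replicate(n, { g <- stats::rexp(4); g / sum(g) }))
}

# Minimal two-chromosome architecture with one marker each (one unlinked
# pair, recombination probability 0.5 between the markers)
unlinked_pair_genome <- function() uniform_genome(2, 1)

# One strong interchromosomal DMI on two 100-marker chromosomes
strong_dmi_design <- function() {
  list(arch = uniform_genome(2, 100),
       dmis = dmi_architecture(50, 150, alpha = 0.001, beta = 0.002,
                               gamma = -0.5))
}

# First generation (starting at 2) at which X(2) at the marker pair of a
# two-marker genome goes negative, from whole-population haplotypes
first_negative_generation <- function(sim) {
  gens <- sort(as.integer(names(sim$samples)))
  for (g in gens) {
    sc <- pairwise_scan(sim$samples[[as.character(g)]], "phased",
                        max_markers = Inf)
    if (!is.na(sc$X2[1]) && sc$X2[1] < 0) return(g)
  }
  NA_integer_
}
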