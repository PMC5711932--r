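# small builders shared across test files

sinusoid_profile <- function(gene = "g1", species = "Kf", phase = 0,
                             baseline = 5, amplitude = 3, noise_sd = 0,
                             n_reps = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tt <- canonical_grid()
  mu <- baseline + amplitude * cos(2 * pi * (tt - phase) / 24)
  vals <- matrix(rep(mu, n_reps), ncol = n_reps) +
    matrix(rnorm(length(tt) * n_reps, 0, noise_sd), ncol = n_reps)
  diel_profile(gene, species, tt, pmax(vals, 0))
}

random_profile <- function(gene = "g1", species = "Kf", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  diel_profile(gene, species, canonical_grid(),
               matrix(runif(12, 0.5, 10), ncol = 1))
}

# random rooted binary tree with species-tagged leaves
random_gene_tree <- function(ntip, species_pool, prefix = "g") {
  phy <- ape::rtree(ntip, rooted = TRUE, br = NULL)
  sp <- sample(species_pool, ntip, replace = TRUE)
  phy$tip.label <- sprintf("%s|%s%d", sp, prefix, seq_len(ntip))
  gene_tree(phy)
}

toy_tribe_msa <- function(seqs) protein_msa(seqs)
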