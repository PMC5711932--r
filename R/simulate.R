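#' Simulate a three-species diel expression dataset with planted convergence
#'
#' Emulates the comparative study design: one gene per species per ortholog
#' group, sampled in replicate at the 12 canonical time points.  Each group
#' draws a peak phase `phi ~ Uniform(0, 24)` and a log-scale cosinor mean;
#' observed abundance is `FPKM(t) = exp(B + A*cos(2*pi*(t - phi_s)/24) + e)`
#' with `e ~ Normal(0, noise_sd)` independent per time point and replicate
#' (multiplicative log-normal noise).  Group classes:
#' \itemize{
#'   \item *convergent*: both CAM species peak at `phi` (each jittered by
#'     `Normal(0, phase_jitter_cam)`), the C3 species at
#'     `phi + phase_at_offset`;
#'   \item *non-convergent*: all three species peak at `phi` (jittered);
#'   \item *flat*: amplitude 0 (noise only).
#' }
#'
#' @param n_groups Number of ortholog groups.
#' @param frac_convergent Fraction of groups with planted convergence.
#' @param frac_flat Fraction of groups with flat (no diel) expression.
#' @param baseline_log_fpkm Mean and sd of the per-gene log-FPKM baseline.
#' @param amplitude Mean and sd of the log-scale oscillation amplitude
#'   (draws truncated at 0).
#' @param phase_jitter_cam Sd (hours) of per-species phase jitter.
#' @param phase_at_offset C3 phase offset in hours for convergent groups
#'   (default 12: antiphase).
#' @param noise_sd Log-scale observation noise sd.
#' @param n_reps Replicates per time point.
#' @param species Species tags `(cam_dicot, cam_monocot, c3)`.
#' @param seed Integer seed (required for reproducibility).
#' @return List: `matrices` (named list of three [diel_matrix()]),
#'   `orthogroups` (list of [ortholog_group()]), `truth` (data frame with
#'   planted label and phases per group), `params`.
#' @export
simulate_diel_dataset <- function(n_groups = 500, frac_convergent = 0.1,
                                  frac_flat = 0.1,
                                  baseline_log_fpkm = c(mean = 2, sd = 1),
                                  amplitude = c(mean = 1.5, sd = 0.4),
                                  phase_jitter_cam = 0.5,
                                  phase_at_offset = 12,
                                  noise_sd = 0.2, n_reps = 3,
                                  species = c(cam_dicot = "Kf",
                                              cam_monocot = "Ac", c3 = "At"),
                                  seed = 1) {
  stopifnot(frac_convergent >= 0, frac_convergent <= 1,
            frac_flat >= 0, frac_convergent + frac_flat <= 1,
            noise_sd >= 0, n_reps >= 1)
  set.seed(seed)
  times <- canonical_grid()
  n_conv <- round(frac_convergent * n_groups)
  n_flat <- round(frac_flat * n_groups)
  label <- c(rep("convergent", n_conv), rep("flat", n_flat),
             rep("non_convergent", n_groups - n_conv - n_flat))
  gid <- sprintf("OG%05d", seq_len(n_groups))
  profs <- stats::setNames(vector("list", 3L), species)
  for (s in species) profs[[s]] <- vector("list", n_groups)
  truth <- data.frame(group_id = gid, label = label,
                      phi = stats::runif(n_groups, 0, 24),
                      amplitude = pmax(stats::rnorm(n_groups,
                                                    amplitude[["mean"]],
                                                    amplitude[["sd"]]), 0),
                      stringsAsFactors = FALSE)
  truth$amplitude[label == "flat"] <- 0
  phases <- matrix(NA_real_, n_groups, 3L,
                   dimnames = list(NULL, names(species)))
  for (g in seq_len(n_groups)) {
    phi <- truth$phi[g]
    phases[g, "cam_dicot"] <- phi + stats::rnorm(1, 0, phase_jitter_cam)
    phases[g, "cam_monocot"] <- phi + stats::rnorm(1, 0, phase_jitter_cam)
    phases[g, "c3"] <-
      if (label[g] == "convergent") phi + phase_at_offset
      else phi + stats::rnorm(1, 0, phase_jitter_cam)
    a <- truth$amplitude[g]
    for (slot in names(species)) {
      sp <- species[[slot]]
      b <- stats::rnorm(1, baseline_log_fpkm[["mean"]],
                        baseline_log_fpkm[["sd"]])
      mu <- b + a * cos(2 * pi * (times - phases[g, slot]) / 24)
      eps <- matrix(stats::rnorm(length(times) * n_reps, 0, noise_sd),
                    length(times), n_reps)
      vals <- exp(mu + eps)
      profs[[sp]][[g]] <- diel_profile(sprintf("%s_g%05d", sp, g), sp,
                                       times, vals)
    }
  }
  truth$phase_kf <- phases[, "cam_dicot"] %% 24
  truth$phase_ac <- phases[, "cam_monocot"] %% 24
  truth$phase_at <- phases[, "c3"] %% 24
  matrices <- lapply(stats::setNames(nm = unname(species)),
                     function(sp) diel_matrix(sp, profs[[sp]]))
  orthogroups <- lapply(seq_len(n_groups), function(g) {
    ortholog_group(gid[g], stats::setNames(
      as.list(sprintf("%s_g%05d", species, g)), species))
  })
  list(matrices = matrices, orthogroups = orthogroups, truth = truth,
       params = list(n_groups = n_groups, frac_convergent = frac_convergent,
                     frac_flat = frac_flat,
                     baseline_log_fpkm = baseline_log_fpkm,
                     amplitude = amplitude,
                     phase_jitter_cam = phase_jitter_cam,
                     phase_at_offset = phase_at_offset, noise_sd = noise_sd,
                     n_reps = n_reps, species = species, seed = seed))
}

#' Simulate a protein alignment on a tree with planted convergent columns
#'
#' The root sequence is drawn uniformly over the 20 amino acids; each branch
#' accumulates `Poisson(branch_length * n_sites)` substitution events at
#' uniformly chosen sites, each replacing the current residue by one of the
#' other 19 uniformly (a Poisson/uniform model; adequate for exercising
#' parsimony and site logic, not an empirical substitution matrix).  At each
#' planted column every foreground leaf is then overwritten with one residue
#' absent from all background leaves at that column (columns where all 20
#' residues occur in the background are resampled).
#'
#' @param tree Rooted `phylo` (or [gene_tree()]) with branch lengths in
#'   expected substitutions/site; tip labels become seq_ids.
#' @param n_sites Alignment length.
#' @param n_planted_sites Number of planted convergent columns.
#' @param foreground Tip labels to overwrite at planted columns.
#' @param seed Integer seed.
#' @return List: `msa` ([protein_msa()]), `tree` (the input as
#'   [gene_tree()]), `truth` (planted columns, residues, event log).
#' @export
simulate_msa_with_convergence <- function(tree, n_sites = 200,
                                          n_planted_sites = 2,
                                          foreground = character(0),
                                          seed = 1) {
  phy <- if (inherits(tree, "gene_tree")) tree$phylo else tree
  stopifnot(inherits(phy, "phylo"), ape::is.rooted(phy),
            n_planted_sites <= n_sites)
  if (is.null(phy$edge.length)) phy$edge.length <- rep(0, nrow(phy$edge))
  set.seed(seed)
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  seqs <- matrix(NA_character_, nn, n_sites)
  root <- ntip + 1L
  seqs[root, ] <- sample(AA_LETTERS, n_sites, replace = TRUE)
  po <- ape::reorder.phylo(phy, "postorder")
  events <- list()
  for (e in rev(seq_len(nrow(po$edge)))) {   # preorder: parent before child
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    s <- seqs[p, ]
    nsub <- stats::rpois(1, po$edge.length[e] * n_sites)
    if (nsub > 0) for (k in seq_len(nsub)) {
      site <- sample.int(n_sites, 1L)
      new <- sample(setdiff(AA_LETTERS, s[site]), 1L)
      events[[length(events) + 1L]] <- data.frame(
        edge_child = ch, site = site, from = s[site], to = new,
        stringsAsFactors = FALSE)
      s[site] <- new
    }
    seqs[ch, ] <- s
  }
  fg_idx <- match(foreground, phy$tip.label)
  if (anyNA(fg_idx)) stop("foreground tip(s) not in tree")
  bg_idx <- setdiff(seq_len(ntip), fg_idx)
  planted <- integer(0); planted_res <- character(0)
  if (n_planted_sites > 0 && length(fg_idx)) {
    pool <- sample.int(n_sites)
    for (site in pool) {
      if (length(planted) == n_planted_sites) break
      absent <- setdiff(AA_LETTERS, unique(seqs[bg_idx, site]))
      if (!length(absent)) next               # impossible column: resample
      res <- if (length(absent) == 1L) absent else sample(absent, 1L)
      seqs[fg_idx, site] <- res
      planted <- c(planted, site); planted_res <- c(planted_res, res)
    }
    ord <- order(planted)
    planted <- planted[ord]; planted_res <- planted_res[ord]
  }
  tipseqs <- apply(seqs[seq_len(ntip), , drop = FALSE], 1L, paste,
                   collapse = "")
  names(tipseqs) <- phy$tip.label
  msa <- protein_msa(tipseqs)
  list(msa = msa, tree = gene_tree(phy),
       truth = list(planted_columns = planted,
                    planted_residues = planted_res,
                    foreground = foreground,
                    events = if (length(events)) do.call(rbind, events)
                             else data.frame(edge_child = integer(0),
                                             site = integer(0),
                                             from = character(0),
                                             to = character(0))))
}

# species tree with every species tip relabelled to one gene id
species_tree_with_genes <- function(species_tree, gene_of) {
  phy <- species_tree
  phy$tip.label <- unname(gene_of[phy$tip.label])
  phy
}

# planted tribe topology: Kf gene re-grafted as sister of the foreground
# monocot gene (the signature convergence imprints on inferred gene trees)
planted_tribe_topology <- function(gene_phy, kf_tip, partner_tip) {
  pruned <- ape::drop.tip(gene_phy, kf_tip)
  pruned$edge.length <- NULL            # topology is all the screen needs
  nwk <- ape::write.tree(pruned)
  nwk2 <- sub(partner_tip, sprintf("(%s,%s)", partner_tip, kf_tip), nwk,
              fixed = TRUE)
  ape::read.tree(text = nwk2)
}

#' Simulate a set of protein tribes with planted sequence convergence
#'
#' Generates `n_tribes` tribes over the preset species set (one gene per
#' species).  Alignments evolve on the species tree; in the first
#' `n_convergent` tribes the CAM-dicot gene and one randomly chosen
#' CAM-monocot gene are foreground for `n_planted_sites` planted convergent
#' columns, and the emitted tribe tree carries the CAM-convergence clade
#' (the CAM-dicot gene re-grafted sister to its foreground partner, the
#' topology convergence imprints on inferred gene trees); other tribes keep
#' the species topology.
#'
#' @param n_tribes Number of tribes.
#' @param n_convergent Number with planted convergence.
#' @param n_sites Alignment length per tribe.
#' @param n_planted_sites Planted columns per convergent tribe.
#' @param roles Species-role vector.
#' @param species_tree Species topology with branch lengths.
#' @param seed Integer seed.
#' @return List: `tribes` (each: `id`, `tree`, `msa`), `truth` (data frame:
#'   tribe, planted, foreground genes, planted columns).
#' @export
simulate_sequence_dataset <- function(n_tribes = 50, n_convergent = 10,
                                      n_sites = 200, n_planted_sites = 2,
                                      roles = cam_species_roles(),
                                      species_tree = default_species_tree(),
                                      seed = 1) {
  stopifnot(n_convergent <= n_tribes)
  set.seed(seed)
  kf_sp <- names(roles)[roles == "CAM_dicot"][1L]
  mono_sp <- names(roles)[roles == "CAM_monocot"]
  tribes <- vector("list", n_tribes)
  truth <- data.frame(tribe = sprintf("TR%04d", seq_len(n_tribes)),
                      planted = seq_len(n_tribes) <= n_convergent,
                      kf_gene = NA_character_, partner_gene = NA_character_,
                      planted_columns = NA_character_,
                      stringsAsFactors = FALSE)
  sub_seeds <- sample.int(2^30, n_tribes)
  for (i in seq_len(n_tribes)) {
    id <- truth$tribe[i]
    gene_of <- stats::setNames(
      sprintf("%s|%sg%04d", species_tree$tip.label, id,
              seq_along(species_tree$tip.label)),
      species_tree$tip.label)
    gphy <- species_tree_with_genes(species_tree, gene_of)
    kf_tip <- gene_of[[kf_sp]]
    if (truth$planted[i]) {
      partner_sp <- if (length(mono_sp) == 1L) mono_sp
                    else sample(mono_sp, 1L)
      partner_tip <- gene_of[[partner_sp]]
      sim <- simulate_msa_with_convergence(
        gphy, n_sites = n_sites, n_planted_sites = n_planted_sites,
        foreground = c(kf_tip, partner_tip), seed = sub_seeds[i])
      tribe_phy <- planted_tribe_topology(gphy, kf_tip, partner_tip)
      truth$kf_gene[i] <- kf_tip
      truth$partner_gene[i] <- partner_tip
      truth$planted_columns[i] <- paste(sim$truth$planted_columns,
                                        collapse = ",")
    } else {
      sim <- simulate_msa_with_convergence(
        gphy, n_sites = n_sites, n_planted_sites = 0,
        foreground = character(0), seed = sub_seeds[i])
      tribe_phy <- gphy
      truth$kf_gene[i] <- kf_tip
    }
    tribes[[i]] <- list(id = id, tree = gene_tree(tribe_phy), msa = sim$msa)
  }
  list(tribes = tribes, truth = truth)
}

#' Simulate a gene-gene similarity graph with planted tribes
#'
#' Dense strong edges (low E-value) inside each planted tribe, sparse weak
#' edges between tribes.  With the default `inter_evalue` above the MCL
#' cutoff the bridges are filtered out and clustering must recover the
#' planted partition exactly.
#'
#' @param n_tribes Number of planted tribes.
#' @param tribe_size Genes per tribe.
#' @param intra_evalue E-value of within-tribe edges.
#' @param inter_evalue E-value of between-tribe bridge edges.
#' @param bridge_prob Probability of a bridge between a pair of tribes.
#' @param seed Integer seed.
#' @return List: `graph` ([similarity_graph()]), `truth` (named membership
#'   vector).
#' @export
simulate_similarity_graph <- function(n_tribes = 5, tribe_size = 6,
                                      intra_evalue = 1e-50,
                                      inter_evalue = 1e-3,
                                      bridge_prob = 0.5, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("g%03d", seq_len(n_tribes * tribe_size))
  member <- rep(seq_len(n_tribes), each = tribe_size)
  edges <- list()
  for (t in seq_len(n_tribes)) {
    ids <- nodes[member == t]
    pairs <- utils::combn(ids, 2L)
    edges[[t]] <- data.frame(gene_a = pairs[1L, ], gene_b = pairs[2L, ],
                             evalue = intra_evalue *
                               10^stats::runif(ncol(pairs), -2, 2),
                             stringsAsFactors = FALSE)
  }
  if (n_tribes > 1L) {
    tp <- utils::combn(seq_len(n_tribes), 2L)
    for (k in seq_len(ncol(tp))) {
      if (stats::runif(1) > bridge_prob) next
      a <- sample(nodes[member == tp[1L, k]], 1L)
      b <- sample(nodes[member == tp[2L, k]], 1L)
      edges[[length(edges) + 1L]] <- data.frame(
        gene_a = a, gene_b = b,
        evalue = inter_evalue * 10^stats::runif(1, -1, 1),
        stringsAsFactors = FALSE)
    }
  }
  graph <- similarity_graph(do.call(rbind, edges), nodes = nodes)
  list(graph = graph, truth = stats::setNames(member, nodes))
}
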