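test_that("expression tables round-trip and preserve shape", {
  tt <- canonical_grid()
  profs <- lapply(c("gA", "gB"), function(g)
    diel_profile(g, "Kf", tt, matrix(runif(36, 0, 10), 12, 3)))
  m <- diel_matrix("Kf", profs)
  expect_identical(dim(m$values), c(2L, 12L, 3L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(m, path)
  m2 <- read_expression_table(path, "Kf")
  expect_identical(genes(m2), genes(m))
  expect_equal(m2$values, m$values, tolerance = 1e-12, ignore_attr = TRUE)
  expect_length(attr(m2, "missing_canonical"), 0)
})

test_that("expression reader rejects malformed and invalid input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tt2_r1\tt4_r1", "g1\t1.0\t-1.0"), path)
  expect_error(read_expression_table(path, "Kf"), "negative")
  writeLines(c("gene_id\tt2_r1\tt4_r1", "g1\t1.0\t2.0", "g1\t3.0\t4.0"), path)
  expect_error(read_expression_table(path, "Kf"), "duplicate")
  writeLines(c("gene_id\tbadcol", "g1\t1.0"), path)
  expect_error(read_expression_table(path, "Kf"), "column name")
  writeLines(c("gene_id\tt2_r1", "g1\tnot_a_number"), path)
  expect_error(read_expression_table(path, "Kf"), "numeric")
})

test_that("4-h sampled tables are flagged as missing canonical points", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(c("gene_id", sprintf("t%d_r1", seq(4, 24, by = 4))),
               collapse = "\t")
  writeLines(c(hdr, paste(c("g1", rep("2.5", 6)), collapse = "\t")), path)
  m <- read_expression_table(path, "At")
  expect_identical(attr(m, "missing_canonical"), seq(2, 22, by = 4))
  expect_identical(m$times, seq(4, 24, by = 4))
})

test_that("orthogroup tables assemble, round-trip and reject cross-group genes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("group_id\tspecies\tgene_id",
               "OG1\tKf\tk1", "OG1\tAc\ta1", "OG1\tAt\tt1"), path)
  gs <- read_orthogroups(path)
  expect_length(gs, 1)
  expect_setequal(names(gs[[1]]$members), c("Kf", "Ac", "At"))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_orthogroups(gs, out)
  expect_equal(lapply(read_orthogroups(out), unclass),
               lapply(gs, unclass))
  writeLines("group_id\tspecies\tgene_id", path)
  expect_identical(read_orthogroups(path), list())
  writeLines(c("group_id\tspecies\tgene_id",
               "OG1\tKf\tk1", "OG2\tKf\tk1"), path)
  expect_error(read_orthogroups(path), "more than one")
})

test_that("alignment FASTA and Newick readers validate and round-trip", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">Kf|g1", "ACDEFGHIKL", ">Ac|g2", "ACDEFGHIK-",
               ">At|g3", "ACDEFGHIKV", ">Os|g4", "ACDEFGAIKV"), fa)
  msa <- read_alignment_fasta(fa)
  expect_s3_class(msa, "protein_msa")
  expect_identical(msa$length, 10L)
  expect_identical(msa$species, c("Kf", "Ac", "At", "Os"))
  out <- withr::local_tempfile(fileext = ".fasta")
  write_alignment_fasta(msa, out)
  expect_identical(read_alignment_fasta(out)$seq, msa$seq)
  writeLines(c(">Kf|g1", "ACDE", ">Ac|g2", "ACD"), fa)
  expect_error(read_alignment_fasta(fa), "ragged")

  nwk <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((Kf|g1,Ac|g2),(At|g3,Os|g4));", nwk)
  tr <- read_tree_newick(nwk)
  expect_length(tr$phylo$tip.label, 4)
  expect_identical(sort(unique(tr$species)), c("Ac", "At", "Kf", "Os"))
  out2 <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(tr, out2)
  tr2 <- read_tree_newick(out2)
  expect_equal(ape::dist.topo(ape::unroot(tr$phylo),
                              ape::unroot(tr2$phylo))[1], 0)
  writeLines("((g1,Ac|g2),(At|g3,Os|g4));", nwk)
  expect_error(read_tree_newick(nwk), "tag")
})

test_that("similarity graphs validate edges and deduplicate", {
  g <- similarity_graph(data.frame(gene_a = c("a", "b", "b"),
                                   gene_b = c("b", "a", "c"),
                                   evalue = c(1e-10, 1e-20, 1e-5)))
  expect_identical(g$nodes, c("a", "b", "c"))
  expect_equal(nrow(g$edges), 2)
  expect_equal(g$edges$evalue[g$edges$gene_a == "a"], 1e-20)
  expect_error(similarity_graph(data.frame(gene_a = "a", gene_b = "a",
                                           evalue = 1e-3)), "self-loop")
})

test_that("result tables round-trip verdict fields in tsv and json", {
  calls <- data.frame(group_id = "OG1", kf_gene = "k1",
                      r_kf_ac = 0.91234567, shift_kf_ac = 1.5,
                      criterion1 = TRUE, criterion2 = TRUE,
                      criterion3 = FALSE, convergent = FALSE,
                      stringsAsFactors = FALSE)
  for (fmt in c("tsv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_results(calls, path, fmt)
    back <- read_results(path, fmt)
    expect_identical(back$convergent, calls$convergent)
    expect_identical(back$criterion1, calls$criterion1)
    expect_equal(back$r_kf_ac, signif(calls$r_kf_ac, 6))
  }
  empty <- calls[0, ]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(empty, path, "tsv")
  expect_identical(readLines(path),
                   paste(names(calls), collapse = "\t"))
})

test_that("config round-trips through yaml and rejects unknown keys", {
  cfg <- cam_config(r_high = 0.85, seed = 7L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$r_high, 0.85)
  expect_equal(cfg2$seed, 7L)
  expect_equal(cfg2$species, cfg$species)
  writeLines("not_a_key: 1", path)
  expect_error(read_config(path), "unknown config key")
})

test_that("profile and matrix constructors enforce invariants", {
  tt <- canonical_grid()
  expect_error(diel_profile("g", "Kf", c(2, 2, 4), 1:3), "increasing")
  expect_error(diel_profile("g", "Kf", c(2, 4), c(-1, 1)), ">= 0")
  expect_error(diel_profile("g", "Kf", c(0, 4), c(1, 1)), "\\(0, 24\\]")
  p1 <- diel_profile("g", "Kf", tt, runif(12))
  expect_error(diel_matrix("Kf", list(p1, p1)), "duplicate")
  expect_error(ortholog_group("OG1", list(Kf = "a", Ac = "a")), "unique")
})
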