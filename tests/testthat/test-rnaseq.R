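test_that("disambiguation keeps exact read accounting", {
  aln <- data.frame(
    read_id = sprintf("r%02d", 1:10),
    maps_human = c(rep(TRUE, 7), FALSE, FALSE, TRUE),
    maps_mouse = c(rep(FALSE, 7), TRUE, TRUE, TRUE),
    gene_id = c(rep("ENSG00001", 4), rep("ENSG00002", 3),
                "ENSMUSG00001", "ENSMUSG00001", NA))
  res <- disambiguate_reads(aln)
  expect_equal(sum(res$counts$human), 7)
  expect_equal(sum(res$counts$mouse), 2)
  expect_equal(res$n_discarded, 1)
  expect_equal(sum(res$report), 1)
  expect_equal(unname(res$report["both"]), 0.1)
  # no ambiguous reads -> empty discard set
  res0 <- disambiguate_reads(aln[1:9, ])
  expect_equal(res0$n_discarded, 0)
  # wrong-species assignment is rejected and logged
  gm <- data.frame(gene_id = c("ENSG00001", "ENSG00002", "ENSMUSG00001"),
                   species = c("human", "human", "mouse"),
                   start = 0, end = 100, strand = "+")
  bad <- aln
  bad$gene_id[8] <- "ENSG00001"           # mouse-only read, human gene
  expect_warning(res_bad <- disambiguate_reads(bad, gm), "wrong species")
  expect_equal(res_bad$n_rejected, 1)
})

test_that("composite gene length is the exon union length", {
  expect_equal(composite_gene_length(rbind(c(100, 200), c(150, 250))), 150)
  expect_equal(composite_gene_length(rbind(c(0, 100), c(200, 300))), 200)
  # bookended exons merge
  expect_equal(composite_gene_length(rbind(c(0, 100), c(100, 180))), 180)
  expect_error(composite_gene_length(rbind(c(10, 10))), "invalid")
  # invariance under permutation and under splitting an exon
  ex <- rbind(c(10, 60), c(40, 120), c(300, 420))
  expect_equal(composite_gene_length(ex),
               composite_gene_length(ex[c(3, 1, 2), ]))
  split_ex <- rbind(c(10, 60), c(40, 80), c(80, 120), c(300, 420))
  expect_equal(composite_gene_length(split_ex), composite_gene_length(ex))
  # 50 random interval sets vs per-base occupancy oracle
  set.seed(31)
  for (i in 1:50) {
    k <- sample(1:12, 1)
    st <- sample(0:2000, k)
    ex <- cbind(st, st + sample(10:400, k, replace = TRUE))
    expect_equal(composite_gene_length(ex), per_base_union_length(ex))
  }
})

test_that("RPKM follows the formula and its invariances", {
  expect_equal(unname(compute_rpkm(matrix(10), lengths = 1000,
                                   totals = 1e6)$rpkm[1]), 10)
  cnt <- matrix(c(0, 5, 20, 8), 2,
                dimnames = list(c("g1", "g2"), NULL))
  em <- compute_rpkm(cnt, lengths = c(g1 = 500, g2 = 2000),
                     totals = c(1e5, 2e5))
  expect_equal(unname(em$rpkm["g1", 1]), 0)
  expect_equal(unname(em$log2["g1", 1]), 0)   # log2(0 + 1)
  expect_equal(unname(em$rpkm["g2", 1]), 1e9 * 5 / (1e5 * 2000))
  # joint scaling of counts and totals leaves RPKM unchanged
  em3 <- compute_rpkm(3 * cnt, lengths = c(g1 = 500, g2 = 2000),
                      totals = 3 * c(1e5, 2e5))
  expect_equal(em3$rpkm, em$rpkm)
  expect_error(compute_rpkm(cnt, lengths = c(g1 = 0, g2 = 10),
                            totals = c(1, 1)), "length")
})

test_that("per-gene ANOVA flags spiked genes and matches a hand oracle", {
  # three-group toy gene: F from hand sums of squares
  v <- c(1.0, 1.2, 0.9, 2.1, 2.3, 2.0, 1.1, 0.8, 1.0)
  g <- rep(c("omalizumab", "a", "b"), each = 3)
  de <- de_anova(matrix(v, 1, dimnames = list("g1", NULL)), g)
  f_hand <- hand_anova_F(v, g)
  p_hand <- pf(f_hand, 2, 6, lower.tail = FALSE)
  expect_equal(unique(de$omnibus_p), p_hand, tolerance = 1e-10)
  # null gene: identical group means
  de0 <- de_anova(matrix(rep(c(1, 2, 3), 3), 1),
                  rep(c("a", "b", "omalizumab"), each = 3))
  expect_false(any(de0$significant))
  # zero-variance gene reports p = 1
  dez <- de_anova(matrix(5, 1, 9), g)
  expect_equal(dez$p_value, c(1, 1))
  expect_equal(dez$log2_ratio, c(0, 0))
  # spiked gene at log2 effect 1 is recovered with the right ratio
  gm <- simulate_gene_models(200, 50, seed = 8)
  des <- rna_sim_design(
    n_genes = 200, groups = c(vanucizumab = 5, omalizumab = 5),
    dispersion = 0.05, library_size = 5e5,
    de_spec = data.frame(gene = 1:10, treatments = "vanucizumab",
                         log2_effect = 1), seed = 9)
  sim <- simulate_xenograft_counts(des, gm)
  expr <- compute_rpkm(sim$counts_human,
                       gene_lengths(gm)[rownames(sim$counts_human)])
  de_s <- de_anova(expr, sim$samples$treatment)
  spiked <- de_s[de_s$gene %in% rownames(sim$counts_human)[1:10], ]
  expect_gte(mean(spiked$significant), 0.9)
  expect_equal(mean(spiked$log2_ratio), 1, tolerance = 0.3)
})

test_that("exclusivity partition is exact set algebra", {
  sets <- list(vanucizumab = c("a", "b", "c"), LC06 = "b",
               bevacizumab = c("c", "z"))
  p <- classify_de_sets(sets)
  expect_equal(p$vanucizumab_only, "a")
  expect_equal(p$vanucizumab_LC06_only, "b")
  expect_equal(p$vanucizumab_bevacizumab_only, "c")
  expect_equal(p$all_three, character(0))
  expect_equal(p$other, "z")
  # all sets equal -> everything in the all-three block
  pe <- classify_de_sets(list(vanucizumab = c("x", "y"), LC06 = c("x", "y"),
                              bevacizumab = c("x", "y")))
  expect_equal(sort(pe$all_three), c("x", "y"))
  expect_true(all(lengths(pe[names(pe) != "all_three"]) == 0))
  # random sets: blocks disjoint, union preserved, sizes match brute force
  set.seed(17)
  genes <- sprintf("g%03d", 1:100)
  rs <- lapply(c(vanucizumab = 40, LC06 = 30, bevacizumab = 30),
               function(k) sample(genes, k))
  pr <- classify_de_sets(rs)
  all_g <- unlist(pr)
  expect_equal(anyDuplicated(all_g), 0)
  expect_setequal(all_g, unique(unlist(rs)))
  brute <- vapply(genes, function(g) {
    v <- g %in% rs$vanucizumab; l <- g %in% rs$LC06; b <- g %in% rs$bevacizumab
    if (v && !l && !b) "vanucizumab_only"
    else if (v && l && !b) "vanucizumab_LC06_only"
    else if (v && !l && b) "vanucizumab_bevacizumab_only"
    else if (v && l && b) "all_three"
    else if (l || b) "other" else "none"
  }, character(1))
  for (blk in names(pr))
    expect_equal(length(pr[[blk]]), sum(brute == blk))
})

test_that("gene models round-trip through GTF", {
  gm <- simulate_gene_models(5, 0, seed = 2)
  gtf <- file.path(tempdir(), "toy.gtf")
  lines <- sprintf(
    "chr1\tsynthetic\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
    gm$start + 1, gm$end, gm$strand, gm$gene_id)
  writeLines(lines, gtf)
  rt <- read_gene_models_gtf(gtf, species = "human")
  expect_equal(nrow(rt), nrow(gm))
  expect_equal(gene_lengths(rt), gene_lengths(gm))
})
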