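# Synthetic-data generator: determinism, planted effect recovery,
# correlation structure, paired-cohort consistency, cell profiles.

test_that("design validation rejects impossible configurations", {
  expect_error(synth_design(frac_concordant_up = 0.7, frac_discordant = 0.5),
               "sum to <= 1")
  expect_error(synth_design(biotype_props = c(a = 0.5, b = 0.4)), "sum to 1")
  expect_error(synth_design(ortholog_coverage = 0), "ortholog_coverage")
  expect_error(synth_design(n_per_group = 2), "n_per_group")
  expect_error(synth_design(n_genes = 100,
                            modules = list(module_spec(80, 0.5, 0.5, "withdrawal"),
                                           module_spec(80, 0.5, 0.5, "withdrawal"))),
               "module overlap")
  expect_error(module_spec(10, 1, 0.5, "withdrawal"), "within")
})

test_that("identical design and seed give bit-identical cohorts", {
  d <- tiny_pair_design(seed = 4)
  g1 <- generate_cohort(d, seed = 4)
  g2 <- generate_cohort(d, seed = 4)
  expect_identical(g1$matrix$values, g2$matrix$values)
  expect_identical(g1$truth$genes, g2$truth$genes)
  g3 <- generate_cohort(d, seed = 5)
  expect_false(identical(g1$matrix$values, g3$matrix$values))
})

test_that("null design has no planted effects and vanishing mean |log2FC|", {
  d <- synth_design(n_genes = 3000, groups = c("control", "withdrawal"),
                    n_per_group = 40, sexes = "F", noise_sd = 0.5, seed = 2)
  g <- generate_cohort(d, seed = 2)
  expect_true(all(g$truth$genes$lfc_a == 0))
  fit <- fit_linear_de(g$matrix, c("control", "withdrawal"))
  expect_lt(mean(abs(fit$log2FC)), 0.5 * sqrt(2 / 40) * 1.2)
  expect_lt(abs(mean(fit$log2FC)), 0.02)
})

test_that("planted concordant-up effects are recovered by the linear fit", {
  d <- synth_design(n_genes = 2000, groups = c("control", "withdrawal"),
                    n_per_group = 20, sexes = "F", frac_concordant_up = 0.1,
                    effect_mean = 1, effect_sd = 0.2, noise_sd = 0.5, seed = 3)
  g <- generate_cohort(d, seed = 3)
  up <- g$truth$genes$class == "conc_up"
  expect_equal(sum(up), 200)
  fit <- fit_linear_de(g$matrix, c("control", "withdrawal"))
  expect_lt(abs(mean(fit$log2FC[up]) - 1), 0.1)
})

test_that("planted within-module correlation matches r to within 0.05 at n = 200", {
  d <- synth_design(n_genes = 300, groups = c("control", "withdrawal"),
                    n_per_group = 100, sexes = c("F", "M"), noise_sd = 0.4,
                    modules = list(module_spec(40, 0.3, 0.7, "withdrawal")),
                    seed = 8)
  g <- generate_cohort(d, seed = 8)
  mem <- g$truth$genes$gene[!is.na(g$truth$genes$module)]
  ctrl <- g$matrix$samples$sample[g$matrix$samples$group == "control"]
  trt <- g$matrix$samples$sample[g$matrix$samples$group == "withdrawal"]
  rc <- cor(t(g$matrix$values[mem, ctrl]))
  rt <- cor(t(g$matrix$values[mem, trt]))
  expect_lt(abs(mean(rc[upper.tri(rc)]) - 0.3), 0.05)
  expect_lt(abs(mean(rt[upper.tri(rt)]) - 0.7), 0.05)
})

test_that("paired cohorts respect concordance classes and ortholog coverage", {
  d <- tiny_pair_design(n_genes = 1000, seed = 6, frac_discordant = 1,
                        ortholog_coverage = 0.8)
  pr <- generate_pair(d, d, seed = 6)
  tg <- pr$truth$genes
  expect_true(all(sign(tg$lfc_a) == -sign(tg$lfc_b)))
  expect_equal(nrow(pr$ortholog_map), 800)
  expect_identical(pr$ortholog_map$symbol_a, toupper(pr$ortholog_map$symbol_a))
  expect_false(any(pr$ortholog_map$symbol_b == toupper(pr$ortholog_map$symbol_b)))
})

test_that("truth classes are self-consistent with the planted effect signs", {
  d <- tiny_pair_design(n_genes = 2000, seed = 9, frac_concordant_up = 0.1,
                        frac_concordant_down = 0.1, frac_discordant = 0.1,
                        frac_unique_a = 0.1, frac_unique_b = 0.1)
  pr <- generate_pair(d, d, seed = 9)
  tg <- pr$truth$genes
  recovered <- with(tg, ifelse(
    lfc_a > 0 & lfc_b > 0, "conc_up",
    ifelse(lfc_a < 0 & lfc_b < 0, "conc_down",
    ifelse(lfc_a != 0 & lfc_b != 0, "disc",
    ifelse(lfc_a != 0, "unique_a",
    ifelse(lfc_b != 0, "unique_b", "null"))))))
  expect_identical(recovered, tg$class)
  # class fractions near design values
  expect_lt(max(abs(table(tg$class)[c("conc_up", "disc")] / 2000 - 0.1)), 0.001)
})

test_that("mismatched group labels abort pairing", {
  d1 <- tiny_pair_design(seed = 1)
  d2 <- synth_design(n_genes = 300, groups = c("control", "abstinence"),
                     n_per_group = 8, sexes = c("F", "M"), seed = 1)
  expect_error(generate_pair(d1, d2), "group labels")
})

test_that("cell profiles are reproducible and rank module genes as planted", {
  univ <- sprintf("G%04d", 1:400)
  mod <- univ[1:20]
  expect_error(generate_cell_profiles(10, "A", character(0), "A", univ),
               "non-empty")
  expect_error(generate_cell_profiles(10, "A", mod, "B", univ), "subset")
  p1 <- generate_cell_profiles(60, c("MSN", "astro"), mod, "MSN", univ, seed = 3)
  p2 <- generate_cell_profiles(60, c("MSN", "astro"), mod, "MSN", univ, seed = 3)
  expect_identical(p1$values, p2$values)
  auc <- aucell_score(p1$values, mod, top_fraction = 0.1, ranked = FALSE)
  expect_gt(median(auc[p1$cell_type == "MSN"]), median(auc[p1$cell_type == "astro"]))
})

test_that("with every type enriched, AUC is exchangeable across types", {
  univ <- sprintf("G%04d", 1:400)
  mod <- univ[1:20]
  p <- generate_cell_profiles(500, c("A", "B"), mod, c("A", "B"), univ, seed = 11)
  auc <- aucell_score(p$values, mod, top_fraction = 0.1, ranked = FALSE)
  w <- wilcox.test(auc[p$cell_type == "A"], auc[p$cell_type == "B"])
  expect_gt(w$p.value, 0.01)
})

test_that("with no type enriched, mean AUC matches the permutation average", {
  univ <- sprintf("G%04d", 1:400)
  mod <- univ[1:20]
  p <- generate_cell_profiles(1000, c("A", "B"), mod, character(0), univ, seed = 5)
  auc <- aucell_score(p$values, mod, top_fraction = 0.1, ranked = FALSE)
  # permutation oracle: naive area over random rank draws
  set.seed(99)
  oracle <- mean(replicate(2000, {
    r <- sample(400, 20)
    brute_aucell(r[r <= 40], 40, 20)
  }))
  expect_lt(abs(mean(auc) - oracle), 0.02)
})
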