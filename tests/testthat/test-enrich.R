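# Enrichment statistics: Fisher/hypergeometric, ORA over GMT collections,
# AUCell scoring, group comparison of module scores.

test_that("fisher enrichment reproduces the 2x2 hand table", {
  bg <- sprintf("g%04d", 1:5000)
  target <- bg[1:100]                       # K = 100
  query <- c(bg[1:5], bg[101:145])          # n = 50, k = 5
  r <- fisher_enrichment(query, target, bg)
  expect_equal(r$k, 5); expect_equal(r$K, 100); expect_equal(r$n, 50)
  expect_equal(r$odds_ratio, (5 * 4855) / (45 * 95), tolerance = 1e-4)
  expect_equal(r$p, hypergeom_tail(5000, 100, 50, 5), tolerance = 1e-12)
  expect_false(r$continuity)
  expect_error(fisher_enrichment(c(query, "nope"), target, bg), "nope")
})

test_that("disjoint small sets in a large background give OR near 0 and p near 1", {
  bg <- sprintf("g%04d", 1:2000)
  r <- fisher_enrichment(bg[1:10], bg[11:20], bg)
  expect_equal(r$odds_ratio, 0)
  expect_gt(r$p, 0.9)
  expect_false(r$continuity)                # zero overlap, denominator intact
})

test_that("fisher enrichment is symmetric in query and target", {
  bg <- sprintf("g%04d", 1:500)
  set.seed(4)
  q <- sample(bg, 40); t <- sample(bg, 60)
  r1 <- fisher_enrichment(q, t, bg)
  r2 <- fisher_enrichment(t, q, bg)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_equal(r1$odds_ratio, r2$odds_ratio, tolerance = 1e-12)
})

test_that("ORA filters sets to the background and composes with BH", {
  bg <- sprintf("g%04d", 1:300)
  coll <- list(self = bg[1:20], half = bg[10:29], out = paste0("x", 1:5),
               rest = bg[100:160])
  res <- ora(coll, query = bg[1:20], background = bg)
  expect_equal(nrow(res), 3)                # 'out' has empty intersection
  expect_equal(res$set[1], "self")
  expect_equal(res$k[res$set == "self"], 20)
  expect_equal(res$q, adjust_bh(res$p), tolerance = 1e-12)
  expect_error(ora(coll, character(0), bg), "empty query")
})

test_that("ORA recovers a planted pathway as the top hit", {
  wins <- 0
  for (i in 1:20) {
    d <- synth_design(n_genes = 500, groups = c("control", "withdrawal"),
                      n_per_group = 12, sexes = "F", frac_concordant_up = 0.1,
                      effect_mean = 1.2, seed = 50 + i)
    g <- generate_cohort(d, seed = 50 + i)
    de <- run_de(g$matrix, c("control", "withdrawal"))
    truth_up <- g$truth$genes$gene[g$truth$genes$class == "conc_up"]
    bg <- g$matrix$genes$gene
    set.seed(i)
    coll <- list(true_pathway = truth_up,
                 decoy1 = sample(bg, 50), decoy2 = sample(bg, 50))
    query <- de$gene[de$class == "up"]
    if (length(query) < 3) next
    res <- ora(coll, query, bg)
    if (res$set[1] == "true_pathway") wins <- wins + 1
  }
  expect_gte(wins / 20, 0.95)
})

test_that("GMT parsing handles the format and reports bad lines", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg4"), path)
  gmt <- read_gmt(path)
  expect_equal(names(gmt), c("setA", "setB"))
  expect_equal(gmt$setB, c("g2", "g4"))
  writeLines(c("setA\tdesc\tg1", "short\tonly"), path)
  expect_error(read_gmt(path), "line 2")
})

test_that("AUCell hits the analytic extremes", {
  genes <- sprintf("g%03d", 1:200)
  ranks <- matrix(1:200, 200, 1, dimnames = list(genes, "best"))
  # module at the very top: AUC exactly 1 under max-area normalization
  expect_equal(unname(aucell_score(ranks, genes[1:5], top_fraction = 0.1)), 1)
  expect_gt(unname(aucell_score(ranks, genes[1:5], top_fraction = 0.1)), 0.95)
  # module entirely below the window: AUC 0
  expect_equal(unname(aucell_score(ranks, genes[50:60], top_fraction = 0.1)), 0)
  expect_error(aucell_score(ranks, genes[1:5], top_fraction = 0.001),
               "at least 1")
  expect_error(aucell_score(ranks, "missing", top_fraction = 0.1), "absent")
})

test_that("AUCell is invariant to relabeling of non-module genes", {
  set.seed(21)
  genes <- sprintf("g%03d", 1:100)
  vals <- matrix(rnorm(100 * 8), 100, 8, dimnames = list(genes, NULL))
  mod <- genes[1:10]
  a1 <- aucell_score(vals, mod, top_fraction = 0.2, ranked = FALSE)
  shuffled <- vals
  rownames(shuffled) <- c(genes[1:10], sample(genes[11:100]))
  a2 <- aucell_score(shuffled, mod, top_fraction = 0.2, ranked = FALSE)
  expect_equal(unname(a1), unname(a2))
})

test_that("group comparison of scores behaves under null and planted effects", {
  set.seed(31)
  auc <- runif(60)
  groups <- rep(c("UC", "OUD"), 30)
  # identical score vectors in both groups: p should be large
  r0 <- compare_module_scores(c(auc, auc), rep(c("UC", "OUD"), each = 60))
  expect_gt(r0$p, 0.5)
  # monotone transformation leaves rank-based p unchanged
  ct <- rep(c("MSN", "astro"), each = 30)
  r1 <- compare_module_scores(auc, groups, ct)
  r2 <- compare_module_scores(auc^3, groups, ct)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_equal(r1$q, adjust_bh(r1$p))
  # a stratum with one group only is skipped with a warning
  expect_warning(
    r3 <- compare_module_scores(auc, groups,
                                ifelse(seq_along(auc) <= 2, "lonely", "rest")),
    "skipped")
  expect_false("lonely" %in% r3$cell_type)
})

test_that("a planted cell-type-specific effect yields the minimal p in that stratum", {
  univ <- sprintf("g%03d", 1:300)
  mod <- univ[1:15]
  wins <- 0
  for (i in 1:20) {
    prof_uc <- generate_cell_profiles(90, c("MSN", "astro", "oligo"), mod,
                                      "MSN", univ, boost = 2, seed = 70 + i)
    prof_oud <- generate_cell_profiles(90, c("MSN", "astro", "oligo"), mod,
                                       "MSN", univ, boost = 1, seed = 170 + i)
    auc <- c(aucell_score(prof_uc$values, mod, 0.1, ranked = FALSE),
             aucell_score(prof_oud$values, mod, 0.1, ranked = FALSE))
    groups <- rep(c("UC", "OUD"), each = 90)
    ct <- c(prof_uc$cell_type, prof_oud$cell_type)
    res <- compare_module_scores(auc, groups, ct)
    if (res$cell_type[which.min(res$p)] == "MSN") wins <- wins + 1
  }
  expect_gte(wins / 20, 0.9)
})

test_that("module/DE enrichment flags the module holding the DE genes", {
  d <- synth_design(n_genes = 400, groups = c("control", "withdrawal"),
                    n_per_group = 15, sexes = "F", seed = 61)
  g <- generate_cohort(d, seed = 61)
  lab <- setNames(rep(c("blue", "red", "grey"), c(50, 50, 300)),
                  g$matrix$genes$gene)
  de <- data.frame(gene = g$matrix$genes$gene,
                   class = ifelse(seq_len(400) %in% 1:30, "up", "ns"))
  res <- module_de_enrichment(de, lab)
  expect_equal(res$module[1], "blue")
  expect_lt(res$p[1], 0.001)
})
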