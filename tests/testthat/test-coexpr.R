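# Co-expression networks: gene selection, soft threshold, adjacency, TOM,
# module detection, eigengenes, MI network with DPI, hubs.

sim_mat <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)), NULL))
}

test_that("variable-gene selection equals a brute-force variance sort", {
  d <- synth_design(n_genes = 150, groups = c("control", "withdrawal"),
                    n_per_group = 5, sexes = "F", seed = 1)
  g <- generate_cohort(d, seed = 1)
  got <- select_variable_genes(g$matrix, 40)
  v <- apply(g$matrix$values, 1, var)
  brute <- names(sort(v, decreasing = TRUE))[1:40]
  expect_setequal(got, brute)
  expect_setequal(select_variable_genes(g$matrix, 1e6), g$matrix$genes$gene)
  # constant gene never selected before a varying one
  m2 <- g$matrix
  m2$values[1, ] <- 5
  expect_false(g$matrix$genes$gene[1] %in% select_variable_genes(m2, 149))
  expect_error(select_variable_genes(g$matrix, 0), "positive")
})

test_that("soft-threshold selection falls back on noise and matches grid search", {
  noise <- sim_mat(80, 30, 2)
  expect_warning(st <- pick_soft_threshold(noise), "falling back")
  expect_equal(st$beta, 6)
  # planted-module data: chosen beta equals the smallest passing power
  d <- synth_design(n_genes = 300, groups = c("control", "withdrawal"),
                    n_per_group = 25, sexes = c("F", "M"),
                    modules = list(module_spec(60, 0.6, 0.6, "withdrawal"),
                                   module_spec(60, 0.4, 0.4, "withdrawal")),
                    seed = 3)
  g <- generate_cohort(d, seed = 3)
  st2 <- pick_soft_threshold(g$matrix)
  passing <- st2$fit_table$power[st2$fit_table$r2 >= 0.8 &
                                   st2$fit_table$mean_k >= 1]
  if (length(passing)) {
    expect_equal(st2$beta, min(passing))
    expect_gte(st2$fit_table$r2[st2$fit_table$power == st2$beta], 0.8)
  } else {
    expect_equal(st2$beta, 6)
  }
})

test_that("adjacency is |cor|^beta with unit diagonal", {
  v <- sim_mat(3, 50, 4)
  v[2, ] <- v[1, ]                         # identical genes
  A <- adjacency(v, 6)
  expect_equal(A[1, 2], 1)
  expect_equal(diag(A), rep(1, 3), ignore_attr = TRUE)
  # brute-force pairwise correlation loop at beta = 1
  v2 <- sim_mat(6, 40, 5)
  A1 <- adjacency(v2, 1)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(A1[i, j], abs(cor(v2[i, ], v2[j, ])), tolerance = 1e-12)
  }
  v3 <- sim_mat(3, 20, 6)
  v3[3, ] <- 2
  expect_warning(A3 <- adjacency(v3, 2), "zero-variance")
  expect_equal(A3[1, 3], 0)
})

test_that("TOM matches hand arithmetic and stays within [0, 1]", {
  # no connections: off-diagonal TOM is 0
  I3 <- diag(3)
  t0 <- tom_similarity(I3)
  expect_equal(t0[upper.tri(t0)], rep(0, 3))
  # all off-diagonal 0.5: TOM_ij = (0.25 + 0.5) / (1 + 1 - 0.5) = 0.5
  A <- matrix(0.5, 3, 3); diag(A) <- 1
  tt <- tom_similarity(A)
  expect_equal(tt[1, 2], 0.5, tolerance = 1e-12)
  # random adjacency: symmetric, bounded, unit diagonal
  set.seed(9)
  R <- abs(cor(matrix(rnorm(300), 20, 15)))
  tr <- tom_similarity(R)
  expect_true(all(tr >= 0 & tr <= 1 + 1e-12))
  expect_equal(tr, t(tr))
  expect_equal(diag(tr), rep(1, 15), ignore_attr = TRUE)
})

test_that("perfect block-diagonal TOM yields exact module memberships", {
  n <- 150
  tm <- matrix(0, n, n, dimnames = list(sprintf("g%03d", 1:n), NULL))
  for (b in 0:2) tm[b * 50 + 1:50, b * 50 + 1:50] <- 0.8
  diag(tm) <- 1
  lab <- detect_modules(tm, min_size = 30)
  expect_equal(length(setdiff(unique(lab), "grey")), 3)
  truth <- rep(1:3, each = 50)
  expect_equal(length(unique(paste(lab, truth))), 3)
})

test_that("pure-noise TOM leaves genes unassigned at min_size 30", {
  grey_runs <- 0
  for (i in 1:10) {
    v <- sim_mat(100, 30, 40 + i)
    tm <- tom_similarity(adjacency(v, 6))
    lab <- suppressWarnings(detect_modules(tm, min_size = 30))
    if (mean(lab == "grey") == 1) grey_runs <- grey_runs + 1
  }
  expect_gt(grey_runs, 5)
})

test_that("planted four-module structure is recovered with high ARI", {
  skip_if_not_installed("mclust")
  mods <- list(module_spec(60, 0.6, 0.6, "withdrawal"),
               module_spec(90, 0.6, 0.6, "withdrawal"),
               module_spec(120, 0.6, 0.6, "withdrawal"),
               module_spec(150, 0.6, 0.6, "withdrawal"))
  d <- synth_design(n_genes = 600, groups = c("control", "withdrawal"),
                    n_per_group = 25, sexes = c("F", "M"), modules = mods,
                    noise_sd = 0.5, seed = 13)
  g <- generate_cohort(d, seed = 13)
  tm <- tom_similarity(adjacency(g$matrix$values, 6))
  lab <- detect_modules(tm, expr = g$matrix$values)
  truth <- ifelse(is.na(g$truth$genes$module), "grey", g$truth$genes$module)
  expect_gte(mclust::adjustedRandIndex(lab, truth), 0.8)
})

test_that("eigengenes are unit-norm, sign-oriented, and match an SVD oracle", {
  v <- sim_mat(30, 40, 7)
  lab <- setNames(rep(c("blue", "red"), each = 15), rownames(v))
  eg <- module_eigengene(v, lab)
  for (m in c("blue", "red")) {
    e <- eg$eigengenes[, m]
    expect_equal(sum(e^2), 1, tolerance = 1e-9)
    z <- t(scale(t(v[lab == m, ])))
    expect_gt(cor(e, colMeans(z)), 0)
    d <- svd(t(z))$d
    expect_equal(eg$var_explained[[m]], d[1]^2 / sum(d^2), tolerance = 1e-9)
  }
  # module of identical profiles: kME = 1 for all members
  v2 <- sim_mat(5, 30, 8)
  v2[2:5, ] <- rep(v2[1, ], each = 4) + matrix(rnorm(120, 0, 1e-8), 4)
  lab2 <- setNames(rep("blue", 5), rownames(v2)[1:5])
  eg2 <- module_eigengene(v2, lab2)
  expect_true(all(abs(eg2$kme[, "blue"]) > 0.999))
})

test_that("MI network keeps direct edges and DPI prunes the indirect one", {
  v <- sim_mat(2, 100, 10)
  # two genes only: retained iff above threshold
  e <- mi_network_dpi(v, rownames(v), mi_threshold = 0)
  expect_equal(nrow(e), 1)
  e2 <- mi_network_dpi(v, rownames(v), mi_threshold = 10)
  expect_equal(nrow(e2), 0)
  expect_error(mi_network_dpi(v[1, , drop = FALSE], "g001", 0), "2 genes")
  # Gaussian chain: X-Z removed
  set.seed(11)
  n <- 200
  x <- rnorm(n); y <- 0.8 * x + sqrt(1 - 0.64) * rnorm(n)
  z <- 0.8 * y + sqrt(1 - 0.64) * rnorm(n)
  ch <- rbind(X = x, Y = y, Z = z)
  edges <- mi_network_dpi(ch, c("X", "Y", "Z"), mi_threshold = 0.05)
  pairs <- paste(edges$gene_a, edges$gene_b)
  expect_true(all(c("X Y", "Y Z") %in% pairs))
  expect_false("X Z" %in% pairs)
})

test_that("independent triples give no edges at a permutation-calibrated threshold", {
  v <- sim_mat(3, 100, 12)
  thr <- mi_threshold_permutation(v, rownames(v), n_perm = 300, seed = 3)
  e <- mi_network_dpi(v, rownames(v), mi_threshold = thr)
  expect_lte(nrow(e), 1)  # at the 95th percentile an occasional edge survives
})

test_that("DPI never removes an edge that is strongest in all its triangles", {
  set.seed(14)
  v <- sim_mat(6, 80, 15)
  v[2, ] <- v[1, ] + rnorm(80, 0, 0.2)      # strongest dependency
  edges <- mi_network_dpi(v, rownames(v), mi_threshold = 0)
  pairs <- paste(edges$gene_a, edges$gene_b)
  expect_true("g001 g002" %in% pairs)
})

test_that("hub ranking matches a brute-force degree sort", {
  genes <- sprintf("h%02d", 1:8)
  set.seed(16)
  edges <- data.frame(gene_a = rep(genes[1], 7), gene_b = genes[2:8],
                      mi = runif(7))
  edges <- rbind(edges, data.frame(gene_a = genes[2], gene_b = genes[3], mi = 2))
  lab <- setNames(rep("blue", 8), genes)
  kme <- matrix(0, 8, 1, dimnames = list(genes, "blue"))
  hs <- suppressWarnings(identify_hubs(kme, lab, top_k = 3, mi_edges = edges))
  deg <- setNames(numeric(8), genes)
  for (i in seq_len(nrow(edges))) {
    deg[edges$gene_a[i]] <- deg[edges$gene_a[i]] + edges$mi[i]
    deg[edges$gene_b[i]] <- deg[edges$gene_b[i]] + edges$mi[i]
  }
  brute_top <- names(sort(deg, decreasing = TRUE))[1:3]
  expect_setequal(hs$blue$gene[hs$blue$is_hub], brute_top)
  # identical case/control networks: no condition-specific hubs
  hs2 <- suppressWarnings(identify_hubs(kme, lab, top_k = 3,
                                        mi_edges_case = edges,
                                        mi_edges_control = edges))
  expect_false(any(hs2$blue$condition_specific))
})

test_that("a gene equal to the eigengene ranks first by kME", {
  v <- sim_mat(10, 50, 17)
  lab <- setNames(rep("blue", 10), rownames(v))
  eg <- module_eigengene(v, lab)
  v2 <- rbind(v, E = eg$eigengenes[, "blue"])
  lab2 <- setNames(rep("blue", 11), rownames(v2))
  eg2 <- module_eigengene(v2, lab2)
  hs <- suppressWarnings(identify_hubs(eg2$kme, lab2, top_k = 1))
  expect_equal(hs$blue$gene[1], "E")
})

test_that("network results are invariant to gene and sample order", {
  v <- sim_mat(20, 30, 18)
  A <- adjacency(v, 6)
  perm_g <- sample(20); perm_s <- sample(30)
  A2 <- adjacency(v[perm_g, perm_s], 6)
  expect_equal(A2, A[perm_g, perm_g], tolerance = 1e-12)
  expect_equal(tom_similarity(A2), tom_similarity(A)[perm_g, perm_g],
               tolerance = 1e-12)
})
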