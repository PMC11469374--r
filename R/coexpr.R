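# Weighted co-expression module detection: soft-thresholded adjacency,
# topological overlap, average-linkage tree cut with eigengene merging,
# kME, and mutual-information hub networks pruned by the data-processing
# inequality.

module_palette <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "lightgreen", "darkorange", "yellowgreen", "tan",
  "salmon", "cyan", "midnightblue", "lightcyan", "grey60", "royalblue",
  "darkred", "darkgreen", "darkturquoise", "orange", "skyblue", "saddlebrown",
  "steelblue", "paleturquoise", "violet", "darkolivegreen", "darkmagenta")

#' Select the most variable genes
#'
#' Top-`n` genes by variance across all samples; ties broken by gene id so
#' the subset is deterministic.
#'
#' @param mat an [expression_matrix()].
#' @param n number of genes to keep (default 5000, the conventional analyzed
#'   universe that later serves as the enrichment background).
#' @return character vector of selected gene ids.
#' @export
select_variable_genes <- function(mat, n = 5000) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (n <= 0) stop("n must be positive", call. = FALSE)
  n <- min(n, nrow(mat$values))
  v <- apply(mat$values, 1, stats::var)
  ord <- order(-v, mat$genes$gene)
  mat$genes$gene[ord[seq_len(n)]]
}

# Scale-free model fit of a degree distribution: R^2 of the linear fit of
# log10 p(k) on log10 k over `bins` equal-width degree bins, required to
# have a negative slope.
scale_free_fit <- function(k, bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(0)
  cut_pts <- seq(min(k), max(k), length.out = bins + 1)
  bin <- cut(k, cut_pts, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mids <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3) return(0)
  x <- log10(mids[keep]); y <- log10(freq[keep] / sum(freq[keep]))
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  if (stats::coef(fit)[2] >= 0) 0 else r2
}

#' Choose the soft-threshold power
#'
#' Smallest power whose network degree distribution satisfies an approximate
#' scale-free fit (`R^2 >= r2_target` with negative slope) while retaining a
#' mean connectivity of at least `min_mean_k` (high powers on noise shrink
#' all degrees toward zero, where an apparent power-law fit is vacuous);
#' falls back to 6 with a warning when no power qualifies.
#'
#' @param mat an [expression_matrix()] or a genes x samples numeric matrix.
#' @param powers candidate powers.
#' @param r2_target scale-free fit target (default 0.8).
#' @param min_mean_k minimum mean connectivity for a power to qualify.
#' @return list with `beta`, and `fit_table` (power, r2, mean_k).
#' @export
pick_soft_threshold <- function(mat, powers = 1:20, r2_target = 0.8,
                                min_mean_k = 1) {
  v <- if (inherits(mat, "expression_matrix")) mat$values else as.matrix(mat)
  if (ncol(v) < 10) warning("fewer than 10 samples: power selection is unstable", call. = FALSE)
  cc <- abs(suppressWarnings(stats::cor(t(v))))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 0
  fit <- vapply(powers, function(p) {
    k <- colSums(cc^p)
    c(r2 = scale_free_fit(k), mean_k = mean(k))
  }, numeric(2))
  tab <- data.frame(power = powers, r2 = fit["r2", ], mean_k = fit["mean_k", ])
  ok <- which(tab$r2 >= r2_target & tab$mean_k >= min_mean_k)
  if (length(ok) == 0) {
    warning("no power reaches the scale-free fit target; falling back to beta = 6",
            call. = FALSE)
    beta <- 6
  } else {
    beta <- powers[min(ok)]
  }
  list(beta = beta, fit_table = tab)
}

#' Unsigned weighted adjacency
#'
#' `A_ij = |cor(x_i, x_j)|^beta` (Pearson), symmetric with unit diagonal.
#' Zero-variance genes get zero correlations with a warning.
#'
#' @param mat an [expression_matrix()] or genes x samples matrix.
#' @param beta soft-threshold power.
#' @param genes optional gene subset (ids for an `expression_matrix`, row
#'   names or indices otherwise).
#' @return adjacency matrix.
#' @export
adjacency <- function(mat, beta, genes = NULL) {
  v <- if (inherits(mat, "expression_matrix")) mat$values else as.matrix(mat)
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (ncol(v) < 3) stop("need at least 3 samples", call. = FALSE)
  sds <- apply(v, 1, stats::sd)
  cc <- suppressWarnings(stats::cor(t(v)))
  if (any(sds == 0)) {
    warning("zero-variance genes: correlations set to 0", call. = FALSE)
    cc[sds == 0, ] <- 0
    cc[, sds == 0] <- 0
  }
  A <- abs(cc)^beta
  diag(A) <- 1
  A
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u A_iu A_uj + A_ij) / (min(k_i, k_j) + 1 - A_ij)` with
#' `k_i = sum_{u != i} A_iu` and the shared-neighbour sum over `u != i, j`.
#'
#' @param A adjacency matrix (entries in \[0,1\], unit diagonal).
#' @return TOM matrix, symmetric, entries in \[0,1\], unit diagonal.
#' @export
tom_similarity <- function(A) {
  A <- as.matrix(A)
  k <- colSums(A) - diag(A)
  L <- A %*% A - 2 * A            # removes u = i and u = j terms (diag(A) = 1)
  kmin <- outer(k, k, pmin)
  tom <- (L + A) / (kmin + 1 - A)
  diag(tom) <- 1
  tom[tom < 0] <- 0
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, a static height cut
#' at the `cut_quantile` quantile of merge heights, removal of clusters
#' below `min_size` (label `"grey"`), and optional merging of modules whose
#' eigengenes correlate above `1 - merge_height` (requires the expression
#' matrix). Modules are named by size rank from a fixed colour palette.
#'
#' The default cut quantile of 0.7 reflects the shape of average-linkage
#' TOM dendrograms: merges below it are dominated by cohesive within-module
#' joins, while the highest merges attach isolated background genes one by
#' one, so a cut near the top would leave a single giant cluster.
#'
#' @param tom TOM (or any similarity in \[0,1\]) with gene dimnames.
#' @param expr optional genes x samples matrix (same genes) enabling
#'   eigengene merging.
#' @param min_size minimum module size (default 30).
#' @param merge_height eigengene dissimilarity threshold below which modules
#'   merge (default 0.15).
#' @param cut_quantile quantile of merge heights at which the tree is cut
#'   (default 0.7).
#' @return named character vector: gene -> module colour (`"grey"` =
#'   unassigned).
#' @export
detect_modules <- function(tom, expr = NULL, min_size = 30, merge_height = 0.15,
                           cut_quantile = 0.7) {
  g <- rownames(tom) %||% paste0("g", seq_len(nrow(tom)))
  h <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  # guard against tiny floating-point non-monotonicity in tied merge heights
  h$height <- round(h$height, 10)
  if (is.unsorted(h$height)) h$height <- cummax(h$height)
  cut_h <- stats::quantile(h$height, cut_quantile, names = FALSE)
  raw <- stats::cutree(h, h = cut_h)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  lab <- ifelse(raw %in% as.integer(keep), as.character(raw), "grey")
  names(lab) <- g
  if (all(lab == "grey")) {
    warning("no cluster reaches min_size: all genes unassigned", call. = FALSE)
    return(lab)
  }
  if (!is.null(expr)) {
    expr <- as.matrix(expr)[g, , drop = FALSE]
    repeat {
      mods <- setdiff(unique(lab), "grey")
      if (length(mods) < 2) break
      eg <- vapply(mods, function(m) {
        eigengene_of(expr[lab == m, , drop = FALSE])
      }, numeric(ncol(expr)))
      cc <- stats::cor(eg)
      diag(cc) <- -Inf
      top <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      if (max(cc) <= 1 - merge_height) break
      lab[lab == mods[top[2]]] <- mods[top[1]]
    }
  }
  mods <- setdiff(unique(lab), "grey")
  sz <- sort(table(lab[lab != "grey"]), decreasing = TRUE)
  pal <- rep_len(module_palette, length(sz))
  recode <- stats::setNames(pal, names(sz))
  out <- ifelse(lab == "grey", "grey", recode[lab])
  names(out) <- g
  out
}

# First principal component of a module's standardized expression, oriented
# to correlate positively with the mean module profile, unit norm.
eigengene_of <- function(block) {
  if (nrow(block) == 1) {
    z <- as.numeric(scale(block[1, ]))
    return(z / sqrt(sum(z^2)))
  }
  z <- t(scale(t(block)))                 # standardize each gene profile
  z[!is.finite(z)] <- 0
  sv <- svd(t(z), nu = 1, nv = 0)
  e <- sv$u[, 1]
  if (stats::cor(e, colMeans(z)) < 0) e <- -e
  e
}

#' Module eigengenes and module-membership correlations (kME)
#'
#' @param mat an [expression_matrix()] or genes x samples matrix.
#' @param module_labels named gene -> module vector (from
#'   [detect_modules()]); `"grey"` genes are skipped for eigengenes.
#' @return list with `eigengenes` (samples x modules, unit-norm columns),
#'   `kme` (genes x modules correlations), and `var_explained` per module.
#' @export
module_eigengene <- function(mat, module_labels) {
  v <- if (inherits(mat, "expression_matrix")) mat$values else as.matrix(mat)
  v <- v[names(module_labels), , drop = FALSE]
  mods <- setdiff(unique(module_labels), "grey")
  if (length(mods) == 0) stop("no modules to summarize", call. = FALSE)
  eg <- matrix(NA_real_, ncol(v), length(mods),
               dimnames = list(colnames(v), mods))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    block <- v[module_labels == m, , drop = FALSE]
    eg[, m] <- eigengene_of(block)
    z <- t(scale(t(block)))
    z[!is.finite(z)] <- 0
    d <- svd(t(z))$d
    ve[m] <- d[1]^2 / sum(d^2)
  }
  kme <- suppressWarnings(stats::cor(t(v), eg))
  kme[!is.finite(kme)] <- 0
  list(eigengenes = eg, kme = kme, var_explained = ve)
}

# Equal-frequency discretization into `bins` levels.
discretize_ef <- function(x, bins) {
  as.integer(cut(rank(x, ties.method = "first"),
                 breaks = seq(0, length(x), length.out = bins + 1),
                 include.lowest = TRUE))
}

# Mutual information (nats) between two discretized vectors.
mi_disc <- function(a, b, bins) {
  tab <- table(factor(a, levels = seq_len(bins)), factor(b, levels = seq_len(bins)))
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Mutual-information network with data-processing-inequality pruning
#'
#' Pairwise mutual information by equal-frequency binning
#' (`floor(sqrt(n_samples))` bins); edges below `mi_threshold` are removed,
#' then for every remaining triangle the weakest edge is removed when its MI
#' is below `min(other two) * (1 - dpi_tolerance)` (all violating edges
#' marked first, removed together).
#'
#' @param mat an [expression_matrix()] or genes x samples matrix.
#' @param genes gene subset to network (>= 2).
#' @param mi_threshold minimum MI to keep an edge; see
#'   [mi_threshold_permutation()] for a permutation-calibrated choice.
#' @param dpi_tolerance DPI tolerance in \[0,1\] (0 = strict).
#' @return data.frame `gene_a`, `gene_b`, `mi` of retained edges.
#' @export
mi_network_dpi <- function(mat, genes, mi_threshold, dpi_tolerance = 0) {
  v <- if (inherits(mat, "expression_matrix")) mat$values else as.matrix(mat)
  v <- v[genes, , drop = FALSE]
  if (nrow(v) < 2) stop("need at least 2 genes", call. = FALSE)
  n <- ncol(v)
  bins <- max(2L, floor(sqrt(n)))
  disc <- t(apply(v, 1, discretize_ef, bins = bins))
  ng <- nrow(v)
  mi <- matrix(0, ng, ng, dimnames = list(genes, genes))
  for (i in seq_len(ng - 1)) {
    for (j in (i + 1):ng) {
      mi[i, j] <- mi[j, i] <- mi_disc(disc[i, ], disc[j, ], bins)
    }
  }
  adj <- mi >= mi_threshold
  diag(adj) <- FALSE
  # DPI: mark the weakest edge of each fully connected triangle.
  drop <- matrix(FALSE, ng, ng)
  if (ng >= 3) {
    for (i in seq_len(ng - 2)) {
      for (j in (i + 1):(ng - 1)) {
        if (!adj[i, j]) next
        for (l in (j + 1):ng) {
          if (!adj[i, l] || !adj[j, l]) next
          e <- c(mi[i, j], mi[i, l], mi[j, l])
          w <- which.min(e)
          others <- min(e[-w])
          if (e[w] < others * (1 - dpi_tolerance)) {
            if (w == 1) drop[i, j] <- TRUE
            else if (w == 2) drop[i, l] <- TRUE
            else drop[j, l] <- TRUE
          }
        }
      }
    }
  }
  adj <- adj & !(drop | t(drop))
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  data.frame(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
             mi = mi[idx], stringsAsFactors = FALSE)
}

#' Permutation-calibrated MI threshold
#'
#' Upper quantile of the MI between sample-permuted gene pairs, breaking any
#' real dependence while preserving marginals.
#'
#' @param mat expression matrix or values.
#' @param genes gene subset.
#' @param n_perm permuted pairs to score.
#' @param q quantile (default 0.95).
#' @param seed integer seed.
#' @return MI threshold.
#' @export
mi_threshold_permutation <- function(mat, genes, n_perm = 200, q = 0.95, seed = 1L) {
  v <- if (inherits(mat, "expression_matrix")) mat$values else as.matrix(mat)
  v <- v[genes, , drop = FALSE]
  n <- ncol(v)
  bins <- max(2L, floor(sqrt(n)))
  with_seed(seed, {
    null_mi <- vapply(seq_len(n_perm), function(i) {
      g1 <- v[sample.int(nrow(v), 1), ]
      g2 <- v[sample.int(nrow(v), 1), sample.int(n)]
      mi_disc(discretize_ef(g1, bins), discretize_ef(g2, bins), bins)
    }, numeric(1))
    stats::quantile(null_mi, q, names = FALSE)
  })
}

#' Identify module hub genes and condition-specific hubs
#'
#' Hubs are the `top_k` genes of a module by intramodular MI degree (sum of
#' retained-edge MI within the module), falling back to kME when no edge
#' list is supplied. A condition-specific hub is a hub of the case network
#' whose connectivity rank in the control network falls outside the top
#' `2 * top_k`.
#'
#' @param kme genes x modules kME matrix (fallback ranking).
#' @param module_labels named gene -> module vector.
#' @param top_k hubs per module (default 11).
#' @param de_table optional `de_table` used to flag DE hubs.
#' @param mi_edges optional edge list from [mi_network_dpi()].
#' @param mi_edges_case,mi_edges_control optional per-condition edge lists
#'   enabling condition-specific hub calls.
#' @return A `hub_set`: per-module data.frames with columns `gene`, `degree`,
#'   `is_hub`, `condition_specific`, `is_de`.
#' @export
identify_hubs <- function(kme, module_labels, top_k = 11, de_table = NULL,
                          mi_edges = NULL, mi_edges_case = NULL,
                          mi_edges_control = NULL) {
  mods <- setdiff(unique(module_labels), "grey")
  if (length(mods) == 0) stop("no modules", call. = FALSE)
  degree_in <- function(edges, members) {
    d <- stats::setNames(numeric(length(members)), members)
    if (is.null(edges) || nrow(edges) == 0) return(d)
    e <- edges[edges$gene_a %in% members & edges$gene_b %in% members, , drop = FALSE]
    for (i in seq_len(nrow(e))) {
      d[e$gene_a[i]] <- d[e$gene_a[i]] + e$mi[i]
      d[e$gene_b[i]] <- d[e$gene_b[i]] + e$mi[i]
    }
    d
  }
  out <- list()
  for (m in mods) {
    members <- names(module_labels)[module_labels == m]
    k <- min(top_k, length(members))
    if (k < top_k) warning(sprintf("top_k clipped to module size in %s", m), call. = FALSE)
    deg <- if (!is.null(mi_edges)) degree_in(mi_edges, members)
           else stats::setNames(kme[members, m], members)
    ord <- order(-deg, members)
    is_hub <- logical(length(members))
    is_hub[ord[seq_len(k)]] <- TRUE
    cond <- rep(NA, length(members))
    if (!is.null(mi_edges_case) && !is.null(mi_edges_control)) {
      deg_case <- degree_in(mi_edges_case, members)
      deg_ctrl <- degree_in(mi_edges_control, members)
      ord_case <- order(-deg_case, members)
      rank_ctrl <- match(members, members[order(-deg_ctrl, members)])
      is_hub <- logical(length(members))
      is_hub[ord_case[seq_len(k)]] <- TRUE
      cond <- is_hub & rank_ctrl > 2 * top_k
      deg <- deg_case
    }
    is_de <- if (!is.null(de_table)) {
      members %in% de_table$gene[de_table$class != "ns"]
    } else rep(NA, length(members))
    tab <- data.frame(gene = members, degree = deg, is_hub = is_hub,
                      condition_specific = cond, is_de = is_de,
                      stringsAsFactors = FALSE, row.names = NULL)
    out[[m]] <- tab[order(-tab$degree, tab$gene), , drop = FALSE]
  }
  structure(out, class = "hub_set")
}

#' @export
print.hub_set <- function(x, ...) {
  for (m in names(x)) {
    h <- x[[m]][x[[m]]$is_hub, ]
    cat(sprintf("%s: %d hubs%s\n", m, nrow(h),
                if (!all(is.na(h$condition_specific)))
                  sprintf(" (%d condition-specific)", sum(h$condition_specific))
                else ""))
  }
  invisible(x)
}
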