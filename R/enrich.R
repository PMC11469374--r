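# Fisher's-exact enrichment, over-representation analysis against GMT
# gene-set collections, and AUCell-style module scoring of cell profiles.

#' Read a GMT gene-set collection
#'
#' Standard tab-separated format: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors (a `gene_set_collection`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop(sprintf("GMT parse error at line %d: fewer than 3 fields", i), call. = FALSE)
    }
    if (f[1] %in% names(sets)) {
      stop(sprintf("GMT parse error at line %d: duplicate set name '%s'", i, f[1]),
           call. = FALSE)
    }
    sets[[f[1]]] <- unique(f[-(1:2)])
  }
  structure(sets, class = "gene_set_collection")
}

#' Fisher's-exact enrichment of one gene set in another
#'
#' 2x2 table (in/out query x in/out target) over an explicit background; the
#' p-value is the exact hypergeometric upper tail and the odds ratio is
#' `ad/bc`, with 0.5 continuity applied (and flagged) only when a zero cell
#' would make the ratio undefined (zero denominator); a zero overlap simply
#' gives an odds ratio of 0.
#'
#' @param query,target gene sets, both subsets of `background`.
#' @param background the gene universe.
#' @return one-row data.frame: `k`, `K`, `n`, `N`, `odds_ratio`, `p`,
#'   `continuity`.
#' @export
fisher_enrichment <- function(query, target, background) {
  bad <- setdiff(c(query, target), background)
  if (length(bad)) {
    stop("genes outside background: ", paste(utils::head(bad, 10), collapse = ", "),
         call. = FALSE)
  }
  query <- unique(query); target <- unique(target); background <- unique(background)
  N <- length(background)
  k <- length(intersect(query, target))
  n <- length(query)
  K <- length(target)
  a <- k; b <- n - k; cc <- K - k; d <- N - n - K + k
  continuity <- b == 0 || cc == 0
  if (continuity) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
  data.frame(k = k, K = K, n = n, N = N,
             odds_ratio = (a * d) / (b * cc),
             p = hypergeom_tail(N, K, n, k),
             continuity = continuity)
}

#' Over-representation analysis against a gene-set collection
#'
#' Each set is filtered to the background before testing; only sets with a
#' non-empty background intersection are tested, and BH adjustment is
#' applied across the tested sets. The background must be supplied
#' explicitly (typically the analyzed-gene universe).
#'
#' @param collection a `gene_set_collection` (see [read_gmt()]) or named
#'   list of gene vectors.
#' @param query non-empty query gene set (subset of `background`).
#' @param background explicit gene universe.
#' @return data.frame, one row per tested set, sorted by p: `set`, `k`, `K`,
#'   `n`, `N`, `odds_ratio`, `p`, `q`.
#' @export
ora <- function(collection, query, background) {
  if (length(query) == 0) stop("empty query set", call. = FALSE)
  rows <- list()
  for (nm in names(collection)) {
    tgt <- intersect(collection[[nm]], background)
    if (length(tgt) == 0) next
    r <- fisher_enrichment(query, tgt, background)
    r$set <- nm
    rows[[nm]] <- r
  }
  if (length(rows) == 0) {
    return(data.frame(set = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), q = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out$q <- adjust_bh(out$p)
  out <- out[order(out$p, out$set), c("set", "k", "K", "n", "N",
                                      "odds_ratio", "p", "q")]
  rownames(out) <- NULL
  out
}

#' Enrichment of DE transcripts within co-expression modules
#'
#' Fisher's exact test of the up/down DE genes against each module's gene
#' set over the analyzed-gene background, BH-adjusted across modules.
#'
#' @param de a `de_table`.
#' @param module_labels named gene -> module vector (`"grey"` skipped).
#' @param background gene universe (default: the labelled genes).
#' @return data.frame per module with the [fisher_enrichment()] columns
#'   plus `q`.
#' @export
module_de_enrichment <- function(de, module_labels,
                                 background = names(module_labels)) {
  sets <- split(names(module_labels), module_labels)
  sets <- sets[setdiff(names(sets), "grey")]
  query <- intersect(de$gene[de$class %in% c("up", "down")], background)
  if (length(query) == 0) stop("no DE genes within the background", call. = FALSE)
  out <- ora(sets, query, background)
  names(out)[names(out) == "set"] <- "module"
  out
}

#' AUCell-style module score per cell profile
#'
#' Area under the gene-recovery curve (cumulative module-gene count against
#' rank) truncated at the top `top_fraction` of the ranking, normalized by
#' the maximal achievable area so a profile with every module gene at the
#' very top scores 1 and one with no module gene in the window scores 0.
#'
#' @param rankings genes x cells matrix of ranks (1 = highest expression;
#'   each column a permutation of `1..N`), or raw expression values with
#'   `ranked = FALSE`.
#' @param module_genes gene ids to score (subset of rownames).
#' @param top_fraction fraction of the ranking scanned (default 0.05).
#' @param ranked set FALSE to rank a raw expression matrix (decreasing,
#'   deterministic tie-break by row order).
#' @return named numeric vector of AUC in \[0,1\] per cell.
#' @export
aucell_score <- function(rankings, module_genes, top_fraction = 0.05,
                         ranked = TRUE) {
  rankings <- as.matrix(rankings)
  N <- nrow(rankings)
  W <- floor(top_fraction * N)
  if (W < 1) stop("top_fraction * n_genes must be at least 1", call. = FALSE)
  if (!all(module_genes %in% rownames(rankings))) {
    stop("module genes absent from the profile universe", call. = FALSE)
  }
  if (!ranked) {
    rankings <- apply(rankings, 2, function(x) rank(-x, ties.method = "first"))
  }
  M <- length(module_genes)
  max_area <- sum(pmin(seq_len(W), M))
  mod_ranks <- rankings[module_genes, , drop = FALSE]
  vapply(seq_len(ncol(rankings)), function(j) {
    r <- sort(mod_ranks[, j])
    r <- r[r <= W]
    if (length(r) == 0) return(0)
    # step-function area: gene with rank r contributes (W - r + 1) cells
    sum(W - r + 1) / max_area
  }, numeric(1)) -> auc
  stats::setNames(auc, colnames(rankings))
}

#' Compare module scores between two groups within cell-type strata
#'
#' Rank-sum (Wilcoxon) comparison of AUC between the two groups within each
#' cell type, BH-adjusted across cell types. Strata with only one group
#' present are skipped with a warning.
#'
#' @param auc named AUC vector (from [aucell_score()]).
#' @param groups per-cell group labels (exactly 2 levels used).
#' @param cell_type per-cell stratum labels; `NULL` compares all cells as
#'   one stratum.
#' @return data.frame: `cell_type`, `n_1`, `n_2`, `median_1`, `median_2`,
#'   `statistic`, `p`, `q`.
#' @export
compare_module_scores <- function(auc, groups, cell_type = NULL) {
  cell_type <- cell_type %||% rep("all", length(auc))
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups required", call. = FALSE)
  rows <- list()
  for (ct in unique(cell_type)) {
    sel <- cell_type == ct
    x <- auc[sel & groups == lv[1]]
    y <- auc[sel & groups == lv[2]]
    if (length(x) < 2 || length(y) < 2) {
      warning(sprintf("stratum '%s' lacks both groups; skipped", ct), call. = FALSE)
      next
    }
    w <- suppressWarnings(stats::wilcox.test(x, y))
    rows[[ct]] <- data.frame(cell_type = ct, n_1 = length(x), n_2 = length(y),
                             median_1 = stats::median(x), median_2 = stats::median(y),
                             statistic = unname(w$statistic), p = w$p.value,
                             stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no stratum had both groups", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- adjust_bh(out$p)
  out
}
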