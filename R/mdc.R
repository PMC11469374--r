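# Module differential connectivity: ratio of summed lower-triangular
# adjacency between case and control networks, with a two-scheme
# permutation null, BH correction and gain/loss calls.

#' Module differential connectivity ratio
#'
#' Ratio of the summed lower-triangular (off-diagonal) adjacency of the case
#' submatrix to that of the control submatrix. MDC > 1 indicates gain of
#' connectivity in cases, MDC < 1 loss.
#'
#' @param A_case,A_ctrl adjacency submatrices over the same module genes in
#'   the same order (size >= 2).
#' @return the connectivity ratio.
#' @export
mdc_ratio <- function(A_case, A_ctrl) {
  if (!all(dim(A_case) == dim(A_ctrl)) || nrow(A_case) < 2) {
    stop("submatrices must match and have size >= 2", call. = FALSE)
  }
  num <- sum(A_case[lower.tri(A_case)])
  den <- sum(A_ctrl[lower.tri(A_ctrl)])
  if (den == 0) stop("disconnected control module", call. = FALSE)
  num / den
}

module_adjacency <- function(values, genes, samples, beta) {
  v <- values[genes, samples, drop = FALSE]
  cc <- suppressWarnings(stats::cor(t(v)))
  cc[!is.finite(cc)] <- 0
  A <- abs(cc)^beta
  diag(A) <- 1
  A
}

#' Permutation null for a module's connectivity ratio
#'
#' Two shuffling schemes: `"shuffle_samples"` permutes the case/control
#' labels across the pooled samples (non-random nodes, random connections);
#' `"shuffle_genes"` replaces the module by random same-size gene sets from
#' the analyzed universe, keeping the original labels (random nodes,
#' non-random connections). The p-value is two-sided on the log scale with
#' the add-one estimator, so it is never zero.
#'
#' @param mat an [expression_matrix()] or genes x samples matrix.
#' @param case_samples,ctrl_samples sample ids (>= 3 each).
#' @param module_genes module gene ids (subset of the matrix genes).
#' @param beta soft-threshold power used for all adjacencies.
#' @param scheme `"shuffle_samples"` or `"shuffle_genes"`.
#' @param n_perm number of permutations (>= 10; convention 1000).
#' @param seed integer seed.
#' @param universe gene pool for `"shuffle_genes"` (default: all genes).
#' @return list with `observed` (the MDC ratio), `null` (permuted ratios),
#'   and `p`.
#' @export
permute_mdc <- function(mat, case_samples, ctrl_samples, module_genes, beta,
                        scheme = c("shuffle_samples", "shuffle_genes"),
                        n_perm = 1000, seed = 1L, universe = NULL) {
  scheme <- match.arg(scheme)
  if (n_perm < 10) stop("n_perm must be at least 10", call. = FALSE)
  v <- if (inherits(mat, "expression_matrix")) mat$values else as.matrix(mat)
  if (!all(module_genes %in% rownames(v))) {
    stop("module genes absent from matrix", call. = FALSE)
  }
  if (length(case_samples) < 3 || length(ctrl_samples) < 3) {
    stop("need at least 3 samples per group", call. = FALSE)
  }
  universe <- universe %||% rownames(v)
  obs <- mdc_ratio(module_adjacency(v, module_genes, case_samples, beta),
                   module_adjacency(v, module_genes, ctrl_samples, beta))
  pooled <- c(case_samples, ctrl_samples)
  n_case <- length(case_samples)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    if (scheme == "shuffle_samples") {
      perm <- sample(pooled)
      g <- module_genes
      cs <- perm[seq_len(n_case)]
      ct <- perm[(n_case + 1):length(perm)]
    } else {
      g <- sample(universe, length(module_genes))
      cs <- case_samples
      ct <- ctrl_samples
    }
    tryCatch(mdc_ratio(module_adjacency(v, g, cs, beta),
                       module_adjacency(v, g, ct, beta)),
             error = function(e) 1)
  }, numeric(1)))
  p <- (1 + sum(abs(log(null)) >= abs(log(obs)))) / (1 + n_perm)
  list(observed = obs, null = null, p = p, scheme = scheme)
}

#' Module differential connectivity test across all modules
#'
#' Runs both shuffling schemes per module, combines them conservatively as
#' `p_final = max(p_shuffle_samples, p_shuffle_genes)`, applies BH across
#' modules, and calls `gain` (MDC > 1) or `loss` (MDC < 1) at `q < 0.05`.
#'
#' @param mat an [expression_matrix()].
#' @param case_group,control_group group labels in the sample annotations.
#' @param module_labels named gene -> module vector (`"grey"` skipped).
#' @param beta soft-threshold power.
#' @param n_perm permutations per scheme (convention 1000).
#' @param seed master seed; per-module scheme seeds are derived stably.
#' @param q_thresh significance threshold on q (default 0.05).
#' @return An `mdc_result` data.frame: `module`, `mdc`, `p_shuffle_samples`,
#'   `p_shuffle_genes`, `p_final`, `q`, `call`, `n_perm`.
#' @export
mdc_test <- function(mat, case_group, control_group, module_labels, beta,
                     n_perm = 1000, seed = 1L, q_thresh = 0.05) {
  stopifnot(inherits(mat, "expression_matrix"))
  mods <- setdiff(unique(module_labels), "grey")
  if (length(mods) == 0) stop("no modules to test", call. = FALSE)
  case_samples <- mat$samples$sample[mat$samples$group == case_group]
  ctrl_samples <- mat$samples$sample[mat$samples$group == control_group]
  universe <- intersect(names(module_labels), rownames(mat$values))
  rows <- list()
  for (m in mods) {
    genes <- names(module_labels)[module_labels == m]
    genes <- intersect(genes, rownames(mat$values))
    if (length(genes) < 2) {
      warning(sprintf("module %s absent from matrix; skipped", m), call. = FALSE)
      next
    }
    ps <- permute_mdc(mat, case_samples, ctrl_samples, genes, beta,
                      scheme = "shuffle_samples", n_perm = n_perm,
                      seed = derive_seed(seed, paste0(m, "_samples")))
    pg <- permute_mdc(mat, case_samples, ctrl_samples, genes, beta,
                      scheme = "shuffle_genes", n_perm = n_perm,
                      seed = derive_seed(seed, paste0(m, "_genes")),
                      universe = universe)
    rows[[m]] <- data.frame(module = m, mdc = ps$observed,
                            p_shuffle_samples = ps$p, p_shuffle_genes = pg$p,
                            p_final = max(ps$p, pg$p), n_perm = n_perm,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- adjust_bh(out$p_final)
  out$call <- ifelse(out$q < q_thresh & out$mdc > 1, "gain",
                     ifelse(out$q < q_thresh & out$mdc < 1, "loss", "none"))
  class(out) <- c("mdc_result", "data.frame")
  out
}

#' @export
print.mdc_result <- function(x, ...) {
  cat(sprintf("mdc_result: %d modules, %d gain, %d loss (n_perm = %d)\n",
              nrow(x), sum(x$call == "gain"), sum(x$call == "loss"),
              x$n_perm[1]))
  print.data.frame(as.data.frame(x))
  invisible(x)
}
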