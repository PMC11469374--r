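# Signed, stratified rank-rank hypergeometric overlap between two ranked
# differential-expression signatures, with quadrant summaries and
# concordant-gene extraction.

#' Align two cohorts' gene symbols into a shared universe
#'
#' Without an explicit map, symbols are matched case-insensitively (human
#' symbols are conventionally upper-case, rodent symbols title-case). Symbols
#' that are duplicated within one cohort, or that match more than one partner,
#' are dropped with a warning so the result is one-to-one.
#'
#' @param symbols_a,symbols_b gene symbols of the two cohorts.
#' @param map optional data.frame with columns `symbol_a`, `symbol_b`.
#' @return data.frame with columns `key`, `symbol_a`, `symbol_b`.
#' @export
map_orthologs <- function(symbols_a, symbols_b, map = NULL) {
  if (length(symbols_a) == 0 || length(symbols_b) == 0) {
    stop("symbol lists must be non-empty", call. = FALSE)
  }
  drop_dups <- function(x, side) {
    d <- duplicated(toupper(x)) | duplicated(toupper(x), fromLast = TRUE)
    if (any(d)) warning(sprintf("dropping %d duplicated symbols on side %s",
                                sum(d), side), call. = FALSE)
    x[!d]
  }
  a <- drop_dups(symbols_a, "a")
  b <- drop_dups(symbols_b, "b")
  if (is.null(map)) {
    ka <- toupper(a); kb <- toupper(b)
    shared <- intersect(ka, kb)
    out <- data.frame(key = shared,
                      symbol_a = a[match(shared, ka)],
                      symbol_b = b[match(shared, kb)],
                      stringsAsFactors = FALSE)
  } else {
    m <- map[toupper(map$symbol_a) %in% toupper(a) &
               toupper(map$symbol_b) %in% toupper(b), , drop = FALSE]
    one <- !(duplicated(toupper(m$symbol_a)) | duplicated(toupper(m$symbol_a), fromLast = TRUE)) &
      !(duplicated(toupper(m$symbol_b)) | duplicated(toupper(m$symbol_b), fromLast = TRUE))
    if (!all(one)) warning("dropping many-to-many ortholog pairs", call. = FALSE)
    m <- m[one, , drop = FALSE]
    out <- data.frame(key = toupper(m$symbol_a),
                      symbol_a = a[match(toupper(m$symbol_a), toupper(a))],
                      symbol_b = b[match(toupper(m$symbol_b), toupper(b))],
                      stringsAsFactors = FALSE)
  }
  if (nrow(out) == 0) stop("no shared genes between the two cohorts", call. = FALSE)
  out[order(out$key), , drop = FALSE]
}

#' Signed significance score for ranking a DE signature
#'
#' `score = sign(log2FC) * min(-log10(p), cap)`; a zero effect is treated as
#' positive sign. `p = 0` is capped with a warning.
#'
#' @param p p-values in (0, 1].
#' @param log2FC finite effect sizes.
#' @param cap maximum |score| (default 300).
#' @return numeric scores.
#' @export
signed_score <- function(p, log2FC, cap = 300) {
  if (any(!is.finite(log2FC))) stop("log2FC must be finite", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("p must lie in (0, 1]", call. = FALSE)
  if (any(p == 0)) warning("p = 0 capped at the maximum score", call. = FALSE)
  mag <- pmin(-log10(p), cap)
  sgn <- ifelse(log2FC >= 0, 1, -1)
  sgn * mag
}

#' Build a ranked signature from a DE table
#'
#' Orders genes by signed score ascending (most-down first). Ties in score
#' are broken by placing zero-effect genes after non-zero ones, then by
#' lexicographic gene id, so the order is total and deterministic.
#'
#' @param genes gene identifiers (unique).
#' @param p,log2FC per-gene statistics.
#' @param cap score cap passed to [signed_score()].
#' @return A `ranked_signature`: data.frame `gene`, `score` in rank order.
#' @export
ranked_signature <- function(genes, p, log2FC, cap = 300) {
  if (anyDuplicated(genes)) stop("gene ids must be unique", call. = FALSE)
  score <- signed_score(p, log2FC, cap)
  ord <- order(score, log2FC == 0, genes)
  structure(data.frame(gene = genes[ord], score = score[ord],
                       stringsAsFactors = FALSE),
            class = c("ranked_signature", "data.frame"))
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for the overlap `X` of a size-`n` draw with `K` successes in a
#' universe of `N`, computed in log space for numerical range.
#'
#' @param N universe size; `K` successes; `n` draws; `k` observed overlap.
#' @param log10p if TRUE, return log10 of the tail instead.
#' @return tail probability (or its log10).
#' @export
hypergeom_tail <- function(N, K, n, k, log10p = FALSE) {
  if (any(c(N, K, n, k) < 0) || k > min(K, n) + 1e-9 || K > N || n > N) {
    stop("inconsistent hypergeometric counts", call. = FALSE)
  }
  lp <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  if (log10p) lp / log(10) else exp(lp)
}

# Overlap counts between all threshold prefixes of two orderings.
# pos_a, pos_b: per-gene 1-based positions in each ordering (same gene order);
# thr_a, thr_b: vectors of prefix lengths. Returns |thr_a| x |thr_b| counts.
prefix_overlap_counts <- function(pos_a, pos_b, thr_a, thr_b) {
  ind_a <- outer(pos_a, thr_a, `<=`)
  ind_b <- outer(pos_b, thr_b, `<=`)
  crossprod(ind_a, ind_b)
}

#' Compute a stratified signed RRHO map
#'
#' Both signatures must be defined on the same universe (use
#' [map_orthologs()] first). The map is a `G x G` grid, `G = ceiling(N/step)`,
#' laid out with the down-most genes of each list at index 1. Quadrant
#' boundaries fall at each list's count of negative scores; within each
#' quadrant the overlap is counted from that quadrant's own ends
#' (down-prefixes for down-down, up-prefixes for up-up, opposite ends for the
#' discordant quadrants). Cell values are `-log10` of the exact
#' hypergeometric upper tail, zeroed when the overlap is below its
#' expectation, capped at 300, and signed positive for concordant and
#' negative for discordant quadrants.
#'
#' @param sig_a,sig_b [ranked_signature()] objects on the same gene universe.
#' @param step rank stride; `"auto"` uses `floor(sqrt(N))`.
#' @return An `rrho_map` with elements `grid`, `step`, `quadrant_summaries`
#'   (max value and argmax thresholds per quadrant), and
#'   `quadrant_gene_sets` (overlap genes at each quadrant's argmax).
#' @export
compute_rrho_map <- function(sig_a, sig_b, step = "auto") {
  stopifnot(inherits(sig_a, "ranked_signature"), inherits(sig_b, "ranked_signature"))
  if (!setequal(sig_a$gene, sig_b$gene)) {
    stop("signatures must share an identical gene universe", call. = FALSE)
  }
  N <- nrow(sig_a)
  if (identical(step, "auto")) step <- max(1L, floor(sqrt(N)))
  step <- as.integer(step)
  G <- as.integer(ceiling(N / step))
  genes <- sig_a$gene                      # reference order: A's ranking
  pos_a_down <- seq_len(N)
  pos_b_down <- match(genes, sig_b$gene)
  pos_a_up <- N + 1L - pos_a_down
  pos_b_up <- N + 1L - pos_b_down
  d_a <- sum(sig_a$score < 0)
  d_b <- sum(sig_b$score < 0)
  thr_down <- pmin(seq_len(G) * step, N)   # prefix sizes from the down end
  thr_up <- N - (seq_len(G) - 1L) * step   # prefix sizes from the up end

  cell_values <- function(k, size_a, size_b) {
    Kn <- outer(size_a, size_b)            # K * n per cell
    lp <- stats::phyper(k - 1, outer(size_a, rep(1, length(size_b))),
                        N - outer(size_a, rep(1, length(size_b))),
                        outer(rep(1, length(size_a)), size_b),
                        lower.tail = FALSE, log.p = TRUE)
    v <- pmin(-lp / log(10), 300)
    v[k * N < Kn] <- 0                     # only enrichment is scored
    v
  }

  # Per-quadrant full grids; assembled by region afterwards.
  k_dd <- prefix_overlap_counts(pos_a_down, pos_b_down, thr_down, thr_down)
  k_uu <- prefix_overlap_counts(pos_a_up, pos_b_up, thr_up, thr_up)
  k_du <- prefix_overlap_counts(pos_a_down, pos_b_up, thr_down, thr_up)
  k_ud <- prefix_overlap_counts(pos_a_up, pos_b_down, thr_up, thr_down)
  v_dd <- cell_values(k_dd, thr_down, thr_down)
  v_uu <- cell_values(k_uu, thr_up, thr_up)
  v_du <- cell_values(k_du, thr_down, thr_up)
  v_ud <- cell_values(k_ud, thr_up, thr_down)

  in_down_a <- thr_down <= d_a             # row regions (A axis)
  in_down_b <- thr_down <= d_b             # column regions (B axis)
  region <- outer(ifelse(in_down_a, "d", "u"), ifelse(in_down_b, "d", "u"), paste0)
  grid <- matrix(0, G, G)
  grid[region == "dd"] <- v_dd[region == "dd"]
  grid[region == "uu"] <- v_uu[region == "uu"]
  grid[region == "du"] <- -v_du[region == "du"]
  grid[region == "ud"] <- -v_ud[region == "ud"]
  dimnames(grid) <- list(paste0("a", thr_down), paste0("b", thr_down))

  quadrants <- c("down-down", "up-up", "down-up", "up-down")
  vals <- list(`down-down` = v_dd, `up-up` = v_uu, `down-up` = v_du, `up-down` = v_ud)
  regs <- c(`down-down` = "dd", `up-up` = "uu", `down-up` = "du", `up-down` = "ud")
  thrs <- list(`down-down` = list(thr_down, thr_down),
               `up-up` = list(thr_up, thr_up),
               `down-up` = list(thr_down, thr_up),
               `up-down` = list(thr_up, thr_down))
  poss <- list(`down-down` = list(pos_a_down, pos_b_down),
               `up-up` = list(pos_a_up, pos_b_up),
               `down-up` = list(pos_a_down, pos_b_up),
               `up-down` = list(pos_a_up, pos_b_down))
  summ <- list()
  gene_sets <- list()
  for (q in quadrants) {
    mask <- region == regs[[q]]
    v <- vals[[q]]
    if (!any(mask)) {
      summ[[q]] <- data.frame(quadrant = q, max = 0, thr_a = NA_integer_,
                              thr_b = NA_integer_, overlap = NA_integer_)
      gene_sets[[q]] <- character(0)
      next
    }
    vm <- v
    vm[!mask] <- -Inf
    am <- which(vm == max(vm), arr.ind = TRUE)[1, ]
    ta <- thrs[[q]][[1]][am[1]]
    tb <- thrs[[q]][[2]][am[2]]
    sel <- poss[[q]][[1]] <= ta & poss[[q]][[2]] <= tb
    summ[[q]] <- data.frame(quadrant = q, max = v[am[1], am[2]],
                            thr_a = ta, thr_b = tb, overlap = sum(sel))
    gene_sets[[q]] <- genes[sel]
  }
  structure(list(grid = grid, step = step, n_genes = N,
                 boundary = c(a = d_a, b = d_b),
                 quadrant_summaries = do.call(rbind, summ),
                 quadrant_gene_sets = gene_sets),
            class = "rrho_map")
}

#' @export
print.rrho_map <- function(x, ...) {
  cat(sprintf("rrho_map: %d genes, step %d, grid %dx%d\n",
              x$n_genes, x$step, nrow(x$grid), ncol(x$grid)))
  print(x$quadrant_summaries, row.names = FALSE)
  invisible(x)
}

#' Heat-matrix plot of an RRHO map
#'
#' @param x an `rrho_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.rrho_map <- function(x, ...) {
  g <- x$grid
  graphics::image(seq_len(nrow(g)), seq_len(ncol(g)), g,
                  xlab = "signature A rank threshold (down -> up)",
                  ylab = "signature B rank threshold (down -> up)",
                  main = "signed -log10 rank-rank hypergeometric overlap", ...)
  graphics::abline(v = x$boundary["a"] / x$step, h = x$boundary["b"] / x$step,
                   lty = 2)
  invisible(x)
}

#' Overlap genes at a quadrant's most significant cell
#'
#' @param map an `rrho_map`.
#' @param quadrant one of `"down-down"`, `"up-up"`, `"down-up"`, `"up-down"`.
#' @return character vector of genes in the prefix intersection at that
#'   quadrant's argmax thresholds.
#' @export
quadrant_genes <- function(map, quadrant = c("down-down", "up-up", "down-up", "up-down")) {
  stopifnot(inherits(map, "rrho_map"))
  quadrant <- match.arg(quadrant)
  map$quadrant_gene_sets[[quadrant]]
}
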