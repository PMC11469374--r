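# Gene-wise differential expression with empirical-Bayes variance
# moderation, BH correction, threshold classification and biotype summaries.

#' Two-group linear differential expression fit
#'
#' Per-gene two-sample linear model on log2 expression: the effect is
#' `mean(group_b) - mean(group_a)` and the variance is the pooled residual
#' variance with `n_a + n_b - 2` degrees of freedom. Sex stratification is
#' performed by subsetting before fitting.
#'
#' @param mat an [expression_matrix()].
#' @param contrast length-2 character vector `(group_a, group_b)`; group_a is
#'   the reference (typically control).
#' @param sex optional single sex label to stratify on.
#' @return data.frame with columns `gene`, `log2FC`, `s2`, `df`, plus
#'   attributes `n_a`, `n_b`.
#' @export
fit_linear_de <- function(mat, contrast, sex = NULL) {
  stopifnot(inherits(mat, "expression_matrix"), length(contrast) == 2)
  keep <- mat$samples$group %in% contrast
  if (!is.null(sex)) keep <- keep & mat$samples$sex %in% sex
  smp <- mat$samples[keep, , drop = FALSE]
  for (g in contrast) {
    if (!any(smp$group == g)) stop(sprintf("group '%s' absent from matrix", g), call. = FALSE)
  }
  ia <- smp$group == contrast[1]
  ib <- smp$group == contrast[2]
  n_a <- sum(ia); n_b <- sum(ib)
  if (n_a < 2 || n_b < 2) stop("need at least 2 samples per group", call. = FALSE)
  df <- n_a + n_b - 2L
  v <- mat$values[, keep, drop = FALSE]
  xa <- v[, ia, drop = FALSE]
  xb <- v[, ib, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  ssa <- rowSums((xa - ma)^2)
  ssb <- rowSums((xb - mb)^2)
  out <- data.frame(gene = mat$genes$gene, log2FC = mb - ma,
                    s2 = (ssa + ssb) / df, df = df, stringsAsFactors = FALSE)
  attr(out, "n_a") <- n_a
  attr(out, "n_b") <- n_b
  out
}

# Invert trigamma by bisection: find y > 0 with trigamma(y) = x.
# trigamma is strictly decreasing on (0, Inf); tolerance on y.
trigamma_inverse <- function(x, tol = 1e-8) {
  if (x <= 0) return(Inf)
  lo <- 1e-8; hi <- 1
  while (trigamma(hi) > x) hi <- hi * 2      # expand until trigamma(hi) <= x
  while (trigamma(lo) < x) lo <- lo / 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (trigamma(mid) > x) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Empirical-Bayes moderation of gene-wise variances
#'
#' Fits a scaled inverse-chi-square prior (`d0`, `s0_sq`) to the gene-wise
#' residual variances by method of moments on `log(s2)` (trigamma inversion
#' by bisection), shrinks each variance to its posterior
#' `(d0*s0_sq + df*s2) / (d0 + df)`, and returns moderated t-statistics with
#' `d0 + df` degrees of freedom.
#'
#' @param s2 per-gene residual variances (balanced design).
#' @param df residual degrees of freedom (single value or per-gene, all
#'   equal).
#' @param log2FC per-gene effect sizes.
#' @param n_a,n_b group sample sizes used for the effect standard error.
#' @param d0 optional: force the prior degrees of freedom (0 recovers the
#'   ordinary t; `Inf` fully shrinks every variance to `s0_sq`).
#' @return list with `params` (d0, s0_sq, df_residual), `s2_post`, `t`, `p`.
#' @export
moderate_variances <- function(s2, df, log2FC, n_a, n_b, d0 = NULL) {
  if (length(unique(df)) != 1L) stop("all residual df must be equal (balanced design)", call. = FALSE)
  df <- df[1]
  if (df <= 0) stop("residual degrees of freedom must be positive", call. = FALSE)
  if (all(s2 == 0)) stop("degenerate variances: all gene variances are zero", call. = FALSE)
  pos <- s2[s2 > 0]
  floor_val <- stats::quantile(pos, 0.01, names = FALSE)
  s2f <- pmax(s2, floor_val)
  z <- log(s2f)
  e <- z - digamma(df / 2) + log(df / 2)
  if (is.null(d0)) {
    target <- stats::var(e) - trigamma(df / 2)
    if (target <= 0) {
      d0 <- Inf
    } else {
      d0 <- 2 * trigamma_inverse(target)
    }
  }
  if (is.infinite(d0)) {
    s0_sq <- exp(mean(e))
    s2_post <- rep(s0_sq, length(s2f))
    df_total <- Inf
  } else if (d0 == 0) {
    s0_sq <- exp(mean(e))   # irrelevant at weight 0; reported for completeness
    s2_post <- s2f
    df_total <- df
  } else {
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s0_sq + df * s2f) / (d0 + df)
    df_total <- d0 + df
  }
  se <- sqrt(s2_post * (1 / n_a + 1 / n_b))
  tstat <- log2FC / se
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  list(params = list(d0 = d0, s0_sq = s0_sq, df_residual = df),
       s2_post = s2_post, t = tstat, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in \[0, 1\].
#' @return q-values (BH-adjusted p-values), order-preserving and clipped at 1.
#' @export
adjust_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Classify genes as up, down, or not significant
#'
#' A gene is `up` iff `p < p_thresh` and `log2FC > lfc_thresh`, `down` iff
#' `p < p_thresh` and `log2FC < -lfc_thresh`, otherwise `ns`. Both
#' inequalities are strict, so boundary values are not called.
#'
#' @param log2FC,p per-gene effect sizes and p-values.
#' @param p_thresh significance threshold (default 0.01).
#' @param lfc_thresh absolute log2 fold-change threshold (default 0.26).
#' @return character vector in `{"up", "down", "ns"}`.
#' @export
classify_de <- function(log2FC, p, p_thresh = 0.01, lfc_thresh = 0.26) {
  if (any(!is.finite(log2FC)) || any(!is.finite(p))) {
    stop("log2FC and p must be finite", call. = FALSE)
  }
  ifelse(p < p_thresh & log2FC > lfc_thresh, "up",
         ifelse(p < p_thresh & log2FC < -lfc_thresh, "down", "ns"))
}

#' Run the full differential-expression stage for one contrast
#'
#' Linear fit, empirical-Bayes moderation, BH adjustment and threshold
#' classification in one call.
#'
#' @inheritParams fit_linear_de
#' @inheritParams classify_de
#' @param use_q if TRUE, classify on the BH-adjusted q instead of the raw p.
#' @return A `de_table` data.frame: `gene`, `log2FC`, `t`, `p`, `q`, `class`,
#'   with the contrast and moderation parameters stored as attributes.
#' @export
run_de <- function(mat, contrast, sex = NULL, p_thresh = 0.01,
                   lfc_thresh = 0.26, use_q = FALSE) {
  fit <- fit_linear_de(mat, contrast, sex = sex)
  mod <- moderate_variances(fit$s2, fit$df, fit$log2FC,
                            attr(fit, "n_a"), attr(fit, "n_b"))
  q <- adjust_bh(mod$p)
  crit <- if (use_q) q else mod$p
  out <- data.frame(gene = fit$gene, log2FC = fit$log2FC, t = mod$t,
                    p = mod$p, q = q,
                    class = classify_de(fit$log2FC, crit, p_thresh, lfc_thresh),
                    stringsAsFactors = FALSE)
  attr(out, "contrast") <- contrast
  attr(out, "sex") <- sex
  attr(out, "moderation") <- mod$params
  class(out) <- c("de_table", "data.frame")
  out
}

#' @export
print.de_table <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat(sprintf("de_table: %s vs %s%s, %d genes (%d up, %d down)\n",
              ct[1], ct[2],
              if (!is.null(attr(x, "sex"))) paste0(", sex ", attr(x, "sex")) else "",
              nrow(x), sum(x$class == "up"), sum(x$class == "down")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Biotype composition of the differentially expressed genes
#'
#' @param de a `de_table`.
#' @param gene_annotations data.frame with columns `gene` and `biotype`.
#' @return data.frame `biotype`, `count`, `proportion` over the up/down
#'   genes; zero rows when no gene is DE.
#' @export
summarize_biotypes <- function(de, gene_annotations) {
  hits <- de$gene[de$class %in% c("up", "down")]
  if (length(hits) == 0) {
    return(data.frame(biotype = character(0), count = integer(0),
                      proportion = numeric(0)))
  }
  bt <- gene_annotations$biotype[match(hits, gene_annotations$gene)]
  if (any(is.na(bt))) {
    stop("missing biotype for DE genes: ",
         paste(hits[is.na(bt)], collapse = ", "), call. = FALSE)
  }
  tab <- table(bt)
  data.frame(biotype = names(tab), count = as.integer(tab),
             proportion = as.numeric(tab) / length(hits),
             stringsAsFactors = FALSE)
}
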