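# Synthetic paired-cohort expression data with planted truth.
#
# The generator emulates the study design the package targets: two cohorts
# (e.g. a human case/control cohort and a rodent exposure-stage cohort),
# a control group plus exposure stages (Intoxication / Withdrawal /
# Abstinence), both sexes, planted cross-cohort DE effects (concordant,
# discordant, cohort-unique), planted correlation modules whose connectivity
# differs between groups, and biotype labels.

#' Construct an expression-matrix container
#'
#' Log2-scale expression values with 1:1-keyed sample and gene annotations.
#'
#' @param values numeric matrix, genes x samples, finite log2 expression.
#' @param samples data.frame with columns `sample`, `group`, `sex`, `cohort`,
#'   one row per column of `values`.
#' @param genes data.frame with columns `gene`, `symbol`, `biotype`, one row
#'   per row of `values`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, samples, genes) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("expression values must be finite numeric", call. = FALSE)
  }
  if (anyDuplicated(genes$gene) || anyDuplicated(samples$sample)) {
    stop("gene and sample ids must be unique", call. = FALSE)
  }
  if (nrow(genes) != nrow(values) || nrow(samples) != ncol(values)) {
    stop("annotation tables must key 1:1 to matrix dimensions", call. = FALSE)
  }
  rownames(values) <- genes$gene
  colnames(values) <- samples$sample
  structure(list(values = values,
                 samples = as.data.frame(samples, stringsAsFactors = FALSE),
                 genes = as.data.frame(genes, stringsAsFactors = FALSE)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("  groups: ", paste(unique(x$samples$group), collapse = ", "), "\n", sep = "")
  cat("  sexes:  ", paste(unique(x$samples$sex), collapse = ", "), "\n", sep = "")
  cat("  cohort: ", paste(unique(x$samples$cohort), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Specify a planted co-expression module
#'
#' @param size number of genes in the module (>= 3).
#' @param r_control within-module pairwise correlation in all samples outside
#'   the target group.
#' @param r_treatment within-module pairwise correlation in the target group.
#' @param group group label whose connectivity differs from control.
#' @return A `module_spec` list.
#' @export
module_spec <- function(size, r_control, r_treatment, group) {
  check_scalar(size, "size", lower = 3)
  check_scalar(r_control, "r_control")
  check_scalar(r_treatment, "r_treatment")
  if (r_control <= -1 || r_control >= 1 || r_treatment <= -1 || r_treatment >= 1) {
    stop("module correlations must lie strictly within (-1, 1)", call. = FALSE)
  }
  structure(list(size = as.integer(size), r_control = r_control,
                 r_treatment = r_treatment, group = as.character(group)),
            class = "module_spec")
}

#' Describe a synthetic two-cohort study design
#'
#' Defaults emulate a control group plus three opioid-exposure stages, both
#' sexes, and the observed biotype mix of differentially expressed
#' transcripts (mostly protein coding, with smaller lncRNA and pseudogene
#' fractions). DE-class fractions refer to the planted cross-cohort effect
#' classes; their sum must not exceed 1 (the remainder are null genes).
#'
#' @param n_genes number of genes per cohort.
#' @param groups group labels; the first is the control group.
#' @param n_per_group samples per group per sex (>= 3).
#' @param sexes sex labels.
#' @param frac_concordant_up,frac_concordant_down,frac_discordant,frac_unique_a,frac_unique_b
#'   fractions of genes assigned to each planted cross-cohort effect class.
#' @param effect_mean,effect_sd mean and sd of planted |log2FC| (log2 units).
#' @param noise_sd residual standard deviation (log2 units).
#' @param modules list of [module_spec()] objects; module gene sets are
#'   allocated disjointly from the null-gene pool.
#' @param biotype_props named proportions summing to 1.
#' @param ortholog_coverage fraction of genes present in both cohorts'
#'   symbol spaces (0 < coverage <= 1).
#' @param de_sexes sexes in which planted effects are expressed
#'   (default: all).
#' @param seed integer default seed for generation.
#' @return A `synth_design` list.
#' @export
synth_design <- function(n_genes = 2000,
                         groups = c("control", "intoxication", "withdrawal", "abstinence"),
                         n_per_group = 10,
                         sexes = c("F", "M"),
                         frac_concordant_up = 0,
                         frac_concordant_down = 0,
                         frac_discordant = 0,
                         frac_unique_a = 0,
                         frac_unique_b = 0,
                         effect_mean = 1,
                         effect_sd = 0.2,
                         noise_sd = 0.5,
                         modules = list(),
                         biotype_props = c(protein_coding = 0.892,
                                           lncRNA = 0.075,
                                           pseudogene = 0.033),
                         ortholog_coverage = 1,
                         de_sexes = NULL,
                         seed = 1L) {
  check_scalar(n_genes, "n_genes", lower = 1)
  check_scalar(n_per_group, "n_per_group", lower = 3)
  fracs <- c(conc_up = frac_concordant_up, conc_down = frac_concordant_down,
             disc = frac_discordant, unique_a = frac_unique_a,
             unique_b = frac_unique_b)
  if (any(fracs < 0) || sum(fracs) > 1 + 1e-12) {
    stop("DE-class proportions must be non-negative and sum to <= 1", call. = FALSE)
  }
  if (abs(sum(biotype_props) - 1) > 1e-9) {
    stop("biotype_props must sum to 1", call. = FALSE)
  }
  if (ortholog_coverage <= 0 || ortholog_coverage > 1) {
    stop("ortholog_coverage must lie in (0, 1]", call. = FALSE)
  }
  if (length(groups) < 2) stop("need a control group and at least one other", call. = FALSE)
  for (m in modules) {
    if (!inherits(m, "module_spec")) stop("modules must be module_spec objects", call. = FALSE)
    if (!m$group %in% groups) stop("module group not among design groups", call. = FALSE)
  }
  if (sum(vapply(modules, `[[`, integer(1), "size")) > n_genes) {
    stop("module overlap: module sizes exceed the gene universe", call. = FALSE)
  }
  de_sexes <- de_sexes %||% sexes
  if (!all(de_sexes %in% sexes)) stop("de_sexes must be a subset of sexes", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes), groups = as.character(groups),
                 n_per_group = as.integer(n_per_group), sexes = as.character(sexes),
                 fracs = fracs, effect_mean = effect_mean, effect_sd = effect_sd,
                 noise_sd = noise_sd, modules = modules,
                 biotype_props = biotype_props,
                 ortholog_coverage = ortholog_coverage,
                 de_sexes = as.character(de_sexes),
                 seed = as.integer(seed)),
            class = "synth_design")
}

# Allocate DE classes, signed effect magnitudes for both cohorts, module
# membership and biotypes. One draw defines the shared truth of a pair.
plant_truth <- function(design, seed) {
  with_seed(seed, {
    n <- design$n_genes
    counts <- round(design$fracs * n)
    if (sum(counts) > n) stop("DE-class proportions sum to more than 1", call. = FALSE)
    cls <- rep("null", n)
    idx <- sample.int(n)
    pos <- 1L
    for (cname in names(counts)) {
      k <- counts[[cname]]
      if (k > 0) {
        cls[idx[pos:(pos + k - 1L)]] <- cname
        pos <- pos + k
      }
    }
    mag_a <- abs(stats::rnorm(n, design$effect_mean, design$effect_sd))
    mag_b <- abs(stats::rnorm(n, design$effect_mean, design$effect_sd))
    sign_free <- sample(c(-1, 1), n, replace = TRUE)
    lfc_a <- numeric(n)
    lfc_b <- numeric(n)
    lfc_a[cls == "conc_up"] <- mag_a[cls == "conc_up"]
    lfc_b[cls == "conc_up"] <- mag_b[cls == "conc_up"]
    lfc_a[cls == "conc_down"] <- -mag_a[cls == "conc_down"]
    lfc_b[cls == "conc_down"] <- -mag_b[cls == "conc_down"]
    lfc_a[cls == "disc"] <- sign_free[cls == "disc"] * mag_a[cls == "disc"]
    lfc_b[cls == "disc"] <- -sign_free[cls == "disc"] * mag_b[cls == "disc"]
    lfc_a[cls == "unique_a"] <- sign_free[cls == "unique_a"] * mag_a[cls == "unique_a"]
    lfc_b[cls == "unique_b"] <- sign_free[cls == "unique_b"] * mag_b[cls == "unique_b"]

    module <- rep(NA_character_, n)
    null_pool <- which(cls == "null")
    need <- sum(vapply(design$modules, `[[`, integer(1), "size"))
    if (need > length(null_pool)) {
      stop("module overlap: not enough null genes to host disjoint modules",
           call. = FALSE)
    }
    if (need > 0) {
      take <- sample(null_pool, need)
      at <- 1L
      for (j in seq_along(design$modules)) {
        sz <- design$modules[[j]]$size
        module[take[at:(at + sz - 1L)]] <- sprintf("M%02d", j)
        at <- at + sz
      }
    }
    biotype <- sample(names(design$biotype_props), n, replace = TRUE,
                      prob = design$biotype_props)
    mods <- if (length(design$modules)) {
      data.frame(
        module = sprintf("M%02d", seq_along(design$modules)),
        group = vapply(design$modules, `[[`, character(1), "group"),
        r_control = vapply(design$modules, `[[`, numeric(1), "r_control"),
        r_treatment = vapply(design$modules, `[[`, numeric(1), "r_treatment"),
        change = vapply(design$modules, function(m) {
          if (m$r_treatment > m$r_control) "gain"
          else if (m$r_treatment < m$r_control) "loss" else "none"
        }, character(1)),
        stringsAsFactors = FALSE)
    } else {
      data.frame(module = character(0), group = character(0),
                 r_control = numeric(0), r_treatment = numeric(0),
                 change = character(0))
    }
    base_symbol <- sprintf("GENE%05d", seq_len(n))
    structure(list(
      genes = data.frame(gene = base_symbol, class = cls,
                         lfc_a = lfc_a, lfc_b = lfc_b, module = module,
                         biotype = biotype, stringsAsFactors = FALSE),
      modules = mods,
      de_sexes = design$de_sexes),
      class = "synthetic_truth")
  })
}

title_case <- function(x) {
  paste0(toupper(substring(x, 1, 1)), tolower(substring(x, 2)))
}

# Build one cohort's matrix from a planted truth. `lfc` is the per-gene
# true effect for this cohort, applied in all non-control groups restricted
# to de_sexes. Module genes follow the equicorrelated latent-factor model
# x = sqrt(r) f + sqrt(1-r) e, scaled by noise_sd, with r depending on
# whether the sample belongs to the module's target group.
build_cohort <- function(design, truth, lfc, cohort_label, symbol_case, seed) {
  with_seed(seed, {
    n <- design$n_genes
    samp <- expand.grid(rep = seq_len(design$n_per_group),
                        sex = design$sexes, group = design$groups,
                        stringsAsFactors = FALSE)
    samp <- data.frame(
      sample = sprintf("%s_%s_%s_%02d", cohort_label, samp$group, samp$sex, samp$rep),
      group = samp$group, sex = samp$sex, cohort = cohort_label,
      stringsAsFactors = FALSE)
    ns <- nrow(samp)
    baseline <- stats::rnorm(n, mean = 7, sd = 1.5)
    eps <- matrix(stats::rnorm(n * ns), n, ns)
    vals <- matrix(0, n, ns)
    plain <- is.na(truth$genes$module)
    vals[plain, ] <- design$noise_sd * eps[plain, , drop = FALSE]
    if (any(!plain)) {
      for (j in seq_len(nrow(truth$modules))) {
        mid <- truth$modules$module[j]
        members <- which(truth$genes$module == mid)
        f <- stats::rnorm(ns)
        r <- ifelse(samp$group == truth$modules$group[j],
                    truth$modules$r_treatment[j], truth$modules$r_control[j])
        load <- sqrt(abs(r)) * sign(r)
        resid <- sqrt(1 - abs(r))
        sig <- outer(rep(1, length(members)), load * f) +
          sweep(eps[members, , drop = FALSE], 2, resid, `*`)
        vals[members, ] <- design$noise_sd * sig
      }
    }
    vals <- vals + baseline
    on_samples <- samp$group != design$groups[1] & samp$sex %in% truth$de_sexes
    if (any(on_samples)) {
      vals[, on_samples] <- vals[, on_samples] + lfc
    }
    symbol <- if (symbol_case == "upper") truth$genes$gene else title_case(truth$genes$gene)
    genes <- data.frame(gene = symbol, symbol = symbol,
                        biotype = truth$genes$biotype, stringsAsFactors = FALSE)
    expression_matrix(vals, samp, genes)
  })
}

#' Generate one synthetic cohort with planted truth
#'
#' @param design a [synth_design()].
#' @param cohort_label label stored in the sample annotations.
#' @param seed integer; identical `(design, seed)` gives identical output.
#' @param symbol_case `"upper"` or `"title"` gene-symbol casing.
#' @return A list with elements `matrix` (an `expression_matrix`) and
#'   `truth` (a `synthetic_truth`: per-gene class, true log2FC, module id,
#'   and per-module connectivity-change labels).
#' @export
generate_cohort <- function(design, cohort_label = "a", seed = design$seed,
                            symbol_case = c("upper", "title")) {
  stopifnot(inherits(design, "synth_design"))
  symbol_case <- match.arg(symbol_case)
  truth <- plant_truth(design, derive_seed(seed, "truth"))
  lfc <- truth$genes$lfc_a
  mat <- build_cohort(design, truth, lfc, cohort_label, symbol_case,
                      derive_seed(seed, paste0("cohort_", cohort_label)))
  if (symbol_case == "title") {
    truth$genes$gene <- title_case(truth$genes$gene)
  }
  list(matrix = mat, truth = truth)
}

#' Generate a paired two-cohort dataset with a shared planted truth
#'
#' Concordant genes receive same-sign true effects in both cohorts,
#' discordant genes opposite signs, and cohort-unique genes an effect in one
#' cohort only. Cohort a uses upper-case symbols and cohort b title-case
#' symbols, so downstream ortholog matching must be case-insensitive.
#'
#' @param design_a,design_b designs for the two cohorts; concordance
#'   fractions and group labels must match.
#' @param seed master seed.
#' @return list with `matrix_a`, `matrix_b`, `ortholog_map` (data.frame with
#'   columns `symbol_a`, `symbol_b`) and `truth`.
#' @export
generate_pair <- function(design_a, design_b = design_a, seed = design_a$seed) {
  stopifnot(inherits(design_a, "synth_design"), inherits(design_b, "synth_design"))
  if (!identical(design_a$groups, design_b$groups)) {
    stop("cohort designs must share group labels", call. = FALSE)
  }
  if (!isTRUE(all.equal(design_a$fracs, design_b$fracs))) {
    stop("cohort designs must share concordance-class fractions", call. = FALSE)
  }
  if (design_a$n_genes != design_b$n_genes) {
    stop("paired designs must share the gene universe size", call. = FALSE)
  }
  truth <- plant_truth(design_a, derive_seed(seed, "truth"))
  mat_a <- build_cohort(design_a, truth, truth$genes$lfc_a, "a", "upper",
                        derive_seed(seed, "cohort_a"))
  mat_b <- build_cohort(design_b, truth, truth$genes$lfc_b, "b", "title",
                        derive_seed(seed, "cohort_b"))
  n_map <- floor(design_a$ortholog_coverage * design_a$n_genes)
  mapped <- with_seed(derive_seed(seed, "orthologs"),
                      sort(sample.int(design_a$n_genes, n_map)))
  omap <- data.frame(symbol_a = truth$genes$gene[mapped],
                     symbol_b = title_case(truth$genes$gene[mapped]),
                     stringsAsFactors = FALSE)
  list(matrix_a = mat_a, matrix_b = mat_b, ortholog_map = omap, truth = truth)
}

#' Generate synthetic single-cell-like profiles for module scoring
#'
#' Cells of enriched types express the module genes at elevated rank
#' positions; all other cells rank genes uniformly.
#'
#' @param n_cells number of cells.
#' @param cell_types vector of cell-type labels to cycle over.
#' @param module_genes genes boosted in enriched cells (non-empty, subset of
#'   `universe`).
#' @param enriched_types subset of `cell_types` receiving the boost.
#' @param universe gene identifiers of the full profile.
#' @param boost mean log-expression shift applied to module genes in
#'   enriched cells (in units of the profile noise sd).
#' @param seed integer seed.
#' @return list with `values` (genes x cells), `cell_type`, `cell_ids`.
#' @export
generate_cell_profiles <- function(n_cells, cell_types, module_genes,
                                   enriched_types, universe, boost = 2,
                                   seed = 1L) {
  if (length(module_genes) == 0) stop("module_genes must be non-empty", call. = FALSE)
  if (!all(enriched_types %in% cell_types)) {
    stop("enriched_types must be a subset of cell_types", call. = FALSE)
  }
  if (!all(module_genes %in% universe)) {
    stop("module_genes must be contained in the universe", call. = FALSE)
  }
  with_seed(seed, {
    n_genes <- length(universe)
    vals <- matrix(stats::rnorm(n_genes * n_cells), n_genes, n_cells,
                   dimnames = list(universe, sprintf("cell%04d", seq_len(n_cells))))
    cell_type <- sample(rep(cell_types, length.out = n_cells))
    hot <- cell_type %in% enriched_types
    if (any(hot)) {
      vals[match(module_genes, universe), hot] <-
        vals[match(module_genes, universe), hot] + boost
    }
    list(values = vals, cell_type = cell_type, cell_ids = colnames(vals))
  })
}
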