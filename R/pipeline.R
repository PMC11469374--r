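# Orchestration of the full cross-species workflow: simulate (or load) two
# cohorts -> per-sex differential expression for every contrast -> RRHO
# between the cohorts' signatures -> co-expression modules on cohort a ->
# module differential connectivity -> module/DE enrichment and hubs ->
# structured report.

#' Assemble and validate a pipeline configuration
#'
#' @param design a [synth_design()] for cohort a (simulation mode), or NULL
#'   with `input_prefix_a`/`input_prefix_b` set (load mode).
#' @param design_b optional design for cohort b (defaults to `design`).
#' @param input_prefix_a,input_prefix_b,ortholog_path paths for load mode
#'   (see [read_expression_tsv()] and [read_ortholog_tsv()]).
#' @param contrasts non-control group labels to test against control
#'   (default: every non-control group of the design).
#' @param sexes sex strata analyzed separately (default: the design's).
#' @param p_thresh,lfc_thresh DE thresholds.
#' @param rrho_step RRHO rank stride or `"auto"`.
#' @param n_network_genes variance-ranked genes entering the network stage.
#' @param beta soft-threshold power or `"auto"`.
#' @param n_perm MDC permutations per scheme.
#' @param gmt_path optional GMT file for over-representation analysis.
#' @param out_dir optional output directory; intermediates are written under
#'   `de/`, `rrho/`, `modules/`, `mdc/`, `enrich/`.
#' @param seed master seed; stage seeds are derived stably from it.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(design = NULL, design_b = NULL,
                            input_prefix_a = NULL, input_prefix_b = NULL,
                            ortholog_path = NULL,
                            contrasts = NULL, sexes = NULL,
                            p_thresh = 0.01, lfc_thresh = 0.26,
                            rrho_step = "auto", n_network_genes = 5000,
                            beta = "auto", n_perm = 1000,
                            gmt_path = NULL, out_dir = NULL, seed = 1L) {
  if (is.null(design) && is.null(input_prefix_a)) {
    stop("either a simulation design or input paths must be given", call. = FALSE)
  }
  if (!is.null(design)) stopifnot(inherits(design, "synth_design"))
  for (p in c(input_prefix_a = input_prefix_a, input_prefix_b = input_prefix_b)) {
    if (!is.null(p) && !file.exists(paste0(p, "_matrix.tsv"))) {
      stop("input matrix not found: ", p, call. = FALSE)
    }
  }
  if (!is.null(ortholog_path) && !file.exists(ortholog_path)) {
    stop("ortholog map not found: ", ortholog_path, call. = FALSE)
  }
  if (!is.null(gmt_path) && !file.exists(gmt_path)) {
    stop("GMT file not found: ", gmt_path, call. = FALSE)
  }
  if (p_thresh <= 0 || lfc_thresh < 0) stop("thresholds must be positive", call. = FALSE)
  structure(list(design = design, design_b = design_b %||% design,
                 input_prefix_a = input_prefix_a, input_prefix_b = input_prefix_b,
                 ortholog_path = ortholog_path,
                 contrasts = contrasts, sexes = sexes,
                 p_thresh = p_thresh, lfc_thresh = lfc_thresh,
                 rrho_step = rrho_step, n_network_genes = n_network_genes,
                 beta = beta, n_perm = n_perm, gmt_path = gmt_path,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Design fields are passed to [synth_design()]; `modules` entries to
#' [module_spec()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$design)) {
    mods <- lapply(y$design$modules, function(m) do.call(module_spec, m))
    y$design$modules <- NULL
    y$design <- do.call(synth_design, c(y$design, list(modules = mods)))
  }
  do.call(pipeline_config, y)
}

rrho_from_de <- function(de_a, de_b, omap, step) {
  uni <- map_orthologs(de_a$gene, de_b$gene, map = omap)
  a <- de_a[match(uni$symbol_a, de_a$gene), ]
  b <- de_b[match(uni$symbol_b, de_b$gene), ]
  sig_a <- ranked_signature(uni$key, a$p, a$log2FC)
  sig_b <- ranked_signature(uni$key, b$p, b$log2FC)
  compute_rrho_map(sig_a, sig_b, step = step)
}

#' Run the full cross-species concordance workflow
#'
#' Executes, in dependency order: data simulation (or loading); per-contrast
#' differential expression, pooled and per sex, in both cohorts; signed RRHO
#' between the cohorts' signatures per stratum; co-expression module
#' detection on cohort a; module differential connectivity per contrast;
#' DE/module enrichment (plus GMT over-representation when configured); and
#' hub identification on the most DE-enriched module. Rerunning with the
#' same config and seed reproduces every output.
#'
#' @param config a [pipeline_config()].
#' @return a `run_report` list: `de` (tables and up/down counts),
#'   `biotypes`, `rrho` (quadrant summaries per comparison), `modules`,
#'   `mdc`, `enrichment`, `hubs`, and `provenance`.
#' @export
run_crossspecies <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  # --- data ---------------------------------------------------------------
  if (!is.null(config$design)) {
    pair <- generate_pair(config$design, config$design_b,
                          seed = derive_seed(seed, "simulate"))
    mat_a <- pair$matrix_a; mat_b <- pair$matrix_b
    omap <- pair$ortholog_map; truth <- pair$truth
  } else {
    mat_a <- read_expression_tsv(config$input_prefix_a)
    mat_b <- if (!is.null(config$input_prefix_b))
      read_expression_tsv(config$input_prefix_b) else NULL
    omap <- if (!is.null(config$ortholog_path))
      read_ortholog_tsv(config$ortholog_path) else NULL
    truth <- NULL
  }
  control <- unique(mat_a$samples$group)[1]
  contrasts <- config$contrasts %||% setdiff(unique(mat_a$samples$group), control)
  sexes <- config$sexes %||% unique(mat_a$samples$sex)
  strata <- c(list(NULL), as.list(sexes))
  names(strata) <- c("pooled", sexes)

  # --- differential expression --------------------------------------------
  de <- list(); de_counts <- list()
  for (ct in contrasts) {
    for (sx in names(strata)) {
      key <- paste(ct, sx, sep = ".")
      de[[paste0("a.", key)]] <- run_de(mat_a, c(control, ct), sex = strata[[sx]],
                                        p_thresh = config$p_thresh,
                                        lfc_thresh = config$lfc_thresh)
      if (!is.null(mat_b)) {
        de[[paste0("b.", key)]] <- run_de(mat_b, c(control, ct), sex = strata[[sx]],
                                          p_thresh = config$p_thresh,
                                          lfc_thresh = config$lfc_thresh)
      }
    }
  }
  de_counts <- do.call(rbind, lapply(names(de), function(k) {
    data.frame(comparison = k, up = sum(de[[k]]$class == "up"),
               down = sum(de[[k]]$class == "down"), stringsAsFactors = FALSE)
  }))
  biotypes <- lapply(de[grep("^a\\.", names(de))], summarize_biotypes,
                     gene_annotations = mat_a$genes)

  # --- RRHO ----------------------------------------------------------------
  rrho <- list()
  if (!is.null(mat_b)) {
    for (ct in contrasts) {
      for (sx in names(strata)) {
        key <- paste(ct, sx, sep = ".")
        rrho[[key]] <- rrho_from_de(de[[paste0("a.", key)]],
                                    de[[paste0("b.", key)]],
                                    omap, config$rrho_step)
      }
    }
  }

  # --- modules -------------------------------------------------------------
  net_genes <- select_variable_genes(mat_a, config$n_network_genes)
  net_vals <- mat_a$values[net_genes, , drop = FALSE]
  beta <- if (identical(config$beta, "auto")) {
    pick_soft_threshold(net_vals)$beta
  } else config$beta
  A <- adjacency(net_vals, beta)
  tomm <- tom_similarity(A)
  labels <- detect_modules(tomm, expr = net_vals)
  eig <- if (any(labels != "grey")) module_eigengene(net_vals, labels) else NULL

  # --- MDC -----------------------------------------------------------------
  mdc <- list()
  if (any(labels != "grey")) {
    for (ct in contrasts) {
      mdc[[ct]] <- mdc_test(mat_a, ct, control, labels, beta,
                            n_perm = config$n_perm,
                            seed = derive_seed(seed, paste0("mdc_", ct)))
    }
  }

  # --- enrichment ----------------------------------------------------------
  enrichment <- list()
  if (any(labels != "grey")) {
    for (ct in contrasts) {
      d <- de[[paste0("a.", ct, ".pooled")]]
      if (any(d$class != "ns" & d$gene %in% net_genes)) {
        enrichment[[paste0("module_de.", ct)]] <-
          module_de_enrichment(d, labels, background = net_genes)
      }
    }
  }
  if (!is.null(config$gmt_path)) {
    gmt <- read_gmt(config$gmt_path)
    first <- names(rrho)[1]
    query <- if (length(rrho)) intersect(quadrant_genes(rrho[[first]], "down-down"),
                                         net_genes) else character(0)
    if (length(query)) {
      enrichment$ora <- ora(gmt, query, net_genes)
    }
  }

  # --- hubs ----------------------------------------------------------------
  hubs <- NULL
  if (!is.null(eig)) {
    top_mod <- names(sort(table(labels[labels != "grey"]), decreasing = TRUE))[1]
    idx <- grep("^module_de", names(enrichment))
    if (length(idx) && nrow(enrichment[[idx[1]]])) {
      top_mod <- enrichment[[idx[1]]]$module[which.min(enrichment[[idx[1]]]$p)]
    }
    hubs <- identify_hubs(eig$kme, labels[labels == top_mod], top_k = 11,
                          de_table = de[[paste0("a.", contrasts[1], ".pooled")]])
  }

  report <- structure(list(
    de = de, de_counts = de_counts, biotypes = biotypes,
    rrho = rrho,
    rrho_summaries = lapply(rrho, `[[`, "quadrant_summaries"),
    modules = labels, beta = beta, eigengenes = eig,
    mdc = mdc, enrichment = enrichment, hubs = hubs, truth = truth,
    provenance = list(seed = seed, control = control, contrasts = contrasts,
                      sexes = sexes, n_network_genes = length(net_genes),
                      package_version = as.character(utils::packageVersion("xsconcord")),
                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
    class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, mat_a, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("cross-species concordance run\n")
  cat(sprintf("  contrasts: %s | sexes: %s | seed %d\n",
              paste(x$provenance$contrasts, collapse = ", "),
              paste(x$provenance$sexes, collapse = ", "), x$provenance$seed))
  cat("  DE counts:\n")
  print(x$de_counts, row.names = FALSE)
  if (length(x$rrho_summaries)) {
    cat("  RRHO concordant maxima (down-down / up-up):\n")
    for (k in names(x$rrho_summaries)) {
      s <- x$rrho_summaries[[k]]
      cat(sprintf("    %-28s %7.2f / %7.2f\n", k,
                  s$max[s$quadrant == "down-down"], s$max[s$quadrant == "up-up"]))
    }
  }
  nmod <- length(setdiff(unique(x$modules), "grey"))
  cat(sprintf("  modules: %d (beta = %s)\n", nmod, format(x$beta)))
  for (ct in names(x$mdc)) {
    m <- x$mdc[[ct]]
    cat(sprintf("  MDC %s: %d gain, %d loss of %d modules\n", ct,
                sum(m$call == "gain"), sum(m$call == "loss"), nrow(m)))
  }
  invisible(x)
}

write_report <- function(report, mat_a, out_dir) {
  for (d in c("de", "rrho", "modules", "mdc", "enrich")) {
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  for (k in names(report$de)) {
    write_de_tsv(report$de[[k]], file.path(out_dir, "de", paste0(k, ".tsv")))
  }
  for (k in names(report$rrho)) {
    utils::write.table(report$rrho[[k]]$grid,
                       file.path(out_dir, "rrho", paste0(k, "_grid.tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
    jsonlite::write_json(report$rrho_summaries[[k]],
                         file.path(out_dir, "rrho", paste0(k, "_summary.json")),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  utils::write.table(data.frame(gene = names(report$modules),
                                module = unname(report$modules)),
                     file.path(out_dir, "modules", "modules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (k in names(report$mdc)) {
    utils::write.table(as.data.frame(report$mdc[[k]]),
                       file.path(out_dir, "mdc", paste0(k, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (k in names(report$enrichment)) {
    utils::write.table(report$enrichment[[k]],
                       file.path(out_dir, "enrich", paste0(k, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary_obj <- list(de_counts = report$de_counts,
                      rrho = report$rrho_summaries,
                      mdc = lapply(report$mdc, as.data.frame),
                      provenance = report$provenance)
  jsonlite::write_json(summary_obj, file.path(out_dir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
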