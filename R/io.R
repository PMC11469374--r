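# Plain-text readers/writers for expression matrices, DE tables and
# ortholog maps. Round-trip safe: writing then reading reproduces values to
# full double precision and annotations exactly.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write an expression matrix as TSV with sidecar annotation tables
#'
#' Writes `<prefix>_matrix.tsv` (first column `gene`, one column per
#' sample), `<prefix>_samples.tsv` and `<prefix>_genes.tsv`.
#'
#' @param mat an [expression_matrix()].
#' @param prefix output path prefix.
#' @return invisibly, the three file paths.
#' @export
write_expression_tsv <- function(mat, prefix) {
  stopifnot(inherits(mat, "expression_matrix"))
  paths <- paste0(prefix, c("_matrix.tsv", "_samples.tsv", "_genes.tsv"))
  header <- paste(c("gene", colnames(mat$values)), collapse = "\t")
  body <- vapply(seq_len(nrow(mat$values)), function(i) {
    paste(c(rownames(mat$values)[i], fmt_num(mat$values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), paths[1])
  utils::write.table(mat$samples, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(mat$genes, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

read_tsv_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sub("\r$", "", lines)
}

#' Read an expression matrix written by [write_expression_tsv()]
#'
#' @param prefix path prefix used at write time.
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(prefix) {
  mpath <- paste0(prefix, "_matrix.tsv")
  lines <- read_tsv_lines(mpath)
  if (length(lines) < 2) stop("malformed matrix TSV: no data rows", call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "gene") {
    stop("malformed header at line 1: first column must be 'gene'", call. = FALSE)
  }
  sample_ids <- header[-1]
  n <- length(lines) - 1L
  vals <- matrix(NA_real_, n, length(sample_ids))
  gene_ids <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(header)) {
      stop(sprintf("malformed row at line %d: %d fields, expected %d",
                   i + 1, length(f), length(header)), call. = FALSE)
    }
    gene_ids[i] <- f[1]
    x <- suppressWarnings(as.numeric(f[-1]))
    if (any(is.na(x))) {
      stop(sprintf("non-numeric cell at line %d", i + 1), call. = FALSE)
    }
    vals[i, ] <- x
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicated gene ids at lines: ",
         paste(which(duplicated(gene_ids)) + 1, collapse = ", "), call. = FALSE)
  }
  samples <- utils::read.delim(paste0(prefix, "_samples.tsv"),
                               stringsAsFactors = FALSE)
  genes <- utils::read.delim(paste0(prefix, "_genes.tsv"),
                             stringsAsFactors = FALSE)
  samples <- samples[match(sample_ids, samples$sample), , drop = FALSE]
  genes <- genes[match(gene_ids, genes$gene), , drop = FALSE]
  expression_matrix(vals, samples, genes)
}

#' Write a DE table as TSV
#'
#' Columns: gene, log2FC, t, p, q, class.
#'
#' @param de a `de_table`.
#' @param path output path.
#' @export
write_de_tsv <- function(de, path) {
  header <- "gene\tlog2FC\tt\tp\tq\tclass"
  body <- vapply(seq_len(nrow(de)), function(i) {
    paste(c(de$gene[i], fmt_num(c(de$log2FC[i], de$t[i], de$p[i], de$q[i])),
            de$class[i]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a DE table TSV
#'
#' @param path file written by [write_de_tsv()] (or any TSV with at least
#'   columns gene, log2FC, p).
#' @return data.frame.
#' @export
read_de_tsv <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "log2FC", "p")
  if (!all(need %in% names(out))) {
    stop("DE TSV must contain columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(out$gene)) stop("duplicated gene ids in DE table", call. = FALSE)
  out
}

#' Read a two-column ortholog symbol map
#'
#' @param path TSV with columns `symbol_a`, `symbol_b` (header optional if
#'   exactly two columns).
#' @return data.frame with columns `symbol_a`, `symbol_b`.
#' @export
read_ortholog_tsv <- function(path) {
  lines <- read_tsv_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty ortholog map", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2)
  if (length(bad)) {
    stop(sprintf("malformed ortholog row at line %d: expected 2 fields", bad[1]),
         call. = FALSE)
  }
  m <- do.call(rbind, fields)
  if (identical(tolower(m[1, ]), c("symbol_a", "symbol_b"))) m <- m[-1, , drop = FALSE]
  data.frame(symbol_a = m[, 1], symbol_b = m[, 2], stringsAsFactors = FALSE)
}
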