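#' Expression dataset container
#'
#' Bundles a raw count matrix (samples in rows, genes in columns) with sample
#' identifiers, unique gene names and integer class labels in `1..n_classes`.
#'
#' @param counts numeric matrix, samples x genes, nonnegative; `dimnames`
#'   supply sample ids (rows) and gene names (columns).
#' @param labels integer vector of class labels, one per sample, values in
#'   `1..n_classes`; every class must be represented.
#' @param n_classes number of classes; defaults to `max(labels)`.
#' @return an object of class `expression_dataset` with elements `counts`,
#'   `labels`, `n_classes`, `gene_names`, `sample_ids`.
#' @export
expression_dataset <- function(counts, labels, n_classes = max(labels)) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("G%06d", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("S%05d", seq_len(nrow(counts)))
  if (anyDuplicated(colnames(counts)))
    stop_format("duplicate gene names: ",
                paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                      collapse = ", "))
  if (anyDuplicated(rownames(counts)))
    stop_format("duplicate sample ids: ",
                paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                      collapse = ", "))
  labels <- as.integer(labels)
  if (length(labels) != nrow(counts))
    stop_format("labels length (", length(labels),
                ") does not match sample count (", nrow(counts), ")")
  n_classes <- as.integer(n_classes)
  if (any(labels < 1L) || any(labels > n_classes))
    stop_format("labels must lie in 1..", n_classes)
  if (!all(seq_len(n_classes) %in% labels))
    stop_format("every class in 1..", n_classes, " needs at least one sample")
  structure(list(counts = counts, labels = labels, n_classes = n_classes,
                 gene_names = colnames(counts),
                 sample_ids = rownames(counts)),
            class = "expression_dataset")
}

#' @exportS3Method base::print
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d samples x %d genes, %d classes\n",
              nrow(x$counts), ncol(x$counts), x$n_classes))
  cat("  samples per class:",
      paste(tabulate(x$labels, x$n_classes), collapse = "/"), "\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$counts)

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read an expression matrix and its sample labels
#'
#' The matrix file holds samples in rows and genes in columns; the first
#' column is the sample id.  The labels file has two columns, `sample_id` and
#' `label`.  Delimiters (tab or comma) are auto-detected per file.
#'
#' @param matrix_path path to the expression table.
#' @param labels_path path to the labels table.
#' @param transpose set `TRUE` for genes-in-rows dumps.
#' @return an [expression_dataset()].
#' @export
read_expression <- function(matrix_path, labels_path, transpose = FALSE) {
  for (p in c(matrix_path, labels_path))
    if (!file.exists(p)) stop_format("file not found: ", p)
  tab <- utils::read.table(matrix_path, sep = detect_sep(matrix_path),
                           header = TRUE, row.names = 1L,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  if (!is.numeric(m)) {
    bad <- which(!vapply(tab, is.numeric, logical(1)))
    stop_format("non-numeric expression column: ",
                paste(colnames(tab)[bad], collapse = ", "))
  }
  if (transpose) m <- t(m)
  lab <- utils::read.table(labels_path, sep = detect_sep(labels_path),
                           header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(lab) < 2L) stop_format("labels file needs sample_id and label columns")
  idx <- match(rownames(m), lab[[1L]])
  if (anyNA(idx))
    stop_format("samples missing from labels file: ",
                paste(rownames(m)[is.na(idx)], collapse = ", "))
  expression_dataset(m, as.integer(lab[[2L]][idx]))
}

#' Write an expression dataset as TSV
#'
#' Emits two files: `<stem>_counts.tsv` (first column `sample_id`, one column
#' per gene) and `<stem>_labels.tsv` (`sample_id`, `label`).
#'
#' @param data an [expression_dataset()].
#' @param stem output path stem.
#' @return invisibly, the two paths written.
#' @export
write_expression <- function(data, stem) {
  mp <- paste0(stem, "_counts.tsv")
  lp <- paste0(stem, "_labels.tsv")
  df <- data.frame(sample_id = data$sample_ids, data$counts,
                   check.names = FALSE)
  utils::write.table(df, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = data$sample_ids,
                                label = data$labels),
                     lp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix = mp, labels = lp))
}

#' Read a GMT gene-set collection
#'
#' Standard MSigDB dialect: one set per line, tab-separated fields
#' `name`, `description`, then member gene names.  Duplicate genes within a
#' line are dropped with a warning.
#'
#' @param path path to a `.gmt` file.
#' @return a `gene_set_collection`: named list of sets, each with
#'   `description` and `genes`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop_format("GMT line ", i, " has fewer than 3 fields")
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes in set '", fields[1L], "' deduplicated")
      genes <- unique(genes)
    }
    sets[[fields[1L]]] <- list(description = fields[2L], genes = genes)
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#'
#' @param collection a `gene_set_collection` as returned by [read_gmt()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm) {
    s <- collection[[nm]]
    paste(c(nm, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Gene ranking container
#'
#' Wraps a vector of per-gene importance scores (higher = more important)
#' together with its induced ranks.  Rank 1 is the most important gene; ties
#' are broken by gene-name lexicographic order so that every ranking is a
#' reproducible permutation.
#'
#' @param scores named numeric vector of finite scores, one per gene.
#' @param method method label, e.g. `"var"`, `"de"`, `"ig"`.
#' @param replicate optional replicate id.
#' @param note free-text direction note.
#' @return an object of class `gene_ranking` with `scores`, `ranks`,
#'   `method`, `replicate`, `note`.
#' @export
gene_ranking <- function(scores, method, replicate = NA_integer_,
                         note = "higher score = more important") {
  if (is.null(names(scores))) stop_format("scores must be named by gene")
  if (any(!is.finite(scores))) stop_format("non-finite score for: ",
    paste(names(scores)[!is.finite(scores)][1:5], collapse = ", "))
  ord <- order(-scores, names(scores), method = "radix")
  ranks <- integer(length(scores))
  ranks[ord] <- seq_along(scores)
  names(ranks) <- names(scores)
  structure(list(scores = scores, ranks = ranks, method = method,
                 replicate = replicate, note = note),
            class = "gene_ranking")
}

#' @exportS3Method base::print
print.gene_ranking <- function(x, ...) {
  cat(sprintf("<gene_ranking> method=%s, %d genes; top: %s\n", x$method,
              length(x$scores), paste(top_genes(x, 5L), collapse = ", ")))
  invisible(x)
}

#' Top / bottom genes of a ranking
#'
#' @param ranking a [gene_ranking()].
#' @param k number of genes.
#' @param from `"top"` (rank 1 upward) or `"bottom"` (last rank downward).
#' @return character vector of gene names, best (or worst) first.
#' @export
top_genes <- function(ranking, k, from = c("top", "bottom")) {
  from <- match.arg(from)
  k <- min(k, length(ranking$ranks))
  ord <- names(sort(ranking$ranks))
  if (from == "top") ord[seq_len(k)] else rev(ord)[seq_len(k)]
}

#' Write / read a ranking as TSV
#'
#' Columns `gene_name`, `score`, `rank` (rank 1 = most important; ties broken
#' lexicographically, recorded in a `#` header line).  `read_ranking` is the
#' exact inverse; scores round-trip through `%.17g` formatting.  This is also
#' the import path for externally computed rankings such as DESeq2 or edgeR
#' results scored as -log10 adjusted p.
#'
#' @param ranking a [gene_ranking()].
#' @param path file path.
#' @return `write_ranking` invisibly returns `path`; `read_ranking` returns a
#'   [gene_ranking()].
#' @export
write_ranking <- function(ranking, path) {
  ord <- order(ranking$ranks)
  lines <- c(sprintf("# method=%s ties=lexicographic", ranking$method),
             "gene_name\tscore\trank",
             sprintf("%s\t%.17g\t%d", names(ranking$scores)[ord],
                     ranking$scores[ord], ranking$ranks[ord]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  lines <- readLines(path)
  meta <- grepl("^#", lines)
  method <- "imported"
  if (any(meta)) {
    m <- regmatches(lines[meta][1], regexec("method=(\\S+)", lines[meta][1]))[[1]]
    if (length(m) == 2L) method <- m[2L]
  }
  tab <- utils::read.table(text = lines[!meta], sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  scores <- stats::setNames(as.numeric(tab$score), tab$gene_name)
  gene_ranking(scores, method)
}
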