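#' Construct a screen count matrix
#'
#' Holds guide-by-sample sequencing counts for a sorted-bin screen together
#' with each sample's role: `input` (the unselected mutant pool),
#' `bin_high` or `bin_low` (the FACS-sorted phenotype bins), and a
#' replicate label pairing sorted bins with their input.
#'
#' @param counts numeric matrix of non-negative integer counts; rows are
#'   guides (rownames = guide ids matching a [guide_library]), columns are
#'   samples.
#' @param samples data frame with columns `sample`, `role`
#'   (`input`/`bin_high`/`bin_low`) and `replicate`, one row per column of
#'   `counts` in column order.
#' @param normalized logical; `TRUE` once values are size-factor scaled
#'   (real-valued).
#' @return An object of class `screen_counts`: a list with elements
#'   `counts`, `samples`, `normalized`.
#' @export
screen_counts <- function(counts, samples, normalized = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    stop("counts must have guide ids as rownames", call. = FALSE)
  if (!normalized) {
    if (any(!is.finite(counts)) || any(counts < 0))
      stop("counts must be finite and non-negative", call. = FALSE)
    if (any(counts != round(counts)))
      stop("raw counts must be integers", call. = FALSE)
    storage.mode(counts) <- "integer"
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample", "role", "replicate")
  if (!all(need %in% names(samples)))
    stop("samples must have columns sample, role, replicate", call. = FALSE)
  if (nrow(samples) != ncol(counts))
    stop("samples must describe every column of counts", call. = FALSE)
  bad <- setdiff(samples$role, c("input", "bin_high", "bin_low"))
  if (length(bad))
    stop("unknown sample role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  colnames(counts) <- samples$sample
  structure(list(counts = counts, samples = samples, normalized = normalized),
            class = "screen_counts")
}

#' @export
print.screen_counts <- function(x, ...) {
  cat(sprintf("screen_counts: %d guides x %d samples%s\n",
              nrow(x$counts), ncol(x$counts),
              if (x$normalized) " (normalized)" else ""))
  tab <- table(x$samples$role)
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

samples_by_role <- function(counts, role) {
  counts$samples$sample[counts$samples$role == role]
}

#' Read a screen count table
#'
#' Reads the de facto pooled-screen count format: a tab-separated file with
#' a header whose first column is `guide_id`, second `gene_id`, and
#' remaining columns are samples. Rows are aligned to the library's guide
#' order; guides present in the library but absent from the file are filled
#' with zero counts (with a warning).
#'
#' @param path path to the TSV count table.
#' @param library a [guide_library] defining guide order.
#' @param sample_roles data frame with columns `sample`, `role`,
#'   `replicate` naming the count-table columns to load and their roles.
#' @return A [screen_counts] aligned to `library`.
#' @export
read_count_matrix <- function(path, library, sample_roles) {
  if (!file.exists(path))
    stop("screen_io.read_counts: count file not found: ", path, call. = FALSE)
  stopifnot(inherits(library, "guide_library"))
  sample_roles <- as.data.frame(sample_roles, stringsAsFactors = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, comment.char = "",
                           quote = "\"", stringsAsFactors = FALSE)
  if (!"guide_id" %in% names(tab))
    stop("screen_io.read_counts: count table lacks a guide_id column",
         call. = FALSE)
  missing_cols <- setdiff(sample_roles$sample, names(tab))
  if (length(missing_cols))
    stop("screen_io.read_counts: sample(s) named in mapping but absent from file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  m <- as.matrix(tab[, sample_roles$sample, drop = FALSE])
  if (!is.numeric(m))
    stop("screen_io.read_counts: non-numeric count cell(s)", call. = FALSE)
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "screen_io.read_counts: invalid count %s at guide '%s', sample '%s' (must be a non-negative integer)",
      format(m[bad[1, 1], bad[1, 2]]), tab$guide_id[bad[1, 1]],
      sample_roles$sample[bad[1, 2]]), call. = FALSE)
  }
  rownames(m) <- tab$guide_id
  extra <- setdiff(tab$guide_id, library$guide_id)
  if (length(extra))
    warning(length(extra), " guide(s) in count file not in library; dropped",
            call. = FALSE)
  absent <- setdiff(library$guide_id, tab$guide_id)
  out <- matrix(0L, nrow = nrow(library), ncol = nrow(sample_roles),
                dimnames = list(library$guide_id, sample_roles$sample))
  keep <- intersect(library$guide_id, tab$guide_id)
  out[keep, ] <- m[keep, , drop = FALSE]
  if (length(absent))
    warning(length(absent),
            " library guide(s) absent from count file; filled with zeros: ",
            paste(utils::head(absent, 5), collapse = ", "),
            if (length(absent) > 5) ", ..." else "", call. = FALSE)
  screen_counts(out, sample_roles)
}

#' Write a screen count table
#'
#' Inverse of [read_count_matrix()]: tab-separated with `guide_id`,
#' `gene_id`, then sample columns.
#'
#' @param counts a [screen_counts].
#' @param library a [guide_library] (supplies the `gene_id` column).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, library, path) {
  stopifnot(inherits(counts, "screen_counts"), inherits(library, "guide_library"))
  gene <- library$gene_id[match(rownames(counts$counts), library$guide_id)]
  gene[is.na(gene)] <- "NTC"
  out <- data.frame(guide_id = rownames(counts$counts), gene_id = gene,
                    counts$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-gene expression table
#'
#' Two-column tab-separated file (`gene_id`, `expression`) of TPM-like
#' values used to decide which targeted genes are transcribed in the
#' screened cell line.
#'
#' @param path path to the TSV file.
#' @return data frame with columns `gene_id` and `expression`.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path))
    stop("expression file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("expression table needs columns gene_id and expression", call. = FALSE)
  names(tab)[1:2] <- c("gene_id", "expression")
  tab$expression <- as.numeric(tab$expression)
  if (any(!is.finite(tab$expression)) || any(tab$expression < 0))
    stop("expression values must be finite and >= 0", call. = FALSE)
  tab[, c("gene_id", "expression")]
}

#' Write a per-gene expression table
#' @param expression data frame with `gene_id`, `expression`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expression, path) {
  utils::write.table(expression[, c("gene_id", "expression")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
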