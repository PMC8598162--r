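#' Construct a guide library
#'
#' A guide library maps each sgRNA to its target gene and records which
#' guides are non-targeting controls (NTCs). Pooled knockout libraries such
#' as Brie carry four guides per protein-coding gene plus a set of NTCs
#' with no genomic target; the NTCs behave as null guides and later anchor
#' normalization and significance calibration.
#'
#' @param guide_id character vector of unique guide identifiers.
#' @param gene_id character vector of target genes; `NA`, the empty string
#'   or the literal token `"NTC"` marks a non-targeting guide.
#' @param sequence optional nucleotide sequences (A/C/G/T), same length.
#' @return An object of class `guide_library`: a data frame with columns
#'   `guide_id`, `gene_id` (`NA` for NTCs), `role`
#'   (`"targeting"`/`"non_targeting"`) and optionally `sequence`, carrying
#'   the guide order of construction.
#' @export
guide_library <- function(guide_id, gene_id, sequence = NULL) {
  guide_id <- as.character(guide_id)
  gene_id <- as.character(gene_id)
  if (length(guide_id) != length(gene_id))
    stop("guide_id and gene_id must have the same length", call. = FALSE)
  dup <- guide_id[duplicated(guide_id)]
  if (length(dup))
    stop("duplicate guide_id in library: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  gene_id[is.na(gene_id) | gene_id == "" | gene_id == "NTC"] <- NA_character_
  role <- ifelse(is.na(gene_id), "non_targeting", "targeting")
  lib <- data.frame(guide_id = guide_id, gene_id = gene_id, role = role,
                    stringsAsFactors = FALSE)
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (length(sequence) != length(guide_id))
      stop("sequence must match guide_id in length", call. = FALSE)
    bad <- grepl("[^ACGT]", sequence[!is.na(sequence)])
    if (any(bad))
      stop("guide sequences must contain only A/C/G/T", call. = FALSE)
    lib$sequence <- sequence
  }
  class(lib) <- c("guide_library", "data.frame")
  lib
}

#' Read a guide library design table
#'
#' Expects a delimited file with a header and columns `guide_id` and
#' `gene_id` (empty, `NA` or `"NTC"` for non-targeting controls), plus an
#' optional `sequence` column. Row order in the file is preserved.
#'
#' @param path path to the design file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A [guide_library].
#' @export
read_guide_library <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop("library file not found: ", path, call. = FALSE)
  sep <- if (dialect == "tsv") "\t" else ","
  nf <- utils::count.fields(path, sep = sep, quote = "\"", comment.char = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("unparseable row in %s at line %d: expected %d fields, found %d",
                 path, bad, nf[1L], nf[bad]), call. = FALSE)
  }
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", comment.char = "",
                           quote = "\"", check.names = FALSE,
                           na.strings = "NA")
  need <- c("guide_id", "gene_id")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("library file lacks required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  guide_library(tab$guide_id, tab$gene_id,
                sequence = if ("sequence" %in% names(tab)) tab$sequence)
}

#' @export
print.guide_library <- function(x, ...) {
  genes <- unique(x$gene_id[x$role == "targeting"])
  cat(sprintf("guide_library: %d guides (%d targeting across %d genes, %d non-targeting)\n",
              nrow(x), sum(x$role == "targeting"), length(genes),
              sum(x$role == "non_targeting")))
  invisible(x)
}

#' Number of non-targeting control guides in a library
#' @param library a [guide_library].
#' @return integer count of NTC guides.
#' @export
n_ntc <- function(library) {
  stopifnot(inherits(library, "guide_library"))
  sum(library$role == "non_targeting")
}

#' Targeting genes of a library
#' @param library a [guide_library].
#' @return character vector of unique targeted gene ids, in library order.
#' @export
library_genes <- function(library) {
  stopifnot(inherits(library, "guide_library"))
  unique(library$gene_id[library$role == "targeting"])
}

#' Write a guide library design table
#' @param library a [guide_library].
#' @param path output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_guide_library <- function(library, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(library, "guide_library"))
  out <- as.data.frame(library)
  out$role <- NULL
  out$gene_id[is.na(out$gene_id)] <- ""
  utils::write.table(out, path, sep = if (dialect == "tsv") "\t" else ",",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
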