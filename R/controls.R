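#' Define the negative-control guide set
#'
#' Control guides are the union of all non-targeting controls and all
#' guides targeting genes that are not transcribed in the screened cell
#' line (expression at or below `threshold`). Because knockout phenotypes
#' require a transcribed target, guides against silent genes are assumed
#' neutral; at genome scale this yields an internal negative-control set of
#' tens of thousands of guides that anchors normalization and significance
#' calibration. Genes targeted by the library but absent from the
#' expression table are treated conservatively as not transcribed (their
#' guides join the control set) and reported via a message.
#'
#' @param library a [guide_library].
#' @param expression data frame (`gene_id`, `expression`) or `NULL` to use
#'   non-targeting controls only.
#' @param threshold expression value (TPM-like) at or below which a gene
#'   counts as not transcribed; default 1.
#' @return character vector of control guide ids, in library order. The
#'   set is monotone in `threshold`: raising it never shrinks the set.
#' @export
control_guides <- function(library, expression = NULL, threshold = 1) {
  stopifnot(inherits(library, "guide_library"))
  if (!is.numeric(threshold) || threshold < 0)
    stop("threshold must be a non-negative number", call. = FALSE)
  is_ctrl <- library$role == "non_targeting"
  if (!is.null(expression)) {
    expr <- expression$expression[match(library$gene_id, expression$gene_id)]
    unknown <- library$role == "targeting" & is.na(expr)
    if (any(unknown)) {
      msg(sum(unknown), " guide(s) target genes absent from the expression ",
          "table; treated as not transcribed (control)")
      expr[unknown] <- 0
    }
    is_ctrl <- is_ctrl | (library$role == "targeting" & expr <= threshold)
  }
  out <- library$guide_id[is_ctrl]
  if (!length(out))
    stop("empty control set: no non-targeting guides and no non-expressed ",
         "genes; control-based normalization is impossible", call. = FALSE)
  out
}
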