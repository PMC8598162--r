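#' Control-set median-of-ratios size factors
#'
#' Computes one positive scale factor per sample from the control guides,
#' correcting for variable sequencing depth and composition skew.
#' Restricting the computation to control guides makes the factors
#' insensitive to true enrichment signal in targeting guides.
#'
#' The factor decomposes as (control library size) x (median-of-ratios
#' skew factor) / 1e6, i.e. effective-library-size normalization reported
#' on a per-million scale: the skew factor is the median, over control
#' guides positive in every sample, of the guide's relative abundance
#' (count over the control library size) divided by the geometric mean of
#' its relative abundances across samples. Because the reference profile
#' is built from relative abundances, it is invariant to any one sample's
#' depth, which makes the factors exactly depth-equivariant: multiplying
#' one sample's counts by `c` multiplies its factor by exactly `c` and
#' leaves its normalized counts (and every other sample's) untouched.
#'
#' @param counts a [screen_counts] of raw counts, or a numeric matrix with
#'   guide rownames.
#' @param control set of control guide ids (see [control_guides()]).
#' @return named numeric vector of size factors, one per sample.
#' @export
control_size_factors <- function(counts, control) {
  m <- if (inherits(counts, "screen_counts")) counts$counts else as.matrix(counts)
  control <- intersect(control, rownames(m))
  if (!length(control))
    stop("no control guides present in the count matrix", call. = FALSE)
  sub <- m[control, , drop = FALSE]
  pos <- rowSums(sub > 0) == ncol(sub)
  if (!any(pos))
    stop("no control guide has positive counts in all samples; ",
         "consider a pseudocount or a larger control set", call. = FALSE)
  sub <- sub[pos, , drop = FALSE]
  libsize <- colSums(sub)
  rel <- sweep(sub, 2, libsize, "/")
  ref <- exp(rowMeans(log(rel)))
  skew <- apply(rel / ref, 2, stats::median)
  factors <- libsize * skew / 1e6
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop("degenerate size factor(s); control counts too sparse", call. = FALSE)
  factors
}

#' Normalize counts by size factors
#'
#' Divides each sample's counts by its size factor (optionally adding a
#' pseudocount afterwards, for downstream steps that need positivity).
#'
#' @param counts a [screen_counts] or numeric matrix.
#' @param factors size factors from [control_size_factors()].
#' @param pseudocount non-negative value added after scaling; default 0.
#' @return object of the same shape as `counts`, real-valued; a
#'   [screen_counts] input is returned with `normalized = TRUE`.
#' @export
normalize_counts <- function(counts, factors, pseudocount = 0) {
  stopifnot(is.numeric(factors), all(factors > 0), pseudocount >= 0)
  if (inherits(counts, "screen_counts")) {
    m <- sweep(counts$counts, 2, factors[colnames(counts$counts)], "/") +
      pseudocount
    return(screen_counts(m, counts$samples, normalized = TRUE))
  }
  sweep(as.matrix(counts), 2, factors, "/") + pseudocount
}
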