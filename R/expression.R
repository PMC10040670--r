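#' FPKM from raw counts
#'
#' FPKM = count / ((length / 1000) * (library_size / 1e6)): fragments per
#' kilobase of transcript per million mapped fragments.
#'
#' @param counts Genes x tissues matrix of non-negative counts (row names =
#'   gene ids, column names = tissue ids).
#' @param lengths Named numeric vector of per-gene effective lengths (bp).
#' @param lib_sizes Named numeric vector of per-tissue mapped-fragment
#'   totals.
#' @return Matrix of FPKM values with the same dimnames.
#' @export
fpkm <- function(counts, lengths, lib_sizes) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts matrix needs gene and tissue dimnames")
  lengths <- lengths[rownames(counts)]
  lib_sizes <- lib_sizes[colnames(counts)]
  if (anyNA(lengths)) stop("missing gene length(s)")
  if (anyNA(lib_sizes)) stop("missing library size(s)")
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  sweep(sweep(counts, 1, lengths / 1000, "/"), 2, lib_sizes / 1e6, "/")
}

#' EL tissue-specificity statistic
#'
#' For one gene across tissues, EL_t = 100 * log2(FPKM_t + 1) /
#' sum_t' log2(FPKM_t' + 1): the log-scale expression in a tissue as a
#' percentage of the gene's total over all tissues. EL is comparable across
#' species where raw FPKM is not. A gene with zero FPKM everywhere gets all
#' EL = 0 and is flagged unexpressed.
#'
#' @param fpkm_row Named non-negative FPKM vector over >= 2 tissues.
#' @return Named numeric vector of EL percentages summing to 100 (or all 0),
#'   with attribute \code{unexpressed} (logical).
#' @export
expression_level <- function(fpkm_row) {
  x <- unlist(fpkm_row)
  if (length(x) < 2) stop("need at least 2 tissues")
  if (any(x < 0)) stop("negative FPKM")
  lg <- log2(x + 1)
  tot <- sum(lg)
  if (tot == 0) {
    el <- setNames(rep(0, length(x)), names(x))
    attr(el, "unexpressed") <- TRUE
    return(el)
  }
  el <- 100 * lg / tot
  attr(el, "unexpressed") <- FALSE
  el
}

#' EL matrix for all genes
#'
#' @param fpkm_mat Genes x tissues FPKM matrix.
#' @return List with \code{el} (matrix of EL percentages) and
#'   \code{unexpressed} (named logical vector).
#' @export
el_matrix <- function(fpkm_mat) {
  fpkm_mat <- as.matrix(fpkm_mat)
  rows <- lapply(seq_len(nrow(fpkm_mat)), function(i)
    expression_level(fpkm_mat[i, ]))
  el <- do.call(rbind, lapply(rows, as.numeric))
  dimnames(el) <- dimnames(fpkm_mat)
  list(el = el,
       unexpressed = setNames(vapply(rows, attr, logical(1), "unexpressed"),
                              rownames(fpkm_mat)))
}

#' Tissue-specificity call for one gene
#'
#' A gene is called focal-dominant (leaf-dominant by default) when the focal
#' tissue's EL is strictly maximal, reaches \code{el_min}, and the focal
#' FPKM reaches \code{fpkm_min}; otherwise broad, or unexpressed when no
#' tissue has any signal.
#'
#' @param el_row Named EL vector (from \code{\link{expression_level}}).
#' @param fpkm_row Matching named FPKM vector.
#' @param focal_tissue Tissue whose dominance is being tested.
#' @param el_min Minimum EL percentage in the focal tissue.
#' @param fpkm_min Minimum FPKM in the focal tissue.
#' @return One of "focal-dominant", "broad", "unexpressed".
#' @export
tissue_specificity_call <- function(el_row, fpkm_row, focal_tissue = "leaf",
                                    el_min = 40, fpkm_min = 1) {
  if (!focal_tissue %in% names(el_row))
    stop("focal tissue '", focal_tissue, "' not present")
  if (all(unlist(fpkm_row) == 0)) return("unexpressed")
  el <- unlist(el_row)
  focal <- el[[focal_tissue]]
  others <- el[setdiff(names(el), focal_tissue)]
  if (focal > max(others) && focal >= el_min &&
      fpkm_row[[focal_tissue]] >= fpkm_min) "focal-dominant" else "broad"
}

#' Leaf-dominance calls for all genes
#'
#' @param fpkm_mat Genes x tissues FPKM matrix.
#' @param focal_tissue,el_min,fpkm_min See
#'   \code{\link{tissue_specificity_call}}.
#' @return Named character vector of calls.
#' @export
leaf_calls <- function(fpkm_mat, focal_tissue = "leaf", el_min = 40,
                       fpkm_min = 1) {
  em <- el_matrix(fpkm_mat)
  setNames(vapply(seq_len(nrow(em$el)), function(i)
    tissue_specificity_call(em$el[i, ], as.matrix(fpkm_mat)[i, ],
                            focal_tissue, el_min, fpkm_min),
    character(1)), rownames(em$el))
}
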