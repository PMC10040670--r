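#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via \code{ape::nj}) with two
#' conventions for determinism and validity: taxa are ordered
#' lexicographically before agglomeration, and negative branch lengths
#' produced by the three-point formulas are clamped to zero.
#'
#' @param d Symmetric numeric distance matrix (or \code{dist}) with at least
#'   three taxa and no missing entries.
#' @return An unrooted \code{phylo} tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("'d' must be a square distance matrix")
  if (nrow(d) < 3) stop("neighbour joining needs at least 3 taxa")
  if (anyNA(d)) stop("distance matrix contains inestimable (NA) entries; ",
                     "impute or drop taxa first")
  ids <- rownames(d)
  if (is.null(ids)) stop("distance matrix must have row names")
  ord <- order(ids)
  tr <- ape::nj(d[ord, ord])
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Neighbour-joining tree with bootstrap support from an alignment
#'
#' Builds the point-estimate NJ tree from JTT ML distances (pairwise
#' deletion), then resamples alignment columns with replacement
#' \code{replicates} times, rebuilding the tree each time. The support of each
#' internal edge of the point tree is the percentage of successful replicate
#' trees containing the same bipartition. Replicates whose distance matrix is
#' unusable (all-gap overlap after resampling) are skipped, counted, and
#' reported with a warning.
#'
#' @param aln Alignment (see \code{\link{as_alignment}}), >= 3 sequences.
#' @param replicates Number of bootstrap replicates (>= 1; the study design
#'   uses 1000).
#' @param seed Integer seed making the resampling reproducible.
#' @param saturated_cap Cap for saturated distances (see
#'   \code{\link{jtt_distance_matrix}}).
#' @return The point-estimate \code{phylo} tree with \code{node.label} set to
#'   integer support percentages (root label empty), plus attributes
#'   \code{n_replicates_used} and \code{n_replicates_failed}.
#' @export
bootstrap_support <- function(aln, replicates = 1000, seed = 1,
                              saturated_cap = 5) {
  stopifnot(replicates >= 1)
  seqs <- as_alignment(aln)
  if (length(seqs) < 3) stop("need at least 3 sequences")
  L <- length(seqs[[1]])
  point <- nj_tree(suppressWarnings(
    jtt_distance_matrix(seqs, saturated_cap = saturated_cap)))

  mat <- do.call(rbind, seqs)   # taxa x columns
  set.seed(seed)
  boots <- vector("list", replicates)
  failed <- 0L
  for (r in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    res <- tryCatch(
      nj_tree(suppressWarnings(
        jtt_distance_matrix(mat[, cols, drop = FALSE],
                            saturated_cap = saturated_cap))),
      error = function(e) NULL)
    if (is.null(res)) failed <- failed + 1L else boots[[r]] <- res
  }
  boots <- boots[!vapply(boots, is.null, logical(1))]
  if (failed > 0)
    warning(failed, " bootstrap replicate(s) failed and were skipped")
  if (length(boots) == 0) stop("all bootstrap replicates failed")
  counts <- ape::prop.clades(point, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / length(boots))
  point$node.label <- as.character(support)
  point$node.label[1] <- ""       # root of the unrooted representation
  attr(point, "n_replicates_used") <- length(boots)
  attr(point, "n_replicates_failed") <- failed
  point
}

#' Cut a support-labelled tree into orthogroups
#'
#' Finds maximal clades whose bootstrap support meets \code{min_support} and
#' in which every species contributes at most its allowed copy number
#' (default one; polyploids such as hexaploid wheat may allow more). Each leaf
#' belongs to at most one group; leaves in no qualifying clade are reported as
#' ungrouped. The full leaf set counts as a trivially certain clade (support
#' 100), so a family that already satisfies the copy limits forms a single
#' orthogroup.
#'
#' @param tree A \code{phylo} tree whose \code{node.label} holds support
#'   percentages (empty or missing labels are treated as unsupported, except
#'   the root).
#' @param species_of Named character vector mapping every leaf to its species.
#' @param min_support Minimum support percentage for a clade to qualify.
#' @param max_copies Either a single integer or a named vector of per-species
#'   copy limits; species not named fall back to \code{default_copies}.
#' @param default_copies Copy limit for species absent from a named
#'   \code{max_copies}.
#' @return A list with \code{groups} (list of leaf-id vectors, named
#'   OG1, OG2, ... in tree traversal order) and \code{ungrouped} (character
#'   vector).
#' @export
cut_orthogroups <- function(tree, species_of, min_support = 50,
                            max_copies = 1, default_copies = 1) {
  tips <- tree$tip.label
  if (!all(tips %in% names(species_of)))
    stop("species_of is missing labels for: ",
         paste(setdiff(tips, names(species_of)), collapse = ", "))
  ntip <- length(tips)
  support <- rep(NA_real_, tree$Nnode)
  if (!is.null(tree$node.label)) {
    s <- suppressWarnings(as.numeric(tree$node.label))
    support[seq_along(s)] <- s
  }

  kids <- split(tree$edge[, 2], tree$edge[, 1])
  tipset <- function(node) {
    if (node <= ntip) return(tips[node])
    unlist(lapply(kids[[as.character(node)]], tipset), use.names = FALSE)
  }
  limit_of <- function(sp) {
    if (length(max_copies) == 1 && is.null(names(max_copies)))
      return(as.integer(max_copies))
    if (sp %in% names(max_copies)) as.integer(max_copies[[sp]])
    else as.integer(default_copies)
  }
  within_limits <- function(members) {
    counts <- table(species_of[members])
    all(vapply(names(counts), function(sp) counts[[sp]] <= limit_of(sp),
               logical(1)))
  }

  ## candidate groups: both sides of every supported internal bipartition
  ## (the tree is unrooted, so a planted group can sit on either side of
  ## ape's arbitrary root), plus the trivially certain full leaf set
  candidates <- list(list(members = sort(tips), support = 100))
  internal <- setdiff(unique(tree$edge[, 2]), seq_len(ntip))
  for (node in internal) {
    s <- support[node - ntip]
    if (is.na(s) || s < min_support) next
    side <- sort(tipset(node))
    for (members in list(side, sort(setdiff(tips, side)))) {
      if (length(members) < 2 || length(members) == ntip) next
      candidates[[length(candidates) + 1L]] <-
        list(members = members, support = s)
    }
  }
  keep <- vapply(candidates, function(cnd) within_limits(cnd$members),
                 logical(1))
  candidates <- candidates[keep]
  ## maximal first; deterministic tie-break by first member id
  ord <- order(-vapply(candidates, function(cnd) length(cnd$members), 0L),
               vapply(candidates, function(cnd) cnd$members[1], ""))
  groups <- list()
  taken <- character(0)
  for (cnd in candidates[ord]) {
    if (length(intersect(cnd$members, taken))) next
    groups[[length(groups) + 1L]] <- cnd$members
    taken <- c(taken, cnd$members)
  }
  names(groups) <- if (length(groups)) paste0("OG", seq_along(groups)) else character(0)
  list(groups = groups, ungrouped = sort(setdiff(tips, taken)))
}
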