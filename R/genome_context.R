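#' Detect tandem-duplicated family members from gene coordinates
#'
#' Two same-family genes are tandem-linked when they sit on the same
#' chromosome with at most \code{max_intervening} non-family genes between
#' them (by genome-wide gene rank); tandem arrays are the connected
#' components of this relation, singletons excluded. This is a deterministic
#' rank-gap simplification of collinearity-based duplication calling; a
#' manual override list of extra array memberships is supported.
#'
#' @param loci Data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{rank} (genome-wide gene rank on the chromosome), and optionally
#'   \code{family} (a single family is assumed when absent).
#' @param max_intervening Maximum number of non-family genes between linked
#'   neighbours.
#' @param override Optional list of character vectors, each an array to add
#'   verbatim (merged with detected arrays sharing members).
#' @return List of character vectors (arrays of >= 2 gene ids), each sorted;
#'   arrays ordered by chromosome then rank of first member.
#' @export
detect_tandem <- function(loci, max_intervening = 5, override = NULL) {
  stopifnot(all(c("gene_id", "chrom", "rank") %in% names(loci)))
  if (anyDuplicated(loci$gene_id))
    stop("duplicate gene ids: ",
         paste(unique(loci$gene_id[duplicated(loci$gene_id)]), collapse = ", "))
  n <- nrow(loci)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  link <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  fam <- if ("family" %in% names(loci)) as.character(loci$family)
         else rep("family", n)
  for (f in unique(fam)) {
    for (chr in unique(loci$chrom[fam == f])) {
      idx <- which(loci$chrom == chr & fam == f)
      idx <- idx[order(loci$rank[idx])]
      if (length(idx) < 2) next
      for (k in seq_len(length(idx) - 1)) {
        i <- idx[k]; j <- idx[k + 1]
        ## genes at intervening ranks: same-family ones between consecutive
        ## members do not exist, so all rank-gap genes are non-family
        gap <- loci$rank[j] - loci$rank[i] - 1
        if (gap <= max_intervening) link(i, j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(loci$gene_id, roots)
  arrays <- Filter(function(x) length(x) >= 2, comps)
  if (!is.null(override)) {
    for (ov in override) arrays <- c(arrays, list(ov))
    arrays <- .merge_overlapping(arrays)
  }
  arrays <- lapply(arrays, function(a) sort(unique(a)))
  ord <- order(vapply(arrays, function(a) {
    i <- match(a[1], loci$gene_id)
    if (is.na(i)) Inf else loci$rank[i] + 1e9 * match(loci$chrom[i],
                                                     unique(loci$chrom))
  }, numeric(1)))
  unname(arrays[ord])
}

.merge_overlapping <- function(sets) {
  changed <- TRUE
  while (changed && length(sets) > 1) {
    changed <- FALSE
    for (i in seq_len(length(sets) - 1)) {
      for (j in (i + 1):length(sets)) {
        if (length(intersect(sets[[i]], sets[[j]]))) {
          sets[[i]] <- union(sets[[i]], sets[[j]])
          sets[[j]] <- NULL
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
  }
  sets
}

#' Tandem-duplication summary for a family
#'
#' @param family_members Character vector of all family gene ids.
#' @param arrays Tandem arrays from \code{\link{detect_tandem}} (members
#'   outside \code{family_members} are ignored).
#' @return List with \code{n_total}, \code{n_tandem}, and \code{percent}
#'   (100 * n_tandem / n_total, rounded to 2 decimals).
#' @export
tandem_summary <- function(family_members, arrays) {
  if (length(family_members) == 0) stop("empty family")
  tandem <- intersect(unique(unlist(arrays)), family_members)
  n_total <- length(unique(family_members))
  n_tandem <- length(tandem)
  list(n_total = n_total, n_tandem = n_tandem,
       percent = round(100 * n_tandem / n_total, 2))
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.revcomp <- function(s) {
  paste(rev(COMPLEMENT[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

#' Extract the promoter (upstream) region of a gene
#'
#' The promoter is the \code{length} bp immediately upstream of the
#' initiation codon: for a + strand gene at [start, end], bases
#' [start - length, start - 1]; for a - strand gene, bases
#' [end + 1, end + length] reverse-complemented. Regions running off the
#' chromosome start/end are truncated and flagged.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param locus A list/row with \code{chrom}, \code{start}, \code{end},
#'   \code{strand} (1-based inclusive coordinates).
#' @param length Promoter length in bp (default 2000).
#' @return The promoter string, 5' to 3', ending immediately before the
#'   initiation codon, with attribute \code{truncated} (logical).
#' @export
extract_promoter <- function(genome, locus, length = 2000) {
  chrom <- as.character(locus$chrom)
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  chrom_seq <- genome[[chrom]]
  L <- nchar(chrom_seq)
  start <- as.integer(locus$start); end <- as.integer(locus$end)
  if (start < 1 || end > L || start > end)
    stop("locus out of chromosome bounds: ", chrom, ":", start, "-", end)
  truncated <- FALSE
  if (identical(as.character(locus$strand), "-")) {
    from <- end + 1
    to <- min(end + length, L)
    if (to < end + length) truncated <- TRUE
    promoter <- if (from > to) "" else .revcomp(substr(chrom_seq, from, to))
  } else {
    from <- max(start - length, 1)
    to <- start - 1
    if (from > start - length) truncated <- TRUE
    promoter <- if (from > to) "" else substr(chrom_seq, from, to)
  }
  attr(promoter, "truncated") <- truncated
  promoter
}

IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

.iupac_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_DNA))
  if (length(bad))
    stop("invalid IUPAC code(s) in pattern: ", paste(bad, collapse = ", "))
  paste(vapply(chars, function(ch) {
    set <- IUPAC_DNA[[ch]]
    if (length(set) == 1) set else paste0("[", paste(set, collapse = ""), "]")
  }, ""), collapse = "")
}

#' Built-in promoter element definitions
#'
#' CAAT-box (consensus C(C/A)AAT, i.e. CMAAT) plus conventional consensi for
#' TATA-box, ABRE (ACGTG core), the MeJA-responsive CGTCA-motif, the
#' meristem CAT-box (GCCACT), and the MYB-binding MBS (CAACTG). All
#' user-overridable.
#'
#' @return Data.frame with columns \code{element}, \code{pattern},
#'   \code{strand_policy}.
#' @export
builtin_elements <- function() {
  data.frame(
    element = c("CAAT-box", "TATA-box", "ABRE", "CGTCA-motif", "CAT-box",
                "MBS"),
    pattern = c("CMAAT", "TATAWA", "ACGTG", "CGTCA", "GCCACT", "CAACTG"),
    strand_policy = "both",
    stringsAsFactors = FALSE)
}

#' Scan a promoter for cis-element matches
#'
#' All (possibly overlapping) matches of each IUPAC pattern, on the given
#' strand or both. Ambiguity codes in the pattern match their residue sets;
#' an N in the promoter never matches. Offsets are relative to the
#' initiation codon: -1 is the base immediately upstream of the ATG, and a
#' hit's offset is that of its 5'-most promoter base. Hits are binned into
#' the proximal (-1..-1000) and distal (-1001..-2000) windows.
#'
#' @param promoter Promoter string from \code{\link{extract_promoter}} (or
#'   any upstream sequence over ACGTN, 5' to 3', ending just before ATG).
#' @param defs Element definitions (see \code{\link{builtin_elements}}).
#' @param gene_id Optional gene id recorded in the output.
#' @return Data.frame with columns \code{gene_id}, \code{element},
#'   \code{offset}, \code{strand}, \code{match}, \code{bin}.
#' @export
scan_elements <- function(promoter, defs = builtin_elements(),
                          gene_id = NA_character_) {
  seq <- toupper(as.character(promoter))
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), c("A", "C", "G", "T", "N"))
  if (length(bad)) stop("promoter contains non-ACGTN character(s): ",
                        paste(bad, collapse = ", "))
  L <- nchar(seq)
  empty <- data.frame(gene_id = character(0), element = character(0),
                      offset = integer(0), strand = character(0),
                      match = character(0), bin = character(0))
  if (nrow(defs) == 0 || L == 0) return(empty)
  out <- list()
  for (i in seq_len(nrow(defs))) {
    rx <- .iupac_regex(defs$pattern[i])
    w <- nchar(defs$pattern[i])
    strands <- if (identical(defs$strand_policy[i], "both")) c("+", "-") else "+"
    for (strand in strands) {
      subject <- if (strand == "+") seq else .revcomp(seq)
      m <- gregexpr(paste0("(?=(", rx, "))"), subject, perl = TRUE)[[1]]
      if (m[1] == -1) next
      starts <- as.integer(m)                 # position in scanned strand
      if (strand == "-") starts <- L - (starts + w - 1) + 1  # 5'-most on promoter
      offs <- starts - L - 1L
      matches <- substr(rep(seq, length(starts)), starts, starts + w - 1)
      out[[length(out) + 1L]] <- data.frame(
        gene_id = gene_id, element = defs$element[i], offset = offs,
        strand = strand,
        match = if (strand == "+") matches
                else vapply(matches, .revcomp, ""),
        bin = ifelse(offs >= -1000, "(-1..-1000)", "(-1001..-2000)"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$element, res$offset, res$strand), , drop = FALSE]
}

#' Compare mean element counts between two gene groups by promoter bin
#'
#' Deterministic descriptive summary (no hypothesis test): for each element
#' and upstream bin, the mean per-gene hit count in each group.
#'
#' @param hits_a,hits_b Hit tables from \code{\link{scan_elements}} (rows
#'   from several genes concatenated, \code{gene_id} filled in).
#' @param genes_a,genes_b Gene id vectors defining each group (denominators;
#'   genes with zero hits count as zeros).
#' @return Data.frame with columns \code{element}, \code{bin},
#'   \code{mean_a}, \code{mean_b}.
#' @export
compare_element_counts <- function(hits_a, hits_b, genes_a, genes_b) {
  if (length(genes_a) == 0 || length(genes_b) == 0)
    stop("both groups must be non-empty")
  elements <- sort(unique(c(hits_a$element, hits_b$element)))
  bins <- c("(-1..-1000)", "(-1001..-2000)")
  if (length(elements) == 0)
    return(data.frame(element = character(0), bin = character(0),
                      mean_a = numeric(0), mean_b = numeric(0)))
  grid <- expand.grid(element = elements, bin = bins,
                      stringsAsFactors = FALSE)
  count_mean <- function(hits, genes, el, b) {
    sub <- hits[hits$element == el & hits$bin == b & hits$gene_id %in% genes, ,
                drop = FALSE]
    nrow(sub) / length(genes)
  }
  grid$mean_a <- mapply(count_mean, el = grid$element, b = grid$bin,
                        MoreArgs = list(hits = hits_a, genes = genes_a))
  grid$mean_b <- mapply(count_mean, el = grid$element, b = grid$bin,
                        MoreArgs = list(hits = hits_b, genes = genes_b))
  grid[order(grid$element, grid$bin), , drop = FALSE]
}
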