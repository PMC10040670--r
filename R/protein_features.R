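## Average residue masses (Da) used by the ExPASy Compute pI/MW tool, and
## the Bjellqvist pK set behind the same tool's pI.
AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01524

PK_SIDE_NEG <- c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
PK_SIDE_POS <- c(H = 5.98, K = 10.0, R = 12.0)
PK_NTERM <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
              E = 7.7)
PK_NTERM_DEFAULT <- 7.5
PK_CTERM <- c(D = 4.55, E = 4.75)
PK_CTERM_DEFAULT <- 3.55

.check_protein <- function(seq) {
  s <- .as_residue_vector(seq)
  if (length(s) == 0) stop("empty protein sequence")
  bad <- setdiff(unique(s), names(AA_AVG_MASS))
  if (length(bad))
    stop("unknown residue(s): ", paste(bad, collapse = ", "))
  s
}

#' Molecular weight of a protein (average masses)
#'
#' Sum of average residue masses plus one water mass, matching the ExPASy
#' Compute pI/MW convention.
#'
#' @param seq Protein sequence over the 20 standard residues.
#' @return Molecular weight in daltons.
#' @export
molecular_weight <- function(seq) {
  s <- .check_protein(seq)
  sum(AA_AVG_MASS[s]) + WATER_MASS
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch charge with the Bjellqvist pK set: free termini
#' (N-terminal pK depending on the first residue, C-terminal on the last)
#' plus D, E, C, Y (negative) and H, K, R (positive) side chains.
#'
#' @param seq Protein sequence.
#' @param pH pH value(s).
#' @return Net charge (vectorised over \code{pH}).
#' @export
protein_charge <- function(seq, pH) {
  s <- .check_protein(seq)
  counts <- table(factor(s, levels = names(AA_AVG_MASS)))
  pk_n <- if (s[1] %in% names(PK_NTERM)) PK_NTERM[[s[1]]] else PK_NTERM_DEFAULT
  last <- s[length(s)]
  pk_c <- if (last %in% names(PK_CTERM)) PK_CTERM[[last]] else PK_CTERM_DEFAULT
  vapply(pH, function(p) {
    pos <- 1 / (1 + 10^(p - pk_n)) +
      sum(vapply(names(PK_SIDE_POS), function(r)
        counts[[r]] / (1 + 10^(p - PK_SIDE_POS[[r]])), numeric(1)))
    neg <- 1 / (1 + 10^(pk_c - p)) +
      sum(vapply(names(PK_SIDE_NEG), function(r)
        counts[[r]] / (1 + 10^(PK_SIDE_NEG[[r]] - p)), numeric(1)))
    pos - neg
  }, numeric(1))
}

#' Isoelectric point of a protein
#'
#' The pH at which \code{\link{protein_charge}} is zero, found by bisection
#' on [0, 14] to a charge tolerance of 1e-4.
#'
#' @param seq Protein sequence.
#' @param tol Charge tolerance at the returned pH.
#' @param max_iter Maximum bisection iterations.
#' @return The pI in pH units.
#' @export
isoelectric_point <- function(seq, tol = 1e-4, max_iter = 200) {
  .check_protein(seq)
  lo <- 0; hi <- 14
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    q <- protein_charge(seq, mid)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' MDH coenzyme specificity from the residue at the OsMDH1-43 site
#'
#' The residue homologous to position 43 of OsMDH1 determines coenzyme use:
#' aspartate (D) for NAD-dependent and glycine (G) for NADP-dependent
#' malate dehydrogenases.
#'
#' @param seq Protein sequence.
#' @param mapped_position Query position homologous to OsMDH1 residue 43
#'   (\code{NA} if unalignable).
#' @return One of "NAD", "NADP", "other", or "unknown" when unalignable.
#' @export
mdh_coenzyme_type <- function(seq, mapped_position) {
  s <- .check_protein(seq)
  if (is.na(mapped_position) || mapped_position < 1 ||
      mapped_position > length(s))
    return("unknown")
  switch(s[mapped_position], D = "NAD", G = "NADP", "other")
}

#' Chloroplast transit peptide evidence for a gene
#'
#' Transit-peptide calls come first-class from an external predictor's
#' annotation table (gene_id, has_ctp, ctp_len). When a gene is absent from
#' the table and \code{heuristic} is on, a naive N-terminal composition
#' screen is applied to \code{seq}: the first 60 residues of cTPs are
#' serine/threonine-rich and poor in acidic residues. Heuristic calls are
#' flagged as low confidence.
#'
#' @param gene_id Gene identifier.
#' @param annotation Data.frame with columns \code{gene_id}, \code{has_ctp}
#'   ("yes"/"no"), \code{ctp_len}.
#' @param seq Protein sequence (needed only for the heuristic).
#' @param heuristic Apply the N-terminal heuristic when unannotated?
#' @param window,st_min,de_max Heuristic parameters: leading window length,
#'   minimum S+T fraction, maximum D+E fraction.
#' @return A list with \code{has_ctp} ("yes"/"no"/"unknown"),
#'   \code{ctp_len} (aa or NA), \code{confidence} ("annotated"/"heuristic"/
#'   "none").
#' @export
ctp_evidence <- function(gene_id, annotation, seq = NULL, heuristic = FALSE,
                         window = 60, st_min = 0.2, de_max = 0.06) {
  i <- match(gene_id, annotation$gene_id)
  if (!is.na(i)) {
    return(list(has_ctp = as.character(annotation$has_ctp[i]),
                ctp_len = if (identical(as.character(annotation$has_ctp[i]), "yes"))
                  as.integer(annotation$ctp_len[i]) else NA_integer_,
                confidence = "annotated"))
  }
  if (!heuristic || is.null(seq))
    return(list(has_ctp = "unknown", ctp_len = NA_integer_,
                confidence = "none"))
  s <- .check_protein(seq)
  lead <- s[seq_len(min(window, length(s)))]
  st <- mean(lead %in% c("S", "T"))
  de <- mean(lead %in% c("D", "E"))
  yes <- st >= st_min && de <= de_max
  list(has_ctp = if (yes) "yes" else "no", ctp_len = NA_integer_,
       confidence = "heuristic")
}

#' Physicochemical profile table for a set of proteins
#'
#' @param proteins Named character vector of protein sequences.
#' @param ctp_annotation Optional cTP annotation table (see
#'   \code{\link{ctp_evidence}}).
#' @param mdh_positions Optional named integer vector: for MDH proteins, the
#'   query position homologous to OsMDH1 residue 43.
#' @return A data.frame with gene_id, length_aa, molecular_weight, pI,
#'   has_ctp, ctp_len, coenzyme.
#' @export
protein_profiles <- function(proteins, ctp_annotation = NULL,
                             mdh_positions = NULL) {
  empty_ann <- data.frame(gene_id = character(0), has_ctp = character(0),
                          ctp_len = integer(0))
  if (is.null(ctp_annotation)) ctp_annotation <- empty_ann
  rows <- lapply(names(proteins), function(g) {
    seq <- proteins[[g]]
    ev <- ctp_evidence(g, ctp_annotation)
    co <- if (!is.null(mdh_positions) && g %in% names(mdh_positions))
      mdh_coenzyme_type(seq, mdh_positions[[g]]) else "n/a"
    data.frame(gene_id = g, length_aa = nchar(seq),
               molecular_weight = molecular_weight(seq),
               pI = isoelectric_point(seq),
               has_ctp = ev$has_ctp, ctp_len = ev$ctp_len, coenzyme = co,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
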