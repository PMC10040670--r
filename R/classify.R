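C4_FAMILIES <- c("beta-CA", "RbcS", "PEPC", "NADP-ME", "MDH", "PPDK")

#' Required evidence criteria for a family's C4-type call
#'
#' Encodes the per-family decision logic: beta-CA copies must belong to the
#' CA3 orthogroup and be leaf-dominant; RbcS copies are called on expression
#' alone (leaf-dominant and carrying the species' maximal leaf FPKM); PEPC
#' needs PEPC4 orthogroup membership, the C-terminal serine site in its C4
#' state, and leaf dominance; NADP-ME needs ME4 membership, chloroplast
#' localization, and leaf dominance; MDH needs MDH3 membership, NADP
#' coenzyme specificity, chloroplast localization, and leaf dominance; PPDK
#' needs its chloroplast (exon-1-containing) transcript and leaf dominance.
#'
#' @param family One of "beta-CA", "RbcS", "PEPC", "NADP-ME", "MDH", "PPDK".
#' @return Character vector of criterion names (see
#'   \code{\link{classify_c4}}).
#' @export
family_rules <- function(family) {
  rules <- list(
    "beta-CA" = c("c4_orthogroup", "leaf_dominant"),
    "RbcS"    = c("leaf_dominant", "max_leaf_fpkm"),
    "PEPC"    = c("c4_orthogroup", "diag_site_c4", "leaf_dominant"),
    "NADP-ME" = c("c4_orthogroup", "chloroplast", "leaf_dominant"),
    "MDH"     = c("c4_orthogroup", "nadp_coenzyme", "chloroplast",
                  "leaf_dominant"),
    "PPDK"    = c("chloroplast", "leaf_dominant"))
  if (!family %in% names(rules))
    stop("unknown family: ", family)
  rules[[family]]
}

#' Assemble an evidence bundle for one gene
#'
#' @param gene_id,family Identification.
#' @param c4_orthogroup Is the gene in the family's C4 orthogroup (the one
#'   containing the known C4 anchor)? logical or NA.
#' @param leaf_call "focal-dominant"/"broad"/"unexpressed" or NA.
#' @param localization One of "chloroplast", "cytoplasm", "mitochondrion",
#'   "peroxisome", "unknown".
#' @param diag_site Diagnostic-site result: "C4-state", "C3-state", "other",
#'   "unalignable", or NA.
#' @param coenzyme "NAD"/"NADP"/"other"/"unknown"/"n/a".
#' @param max_leaf_fpkm Does this gene carry the maximal leaf FPKM of its
#'   family within its species? logical or NA.
#' @param tandem Is the gene in a tandem array? logical or NA.
#' @param orthogroup Orthogroup id (bookkeeping only).
#' @return A list of class \code{evidence_bundle}.
#' @export
evidence_bundle <- function(gene_id, family, c4_orthogroup = NA,
                            leaf_call = NA_character_,
                            localization = "unknown",
                            diag_site = NA_character_,
                            coenzyme = "n/a", max_leaf_fpkm = NA,
                            tandem = NA, orthogroup = NA_character_) {
  if (!family %in% C4_FAMILIES) stop("unknown family: ", family)
  structure(list(gene_id = gene_id, family = family,
                 c4_orthogroup = c4_orthogroup, leaf_call = leaf_call,
                 localization = localization, diag_site = diag_site,
                 coenzyme = coenzyme, max_leaf_fpkm = max_leaf_fpkm,
                 tandem = tandem, orthogroup = orthogroup),
            class = "evidence_bundle")
}

.criterion_value <- function(bundle, criterion) {
  tri <- function(x) if (is.na(x)) NA else isTRUE(x)
  switch(criterion,
    c4_orthogroup = tri(bundle$c4_orthogroup),
    leaf_dominant = if (is.na(bundle$leaf_call)) NA
                    else bundle$leaf_call == "focal-dominant",
    max_leaf_fpkm = tri(bundle$max_leaf_fpkm),
    diag_site_c4 = if (is.na(bundle$diag_site) ||
                       bundle$diag_site == "unalignable") NA
                   else bundle$diag_site == "C4-state",
    chloroplast = if (is.na(bundle$localization) ||
                      bundle$localization == "unknown") NA
                  else bundle$localization == "chloroplast",
    nadp_coenzyme = if (bundle$coenzyme %in% c("unknown", "n/a")) NA
                    else bundle$coenzyme == "NADP",
    stop("unknown criterion: ", criterion))
}

#' Classify one gene copy as C4-type or non-photosynthetic
#'
#' Evaluates the family's required criteria on the evidence bundle: all true
#' gives "C4-type"; any false gives "non-photosynthetic" (with the failed
#' criteria as reasons); otherwise — some evidence unknown and none failing —
#' "indeterminate". Classification is a pure function of the bundle.
#'
#' @param bundle An \code{\link{evidence_bundle}}.
#' @return A list of class \code{c4_call} with \code{gene_id},
#'   \code{family}, \code{label}, \code{satisfied}, \code{failed},
#'   \code{missing}.
#' @export
classify_c4 <- function(bundle) {
  stopifnot(inherits(bundle, "evidence_bundle"))
  criteria <- family_rules(bundle$family)
  vals <- setNames(lapply(criteria, .criterion_value, bundle = bundle),
                   criteria)
  failed <- names(vals)[vapply(vals, function(v) !is.na(v) && !v, logical(1))]
  satisfied <- names(vals)[vapply(vals, isTRUE, logical(1))]
  missing <- names(vals)[vapply(vals, is.na, logical(1))]
  label <- if (length(failed)) "non-photosynthetic"
           else if (length(missing)) "indeterminate"
           else "C4-type"
  structure(list(gene_id = bundle$gene_id, family = bundle$family,
                 label = label, satisfied = satisfied, failed = failed,
                 missing = missing),
            class = "c4_call")
}

#' @export
print.c4_call <- function(x, ...) {
  cat(x$gene_id, " (", x$family, "): ", x$label, "\n", sep = "")
  if (length(x$satisfied)) cat("  satisfied:", paste(x$satisfied, collapse = ", "), "\n")
  if (length(x$failed)) cat("  failed:", paste(x$failed, collapse = ", "), "\n")
  if (length(x$missing)) cat("  unknown:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

#' Split a dual-promoter PPDK gene model into its two isoforms
#'
#' PPDK is transcribed from a promoter upstream of exon 1 (yielding the
#' chloroplast isoform, whose first exon encodes the transit peptide) and a
#' second promoter in intron 1 (yielding the cytosolic isoform, which lacks
#' exon 1). Each transcript gets its own localization and leaf call, and the
#' family rules are then applied per isoform.
#'
#' @param gene_model A list with \code{gene_id} and \code{exons} (data.frame
#'   with \code{start}, \code{end}; >= 2 exons) and \code{transcripts}, a
#'   named list of integer vectors of exon indices.
#' @param leaf_calls Named character vector of per-transcript leaf calls
#'   ("focal-dominant"/"broad"/"unexpressed").
#' @return Data.frame with one row per transcript: \code{transcript},
#'   \code{isoform} ("chloroplast"/"cytoplasm"), \code{leaf_call},
#'   \code{label} from \code{\link{classify_c4}} under the PPDK rules.
#'   A missing exon-1 transcript yields only the cytosolic record, with a
#'   warning.
#' @export
ppdk_isoforms <- function(gene_model, leaf_calls) {
  if (nrow(gene_model$exons) < 2)
    stop("dual-promoter model needs >= 2 exons; single-exon model given")
  txs <- gene_model$transcripts
  if (length(txs) == 0) stop("no transcripts in gene model")
  has_exon1 <- vapply(txs, function(ex) 1L %in% ex, logical(1))
  if (!any(has_exon1))
    warning("no exon-1-containing transcript: only the cytosolic isoform ",
            "is emitted for ", gene_model$gene_id)
  rows <- lapply(names(txs), function(tx) {
    chloro <- has_exon1[[tx]]
    lc <- if (tx %in% names(leaf_calls)) leaf_calls[[tx]] else NA_character_
    b <- evidence_bundle(paste0(gene_model$gene_id, ".", tx), "PPDK",
                         leaf_call = lc,
                         localization = if (chloro) "chloroplast" else "cytoplasm")
    call <- classify_c4(b)
    data.frame(transcript = tx,
               isoform = if (chloro) "chloroplast" else "cytoplasm",
               leaf_call = lc, label = call$label, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify a set of evidence bundles and write the calls table
#'
#' @param bundles List of \code{\link{evidence_bundle}} objects.
#' @param path Optional TSV output path; a JSON evidence dump is written
#'   alongside (same path with extension .json) when given.
#' @return Data.frame of calls (gene_id, family, label, satisfied, failed,
#'   missing as ;-separated strings).
#' @export
classify_all <- function(bundles, path = NULL) {
  calls <- lapply(bundles, classify_c4)
  out <- do.call(rbind, lapply(calls, function(cl)
    data.frame(gene_id = cl$gene_id, family = cl$family, label = cl$label,
               satisfied = paste(cl$satisfied, collapse = ";"),
               failed = paste(cl$failed, collapse = ";"),
               missing = paste(cl$missing, collapse = ";"),
               stringsAsFactors = FALSE)))
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(bundles,
                         sub("\\.tsv$", ".json", path),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }
  out
}
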