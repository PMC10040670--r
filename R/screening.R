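#' Family specifications for the six C4-pathway enzymes
#'
#' Returns the membership thresholds and required conserved domains used to
#' screen homology-search results: best BLAST hit E-value strictly below
#' \code{evalue_max} (default 1e-5), best-hit identity at least
#' \code{identity_min} percent (default 60), and presence of every required
#' Pfam domain. The domain sets per family are: beta-CA PF00484; RbcS
#' PF12338 + PF00101; PEPC PF00311; NADP-ME PF03949 + PF00390; MDH PF02866;
#' PPDK PF02896 + PF01326 + PF00391. CDD superfamily accessions are carried
#' as metadata.
#'
#' @param family One of "beta-CA", "RbcS", "PEPC", "NADP-ME", "MDH", "PPDK";
#'   \code{NULL} returns the full registry.
#' @param evalue_max,identity_min Threshold overrides.
#' @return A list (or list of lists) with fields \code{family_name},
#'   \code{required_domains}, \code{cdd_id}, \code{evalue_max},
#'   \code{identity_min}.
#' @export
family_spec <- function(family = NULL, evalue_max = 1e-5, identity_min = 60) {
  registry <- list(
    "beta-CA" = list(required_domains = "PF00484", cdd_id = "cl00391"),
    "RbcS"    = list(required_domains = c("PF12338", "PF00101"), cdd_id = "cl01843"),
    "PEPC"    = list(required_domains = "PF00311", cdd_id = "cl21521"),
    "NADP-ME" = list(required_domains = c("PF03949", "PF00390"), cdd_id = "cl27704"),
    "MDH"     = list(required_domains = "PF02866", cdd_id = "cl27704"),
    "PPDK"    = list(required_domains = c("PF02896", "PF01326", "PF00391"),
                     cdd_id = "cl27021"))
  registry <- lapply(names(registry), function(nm) {
    c(list(family_name = nm), registry[[nm]],
      list(evalue_max = evalue_max, identity_min = identity_min))
  })
  names(registry) <- vapply(registry, `[[`, "", "family_name")
  if (is.null(family)) return(registry)
  if (!family %in% names(registry))
    stop("unknown family: ", family, " (expected one of ",
         paste(names(registry), collapse = ", "), ")")
  registry[[family]]
}

#' Read BLAST tabular output (outfmt 6)
#'
#' Parses the standard 12-column tab-separated BLAST table. Rows with fewer
#' than 12 columns or non-numeric identity/E-value raise an error naming the
#' offending line.
#'
#' @param path Path to the BLAST tabular file.
#' @return A data.frame with columns \code{query_id}, \code{subject_id},
#'   \code{percent_identity}, \code{align_length}, \code{mismatches},
#'   \code{gap_opens}, \code{q_start}, \code{q_end}, \code{s_start},
#'   \code{s_end}, \code{evalue}, \code{bit_score}; zero rows for an empty
#'   file.
#' @export
read_blast_tabular <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  cols <- c("query_id", "subject_id", "percent_identity", "align_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start",
            "s_end", "evalue", "bit_score")
  if (length(lines) == 0) {
    out <- as.data.frame(setNames(rep(list(character(0)), 12), cols))
    num <- c(3:12)
    out[num] <- lapply(out[num], as.numeric)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 12)
  if (length(bad))
    stop("malformed BLAST tabular row(s) with < 12 columns at line(s): ",
         paste(bad, collapse = ", "))
  m <- do.call(rbind, lapply(fields, function(f) f[1:12]))
  out <- data.frame(m, stringsAsFactors = FALSE)
  names(out) <- cols
  for (j in 3:12) {
    v <- suppressWarnings(as.numeric(out[[j]]))
    if (anyNA(v))
      stop("non-numeric value in column '", cols[j], "' at line(s): ",
           paste(which(is.na(v)), collapse = ", "))
    out[[j]] <- v
  }
  if (any(out$percent_identity < 0 | out$percent_identity > 100))
    stop("percent identity outside [0, 100]")
  if (any(out$evalue < 0)) stop("negative E-value")
  out
}

#' Read a HMMER3 per-domain table (domtblout)
#'
#' Skips '#' comment lines, splits the whitespace-separated columns, and
#' returns one record per domain row. The domain accession is the profile
#' accession with any version suffix stripped.
#'
#' @param path Path to the domtblout file.
#' @return A data.frame with columns \code{gene_id}, \code{domain_accession},
#'   \code{domain_evalue}, \code{env_from}, \code{env_to}.
#' @export
read_hmmer_domtbl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  data_lines <- lines[keep]
  empty <- data.frame(gene_id = character(0), domain_accession = character(0),
                      domain_evalue = numeric(0), env_from = integer(0),
                      env_to = integer(0))
  if (length(data_lines) == 0) return(empty)
  fields <- strsplit(trimws(data_lines), "[[:space:]]+")
  bad <- which(lengths(fields) < 22)
  if (length(bad))
    stop("truncated domtblout row(s) at data line(s): ",
         paste(bad, collapse = ", "))
  acc <- vapply(fields, `[[`, "", 5)
  ie <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 13)))
  from <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 20)))
  to <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 21)))
  if (anyNA(ie) || anyNA(from) || anyNA(to))
    stop("non-numeric i-Evalue or envelope coordinate in domtblout")
  data.frame(gene_id = vapply(fields, `[[`, "", 1),
             domain_accession = sub("\\.\\d+$", "", acc),
             domain_evalue = ie, env_from = from, env_to = to,
             stringsAsFactors = FALSE)
}

#' Screen candidate genes for family membership
#'
#' A gene passes when its best BLAST hit (minimum E-value, ties broken by
#' maximum identity then lexicographically smallest partner id) has E-value
#' strictly below the threshold and identity at or above the threshold, and
#' every required conserved domain is present in the HMMER table. Candidate
#' genes are the BLAST subject sequences (the screen queries curated
#' references against each species' protein set). Output is sorted and
#' duplicate-free.
#'
#' @param candidates BLAST hit data.frame from \code{\link{read_blast_tabular}}.
#' @param domains Domain hit data.frame from \code{\link{read_hmmer_domtbl}}.
#' @param spec Family specification from \code{\link{family_spec}}.
#' @param domain_evalue_max Optional per-domain independent E-value cutoff;
#'   \code{NULL} (default) accepts a domain at any E-value, as the screening
#'   protocol states no domain-level threshold.
#' @param include,exclude Manual-curation overrides: gene ids forced in or
#'   out after the automatic filter (exclusions win over inclusions).
#' @return Sorted character vector of passing gene ids.
#' @export
screen_family <- function(candidates, domains, spec,
                          domain_evalue_max = NULL,
                          include = character(0), exclude = character(0)) {
  if (length(spec$required_domains) == 0)
    stop("configuration error: family spec has no required domains")
  passed <- character(0)
  if (nrow(candidates) > 0) {
    best <- do.call(rbind, lapply(split(candidates, candidates$subject_id),
      function(h) {
        h <- h[order(h$evalue, -h$percent_identity, h$query_id), , drop = FALSE]
        h[1, , drop = FALSE]
      }))
    ok <- best$evalue < spec$evalue_max & best$percent_identity >= spec$identity_min
    passed <- best$subject_id[ok]
  }
  dom <- domains
  if (!is.null(domain_evalue_max))
    dom <- dom[dom$domain_evalue <= domain_evalue_max, , drop = FALSE]
  has_all <- vapply(passed, function(g) {
    all(spec$required_domains %in% dom$domain_accession[dom$gene_id == g])
  }, logical(1))
  passed <- passed[has_all]
  passed <- union(passed, include)
  passed <- setdiff(passed, exclude)
  sort(unique(passed))
}

#' Write the family-membership table
#'
#' @param candidates,domains,spec As in \code{\link{screen_family}}.
#' @param path Output TSV path.
#' @param ... Passed to \code{\link{screen_family}}.
#' @return Invisibly, the written data.frame (gene_id, family, best_evalue,
#'   best_identity, domains_found).
#' @export
write_family_members <- function(candidates, domains, spec, path, ...) {
  genes <- screen_family(candidates, domains, spec, ...)
  rows <- lapply(genes, function(g) {
    h <- candidates[candidates$subject_id == g, , drop = FALSE]
    if (nrow(h)) {
      h <- h[order(h$evalue, -h$percent_identity, h$query_id), , drop = FALSE]
      be <- h$evalue[1]; bi <- h$percent_identity[1]
    } else be <- bi <- NA_real_  # manually included gene without a hit
    data.frame(gene_id = g, family = spec$family_name, best_evalue = be,
               best_identity = bi,
               domains_found = paste(sort(unique(
                 domains$domain_accession[domains$gene_id == g])),
                 collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), family = character(0),
               best_evalue = numeric(0), best_identity = numeric(0),
               domains_found = character(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
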