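AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Tokenise one flanking-region string into residue-state sets.
## "(X/Y)" -> multi-state column; "(K)" -> parenthesised single residue,
## treated as a lineage-specific insertion and dropped; bold markers ("*")
## are presentation metadata and stripped.
.tokenize_flank <- function(text) {
  s <- gsub("*", "", text, fixed = TRUE)
  s <- gsub("[[:space:]]", "", s)
  tokens <- list()
  i <- 1L
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      close <- NULL
      for (j in (i + 1):n) if (chars[j] == ")") { close <- j; break }
      if (is.null(close)) stop("unbalanced parentheses in: ", text)
      inner <- paste(chars[(i + 1):(close - 1)], collapse = "")
      states <- toupper(strsplit(inner, "/", fixed = TRUE)[[1]])
      states <- states[nzchar(states)]
      if (length(states) == 0) stop("empty parenthetical in: ", text)
      bad <- setdiff(states, c(AA20, "X"))
      if (length(bad)) stop("non-residue character(s) ",
                            paste(bad, collapse = ","), " in: ", text)
      if (length(states) > 1)
        tokens[[length(tokens) + 1L]] <- unique(states)
      ## single parenthesised residue: insertion, dropped
      i <- close + 1L
    } else if (ch == ")") {
      stop("unbalanced parentheses in: ", text)
    } else {
      r <- toupper(ch)
      if (!r %in% c(AA20, "X"))
        stop("non-residue character '", ch, "' in: ", text)
      tokens[[length(tokens) + 1L]] <- r
      i <- i + 1L
    }
  }
  tokens
}

#' Parse a table of labelled flanking-region sequences into an ambiguity matrix
#'
#' Each row is a short aligned region written with the "(A/B)" notation for
#' residues that vary within a lineage: "(X/Y)" becomes one column whose
#' state set is \{X, Y\}; a parenthesised single residue such as "(K)" is
#' read as a lineage-specific insertion and dropped, so rows line up with the
#' modal column count. Rows whose column count still differs from the mode
#' are rejected.
#'
#' @param rows A data.frame with columns \code{id}, \code{sequence} and
#'   \code{label} (each label one of "C3", "C4", "facultative").
#' @return An object of class \code{ambiguity_matrix}: a list with \code{ids},
#'   \code{labels}, and \code{states}, a rows x columns matrix of
#'   slash-collapsed state sets (e.g. \code{"N/G"}).
#' @export
parse_flank_table <- function(rows) {
  stopifnot(all(c("id", "sequence", "label") %in% names(rows)))
  lab <- as.character(rows$label)
  bad_lab <- setdiff(lab, c("C3", "C4", "facultative"))
  if (length(bad_lab))
    stop("unknown label(s): ", paste(unique(bad_lab), collapse = ", "))
  toks <- lapply(as.character(rows$sequence), .tokenize_flank)
  counts <- lengths(toks)
  tab <- table(counts)
  mode_count <- as.integer(names(tab)[which.max(tab)])
  off <- which(counts != mode_count)
  if (length(off))
    stop("row(s) ", paste(rows$id[off], collapse = ", "),
         " have ", paste(unique(counts[off]), collapse = "/"),
         " columns; expected ", mode_count)
  states <- t(vapply(toks, function(tk)
    vapply(tk, function(s) paste(sort(s), collapse = "/"), ""),
    character(mode_count)))
  if (mode_count == 1) states <- matrix(states, ncol = 1)
  structure(list(ids = as.character(rows$id), labels = lab, states = states),
            class = "ambiguity_matrix")
}

#' @export
print.ambiguity_matrix <- function(x, ...) {
  cat("ambiguity_matrix:", length(x$ids), "rows x", ncol(x$states),
      "columns;", sum(x$labels == "C4"), "C4,", sum(x$labels == "C3"), "C3,",
      sum(x$labels == "facultative"), "facultative\n")
  invisible(x)
}

.state_sets <- function(m, col) {
  lapply(m$states[, col], function(s) {
    st <- strsplit(s, "/", fixed = TRUE)[[1]]
    ## unknowns expand to all 20 states so they can never create a
    ## spuriously perfect site
    if ("X" %in% st) AA20 else st
  })
}

.contrast_rows <- function(m, include_facultative) {
  keep <- if (include_facultative) rep(TRUE, length(m$labels))
          else m$labels != "facultative"
  labs <- m$labels[keep]
  if (!any(labs == "C3") || !any(labs == "C4"))
    stop("need at least one C3 and one C4 row for a label contrast")
  keep
}

#' Find alignment columns that perfectly separate C4 from C3 rows
#'
#' A column discriminates when the union of its residue states over C4 rows
#' is disjoint from the union over C3 rows. Facultative rows are excluded
#' from the contrast by default.
#'
#' @param m An \code{ambiguity_matrix} from \code{\link{parse_flank_table}}.
#' @param include_facultative Count facultative rows with their own label?
#'   (They are then ignored either way by the C3/C4 contrast but their
#'   states are not pooled; kept for symmetry with the ranking operation.)
#' @return Ascending integer vector of 1-based column indices.
#' @export
find_discriminating_columns <- function(m, include_facultative = FALSE) {
  keep <- .contrast_rows(m, include_facultative)
  is_c4 <- m$labels == "C4" & keep
  is_c3 <- m$labels == "C3" & keep
  out <- integer(0)
  for (col in seq_len(ncol(m$states))) {
    sets <- .state_sets(m, col)
    u4 <- unique(unlist(sets[is_c4]))
    u3 <- unique(unlist(sets[is_c3]))
    if (length(intersect(u4, u3)) == 0) out <- c(out, col)
  }
  out
}

#' Rank columns by single-state discrimination accuracy
#'
#' For every column, the score is the best achievable classification accuracy
#' of a rule of the form "state set contains residue s => C4, else C3",
#' maximised over the 20 residues s, evaluated on the non-facultative rows.
#' Columns are returned in decreasing score order, ties broken by ascending
#' column index. Perfectly discriminating columns
#' (\code{\link{find_discriminating_columns}}) are exactly those that can
#' reach score 1 here.
#'
#' @inheritParams find_discriminating_columns
#' @return A data.frame with columns \code{column}, \code{score},
#'   \code{best_state}.
#' @export
rank_columns_by_discrimination <- function(m, include_facultative = FALSE) {
  keep <- .contrast_rows(m, include_facultative)
  labs <- m$labels[keep]
  n <- sum(keep)
  res <- lapply(seq_len(ncol(m$states)), function(col) {
    sets <- .state_sets(m, col)[keep]
    acc <- vapply(AA20, function(s) {
      pred <- vapply(sets, function(st) s %in% st, logical(1))
      sum((pred & labs == "C4") | (!pred & labs == "C3")) / n
    }, numeric(1))
    best <- which.max(acc)
    data.frame(column = col, score = acc[best], best_state = AA20[best])
  })
  out <- do.call(rbind, res)
  out[order(-out$score, out$column), , drop = FALSE]
}

#' Check a protein against known diagnostic sites
#'
#' Sites are defined on a reference protein (e.g. position 780 of ZmPEPC4 or
#' position 43 of OsMDH1); a pairwise position mapping from the reference to
#' the query (derived from an alignment) says where each site falls on the
#' query. The residue found there is classified against the expected C4 and
#' C3 state sets.
#'
#' @param protein_seq Query protein sequence (string or character vector).
#' @param mapping A data.frame with columns \code{ref_pos} and
#'   \code{query_pos} (1-based; sites absent from the mapping are
#'   unalignable, e.g. deletions).
#' @param sites A data.frame with columns \code{site_id}, \code{position}
#'   (on the reference), \code{c4_states}, \code{c3_states} (slash-separated),
#'   and optionally \code{reference} and \code{family}.
#' @param reference_length Optional length of the reference protein; site
#'   positions beyond it raise a configuration error.
#' @return A data.frame with one row per site: \code{site_id},
#'   \code{position}, \code{residue}, and \code{call} in
#'   \{"C4-state", "C3-state", "other", "unalignable"\}.
#' @export
check_known_sites <- function(protein_seq, mapping, sites,
                              reference_length = NULL) {
  seq <- .as_residue_vector(protein_seq)
  stopifnot(all(c("ref_pos", "query_pos") %in% names(mapping)),
            all(c("site_id", "position", "c4_states", "c3_states") %in%
                  names(sites)))
  if (!is.null(reference_length) && any(sites$position > reference_length))
    stop("configuration error: site position beyond reference length ",
         reference_length)
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    pos <- sites$position[i]
    qp <- mapping$query_pos[match(pos, mapping$ref_pos)]
    if (is.na(qp) || qp < 1 || qp > length(seq)) {
      res <- NA_character_; call <- "unalignable"
    } else {
      res <- seq[qp]
      c4 <- strsplit(as.character(sites$c4_states[i]), "/", fixed = TRUE)[[1]]
      c3 <- strsplit(as.character(sites$c3_states[i]), "/", fixed = TRUE)[[1]]
      if (length(intersect(c4, c3)))
        stop("configuration error: overlapping C4/C3 state sets for site ",
             sites$site_id[i])
      call <- if (res %in% c4) "C4-state" else if (res %in% c3) "C3-state"
              else "other"
    }
    data.frame(site_id = sites$site_id[i], position = pos,
               residue = res, call = call, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Built-in diagnostic site definitions
#'
#' The residue positions reported to separate C4 from C3 gene copies:
#' OsRbcS1 24 (C4 T/S/R vs C3 G/D), OsRbcS1 56 (C4 N vs C3 I), ZmPEPC4 780
#' (C-terminal serine of C4 PEPC), ZmPEPC4 842 (C4 glycine vs C3 alanine),
#' and OsMDH1 43 (coenzyme specificity: D = NAD, G = NADP).
#'
#' @return A data.frame usable as the \code{sites} argument of
#'   \code{\link{check_known_sites}}.
#' @export
known_diagnostic_sites <- function() {
  data.frame(
    site_id = c("RbcS_24", "RbcS_56", "PEPC_Ser780", "PEPC_Gly842",
                "MDH_coenzyme_43"),
    reference = c("OsRbcS1", "OsRbcS1", "ZmPEPC4", "ZmPEPC4", "OsMDH1"),
    family = c("RbcS", "RbcS", "PEPC", "PEPC", "MDH"),
    position = c(24L, 56L, 780L, 842L, 43L),
    c4_states = c("T/S/R", "N", "S", "G", "G"),
    c3_states = c("G/D", "I", "A", "A", "D"),
    stringsAsFactors = FALSE)
}
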