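## JTT amino-acid substitution model: published exchangeabilities and
## stationary frequencies (Jones, Taylor & Thornton 1992), amino acids in
## ARNDCQEGHILKMFPSTWYV order. Exchangeabilities are the lower triangle of
## the symmetric matrix, column-major.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

JTT_EXCHANGEABILITIES <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475, 9,
  11, 298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101,
  64, 126, 20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15,
  503, 232, 8, 70, 16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59,
  38, 4, 46, 31, 9, 5, 59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209,
  62, 323, 26, 597, 9, 72, 292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26,
  12, 9, 181, 18, 5, 18, 30, 32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201,
  33, 55, 8, 47, 16, 56, 45, 33, 40, 115, 73, 46, 8, 573, 11, 229, 21,
  479, 89, 10, 40, 245, 9, 32, 961, 14, 388, 248, 102, 59, 25, 52, 24,
  180, 65, 4, 21, 47, 103, 10, 8, 14, 43, 16, 29, 226, 24, 18, 323, 17,
  92, 12, 53, 536, 62, 285, 118, 6, 10, 23, 477, 35, 63, 38, 12, 21, 112,
  71, 25, 16)

JTT_FREQUENCIES <- c(
  0.076748, 0.051691, 0.042645, 0.051544, 0.019803, 0.040752, 0.061830,
  0.073152, 0.022944, 0.053761, 0.091904, 0.058676, 0.023826, 0.040126,
  0.050901, 0.068765, 0.058565, 0.014261, 0.032102, 0.066005)

#' Instantaneous rate matrix of the JTT model
#'
#' Builds the 20x20 JTT generator Q from the published exchangeabilities and
#' stationary frequencies, normalised so that the expected number of
#' substitutions per site per unit time equals 1 (distances are therefore in
#' substitutions per site).
#'
#' @return A 20x20 matrix with row/column names in ARNDCQEGHILKMFPSTWYV order.
#' @export
jtt_rate_matrix <- function() {
  freqs <- JTT_FREQUENCIES / sum(JTT_FREQUENCIES)
  S <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  S[lower.tri(S)] <- JTT_EXCHANGEABILITIES
  S <- S + t(S)
  Q <- S * rep(freqs, each = 20)      # q_ij = s_ij * pi_j
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  Q / scale
}

## Eigendecomposition cache for fast P(t). Q = D^{-1/2} B D^{1/2} with B
## symmetric, so the decomposition is numerically stable and real.
.jtt_cache <- new.env(parent = emptyenv())

.jtt_eigen <- function() {
  if (is.null(.jtt_cache$V)) {
    freqs <- JTT_FREQUENCIES / sum(JTT_FREQUENCIES)
    Q <- jtt_rate_matrix()
    d <- sqrt(freqs)
    B <- diag(d) %*% Q %*% diag(1 / d)
    e <- eigen((B + t(B)) / 2, symmetric = TRUE)
    .jtt_cache$values <- e$values
    .jtt_cache$V <- diag(1 / d) %*% e$vectors
    .jtt_cache$Vinv <- t(e$vectors) %*% diag(d)
    .jtt_cache$freqs <- freqs
  }
  .jtt_cache
}

#' JTT transition probability matrix
#'
#' @param t Evolutionary time (expected substitutions per site), >= 0.
#' @return 20x20 matrix P with P[i, j] = Prob(j at time t | i at time 0).
#' @export
jtt_prob_matrix <- function(t) {
  stopifnot(is.numeric(t), length(t) == 1, t >= 0)
  ce <- .jtt_eigen()
  P <- ce$V %*% (exp(ce$values * t) * ce$Vinv)
  dimnames(P) <- list(AA_ALPHABET, AA_ALPHABET)
  ## tiny negative entries from roundoff
  P[P < 0] <- 0
  P
}

.pair_site_counts <- function(row_a, row_b) {
  a <- .as_residue_vector(row_a)
  b <- .as_residue_vector(row_b)
  if (length(a) != length(b))
    stop("sequences have different lengths (", length(a), " vs ", length(b), ")")
  drop <- !(a %in% AA_ALPHABET) | !(b %in% AA_ALPHABET)
  a <- a[!drop]
  b <- b[!drop]
  if (length(a) == 0) return(NULL)
  table(factor(a, levels = AA_ALPHABET), factor(b, levels = AA_ALPHABET))
}

.as_residue_vector <- function(x) {
  if (length(x) == 1 && is.character(x)) x <- strsplit(x, "")[[1]]
  toupper(as.character(x))
}

.jtt_loglik <- function(t, counts, freqs) {
  P <- jtt_prob_matrix(t)
  lik <- freqs * P
  lik[lik <= 0] <- .Machine$double.xmin
  sum(counts * log(lik))
}

#' Maximum likelihood JTT distance between two aligned sequences
#'
#' Columns where either sequence carries a gap (\code{-}) or an unknown
#' residue (\code{X}, or any non-standard symbol) are removed first (pairwise
#' deletion). The distance is the time \code{t} maximising the likelihood of
#' the residue-pair counts under the reversible JTT model,
#' \eqn{\sum_{ij} n_{ij} \log(\pi_i P_{ij}(t))}, found by 1-D optimisation.
#'
#' @param row_a,row_b Aligned residue strings (or character vectors) of equal
#'   length.
#' @param max_time Upper bracket of the optimisation (substitutions/site).
#' @return The ML distance, \code{0} for identical overlap, or \code{NA}
#'   (inestimable) when fewer than 1 comparable column remains or the
#'   likelihood is still increasing at \code{max_time} (saturation).
#' @export
jtt_distance <- function(row_a, row_b, max_time = 5) {
  counts <- .pair_site_counts(row_a, row_b)
  if (is.null(counts)) return(NA_real_)
  if (sum(counts) == sum(diag(counts))) return(0)
  ce <- .jtt_eigen()
  opt <- stats::optimize(.jtt_loglik, interval = c(1e-8, max_time),
                         counts = counts, freqs = ce$freqs,
                         maximum = TRUE, tol = 1e-8)
  ## saturation: optimum pinned to the bracket end with likelihood still rising
  if (opt$maximum > max_time - 1e-4) {
    at_end <- .jtt_loglik(max_time, counts, ce$freqs)
    just_in <- .jtt_loglik(max_time * 0.999, counts, ce$freqs)
    if (at_end >= just_in) return(NA_real_)
  }
  opt$maximum
}

#' Pairwise JTT distance matrix for an alignment
#'
#' @param aln An alignment: named character vector of equal-length residue
#'   strings, or a list of such, or a character matrix (rows = sequences).
#' @param saturated_cap Distance assigned (with a warning) to pairs whose ML
#'   distance is inestimable due to saturation, so that tree building remains
#'   possible. Pairs with no comparable columns stay \code{NA}.
#' @param max_time Upper bracket passed to \code{\link{jtt_distance}}.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
jtt_distance_matrix <- function(aln, saturated_cap = 5, max_time = 5) {
  seqs <- as_alignment(aln)
  n <- length(seqs)
  ids <- names(seqs)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  n_saturated <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dij <- jtt_distance(seqs[[i]], seqs[[j]], max_time = max_time)
      if (is.na(dij)) {
        cnt <- .pair_site_counts(seqs[[i]], seqs[[j]])
        if (!is.null(cnt)) {           # saturated, not empty-overlap
          dij <- saturated_cap
          n_saturated <- n_saturated + 1L
        }
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  if (n_saturated > 0)
    warning(n_saturated, " saturated pair(s) capped at distance ", saturated_cap)
  d
}

#' Coerce alignment input to a named list of residue-character vectors
#'
#' Accepts a named character vector of sequences, a list of sequences, or a
#' character matrix with one row per sequence. All sequences must have equal
#' length.
#'
#' @param aln Alignment in any accepted form.
#' @return Named list of uppercase residue character vectors.
#' @export
as_alignment <- function(aln) {
  if (is.matrix(aln)) {
    ids <- rownames(aln)
    seqs <- lapply(seq_len(nrow(aln)), function(i) .as_residue_vector(aln[i, ]))
  } else if (is.list(aln)) {
    ids <- names(aln)
    seqs <- lapply(aln, .as_residue_vector)
  } else if (is.character(aln)) {
    ids <- names(aln)
    seqs <- lapply(aln, .as_residue_vector)
  } else {
    stop("unsupported alignment representation: ", class(aln)[1])
  }
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("alignment sequences must be named")
  lens <- lengths(seqs)
  if (length(unique(lens)) > 1)
    stop("alignment rows have unequal lengths: ", paste(unique(lens), collapse = ", "))
  names(seqs) <- ids
  seqs
}
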