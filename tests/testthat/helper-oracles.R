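# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths: matrix exponentials via Taylor series with
# scaling and squaring (the package uses an eigendecomposition), distances
# via dense grid scans (the package uses 1-D optimisation), NJ via exhaustive
# topology enumeration with least-squares fits, and scanners/filters via
# direct brute force.

# matrix exponential: scaling and squaring with a plain Taylor series
expm_taylor <- function(A, k = 12, squarings = 12) {
  As <- A / 2^squarings
  P <- diag(nrow(A))
  term <- diag(nrow(A))
  for (i in seq_len(k)) {
    term <- term %*% As / i
    P <- P + term
  }
  for (i in seq_len(squarings)) P <- P %*% P
  P
}

# log-likelihood of a residue-pair count table at time t, from first
# principles (generator built locally from the published constants)
oracle_jtt_Q <- function() {
  f <- c4ortho:::JTT_FREQUENCIES / sum(c4ortho:::JTT_FREQUENCIES)
  S <- matrix(0, 20, 20)
  S[lower.tri(S)] <- c4ortho:::JTT_EXCHANGEABILITIES
  S <- S + t(S)
  Q <- S * rep(f, each = 20)
  diag(Q) <- -rowSums(Q)
  Q / -sum(f * diag(Q))
}

oracle_pair_counts <- function(a, b) {
  aa <- strsplit(a, "")[[1]]; bb <- strsplit(b, "")[[1]]
  keep <- aa %in% c4ortho:::AA_ALPHABET & bb %in% c4ortho:::AA_ALPHABET
  table(factor(aa[keep], c4ortho:::AA_ALPHABET),
        factor(bb[keep], c4ortho:::AA_ALPHABET))
}

# dense two-stage grid scan for the ML JTT distance
oracle_jtt_grid_distance <- function(a, b, coarse_step = 0.01, fine_step = 2e-5,
                                     t_max = 5) {
  Q <- oracle_jtt_Q()
  f <- c4ortho:::JTT_FREQUENCIES / sum(c4ortho:::JTT_FREQUENCIES)
  counts <- oracle_pair_counts(a, b)
  ll <- function(t) {
    P <- expm_taylor(Q * t)
    lik <- f * P
    lik[lik <= 0] <- .Machine$double.xmin
    sum(counts * log(lik))
  }
  coarse <- seq(coarse_step, t_max, by = coarse_step)
  lls <- vapply(coarse, ll, numeric(1))
  t0 <- coarse[which.max(lls)]
  fine <- seq(max(fine_step, t0 - coarse_step), min(t_max, t0 + coarse_step),
              by = fine_step)
  fine[which.max(vapply(fine, ll, numeric(1)))]
}

# all unrooted binary topologies on taxa (sequential leaf insertion);
# each returned as an ape phylo
enumerate_topologies <- function(taxa) {
  n <- length(taxa)
  stopifnot(n >= 3)
  base <- ape::read.tree(text = paste0("(", taxa[1], ":1,", taxa[2], ":1,",
                                       taxa[3], ":1);"))
  trees <- list(base)
  if (n == 3) return(trees)
  tip <- ape::read.tree(text = paste0("(", "PLACEHOLDER", ":1);"))
  for (k in 4:n) {
    nxt <- list()
    tip$tip.label <- taxa[k]
    for (tr in trees) {
      tr$edge.length <- rep(1, nrow(tr$edge))
      for (e in seq_len(nrow(tr$edge))) {
        tr2 <- ape::bind.tree(tr, tip, where = tr$edge[e, 2],
                              position = 0.5)
        nxt[[length(nxt) + 1L]] <- tr2
      }
    }
    trees <- nxt
  }
  trees
}

# least-squares branch lengths of a topology against a distance matrix;
# returns list(rss, lengths)
ls_fit_topology <- function(tree, d) {
  taxa <- tree$tip.label
  n <- length(taxa)
  pairs <- t(combn(n, 2))
  # incidence: which edges lie on the path between each pair of tips
  tr <- tree
  tr$edge.length <- rep(1, nrow(tr$edge))
  X <- matrix(0, nrow(pairs), nrow(tr$edge))
  for (p in seq_len(nrow(pairs))) {
    path <- path_edges(tr, pairs[p, 1], pairs[p, 2])
    X[p, path] <- 1
  }
  y <- d[cbind(match(taxa[pairs[, 1]], rownames(d)),
               match(taxa[pairs[, 2]], rownames(d)))]
  fit <- stats::lm.fit(X, y)
  list(rss = sum(fit$residuals^2), lengths = fit$coefficients)
}

# indices of the edges on the tip-to-tip path (via node ancestry)
path_edges <- function(tree, t1, t2) {
  parent_of <- function(node) {
    e <- which(tree$edge[, 2] == node)
    if (length(e) == 0) NA_integer_ else tree$edge[e, 1]
  }
  anc <- function(node) {
    out <- node
    repeat {
      p <- parent_of(node)
      if (is.na(p)) break
      out <- c(out, p); node <- p
    }
    out
  }
  a1 <- anc(t1); a2 <- anc(t2)
  common <- intersect(a1, a2)[1]
  nodes <- c(a1[seq_len(which(a1 == common) - 1)],
             a2[seq_len(which(a2 == common) - 1)])
  vapply(nodes, function(nd) which(tree$edge[, 2] == nd), integer(1))
}

# random additive (tree-metric) distance matrix and its generating tree
random_additive_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.2, 1.5))
  tr$tip.label <- sort(tr$tip.label)
  d <- ape::cophenetic.phylo(tr)
  d <- d[order(rownames(d)), order(colnames(d))]
  list(tree = tr, d = d)
}

# brute-force sliding-window IUPAC scanner (no regex)
oracle_scan <- function(promoter, pattern) {
  codes <- c4ortho:::IUPAC_DNA
  pat <- strsplit(toupper(pattern), "")[[1]]
  revcomp <- function(s) paste(rev(c(A = "T", C = "G", G = "C",
                                     T = "A", N = "N")[strsplit(s, "")[[1]]]),
                               collapse = "")
  find <- function(seqstr) {
    s <- strsplit(toupper(seqstr), "")[[1]]
    w <- length(pat)
    out <- integer(0)
    if (length(s) < w) return(out)
    for (i in seq_len(length(s) - w + 1)) {
      ok <- TRUE
      for (j in seq_len(w)) {
        if (!(s[i + j - 1] %in% codes[[pat[j]]])) { ok <- FALSE; break }
      }
      if (ok) out <- c(out, i)
    }
    out
  }
  L <- nchar(promoter)
  w <- length(pat)
  plus <- find(promoter)
  minus_raw <- find(revcomp(promoter))
  minus <- L - (minus_raw + w - 1) + 1
  sort(c(plus, minus))
}

# brute-force screening filter over all candidate genes
oracle_screen <- function(candidates, domains, spec) {
  genes <- unique(candidates$subject_id)
  ok <- vapply(genes, function(g) {
    h <- candidates[candidates$subject_id == g, ]
    h <- h[order(h$evalue, -h$percent_identity, h$query_id), ]
    pass_blast <- h$evalue[1] < spec$evalue_max &&
      h$percent_identity[1] >= spec$identity_min
    pass_dom <- all(spec$required_domains %in%
                      domains$domain_accession[domains$gene_id == g])
    pass_blast && pass_dom
  }, logical(1))
  sort(genes[ok])
}

# brute-force all-pairs tandem linkage, transitive closure
oracle_tandem <- function(loci, max_intervening = 5) {
  n <- nrow(loci)
  fam <- if ("family" %in% names(loci)) loci$family else rep("f", n)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (loci$chrom[i] != loci$chrom[j] || fam[i] != fam[j]) next
    lo <- min(loci$rank[i], loci$rank[j]); hi <- max(loci$rank[i], loci$rank[j])
    between <- sum(fam == fam[i] & loci$chrom == loci$chrom[i] &
                     loci$rank > lo & loci$rank < hi)
    non_family_between <- (hi - lo - 1) - between
    if (non_family_between <= max_intervening) adj[i, j] <- TRUE
  }
  for (k in seq_len(n)) adj <- adj | (adj[, k] %o% adj[k, ] > 0)
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1
    comp[i] <- cid
    comp[which(adj[i, ])] <- cid
  }
  arrays <- split(loci$gene_id, comp)
  arrays <- Filter(function(a) length(a) >= 2, arrays)
  unname(lapply(arrays, sort))
}

local_tmpdir <- function(env = parent.frame()) {
  d <- tempfile("c4ortho-test-")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}
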