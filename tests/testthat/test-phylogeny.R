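test_that("JTT generator matches the published model and its properties", {
  Q <- jtt_rate_matrix()
  expect_equal(max(abs(rowSums(Q))), 0, tolerance = 1e-12)
  f <- c4ortho:::JTT_FREQUENCIES / sum(c4ortho:::JTT_FREQUENCIES)
  expect_equal(-sum(f * diag(Q)), 1, tolerance = 1e-12)
  P <- jtt_prob_matrix(0.7)
  expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-10,
               ignore_attr = TRUE)
  # time reversibility: pi_i P_ij = pi_j P_ji
  expect_equal(max(abs(f * P - t(f * P))), 0, tolerance = 1e-10)
  skip_if_not_installed("phangorn")
  jtt <- phangorn:::.JTT
  expect_equal(unname(c4ortho:::JTT_EXCHANGEABILITIES), unname(jtt$Q))
  expect_equal(unname(f), unname(jtt$bf), tolerance = 1e-6)
})

test_that("JTT distances: degenerate cases and basic properties", {
  expect_equal(jtt_distance("ACDEFGHIKL", "ACDEFGHIKL"), 0)
  expect_true(is.na(jtt_distance("AC---", "--XAA")))
  expect_error(jtt_distance("ACD", "AC"), "length")
  set.seed(5)
  a <- paste(random_jtt_protein(100), collapse = "")
  b <- paste(evolve_jtt(a, 0.4), collapse = "")
  expect_equal(jtt_distance(a, b), jtt_distance(b, a))
  # more differing sites at fixed length => larger distance
  base <- strsplit(a, "")[[1]]
  flip <- function(k) {
    s <- base
    s[seq_len(k)] <- ifelse(s[seq_len(k)] == "A", "R", "A")
    paste(s, collapse = "")
  }
  d5 <- jtt_distance(a, flip(5)); d20 <- jtt_distance(a, flip(20))
  expect_true(d5 < d20)
})

test_that("ML distance matches a dense grid-search likelihood oracle", {
  set.seed(17)
  for (i in 1:8) {
    a <- paste(random_jtt_protein(150), collapse = "")
    b <- paste(evolve_jtt(a, runif(1, 0.05, 1.5)), collapse = "")
    est <- jtt_distance(a, b)
    grid <- oracle_jtt_grid_distance(a, b)
    expect_equal(est, grid, tolerance = 1e-4)
  }
})

test_that("distance-matrix construction caps saturated pairs with a warning", {
  set.seed(23)
  aln <- list(s1 = paste(random_jtt_protein(60), collapse = ""),
              s2 = paste(random_jtt_protein(60), collapse = ""),
              s3 = paste(random_jtt_protein(60), collapse = ""))
  aln$s2 <- aln$s1   # one zero-distance pair keeps the matrix sane
  d <- suppressWarnings(jtt_distance_matrix(aln, saturated_cap = 5))
  expect_true(isSymmetric(d))
  expect_equal(diag(d), c(s1 = 0, s2 = 0, s3 = 0))
  expect_true(all(d >= 0))
})

test_that("NJ solves the additive four-taxon case exactly", {
  d <- matrix(c(0, 2, 3, 3,
                2, 0, 3, 3,
                3, 3, 0, 2,
                3, 3, 2, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(d)
  expect_true(ape::is.monophyletic(tr, c("A", "B")))
  expect_true(ape::is.monophyletic(tr, c("C", "D")))
  # recovered metric reproduces the input distances exactly
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)
  expect_error(nj_tree(d[1:2, 1:2]), "3 taxa")
  dna <- d; dna[1, 2] <- dna[2, 1] <- NA
  expect_error(nj_tree(dna), "inestimable")
})

test_that("NJ recovers random additive trees, verified by topology enumeration", {
  # enumeration oracle at sizes where the full topology space is searchable;
  # the generating tree is checked directly at 7 and 8 taxa
  for (n in c(5, 6)) {
    gen <- random_additive_tree(n, seed = 100 + n)
    tr <- nj_tree(gen$d)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(gen$tree)), 0,
                 ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(gen$d), colnames(gen$d)],
                 gen$d, tolerance = 1e-8)
    topos <- enumerate_topologies(sort(gen$tree$tip.label))
    rss <- vapply(topos, function(tp) ls_fit_topology(tp, gen$d)$rss,
                  numeric(1))
    best <- which(rss < 1e-16)
    expect_length(best, 1)   # the additive matrix fits exactly one topology
    expect_equal(ape::dist.topo(ape::unroot(tr),
                                ape::unroot(topos[[best]])), 0,
                 ignore_attr = TRUE)
  }
  for (n in c(7, 8)) {
    gen <- random_additive_tree(n, seed = 200 + n)
    tr <- nj_tree(gen$d)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(gen$tree)), 0,
                 ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(gen$d), colnames(gen$d)],
                 gen$d, tolerance = 1e-8)
  }
})

make_two_clade_alignment <- function(seed = 7, deep = 1.2, shallow = 0.05,
                                     L = 300) {
  set.seed(seed)
  root <- random_jtt_protein(L)
  a1 <- evolve_jtt(root, deep); a2 <- evolve_jtt(root, deep)
  aln <- c(lapply(1:3, function(i) evolve_jtt(a1, shallow)),
           lapply(1:3, function(i) evolve_jtt(a2, shallow)))
  names(aln) <- c("x1", "x2", "x3", "y1", "y2", "y3")
  lapply(aln, paste, collapse = "")
}

test_that("bootstrap support: range, determinism, separated clades", {
  aln <- make_two_clade_alignment()
  tr1 <- bootstrap_support(aln, replicates = 60, seed = 42)
  tr2 <- bootstrap_support(aln, replicates = 60, seed = 42)
  expect_identical(tr1$node.label, tr2$node.label)
  sup <- suppressWarnings(as.numeric(tr1$node.label))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
  # support of the bipartition separating the two planted clades
  node <- ape::getMRCA(tr1, c("x1", "x2", "x3"))
  xs <- ape::extract.clade(tr1, node)$tip.label
  if (setequal(xs, c("x1", "x2", "x3"))) {
    sep <- as.numeric(tr1$node.label[node - ape::Ntip(tr1)])
    expect_equal(sep, 100)
  }
  # single replicate gives all-or-nothing supports
  tr3 <- bootstrap_support(aln, replicates = 1, seed = 1)
  s3 <- suppressWarnings(as.numeric(tr3$node.label))
  expect_true(all(s3[!is.na(s3)] %in% c(0, 100)))
})

test_that("orthogroup cutting recovers planted partitions and handles stars", {
  aln <- make_two_clade_alignment(seed = 9)
  tr <- bootstrap_support(aln, replicates = 60, seed = 5)
  sp <- setNames(rep(c("s1", "s2", "s3"), 2), names(aln))
  cut <- cut_orthogroups(tr, sp, min_support = 50)
  expect_equal(length(cut$groups), 2)
  expect_setequal(vapply(cut$groups, paste, "", collapse = ","),
                  c("x1,x2,x3", "y1,y2,y3"))
  expect_length(cut$ungrouped, 0)
  # leaves are never assigned twice
  expect_equal(anyDuplicated(unlist(cut$groups)), 0)

  star <- ape::read.tree(text = "(a1:1,a2:1,(b1:1,b2:1)10:0.1);")
  sp2 <- setNames(c("s1", "s1", "s2", "s2"), c("a1", "a2", "b1", "b2"))
  cut2 <- cut_orthogroups(star, sp2, min_support = 50)
  expect_length(cut2$groups, 0)
  expect_setequal(cut2$ungrouped, names(sp2))

  # a whole family within per-species copy limits is a single orthogroup:
  # the seven-gene carbonic-anhydrase CA3 case (three wheat homoeologs)
  ca3 <- c("OsCA3", "SiCA3", "SbCA3", "ZmCA3", "TaCA3.3A", "TaCA3.3B",
           "TaCA3.3D")
  tr3 <- ape::read.tree(text = paste0(
    "(OsCA3:1,SiCA3:1,(SbCA3:1,(ZmCA3:1,(TaCA3.3A:1,",
    "(TaCA3.3B:1,TaCA3.3D:1)90:1)88:1)92:1)95:1);"))
  sp3 <- setNames(c("rice", "millet", "sorghum", "maize",
                    "wheat", "wheat", "wheat"), ca3)
  cut3 <- cut_orthogroups(tr3, sp3, min_support = 50,
                          max_copies = c(wheat = 3), default_copies = 1)
  expect_length(cut3$groups, 1)
  expect_setequal(cut3$groups[[1]], ca3)
  expect_error(cut_orthogroups(tr3, sp3[-1]), "missing labels")
})
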