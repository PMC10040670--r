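test_that("tandem detection links near-adjacent same-family genes", {
  # three adjacent copies (the TaCA5/6/7-7A pattern) form one array
  loci <- data.frame(gene_id = c("TaCA5.7A", "TaCA6.7A", "TaCA7.7A"),
                     chrom = "7A", rank = c(100, 101, 102))
  arr <- detect_tandem(loci)
  expect_length(arr, 1)
  expect_setequal(arr[[1]], loci$gene_id)
  # singleton
  expect_length(detect_tandem(loci[1, , drop = FALSE]), 0)
  # duplicate ids rejected
  expect_error(detect_tandem(rbind(loci, loci[1, ])), "duplicate")
  # rank gap above the threshold breaks the link
  far <- data.frame(gene_id = c("a", "b"), chrom = "1", rank = c(1, 8))
  expect_length(detect_tandem(far, max_intervening = 5), 0)
  expect_length(detect_tandem(far, max_intervening = 6), 1)
})

test_that("tandem detection matches the all-pairs brute-force oracle", {
  set.seed(13)
  for (rep in 1:10) {
    n <- 14
    loci <- data.frame(
      gene_id = sprintf("g%02d", 1:n),
      chrom = sample(c("c1", "c2"), n, replace = TRUE),
      rank = NA_integer_,
      family = sample(c("famA", "famB"), n, replace = TRUE))
    for (ch in unique(loci$chrom)) {
      k <- sum(loci$chrom == ch)
      loci$rank[loci$chrom == ch] <- sort(sample.int(40, k))
    }
    got <- detect_tandem(loci, max_intervening = 5)
    want <- oracle_tandem(loci, max_intervening = 5)
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(want, paste, "", collapse = ","))
    # arrays partition their members
    expect_equal(anyDuplicated(unlist(got)), 0)
    # relaxing the gap never splits an array
    wider <- detect_tandem(loci, max_intervening = 10)
    for (a in got) {
      holder <- Filter(function(w) all(a %in% w), wider)
      expect_length(holder, 1)
    }
  }
})

test_that("tandem summaries report the printed family fractions", {
  arr <- list(sprintf("r%02d", 1:30))
  s1 <- tandem_summary(sprintf("r%02d", 1:36), arr)
  expect_equal(s1$percent, 83.33)
  expect_equal(s1$n_tandem, 30)
  s2 <- tandem_summary(sprintf("c%02d", 1:34), list(sprintf("c%02d", 1:25)))
  expect_equal(s2$percent, 73.53)
  expect_equal(tandem_summary(letters[1:5], list())$percent, 0)
  expect_error(tandem_summary(character(0), list()), "empty")
})

test_that("promoter extraction respects strand and chromosome edges", {
  chrom <- paste(rep(c("A", "C", "G", "T"), 2500), collapse = "")
  genome <- c(chr1 = chrom)
  plus <- list(chrom = "chr1", start = 3000, end = 4000, strand = "+")
  p <- extract_promoter(genome, plus, length = 2000)
  expect_equal(nchar(p), 2000)
  expect_false(attr(p, "truncated"))
  expect_equal(as.character(p), substr(chrom, 1000, 2999))
  # round-trip: re-embedding reproduces the genome slice
  expect_equal(substr(chrom, 1000, 2999), as.character(p))

  minus <- list(chrom = "chr1", start = 3000, end = 4000, strand = "-")
  m <- extract_promoter(genome, minus, length = 100)
  expect_equal(as.character(m),
               c4ortho:::.revcomp(substr(chrom, 4001, 4100)))

  short <- list(chrom = "chr1", start = 500, end = 600, strand = "+")
  s <- extract_promoter(genome, short, length = 2000)
  expect_equal(nchar(s), 499)
  expect_true(attr(s, "truncated"))
  expect_error(extract_promoter(genome,
                                list(chrom = "chr1", start = 0, end = 10,
                                     strand = "+")), "bounds")
  expect_error(extract_promoter(genome,
                                list(chrom = "chrX", start = 1, end = 10,
                                     strand = "+")), "chromosome")
})

test_that("IUPAC scanning finds planted elements with correct offsets/bins", {
  bg <- paste(rep("A", 2000), collapse = "")
  # CCAAT planted so its 5' base sits 1500 bases upstream of the ATG
  substr(bg, 501, 505) <- "CCAAT"
  hits <- scan_elements(bg, builtin_elements()[1, , drop = FALSE], "g")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$offset, -1500L)
  expect_equal(hits$bin, "(-1001..-2000)")
  expect_equal(hits$match, "CCAAT")
  # the C(C/A)AAT consensus also matches CAAAT
  bg2 <- paste(rep("G", 100), collapse = "")
  substr(bg2, 96, 100) <- "CAAAT"
  h2 <- scan_elements(bg2, builtin_elements()[1, , drop = FALSE])
  expect_equal(h2$offset, -5L)
  expect_equal(h2$bin, "(-1..-1000)")
  # reverse-strand hit: ATTGG on the + strand is CCAAT on the - strand
  bg3 <- paste(rep("G", 100), collapse = "")
  substr(bg3, 11, 15) <- "ATTGG"
  h3 <- scan_elements(bg3, builtin_elements()[1, , drop = FALSE])
  expect_equal(h3$strand, "-")
  expect_equal(h3$offset, -90L)
  # N never matches
  bg4 <- paste(rep("N", 50), collapse = "")
  expect_equal(nrow(scan_elements(bg4, builtin_elements())), 0)
  expect_error(scan_elements("ACGTQ", builtin_elements()), "non-ACGTN")
  expect_error(scan_elements("ACGT", data.frame(element = "bad",
                                                pattern = "AZT",
                                                strand_policy = "both")),
               "IUPAC")
})

test_that("scanner matches the sliding-window oracle, overlaps included", {
  set.seed(21)
  defs <- builtin_elements()
  for (rep in 1:5) {
    prom <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                  collapse = "")
    hits <- scan_elements(prom, defs)
    for (i in seq_len(nrow(defs))) {
      want <- oracle_scan(prom, defs$pattern[i])
      got <- sort(hits$offset[hits$element == defs$element[i]] +
                    nchar(prom) + 1)
      expect_equal(got, want)
    }
  }
  # overlapping occurrences are all reported
  tandem_tata <- "TATATATATA"
  h <- scan_elements(tandem_tata,
                     data.frame(element = "TATA-box", pattern = "TATAWA",
                                strand_policy = "both"))
  expect_equal(sort(h$offset + nchar(tandem_tata) + 1),
               oracle_scan(tandem_tata, "TATAWA"))
})

test_that("promoters built to a plan contain exactly the planted content", {
  set.seed(2)
  plan <- data.frame(element = c("CAAT-box", "ABRE"),
                     bin = c("(-1001..-2000)", "(-1..-1000)"),
                     n = c(3L, 2L))
  prom <- make_promoter(plan)
  hits <- scan_elements(prom)
  expect_equal(nrow(hits), 5)
  expect_equal(sum(hits$element == "CAAT-box" &
                     hits$bin == "(-1001..-2000)"), 3)
  expect_equal(sum(hits$element == "ABRE" & hits$bin == "(-1..-1000)"), 2)
})

test_that("element-count comparison is a deterministic descriptive table", {
  set.seed(6)
  mk <- function(gene, n_distal) {
    prom <- make_promoter(data.frame(element = "CAAT-box",
                                     bin = "(-1001..-2000)", n = n_distal))
    scan_elements(prom, gene_id = gene)
  }
  a <- do.call(rbind, lapply(c("a1", "a2"), mk, n_distal = 4L))
  b <- do.call(rbind, lapply(c("b1", "b2"), mk, n_distal = 2L))
  tab <- compare_element_counts(a, b, c("a1", "a2"), c("b1", "b2"))
  row <- tab[tab$element == "CAAT-box" & tab$bin == "(-1001..-2000)", ]
  expect_equal(row$mean_a, 4)
  expect_equal(row$mean_b, 2)
  expect_gt(row$mean_a, row$mean_b)
  same <- compare_element_counts(a, a, c("a1", "a2"), c("a1", "a2"))
  expect_equal(same$mean_a, same$mean_b)
  empty <- compare_element_counts(a[0, ], b[0, ], "a1", "b1")
  expect_equal(nrow(empty), 0)
  expect_error(compare_element_counts(a, b, character(0), "b1"),
               "non-empty")
})
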