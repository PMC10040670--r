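blast_line <- function(q, s, id, ev) {
  sprintf("%s\t%s\t%.2f\t100\t5\t0\t1\t100\t1\t100\t%s\t180.0", q, s, id, ev)
}

dom_line <- function(g, acc) {
  sprintf(paste0("%s -          120 prof %s.3 120 1e-40 500.0 0.1 1 1 ",
                 "1e-42 1e-41 400.0 0.1 1 120 1 120 1 120 0.95"), g, acc)
}

test_that("BLAST tabular round-trips and rejects malformed rows", {
  d <- local_tmpdir()
  p <- file.path(d, "hits.tsv")
  writeLines(c(blast_line("ref", "g1", 85.00, "1e-30"),
               blast_line("ref", "g2", 61.25, "2.5e-08")), p)
  hits <- read_blast_tabular(p)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$percent_identity, c(85.00, 61.25))
  expect_equal(hits$evalue, c(1e-30, 2.5e-08))
  expect_equal(hits$subject_id, c("g1", "g2"))

  writeLines(character(0), p)
  expect_equal(nrow(read_blast_tabular(p)), 0)

  writeLines(c(blast_line("ref", "g1", 85, "1e-30"), "ref\tg2\tbroken"), p)
  expect_error(read_blast_tabular(p), "line")
  writeLines(blast_line("ref", "g1", 85, "not-a-number"), p)
  expect_error(read_blast_tabular(p), "evalue")
  expect_error(read_blast_tabular(file.path(d, "absent.tsv")), "not found")
})

test_that("HMMER domtblout parsing skips comments and strips versions", {
  d <- local_tmpdir()
  p <- file.path(d, "dom.txt")
  writeLines(c("# comment 1", "# comment 2", "#", dom_line("g1", "PF02896")),
             p)
  doms <- read_hmmer_domtbl(p)
  expect_equal(nrow(doms), 1)
  expect_equal(doms$gene_id, "g1")
  expect_equal(doms$domain_accession, "PF02896")
  expect_equal(doms$domain_evalue, 1e-41)
  expect_equal(doms$env_from, 1L)
  expect_equal(doms$env_to, 120L)

  writeLines(c("# only comments"), p)
  expect_equal(nrow(read_hmmer_domtbl(p)), 0)

  writeLines("g1 - 120 truncated", p)
  expect_error(read_hmmer_domtbl(p), "truncated")
})

test_that("family specs carry the required screening domains", {
  ppdk <- family_spec("PPDK")
  expect_setequal(ppdk$required_domains, c("PF02896", "PF01326", "PF00391"))
  expect_equal(ppdk$evalue_max, 1e-5)
  expect_equal(ppdk$identity_min, 60)
  expect_equal(family_spec("RbcS")$required_domains, c("PF12338", "PF00101"))
  expect_error(family_spec("XYZ"), "unknown family")
})

test_that("a PPDK candidate missing one required domain is excluded", {
  spec <- family_spec("PPDK")
  hits <- read_blast_tabular({
    d <- local_tmpdir()
    p <- file.path(d, "b.tsv")
    writeLines(blast_line("ref", "cand", 80, "1e-30"), p)
    p
  })
  d <- local_tmpdir()
  p <- file.path(d, "d.txt")
  writeLines(c(dom_line("cand", "PF02896"), dom_line("cand", "PF01326")), p)
  doms <- read_hmmer_domtbl(p)
  expect_equal(screen_family(hits, doms, spec), character(0))
  writeLines(c(dom_line("cand", "PF02896"), dom_line("cand", "PF01326"),
               dom_line("cand", "PF00391")), p)
  expect_equal(screen_family(hits, read_hmmer_domtbl(p), spec), "cand")
})

test_that("threshold edges: E-value is strict, identity is inclusive", {
  spec <- family_spec("beta-CA")
  d <- local_tmpdir()
  pb <- file.path(d, "b.tsv"); pd <- file.path(d, "d.txt")
  writeLines(c(blast_line("ref", "at_evalue", 80, "1e-5"),
               blast_line("ref", "at_identity", 60, "1e-30"),
               blast_line("ref", "below_identity", 59.99, "1e-30")), pb)
  writeLines(vapply(c("at_evalue", "at_identity", "below_identity"),
                    dom_line, "", acc = "PF00484"), pd)
  got <- screen_family(read_blast_tabular(pb), read_hmmer_domtbl(pd), spec)
  expect_equal(got, "at_identity")
})

test_that("screening matches a brute-force filter and is idempotent/monotone", {
  spec <- family_spec("MDH")
  set.seed(11)
  d <- local_tmpdir()
  pb <- file.path(d, "b.tsv"); pd <- file.path(d, "d.txt")
  genes <- sprintf("g%02d", 1:10)
  planted <- c("g01", "g04", "g07", "g09")
  lines <- unlist(lapply(genes, function(g) {
    if (g %in% planted)
      blast_line("ref", g, runif(1, 65, 95), format(10^-runif(1, 10, 40)))
    else
      blast_line("ref", g, runif(1, 20, 55), format(10^-runif(1, 0, 4)))
  }))
  writeLines(lines, pb)
  writeLines(vapply(genes, dom_line, "", acc = "PF02866"), pd)
  hits <- read_blast_tabular(pb)
  doms <- read_hmmer_domtbl(pd)
  got <- screen_family(hits, doms, spec)
  expect_equal(got, sort(planted))
  expect_equal(got, oracle_screen(hits, doms, spec))
  # output is a subset of input and stable under re-screening
  expect_true(all(got %in% hits$subject_id))
  hits2 <- hits[hits$subject_id %in% got, ]
  expect_equal(screen_family(hits2, doms, spec), got)
  # tightening thresholds never adds genes
  tighter <- family_spec("MDH", evalue_max = 1e-20, identity_min = 80)
  expect_true(all(screen_family(hits, doms, tighter) %in% got))
  # no candidates
  expect_equal(screen_family(hits[0, ], doms, spec), character(0))
  # configuration error on empty domain set
  broken <- spec; broken$required_domains <- character(0)
  expect_error(screen_family(hits, doms, broken), "configuration")
})

test_that("manual curation overrides are applied after the filter", {
  spec <- family_spec("beta-CA")
  d <- local_tmpdir()
  pb <- file.path(d, "b.tsv"); pd <- file.path(d, "d.txt")
  writeLines(blast_line("ref", "good", 80, "1e-30"), pb)
  writeLines(dom_line("good", "PF00484"), pd)
  hits <- read_blast_tabular(pb); doms <- read_hmmer_domtbl(pd)
  expect_equal(screen_family(hits, doms, spec, include = "curated_in"),
               c("curated_in", "good"))
  expect_equal(screen_family(hits, doms, spec, exclude = "good"),
               character(0))
})
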