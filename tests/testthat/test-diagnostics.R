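test_that("flanking-region parsing expands ambiguity sets and drops insertions", {
  m <- parse_flank_table(data.frame(
    id = c("a", "b", "c"),
    sequence = c("CMQVWP(A/I)EG(N/G)", "CMQVWPIEGI", "CMQVWP(V/I)(D/E)G(K)I"),
    label = c("C4", "C3", "C3")))
  expect_equal(ncol(m$states), 10)
  expect_equal(m$states[1, 7], "A/I")
  expect_equal(m$states[1, 10], "G/N")
  expect_equal(m$states[3, 7], "I/V")
  expect_equal(m$states[3, 8], "D/E")
  expect_equal(m$states[3, 10], "I")   # "(K)" dropped as an insertion

  m2 <- parse_flank_table(data.frame(id = "z", sequence = "AAAA",
                                     label = "C3"))
  expect_equal(dim(m2$states), c(1, 4))
  expect_true(all(m2$states == "A"))

  expect_error(parse_flank_table(data.frame(
    id = c("a", "b"), sequence = c("ACDEF", "ACD"),
    label = c("C3", "C4"))), "columns")
  expect_error(parse_flank_table(data.frame(
    id = "a", sequence = "AC(DE", label = "C3")), "parentheses")
  expect_error(parse_flank_table(data.frame(
    id = "a", sequence = "AC1DE", label = "C3")), "non-residue")
  expect_error(parse_flank_table(data.frame(
    id = "a", sequence = "ACDEF", label = "C5")), "label")
})

test_that("perfect discrimination requires disjoint state unions", {
  m <- parse_flank_table(data.frame(
    id = c("c4a", "c4b", "c3a", "c3b"),
    sequence = c("AN", "A(N/G)", "AI", "AI"),
    label = c("C4", "C4", "C3", "C3")))
  expect_equal(find_discriminating_columns(m), 2L)

  same <- parse_flank_table(data.frame(
    id = c("a", "b"), sequence = c("AC", "AC"), label = c("C4", "C3")))
  expect_equal(find_discriminating_columns(same), integer(0))

  only_c4 <- parse_flank_table(data.frame(
    id = "a", sequence = "AC", label = "C4"))
  expect_error(find_discriminating_columns(only_c4), "C3")

  # unknown residues expand to all states and can never look diagnostic
  withX <- parse_flank_table(data.frame(
    id = c("a", "b"), sequence = c("XN", "AI"), label = c("C4", "C3")))
  expect_equal(find_discriminating_columns(withX), 2L)
})

test_that("the transcribed RbcS table yields exactly the reported site", {
  t4 <- load_paper_fixture("table4")
  expect_equal(length(t4$region2$ids), 39)
  expect_equal(sum(t4$region2$labels == "C4"), 7)
  expect_equal(ncol(t4$region1$states), 11)
  expect_equal(ncol(t4$region2$states), 10)
  # second region: one strictly discriminating column, the bolded 10th
  expect_equal(find_discriminating_columns(t4$region2), 10L)
  # first region: the bolded column shares G between C3 and C4 rows
  expect_equal(find_discriminating_columns(t4$region1), integer(0))
})

test_that("graded ranking agrees with perfect discrimination and brute force", {
  t4 <- load_paper_fixture("table4")
  r <- rank_columns_by_discrimination(t4$region2)
  perfect <- find_discriminating_columns(t4$region2)
  expect_setequal(r$column[r$score == 1], perfect)
  expect_equal(r$column[1], 10)

  t5 <- load_paper_fixture("table5")
  expect_equal(length(t5$region$ids), 65)
  expect_equal(sum(t5$region$labels == "facultative"), 1)
  r5 <- rank_columns_by_discrimination(t5$region)
  # brute-force oracle over all columns and all single-state rules
  keep <- t5$region$labels != "facultative"
  labs <- t5$region$labels[keep]
  oracle_score <- vapply(seq_len(ncol(t5$region$states)), function(col) {
    sets <- lapply(t5$region$states[keep, col], function(s) {
      st <- strsplit(s, "/")[[1]]
      if ("X" %in% st) c4ortho:::AA20 else st
    })
    max(vapply(c4ortho:::AA20, function(s) {
      pred <- vapply(sets, function(x) s %in% x, logical(1))
      mean((pred & labs == "C4") | (!pred & labs == "C3"))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(r5$score, sort(oracle_score, decreasing = TRUE))
  # the reported site (9th position of the printed region) ranks first,
  # below a perfect score: some species break the rule
  expect_equal(r5$column[1], 9)
  expect_lt(r5$score[1], 1)
  expect_equal(find_discriminating_columns(t5$region), integer(0))

  # identical columns tie and fall back to index order
  tie <- parse_flank_table(data.frame(
    id = c("a", "b"), sequence = c("NN", "II"), label = c("C4", "C3")))
  rt <- rank_columns_by_discrimination(tie)
  expect_equal(rt$column, c(1, 2))
  expect_equal(rt$score, c(1, 1))
})

test_that("row addition shrinks the perfect set; label shuffling destroys it", {
  t4 <- load_paper_fixture("table4")
  base <- t4$raw
  perfect_full <- find_discriminating_columns(t4$region2)
  sub <- base[c(1:7, 8:20), ]
  msub <- parse_flank_table(data.frame(id = sub$species,
                                       sequence = sub$region2,
                                       label = sub$ptype))
  expect_true(all(perfect_full %in% find_discriminating_columns(msub)))
  set.seed(99)
  destroyed <- 0
  for (i in 1:20) {
    shuffled <- parse_flank_table(data.frame(
      id = base$species, sequence = base$region2,
      label = sample(base$ptype)))
    if (length(find_discriminating_columns(shuffled)) == 0)
      destroyed <- destroyed + 1
  }
  expect_gt(destroyed, 15)
})

test_that("known-site checks classify mapped residues and handle deletions", {
  sites <- known_diagnostic_sites()
  expect_true(all(vapply(seq_len(nrow(sites)), function(i)
    length(intersect(strsplit(sites$c4_states[i], "/")[[1]],
                     strsplit(sites$c3_states[i], "/")[[1]])) == 0,
    logical(1))))

  seq <- paste(rep("A", 100), collapse = "")
  substr(seq, 50, 50) <- "S"
  map <- data.frame(ref_pos = 780, query_pos = 50)
  ser <- sites[sites$site_id == "PEPC_Ser780", ]
  rep1 <- check_known_sites(seq, map, ser)
  expect_equal(rep1$call, "C4-state")

  substr(seq, 50, 50) <- "G"
  mdh <- sites[sites$site_id == "MDH_coenzyme_43", ]
  rep2 <- check_known_sites(seq, data.frame(ref_pos = 43, query_pos = 50), mdh)
  expect_equal(rep2$call, "C4-state")   # G = NADP-dependent, the C4 state

  # deletion covering the site -> unalignable
  rep3 <- check_known_sites(seq, data.frame(ref_pos = 1, query_pos = 1), mdh)
  expect_equal(rep3$call, "unalignable")
  expect_error(check_known_sites(seq, map, ser, reference_length = 100),
               "configuration")
})
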