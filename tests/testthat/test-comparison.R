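test_that("similarity score reproduces the four-protein worked example", {
  s <- similarity_score(data.frame(
    query_length = c(545, 393, 130, 75),
    identity = c(0.9853, 0.9975, 1, 1)))
  expect_equal(round(s, 4), 0.9921)
})

test_that("similarity score degenerate and single cases", {
  expect_equal(similarity_score(data.frame(query_length = c(10, 20),
                                           identity = c(1, 1))), 1)
  expect_equal(similarity_score(data.frame(query_length = c(10, 20),
                                           identity = c(0, 0))), 0)
  expect_equal(similarity_score(data.frame(query_length = 100,
                                           identity = 0.95)), 0.95)
  expect_error(similarity_score(data.frame(query_length = numeric(0),
                                           identity = numeric(0))),
               "at least one protein")
  expect_error(similarity_score(data.frame(query_length = 10,
                                           identity = 1.2)), "\\[0, 1\\]")
})

test_that("similarity is bounded by the extreme per-protein identities", {
  set.seed(71)
  for (i in 1:20) {
    n <- sample(1:10, 1)
    m <- data.frame(query_length = sample(50:500, n, replace = TRUE),
                    identity = runif(n))
    s <- similarity_score(m)
    expect_gte(s, min(m$identity))
    expect_lte(s, max(m$identity))
  }
})

test_that("size heuristic follows the 10000-vs-1000 example", {
  expect_false(size_heuristic(10000, 1000))  # 10000 * 0.9 > 1000: skip
  expect_true(size_heuristic(1000, 10000))   # the reverse is performed
  expect_true(size_heuristic(500, 500))      # equal counts: both directions
})

test_that("size heuristic is monotone in the subject count", {
  set.seed(81)
  for (i in 1:50) {
    q <- sample(1:5000, 1)
    s <- sample(1:5000, 1)
    if (size_heuristic(q, s)) expect_true(size_heuristic(q, s + 1))
  }
})

test_that("species grouping partitions the proteome set", {
  ps <- c(
    lapply(1:3, function(i) generate_base_proteome(
      2, c(40, 60), seed = i, proteome_id = paste0("a", i),
      species_group_id = "sp1")),
    lapply(1:2, function(i) generate_base_proteome(
      2, c(40, 60), seed = 10 + i, proteome_id = paste0("b", i),
      species_group_id = "sp2")))
  g <- group_by_species(ps)
  expect_equal(lengths(g), c(sp1 = 3L, sp2 = 2L))
  expect_setequal(unlist(g), vapply(ps, `[[`, character(1), "proteome_id"))
})

test_that("identical proteomes score 1 in both directions", {
  a <- generate_base_proteome(5, c(60, 150), seed = 91, proteome_id = "A",
                              species_group_id = "g")
  b <- a; b$proteome_id <- "B"
  cmp <- compare_group(list(a, b))
  expect_equal(nrow(cmp), 2)
  expect_true(all(cmp$performed))
  expect_equal(cmp$similarity, c(1, 1))
})

test_that("an exact sub-proteome demonstrates non-symmetry", {
  a <- generate_base_proteome(10, c(60, 150), seed = 92, proteome_id = "A",
                              species_group_id = "g")
  b <- a
  b$proteome_id <- "B"
  b$proteins <- b$proteins[1:4, ]  # B is a strict subset of A
  # S(A, B) = 1: every B protein matches its copy in A
  expect_equal(compare_proteomes(a, b), 1)
  # in the group, the B-as-query direction is performed and scores 1;
  # the reverse is either skipped by the size heuristic or scores < 1
  cmp <- compare_group(list(a, b))
  fwd <- cmp[cmp$subject_id == "A", ]
  rev <- cmp[cmp$subject_id == "B", ]
  expect_equal(fwd$similarity, 1)
  expect_true(!rev$performed || rev$similarity < 1)
})

test_that("self-comparison scores exactly 1", {
  a <- generate_base_proteome(6, c(50, 120), seed = 93, proteome_id = "A")
  expect_identical(compare_proteomes(a, a), 1)
})

test_that("an engineered strain pair reproduces the worked-example score", {
  # lengths 545/393/130/75; substitute 8 of 545 and 1 of 393 residues with
  # a residue absent from both sequences, so the per-protein identities are
  # exactly 537/545 and 392/393 (0.9853 and 0.9975 to 4 decimals)
  set.seed(94)
  aa19 <- setdiff(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                    "K", "M", "F", "P", "S", "T", "Y", "V", "W"), "W")
  seqs_a <- vapply(c(545, 393, 130, 75), function(L) {
    paste(sample(aa19, L, replace = TRUE), collapse = "")
  }, character(1))
  seqs_b <- c(substitute_positions(seqs_a[1], 8, replacement = "W"),
              substitute_positions(seqs_a[2], 1, replacement = "W"),
              seqs_a[3], seqs_a[4])
  a <- toy_proteome("A", seqs_a)
  b <- toy_proteome("B", seqs_b)
  cmp <- compare_group(list(a, b))
  s_ab <- cmp$similarity[cmp$subject_id == "A"]
  # oracle: the score formula applied to the exact per-protein identities
  expected <- similarity_score(data.frame(
    query_length = c(545, 393, 130, 75),
    identity = c(537 / 545, 392 / 393, 1, 1)))
  expect_equal(s_ab, expected)
  expect_equal(round(s_ab, 4), 0.9921)
})

test_that("duplicating an already-matched protein never lowers the score", {
  a <- generate_base_proteome(5, c(60, 120), seed = 95, proteome_id = "A",
                              species_group_id = "g")
  b <- mutate_strain(a, 0.02, seed = 96, proteome_id = "B")
  s0 <- compare_proteomes(a, b)
  b2 <- b
  matched <- b2$proteins[1, ]
  matched$protein_id <- "dup_copy"
  # replace the duplicate with an exact copy of an A protein (identity 1)
  matched$sequence <- a$proteins$sequence[1]
  matched$length <- a$proteins$length[1]
  b2$proteins <- rbind(b2$proteins, matched)
  expect_gte(compare_proteomes(a, b2), s0)
})

test_that("compare_group refuses mixed species groups", {
  a <- generate_base_proteome(2, c(40, 60), seed = 97, proteome_id = "A",
                              species_group_id = "g1")
  b <- generate_base_proteome(2, c(40, 60), seed = 98, proteome_id = "B",
                              species_group_id = "g2")
  expect_error(compare_group(list(a, b)), "single species group")
})
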