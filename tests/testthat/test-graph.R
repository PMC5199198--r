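test_that("graph building applies the edge threshold", {
  md <- toy_metadata(c("A", "B", "C"))
  cmp <- tibble::tibble(
    subject_id = c("A", "A"), query_id = c("B", "C"),
    similarity = c(0.95, 0.89), performed = TRUE)
  g <- build_graph(cmp, md)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$from, "B")
  expect_equal(g$edges$to, "A")
})

test_that("mutual similarity yields a 2-cycle and no comparisons yield isolated nodes", {
  md <- toy_metadata(c("A", "B"))
  cmp <- tibble::tibble(subject_id = c("A", "B"), query_id = c("B", "A"),
                        similarity = 0.99, performed = TRUE)
  g <- build_graph(cmp, md)
  expect_equal(nrow(g$edges), 2)

  md3 <- toy_metadata(c("A", "B", "C"))
  empty <- tibble::tibble(subject_id = character(0), query_id = character(0),
                          similarity = numeric(0), performed = logical(0))
  g3 <- build_graph(empty, md3)
  expect_equal(nrow(g3$edges), 0)
  expect_equal(nrow(g3$nodes), 3)
})

test_that("a similarity of exactly the threshold makes an edge", {
  md <- toy_metadata(c("A", "B"))
  cmp <- tibble::tibble(subject_id = "A", query_id = "B",
                        similarity = 0.3 * 3, performed = TRUE)
  g <- build_graph(cmp, md)
  expect_equal(nrow(g$edges), 1)
})

test_that("comparisons about unknown proteomes are rejected", {
  md <- toy_metadata("A")
  cmp <- tibble::tibble(subject_id = "A", query_id = "Z",
                        similarity = 0.95, performed = TRUE)
  expect_error(build_graph(cmp, md), "absent from metadata")
})

test_that("rank vectors count degrees on the surviving subgraph", {
  md <- toy_metadata("A", is_reference = TRUE, annotation_level = 100L)
  g <- toy_graph(data.frame(from = character(0), to = character(0)),
                 metadata = md)
  st <- new_reduction_state(g)
  expect_equal(unname(rank_vector(g, st, "A")), c(0, 0, 2, 100, 1))

  # star: X, Y each pointed at by three leaves; X also points at Y
  edges <- data.frame(
    from = c("L1", "L2", "L3", "L1", "L2", "L3", "X"),
    to = c("X", "X", "X", "Y", "Y", "Y", "Y"))
  g2 <- toy_graph(edges)
  st2 <- new_reduction_state(g2)
  expect_equal(rank_vector(g2, st2, "Y")[["indegree"]], 4)
  st2 <- remove_node(g2, st2, "L1")
  expect_equal(rank_vector(g2, st2, "Y")[["indegree"]], 3)
  expect_equal(rank_vector(g2, st2, "X")[["indegree"]], 2)
  expect_error(rank_vector(g2, st2, "L1"), "not in the surviving set")
})

test_that("rank comparison reproduces the five printed ranking examples", {
  pairs <- list(
    list(a = c(4, 5, 1, 0, 1), b = c(5, 4, 1, 0, 1)),
    list(a = c(0, 5, 1, 0, 1), b = c(0, 3, 1, 0, 1)),
    list(a = c(5, 2, 1, 0, 1), b = c(6, 1, 1, 0, 1)),
    list(a = c(5, 2, 1, 0, 1), b = c(5, 2, 2, 0, 1)),
    list(a = c(5, 2, 1, 105, 1), b = c(5, 2, 2, 200, 1)))
  for (p in pairs) {
    expect_equal(compare_rank(p$a, p$b), "b-higher")
    expect_equal(compare_rank(p$b, p$a), "a-higher")
  }
  expect_equal(compare_rank(c(4, 5, 1, 0, 1), c(4, 5, 1, 0, 1)), "tie")
})

test_that("rank comparison is a complete, transitive, antisymmetric preorder", {
  set.seed(101)
  vecs <- replicate(40, c(sample(0:6, 2, replace = TRUE), sample(1:2, 1),
                          sample(0:300, 1), sample(0:1, 1)),
                    simplify = FALSE)
  for (i in 1:60) {
    a <- vecs[[sample(40, 1)]]; b <- vecs[[sample(40, 1)]]
    c_ <- vecs[[sample(40, 1)]]
    ab <- compare_rank(a, b)
    expect_true(ab %in% c("a-higher", "b-higher", "tie"))
    # antisymmetry
    ba <- compare_rank(b, a)
    expect_equal(ba, switch(ab, "a-higher" = "b-higher",
                            "b-higher" = "a-higher", "tie" = "tie"))
    # transitivity of "not lower"
    if (ab != "b-higher" && compare_rank(b, c_) != "b-higher") {
      expect_true(compare_rank(a, c_) != "b-higher")
    }
  }
})

test_that("removability respects protection, domination and out-edges", {
  g <- toy_graph(data.frame(from = c("A", "A"), to = c("B", "C")))
  st <- new_reduction_state(g, protected = "A")
  expect_false(is_removable(g, st, "A"))     # protected
  expect_false(is_removable(g, st, "B"))     # no out-edge: nothing represents it

  st2 <- new_reduction_state(g)
  expect_true(is_removable(g, st2, "A"))
  st2 <- remove_node(g, st2, "A")
  # B and C are each now droppable only while the other still covers A;
  # neither has out-edges, so neither is removable at all
  expect_false(is_removable(g, st2, "B"))

  chain <- toy_graph(data.frame(from = c("X", "Y"), to = c("Y", "Z")))
  st3 <- new_reduction_state(chain)
  st3 <- remove_node(chain, st3, "X")
  # Y is X's last surviving neighbour: removing it would strand X
  expect_false(is_removable(chain, st3, "Y"))
})

test_that("node removal records representatives via original direct edges", {
  g <- toy_graph(data.frame(from = c("A", "A"), to = c("B", "C")))
  st <- new_reduction_state(g)
  st <- remove_node(g, st, "A")
  expect_setequal(st$surviving_neighbours[["A"]], c("B", "C"))
  expect_equal(st$represented[["B"]], "A")
  expect_equal(st$represented[["C"]], "A")
  expect_error(remove_node(g, st, "B"), "not removable")

  # removing a node that inherited a represented set: its own represented
  # members keep their original surviving_neighbours entries
  g2 <- toy_graph(data.frame(from = c("A", "A", "B"),
                             to = c("B", "C", "C")))
  st2 <- new_reduction_state(g2)
  st2 <- remove_node(g2, st2, "A")   # represented by B and C
  st2 <- remove_node(g2, st2, "B")   # B itself represented A
  expect_equal(st2$surviving_neighbours[["A"]], "C")  # A's own direct edge
  expect_equal(st2$surviving_neighbours[["B"]], "C")
  expect_equal(sort(st2$represented[["C"]]), c("A", "B"))
})

test_that("weakest selection follows rank, then represented size, then seed", {
  # mutual 2-cycle, annotation 105 vs 200: the 105 node is weaker
  md <- toy_metadata(c("A", "B"), annotation_level = c(105L, 200L))
  g <- toy_graph(data.frame(from = c("A", "B"), to = c("B", "A")),
                 metadata = md)
  st <- new_reduction_state(g)
  expect_equal(
    unname(c(compare_rank(rank_vector(g, st, "A"), rank_vector(g, st, "B")))),
    "b-higher")
  expect_equal(select_weakest(g, st), "A")

  # all nodes protected: nothing to select
  stp <- new_reduction_state(g, protected = c("A", "B"))
  expect_null(select_weakest(g, stp))

  # fully tied pair: the seeded choice is repeatable
  md2 <- toy_metadata(c("A", "B"))
  g2 <- toy_graph(data.frame(from = c("A", "B"), to = c("B", "A")),
                  metadata = md2)
  st2 <- new_reduction_state(g2)
  picks <- vapply(1:5, function(i) {
    set.seed(123)
    select_weakest(g2, st2)
  }, character(1))
  expect_equal(length(unique(picks)), 1)
})
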