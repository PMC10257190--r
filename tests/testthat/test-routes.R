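test_that("route extraction follows proven reactions and fails honestly", {
  # block target: empty route, success
  tr <- plan("A", toy_universe("A"), NULL, planner_config(iter_limit = 5))
  r <- extract_route(tr)
  expect_true(r$success)
  expect_identical(route_length(r), 0L)
  expect_true(route_is_valid(r, "A"))

  # one proven step: all reactants in the blocks
  u <- toy_universe(c("A", "B"), list(tmpl("X", "T1", 0.8, c("A", "B"))))
  tr1 <- plan("X", u, NULL, planner_config(iter_limit = 5, seed = 1))
  r1 <- extract_route(tr1)
  expect_true(r1$success)
  expect_identical(route_length(r1), 1L)
  expect_setequal(r1$steps$reactants[[1]], c("A", "B"))
  expect_true(route_replays(r1, u))

  # unproven root: failure with an empty reaction list
  u2 <- toy_universe("A", list(tmpl("X", "T1", 0.5, "D")))
  tr2 <- plan("X", u2, NULL, planner_config(iter_limit = 5, seed = 1))
  expect_false(tr2$root$status == "proven")
  r2 <- extract_route(tr2)
  expect_false(r2$success)
  expect_identical(route_length(r2), 0L)
})

test_that("extraction succeeds iff the root is proven, and routes obey invariants", {
  lens_ok <- TRUE
  for (seed in 1:25) {
    u <- generate_universe(4, 12, unsolvable_fraction = 0.3, seed = seed)
    target <- utils::tail(u$molecules, 1)
    tr <- plan(target, u, NULL, planner_config(iter_limit = 300, seed = seed))
    r <- extract_route(tr)
    expect_identical(r$success, tr$root$status == "proven",
                     label = sprintf("success iff proven, seed %d", seed))
    if (r$success) {
      expect_true(route_is_valid(r, u$blocks), label = sprintf("valid, seed %d", seed))
      expect_true(route_replays(r, u), label = sprintf("replays, seed %d", seed))
      # the oracle-minimal route is never longer than the extracted one
      # (extraction synthesizes each intermediate once, so the bound is the
      # smallest possible synthesis set)
      lens_ok <- lens_ok && (oracle_min_route_size(u, target) <= route_length(r))
    }
  }
  expect_true(lens_ok)
})

test_that("matching degree counts ordered shared steps", {
  g <- make_route("X",
                  products = c("X", "Y", "Z", "W"),
                  reactants = list(c("Y", "b1"), c("Z", "b2"), c("W", "b3"), "b4"))
  # identical routes match fully
  expect_equal(matching_degree(g, g), 1)
  # disjoint step sets match nowhere
  d <- make_route("X", products = c("P", "Q"),
                  reactants = list("b1", "b2"))
  expect_equal(matching_degree(g, d), 0)
  # three of four generated steps appear, in order, in the published route
  pub <- make_route("X",
                    products = c("X", "Y", "E", "W"),
                    reactants = list(c("Y", "b1"), c("Z", "b2"), "b9", "b4"))
  expect_equal(matching_degree(g, pub), 0.75)
  # ordered-but-not-consecutive occurrences still count
  pub2 <- make_route("X",
                     products = c("X", "E1", "Y", "E2", "Z", "W"),
                     reactants = list(c("Y", "b1"), "e", c("Z", "b2"), "e",
                                      c("W", "b3"), "b4"))
  expect_equal(matching_degree(g, pub2), 1)
  # duplicated by-products change nothing on either side
  g_dup <- make_route("X",
                      products = c("X", "Y", "Z", "W"),
                      reactants = list(c("Y", "b1", "b1"), c("Z", "b2", "b2"),
                                       c("W", "b3"), "b4"))
  expect_equal(matching_degree(g_dup, pub), 0.75)
  expect_error(matching_degree(make_route("X", character(0), list()), g),
               class = "egmcts_argument_error")
})

test_that("out-of-order steps do not match", {
  ab <- make_route("X", c("A", "B"), list("b1", "b2"))
  ba <- make_route("X", c("B", "A"), list("b2", "b1"))
  expect_equal(matching_degree(ab, ba), 0.5)   # only one step can keep order
})

test_that("similarity statistics agree with a double-loop oracle", {
  test_set <- sprintf("M%02d", 1:5)
  train_set <- c(sprintf("N%02d", 1:4), "M03")
  s <- similarity_stats(test_set, train_set)

  for (i in seq_along(test_set)) {
    sims <- vapply(train_set, function(t) {
      tanimoto(fingerprint_bits(test_set[i]), fingerprint_bits(t))
    }, numeric(1))
    expect_equal(s$per_molecule$s_max[i], max(sims))
    expect_equal(s$per_molecule$s_avg[i], mean(sims))
  }
  # a test molecule present in the training set has maximal self-similarity
  expect_equal(s$per_molecule$s_max[test_set == "M03"], 1)
  # a single-molecule training set collapses max and mean
  s1 <- similarity_stats(test_set, "N01")
  expect_equal(s1$per_molecule$s_max, s1$per_molecule$s_avg)
  expect_error(similarity_stats(character(0), train_set),
               class = "egmcts_argument_error")
})
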