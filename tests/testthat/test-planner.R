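test_that("the PUCT score reproduces hand-evaluated cases", {
  # Q/N + c P sqrt(N') / (1 + N) with the stated inputs
  expect_equal(puct_score(0.6, 1, 0.5, c = 0.5, grandparent_n = 4), 0.85)
  # fresh node: exploitation divisor floored at 1, exploration term vanishes
  expect_equal(puct_score(0.4, 0, 1.0, c = 0.5, grandparent_n = 0), 0.4)
  # degenerate exploration: ranking by q_bar / max(N, 1) alone
  qs <- c(0.9, 0.3, 0.7); ns <- c(3, 0, 1)
  s <- mapply(puct_score, qs, ns, 0.5, c = 1e-12, grandparent_n = 10)
  expect_identical(order(s), order(qs / pmax(ns, 1)))
  # the conventional reading keeps q_bar undivided
  expect_equal(puct_score(0.6, 3, 0, c = 0.5, grandparent_n = 0,
                          exploitation = "plain"), 0.6)
})

test_that("selection follows argmax at molecule nodes and priority rules at reaction nodes", {
  # two templates whose q_bar values differ; tiny c isolates the argmax
  cfg <- planner_config(c = 1e-9, iter_limit = 10, seed = 1)
  u2 <- toy_universe(c("A", "B"), list(
    tmpl("X", "T1", 0.3, "M1"),
    tmpl("X", "T2", 0.3, "M2"),
    tmpl("M1", "T3", 0.4, "A"),
    tmpl("M2", "T4", 0.4, "B")
  ))
  tr <- init_tree("X", blocks = u2)
  expand(tr$root, u2, NULL, cfg, tr)
  update_tree(tr, tr$root, cfg)
  tr$root$children[[1]]$q_bar <- 0.7
  tr$root$children[[2]]$q_bar <- 0.2
  leaf <- withr::with_seed(1, select_leaf(tr, cfg))
  expect_identical(leaf$molecule,
                   tr$root$children[[1]]$children[[1]]$molecule)

  # reaction node with one proven (block) and one unexpanded child: the
  # unexpanded child is chosen with probability 1
  u3 <- toy_universe("A", list(
    tmpl("X", "T1", 0.5, c("A", "M1")),
    tmpl("M1", "T2", 0.4, "A")
  ))
  tr3 <- init_tree("X", blocks = u3)
  expand(tr3$root, u3, NULL, cfg, tr3)
  update_tree(tr3, tr3$root, cfg)
  for (s in 1:10) {
    leaf <- withr::with_seed(s, select_leaf(tr3, cfg))
    expect_identical(leaf$molecule, "M1")
  }
})

test_that("expansion honours the empty, top-k and cycle-guard contracts", {
  cfg <- planner_config(k = 2, iter_limit = 10, seed = 1)
  # dead-end molecule: leaf disproven, no children
  u <- toy_universe("A", list(tmpl("X", "T1", 0.5, "D")))
  tr <- init_tree("X", blocks = u)
  expand(tr$root, u, NULL, cfg, tr)
  update_tree(tr, tr$root, cfg)
  leaf <- select_leaf(tr, cfg)          # the D node
  expect_identical(leaf$molecule, "D")
  n <- expand(leaf, u, NULL, cfg, tr)
  expect_identical(n, 0L)
  expect_identical(leaf$status, "disproven")
  expect_error(expand(leaf, u, NULL, cfg, tr), class = "egmcts_state_error")

  # three templates, k = 2: two children, each with q_bar equal to its q0
  u2 <- toy_universe("A", list(
    tmpl("X", "T1", 0.5, "A"), tmpl("X", "T2", 0.3, "A"),
    tmpl("X", "T3", 0.1, "A")
  ))
  tr2 <- init_tree("X", blocks = u2)
  expect_identical(expand(tr2$root, u2, NULL, cfg, tr2), 2L)
  for (ch in tr2$root$children) {
    expect_identical(ch$q_bar, ch$q0)
    expect_identical(ch$n_updates, 0L)
  }

  # a template regenerating an ancestor molecule is disproven at expansion
  u3 <- toy_universe("A", list(
    tmpl("X", "T1", 0.6, "Y"),
    tmpl("Y", "T2", 0.6, "X"),       # cycle back to the root molecule
    tmpl("Y", "T3", 0.3, "A")
  ))
  cfg3 <- planner_config(k = 50, iter_limit = 10, seed = 1)
  tr3 <- init_tree("X", blocks = u3)
  expand(tr3$root, u3, NULL, cfg3, tr3)
  y <- tr3$root$children[[1]]$children[[1]]
  expect_identical(expand(y, u3, NULL, cfg3, tr3), 2L)
  cyc <- Filter(function(r) r$template == "T2", y$children)[[1]]
  expect_identical(cyc$status, "disproven")
  expect_identical(cyc$children[[1]]$cycle_guard, TRUE)
})

test_that("the reward function matches the worked one-block-one-open case", {
  m <- egmcts:::new_molecule_node("L", FALSE)
  r <- egmcts:::new_reaction_node("T", 0.5, 0.5, m)
  r$children <- list(
    egmcts:::new_molecule_node("M", TRUE, r, 1),    # building block, V = 1
    egmcts:::new_molecule_node("N", FALSE, r, 1)    # unexpanded, V = 0
  )
  refresh_status(r)
  expect_identical(r$status, "open")
  expect_equal(reward_value(r, z = 10), 0.5)

  # all reactants in the blocks: +z; any disproven reactant: -z
  r$children[[2]]$is_block <- TRUE; r$children[[2]]$status <- "proven"
  refresh_status(r)
  expect_equal(reward_value(r, z = 10), 10)
  r$children[[2]]$is_block <- FALSE
  r$children[[2]]$expanded <- TRUE
  refresh_status(r$children[[2]])
  refresh_status(r)
  expect_equal(reward_value(r, z = 10), -10)
})

test_that("the update pass maintains the running-average and max equations", {
  cfg <- planner_config(iter_limit = 10, seed = 1)
  u <- toy_universe(c("A", "B"), list(
    tmpl("X", "T1", 0.5, c("A", "B")),
    tmpl("X", "T2", 0.2, "M1"),
    tmpl("M1", "T3", 0.4, "A")
  ))
  tr <- init_tree("X", blocks = u)
  expand(tr$root, u, NULL, cfg, tr)
  # hand-set q0 = 0.5 on the proven template, then run one update
  t1 <- tr$root$children[[1]]
  expect_identical(t1$status, "proven")
  update_tree(tr, tr$root, cfg)
  # first update: N = 1 although two terms are averaged (q0 not counted)
  expect_identical(t1$n_updates, 1L)
  expect_equal(t1$q_bar, (0.5 + 10) / 2)
  # molecule value takes the maximum child q_bar
  expect_equal(tr$root$value, 5.25)
  expect_identical(tr$root$status, "proven")
})

test_that("planning solves, refuses and bounds as the oracle dictates", {
  # block target: proven with zero iterations
  u1 <- toy_universe("A")
  tr <- plan("A", u1, NULL, planner_config(iter_limit = 5, seed = 1))
  expect_identical(tr$root$status, "proven")
  expect_identical(tr$iterations_used, 0L)

  # one-step universe: proven within one iteration
  u2 <- toy_universe(c("A", "B"), list(tmpl("X", "T1", 0.8, c("A", "B"))))
  tr2 <- plan("X", u2, NULL, planner_config(iter_limit = 5, seed = 1))
  expect_identical(tr2$root$status, "proven")
  expect_identical(tr2$iterations_used, 1L)

  # unsolvable target stays unproven within the budget
  u3 <- generate_universe(3, 6, unsolvable_fraction = 0.5, seed = 1)
  unsolv <- names(which(!u3$solvable))[1]
  expect_false(oracle_solvable(u3, unsolv))
  tr3 <- plan(unsolv, u3, NULL, planner_config(iter_limit = 50, seed = 2))
  expect_false(tr3$root$status == "proven")
  expect_lte(tr3$iterations_used, 50L)
})

test_that("planning is deterministic and monotone in the iteration budget", {
  u <- generate_universe(4, 14, unsolvable_fraction = 0.3, seed = 21)
  target <- utils::tail(u$molecules, 1)
  cfg <- planner_config(iter_limit = 80, seed = 5)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_tree(plan(target, u, NULL, cfg), f1)
  write_tree(plan(target, u, NULL, cfg), f2)
  expect_identical(readLines(f1), readLines(f2))

  # proven set is non-decreasing in the budget, per seed
  targets <- setdiff(u$molecules, u$blocks)
  proven_at <- function(limit) {
    vapply(targets, function(m) {
      cfg <- planner_config(iter_limit = limit, seed = 5)
      plan(m, u, NULL, cfg)$root$status == "proven"
    }, logical(1))
  }
  p20 <- proven_at(20); p100 <- proven_at(100)
  expect_true(all(p100[p20]))
})
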