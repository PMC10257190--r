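test_that("greedy depth-first search backtracks past misleading priors", {
  # block target: nothing to do
  r <- greedy_dfs("A", toy_universe("A"))
  expect_true(r$success)
  expect_identical(r$iterations, 0L)
  expect_identical(route_length(r$route), 0L)

  # the highest-probability template leads into a dead end; greedy must
  # backtrack and still solve via the lower-probability one-step template
  u <- toy_universe(c("A", "B"), list(
    tmpl("X", "Ttrap", 0.7, "D1"),     # D1 decomposes only into dead ends
    tmpl("X", "Tgood", 0.2, c("A", "B")),
    tmpl("D1", "TD", 0.5, "D2")        # D2 has no templates
  ))
  res <- greedy_dfs("X", u, max_depth = 10)
  expect_true(res$success)
  expect_identical(route_length(res$route), 1L)
  expect_identical(res$route$steps$template[1], "Tgood")
  expect_gt(res$iterations, 1L)        # wasted calls inside the trap

  # a route deeper than max_depth cannot be found
  u2 <- toy_universe("A", list(
    tmpl("X", "T1", 0.5, "Y"), tmpl("Y", "T2", 0.5, "Z"),
    tmpl("Z", "T3", 0.5, "A")
  ))
  expect_true(greedy_dfs("X", u2, max_depth = 3)$success)
  expect_false(greedy_dfs("X", u2, max_depth = 2)$success)

  # the iteration budget is honoured
  ub <- generate_universe(3, 10, unsolvable_fraction = 0.5, seed = 9)
  un <- names(which(!ub$solvable))[1]
  rb <- greedy_dfs(un, ub, iter_limit = 7)
  expect_false(rb$success)
  expect_lte(rb$iterations, 7L)
})

test_that("route-quality metrics count longest and shortest first-routes", {
  mk <- function(n) make_route("X", sprintf("P%d", seq_len(n)),
                               replicate(n, "b", simplify = FALSE))
  # identical routes everywhere: every molecule ties both ways
  fr <- list(a1 = list(m1 = mk(2), m2 = mk(3)),
             a2 = list(m1 = mk(2), m2 = mk(3)))
  q <- route_quality_metrics(fr)
  expect_identical(q$metrics$LRN, c(2L, 2L))
  expect_identical(q$metrics$SRN, c(2L, 2L))

  # lengths {3, 5}: the shorter route scores SRN, the longer LRN
  fr2 <- list(a1 = list(m1 = mk(3)), a2 = list(m1 = mk(5)))
  q2 <- route_quality_metrics(fr2)
  expect_identical(q2$metrics$SRN[q2$metrics$algorithm == "a1"], 1L)
  expect_identical(q2$metrics$LRN[q2$metrics$algorithm == "a2"], 1L)
  expect_equal(q2$metrics$avg_length, c(3, 5))

  # ten molecules, three algorithms: counts equal a brute-force scan, and
  # without ties the increments sum to the number of common molecules
  set.seed(8)
  lens <- matrix(sample(3:12, 30, TRUE), 10, 3)
  while (any(apply(lens, 1, function(r) anyDuplicated(r) > 0))) {
    lens <- matrix(sample(3:12, 30, TRUE), 10, 3)
  }
  fr3 <- lapply(1:3, function(a) {
    stats::setNames(lapply(1:10, function(m) mk(lens[m, a])),
                    sprintf("mol%d", 1:10))
  })
  names(fr3) <- sprintf("alg%d", 1:3)
  q3 <- route_quality_metrics(fr3)
  brute_lrn <- colSums(lens == apply(lens, 1, max))
  brute_srn <- colSums(lens == apply(lens, 1, min))
  expect_identical(q3$metrics$LRN, as.integer(brute_lrn))
  expect_identical(q3$metrics$SRN, as.integer(brute_srn))
  expect_identical(sum(q3$metrics$LRN), 10L)
  expect_identical(sum(q3$metrics$SRN), 10L)

  # unsolved molecules drop out of the common set
  fr4 <- list(a1 = list(m1 = mk(2), m2 = NULL), a2 = list(m1 = mk(2), m2 = mk(2)))
  expect_identical(route_quality_metrics(fr4)$common_molecules, "m1")
  expect_error(route_quality_metrics(fr4["a1"]), class = "egmcts_argument_error")
})

test_that("omniscient value guidance beats the constant initialization under plain exploitation", {
  # ground-truth Q0 (0.9 on templates whose reactants are all solvable,
  # 0.1 otherwise) must help the search under the conventional PUCT
  # exploitation; this anchors the package's choice of that form for the
  # learning-effect study
  u <- generate_universe(30, 150, max_templates_per_molecule = 5,
                         max_reactants = 3, unsolvable_fraction = 0.4,
                         n_layers = 8, chain_bias = 0.85, seed = 77)
  nbm <- setdiff(u$molecules, u$blocks)
  pool <- nbm[u$layer[nbm] >= 4]
  targets <- withr::with_seed(1, sample(pool, 25))
  viable <- vapply(u$templates, function(t) all(u$solvable[u$reactants[[t]]]),
                   logical(1))
  names(viable) <- u$templates
  oracle_q0 <- function(m, ts) ifelse(viable[ts], 0.9, 0.1)
  run <- function(egn) {
    solved <- logical(length(targets)); iters <- numeric(length(targets))
    for (j in seq_along(targets)) {
      cfg <- planner_config(iter_limit = 100, seed = 500 + j,
                            exploitation = "plain")
      tr <- plan(targets[j], u, egn, cfg)
      solved[j] <- tr$root$status == "proven"
      iters[j] <- if (solved[j]) tr$iterations_used else 100
    }
    c(sr = mean(solved), ai = mean(iters))
  }
  base <- run(NULL)
  orac <- run(oracle_q0)
  expect_gte(orac[["sr"]], base[["sr"]])
  expect_lt(orac[["ai"]], base[["ai"]])
})

test_that("the benchmark harness produces consistent, nested, reproducible reports", {
  u <- generate_universe(5, 20, unsolvable_fraction = 0.3, seed = 41)
  nb <- setdiff(u$molecules, u$blocks)
  targets <- utils::tail(nb, 8)
  cfg <- planner_config(iter_limit = 120, seed = 3)
  rep1 <- run_benchmark(u, targets, algorithms = c("egmcts0", "greedy"),
                        config = cfg, checkpoints = c(30L, 60L, 120L))
  rep2 <- run_benchmark(u, targets, algorithms = c("egmcts0", "greedy"),
                        config = cfg, checkpoints = c(30L, 60L, 120L))
  expect_identical(rep1$per_molecule, rep2$per_molecule)

  # checkpoint success rates are non-decreasing per algorithm
  for (a in unique(rep1$success_curve$algorithm)) {
    sr <- rep1$success_curve$success_rate[rep1$success_curve$algorithm == a]
    expect_true(all(diff(sr) >= 0))
  }

  # aggregates recompute from the per-molecule table
  for (a in unique(rep1$aggregates$algorithm)) {
    sub <- rep1$per_molecule[rep1$per_molecule$algorithm == a, ]
    agg <- rep1$aggregates[rep1$aggregates$algorithm == a, ]
    expect_equal(agg$success_rate, mean(sub$solved))
    expect_equal(agg$avg_iter, mean(sub$iterations))
    expect_lte(mean(sub$iterations[sub$solved]), 120)
  }
  # node counters are reported for tree search, absent for greedy
  expect_false(is.na(rep1$aggregates$avg_M[rep1$aggregates$algorithm == "egmcts0"]))
  expect_true(is.na(rep1$aggregates$avg_M[rep1$aggregates$algorithm == "greedy"]))

  d <- withr::local_tempdir()
  write_benchmark_report(rep1, d)
  csv <- utils::read.csv(file.path(d, "per_molecule.csv"))
  expect_identical(nrow(csv), nrow(rep1$per_molecule))
  doc <- jsonlite::read_json(file.path(d, "aggregates.json"))
  expect_length(doc$aggregates, nrow(rep1$aggregates))
})
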