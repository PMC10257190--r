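rxn <- function(reactants, products) list(reactants = reactants,
                                          products = products)

test_that("closure construction adds products only when all reactants are present", {
  # no reactions: the graph is the seed set
  g0 <- build_noc(list(), blocks = c("a", "b"))
  expect_setequal(g0$nodes, c("a", "b"))
  expect_identical(nrow(g0$edges), 0L)

  # a reaction with an absent reactant never fires
  g1 <- build_noc(list(rxn(c("a", "ghost"), "x")), blocks = c("a", "b"))
  expect_false("x" %in% g1$nodes)

  # two-pass dependency closes in either scan order
  rs <- list(rxn("x", "y"), rxn("a", "x"))
  g2 <- build_noc(rs, blocks = "a")
  g3 <- build_noc(rev(rs), blocks = "a")
  expect_setequal(g2$nodes, c("a", "x", "y"))
  expect_setequal(g3$nodes, g2$nodes)
  expect_setequal(paste(g2$edges$from, g2$edges$to),
                  paste(g3$edges$from, g3$edges$to))
})

test_that("closure is order-independent and idempotent on generated universes", {
  u <- generate_universe(4, 10, seed = 13)
  rs <- universe_reactions(u)
  g <- build_noc(rs, u$blocks)
  for (perm_seed in 1:3) {
    gp <- build_noc(withr::with_seed(perm_seed, sample(rs)), u$blocks)
    expect_setequal(gp$nodes, g$nodes)
    expect_setequal(paste(gp$edges$from, gp$edges$to),
                    paste(g$edges$from, g$edges$to))
  }
  # solvable molecules are exactly the closure (poisoned chains never fire)
  expect_setequal(g$nodes, u$molecules[u$solvable])
})

test_that("cost is the longest path back to the leaves", {
  g <- build_noc(list(rxn("a", "x"), rxn("x", "y")), blocks = "a")
  expect_identical(node_cost(g, "a"), 0)
  expect_identical(node_cost(g, "x"), 1)
  expect_identical(node_cost(g, "y"), 2)

  # diamond with arms of length 2 and 3: the longest arm wins
  g2 <- build_noc(list(
    rxn("a", "p"), rxn("p", "q"),                      # short arm to q
    rxn("a", "r"), rxn("r", "s"), rxn(c("q", "s"), "t")
  ), blocks = "a")
  expect_identical(node_cost(g2, "t"), 3)

  # exhaustive-path oracle over a generated universe
  u <- generate_universe(3, 8, seed = 5)
  g3 <- build_noc(universe_reactions(u), u$blocks)
  all_paths_cost <- function(n) {
    preds <- g3$edges$from[g3$edges$to == n]
    if (length(preds) == 0) return(0)
    1 + max(vapply(unique(preds), all_paths_cost, numeric(1)))
  }
  for (n in g3$nodes) expect_identical(node_cost(g3, n), all_paths_cost(n))

  # cost is monotone along edges
  cost <- node_cost(g3)
  for (i in seq_len(nrow(g3$edges))) {
    expect_gte(cost[[g3$edges$to[i]]], cost[[g3$edges$from[i]]] + 1)
  }

  # cycles are an error, not a truncation
  gc <- structure(list(
    nodes = c("a", "u", "v"),
    edges = data.frame(from = c("a", "u", "v"), to = c("u", "v", "u"),
                       reaction = 1:3, stringsAsFactors = FALSE),
    blocks = "a"
  ), class = "noc_graph")
  expect_error(node_cost(gc, "v"), class = "egmcts_cycle_error")
})

test_that("candidate selection filters by outdegree and cost thresholds", {
  # a 12-node toy graph: chain with branches
  g <- build_noc(list(
    rxn("a", "m1"), rxn("m1", "m2"), rxn("m2", "m3"), rxn("m3", "m4"),
    rxn("m4", "m5"), rxn("m1", "n1"), rxn("m2", "n2"), rxn("m2", "n3"),
    rxn(c("n2", "n3"), "n4"), rxn("b", "p1"), rxn("m4", "p2")
  ), blocks = c("a", "b"))
  expect_setequal(select_candidates(g, 0, 0), g$nodes)
  deg <- node_outdegree(g); cost <- node_cost(g)
  expected <- sort(g$nodes[deg >= 2 & cost >= 2])
  expect_identical(select_candidates(g, 2, 2), expected)
  # outdegree below threshold excludes regardless of cost
  expect_false("m3" %in% select_candidates(g, 2, 0))
  expect_identical(node_outdegree(g, "m2"), 3L)
})

test_that("reaction lists and graphs round-trip through files", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a.b\tx", "x\ty.z"), f)
  rs <- read_reactions_tsv(f)
  expect_identical(rs[[1]]$reactants, c("a", "b"))
  expect_identical(rs[[2]]$products, c("y", "z"))
  g <- build_noc(rs, blocks = c("a", "b"))
  base <- file.path(withr::local_tempdir(), "graph")
  write_noc(g, base)
  expect_true(file.exists(paste0(base, ".tsv")))
  doc <- jsonlite::read_json(paste0(base, ".json"))
  expect_setequal(unlist(doc$nodes), g$nodes)
})

test_that("the hard-molecule filter keeps what the budgeted search cannot solve", {
  u <- generate_universe(4, 12, unsolvable_fraction = 0.5, seed = 17)
  nb <- setdiff(u$molecules, u$blocks)
  hard_g <- hard_molecule_filter(nb, u, "greedy", iter_limit = 50)
  # everything the oracle calls unsolvable must be kept
  expect_true(all(nb[!u$solvable[nb]] %in% hard_g))
  hard_e <- hard_molecule_filter(nb, u, "egmcts0", iter_limit = 200, seed = 2)
  expect_true(all(nb[!u$solvable[nb]] %in% hard_e))
})
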