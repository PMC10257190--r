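# Baselines and the evaluation harness: probability-greedy depth-first
# search, the non-learning tree search (all Q0 = 0.5, i.e. plan() with
# egn = NULL), and the trained planner, compared by success rate under
# nested iteration checkpoints, average iterations (failures charged the
# full limit, so the figure is comparable across success rates), expanded
# node counts, and first-route quality (longest/shortest-route counts and
# mean length over the molecules every compared algorithm solves).

#' Probability-greedy depth-first search baseline
#'
#' Depth-first over molecule goals, always trying the highest-probability
#' template first and backtracking on dead ends. One iteration is counted
#' per single-step model call; the search fails when the route would need
#' to expand a molecule at `max_depth` or the iteration budget runs out.
#'
#' @param target Target molecule id.
#' @param model Single-step model.
#' @param max_depth Maximum expansion depth (the route's longest reaction
#'   chain cannot exceed it).
#' @param iter_limit Budget of model calls.
#' @param k Templates requested per call.
#' @return List with `success`, `route` (a `synth_route`), `iterations`.
#' @export
greedy_dfs <- function(target, model, max_depth = 10L, iter_limit = Inf,
                       k = 50L) {
  if (max_depth < 1) stop_egmcts("argument", "max_depth must be >= 1")
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  counter$exhausted <- FALSE

  solve <- function(m, depth, ancestors) {
    if (model_is_block(model, m)) {
      return(list(products = character(0), templates = character(0),
                  reactants = list()))
    }
    if (depth >= max_depth) return(NULL)
    if (counter$exhausted) return(NULL)
    if (counter$n >= iter_limit) {
      counter$exhausted <- TRUE
      return(NULL)
    }
    counter$n <- counter$n + 1L
    pred <- model_predict(model, m, k)
    for (j in seq_len(nrow(pred))) {
      rs <- model_reactants(model, pred$template[j], m)
      if (any(rs %in% c(ancestors, m))) next   # cycle guard
      products <- m
      templates <- pred$template[j]
      reactants <- list(rs)
      ok <- TRUE
      for (r in rs) {
        sub <- solve(r, depth + 1L, c(ancestors, m))
        if (is.null(sub)) { ok <- FALSE; break }
        products <- c(products, sub$products)
        templates <- c(templates, sub$templates)
        reactants <- c(reactants, sub$reactants)
      }
      if (ok) return(list(products = products, templates = templates,
                          reactants = reactants))
      if (counter$exhausted) return(NULL)
    }
    NULL
  }

  res <- solve(target, 0L, character(0))
  if (is.null(res)) {
    route <- structure(list(success = FALSE, target = target,
                            steps = {
                              s <- data.frame(product = character(0),
                                              template = character(0))
                              s$reactants <- list()
                              s
                            }),
                       class = "synth_route")
    return(list(success = FALSE, route = route, iterations = counter$n))
  }
  # collapse repeats: a molecule synthesized once suffices
  keep <- !duplicated(res$products)
  route <- make_route(target, res$products[keep],
                      res$reactants[keep], res$templates[keep])
  list(success = TRUE, route = route, iterations = counter$n)
}

#' Longest/shortest-route counts and mean length
#'
#' Restricted to the molecules solved by every compared algorithm: per
#' molecule, every algorithm attaining the maximum first-route length has
#' its LRN incremented, every algorithm attaining the minimum its SRN
#' (ties count for all). Avg is the mean first-route length over the
#' common molecules.
#'
#' @param first_routes Named list (by algorithm) of named lists (by
#'   molecule) of `synth_route` objects; unsolved molecules are `NULL` or
#'   failed routes.
#' @return List with `common_molecules` and a data.frame `metrics`
#'   (`algorithm`, `LRN`, `SRN`, `avg_length`); when no molecule is solved
#'   by all algorithms, `metrics` has zero counts and `NA` lengths and
#'   `empty` is `TRUE`.
#' @export
route_quality_metrics <- function(first_routes) {
  if (length(first_routes) < 2L) {
    stop_egmcts("argument", "at least two algorithms are required")
  }
  algos <- names(first_routes)
  solved_by <- lapply(first_routes, function(rs) {
    names(Filter(function(r) !is.null(r) && isTRUE(r$success), rs))
  })
  common <- Reduce(intersect, solved_by)
  lrn <- stats::setNames(rep(0L, length(algos)), algos)
  srn <- lrn
  lens <- stats::setNames(rep(list(numeric(0)), length(algos)), algos)
  for (m in common) {
    ls <- vapply(algos, function(a) route_length(first_routes[[a]][[m]]),
                 numeric(1))
    lrn[ls == max(ls)] <- lrn[ls == max(ls)] + 1L
    srn[ls == min(ls)] <- srn[ls == min(ls)] + 1L
    for (a in algos) lens[[a]] <- c(lens[[a]], ls[[a]])
  }
  metrics <- data.frame(
    algorithm = algos,
    LRN = as.integer(lrn),
    SRN = as.integer(srn),
    avg_length = vapply(lens, function(v) if (length(v)) mean(v) else NA_real_,
                        numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(common_molecules = common, metrics = metrics,
       empty = length(common) == 0L)
}

#' Run the benchmark harness
#'
#' Attempts every target with every algorithm, recording the first route,
#' the iterations used, and (for the tree-search algorithms) the expanded
#' node counts. Success at an iteration checkpoint L means the molecule
#' was solved using at most L iterations, so the checkpoint curve is
#' nested by construction. Average iterations are taken over all attempted
#' molecules with failures charged the full limit.
#'
#' @param model Single-step model (e.g. a `reaction_universe`).
#' @param targets Character vector of target molecule ids.
#' @param algorithms Subset of `"egmcts"`, `"egmcts0"`, `"greedy"`.
#' @param egn `egn_params` for `"egmcts"` (ignored by the others).
#' @param config `planner_config`; its `iter_limit` should be at least the
#'   largest checkpoint.
#' @param checkpoints Iteration checkpoints for the success-rate curve.
#' @param greedy_max_depth Depth bound for the greedy baseline.
#' @return Object of class `benchmark_report`: `per_molecule` data.frame,
#'   `aggregates` data.frame, `success_curve` data.frame, `quality` (when
#'   two or more algorithms ran), `first_routes`.
#' @export
run_benchmark <- function(model, targets,
                          algorithms = c("egmcts", "egmcts0", "greedy"),
                          egn = NULL,
                          config = planner_config(),
                          checkpoints = c(100L, 200L, 300L, 400L, 500L),
                          greedy_max_depth = 10L) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  if ("egmcts" %in% algorithms && is.null(egn)) {
    stop_egmcts("argument", "algorithm 'egmcts' needs trained egn parameters")
  }
  limit <- max(config$iter_limit, checkpoints)
  rows <- list()
  first_routes <- stats::setNames(
    rep(list(stats::setNames(vector("list", length(targets)), targets)),
        length(algorithms)),
    algorithms
  )
  for (a in algorithms) {
    for (i in seq_along(targets)) {
      m <- targets[i]
      if (a == "greedy") {
        res <- greedy_dfs(m, model, max_depth = greedy_max_depth,
                          iter_limit = limit, k = config$k)
        solved <- res$success
        iters <- res$iterations
        route <- res$route
        n_mol <- NA_integer_; n_rxn <- NA_integer_
      } else {
        cfg <- config
        cfg$iter_limit <- as.integer(limit)
        cfg$seed <- as.integer((config$seed + i) %% 2^31)
        cfg$stop_on_proven <- TRUE
        tr <- plan(m, model, egn = if (a == "egmcts") egn else NULL,
                   config = cfg)
        solved <- tr$root$status == "proven"
        iters <- tr$iterations_used
        route <- extract_route(tr)
        n_mol <- tr$expanded_molecule_nodes
        n_rxn <- tr$expanded_reaction_nodes
      }
      if (solved) first_routes[[a]][[m]] <- route
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm = a, molecule = m, solved = solved,
        iterations = if (solved) iters else limit,
        route_length = if (solved) route_length(route) else NA_integer_,
        n_molecule_nodes = n_mol, n_reaction_nodes = n_rxn,
        stringsAsFactors = FALSE
      )
    }
  }
  per_molecule <- do.call(rbind, rows)

  agg <- lapply(algorithms, function(a) {
    sub <- per_molecule[per_molecule$algorithm == a, ]
    data.frame(
      algorithm = a,
      success_rate = mean(sub$solved),
      avg_iter = mean(sub$iterations),
      avg_M = if (all(is.na(sub$n_molecule_nodes))) NA_real_
              else mean(sub$n_molecule_nodes, na.rm = TRUE),
      avg_T = if (all(is.na(sub$n_reaction_nodes))) NA_real_
              else mean(sub$n_reaction_nodes, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  aggregates <- do.call(rbind, agg)

  curve <- expand.grid(algorithm = algorithms, checkpoint = sort(checkpoints),
                       stringsAsFactors = FALSE)
  curve$success_rate <- mapply(function(a, cp) {
    sub <- per_molecule[per_molecule$algorithm == a, ]
    mean(sub$solved & sub$iterations <= cp)
  }, curve$algorithm, curve$checkpoint)

  quality <- if (length(algorithms) >= 2L) route_quality_metrics(first_routes)
             else NULL

  structure(
    list(per_molecule = per_molecule, aggregates = aggregates,
         success_curve = curve, quality = quality,
         first_routes = first_routes,
         config = list(iter_limit = limit, checkpoints = sort(checkpoints),
                       seed = config$seed,
                       avg_iter_convention = "failures charged the full iteration limit")),
    class = "benchmark_report"
  )
}

#' One paired replicate of the learning-effect experiment
#'
#' Generates a synthetic universe, trains the guidance network on a
#' disjoint training set, then evaluates guided and non-learning search
#' on held-out targets with identical per-target seeds. The replicate
#' "wins" when the guided search attains strictly higher success rate and
#' strictly fewer average iterations (failures charged the full budget).
#'
#' The default conditions are the package's study conditions (see the
#' methods vignette): universes of 50 building blocks and 400 non-block
#' molecules in 10 layers with up to 5 templates per molecule, 40%
#' unsolvable molecules, chain bias 0.85 and mildly informative priors;
#' 100 training, 20 validation and 50 held-out molecules from layers 4
#' and up; one phase-I round; evaluation at 100 iterations with the
#' conventional PUCT exploitation term.
#'
#' @param seed Integer replicate seed (drives the universe, the split,
#'   training and evaluation).
#' @param n_train,n_val,n_held Split sizes.
#' @param iter_limit Planning budget for training, validation and
#'   evaluation.
#' @param min_layer Targets are drawn from this layer upwards.
#' @param rounds_max Phase-I training rounds.
#' @param universe_args Arguments passed to [generate_universe()] (seed
#'   excluded).
#' @return List with `sr_egmcts`, `sr_egmcts0`, `avg_iter_egmcts`,
#'   `avg_iter_egmcts0`, `oracle_solvable_rate` (ground-truth solvable
#'   fraction of the held-out set), `win`.
#' @export
learning_effect_replicate <- function(seed,
                                      n_train = 100L, n_val = 20L,
                                      n_held = 50L, iter_limit = 100L,
                                      min_layer = 4L, rounds_max = 1L,
                                      universe_args = list(
                                        n_blocks = 50L, n_nonblocks = 400L,
                                        max_templates_per_molecule = 5L,
                                        max_reactants = 3L,
                                        unsolvable_fraction = 0.4,
                                        n_layers = 10L, chain_bias = 0.85,
                                        prior_quality = 1
                                      )) {
  u <- do.call(generate_universe, c(universe_args, list(seed = seed)))
  nbm <- setdiff(u$molecules, u$blocks)
  pool <- nbm[u$layer[nbm] >= min_layer]
  n_need <- n_train + n_val + n_held
  if (length(pool) < n_need) {
    stop_egmcts("argument", "universe too small for the requested split")
  }
  pick <- withr::with_seed(seed, sample(pool, n_need))
  train <- pick[seq_len(n_train)]
  val <- pick[n_train + seq_len(n_val)]
  held <- pick[n_train + n_val + seq_len(n_held)]

  cfg <- planner_config(iter_limit = iter_limit, seed = seed,
                        exploitation = "plain")
  fit <- train_egn_loop(train, val, u, config = cfg, rounds_max = rounds_max,
                        baseline = FALSE, seed = seed)

  eval_algo <- function(egn) {
    solved <- logical(length(held))
    iters <- numeric(length(held))
    for (j in seq_along(held)) {
      cj <- cfg
      cj$seed <- as.integer((seed * 1009 + j) %% 2^31)
      tr <- plan(held[j], u, egn, cj)
      solved[j] <- tr$root$status == "proven"
      iters[j] <- if (solved[j]) tr$iterations_used else iter_limit
    }
    c(sr = mean(solved), ai = mean(iters))
  }
  r1 <- eval_algo(fit$egn)
  r0 <- eval_algo(NULL)
  list(
    sr_egmcts = r1[["sr"]], sr_egmcts0 = r0[["sr"]],
    avg_iter_egmcts = r1[["ai"]], avg_iter_egmcts0 = r0[["ai"]],
    oracle_solvable_rate = mean(u$solvable[held]),
    win = r1[["sr"]] > r0[["sr"]] && r1[["ai"]] < r0[["ai"]]
  )
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report>\n")
  print(x$aggregates, row.names = FALSE)
  if (!is.null(x$quality) && !x$quality$empty) {
    cat(sprintf("route quality over %d commonly solved molecule(s):\n",
                length(x$quality$common_molecules)))
    print(x$quality$metrics, row.names = FALSE)
  }
  invisible(x)
}

#' Write a benchmark report to CSV + JSON
#'
#' Per-molecule CSV next to an aggregate JSON (with the run configuration
#' echoed), under the given directory.
#'
#' @param report A `benchmark_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_benchmark_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$per_molecule,
                   file.path(dir, "per_molecule.csv"), row.names = FALSE)
  doc <- list(
    aggregates = report$aggregates,
    success_curve = report$success_curve,
    quality = if (!is.null(report$quality)) list(
      common_molecules = report$quality$common_molecules,
      metrics = report$quality$metrics
    ),
    config = report$config
  )
  jsonlite::write_json(doc, file.path(dir, "aggregates.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
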