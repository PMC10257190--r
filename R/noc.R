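# Network of organic chemistry: a directed molecule graph grown from the
# building blocks by closing a reaction list -- a reaction's products join
# the graph only once all of its reactants are present, with an edge from
# each reactant to each product. Node outdegree and cost (longest path
# back to the seed leaves, counted in edges) drive training-molecule
# selection.

#' Build a network of organic chemistry from a reaction list
#'
#' Seeds the graph with the building blocks and repeatedly scans the
#' reaction list, firing every reaction whose reactants are all present:
#' its products are added as nodes and an edge is drawn from each reactant
#' to each product. The scan repeats until a fixed point; the resulting
#' node and edge sets are independent of the order of the reaction list.
#'
#' @param reactions List of reactions, each a list with character vectors
#'   `reactants` and `products`.
#' @param blocks Character vector of seed molecules.
#' @return Object of class `noc_graph`: list with `nodes`, `edges`
#'   (data.frame `from`, `to`, `reaction` index provenance), `blocks`.
#' @export
build_noc <- function(reactions, blocks) {
  nodes <- unique(blocks)
  fired <- rep(FALSE, length(reactions))
  edges_from <- character(0)
  edges_to <- character(0)
  edges_rxn <- integer(0)
  repeat {
    changed <- FALSE
    for (i in seq_along(reactions)) {
      if (fired[i]) next
      rx <- reactions[[i]]
      if (all(rx$reactants %in% nodes)) {
        fired[i] <- TRUE
        changed <- TRUE
        nodes <- union(nodes, rx$products)
        grid <- expand.grid(from = rx$reactants, to = rx$products,
                            stringsAsFactors = FALSE)
        edges_from <- c(edges_from, grid$from)
        edges_to <- c(edges_to, grid$to)
        edges_rxn <- c(edges_rxn, rep(i, nrow(grid)))
      }
    }
    if (!changed) break
  }
  structure(
    list(
      nodes = sort(nodes),
      edges = data.frame(from = edges_from, to = edges_to,
                         reaction = edges_rxn, stringsAsFactors = FALSE),
      blocks = unique(blocks)
    ),
    class = "noc_graph"
  )
}

#' @export
print.noc_graph <- function(x, ...) {
  cat(sprintf("<noc_graph> %d nodes (%d seeds), %d edges\n",
              length(x$nodes), length(x$blocks), nrow(x$edges)))
  invisible(x)
}

# longest-path costs for all nodes; memoized DFS over incoming edges,
# cycles are an error
.noc_costs <- function(graph) {
  preds <- split(graph$edges$from, graph$edges$to)
  cost <- stats::setNames(rep(NA_real_, length(graph$nodes)), graph$nodes)
  state <- stats::setNames(rep(0L, length(graph$nodes)), graph$nodes)
  visit <- function(n) {
    if (state[[n]] == 1L) stop_egmcts("cycle", sprintf(
      "cycle reachable from node %s; costs are defined on acyclic graphs", n))
    if (state[[n]] == 2L) return(cost[[n]])
    state[[n]] <<- 1L
    p <- preds[[n]]
    cost[[n]] <<- if (is.null(p) || length(p) == 0L) 0
                  else 1 + max(vapply(unique(p), visit, numeric(1)))
    state[[n]] <<- 2L
    cost[[n]]
  }
  for (n in graph$nodes) visit(n)
  cost
}

#' Longest-path cost of a node
#'
#' The length (in edges) of the longest path from the node back to the
#' seed leaves; seeds have cost 0. Defined only on acyclic graphs; a cycle
#' reachable from the node is an error, never silently truncated.
#'
#' @param graph A `noc_graph`.
#' @param molecule Node id; if missing, the full named cost vector is
#'   returned.
#' @return Numeric cost (or named vector).
#' @export
node_cost <- function(graph, molecule) {
  stopifnot(inherits(graph, "noc_graph"))
  costs <- .noc_costs(graph)
  if (missing(molecule)) return(costs)
  if (!molecule %in% graph$nodes) {
    stop_egmcts("argument", sprintf("unknown node: %s", molecule))
  }
  costs[[molecule]]
}

#' Outdegree of a node
#'
#' Number of edges leaving the node.
#'
#' @param graph A `noc_graph`.
#' @param molecule Node id; if missing, the full named vector is returned.
#' @return Integer outdegree (or named vector).
#' @export
node_outdegree <- function(graph, molecule) {
  stopifnot(inherits(graph, "noc_graph"))
  tab <- table(graph$edges$from)
  out <- stats::setNames(rep(0L, length(graph$nodes)), graph$nodes)
  out[names(tab)] <- as.integer(tab)
  if (missing(molecule)) return(out)
  if (!molecule %in% graph$nodes) {
    stop_egmcts("argument", sprintf("unknown node: %s", molecule))
  }
  out[[molecule]]
}

#' Select training-candidate molecules by outdegree and cost
#'
#' Molecules whose outdegree and longest-path cost both reach the given
#' thresholds, in deterministic id order. Thresholds (0, 0) return every
#' node.
#'
#' @param graph A `noc_graph`.
#' @param min_outdegree Minimum outdegree.
#' @param min_cost Minimum cost.
#' @return Character vector of molecule ids.
#' @export
select_candidates <- function(graph, min_outdegree = 2L, min_cost = 4L) {
  deg <- node_outdegree(graph)
  cost <- node_cost(graph)
  sort(graph$nodes[deg >= min_outdegree & cost >= min_cost])
}

#' Keep the molecules a search fails to solve within a budget
#'
#' The selection recipe for hard training molecules: run a cheap planner
#' over the candidates and keep those for which no route is found within
#' the iteration budget. `algorithm = "greedy"` uses probability-greedy
#' depth-first search; `"egmcts0"` uses the non-learning tree search.
#'
#' @param molecules Candidate molecule ids.
#' @param model Single-step model.
#' @param algorithm `"greedy"` or `"egmcts0"`.
#' @param iter_limit Iteration budget per molecule.
#' @param max_depth Depth bound for the search.
#' @param seed Integer seed.
#' @return Character vector: the unsolved subset, in input order.
#' @export
hard_molecule_filter <- function(molecules, model,
                                 algorithm = c("greedy", "egmcts0"),
                                 iter_limit = 100L, max_depth = 10L,
                                 seed = 1L) {
  algorithm <- match.arg(algorithm)
  unsolved <- logical(length(molecules))
  for (i in seq_along(molecules)) {
    if (algorithm == "greedy") {
      res <- greedy_dfs(molecules[i], model, max_depth = max_depth,
                        iter_limit = iter_limit)
      unsolved[i] <- !res$success
    } else {
      cfg <- planner_config(iter_limit = iter_limit, max_depth = max_depth,
                            seed = as.integer((seed + i) %% 2^31))
      tr <- plan(molecules[i], model, egn = NULL, config = cfg)
      unsolved[i] <- tr$root$status != "proven"
    }
  }
  molecules[unsolved]
}

#' Read a reaction list from TSV
#'
#' Two tab-separated columns per line: dot-separated reactant ids, then
#' dot-separated product ids.
#'
#' @param path TSV file path.
#' @return List of reactions for [build_noc()].
#' @export
read_reactions_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    list(reactants = strsplit(parts[1L], ".", fixed = TRUE)[[1L]],
         products = strsplit(parts[2L], ".", fixed = TRUE)[[1L]])
  })
}

#' Write a NOC graph to files
#'
#' Edge-list TSV (`from<TAB>to`) plus a JSON document with per-node
#' outdegree and cost.
#'
#' @param graph A `noc_graph`.
#' @param path Base path; `.tsv` and `.json` are appended.
#' @return `path`, invisibly.
#' @export
write_noc <- function(graph, path) {
  writeLines(paste(graph$edges$from, graph$edges$to, sep = "\t"),
             paste0(path, ".tsv"))
  doc <- list(
    nodes = graph$nodes,
    blocks = graph$blocks,
    outdegree = as.list(node_outdegree(graph)),
    cost = as.list(node_cost(graph)),
    edges = graph$edges
  )
  jsonlite::write_json(doc, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Derive the reaction list implied by a universe's decomposition table
#'
#' Each template becomes one forward reaction reactants -> product, giving
#' NOC construction a synthetic input with known structure.
#'
#' @param universe A `reaction_universe`.
#' @return List of reactions for [build_noc()].
#' @export
universe_reactions <- function(universe) {
  stopifnot(inherits(universe, "reaction_universe"))
  lapply(universe$templates, function(tid) {
    list(reactants = universe$reactants[[tid]],
         products = universe$template_product[[tid]])
  })
}
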