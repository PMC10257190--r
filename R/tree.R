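# AND-OR search tree.
#
# Molecule nodes are OR nodes: proven when the molecule is a building block
# or at least one child reaction is proven; disproven when expansion found
# no applicable template or every child reaction is disproven. Reaction
# nodes are AND nodes: proven when all reactant children are proven,
# disproven when any is. Nodes are environments so that value/status/visit
# updates during search mutate in place, as MCTS requires.
#
# Value conventions at leaves: V = 1 for building blocks, V = 0 for
# unexpanded non-block molecules, and disproven molecule nodes pin V = 0.
# With these conventions a template splitting a molecule into one building
# block and one unproven molecule is rewarded 1/2.

new_molecule_node <- function(molecule, is_block, parent = NULL, depth = 0L,
                              cycle_guard = FALSE) {
  node <- new.env(parent = emptyenv())
  node$kind <- "mol"
  node$molecule <- molecule
  node$is_block <- is_block
  node$cycle_guard <- cycle_guard
  node$expanded <- FALSE
  node$children <- list()
  node$parent <- parent
  node$depth <- as.integer(depth)
  if (is_block) {
    node$status <- "proven"
    node$value <- 1
  } else if (cycle_guard) {
    node$status <- "disproven"
    node$value <- 0
  } else {
    node$status <- "open"
    node$value <- 0
  }
  class(node) <- "egmcts_node"
  node
}

new_reaction_node <- function(template, q0, prior, parent) {
  node <- new.env(parent = emptyenv())
  node$kind <- "rxn"
  node$template <- template
  node$q0 <- q0
  node$q_bar <- q0
  node$n_updates <- 0L
  node$reward_sum <- 0
  node$prior <- prior
  node$status <- "open"
  node$children <- list()
  node$parent <- parent
  class(node) <- "egmcts_node"
  node
}

#' Initialize a search tree for a target molecule
#'
#' A single-node tree whose root holds the target. The root is proven
#' immediately when the target is itself a building block; otherwise it is
#' open with no children.
#'
#' @param target Target molecule id.
#' @param blocks Character vector of building-block ids (or a model object
#'   with a [model_is_block()] method).
#' @param seed Integer seed recorded on the tree; the planner draws all of
#'   its randomness from it.
#' @return An environment of class `search_tree` with fields `root`,
#'   `iterations_used`, `expanded_molecule_nodes`, `expanded_reaction_nodes`
#'   and `rng_seed`.
#' @export
init_tree <- function(target, blocks = character(0), seed = 0L) {
  is_block <- if (is.character(blocks)) target %in% blocks
              else model_is_block(blocks, target)
  tree <- new.env(parent = emptyenv())
  tree$root <- new_molecule_node(target, is_block, parent = NULL, depth = 0L)
  tree$iterations_used <- 0L
  tree$expanded_molecule_nodes <- 1L   # node-count tallies, root included
  tree$expanded_reaction_nodes <- 0L
  tree$rng_seed <- as.integer(seed)
  class(tree) <- "search_tree"
  tree
}

#' @export
print.search_tree <- function(x, ...) {
  cat(sprintf(
    "<search_tree> target %s [%s], %d iterations, %d molecule nodes, %d reaction nodes\n",
    x$root$molecule, x$root$status, x$iterations_used,
    x$expanded_molecule_nodes, x$expanded_reaction_nodes
  ))
  invisible(x)
}

#' Recompute a node's status from its children
#'
#' Applies the AND/OR success semantics to one node and stores the result:
#' a molecule node is proven iff it is a building block or has a proven
#' child reaction, disproven iff expansion yielded no templates, a cycle
#' guard fired, or all children are disproven; a reaction node is proven
#' iff all children are proven and disproven iff any child is. Propagation
#' to ancestors is the update step's duty, not this function's.
#'
#' @param node A molecule or reaction node.
#' @return The recomputed status string, invisibly stored on the node.
#' @export
refresh_status <- function(node) {
  st <- if (node$kind == "mol") {
    if (node$is_block) "proven"
    else if (node$cycle_guard) "disproven"
    else if (length(node$children) == 0L) {
      if (node$expanded) "disproven" else "open"
    } else {
      cs <- vapply(node$children, function(ch) ch$status, character(1))
      if (any(cs == "proven")) "proven"
      else if (all(cs == "disproven")) "disproven"
      else "open"
    }
  } else {
    cs <- vapply(node$children, function(ch) ch$status, character(1))
    if (any(cs == "disproven")) "disproven"
    else if (length(cs) > 0L && all(cs == "proven")) "proven"
    else "open"
  }
  node$status <- st
  st
}

#' All nodes of a tree in preorder
#'
#' @param tree A `search_tree`.
#' @return List of node environments.
#' @export
tree_nodes <- function(tree) {
  out <- list()
  stack <- list(tree$root)
  while (length(stack) > 0L) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    out[[length(out) + 1L]] <- node
    for (ch in rev(node$children)) stack[[length(stack) + 1L]] <- ch
  }
  out
}

#' Audit a search tree's bookkeeping invariants
#'
#' Recomputes, from scratch and bottom-up, every node's status and checks
#' it against the stored status; verifies the running-average identity
#' q_bar * (n_updates + 1) - q0 = reward_sum on every reaction node; and
#' checks that every expanded, non-disproven molecule node stores
#' V = max over children's q_bar. Used by tests and available for
#' diagnostics.
#'
#' @param tree A `search_tree`.
#' @param tol Numeric tolerance for the running-average identity.
#' @return List with `status_ok`, `qbar_max_err`, `vm_max_err`, `ok`.
#' @export
audit_tree <- function(tree, tol = 1e-9) {
  nodes <- tree_nodes(tree)
  # bottom-up status recomputation on a scratch copy
  recompute <- function(node) {
    for (ch in node$children) recompute(ch)
    stored <- node$status
    fresh <- refresh_status(node)   # refresh_status is itself the rule
    if (!identical(stored, fresh)) status_bad <<- status_bad + 1L
    node$status <- stored
  }
  status_bad <- 0L
  recompute(tree$root)

  qbar_err <- 0
  vm_err <- 0
  for (node in nodes) {
    if (node$kind == "rxn") {
      qbar_err <- max(qbar_err,
                      abs(node$q_bar * (node$n_updates + 1) - node$q0 - node$reward_sum))
    } else if (node$expanded && node$status != "disproven" &&
               length(node$children) > 0L) {
      vmax <- max(vapply(node$children, function(ch) ch$q_bar, numeric(1)))
      vm_err <- max(vm_err, abs(node$value - vmax))
    }
  }
  list(
    status_ok = status_bad == 0L,
    qbar_max_err = qbar_err,
    vm_max_err = vm_err,
    ok = status_bad == 0L && qbar_err <= tol && vm_err <= tol
  )
}

node_to_list <- function(node, index_of) {
  idx <- vapply(node$children, function(ch) index_of(ch), integer(1))
  if (node$kind == "mol") {
    list(type = "molecule", molecule = node$molecule, value = node$value,
         status = node$status, depth = node$depth, is_block = node$is_block,
         expanded = node$expanded, cycle_guard = node$cycle_guard,
         children = as.list(idx))
  } else {
    list(type = "reaction", template = node$template, q_bar = node$q_bar,
         n_updates = node$n_updates, q0 = node$q0, prior = node$prior,
         reward_sum = node$reward_sum, status = node$status,
         children = as.list(idx))
  }
}

#' Dump a search tree to JSON
#'
#' Flat node table (preorder indices) with per-node type, identifiers,
#' values, statuses and child indices; used for debugging and for
#' experience extraction outside the session.
#'
#' @param tree A `search_tree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  nodes <- tree_nodes(tree)
  for (i in seq_along(nodes)) nodes[[i]]$.idx <- i
  index_of <- function(node) node$.idx
  doc <- list(
    target = tree$root$molecule,
    iterations_used = tree$iterations_used,
    expanded_molecule_nodes = tree$expanded_molecule_nodes,
    expanded_reaction_nodes = tree$expanded_reaction_nodes,
    rng_seed = tree$rng_seed,
    nodes = lapply(nodes, node_to_list, index_of = index_of)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
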