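# The planning loop: Selection - Expansion - Update over the AND-OR tree.
#
# Selection walks down from the root. At a molecule node it takes the
# argmax of the PUCT score over its (non-disproven) reaction children; at a
# reaction node it gives priority to unexpanded molecule children (chosen
# uniformly at random) and otherwise picks uniformly among children not yet
# proven. The walk ends at an unexpanded, non-block molecule node, which is
# then expanded with the single-step model: one reaction child per
# predicted template, initialized with q_bar = Q0 from the experience
# guidance network, and one molecule grandchild per reactant. The update
# step walks back to the root, refreshing statuses, setting each molecule's
# V to the highest child q_bar, and folding a fresh reward into each
# reaction node's running average.

#' Planner configuration
#'
#' @param c Exploration constant (> 0).
#' @param z Reward magnitude for a decided reaction node (> 1): proven
#'   nodes receive +z, disproven nodes -z.
#' @param k Number of templates requested from the single-step model.
#' @param iter_limit Iteration budget; one single-step model call is made
#'   per iteration.
#' @param max_depth Maximum molecule depth the selection will descend to;
#'   non-block molecules at the limit are left unexpanded (value 0).
#' @param seed Integer seed for all of the planner's randomness.
#' @param exploitation `"printed"` divides q_bar by max(N, 1) in the PUCT
#'   exploitation term; `"plain"` uses q_bar itself (the conventional PUCT
#'   form). Both readings are kept because the dividing form is undefined
#'   at N = 0 and is floored at 1 here.
#' @param stop_on_proven If `TRUE` (route-finding mode) the loop stops as
#'   soon as the root is proven; if `FALSE` (multi-route mode) the budget
#'   is always exhausted unless the tree saturates.
#' @return A list of class `planner_config`.
#' @export
planner_config <- function(c = 0.5, z = 10, k = 50L, iter_limit = 500L,
                           max_depth = 15L, seed = 0L,
                           exploitation = c("printed", "plain"),
                           stop_on_proven = TRUE) {
  exploitation <- match.arg(exploitation)
  if (c <= 0) stop_egmcts("config", "exploration constant c must be > 0")
  if (z <= 1) stop_egmcts("config", "success reward z must exceed 1")
  if (iter_limit < 1) stop_egmcts("config", "iter_limit must be >= 1")
  if (k < 1) stop_egmcts("config", "k must be >= 1")
  if (max_depth < 1) stop_egmcts("config", "max_depth must be >= 1")
  structure(
    list(c = c, z = z, k = as.integer(k), iter_limit = as.integer(iter_limit),
         max_depth = as.integer(max_depth), seed = as.integer(seed),
         exploitation = exploitation, stop_on_proven = stop_on_proven),
    class = "planner_config"
  )
}

#' PUCT selection score of a reaction node
#'
#' Score = q_bar / max(N, 1) + c * P * sqrt(N') / (1 + N), where N is the
#' node's update count, P its prior probability from the single-step model
#' and N' the update count of its grandparent reaction node. With
#' `exploitation = "plain"` the first term is q_bar itself. For reaction
#' nodes directly under the root (which have no grandparent reaction node)
#' the caller substitutes 1 + the summed update counts of the siblings for
#' N'.
#'
#' @param q_bar Running average score of the node.
#' @param n_updates Update count N of the node.
#' @param prior Prior probability P from the single-step model.
#' @param c Exploration constant.
#' @param grandparent_n Update count N' of the grandparent reaction node.
#' @param exploitation `"printed"` or `"plain"` (see [planner_config()]).
#' @return Numeric score.
#' @export
puct_score <- function(q_bar, n_updates, prior, c = 0.5, grandparent_n = 0,
                       exploitation = c("printed", "plain")) {
  exploitation <- match.arg(exploitation)
  exploit <- if (exploitation == "printed") q_bar / max(n_updates, 1) else q_bar
  exploit + c * prior * sqrt(grandparent_n) / (1 + n_updates)
}

# effective N' for the children of molecule node `mnode`
.grandparent_n <- function(mnode) {
  if (!is.null(mnode$parent)) {
    mnode$parent$n_updates
  } else {
    1 + sum(vapply(mnode$children, function(ch) ch$n_updates, numeric(1)))
  }
}

.selectable_leaf <- function(mnode, max_depth) {
  !mnode$is_block && !mnode$expanded && !mnode$cycle_guard &&
    mnode$status != "disproven" && mnode$depth <= max_depth
}

.select_from_mol <- function(mnode, config) {
  if (.selectable_leaf(mnode, config$max_depth)) return(mnode)
  ch <- mnode$children
  nch <- length(ch)
  if (nch == 0L) return(NULL)
  gp_n <- .grandparent_n(mnode)
  # inlined puct_score (hot path); disproven children sit at -Inf
  printed <- config$exploitation == "printed"
  croot <- config$c * sqrt(gp_n)
  scores <- rep(-Inf, nch)
  for (i in seq_len(nch)) {
    ci <- ch[[i]]
    if (ci$status == "disproven") next
    n <- ci$n_updates
    exploit <- if (printed) ci$q_bar / max(n, 1) else ci$q_bar
    scores[i] <- exploit + croot * ci$prior / (1 + n)
  }
  # argmax; ties broken by insertion order (descending prior); if the best
  # subtree holds no selectable leaf, fall through to the next best
  for (i in order(-scores)) {
    if (scores[i] == -Inf) break
    found <- .select_from_rxn(ch[[i]], config)
    if (!is.null(found)) return(found)
  }
  NULL
}

.select_from_rxn <- function(rnode, config) {
  ch <- rnode$children
  unexp <- integer(0)
  open <- integer(0)
  for (i in seq_along(ch)) {
    ci <- ch[[i]]
    if (ci$status != "open") next
    if (.selectable_leaf(ci, config$max_depth)) unexp <- c(unexp, i)
    else open <- c(open, i)
  }
  if (length(unexp) > 0L) {
    return(ch[[unexp[sample.int(length(unexp), 1L)]]])
  }
  if (length(open) == 0L) return(NULL)
  for (i in sample.int(length(open))) {
    found <- .select_from_mol(ch[[open[i]]], config)
    if (!is.null(found)) return(found)
  }
  NULL
}

#' Select the next leaf molecule node to expand
#'
#' Walks the tree under the selection policy and returns an unexpanded,
#' non-block molecule node, or `NULL` when no selectable leaf remains
#' anywhere (the tree is saturated and the iteration is a no-op).
#'
#' @param tree A `search_tree`.
#' @param config A `planner_config`.
#' @return A molecule node environment, or `NULL`.
#' @export
select_leaf <- function(tree, config) {
  if (tree$root$status == "disproven") {
    stop_egmcts("state", "selection requires a root that is not disproven")
  }
  .select_from_mol(tree$root, config)
}

#' Expand a leaf molecule node
#'
#' Queries the single-step model for the top-k templates of the leaf's
#' molecule. An empty prediction disproves the leaf (no applicable
#' template). Otherwise one reaction child is created per template with
#' q_bar = Q0 from the experience guidance network (or 0.5 everywhere when
#' `egn` is `NULL`, the non-learning configuration) and prior P from the
#' model, plus one molecule grandchild per reactant. A reactant equal to
#' any molecule on the path to the root trips the cycle guard: that
#' grandchild is created disproven, which disproves its reaction.
#'
#' @param leaf Unexpanded non-block molecule node.
#' @param model Single-step model (e.g. a `reaction_universe`).
#' @param egn `egn_params`; or `NULL` for the non-learning configuration
#'   (every Q0 = 0.5); or a function `(molecule_id, template_ids) ->
#'   numeric` supplying custom initial scores, e.g. for ablations.
#' @param config A `planner_config`.
#' @param tree The owning `search_tree` (node-count bookkeeping).
#' @return Number of reaction children added.
#' @export
expand <- function(leaf, model, egn, config, tree) {
  if (leaf$expanded) stop_egmcts("state", "leaf is already expanded")
  if (leaf$is_block) stop_egmcts("state", "building blocks are not expanded")
  pred <- model_predict(model, leaf$molecule, config$k)
  leaf$expanded <- TRUE
  if (nrow(pred) == 0L) {
    leaf$status <- "disproven"
    leaf$value <- 0
    return(0L)
  }
  ancestors <- character(0)
  anc <- leaf
  while (!is.null(anc)) {
    if (anc$kind == "mol") ancestors <- c(ancestors, anc$molecule)
    anc <- anc$parent
  }
  q0 <- if (is.null(egn)) {
    rep(0.5, nrow(pred))
  } else if (is.function(egn)) {
    egn(leaf$molecule, pred$template)
  } else {
    egn_predict_pairs(egn, rep(leaf$molecule, nrow(pred)), pred$template)
  }
  for (j in seq_len(nrow(pred))) {
    rnode <- new_reaction_node(pred$template[j], q0[j], pred$prob[j], leaf)
    rs <- model_reactants(model, pred$template[j], leaf$molecule)
    for (r in rs) {
      child <- new_molecule_node(
        r, model_is_block(model, r), parent = rnode,
        depth = leaf$depth + 1L, cycle_guard = r %in% ancestors
      )
      rnode$children[[length(rnode$children) + 1L]] <- child
    }
    refresh_status(rnode)
    leaf$children[[length(leaf$children) + 1L]] <- rnode
    tree$expanded_reaction_nodes <- tree$expanded_reaction_nodes + 1L
    tree$expanded_molecule_nodes <- tree$expanded_molecule_nodes + length(rs)
  }
  nrow(pred)
}

#' Reward of a reaction node
#'
#' +z when the node is proven, -z when disproven; otherwise the mean of the
#' children's V values under the leaf conventions (building block 1,
#' unexpanded molecule 0, disproven molecule 0). The worked case: a
#' template splitting a molecule into one building block and one unproven
#' molecule is rewarded (1 + 0) / 2 = 1/2.
#'
#' @param rnode A reaction node.
#' @param z Reward magnitude.
#' @return Numeric reward.
#' @export
reward_value <- function(rnode, z = 10) {
  if (rnode$status == "proven") return(z)
  if (rnode$status == "disproven") return(-z)
  mean(vapply(rnode$children, function(ch) ch$value, numeric(1)))
}

#' Update pass from a just-expanded leaf to the root
#'
#' First scores those newly created reaction children whose status is
#' already decided -- a template whose reactants are all building blocks
#' is proven at creation and receives +z, a cycle-guarded one is
#' disproven and receives -z -- so the tree's stored scores always
#' reflect known verdicts. Undecided children keep q_bar = Q0 until an
#' update pass reaches them from below, leaving the network's guidance
#' undiluted at fresh nodes. Then walks to the root: at each
#' molecule node refresh the status and, unless disproven (V pinned to 0),
#' set V to the highest child q_bar; at each reaction node refresh the
#' status, increment the update count N, draw a reward, and recompute
#' q_bar = (Q0 + sum of rewards) / (N + 1). Q0 is averaged in but never
#' counted in N.
#'
#' @param tree A `search_tree`.
#' @param from_leaf The molecule node the iteration expanded.
#' @param config A `planner_config`.
#' @return `NULL`, invisibly.
#' @export
update_tree <- function(tree, from_leaf, config) {
  score_reaction <- function(rnode) {
    refresh_status(rnode)
    rnode$n_updates <- rnode$n_updates + 1L
    q_n <- reward_value(rnode, config$z)
    rnode$reward_sum <- rnode$reward_sum + q_n
    rnode$q_bar <- (rnode$q0 + rnode$reward_sum) / (rnode$n_updates + 1)
  }
  for (ch in from_leaf$children) {
    if (ch$status %in% c("proven", "disproven")) score_reaction(ch)
  }
  node <- from_leaf
  repeat {
    refresh_status(node)
    if (node$status == "disproven") {
      node$value <- 0
    } else if (length(node$children) > 0L) {
      node$value <- max(vapply(node$children, function(ch) ch$q_bar, numeric(1)))
    } else {
      node$value <- if (node$is_block) 1 else 0
    }
    rnode <- node$parent
    if (is.null(rnode)) break
    score_reaction(rnode)
    node <- rnode$parent
  }
  invisible(NULL)
}

#' Run the planning loop for one target
#'
#' Repeats Selection, Expansion and Update until the iteration budget is
#' exhausted, the root's fate is decided (in route-finding mode), or the
#' tree saturates. Every iteration makes exactly one single-step model
#' call; `iterations_used` on the returned tree counts them.
#'
#' @param target Target molecule id.
#' @param model Single-step model (e.g. a `reaction_universe`).
#' @param egn `egn_params`, or `NULL` for the non-learning configuration in
#'   which every Q0 is 0.5.
#' @param config A `planner_config`.
#' @return The finished `search_tree`.
#' @export
plan <- function(target, model, egn = NULL, config = planner_config()) {
  stopifnot(inherits(config, "planner_config"))
  tree <- init_tree(target, blocks = model, seed = config$seed)
  if (tree$root$status == "proven") return(tree)
  withr::with_seed(config$seed, {
    for (i in seq_len(config$iter_limit)) {
      if (config$stop_on_proven && tree$root$status == "proven") break
      if (tree$root$status == "disproven") break
      leaf <- .select_from_mol(tree$root, config)
      if (is.null(leaf)) break              # saturated: no selectable leaf
      tree$iterations_used <- tree$iterations_used + 1L
      expand(leaf, model, egn, config, tree)
      update_tree(tree, leaf, config)
    }
  })
  tree
}
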