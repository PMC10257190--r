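# Route extraction and route-level metrics.
#
# A route is an ordered list of reactions product -> {reactants} whose
# first product is the target and whose every reactant is either a
# building block or the product of a later step. Extraction is a
# breadth-first queue walk over a finished tree: at each non-block
# molecule node it follows one proven reaction child (the one with the
# highest q_bar, matching the search's own preference) and fails with an
# empty reaction list if a non-block molecule has no proven child.

#' Extract a synthetic route from a finished tree
#'
#' @param tree A finished `search_tree`.
#' @return List of class `synth_route` with elements `success` (logical),
#'   `target`, and `steps`: a data.frame with columns `product`,
#'   `template`, and list-column `reactants`. On failure `steps` has zero
#'   rows.
#' @export
extract_route <- function(tree) {
  empty <- data.frame(product = character(0), template = character(0))
  empty$reactants <- list()
  fail <- structure(list(success = FALSE, target = tree$root$molecule,
                         steps = empty), class = "synth_route")
  queue <- list(tree$root)
  products <- character(0)
  templates <- character(0)
  reactants <- list()
  while (length(queue) > 0L) {
    node <- queue[[1L]]
    queue <- queue[-1L]
    if (node$is_block) next
    if (node$molecule %in% products) next   # synthesized by an earlier step
    proven <- Filter(function(ch) ch$status == "proven", node$children)
    if (length(proven) == 0L) return(fail)
    qb <- vapply(proven, function(ch) ch$q_bar, numeric(1))
    best <- proven[[which.max(qb)]]     # ties: which.max keeps lowest index
    products <- c(products, node$molecule)
    templates <- c(templates, best$template)
    reactants[[length(reactants) + 1L]] <-
      vapply(best$children, function(ch) ch$molecule, character(1))
    queue <- c(queue, best$children)
  }
  steps <- data.frame(product = products, template = templates,
                      stringsAsFactors = FALSE)
  steps$reactants <- reactants
  structure(list(success = TRUE, target = tree$root$molecule, steps = steps),
            class = "synth_route")
}

#' @export
print.synth_route <- function(x, ...) {
  if (!x$success) {
    cat(sprintf("<synth_route> target %s: FAILED (no route)\n", x$target))
    return(invisible(x))
  }
  cat(sprintf("<synth_route> target %s, %d step(s)\n", x$target, nrow(x$steps)))
  for (i in seq_len(nrow(x$steps))) {
    cat(sprintf("  %s >> %s\n", x$steps$product[i],
                paste(x$steps$reactants[[i]], collapse = " . ")))
  }
  invisible(x)
}

#' Number of reactions in a route
#'
#' @param route A `synth_route`.
#' @return Integer step count (0 for a block target or a failed route).
#' @export
route_length <- function(route) nrow(route$steps)

#' Check the structural invariants of a route
#'
#' The first step's product must be the target (unless the target is
#' itself a building block and the route is empty); each molecule is
#' synthesized by at most one step; every reactant must be a building
#' block or the product of another step; and the synthesize-from relation
#' among products must be acyclic, so the route can be replayed forward
#' from the blocks.
#'
#' @param route A `synth_route`.
#' @param blocks Character vector of building-block ids.
#' @return Logical.
#' @export
route_is_valid <- function(route, blocks) {
  if (!route$success) return(FALSE)
  st <- route$steps
  if (nrow(st) == 0L) return(route$target %in% blocks)
  if (st$product[1L] != route$target) return(FALSE)
  if (anyDuplicated(st$product) > 0L) return(FALSE)
  for (i in seq_len(nrow(st))) {
    for (r in st$reactants[[i]]) {
      if (!(r %in% blocks) && !(r %in% st$product)) return(FALSE)
    }
  }
  # acyclicity of product -> non-block reactant dependencies
  color <- stats::setNames(rep(0L, nrow(st)), st$product)
  dfs <- function(p) {
    if (color[[p]] == 1L) return(FALSE)
    if (color[[p]] == 2L) return(TRUE)
    color[[p]] <<- 1L
    deps <- intersect(st$reactants[[match(p, st$product)]], st$product)
    for (d in deps) if (!dfs(d)) return(FALSE)
    color[[p]] <<- 2L
    TRUE
  }
  all(vapply(st$product, dfs, logical(1)))
}

#' Replay a route forward against a universe
#'
#' Applies each reaction bottom-up and checks that the route synthesizes
#' exactly the target from building-block members: every step's stored
#' reactants must match the universe's decomposition table.
#'
#' @param route A `synth_route`.
#' @param universe A `reaction_universe`.
#' @return Logical.
#' @export
route_replays <- function(route, universe) {
  if (!route$success) return(FALSE)
  st <- route$steps
  for (i in seq_len(nrow(st))) {
    rs <- tryCatch(apply_template(universe, st$template[i], st$product[i]),
                   error = function(e) NULL)
    if (is.null(rs) || !setequal(rs, st$reactants[[i]])) return(FALSE)
  }
  route_is_valid(route, universe$blocks)
}

.step_signatures <- function(route) {
  st <- route$steps
  vapply(seq_len(nrow(st)), function(i) {
    paste0(st$product[i], ">>",
           paste(sort(unique(st$reactants[[i]])), collapse = "."))
  }, character(1))
}

.lcs_length <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) return(0L)
  prev <- integer(nb + 1L)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    for (j in seq_len(nb)) {
      cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L
                     else max(cur[j], prev[j + 1L])
    }
    prev <- cur
  }
  prev[nb + 1L]
}

#' Matching degree between a generated and a published route
#'
#' A generated step matches when it appears in the published route in the
#' same order (order means subsequence order, not adjacency): the number
#' of matches is the longest common ordered subsequence of step
#' signatures, where a signature is the product plus the deduplicated set
#' of reactants -- duplicated by-products are immaterial. The degree is
#' matches / number of generated steps.
#'
#' @param generated Non-empty `synth_route`.
#' @param published `synth_route` (or any object with the same `steps`
#'   layout) to compare against.
#' @return Real in \eqn{[0, 1]}.
#' @export
matching_degree <- function(generated, published) {
  if (route_length(generated) == 0L) {
    stop_egmcts("argument", "generated route must be non-empty")
  }
  g <- .step_signatures(generated)
  p <- .step_signatures(published)
  .lcs_length(g, p) / length(g)
}

#' Build a route object from explicit steps
#'
#' Convenience constructor used when comparing against externally given
#' (published) routes.
#'
#' @param target Target molecule id.
#' @param products Character vector of step products.
#' @param templates Character vector of step templates (optional, defaults
#'   to empty strings).
#' @param reactants List of character vectors, one per step.
#' @return A `synth_route`.
#' @export
make_route <- function(target, products, reactants,
                       templates = rep("", length(products))) {
  steps <- data.frame(product = products, template = templates,
                      stringsAsFactors = FALSE)
  steps$reactants <- reactants
  structure(list(success = TRUE, target = target, steps = steps),
            class = "synth_route")
}

#' Write a route to JSON (and optionally flat text)
#'
#' JSON list of steps `{product, template, reactants}`; with
#' `text = TRUE` a flat rendering `product >> r1 . r2` is written next to
#' it with extension `.txt`.
#'
#' @param route A `synth_route`.
#' @param path Output JSON path.
#' @param text Also write the flat text rendering.
#' @return `path`, invisibly.
#' @export
write_route <- function(route, path, text = FALSE) {
  doc <- list(
    target = route$target,
    success = route$success,
    steps = lapply(seq_len(nrow(route$steps)), function(i) {
      list(product = route$steps$product[i],
           template = route$steps$template[i],
           reactants = route$steps$reactants[[i]])
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  if (text) {
    writeLines(
      vapply(seq_len(nrow(route$steps)), function(i) {
        sprintf("%s >> %s", route$steps$product[i],
                paste(route$steps$reactants[[i]], collapse = " . "))
      }, character(1)),
      sub("\\.json$", ".txt", path)
    )
  }
  invisible(path)
}

#' Fingerprint-similarity statistics between a test and a training set
#'
#' For every test molecule, the highest and the mean Tanimoto similarity
#' to the training molecules (over the molecule hash fingerprints), plus
#' the set-level means of both.
#'
#' @param test_set,train_set Non-empty character vectors of molecule ids.
#' @return List with `per_molecule` (data.frame of `molecule`, `s_max`,
#'   `s_avg`), `mean_s_max`, `mean_s_avg`.
#' @export
similarity_stats <- function(test_set, train_set) {
  if (length(test_set) == 0L || length(train_set) == 0L) {
    stop_egmcts("argument", "both molecule sets must be non-empty")
  }
  train_fp <- lapply(train_set, fingerprint_bits)
  s_max <- numeric(length(test_set))
  s_avg <- numeric(length(test_set))
  for (i in seq_along(test_set)) {
    fp <- fingerprint_bits(test_set[i])
    sims <- vapply(train_fp, tanimoto, numeric(1), bits_a = fp)
    s_max[i] <- max(sims)
    s_avg[i] <- mean(sims)
  }
  list(
    per_molecule = data.frame(molecule = test_set, s_max = s_max,
                              s_avg = s_avg, stringsAsFactors = FALSE),
    mean_s_max = mean(s_max),
    mean_s_avg = mean(s_avg)
  )
}
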