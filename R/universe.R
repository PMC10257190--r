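# Synthetic reaction universes.
#
# A universe stands in for the pair (single-step retrosynthetic model S(.),
# building-blocks set B) that a real deployment would obtain from a
# template-based model trained on a reaction corpus. Molecules are opaque
# tokens; templates are lookup keys into a stored decomposition table.
# Construction is layered (building blocks in layer 0, each template's
# reactants strictly below its product's layer) so the decomposition
# relation is acyclic and exact ground truth -- solvability and minimal
# route length -- is computable for every molecule.

#' Generate a synthetic reaction universe
#'
#' Builds a random universe of molecules, reaction templates and a
#' building-blocks set with known ground truth. Non-block molecules are
#' placed in layers above the blocks; every template decomposes its product
#' into reactants from strictly lower layers, so decompositions are acyclic.
#' Each molecule designated solvable receives at least one template whose
#' reactants are all solvable (a viable decomposition) plus possibly
#' further templates drawn from the whole lower population, which may lead
#' into dead ends. Molecules designated unsolvable receive either no
#' template or only templates containing at least one unsolvable reactant,
#' so no route to the blocks exists for them.
#'
#' Template probabilities are drawn from a Dirichlet-style allocation
#' (exponential weights, normalized so the per-molecule total stays below
#' 1). `prior_quality` controls how informative the emulated single-step
#' model is: the viable template's weight is multiplied by
#' `1 + prior_quality`, so at 0 the probabilities are pure noise while at
#' larger values the model ranks the productive decomposition higher on
#' average -- as a policy trained on real reaction corpora does -- without
#' guaranteeing it the top rank. Unsolvable molecules receive no boost
#' anywhere: the emulated model is confidently wrong on them, exactly the
#' regime in which value guidance must help. Probabilities are stored once
#' and never re-sampled, so the single-step model is a fixed function of
#' the molecule during any search.
#'
#' @param n_blocks Number of building-block molecules.
#' @param n_nonblocks Number of non-block molecules.
#' @param max_templates_per_molecule Maximum templates per molecule.
#' @param max_reactants Maximum reactants per template.
#' @param unsolvable_fraction Fraction of non-block molecules designated
#'   unsolvable (no route to the blocks exists).
#' @param n_layers Number of layers for the non-block molecules; default
#'   scales with `n_nonblocks` (roughly one layer per five molecules, at
#'   most eight).
#' @param chain_bias Probability that a reactant is drawn from the layer
#'   immediately below its product rather than uniformly from all lower
#'   layers. Higher values give deeper synthesis chains (route lengths
#'   that grow with the target's layer), mimicking the multi-step
#'   structure of real synthesis corpora; 0 reduces to uniform sampling.
#' @param prior_quality Multiplicative weight boost for the viable
#'   template in the probability allocation (see above); 0 gives
#'   uninformative priors.
#' @param seed Integer seed; identical seeds give identical universes.
#' @return An object of class `reaction_universe`: a list with elements
#'   `molecules`, `blocks`, `templates`, `template_product`,
#'   `template_pattern`, `reactants` (template id -> reactant ids),
#'   `mol_templates` (molecule -> data.frame of template, prob, sorted by
#'   descending probability), `layer`, `solvable`, `min_len` (ground-truth
#'   minimal route length counted with repetition -- every occurrence of an
#'   intermediate adds its reactions; `NA` for unsolvable molecules), and
#'   `seed`.
#' @export
generate_universe <- function(n_blocks, n_nonblocks,
                              max_templates_per_molecule = 4L,
                              max_reactants = 3L,
                              unsolvable_fraction = 0,
                              n_layers = NULL,
                              chain_bias = 0.7,
                              prior_quality = 1,
                              seed = 1L) {
  if (n_blocks < 0 || n_nonblocks < 0) {
    stop_egmcts("argument", "n_blocks and n_nonblocks must be >= 0")
  }
  if (unsolvable_fraction < 0 || unsolvable_fraction > 1) {
    stop_egmcts("argument", "unsolvable_fraction must lie in [0, 1]")
  }
  if (max_templates_per_molecule < 1 || max_reactants < 1) {
    stop_egmcts("argument", "template and reactant caps must be >= 1")
  }
  withr::with_seed(seed, {
    blocks <- if (n_blocks > 0) sprintf("B%04d", seq_len(n_blocks)) else character(0)
    nonblocks <- if (n_nonblocks > 0) sprintf("M%04d", seq_len(n_nonblocks)) else character(0)
    molecules <- c(blocks, nonblocks)

    if (is.null(n_layers)) {
      n_layers <- max(1L, min(8L, as.integer(ceiling(n_nonblocks / 5))))
    }
    layer <- c(
      stats::setNames(rep(0L, n_blocks), blocks),
      stats::setNames(
        if (n_nonblocks > 0) sort(1L + (seq_len(n_nonblocks) - 1L) %% n_layers) else integer(0),
        nonblocks
      )
    )

    n_unsolv <- as.integer(floor(unsolvable_fraction * n_nonblocks + 0.5))
    solvable <- stats::setNames(rep(TRUE, length(molecules)), molecules)
    if (n_blocks == 0 && n_nonblocks > 0) {
      solvable[nonblocks] <- FALSE          # nothing can terminate at B
    } else if (n_unsolv > 0) {
      solvable[sample(nonblocks, n_unsolv)] <- FALSE
    }

    # sample `size` distinct reactants from `pool`, preferring the layer
    # immediately below the product's
    biased_sample <- function(pool, size, prod_layer) {
      size <- min(size, length(pool))
      if (size == length(pool)) return(pool)
      adj <- layer[pool] == prod_layer - 1L
      w <- numeric(length(pool))
      if (any(adj)) w[adj] <- chain_bias / sum(adj)
      if (any(!adj)) w[!adj] <- (1 - chain_bias) / sum(!adj)
      if (sum(w) == 0) w <- rep(1, length(pool))
      pool[sample.int(length(pool), size, prob = w / sum(w))]
    }

    template_product <- character(0)
    template_pattern <- character(0)
    reactants <- list()
    mol_templates <- stats::setNames(vector("list", length(molecules)), molecules)
    tcount <- 0L

    for (m in molecules) {
      if (layer[[m]] == 0L) {
        mol_templates[[m]] <- data.frame(template = character(0), prob = numeric(0),
                                         stringsAsFactors = FALSE)
        next
      }
      lower_all <- molecules[layer[molecules] < layer[[m]]]
      lower_solv <- lower_all[solvable[lower_all]]
      lower_unsolv <- lower_all[!solvable[lower_all]]

      if (solvable[[m]]) {
        nt <- sample.int(max_templates_per_molecule, 1L)
        good_n <- sample.int(min(max_reactants, length(lower_solv)), 1L)
        rsets <- list(biased_sample(lower_solv, good_n, layer[[m]]))
        if (nt > 1L) {
          for (j in seq_len(nt - 1L)) {
            sz <- sample.int(min(max_reactants, length(lower_all)), 1L)
            rsets[[j + 1L]] <- biased_sample(lower_all, sz, layer[[m]])
          }
        }
      } else {
        if (length(lower_unsolv) == 0L) {
          nt <- 0L
          rsets <- list()
        } else {
          nt <- sample(0:max_templates_per_molecule, 1L)
          # every template carries a "poison" unsolvable reactant, so the
          # molecule is unsolvable by induction over layers
          rsets <- lapply(seq_len(nt), function(j) {
            sz <- sample.int(min(max_reactants, length(lower_all)), 1L)
            poison <- biased_sample(lower_unsolv, 1L, layer[[m]])
            others <- setdiff(lower_all, poison)
            extra <- if (sz > 1L && length(others) > 0L) {
              biased_sample(others, min(sz - 1L, length(others)), layer[[m]])
            } else character(0)
            c(poison, extra)
          })
        }
      }

      if (nt == 0L) {
        mol_templates[[m]] <- data.frame(template = character(0), prob = numeric(0),
                                         stringsAsFactors = FALSE)
        next
      }
      ids <- sprintf("T%05d", tcount + seq_len(nt))
      tcount <- tcount + nt
      # iid exponential weights keep the ranking noisy; the boost makes the
      # viable template (index 1) *likelier*, not certain, to rank high
      w <- stats::rexp(nt)
      if (solvable[[m]]) w[1L] <- w[1L] * (1 + prior_quality)
      probs <- w / sum(w) * stats::runif(1, 0.75, 0.95)
      for (j in seq_len(nt)) {
        template_product[[ids[j]]] <- m
        template_pattern[[ids[j]]] <- paste0(m, ">>", paste(rsets[[j]], collapse = "."))
        reactants[[ids[j]]] <- rsets[[j]]
      }
      ord <- order(probs, decreasing = TRUE)
      mol_templates[[m]] <- data.frame(template = ids[ord], prob = probs[ord],
                                       stringsAsFactors = FALSE)
    }

    # ground-truth minimal route length by dynamic programming over layers
    min_len <- stats::setNames(rep(NA_real_, length(molecules)), molecules)
    min_len[blocks] <- 0
    for (m in molecules[order(layer[molecules])]) {
      if (layer[[m]] == 0L) next
      mt <- mol_templates[[m]]
      best <- Inf
      for (tid in mt$template) {
        rl <- min_len[reactants[[tid]]]
        if (!anyNA(rl)) best <- min(best, 1 + sum(rl))
      }
      min_len[[m]] <- if (is.finite(best)) best else NA_real_
    }
    # reconcile: a "decoy" template can accidentally be viable only for
    # solvable molecules (unsolvable ones always carry a poison reactant)
    stopifnot(all(is.na(min_len[molecules[!solvable[molecules]]])))

    structure(
      list(
        molecules = molecules,
        blocks = blocks,
        templates = names(template_product),
        template_product = template_product,
        template_pattern = template_pattern,
        reactants = reactants,
        mol_templates = mol_templates,
        layer = layer,
        solvable = solvable,
        min_len = min_len,
        seed = as.integer(seed),
        params = list(
          n_blocks = as.integer(n_blocks),
          n_nonblocks = as.integer(n_nonblocks),
          max_templates_per_molecule = as.integer(max_templates_per_molecule),
          max_reactants = as.integer(max_reactants),
          unsolvable_fraction = unsolvable_fraction,
          n_layers = as.integer(n_layers),
          chain_bias = chain_bias,
          prior_quality = prior_quality
        )
      ),
      class = "reaction_universe"
    )
  })
}

#' @export
print.reaction_universe <- function(x, ...) {
  cat(sprintf(
    "<reaction_universe> %d molecules (%d blocks), %d templates, %d solvable non-blocks, seed %d\n",
    length(x$molecules), length(x$blocks), length(x$templates),
    sum(x$solvable) - length(x$blocks), x$seed
  ))
  invisible(x)
}

#' Apply a reaction template to a molecule
#'
#' Looks up the stored decomposition of `molecule` under `template` and
#' returns its reactant list (order-stable). Applying a template to a
#' molecule it does not decompose is an error, distinct from an empty
#' reactant list.
#'
#' @param universe A `reaction_universe`.
#' @param template Template id.
#' @param molecule Molecule id.
#' @return Character vector of reactant ids.
#' @export
apply_template <- function(universe, template, molecule) {
  stopifnot(inherits(universe, "reaction_universe"))
  prod <- universe$template_product[template]
  if (is.na(prod) || prod != molecule) {
    stop_egmcts("inapplicable",
                sprintf("template %s is not applicable to molecule %s",
                        template, molecule))
  }
  universe$reactants[[template]]
}

#' Single-step retrosynthetic prediction
#'
#' The single-step model contract S(m): the top-`k` templates applicable to
#' `molecule`, with probabilities in non-increasing order. A molecule with
#' no applicable template (every building block, and some dead-end
#' molecules) yields an empty prediction. When fewer than `k` templates
#' exist, all of them are returned; none are fabricated.
#'
#' @param universe A `reaction_universe`.
#' @param molecule Molecule id present in the universe.
#' @param k Maximum number of templates to return (>= 1).
#' @return A data.frame of class `single_step_prediction` with columns
#'   `template` and `prob`.
#' @export
single_step_predict <- function(universe, molecule, k = 50L) {
  stopifnot(inherits(universe, "reaction_universe"))
  if (k < 1) stop_egmcts("argument", "k must be >= 1")
  if (!molecule %in% universe$molecules) {
    stop_egmcts("argument", sprintf("unknown molecule: %s", molecule))
  }
  mt <- universe$mol_templates[[molecule]]
  out <- mt[seq_len(min(nrow(mt), k)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("single_step_prediction", "data.frame")
  out
}

#' Dispatching wrapper around a single-step model
#'
#' Generic S(m) contract used by the planner and baselines: any object with
#' a `model_predict` method can serve as the single-step model. The shipped
#' method covers `reaction_universe`; a real-chemistry adapter (template
#' SMARTS application over SMILES) would add another method.
#'
#' @param model Model object.
#' @param molecule Molecule id.
#' @param k Maximum number of templates.
#' @return A `single_step_prediction`.
#' @export
model_predict <- function(model, molecule, k = 50L) UseMethod("model_predict")

#' @export
model_predict.reaction_universe <- function(model, molecule, k = 50L) {
  single_step_predict(model, molecule, k)
}

#' Is the molecule a building block?
#'
#' @param model Model object (dispatches like [model_predict()]).
#' @param molecule Molecule id.
#' @return Logical.
#' @export
model_is_block <- function(model, molecule) UseMethod("model_is_block")

#' @export
model_is_block.reaction_universe <- function(model, molecule) {
  molecule %in% model$blocks
}

#' Reactants of a template under a model
#'
#' @inheritParams apply_template
#' @param model Model object.
#' @return Character vector of reactant ids.
#' @export
model_reactants <- function(model, template, molecule) UseMethod("model_reactants")

#' @export
model_reactants.reaction_universe <- function(model, template, molecule) {
  apply_template(model, template, molecule)
}

#' Serialize a universe to JSON
#'
#' @param universe A `reaction_universe`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_universe <- function(universe, path) {
  stopifnot(inherits(universe, "reaction_universe"))
  doc <- list(
    molecules = universe$molecules,
    blocks = universe$blocks,
    templates = universe$templates,
    template_product = as.list(universe$template_product),
    template_pattern = as.list(universe$template_pattern),
    reactants = universe$reactants,
    mol_templates = lapply(universe$mol_templates, function(mt) {
      list(template = mt$template, prob = mt$prob)
    }),
    layer = as.list(universe$layer),
    solvable = as.list(universe$solvable),
    min_len = as.list(universe$min_len),
    seed = universe$seed,
    params = universe$params
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a universe back from JSON
#'
#' Inverse of [write_universe()]: `read_universe(write_universe(u, f))`
#' reproduces `u`.
#'
#' @param path JSON file written by [write_universe()].
#' @return A `reaction_universe`.
#' @export
read_universe <- function(path) {
  doc <- jsonlite::read_json(path)
  mols <- unlist(doc$molecules)
  unl_named <- function(x) if (length(x)) unlist(x) else
    stats::setNames(character(0), character(0))
  min_len <- vapply(doc$min_len, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
                    numeric(1))
  names(min_len) <- names(doc$min_len)
  structure(
    list(
      molecules = mols,
      blocks = if (length(doc$blocks)) unlist(doc$blocks) else character(0),
      templates = if (length(doc$templates)) unlist(doc$templates) else character(0),
      template_product = unl_named(doc$template_product),
      template_pattern = unl_named(doc$template_pattern),
      reactants = lapply(doc$reactants, unlist),
      mol_templates = lapply(doc$mol_templates, function(mt) {
        data.frame(
          template = if (length(mt$template)) unlist(mt$template) else character(0),
          prob = if (length(mt$prob)) unlist(mt$prob) else numeric(0),
          stringsAsFactors = FALSE
        )
      }),
      layer = vapply(doc$layer, as.integer, integer(1)),
      solvable = vapply(doc$solvable, as.logical, logical(1)),
      min_len = min_len,
      seed = as.integer(doc$seed),
      params = list(
        n_blocks = as.integer(doc$params$n_blocks),
        n_nonblocks = as.integer(doc$params$n_nonblocks),
        max_templates_per_molecule = as.integer(doc$params$max_templates_per_molecule),
        max_reactants = as.integer(doc$params$max_reactants),
        unsolvable_fraction = as.numeric(doc$params$unsolvable_fraction),
        n_layers = as.integer(doc$params$n_layers),
        chain_bias = as.numeric(doc$params$chain_bias),
        prior_quality = as.numeric(doc$params$prior_quality)
      )
    ),
    class = "reaction_universe"
  )
}

#' Write a building-blocks file
#'
#' Newline-delimited molecule identifiers, the interchange format for the
#' building-blocks set.
#'
#' @param blocks Character vector of block ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blocks <- function(blocks, path) {
  writeLines(blocks, path)
  invisible(path)
}

#' Read a building-blocks file
#'
#' @param path Newline-delimited identifier file.
#' @return Character vector of ids (empty lines dropped).
#' @export
read_blocks <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}
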