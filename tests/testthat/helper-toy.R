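# Hand-built universes with exactly controlled decompositions and
# probabilities; unlike the generator these may contain cycles, which the
# loop-guard tests need.
#
# `templates` is a list of lists with fields: product, id, prob, reactants.
toy_universe <- function(blocks, templates = list()) {
  products <- vapply(templates, `[[`, character(1), "product")
  ids <- vapply(templates, `[[`, character(1), "id")
  probs <- vapply(templates, `[[`, numeric(1), "prob")
  reactant_sets <- lapply(templates, `[[`, "reactants")
  molecules <- unique(c(blocks, products, unlist(reactant_sets)))
  mol_templates <- stats::setNames(lapply(molecules, function(m) {
    sel <- which(products == m)
    sel <- sel[order(-probs[sel])]
    data.frame(template = ids[sel], prob = probs[sel], stringsAsFactors = FALSE)
  }), molecules)
  structure(
    list(
      molecules = molecules,
      blocks = blocks,
      templates = ids,
      template_product = stats::setNames(products, ids),
      template_pattern = stats::setNames(
        paste0(products, ">>", vapply(reactant_sets, paste, character(1),
                                      collapse = ".")), ids),
      reactants = stats::setNames(reactant_sets, ids),
      mol_templates = mol_templates,
      layer = NULL, solvable = NULL, min_len = NULL,
      seed = 0L, params = list()
    ),
    class = "reaction_universe"
  )
}

tmpl <- function(product, id, prob, reactants) {
  list(product = product, id = id, prob = prob, reactants = reactants)
}
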