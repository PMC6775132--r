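#' Construct a metabolic model
#'
#' A light tabular container for a stoichiometric model: species with
#' compartment tags, reactions with subsystem labels and boolean gene rules,
#' and a long-format stoichiometry table. Gene rules are flattened for
#' distance calculations: any gene appearing in a reaction's rule is
#' associated with that reaction (reachability needs membership, not enzyme
#' logic).
#'
#' @param metabolites Tibble with columns `id` and `compartment` (e.g. "c",
#'   "p", "e").
#' @param reactions Tibble with columns `id`, `subsystem`, `gene_rule`
#'   (boolean rule string; empty for geneless reactions).
#' @param stoich Tibble with columns `reaction`, `metabolite`, `coef`
#'   (signed stoichiometric coefficients).
#' @param cofactors Character vector of metabolite ids treated as cofactors
#'   (pruned before distance calculations). Defaults to a standard list of
#'   energy and redox carriers.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoich,
                            cofactors = default_cofactors()) {
  metabolites <- as_tibble(metabolites)
  reactions <- as_tibble(reactions)
  stoich <- as_tibble(stoich)
  if (anyDuplicated(metabolites$id)) stopf("duplicate metabolite ids in model")
  if (anyDuplicated(reactions$id)) stopf("duplicate reaction ids in model")
  bad <- setdiff(stoich$metabolite, metabolites$id)
  if (length(bad))
    stopf("stoichiometry references unknown metabolite(s): %s",
          paste(head(bad, 3), collapse = ", "))
  bad <- setdiff(stoich$reaction, reactions$id)
  if (length(bad))
    stopf("stoichiometry references unknown reaction(s): %s",
          paste(head(bad, 3), collapse = ", "))
  if (!"subsystem" %in% names(reactions)) reactions$subsystem <- NA_character_
  if (!"gene_rule" %in% names(reactions)) reactions$gene_rule <- ""
  reactions$gene_rule[is.na(reactions$gene_rule)] <- ""
  cofactors <- intersect(cofactors, metabolites$id)
  structure(list(metabolites = metabolites, reactions = reactions,
                 stoich = stoich, cofactors = cofactors),
            class = "metabolic_model")
}

#' Default cofactor list
#'
#' Common energy and redox carriers pruned from the metabolite-gene graph so
#' that they do not short-circuit network distances.
#' @return Character vector of metabolite id stems; compartment-suffixed
#'   variants (`_c`, `_p`, `_e`) are matched too.
#' @export
default_cofactors <- function() {
  stems <- c("atp", "adp", "amp", "nad", "nadh", "nadp", "nadph", "coa",
             "accoa", "h", "h2o", "pi", "ppi", "co2", "o2", "nh4")
  c(stems, paste0(rep(stems, each = 3), "_", c("c", "p", "e")))
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %d metabolites x %d reactions, %d subsystems, %d declared cofactors\n",
              nrow(x$metabolites), nrow(x$reactions),
              dplyr::n_distinct(stats::na.omit(x$reactions$subsystem)),
              length(x$cofactors)))
  invisible(x)
}

# flatten a boolean gene rule to the genes it mentions
flatten_gene_rule <- function(rule) {
  toks <- stringr::str_extract_all(rule %||% "", "[A-Za-z0-9_.\\-]+")[[1]]
  unique(setdiff(toks, c("and", "or", "AND", "OR", "And", "Or")))
}

#' Extract the stoichiometric and reaction-gene matrices of a model
#'
#' @param model A [metabolic_model()].
#' @return A list with `N` (metabolites x reactions, signed coefficients),
#'   `G` (reactions x genes, logical) and `genes` (character).
#' @export
model_matrices <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  N <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  N[cbind(match(model$stoich$metabolite, mets),
          match(model$stoich$reaction, rxns))] <- model$stoich$coef
  gene_sets <- lapply(model$reactions$gene_rule, flatten_gene_rule)
  genes <- sort(unique(unlist(gene_sets)))
  G <- matrix(FALSE, length(rxns), length(genes),
              dimnames = list(rxns, genes))
  for (i in seq_along(gene_sets))
    if (length(gene_sets[[i]])) G[i, gene_sets[[i]]] <- TRUE
  list(N = N, G = G, genes = genes)
}

#' Reaction-gene association table
#'
#' @param model A [metabolic_model()].
#' @return Tibble with columns `reaction`, `gene`, `subsystem`; geneless
#'   reactions are flagged with a message and omitted.
#' @export
reaction_genes <- function(model) {
  sets <- lapply(model$reactions$gene_rule, flatten_gene_rule)
  geneless <- model$reactions$id[lengths(sets) == 0]
  if (length(geneless))
    inform(sprintf("%d geneless reaction(s) retained but contribute no metabolite-gene edges",
                   length(geneless)))
  purrr::map_dfr(seq_along(sets), function(i) {
    if (!length(sets[[i]])) return(NULL)
    tibble(reaction = model$reactions$id[i], gene = sets[[i]],
           subsystem = model$reactions$subsystem[i])
  })
}
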