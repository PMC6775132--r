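# Metabolic-model serialization: a JSON schema (cobrapy-like, lossless for
# the package's own models) and a minimal SBML reader covering the subset
# distance calculations need (species/compartments, reactions with
# stoichiometry, fbc gene-product associations, group-based subsystems).

#' Write a metabolic model as JSON
#'
#' @param model A [metabolic_model()].
#' @param path Output path (.json).
#' @export
write_metabolic_model <- function(model, path) {
  obj <- list(
    metabolites = model$metabolites,
    reactions = purrr::map(seq_len(nrow(model$reactions)), function(i) {
      rid <- model$reactions$id[i]
      st <- model$stoich %>% filter(.data$reaction == rid)
      list(id = rid,
           subsystem = model$reactions$subsystem[i],
           gene_rule = model$reactions$gene_rule[i],
           metabolites = as.list(setNames(st$coef, st$metabolite)))
    }),
    cofactors = model$cofactors
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  mets <- purrr::map_dfr(obj$metabolites, function(m)
    tibble(id = m$id, compartment = m$compartment %||% "c"))
  rxns <- purrr::map_dfr(obj$reactions, function(r)
    tibble(id = r$id, subsystem = r$subsystem %||% NA_character_,
           gene_rule = r$gene_rule %||% ""))
  stoich <- purrr::map_dfr(obj$reactions, function(r) {
    if (!length(r$metabolites)) return(NULL)
    tibble(reaction = r$id, metabolite = names(r$metabolites),
           coef = as.numeric(unlist(r$metabolites)))
  })
  metabolic_model(mets, rxns, stoich,
                  cofactors = as.character(unlist(obj$cofactors %||% list())))
}

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- tibble(
    id = xml2::xml_attr(sp, "id"),
    compartment = vapply(xml2::xml_attr(sp, "compartment"), function(cc) {
      # treat compartment ids like "c", "p", "e" (optionally suffixed) by
      # their first letter
      if (is.na(cc) || !nchar(cc)) "c" else substr(cc, 1, 1)
    }, character(1), USE.NAMES = FALSE)
  )

  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- list(); stoich <- list()
  for (r in rx) {
    rid <- xml2::xml_attr(r, "id")
    genes <- xml2::xml_attr(
      xml2::xml_find_all(r, ".//*[local-name()='geneProductRef']"),
      "geneProduct")
    if (!length(genes)) {
      notes <- xml2::xml_text(xml2::xml_find_first(r, ".//notes"))
      ga <- stringr::str_match(notes %||% "",
                               "GENE_ASSOCIATION:\\s*([^<\\n]+)")[, 2]
      if (!is.na(ga)) genes <- flatten_gene_rule(ga)
    }
    subsystem <- stringr::str_match(
      xml2::xml_text(xml2::xml_find_first(r, ".//notes")) %||% "",
      "SUBSYSTEM:\\s*([^<\\n]+)")[, 2]
    rxns[[rid]] <- tibble(id = rid,
                          subsystem = stringr::str_trim(subsystem),
                          gene_rule = paste(genes, collapse = " or "))
    reac <- xml2::xml_find_all(r, "./listOfReactants/speciesReference")
    prod <- xml2::xml_find_all(r, "./listOfProducts/speciesReference")
    coef <- function(nodes, sgn) {
      if (!length(nodes)) return(NULL)
      s <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
      s[is.na(s)] <- 1
      tibble(reaction = rid, metabolite = xml2::xml_attr(nodes, "species"),
             coef = sgn * s)
    }
    stoich[[rid]] <- bind_rows(coef(reac, -1), coef(prod, 1))
  }
  rxn_tbl <- bind_rows(rxns)

  # group-based subsystem annotation overrides note-based ones when present
  groups <- xml2::xml_find_all(doc, ".//*[local-name()='group']")
  for (g in groups) {
    nm <- xml2::xml_attr(g, "name")
    members <- xml2::xml_attr(
      xml2::xml_find_all(g, ".//*[local-name()='member']"), "idRef")
    rxn_tbl$subsystem[rxn_tbl$id %in% members] <- nm
  }
  geneless <- sum(rxn_tbl$gene_rule == "")
  if (geneless)
    inform(sprintf("%d reaction(s) without gene association retained as geneless",
                   geneless))
  metabolic_model(mets, rxn_tbl, bind_rows(stoich))
}

#' Read a metabolic model
#'
#' Dispatches on the file extension: `.json` uses the package's JSON schema
#' (lossless round trip with [write_metabolic_model()]); `.xml`/`.sbml` uses a
#' minimal SBML reader covering species, reactions with stoichiometry, fbc
#' gene-product associations (or `GENE_ASSOCIATION` notes) and group/notes
#' subsystem annotations. Reactions without gene associations are retained but
#' contribute no metabolite-gene edges.
#'
#' @param path Model file (.json, .xml or .sbml).
#' @return A [metabolic_model()].
#' @export
read_metabolic_model <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = read_model_json(path),
         xml = ,
         sbml = read_model_sbml(path),
         stopf("unsupported model format: .%s", ext))
}
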