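# Metabolite-gene distances on the bipartite graph derived from a
# stoichiometric model. Cofactors and non-cytosolic metabolites are pruned
# from the stoichiometric matrix N, the metabolite-gene adjacency is
# F = |N| . G (so substrates and products both yield edges), its boolean
# F' defines an undirected bipartite graph, and shortest paths give the
# distance matrix D. Finite distances are odd by construction
# (metabolite-gene alternation).

#' Build the pruned metabolite-gene adjacency and bipartite graph
#'
#' Removes the model's cofactors and all non-cytosolic (periplasmic,
#' extracellular, ...) metabolites from the stoichiometric matrix, forms the
#' metabolite-gene adjacency `F = |N| %*% G`, booleanizes it to `F'`, and
#' returns the corresponding undirected bipartite graph with metabolite and
#' gene nodes.
#'
#' @param model A [metabolic_model()].
#' @param cofactors Metabolite ids to prune; defaults to the model's declared
#'   cofactor list.
#' @param keep_compartments Compartment tags retained (default `"c"`).
#' @return List of class `met_gene_graph` with `graph` (igraph), `edges`
#'   (tibble `metabolite`, `gene`), `metabolites`, `genes`.
#' @export
build_adjacency <- function(model, cofactors = NULL,
                            keep_compartments = "c") {
  cofactors <- cofactors %||% model$cofactors
  keep <- model$metabolites %>%
    filter(.data$compartment %in% keep_compartments,
           !.data$id %in% cofactors) %>%
    pull("id")
  mm <- model_matrices(model)
  N <- abs(mm$N[intersect(rownames(mm$N), keep), , drop = FALSE])
  if (!nrow(N) || !ncol(mm$G) )
    stopf("empty metabolite-gene graph after pruning")
  Fmat <- N %*% mm$G
  Fb <- Fmat > 0
  edges <- which(Fb, arr.ind = TRUE)
  if (!nrow(edges)) stopf("empty metabolite-gene graph after pruning")
  edge_tbl <- tibble(metabolite = rownames(Fb)[edges[, 1]],
                     gene = colnames(Fb)[edges[, 2]]) %>%
    arrange(.data$metabolite, .data$gene)
  g <- igraph::graph_from_data_frame(
    edge_tbl,
    directed = FALSE,
    vertices = tibble(name = c(rownames(Fb), colnames(Fb)),
                      type = rep(c("metabolite", "gene"),
                                 c(nrow(Fb), ncol(Fb)))))
  structure(list(graph = g, edges = edge_tbl,
                 metabolites = rownames(Fb), genes = colnames(Fb)),
            class = "met_gene_graph")
}

#' All metabolite-gene shortest-path distances
#'
#' Breadth-first shortest paths from every metabolite node of the bipartite
#' graph to every gene node; unreachable pairs are `Inf`. All finite
#' distances are odd positive integers because paths alternate between
#' metabolite and gene nodes.
#'
#' @param adj A `met_gene_graph` from [build_adjacency()].
#' @return Numeric matrix (metabolites x genes) of path lengths.
#' @export
metabolite_gene_distances <- function(adj) {
  D <- igraph::distances(adj$graph, v = adj$metabolites, to = adj$genes,
                         algorithm = "unweighted")
  D[adj$metabolites, adj$genes, drop = FALSE]
}

#' Smallest distance between a metabolite and a TF's target genes
#'
#' @param D Distance matrix from [metabolite_gene_distances()].
#' @param metabolite Metabolite id.
#' @param targets Character vector of the TF's target genes.
#' @return The minimum distance over targets present in `D`; `Inf` when all
#'   present targets are unreachable; `NA` (not computable) when the
#'   metabolite is absent from the model or no target gene is in the model.
#' @export
tf_min_distance <- function(D, metabolite, targets) {
  if (!metabolite %in% rownames(D)) return(NA_real_)
  targets <- intersect(targets, colnames(D))
  if (!length(targets)) return(NA_real_)
  min(D[metabolite, targets])
}

# subsystems of the reactions adjacent to each metabolite (used as the
# default metabolite-subsystem annotation)
adjacent_subsystems <- function(model) {
  model$stoich %>%
    left_join(model$reactions %>% select("id", "subsystem"),
              by = c(reaction = "id")) %>%
    filter(!is.na(.data$subsystem)) %>%
    distinct(metabolite = .data$metabolite, subsystem = .data$subsystem)
}

#' Apply the two-part distance criterion to metabolite-TF pairs
#'
#' A pair passes when (1) the metabolite is a substrate or product of a
#' reaction encoded by one of the TF's target genes, or (2) the metabolite is
#' annotated to a metabolic subsystem shared with a reaction encoded by a
#' target gene ("the metabolic pathways controlled by the TF"). The criterion
#' is distance-free beyond adjacency: criterion 2 can pass for arbitrarily
#' remote pairs. A pair is not computable when the metabolite is absent from
#' the model and has no subsystem annotation.
#'
#' @param pairs Tibble with columns `metabolite`, `regulator` (one row per
#'   pair to judge).
#' @param model A [metabolic_model()].
#' @param regulon Tibble `regulator`, `gene` mapping each TF to its target
#'   genes.
#' @param met_subsystems Optional tibble `metabolite`, `subsystem`; when
#'   omitted, each metabolite inherits the subsystems of its adjacent
#'   reactions.
#' @param cofactors,keep_compartments Passed to [build_adjacency()] for the
#'   substrate/product test.
#' @return Tibble `metabolite`, `regulator`, `passes` (logical, `NA` when not
#'   computable), `satisfied_by` (`"substrate_product"`, `"subsystem"`,
#'   `"none"` or `"not_computable"`), `witness_gene`, `min_distance`.
#' @export
distance_criterion <- function(pairs, model, regulon, met_subsystems = NULL,
                               cofactors = NULL, keep_compartments = "c") {
  adj <- build_adjacency(model, cofactors = cofactors,
                         keep_compartments = keep_compartments)
  D <- metabolite_gene_distances(adj)
  rg <- reaction_genes(model)
  if (is.null(met_subsystems)) met_subsystems <- adjacent_subsystems(model)
  met_subsystems <- as_tibble(met_subsystems)

  regulon_sets <- split(regulon$gene, regulon$regulator)
  # subsystems reachable through each gene's reactions
  gene_subsystems <- rg %>%
    filter(!is.na(.data$subsystem)) %>%
    distinct(.data$gene, .data$subsystem)

  purrr::pmap_dfr(pairs %>% select("metabolite", "regulator"),
                  function(metabolite, regulator) {
    targets <- unique(regulon_sets[[regulator]] %||% character())
    m_in_model <- metabolite %in% model$metabolites$id
    m_sub <- met_subsystems$subsystem[met_subsystems$metabolite == metabolite]
    base <- tibble(metabolite = metabolite, regulator = regulator)
    if ((!m_in_model && !length(m_sub)) || !length(targets)) {
      return(dplyr::bind_cols(base, tibble(
        passes = NA, satisfied_by = "not_computable",
        witness_gene = NA_character_, min_distance = NA_real_)))
    }
    # criterion 1: substrate/product of an enzyme encoded by a target gene
    w1 <- NA_character_
    if (metabolite %in% rownames(D)) {
      tg <- intersect(targets, colnames(D))
      hit <- tg[D[metabolite, tg] == 1]
      if (length(hit)) w1 <- hit[1]
    }
    md <- tf_min_distance(D, metabolite, targets)
    if (!is.na(w1)) {
      return(dplyr::bind_cols(base, tibble(
        passes = TRUE, satisfied_by = "substrate_product",
        witness_gene = w1, min_distance = md)))
    }
    # criterion 2: shared metabolic subsystem with a target-gene enzyme
    tsub <- gene_subsystems %>% filter(.data$gene %in% targets)
    shared <- tsub %>% filter(.data$subsystem %in% m_sub)
    if (nrow(shared)) {
      return(dplyr::bind_cols(base, tibble(
        passes = TRUE, satisfied_by = "subsystem",
        witness_gene = shared$gene[1], min_distance = md)))
    }
    dplyr::bind_cols(base, tibble(
      passes = FALSE, satisfied_by = "none",
      witness_gene = NA_character_, min_distance = md))
  })
}

#' Write a metabolite-gene distance matrix as TSV
#'
#' Unreachable pairs are encoded as `Inf`.
#' @param D Distance matrix from [metabolite_gene_distances()].
#' @param path Output TSV path.
#' @export
write_distances <- function(D, path) {
  tbl <- as_tibble(D, rownames = "metabolite")
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}
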