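# Readers and writers for the delimited formats the pipeline consumes:
# expression TSV (genes x samples, TPM), metabolite TSV (uM), interaction
# triplet TSV, and the ground-truth JSON emitted by the generators.
# Sample columns are headed "t<time>_r<replicate>", e.g. "t6.43_r2".

parse_sample_headers <- function(nms) {
  m <- stringr::str_match(nms, "^t([0-9.eE+-]+)_r(\\d+)$")
  if (anyNA(m[, 1]))
    stopf("unparsable sample column header(s): %s",
          paste(head(nms[is.na(m[, 1])], 3), collapse = ", "))
  tibble(column = nms, time = as.numeric(m[, 2]), replicate = as.integer(m[, 3]))
}

read_omics_table <- function(path, id_col) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(raw)[1] <- id_col
  ids <- raw[[id_col]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stopf("duplicate %s id(s): %s", id_col, paste(unique(dup), collapse = ", "))
  vals <- raw[, -1, drop = FALSE]
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    bad <- names(vals)[!vapply(vals, is.numeric, logical(1))]
    stopf("non-numeric values in column(s): %s", paste(bad, collapse = ", "))
  }
  hdr <- parse_sample_headers(names(vals))
  long <- raw %>%
    tidyr::pivot_longer(-1, names_to = "column", values_to = "value") %>%
    left_join(hdr, by = "column") %>%
    select(dplyr::all_of(id_col), "time", "replicate", "value") %>%
    arrange(.data[[id_col]], .data$time, .data$replicate)
  long
}

write_omics_table <- function(tbl, path, id_col, value_col) {
  wide <- tbl %>%
    mutate(column = sprintf("t%.12g_r%d", .data$time, .data$replicate)) %>%
    select(dplyr::all_of(id_col), "column", dplyr::all_of(value_col)) %>%
    tidyr::pivot_wider(names_from = "column",
                       values_from = dplyr::all_of(value_col))
  ord <- parse_sample_headers(names(wide)[-1]) %>%
    arrange(.data$time, .data$replicate)
  wide <- wide[, c(id_col, ord$column)]
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read a gene-expression time course
#'
#' Reads a genes-by-samples TSV of TPM values (first column gene ids, sample
#' columns headed `t<time>_r<replicate>`) and returns log10-transformed
#' expression. Zeros are raised to `pseudocount` TPM before the log so that
#' all stored values are finite.
#'
#' @param path TSV file of TPM values.
#' @param pseudocount TPM floor applied before log10 (default 0.01).
#' @return Tibble `gene`, `time` (hours), `replicate`, `value` (log10 TPM).
#' @export
read_expression <- function(path, pseudocount = 0.01) {
  long <- read_omics_table(path, "gene")
  if (any(long$value < 0))
    stopf("negative TPM values in %s", path)
  long %>% mutate(value = log10(pmax(.data$value, pseudocount)))
}

#' Write a gene-expression time course
#'
#' Inverse of [read_expression()]: converts log10 values back to TPM and
#' writes the genes-by-samples TSV layout.
#'
#' @param expression Tibble `gene`, `time`, `replicate`, `value` (log10 TPM).
#' @param path Output TSV path.
#' @export
write_expression <- function(expression, path) {
  expression %>%
    mutate(value = 10^.data$value) %>%
    write_omics_table(path, "gene", "value")
}

#' Read a metabolite concentration time course
#'
#' @param path TSV of concentrations in uM, first column metabolite ids,
#'   sample columns headed `t<time>_r<replicate>`.
#' @return Tibble `metabolite`, `time`, `replicate`, `concentration`.
#' @export
read_metabolites <- function(path) {
  long <- read_omics_table(path, "metabolite")
  if (any(long$value < 0, na.rm = TRUE))
    stopf("negative concentrations in %s", path)
  long %>% rename(concentration = "value")
}

#' Write a metabolite concentration time course
#' @param metabolites Tibble `metabolite`, `time`, `replicate`,
#'   `concentration`.
#' @param path Output TSV path.
#' @export
write_metabolites <- function(metabolites, path) {
  write_omics_table(metabolites, path, "metabolite", "concentration")
}

#' Read a regulator-gene interaction table
#'
#' @param path TSV with columns `regulator`, `gene` and optionally `sign`.
#' @return Tibble `regulator`, `gene`, `sign` (NA when unknown).
#' @export
read_interactions <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("regulator", "gene") %in% names(tbl)))
    stopf("interaction table needs 'regulator' and 'gene' columns: %s", path)
  if (!"sign" %in% names(tbl)) tbl$sign <- NA_integer_
  tbl %>% select("regulator", "gene", "sign")
}

#' Assemble the NCA connectivity matrix from interaction tables
#'
#' Takes the union of one or more regulator-gene interaction tables (TF
#' regulons, sigma-factor regulons, further regulons such as (p)ppGpp targets
#' or attenuation are simply additional tables), appends a global basal
#' regulator connected to every gene (accounting for basal expression by RNA
#' polymerase), and restricts the result to genes present in the supplied
#' gene universe (typically the measured genes). Regulators left without
#' targets after restriction are dropped with a message; genes absent from
#' the universe are excluded with a message.
#'
#' @param tables A tibble of `regulator`, `gene`(, `sign`) edges, or a list
#'   of such tibbles.
#' @param gene_universe Character vector of genes to retain (e.g. the genes
#'   in the expression table).
#' @return Network tibble `regulator`, `gene`, `sign`, `is_global`.
#' @export
assemble_connectivity <- function(tables, gene_universe) {
  if (is.data.frame(tables)) tables <- list(tables)
  edges <- purrr::map_dfr(tables, function(t) {
    t <- as_tibble(t)
    if (!"sign" %in% names(t)) t$sign <- NA_integer_
    t %>% select("regulator", "gene", "sign")
  }) %>%
    # union of all tables; the sign is the consensus of non-missing
    # annotations and NA when tables disagree, so assembly is
    # order-independent
    group_by(.data$regulator, .data$gene) %>%
    summarise(sign = {
      s <- unique(.data$sign[!is.na(.data$sign)])
      if (length(s) == 1) s else NA_integer_
    }, .groups = "drop") %>%
    arrange(.data$regulator, .data$gene)
  if (!nrow(edges)) stopf("no interactions supplied")
  dropped_genes <- setdiff(edges$gene, gene_universe)
  if (length(dropped_genes))
    inform(sprintf("%d gene(s) absent from the expression data excluded from the connectivity matrix",
                   length(dropped_genes)))
  regs_before <- unique(edges$regulator)
  edges <- edges %>% filter(.data$gene %in% gene_universe)
  if (!nrow(edges)) stopf("no interactions left after restricting to the gene universe")
  empty_regs <- setdiff(regs_before, edges$regulator)
  if (length(empty_regs))
    inform(sprintf("regulator(s) dropped with zero targets after restriction: %s",
                   paste(empty_regs, collapse = ", ")))
  edges$is_global <- FALSE
  global <- tibble(regulator = "global", gene = sort(unique(gene_universe)),
                   sign = 1L, is_global = TRUE)
  bind_rows(edges, global)
}

#' Write / read planted ground truth
#'
#' Serializes the planted interaction table (and optionally the true activity
#' profiles) as JSON so synthetic runs can be re-scored later.
#' @param truth Planted interaction tibble.
#' @param path JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Read a literature metabolite-TF network
#'
#' @param path TSV with columns `metabolite`, `regulator`, `mode`
#'   (activation/inhibition/unknown).
#' @param metabolite_ids,regulator_ids Optional id universes; unresolvable
#'   ids are reported with a message but kept in the table.
#' @return Tibble `metabolite`, `regulator`, `mode`.
#' @export
read_literature_network <- function(path, metabolite_ids = NULL,
                                    regulator_ids = NULL) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("metabolite", "regulator") %in% names(tbl)))
    stopf("literature network needs 'metabolite' and 'regulator' columns")
  if (!"mode" %in% names(tbl)) tbl$mode <- "unknown"
  tbl$mode[!tbl$mode %in% c("activation", "inhibition")] <- "unknown"
  if (!is.null(metabolite_ids)) {
    bad <- setdiff(tbl$metabolite, metabolite_ids)
    if (length(bad))
      inform(sprintf("literature metabolite id(s) not in data: %s",
                     paste(head(bad, 5), collapse = ", ")))
  }
  if (!is.null(regulator_ids)) {
    bad <- setdiff(tbl$regulator, regulator_ids)
    if (length(bad))
      inform(sprintf("literature regulator id(s) not in data: %s",
                     paste(head(bad, 5), collapse = ", ")))
  }
  tbl %>% select("metabolite", "regulator", "mode")
}
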