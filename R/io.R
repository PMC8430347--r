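## Readers and writers for the plain-text interchange formats: one-symbol-
## per-line gene lists, edge-list TSV, ortholog-map TSV, GMT gene sets,
## long-format expression TSV, drug-target TSV, and the gene-catalog TSV.

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
}

read_tsv_plain <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

#' Read / write a one-symbol-per-line gene list
#' @param path file path.
#' @return character vector of canonical symbols.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- canonical_symbol(x)
  x[nzchar(x)]
}

#' @rdname read_gene_list
#' @param genes character vector to write.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read / write an interactome edge list (TSV: node_a, node_b, provenance)
#' @param path file path.
#' @param name network name for the constructed object.
#' @return an `interactome`.
#' @export
read_edge_list <- function(path, name = basename(path)) {
  df <- read_tsv_plain(path)
  build_interactome(df, name = name)
}

#' @rdname read_edge_list
#' @param net an `interactome` to write.
#' @export
write_edge_list <- function(net, path) {
  df <- net$edges
  names(df) <- c("node_a", "node_b", "provenance")
  write_tsv_plain(df, path)
  invisible(path)
}

#' Read / write an ortholog map (TSV: gene, species, ortholog_id or NA)
#' @param path file path.
#' @param species optional explicit species order.
#' @return an `ortholog_map`.
#' @export
read_ortholog_map <- function(path, species = NULL) {
  df <- read_tsv_plain(path)
  names(df)[names(df) == "ortholog_id"] <- "ortholog"
  ortholog_map(df, species = species)
}

#' @rdname read_ortholog_map
#' @param map an `ortholog_map` to write.
#' @export
write_ortholog_map <- function(map, path) {
  df <- as.data.frame(map)
  names(df) <- c("gene", "species", "ortholog_id")
  df$ortholog_id[is.na(df$ortholog_id)] <- "NA"
  write_tsv_plain(df, path)
  invisible(path)
}

#' Read / write gene-set annotations in GMT format
#'
#' GMT: one term per line, `term_id TAB description TAB member1 TAB ...`.
#'
#' @param path file path.
#' @param background background universe for the constructed database;
#'   defaults to the union of all term members.
#' @return an `annotation_db`.
#' @export
read_gmt <- function(path, background = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[`, "", 1L)
  desc <- vapply(fields, `[`, "", 2L)
  terms <- lapply(fields, function(f) f[-(1:2)])
  names(terms) <- ids
  if (is.null(background)) background <- unique(unlist(terms))
  annotation_db(terms, background, stats::setNames(desc, ids))
}

#' @rdname read_gmt
#' @param db an `annotation_db` to write.
#' @export
write_gmt <- function(db, path) {
  lines <- vapply(names(db$terms), function(id) {
    paste(c(id, db$descriptions[[id]], db$terms[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write an expression profile (long TSV: gene, tissue, tpm, protein_level)
#' @param path file path.
#' @return an `expression_profile`.
#' @export
read_expression <- function(path) {
  expression_profile(read_tsv_plain(path))
}

#' @rdname read_expression
#' @param expr an `expression_profile` to write.
#' @export
write_expression <- function(expr, path) {
  df <- as.data.frame(expr)
  df$tpm <- sprintf("%.6g", df$tpm)
  write_tsv_plain(df, path)
  invisible(path)
}

#' Read / write a drug-target table (TSV: drug_id, species, target, confidence)
#' @param path file path.
#' @return a `drug_target_table`.
#' @export
read_drug_targets <- function(path) {
  df <- read_tsv_plain(path)
  names(df)[names(df) == "drug_id"] <- "drug"
  drug_target_table(df)
}

#' @rdname read_drug_targets
#' @param table a `drug_target_table` to write.
#' @export
write_drug_targets <- function(table, path) {
  df <- as.data.frame(table)
  names(df) <- c("drug_id", "species", "target", "confidence")
  df$confidence <- sprintf("%.6g", df$confidence)
  write_tsv_plain(df, path)
  invisible(path)
}

#' Read / write a gene catalog (TSV: gene, n_sources, ces, rank)
#' @param path file path.
#' @return a `gene_catalog` data frame.
#' @export
read_gene_catalog <- function(path) {
  df <- read_tsv_plain(path)
  stopifnot(all(c("gene", "n_sources", "ces", "rank") %in% names(df)))
  df$gene <- canonical_symbol(df$gene)
  df$n_sources <- as.integer(df$n_sources)
  df$rank <- as.integer(df$rank)
  class(df) <- c("gene_catalog", "data.frame")
  df
}

#' @rdname read_gene_catalog
#' @param catalog a `gene_catalog` to write. CES is written as an exact
#'   ratio-derived decimal with enough digits to round-trip.
#' @export
write_gene_catalog <- function(catalog, path) {
  df <- as.data.frame(catalog)
  df$ces <- sprintf("%.17g", df$ces)
  write_tsv_plain(df, path)
  invisible(path)
}
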