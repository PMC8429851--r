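# Shared TSV readers/writers. Every pipeline stage and the synthetic-data
# generator go through these, so file dialects stay consistent.

#' Read / write a ligand-receptor pair table
#'
#' TSV with columns `ligand`, `receptor`.
#' @param path File path.
#' @return `data.table` of pairs.
#' @export
read_pairs <- function(path) {
  dt <- data.table::fread(path, sep = "\t", colClasses = "character")
  if (!all(c("ligand", "receptor") %in% names(dt)))
    stop("pair table needs `ligand` and `receptor` columns: ", path)
  dt[, .(ligand, receptor)]
}

#' @rdname read_pairs
#' @param pairs Pair table.
#' @export
write_pairs <- function(pairs, path) {
  data.table::fwrite(data.table::as.data.table(pairs)[, .(ligand, receptor)],
                     path, sep = "\t")
  invisible(path)
}

#' Read / write a numeric matrix with a leading id column
#'
#' TSV where the first column holds row ids (genes or cell types) and the
#' remaining columns are samples or replicates.
#' @param path File path.
#' @param id_name Name of the id column when writing.
#' @return Numeric matrix with rownames.
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  ids <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  m
}

#' @rdname read_matrix_tsv
#' @param m Matrix to write.
#' @export
write_matrix_tsv <- function(m, path, id_name = "gene") {
  dt <- data.table::as.data.table(m, keep.rownames = id_name)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read / write a replicate-to-cell-type harmonization map
#'
#' TSV with columns `replicate`, `cell`.
#' @param path File path.
#' @return Named character vector (names = replicates, values = cells).
#' @export
read_cellmap <- function(path) {
  dt <- data.table::fread(path, sep = "\t", colClasses = "character")
  if (!all(c("replicate", "cell") %in% names(dt)))
    stop("cell map needs `replicate` and `cell` columns: ", path)
  stats::setNames(dt$cell, dt$replicate)
}

#' @rdname read_cellmap
#' @param cellmap Named character vector.
#' @export
write_cellmap <- function(cellmap, path) {
  data.table::fwrite(
    data.table::data.table(replicate = names(cellmap), cell = unname(cellmap)),
    path, sep = "\t")
  invisible(path)
}

#' Read / write a scaffold edge table
#' @param path File path.
#' @return `data.table` with `edge_id`, `lcell`, `ligand`, `receptor`, `rcell`.
#' @export
read_scaffold <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  dt[, edge_id := as.integer(edge_id)]
  dt[]
}

#' @rdname read_scaffold
#' @param scaffold Scaffold table.
#' @export
write_scaffold <- function(scaffold, path) {
  data.table::fwrite(scaffold, path, sep = "\t")
  invisible(path)
}

#' Read / write the long edge-weight table
#' @param path File path.
#' @return `data.table` with `sample_id`, `edge_id`, `weight` (+ optional
#'   factor columns).
#' @export
read_weights <- function(path) {
  data.table::fread(path, sep = "\t")
}

#' @rdname read_weights
#' @param weights Long weight table.
#' @export
write_weights <- function(weights, path) {
  data.table::fwrite(weights, path, sep = "\t")
  invisible(path)
}

#' Read / write a clinical table
#'
#' TSV with columns `sample_id`, `study`, `pfi_time_days`, `pfi_event`,
#' `ajcc_stage`.
#' @param path File path.
#' @return `data.table`.
#' @export
read_clinical <- function(path) {
  dt <- data.table::fread(path, sep = "\t", na.strings = c("NA", ""))
  need <- c("sample_id", "study", "pfi_time_days", "pfi_event", "ajcc_stage")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("clinical table missing columns: ", paste(miss, collapse = ", "))
  dt[]
}

#' @rdname read_clinical
#' @param clinical Clinical table.
#' @export
write_clinical <- function(clinical, path) {
  data.table::fwrite(clinical, path, sep = "\t")
  invisible(path)
}

#' Read / write a two-group sample assignment
#' @param path File path.
#' @return `data.table` with `sample_id`, `group`.
#' @export
read_groups <- function(path) {
  dt <- data.table::fread(path, sep = "\t", colClasses = "character")
  if (!all(c("sample_id", "group") %in% names(dt)))
    stop("group table needs `sample_id` and `group` columns: ", path)
  dt[]
}

#' @rdname read_groups
#' @param groups Group assignment.
#' @export
write_groups <- function(groups, path) {
  data.table::fwrite(data.table::as.data.table(groups)[, .(sample_id, group)],
                     path, sep = "\t")
  invisible(path)
}

#' Export a scaffold or DWE network as GraphML
#'
#' The cell-level multigraph: one vertex per cell type, one edge per
#' scaffold channel with `ligand`/`receptor` attributes; when a contrast
#' table is supplied, `s_xy` and `S1` are attached as edge attributes so
#' magnitude and direction can drive edge coloring.
#'
#' @param scaffold Scaffold table (or the scaffold rows of a DWE set).
#' @param path Output file.
#' @param stats Optional contrast/DWE table with `edge_id`, `s_xy`, `S1`.
#' @export
export_graphml <- function(scaffold, path, stats = NULL) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("GraphML export requires the `igraph` package")
  scaffold <- data.table::as.data.table(scaffold)
  if (!is.null(stats))
    scaffold <- merge(scaffold,
                      data.table::as.data.table(stats)[, .(edge_id, s_xy, S1)],
                      by = "edge_id")
  g <- igraph::graph_from_data_frame(
    scaffold[, c(list(from = lcell, to = rcell),
                 .SD), .SDcols = setdiff(names(scaffold), c("lcell", "rcell"))],
    directed = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
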