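#' Construct a reference expression dataset
#'
#' Bundles a cell-sorted expression matrix with the mapping from its
#' replicate columns to harmonized cell-type names. These datasets supply
#' the votes that decide which ligands and receptors each cell type
#' expresses.
#'
#' @param id Character scalar identifying the dataset.
#' @param expr Numeric matrix, genes in rows (rownames required),
#'   cell-type replicates in columns (colnames required). All values must
#'   be non-negative (TPM-like).
#' @param cellmap Named character vector mapping each replicate column name
#'   to a harmonized cell-type label. Every column of `expr` must appear.
#' @return An object of class `ccnet_reference`.
#' @export
reference_expression <- function(id, expr, cellmap) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("`expr` must be a numeric matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("`expr` must have gene rownames and replicate colnames")
  if (anyNA(expr) || any(expr < 0))
    stop("reference expression values must be non-negative and non-missing")
  missing_rep <- setdiff(colnames(expr), names(cellmap))
  if (length(missing_rep))
    stop("replicates missing from cell map: ", paste(missing_rep, collapse = ", "))
  structure(
    list(id = id, expr = expr, cellmap = cellmap[colnames(expr)]),
    class = "ccnet_reference"
  )
}

#' @export
print.ccnet_reference <- function(x, ...) {
  cat(sprintf("<ccnet_reference '%s': %d genes x %d replicates, %d cell types>\n",
              x$id, nrow(x$expr), ncol(x$expr), length(unique(x$cellmap))))
  invisible(x)
}

# Median threshold of one dataset: either one global value over every
# (gene, replicate) entry, or a per-gene median across replicates.
.dataset_median <- function(ref, gene, median_mode) {
  if (median_mode == "global") stats::median(ref$expr)
  else stats::median(ref$expr[gene, ])
}

#' Majority vote on whether a cell type expresses a gene
#'
#' Each reference dataset containing the gene and at least one replicate of
#' the cell type casts one vote. Replicates of the cell type are first
#' collapsed by their median; the dataset votes "expressed" when that value
#' is strictly greater than the dataset's median expression level. The gene
#' is accepted when votes exceed half the possible votes (strict majority;
#' a tie is not accepted).
#'
#' @param refs List of [reference_expression()] objects.
#' @param cell Harmonized cell-type label.
#' @param gene Gene symbol.
#' @param median_mode `"global"` (default) compares against the median over
#'   all values of a dataset; `"per-gene"` compares against the gene's own
#'   median across all replicates of that dataset.
#' @return List with `votes`, `possible`, `expressed`, and `no_evidence`
#'   (`TRUE` when no dataset could cast a vote, distinct from losing 0/n).
#' @export
vote_expressed <- function(refs, cell, gene,
                           median_mode = c("global", "per-gene")) {
  median_mode <- match.arg(median_mode)
  stopifnot(length(refs) >= 1L)
  votes <- 0L
  possible <- 0L
  for (ref in refs) {
    if (!gene %in% rownames(ref$expr)) next
    reps <- which(ref$cellmap == cell)
    if (!length(reps)) next
    possible <- possible + 1L
    rep_value <- stats::median(ref$expr[gene, reps])
    if (rep_value > .dataset_median(ref, gene, median_mode))
      votes <- votes + 1L
  }
  list(votes = votes, possible = possible,
       expressed = possible > 0L && votes > possible / 2,
       no_evidence = possible == 0L)
}

#' Tally expressed genes for every cell type
#'
#' Applies [vote_expressed()] across all cell types present in the
#' references and all requested genes, producing the expressed-gene map the
#' scaffold builder consumes.
#'
#' @param refs List of [reference_expression()] objects.
#' @param genes Character vector of genes to vote on (typically the union
#'   of ligands and receptors in the pair table).
#' @param cells Optional character vector of cell types; defaults to all
#'   harmonized cell types seen in the references.
#' @inheritParams vote_expressed
#' @return A `data.table` with columns `cell`, `gene`, `votes`, `possible`,
#'   `expressed`, `no_evidence`; class `ccnet_expressed_map`.
#' @export
expressed_gene_map <- function(refs, genes, cells = NULL,
                               median_mode = c("global", "per-gene")) {
  median_mode <- match.arg(median_mode)
  if (is.null(cells))
    cells <- sort(unique(unlist(lapply(refs, function(r) unname(r$cellmap)))))
  genes <- unique(genes)
  grid <- data.table::CJ(cell = cells, gene = genes)
  res <- grid[, {
    v <- vote_expressed(refs, cell, gene, median_mode)
    list(votes = v$votes, possible = v$possible,
         expressed = v$expressed, no_evidence = v$no_evidence)
  }, by = .(cell, gene)]
  data.table::setattr(res, "class",
                      c("ccnet_expressed_map", class(res)))
  res[]
}

#' Assemble the cell-ligand-receptor-cell scaffold
#'
#' Enumerates every edge (producing cell, ligand, receptor, receiving cell)
#' such that the ligand is expressed in the producing cell, the receptor is
#' expressed in the receiving cell, and the ligand-receptor pair is in the
#' pair table. Autocrine self-loops (same cell on both sides) are included
#' by default. Edge ids are assigned deterministically by lexicographic
#' order of (lcell, ligand, receptor, rcell), so the result is invariant to
#' input row order.
#'
#' @param pairs `data.frame` with columns `ligand` and `receptor`; pairs
#'   must be unique.
#' @param expressed An expressed-gene map from [expressed_gene_map()], or
#'   any `data.frame` with logical column `expressed` and columns
#'   `cell`, `gene`.
#' @param include_self_loops Keep autocrine edges (default `TRUE`).
#' @return `data.table` with columns `edge_id`, `lcell`, `ligand`,
#'   `receptor`, `rcell`.
#' @export
build_scaffold <- function(pairs, expressed, include_self_loops = TRUE) {
  pairs <- data.table::as.data.table(pairs)
  if (!nrow(pairs)) stop("pair table is empty")
  if (!all(c("ligand", "receptor") %in% names(pairs)))
    stop("pair table needs `ligand` and `receptor` columns")
  if (anyDuplicated(pairs[, .(ligand, receptor)]))
    stop("duplicate ligand-receptor pairs")
  if (any(!nzchar(pairs$ligand)) || any(!nzchar(pairs$receptor)))
    stop("empty gene symbols in pair table")
  em <- data.table::as.data.table(expressed)[expressed == TRUE]
  if (!nrow(em)) stop("expressed-gene map is empty")

  lig <- em[, .(ligand = gene, lcell = cell)]
  rec <- em[, .(receptor = gene, rcell = cell)]
  edges <- merge(pairs, lig, by = "ligand", allow.cartesian = TRUE)
  edges <- merge(edges, rec, by = "receptor", allow.cartesian = TRUE)
  if (!include_self_loops) edges <- edges[lcell != rcell]
  data.table::setorder(edges, lcell, ligand, receptor, rcell)
  edges[, edge_id := seq_len(.N)]
  edges[, .(edge_id, lcell, ligand, receptor, rcell)]
}

#' Summarize scaffold connectivity
#'
#' Counts, per cell type, the edges on which it is the ligand producer and
#' the edges on which it bears the receptor, plus the total degree (edges
#' touching the cell; an autocrine edge counts once).
#'
#' @param scaffold Scaffold table from [build_scaffold()].
#' @return `data.table` with columns `cell`, `ligand_side`, `receptor_side`,
#'   `degree`.
#' @export
scaffold_degree_summary <- function(scaffold) {
  scaffold <- data.table::as.data.table(scaffold)
  if (!nrow(scaffold)) stop("scaffold is empty")
  cells <- sort(unique(c(scaffold$lcell, scaffold$rcell)))
  out <- data.table::data.table(cell = cells)
  ls <- scaffold[, .N, by = .(cell = lcell)]
  rs <- scaffold[, .N, by = .(cell = rcell)]
  deg <- scaffold[, .(touch = unique(c(lcell, rcell))), by = edge_id][
    , .N, by = .(cell = touch)]
  out <- merge(out, ls, by = "cell", all.x = TRUE)
  data.table::setnames(out, "N", "ligand_side")
  out <- merge(out, rs, by = "cell", all.x = TRUE)
  data.table::setnames(out, "N", "receptor_side")
  out <- merge(out, deg, by = "cell", all.x = TRUE)
  data.table::setnames(out, "N", "degree")
  for (col in c("ligand_side", "receptor_side", "degree"))
    data.table::set(out, which(is.na(out[[col]])), col, 0L)
  out[]
}
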