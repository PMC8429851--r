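# Empirical CDFs are stored as sorted support vectors and evaluated by
# binary search. mode "le" is the R ecdf convention F(v) = #{x <= v}/n;
# "lt" is the strict variant #{x < v}/n.
.ecdf_eval <- function(sorted, v, mode = "le") {
  n <- length(sorted)
  if (mode == "le") findInterval(v, sorted) / n
  else findInterval(v, sorted, left.open = TRUE) / n
}

# Quartile bin of a score given type-7 boundaries (25/50/75%); values equal
# to a boundary fall in the lower bin.
.quartile_bin <- function(v, breaks) {
  1L + (v > breaks[1L]) + (v > breaks[2L]) + (v > breaks[3L])
}

.pair_key <- function(gene, cell) paste(gene, cell, sep = "\r")

#' Fit the cohort-level edge-weight probability model
#'
#' Precomputes, from a cohort of bulk samples, (i) one marginal empirical
#' CDF per scaffold cell type over its deconvolution scores, and (ii) for
#' every (gene, cell) combination appearing on either side of a scaffold
#' edge, four empirical CDFs of the gene's expression conditioned on which
#' quartile of the cell's score distribution a sample falls in. Quartile
#' boundaries use the standard type-7 quantile; a sample on a boundary is
#' assigned to the lower bin. When a cell's scores are constant the
#' quartiles are degenerate and the conditional model collapses to a single
#' unconditional expression CDF (with a warning).
#'
#' The model is a pure function of the cohort: no randomness is involved,
#' and it should be fitted once on the full sample universe, not per
#' contrast group.
#'
#' @param expr Numeric matrix of expression, genes x samples, values >= 0.
#' @param scores Numeric matrix of cell-type scores, cell types x samples,
#'   values >= 0; columns must match `expr`.
#' @param scaffold Scaffold table from [build_scaffold()].
#' @param ecdf_mode `"le"` (default, the R `ecdf` convention) or `"lt"`
#'   for strict inequality.
#' @return A `ccnet_weight_model` list with elements `cells` (per-cell
#'   sorted score supports), `cond` (per gene-cell conditional models),
#'   and `ecdf_mode`.
#' @export
fit_weight_model <- function(expr, scores, scaffold,
                             ecdf_mode = c("le", "lt")) {
  ecdf_mode <- match.arg(ecdf_mode)
  scaffold <- data.table::as.data.table(scaffold)
  if (!nrow(scaffold)) stop("scaffold is empty")
  if (!identical(colnames(expr), colnames(scores)))
    stop("expression and score matrices must share the same sample columns")
  n <- ncol(expr)
  if (n < 8L) stop("cohort too small: need >= 8 samples for quartile bins")
  if (anyNA(expr) || any(expr < 0) || anyNA(scores) || any(scores < 0))
    stop("expression and scores must be non-negative and non-missing")

  cells <- sort(unique(c(scaffold$lcell, scaffold$rcell)))
  miss <- setdiff(cells, rownames(scores))
  if (length(miss))
    stop("cell types missing from score matrix: ", paste(miss, collapse = ", "))
  genes_needed <- unique(c(scaffold$ligand, scaffold$receptor))
  miss <- setdiff(genes_needed, rownames(expr))
  if (length(miss))
    stop("genes missing from expression matrix: ", paste(miss, collapse = ", "))

  cell_cdfs <- lapply(cells, function(cl) sort(scores[cl, ]))
  names(cell_cdfs) <- cells

  gc_pairs <- unique(rbind(
    scaffold[, .(gene = ligand, cell = lcell)],
    scaffold[, .(gene = receptor, cell = rcell)]
  ))
  n_degenerate <- 0L
  cond <- vector("list", nrow(gc_pairs))
  for (i in seq_len(nrow(gc_pairs))) {
    g <- gc_pairs$gene[i]; cl <- gc_pairs$cell[i]
    sc <- scores[cl, ]
    breaks <- stats::quantile(sc, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    if (breaks[1L] == breaks[3L]) {
      n_degenerate <- n_degenerate + 1L
      cond[[i]] <- list(degenerate = TRUE, breaks = breaks,
                        bins = list(sort(expr[g, ])))
    } else {
      bin <- .quartile_bin(sc, breaks)
      sizes <- tabulate(bin, nbins = 4L)
      if (any(sizes < 1L))
        stop(sprintf("empty quartile bin for gene '%s' in cell '%s'", g, cl))
      cond[[i]] <- list(
        degenerate = FALSE, breaks = breaks,
        bins = lapply(1:4, function(b) sort(expr[g, bin == b]))
      )
    }
  }
  names(cond) <- .pair_key(gc_pairs$gene, gc_pairs$cell)
  if (n_degenerate > 0L)
    warning(sprintf(paste0("%d (gene, cell) conditional model(s) had constant",
                           " cell scores; collapsed to unconditional CDFs"),
                    n_degenerate))

  structure(list(cells = cell_cdfs, cond = cond, ecdf_mode = ecdf_mode,
                 n_samples = n),
            class = "ccnet_weight_model")
}

#' @export
print.ccnet_weight_model <- function(x, ...) {
  cat(sprintf(paste0("<ccnet_weight_model: %d cell-type CDFs, %d conditional",
                     " (gene, cell) models, fitted on %d samples, ecdf='%s'>\n"),
              length(x$cells), length(x$cond), x$n_samples, x$ecdf_mode))
  invisible(x)
}

# One side of an edge: P(gene expr | cell score quartile) * P(cell score).
.side_prob <- function(model, gene, cell, expr_value, score_value) {
  cdf <- model$cells[[cell]]
  if (is.null(cdf)) stop("cell type not in model: ", cell)
  p_cell <- .ecdf_eval(cdf, score_value, model$ecdf_mode)
  cm <- model$cond[[.pair_key(gene, cell)]]
  if (is.null(cm))
    stop(sprintf("no conditional model for gene '%s' in cell '%s'", gene, cell))
  support <- if (cm$degenerate) cm$bins[[1L]]
             else cm$bins[[.quartile_bin(score_value, cm$breaks)]]
  p_expr <- .ecdf_eval(support, expr_value, model$ecdf_mode)
  c(p_expr = p_expr, p_cell = p_cell)
}

#' Weight of one scaffold edge in one sample
#'
#' The edge weight is the product of four empirical probabilities: the
#' conditional probability of the ligand's expression given the producing
#' cell's score quartile, the marginal probability of the producing cell's
#' score, and the same two factors on the receptor side. The quartile bin
#' is chosen by the sample's own cell score. For an autocrine edge the two
#' cell-score factors coincide, so the weight depends on a single cell
#' value squared.
#'
#' @param sample_expr Named numeric vector of the sample's expression.
#' @param sample_scores Named numeric vector of the sample's cell scores.
#' @param edge One-row scaffold edge (list or data.frame row with `lcell`,
#'   `ligand`, `receptor`, `rcell`).
#' @param model Fitted [fit_weight_model()] object.
#' @return Named numeric vector with `weight` and the four factors
#'   `p_ligand`, `p_lcell`, `p_receptor`, `p_rcell`.
#' @export
edge_weight <- function(sample_expr, sample_scores, edge, model) {
  for (g in c(edge$ligand, edge$receptor))
    if (is.na(sample_expr[g]))
      stop("expression missing for gene ", g)
  for (cl in c(edge$lcell, edge$rcell))
    if (is.na(sample_scores[cl]))
      stop("score missing for cell ", cl)
  l <- .side_prob(model, edge$ligand, edge$lcell,
                  sample_expr[[edge$ligand]], sample_scores[[edge$lcell]])
  r <- .side_prob(model, edge$receptor, edge$rcell,
                  sample_expr[[edge$receptor]], sample_scores[[edge$rcell]])
  c(weight = unname(l["p_expr"] * l["p_cell"] * r["p_expr"] * r["p_cell"]),
    p_ligand = unname(l["p_expr"]), p_lcell = unname(l["p_cell"]),
    p_receptor = unname(r["p_expr"]), p_rcell = unname(r["p_cell"]))
}

#' Weight every scaffold edge for every sample in a cohort
#'
#' Batch application of [edge_weight()]: evaluates the four-factor product
#' for each (sample, edge) combination, vectorized over samples within each
#' edge. Results are identical to the per-sample loop and independent of
#' sample order.
#'
#' @inheritParams fit_weight_model
#' @param model Fitted weight model.
#' @param audit_factors Keep the four factor probabilities as extra columns.
#' @return Long `data.table` with columns `sample_id`, `edge_id`, `weight`
#'   (plus factor columns in audit mode); one row per (sample, edge).
#' @export
weight_cohort <- function(expr, scores, scaffold, model,
                          audit_factors = FALSE) {
  scaffold <- data.table::as.data.table(scaffold)
  samples <- colnames(expr)
  if (!identical(samples, colnames(scores)))
    stop("expression and score matrices must share the same sample columns")

  # per-cell marginal probabilities, all samples at once
  cells <- sort(unique(c(scaffold$lcell, scaffold$rcell)))
  p_cell <- lapply(cells, function(cl)
    .ecdf_eval(model$cells[[cl]], scores[cl, ], model$ecdf_mode))
  names(p_cell) <- cells

  # per (gene, cell) conditional probabilities, all samples at once
  gc_pairs <- unique(rbind(
    scaffold[, .(gene = ligand, cell = lcell)],
    scaffold[, .(gene = receptor, cell = rcell)]
  ))
  p_cond <- vector("list", nrow(gc_pairs))
  for (i in seq_len(nrow(gc_pairs))) {
    g <- gc_pairs$gene[i]; cl <- gc_pairs$cell[i]
    cm <- model$cond[[.pair_key(g, cl)]]
    if (is.null(cm))
      stop(sprintf("no conditional model for gene '%s' in cell '%s'", g, cl))
    ev <- expr[g, ]
    if (cm$degenerate) {
      p_cond[[i]] <- .ecdf_eval(cm$bins[[1L]], ev, model$ecdf_mode)
    } else {
      bin <- .quartile_bin(scores[cl, ], cm$breaks)
      out <- numeric(length(ev))
      for (b in 1:4) {
        idx <- bin == b
        if (any(idx)) out[idx] <- .ecdf_eval(cm$bins[[b]], ev[idx],
                                             model$ecdf_mode)
      }
      p_cond[[i]] <- out
    }
  }
  names(p_cond) <- .pair_key(gc_pairs$gene, gc_pairs$cell)

  ns <- length(samples)
  res <- scaffold[, {
    pl <- p_cond[[.pair_key(ligand, lcell)]]
    pr <- p_cond[[.pair_key(receptor, rcell)]]
    cl <- p_cell[[lcell]]
    cr <- p_cell[[rcell]]
    w <- pl * cl * pr * cr
    list(sample_id = samples, weight = w, p_ligand = pl, p_lcell = cl,
         p_receptor = pr, p_rcell = cr)
  }, by = edge_id]
  if (!audit_factors)
    res[, c("p_ligand", "p_lcell", "p_receptor", "p_rcell") := NULL]
  data.table::setcolorder(res, c("sample_id", "edge_id", "weight"))
  res[]
}
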