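# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's code paths (and stats::mad).

# sort-based median
naive_median <- function(v) {
  s <- sort(v)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

naive_s1 <- function(x, y, b = 1.4826) {
  mx <- naive_median(x); my <- naive_median(y)
  wx <- b * naive_median(abs(x - mx))
  wy <- b * naive_median(abs(y - my))
  (mx - my) / (wx + wy)
}

# counting-based empirical CDF
count_ecdf <- function(values, q, mode = "le") {
  if (mode == "le") sum(values <= q) / length(values)
  else sum(values < q) / length(values)
}

# quartile membership by explicit sort-and-split against type-7 boundaries
brute_quartile_bins <- function(scores) {
  br <- stats::quantile(scores, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  vapply(scores, function(v) {
    if (v <= br[1]) 1L else if (v <= br[2]) 2L else if (v <= br[3]) 3L else 4L
  }, integer(1))
}

# full from-scratch edge weight: counting ECDFs + explicit quartile split
brute_edge_weight <- function(expr, scores, edge, sample, mode = "le") {
  side <- function(gene, cell) {
    sc <- scores[cell, ]
    p_cell <- count_ecdf(sc, sc[sample], mode)
    bins <- brute_quartile_bins(sc)
    br <- stats::quantile(sc, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    if (br[1] == br[3]) {
      support <- expr[gene, ]
    } else {
      support <- expr[gene, bins == bins[sample]]
    }
    p_expr <- count_ecdf(support, expr[gene, sample], mode)
    p_expr * p_cell
  }
  side(edge$ligand, edge$lcell) * side(edge$receptor, edge$rcell)
}

# exhaustive triple-loop scaffold enumeration
brute_scaffold <- function(pairs, expressed_df, include_self_loops = TRUE) {
  exp_set <- function(cl) expressed_df$gene[expressed_df$cell == cl &
                                            expressed_df$expressed]
  cells <- unique(expressed_df$cell)
  rows <- list()
  for (cl in cells) for (i in seq_len(nrow(pairs))) for (cr in cells) {
    if (!include_self_loops && cl == cr) next
    if (pairs$ligand[i] %in% exp_set(cl) && pairs$receptor[i] %in% exp_set(cr))
      rows[[length(rows) + 1L]] <- data.frame(
        lcell = cl, ligand = pairs$ligand[i],
        receptor = pairs$receptor[i], rcell = cr)
  }
  if (!length(rows)) return(data.frame(lcell = character(), ligand = character(),
                                       receptor = character(), rcell = character()))
  out <- do.call(rbind, rows)
  out[order(out$lcell, out$ligand, out$receptor, out$rcell), , drop = FALSE]
}

# small random expressed-gene map + pair table for property tests
random_expressed_setup <- function(n_cells, n_pairs, p_expressed = 0.4) {
  cells <- sprintf("c%02d", seq_len(n_cells))
  pairs <- data.frame(ligand = sprintf("L%03d", seq_len(n_pairs)),
                      receptor = sprintf("R%03d", seq_len(n_pairs)))
  genes <- c(pairs$ligand, pairs$receptor)
  grid <- expand.grid(cell = cells, gene = genes, stringsAsFactors = FALSE)
  grid$expressed <- runif(nrow(grid)) < p_expressed
  list(pairs = pairs, expressed = grid)
}

# hand-built reference trio for vote tallies
make_ref <- function(id, genes, cells, values, reps_per_cell = 1L) {
  rep_cells <- rep(cells, each = reps_per_cell)
  rep_names <- sprintf("%s_r%d", rep_cells,
                       rep(seq_len(reps_per_cell), times = length(cells)))
  m <- matrix(values, nrow = length(genes), ncol = length(rep_names),
              dimnames = list(genes, rep_names))
  reference_expression(id, m, stats::setNames(rep_cells, rep_names))
}
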