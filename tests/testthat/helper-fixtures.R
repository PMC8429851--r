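# small fully-connected 2-cell, 2-pair cohort (8 scaffold edges) used by
# the weight and ranking tests
make_weight_fixture <- function(n = 20, seed = 11) {
  set.seed(seed)
  pairs <- data.frame(ligand = c("L1", "L2"), receptor = c("R1", "R2"))
  expressed <- expand.grid(cell = c("a", "b"),
                           gene = c("L1", "L2", "R1", "R2"),
                           stringsAsFactors = FALSE)
  expressed$expressed <- TRUE
  scaffold <- build_scaffold(pairs, expressed)
  samples <- sprintf("s%02d", seq_len(n))
  expr <- matrix(stats::rlnorm(4 * n), nrow = 4,
                 dimnames = list(c("L1", "L2", "R1", "R2"), samples))
  scores <- matrix(stats::rbeta(2 * n, 2, 5), nrow = 2,
                   dimnames = list(c("a", "b"), samples))
  list(scaffold = scaffold, expr = expr, scores = scores, samples = samples)
}
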