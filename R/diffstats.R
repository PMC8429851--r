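#' Robust standardized group difference for one edge
#'
#' The signed statistic is the difference of group medians divided by the
#' sum of the two groups' median absolute deviations (MAD, scaled by the
#' usual normal-consistency constant b = 1.4826):
#' \deqn{s_{xy} = (M_x - M_y) / (\omega_x + \omega_y)}
#' and its magnitude \eqn{S_1 = |s_{xy}|} ranks edges by how strongly their
#' weights differ between the groups. When both MADs are zero the ratio is
#' undefined: if the medians also agree the statistic is 0; otherwise the
#' result is flagged degenerate (`s_xy = NA`) so that infinite values never
#' dominate a ranking.
#'
#' @param x,y Numeric vectors of edge weights for the two groups (each of
#'   length >= 2).
#' @param b MAD scale constant, default 1.4826.
#' @return List with `s_xy`, `S1`, `M_x`, `M_y`, `omega_x`, `omega_y`,
#'   `median_diff`, `degenerate`.
#' @export
s1_statistic <- function(x, y, b = 1.4826) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 values")
  m_x <- stats::median(x)
  m_y <- stats::median(y)
  w_x <- b * stats::median(abs(x - m_x))
  w_y <- b * stats::median(abs(y - m_y))
  den <- w_x + w_y
  if (den == 0) {
    if (m_x == m_y) {
      s <- 0; degen <- FALSE
    } else {
      s <- NA_real_; degen <- TRUE
    }
  } else {
    s <- (m_x - m_y) / den
    degen <- FALSE
  }
  list(s_xy = s, S1 = abs(s), M_x = m_x, M_y = m_y,
       omega_x = w_x, omega_y = w_y, median_diff = m_x - m_y,
       degenerate = degen)
}

#' Per-edge contrast statistics between two groups
#'
#' Applies [s1_statistic()] to every edge of a long weight table, using a
#' group assignment that labels each sample `x` or `y`.
#'
#' @param weights Long weight table (`sample_id`, `edge_id`, `weight`) from
#'   [weight_cohort()].
#' @param groups Group assignment: `data.frame` with `sample_id` and
#'   `group` in `{"x", "y"}` (see [binarize_pfi()] / [binarize_stage()]).
#'   Samples absent from the assignment are ignored.
#' @param b MAD scale constant.
#' @return `data.table` with one row per edge: `edge_id`, `M_x`, `M_y`,
#'   `omega_x`, `omega_y`, `s_xy`, `S1`, `median_diff`, `degenerate`.
#'   Group sizes are attached as attributes `n_x` and `n_y`.
#' @export
contrast_edges <- function(weights, groups, b = 1.4826) {
  weights <- data.table::as.data.table(weights)
  groups <- data.table::as.data.table(groups)
  if (!all(groups$group %in% c("x", "y")))
    stop("group labels must be 'x' or 'y'")
  dt <- merge(weights, groups[, .(sample_id, group)], by = "sample_id")
  n_x <- length(unique(dt[group == "x", sample_id]))
  n_y <- length(unique(dt[group == "y", sample_id]))
  if (n_x < 2L || n_y < 2L)
    stop("each group needs at least 2 samples with weights")
  res <- dt[, {
    s <- s1_statistic(weight[group == "x"], weight[group == "y"], b = b)
    s[c("M_x", "M_y", "omega_x", "omega_y", "s_xy", "S1",
        "median_diff", "degenerate")]
  }, by = edge_id]
  data.table::setorder(res, edge_id)
  data.table::setattr(res, "n_x", n_x)
  data.table::setattr(res, "n_y", n_y)
  res[]
}

#' Resampling null distribution for the S1 statistic
#'
#' Builds an ensemble of sample pools by drawing (with replacement) from
#' the observed edge weights, then for each ensemble member repeatedly
#' draws two groups of the analyzed contrast's sizes from the pool and
#' records the magnitude of the resulting statistic. The detection
#' threshold is the empirical quantile, at `quantile_level`, of the
#' combined null statistics across the ensemble. Degenerate draws (both
#' MADs zero with differing medians) are excluded, matching the treatment
#' of observed edges.
#'
#' All randomness flows from `seed`; each ensemble member runs on its own
#' deterministic substream, so results are reproducible and independent of
#' evaluation order.
#'
#' @param weights Numeric vector of edge weights to pool from, or a long
#'   weight table with a `weight` column (typically all weights of the
#'   tissue under study).
#' @param n_x,n_y Group sizes of the contrast being calibrated.
#' @param n_pools Ensemble size (default 3).
#' @param pool_size Weights per pool (default 100000).
#' @param n_iter Null statistics per pool (default 1e6).
#' @param quantile_level Quantile of the combined null used as the
#'   threshold; default `1 - 1e-6` (the top-millionth percentile).
#' @param b MAD scale constant.
#' @param seed Integer seed (mandatory).
#' @return A `ccnet_null` list: `threshold`, `s1` (combined null sample),
#'   `n_degenerate`, plus the calibration parameters.
#' @export
build_null <- function(weights, n_x, n_y, n_pools = 3L, pool_size = 100000L,
                       n_iter = 1000000L, quantile_level = 1 - 1e-6,
                       b = 1.4826, seed) {
  if (is.data.frame(weights)) weights <- weights$weight
  weights <- as.numeric(weights)
  if (!length(weights)) stop("empty weight pool source")
  if (missing(seed)) stop("`seed` is required")
  if (pool_size < 1L || n_iter < 1L) stop("pool_size and n_iter must be >= 1")
  if (quantile_level <= 0 || quantile_level >= 1)
    stop("quantile_level must be in (0, 1)")
  if (n_x < 2L || n_y < 2L) stop("group sizes must be >= 2")

  s1 <- vector("list", n_pools)
  for (p in seq_len(n_pools)) {
    # per-pool substream: deterministic function of (seed, pool index)
    set.seed((as.integer(seed) + 1000003L * p) %% .Machine$integer.max)
    pool <- sample(weights, pool_size, replace = TRUE)
    s1[[p]] <- .null_s1_cpp(pool, as.integer(n_iter), as.integer(n_x),
                            as.integer(n_y), b)
  }
  s1 <- unlist(s1)
  n_degen <- sum(is.na(s1))
  s1 <- s1[!is.na(s1)]
  if (!length(s1)) stop("all null draws were degenerate")
  threshold <- stats::quantile(s1, quantile_level, type = 7, names = FALSE)
  structure(list(threshold = threshold, s1 = s1, n_degenerate = n_degen,
                 n_pools = n_pools, pool_size = pool_size, n_iter = n_iter,
                 n_x = n_x, n_y = n_y, quantile_level = quantile_level,
                 b = b, seed = seed),
            class = "ccnet_null")
}

#' @export
print.ccnet_null <- function(x, ...) {
  cat(sprintf(paste0("<ccnet_null: threshold %.6g at level %g from %d x %d",
                     " draws (group sizes %d/%d, seed %d)>\n"),
              x$threshold, x$quantile_level, x$n_pools, x$n_iter,
              x$n_x, x$n_y, x$seed))
  invisible(x)
}

#' Call differentially weighted edges against a resampling null
#'
#' Retains edges whose |S1| strictly exceeds the null threshold,
#' producing the differentially weighted subgraph of the scaffold.
#' Degenerate-scale edges are never called. The output is sorted by |S1|
#' descending with ties broken by edge id.
#'
#' @param stats Contrast table from [contrast_edges()].
#' @param null Null model from [build_null()]; its group sizes must match
#'   those of the contrast.
#' @return `data.table` of retained edges with all contrast columns plus
#'   `direction` (sign of `s_xy`).
#' @export
call_dwes <- function(stats, null) {
  stats <- data.table::as.data.table(stats)
  sn_x <- attr(stats, "n_x"); sn_y <- attr(stats, "n_y")
  if (!is.null(sn_x) && (sn_x != null$n_x || sn_y != null$n_y))
    stop(sprintf("group sizes of contrast (%d/%d) and null (%d/%d) differ",
                 sn_x, sn_y, null$n_x, null$n_y))
  dwe <- stats[degenerate == FALSE & S1 > null$threshold]
  data.table::setorder(dwe, -S1, edge_id)
  dwe[, direction := sign(s_xy)]
  dwe[]
}
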