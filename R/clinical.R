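#' Binarize progression-free interval per tissue
#'
#' Computes the median PFI time among uncensored (event) samples of a
#' tissue, then splits all samples of that tissue — censored and
#' uncensored alike — at that threshold: time less than or equal to the
#' median goes to the "short" group (`x`), longer times to "long" (`y`).
#' Samples with missing times are excluded with a warning.
#'
#' @param clinical `data.frame` with columns `sample_id`, `study`,
#'   `pfi_time_days` (numeric, >= 0), `pfi_event` (logical or 0/1).
#' @param tissue Study/tissue label to subset on.
#' @return `data.table` with `sample_id`, `group` (`"x"` = short,
#'   `"y"` = long); attributes `contrast`, `threshold`, and per-group
#'   counts `n_x`/`n_y`.
#' @export
binarize_pfi <- function(clinical, tissue) {
  cl <- data.table::as.data.table(clinical)[study == tissue]
  if (!nrow(cl)) stop("no samples for tissue ", tissue)
  if (anyNA(cl$pfi_time_days)) {
    warning(sum(is.na(cl$pfi_time_days)), " samples with missing PFI time excluded")
    cl <- cl[!is.na(pfi_time_days)]
  }
  ev <- cl[as.logical(pfi_event) == TRUE]
  if (nrow(ev) < 2L)
    stop("need >= 2 uncensored samples in tissue ", tissue)
  threshold <- stats::median(ev$pfi_time_days)
  out <- cl[, .(sample_id,
                group = ifelse(pfi_time_days <= threshold, "x", "y"))]
  .as_group_assignment(out, paste0("PFI:", tissue), threshold = threshold)
}

# Extract the major AJCC stage (I-IV) from dialect variants such as
# "Stage IIB", "iib", "III". Returns NA for unparseable values ("Stage X",
# missing, "I/II NOS", ...).
.major_stage <- function(stage) {
  s <- toupper(trimws(sub("(?i)^stage\\s*", "", as.character(stage),
                          perl = TRUE)))
  out <- rep(NA_character_, length(s))
  hit <- regexpr("^(IV|III|II|I)", s)
  ok <- !is.na(s) & hit == 1L
  major <- substr(s, 1L, attr(hit, "match.length"))
  # only substage suffixes (A/B/C, optional digit) may follow, so "Stage X"
  # and "I/II NOS" stay unparseable
  rest <- substr(s, attr(hit, "match.length") + 1L, nchar(s))
  ok <- ok & grepl("^[ABC]?[0-9]?$", rest)
  out[ok] <- major[ok]
  out
}

#' Binarize AJCC pathologic stage per tissue
#'
#' Substages collapse to their major stage; stages I-II form the "early"
#' group (`x`) and III-IV the "late" group (`y`). Samples with missing or
#' unparseable stages (e.g. "Stage X") are excluded.
#'
#' @param clinical `data.frame` with columns `sample_id`, `study`,
#'   `ajcc_stage`.
#' @inheritParams binarize_pfi
#' @return `data.table` with `sample_id`, `group` (`"x"` = early,
#'   `"y"` = late); attributes `contrast` and group counts.
#' @export
binarize_stage <- function(clinical, tissue) {
  cl <- data.table::as.data.table(clinical)[study == tissue]
  if (!nrow(cl)) stop("no samples for tissue ", tissue)
  major <- .major_stage(cl$ajcc_stage)
  keep <- !is.na(major)
  if (!any(keep)) stop("no parseable stages in tissue ", tissue)
  out <- data.table::data.table(
    sample_id = cl$sample_id[keep],
    group = ifelse(major[keep] %in% c("I", "II"), "x", "y")
  )
  .as_group_assignment(out, paste0("stage:", tissue))
}

.as_group_assignment <- function(dt, contrast, threshold = NULL) {
  if (anyDuplicated(dt$sample_id)) stop("duplicate sample ids in assignment")
  n_x <- sum(dt$group == "x"); n_y <- sum(dt$group == "y")
  if (n_x == 0L || n_y == 0L)
    stop("invalid contrast '", contrast, "': one group is empty")
  data.table::setattr(dt, "contrast", contrast)
  data.table::setattr(dt, "n_x", n_x)
  data.table::setattr(dt, "n_y", n_y)
  if (!is.null(threshold)) data.table::setattr(dt, "threshold", threshold)
  dt[]
}
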