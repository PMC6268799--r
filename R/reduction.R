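#' Data-reduction configuration
#'
#' The descriptor pool is pruned by three serial filters before model
#' search: (1) drop descriptors whose absolute Pearson correlation with the
#' activity is below `min_abs_activity_corr`; (2) drop descriptors whose
#' sample variance (n-1 denominator) over the training compounds is below
#' `min_self_variance`; (3) drop descriptors that are zero for more than
#' `max_empty_cells` training compounds.
#'
#' @param min_abs_activity_corr minimum |R| with activity (default 0.1).
#' @param min_self_variance minimum descriptor variance.
#' @param max_empty_cells maximum allowed count of compounds with exactly
#'   zero occupancy.
#' @return an object of class `reduction_config`.
#' @export
reduction_config <- function(min_abs_activity_corr = 0.1,
                             min_self_variance = 0.004,
                             max_empty_cells = 37L) {
  stopifnot(min_abs_activity_corr >= 0, min_self_variance >= 0,
            max_empty_cells >= 0)
  structure(list(min_abs_activity_corr = min_abs_activity_corr,
                 min_self_variance = min_self_variance,
                 max_empty_cells = as.integer(max_empty_cells)),
            class = "reduction_config")
}

# Benchmark presets per alignment x cell size: self-variance floor and
# empty-cell ceiling (of the 41 training compounds).
.reduction_presets <- list(
  a1_c20 = list(min_self_variance = 0.00800, max_empty_cells = 37L),
  a1_c10 = list(min_self_variance = 0.00400, max_empty_cells = 37L),
  a2_c20 = list(min_self_variance = 0.00500, max_empty_cells = 37L),
  a2_c10 = list(min_self_variance = 0.00015, max_empty_cells = 36L),
  a3_c20 = list(min_self_variance = 0.00500, max_empty_cells = 38L),
  a3_c10 = list(min_self_variance = 0.00018, max_empty_cells = 36L)
)

#' Named reduction presets
#'
#' Presets `a<alignment>_c<cellsize*10>` carry the published per-alignment,
#' per-cell-size thresholds (e.g. `a1_c10`: variance floor 0.004, empty-cell
#' ceiling 37). The activity-correlation floor is 0.1 in all presets.
#'
#' @param name one of `"a1_c20"`, `"a1_c10"`, `"a2_c20"`, `"a2_c10"`,
#'   `"a3_c20"`, `"a3_c10"`.
#' @return a [reduction_config()].
#' @export
reduction_preset <- function(name) {
  if (!name %in% names(.reduction_presets)) {
    stop("unknown reduction preset: ", name)
  }
  p <- .reduction_presets[[name]]
  reduction_config(min_abs_activity_corr = 0.1,
                   min_self_variance = p$min_self_variance,
                   max_empty_cells = p$max_empty_cells)
}

#' Apply the three serial reduction filters to a descriptor pool
#'
#' Filters are per-column predicates, so the surviving set is independent
#' of stage order; the audit log records at which serial stage each dropped
#' column fell.
#'
#' @param occupancy occupancy matrix restricted to training compounds
#'   (rows) by GCOD keys (columns).
#' @param activities numeric activity vector, one per row of `occupancy`.
#' @param config a [reduction_config()].
#' @return a list with `occupancy` (the filtered matrix) and `audit`
#'   (data.frame: `key`, `fate` in `kept`/`dropped`, `stage` 1-3 or `NA`,
#'   `abs_corr`, `variance`, `n_empty`).
#' @export
reduce_gcods <- function(occupancy, activities, config = reduction_config()) {
  stopifnot(nrow(occupancy) == length(activities))
  if (nrow(occupancy) < 3) stop("need at least 3 training compounds")
  if (stats::var(activities) == 0) {
    stop("activity vector has zero variance; correlations are undefined")
  }
  keys <- colnames(occupancy)
  vars <- apply(occupancy, 2, stats::var)
  corr <- rep(NA_real_, ncol(occupancy))
  nz <- vars > 0
  if (any(nz)) {
    corr[nz] <- drop(stats::cor(occupancy[, nz, drop = FALSE], activities))
  }
  abs_corr <- abs(corr)
  n_empty <- colSums(occupancy == 0)

  # a zero-variance column has no defined correlation; it passes stage 1
  # and falls to the variance filter
  fail1 <- !is.na(abs_corr) & abs_corr < config$min_abs_activity_corr
  fail2 <- vars < config$min_self_variance
  fail3 <- n_empty > config$max_empty_cells
  stage <- ifelse(fail1, 1L, ifelse(fail2, 2L, ifelse(fail3, 3L, NA_integer_)))
  keep <- is.na(stage)

  audit <- data.frame(key = keys,
                      fate = ifelse(keep, "kept", "dropped"),
                      stage = stage,
                      abs_corr = abs_corr,
                      variance = vars,
                      n_empty = n_empty,
                      row.names = NULL, stringsAsFactors = FALSE)
  list(occupancy = occupancy[, keep, drop = FALSE], audit = audit)
}
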