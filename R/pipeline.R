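#' End-to-end 4D-QSAR run over one alignment and grid size
#'
#' Orchestrates the pipeline on a compound series: grid cell occupancy
#' descriptors for the training compounds, the three serial reduction
#' filters, the GA-PLS size sweep, internal validation of the per-size
#' winners, and external prediction for the test compounds. A winner whose
#' adjusted Q-squared falls below `q2_adj_floor` is flagged as weak in the
#' summary (mirroring the elimination of under-performing sizes in the
#' benchmark); it is reported, never silently dropped.
#'
#' @param occupancy occupancy matrix over all compounds (rows named by
#'   compound id).
#' @param activity data.frame with columns `id`, `role`
#'   (`train`/`test`), and the activity column `pic50`.
#' @param reduction a [reduction_config()] or preset name string.
#' @param gfa a [gfa_config()].
#' @param sizes model sizes to sweep.
#' @param q2_adj_floor threshold below which a model is flagged weak.
#' @return an object of class `qsar_run`: list with `summary` (one row per
#'   size: size, lof, r2, r2_adj, q2, q2_adj, sd_res, n_outliers, weak),
#'   `models`, `reports`, `external` (test-set predictions and residuals
#'   for the best size), `pool_size`, `audit`, `config`.
#' @export
run_qsar_pipeline <- function(occupancy, activity,
                              reduction = reduction_config(),
                              gfa = gfa_config(), sizes = c(7L, 8L, 9L),
                              q2_adj_floor = 0.5) {
  if (is.character(reduction)) reduction <- reduction_preset(reduction)
  stopifnot(all(c("id", "role", "pic50") %in% names(activity)))
  train <- activity$role == "train"
  ids <- as.character(activity$id)
  occ_train <- occupancy[match(ids[train], rownames(occupancy)), ,
                         drop = FALSE]
  y_train <- activity$pic50[train]

  red <- reduce_gcods(occ_train, y_train, reduction)
  pool <- red$occupancy
  if (ncol(pool) < max(sizes)) {
    stop("reduction stage left only ", ncol(pool),
         " descriptors; cannot fit ", max(sizes), "-term models")
  }

  sweep_out <- size_sweep(pool, y_train, gfa, sizes = sizes)
  fitter <- function(Xt, yt) fit_pls(Xt, yt, gfa$pls_components)
  reports <- lapply(sweep_out, function(s) {
    validation_report(pool[, s$candidate$descriptor_keys, drop = FALSE],
                      y_train, fitter, ids = ids[train])
  })
  summary <- do.call(rbind, lapply(seq_along(sweep_out), function(i) {
    s <- sweep_out[[i]]; r <- reports[[i]]
    data.frame(size = s$size, lof = s$candidate$lof, r2 = r$r2,
               r2_adj = r$r2_adj, q2 = r$q2, q2_adj = r$q2_adj,
               sd_res = r$sd_res, n_outliers = length(r$outlier_ids),
               weak = r$q2_adj < q2_adj_floor)
  }))

  best_i <- which.max(summary$q2_adj)
  best <- sweep_out[[best_i]]$candidate
  test <- !train
  external <- NULL
  if (any(test)) {
    occ_test <- occupancy[match(ids[test], rownames(occupancy)), ,
                          drop = FALSE]
    keys <- best$descriptor_keys
    Xt <- matrix(0, sum(test), length(keys),
                 dimnames = list(ids[test], keys))
    hit <- intersect(keys, colnames(occ_test))
    Xt[, hit] <- occ_test[, hit]
    pred <- best$intercept + drop(Xt %*% best$coefficients)
    resid <- pred - activity$pic50[test]
    external <- data.frame(id = activity$id[test], pic50 = activity$pic50[test],
                           predicted = pred, residual = resid)
    external$outlier <- external$id %in%
      find_outliers(resid, residual_sd(resid), activity$id[test])
  }
  structure(list(summary = summary,
                 models = lapply(sweep_out, `[[`, "candidate"),
                 reports = reports,
                 external = external,
                 best_size = sweep_out[[best_i]]$size,
                 pool_size = ncol(pool),
                 audit = red$audit,
                 config = list(reduction = reduction, gfa = gfa,
                               sizes = sizes, seed = gfa$seed)),
            class = "qsar_run")
}

#' @export
print.qsar_run <- function(x, ...) {
  cat(sprintf("qsar_run: pool of %d descriptors after reduction (seed %d)\n",
              x$pool_size, x$config$seed))
  print(x$summary, row.names = FALSE)
  cat(sprintf("best size by Q2_adj: %d terms\n", x$best_size))
  invisible(x)
}
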