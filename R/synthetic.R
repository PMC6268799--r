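#' Specification of a synthetic compound series
#'
#' Defines a generated series whose activities are a known sparse linear
#' function of grid cell occupancies, so descriptor generation, reduction,
#' model search, and validation can all be exercised against a planted
#' truth. Defaults mirror the benchmark study conditions: 41 training plus
#' 13 test compounds, 2,000 conformations per ensemble, a 1.0-angstrom
#' grid, and at most nine model terms downstream.
#'
#' @param n_compounds total number of compounds (train + test).
#' @param n_train number of training compounds.
#' @param atoms_per_compound atoms in each generated atom cloud (the first
#'   three are rigid anchors used for alignment).
#' @param n_true_descriptors number of descriptors with planted nonzero
#'   coefficients.
#' @param coefficients planted coefficient values (recycled/truncated to
#'   `n_true_descriptors`); default magnitudes echo the published
#'   equations.
#' @param intercept planted intercept, pIC50 units.
#' @param noise_sd activity noise standard deviation, pIC50 units.
#' @param ensemble_size conformations per compound.
#' @param compound_sd per-compound displacement of the shared scaffold
#'   atoms, angstroms (the across-series structural variation of a
#'   congeneric set).
#' @param jitter_sd per-conformer Gaussian jitter of non-anchor atoms,
#'   angstroms (the conformational spread).
#' @param box half-width of the scaffold placement box, angstroms.
#' @param seed integer seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds = 54L, n_train = 41L,
                           atoms_per_compound = 15L,
                           n_true_descriptors = 3L,
                           coefficients = c(8, -6, 4, 3, -3, 2, -2),
                           intercept = 7.5, noise_sd = 0.1,
                           ensemble_size = 2000L, compound_sd = 0.5,
                           jitter_sd = 0.35, box = 4, seed = 1L) {
  stopifnot(n_true_descriptors >= 1, noise_sd >= 0,
            n_train <= n_compounds, atoms_per_compound >= 4)
  coefficients <- rep_len(coefficients, n_true_descriptors)
  structure(list(n_compounds = as.integer(n_compounds),
                 n_train = as.integer(n_train),
                 atoms_per_compound = as.integer(atoms_per_compound),
                 n_true_descriptors = as.integer(n_true_descriptors),
                 coefficients = coefficients, intercept = intercept,
                 noise_sd = noise_sd,
                 ensemble_size = as.integer(ensemble_size),
                 compound_sd = compound_sd, jitter_sd = jitter_sd, box = box,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic compound series with planted activity coefficients
#'
#' Each compound is an atom cloud built like a congeneric series: three
#' fixed anchor atoms shared by every compound (the alignment triple), a
#' scaffold of `atoms_per_compound - 3` carbon positions drawn once and
#' shared across the series, a per-compound Gaussian displacement of each
#' scaffold atom (`compound_sd`; the structural variation between analogs),
#' and a per-conformer jitter (`jitter_sd`; the conformational spread).
#' Cells near the scaffold are therefore occupied by most compounds with a
#' frequency that varies continuously across the series, which is the
#' regime the occupancy descriptors assume. Occupancies are computed
#' on the `any` class over the given grid; `n_true_descriptors` columns
#' with across-compound variance are picked as the true descriptors, and
#' activities are `intercept + sum(coef * occupancy) + N(0, noise_sd)`.
#'
#' @param spec a [synthetic_spec()].
#' @param grid a [grid_spec()].
#' @return a list with `activity` (data.frame: `id`, `role`, `pic50`),
#'   `ensembles` (list of [conformer_ensemble()]), `occupancy` (the
#'   [compute_gcods()] matrix over all compounds), `true_model` (list:
#'   `descriptor_keys`, `coefficients`, `intercept`, `noise_sd`),
#'   `alignment`, `reference`.
#' @export
generate_synthetic_series <- function(spec = synthetic_spec(),
                                      grid = grid_spec(1.0)) {
  old_seed <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  anchors <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.5, 0))
  n_free <- spec$atoms_per_compound - 3L
  elements <- c(rep("C", 3L), rep("C", n_free))
  alignment <- alignment_spec("synthetic", 1:3)

  scaffold <- matrix(stats::runif(n_free * 3, -spec$box, spec$box), ncol = 3)
  ensembles <- vector("list", spec$n_compounds)
  for (i in seq_len(spec$n_compounds)) {
    base <- rbind(anchors,
                  scaffold + matrix(stats::rnorm(n_free * 3, 0,
                                                 spec$compound_sd),
                                    ncol = 3))
    coords <- array(NA_real_,
                    dim = c(spec$atoms_per_compound, 3L, spec$ensemble_size))
    for (k in seq_len(spec$ensemble_size)) {
      jit <- matrix(stats::rnorm(n_free * 3, 0, spec$jitter_sd), ncol = 3)
      coords[, , k] <- rbind(anchors, base[-(1:3), , drop = FALSE] + jit)
    }
    ensembles[[i]] <- conformer_ensemble(i, coords,
                                         energies = rep(0, spec$ensemble_size),
                                         elements = elements)
  }
  reference <- rbind(anchors,
                     matrix(0, n_free, 3))

  occupancy <- compute_gcods(ensembles, reference, alignment, grid,
                             align = FALSE)
  # all-carbon clouds duplicate every `any` column as `np`; keep the `any`
  # class so the planted descriptor subset is identifiable
  keep <- parse_gcod_key(colnames(occupancy))$ipe == "any"
  occupancy <- occupancy[, keep, drop = FALSE]

  train_rows <- seq_len(spec$n_train)
  occ_train <- occupancy[train_rows, , drop = FALSE]
  vars <- apply(occ_train, 2, stats::var)
  # plant only on cells occupied by most training compounds: a causal
  # descriptor that is empty for nearly everyone would (correctly) be
  # discarded by the empty-cell reduction filter before model search
  populated <- colSums(occ_train > 0) >= ceiling(0.5 * spec$n_train)
  eligible <- names(sort(vars[populated & vars > 0], decreasing = TRUE))
  if (length(eligible) < spec$n_true_descriptors) {
    stop("degenerate spec: not enough occupancy variance to plant ",
         spec$n_true_descriptors, " descriptors")
  }
  # plant on high-variance cells so the signal is identifiable
  n_top <- min(length(eligible), max(20L, spec$n_true_descriptors))
  true_keys <- sample(eligible[seq_len(n_top)], spec$n_true_descriptors)
  signal <- drop(occupancy[, true_keys, drop = FALSE] %*% spec$coefficients)
  activity <- spec$intercept + signal +
    stats::rnorm(spec$n_compounds, 0, spec$noise_sd)

  roles <- c(rep("train", spec$n_train),
             rep("test", spec$n_compounds - spec$n_train))
  list(activity = data.frame(id = seq_len(spec$n_compounds), role = roles,
                             pic50 = activity),
       ensembles = ensembles,
       occupancy = occupancy,
       true_model = list(descriptor_keys = true_keys,
                         coefficients = stats::setNames(spec$coefficients,
                                                        true_keys),
                         intercept = spec$intercept,
                         noise_sd = spec$noise_sd),
       alignment = alignment,
       reference = reference)
}

#' Score recovery of a planted model by a fitted one
#'
#' @param true_model list with `descriptor_keys` and named `coefficients`
#'   (as returned in `generate_synthetic_series()$true_model`).
#' @param fitted_model a model candidate with `descriptor_keys` and named
#'   `coefficients`.
#' @return list with `overlap` (fraction of true descriptors selected) and
#'   `coef_rmse` (RMSE over the matched coefficients; `NA` when no keys
#'   match).
#' @export
recovery_score <- function(true_model, fitted_model) {
  true_keys <- true_model$descriptor_keys
  sel <- fitted_model$descriptor_keys
  matched <- intersect(true_keys, sel)
  overlap <- length(matched) / length(true_keys)
  coef_rmse <- if (length(matched)) {
    sqrt(mean((fitted_model$coefficients[matched] -
                 true_model$coefficients[matched])^2))
  } else NA_real_
  list(overlap = overlap, coef_rmse = coef_rmse)
}
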