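#' Friedman's lack-of-fit fitness
#'
#' LOF penalizes the training least-squares error by model size:
#' `LOF = (LSE/M) / (1 - (c + d p)/M)^2`, where `M` is the number of
#' training samples, `c` counts the fitted terms including the intercept,
#' `p` the number of selected descriptors (for the linear models here,
#' `p = c - 1`), and `d` the smoothing factor that steers how strongly
#' extra descriptors are punished (published range 0.5-3.0).
#'
#' @param lse sum of squared training residuals.
#' @param n_terms `c`, non-intercept terms plus one for the intercept.
#' @param n_descriptors `p`, number of selected descriptors.
#' @param smoothing_d smoothing factor `d`.
#' @param n_samples `M`, number of training samples.
#' @return the LOF value; smaller is fitter.
#' @examples
#' lof(4.1, n_terms = 10, n_descriptors = 9, smoothing_d = 1, n_samples = 41)
#' @export
lof <- function(lse, n_terms, n_descriptors, smoothing_d, n_samples) {
  stopifnot(lse >= 0, n_samples > 0)
  pen <- 1 - (n_terms + smoothing_d * n_descriptors) / n_samples
  if (pen <= 0) {
    stop("infeasible model: M <= c + d*p (penalty denominator <= 0)")
  }
  (lse / n_samples) / pen^2
}

#' Fit a PLS regression and report coefficients in descriptor space
#'
#' PLS1 by orthogonalized NIPALS: predictors and response are centered
#' internally, latent components are extracted from the covariance
#' direction, and the final model is back-transformed so it prints as an
#' ordinary linear equation (intercept plus one coefficient per
#' descriptor). With `n_components` equal to the number of (linearly
#' independent) descriptors the fit coincides with ordinary least squares.
#' A column that is constant after centering simply receives a zero
#' loading.
#'
#' @param X numeric training matrix (samples x descriptors).
#' @param y numeric response vector.
#' @param n_components number of latent components, or `"auto"` to pick
#'   the count (1..min(5, p)) maximizing leave-one-out Q-squared.
#' @return a list with `intercept`, `coefficients` (named by column),
#'   `lse` (training sum of squared residuals), `fitted`, `n_components`.
#' @export
fit_pls <- function(X, y, n_components = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  p <- ncol(X)
  if (p == 0) stop("no descriptors to fit")
  if (identical(n_components, "auto")) {
    cand <- seq_len(min(5L, p))
    q2 <- vapply(cand, function(a) {
      loo_q2(X, y, function(Xt, yt) fit_pls(Xt, yt, a))$q2
    }, numeric(1))
    n_components <- cand[which.max(q2)]
  }
  if (is.null(n_components)) n_components <- min(p, nrow(X) - 1L)
  a_max <- min(n_components, p, nrow(X) - 1L)

  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  W <- matrix(0, p, a_max)   # X weights
  P <- matrix(0, p, a_max)   # X loadings
  qv <- numeric(a_max)       # y loadings
  E <- Xc
  f <- yc
  a_used <- 0L
  for (a in seq_len(a_max)) {
    w <- drop(crossprod(E, f))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break
    w <- w / wn
    t_ <- drop(E %*% w)
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    p_ <- drop(crossprod(E, t_)) / tt
    q_ <- sum(t_ * f) / tt
    E <- E - tcrossprod(t_, p_)
    f <- f - t_ * q_
    a_used <- a + 0L
    W[, a] <- w
    P[, a] <- p_
    qv[a] <- q_
  }
  if (a_used == 0L) {
    beta <- rep(0, p)
  } else {
    Wa <- W[, seq_len(a_used), drop = FALSE]
    Pa <- P[, seq_len(a_used), drop = FALSE]
    qa <- qv[seq_len(a_used)]
    # beta = W (P'W)^-1 q
    beta <- drop(Wa %*% solve(crossprod(Pa, Wa), qa))
  }
  names(beta) <- colnames(X)
  intercept <- ym - sum(beta * xm)
  fitted <- drop(X %*% beta) + intercept
  list(intercept = intercept, coefficients = beta,
       lse = sum((fitted - y)^2), fitted = fitted, n_components = a_used)
}

#' GA search configuration
#'
#' @param population_size number of descriptor subsets kept in the
#'   population.
#' @param n_crossovers total number of crossover operations (published
#'   range 6,000-20,000).
#' @param mutation_prob probability that an offspring undergoes one
#'   mutation event (published setting: 1.0).
#' @param smoothing_d LOF smoothing factor (published range 0.5-3.0).
#' @param max_terms maximum descriptors per model (at most 9 in the
#'   published analysis).
#' @param min_terms minimum descriptors per model.
#' @param pls_components fixed component count, `"auto"`, or `NULL` for
#'   full rank (OLS-equivalent).
#' @param seed integer seed; the search is bit-reproducible for a fixed
#'   seed.
#' @return an object of class `gfa_config`.
#' @export
gfa_config <- function(population_size = 100L, n_crossovers = 6000L,
                       mutation_prob = 1.0, smoothing_d = 1.0,
                       max_terms = 9L, min_terms = 1L,
                       pls_components = NULL, seed = 1L) {
  stopifnot(mutation_prob >= 0, mutation_prob <= 1, max_terms >= 1,
            min_terms >= 1, min_terms <= max_terms,
            n_crossovers >= population_size)
  structure(list(population_size = as.integer(population_size),
                 n_crossovers = as.integer(n_crossovers),
                 mutation_prob = mutation_prob,
                 smoothing_d = smoothing_d,
                 max_terms = as.integer(max_terms),
                 min_terms = as.integer(min_terms),
                 pls_components = pls_components,
                 seed = as.integer(seed)),
            class = "gfa_config")
}

# Fit one descriptor subset and score it; returns a model candidate.
.fit_candidate <- function(keys, pool, activities, config) {
  X <- pool[, keys, drop = FALSE]
  fit <- fit_pls(X, activities, config$pls_components)
  n <- length(activities)
  p <- length(keys)
  score <- tryCatch(
    lof(fit$lse, n_terms = p + 1L, n_descriptors = p,
        smoothing_d = config$smoothing_d, n_samples = n),
    error = function(e) Inf)   # infeasible size: worst fitness
  list(descriptor_keys = keys, intercept = fit$intercept,
       coefficients = fit$coefficients, lse = fit$lse, lof = score)
}

.random_subset <- function(keys, config) {
  size <- sample(seq(config$min_terms, min(config$max_terms, length(keys))), 1L)
  sort(sample(keys, size))
}

# Crossover: child takes the shared descriptors plus a random draw from the
# symmetric difference, then is clamped into [min_terms, max_terms].
.crossover <- function(k1, k2, keys, config) {
  shared <- intersect(k1, k2)
  rest <- setdiff(union(k1, k2), shared)
  child <- shared
  if (length(rest)) {
    take <- stats::rbinom(length(rest), 1L, 0.5) == 1L
    child <- c(child, rest[take])
  }
  if (length(child) < config$min_terms) {
    extra <- setdiff(union(rest, keys), child)
    child <- c(child, sample(extra, config$min_terms - length(child)))
  }
  if (length(child) > config$max_terms) {
    child <- sample(child, config$max_terms)
  }
  sort(child)
}

# Mutation event: swap a descriptor with an unused one (80%), insert (10%)
# or delete (10%), respecting the size bounds.
.mutate <- function(child, keys, config) {
  unused <- setdiff(keys, child)
  u <- stats::runif(1)
  if (u < 0.8 || (u < 0.9 && !length(unused)) ) {
    if (length(unused)) {
      child[sample.int(length(child), 1L)] <- sample(unused, 1L)
    }
  } else if (u < 0.9) {
    if (length(unused) && length(child) < config$max_terms) {
      child <- c(child, sample(unused, 1L))
    }
  } else {
    if (length(child) > config$min_terms) {
      child <- child[-sample.int(length(child), 1L)]
    }
  }
  sort(unique(child))
}

#' Genetic-function-approximation search over descriptor subsets
#'
#' Evolves a population of descriptor subsets: random initialization,
#' rank-based tournament parent selection (k = 2), crossover recombining
#' the parents' descriptor sets, one mutation event per offspring with
#' probability `mutation_prob`, elitism of the top two, all scored by
#' [lof()] over [fit_pls()] fits. Returns the distinct candidates seen,
#' ranked by ascending LOF.
#'
#' @param pool reduced occupancy matrix (training rows x descriptor keys).
#' @param activities numeric activity vector.
#' @param config a [gfa_config()].
#' @return list of model candidates (fields `descriptor_keys`, `intercept`,
#'   `coefficients`, `lse`, `lof`), best first.
#' @export
gfa_search <- function(pool, activities, config = gfa_config()) {
  keys <- colnames(pool)
  if (!length(keys)) stop("empty descriptor pool")
  if (length(activities) < config$max_terms + 2L) {
    stop("too few training samples for max_terms")
  }
  old_seed <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  seen <- new.env(hash = TRUE)
  note <- function(cand) {
    id <- paste(cand$descriptor_keys, collapse = ";")
    if (is.null(seen[[id]])) seen[[id]] <- cand
    cand
  }
  pop <- lapply(seq_len(config$population_size), function(i) {
    note(.fit_candidate(.random_subset(keys, config), pool, activities,
                        config))
  })
  pop_lof <- vapply(pop, `[[`, numeric(1), "lof")

  pick_parent <- function() {
    i <- sample.int(length(pop), 2L)
    if (pop_lof[i[1]] <= pop_lof[i[2]]) i[1] else i[2]
  }
  for (gen in seq_len(config$n_crossovers)) {
    p1 <- pop[[pick_parent()]]
    p2 <- pop[[pick_parent()]]
    child_keys <- .crossover(p1$descriptor_keys, p2$descriptor_keys, keys,
                             config)
    if (stats::runif(1) < config$mutation_prob) {
      child_keys <- .mutate(child_keys, keys, config)
    }
    child <- note(.fit_candidate(child_keys, pool, activities, config))
    # replace the worst member if the child improves on it (elitism of the
    # top two is implied: they are never the worst while better exists)
    worst <- which.max(pop_lof)
    if (child$lof < pop_lof[worst]) {
      pop[[worst]] <- child
      pop_lof[worst] <- child$lof
    }
  }
  all_cands <- mget(ls(seen), envir = seen)
  ord <- order(vapply(all_cands, `[[`, numeric(1), "lof"))
  unname(all_cands[ord])
}

#' Best model per model size
#'
#' Runs the GA once per requested size with the term count pinned
#' (`min_terms = max_terms = size`) and reports, for each size, the
#' candidate with the highest adjusted leave-one-out Q-squared (the
#' Q2_adj-versus-terms sweep used to pick the model size).
#'
#' @param pool reduced occupancy matrix.
#' @param activities numeric activity vector.
#' @param config a [gfa_config()]; its size bounds are overridden per size.
#' @param sizes integer vector of model sizes (default 7, 8, 9).
#' @param rank_top how many top-LOF candidates per size are re-ranked by
#'   Q2_adj.
#' @return a list per size with fields `size`, `candidate`, `q2`, `q2_adj`.
#' @export
size_sweep <- function(pool, activities, config = gfa_config(),
                       sizes = c(7L, 8L, 9L), rank_top = 10L) {
  lapply(sizes, function(s) {
    cfg <- config
    cfg$min_terms <- cfg$max_terms <- as.integer(s)
    cfg$seed <- config$seed + as.integer(s)
    cands <- gfa_search(pool, activities, cfg)
    cands <- Filter(function(c) length(c$descriptor_keys) == s, cands)
    if (!length(cands)) stop("no feasible candidate of size ", s)
    top <- cands[seq_len(min(rank_top, length(cands)))]
    q2a <- vapply(top, function(cand) {
      q2 <- loo_q2(pool[, cand$descriptor_keys, drop = FALSE], activities,
                   function(Xt, yt) fit_pls(Xt, yt, config$pls_components))$q2
      adjusted(q2, length(activities), s)
    }, numeric(1))
    best <- which.max(q2a)
    q2 <- loo_q2(pool[, top[[best]]$descriptor_keys, drop = FALSE],
                 activities,
                 function(Xt, yt) fit_pls(Xt, yt, config$pls_components))$q2
    list(size = s, candidate = top[[best]], q2 = q2, q2_adj = q2a[best])
  })
}

#' Format a model candidate as a printable linear equation
#'
#' @param candidate a model candidate from [gfa_search()] or a published
#'   model from [load_published_model()].
#' @param digits coefficient digits.
#' @return a single character string, e.g.
#'   `"pIC50 = 8.19 - 18.84 (2,11,4)(any) + ..."`.
#' @export
format_equation <- function(candidate, digits = 2) {
  if (inherits(candidate, "qsar_model")) {
    keys <- vapply(seq_along(candidate$coefficients), function(i) {
      sprintf("(%s)(%s)", paste(candidate$cells[i, ], collapse = ","),
              candidate$ipes[i])
    }, character(1))
    coefs <- candidate$coefficients
    intercept <- candidate$intercept
  } else {
    pk <- parse_gcod_key(candidate$descriptor_keys)
    keys <- sprintf("(%d,%d,%d)(%s)", pk$x, pk$y, pk$z, pk$ipe)
    coefs <- candidate$coefficients
    intercept <- candidate$intercept
  }
  terms <- sprintf("%s %s %s",
                   ifelse(coefs < 0, "-", "+"),
                   formatC(abs(coefs), digits = digits, format = "f"),
                   keys)
  paste("pIC50 =", formatC(intercept, digits = digits, format = "f"),
        paste(terms, collapse = " "))
}
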