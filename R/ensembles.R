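#' Conformational sampling schedule
#'
#' Bundles the stochastic-sampling parameters that define the size of a
#' conformational ensemble profile (CEP). The default mirrors the benchmark
#' protocol: 310 K, 100 ps sampled at 0.001 ps per step, snapshots recorded
#' every 50 steps, giving 2,000 conformations per compound.
#'
#' @param temperature_K simulation temperature in kelvin.
#' @param duration_ps total sampled time in picoseconds.
#' @param step_ps time step in picoseconds.
#' @param record_every record a snapshot every this many steps.
#' @param seed integer seed for the stochastic sampler.
#' @return an object of class `sampling_schedule`.
#' @export
sampling_schedule <- function(temperature_K = 310, duration_ps = 100,
                              step_ps = 0.001, record_every = 50L,
                              seed = 1L) {
  stopifnot(temperature_K > 0, duration_ps > 0)
  if (step_ps <= 0 || record_every <= 0) {
    stop("step_ps and record_every must be positive")
  }
  structure(list(temperature_K = temperature_K, duration_ps = duration_ps,
                 step_ps = step_ps, record_every = as.integer(record_every),
                 seed = as.integer(seed)),
            class = "sampling_schedule")
}

#' Number of snapshots a schedule records
#'
#' @param schedule a [sampling_schedule()].
#' @return integer: `floor(duration_ps / step_ps / record_every)`.
#' @examples
#' snapshot_count(sampling_schedule())  # 2000
#' @export
snapshot_count <- function(schedule) {
  n <- floor(schedule$duration_ps / schedule$step_ps / schedule$record_every)
  if (n < 1) stop("schedule records no snapshots")
  as.integer(n)
}

#' Construct a conformer ensemble
#'
#' A conformer ensemble holds one compound's set of 3D conformations (the
#' "fourth dimension"): an `natoms x 3 x nconf` coordinate array in
#' angstroms, per-conformer energies in kcal/mol (reported relative to the
#' ensemble minimum), per-atom element symbols, and optional per-atom
#' partial charges and bonds.
#'
#' @param compound_id identifier of the compound.
#' @param coords numeric array `natoms x 3 x nconf`, or a list of
#'   `natoms x 3` matrices.
#' @param energies numeric vector of length `nconf` (kcal/mol).
#' @param elements character vector of element symbols, length `natoms`.
#' @param charges optional numeric per-atom partial charges.
#' @param bonds optional two-column integer matrix of bonded atom pairs.
#' @param schedule optional [sampling_schedule()] provenance.
#' @return an object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(compound_id, coords, energies, elements,
                               charges = NULL, bonds = NULL,
                               schedule = NULL) {
  if (is.list(coords)) {
    coords <- array(unlist(coords),
                    dim = c(nrow(coords[[1]]), 3L, length(coords)))
  }
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  natoms <- dim(coords)[1]
  nconf <- dim(coords)[3]
  if (nconf < 1) stop("ensemble must contain at least one conformation")
  if (length(energies) != nconf) stop("one energy per conformation required")
  if (any(!is.finite(energies))) stop("energies must be finite")
  if (length(elements) != natoms) stop("one element symbol per atom required")
  structure(list(compound_id = compound_id,
                 coords = coords,
                 energies = energies - min(energies),
                 elements = elements,
                 charges = charges,
                 bonds = bonds,
                 schedule = schedule),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("conformer_ensemble: compound %s, %d atoms, %d conformations\n",
              as.character(x$compound_id), dim(x$coords)[1], dim(x$coords)[3]))
  cat(sprintf("  relative energy range: 0 - %.2f kcal/mol\n", max(x$energies)))
  invisible(x)
}

#' Number of conformations in an ensemble
#' @param ensemble a `conformer_ensemble`.
#' @return integer count.
#' @export
n_conformations <- function(ensemble) dim(ensemble$coords)[3]

# kcal/mol per kelvin
.kB <- 0.0019872041

# Rotatable bonds: non-ring single bonds whose both atoms have at least one
# further heavy-atom neighbour. Ring membership detected by checking whether
# removing the bond disconnects its endpoints (BFS).
.rotatable_bonds <- function(bonds, natoms, elements) {
  if (is.null(bonds) || nrow(bonds) == 0) return(matrix(integer(0), ncol = 2))
  adj <- vector("list", natoms)
  for (i in seq_len(nrow(bonds))) {
    a <- bonds[i, 1]; b <- bonds[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  heavy <- elements != "H"
  connected_without <- function(a, b) {
    seen <- rep(FALSE, natoms)
    queue <- a
    seen[a] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if ((v == a && w == b) || (v == b && w == a)) next
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    seen[b]
  }
  keep <- logical(nrow(bonds))
  for (i in seq_len(nrow(bonds))) {
    a <- bonds[i, 1]; b <- bonds[i, 2]
    deg_a <- sum(heavy[adj[[a]]])
    deg_b <- sum(heavy[adj[[b]]])
    terminal <- deg_a < 2 || deg_b < 2
    keep[i] <- !terminal && !connected_without(a, b)
  }
  bonds[keep, , drop = FALSE]
}

# Atoms on the b-side of rotatable bond a-b (moved when the torsion turns).
.downstream_atoms <- function(bonds, natoms, a, b) {
  adj <- vector("list", natoms)
  for (i in seq_len(nrow(bonds))) {
    p <- bonds[i, 1]; q <- bonds[i, 2]
    adj[[p]] <- c(adj[[p]], q)
    adj[[q]] <- c(adj[[q]], p)
  }
  seen <- rep(FALSE, natoms)
  seen[a] <- TRUE  # block traversal through a
  queue <- b
  seen[b] <- TRUE
  out <- b
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) {
      seen[w] <- TRUE
      queue <- c(queue, w)
      out <- c(out, w)
    }
  }
  out
}

# Rotate points about the axis through `origin` along unit vector `axis`.
.rotate_about_axis <- function(pts, origin, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  p <- sweep(pts, 2, origin)
  ca <- cos(angle); sa <- sin(angle)
  cross <- cbind(axis[2] * p[, 3] - axis[3] * p[, 2],
                 axis[3] * p[, 1] - axis[1] * p[, 3],
                 axis[1] * p[, 2] - axis[2] * p[, 1])
  dot <- drop(p %*% axis)
  rotated <- p * ca + cross * sa + outer(dot * (1 - ca), axis)
  sweep(rotated, 2, -origin)
}

# Default stand-in energy (kcal/mol): threefold periodic torsion barriers
# plus a soft-sphere clash term over non-bonded heavy-atom pairs.
.default_energy <- function(coords, rot, elements, bonds,
                            barrier = 2.0, clash_k = 10, clash_r = 2.4) {
  e <- 0
  if (nrow(rot) > 0) {
    for (i in seq_len(nrow(rot))) {
      # torsion angle proxy: use the bond vector's neighbours; a full
      # dihedral needs 4 atoms, so pick any neighbour of each end
      phi <- .torsion_angle(coords, bonds, rot[i, 1], rot[i, 2])
      if (!is.na(phi)) e <- e + barrier / 2 * (1 + cos(3 * phi))
    }
  }
  heavy <- which(elements != "H")
  if (length(heavy) > 1) {
    bonded <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
    d <- as.matrix(stats::dist(coords[heavy, , drop = FALSE]))
    for (i in seq_along(heavy)) for (j in seq_len(i - 1L)) {
      key <- paste(min(heavy[i], heavy[j]), max(heavy[i], heavy[j]))
      if (key %in% bonded) next
      if (d[i, j] < clash_r) e <- e + clash_k * (clash_r - d[i, j])^2
    }
  }
  e
}

# Dihedral about bond a-b using one neighbour on each side; NA if either
# end has no further neighbour.
.torsion_angle <- function(coords, bonds, a, b) {
  nb <- function(x, excl) {
    hits <- c(bonds[bonds[, 1] == x, 2], bonds[bonds[, 2] == x, 1])
    hits <- setdiff(hits, excl)
    if (length(hits)) min(hits) else NA_integer_
  }
  i <- nb(a, b); l <- nb(b, a)
  if (is.na(i) || is.na(l)) return(NA_real_)
  b1 <- coords[a, ] - coords[i, ]
  b2 <- coords[b, ] - coords[a, ]
  b3 <- coords[l, ] - coords[b, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  b2n <- b2 / sqrt(sum(b2^2))
  atan2(sum(m1 / sqrt(sum(b2^2)) * n2), sum(n1 * n2))
}

#' Sample a conformational ensemble with a Metropolis torsional sampler
#'
#' Stands in for force-field molecular dynamics: starting from a seed 3D
#' conformation, rotatable torsions are perturbed (Gaussian, `sigma_torsion`
#' radians) and a small isotropic Cartesian jitter (`sigma_jitter`
#' angstroms) is added; moves are accepted by the Metropolis criterion at
#' the schedule temperature under a simple torsional-plus-clash energy.
#' Snapshot thinning follows `record_every`, so the ensemble has
#' [snapshot_count()] conformations. Molecules without rotatable bonds
#' yield an ensemble of jittered copies of the seed (never an error).
#' Deterministic for a fixed `schedule$seed`.
#'
#' @param coords seed conformation, `natoms x 3` matrix (angstroms).
#' @param elements per-atom element symbols.
#' @param bonds two-column integer matrix of bonds (may be `NULL`).
#' @param schedule a [sampling_schedule()].
#' @param compound_id identifier stored in the ensemble.
#' @param sigma_torsion torsion proposal width, radians.
#' @param sigma_jitter Cartesian jitter width, angstroms.
#' @param energy_fn energy function `function(coords)` returning kcal/mol;
#'   defaults to the built-in torsion + soft-sphere clash energy.
#' @return a [conformer_ensemble()].
#' @export
sample_ensemble <- function(coords, elements, bonds = NULL,
                            schedule = sampling_schedule(),
                            compound_id = NA, sigma_torsion = 0.3,
                            sigma_jitter = 0.05, energy_fn = NULL) {
  stopifnot(is.matrix(coords), ncol(coords) == 3,
            nrow(coords) == length(elements))
  natoms <- nrow(coords)
  nsnap <- snapshot_count(schedule)
  rot <- .rotatable_bonds(bonds, natoms, elements)
  if (is.null(energy_fn)) {
    if (is.null(bonds) || nrow(rot) == 0) {
      energy_fn <- function(x) 0
    } else {
      energy_fn <- function(x) .default_energy(x, rot, elements, bonds)
    }
  }
  down <- if (nrow(rot) > 0) {
    lapply(seq_len(nrow(rot)),
           function(i) .downstream_atoms(bonds, natoms, rot[i, 1], rot[i, 2]))
  } else list()

  kT <- .kB * schedule$temperature_K
  out <- array(NA_real_, dim = c(natoms, 3L, nsnap))
  energies <- numeric(nsnap)

  old_seed <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(schedule$seed)

  if (nrow(rot) == 0) {
    # no torsional degrees of freedom: the ensemble is independent
    # Gaussian-jittered copies of the seed (a chain of accepted jitter
    # moves would random-walk away from it)
    for (snap in seq_len(nsnap)) {
      out[, , snap] <- coords + matrix(stats::rnorm(natoms * 3, 0,
                                                    sigma_jitter), ncol = 3)
      energies[snap] <- energy_fn(out[, , snap])
    }
    return(conformer_ensemble(compound_id, out, energies, elements,
                              bonds = bonds, schedule = schedule))
  }

  cur <- coords
  e_cur <- energy_fn(cur)
  for (snap in seq_len(nsnap)) {
    # one Metropolis sweep per recorded snapshot (thinning folded in)
    prop <- cur
    if (nrow(rot) > 0) {
      k <- sample.int(nrow(rot), 1L)
      a <- rot[k, 1]; b <- rot[k, 2]
      axis <- prop[b, ] - prop[a, ]
      if (sum(axis^2) > 1e-12) {
        ang <- stats::rnorm(1, 0, sigma_torsion)
        idx <- down[[k]]
        prop[idx, ] <- .rotate_about_axis(prop[idx, , drop = FALSE],
                                          prop[a, ], axis, ang)
      }
    }
    prop <- prop + matrix(stats::rnorm(natoms * 3, 0, sigma_jitter),
                          ncol = 3)
    e_prop <- energy_fn(prop)
    if (e_prop <= e_cur || stats::runif(1) < exp(-(e_prop - e_cur) / kT)) {
      cur <- prop
      e_cur <- e_prop
    }
    out[, , snap] <- cur
    energies[snap] <- e_cur
  }
  conformer_ensemble(compound_id, out, energies, elements,
                     bonds = bonds, schedule = schedule)
}

#' Write a conformer ensemble to disk
#'
#' `"sdf"` writes a multi-record V2000 SDF with the relative energy in an
#' `ENERGY_KCAL` data field; `"xyz"` writes a multi-frame XYZ file with the
#' energy on each comment line (`energy= <value>`).
#'
#' @param ensemble a [conformer_ensemble()].
#' @param path output file path.
#' @param format `"sdf"` or `"xyz"`.
#' @export
write_ensemble <- function(ensemble, path, format = c("sdf", "xyz")) {
  format <- match.arg(format)
  natoms <- dim(ensemble$coords)[1]
  nconf <- dim(ensemble$coords)[3]
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "xyz") {
    for (k in seq_len(nconf)) {
      writeLines(as.character(natoms), con)
      writeLines(sprintf("compound=%s conformer=%d energy= %.6f",
                         as.character(ensemble$compound_id), k,
                         ensemble$energies[k]), con)
      writeLines(sprintf("%-2s %12.4f %12.4f %12.4f",
                         ensemble$elements,
                         ensemble$coords[, 1, k],
                         ensemble$coords[, 2, k],
                         ensemble$coords[, 3, k]), con)
    }
  } else {
    nb <- if (is.null(ensemble$bonds)) 0L else nrow(ensemble$bonds)
    for (k in seq_len(nconf)) {
      writeLines(sprintf("compound_%s", as.character(ensemble$compound_id)),
                 con)
      writeLines("  qsar4d", con)
      writeLines("", con)
      writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                         natoms, nb), con)
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         ensemble$coords[, 1, k],
                         ensemble$coords[, 2, k],
                         ensemble$coords[, 3, k],
                         ensemble$elements), con)
      if (nb > 0) {
        writeLines(sprintf("%3d%3d  1  0", ensemble$bonds[, 1],
                           ensemble$bonds[, 2]), con)
      }
      writeLines("M  END", con)
      writeLines(">  <ENERGY_KCAL>", con)
      writeLines(sprintf("%.6f", ensemble$energies[k]), con)
      writeLines("", con)
      writeLines("$$$$", con)
    }
  }
  invisible(path)
}

#' Read a conformer ensemble from disk
#'
#' Counterpart of [write_ensemble()]; write then read round-trips
#' coordinates to 1e-4 angstroms and energies to 1e-6 kcal/mol. Records
#' with inconsistent atom counts raise an error naming the record index.
#'
#' @param path input file path.
#' @param format `"sdf"` or `"xyz"`.
#' @param compound_id identifier stored in the ensemble (default: parsed
#'   from the file where present).
#' @return a [conformer_ensemble()].
#' @export
read_ensemble <- function(path, format = c("sdf", "xyz"), compound_id = NULL) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    stop("empty ensemble file: ", path)
  }
  if (format == "xyz") {
    frames <- list(); energies <- numeric(0); elements <- NULL
    i <- 1L; rec <- 0L
    while (i <= length(lines)) {
      if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
      rec <- rec + 1L
      n <- suppressWarnings(as.integer(trimws(lines[i])))
      if (is.na(n) || n < 1) stop("unparseable atom count in record ", rec)
      if (i + 1L + n > length(lines)) stop("truncated record ", rec)
      comment <- lines[i + 1L]
      e <- regmatches(comment, regexec("energy=\\s*([-0-9.eE+]+)", comment))[[1]]
      energies <- c(energies, if (length(e) == 2) as.numeric(e[2]) else 0)
      block <- lines[(i + 2L):(i + 1L + n)]
      parts <- strsplit(trimws(block), "\\s+")
      el <- vapply(parts, `[`, character(1), 1)
      xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
      if (is.null(elements)) elements <- el
      else if (length(el) != length(elements)) {
        stop("inconsistent atom count in record ", rec)
      }
      frames[[rec]] <- xyz
      if (is.null(compound_id)) {
        cid <- regmatches(comment, regexec("compound=(\\S+)", comment))[[1]]
        if (length(cid) == 2) compound_id <- cid[2]
      }
      i <- i + 2L + n
    }
    coords <- array(NA_real_, dim = c(nrow(frames[[1]]), 3L, rec))
    for (k in seq_len(rec)) coords[, , k] <- frames[[k]]
    return(conformer_ensemble(compound_id %||% NA, coords, energies, elements))
  }
  # SDF
  recs <- split(lines, cumsum(c(0, utils::head(lines, -1) == "$$$$")))
  recs <- Filter(function(r) any(nzchar(trimws(r))), recs)
  frames <- list(); energies <- numeric(0); elements <- NULL; bonds <- NULL
  for (rec in seq_along(recs)) {
    r <- recs[[rec]]
    if (length(r) < 5) stop("unparseable record ", rec)
    counts <- r[4]
    n <- suppressWarnings(as.integer(substr(counts, 1, 3)))
    nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
    if (is.na(n) || n < 1) stop("unparseable atom count in record ", rec)
    atom_lines <- r[5:(4 + n)]
    xyz <- t(vapply(atom_lines, function(l) {
      as.numeric(c(substr(l, 1, 10), substr(l, 11, 20), substr(l, 21, 30)))
    }, numeric(3)))
    el <- trimws(substr(atom_lines, 31, 34))
    if (is.null(elements)) {
      elements <- el
      if (!is.na(nb) && nb > 0) {
        bl <- r[(5 + n):(4 + n + nb)]
        bonds <- cbind(as.integer(substr(bl, 1, 3)),
                       as.integer(substr(bl, 4, 6)))
      }
    } else if (length(el) != length(elements)) {
      stop("inconsistent atom count in record ", rec)
    }
    e_idx <- grep("^>.*<ENERGY_KCAL>", r)
    energies <- c(energies,
                  if (length(e_idx)) as.numeric(r[e_idx[1] + 1L]) else 0)
    frames[[rec]] <- xyz
    if (is.null(compound_id)) {
      cid <- regmatches(r[1], regexec("^compound_(\\S+)", r[1]))[[1]]
      if (length(cid) == 2) compound_id <- cid[2]
    }
  }
  coords <- array(NA_real_, dim = c(nrow(frames[[1]]), 3L, length(frames)))
  for (k in seq_along(frames)) coords[, , k] <- frames[[k]]
  conformer_ensemble(compound_id %||% NA, coords, energies, elements,
                     bonds = bonds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
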