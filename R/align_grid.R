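#' Three-atom alignment specification
#'
#' Every conformation is rigidly superposed onto a reference conformation
#' by least-squares fitting an ordered triple of alignment atoms. The three
#' benchmark alignments use, on the raloxifene template: (1) the
#' benzothiophene C3, the carbonyl carbon, and the piperidine nitrogen;
#' (2) the benzothiophene C3, a 2-aryl ring carbon, and a basic-side-chain
#' carbon; (3) three non-pharmacophoric side-chain ether-region atoms. The
#' original atom numbers came from an unpublished program-internal
#' numbering, so the concrete indices here are a declared, re-mappable
#' assumption.
#'
#' @param name label, e.g. `"alignment1"`.
#' @param atom_indices ordered integer triple of atom indices.
#' @return an object of class `alignment_spec`.
#' @export
alignment_spec <- function(name, atom_indices) {
  atom_indices <- as.integer(atom_indices)
  if (length(atom_indices) != 3 || anyDuplicated(atom_indices)) {
    stop("alignment requires three distinct atom indices")
  }
  structure(list(name = name, atom_indices = atom_indices),
            class = "alignment_spec")
}

.collinear <- function(p) {
  v1 <- p[2, ] - p[1, ]
  v2 <- p[3, ] - p[1, ]
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  sqrt(sum(cr^2)) < 1e-8 * max(1, sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
}

#' Rigidly superpose a conformation onto a reference by three atoms
#'
#' Finds the proper rigid transform (rotation with determinant +1 plus
#' translation; reflections are forbidden) that minimizes the least-squares
#' distance of the conformation's three alignment atoms to the reference
#' triple (Kabsch), and applies it to all atoms.
#'
#' @param coords `natoms x 3` conformation to move.
#' @param reference `natoms_ref x 3` reference conformation.
#' @param alignment an [alignment_spec()]; indices must be valid in both.
#' @return the transformed `natoms x 3` coordinate matrix.
#' @export
superpose_three_point <- function(coords, reference, alignment) {
  idx <- alignment$atom_indices
  if (max(idx) > nrow(coords) || max(idx) > nrow(reference)) {
    stop("alignment atom index out of range")
  }
  mob <- coords[idx, , drop = FALSE]
  ref <- reference[idx, , drop = FALSE]
  if (.collinear(ref) || .collinear(mob)) {
    stop("degenerate alignment: the three alignment atoms are collinear")
  }
  cm <- colMeans(mob)
  cr <- colMeans(ref)
  H <- t(sweep(mob, 2, cm)) %*% sweep(ref, 2, cr)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(sweep(coords, 2, cm) %*% t(R), 2, -cr)
}

#' IPE class labels
#'
#' The seven interaction pharmacophore element classes used to partition
#' occupancy: `any` (all atoms), `np` (nonpolar), `p+` (polar positive),
#' `p-` (polar negative), `hba` (hydrogen-bond acceptor), `hbd`
#' (hydrogen-bond donor), `ar` (aromatic).
#' @export
IPE_CLASSES <- c("any", "np", "p+", "p-", "hba", "hbd", "ar")

# Rule-based partial charges used when none are supplied: crude but enough
# to drive the p+/p- classes without quantum charges.
.rule_charges <- function(elements, bonds, formal_charges) {
  q <- rep(0, length(elements))
  q[elements == "O"] <- -0.40
  q[elements == "N"] <- -0.30
  q[elements == "S"] <- -0.10
  q[formal_charges > 0] <- 0.50
  q[formal_charges < 0] <- -0.50
  if (!is.null(bonds) && nrow(bonds) > 0) {
    # hydrogens inherit a positive fraction from charged/electronegative hosts
    for (i in which(elements == "H")) {
      nb <- c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
      if (length(nb) && elements[nb[1]] %in% c("N", "O", "S")) {
        q[i] <- if (formal_charges[nb[1]] > 0) 0.30 else 0.20
      }
    }
  }
  q
}

# Aromatic perception: atoms lying on 5- or 6-membered cycles whose members
# are all C/N/O/S with total degree at most 3 (which excludes saturated
# ring atoms such as piperidine CH2/NH2+, provided hydrogens are explicit
# in the bond graph). Cycle detection via bounded DFS; adequate for the
# planar ring systems handled here.
.aromatic_atoms <- function(elements, bonds) {
  natoms <- length(elements)
  arom <- rep(FALSE, natoms)
  if (is.null(bonds) || nrow(bonds) == 0) return(arom)
  adj <- vector("list", natoms)
  for (i in seq_len(nrow(bonds))) {
    a <- bonds[i, 1]; b <- bonds[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  deg <- lengths(adj)
  ring_ok <- elements %in% c("C", "N", "O", "S") & deg <= 3
  # enumerate simple cycles of length 5 or 6 by bounded DFS from each atom
  for (start in which(ring_ok)) {
    stack <- list(start)
    paths <- list(c(start))
    while (length(paths)) {
      p <- paths[[1]]; paths <- paths[-1]
      last <- p[length(p)]
      for (w in adj[[last]]) {
        if (!ring_ok[w]) next
        if (w == start && length(p) >= 5) {
          arom[p] <- TRUE
        } else if (!(w %in% p) && length(p) < 6 && w > start) {
          paths <- c(paths, list(c(p, w)))
        }
      }
    }
  }
  arom
}

#' Assign IPE classes to the atoms of an ensemble
#'
#' Applies the typing table: every atom belongs to `any`; `np` is carbon
#' and hydrogen bonded to carbon; `p+` is formal charge > 0 or partial
#' charge >= +0.25 (covers a protonated amine nitrogen and its hydrogens);
#' `p-` is formal charge < 0 or partial charge <= -0.25 (covers phenolic
#' and carbonyl oxygens); `hba` is N/O/S (lone-pair bearer); `hbd` is a
#' hydrogen bonded to N/O/S together with that heteroatom; `ar` is atoms in
#' perceived 5- or 6-membered aromatic rings. Assignments depend only on
#' connectivity and charges, so they are identical across the ensemble's
#' conformations. If no partial charges are stored, rule-based charges are
#' derived from elements and connectivity.
#'
#' @param ensemble a [conformer_ensemble()] (or a list with `elements`,
#'   optional `bonds`, `charges`, `formal_charges`).
#' @return a logical matrix `natoms x 7` with columns [IPE_CLASSES].
#' @export
assign_ipe <- function(ensemble) {
  elements <- ensemble$elements
  known <- c("H", "C", "N", "O", "S", "F", "Cl", "Br", "I", "P")
  if (any(!elements %in% known)) {
    stop("unknown element(s): ",
         paste(unique(elements[!elements %in% known]), collapse = ", "))
  }
  natoms <- length(elements)
  bonds <- ensemble$bonds
  formal <- ensemble$formal_charges %||% rep(0, natoms)
  charges <- ensemble$charges %||% .rule_charges(elements, bonds, formal)

  hetero_host <- rep(NA_character_, natoms)
  if (!is.null(bonds) && nrow(bonds) > 0) {
    for (i in which(elements == "H")) {
      nb <- c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
      if (length(nb)) hetero_host[i] <- elements[nb[1]]
    }
  }
  h_on_c <- elements == "H" & !is.na(hetero_host) & hetero_host == "C"
  h_on_het <- elements == "H" & !is.na(hetero_host) &
    hetero_host %in% c("N", "O", "S")
  het_with_h <- rep(FALSE, natoms)
  if (!is.null(bonds) && nrow(bonds) > 0) {
    for (i in which(h_on_het)) {
      nb <- c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
      het_with_h[nb[1]] <- TRUE
    }
  }

  m <- matrix(FALSE, natoms, length(IPE_CLASSES),
              dimnames = list(NULL, IPE_CLASSES))
  m[, "any"] <- TRUE
  m[, "np"] <- elements == "C" | h_on_c
  m[, "p+"] <- formal > 0 | charges >= 0.25
  m[, "p-"] <- formal < 0 | charges <= -0.25
  # a positively charged heteroatom (e.g. protonated amine N) has no
  # available lone pair and is not an acceptor
  m[, "hba"] <- elements %in% c("N", "O", "S") & formal <= 0
  m[, "hbd"] <- h_on_het | het_with_h
  m[, "ar"] <- .aromatic_atoms(elements, bonds)
  m
}

#' Cubic grid specification
#'
#' Cells are half-open axis-aligned cubes: an atom at position `p` falls in
#' cell `floor((p - origin) / cell_size)` per axis. By default the lattice
#' is registered so cells are centered on integer multiples of the cell
#' size (origin at `-cell_size/2` per axis): cell `(x,y,z)` then has its
#' center at Cartesian `(x,y,z) * cell_size`, matching how the published
#' descriptor indices are read as Cartesian coordinates, and it keeps the
#' alignment atoms - which always lie in the reference triple's plane -
#' away from cell boundaries. The benchmark explored cell sizes of 2.0 and
#' 1.0 angstroms.
#'
#' @param cell_size cell edge length in angstroms (> 0).
#' @param origin 3-vector, lattice origin in the reference frame; `NULL`
#'   (default) centers cells on the integer lattice.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(cell_size = 1.0, origin = NULL) {
  stopifnot(cell_size > 0)
  if (is.null(origin)) origin <- rep(-cell_size / 2, 3)
  stopifnot(length(origin) == 3)
  structure(list(cell_size = cell_size, origin = as.numeric(origin)),
            class = "grid_spec")
}

#' Map coordinates to grid cell indices
#' @param coords `n x 3` coordinate matrix.
#' @param grid a [grid_spec()].
#' @return `n x 3` integer matrix of cell indices.
#' @export
cell_index <- function(coords, grid) {
  idx <- floor(sweep(coords, 2, grid$origin) / grid$cell_size)
  storage.mode(idx) <- "integer"
  idx
}

#' Distance between grid cell centers
#'
#' The lattice is cubic, so the center-to-center distance between cells is
#' the cell size times the Euclidean norm of the index difference.
#'
#' @param a,b integer cell index triples.
#' @param cell_size cell edge length in angstroms.
#' @return distance in angstroms.
#' @examples
#' cell_center_distance(c(1, 13, 1), c(-1, 8, 2), 1.0)  # 5.48
#' @export
cell_center_distance <- function(a, b, cell_size = 1.0) {
  stopifnot(length(a) == 3, length(b) == 3, cell_size > 0)
  cell_size * sqrt(sum((as.numeric(a) - as.numeric(b))^2))
}

#' GCOD key string
#'
#' Descriptor columns are keyed `"(x,y,z)|ipe"`; this builds the key from a
#' cell triple and an IPE class.
#' @param cell integer triple.
#' @param ipe one of [IPE_CLASSES].
#' @return character key.
#' @export
gcod_key <- function(cell, ipe) {
  sprintf("(%d,%d,%d)|%s", cell[1], cell[2], cell[3], ipe)
}

#' Parse GCOD keys back into cells and classes
#' @param keys character vector of `"(x,y,z)|ipe"` keys.
#' @return data.frame with columns `x`, `y`, `z`, `ipe`.
#' @export
parse_gcod_key <- function(keys) {
  m <- regmatches(keys, regexec("^\\((-?\\d+),(-?\\d+),(-?\\d+)\\)\\|(.+)$",
                                keys))
  bad <- lengths(m) != 5
  if (any(bad)) stop("unparseable GCOD key: ", keys[bad][1])
  data.frame(x = as.integer(vapply(m, `[`, "", 2)),
             y = as.integer(vapply(m, `[`, "", 3)),
             z = as.integer(vapply(m, `[`, "", 4)),
             ipe = vapply(m, `[`, "", 5),
             stringsAsFactors = FALSE)
}

# Occupancy counts for one ensemble: named vector of raw counts per
# "(x,y,z)|ipe" key, over the given conformer indices.
.count_occupancy <- function(ensemble, reference, alignment, grid, typing,
                             conformers = seq_len(n_conformations(ensemble)),
                             align = TRUE) {
  classes <- IPE_CLASSES[colSums(typing) > 0]
  chunks <- vector("list", length(conformers))
  for (j in seq_along(conformers)) {
    conf <- matrix(ensemble$coords[, , conformers[j]], ncol = 3)
    if (align) conf <- superpose_three_point(conf, reference, alignment)
    idx <- cell_index(conf, grid)
    keys <- lapply(classes, function(ipe) {
      atoms <- typing[, ipe]
      sprintf("(%d,%d,%d)|%s", idx[atoms, 1], idx[atoms, 2], idx[atoms, 3],
              ipe)
    })
    chunks[[j]] <- unlist(keys, use.names = FALSE)
  }
  tab <- table(unlist(chunks, use.names = FALSE))
  stats::setNames(as.numeric(tab), names(tab))
}

#' Compute the grid cell occupancy descriptor matrix
#'
#' For each compound's conformer ensemble, every conformation is rigidly
#' aligned to the reference by the three alignment atoms, atoms are binned
#' into lattice cells, and occupations are counted per (cell, IPE class)
#' and normalized by the ensemble size (the CEP size). Several atoms of one
#' class in the same cell in one conformation each count, so normalized
#' occupancy can exceed 1.
#'
#' @param ensembles list of [conformer_ensemble()] objects.
#' @param reference `natoms x 3` reference conformation (template compound).
#' @param alignment an [alignment_spec()].
#' @param grid a [grid_spec()].
#' @param typing optional list of per-ensemble typing matrices from
#'   [assign_ipe()]; computed per ensemble when `NULL`.
#' @param align set `FALSE` if the ensembles are already in the reference
#'   frame.
#' @return an `occupancy_matrix`: numeric matrix, rows = compounds,
#'   columns = GCOD keys, with attributes `cep_sizes`, `grid`, `alignment`.
#' @export
compute_gcods <- function(ensembles, reference, alignment, grid,
                          typing = NULL, align = TRUE) {
  if (!length(ensembles)) stop("no ensembles supplied")
  per <- vector("list", length(ensembles))
  ids <- character(length(ensembles))
  cep <- integer(length(ensembles))
  for (i in seq_along(ensembles)) {
    ens <- ensembles[[i]]
    if (n_conformations(ens) < 1) stop("empty ensemble at position ", i)
    ty <- if (is.null(typing)) assign_ipe(ens) else typing[[i]]
    cnt <- .count_occupancy(ens, reference, alignment, grid, ty,
                            align = align)
    per[[i]] <- cnt / n_conformations(ens)
    ids[i] <- as.character(ens$compound_id)
    cep[i] <- n_conformations(ens)
  }
  all_keys <- sort(unique(unlist(lapply(per, names))))
  M <- matrix(0, nrow = length(ensembles), ncol = length(all_keys),
              dimnames = list(ids, all_keys))
  for (i in seq_along(per)) M[i, names(per[[i]])] <- per[[i]]
  structure(M, cep_sizes = cep, grid = grid,
            alignment = if (inherits(alignment, "alignment_spec"))
              alignment$name else NA,
            class = c("occupancy_matrix", class(M)))
}

#' Per-conformer occupancy vectors
#'
#' Computes the occupancy vector of each single conformation (CEP size 1),
#' as needed by the bioactive-conformation rule. Averaging these rows
#' reproduces the ensemble occupancy exactly.
#'
#' @inheritParams compute_gcods
#' @param ensemble one [conformer_ensemble()].
#' @return numeric matrix, rows = conformers, columns = GCOD keys.
#' @export
per_conformer_occupancy <- function(ensemble, reference, alignment, grid,
                                    typing = NULL, align = TRUE) {
  ty <- if (is.null(typing)) assign_ipe(ensemble) else typing
  rows <- lapply(seq_len(n_conformations(ensemble)), function(k) {
    .count_occupancy(ensemble, reference, alignment, grid, ty,
                     conformers = k, align = align)
  })
  all_keys <- sort(unique(unlist(lapply(rows, names))))
  M <- matrix(0, nrow = length(rows), ncol = length(all_keys),
              dimnames = list(NULL, all_keys))
  for (k in seq_along(rows)) M[k, names(rows[[k]])] <- rows[[k]]
  M
}
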