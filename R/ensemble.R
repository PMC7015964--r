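#' Construct a structural ensemble
#'
#' An ensemble is an ordered set of conformers sharing one atom roster, with
#' equilibrium populations and (optionally) annotations of magnetically
#' equivalent rotation groups (methyls, aromatic rings) and a partition of
#' the members into named kinetic groups.
#'
#' @param atoms data.frame with columns `atom_id`, `resno`, `resname`,
#'   `atom_name`; one row per atom of the shared roster.
#' @param coords numeric array of dimension `c(n_atoms, 3, n_members)`, in
#'   Angstrom.
#' @param populations equilibrium member populations; default uniform.
#' @param rotation_groups list of rotation groups as returned by
#'   [detect_rotation_groups()], or `NULL` to auto-detect lazily.
#' @param group_labels optional character/factor of length `n_members`
#'   assigning each conformer to a named kinetic group (e.g. open/closed).
#' @return an object of class `ke_ensemble`.
#' @export
ke_ensemble <- function(atoms, coords, populations = NULL,
                        rotation_groups = NULL, group_labels = NULL) {
  atoms <- as.data.frame(atoms)
  needed <- c("atom_id", "resno", "resname", "atom_name")
  if (!all(needed %in% names(atoms))) {
    stopf("atoms must have columns: %s", paste(needed, collapse = ", "))
  }
  if (anyDuplicated(atoms$atom_id)) {
    stopf("atom_ids must be unique within a conformer")
  }
  if (length(dim(coords)) == 2L) dim(coords) <- c(dim(coords), 1L)
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L,
            dim(coords)[1] == nrow(atoms))
  if (!all(is.finite(coords))) stopf("coordinates must be finite")
  n <- dim(coords)[3]
  if (is.null(populations)) populations <- rep(1 / n, n)
  stopifnot(length(populations) == n, all(populations >= 0))
  if (abs(sum(populations) - 1) > 1e-8) {
    stopf("populations must sum to 1")
  }
  populations <- populations / sum(populations)
  if (!is.null(group_labels)) {
    stopifnot(length(group_labels) == n)
    group_labels <- as.character(group_labels)
  }
  structure(
    list(atoms = atoms, coords = coords, populations = populations,
         rotation_groups = rotation_groups, group_labels = group_labels),
    class = "ke_ensemble"
  )
}

#' @export
print.ke_ensemble <- function(x, ...) {
  cat(sprintf("<ke_ensemble> %d members, %d atoms (%d protons)\n",
              n_members(x), nrow(x$atoms),
              length(proton_indices(x))))
  if (!is.null(x$rotation_groups)) {
    cat(sprintf("  rotation groups: %d\n", length(x$rotation_groups)))
  }
  if (!is.null(x$group_labels)) {
    tb <- table(x$group_labels)
    cat(sprintf("  kinetic groups: %s\n",
                paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
  }
  invisible(x)
}

#' Number of ensemble members
#' @param ensemble a `ke_ensemble`.
#' @export
n_members <- function(ensemble) dim(ensemble$coords)[3]

# Indices of hydrogen atoms (PDB v3 naming: atom name starts with H).
proton_indices <- function(ensemble) {
  which(grepl("^H", ensemble$atoms$atom_name))
}

atom_index <- function(ensemble, resno, atom_name) {
  i <- which(ensemble$atoms$resno == resno &
               ensemble$atoms$atom_name == atom_name)
  if (length(i) != 1L) {
    stopf("atom %s in residue %s not found (or ambiguous); missing hydrogens?",
          atom_name, resno)
  }
  i
}

#' Internuclear geometry of a proton pair across the ensemble
#'
#' Returns, for each ensemble member, the vector connecting atoms `i` and
#' `j` and its length.
#'
#' @param ensemble a `ke_ensemble`.
#' @param i,j atom indices into `ensemble$atoms`.
#' @return a `ke_geometry`: list with `vectors` (members x 3, Angstrom),
#'   `r` (distances), `populations`.
#' @export
pair_geometry <- function(ensemble, i, j) {
  v <- t(ensemble$coords[j, , ] - ensemble$coords[i, , ])
  ke_geometry(v, ensemble$populations)
}

#' Spin-pair geometry object
#'
#' @param vectors matrix (states x 3) of internuclear vectors in Angstrom.
#' @param populations state populations; default uniform.
#' @export
ke_geometry <- function(vectors, populations = NULL) {
  vectors <- rbind(vectors)
  r <- sqrt(rowSums(vectors^2))
  if (any(r <= 0)) stopf("zero-length internuclear vector")
  n <- nrow(vectors)
  if (is.null(populations)) populations <- rep(1 / n, n)
  stopifnot(length(populations) == n)
  structure(list(vectors = vectors, r = r,
                 populations = populations / sum(populations)),
            class = "ke_geometry")
}

# ---------------------------------------------------------------------------
# PDB input/output.  bio3d does the record-level parsing/formatting; here we
# only split MODEL blocks (so rosters can be compared across models) and
# expand alternate-location sets into separate conformers.

#' Read a (multi-model, altloc-aware) PDB file as an ensemble
#'
#' Each MODEL becomes one conformer.  Where alternate conformations are
#' present, each altloc label is expanded into a full conformer carrying all
#' non-altloc atoms plus that altloc set, with populations taken from the
#' altloc occupancies.  Structures must already carry hydrogens.
#'
#' @param path PDB file.
#' @param model_selection `"all"` or an integer vector of model numbers.
#' @return a `ke_ensemble`.
#' @export
read_pdb_ensemble <- function(path, model_selection = "all") {
  if (!file.exists(path)) stopf("PDB file not found: %s", path)
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  blocks <- if (length(starts) == 0L) {
    list(lines)
  } else {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(starts)) {
      stopf("unbalanced MODEL/ENDMDL records in %s", path)
    }
    mapply(function(s, e) lines[seq(s + 1L, e - 1L)], starts, ends,
           SIMPLIFY = FALSE)
  }
  if (!identical(model_selection, "all")) {
    blocks <- blocks[as.integer(model_selection)]
  }
  models <- lapply(blocks, function(b) {
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf), add = TRUE)
    writeLines(c(b, "END"), tf)
    bio3d::read.pdb(tf, rm.alt = FALSE, verbose = FALSE)
  })

  # expand altlocs within each model
  conf <- list()
  weights <- numeric()
  for (m in models) {
    at <- m$atom[m$atom$type %in% c("ATOM", "HETATM"), ]
    alt <- at$alt
    alt[is.na(alt)] <- ""
    labels <- sort(unique(alt[alt != ""]))
    if (length(labels) == 0L) {
      conf[[length(conf) + 1L]] <- at
      weights <- c(weights, 1)
    } else {
      for (lb in labels) {
        sel <- alt == "" | alt == lb
        conf[[length(conf) + 1L]] <- at[sel, ]
        occ <- at$o[alt == lb]
        weights <- c(weights, mean(occ[is.finite(occ)]) %||% 1)
      }
    }
  }
  rosters <- lapply(conf, function(a) {
    paste(a$resno, a$resid, a$elety, sep = "|")
  })
  for (k in seq_along(rosters)[-1]) {
    if (!identical(rosters[[k]], rosters[[1]])) {
      d <- union(setdiff(rosters[[k]], rosters[[1]]),
                 setdiff(rosters[[1]], rosters[[k]]))
      stopf("inconsistent atom rosters across conformers (conformer %d differs: %s)",
            k, paste(d, collapse = ", "))
    }
  }
  a1 <- conf[[1]]
  atoms <- data.frame(
    atom_id = paste(a1$resno, a1$elety, sep = "."),
    resno = a1$resno, resname = a1$resid, atom_name = a1$elety,
    stringsAsFactors = FALSE
  )
  coords <- array(0, c(nrow(atoms), 3, length(conf)))
  for (k in seq_along(conf)) {
    coords[, , k] <- as.matrix(conf[[k]][, c("x", "y", "z")])
  }
  if (!any(is.finite(weights)) || sum(weights) == 0) weights <- rep(1, length(conf))
  ens <- ke_ensemble(atoms, coords, populations = weights / sum(weights))
  ens$rotation_groups <- detect_rotation_groups(ens)
  ens
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ensemble a `ke_ensemble`.
#' @param path output file.
#' @export
write_pdb_ensemble <- function(ensemble, path) {
  n <- n_members(ensemble)
  at <- ensemble$atoms
  out <- character()
  for (k in seq_len(n)) {
    tf <- tempfile(fileext = ".pdb")
    bio3d::write.pdb(
      file = tf,
      xyz = as.vector(t(ensemble$coords[, , k])),
      resno = at$resno, resid = at$resname,
      eleno = seq_len(nrow(at)), elety = at$atom_name,
      o = rep(1, nrow(at))
    )
    rec <- grep("^ATOM|^HETATM|^TER", readLines(tf), value = TRUE)
    unlink(tf)
    out <- c(out, sprintf("MODEL     %4d", k), rec, "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Rotation groups

methyl_carbons <- list(
  ALA = "CB", VAL = c("CG1", "CG2"), LEU = c("CD1", "CD2"),
  ILE = c("CG2", "CD1"), THR = "CG2", MET = "CE"
)

#' Detect magnetically equivalent rotation groups
#'
#' Finds the three-fold methyl groups (ALA CB; VAL CG1/CG2; LEU CD1/CD2;
#' ILE CG2/CD1; THR CG2; MET CE) and the two-fold PHE/TYR ring flips
#' (HD1/HD2 with HE1/HE2 exchanged jointly) from standard amino-acid atom
#' naming.  Residues with nonstandard names are skipped with a warning.
#'
#' @param ensemble a `ke_ensemble`.
#' @return list of rotation groups: each a list with `kind`
#'   (`"methyl"`/`"aromatic"`), `order` (3 or 2), `resno`, `stem` (the
#'   heavy-atom or pseudoatom stem, e.g. `"CG2"`), `atom_idx` (indices of the
#'   exchanging hydrogens) and `perm` (one cyclic rotation step as a
#'   permutation of `atom_idx`).
#' @export
detect_rotation_groups <- function(ensemble) {
  at <- ensemble$atoms
  groups <- list()
  standard <- c(names(aa_three_to_one), "SYN", "HOH")
  for (rn in unique(at$resno)) {
    rows <- at$resno == rn
    resname <- toupper(at$resname[rows][1])
    if (!resname %in% standard) {
      warning(sprintf("residue %s %s: nonstandard name, rotation groups skipped",
                      resname, rn), call. = FALSE)
      next
    }
    # methyls
    for (cb in methyl_carbons[[resname]] %||% character()) {
      hn <- paste0(sub("^C", "H", cb), 1:3)
      idx <- match(hn, ifelse(rows, at$atom_name, NA))
      if (!anyNA(idx)) {
        groups[[length(groups) + 1L]] <- list(
          kind = "methyl", order = 3L, resno = rn, stem = cb,
          atom_idx = idx, perm = c(2L, 3L, 1L)
        )
      }
    }
    # aromatic ring flips
    if (resname %in% c("PHE", "TYR")) {
      hn <- c("HD1", "HD2", "HE1", "HE2")
      idx <- match(hn, ifelse(rows, at$atom_name, NA))
      if (!anyNA(idx)) {
        groups[[length(groups) + 1L]] <- list(
          kind = "aromatic", order = 2L, resno = rn, stem = "ring",
          atom_idx = idx, perm = c(2L, 1L, 4L, 3L)
        )
      }
    }
  }
  groups
}

# Rotation group containing atom index i, or NA.
rotation_group_of <- function(ensemble, i) {
  gs <- ensemble$rotation_groups
  if (is.null(gs)) return(NA_integer_)
  for (k in seq_along(gs)) if (i %in% gs[[k]]$atom_idx) return(k)
  NA_integer_
}

# Index of atom i after applying r rotation steps of its group.
rotated_atom <- function(group, i, r) {
  pos <- match(i, group$atom_idx)
  perm <- seq_along(group$atom_idx)
  r <- r %% group$order
  if (r > 0) for (s in seq_len(r)) perm <- group$perm[perm]
  group$atom_idx[perm[pos]]
}

#' Restrict an ensemble to a subset of members
#'
#' @param ensemble a `ke_ensemble`.
#' @param members logical mask or integer indices.
#' @param populations populations of the subset; default uniform.
#' @export
subset_ensemble <- function(ensemble, members, populations = NULL) {
  if (is.logical(members)) members <- which(members)
  stopifnot(length(members) >= 1)
  ke_ensemble(ensemble$atoms,
              ensemble$coords[, , members, drop = FALSE],
              populations = populations,
              rotation_groups = ensemble$rotation_groups,
              group_labels = ensemble$group_labels[members])
}
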