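#' Load the packaged ideal geometry table
#'
#' A compact Engh-Huber-style restraint subset: backbone and C-beta bond
#' lengths and angles shared by the standard amino acids (rows with
#' `resname = "*"`), the peptide C-N link (atom names suffixed `+` refer to
#' the next residue in sequence), and per-element van der Waals radii.
#' Atoms not covered by the templates are skipped by the geometry metrics,
#' never guessed.
#'
#' @param bonds,angles,vdw Optional paths to replacement TSVs with the same
#'   columns as the packaged files.
#' @return List with tibbles `bonds` (`resname`, `atom1`, `atom2`,
#'   `length`), `angles` (`resname`, `atom1..3`, `angle`) and a named
#'   numeric vector `vdw` of radii.
#' @export
ideal_geometry_table <- function(bonds = NULL, angles = NULL, vdw = NULL) {
  pkg_file <- function(f) system.file("extdata", f, package = "trxscore",
                                      mustWork = TRUE)
  rd <- function(p) as_tibble(read.delim(p, sep = "\t",
                                         stringsAsFactors = FALSE))
  b <- rd(bonds %||% pkg_file("ideal_bonds.tsv"))
  a <- rd(angles %||% pkg_file("ideal_angles.tsv"))
  v <- rd(vdw %||% pkg_file("vdw_radii.tsv"))
  stopifnot(all(b$length > 0.5 & b$length < 3.0),
            all(a$angle > 0 & a$angle < 180),
            all(v$radius > 1.0 & v$radius < 2.5))
  list(bonds = b, angles = a, vdw = setNames(v$radius, v$element))
}

# residue table in model order with a chain-local sequence index used to
# resolve "+" template atoms (next residue = resno + 1, same chain, no gap)
residue_index <- function(atoms) {
  res <- distinct(atoms[, c("chain", "resno", "ins", "resname")])
  res$rid <- seq_len(nrow(res))
  res
}

# plain-vector lookup context: atom rows hashed by (chain, resno, ins, atom)
geometry_context <- function(atoms, res) {
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$atom, sep = "\r")
  list(altloc = atoms$altloc,
       index = split(seq_along(key), key),
       res_chain = res$chain, res_resno = res$resno, res_ins = res$ins)
}

# resolve a template atom name within (residue rid or its successor),
# returning matching atom-row indices (one per altloc)
template_atom_rows <- function(ctx, rid, name) {
  plus <- endsWith(name, "+")
  if (plus) name <- substr(name, 1, nchar(name) - 1)
  resno <- ctx$res_resno[rid] + plus
  ins <- if (plus) "" else ctx$res_ins[rid]
  ctx$index[[paste(ctx$res_chain[rid], resno, ins, name, sep = "\r")]] %||%
    integer(0)
}

altloc_compatible <- function(a, b) a == "" | b == "" | a == b

# enumerate measured (observed, ideal) values for one template row across
# conformers; returns rows of atom indices (one set per altloc variant)
match_template <- function(ctx, rid, names) {
  idx <- lapply(names, function(nm) template_atom_rows(ctx, rid, nm))
  len <- lengths(idx)
  if (any(len == 0)) return(NULL)
  if (all(len == 1)) {
    rows <- unlist(idx)
    al <- ctx$altloc[rows]
    if (length(unique(al[al != ""])) > 1) return(NULL)
    return(matrix(rows, 1))
  }
  combos <- as.matrix(expand.grid(idx, KEEP.OUT.ATTRS = FALSE))
  alt <- matrix(ctx$altloc[combos], nrow(combos))
  ok <- apply(alt, 1, function(al) length(unique(al[al != ""])) <= 1)
  combos <- combos[ok, , drop = FALSE]
  if (nrow(combos) == 0) return(NULL)
  # one measurement per conformer variant: blank-only counts once
  variant <- apply(matrix(ctx$altloc[combos], nrow(combos)), 1,
                   function(al) paste(sort(unique(al[al != ""])), collapse = ""))
  combos[!duplicated(variant), , drop = FALSE]
}

vdist <- function(p, q) sqrt(sum((p - q)^2))

vangle <- function(p, q, r) {
  u <- p - q; v <- r - q
  acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

#' Bond-length and bond-angle RMS deviations from ideal values
#'
#' RMS of (observed - ideal) over every bond and angle matched against the
#' restraint templates; template terms whose atoms are absent are skipped
#' and counted. Alternative conformers are measured once per conformer.
#'
#' @param model A [struct_model()].
#' @param table An [ideal_geometry_table()].
#' @param residues Optional residue selection; restricts the terms to those
#'   anchored at the given residues (a term is anchored at the residue
#'   owning its first template atom). Useful for combining partial RMS
#'   values via their counts.
#' @return List with `rms_bond` (angstrom), `rms_angle` (degrees),
#'   `n_bonds`, `n_angles` matched. Zero matched bonds give `NA` values.
#' @export
bond_angle_rms <- function(model, table = ideal_geometry_table(),
                           residues = NULL) {
  atoms <- as_tibble(model)
  res <- residue_index(atoms)
  rids <- res$rid
  if (!is.null(residues)) {
    sel <- as_tibble(residues)
    if (!"ins" %in% names(sel)) sel$ins <- ""
    rids <- res$rid[paste(res$chain, res$resno, res$ins) %in%
                      paste(sel$chain, sel$resno, sel$ins)]
  }
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  ctx <- geometry_context(atoms, res)
  dev_b <- numeric(0); dev_a <- numeric(0)
  for (rid in rids) {
    rnm <- res$resname[rid]
    brow <- table$bonds[table$bonds$resname %in% c("*", rnm), ]
    for (k in seq_len(nrow(brow))) {
      m <- match_template(ctx, rid, c(brow$atom1[k], brow$atom2[k]))
      if (is.null(m)) next
      for (i in seq_len(nrow(m))) {
        dev_b <- c(dev_b, vdist(pos[m[i, 1], ], pos[m[i, 2], ]) - brow$length[k])
      }
    }
    arow <- table$angles[table$angles$resname %in% c("*", rnm), ]
    for (k in seq_len(nrow(arow))) {
      m <- match_template(ctx, rid,
                          c(arow$atom1[k], arow$atom2[k], arow$atom3[k]))
      if (is.null(m)) next
      for (i in seq_len(nrow(m))) {
        dev_a <- c(dev_a, vangle(pos[m[i, 1], ], pos[m[i, 2], ],
                                 pos[m[i, 3], ]) - arow$angle[k])
      }
    }
  }
  list(rms_bond = if (length(dev_b)) sqrt(mean(dev_b^2)) else NA_real_,
       rms_angle = if (length(dev_a)) sqrt(mean(dev_a^2)) else NA_real_,
       n_bonds = length(dev_b), n_angles = length(dev_a))
}

#' Bond graph used by the clash detector
#'
#' Builds the restraint-template bond graph over a model's heavy-atom rows
#' (or all rows with `include_hydrogens`). The graph depends only on the
#' model's topology, so it can be computed once and passed to
#' [clashscore()] for every model sharing that topology.
#'
#' @param model A [struct_model()].
#' @param table An [ideal_geometry_table()].
#' @param include_hydrogens Must match the [clashscore()] call.
#' @return An igraph object with one vertex per atom row.
#' @export
clash_bond_graph <- function(model, table = ideal_geometry_table(),
                             include_hydrogens = FALSE) {
  atoms <- as_tibble(model)
  if (!include_hydrogens) atoms <- atoms[atoms$element != "H", ]
  bond_graph(atoms, residue_index(atoms), table)
}

# bond graph over atom rows: template bonds within/between residues,
# edges only between altloc-compatible atoms
bond_graph <- function(atoms, res, table) {
  edges <- integer(0)
  ctx <- geometry_context(atoms, res)
  for (rid in res$rid) {
    rnm <- res$resname[rid]
    brow <- table$bonds[table$bonds$resname %in% c("*", rnm), ]
    for (k in seq_len(nrow(brow))) {
      i1 <- template_atom_rows(ctx, rid, brow$atom1[k])
      i2 <- template_atom_rows(ctx, rid, brow$atom2[k])
      for (i in i1) for (j in i2) {
        if (altloc_compatible(atoms$altloc[i], atoms$altloc[j])) {
          edges <- c(edges, i, j)
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n = nrow(atoms), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  g
}

#' MolProbity-style clashscore (heavy atoms by default)
#'
#' A clash is an unbonded atom pair whose van der Waals overlap
#' `r1 + r2 - d` meets the cutoff (0.4 A by default). Pairs within the
#' same or sequence-adjacent residues are exempt unless separated by at
#' least 4 bonds in the restraint-template bond graph; pairs whose altlocs
#' are both non-blank and different are mutually exclusive conformers and
#' never clash. The score is clashes per 1000 atoms (atom records counted
#' once per altloc).
#'
#' @param model A [struct_model()].
#' @param table An [ideal_geometry_table()] (supplies vdW radii and
#'   topology).
#' @param overlap_cutoff Minimum overlap in angstrom, default 0.4.
#' @param include_hydrogens Include H atoms, default FALSE.
#' @param graph Optional precomputed bond graph over the (hydrogen-filtered)
#'   atom rows, as built by [clash_bond_graph()]; reuse it across models
#'   that share a topology.
#' @return List with `clashscore`, `n_atoms`, `n_clashes` and `clashes`, a
#'   duplicate-free tibble (`atom1`, `atom2`, `distance`, `overlap`).
#' @export
clashscore <- function(model, table = ideal_geometry_table(),
                       overlap_cutoff = 0.4, include_hydrogens = FALSE,
                       graph = NULL) {
  atoms <- as_tibble(model)
  if (!include_hydrogens) atoms <- atoms[atoms$element != "H", ]
  n <- nrow(atoms)
  empty <- tibble(atom1 = character(0), atom2 = character(0),
                  distance = numeric(0), overlap = numeric(0))
  if (n < 2) {
    return(list(clashscore = 0, n_atoms = n, n_clashes = 0L, clashes = empty))
  }
  res <- residue_index(atoms)
  radius <- table$vdw[atoms$element]
  if (anyNA(radius)) {
    abort(paste0("no vdW radius for element(s): ",
                 paste(unique(atoms$element[is.na(radius)]), collapse = ", ")))
  }
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  dmat <- as.matrix(stats::dist(pos))
  rsum <- outer(radius, radius, "+")
  cand <- which(upper.tri(dmat) & dmat <= rsum - overlap_cutoff,
                arr.ind = TRUE)
  lab <- sprintf("%s:%d%s %s %s%s", atoms$chain, atoms$resno, atoms$ins,
                 atoms$resname, atoms$atom,
                 ifelse(atoms$altloc == "", "", paste0("(", atoms$altloc, ")")))
  i <- cand[, 1]; j <- cand[, 2]
  ai <- atoms$altloc[i]; aj <- atoms$altloc[j]
  keep <- !(ai != "" & aj != "" & ai != aj)  # exclusive conformers never clash
  near_seq <- atoms$chain[i] == atoms$chain[j] &
    abs(atoms$resno[i] - atoms$resno[j]) <= 1
  need <- keep & near_seq
  if (any(need)) {
    g <- graph %||% bond_graph(atoms, res, table)
    in_graph <- igraph::degree(g) > 0
    vi <- sort(unique(c(i[need], j[need])))
    pd <- igraph::distances(g, v = vi, to = vi)
    path <- pd[cbind(match(i, vi), match(j, vi))]
    # intra/adjacent-residue pairs clash only when separated by >= 4 bonds;
    # atoms unknown to the templates (or disconnected) are skipped
    keep[need] <- in_graph[i[need]] & in_graph[j[need]] &
      is.finite(path[need]) & path[need] >= 4
  }
  hits <- cand[keep, , drop = FALSE]
  clashes <- tibble(atom1 = lab[hits[, 1]], atom2 = lab[hits[, 2]],
                    distance = dmat[hits],
                    overlap = rsum[hits] - dmat[hits])
  list(clashscore = 1000 * nrow(clashes) / n, n_atoms = n,
       n_clashes = nrow(clashes), clashes = clashes)
}

#' RMSD between the two conformers of a merged model
#'
#' Coordinate RMSD over same-named atom pairs (conformer B vs A) across the
#' selected residues, with no re-superposition; used to penalise candidate
#' conformers that stray far from the reference state.
#'
#' @param model A merged two-state [struct_model()].
#' @param selection Residues carrying both conformers.
#' @param labels Altloc labels `c(A, B)`.
#' @return RMSD in angstrom.
#' @export
conformer_rmsd <- function(model, selection, labels = c("A", "B")) {
  selection <- check_selection(model, selection)
  a <- as_tibble(model)
  key <- paste(a$chain, a$resno, a$ins, sep = "\r")
  skey <- paste(selection$chain, selection$resno, selection$ins, sep = "\r")
  a <- a[key %in% skey, ]
  A <- a[a$altloc == labels[1], ]
  B <- a[a$altloc == labels[2], ]
  ak <- paste(A$chain, A$resno, A$ins, A$atom, sep = "\r")
  bk <- paste(B$chain, B$resno, B$ins, B$atom, sep = "\r")
  m <- match(bk, ak)
  if (anyNA(m) || nrow(B) == 0) {
    miss <- B[is.na(m), ]
    abort(paste0("unpaired conformer atoms: ",
                 if (nrow(B) == 0) "no B-conformer atoms in selection" else
                   paste(sprintf("%s:%d%s %s", miss$chain, miss$resno,
                                 miss$ins, miss$atom), collapse = ", ")))
  }
  d2 <- (B$x - A$x[m])^2 + (B$y - A$y[m])^2 + (B$z - A$z[m])^2
  sqrt(mean(d2))
}

#' All native geometry metrics for a model
#'
#' @param model A merged two-state [struct_model()].
#' @param selection Residues carrying both conformers (for `rmsd_ab`);
#'   NULL skips that term.
#' @param table An [ideal_geometry_table()].
#' @param ... Passed to [clashscore()].
#' @return One-row tibble: `clashscore`, `rms_bond`, `rms_angle`, `rmsd_ab`.
#' @export
geometry_metrics <- function(model, selection = NULL,
                             table = ideal_geometry_table(), ...) {
  cs <- clashscore(model, table, ...)
  ba <- bond_angle_rms(model, table)
  tibble(clashscore = cs$clashscore, rms_bond = ba$rms_bond,
         rms_angle = ba$rms_angle,
         rmsd_ab = if (is.null(selection)) NA_real_ else
           conformer_rmsd(model, selection))
}
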