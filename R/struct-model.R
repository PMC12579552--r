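#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join bind_rows n row_number distinct across
#'   rename count pull if_else
#' @importFrom purrr map map_dbl map_chr map_lgl pmap imap
#' @importFrom stats sd median mad rnorm runif setNames cor
#' @importFrom utils head read.delim write.table
NULL

# electron counts for the elements that occur in protein models
.element_z <- c(
  H = 1, C = 6, N = 7, O = 8, P = 15, S = 16, SE = 34, F = 9, CL = 17,
  BR = 35, I = 53, FE = 26, ZN = 30, MG = 12, NA. = 11, K = 19, CA = 20
)

#' Number of electrons for an element symbol
#'
#' @param element Character vector of element symbols (e.g. `"C"`, `"N"`).
#' @return Numeric vector of electron counts.
#' @export
electron_count <- function(element) {
  z <- .element_z[toupper(ifelse(element == "NA", "NA.", element))]
  if (anyNA(z)) {
    abort(paste0("unknown element(s): ",
                 paste(unique(element[is.na(z)]), collapse = ", ")))
  }
  unname(z)
}

#' Construct a structure model
#'
#' A structure model is a tibble with one row per atom record and the
#' columns `chain`, `resno`, `ins`, `resname`, `atom`, `altloc`, `element`,
#' `x`, `y`, `z`, `occ`, `b`, plus a unit cell and space group carried as
#' attributes. Alternative conformers live on separate rows distinguished
#' by `altloc`; a blank altloc (`""`) marks a single-conformer atom.
#'
#' @param atoms Data frame with the columns above (missing `ins`, `altloc`,
#'   `element`, `occ`, `b` are filled with defaults).
#' @param cell Unit cell `c(a, b, c, alpha, beta, gamma)` in angstrom and
#'   degrees; defaults to a P1 box padded around the coordinates.
#' @param spacegroup Space group symbol, default `"P 1"`.
#' @return A `struct_model` tibble.
#' @export
struct_model <- function(atoms, cell = NULL, spacegroup = "P 1") {
  atoms <- as_tibble(atoms)
  if (!"ins" %in% names(atoms)) atoms$ins <- ""
  if (!"altloc" %in% names(atoms)) atoms$altloc <- ""
  if (!"element" %in% names(atoms)) atoms$element <- guess_element(atoms$atom)
  if (!"occ" %in% names(atoms)) atoms$occ <- 1
  if (!"b" %in% names(atoms)) atoms$b <- 0
  atoms$ins[is.na(atoms$ins)] <- ""
  atoms$altloc[is.na(atoms$altloc)] <- ""
  atoms$resno <- as.integer(atoms$resno)
  cols <- c("chain", "resno", "ins", "resname", "atom", "altloc", "element",
            "x", "y", "z", "occ", "b")
  missing <- setdiff(cols, names(atoms))
  if (length(missing)) {
    abort(paste0("atoms is missing column(s): ", paste(missing, collapse = ", ")))
  }
  atoms <- atoms[, cols]
  if (is.null(cell)) {
    pad <- 10
    span <- vapply(atoms[, c("x", "y", "z")],
                   function(v) diff(range(v)), numeric(1))
    cell <- c(span + 2 * pad, 90, 90, 90)
  }
  m <- tibble::new_tibble(atoms, class = "struct_model",
                          cell = as.numeric(cell),
                          spacegroup = spacegroup)
  validate_struct_model(m)
  m
}

#' @export
print.struct_model <- function(x, ...) {
  cell <- model_cell(x)
  cat(sprintf("<struct_model> %d atoms, %d residues, cell %s, %s\n",
              nrow(x), nrow(distinct(as_tibble(x)[, c("chain", "resno", "ins")])),
              paste(format(cell, digits = 5), collapse = " "),
              attr(x, "spacegroup") %||% "P 1"))
  print(as_tibble(x), ...)
  invisible(x)
}

#' @rdname struct_model
#' @param model A `struct_model`.
#' @export
model_cell <- function(model) attr(model, "cell")

# rebuild a struct_model from a (possibly dplyr-mangled) tibble, keeping
# the geometry of a template model
rebuild_model <- function(atoms, template) {
  struct_model(atoms, cell = model_cell(template),
               spacegroup = attr(template, "spacegroup") %||% "P 1")
}

validate_struct_model <- function(m) {
  if (any(!is.finite(m$x) | !is.finite(m$y) | !is.finite(m$z))) {
    abort("non-finite coordinates in structure model")
  }
  if (any(m$occ < 0 | m$occ > 1, na.rm = TRUE)) {
    abort("occupancies must lie in [0, 1]")
  }
  if (any(m$b < 0, na.rm = TRUE)) abort("B-factors must be >= 0")
  key <- paste(m$chain, m$resno, m$ins, m$atom, m$altloc, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))
    abort(paste0("duplicate (residue, atom, altloc) record(s): ",
                 paste(sprintf("%s:%d%s %s '%s'", m$chain[d], m$resno[d],
                               m$ins[d], m$atom[d], m$altloc[d]),
                       collapse = "; ")))
  }
  invisible(m)
}

guess_element <- function(atom_name) {
  first <- substr(gsub("[0-9]", "", trimws(atom_name)), 1, 1)
  toupper(first)
}

#' Subset a model to a residue selection
#'
#' @param model A `struct_model`.
#' @param selection Residue selection (`chain`, `resno`, `ins`).
#' @return A `struct_model` containing only the selected residues.
#' @export
subset_residues <- function(model, selection) {
  sel <- as_tibble(selection)
  if (!"ins" %in% names(sel)) sel$ins <- ""
  a <- as_tibble(model)
  keep <- paste(a$chain, a$resno, a$ins) %in%
    paste(sel$chain, sel$resno, sel$ins)
  rebuild_model(a[keep, ], model)
}

#' Residue keys of a model
#'
#' @param model A `struct_model`.
#' @return Tibble with one row per residue: `chain`, `resno`, `ins`, `resname`.
#' @export
residue_keys <- function(model) {
  distinct(as_tibble(model)[, c("chain", "resno", "ins", "resname")])
}

#' Build a residue selection
#'
#' @param chain,resno,ins Vectors (recycled) identifying residues.
#' @return Tibble with columns `chain`, `resno`, `ins` usable wherever a
#'   residue selection is expected.
#' @export
residue_selection <- function(chain, resno, ins = "") {
  tibble(chain = as.character(chain), resno = as.integer(resno),
         ins = as.character(ins))
}

check_selection <- function(model, selection) {
  selection <- as_tibble(selection)
  if (!"ins" %in% names(selection)) selection$ins <- ""
  if (nrow(selection) == 0) abort("residue selection is empty")
  missing <- anti_join(selection, residue_keys(model),
                       by = c("chain", "resno", "ins"))
  if (nrow(missing) > 0) {
    abort(paste0("selection residue(s) absent from model: ",
                 paste(sprintf("%s:%d%s", missing$chain, missing$resno,
                               missing$ins), collapse = ", ")))
  }
  selection[, c("chain", "resno", "ins")]
}

#' Read a structure from a PDB file
#'
#' Altloc, occupancy and B-factor columns are preserved exactly as printed;
#' atom record order is kept. The `CRYST1` record, when present, supplies
#' the unit cell and space group.
#'
#' @param path Path to a PDB file.
#' @param dialect Only `"pdb"` is supported.
#' @return A [struct_model()].
#' @export
read_structure <- function(path, dialect = "pdb") {
  dialect <- match.arg(dialect, "pdb")
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  bad <- which(rec & !grepl(
    "^(ATOM  |HETATM).{5}.{5}....((\\s|[-0-9.]){8}){3}", lines))
  for (i in which(rec)) {
    flds <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
              substr(lines[i], 47, 54), substr(lines[i], 55, 60),
              substr(lines[i], 61, 66), substr(lines[i], 23, 26))
    if (anyNA(suppressWarnings(as.numeric(flds)))) {
      abort(sprintf("malformed ATOM/HETATM record at line %d of %s", i, path))
    }
  }
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  blank <- function(v) ifelse(is.na(v), "", v)
  elesy <- blank(a$elesy)
  atoms <- tibble(
    chain = blank(a$chain), resno = as.integer(a$resno),
    ins = blank(a$insert), resname = a$resid, atom = a$elety,
    altloc = blank(a$alt),
    element = ifelse(elesy == "", guess_element(a$elety), toupper(elesy)),
    x = a$x, y = a$y, z = a$z, occ = a$o, b = a$b)
  cryst <- grep("^CRYST1", lines, value = TRUE)
  cell <- NULL; sg <- "P 1"
  if (length(cryst) >= 1) {
    cl <- cryst[[1]]
    cell <- as.numeric(c(substr(cl, 7, 15), substr(cl, 16, 24),
                         substr(cl, 25, 33), substr(cl, 34, 40),
                         substr(cl, 41, 47), substr(cl, 48, 54)))
    sg <- trimws(substr(cl, 56, 66))
    if (sg == "") sg <- "P 1"
  }
  struct_model(atoms, cell = cell, spacegroup = sg)
}

#' Write a structure to a PDB file
#'
#' Coordinates are printed to 3 decimals, occupancy and B-factor to 2, in
#' the fixed PDB columns, so a write/read round trip reproduces the model
#' at format precision. A `CRYST1` record carries the unit cell.
#'
#' @param model A [struct_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  validate_struct_model(model)
  cell <- model_cell(model)
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  bio3d::write.pdb(
    pdb = NULL, file = tmp,
    xyz = as.numeric(t(as.matrix(model[, c("x", "y", "z")]))),
    resno = model$resno, resid = model$resname, chain = model$chain,
    insert = model$ins, alt = model$altloc, o = model$occ, b = model$b,
    elety = model$atom, elesy = model$element)
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                   cell[1], cell[2], cell[3], cell[4], cell[5], cell[6],
                   attr(model, "spacegroup") %||% "P 1")
  ok <- tryCatch({
    writeLines(c(cryst, readLines(tmp, warn = FALSE)), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort(paste0("cannot write to ", path))
  invisible(path)
}

#' Rename atoms according to a mapping table
#'
#' Makes conformer atom naming consistent with a reference structure.
#' Only `atom` fields change; unmapped names pass through untouched.
#'
#' @param fragment A [struct_model()].
#' @param mapping Data frame with columns `resname`, `from`, `to` (a
#'   `resname` of `"*"` applies to every residue type).
#' @return The renamed model, with the number of renamed atoms reported via
#'   attribute `"n_renamed"` and a message.
#' @export
map_atom_names <- function(fragment, mapping) {
  mapping <- as_tibble(mapping)
  if (nrow(mapping) == 0) {
    attr(fragment, "n_renamed") <- 0L
    return(fragment)
  }
  stopifnot(all(c("resname", "from", "to") %in% names(mapping)))
  new <- fragment$atom
  hit <- rep(FALSE, nrow(fragment))
  for (k in seq_len(nrow(mapping))) {
    sel <- fragment$atom == mapping$from[k] &
      (mapping$resname[k] == "*" | fragment$resname == mapping$resname[k]) &
      !hit
    new[sel] <- mapping$to[k]
    hit <- hit | sel
  }
  out <- as_tibble(fragment)
  out$atom <- new
  out <- tryCatch(rebuild_model(out, fragment), error = function(e) {
    abort(paste0("atom-name mapping collides atoms within a residue: ",
                 conditionMessage(e)))
  })
  n <- sum(hit & fragment$atom != new)
  inform(sprintf("map_atom_names: renamed %d atom(s)", n))
  attr(out, "n_renamed") <- n
  out
}

#' Merge a conformer fragment into a reference model as alternative conformers
#'
#' For every selected residue the reference atoms become conformer
#' `labels[1]` with occupancy `1 - q_init` and the fragment atoms become
#' conformer `labels[2]` with occupancy `q_init`; all conformer-B atoms are
#' one occupancy group whose complement constraint holds by construction.
#' Each B atom inherits the B-factor of the same-named reference atom
#' (displacement parameters are assumed equal in the two states).
#' Unselected residues pass through with blank altlocs.
#'
#' @param reference Reference-state [struct_model()].
#' @param fragment Conformer supplying the triggered-state coordinates.
#' @param selection Residues to merge, see [residue_selection()].
#' @param q_init Initial occupancy of the triggered conformer, in (0, 1);
#'   default 0.25.
#' @param labels Altloc labels for (reference, triggered), default
#'   `c("A", "B")`.
#' @param keep_hydrogens Keep fragment hydrogens (default drops them).
#' @return The merged two-state [struct_model()].
#' @export
merge_alt_conformers <- function(reference, fragment, selection,
                                 q_init = 0.25, labels = c("A", "B"),
                                 keep_hydrogens = FALSE) {
  if (!(q_init > 0 && q_init < 1)) abort("q_init must lie strictly in (0, 1)")
  selection <- check_selection(reference, selection)
  check_selection(fragment, selection)
  key <- function(df) paste(df$chain, df$resno, df$ins, sep = "\r")
  skey <- key(selection)
  ref <- as_tibble(reference)
  frag <- as_tibble(fragment)
  ref_sel <- ref[key(ref) %in% skey, ]
  frag_sel <- frag[key(frag) %in% skey, ]
  if (!keep_hydrogens) frag_sel <- frag_sel[frag_sel$element != "H", ]

  rn <- distinct(bind_rows(ref_sel, frag_sel)[, c("chain", "resno", "ins",
                                                  "resname")])
  bad <- count(rn, .data$chain, .data$resno, .data$ins) |> filter(.data$n > 1)
  if (nrow(bad) > 0) {
    abort(paste0("residue name mismatch between reference and fragment at: ",
                 paste(sprintf("%s:%d%s", bad$chain, bad$resno, bad$ins),
                       collapse = ", ")))
  }
  akey <- function(df) paste(key(df), df$atom, sep = "\r")
  orphan <- !(akey(frag_sel) %in% akey(ref_sel))
  if (any(orphan)) {
    o <- frag_sel[orphan, ]
    abort(paste0(
      "fragment atom(s) with no same-named reference atom ",
      "(B-factor source undefined): ",
      paste(sprintf("%s:%d%s %s", o$chain, o$resno, o$ins, o$atom),
            collapse = ", ")))
  }
  ref_sel$altloc <- labels[1]
  ref_sel$occ <- 1 - q_init
  frag_sel$altloc <- labels[2]
  frag_sel$occ <- q_init
  frag_sel$b <- ref_sel$b[match(akey(frag_sel), akey(ref_sel))]

  # keep original atom order: selected residues are replaced in place with
  # the A conformer followed by the B conformer
  in_sel <- key(ref) %in% skey
  res_order <- unique(key(ref))
  combined <- bind_rows(
    mutate(ref[!in_sel, ], .grp = 0L, .row = row_number()),
    mutate(ref_sel, .grp = 1L, .row = row_number()),
    mutate(frag_sel, .grp = 2L, .row = row_number()))
  combined <- combined[order(match(key(combined), res_order),
                             combined$.grp, combined$.row), ]
  combined$.grp <- combined$.row <- NULL
  rebuild_model(combined, reference)
}
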