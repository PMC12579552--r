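#' Assemble aligned conformations into a frame set
#'
#' A frame set is a long tibble with one row per atom per frame
#' (`frame`, `chain`, `resno`, `ins`, `resname`, `atom`, `x`, `y`, `z`).
#' Frames must already be superposed (see [superpose_calpha()]); RMSF is
#' computed on coordinates as given.
#'
#' @param models Named list of [struct_model()]s (names become frame ids)
#'   or an existing long tibble, returned unchanged.
#' @param selection Optional residue selection to restrict the atom set.
#' @return Long frame tibble.
#' @export
frame_set <- function(models, selection = NULL) {
  if (is.data.frame(models)) return(as_tibble(models))
  if (is.null(names(models))) {
    names(models) <- sprintf("frame_%04d", seq_along(models))
  }
  frames <- imap(models, function(m, id) {
    a <- as_tibble(m)[, c("chain", "resno", "ins", "resname", "atom",
                          "x", "y", "z")]
    a$frame <- id
    a
  }) |> bind_rows()
  if (!is.null(selection)) {
    sel <- as_tibble(selection)
    if (!"ins" %in% names(sel)) sel$ins <- ""
    frames <- inner_join(frames, sel[, c("chain", "resno", "ins")],
                         by = c("chain", "resno", "ins"))
  }
  frames[, c("frame", "chain", "resno", "ins", "resname", "atom",
             "x", "y", "z")]
}

check_inventory <- function(frames) {
  inv <- frames |>
    count(.data$chain, .data$resno, .data$ins, .data$atom, name = "n_frames")
  n <- length(unique(frames$frame))
  bad <- inv[inv$n_frames != n, ]
  if (nrow(bad) > 0) {
    abort(paste0("atom inventory differs across frames: ",
                 paste(utils::head(sprintf("%s:%d%s %s", bad$chain, bad$resno,
                                           bad$ins, bad$atom), 10),
                       collapse = ", "),
                 if (nrow(bad) > 10) sprintf(" (+%d more)", nrow(bad) - 10)))
  }
  n
}

#' Atomic root mean square fluctuation over a frame set
#'
#' For each atom i, `rmsf_i = sqrt(mean_n |r_in - rbar_i|^2)` where the
#' mean position `rbar_i` is taken over all N frames. No re-superposition
#' is performed, so per-frame rigid motions inflate the result; align
#' frames first.
#'
#' @param frames A [frame_set()] with at least 2 frames and identical atom
#'   inventories.
#' @return Tibble per atom: `chain`, `resno`, `ins`, `resname`, `atom`,
#'   `rmsf`, mean position `x`, `y`, `z`.
#' @export
atomic_rmsf <- function(frames) {
  frames <- as_tibble(frames)
  n <- check_inventory(frames)
  if (n < 2) abort("need at least 2 frames for RMSF")
  frames |>
    group_by(.data$chain, .data$resno, .data$ins, .data$resname,
             .data$atom) |>
    summarise(rmsf = sqrt(mean((.data$x - mean(.data$x))^2 +
                                 (.data$y - mean(.data$y))^2 +
                                 (.data$z - mean(.data$z))^2)),
              x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
              .groups = "drop")
}

#' Per-residue RMSF profile
#'
#' Aggregates atomic RMSF values per residue. The default is the RMS form
#' `sqrt((1/M) * sum_i rmsf_i^2)` over the M atoms of the residue;
#' `agg = "mean"` gives the plain average instead. A residue profile below
#' 1 A indicates stable refined coordinates, recorded in the `stable`
#' column.
#'
#' @param atomic Output of [atomic_rmsf()].
#' @param agg `"rms"` (default) or `"mean"`.
#' @param stable_threshold Stability cutoff in angstrom, default 1.0.
#' @return An `rmsf_profile` tibble: `chain`, `resno`, `ins`, `resname`,
#'   `rmsf_res`, `n_atoms`, `stable`.
#' @export
residue_rmsf <- function(atomic, agg = c("rms", "mean"),
                         stable_threshold = 1.0) {
  agg <- match.arg(agg)
  out <- as_tibble(atomic) |>
    group_by(.data$chain, .data$resno, .data$ins, .data$resname) |>
    summarise(rmsf_res = if (agg == "rms") sqrt(mean(.data$rmsf^2))
              else mean(.data$rmsf),
              n_atoms = n(), .groups = "drop") |>
    mutate(stable = .data$rmsf_res < stable_threshold)
  class(out) <- c("rmsf_profile", class(out))
  out
}

#' Plot a per-residue RMSF profile
#'
#' @param object An `rmsf_profile` from [residue_rmsf()].
#' @param ... Unused.
#' @return A ggplot object with the 1 A stability threshold marked.
#' @export
autoplot.rmsf_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$resno, y = .data$rmsf_res,
                               colour = .data$chain)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1.0, linetype = "dashed") +
    ggplot2::labs(x = "residue", y = "residue RMSF (Å)") +
    ggplot2::theme_minimal()
}

#' Coordinate RMSD between paired models
#'
#' Per-pair RMSD over the selected residues' atoms, matched by residue key
#' and atom name, with no re-superposition; quantifies how far refinement
#' moved each input conformer.
#'
#' @param before,after Lists of [struct_model()]s of equal length (paired
#'   by position, e.g. input vs refined).
#' @param selection Residue selection to measure over (NULL = all).
#' @return Tibble: `pair`, `rmsd`, `n_atoms`.
#' @export
before_after_rmsd <- function(before, after, selection = NULL) {
  stopifnot(length(before) == length(after))
  ids <- names(before) %||% sprintf("pair_%04d", seq_along(before))
  rows <- purrr::map2(before, after, function(b, a) {
    bt <- as_tibble(b); at <- as_tibble(a)
    if (!is.null(selection)) {
      sel <- as_tibble(selection)
      if (!"ins" %in% names(sel)) sel$ins <- ""
      bt <- inner_join(bt, sel[, c("chain", "resno", "ins")],
                       by = c("chain", "resno", "ins"))
      at <- inner_join(at, sel[, c("chain", "resno", "ins")],
                       by = c("chain", "resno", "ins"))
    }
    j <- inner_join(bt, at, by = c("chain", "resno", "ins", "atom", "altloc"),
                    suffix = c("_b", "_a"))
    if (nrow(j) != nrow(bt) || nrow(j) != nrow(at)) {
      abort("paired atom inventories do not match on the selection")
    }
    tibble(rmsd = sqrt(mean((j$x_b - j$x_a)^2 + (j$y_b - j$y_a)^2 +
                              (j$z_b - j$z_a)^2)),
           n_atoms = nrow(j))
  })
  bind_rows(rows) |> mutate(pair = ids, .before = 1)
}

#' Encode atomic RMSF values into the B-factor column
#'
#' Writes each atom's RMSF into `b` so the profile can be visualized by
#' B-factor colouring in any structure viewer.
#'
#' @param model A [struct_model()] (typically the ensemble mean or a
#'   representative frame).
#' @param atomic Output of [atomic_rmsf()].
#' @return The model with `b` replaced by RMSF (unmatched atoms get 0).
#' @export
encode_rmsf_b <- function(model, atomic) {
  a <- as_tibble(model)
  key <- function(df) paste(df$chain, df$resno, df$ins, df$atom, sep = "\r")
  m <- match(key(a), key(atomic))
  a$b <- ifelse(is.na(m), 0, atomic$rmsf[m])
  rebuild_model(a, model)
}
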