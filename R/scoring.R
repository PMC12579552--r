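#' Min-max normalization across a model pool
#'
#' Rescales a metric so its batch minimum maps to 0 and maximum to 1.
#' A constant pool cannot discriminate and is mapped to all zeros; missing
#' values stay missing.
#'
#' @param values Numeric vector (the pool of raw values across the batch).
#' @return Numeric vector in `[0, 1]`.
#' @export
minmax_normalize <- function(values) {
  if (length(values) == 0) abort("empty pool")
  rng <- range(values, na.rm = TRUE)
  if (!is.finite(rng[1])) return(values)  # all missing: nothing to rescale
  if (rng[2] == rng[1]) {
    out <- ifelse(is.na(values), NA_real_, 0)
    return(out)
  }
  (values - rng[1]) / (rng[2] - rng[1])
}

# normalize one metric column under the missing-value policy:
# all-missing -> NULL (caller drops term with a warning); partially missing
# models get the worst normalized value 1 and are flagged.
norm_col <- function(metrics, col, flags_env) {
  if (!col %in% names(metrics)) v <- rep(NA_real_, nrow(metrics))
  else v <- metrics[[col]]
  if (all(is.na(v))) return(NULL)
  nv <- minmax_normalize(v)
  if (anyNA(nv)) {
    flagged <- metrics$model_id[is.na(nv)]
    flags_env$flags <- bind_rows(flags_env$flags,
                                 tibble(model_id = flagged, column = col,
                                        issue = "missing_worst_assigned"))
    nv[is.na(nv)] <- 1
  }
  nv
}

#' R-factor term of the composite score
#'
#' Sum of the batch-normalized R-free and R-work, in `[0, 2]`.
#'
#' @param metrics Tibble with `model_id`, `r_work`, `r_free` (one row per
#'   model; the whole batch is the normalization pool).
#' @return Tibble `model_id`, `r_factor_term`.
#' @export
r_factor_term <- function(metrics) {
  metrics <- as_tibble(metrics)
  if (nrow(metrics) < 2) abort("need at least 2 models to normalize")
  fe <- new.env(); fe$flags <- NULL
  rf <- norm_col(metrics, "r_free", fe)
  rw <- norm_col(metrics, "r_work", fe)
  if (is.null(rf) || is.null(rw)) abort("r_work/r_free missing for every model")
  out <- tibble(model_id = metrics$model_id, r_factor_term = rf + rw)
  attr(out, "flags") <- fe$flags
  out
}

.geometry_terms <- c("molprobity_score", "ramachandran_outliers",
                     "rotamer_outliers", "cbeta_outliers", "rms_bond",
                     "rms_angle", "clashscore", "rmsd_ab")

#' Geometry term of the composite score
#'
#' Sum of up to eight batch-normalized geometry metrics (MolProbity score,
#' Ramachandran/rotamer/C-beta outliers, bond and angle RMS, clashscore,
#' conformer-B RMSD). Columns missing for the whole batch contribute 0 with
#' a warning; models missing an otherwise-present column get that column's
#' worst normalized value (1) and are flagged.
#'
#' @param metrics Tibble with `model_id` and any of the eight columns.
#' @return Tibble `model_id`, `geometry_score`, with attributes `"flags"`
#'   and `"dropped_terms"`.
#' @export
geometry_score <- function(metrics) {
  metrics <- as_tibble(metrics)
  if (nrow(metrics) < 2) abort("need at least 2 models to normalize")
  fe <- new.env(); fe$flags <- NULL
  total <- rep(0, nrow(metrics))
  dropped <- character(0)
  for (col in .geometry_terms) {
    nv <- norm_col(metrics, col, fe)
    if (is.null(nv)) dropped <- c(dropped, col) else total <- total + nv
  }
  if (length(dropped)) {
    warn(paste0("geometry term(s) absent for every model, contributing 0: ",
                paste(dropped, collapse = ", ")))
  }
  out <- tibble(model_id = metrics$model_id, geometry_score = total)
  attr(out, "flags") <- fe$flags
  attr(out, "dropped_terms") <- dropped
  out
}

#' Weighted per-residue RSZD summary for each model
#'
#' Combines the per-residue positive and negative RSZD magnitudes with the
#' isomorphous difference-density weights:
#' `RSZD_n = (1/m) * sum_j (rho_neg_j * RSZD-_jn + rho_pos_j * RSZD+_jn)`,
#' where `m` counts the residues in the weight set (zero-weight residues
#' included).
#'
#' @param residue_metrics Long tibble: `model_id`, `chain`, `resno`, `ins`,
#'   `rszd_plus`, `rszd_minus`.
#' @param weights Weight tibble from [residue_difference_weights()].
#' @return Tibble `model_id`, `weighted_rszd`.
#' @export
weighted_rszd <- function(residue_metrics, weights) {
  weights <- as_tibble(weights)
  m <- attr(weights, "m") %||% nrow(weights)
  if (m < 1) abort("weight set is empty (m = 0)")
  rm_ <- as_tibble(residue_metrics)
  if (!"ins" %in% names(rm_)) rm_$ins <- ""
  if (!"ins" %in% names(weights)) weights$ins <- ""
  j <- inner_join(weights, rm_, by = c("chain", "resno", "ins"))
  per_model_rows <- count(j, .data$model_id)
  if (any(per_model_rows$n < nrow(weights))) {
    abort("weight residues missing from residue metrics for some model(s)")
  }
  j |>
    group_by(.data$model_id) |>
    summarise(weighted_rszd = sum(.data$rho_neg * abs(.data$rszd_minus) +
                                    .data$rho_pos * abs(.data$rszd_plus)) / m,
              .groups = "drop")
}

#' Per-model average of a residue-level metric
#'
#' Mean of RSCC or RSZO across the residues modelled with alternative
#' conformers; residues with a missing value are excluded with the count
#' adjusted and the model flagged.
#'
#' @param residue_metrics Long per-residue tibble (see [weighted_rszd()]).
#' @param metric `"rscc"` or `"rszo"`.
#' @return Tibble `model_id`, `<metric>_bar`, with attribute `"flags"`.
#' @export
residue_average <- function(residue_metrics, metric = c("rscc", "rszo")) {
  metric <- match.arg(metric)
  rm_ <- as_tibble(residue_metrics)
  if (nrow(rm_) == 0) abort("no residues to average (R = 0)")
  out <- rm_ |>
    group_by(.data$model_id) |>
    summarise(value = mean(.data[[metric]], na.rm = TRUE),
              n_missing = sum(is.na(.data[[metric]])), .groups = "drop")
  flags <- NULL
  if (any(out$n_missing > 0)) {
    flags <- tibble(model_id = out$model_id[out$n_missing > 0],
                    column = metric, issue = "residues_excluded_from_average")
  }
  res <- tibble(model_id = out$model_id)
  res[[paste0(metric, "_bar")]] <- out$value
  attr(res, "flags") <- flags
  res
}

#' Density term of the composite score
#'
#' `RSZD' + (1 - RSCC') + (1 - RSZO')` per model, where each primed
#' quantity is the batch min-max normalization of the weighted RSZD and the
#' residue-averaged RSCC and RSZO (the averages are inverted because higher
#' is better for them). Range `[0, 3]`.
#'
#' @param residue_metrics Long per-residue tibble.
#' @param weights Difference-density weights.
#' @return Tibble `model_id`, `weighted_rszd`, `rscc_bar`, `rszo_bar`,
#'   `density_score`.
#' @export
density_score <- function(residue_metrics, weights) {
  wz <- weighted_rszd(residue_metrics, weights)
  cb <- residue_average(residue_metrics, "rscc")
  ob <- residue_average(residue_metrics, "rszo")
  if (nrow(wz) < 2) abort("need at least 2 models to normalize")
  out <- wz |>
    inner_join(cb, by = "model_id") |>
    inner_join(ob, by = "model_id") |>
    mutate(density_score = minmax_normalize(.data$weighted_rszd) +
             (1 - minmax_normalize(.data$rscc_bar)) +
             (1 - minmax_normalize(.data$rszo_bar)))
  attr(out, "flags") <- bind_rows(attr(cb, "flags"), attr(ob, "flags"))
  out
}

#' Composite score and ranking for a batch of candidate models
#'
#' Sums the three terms -- normalized R-factors, normalized geometry
#' metrics, and the weighted density term -- into a single composite score
#' per model (lower is better; range 0 to 13 when all terms are present)
#' and ranks the batch ascending.
#'
#' @param metrics Per-model metric tibble (`model_id`, `r_work`, `r_free`,
#'   geometry columns; see [geometry_score()]).
#' @param residue_metrics Long per-residue density metric tibble.
#' @param weights Difference-density weight tibble.
#' @return A `score_breakdown` tibble: `model_id`, `r_factor_term`,
#'   `geometry_score`, `weighted_rszd`, `rscc_bar`, `rszo_bar`,
#'   `density_score`, `composite`, `rank`, ordered by rank, with attribute
#'   `"flags"` recording missing-metric substitutions.
#' @export
composite_score <- function(metrics, residue_metrics, weights) {
  metrics <- as_tibble(metrics)
  rf <- r_factor_term(metrics)
  gs <- geometry_score(metrics)
  ds <- density_score(residue_metrics, weights)
  out <- rf |>
    inner_join(gs, by = "model_id") |>
    inner_join(ds, by = "model_id") |>
    mutate(composite = .data$r_factor_term + .data$geometry_score +
             .data$density_score) |>
    left_join(select(metrics, "model_id",
                     r_free = dplyr::any_of("r_free")), by = "model_id")
  out <- rank_models(out)
  attr(out, "flags") <- bind_rows(attr(rf, "flags"), attr(gs, "flags"),
                                  attr(ds, "flags"))
  attr(out, "dropped_terms") <- attr(gs, "dropped_terms")
  class(out) <- c("score_breakdown", class(out))
  out
}

#' Rank models by composite score
#'
#' Ascending composite; ties broken by lower R-free, then by model id.
#'
#' @param breakdowns Tibble with `composite` (and optionally `r_free`,
#'   `model_id`).
#' @return The tibble ordered by rank with a 1-based `rank` column.
#' @export
rank_models <- function(breakdowns) {
  b <- as_tibble(breakdowns)
  if (nrow(b) == 0) abort("no score breakdowns to rank")
  if (!"r_free" %in% names(b)) b$r_free <- NA_real_
  b |>
    arrange(.data$composite, .data$r_free, .data$model_id) |>
    mutate(rank = row_number())
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf("<score_breakdown> %d models; best: %s (composite %.4f)\n",
              nrow(x), x$model_id[1], x$composite[1]))
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a score breakdown
#'
#' @param x A `score_breakdown` from [composite_score()].
#' @param ... Unused.
#' @return Long tibble: `model_id`, `rank`, `term`, `value` for the three
#'   composite terms plus the composite itself.
#' @export
tidy.score_breakdown <- function(x, ...) {
  as_tibble(x) |>
    select("model_id", "rank", "r_factor_term", "geometry_score",
           "density_score", "composite") |>
    tidyr::pivot_longer(cols = c("r_factor_term", "geometry_score",
                                 "density_score", "composite"),
                        names_to = "term", values_to = "value")
}

#' Summarise a score breakdown
#'
#' @param x A `score_breakdown`.
#' @param ... Unused.
#' @return One-row tibble: number of models, best model and its composite,
#'   number of missing-metric flags.
#' @export
glance.score_breakdown <- function(x, ...) {
  tibble(n_models = nrow(x), best_model = x$model_id[which.min(x$rank)],
         best_composite = min(x$composite),
         worst_composite = max(x$composite),
         n_flags = nrow(attr(x, "flags") %||% tibble()))
}

#' Plot the composite-score breakdown of the top-ranked models
#'
#' Stacked bars of the three composite terms for the `top_n` best models.
#'
#' @param object A `score_breakdown`.
#' @param top_n Number of models to display, default 20.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.score_breakdown <- function(object, top_n = 20, ...) {
  df <- tidy(object) |>
    filter(.data$term != "composite", .data$rank <= top_n) |>
    mutate(model_id = stats::reorder(.data$model_id, .data$rank))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model_id, y = .data$value,
                                   fill = .data$term)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "model (ranked)", y = "composite score contribution",
                  fill = "term") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
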