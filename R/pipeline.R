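#' Ingest externally computed validation metrics
#'
#' Merges metric columns produced by external tools (refinement logs,
#' MolProbity-style geometry tables, per-residue density statistics) into a
#' per-model metric tibble, tracking provenance per field. Native values
#' are never silently overwritten: a conflicting non-missing value raises
#' an error unless `prefer` says which side wins.
#'
#' @param metrics Per-model tibble with `model_id` (native values).
#' @param table Data frame or TSV path with `model_id` plus metric columns.
#' @param prefer `"error"` (default), `"ingested"`, or `"native"`.
#' @return Updated tibble; attribute `"provenance"` is a long tibble
#'   (`model_id`, `field`, `provenance`).
#' @export
ingest_external_metrics <- function(metrics, table,
                                    prefer = c("error", "ingested", "native")) {
  prefer <- match.arg(prefer)
  metrics <- as_tibble(metrics)
  if (is.character(table)) {
    table <- as_tibble(read.delim(table, sep = "\t", stringsAsFactors = FALSE))
  }
  table <- as_tibble(table)
  if (!"model_id" %in% names(table)) abort("ingest table lacks a model_id column")
  unknown <- setdiff(table$model_id, metrics$model_id)
  if (length(unknown)) {
    abort(paste0("ingest table row(s) for unknown model id(s): ",
                 paste(unknown, collapse = ", ")))
  }
  prov <- attr(metrics, "provenance") %||%
    tibble(model_id = character(0), field = character(0),
           provenance = character(0))
  for (col in setdiff(names(table), "model_id")) {
    idx <- match(table$model_id, metrics$model_id)
    new <- table[[col]]
    if (!col %in% names(metrics)) metrics[[col]] <- NA
    old <- metrics[[col]][idx]
    conflict <- !is.na(old) & !is.na(new) & old != new
    if (any(conflict) && prefer == "error") {
      abort(paste0("native and ingested values conflict for '", col,
                   "' (models: ",
                   paste(table$model_id[conflict], collapse = ", "),
                   "); pass prefer = 'ingested' or 'native'"))
    }
    take <- !is.na(new) & (is.na(old) | prefer == "ingested")
    metrics[[col]][idx[take]] <- new[take]
    if (any(take)) {
      prov <- bind_rows(prov, tibble(model_id = table$model_id[take],
                                     field = col, provenance = "ingested"))
    }
  }
  attr(metrics, "provenance") <- prov
  metrics
}

#' Run an external refinement command for one model
#'
#' Contract wrapper around a user-supplied refiner command line. The
#' template must contain `{model}` and `{out}` placeholders; the command's
#' stdout/stderr are captured to a log next to the output. The literal
#' template `"mock"` signals the caller to route to
#' [mock_refine_occupancy()] instead.
#'
#' @param template Command template, e.g.
#'   `"phenix.refine {model} data.mtz output.prefix={out}"`.
#' @param model_path Path to the merged model PDB.
#' @param out_path Expected refined-model output path.
#' @param timeout Seconds before the command is killed, default 600.
#' @return List: `status` (`"refined"` or `"failed:refiner"`), `out_path`,
#'   `log`.
#' @export
run_external_refiner <- function(template, model_path, out_path,
                                 timeout = 600) {
  if (identical(template, "mock")) {
    abort("the 'mock' template is dispatched by the pipeline, not run here")
  }
  if (!grepl("\\{model\\}", template) || !grepl("\\{out\\}", template)) {
    abort("refiner template must contain {model} and {out} placeholders")
  }
  cmd <- gsub("\\{model\\}", shQuote(model_path),
              gsub("\\{out\\}", shQuote(out_path), template))
  log <- suppressWarnings(
    tryCatch(system(cmd, intern = TRUE, timeout = timeout,
                    ignore.stderr = FALSE),
             error = function(e) structure(conditionMessage(e), status = 124L)))
  status_code <- attr(log, "status") %||% 0L
  ok <- status_code == 0L && file.exists(out_path)
  list(status = if (ok) "refined" else "failed:refiner",
       out_path = if (ok) out_path else NA_character_,
       log = as.character(log))
}

#' Run the full two-state modeling pipeline over a batch of conformers
#'
#' Executes, for every candidate frame: alternative-conformer merge at
#' `q_init`, occupancy refinement (mock closed-form by default), real-space
#' density metrics (RSCC/RSZO per residue against the triggered map, RSZD
#' against the post-refinement residual map), native geometry metrics, and
#' surrogate real-space R-factors on a deterministic work/free voxel split.
#' Residue weights come from the isomorphous difference map. The batch is
#' then ranked by composite score. Frames that fail any stage are recorded
#' in the manifest and skipped, never aborting the batch.
#'
#' @param reference Reference-state [struct_model()].
#' @param frames Named list of candidate conformer models (same residue
#'   keys as the reference).
#' @param selection Triggered-residue selection.
#' @param map_ref,map_trig Reference and triggered observed maps.
#' @param q_init Initial triggered-conformer occupancy, default 0.25.
#' @param skip_frames Leading frames to exclude (burn-in), default 0.
#' @param radius Mask radius in angstrom, default 2.0.
#' @param z_threshold Weight threshold in sigma, default 3.0.
#' @param sigma_method Noise convention, `"rms"` or `"mad"`.
#' @param refiner `"mock"` or an external command template for
#'   [run_external_refiner()].
#' @param free_fraction Fraction of voxels held out for the surrogate
#'   R-free, default 0.1.
#' @param seed Seed for the work/free voxel split, default 1.
#' @param workers Parallel workers (forked); results are independent of
#'   this value.
#' @return List: `scores` (a ranked `score_breakdown`), `metrics`,
#'   `residue_metrics`, `weights`, `q_hat` (per-frame occupancies),
#'   `manifest` (per-frame status), `config`.
#' @export
run_two_state_pipeline <- function(reference, frames, selection,
                                   map_ref, map_trig,
                                   q_init = 0.25, skip_frames = 0,
                                   radius = 2.0, z_threshold = 3.0,
                                   sigma_method = "rms", refiner = "mock",
                                   free_fraction = 0.1, seed = 1,
                                   workers = 1) {
  config <- list(q_init = q_init, skip_frames = skip_frames, radius = radius,
                 z_threshold = z_threshold, sigma_method = sigma_method,
                 refiner = refiner, free_fraction = free_fraction,
                 seed = as.integer(seed), workers = workers)
  all_ids <- names(frames) %||% sprintf("frame_%04d", seq_along(frames))
  names(frames) <- all_ids
  keep <- select_frames(all_ids, skip_frames)
  frames <- frames[keep]
  if (length(frames) == 0) abort("no frames left after skip_frames")
  selection <- check_selection(reference, selection)

  diff_obs <- difference_grid(map_trig, map_ref)
  weights <- residue_difference_weights(diff_obs, reference, selection,
                                        z_threshold = z_threshold)
  rho_A <- compute_model_density(reference, grid = map_trig)
  # deterministic work/free voxel split for the surrogate R-factors
  set.seed(seed)
  nvox <- length(map_trig$values)
  free_idx <- sort(sample.int(nvox, max(1, round(free_fraction * nvox))))
  is_free <- logical(nvox); is_free[free_idx] <- TRUE

  geom_table <- ideal_geometry_table()
  # frames share the reference outside the selection, so per-frame density
  # and geometry work is confined to the selection (plus, for the bonded
  # terms, the preceding residues whose peptide templates reach into it)
  sel_model <- subset_residues(reference, selection)
  rho_A_sel <- compute_model_density(sel_model, grid = map_trig)
  touched <- bind_rows(selection,
                       mutate(selection, resno = .data$resno - 1L)) |>
    distinct()
  ref_res <- residue_keys(reference)[, c("chain", "resno", "ins")]
  untouched <- anti_join(ref_res, touched, by = c("chain", "resno", "ins"))
  ba_base <- bond_angle_rms(reference, geom_table, residues = untouched)
  touched <- inner_join(touched, ref_res, by = c("chain", "resno", "ins"))
  clash_graph <- tryCatch(
    clash_bond_graph(merge_alt_conformers(reference, frames[[1]], selection,
                                          q_init = q_init), geom_table),
    error = function(e) NULL)

  one_frame <- function(id) {
    tryCatch({
      frame <- frames[[id]]
      merged <- merge_alt_conformers(reference, frame, selection,
                                     q_init = q_init)
      rho_f_sel <- compute_model_density(subset_residues(frame, selection),
                                         grid = map_trig)
      rho_B <- density_grid(rho_A$values - rho_A_sel$values + rho_f_sel$values,
                            spacing = rho_A$spacing, origin = rho_A$origin,
                            cell = rho_A$cell)
      if (identical(refiner, "mock")) {
        ref_out <- mock_refine_occupancy(merged, map_trig, rho_A, rho_B)
      } else {
        mp <- tempfile(fileext = ".pdb"); op <- tempfile(fileext = ".pdb")
        write_structure(merged, mp)
        rr <- run_external_refiner(refiner, mp, op)
        if (rr$status != "refined") {
          return(list(status = "failed:refiner", id = id))
        }
        refined <- read_structure(rr$out_path)
        q <- mean(refined$occ[refined$altloc == "B"])
        ref_out <- list(q_hat = q, model = refined)
      }
      q_hat <- ref_out$q_hat
      calc <- density_grid((1 - q_hat) * rho_A$values + q_hat * rho_B$values,
                           spacing = map_trig$spacing,
                           origin = map_trig$origin, cell = map_trig$cell)
      residual <- difference_grid(map_trig, calc)
      res_met <- residue_density_metrics(ref_out$model, obs = map_trig,
                                         calc = calc, diff = residual,
                                         selection = selection,
                                         radius = radius,
                                         sigma_method = sigma_method)
      res_met$model_id <- id
      cs <- clashscore(ref_out$model, geom_table, graph = clash_graph)
      ba_f <- bond_angle_rms(ref_out$model, geom_table, residues = touched)
      pool_rms <- function(a, b, na, nb) {
        sqrt((na * ifelse(na > 0, a^2, 0) + nb * ifelse(nb > 0, b^2, 0)) /
               (na + nb))
      }
      rms_bond <- pool_rms(ba_base$rms_bond, ba_f$rms_bond,
                           ba_base$n_bonds, ba_f$n_bonds)
      rms_angle <- pool_rms(ba_base$rms_angle, ba_f$rms_angle,
                            ba_base$n_angles, ba_f$n_angles)
      rmsd_ab <- conformer_rmsd(ref_out$model, selection)
      o <- as.numeric(map_trig$values); c_ <- as.numeric(calc$values)
      r_work <- sum(abs(o[!is_free] - c_[!is_free])) / sum(abs(o[!is_free]))
      r_free <- sum(abs(o[is_free] - c_[is_free])) / sum(abs(o[is_free]))
      list(status = "scored", id = id, q_hat = q_hat,
           metrics = tibble(model_id = id, r_work = r_work, r_free = r_free,
                            clashscore = cs$clashscore,
                            rms_bond = rms_bond, rms_angle = rms_angle,
                            rmsd_ab = rmsd_ab),
           residue_metrics = res_met)
    }, error = function(e) list(status = paste0("failed:", conditionMessage(e)),
                                id = id))
  }
  results <- if (workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(names(frames), one_frame, mc.cores = workers)
  } else {
    lapply(names(frames), one_frame)
  }
  status <- map_chr(results, "status")
  manifest <- tibble(frame = all_ids,
                     status = ifelse(all_ids %in% keep,
                                     status[match(all_ids, names(frames))],
                                     "skipped"))
  ok <- status == "scored"
  if (!any(ok)) abort("every frame failed; see manifest for reasons")
  metrics <- bind_rows(map(results[ok], "metrics"))
  residue_metrics <- bind_rows(map(results[ok], "residue_metrics"))
  q_hat <- tibble(model_id = map_chr(results[ok], "id"),
                  q_hat = map_dbl(results[ok], "q_hat"))
  scores <- composite_score(metrics, residue_metrics, weights)
  list(scores = scores, metrics = metrics, residue_metrics = residue_metrics,
       weights = weights, q_hat = q_hat, manifest = manifest, config = config)
}

#' Frame subsetting with burn-in skipping
#'
#' Drops the first `skip` frames of a pool (e.g. skipping 200 of 4000
#' trajectory snapshots to remove the influence of the starting structure).
#'
#' @param ids Character vector of frame ids in order.
#' @param skip Number of leading frames to drop.
#' @return The retained ids.
#' @export
select_frames <- function(ids, skip = 0) {
  if (skip < 0) abort("skip must be >= 0")
  if (skip >= length(ids)) abort("skip leaves no frames")
  ids[seq.int(skip + 1L, length(ids))]
}

#' Write pipeline outputs as TSV files
#'
#' @param result Output of [run_two_state_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) write.table(as_tibble(df), file.path(dir, f),
                                    sep = "\t", quote = FALSE,
                                    row.names = FALSE)
  wt(result$scores, "scores.tsv")
  wt(result$metrics, "metrics.tsv")
  wt(result$residue_metrics, "residue_metrics.tsv")
  wt(result$weights, "weights.tsv")
  wt(result$q_hat, "occupancies.tsv")
  wt(result$manifest, "manifest.tsv")
  jsonlite::write_json(result$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
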