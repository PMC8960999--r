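#' Configuration for the end-to-end cohort pipeline
#'
#' @param phantom a [phantom_config()].
#' @param tracking a [tracking_params()].
#' @param n_subjects cohort size (>= 2).
#' @param threshold_fraction adaptive threshold fraction for localisation.
#' @param ml_offset atlas lateral offset (mm).
#' @param seed integer seed covering every random stage.
#' @param out_dir optional output directory; `NULL` keeps everything in
#'   memory.
#' @param write_volumes also write per-subject NIfTI volumes (slow, large).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_config(),
                            tracking = tracking_params(),
                            n_subjects = 5L,
                            threshold_fraction = 0.2,
                            ml_offset = 12.5,
                            seed = 1L,
                            out_dir = NULL,
                            write_volumes = FALSE) {
  if (n_subjects < 2L) stop("the cohort pipeline needs at least 2 subjects")
  structure(list(phantom = phantom, tracking = tracking,
                 n_subjects = as.integer(n_subjects),
                 threshold_fraction = threshold_fraction,
                 ml_offset = ml_offset, seed = as.integer(seed),
                 out_dir = out_dir, write_volumes = write_volumes),
            class = "pipeline_config")
}

#' Reconstruct one hemisphere's DTCp on a phantom
#'
#' Runs the two-seed strategy for the pathway of hemisphere `side`:
#' M1-seeded with the ipsilateral thalamus and contralateral cerebellum as
#' waypoints, then cerebellum-seeded with the contralateral M1 and thalamus
#' as waypoints, both with the contralateral-cerebrum and ipsilateral-
#' cerebellum exclusion masks and the CSF termination mask. The two raw maps
#' are combined and normalised with [reconstruct_dtcp()].
#'
#' @param phantom a [build_phantom()] result.
#' @param side `"L"` or `"R"` (pathway hemisphere).
#' @param params a [tracking_params()].
#' @return A combined-normalised [pico_map()]; `$log` holds both run logs.
#' @export
track_pathway <- function(phantom, side = c("L", "R"),
                          params = tracking_params()) {
  side <- match.arg(side)
  contra <- side_flip(side)
  mk <- phantom$masks
  excl <- list(mk[[paste0("exclusion_contralateral_cerebrum_", side)]],
               mk[[paste0("exclusion_ipsilateral_cerebellum_", side)]])
  m1 <- mk[[paste0("m1_", side)]]
  thal <- mk[[paste0("thalamus_", side)]]
  cereb <- mk[[paste0("cerebellum_", contra)]]
  run1 <- track_seed_region(m1, waypoints = list(cereb, thal),
                            exclusions = excl,
                            termination = mk$csf_termination,
                            field = phantom$field, params = params)
  run2 <- track_seed_region(cereb, waypoints = list(m1, thal),
                            exclusions = excl,
                            termination = mk$csf_termination,
                            field = phantom$field, params = params)
  dtcp <- reconstruct_dtcp(run1, run2)
  dtcp$log <- list(m1_seeded = run1$log, cerebellum_seeded = run2$log)
  dtcp
}

subject_row <- function(id, side, vim, dtcp, scp_volume) {
  data.frame(subject = id, hemisphere = if (side == "L") "left" else "right",
             ml = vim$centroid[1], ap = vim$centroid[2], si = vim$centroid[3],
             volume_mm3 = vim$roi_volume_mm3,
             volume_prethreshold_mm3 = vim$roi_volume_prethreshold_mm3,
             max_pico_intersection = vim$max_pico_in_intersection,
             max_raw_pico = dtcp$raw_max,
             scp_volume_contralateral_mm3 = scp_volume,
             stringsAsFactors = FALSE)
}

#' Run the full phantom-to-statistics pipeline
#'
#' Simulates a cohort, reconstructs both DTCps per subject (two seeded runs
#' per pathway), localises the connectivity-defined Vim in each hemisphere,
#' and computes the cohort statistics: mean (SD) centroid coordinates,
#' dispersion summaries against the cohort mean and the atlas-based target,
#' paired hemispheric position and Pitman-Morgan variance tests, the atlas
#' offset tests, ROI volume asymmetry, the confound regression screen,
#' principal directions of variance, and the SCP volume vs maximum PICo
#' correlations. Subjects whose DTCp reaches no thalamic voxel are excluded
#' and logged; the pipeline continues with the rest.
#'
#' Reported coordinates follow the stereotactic sign convention of the world
#' frame: negative ML is left of the mid-commissural plane, negative AP
#' posterior, negative SI inferior to the axial AC-PC plane.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `cdvim_report` with `centroids` (per
#'   subject-hemisphere data.frame), `stats`, `exclusions`, `atlas`,
#'   `truth` (per-subject generator truth) and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  set.seed(config$seed)
  pc <- config$phantom
  subjects <- sample_subject_params(pc, config$n_subjects)
  rows <- list()
  truths <- list()
  exclusions <- list()
  landmark_set <- NULL

  for (i in seq_along(subjects)) {
    ph <- build_phantom(pc, subject = subjects[[i]])
    landmark_set <- ph$landmarks
    truths[[i]] <- ph$truth
    for (side in c("L", "R")) {
      res <- tryCatch({
        dtcp <- track_pathway(ph, side, config$tracking)
        vim <- localise_vim(dtcp, ph$masks[[paste0("thalamus_", side)]],
                            fraction = config$threshold_fraction,
                            hemisphere = if (side == "L") "left" else "right")
        scp_vol <- integrate_jacobian(
          ph$jacobian, ph$masks[[paste0("scp_", side_flip(side))]], ph$grid)
        subject_row(i, side, vim, dtcp, scp_vol)
      }, cdvim_no_connectivity = function(e) {
        exclusions[[length(exclusions) + 1L]] <<-
          list(subject = i, hemisphere = side, reason = conditionMessage(e))
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
    if (!is.null(config$out_dir) && config$write_volumes)
      write_phantom(ph, file.path(config$out_dir,
                                  sprintf("subject_%03d", i)))
  }
  centroids <- do.call(rbind, rows)
  if (is.null(centroids))
    stop("every subject-hemisphere was excluded; nothing to summarise")
  atlas <- atlas_vim_coordinates(landmark_set, ml_offset = config$ml_offset)
  stats <- cohort_statistics(centroids, truths, atlas)
  manifest <- list(seed = config$seed, n_subjects = config$n_subjects,
                   samples_per_voxel = config$tracking$samples_per_voxel,
                   threshold_fraction = config$threshold_fraction,
                   n_rows = nrow(centroids),
                   n_excluded = length(exclusions))
  report <- structure(list(centroids = centroids, stats = stats,
                           atlas = atlas, truth = truths,
                           exclusions = exclusions, manifest = manifest),
                      class = "cdvim_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

try_stat <- function(expr) {
  tryCatch(expr, error = function(e) list(skipped = conditionMessage(e)))
}

#' Cohort statistics over a centroid table
#'
#' @param centroids data.frame as produced by [run_pipeline()] (columns
#'   `subject`, `hemisphere`, `ml`, `ap`, `si`, `volume_mm3`,
#'   `max_raw_pico`, `scp_volume_contralateral_mm3`).
#' @param truths optional list of per-subject generator truths supplying the
#'   confound table.
#' @param atlas optional [atlas_vim_coordinates()] result.
#' @return A nested list mirroring the reported tables: per-hemisphere
#'   summaries, dispersion, tests and principal directions.
#' @export
cohort_statistics <- function(centroids, truths = NULL, atlas = NULL) {
  out <- list()
  sides <- list(left = "left", right = "right")
  per_side <- lapply(sides, function(h) {
    sub <- centroids[centroids$hemisphere == h, , drop = FALSE]
    m <- as.matrix(sub[, c("ml", "ap", "si")])
    disp_tab <- displacement_table(m, colMeans(m))
    res <- list(
      n = nrow(sub),
      mean = colMeans(m),
      sd = apply(m, 2, stats::sd),
      dispersion = try_stat(cohort_dispersion(m)),
      principal_directions = try_stat(principal_directions(m)),
      median_volume_mm3 = stats::median(sub$volume_mm3),
      displacements = disp_tab)
    if (!is.null(atlas)) {
      ref <- if (h == "left") atlas$left else atlas$right
      res$dispersion_vs_atlas <- try_stat(cohort_dispersion(m, ref))
      res$atlas_offset <- try_stat(atlas_offset_test(m, ref))
    }
    if (!is.null(truths)) {
      conf <- confound_table(truths)[sub$subject, , drop = FALSE]
      res$confound_screen <- try_stat(confound_screen(conf, disp_tab))
    }
    res
  })
  out$per_hemisphere <- per_side

  both <- intersect(centroids$subject[centroids$hemisphere == "left"],
                    centroids$subject[centroids$hemisphere == "right"])
  if (length(both) >= 4L) {
    L <- as.matrix(centroids[centroids$hemisphere == "left" &
                               centroids$subject %in% both,
                             c("ml", "ap", "si")])
    R <- as.matrix(centroids[centroids$hemisphere == "right" &
                               centroids$subject %in% both,
                             c("ml", "ap", "si")])
    out$hemispheric_position <- try_stat(hemispheric_position_test(L, R))
    out$hemispheric_variance <- try_stat(hemispheric_variance_test(L, R))
    vl <- centroids$volume_mm3[centroids$hemisphere == "left" &
                                 centroids$subject %in% both]
    vr <- centroids$volume_mm3[centroids$hemisphere == "right" &
                                 centroids$subject %in% both]
    out$volume_asymmetry <- try_stat(volume_asymmetry_test(vl, vr))
    pico <- list(L = centroids$max_raw_pico[centroids$hemisphere == "left" &
                                              centroids$subject %in% both],
                 R = centroids$max_raw_pico[centroids$hemisphere == "right" &
                                              centroids$subject %in% both])
    scp <- list(R = centroids$scp_volume_contralateral_mm3[
                      centroids$hemisphere == "left" &
                        centroids$subject %in% both],
                L = centroids$scp_volume_contralateral_mm3[
                      centroids$hemisphere == "right" &
                        centroids$subject %in% both])
    out$scp_pico <- try_stat(scp_pico_correlation(scp, pico))
  }
  out
}

# per-subject displacement metrics against a reference coordinate
displacement_table <- function(m, reference) {
  d <- sweep(m, 2, as.numeric(reference))
  data.frame(d_ml = abs(d[, 1]), d_ap = abs(d[, 2]), d_si = abs(d[, 3]),
             ed = sqrt(rowSums(d^2)))
}

confound_table <- function(truths) {
  do.call(rbind, lapply(truths, function(tr)
    as.data.frame(tr$confounds, stringsAsFactors = FALSE)))
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$centroids, file.path(dir, "centroids.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(stats = report$stats, manifest = report$manifest,
         atlas = report$atlas[c("left", "right", "mcp", "acpc_length")],
         exclusions = report$exclusions),
    file.path(dir, "stats.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' @export
print.cdvim_report <- function(x, ...) {
  cat("cdvim_report:", x$manifest$n_subjects, "subjects,",
      nrow(x$centroids), "hemisphere results,",
      x$manifest$n_excluded, "excluded\n")
  for (h in names(x$stats$per_hemisphere)) {
    s <- x$stats$per_hemisphere[[h]]
    cat(sprintf("  %s: mean (ML %.2f, AP %.2f, SI %.2f) mm, median volume %.2f mm^3\n",
                h, s$mean[1], s$mean[2], s$mean[3], s$median_volume_mm3))
  }
  invisible(x)
}
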