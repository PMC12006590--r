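# Experiment orchestration: simulate -> segment -> extract -> reduce, from
# one serialisable config, with a checksummed output manifest.

#' Experiment configuration
#'
#' A fully serialisable description of one robustness experiment; a run is
#' reproducible from the config plus the package version alone.
#'
#' @param radionuclide `"tc99m"` or `"lu177"`.
#' @param out_dir output directory.
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param n_repeats Revolver repeat scans per insert (protocol: 4).
#' @param insert_sizes syringe sizes (ml) to simulate.
#' @param voxel voxel edge (mm).
#' @param voi spherical VOI series block (`d_min`, `d_max`, `step`, mm).
#' @param segmentation block: `method` (`"percent_max"` or
#'   `"adaptive_background"`) and `factor`.
#' @param scheme discretisation block (`n_bins`, `lower`, `upper`).
#' @param thresholds robustness block (`cov` %, `v_conv` ml, `tail_tol`).
#' @param uniform uniform-phantom block (`height`, `diameter` mm,
#'   `fill_volume_ml`, `activity_MBq` or NULL for the protocol default).
#' @param body Revolver body block (`axes` half-axes mm, `length` mm,
#'   `background_activity_MBq` or NULL for the protocol default).
#' @param background_region sphere (`center` mm, `radius` mm) used for
#'   adaptive segmentation background.
#' @param ratios 7 syringe:background ratios.
#' @param write_images write NIfTI images/masks alongside the tables?
#' @return An object of class `run_config`.
#' @export
run_config <- function(radionuclide = c("tc99m", "lu177"), out_dir,
                       seed = 1L, n_repeats = 4L,
                       insert_sizes = c(2.5, 5, 10), voxel = 1.95,
                       voi = list(d_min = 10, d_max = 122, step = 4),
                       segmentation = list(method = "percent_max",
                                           factor = 0.40),
                       scheme = list(n_bins = 64, lower = 0, upper = 20),
                       thresholds = list(cov = 10, v_conv = 25,
                                         tail_tol = 0.10),
                       uniform = list(height = 200, diameter = 220,
                                      fill_volume_ml = 6244,
                                      activity_MBq = NULL),
                       body = list(axes = c(150, 110), length = 180,
                                   background_activity_MBq = NULL),
                       background_region = list(center = c(80, 0, 0),
                                                radius = 15),
                       ratios = c(16, 4, 8, 4, 8, 4, 8),
                       write_images = FALSE) {
  radionuclide <- match.arg(radionuclide)
  structure(
    list(radionuclide = radionuclide, out_dir = out_dir,
         seed = as.integer(seed), n_repeats = as.integer(n_repeats),
         insert_sizes = insert_sizes, voxel = voxel, voi = voi,
         segmentation = segmentation, scheme = scheme,
         thresholds = thresholds, uniform = uniform, body = body,
         background_region = background_region, ratios = ratios,
         write_images = isTRUE(write_images)),
    class = "run_config"
  )
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file.
#' @return [run_config()] for the reader; `path` invisibly for the writer.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' @param config a [run_config()].
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' Run the full robustness experiment
#'
#' Executes both arms for one radionuclide: the uniform-phantom scan with
#' the spherical VOI series (volume-dependency screen) and the Revolver
#' repeat series for each insert size (repeatability screen), then the
#' combined feature reduction. Writes `uniform_features.csv`,
#' `dependency.csv`, `revolver_features.csv`, `cov.csv`, `reduction.json`
#' and a checksummed `manifest.json` to the output directory. Re-running
#' with the same config produces bit-identical outputs.
#'
#' @param config a [run_config()].
#' @return the report bundle (tables, reduction, manifest), invisibly.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  prof <- radionuclide_profile(config$radionuclide)
  scheme <- discretisation_scheme(config$scheme$n_bins, config$scheme$lower,
                                  config$scheme$upper)
  model <- imaging_model(config$radionuclide, voxel_size = config$voxel,
                         seed = config$seed)
  files <- character()
  put <- function(df, name) {
    p <- file.path(config$out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
    p
  }

  ## --- uniform phantom arm: volume dependency -------------------------
  geom_u <- phantom_geometry("uniform_cylinder",
                             cylinder_height = config$uniform$height,
                             cylinder_diameter = config$uniform$diameter,
                             fill_volume_ml = config$uniform$fill_volume_ml)
  act_u <- activity_spec(config$uniform$activity_MBq %||%
                           prof$uniform_activity_MBq,
                         fill_volume_ml = config$uniform$fill_volume_ml)
  img_u <- simulate_scan(build_uniform_phantom(geom_u, act_u, config$voxel),
                         model, act_u)
  r_cyl <- geom_u$cylinder_diameter / 2
  h_fill <- min(geom_u$cylinder_height,
                act_u$fill_volume_ml * 1000 / (pi * r_cyl^2))
  interior <- function(p) {
    p[1]^2 + p[2]^2 <= r_cyl^2 && abs(p[3]) <= h_fill / 2
  }
  series <- spherical_voi_series(c(0, 0, 0), img_u,
                                 d_min = config$voi$d_min,
                                 d_max = config$voi$d_max,
                                 step = config$voi$step,
                                 interior = interior)
  message(sprintf("[uniform] extracting %d VOIs", length(series)))
  uni_tbl <- extract_series(img_u, series, scheme)
  put(uni_tbl, "uniform_features.csv")
  curves <- volume_curves(uni_tbl)
  dep <- lapply(curves, classify_dependency,
                v_conv = config$thresholds$v_conv,
                tail_tol = config$thresholds$tail_tol)
  dep_tbl <- data.frame(
    feature = names(dep),
    label = vapply(dep, `[[`, character(1), "label"),
    convergence_volume_ml = vapply(dep, `[[`, numeric(1),
                                   "convergence_volume"),
    row.names = NULL
  )
  put(dep_tbl, "dependency.csv")

  ## --- Revolver arm: repeatability ------------------------------------
  rev_rows <- list()
  for (si in seq_along(config$insert_sizes)) {
    size <- config$insert_sizes[si]
    geom_r <- phantom_geometry("revolver_body", syringe_volume_ml = size,
                               body_axes = config$body$axes,
                               body_length = config$body$length)
    act_r <- revolver_activity_spec(
      geom_r,
      config$body$background_activity_MBq %||% prof$background_activity_MBq,
      ratios = config$ratios)
    model_r <- model
    model_r$seed <- config$seed + 100L * si
    message(sprintf("[revolver %g ml] %d repeats", size, config$n_repeats))
    scans <- generate_repeat_series(geom_r, act_r, model_r,
                                    n_repeats = config$n_repeats,
                                    voxel = config$voxel)
    for (k in seq_along(scans)) {
      img <- scans[[k]]
      params <- if (config$segmentation$method == "adaptive_background") {
        bgm <- rasterize_sphere(config$background_region$center,
                                2 * config$background_region$radius, img)
        segmentation_params("adaptive_background",
                            factor = config$segmentation$factor,
                            background_region = bgm)
      } else {
        segmentation_params("percent_max",
                            factor = config$segmentation$factor)
      }
      mask <- segment_voi(img, params, geom_r$insert_center)
      fv <- extract_features(img, mask, scheme)
      rev_rows[[length(rev_rows) + 1L]] <- cbind(
        data.frame(insert = sprintf("%g ml", size), scan = k,
                   seg_volume_ml = mask$volume_ml,
                   threshold = attr(mask, "threshold")),
        as.data.frame(as.list(fv), check.names = FALSE))
      if (config$write_images) {
        write_voxel_nifti(img, file.path(config$out_dir,
          sprintf("revolver_%gml_scan%d.nii.gz", size, k)),
          sidecar = list(radionuclide = config$radionuclide,
                         seed = model_r$seed + k - 1L))
        write_voxel_nifti(mask, file.path(config$out_dir,
          sprintf("revolver_%gml_scan%d_mask.nii.gz", size, k)),
          sidecar = NULL)
      }
    }
  }
  rev_tbl <- do.call(rbind, rev_rows)
  put(rev_tbl, "revolver_features.csv")
  flags <- repeatability_flags(
    rev_tbl[, !names(rev_tbl) %in% c("seg_volume_ml", "threshold")],
    threshold = config$thresholds$cov)
  cov_tbl <- cbind(feature = rownames(flags$cov), flags$cov)
  put(cov_tbl, "cov.csv")

  ## --- reduction -------------------------------------------------------
  labels <- stats::setNames(dep_tbl$label, dep_tbl$feature)
  red <- reduce_features(feature_names(), dependency = labels,
                         cov_fail = flags,
                         keep_exceptions = keep_exceptions()$volume_dependency_exempt)
  red_path <- file.path(config$out_dir, "reduction.json")
  jsonlite::write_json(
    list(radionuclide = config$radionuclide,
         retained = red$retained,
         excluded_by = as.list(red$excluded_by),
         unevaluable = red$unevaluable),
    red_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, red_path)

  ## --- manifest --------------------------------------------------------
  manifest <- list(
    config = unclass(config),
    package_version = as.character(utils::packageVersion("spectrad")),
    files = lapply(stats::setNames(files, basename(files)), function(f)
      unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(uniform_features = uni_tbl, dependency = dep_tbl,
                 revolver_features = rev_tbl, cov = cov_tbl,
                 reduction = red, manifest = manifest))
}
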