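# End-to-end orchestration: simulate stained sections per defect, segment,
# measure, assemble the per-defect study table, fit the mixed model and the
# Scheffe pairwise comparisons, and write results plus a reproducibility
# manifest. Every stochastic stage draws its seed deterministically from
# the run seed, so a rerun with the same config is numerically identical.

#' Default pipeline configuration
#'
#' The stated in-vivo design at desk scale: 5 animals, 6 defects per
#' animal, the three materials balanced within each animal, one animal
#' excluded from analysis. Scene size and particle count are kept modest so
#' a full run stays interactive; both can be raised in the config.
#'
#' @return Nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    scale_um_per_px = 10,
    outcome = "bmc_pct",
    scene = list(size = 320, n_particles = 4,
                 particle_um_range = c(250, 1000),
                 noise_sd = 15, rim_px = 3),
    study = list(
      n_animals = 5L,
      defects_per_animal = 6L,
      groups = c("HAN", "HA820", "HA1200"),
      contact_mean = c(HAN = 0.55, HA820 = 0.50, HA1200 = 0.25),
      contact_sd_animal = 0.05,
      contact_sd_defect = 0.08,
      exclude_animals = "A05"))
}

#' Validate a pipeline configuration
#'
#' Checks structural validity and that every referenced file path exists,
#' before any computation is started.
#'
#' @param config list or path to a YAML file.
#' @return The normalized config list, invisibly on success; errors
#'   otherwise.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  base <- default_pipeline_config()
  config <- utils::modifyList(base, config)
  if (!is.numeric(config$seed)) stop("seed must be an integer")
  st <- config$study
  if (st$defects_per_animal %% length(st$groups) != 0)
    stop("defects_per_animal must be a multiple of the number of groups")
  cm <- unlist(st$contact_mean)
  if (!all(st$groups %in% names(cm)))
    stop("contact_mean must name every group")
  # any externally referenced inputs must exist up front
  for (p in unlist(config$images))
    if (!file.exists(p)) stop("referenced image path does not exist: ", p)
  invisible(config)
}

#' Run the full quantification pipeline
#'
#' Simulates one stained section per defect (per-group contact-fraction
#' means, an animal-level shift, and defect-level variation), segments each
#' image with the configured palette, measures the histomorphometric
#' parameters, assembles the study table, fits the random-intercept model
#' on the configured outcome and the Scheffe pairwise comparisons, and
#' writes `measurements.csv`, `fit.json` and `manifest.json` into the run
#' directory.
#'
#' @param config list or YAML path; see [default_pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param verbose log progress to stderr.
#' @return Invisibly, a list with `measurements` (data frame), `fit`
#'   (`ri_fit`), `scheffe`, `bookkeeping` and `manifest`.
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  cfg <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  note <- function(...) if (verbose) message(sprintf(...))
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    st <- cfg$study
    k <- length(st$groups)
    reps <- st$defects_per_animal %/% k
    animals <- sprintf("A%02d", seq_len(st$n_animals))
    excl <- as.character(st$exclude_animals)

    # ---- bookkeeping (before any simulation) ----
    planned <- expand.grid(rep = seq_len(reps), group = st$groups,
                           animal = animals, stringsAsFactors = FALSE)
    bookkeeping <- list(
      n_animals_planned = st$n_animals,
      n_defects_planned = nrow(planned),
      per_condition_planned = as.vector(table(planned$group))[1],
      excluded_animals = excl,
      n_animals_analyzed = sum(!animals %in% excl),
      n_defects_analyzed = sum(!planned$animal %in% excl),
      per_condition_analyzed =
        as.vector(table(planned$group[!planned$animal %in% excl]))[1])

    # ---- simulate + segment + measure ----
    stage <- "simulate/segment/measure"
    keep <- planned[!planned$animal %in% excl, , drop = FALSE]
    base_seed <- as.integer(cfg$seed)
    set.seed(base_seed)
    animal_shift <- setNames(rnorm(st$n_animals, 0, st$contact_sd_animal),
                             animals)
    cm <- unlist(st$contact_mean)
    rows <- vector("list", nrow(keep))
    for (i in seq_len(nrow(keep))) {
      an <- keep$animal[i]; gr <- keep$group[i]
      defect_seed <- (base_seed * 1000L + i) %% .Machine$integer.max
      set.seed(defect_seed)
      fr <- pmin(pmax(rnorm(cfg$scene$n_particles,
                            cm[[gr]] + animal_shift[[an]],
                            st$contact_sd_defect), 0.02), 0.98)
      sp <- scene_spec(size = cfg$scene$size,
                       scale_um_per_px = cfg$scale_um_per_px,
                       n_particles = cfg$scene$n_particles,
                       particle_um_range = cfg$scene$particle_um_range,
                       contact_fraction = fr,
                       noise_sd = cfg$scene$noise_sd,
                       rim_px = cfg$scene$rim_px,
                       seed = defect_seed)
      scene <- make_histology_scene(sp)
      mask <- segment_colors(scene$image, roi = scene$truth$roi1)
      res <- measure_defect(mask, scene$truth$roi1_mask,
                            scene$truth$roi2_mask,
                            scale_um_per_px = cfg$scale_um_per_px,
                            defect_id = sprintf("%s_%s_%d", an, gr, keep$rep[i]))
      df <- as.data.frame(res)
      df$animal <- an; df$group <- gr
      df$true_bmc_pct <- scene$truth$bmc_pct
      rows[[i]] <- df
      note("measured defect %d/%d (%s %s): BMC %.1f%%",
           i, nrow(keep), an, gr, df$bmc_pct)
    }
    measurements <- do.call(rbind, rows)

    stage <- "tabulate"
    meas_path <- file.path(out_dir, "measurements.csv")
    write.csv(measurements, meas_path, row.names = FALSE)

    # ---- group comparison ----
    stage <- "compare"
    measurements$group <- factor(measurements$group, levels = st$groups)
    fit <- fit_random_intercept(measurements, outcome = cfg$outcome)
    sch <- scheffe_pairwise(fit)
    fit_report <- list(
      outcome = cfg$outcome,
      group_means = as.list(fit$group_means),
      sigma2_animal = fit$sigma2_animal,
      sigma2_resid = fit$sigma2_resid,
      f_overall = fit$f_overall,
      df = c(length(st$groups) - 1, fit$df_error),
      p_overall = fit$p_overall,
      scheffe = sch)
    jsonlite::write_json(fit_report, file.path(out_dir, "fit.json"),
                         auto_unbox = TRUE, digits = NA)

    # ---- manifest ----
    stage <- "manifest"
    cfg_tmp <- tempfile(fileext = ".yaml")
    yaml::write_yaml(cfg, cfg_tmp)
    cfg_hash <- unname(tools::md5sum(cfg_tmp))
    unlink(cfg_tmp)
    manifest <- list(
      config_md5 = cfg_hash,
      seed = base_seed,
      package = "osteoquant",
      package_version = as.character(utils::packageVersion("osteoquant")),
      bookkeeping = bookkeeping)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    invisible(list(measurements = measurements, fit = fit, scheffe = sch,
                   bookkeeping = bookkeeping, manifest = manifest))
  }, error = on_fail)
}
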