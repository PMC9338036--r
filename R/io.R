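# Readers, writers, configuration and the end-to-end pipeline
# (simulate images -> segment -> assemble species table -> analyse ->
# partition variance).

canonical_species_columns <- function() {
  c("species", "family", "lifeform", "height_cm", "latitude", "longitude",
    "elevation", "temp_warmest_quarter", "annual_precip", "dcwl")
}

#' Read and validate a species-site table
#'
#' Accepts the CSV written by [write_study()] as well as externally supplied
#' tables (e.g. a deposited supplementary data table) via `column_map`,
#' which renames file columns to the canonical schema.  Rows failing range
#' validation (DCWL outside `[0, 1]`, latitude outside `[-90, 90]`,
#' longitude outside `[-180, 180]`, non-positive height, unparsable
#' numbers) are dropped with a row-numbered warning.
#'
#' @param path CSV file with a header row.
#' @param column_map Optional named character vector
#'   `c(canonical = "file_column", ...)`.
#' @param required Canonical columns that must be present after mapping.
#' @return Validated `data.frame` in canonical column order.
#' @export
read_species_table <- function(path, column_map = NULL,
                               required = c("species", "lifeform", "dcwl")) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop(sprintf("empty table: %s", path), call. = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) {
        stop(sprintf("mapped column '%s' (for '%s') missing from %s",
                     src, canon, path), call. = FALSE)
      }
      names(df)[names(df) == src] <- canon
    }
  }
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }

  numeric_cols <- intersect(
    c("height_cm", "latitude", "longitude", "elevation",
      "temp_warmest_quarter", "annual_precip", "dcwl"), names(df))
  for (cc in numeric_cols) df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  if ("lifeform" %in% names(df)) {
    df$lifeform <- tolower(trimws(df$lifeform))
    df$lifeform[df$lifeform %in% c("dwarf shrub", "dwarf_shrub")] <- "shrub"
  }

  bad <- rep(FALSE, nrow(df))
  flag <- function(cond) bad | (!is.na(cond) & cond)
  for (cc in numeric_cols) bad <- bad | is.na(df[[cc]])
  if ("dcwl" %in% names(df)) bad <- flag(df$dcwl < 0 | df$dcwl > 1)
  if ("latitude" %in% names(df)) bad <- flag(abs(df$latitude) > 90)
  if ("longitude" %in% names(df)) bad <- flag(abs(df$longitude) > 180)
  if ("height_cm" %in% names(df)) bad <- flag(df$height_cm <= 0)
  if ("lifeform" %in% names(df)) {
    bad <- bad | !df$lifeform %in% c("tree", "shrub", "herb")
  }
  if (any(bad)) {
    warning(sprintf("dropped %d invalid row(s): %s", sum(bad),
                    paste(utils::head(which(bad), 20), collapse = ", ")),
            call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no valid rows after validation", call. = FALSE)
  ord <- c(intersect(canonical_species_columns(), names(df)),
           setdiff(names(df), canonical_species_columns()))
  rownames(df) <- NULL
  df[, ord, drop = FALSE]
}

#' Write a generated study to CSV
#'
#' @param study Result of [generate_study()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths of the species and occurrence CSVs.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- file.path(dir, "species.csv")
  oc <- file.path(dir, "occurrences.csv")
  utils::write.csv(study$species, sp, row.names = FALSE)
  utils::write.csv(study$occurrences, oc, row.names = FALSE)
  invisible(c(species = sp, occurrences = oc))
}

#' Headline descriptive statistics of a species-site study
#'
#' One pass over the table: dataset counts, lifeform composition, the
#' trees/shrubs-vs-herbs comparison, the number of families with more than
#' `min_species` species, correlations of DCWL with the gradient variables,
#' and the minimum DCWL among trees taller than 10 m.
#'
#' @param species Species table (canonical schema).
#' @param occurrences Optional occurrence table.
#' @param min_species Family-size threshold (strict), default 25.
#' @return Named list of summary statistics.
#' @export
summarize_study <- function(species, occurrences = NULL, min_species = 25) {
  comp <- lifeform_comparison(species)
  tall_trees <- species[species$lifeform == "tree" & species$height_cm > 1000, ]
  fam_n <- table(species$family)
  cors <- lapply(intersect(c("temp_warmest_quarter", "elevation", "latitude"),
                           names(species)),
                 function(v) {
                   ct <- pearson_correlation(species[[v]], species$dcwl)
                   list(variable = v, r = ct$r, p_value = ct$p_value)
                 })
  list(
    n_species = length(unique(species$species)),
    n_sites = if ("site_id" %in% names(species))
      length(unique(species$site_id)) else NA_integer_,
    n_families = length(fam_n),
    n_occurrences = if (!is.null(occurrences)) nrow(occurrences) else NA_integer_,
    lifeform_pct = as.list(round(100 * prop.table(table(species$lifeform)), 4)),
    trees_shrubs_mean = comp$mean_a, trees_shrubs_sd = comp$sd_a,
    herbs_mean = comp$mean_b, herbs_sd = comp$sd_b,
    welch_t = comp$t_stat, welch_df = comp$df, welch_p = comp$p_value,
    families_over_threshold = sum(fam_n > min_species),
    n_trees_over_10m = nrow(tall_trees),
    min_dcwl_trees_over_10m = if (nrow(tall_trees)) min(tall_trees$dcwl) else NA_real_,
    correlations = cors
  )
}

#' Default pipeline configuration
#'
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param n_demo_images Synthetic micrographs to simulate and segment.
#' @param image_fractions Lignified wall fractions of the demo images.
#' @param image_noise_sd Noise SD of the demo images.
#' @param study_params A [study_params()] list.
#' @param bin_vars Gradient variables to bin and fit.
#' @param loess_span,loess_degree Loess settings for the gradient curves.
#' @param trim_pct Lower/upper DCWL percentile bounds of the trimmed view.
#' @param rda_vars Explanatory variables of the variance partitioning.
#' @param permutations Permutations of the significance tests.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            n_demo_images = 3,
                            image_fractions = c(0.2, 0.5, 0.8),
                            image_noise_sd = 8,
                            study_params = lignoscope::study_params(),
                            bin_vars = c("temp_warmest_quarter", "elevation",
                                         "latitude", "height_cm"),
                            loess_span = 0.75, loess_degree = 2,
                            trim_pct = c(2, 98),
                            rda_vars = c("elevation", "latitude",
                                         "temp_warmest_quarter", "height_cm"),
                            permutations = 999) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()];
#' `study_params` is a nested mapping passed to [study_params()].  Unknown
#' keys are rejected.
#'
#' @param path YAML file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(raw$study_params)) {
    sp_known <- names(formals(study_params))
    sp_unknown <- setdiff(names(raw$study_params), sp_known)
    if (length(sp_unknown)) {
      stop(sprintf("unknown study_params key(s): %s",
                   paste(sp_unknown, collapse = ", ")), call. = FALSE)
    }
    raw$study_params <- do.call(study_params, raw$study_params)
  }
  do.call(pipeline_config, raw)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  # version and no compression so the serialized bytes are stable
  saveRDS(unclass(config), tmp, version = 3, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Simulates and segments demonstration micrographs, generates the synthetic
#' species-site study, computes the gradient and lifeform statistics, runs
#' the variance partitioning, and writes all intermediate CSVs plus a
#' `summary.json` and a `run_manifest.json` (config hash, seed, file list)
#' to `out_dir`.  Re-running with the same configuration reproduces
#' byte-identical tables and summary.
#'
#' @param config A `pipeline_config` (or path to a YAML file).
#' @param out_dir Output directory.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- stage_seeds(config$seed)
  say <- function(...) if (!quiet) message(sprintf(...))

  say("stage 1/4: simulating and segmenting %d micrograph(s)", config$n_demo_images)
  img_rows <- list()
  if (config$n_demo_images > 0) {
    fr <- rep_len(config$image_fractions, config$n_demo_images)
    for (i in seq_len(config$n_demo_images)) {
      spec <- micrograph_spec(width_px = 160, height_px = 160,
                              cell_types = default_cell_types(scale = 0.45),
                              lignified_wall_fraction = fr[i],
                              noise_sd = config$image_noise_sd,
                              seed = seeds[["image"]] + i)
      m <- generate_micrograph(spec)
      rec <- dcwl_from_image(m, image_id = sprintf("demo_%02d", i))
      img_rows[[i]] <- data.frame(image_id = rec$image_id,
                                  true_dcwl = m$true_dcwl,
                                  red_px = rec$areas$red_px,
                                  blue_px = rec$areas$blue_px,
                                  white_px = rec$areas$white_px,
                                  unclassified_px = rec$areas$unclassified_px,
                                  dcwl = rec$dcwl, stringsAsFactors = FALSE)
    }
    utils::write.csv(do.call(rbind, img_rows),
                     file.path(out_dir, "segmentation.csv"), row.names = FALSE)
  }

  say("stage 2/4: generating species-site study")
  study <- generate_study(config$study_params, seed = seeds[["study"]])
  write_study(study, out_dir)

  say("stage 3/4: gradient and lifeform statistics")
  curves <- lapply(config$bin_vars, function(v) {
    gc <- gradient_curve(study$species, v, span = config$loess_span,
                         degree = config$loess_degree)
    utils::write.csv(as.data.frame(gc$bins),
                     file.path(out_dir, sprintf("bins_%s.csv", v)),
                     row.names = FALSE)
    gc
  })
  names(curves) <- config$bin_vars
  trimmed <- percentile_trim(study$species$dcwl, config$trim_pct[1],
                             config$trim_pct[2], data = study$species)
  fam <- family_summary(study$species)
  utils::write.csv(fam, file.path(out_dir, "family_summary.csv"),
                   row.names = FALSE)
  summary <- summarize_study(study$species, study$occurrences)

  say("stage 4/4: variance partitioning (%d permutations)", config$permutations)
  part <- variance_partition(study$species$dcwl,
                             study$species[, config$rda_vars, drop = FALSE],
                             permutations = config$permutations,
                             seed = seeds[["rda"]])
  utils::write.csv(as.data.frame(part),
                   file.path(out_dir, "variance_partition.csv"),
                   row.names = FALSE)

  summary$variance_partition <- list(
    total_explained = attr(part, "total_explained"),
    shared_total = attr(part, "shared_total"),
    variables = as.data.frame(part))
  summary$trim_bounds <- as.numeric(attr(trimmed, "bounds"))
  summary$seed <- as.integer(config$seed)
  summary$config_hash <- config_hash(config)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")

  manifest <- list(seed = as.integer(config$seed),
                   config_hash = summary$config_hash,
                   stage_seeds = as.list(seeds),
                   package_version = as.character(utils::packageVersion("lignoscope")),
                   files = sort(list.files(out_dir)))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(summary)
}
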