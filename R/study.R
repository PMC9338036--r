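# Synthetic species-site study generator.  Emulates the statistical
# structure of a global collection network: 198 sites from 40 deg S to
# 80 deg N and sea level to ~6150 m, 1770 woody dicot species dominated by
# herbs (78.7%) over trees (16.9%) and shrubs (4.4%), one sampled individual
# per species, and up to ten occurrence records per species with climate
# attributes attached.  DCWL is generated from a logit-normal model whose
# mean increases with the temperature of the warmest quarter, with a high
# tree/shrub baseline (upright self-supporting stems are always lignified)
# and a large herb variance (herb stems range from nearly un-lignified to
# almost fully lignified).

# A fixed pool of angiosperm family names; sampled with Zipf-like weights so
# a few large families dominate and a "families with more than 25 species"
# filter is meaningful.
family_pool <- function(n_families) {
  known <- c("Asteraceae", "Brassicaceae", "Caryophyllaceae", "Saxifragaceae",
             "Rosaceae", "Fabaceae", "Lamiaceae", "Ranunculaceae", "Apiaceae",
             "Ericaceae", "Plantaginaceae", "Boraginaceae", "Polygonaceae",
             "Primulaceae", "Gentianaceae", "Salicaceae", "Betulaceae",
             "Fagaceae", "Euphorbiaceae", "Malvaceae", "Rubiaceae",
             "Onagraceae", "Crassulaceae", "Campanulaceae", "Violaceae",
             "Amaranthaceae", "Geraniaceae", "Oleaceae", "Solanaceae",
             "Sapindaceae")
  if (n_families <= length(known)) return(known[seq_len(n_families)])
  c(known, sprintf("family_%03d", seq_len(n_families - length(known))))
}

#' Parameters of the synthetic species-site study
#'
#' Defaults reproduce the scale and composition of the emulated collection
#' network; the DCWL model coefficients are calibrated so that the expected
#' tree/shrub and herb group means are about 0.81 and 0.50 with standard
#' deviations near 0.17 and 0.31.
#'
#' @param n_species,n_sites Numbers of species and sampling sites.
#' @param lifeform_props Named proportions for `herb`, `tree`, `shrub`
#'   (must sum to 1).
#' @param lat_range Site latitude range in degrees.
#' @param max_elevation_m Upper bound of site elevations (metres).
#' @param elevation_shape Exponent of the `U^shape` elevation draw; larger
#'   values concentrate sites at low elevation while keeping the maximum
#'   near `max_elevation_m`.
#' @param temp_sea_level Temperature of the warmest quarter at sea level on
#'   the equator (deg C).
#' @param lapse_rate Temperature decrease per metre of elevation (deg C/m).
#' @param lat_coeff Temperature decrease per degree of absolute latitude.
#' @param temp_sd Site-level temperature noise SD (deg C).
#' @param precip_meanlog,precip_lat_slope,precip_sdlog Log-normal annual
#'   precipitation: `meanlog = precip_meanlog - precip_lat_slope * |lat|`.
#' @param dcwl_beta_temp Slope of the DCWL logit mean per deg C.
#' @param dcwl_alpha Named intercepts of the logit mean per lifeform.
#' @param dcwl_sigma Named SDs of the logit-scale noise per lifeform.
#' @param tree_temp_cutoff,shrub_temp_cutoff Minimum warmest-quarter
#'   temperature (deg C) at which trees/shrubs occur; colder sites hold only
#'   herbs, emulating the thermal limit of upright woody growth.
#' @param height_meanlog,height_sdlog,height_range Named per-lifeform
#'   log-normal height parameters (cm) and plausibility clamps
#'   (herbs 2-200, shrubs 30-500, trees 200-4000 cm).
#' @param n_families Size of the family pool.
#' @param family_zipf Zipf exponent of the family size distribution.
#' @param max_occurrences Hard cap on occurrence records per species.
#' @param occ_count_weights Sampling weights for 1..`max_occurrences`
#'   occurrences per species (mean about 7.4, so ~13,000 records at the
#'   default species count).
#' @param occ_coord_sd,occ_elev_sd SD of the occurrence scatter around the
#'   home site (degrees; metres).
#' @return A `study_params` list.
#' @export
study_params <- function(n_species = 1770,
                         n_sites = 198,
                         lifeform_props = c(herb = 0.787, tree = 0.169, shrub = 0.044),
                         lat_range = c(-40, 80),
                         max_elevation_m = 6150,
                         elevation_shape = 2.5,
                         temp_sea_level = 28,
                         lapse_rate = 0.0055,
                         lat_coeff = 0.25,
                         temp_sd = 1,
                         precip_meanlog = log(1500),
                         precip_lat_slope = 0.012,
                         precip_sdlog = 0.5,
                         dcwl_beta_temp = 0.12,
                         dcwl_alpha = c(herb = -1.25, tree = -0.15, shrub = -0.15),
                         dcwl_sigma = c(herb = 1.45, tree = 1.0, shrub = 1.0),
                         tree_temp_cutoff = 6,
                         shrub_temp_cutoff = 5,
                         height_meanlog = c(herb = log(20), tree = log(900), shrub = log(120)),
                         height_sdlog = c(herb = 0.9, tree = 0.6, shrub = 0.6),
                         height_range = list(herb = c(2, 200), tree = c(200, 4000),
                                             shrub = c(30, 500)),
                         n_families = 118,
                         family_zipf = 0.8,
                         max_occurrences = 10,
                         occ_count_weights = c(1, 1, 2, 3, 4, 6, 8, 10, 12, 15),
                         occ_coord_sd = 3,
                         occ_elev_sd = 300) {
  p <- as.list(environment())
  if (abs(sum(p$lifeform_props) - 1) > 1e-8) {
    stop("lifeform_props must sum to 1", call. = FALSE)
  }
  if (!all(c("herb", "tree", "shrub") %in% names(p$lifeform_props))) {
    stop("lifeform_props must name 'herb', 'tree' and 'shrub'", call. = FALSE)
  }
  if (length(p$occ_count_weights) != p$max_occurrences) {
    stop("occ_count_weights must have length max_occurrences", call. = FALSE)
  }
  structure(p, class = "study_params")
}

#' Synthetic climate attributes for a location
#'
#' A deterministic lapse-rate model with optional site noise, standing in
#' for gridded bioclimatic layers: temperature of the warmest quarter
#' decreases linearly with elevation and absolute latitude, and annual
#' precipitation is log-normal with a latitude-dependent mean.
#'
#' @param latitude,elevation Vectors of degrees and metres (recycled).
#' @param params A [study_params()] list.
#' @param noise If `FALSE`, return the deterministic component only.
#' @return `data.frame` with `temp_warmest_quarter` (deg C) and
#'   `annual_precip` (mm/yr).
#' @examples
#' climate_model(0, 0, noise = FALSE)$temp_warmest_quarter  # 28 at origin
#' @export
climate_model <- function(latitude, elevation, params = study_params(),
                          noise = TRUE) {
  n <- max(length(latitude), length(elevation))
  latitude <- rep_len(latitude, n)
  elevation <- rep_len(elevation, n)
  stopifnot(all(abs(latitude) <= 90), all(elevation >= 0))
  temp <- params$temp_sea_level - params$lapse_rate * elevation -
    params$lat_coeff * abs(latitude)
  meanlog <- params$precip_meanlog - params$precip_lat_slope * abs(latitude)
  if (noise) {
    temp <- temp + stats::rnorm(n, 0, params$temp_sd)
    precip <- stats::rlnorm(n, meanlog, params$precip_sdlog)
  } else {
    precip <- exp(meanlog)
  }
  data.frame(temp_warmest_quarter = temp, annual_precip = precip)
}

generate_sites <- function(params) {
  lat <- stats::runif(params$n_sites, params$lat_range[1], params$lat_range[2])
  lon <- stats::runif(params$n_sites, -180, 180)
  elev <- params$max_elevation_m *
    stats::runif(params$n_sites)^params$elevation_shape
  clim <- climate_model(lat, elev, params)
  data.frame(site_id = sprintf("site_%03d", seq_len(params$n_sites)),
             latitude = lat, longitude = lon, elevation = elev,
             temp_warmest_quarter = clim$temp_warmest_quarter,
             annual_precip = clim$annual_precip,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic species-site study with known structure
#'
#' Draws sites, assigns each species a lifeform, a home site (trees and
#' shrubs only at sites warmer than their thermal cutoffs), a family from a
#' Zipf-weighted pool, a log-normal plant height, a logit-normal DCWL whose
#' mean rises with the site's warmest-quarter temperature, and up to
#' `max_occurrences` occurrence records scattered around the home site.
#'
#' @param params A [study_params()] list.
#' @param seed Integer seed; identical `(params, seed)` yield identical
#'   tables.
#' @return A list with two data frames:
#'   \describe{
#'     \item{species}{one row per species: `species`, `family`, `lifeform`,
#'       `height_cm`, `site_id`, `latitude`, `longitude`, `elevation`,
#'       `temp_warmest_quarter`, `annual_precip`, `dcwl`.}
#'     \item{occurrences}{`species`, `latitude`, `longitude`, `elevation`,
#'       `temp_warmest_quarter`, `annual_precip`.}
#'   }
#' @examples
#' study <- generate_study(study_params(n_species = 200, n_sites = 40), seed = 7)
#' table(study$species$lifeform)
#' @export
generate_study <- function(params = study_params(), seed = 1L) {
  stopifnot(inherits(params, "study_params"))
  with_seed(seed, {
    sites <- generate_sites(params)

    lf_names <- c("herb", "tree", "shrub")
    lifeform <- sample(lf_names, params$n_species, replace = TRUE,
                       prob = params$lifeform_props[lf_names])

    cutoffs <- c(herb = -Inf, tree = params$tree_temp_cutoff,
                 shrub = params$shrub_temp_cutoff)
    site_idx <- integer(params$n_species)
    for (lf in lf_names) {
      ok <- which(sites$temp_warmest_quarter >= cutoffs[lf])
      if (length(ok) == 0L) {
        stop(sprintf("no site warm enough for lifeform '%s'", lf), call. = FALSE)
      }
      sel <- lifeform == lf
      site_idx[sel] <- sample(ok, sum(sel), replace = TRUE)
    }

    fams <- family_pool(params$n_families)
    fam_w <- seq_along(fams)^(-params$family_zipf)
    family <- sample(fams, params$n_species, replace = TRUE, prob = fam_w)

    height <- stats::rlnorm(params$n_species,
                            params$height_meanlog[lifeform],
                            params$height_sdlog[lifeform])
    for (lf in lf_names) {
      rng <- params$height_range[[lf]]
      sel <- lifeform == lf
      height[sel] <- pmin(pmax(height[sel], rng[1]), rng[2])
    }

    temp <- sites$temp_warmest_quarter[site_idx]
    mu_logit <- params$dcwl_alpha[lifeform] + params$dcwl_beta_temp * temp
    dcwl <- stats::plogis(stats::rnorm(params$n_species, mu_logit,
                                       params$dcwl_sigma[lifeform]))

    species <- data.frame(
      species = sprintf("species_%04d", seq_len(params$n_species)),
      family = family, lifeform = lifeform, height_cm = height,
      site_id = sites$site_id[site_idx],
      latitude = sites$latitude[site_idx],
      longitude = sites$longitude[site_idx],
      elevation = sites$elevation[site_idx],
      temp_warmest_quarter = temp,
      annual_precip = sites$annual_precip[site_idx],
      dcwl = dcwl, stringsAsFactors = FALSE)

    n_occ <- sample.int(params$max_occurrences, params$n_species,
                        replace = TRUE, prob = params$occ_count_weights)
    sp_rep <- rep(seq_len(params$n_species), n_occ)
    m <- length(sp_rep)
    occ_lat <- pmin(pmax(species$latitude[sp_rep] +
                           stats::rnorm(m, 0, params$occ_coord_sd), -90), 90)
    occ_lon <- ((species$longitude[sp_rep] +
                   stats::rnorm(m, 0, params$occ_coord_sd) + 180) %% 360) - 180
    occ_elev <- pmin(pmax(species$elevation[sp_rep] +
                            stats::rnorm(m, 0, params$occ_elev_sd), 0),
                     params$max_elevation_m)
    occ_clim <- climate_model(occ_lat, occ_elev, params)
    occurrences <- data.frame(species = species$species[sp_rep],
                              latitude = occ_lat, longitude = occ_lon,
                              elevation = occ_elev,
                              temp_warmest_quarter = occ_clim$temp_warmest_quarter,
                              annual_precip = occ_clim$annual_precip,
                              stringsAsFactors = FALSE)

    list(species = species, occurrences = occurrences, sites = sites,
         params = params, seed = as.integer(seed))
  })
}
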