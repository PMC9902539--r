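## Study orchestration: session success accounting, the milling-rate study,
## and the end-to-end depth-damage study. Configs are YAML files or plain R
## lists; every report carries a resolved-config snapshot, a config hash,
## the seeds used, and the package version.

#' Lamella session success accounting
#'
#' Cumulative per-stage success percentages of a milling session: sites
#' surviving coarse milling, polishing, and final suitability for
#' tomography, each as an integer-rounded percentage of the initial sites.
#'
#' @param n_sites Initial targeted lamella sites.
#' @param n_after_coarse Sites intact after coarse milling.
#' @param n_after_polish Sites intact after the final polish.
#' @param n_suitable Sites suitable for tomography.
#' @return Tibble with `stage`, `count`, `percent`.
#' @export
#' @examples
#' summarize_success(74, 66, 63, 44)
summarize_success <- function(n_sites, n_after_coarse, n_after_polish, n_suitable) {
  counts <- c(n_sites, n_after_coarse, n_after_polish, n_suitable)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers.", class = "lamellar_domain_error")
  }
  if (any(diff(counts) > 0)) {
    abort("counts must be non-increasing across stages.", class = "lamellar_domain_error")
  }
  if (n_sites == 0) {
    abort("`n_sites` must be > 0.", class = "lamellar_domain_error")
  }
  tibble(
    stage = c("sites", "coarse_milling", "polishing", "suitable_for_tomography"),
    count = counts,
    percent = as.integer(round(100 * counts / n_sites))
  )
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort("`config` must be a list or the path to a YAML file.",
          class = "lamellar_config_error")
  }
  config
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

provenance <- function(config, seed) {
  list(config = config, config_hash = config_hash(config), seed = seed,
       package_version = as.character(utils::packageVersion("lamellar")))
}

#' Run the milling-rate study
#'
#' Either consumes a table of SEM measurements (columns `gas`, `angle_deg`,
#' `current_nA`, `w_um`, `bm_um`, `zm_um`, `time_s`) or generates synthetic
#' measurements from stated true rates, then fits a through-origin rate per
#' gas and angle and summarises the angular dependence: per-angle rate
#' ratios between gases and per-gas fold changes across angles.
#'
#' @param config A list (or YAML path) with either `measurements` (data
#'   frame or CSV path) or `synthetic` (`rates`: data frame with `gas`,
#'   `angle_deg`, `rate`; optional `currents`, `times`, `noise_frac`).
#'   Optional `theta` (default 52) and `seed`.
#' @return Object of class `millrate_report`: `rates` (gas, angle_deg,
#'   rate_um3_nC, stderr, n), `ratios`, `folds`, `provenance`.
#' @export
run_millrate_study <- function(config) {
  config <- read_config(config)
  theta <- config$theta %||% 52
  seed <- config$seed %||% 1
  if (is.null(config$measurements) && is.null(config$synthetic)) {
    abort("config needs either `measurements` or `synthetic`.",
          class = "lamellar_config_error")
  }
  if (!is.null(config$measurements)) {
    meas <- config$measurements
    if (is.character(meas)) meas <- utils::read.csv(meas)
    meas <- as_tibble(meas)
    need <- c("gas", "angle_deg", "current_nA", "w_um", "bm_um", "zm_um", "time_s")
    missing_cols <- setdiff(need, names(meas))
    if (length(missing_cols)) {
      abort(paste0("measurement table lacks column(s): ",
                   paste(missing_cols, collapse = ", ")),
            class = "lamellar_config_error")
    }
    if (!"theta" %in% names(meas)) meas$theta <- theta
  } else {
    syn <- config$synthetic
    rates <- as_tibble(syn$rates)
    if (!all(c("gas", "angle_deg", "rate") %in% names(rates))) {
      abort("`synthetic$rates` needs columns gas, angle_deg, rate.",
            class = "lamellar_config_error")
    }
    meas <- purrr::pmap_dfr(rates, function(gas, angle_deg, rate) {
      sim <- simulate_milling_measurements(
        true_rate = rate,
        currents = syn$currents %||% rep(c(0.5, 0.75, 1, 1.25, 1.5, 2), each = 3),
        times = syn$times %||% 60,
        noise_frac = syn$noise_frac %||% 0.05,
        alpha = angle_deg, theta = theta,
        seed = seed + round(angle_deg) * 1000 + sum(utf8ToInt(gas))
      )
      m <- sim$measurements
      tibble(gas = gas, angle_deg = angle_deg, current_nA = m$current,
             w_um = m$w, bm_um = m$b_m, zm_um = m$z_m, time_s = m$mill_time,
             theta = theta)
    })
  }
  volume <- parallelepiped_volume(
    tibble(w = meas$w_um, b_m = meas$bm_um, z_m = meas$zm_um,
           alpha = meas$angle_deg, theta = meas$theta)
  )
  meas$rate_um3_s <- volume / meas$time_s
  rates <- meas |>
    dplyr::group_by(.data$gas, .data$angle_deg) |>
    dplyr::group_modify(function(df, key) {
      glance(fit_rate_through_origin(
        tibble(current = df$current_nA, rate = df$rate_um3_s)))
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(rate_um3_nC = "slope")
  ## per-angle ratio between every ordered pair of gases
  ratios <- rates |>
    dplyr::inner_join(rates, by = "angle_deg", suffix = c("_a", "_b"),
                      relationship = "many-to-many") |>
    dplyr::filter(.data$gas_a != .data$gas_b) |>
    dplyr::transmute(
      angle_deg = .data$angle_deg,
      gas_a = .data$gas_a, gas_b = .data$gas_b,
      fold = rate_ratio(.data$rate_um3_nC_a, .data$rate_um3_nC_b, 1)
    )
  ## per-gas fold change from the largest to the smallest angle measured
  folds <- rates |>
    dplyr::group_by(.data$gas) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2) return(tibble())
      tibble(
        angle_from = max(df$angle_deg), angle_to = min(df$angle_deg),
        fold = fold_change_across_angles(
          tibble(angle = df$angle_deg, rate = df$rate_um3_nC),
          max(df$angle_deg), min(df$angle_deg), 1)
      )
    }) |>
    dplyr::ungroup()
  structure(list(rates = rates, ratios = ratios, folds = folds,
                 measurements = meas, provenance = provenance(config, seed)),
            class = "millrate_report")
}

#' @export
print.millrate_report <- function(x, ...) {
  cat("Milling-rate study\n\nRates (um^3/nC):\n")
  print(as.data.frame(x$rates), row.names = FALSE)
  if (nrow(x$ratios)) { cat("\nPer-angle gas ratios:\n"); print(as.data.frame(x$ratios), row.names = FALSE) }
  if (nrow(x$folds)) { cat("\nPer-gas fold change across angles:\n"); print(as.data.frame(x$folds), row.names = FALSE) }
  invisible(x)
}

damage_study_defaults <- function() {
  list(
    n_tomograms = 20,
    particles_per_tomogram = 150,
    extent = c(2000, 2000),
    plane_spacing = 250,
    thickness_front_mean = 200, thickness_front_sd = 15,
    thickness_gradient_min = 1.2, thickness_gradient_max = 1.8,
    tilt_range = c(-10, 10),
    jitter_sd = 1,
    margin = 2,
    edges = c(0, 15, 30, 45, 60),
    box = 48, voxel = 1.9, n_blobs = 60,
    damage = list(b_bulk = 450, b_surface_excess = 2000, damage_depth = 40),
    noise_sd = 2,
    mask_radius_frac = 0.4,
    retention_scale_nm = 20,
    compute_bfactors = TRUE,
    use_true_depths = FALSE,
    seed = 1
  )
}

#' Run the end-to-end depth-damage study on synthetic data
#'
#' Generates a cohort of synthetic lamellae with known damage, runs the full
#' analysis pipeline — surface interpolation, particle annotation, distance
#' shells with matched controls, half-map FSC per set — and reports the
#' per-shell resolutions, B-factors, particle-weighted thicknesses, the
#' retention-vs-depth profile, fallback counts and seeds.
#'
#' @param config List (or YAML path) overriding any of the documented
#'   defaults: cohort size (`n_tomograms`, `particles_per_tomogram`),
#'   geometry (`extent`, `plane_spacing`, thickness/tilt ranges,
#'   `jitter_sd`), shells (`edges`), simulation (`box`, `voxel`, `n_blobs`,
#'   `damage`, `noise_sd`), `compute_bfactors`, `use_true_depths` (bypass
#'   surface annotation and bin on the generator's analytic depths — faster,
#'   used for quick looks), and `seed`.
#' @return Object of class `damage_report`: `shell_table` (distance range,
#'   particle count, resolution, B-factor, weighted average thickness for
#'   every shell and its matched control), `thickness` summary across
#'   tomograms, `retention`, `fallback_counts`, `particles`, `provenance`.
#' @export
run_damage_study <- function(config = list()) {
  config <- modifyList(damage_study_defaults(), read_config(config))
  seed <- config$seed
  dm <- do.call(damage_model, config$damage)
  ## --- cohort generation -------------------------------------------------
  cohort <- with_seed(seed, {
    tibble(
      tomogram_id = sprintf("synth_tomo_%02d", seq_len(config$n_tomograms)),
      front = rnorm(config$n_tomograms, config$thickness_front_mean,
                    config$thickness_front_sd),
      gradient = runif(config$n_tomograms, config$thickness_gradient_min,
                       config$thickness_gradient_max),
      tilt = runif(config$n_tomograms, config$tilt_range[1], config$tilt_range[2])
    )
  })
  particles <- NULL; truths <- NULL; thick <- numeric(0)
  for (i in seq_len(nrow(cohort))) {
    geo <- make_lamella_geometry(
      thickness_front = cohort$front[i],
      thickness_back = cohort$front[i] * cohort$gradient[i],
      tilt = cohort$tilt[i], extent = config$extent,
      plane_spacing = config$plane_spacing, jitter_sd = config$jitter_sd,
      tomogram_id = cohort$tomogram_id[i], seed = seed + 100 + i
    )
    smp <- sample_particles(geo, config$particles_per_tomogram,
                            margin = config$margin, seed = seed + 200 + i)
    p <- smp$particles
    if (config$use_true_depths) {
      p$depth_nm <- smp$truth$true_depth_nm
      s <- interpolate_surfaces(geo$model)
      p$tomo_thickness_nm <- tomogram_thickness(s)
    } else {
      s <- interpolate_surfaces(geo$model)
      p <- annotate_particles(p, s)
    }
    thick <- c(thick, p$tomo_thickness_nm[1])
    particles <- dplyr::bind_rows(particles, p)
    truths <- dplyr::bind_rows(truths, smp$truth)
  }
  particles <- dplyr::left_join(particles, truths, by = "particle_id")
  ## --- shells and matched controls --------------------------------------
  assignment <- assign_shells(particles, config$edges)
  labels <- assignment$counts$shell
  for (k in seq_along(labels)) {
    if (assignment$counts$n[k] > 0) {
      assignment <- select_matched_controls(particles, assignment, labels[k],
                                            seed = seed + 300 + k)
    }
  }
  ## --- per-set half-map FSC ---------------------------------------------
  ref <- make_reference_volume(config$box, config$voxel, config$n_blobs,
                               seed = seed + 400)
  mask <- spherical_mask(config$box,
                         radius_voxels = config$mask_radius_frac * config$box,
                         soft_edge_voxels = 3, voxel_size = config$voxel)
  ## one noise/split seed per run, shared by all sets: a paired design, so
  ## that shell-vs-control and shell-vs-shell comparisons reflect the damage
  ## filter and set size, not independent noise realisations
  noise_seed <- seed + 500
  measure_set <- function(members, set_seed = noise_seed) {
    sub <- particles[match(members$particle_id, particles$particle_id), ]
    ## damage acts on the generator's true depth; binning used the
    ## annotated depth
    phys <- sub
    phys$depth_nm <- sub$true_depth_nm
    halves <- simulate_damaged_half_maps(ref, phys, dm, config$noise_sd,
                                         seed = set_seed, split_seed = set_seed + 1)
    res <- resolution_at_threshold(fsc_curve(halves$half1, halves$half2, mask))
    list(resolution = res$resolution_A, at_nyquist = res$at_nyquist,
         thickness = thickness_summary(sub$tomo_thickness_nm))
  }
  bfactor_for_set <- function(members, set_seed) {
    ns <- unique(round(nrow(members) / 2^(0:5)))
    ns <- ns[ns >= 24]
    if (length(ns) < 2) return(NA_real_)
    d <- vapply(seq_along(ns), function(j) {
      sel <- with_seed(set_seed + 10 + j,
                       members[sample.int(nrow(members), ns[j]), ])
      measure_set(sel, set_seed + 50 + j)$resolution
    }, numeric(1))
    tryCatch(rosenthal_henderson_bfactor(tibble(n = ns, d = d))$bfactor,
             error = function(e) NA_real_)
  }
  rows <- list()
  for (k in seq_along(labels)) {
    if (assignment$counts$n[k] == 0) next
    for (set in c("shell", "control")) {
      members <- shell_members(assignment, labels[k], set)
      m <- measure_set(members)
      b <- if (isTRUE(config$compute_bfactors)) {
        bfactor_for_set(members, seed + 700 + 10 * k + (set == "control"))
      } else NA_real_
      rows[[length(rows) + 1L]] <- tibble(
        distance_range = if (set == "shell") labels[k] else
          sprintf(">%g nm matched control", assignment$counts$upper[k]),
        set = set, shell = labels[k],
        n_particles = nrow(members),
        resolution_A = m$resolution, at_nyquist = m$at_nyquist,
        bfactor = b,
        weighted_avg_thickness_nm = m$thickness$mean,
        weighted_avg_thickness_sd = m$thickness$sd
      )
    }
  }
  shell_table <- dplyr::bind_rows(rows)
  ## --- retention profile -------------------------------------------------
  retained <- with_seed(seed + 900, {
    p_keep <- pmin(1, particles$depth_nm / config$retention_scale_nm)
    particles[runif(nrow(particles)) < p_keep, ]
  })
  retention <- retention_profile(particles, retained, bin_width = 5)
  structure(
    list(shell_table = shell_table,
         thickness = thickness_summary(thick),
         retention = retention,
         fallback_counts = assignment$fallback_counts,
         seeds = assignment$seeds,
         assignment = assignment,
         particles = particles,
         provenance = provenance(config, seed)),
    class = "damage_report"
  )
}

#' @export
print.damage_report <- function(x, ...) {
  cat("Depth-damage study\n\n")
  cols <- c("distance_range", "n_particles", "resolution_A", "bfactor",
            "weighted_avg_thickness_nm")
  print(as.data.frame(x$shell_table[, cols]), row.names = FALSE, digits = 4)
  cat(sprintf("\nLamella thickness: %.0f +/- %.0f nm (n = %d tomograms)\n",
              x$thickness$mean, x$thickness$sd, x$thickness$n))
  fb <- x$fallback_counts[x$fallback_counts > 0]
  if (length(fb)) {
    cat("Fallback control draws:",
        paste(sprintf("%s: %d", names(fb), fb), collapse = ", "), "\n")
  } else cat("No fallback control draws needed.\n")
  invisible(x)
}
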