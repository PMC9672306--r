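#' Experiment configuration
#'
#' Bundles everything one invariance-property experiment needs: the `(R, d)`
#' grid, mode (`synthetic` Monte Carlo walkers or `replay` of recorded
#' trajectory files), the step model and launch mode, sample sizes and seed.
#' Two named profiles are shipped: `"full"` (2e6 walkers per cell, the
#' fidelity used for the headline bounds) and `"quick"` (1e4 walkers,
#' suitable for the 3-standard-error consistency checks and interactive use).
#'
#' @param mode `"synthetic"` or `"replay"`.
#' @param R_mm inner-disk radii in mm.
#' @param d_mm source gaps in mm. When omitted, `d = 200 - R` per radius (the
#'   fixed source circle `R_e = 200` mm of the reference geometry) and the
#'   grid is the paired sequence of cells; when given explicitly, the grid is
#'   the full `R x d` cross unless `paired = TRUE`.
#' @param paired treat `R_mm` and `d_mm` as parallel vectors of cells rather
#'   than crossing them.
#' @param model a [step_model()].
#' @param launch `"isotropic"` or `"lambertian"`.
#' @param n_walkers synthetic walkers per cell.
#' @param n_placements replay placements per cell.
#' @param bootstrap_B bootstrap replicates for replay standard errors.
#' @param denominator `"entries"` or `"placements"` (see
#'   [mean_path_length()]).
#' @param n_annuli annuli for the density profile.
#' @param budget_mm walk length budget (default [default_length_budget()]).
#' @param seed master seed for the experiment.
#' @param random_source random source angles instead of the symmetry-fixed
#'   point.
#' @param profile `"quick"` or `"full"`: presets for `n_walkers`.
#' @return An object of class `ip_config` (a named list).
#' @export
ip_config <- function(mode = c("synthetic", "replay"),
                      R_mm = c(25, 50, 75, 100, 125),
                      d_mm = NULL,
                      paired = is.null(d_mm),
                      model = step_model("exponential", 50),
                      launch = "isotropic",
                      n_walkers = NULL,
                      n_placements = 1e4,
                      bootstrap_B = 200,
                      denominator = "entries",
                      n_annuli = 20,
                      budget_mm = NULL,
                      seed = 1L,
                      random_source = FALSE,
                      profile = c("quick", "full")) {
  mode <- match.arg(mode)
  profile <- match.arg(profile)
  if (is.null(n_walkers)) {
    n_walkers <- if (profile == "full") 2e6 else 1e4
  }
  force(paired) # must see d_mm before the default grid is filled in
  d_mm <- d_mm %||% (200 - R_mm)
  if (length(R_mm) == 0) abort("empty R_mm", class = "ipwalk_config_error")
  if (any(R_mm <= 0) || any(d_mm < 0)) {
    abort("need R > 0 and d >= 0", class = "ipwalk_config_error")
  }
  if (paired && length(d_mm) != length(R_mm)) {
    abort("paired grids need R_mm and d_mm of equal length",
      class = "ipwalk_config_error"
    )
  }
  structure(
    list(
      mode = mode, R_mm = R_mm, d_mm = d_mm, paired = paired,
      model = model, launch = launch,
      n_walkers = n_walkers, n_placements = n_placements,
      bootstrap_B = bootstrap_B, denominator = denominator,
      n_annuli = n_annuli, budget_mm = budget_mm, seed = seed,
      random_source = random_source, profile = profile
    ),
    class = "ip_config"
  )
}

#' Read an experiment configuration from a YAML file
#'
#' Keys mirror the arguments of [ip_config()]; the step model is given as a
#' nested mapping `model: {family, mfp, pareto_mu, min_step}`.
#'
#' @param path YAML file path.
#' @return An `ip_config`.
#' @export
read_ip_config <- function(path) {
  raw <- yaml::read_yaml(path)
  model_args <- raw$model %||% list()
  model <- do.call(step_model, model_args)
  raw$model <- NULL
  args <- raw
  args$model <- model
  do.call(ip_config, args)
}

#' Run the full invariance-property experiment
#'
#' Orchestrates the end-to-end pipeline with one master seed: the
#' mean-path-length sweep over the `(R, d)` grid, the radial density profile
#' over the source disk, and (in replay mode, or on a materialized sample of
#' synthetic walkers) the mean-free-path estimate. Tables are written as TSV,
#' figures as PNG, and a JSON manifest records the configuration snapshot,
#' seed, package version and per-stage row counts — enough to regenerate
#' every output identically.
#'
#' @param config an [ip_config()].
#' @param out_dir output directory (created if missing); `NULL` returns the
#'   results without writing anything.
#' @param data trajectory table for replay mode.
#' @param figures write PNG figures (requires a functioning png device).
#' @return Invisibly, a list with elements `mpl` (`ip_mpl` tibble),
#'   `density` (`ip_density` tibble), `mfp` (one-row tibble), and `manifest`
#'   (list).
#' @export
run_ip_experiment <- function(config, out_dir = NULL, data = NULL,
                              figures = FALSE) {
  stopifnot(inherits(config, "ip_config"))
  seed <- as.integer(config$seed)

  mpl <- ip_sweep(config, data = data)

  R_e <- max(config$R_mm + config$d_mm)
  if (config$mode == "synthetic") {
    density <- simulate_density(
      R_e_mm = R_e, n_annuli = config$n_annuli, model = config$model,
      launch = config$launch, n_walkers = config$n_walkers,
      budget_mm = config$budget_mm, seed = seed + 1L,
      random_source = config$random_source
    )
    # a modest materialized sample is enough for the step-scale estimate
    sample_n <- min(500, config$n_walkers)
    walks <- generate_ensemble(
      config$model, R_e,
      mode = config$launch, n_walkers = sample_n,
      length_budget = config$budget_mm %||%
        default_length_budget(config$model$mfp, R_e),
      seed = seed + 2L
    )
    mfp <- estimate_mfp_trajset(walks)$pooled
  } else {
    if (is.null(data)) {
      abort("replay mode needs trajectory data", class = "ipwalk_config_error")
    }
    set.seed(seed + 1L)
    placed <- dplyr::bind_rows(purrr::map(
      seq_len(min(config$n_placements, 2000)),
      function(i) {
        ids <- unique(data$traj_id)
        tr <- data[data$traj_id == ids[(i - 1) %% length(ids) + 1], ]
        out <- translate_rotate(tr, c(R_e, 0), runif(1, 0, 2 * pi))
        out$traj_id <- paste0(out$traj_id, "_p", i)
        out
      }
    ))
    density <- density_profile(placed, R_e_mm = R_e, n_annuli = config$n_annuli)
    mfp <- estimate_mfp_trajset(data)$pooled
  }

  flat <- density_flatness(density, min_depth_mm = config$model$mfp)
  manifest <- list(
    package = "ipwalk",
    version = as.character(utils::packageVersion("ipwalk")),
    seed = seed,
    config = config_snapshot(config),
    rows = list(
      mpl = nrow(mpl), density = nrow(density), mfp = nrow(mfp)
    ),
    max_abs_ratio_dev = max(abs(mpl$ratio[mpl$valid] - 1)),
    density_max_rel_dev = flat$max_rel_dev,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(as_tibble(mpl), file.path(out_dir, "mpl.tsv"))
    readr::write_tsv(as_tibble(density), file.path(out_dir, "density.tsv"))
    readr::write_tsv(mfp, file.path(out_dir, "mfp.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    if (figures) {
      ggplot2::ggsave(file.path(out_dir, "ratio_vs_R.png"),
        ggplot2::autoplot(mpl),
        width = 6, height = 4, dpi = 150
      )
      ggplot2::ggsave(file.path(out_dir, "density_profile.png"),
        ggplot2::autoplot(density),
        width = 6, height = 4, dpi = 150
      )
    }
  }
  invisible(list(mpl = mpl, density = density, mfp = mfp, manifest = manifest))
}

# serializable snapshot of a config (step model flattened)
config_snapshot <- function(config) {
  out <- unclass(config)
  out$model <- unclass(config$model)
  out
}
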