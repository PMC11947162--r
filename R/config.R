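#' Modifier flags for the propagation simulator
#'
#' Perturbations applied on top of the baseline contact-spread model. Each maps
#' to an experimental intervention:
#'
#' * `fer1_time` / `fer1_efficacy`: radical-trapping antioxidant (Fer-1) added
#'   at `fer1_time` minutes; from then on the per-contact conversion
#'   probability is multiplied by `fer1_efficacy` (0 = complete block).
#' * `iron_factor`: multiplier on the conversion probability modelling
#'   extracellular iron chelation (DFO); 0 abolishes spread.
#' * `contacts_enabled`: `FALSE` removes the cell-contact channel entirely
#'   (alpha-catenin loss, calcium-free medium).
#' * `bilayer_range`: if set (micrometres), newly dead cells also expose
#'   non-contacting cells within this range, with probability decaying
#'   linearly to zero at `bilayer_range` (a supported-bilayer bridge). This
#'   channel is deliberately not gated by `contacts_enabled`.
#' * `draq7_lag`: minutes between morphological death (blebbing) and DRAQ7
#'   positivity (membrane permeabilization).
#'
#' @param fer1_time minutes after activation at which Fer-1 is added, or
#'   `NULL` for no treatment.
#' @param fer1_efficacy multiplier in \[0, 1\] applied from `fer1_time` on.
#' @param iron_factor multiplier in \[0, 1\].
#' @param contacts_enabled logical flag.
#' @param bilayer_range micrometres, or `NULL`.
#' @param draq7_lag minutes, non-negative.
#' @return a named list of class `ferro_modifiers`.
#' @export
modifier_set <- function(fer1_time = NULL, fer1_efficacy = 1, iron_factor = 1,
                         contacts_enabled = TRUE, bilayer_range = NULL,
                         draq7_lag = 4) {
  m <- list(fer1_time = fer1_time, fer1_efficacy = fer1_efficacy,
            iron_factor = iron_factor, contacts_enabled = contacts_enabled,
            bilayer_range = bilayer_range, draq7_lag = draq7_lag)
  class(m) <- "ferro_modifiers"
  validate_modifiers(m)
  m
}

validate_modifiers <- function(m) {
  if (!is.null(m$fer1_time)) check_nonneg(m$fer1_time, "fer1_time")
  check_prob(m$fer1_efficacy, "fer1_efficacy")
  check_prob(m$iron_factor, "iron_factor")
  if (!is.logical(m$contacts_enabled) || length(m$contacts_enabled) != 1L)
    stopf("`contacts_enabled` must be TRUE or FALSE")
  if (!is.null(m$bilayer_range)) check_pos(m$bilayer_range, "bilayer_range")
  check_nonneg(m$draq7_lag, "draq7_lag")
  invisible(m)
}

#' Configuration for the synthetic monolayer and propagation simulator
#'
#' Defaults describe a 500 um square field at 50% confluency of ~23 um cells
#' (the average HeLa diameter), of which 30% carry the optogenetic construct;
#' five transfected cells are light-activated at t = 0 and die by ferroptosis
#' after 13-20 min (mean 17). Death then spreads to contacting neighbours with
#' per-contact probability `p_spread` per newly dead neighbour; converted
#' bystanders show lipid-peroxidation onset after a lognormal delay
#' (median 30 min) and die a further truncated-normal 60 +/- 15 min later.
#' The assay window is 6 h sampled on a 2 min clock.
#'
#' @param field_size square field side, micrometres.
#' @param target_confluency target disc-area fraction in (0, 1\].
#' @param diameter_mean,diameter_sd cell diameter distribution, micrometres.
#' @param transfected_fraction probability a cell carries the construct.
#' @param n_illuminated number of transfected cells activated at t = 0.
#' @param t_end,dt assay length and simulation step, minutes; `dt` must divide
#'   `t_end`.
#' @param opto_death_mean,opto_death_sd,opto_death_min,opto_death_max
#'   truncated-normal time from activation to blebbing for activated cells,
#'   minutes.
#' @param onset_delay_meanlog,onset_delay_sdlog lognormal delay (log-minutes)
#'   from conversion to detectable oxidation onset in bystanders.
#' @param onset_to_death_mean,onset_to_death_sd normal (truncated at 0) delay
#'   from oxidation onset to blebbing, minutes.
#' @param p_spread per-contact conversion probability in \[0, 1\] per newly
#'   dead neighbour per step.
#' @param background_hazard per-minute probability of spontaneous
#'   (contact-independent) death, e.g. photo-toxicity.
#' @param modifiers a [modifier_set()].
#' @param overlap_tolerance fraction of the summed radii by which two discs
#'   may overlap during packing (adherent cells squish slightly).
#' @param seed integer seed; every simulator draw derives from it.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(field_size = 500, target_confluency = 0.5,
                              diameter_mean = 23, diameter_sd = 2,
                              transfected_fraction = 0.3, n_illuminated = 5,
                              t_end = 360, dt = 2,
                              opto_death_mean = 17, opto_death_sd = 2,
                              opto_death_min = 13, opto_death_max = 20,
                              onset_delay_meanlog = log(30),
                              onset_delay_sdlog = 0.4,
                              onset_to_death_mean = 60, onset_to_death_sd = 15,
                              p_spread = 0.6, background_hazard = 0,
                              modifiers = modifier_set(),
                              overlap_tolerance = 0.1, seed = 1L) {
  cfg <- list(field_size = field_size, target_confluency = target_confluency,
              diameter_mean = diameter_mean, diameter_sd = diameter_sd,
              transfected_fraction = transfected_fraction,
              n_illuminated = n_illuminated, t_end = t_end, dt = dt,
              opto_death_mean = opto_death_mean, opto_death_sd = opto_death_sd,
              opto_death_min = opto_death_min, opto_death_max = opto_death_max,
              onset_delay_meanlog = onset_delay_meanlog,
              onset_delay_sdlog = onset_delay_sdlog,
              onset_to_death_mean = onset_to_death_mean,
              onset_to_death_sd = onset_to_death_sd,
              p_spread = p_spread, background_hazard = background_hazard,
              modifiers = modifiers, overlap_tolerance = overlap_tolerance,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

#' @rdname simulation_config
#' @param config object to validate.
#' @export
validate_simulation_config <- function(config) {
  if (!inherits(config, "simulation_config"))
    stopf("`config` must be built with simulation_config()")
  with(config, {
    check_pos(field_size, "field_size")
    check_prob(target_confluency, "target_confluency")
    if (target_confluency == 0) stopf("`target_confluency` must be > 0")
    check_pos(diameter_mean, "diameter_mean")
    check_nonneg(diameter_sd, "diameter_sd")
    check_prob(transfected_fraction, "transfected_fraction")
    check_nonneg(n_illuminated, "n_illuminated")
    check_pos(t_end, "t_end")
    check_pos(dt, "dt")
    if (abs(t_end / dt - round(t_end / dt)) > 1e-8)
      stopf("`dt` (%g) must divide `t_end` (%g)", dt, t_end)
    check_nonneg(opto_death_sd, "opto_death_sd")
    check_nonneg(opto_death_min, "opto_death_min")
    if (!(opto_death_min <= opto_death_mean && opto_death_mean <= opto_death_max))
      stopf("need opto_death_min <= opto_death_mean <= opto_death_max")
    check_nonneg(onset_delay_sdlog, "onset_delay_sdlog")
    check_nonneg(onset_to_death_mean, "onset_to_death_mean")
    check_nonneg(onset_to_death_sd, "onset_to_death_sd")
    check_prob(p_spread, "p_spread")
    check_prob(background_hazard, "background_hazard")
    check_prob(overlap_tolerance, "overlap_tolerance")
  })
  validate_modifiers(config$modifiers)
  invisible(config)
}

#' Configuration for rendering synthetic time-lapse stacks
#'
#' Four channels are rendered: `marker` (constitutive transfection marker),
#' `draq7` (nuclear death dye, steps on at `draq7_time`), and
#' `bodipy_green` / `bodipy_red` (oxidized and reduced forms of the
#' ratiometric lipid-peroxidation probe; green rises and red falls after
#' oxidation onset, conserving their per-cell sum).
#'
#' @param pixel_size micrometres per pixel.
#' @param frame_interval minutes between frames.
#' @param psf_sigma point-spread blur, pixels; added in quadrature to the
#'   cell-size blob width.
#' @param gains named peak amplitudes (arbitrary intensity units) for
#'   `marker`, `draq7`, `bodipy_green`, `bodipy_red`.
#' @param offsets named per-channel camera offsets.
#' @param noise_sd additive Gaussian read-noise standard deviation.
#' @param bodipy_baseline oxidized fraction of the probe before onset.
#' @param bodipy_tau time constant (minutes) of the post-onset oxidation rise.
#' @param blob_frac named per-channel Gaussian blob width as a fraction of
#'   the cell diameter: the membrane probe and cytosolic marker fill the
#'   cell (sigma = diameter/4), the nuclear dye is confined to the nucleus
#'   (sigma = diameter/8).
#' @param seed integer seed for the noise draws.
#' @return a validated list of class `imaging_config`.
#' @export
imaging_config <- function(pixel_size = 1, frame_interval = 10,
                           psf_sigma = 1.5,
                           gains = c(marker = 120, draq7 = 150,
                                     bodipy_green = 100, bodipy_red = 100),
                           offsets = c(marker = 10, draq7 = 10,
                                       bodipy_green = 10, bodipy_red = 10),
                           noise_sd = 2, bodipy_baseline = 0.1,
                           bodipy_tau = 20,
                           blob_frac = c(marker = 0.25, draq7 = 0.125,
                                         bodipy_green = 0.25,
                                         bodipy_red = 0.25),
                           seed = 1L) {
  cfg <- list(pixel_size = pixel_size, frame_interval = frame_interval,
              psf_sigma = psf_sigma, gains = gains, offsets = offsets,
              noise_sd = noise_sd, bodipy_baseline = bodipy_baseline,
              bodipy_tau = bodipy_tau, blob_frac = blob_frac,
              seed = as.integer(seed))
  class(cfg) <- "imaging_config"
  check_pos(cfg$pixel_size, "pixel_size")
  check_pos(cfg$frame_interval, "frame_interval")
  check_nonneg(cfg$psf_sigma, "psf_sigma")
  chn <- c("marker", "draq7", "bodipy_green", "bodipy_red")
  if (!all(chn %in% names(cfg$gains)) || !all(chn %in% names(cfg$offsets)) ||
      !all(chn %in% names(cfg$blob_frac)))
    stopf("gains, offsets and blob_frac must name channels: %s",
          paste(chn, collapse = ", "))
  if (any(cfg$blob_frac <= 0)) stopf("`blob_frac` must be positive")
  check_nonneg(cfg$noise_sd, "noise_sd")
  check_prob(cfg$bodipy_baseline, "bodipy_baseline")
  check_pos(cfg$bodipy_tau, "bodipy_tau")
  cfg
}

#' Configuration for the two-vesicle oxidation-transfer model
#'
#' A photosensitizer-loaded donor vesicle oxidizes with first-order rate
#' `k_act`; oxidation transfers to a contacting acceptor vesicle at a rate
#' proportional to external iron concentration and the donor's oxidized
#' fraction. See [simulate_guv_pair()].
#'
#' @param k_act donor oxidation rate, per minute.
#' @param k0 transfer coefficient, per minute per mM iron.
#' @param iron_conc external iron concentration, mM.
#' @param contact logical; are the two membranes in close contact?
#' @param baseline_ratio probe oxidation ratio of an unoxidized vesicle,
#'   in \[0, 1).
#' @param dt,t_end reporting step and duration, minutes.
#' @return a validated list of class `guv_pair_config`.
#' @export
guv_pair_config <- function(k_act = 0.2, k0 = 0.05, iron_conc = 1,
                            contact = TRUE, baseline_ratio = 0.1,
                            dt = 0.5, t_end = 60) {
  cfg <- list(k_act = k_act, k0 = k0, iron_conc = iron_conc,
              contact = contact, baseline_ratio = baseline_ratio,
              dt = dt, t_end = t_end)
  class(cfg) <- "guv_pair_config"
  check_nonneg(cfg$k_act, "k_act")
  check_nonneg(cfg$k0, "k0")
  check_nonneg(cfg$iron_conc, "iron_conc")
  if (!is.logical(cfg$contact) || length(cfg$contact) != 1L)
    stopf("`contact` must be TRUE or FALSE")
  if (!is_scalar_number(cfg$baseline_ratio) ||
      cfg$baseline_ratio < 0 || cfg$baseline_ratio >= 1)
    stopf("`baseline_ratio` must be in [0, 1)")
  if (!is_scalar_number(cfg$dt) || cfg$dt <= 0) stopf("`dt` must be > 0")
  check_pos(cfg$t_end, "t_end")
  cfg
}

#' Configuration for the synthetic lipidomics generator
#'
#' Emulates a targeted mass-spectrometry experiment: per species, condition
#' (`illuminated` vs `control`) and replicate, a raw peak area is produced as
#' true normalized ratio x internal-standard area x protein content x
#' multiplicative noise. Downstream normalisation
#' ([normalize_areas()], [fold_changes()]) should recover `true_fc`.
#'
#' @param species character vector of lipid species ids.
#' @param true_fc ground-truth illuminated/control fold change per species.
#' @param species_class named map species -> standard class; defaults to one
#'   class `"PC"` for all species.
#' @param standard_areas named internal-standard peak area per class.
#' @param base_ratio true control-condition normalized ratio per species
#'   (recycled).
#' @param protein_ug protein content per sample, micrograms; scalar or one
#'   value per (condition x replicate) sample.
#' @param n_replicates biological replicates per condition.
#' @param cv coefficient of variation of the multiplicative area noise.
#' @param seed integer seed.
#' @return a validated list of class `lipid_sim_config`.
#' @export
lipid_sim_config <- function(species = c("PC_34_2_OH", "PE_38_4_OOH", "PC_36_4_OH"),
                             true_fc = c(3, 2, 1),
                             species_class = NULL,
                             standard_areas = c(PC = 1e5, PE = 8e4),
                             base_ratio = 0.01, protein_ug = 50,
                             n_replicates = 3, cv = 0.1, seed = 1L) {
  if (length(true_fc) != length(species))
    stopf("`true_fc` must have one value per species")
  if (is.null(species_class)) {
    cls <- sub("_.*$", "", species)
    cls[!cls %in% names(standard_areas)] <- names(standard_areas)[1L]
    species_class <- setNames(cls, species)
  }
  cfg <- list(species = species, true_fc = true_fc,
              species_class = species_class,
              standard_areas = standard_areas,
              base_ratio = rep_len(base_ratio, length(species)),
              protein_ug = protein_ug, n_replicates = as.integer(n_replicates),
              cv = cv, seed = as.integer(seed))
  class(cfg) <- "lipid_sim_config"
  if (any(cfg$true_fc <= 0)) stopf("fold changes must be > 0")
  if (any(cfg$standard_areas <= 0)) stopf("internal-standard areas must be > 0")
  if (any(cfg$base_ratio <= 0)) stopf("`base_ratio` must be > 0")
  if (any(cfg$protein_ug <= 0)) stopf("`protein_ug` must be > 0")
  if (cfg$n_replicates < 1L) stopf("`n_replicates` must be >= 1")
  check_nonneg(cfg$cv, "cv")
  if (!all(cfg$species_class %in% names(cfg$standard_areas)))
    stopf("every species class needs an entry in `standard_areas`")
  cfg
}

#' Read or write a simulation configuration
#'
#' Configurations serialize to YAML (`.yml`/`.yaml`) or JSON (`.json`);
#' unspecified fields fall back to [simulation_config()] defaults on read.
#'
#' @param config a `simulation_config`.
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_simulation_config()` returns a validated
#'   `simulation_config`; `write_simulation_config()` returns `path`
#'   invisibly.
#' @export
write_simulation_config <- function(config, path) {
  validate_simulation_config(config)
  x <- unclass(config)
  x$modifiers <- unclass(x$modifiers)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  mods <- do.call(modifier_set, x$modifiers %||% list())
  x$modifiers <- NULL
  x <- x[names(x) %in% names(formals(simulation_config))]
  do.call(simulation_config, c(x, list(modifiers = mods)))
}
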