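#' Simulate a lipidomics peak-area table with known ground truth
#'
#' For each species, condition (`control`, `illuminated`) and replicate, the
#' raw peak area is
#' `true_ratio * standard_area(class) * protein_ug * noise`, where
#' `true_ratio` is `base_ratio` in controls and `base_ratio * true_fc` under
#' illumination, and `noise` is multiplicative, `1 + N(0, cv)` truncated at
#' 0.05. [normalize_areas()] followed by [fold_changes()] recovers `true_fc`
#' exactly when `cv = 0`.
#'
#' @param config a [lipid_sim_config()].
#' @return a `lipid_table`: data frame with columns `species`, `condition`,
#'   `replicate`, `area`, `is_area`, `protein_ug`; attributes `config` and
#'   `true_fc`.
#' @export
simulate_lipidomics <- function(config) {
  if (!inherits(config, "lipid_sim_config"))
    stopf("`config` must be built with lipid_sim_config()")
  conds <- c("control", "illuminated")
  grid <- expand.grid(species = config$species, condition = conds,
                      replicate = seq_len(config$n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  prot <- rep_len(config$protein_ug, 2L * config$n_replicates)
  grid$protein_ug <- prot[(grid$replicate - 1L) * 2L +
                            match(grid$condition, conds)]
  sp_i <- match(grid$species, config$species)
  grid$is_area <- unname(config$standard_areas[config$species_class[grid$species]])
  ratio <- config$base_ratio[sp_i] *
    ifelse(grid$condition == "illuminated", config$true_fc[sp_i], 1)
  withr::with_seed(config$seed, {
    noise <- if (config$cv > 0)
      pmax(0.05, 1 + rnorm(nrow(grid), 0, config$cv)) else rep(1, nrow(grid))
    grid$area <- ratio * grid$is_area * grid$protein_ug * noise
  })
  out <- grid[, c("species", "condition", "replicate", "area", "is_area",
                  "protein_ug")]
  attr(out, "config") <- config
  attr(out, "true_fc") <- setNames(config$true_fc, config$species)
  class(out) <- c("lipid_table", "data.frame")
  out
}
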