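# Shared loader for stages 3-5: re-assembles the stack and the turnover maps
# written by the earlier stages into the objects the package functions take.

read_turnover_stage <- function(world_dir = "results/world",
                                tau_dir = "results/turnover") {
  layers <- c("OC", "BD", "G", "pH", "clay", "silt", "sand", "ECE", "ESP",
              "CaSO4", "CaCO3", "TEB", "BS", "MAT", "MAP", "NPP", "biome")
  paths <- setNames(file.path(world_dir, paste0(layers, ".asc")), layers)
  stack <- assemble_stack(paths)
  manifest <- jsonlite::fromJSON(file.path(tau_dir, "manifest.json"))
  ens <- structure(list(
    mean = read_grid(file.path(tau_dir, "tau_mean.asc"), "tau_mean"),
    lower = read_grid(file.path(tau_dir, "tau_lower.asc"), "tau_lower"),
    upper = read_grid(file.path(tau_dir, "tau_upper.asc"), "tau_upper"),
    soc = read_grid(file.path(tau_dir, "soc_stock.asc"), "SOC"),
    bnpp_mean = read_grid(file.path(tau_dir, "bnpp_mean.asc"), "bnpp_mean"),
    draws = NULL, draw_index = NULL,
    n_flux_masked = manifest$n_flux_masked,
    config = run_config(seed = manifest$seed,
                        n_ensemble = manifest$n_ensemble)),
    class = "turnover_ensemble")
  ens$pct_uncertainty <- percentage_uncertainty(ens)
  list(stack = stack, ens = ens)
}
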