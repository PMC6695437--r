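# Fixture builders shared across the suite. Everything is generated in code;
# no files on disk.

# A grid with explicit values (vector filled by row for readability).
mk_grid <- function(vals, nrow = 1, ncol = length(vals) / nrow,
                    origin_lat = nrow * 0.1, resolution = 0.1,
                    name = "x", mask = NULL) {
  grid2d(matrix(vals, nrow, ncol, byrow = TRUE), mask = mask,
         origin_lat = origin_lat, origin_lon = 0, resolution = resolution,
         name = name)
}

# Single-pixel world stack with the layers the ensemble needs.
mk_pixel_stack <- function(oc = 2, bd = 1400, gravel = 10, npp = 0.6,
                           biome = 3) {
  assemble_stack(list(
    OC = mk_grid(oc, name = "OC"), BD = mk_grid(bd, name = "BD"),
    G = mk_grid(gravel, name = "G"), NPP = mk_grid(npp, name = "NPP"),
    biome = mk_grid(biome, name = "biome")))
}

# Degenerate allocation tables: every biome holds two identical records, so
# bootstrap draws are constants. Crop SE defaults to zero for the
# zero-input-uncertainty limit.
mk_const_tables <- function(f_bnpp = 0.4, d50 = 0.2, d95 = 1.0,
                            crop_se = 0) {
  structure(
    list(
      fbnpp_records = data.frame(biome = rep(1:9, each = 2),
                                 f_bnpp = f_bnpp),
      root_records = data.frame(biome = rep(1:8, each = 2),
                                d50_m = d50, d95_m = d95),
      crop_d50_mean = d50, crop_d50_se_fraction = crop_se,
      crop_d95_ratio = d95 / d50),
    class = "allocation_tables")
}

# Random valid (d50, d95) profiles.
mk_profiles <- function(n, seed = 1) {
  set.seed(seed)
  d50 <- runif(n, 0.02, 1.0)
  ratio <- runif(n, 1.05, 20)
  data.frame(d50 = d50, d95 = d50 * ratio)
}
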