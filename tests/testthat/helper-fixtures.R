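# Small reusable fixtures, all generated in code.

# a tiny hillslope with one platform of known area, no confusers
one_platform_scenario <- function(area_m2 = 63, slope_deg = 25, seed = 101) {
  terrain_scenario(
    extent_m = c(50, 50), base_slope_deg = slope_deg,
    relief_amplitude_m = 0.15, n_platforms = 1,
    platform_area_range_m2 = c(area_m2, area_m2),
    lip_width_range_m = c(1.5, 1.5), n_confusers = 0, seed = seed
  )
}

# best Jaccard of any segmented object against each truth platform
platform_jaccards <- function(sim, labels) {
  vapply(sim$truth$id, function(i) {
    m <- truth_mask(sim$dem, sim$truth, i)
    ids <- unique(labels$values[m])
    ids <- ids[!is.na(ids) & ids > 0]
    if (length(ids) == 0) return(0)
    max(vapply(ids, function(id) jaccard_index(labels, id, m), numeric(1)))
  }, numeric(1))
}

random_grid <- function(nr, nc, seed, cell = 1) {
  set.seed(seed)
  dem_grid(matrix(runif(nr * nc, 0, 50), nr, nc), cell_size_m = cell)
}

# shoelace area of a closed ring
ring_area <- function(ring) {
  n <- nrow(ring)
  abs(sum(ring[-n, 1] * ring[-1, 2] - ring[-1, 1] * ring[-n, 2])) / 2
}
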