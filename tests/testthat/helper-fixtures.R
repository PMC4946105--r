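# Shared fixtures: tiny worlds built in code.

# A small, fast filter spot (one-pass defaults, ~200 um field).
tiny_spot <- function(n_leukocytes = 60, n_ctc = 2, n_debris = 15,
                      n_clusters = 2, seed = 2, ...) {
  generate_filter_spot(
    population = cell_population(n_leukocytes = n_leukocytes, n_ctc = n_ctc,
                                 n_debris = n_debris, n_clusters = n_clusters, ...),
    seed = seed)
}

# Noise-free detector.
quiet_model <- function() exposure_model(read_noise_sd = 0, shot_noise = FALSE)

# Logical disc mask.
disc_mask <- function(n = 60, cx = (n + 1) / 2, cy = (n + 1) / 2, r = n / 3) {
  g <- expand.grid(row = seq_len(n), col = seq_len(n))
  m <- matrix(FALSE, n, n)
  m[(g$row - cy)^2 + (g$col - cx)^2 <= r^2] <- TRUE
  m
}

# A classed fish_spots table built directly (for fusion/calling units).
make_spots <- function(x = numeric(), y = numeric(), z = numeric(),
                       merged = logical(length(x)), interpretable = TRUE) {
  df <- data.frame(x_um = x, y_um = y, z_um = z,
                   peak = rep(100, length(x)),
                   diameter_um = rep(1, length(x)),
                   z_extent = rep(1L, length(x)),
                   merged = merged)
  structure(df, class = c("fish_spots", "data.frame"),
            interpretable = interpretable,
            reason = if (interpretable) NA_character_ else "synthetic")
}

# Independent re-statement of the selection rules (oracle for gate tests).
oracle_select <- function(cand, gates) {
  single <- cand$dapi_avg >= gates$dapi_min & cand$cd45_avg <= gates$cd45_max &
    cand$area_um2 > gates$area_min_um2
  cluster <- cand$dapi_avg >= gates$dapi_min & cand$area_um2 > gates$cluster_area_min_um2
  list(selected = which(single | cluster),
       rule = ifelse(cluster, "cluster-candidate", "single"))
}

# Fraction of a Uniform(-range/2, range/2) axial spot position captured by a
# comb of n planes spaced step apart (capture iff distance to the nearest
# plane is < support): numeric-integration oracle for the axial-capture
# property.
oracle_capture <- function(n, step, support, range, grid = 20001) {
  z <- seq(-range / 2, range / 2, length.out = grid)
  planes <- (seq_len(n) - (n + 1) / 2) * step
  hit <- vapply(z, function(zz) min(abs(zz - planes)) < support, logical(1))
  mean(hit)
}
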