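# Simulator: geometry, exposure model, focal surface, spot generation,
# z-stack rendering.

test_that("filter geometry validates pores and snick asymmetry", {
  g <- filter_geometry()
  expect_equal(g$pore_diameter_um, 8)
  expect_error(filter_geometry(pore_pitch_um = 7), "overlap")
  expect_error(filter_geometry(snick = list(angle_deg = 0, depth_um = 100, skew = 0.5)),
               "ambiguous")
  lat <- pore_lattice(g, c(100, 100))
  expect_true(all(lat$x_um <= 100 & lat$y_um <= 100))
  # no two pores closer than the pitch (less numerical slack)
  d <- as.matrix(dist(lat))
  diag(d) <- Inf
  expect_gte(min(d), g$pore_pitch_um * 0.99)
})

test_that("snick outline is asymmetric and scales with geometry", {
  g <- filter_geometry()
  o <- snick_outline(g, 101)
  expect_equal(dim(o), c(101, 2))
  # points lie near the rim radius
  r <- sqrt(rowSums(o^2))
  R <- g$spot_diameter_mm * 1000 / 2
  expect_true(all(r <= R + 1e-6 & r >= R - g$snick$depth_um - 1e-6))
  # direction-reversal changes the shape (no mirror symmetry about the apex)
  rev_r <- rev(r)
  expect_gt(max(abs(r - rev_r)), 1)
})

test_that("exposure model: monotonicity, saturation, linearity, clipping", {
  m <- quiet_model()
  rate <- matrix(c(0, 0.5, 2, 10), 2, 2)
  imgs <- lapply(c(5, 20, 40, 100), function(e) apply_exposure(rate, e, m, noise = FALSE))
  for (i in seq_len(3))
    expect_true(all(imgs[[i + 1]] >= imgs[[i]])) # pointwise monotone
  expect_equal(max(imgs[[4]]), 255)              # saturates exactly at 255
  # doubling exposure doubles signal-minus-dark below saturation
  a <- apply_exposure(matrix(1), 20, m, noise = FALSE) - m$dark_level
  b <- apply_exposure(matrix(1), 40, m, noise = FALSE) - m$dark_level
  expect_equal(as.numeric(b), 2 * as.numeric(a))
  # sub-count signal at minimum exposure leaves the image at dark level
  dim_img <- apply_exposure(matrix(0.05 / 5, 3, 3), 5, m, noise = FALSE)
  expect_true(all(dim_img == m$dark_level))
  expect_error(apply_exposure(matrix(1), 3, m), "\\[5, 100\\]")
  expect_error(apply_exposure(matrix(1), 150, m), "\\[5, 100\\]")
})

test_that("bright-spot footprint grows with exposure and clips to a plateau", {
  # evaluate the model on a synthetic Gaussian spot (the derived example)
  m <- quiet_model()
  ax <- seq(-5, 5, by = 0.2)
  spot <- 8 * exp(-outer(ax^2, ax^2, `+`) / (2 * 0.8^2))
  lo <- apply_exposure(spot, 20, m, noise = FALSE)
  hi <- apply_exposure(spot, 100, m, noise = FALSE)
  thr <- m$dark_level + 20
  expect_gt(sum(hi > thr), sum(lo > thr))     # footprint strictly larger
  expect_gt(sum(hi == 255), 0)                 # clipped plateau at 255
  expect_equal(sum(lo == 255), 0)
})

test_that("focal surface respects peak-to-peak bound and refocus residual", {
  s <- focal_surface(field_um = c(500, 500), peak_to_peak_um = 10, seed = 3)
  g <- expand.grid(x = seq(0, 500, 10), y = seq(0, 500, 10))
  z <- eval_surface(s, g$x, g$y)
  expect_lte(diff(range(z)), 10 * 1.01)
  expect_gt(diff(range(z)), 5)  # actually uses its amplitude
  set.seed(1)
  r <- isetscan:::refocus_error(s, 2000)
  expect_lt(abs(sd(r) - 0.5), 0.08)
})

test_that("empty population gives blank planes at dark level plus pore texture", {
  spot <- generate_filter_spot(
    population = cell_population(n_leukocytes = 0, n_ctc = 0, n_debris = 0,
                                 n_clusters = 0),
    model = quiet_model(), field_um = c(100, 100), seed = 1)
  expect_true(is.null(spot$truth) || nrow(spot$truth) == 0)
  cd45 <- spot$channels$cd45$data
  expect_true(all(cd45 == quiet_model()$dark_level))
  # DAPI: background at dark level, pore autofluorescence above it
  dapi <- spot$channels$dapi$data
  expect_equal(min(dapi), quiet_model()$dark_level)
  expect_gt(max(dapi), quiet_model()$dark_level)
})

test_that("same seed reproduces bit-identical images and truth", {
  a <- tiny_spot(n_leukocytes = 30, seed = 5)
  b <- tiny_spot(n_leukocytes = 30, seed = 5)
  expect_identical(a$channels$dapi$data, b$channels$dapi$data)
  expect_identical(a$channels$cd45$data, b$channels$cd45$data)
  expect_identical(a$truth, b$truth)
  c <- tiny_spot(n_leukocytes = 30, seed = 6)
  expect_false(identical(a$channels$dapi$data, c$channels$dapi$data))
})

test_that("every truth cell intersects rendered DAPI above dark level", {
  spot <- tiny_spot(n_leukocytes = 40, n_ctc = 2, n_debris = 10, seed = 8)
  dapi <- spot$channels$dapi$data
  px <- spot$pixel_size_um
  dark <- spot$model$dark_level
  for (i in seq_len(nrow(spot$truth))) {
    r <- round(spot$truth$y_um[i] / px)
    c <- round(spot$truth$x_um[i] / px)
    rows <- max(1, r - 3):min(nrow(dapi), r + 3)
    cols <- max(1, c - 3):min(ncol(dapi), c + 3)
    expect_gt(max(dapi[rows, cols]), dark)
  }
})

test_that("debris is confined to pore interiors", {
  spot <- tiny_spot(n_leukocytes = 10, n_ctc = 0, n_debris = 25, seed = 9)
  deb <- spot$truth[spot$truth$type == "debris", ]
  for (i in seq_len(nrow(deb))) {
    d <- sqrt((spot$pores$x_um - deb$x_um[i])^2 + (spot$pores$y_um - deb$y_um[i])^2)
    expect_lte(min(d), spot$geometry$pore_diameter_um / 2)
  }
})

test_that("overfull population fails explicitly instead of truncating", {
  expect_error(
    generate_filter_spot(population = cell_population(n_leukocytes = 500, n_ctc = 0,
                                                      n_debris = 0, n_clusters = 0),
                         field_um = c(100, 100), seed = 1),
    "pack")
})

test_that("leukocyte areas respect the sub-gate invariant; CTCs are larger", {
  spot <- tiny_spot(n_leukocytes = 80, n_ctc = 4, seed = 10)
  tr <- spot$truth
  expect_true(all(tr$area_um2[tr$type == "leukocyte"] < 55))
  expect_true(all(tr$area_um2[tr$type == "ctc" & is.na(tr$cluster_id)] > 55))
  expect_equal(tr$equiv_diameter_um, equiv_diameter_um(tr$area_um2))
})

# --- z-stack rendering ----------------------------------------------------

test_that("a spot outside the comb is absent from every plane", {
  sp <- data.frame(x_um = 0, y_um = 0, z_um = 9, channel = "red", rate = 5)
  zs <- render_zstack(sp, scan_config(30, 0.6), "red", exposure_ms = 50,
                      model = quiet_model(), noise = FALSE)
  expect_equal((n_planes(zs) - 1) * zs$step_um, 17.4)  # comb span
  expect_true(all(zs$planes == quiet_model()$dark_level))
})

test_that("a spot at focus is brightest in the centre plane, symmetric decay", {
  sp <- data.frame(x_um = 0, y_um = 0, z_um = 0, channel = "red", rate = 5)
  scan <- scan_config(5, 0.2)   # planes at -0.4 ... 0.4, inside axial support
  zs <- render_zstack(sp, scan, "red", exposure_ms = 50, model = quiet_model(),
                      psf = fish_psf(axial_support_um = 1), noise = FALSE)
  peaks <- apply(zs$planes, 3, max)
  expect_equal(which.max(peaks), 3L)
  expect_equal(peaks[1], peaks[5], tolerance = 0.05)
  expect_equal(peaks[2], peaks[4], tolerance = 0.05)
  expect_true(peaks[2] > peaks[1])
})

test_that("axial capture grows with stack count and matches the integration oracle", {
  # spots uniform through a 14-um nucleus; compare captured fraction under a
  # 5-plane vs 30-plane comb with the closed-form/numeric oracle
  psf <- fish_psf()
  oc5 <- oracle_capture(5, 0.6, psf$axial_support_um, 14)
  oc30 <- oracle_capture(30, 0.6, psf$axial_support_um, 14)
  expect_lt(oc5, oc30)
  set.seed(42)
  z <- runif(4000, -7, 7)
  frac <- function(n) {
    planes <- (seq_len(n) - (n + 1) / 2) * 0.6
    mean(vapply(z, function(zz) min(abs(zz - planes)) < psf$axial_support_um,
                logical(1)))
  }
  expect_equal(frac(5), oc5, tolerance = 0.03)
  expect_equal(frac(30), oc30, tolerance = 0.03)
  # monotone non-decreasing in n_stacks at fixed step
  caps <- vapply(c(5, 10, 15, 20, 25, 30), oracle_capture, numeric(1),
                 step = 0.6, support = psf$axial_support_um, range = 14)
  # tolerance: the capture indicator's boundary points discretize on the grid
  expect_true(all(diff(caps) >= -2e-3))
})
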