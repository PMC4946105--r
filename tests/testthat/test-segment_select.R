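# Nucleus segmentation, background estimation, candidate measurement, and
# the DAPI+/CD45- selection gates.

test_that("blank image segments to an empty candidate list", {
  img <- channel_image(matrix(8, 120, 120), 0.5, "dapi")
  seg <- segment_nuclei(img)
  expect_equal(seg$n, 0L)
  cands <- measure_candidates(seg, list(
    dapi = img, cd45 = img, epithelial = img, mesenchymal = img),
    background = list(dapi = list(value = 8, sd = 0)))
  expect_equal(nrow(cands), 0L)
})

test_that("missing pixel size is an error (area undefined)", {
  expect_error(segment_nuclei(structure(list(data = matrix(0, 5, 5),
                                             pixel_size_um = NA_real_),
                                        class = "channel_image")),
               "pixel size")
})

test_that("noiseless spot: every nucleus found, areas within 10% of truth", {
  spot <- generate_filter_spot(
    population = cell_population(n_leukocytes = 100, n_ctc = 0, n_debris = 0,
                                 n_clusters = 0, on_pore_frac = 0,
                                 rates = list(pore_autofluor = 0)),
    model = quiet_model(), seed = 4)
  seg <- segment_nuclei(spot$channels$dapi)
  expect_equal(seg$n, 100L)
  cands <- measure_candidates(seg, spot)
  m <- vapply(seq_len(nrow(spot$truth)), function(i)
    which.min((cands$centroid_x_um - spot$truth$x_um[i])^2 +
                (cands$centroid_y_um - spot$truth$y_um[i])^2), integer(1))
  rel <- cands$area_um2[m] / spot$truth$area_um2 - 1
  expect_true(all(abs(rel) < 0.10))
  # masks are disjoint by construction: label image partitions foreground
  expect_equal(sort(unique(as.vector(seg$labels))), 0:100)
})

test_that("two overlapping nuclei: split in split mode, merged in cluster mode", {
  # draw two discs overlapping by ~30% of a radius
  px <- 0.5
  n <- 80
  img <- matrix(8, n, n)
  add_disc <- function(img, cx, cy, r, amp) {
    g <- expand.grid(row = 1:n, col = 1:n)
    d <- sqrt((g$row - cy)^2 + (g$col - cx)^2)
    img + matrix(amp * plogis((r - d) / 0.5), n, n)
  }
  img <- add_disc(img, 30, 40, 8, 120)
  img <- add_disc(img, 44, 40, 8, 120)
  ci <- channel_image(img, px, "dapi")
  seg_split <- segment_nuclei(ci, segmentation_params(split = TRUE))
  seg_merge <- segment_nuclei(ci, segmentation_params(split = FALSE))
  expect_equal(seg_split$n, 2L)
  expect_equal(seg_merge$n, 1L)
})

test_that("background estimation is robust to masks and pores", {
  flat <- channel_image(matrix(42, 50, 50), 0.5, "cd45")
  bg <- estimate_background(flat)
  expect_equal(bg$value, 42)
  # constant background plus bright nuclei, masked out
  img <- matrix(10, 100, 100)
  img[30:45, 30:45] <- 200
  lab <- matrix(0L, 100, 100); lab[30:45, 30:45] <- 1L
  seg <- structure(list(labels = lab, n = 1L, pixel_size_um = 0.5),
                   class = "nucleus_segmentation")
  bg2 <- estimate_background(channel_image(img, 0.5), seg = seg)
  expect_equal(bg2$value, 10)
  # all pixels masked -> explicit error
  seg_all <- structure(list(labels = matrix(1L, 5, 5), n = 1L, pixel_size_um = 0.5),
                       class = "nucleus_segmentation")
  expect_error(estimate_background(channel_image(matrix(1, 5, 5), 0.5), seg = seg_all),
               "no background")
  # simulator: estimate lands within 2 counts of the configured dark level
  spot <- tiny_spot(n_leukocytes = 50, seed = 3)
  seg3 <- segment_nuclei(spot$channels$dapi)
  bg3 <- estimate_background(spot$channels$dapi, seg = seg3, pores = spot$pores)
  expect_lt(abs(bg3$value - spot$model$dark_level), 2)
})

test_that("measurement arithmetic: pixel count to um^2, uniform channels", {
  lab <- matrix(0L, 40, 40)
  lab[11:20, 11:30] <- 1L   # 200 px
  seg <- structure(list(labels = lab, n = 1L, pixel_size_um = 0.5),
                   class = "nucleus_segmentation")
  mk <- function(v, ch) channel_image(matrix(v, 40, 40), 0.5, ch)
  cands <- measure_candidates(
    seg, list(dapi = mk(100, "dapi"), cd45 = mk(180, "cd45"),
              epithelial = mk(20, "epithelial"), mesenchymal = mk(30, "mesenchymal")),
    background = list(dapi = list(value = 8, sd = 1)))
  expect_equal(cands$area_um2, 50)                     # 200 px * 0.25 um^2
  expect_equal(cands$equiv_diameter_um, 2 * sqrt(50 / pi))
  expect_equal(cands$cd45_avg, 180)
  expect_equal(cands$dapi_avg, 100)
  expect_equal(cands$background_avg, 8)
  # channel/pixel-size mismatch -> error
  expect_error(measure_candidates(
    seg, list(dapi = mk(1, "dapi"), cd45 = channel_image(matrix(1, 40, 40), 1, "cd45"),
              epithelial = mk(1, "epithelial"), mesenchymal = mk(1, "mesenchymal"))),
    "pixel size")
})

test_that("measured marker means track simulator truth within noise", {
  spot <- tiny_spot(n_leukocytes = 40, n_ctc = 3, n_clusters = 0, seed = 12)
  seg <- segment_nuclei(spot$channels$dapi)
  cands <- measure_candidates(seg, spot)
  tr <- spot$truth[spot$truth$type == "ctc", ]
  for (i in seq_len(nrow(tr))) {
    k <- which.min((cands$centroid_x_um - tr$x_um[i])^2 +
                     (cands$centroid_y_um - tr$y_um[i])^2)
    expected_epi <- spot$model$dark_level +
      tr$epithelial_rate[i] * spot$exposures_ms[["epithelial"]]
    expect_lt(abs(cands$epithelial_avg[k] - min(expected_epi, 255)) /
                max(expected_epi, 10), 0.35)
  }
})

test_that("selection rules: worked examples and strict boundaries", {
  gates <- selection_gates(dapi_min = 20, cd45_max = 12)
  mk <- function(area, dapi, cd45)
    data.frame(id = 1, dapi_avg = dapi, cd45_avg = cd45, area_um2 = area)
  # area 60, DAPI+, CD45 at background -> selected (single)
  s <- select_cd45_negative(mk(60, 100, 8), gates)
  expect_equal(nrow(s), 1L)
  expect_equal(as.character(s$selection_rule), "single")
  # area 50 rejected; area exactly 55 rejected ("superior to 55" is strict)
  expect_equal(nrow(select_cd45_negative(mk(50, 100, 8), gates)), 0L)
  expect_equal(nrow(select_cd45_negative(mk(55, 100, 8), gates)), 0L)
  # area 160, CD45 strongly positive -> cluster-candidate (CD45 ignored)
  s2 <- select_cd45_negative(mk(160, 100, 200), gates)
  expect_equal(as.character(s2$selection_rule), "cluster-candidate")
  # area exactly 150 rejected by the cluster rule (strict)
  expect_equal(nrow(select_cd45_negative(mk(150, 100, 200), gates)), 0L)
  # unmeasured candidates -> error
  expect_error(select_cd45_negative(data.frame(id = 1), gates), "unmeasured")
  expect_error(select_cd45_negative(mk(60, NA, 8), gates), "non-finite")
})

test_that("selection equals the brute-force rule oracle on 10^4 candidates", {
  set.seed(99)
  n <- 10000
  cand <- data.frame(
    id = seq_len(n),
    dapi_avg = runif(n, 0, 255),
    cd45_avg = runif(n, 0, 255),
    area_um2 = runif(n, 1, 400))
  gates <- selection_gates(dapi_min = 30, cd45_max = 25)
  sel <- select_cd45_negative(cand, gates)
  orc <- oracle_select(cand, gates)
  expect_equal(sel$id, orc$selected)
  expect_equal(as.character(sel$selection_rule), orc$rule[orc$selected])
})

test_that("gate idempotence and monotonicity", {
  set.seed(7)
  cand <- data.frame(id = 1:500, dapi_avg = runif(500, 0, 255),
                     cd45_avg = runif(500, 0, 255), area_um2 = runif(500, 1, 300))
  gates <- selection_gates(dapi_min = 40, cd45_max = 30)
  s1 <- select_cd45_negative(cand, gates)
  s2 <- select_cd45_negative(s1[names(cand)], gates)
  expect_equal(s1$id, s2$id)
  # lowering cd45_max never adds a single-rule selection
  tighter <- selection_gates(dapi_min = 40, cd45_max = 15)
  st <- select_cd45_negative(cand, tighter)
  expect_true(all(st$id[st$selection_rule == "single"] %in%
                    s1$id[s1$selection_rule == "single"]))
  # raising area_min never adds any selection
  bigger <- selection_gates(dapi_min = 40, cd45_max = 30, area_min_um2 = 80)
  sb <- select_cd45_negative(cand, bigger)
  expect_true(all(sb$id %in% s1$id))
})

test_that("on a populous spot the selected count sits in the tens-to-hundreds", {
  spot <- tiny_spot(n_leukocytes = 300, n_ctc = 3, n_clusters = 6, seed = 21)
  res <- analyze_spot(spot)
  # scaled-down spot (300 leukocytes ~ 1/20 of a real one): selection must
  # stay orders of magnitude below the candidate count
  expect_gt(nrow(res$selected), 0)
  expect_lt(nrow(res$selected), 40)
  expect_gt(nrow(res$candidates), 250)
})
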