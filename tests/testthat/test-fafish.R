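# FISH spot detection, multi-exposure fusion, break-apart calling, and the
# spot-count table / detection-rate statistic.

test_that("scan config enforces the scanner limits", {
  expect_error(scan_config(n_stacks = 31), "<= 30")
  expect_error(scan_config(n_stacks = 0), "positive")
  expect_error(scan_config(step_um = 0), "step_um")
  expect_error(scan_config(exposures_ms = list(red = c(2, 50))), "\\[5, 100\\]")
  expect_error(scan_config(exposures_ms = list(red = c(10, 20, 30, 40))), "1-3")
  expect_error(scan_config(exposures_ms = list(a = 10, b = 10, c = 10, d = 10)),
               "3 FISH channels")
  s <- scan_config(30, 0.6)
  expect_equal(plane_positions(s)[1], -8.7)
  expect_equal(max(plane_positions(s)) - min(plane_positions(s)), 17.4)
})

test_that("empty stack yields zero spots; saturated stack is non-interpretable", {
  zs <- zstack_series(array(8, dim = c(40, 40, 4)), step_um = 0.6,
                      pixel_size_um = 0.2)
  d <- detect_spots(zs)
  expect_equal(nrow(d), 0L)
  expect_true(attr(d, "interpretable"))
  sat <- zstack_series(array(255, dim = c(40, 40, 3)), step_um = 0.6,
                       pixel_size_um = 0.2)
  ds <- detect_spots(sat)
  expect_equal(nrow(ds), 0L)
  expect_false(attr(ds, "interpretable"))
  expect_equal(attr(ds, "reason"), "saturated")
  expect_true(is.na(countable_spots(ds)))
})

test_that("16 planted spots inside the comb are recovered within 1 px", {
  set.seed(3)
  xy <- expand.grid(x = seq(-9, 9, length.out = 4), y = seq(-9, 9, length.out = 4))
  sp <- data.frame(x_um = xy$x + runif(16, -0.5, 0.5),
                   y_um = xy$y + runif(16, -0.5, 0.5),
                   z_um = runif(16, -7, 7), channel = "red", rate = 4)
  zs <- render_zstack(sp, scan_config(30, 0.6), "red", exposure_ms = 50,
                      field_um = 24)
  d <- detect_spots(zs)
  expect_equal(nrow(d), 16L)
  err <- vapply(seq_len(16), function(i)
    min(sqrt((d$x_um - sp$x_um[i])^2 + (d$y_um - sp$y_um[i])^2)), numeric(1))
  expect_true(all(err < 0.2))  # 1 px at 0.2 um/px
})

test_that("a sub-resolution pair (0.3 um) is reported once", {
  pair <- data.frame(x_um = c(-0.15, 0.15), y_um = 0, z_um = 0,
                     channel = "red", rate = 4)
  zs <- render_zstack(pair, scan_config(1, 0.6), "red", exposure_ms = 50,
                      field_um = 10, noise = FALSE)
  d <- detect_spots(zs)
  expect_equal(nrow(d), 1L)
})

test_that("an unresolved pair is flagged merged; detection is exposure-stable", {
  # 0.8-um pair: one band-pass maximum -> one detection carrying the merged
  # flag (elongated footprint), at low and mid exposure alike
  for (e in c(10, 30)) {
    pr <- data.frame(x_um = c(-0.4, 0.4), y_um = 0, z_um = 0,
                     channel = "red", rate = 8)
    zz <- render_zstack(pr, scan_config(1, 0.6), "red", exposure_ms = e,
                        field_um = 10, noise = FALSE)
    dd <- detect_spots(zz)
    expect_equal(nrow(dd), 1L)
    expect_true(dd$merged)
    expect_equal(countable_spots(dd), 0L)
  }
})

test_that("3D linking merges per-plane detections of one spot", {
  sp <- data.frame(x_um = 0, y_um = 0, z_um = 0.1, channel = "red", rate = 6)
  zs <- render_zstack(sp, scan_config(9, 0.2), "red", exposure_ms = 50,
                      field_um = 8, psf = fish_psf(axial_support_um = 0.5),
                      noise = FALSE)
  d <- detect_spots(zs)
  expect_equal(nrow(d), 1L)   # one 3D spot despite several planes
  expect_gte(d$z_extent, 3L)
  expect_lt(abs(d$z_um - 0.1), 0.2)
})

test_that("fusion: ties to lowest exposure, max countable wins, n.i. propagates", {
  s2 <- make_spots(x = c(0, 2), y = c(0, 0), z = c(0, 0))
  res <- multi_exposure_fuse(list(`20` = s2, `50` = s2, `100` = s2))
  expect_equal(res$exposure_ms, 20)    # identical detections -> lowest wins
  # highest exposure fuses a pair that mid exposure resolves -> mid chosen
  dim1 <- make_spots(x = 0, y = 0, z = 0)                     # too dim: 1 seen
  mid <- make_spots(x = c(0, 1.2), y = c(0, 0), z = c(0, 0))  # resolved
  hi <- make_spots(x = 0.6, y = 0, z = 0, merged = TRUE)      # bloomed pair
  res2 <- multi_exposure_fuse(list(`20` = dim1, `50` = mid, `100` = hi))
  expect_equal(res2$exposure_ms, 50)
  expect_equal(res2$countable, 2L)
  # all non-interpretable -> non-interpretable
  ni <- make_spots(interpretable = FALSE)
  res3 <- multi_exposure_fuse(list(`20` = ni, `50` = ni))
  expect_false(res3$interpretable)
  # partial n.i.: the interpretable one wins
  res4 <- multi_exposure_fuse(list(`20` = ni, `50` = mid))
  expect_equal(res4$exposure_ms, 50)
})

test_that("fusion never selects fewer countable spots than an alternative", {
  set.seed(12)
  for (rep in 1:30) {
    dets <- setNames(lapply(1:3, function(i) {
      n <- sample(0:6, 1)
      make_spots(x = runif(n, -5, 5), y = runif(n, -5, 5), z = runif(n, -3, 3),
                 merged = runif(n) < 0.3)
    }), c("20", "50", "100"))
    res <- multi_exposure_fuse(dets)
    cnt <- unname(vapply(dets, countable_spots, integer(1)))
    expect_equal(res$countable, max(cnt))       # brute-force comparison
  }
})

test_that("break-apart calling follows the pattern conventions", {
  fused2 <- list(r = make_spots(x = c(0, 4), y = 0, z = 0),
                 g = make_spots(x = c(0.3, 4.3), y = 0, z = 0))
  expect_equal(call_break_apart(fused2$r, fused2$g)$verdict, "native")
  # 1 fused + 1 split pair
  r <- make_spots(x = c(0, 5), y = 0, z = 0)
  g <- make_spots(x = c(0.3, 9), y = 0, z = 0)
  cb <- call_break_apart(r, g)
  expect_equal(cb$verdict, "rearranged")
  expect_equal(cb$fused_pairs, 1L)
  expect_equal(cb$split_pairs, 1L)
  # 5 fused pairs, no split -> native copy gain
  r5 <- make_spots(x = seq(0, 20, by = 5), y = 0, z = 0)
  g5 <- make_spots(x = seq(0, 20, by = 5) + 0.3, y = 0, z = 0)
  expect_equal(call_break_apart(r5, g5)$verdict, "native-copy-gain")
  # isolated single-colour signal counts toward rearrangement
  r1 <- make_spots(x = c(0, 6), y = 0, z = 0)
  g1 <- make_spots(x = 0.2, y = 0, z = 0)
  cb1 <- call_break_apart(r1, g1)
  expect_equal(cb1$verdict, "rearranged")
  expect_equal(cb1$singles, 1L)
  # both channels empty -> non-interpretable
  expect_equal(call_break_apart(make_spots(), make_spots())$verdict,
               "non-interpretable")
  # n.i. detection propagates with a reason
  ni <- call_break_apart(make_spots(interpretable = FALSE), make_spots(x = 1, y = 1, z = 0))
  expect_equal(ni$verdict, "non-interpretable")
  expect_match(ni$reason, "non-interpretable")
})

test_that("spot-count table: construction, duplicates, CSV round trip", {
  m <- matrix(c(4, NA, 2, 6), 2, 2, dimnames = list(c("1", "2"), c("z5", "z30")))
  tab <- spot_count_table(m)
  expect_equal(dim(tab), c(2L, 2L))
  expect_error(spot_count_table(cbind(m, m)), "duplicate setting")
  expect_error(spot_count_table(rbind(m, m)), "duplicate cell")
  expect_error(spot_count_table(matrix(-1, 1, 1, dimnames = list("a", "x"))), ">= 0")
  path <- withr::local_tempfile(fileext = ".csv")
  write_fish_table_csv(tab, path)
  expect_true(any(grepl("n.i.", readLines(path), fixed = TRUE)))
  back <- read_fish_table_csv(path)
  expect_equal(back$counts, tab$counts)
})

test_that("detection rate: single setting, ties, n.i. rules, rounding", {
  one <- spot_count_table(matrix(c(4, 7), 2, 1, dimnames = list(NULL, "z30")))
  expect_equal(detection_rate(one, "z30"), 100L)
  # a row with identical counts everywhere counts for every setting
  m <- matrix(c(2, 4, 6, 8, 9, 12), 1, 6,
              dimnames = list("1", paste0("z", c(5, 10, 15, 20, 25, 30))))
  flat <- spot_count_table(rbind(m, matrix(10, 1, 6, dimnames = list("x", colnames(m)))))
  expect_equal(detection_rate(flat, "z5"), 50L)   # only the all-10 row ties at z5
  expect_equal(detection_rate(flat, "z30"), 100L) # both rows peak at z30
  # n.i. ignored in the row max; fully-missing rows dropped with a warning
  m2 <- matrix(c(NA, 5, 2, NA, 9, NA), 3, 2,
               dimnames = list(1:3, c("a", "b")))
  t2 <- spot_count_table(m2)
  expect_warning(r <- detection_rate(t2, "b"), "dropped")
  expect_equal(r, 50L)  # row2 peaks at b, row3 at a, row1 dropped
  expect_warning(expect_equal(detection_rate(t2, "a"), 50L), "dropped")
  expect_error(detection_rate(t2, "zzz"), "unknown setting")
})

test_that("detection rates equal a brute-force oracle on random tables", {
  set.seed(77)
  for (rep in 1:40) {
    nr <- sample(3:12, 1); nc <- sample(2:6, 1)
    m <- matrix(sample(c(NA, 0:30), nr * nc, TRUE, prob = c(0.12, rep(1, 31))),
                nr, nc, dimnames = list(seq_len(nr), paste0("s", seq_len(nc))))
    keep <- rowSums(!is.na(m)) > 0
    m2 <- m[keep, , drop = FALSE]
    if (nrow(m2) == 0) next
    tab <- spot_count_table(m2)
    for (s in colnames(m2)) {
      hits <- 0
      for (i in seq_len(nrow(m2))) {
        rmax <- max(m2[i, ], na.rm = TRUE)
        if (!is.na(m2[i, s]) && m2[i, s] == rmax) hits <- hits + 1
      }
      expect_equal(detection_rate(tab, s),
                   as.integer(round(100 * hits / nrow(m2))))
    }
  }
})

test_that("detection rate is scale-free per row", {
  m <- matrix(c(2, 4, 6, 3, 8, 5), 2, 3,
              dimnames = list(1:2, c("a", "b", "c")))
  t1 <- spot_count_table(m)
  m2 <- m; m2[1, ] <- m[1, ] * 7; m2[2, ] <- m[2, ] * 3
  t2 <- spot_count_table(m2)
  expect_equal(detection_rates(t1), detection_rates(t2))
})

test_that("transcribed calibration tables load and have the printed shape", {
  t4 <- read_fish_table_csv(system.file("extdata", "step_sweep_alk.csv",
                                        package = "isetscan"))
  expect_equal(dim(t4), c(24L, 4L))
  expect_equal(colnames(t4$counts), paste0("step", c(0.5, 0.6, 0.7, 0.8)))
  t1 <- read_fish_table_csv(system.file("extdata", "zstack_sweep_alk.csv",
                                        package = "isetscan"))
  expect_equal(dim(t1), c(22L, 6L))
  expect_equal(sum(is.na(t1$counts)), 11L)  # the n.i. footnote entries
})

test_that("degenerate flat cohort: all z-stack settings equal", {
  # hand-built cells: well-separated spots, all at one height near focus,
  # so every comb captures every spot and all settings tie
  mk_cell <- function(id) structure(
    list(id = id, pattern = "native", nucleus_diameter_um = 20,
         thickness_um = 0, z_offset_um = 0,
         spots = data.frame(x_um = c(-5, 5, -5, 5), y_um = c(-5, -5, 5, 5),
                            z_um = 0.1, channel = c("red", "red", "green", "green"),
                            rate = 4, pair = c(1, 2, 1, 2), pair_type = "fused")),
    class = "fish_cell")
  cells <- lapply(1:4, mk_cell)
  sw <- zstack_sweep(cells, stacks = c(5, 15, 30), seed = 3,
                     model = quiet_model(), noise = FALSE)
  expect_true(all(sw$table$counts == 4))
  expect_true(all(sw$rates == 100L))
})

test_that("z-stack sweep: more stacks capture more; table trends upward", {
  cells <- simulate_fish_cells(8, nucleus_thickness_um = 14, seed = 5)
  sw <- zstack_sweep(cells, stacks = c(5, 30), seed = 6)
  expect_gte(sw$rates[["z30"]], sw$rates[["z5"]])
  expect_gt(sw$capture[["z30"]], sw$capture[["z5"]])
  # spot conservation: detected <= planted, per cell and setting
  planted <- vapply(cells, function(cl) nrow(cl$spots), numeric(1))
  expect_true(all(sw$table$counts <= planted + 1e-9, na.rm = TRUE))
  # reproducibility: same cohort + seed -> identical table
  sw2 <- zstack_sweep(cells, stacks = c(5, 30), seed = 6)
  expect_identical(sw$table$counts, sw2$table$counts)
})
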