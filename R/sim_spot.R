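# Synthetic filter-spot generator. Emulates what a scanned 1-mL ISET spot
# looks like in the four fluorescence channels: a hexagonal lattice of 8-um
# pores with autofluorescent debris, thousands of leukocyte-scale DAPI+/CD45+
# nuclei, rare CTC-scale DAPI+/CD45- cells with variable epithelial /
# mesenchymal marker levels, and deliberate touching-cell clusters. Every
# rendered cell is returned in a ground-truth table so downstream stages can
# be scored.

#' Cell population specification for a simulated spot
#'
#' Counts per cell type and the distributions of nuclear size and true marker
#' photon rates. Defaults state the conditions the assay describes: thousands
#' of leukocytes (6,000-20,000 per spot), rare CTCs, debris confined to
#' pores, and touching clusters of mixed composition to exercise the cluster
#' gates. Leukocyte nuclear areas stay below the 55 um^2 single-cell gate;
#' CTC areas are configurable up to >700 um^2 (a 30-um nucleus).
#'
#' @param n_leukocytes,n_ctc,n_debris Counts of single leukocytes, single
#'   CTCs and pore-debris blobs.
#' @param n_clusters Number of touching-cell clusters.
#' @param cluster_cells Integer range (length 2) of cells per cluster.
#' @param cluster_cd45neg_frac Probability that a cluster constituent is
#'   CD45-negative (CTC-like).
#' @param leukocyte_area_um2 Mean and sd of leukocyte nuclear area (um^2);
#'   draws are truncated below 55.
#' @param ctc_area_um2 Mean and sd of CTC nuclear area (um^2).
#' @param debris_area_um2 Range of debris blob area (um^2), sub-nuclear.
#' @param on_pore_frac Fraction of cells whose centre is snapped onto a pore.
#' @param ctc_phenotype_probs Probabilities of CTC phenotype
#'   (E+/M-, E+/M+, E-/M+, E-/M-).
#' @param rates Named list of photon-rate parameters (counts/ms units); see
#'   source for fields. Override to move marker levels.
#' @return Object of class `cell_population`.
#' @export
cell_population <- function(n_leukocytes = 6000, n_ctc = 10, n_debris = 400,
                            n_clusters = 30, cluster_cells = c(4, 6),
                            cluster_cd45neg_frac = 0.25,
                            leukocyte_area_um2 = c(mean = 42, sd = 7),
                            ctc_area_um2 = c(mean = 250, sd = 80),
                            debris_area_um2 = c(5, 20),
                            on_pore_frac = 0.3,
                            ctc_phenotype_probs = c(0.4, 0.3, 0.2, 0.1),
                            rates = NULL) {
  default_rates <- list(
    dapi_cell = c(3.0, 0.4), dapi_debris = c(1.2, 0.3),
    cd45_pos = c(2.5, 0.5), cd45_neg = 0.02,
    epi_pos = c(meanlog = log(1.5), sdlog = 0.5), marker_neg = 0.02,
    mes_pos_ctc = c(meanlog = log(1.2), sdlog = 0.5),
    mes_leukocyte = c(1.8, 0.4),
    pore_autofluor = 0.25)
  rates <- utils::modifyList(default_rates, rates %||% list())
  counts <- c(n_leukocytes, n_ctc, n_debris, n_clusters)
  if (any(counts < 0) || any(counts != round(counts))) stop("counts must be non-negative integers")
  stopifnot(length(cluster_cells) == 2L, cluster_cells[1] >= 2)
  structure(
    list(n_leukocytes = n_leukocytes, n_ctc = n_ctc, n_debris = n_debris,
         n_clusters = n_clusters, cluster_cells = as.integer(cluster_cells),
         cluster_cd45neg_frac = cluster_cd45neg_frac,
         leukocyte_area_um2 = leukocyte_area_um2, ctc_area_um2 = ctc_area_um2,
         debris_area_um2 = debris_area_um2, on_pore_frac = on_pore_frac,
         ctc_phenotype_probs = ctc_phenotype_probs, rates = rates),
    class = "cell_population")
}

# Draw per-cell truth rows for one cell of a given type.
draw_cell <- function(type, pop) {
  r <- pop$rates
  trunc_norm <- function(par, lo, hi) {
    repeat {
      v <- rnorm(1, par[[1]], par[[2]])
      if (v > lo && v < hi) return(v)
    }
  }
  if (type == "leukocyte" || type == "cluster_leukocyte") {
    area <- trunc_norm(pop$leukocyte_area_um2, 12, 54.9)
    list(area = area, thickness = runif(1, 3, 5),
         dapi = trunc_norm(r$dapi_cell, 1, 10),
         cd45 = trunc_norm(r$cd45_pos, 1.0, 10),
         epi = r$marker_neg, mes = trunc_norm(r$mes_leukocyte, 0.5, 10),
         phenotype = NA_character_)
  } else if (type == "ctc" || type == "cluster_ctc") {
    area <- trunc_norm(pop$ctc_area_um2, 60, 750)
    ph <- sample(c("E+/M-", "E+/M+", "E-/M+", "E-/M-"), 1,
                 prob = pop$ctc_phenotype_probs)
    epi <- if (ph %in% c("E+/M-", "E+/M+"))
      stats::rlnorm(1, r$epi_pos[["meanlog"]], r$epi_pos[["sdlog"]]) else r$marker_neg
    mes <- if (ph %in% c("E+/M+", "E-/M+"))
      stats::rlnorm(1, r$mes_pos_ctc[["meanlog"]], r$mes_pos_ctc[["sdlog"]]) else r$marker_neg
    list(area = area, thickness = runif(1, 8, 14),
         dapi = trunc_norm(r$dapi_cell, 1, 10), cd45 = r$cd45_neg,
         epi = epi, mes = mes, phenotype = ph)
  } else { # debris
    area <- runif(1, pop$debris_area_um2[1], pop$debris_area_um2[2])
    list(area = area, thickness = runif(1, 1, 2),
         dapi = trunc_norm(r$dapi_debris, 0.4, 4), cd45 = 0.05,
         epi = 0.02, mes = 0.02, phenotype = NA_character_)
  }
}

#' Generate a synthetic filter-spot image set
#'
#' Renders the four fluorescence channels (DAPI, CD45, epithelial,
#' mesenchymal) of a rectangular field of a filter spot, with a hexagonal
#' pore lattice, the requested cell population and per-channel detector
#' exposure, and returns the ground truth of every rendered object.
#'
#' A full 1-mL spot (~6 mm) is beyond desk scale at sub-micron pixels, so the
#' field is a sub-region sized automatically (unless `field_um` is given) to
#' hold the population at a leukocyte-realistic packing pitch; cell counts are
#' the quantity stated per spot. Debris blobs are confined to pore interiors.
#' If an explicit `field_um` cannot pack the requested population the
#' function fails rather than silently truncating.
#'
#' @param geometry A [filter_geometry()].
#' @param population A [cell_population()].
#' @param pixel_size_um Pixel size (um/px), default 0.5.
#' @param exposures_ms Named exposure times (ms) for channels
#'   `dapi`, `cd45`, `epithelial`, `mesenchymal`.
#' @param model An [exposure_model()].
#' @param field_um Optional length-2 field size (um); auto-sized when NULL.
#' @param placement_pitch_um Centre spacing of the jittered placement grid.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return Object of class `filter_spot`: list with `channels` (named list of
#'   [channel_image()]), `truth` (data frame, one row per rendered object),
#'   `pores` (pore centres), `geometry`, `field_um`, `pixel_size_um`, `model`.
#' @export
generate_filter_spot <- function(geometry = filter_geometry(),
                                 population = cell_population(),
                                 pixel_size_um = 0.5,
                                 exposures_ms = c(dapi = 30, cd45 = 60,
                                                  epithelial = 60, mesenchymal = 40),
                                 model = exposure_model(),
                                 field_um = NULL,
                                 placement_pitch_um = 18,
                                 seed = 1) {
  stopifnot(inherits(geometry, "filter_geometry"),
            inherits(population, "cell_population"))
  with_seed(seed, {
    pop <- population
    n_sites_needed <- pop$n_leukocytes + pop$n_ctc + pop$n_clusters
    if (is.null(field_um)) {
      side <- max(ceiling(sqrt(max(n_sites_needed, 1) * 1.1)), 4) * placement_pitch_um
      field_um <- c(side, side)
    } else {
      n_avail <- floor(field_um[1] / placement_pitch_um) *
        floor(field_um[2] / placement_pitch_um)
      if (n_avail < n_sites_needed)
        stop(sprintf(
          "population needs %d placement sites but the %g x %g um field packs only %d",
          n_sites_needed, field_um[1], field_um[2], n_avail), call. = FALSE)
    }
    nx <- as.integer(ceiling(field_um[1] / pixel_size_um))
    ny <- as.integer(ceiling(field_um[2] / pixel_size_um))

    chans <- c("dapi", "cd45", "epithelial", "mesenchymal")
    rate <- setNames(lapply(chans, function(ch) matrix(0, ny, nx)), chans)

    # --- pore lattice + autofluorescent texture in DAPI ------------------
    pores <- pore_lattice(geometry, field_um)
    pore_r_px <- geometry$pore_diameter_um / 2 / pixel_size_um
    pore_rate <- pop$rates$pore_autofluor
    if (nrow(pores) > 0 && pore_rate > 0) {
      jitter_lvl <- pore_rate * runif(nrow(pores), 0.5, 1.5)
      for (p in seq_len(nrow(pores))) {
        cx <- pores$x_um[p] / pixel_size_um + 0.5
        cy <- pores$y_um[p] / pixel_size_um + 0.5
        xs <- max(1L, floor(cx - pore_r_px - 1)):min(nx, ceiling(cx + pore_r_px + 1))
        ys <- max(1L, floor(cy - pore_r_px - 1)):min(ny, ceiling(cy + pore_r_px + 1))
        if (!length(xs) || !length(ys)) next
        dx <- (xs - cx); dy <- (ys - cy)
        rr <- sqrt(outer(dy^2, dx^2, `+`))
        inside <- rr <= pore_r_px
        rate$dapi[ys, xs][inside] <- rate$dapi[ys, xs][inside] + jitter_lvl[p]
      }
    }

    # --- place cells -----------------------------------------------------
    pitch <- placement_pitch_um
    gx <- seq(pitch / 2, field_um[1] - pitch / 2, by = pitch)
    gy <- seq(pitch / 2, field_um[2] - pitch / 2, by = pitch)
    sites <- expand.grid(x = gx, y = gy)
    sites <- sites[sample.int(nrow(sites)), , drop = FALSE]
    jit <- pitch * 0.18
    sites$x <- clamp(sites$x + runif(nrow(sites), -jit, jit), 4, field_um[1] - 4)
    sites$y <- clamp(sites$y + runif(nrow(sites), -jit, jit), 4, field_um[2] - 4)
    if (nrow(sites) < n_sites_needed)
      stop("population exceeds packable area", call. = FALSE)

    truth <- list(); cell_id <- 0L; site_i <- 0L
    add_cell <- function(type, x, y, cluster_id = NA_integer_, on_pore = FALSE) {
      cell_id <<- cell_id + 1L
      d <- draw_cell(type, pop)
      ecc <- runif(1, 0.75, 1)                     # axis ratio b/a
      a <- sqrt(d$area / (pi * ecc)); b <- a * ecc # um semi-axes
      truth[[cell_id]] <<- data.frame(
        id = cell_id, type = sub("cluster_", "", type),
        x_um = x, y_um = y, area_um2 = pi * a * b,
        equiv_diameter_um = equiv_diameter_um(pi * a * b),
        thickness_um = d$thickness, axis_a_um = a, axis_b_um = b,
        angle = runif(1, 0, pi),
        dapi_rate = d$dapi, cd45_rate = d$cd45,
        epithelial_rate = d$epi, mesenchymal_rate = d$mes,
        phenotype = d$phenotype, on_pore = on_pore,
        cluster_id = cluster_id, stringsAsFactors = FALSE)
    }
    pore_taken <- rep(FALSE, nrow(pores))
    snap_to_pore <- function(x, y) {
      # a pore seats one cell: snapping two cells onto the same pore centre
      # would stack them, which filtration does not do
      if (nrow(pores) == 0) return(c(x, y, FALSE))
      d2 <- (pores$x_um - x)^2 + (pores$y_um - y)^2
      d2[pore_taken] <- Inf
      k <- which.min(d2)
      if (!is.finite(d2[k]) || d2[k] > geometry$pore_pitch_um^2)
        return(c(x, y, FALSE))
      pore_taken[k] <<- TRUE
      c(pores$x_um[k], pores$y_um[k], TRUE)
    }
    next_site <- function() {
      site_i <<- site_i + 1L
      if (site_i > nrow(sites)) stop("population exceeds packable area", call. = FALSE)
      sites[site_i, ]
    }

    # CTCs first, with a clearance zone: isolated (non-cluster) cells do not
    # overlap in projection - touching-nuclei groups are what the cluster
    # spec models, so accidental CTC/leukocyte merges are not part of the
    # stated world
    ctc_pos <- matrix(numeric(0), 0, 3)  # x, y, clearance radius
    for (i in seq_len(pop$n_ctc)) {
      repeat {
        s <- next_site(); x <- s$x; y <- s$y; onp <- FALSE
        if (runif(1) < pop$on_pore_frac) {
          sp <- snap_to_pore(x, y); x <- sp[1]; y <- sp[2]; onp <- sp[3] > 0
        }
        if (nrow(ctc_pos) == 0 ||
            all(sqrt((ctc_pos[, 1] - x)^2 + (ctc_pos[, 2] - y)^2) >
                  ctc_pos[, 3] + 16)) break
      }
      add_cell("ctc", x, y, on_pore = onp)
      r_clear <- truth[[cell_id]]$equiv_diameter_um / 2 + 5.5
      ctc_pos <- rbind(ctc_pos, c(x, y, r_clear))
    }
    clear_of_ctcs <- function(x, y) {
      nrow(ctc_pos) == 0 ||
        all(sqrt((ctc_pos[, 1] - x)^2 + (ctc_pos[, 2] - y)^2) > ctc_pos[, 3])
    }
    for (i in seq_len(pop$n_leukocytes)) {
      repeat {
        s <- next_site(); x <- s$x; y <- s$y
        if (clear_of_ctcs(x, y)) break
      }
      onp <- FALSE
      if (runif(1) < pop$on_pore_frac) {
        sp <- snap_to_pore(x, y)
        if (clear_of_ctcs(sp[1], sp[2])) { x <- sp[1]; y <- sp[2]; onp <- sp[3] > 0 }
      }
      add_cell("leukocyte", x, y, on_pore = onp)
    }
    for (cl in seq_len(pop$n_clusters)) {
      repeat { s <- next_site(); if (clear_of_ctcs(s$x, s$y)) break }
      k <- sample(pop$cluster_cells[1]:pop$cluster_cells[2], 1)
      ang0 <- runif(1, 0, 2 * pi)
      px <- s$x; py <- s$y
      for (m in seq_len(k)) {
        add_cell("cluster_leukocyte", px, py, cluster_id = cl)
        if (runif(1) < pop$cluster_cd45neg_frac) {
          # CTC-like constituent: leukocyte-sized but CD45-negative
          truth[[cell_id]]$cd45_rate <- pop$rates$cd45_neg
          truth[[cell_id]]$type <- "ctc"
        }
        # chain placement: next cell touches the previous one
        r_prev <- truth[[cell_id]]$equiv_diameter_um / 2
        step <- 2 * r_prev * 0.85
        ang0 <- ang0 + runif(1, -0.9, 0.9)
        px <- clamp(px + step * cos(ang0), 4, field_um[1] - 4)
        py <- clamp(py + step * sin(ang0), 4, field_um[2] - 4)
      }
    }
    # debris: only inside pores
    if (pop$n_debris > 0 && nrow(pores) > 0) {
      marg <- geometry$pore_diameter_um / 2 + 1
      inner <- pores[pores$x_um > marg & pores$x_um < field_um[1] - marg &
                       pores$y_um > marg & pores$y_um < field_um[2] - marg, , drop = FALSE]
      dp <- inner[sample.int(nrow(inner), min(pop$n_debris, nrow(inner))), , drop = FALSE]
      for (i in seq_len(nrow(dp))) {
        off <- runif(2, -1, 1) * geometry$pore_diameter_um / 4
        add_cell("debris", dp$x_um[i] + off[1], dp$y_um[i] + off[2], on_pore = TRUE)
      }
    }
    truth <- do.call(rbind, truth)

    # --- render cells into rate images -----------------------------------
    edge_w <- 0.12  # um; soft-edge width of the nuclear boundary
    if (!is.null(truth) && nrow(truth) > 0) {
      for (i in seq_len(nrow(truth))) {
        a <- truth$axis_a_um[i]; b <- truth$axis_b_um[i]; th <- truth$angle[i]
        cx <- truth$x_um[i] / pixel_size_um + 0.5
        cy <- truth$y_um[i] / pixel_size_um + 0.5
        rmax <- (max(a, b) + 1) / pixel_size_um
        xs <- max(1L, floor(cx - rmax)):min(nx, ceiling(cx + rmax))
        ys <- max(1L, floor(cy - rmax)):min(ny, ceiling(cy + rmax))
        if (!length(xs) || !length(ys)) next
        dx <- (xs - cx) * pixel_size_um; dy <- (ys - cy) * pixel_size_um
        DX <- matrix(dx, length(ys), length(xs), byrow = TRUE)
        DY <- matrix(dy, length(ys), length(xs))
        xr <- DX * cos(th) + DY * sin(th)
        yr <- -DX * sin(th) + DY * cos(th)
        rn <- sqrt((xr / a)^2 + (yr / b)^2)
        fac <- stats::plogis((1 - rn) * sqrt(a * b) / edge_w)
        fac[fac < 1e-3] <- 0
        if (all(fac == 0)) next
        rate$dapi[ys, xs] <- rate$dapi[ys, xs] + truth$dapi_rate[i] * fac
        rate$cd45[ys, xs] <- rate$cd45[ys, xs] + truth$cd45_rate[i] * fac
        rate$epithelial[ys, xs] <- rate$epithelial[ys, xs] + truth$epithelial_rate[i] * fac
        rate$mesenchymal[ys, xs] <- rate$mesenchymal[ys, xs] + truth$mesenchymal_rate[i] * fac
      }
    }

    channels <- setNames(lapply(chans, function(ch) {
      img <- apply_exposure(rate[[ch]], exposures_ms[[ch]], model,
                            noise = model$read_noise_sd > 0 || model$shot_noise)
      channel_image(img, pixel_size_um, channel = ch,
                    exposure_ms = exposures_ms[[ch]])
    }), chans)

    structure(
      list(channels = channels, truth = truth, pores = pores,
           geometry = geometry, field_um = field_um,
           pixel_size_um = pixel_size_um, model = model,
           exposures_ms = exposures_ms, seed = seed),
      class = "filter_spot")
  })
}

#' @export
print.filter_spot <- function(x, ...) {
  n <- if (is.null(x$truth)) 0L else nrow(x$truth)
  cat(sprintf(
    "<filter_spot> %.0f x %.0f um field @ %.2g um/px; %d objects (%s); %d pores\n",
    x$field_um[1], x$field_um[2], x$pixel_size_um, n,
    if (n) paste(names(table(x$truth$type)), table(x$truth$type),
                 sep = ":", collapse = " ") else "empty",
    nrow(x$pores)))
  invisible(x)
}
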