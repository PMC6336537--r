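# Synthetic screen generator: a planted differentiation/morphology response
# driven by topography descriptors, realised as per-cell measurement tables
# and, optionally, rendered three-channel image stacks with ground truth.

#' Construct a planted response model
#'
#' Rules are evaluated in order against a design's descriptor vector; the
#' first rule whose conditions all hold assigns the unit's differentiation
#' probability and the morphology class of its differentiated cells. A
#' condition on an absent (`NA`) descriptor never holds, so e.g. the flat
#' control always falls through to the baseline. Each rule is a list with
#' elements `conditions` (list of `list(feature, op, value)` with `op` one
#' of `">="`, `"<"`, `">"`, `"<="`), `p_diff` and `morph` (`"round"` or
#' `"spread"`).
#'
#' @param rules Ordered list of rules.
#' @param baseline Differentiation probability when no rule matches.
#' @param baseline_morph Morphology of baseline differentiated cells.
#' @return An object of class `planted_model`.
#' @export
planted_model <- function(rules, baseline = 0.12, baseline_morph = "round") {
  for (r in rules) {
    if (is.null(r$p_diff) || r$p_diff < 0 || r$p_diff > 1) {
      stopf("rule p_diff must lie in [0, 1]")
    }
    if (!r$morph %in% c("round", "spread")) stopf("rule morph must be round/spread")
    for (cond in r$conditions) {
      if (!cond$op %in% c(">=", "<", ">", "<=")) stopf("bad rule operator")
    }
  }
  if (baseline < 0 || baseline > 1) stopf("baseline must lie in [0, 1]")
  structure(list(rules = rules, baseline = baseline,
                 baseline_morph = baseline_morph),
            class = "planted_model")
}

#' The default planted model
#'
#' Encodes the decision structure used throughout the package's synthetic
#' screens: units with high coverage and large circle elements
#' (`fcp >= 0.256`, `circ_diam >= 8.293`) differentiate strongly as round
#' cells; units with low coverage and short line elements (`fcp < 0.256`,
#' `line_len < 15.849`) differentiate strongly as spread cells when the
#' topography is either low-coverage under added variation
#' (`fcpn01 < 0.397`) or irregular (`rot_sd >= 40.876`), and as round cells
#' otherwise; everything else differentiates at the baseline rate of 0.12.
#'
#' @return A `planted_model`.
#' @export
default_planted_model <- function() {
  cond <- function(f, op, v) list(feature = f, op = op, value = v)
  planted_model(list(
    list(name = "round_high_coverage",
         conditions = list(cond("fcp", ">=", 0.256),
                           cond("circ_diam", ">=", 8.293)),
         p_diff = 0.5, morph = "round"),
    list(name = "spread_low_coverage",
         conditions = list(cond("fcp", "<", 0.256),
                           cond("line_len", "<", 15.849),
                           cond("fcpn01", "<", 0.397)),
         p_diff = 0.45, morph = "spread"),
    list(name = "spread_irregular",
         conditions = list(cond("fcp", "<", 0.256),
                           cond("line_len", "<", 15.849),
                           cond("rot_sd", ">=", 40.876)),
         p_diff = 0.45, morph = "spread"),
    list(name = "round_low_coverage",
         conditions = list(cond("fcp", "<", 0.256),
                           cond("line_len", "<", 15.849)),
         p_diff = 0.45, morph = "round")
  ), baseline = 0.12, baseline_morph = "round")
}

#' Features named by a planted model's rules
#' @param model A `planted_model`.
#' @return Character vector of descriptor names.
#' @export
planted_features <- function(model) {
  unique(unlist(lapply(model$rules, function(r) {
    vapply(r$conditions, function(cond) cond$feature, character(1))
  })))
}

#' Match a descriptor vector against a planted model
#'
#' @param model A `planted_model`.
#' @param dv A one-row data.frame (or named list) of descriptors.
#' @return A list `p_diff`, `morph`, `rule` (rule name or `"baseline"`).
#' @export
match_rule <- function(model, dv) {
  for (r in model$rules) {
    ok <- TRUE
    for (cond in r$conditions) {
      v <- dv[[cond$feature]]
      if (is.null(v) || length(v) == 0L || is.na(v)) { ok <- FALSE; break }
      hold <- switch(cond$op,
                     ">=" = v >= cond$value, "<" = v < cond$value,
                     ">" = v > cond$value, "<=" = v <= cond$value)
      if (!hold) { ok <- FALSE; break }
    }
    if (ok) {
      return(list(p_diff = r$p_diff, morph = r$morph,
                  rule = r$name %||% "rule"))
    }
  }
  list(p_diff = model$baseline, morph = model$baseline_morph,
       rule = "baseline")
}

#' Write / read a planted model (JSON)
#' @param model A `planted_model`.
#' @param path File path.
#' @export
write_planted_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_planted_model
#' @export
read_planted_model <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  planted_model(x$rules, baseline = x$baseline,
                baseline_morph = x$baseline_morph %||% "round")
}

#' Cell population parameters of the generator
#'
#' Differentiated cells draw spread area from a log-normal whose median and
#' log-sd depend on the morphology class (round: median 500 um2; spread:
#' median 1800 um2; both sigma_log 0.5, matching the wide per-unit spread
#' of screened cell areas) and roundness from a beta
#' distribution with class mean 0.70 (round) or 0.30 (spread); the
#' perimeter is derived as `P = sqrt(4*pi*area/roundness)` so that the
#' circularity statistic recovers the drawn roundness by construction.
#' Undifferentiated cells use the round (confined stem cell) morphology.
#' TGM1 MFI is Normal(600, 120) for differentiated cells and
#' Normal(80, 40) truncated at zero otherwise, placing the MFI = 270
#' positivity cutoff between the two modes.
#'
#' @param round_area_median,spread_area_median Log-normal medians (um2).
#' @param area_sdlog Log-sd of the area distributions.
#' @param round_roundness_mean,spread_roundness_mean Beta means.
#' @param roundness_conc Beta concentration (a + b).
#' @param mfi_pos_mean,mfi_pos_sd,mfi_neg_mean,mfi_neg_sd MFI parameters.
#' @param n_cells_range Uniform integer range of cells per unit.
#' @param min_spacing Minimum nucleus centre spacing (um).
#' @param margin Margin kept between nucleus centres and unit walls (um).
#' @return A list of class `morph_params`.
#' @export
morph_params <- function(round_area_median = 500, spread_area_median = 1800,
                         area_sdlog = 0.5, round_roundness_mean = 0.70,
                         spread_roundness_mean = 0.30, roundness_conc = 10,
                         mfi_pos_mean = 600, mfi_pos_sd = 120,
                         mfi_neg_mean = 80, mfi_neg_sd = 40,
                         n_cells_range = c(5, 25), min_spacing = 20,
                         margin = 20) {
  structure(as.list(environment()), class = "morph_params")
}

# rejection-free truncated normal (lower bound) via inverse CDF
rtnorm_lower <- function(n, mean, sd, lower) {
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(stats::runif(n, p0, 1), mean, sd)
}

rbeta_mean <- function(n, mean, conc) stats::rbeta(n, mean * conc, (1 - mean) * conc)

place_nuclei <- function(n, unit_side, min_spacing, margin, max_tries = 200L) {
  lo <- margin; hi <- unit_side - margin
  if (hi <= lo) stopf("margin leaves no room for nuclei")
  xs <- numeric(n); ys <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      x <- stats::runif(1, lo, hi); y <- stats::runif(1, lo, hi)
      if (i == 1L ||
          min((xs[1:(i - 1)] - x)^2 + (ys[1:(i - 1)] - y)^2) >= min_spacing^2) {
        xs[i] <- x; ys[i] <- y; ok <- TRUE; break
      }
    }
    if (!ok) {
      stopf("could not place %d nuclei with %g um spacing after %d tries",
            n, min_spacing, max_tries)
    }
  }
  list(x = xs, y = ys)
}

# core cell draw shared by simulate_unit and simulate_screen; assumes the
# RNG is already seeded by the caller
draw_cells <- function(n_cells, p_diff, morph, params, unit_side,
                       positions = TRUE) {
  diff <- stats::runif(n_cells) < p_diff
  cls <- ifelse(diff, morph, "round")
  spread <- cls == "spread"
  med <- ifelse(spread, params$spread_area_median, params$round_area_median)
  area <- stats::rlnorm(n_cells, log(med), params$area_sdlog)
  rmean <- ifelse(spread, params$spread_roundness_mean,
                  params$round_roundness_mean)
  roundness <- rbeta_mean(n_cells, rmean, params$roundness_conc)
  perimeter <- sqrt(4 * pi * area / roundness)
  mfi <- ifelse(diff,
                stats::rnorm(n_cells, params$mfi_pos_mean, params$mfi_pos_sd),
                rtnorm_lower(n_cells, params$mfi_neg_mean, params$mfi_neg_sd, 0))
  orient <- stats::runif(n_cells, 0, 180)
  pos <- if (positions) {
    place_nuclei(n_cells, unit_side, params$min_spacing, params$margin)
  } else list(x = rep(NA_real_, n_cells), y = rep(NA_real_, n_cells))
  quick_df(list(cell_id = seq_len(n_cells), true_diff = diff,
                true_morph = cls, area_um2 = area, perimeter_um = perimeter,
                roundness = roundness, tgm1_mfi = mfi,
                nx_um = pos$x, ny_um = pos$y, orient_deg = orient))
}

#' Simulate the cells of one TopoUnit
#'
#' The number of cells is uniform on `n_cells_range` (default 5 to 25, the
#' density observed on screened units); each cell differentiates with the
#' unit's matched probability and draws morphology and TGM1 intensity from
#' the class distributions of [morph_params()]. Nucleus centres are placed
#' uniformly with a minimum spacing.
#'
#' @param dv Descriptor vector (one-row data.frame or named list).
#' @param model A `planted_model`.
#' @param seed Integer seed.
#' @param params A [morph_params()].
#' @param unit_side Unit side in micrometres.
#' @param positions Sample nucleus centres (disable for table-only speed).
#' @return A data.frame of simulated cells with the planted assignment in
#'   attributes `p_diff`, `morph` and `rule`.
#' @export
simulate_unit <- function(dv, model, seed = 1, params = morph_params(),
                          unit_side = 300, positions = TRUE) {
  hit <- match_rule(model, dv)
  cells <- with_seed(seed, {
    n <- sample.int(params$n_cells_range[2] - params$n_cells_range[1] + 1L,
                    1L) + params$n_cells_range[1] - 1L
    draw_cells(n, hit$p_diff, hit$morph, params, unit_side, positions)
  })
  attr(cells, "p_diff") <- hit$p_diff
  attr(cells, "morph") <- hit$morph
  attr(cells, "rule") <- hit$rule
  cells
}

#' Simulate a whole-chip screen
#'
#' Draws an independent cell population for every occupied layout position
#' (duplicate units of a design share their planted parameters but not
#' their realisations) and records the planted ground truth per unit.
#' Per-unit seeds are derived from `seed` and the position index, so the
#' whole screen is a pure function of `(seed, library, layout, model)`.
#'
#' @param library A `topo_library` (used for unit geometry).
#' @param layout A `chip_layout`.
#' @param model A `planted_model`.
#' @param descriptors Descriptor table from [library_descriptors()].
#' @param seed Integer seed.
#' @param params A [morph_params()].
#' @param positions Sample nucleus centres per cell.
#' @param chip_id Identifier recorded in the tables.
#' @return A list of class `screen_tables` with `cells` (one row per cell)
#'   and `truth` (one row per unit: planted `p_diff`, `morph`, `rule`,
#'   realised `n_cells`).
#' @export
simulate_screen <- function(library, layout, model, descriptors, seed = 1,
                            params = morph_params(), positions = TRUE,
                            chip_id = "chip1") {
  cells_pos <- layout$cells
  n_units <- nrow(cells_pos)
  unit_side <- library[[1]]$unit_side
  drow <- match(cells_pos$design_id, descriptors$design_id)
  if (anyNA(drow)) stopf("descriptors missing for some layout designs")
  unit_cells <- vector("list", n_units)
  p_diff <- numeric(n_units); morph <- character(n_units)
  rule <- character(n_units); n_cells <- integer(n_units)
  for (u in seq_len(n_units)) {
    dv <- descriptors[drow[u], , drop = FALSE]
    cells <- simulate_unit(dv, model, seed = seed + u, params = params,
                           unit_side = unit_side, positions = positions)
    p_diff[u] <- attr(cells, "p_diff")
    morph[u] <- attr(cells, "morph")
    rule[u] <- attr(cells, "rule")
    n_cells[u] <- nrow(cells)
    unit_cells[[u]] <- cells
  }
  per_unit <- rep.int(seq_len(n_units), n_cells)
  bind_col <- function(col) unlist(lapply(unit_cells, `[[`, col), use.names = FALSE)
  cells <- quick_df(list(
    chip_id = rep(chip_id, length(per_unit)),
    row = cells_pos$row[per_unit], col = cells_pos$col[per_unit],
    design_id = cells_pos$design_id[per_unit],
    cell_id = bind_col("cell_id"),
    true_diff = bind_col("true_diff"), true_morph = bind_col("true_morph"),
    area_um2 = bind_col("area_um2"), perimeter_um = bind_col("perimeter_um"),
    roundness = bind_col("roundness"), tgm1_mfi = bind_col("tgm1_mfi"),
    nx_um = bind_col("nx_um"), ny_um = bind_col("ny_um"),
    orient_deg = bind_col("orient_deg")))
  truth <- quick_df(list(
    chip_id = rep(chip_id, n_units),
    row = cells_pos$row, col = cells_pos$col,
    design_id = cells_pos$design_id,
    p_diff = p_diff, morph = morph, rule = rule, n_cells = n_cells))
  structure(list(cells = cells, truth = truth), class = "screen_tables")
}

#' @export
print.screen_tables <- function(x, ...) {
  cat(sprintf("screen_tables: %d units, %d cells, %.1f%% planted above baseline\n",
              nrow(x$truth), nrow(x$cells),
              100 * mean(x$truth$rule != "baseline")))
  invisible(x)
}

# roundness of an ellipse as a function of its axis ratio q = b/a
# (Ramanujan perimeter approximation); monotone increasing in q
ellipse_roundness <- function(q) {
  h <- ((1 - q) / (1 + q))^2
  p <- pi * (3 * (1 + q) - sqrt((3 + q) * (1 + 3 * q)))
  pr <- p * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))  # perimeter / a
  4 * pi * (pi * q) / pr^2
}

ellipse_axis_ratio <- function(roundness) {
  if (roundness >= 1) return(1)
  stats::uniroot(function(q) ellipse_roundness(q) - roundness,
                 c(1e-4, 1), tol = 1e-9)$root
}

#' Render a simulated unit as a three-channel image stack
#'
#' Each cell is drawn as a rotated ellipse matching its drawn area and
#' roundness. Where cell bodies touch or overlap, each foreground pixel
#' belongs to the nearest nucleus within its connected clump of cells,
#' mirroring the seeded region growing used at quantification time (cells
#' in a clump share a continuous F-actin region whose internal boundaries
#' fall midway between nuclei). DAPI shows nucleus
#' disks (diameter 10 um), F-actin fills cell bodies at intensity 200 and
#' the TGM1 channel fills each cell at its own MFI, so the median intensity
#' over a correctly segmented cell recovers the simulated MFI exactly.
#' Independent Gaussian noise (sd `noise_sd`, clamped at zero) is added to
#' the three intensity channels; the label raster is noise-free.
#'
#' @param cells A data.frame from [simulate_unit()] (with positions).
#' @param resolution Micrometres per pixel.
#' @param unit_side Unit side in micrometres.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param seed Integer seed for the noise.
#' @param factin_intensity,dapi_intensity Channel fill intensities.
#' @param nucleus_diam Nucleus disk diameter in micrometres.
#' @return A list of class `image_stack` with matrices `dapi`, `factin`,
#'   `tgm1`, `labels` and the `resolution`.
#' @export
render_unit <- function(cells, resolution = 0.5, unit_side = 300,
                        noise_sd = 0, seed = 1, factin_intensity = 200,
                        dapi_intensity = 255, nucleus_diam = 10) {
  if (anyNA(cells$nx_um)) stopf("cells carry no nucleus positions")
  n <- round(unit_side / resolution)
  union <- matrix(FALSE, n, n)
  tgm1 <- matrix(0, n, n); factin <- matrix(0, n, n); dapi <- matrix(0, n, n)
  cs <- (seq_len(n) - 0.5) * resolution
  ctr_r <- integer(nrow(cells)); ctr_c <- integer(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    q <- ellipse_axis_ratio(min(cells$roundness[i], 1))
    a <- sqrt(cells$area_um2[i] / (pi * q)); b <- a * q
    th <- cells$orient_deg[i] * pi / 180
    cx <- cells$nx_um[i]; cy <- cells$ny_um[i]
    half <- a
    ci <- max(1L, ceiling((cx - half) / resolution))
    cj <- min(n, floor((cx + half) / resolution + 1))
    ri <- max(1L, ceiling((cy - half) / resolution))
    rj <- min(n, floor((cy + half) / resolution + 1))
    ctr_r[i] <- min(n, max(1L, round(cy / resolution + 0.5)))
    ctr_c[i] <- min(n, max(1L, round(cx / resolution + 0.5)))
    union[ctr_r[i], ctr_c[i]] <- TRUE
    if (ci > cj || ri > rj) next
    X <- matrix(cs[ci:cj], rj - ri + 1L, cj - ci + 1L, byrow = TRUE) - cx
    Y <- matrix(cs[ri:rj], rj - ri + 1L, cj - ci + 1L) - cy
    U <- (X * cos(th) + Y * sin(th)) / a
    V <- (-X * sin(th) + Y * cos(th)) / b
    union[ri:rj, ci:cj] <- union[ri:rj, ci:cj] | ((U * U + V * V) <= 1)
  }
  # assign each foreground pixel to the nearest nucleus of its clump
  labels <- matrix(0L, n, n)
  comp <- label_components8(union)
  nuc_comp <- comp[cbind(ctr_r, ctr_c)]
  for (cc in unique(nuc_comp)) {
    idx <- which(comp == cc)
    members <- which(nuc_comp == cc)
    px <- cs[((idx - 1L) %/% n) + 1L]  # column -> x
    py <- cs[((idx - 1L) %% n) + 1L]   # row -> y
    best_d <- rep(Inf, length(idx)); best_i <- integer(length(idx))
    for (i in members) {
      d2 <- (px - cells$nx_um[i])^2 + (py - cells$ny_um[i])^2
      upd <- d2 < best_d
      best_d[upd] <- d2[upd]; best_i[upd] <- i
    }
    labels[idx] <- best_i
  }
  body <- labels > 0L
  factin[body] <- factin_intensity
  tgm1[body] <- cells$tgm1_mfi[labels[body]]
  # nucleus disks
  rad <- nucleus_diam / 2
  for (i in seq_len(nrow(cells))) {
    cx <- cells$nx_um[i]; cy <- cells$ny_um[i]
    ci <- max(1L, ceiling((cx - rad) / resolution))
    cj <- min(n, floor((cx + rad) / resolution + 1))
    ri <- max(1L, ceiling((cy - rad) / resolution))
    rj <- min(n, floor((cy + rad) / resolution + 1))
    X <- matrix(cs[ci:cj], rj - ri + 1L, cj - ci + 1L, byrow = TRUE) - cx
    Y <- matrix(cs[ri:rj], rj - ri + 1L, cj - ci + 1L) - cy
    disk <- (X * X + Y * Y) <= rad^2
    sub <- dapi[ri:rj, ci:cj]
    sub[disk] <- dapi_intensity
    dapi[ri:rj, ci:cj] <- sub
  }
  if (noise_sd > 0) {
    with_seed(seed, {
      dapi <- pmax(dapi + stats::rnorm(n * n, 0, noise_sd), 0)
      factin <- pmax(factin + stats::rnorm(n * n, 0, noise_sd), 0)
      tgm1 <- pmax(tgm1 + stats::rnorm(n * n, 0, noise_sd), 0)
    })
    dim(dapi) <- dim(factin) <- dim(tgm1) <- c(n, n)
  }
  structure(list(dapi = dapi, factin = factin, tgm1 = tgm1, labels = labels,
                 resolution = resolution),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image_stack: %d x %d px at %g um/px, %d cells\n",
              nrow(x$dapi), ncol(x$dapi), x$resolution,
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

#' Write / read an image stack as a multi-page TIFF
#'
#' Pages are DAPI, F-actin, TGM1 and the ground-truth label raster, stored
#' as 32-bit floats; the resolution is recorded in a JSON sidecar.
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path.
#' @export
write_stack <- function(stack, path) {
  pages <- lapply(stack[c("dapi", "factin", "tgm1")],
                  function(m) m / 65535)
  pages$labels <- stack$labels / 65535
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(resolution_um_px = stack$resolution),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  structure(list(dapi = pages[[1]] * 65535, factin = pages[[2]] * 65535,
                 tgm1 = pages[[3]] * 65535,
                 labels = matrix(as.integer(round(pages[[4]] * 65535)),
                                 nrow(pages[[4]])),
                 resolution = meta$resolution_um_px),
            class = "image_stack")
}
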