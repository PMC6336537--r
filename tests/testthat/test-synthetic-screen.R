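test_that("rule matching is ordered and treats absent descriptors as no-match", {
  pm <- default_planted_model()
  flat <- list(fcp = 0, fcpn01 = 0.01, line_len = NA_real_,
               circ_diam = NA_real_, rot_sd = NA_real_)
  hit <- match_rule(pm, flat)
  expect_equal(hit$rule, "baseline")
  expect_equal(hit$p_diff, 0.12)
  round_dv <- list(fcp = 0.3, fcpn01 = 0.31, line_len = 30, circ_diam = 10,
                   rot_sd = 50)
  hit <- match_rule(pm, round_dv)
  expect_equal(hit$morph, "round")
  expect_equal(hit$p_diff, 0.5)
  spread_dv <- list(fcp = 0.1, fcpn01 = 0.11, line_len = 10, circ_diam = 5,
                    rot_sd = 50)
  hit <- match_rule(pm, spread_dv)
  expect_equal(hit$morph, "spread")
  expect_equal(hit$p_diff, 0.45)
})

test_that("planted model JSON round-trips", {
  pm <- default_planted_model()
  f <- withr::local_tempfile(fileext = ".json")
  write_planted_model(pm, f)
  back <- read_planted_model(f)
  expect_equal(back$baseline, pm$baseline)
  expect_equal(planted_features(back), planted_features(pm))
  expect_equal(length(back$rules), length(pm$rules))
})

test_that("no cell differentiates under a zero planted probability", {
  pm <- planted_model(list(), baseline = 0)
  cells <- simulate_unit(list(fcp = 0.2), pm, seed = 1, positions = FALSE)
  expect_false(any(cells$true_diff))
})

test_that("forced spread differentiation yields the log-normal mean area", {
  pm <- planted_model(list(), baseline = 1, baseline_morph = "spread")
  mp <- morph_params(n_cells_range = c(1000, 1000))
  cells <- simulate_unit(list(fcp = 0.2), pm, seed = 3, params = mp,
                         positions = FALSE)
  expect_true(all(cells$true_diff))
  expect_gt(mean(cells$area_um2), 1500)
  expect_lt(mean(cells$area_um2), 2200)
})

test_that("every simulated cell satisfies the isoperimetric identity", {
  fx <- fx_small()
  pm <- default_planted_model()
  cells <- do.call(rbind, lapply(1:20, function(i) {
    simulate_unit(fx$dv[i, ], pm, seed = i, positions = FALSE)
  }))
  expect_true(all(cells$area_um2 > 0))
  expect_equal(4 * pi * cells$area_um2 / cells$perimeter_um^2,
               cells$roundness, tolerance = 1e-9)
  # isoperimetric bound: perimeter >= that of a disk of equal area
  expect_true(all(cells$perimeter_um >= 2 * sqrt(pi * cells$area_um2) - 1e-9))
  expect_true(all(cells$tgm1_mfi >= 0))
})

test_that("the MFI cutoff recovers the planted rate at baseline", {
  pm <- planted_model(list(), baseline = 0.12)
  mp <- morph_params(n_cells_range = c(10000, 10000))
  cells <- simulate_unit(list(fcp = 0), pm, seed = 9, params = mp,
                         positions = FALSE)
  realized <- mean(cells$tgm1_mfi > 270)
  # misclassification across the 270 cutoff is below 0.5%
  mis_pos <- pnorm(270, 600, 120)
  expect_lt(mis_pos, 0.005)
  se <- sqrt(0.12 * 0.88 / 10000)
  expect_lt(abs(realized - 0.12 * (1 - mis_pos)), 3 * se + 0.005 * 0.12)
})

test_that("screens are pure functions of the seed with shared planted truth", {
  fx <- fx_small()
  lay <- layout_chip(fx$lib, 12, 12, seed = 2)
  pm <- default_planted_model()
  s1 <- simulate_screen(fx$lib, lay, pm, fx$dv, seed = 4, positions = FALSE)
  s2 <- simulate_screen(fx$lib, lay, pm, fx$dv, seed = 4, positions = FALSE)
  expect_identical(s1, s2)
  s3 <- simulate_screen(fx$lib, lay, pm, fx$dv, seed = 5, positions = FALSE)
  # planted truth depends only on descriptors, not the realisation seed
  o1 <- order(s1$truth$row, s1$truth$col)
  o3 <- order(s3$truth$row, s3$truth$col)
  expect_identical(s1$truth[o1, c("design_id", "p_diff", "morph", "rule")],
                   s3$truth[o3, c("design_id", "p_diff", "morph", "rule")])
  expect_false(identical(s1$cells$tgm1_mfi, s3$cells$tgm1_mfi))
  # duplicates share planted parameters but differ in realisation
  for (id in unique(s1$truth$design_id)[1:10]) {
    tt <- s1$truth[s1$truth$design_id == id, ]
    expect_equal(tt$p_diff[1], tt$p_diff[2])
    expect_equal(tt$morph[1], tt$morph[2])
  }
  # the flat control is a baseline unit
  expect_true(all(s1$truth$rule[s1$truth$design_id == "FLAT"] == "baseline"))
})

test_that("realized differentiation tracks the planted rate per stratum", {
  fx <- fx_screen()
  truth <- fx$scr$truth
  cells <- fx$scr$cells
  key <- paste(cells$row, cells$col)
  tkey <- paste(truth$row, truth$col)
  cells$p <- truth$p_diff[match(key, tkey)]
  cells$rule <- truth$rule[match(key, tkey)]
  for (r in unique(truth$rule)) {
    sel <- cells$rule == r
    n <- sum(sel)
    units_in <- sum(truth$rule == r)
    if (units_in < 50) next
    p <- cells$p[sel][1]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(cells$true_diff[sel]) - p), 3 * se)
  }
})

test_that("nucleus placement honours the minimum spacing or errors", {
  pm <- default_planted_model()
  cells <- simulate_unit(list(fcp = 0), pm, seed = 2)
  d <- as.matrix(dist(cbind(cells$nx_um, cells$ny_um)))
  diag(d) <- Inf
  expect_true(all(d >= 20))
  # an impossible packing errors out
  mp <- morph_params(n_cells_range = c(25, 25), min_spacing = 290)
  expect_error(simulate_unit(list(fcp = 0), pm, seed = 2, params = mp),
               "could not place")
})

test_that("rendered units carry exact labels and fill intensities", {
  cells <- data.frame(cell_id = 1:3, true_diff = c(TRUE, FALSE, TRUE),
                      true_morph = c("round", "round", "spread"),
                      area_um2 = c(500, 400, 1800),
                      roundness = c(0.8, 0.7, 0.3),
                      tgm1_mfi = c(600, 80, 450),
                      nx_um = c(60, 150, 240), ny_um = c(60, 230, 80),
                      orient_deg = c(0, 45, 120))
  cells$perimeter_um <- sqrt(4 * pi * cells$area_um2 / cells$roundness)
  stack <- render_unit(cells, noise_sd = 0)
  expect_equal(sort(setdiff(unique(as.vector(stack$labels)), 0L)), 1:3)
  for (i in 1:3) {
    px <- stack$tgm1[stack$labels == i]
    expect_equal(median(px), cells$tgm1_mfi[i])
    # ellipse pixel area within 3% of the drawn area
    expect_lt(abs(sum(stack$labels == i) * 0.25 / cells$area_um2[i] - 1), 0.03)
  }
  expect_true(all(stack$factin[stack$labels > 0] == 200))
  expect_true(all(stack$factin[stack$labels == 0] == 0))
})

test_that("image stacks survive a TIFF round-trip", {
  cells <- data.frame(cell_id = 1:2, true_diff = c(TRUE, FALSE),
                      true_morph = "round", area_um2 = c(500, 600),
                      roundness = c(0.8, 0.75), tgm1_mfi = c(600, 90),
                      nx_um = c(80, 200), ny_um = c(90, 210),
                      orient_deg = c(10, 100))
  stack <- render_unit(cells, noise_sd = 5, seed = 3)
  f <- withr::local_tempfile(fileext = ".tif")
  write_stack(stack, f)
  back <- read_stack(f)
  expect_equal(back$labels, stack$labels)
  expect_equal(back$tgm1, stack$tgm1, tolerance = 1e-2)
  expect_equal(back$resolution, stack$resolution)
})
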