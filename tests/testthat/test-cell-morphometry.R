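test_that("nucleus segmentation recovers rendered nuclei, with and without noise", {
  pm <- default_planted_model()
  mp <- morph_params(n_cells_range = c(7, 7))
  cells <- simulate_unit(list(fcp = 0), pm, seed = 21, params = mp)
  clean <- render_unit(cells, noise_sd = 0)
  expect_equal(max(segment_nuclei(clean$dapi)), 7L)
  noisy <- render_unit(cells, noise_sd = 10, seed = 4)
  expect_equal(max(segment_nuclei(noisy$dapi)), 7L)
})

test_that("blank images yield zero labels with a flag", {
  lb <- segment_nuclei(matrix(0, 50, 50))
  expect_equal(max(lb), 0L)
  expect_true(attr(lb, "blank"))
})

test_that("diagonally touching nuclei form one 8-connected component", {
  img <- matrix(0, 30, 30)
  img[5:10, 5:10] <- 100
  img[11:16, 11:16] <- 100  # touches only at the (10,10)/(11,11) corner
  lb <- segment_nuclei(img, min_area = 1, resolution = 1, threshold = 50)
  expect_equal(max(lb), 1L)
})

test_that("cell segmentation matches rendered ground truth when cells are disjoint", {
  cells <- data.frame(cell_id = 1:4, true_diff = TRUE, true_morph = "round",
                      area_um2 = c(500, 700, 450, 600),
                      roundness = c(0.8, 0.75, 0.85, 0.7),
                      tgm1_mfi = c(600, 90, 400, 150),
                      nx_um = c(60, 60, 230, 230), ny_um = c(60, 230, 60, 230),
                      orient_deg = c(0, 50, 100, 150))
  stack <- render_unit(cells, noise_sd = 0)
  nuc <- segment_nuclei(stack$dapi)
  seg <- segment_cells(stack$factin, nuc)
  expect_equal(max(seg), 4L)
  # equality up to label permutation
  for (i in 1:4) {
    truth_px <- stack$labels == i
    ids <- unique(seg[truth_px])
    expect_length(ids, 1L)
    expect_true(all((seg == ids) == truth_px))
  }
})

test_that("touching cells split into two regions that tile the foreground", {
  # crafted 40 x 40 fixture: two overlapping intensity squares, two nuclei
  factin <- matrix(0, 40, 40)
  factin[10:30, 5:22] <- 200
  factin[10:30, 18:36] <- 200
  nuclei <- matrix(0L, 40, 40)
  nuclei[19:21, 9:11] <- 1L
  nuclei[19:21, 30:32] <- 2L
  seg <- segment_cells(factin, nuclei, threshold = 100)
  fg <- factin > 100
  expect_equal(sort(unique(as.vector(seg[fg]))), 1:2)
  expect_true(all((seg > 0) == fg))
  # each seed keeps its own side
  expect_equal(seg[20, 10], 1L)
  expect_equal(seg[20, 31], 2L)
})

test_that("segmentation with no nuclei returns an empty raster", {
  seg <- segment_cells(matrix(100, 20, 20), matrix(0L, 20, 20))
  expect_true(all(seg == 0L))
})

test_that("a nucleus outside the foreground becomes a nucleus-sized cell", {
  factin <- matrix(0, 40, 40)
  factin[5:15, 5:15] <- 200
  nuclei <- matrix(0L, 40, 40)
  nuclei[8:10, 8:10] <- 1L
  nuclei[30:32, 30:32] <- 2L  # no actin there
  seg <- segment_cells(factin, nuclei, threshold = 100)
  expect_equal(sum(seg == 2L), 9L)
})

test_that("the perimeter estimator calibrates on disks and squares", {
  # disks of radius 5..50 um at 0.25 um/px score roundness within 3% of 1
  for (r_um in c(5, 10, 20, 35, 50)) {
    m <- make_disk(r_um / 0.25)
    cells <- measure_cells(m, matrix(0, nrow(m), ncol(m)), resolution = 0.25)
    expect_gt(cells$roundness, 0.97)
    expect_lt(cells$roundness, 1.03)
  }
  # a 40 um square scores within 3% of pi/4
  sq <- make_square(160L)
  cells <- measure_cells(sq, matrix(0, nrow(sq), ncol(sq)), resolution = 0.25)
  expect_lt(abs(cells$roundness / (pi / 4) - 1), 0.03)
})

test_that("cell measurement reports exact areas and median intensities", {
  m <- matrix(0L, 30, 30)
  m[5:14, 5:14] <- 1L   # 100 px
  m[20:27, 20:25] <- 2L # 48 px
  tgm1 <- matrix(0, 30, 30)
  tgm1[m == 1L] <- 600
  tgm1[m == 2L] <- c(rep(100, 24), rep(300, 24))
  cells <- measure_cells(m, tgm1, resolution = 0.5)
  expect_equal(cells$area_um2, c(100, 48) * 0.25)
  expect_equal(cells$tgm1_mfi[1], 600)
  expect_equal(cells$tgm1_mfi[2], 200)
  empty <- measure_cells(matrix(0L, 5, 5), matrix(0, 5, 5))
  expect_equal(nrow(empty), 0L)
})

test_that("TGM1 positivity is a strict threshold at 270", {
  cells <- data.frame(tgm1_mfi = c(271, 270, 0, 269.5, 1000))
  out <- classify_tgm1(cells)
  expect_equal(out$is_positive, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  out2 <- classify_tgm1(cells, cutoff = 250)
  expect_equal(out2$is_positive, c(TRUE, TRUE, FALSE, TRUE, TRUE))
})

test_that("unit summaries follow the screen averaging rules", {
  cells <- data.frame(area_um2 = c(1000, 2000, 700, 800),
                      roundness = c(0.8, 0.3, 0.5, 0.6),
                      tgm1_mfi = c(500, 400, 100, 90))
  cells <- classify_tgm1(cells)
  s <- summarize_unit(cells)
  expect_equal(s$n_cells, 4L)
  expect_equal(s$n_pos, 2L)
  expect_equal(s$pct_pos, 50)
  expect_equal(s$avg_spread_area_pos, 1500)
  expect_equal(s$mean_roundness_pos, 0.55)
  # 3 positives of 20 cells
  c20 <- classify_tgm1(data.frame(area_um2 = rep(1, 20), roundness = 0.5,
                                  tgm1_mfi = c(rep(500, 3), rep(0, 17))))
  expect_equal(summarize_unit(c20)$pct_pos, 15)
  # no positives: shape fields absent
  c0 <- classify_tgm1(data.frame(area_um2 = 1:3, roundness = 0.5,
                                 tgm1_mfi = c(0, 0, 0)))
  s0 <- summarize_unit(c0)
  expect_equal(s0$pct_pos, 0)
  expect_true(is.na(s0$avg_spread_area_pos))
  expect_true(is.na(s0$mean_roundness_pos))
  expect_error(summarize_unit(c0[0, ]), "empty")
})

test_that("screen-level summaries equal the per-unit brute force", {
  fx <- fx_screen()
  cells <- classify_tgm1(fx$scr$cells)
  units <- summarize_units(cells)
  set.seed(8)
  for (i in sample(nrow(units), 25)) {
    sel <- cells$row == units$row[i] & cells$col == units$col[i]
    s <- summarize_unit(cells[sel, ])
    expect_equal(units$n_cells[i], s$n_cells)
    expect_equal(units$pct_pos[i], s$pct_pos)
    expect_equal(units$avg_spread_area_pos[i], s$avg_spread_area_pos)
    expect_equal(units$mean_roundness_pos[i], s$mean_roundness_pos)
  }
})

test_that("count correlation behaves at its extremes and under the null", {
  prop <- data.frame(n_cells = 5:24, n_pos = (5:24) * 2)
  expect_equal(count_correlation(prop), 1)
  const <- data.frame(n_cells = 5:24, n_pos = rep(3, 20))
  expect_warning(r2 <- count_correlation(const), "zero variance")
  expect_true(is.na(r2))
  set.seed(99)
  null <- data.frame(n_cells = sample(5:25, 1000, replace = TRUE),
                     n_pos = rbinom(1000, 10, 0.3))
  expect_lt(count_correlation(null), 0.01)
})

test_that("noise-free quantification recovers counts and positivity exactly", {
  fx <- fx_small()
  pm <- default_planted_model()
  for (u in 1:5) {
    cells <- simulate_unit(fx$dv[u, ], pm, seed = 300 + u)
    stack <- render_unit(cells, noise_sd = 0)
    meas <- analyze_stack(stack)
    expect_equal(nrow(meas), nrow(cells))
    expect_equal(mean(meas$is_positive), mean(cells$tgm1_mfi > 270))
  }
})
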