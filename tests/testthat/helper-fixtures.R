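# Shared fixtures, memoised so expensive objects are built once per run.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# a 60-design library with descriptors (for simulation/morphometry tests)
fx_small <- function() {
  fx_get("small", function() {
    lib <- generate_library(60, seed = 5)
    list(lib = lib, dv = library_descriptors(lib))
  })
}

# a 300-design screen on a 26 x 26 grid (for hits/model/pipeline tests)
fx_screen <- function() {
  fx_get("screen", function() {
    lib <- generate_library(300, seed = 1)
    lay <- layout_chip(lib, 26, 26, seed = 2)
    dv <- library_descriptors(lib)
    pm <- default_planted_model()
    scr <- simulate_screen(lib, lay, pm, dv, seed = 3, positions = FALSE)
    units <- summarize_units(classify_tgm1(scr$cells))
    list(lib = lib, lay = lay, dv = dv, pm = pm, scr = scr, units = units)
  })
}

# binary disk raster: radius in pixels, square image with margin
make_disk <- function(r_px, margin = 10L) {
  n <- 2L * ceiling(r_px) + 2L * margin
  x <- outer(rep(1, n), seq_len(n)); y <- t(x)
  c0 <- (n + 1) / 2
  matrix(as.integer((x - c0)^2 + (y - c0)^2 <= r_px^2), n, n)
}

# axis-aligned square raster: side in pixels
make_square <- function(s_px, margin = 10L) {
  n <- s_px + 2L * margin
  m <- matrix(0L, n, n)
  m[(margin + 1):(margin + s_px), (margin + 1):(margin + s_px)] <- 1L
  m
}

# random blob mask (union of random disks) for spectral property tests
random_blob_mask <- function(n = 64L, k = 6L, resolution = 0.5) {
  cx <- runif(k, 1, n); cy <- runif(k, 1, n); r <- runif(k, 2, n / 6)
  x <- outer(rep(1, n), seq_len(n)); y <- t(x)
  m <- matrix(0L, n, n)
  for (i in seq_len(k)) {
    m <- m | ((x - cx[i])^2 + (y - cy[i])^2 <= r[i]^2)
  }
  unit_mask(m, resolution = resolution, unit_side = n * resolution)
}

# single-primitive design placed fully inside the unit, with analytic area;
# sizes span the tens-of-micrometre regime the 0.5 um/px raster resolves to
# within 1% (smaller features carry visibly more quantization error near
# grid-aligned orientations)
random_single_primitive <- function(unit_side = 300) {
  kind <- sample(c("circle", "triangle", "rectangle"), 1)
  size1 <- runif(1, 30, 80)
  size2 <- if (kind == "rectangle") runif(1, max(5, 0.2 * size1), size1) else NA_real_
  half <- switch(kind, circle = size1 / 2, triangle = size1 / sqrt(3),
                 rectangle = sqrt(size1^2 + size2^2) / 2)
  cx <- runif(1, half + 1, unit_side - half - 1)
  cy <- runif(1, half + 1, unit_side - half - 1)
  rot <- runif(1, 0, 360)
  area <- switch(kind, circle = pi * size1^2 / 4,
                 triangle = sqrt(3) / 4 * size1^2,
                 rectangle = size1 * size2)
  list(design = topo_design("P", data.frame(kind = kind, size1 = size1,
                                            size2 = size2, cx = cx, cy = cy,
                                            rot = rot)),
       area = area)
}

# brute-force hit-selection oracle: sort-and-threshold on defined values
oracle_hits <- function(values, k_top, k_bottom) {
  ok <- is.finite(values)
  med <- median(values[ok]); sdev <- sd(values[ok])
  top <- med + k_top * sdev; bottom <- med + k_bottom * sdev
  lab <- rep("mid", length(values))
  lab[!ok] <- "excluded"
  lab[ok & values > top] <- "high"
  lab[ok & values < bottom] <- "low"
  list(label = lab, top = top, bottom = bottom)
}

# exhaustive-search oracle for the best root split (Gini)
oracle_root_split <- function(X, y, min_leaf) {
  n <- length(y)
  gini <- function(yy) {
    p <- mean(yy)
    2 * p * (1 - p) * length(yy)
  }
  parent <- gini(y)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    v <- sort(unique(X[, j]))
    if (length(v) < 2) next
    for (t in (v[-length(v)] + v[-1]) / 2) {
      l <- X[, j] < t
      if (sum(l) < min_leaf || sum(!l) < min_leaf) next
      dec <- parent - gini(y[l]) - gini(y[!l])
      if (dec <= 1e-10) next
      if (is.null(best) || dec > best$dec + 1e-10) {
        best <- list(feature = colnames(X)[j], threshold = t, dec = dec)
      }
    }
  }
  best
}
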