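# Per-design topography descriptors: coverage (FCP, FCPN01), radial spectral
# energy bands (WnX), line length, circle diameter and rotational
# irregularity (RotSD). These are the model inputs of the screen analysis.

#' Default wavenumber band centres (cycles per 10 micrometres)
#' @export
default_wn_centers <- function() c(0.1, 0.2, 0.3, 0.5, 1, 2, 4)

#' Descriptor configuration
#'
#' @param resolution Raster resolution in micrometres per pixel.
#' @param flip_p Bernoulli pixel-flip probability for FCPN01.
#' @param reps Number of flip replicates averaged for FCPN01.
#' @param wn_centers Band centres in cycles per 10 um; band edges are the
#'   geometric midpoints of consecutive centres, the lowest edge sits just
#'   above DC and the highest band extends to the spectral limit so that the
#'   bands tile the whole AC spectrum.
#' @param fcpn_seed Base seed for the FCPN01 noise replicates.
#' @param fold_by_symmetry Fold primitive rotations into their symmetry
#'   period before computing RotSD.
#' @param line_aspect_min Minimum rectangle aspect ratio to count as a line.
#' @param wn_pool Integer block-averaging factor applied to the mask before
#'   the spectral analysis. The default (2, i.e. 1 um/px from a 0.5 um/px
#'   mask) keeps the Nyquist limit at 5 cycles per 10 um, well above the
#'   highest band centre, at a quarter of the transform cost.
#' @return A list of class `descriptor_config`.
#' @export
descriptor_config <- function(resolution = 0.5, flip_p = 0.01, reps = 25,
                              wn_centers = default_wn_centers(),
                              fcpn_seed = 101, fold_by_symmetry = TRUE,
                              line_aspect_min = 3, wn_pool = 2L) {
  structure(list(resolution = resolution, flip_p = flip_p, reps = reps,
                 wn_centers = wn_centers, fcpn_seed = fcpn_seed,
                 fold_by_symmetry = fold_by_symmetry,
                 line_aspect_min = line_aspect_min,
                 wn_pool = as.integer(wn_pool)),
            class = "descriptor_config")
}

#' Fraction of covered pixels (FCP)
#'
#' @param mask A binary `unit_mask` (or 0/1 matrix).
#' @return The fraction of foreground pixels, in `[0, 1]`.
#' @export
compute_fcp <- function(mask) {
  if (length(mask) == 0L) stopf("empty raster")
  mean(mask != 0)
}

#' Coverage under simulated experimental variation (FCPN01)
#'
#' Mean FCP over `reps` noisy replicates of the mask in which every pixel is
#' independently flipped with probability `flip_p`. Because FCP depends on
#' the mask only through its foreground count, each replicate is drawn by
#' sampling the binomial numbers of 1->0 and 0->1 flips, which is
#' distributionally identical to flipping individual pixels. The expected
#' value is `fcp * (1 - flip_p) + (1 - fcp) * flip_p`.
#'
#' @inheritParams compute_fcp
#' @param flip_p Flip probability in `[0, 0.5)`.
#' @param reps Number of replicates.
#' @param seed Integer seed (replicates are deterministic per seed).
#' @return Mean coverage over replicates.
#' @export
compute_fcpn01 <- function(mask, flip_p = 0.01, reps = 25, seed = 1) {
  if (length(mask) == 0L) stopf("empty raster")
  if (!is.numeric(flip_p) || flip_p < 0 || flip_p >= 0.5) {
    stopf("flip_p must lie in [0, 0.5)")
  }
  n <- length(mask)
  n1 <- sum(mask != 0)
  if (flip_p == 0) return(n1 / n)
  with_seed(seed, {
    lost <- stats::rbinom(reps, n1, flip_p)
    gained <- stats::rbinom(reps, n - n1, flip_p)
    mean((n1 - lost + gained) / n)
  })
}

#' Block-average (pool) a raster by an integer factor
#'
#' @param m A matrix whose dimensions are divisible by `factor`.
#' @param factor Pooling factor.
#' @return A `nrow/factor` by `ncol/factor` matrix of block means.
#' @export
block_average <- function(m, factor) {
  f <- as.integer(factor)
  nr <- nrow(m) %/% f; nc <- ncol(m) %/% f
  if (nr * f != nrow(m) || nc * f != ncol(m)) {
    stopf("matrix dimensions must be divisible by the pooling factor")
  }
  m <- matrix(as.numeric(m), nrow(m), ncol(m))
  # sum over row blocks, then column blocks
  rs <- rowsum(m, rep(seq_len(nr), each = f))
  cs <- t(rowsum(t(rs), rep(seq_len(nc), each = f)))
  cs / (f * f)
}

# cache of band index assignments keyed by (n, resolution, centers)
.wn_cache <- new.env(parent = emptyenv())

wn_band_index <- function(n, resolution, centers) {
  key <- paste(n, resolution, paste(centers, collapse = ","), sep = "|")
  hit <- .wn_cache[[key]]
  if (!is.null(hit)) return(hit)
  # radial spatial frequency of each DFT element, cycles per 10 um
  k <- c(0:(n %/% 2), -((n - (n %/% 2 + 1)):1)) / (n * resolution)  # cycles/um
  f <- sqrt(outer(k^2, k^2, "+")) * 10
  edges <- c(0, sqrt(centers[-length(centers)] * centers[-1]), Inf)
  idx <- findInterval(f, edges, left.open = TRUE)  # 0 for DC only
  idx <- matrix(idx, n, n)
  out <- lapply(seq_along(centers), function(b) which(idx == b))
  .wn_cache[[key]] <- out
  out
}

#' Radial spectral energy band fractions (WnX)
#'
#' Takes the 2-D discrete Fourier power spectrum of the mean-centred mask,
#' sums power over annuli of radial spatial frequency (expressed in cycles
#' per 10 um) and reports each band's share of the total non-DC power. Over
#' the default full tiling the fractions sum to one. A constant mask has no
#' AC energy: all fractions are 0 and the result carries attribute
#' `no_ac_energy = TRUE`.
#'
#' @inheritParams compute_fcp
#' @param centers Band centres in cycles per 10 um.
#' @param resolution Micrometres per pixel (default taken from the mask).
#' @return Named numeric vector `wn_<center>` of band fractions.
#' @export
compute_wn <- function(mask, centers = default_wn_centers(),
                       resolution = attr(mask, "resolution") %||% 0.5) {
  n <- nrow(mask)
  if (is.null(n) || n != ncol(mask)) stopf("mask must be a square matrix")
  if (is.unsorted(centers) || any(centers <= 0)) {
    stopf("band centres must be positive and increasing")
  }
  nm <- paste0("wn_", centers)
  m <- mask - mean(mask)
  out <- stats::setNames(numeric(length(centers)), nm)
  if (all(m == 0)) {
    attr(out, "no_ac_energy") <- TRUE
    return(out)
  }
  p <- Mod(stats::fft(m))^2
  bands <- wn_band_index(n, resolution, centers)
  e <- vapply(bands, function(i) sum(p[i]), numeric(1))
  out[] <- e / sum(e)
  attr(out, "no_ac_energy") <- FALSE
  out
}

#' Standard deviation of primitive placement angles (RotSD)
#'
#' Rotations are folded into each primitive's rotational symmetry period
#' (rectangle 180 degrees, triangle 120 degrees), rescaled to a common
#' `[0, 180)` range and summarised by the sample standard deviation.
#' Circles carry no orientation and are excluded; a design with no oriented
#' primitive returns `NA`. A single oriented primitive has zero spread.
#'
#' @param design A `topo_design`.
#' @param fold_by_symmetry Fold angles into the symmetry period first.
#' @return Standard deviation in degrees, or `NA_real_`.
#' @export
compute_rotsd <- function(design, fold_by_symmetry = TRUE) {
  p <- design$primitives
  oriented <- p$kind != "circle"
  if (!any(oriented)) return(NA_real_)
  rot <- p$rot[oriented]
  kind <- p$kind[oriented]
  if (fold_by_symmetry) {
    period <- ifelse(kind == "triangle", 120, 180)
    rot <- (rot %% period) * (180 / period)
  }
  if (length(rot) == 1L) return(0)
  stats::sd(rot)
}

#' Assemble the descriptor vector of a design
#'
#' Coverage and spectral features come from the rasterized mask; line
#' length, circle diameter and RotSD come from the design metadata.
#' `line_len` is the mean length of rectangle primitives with aspect ratio
#' at least `line_aspect_min` ("lines"); `circ_diam` is the mean circle
#' diameter; both are `NA` when no qualifying primitive exists.
#'
#' @param design A `topo_design`.
#' @param mask Optional pre-rasterized `unit_mask` (must match the config
#'   resolution); rasterized on the fly when `NULL`.
#' @param config A [descriptor_config()].
#' @param fcpn_seed Seed for the FCPN01 replicates.
#' @return A one-row data.frame: `design_id`, `fcp`, `fcpn01`, one `wn_*`
#'   column per band, `line_len`, `circ_diam`, `rot_sd`.
#' @export
design_descriptors <- function(design, mask = NULL,
                               config = descriptor_config(),
                               fcpn_seed = config$fcpn_seed) {
  if (is.null(mask)) {
    mask <- rasterize(design, config$resolution)
  } else {
    expect_n <- round(design$unit_side / config$resolution)
    if (nrow(mask) != expect_n || ncol(mask) != expect_n) {
      stopf("design '%s': mask dimensions %d x %d do not match unit side %g at %g um/px",
            design$design_id, nrow(mask), ncol(mask), design$unit_side,
            config$resolution)
    }
  }
  p <- design$primitives
  circ <- p$kind == "circle"
  line <- p$kind == "rectangle" & (p$size1 / p$size2) >= config$line_aspect_min
  wn <- if (config$wn_pool > 1L && nrow(mask) %% config$wn_pool == 0L) {
    compute_wn(block_average(mask, config$wn_pool), config$wn_centers,
               config$resolution * config$wn_pool)
  } else {
    compute_wn(mask, config$wn_centers, config$resolution)
  }
  out <- c(list(design_id = design$design_id,
                fcp = compute_fcp(mask),
                fcpn01 = compute_fcpn01(mask, config$flip_p, config$reps,
                                        seed = fcpn_seed)),
           as.list(wn),
           list(line_len = if (any(line)) mean(p$size1[line]) else NA_real_,
                circ_diam = if (any(circ)) mean(p$size1[circ]) else NA_real_,
                rot_sd = compute_rotsd(design, config$fold_by_symmetry)))
  quick_df(out)
}

#' Compute descriptors for a whole library
#'
#' Rasterizes each design at the configured resolution and assembles the
#' descriptor table. FCPN01 replicate seeds are derived deterministically
#' from `config$fcpn_seed` and the design position.
#'
#' @param library A `topo_library`.
#' @param config A [descriptor_config()].
#' @param verbose Print progress every 500 designs.
#' @return A data.frame, one row per design.
#' @export
library_descriptors <- function(library, config = descriptor_config(),
                                verbose = FALSE) {
  rows <- vector("list", length(library))
  for (i in seq_along(library)) {
    rows[[i]] <- design_descriptors(library[[i]], config = config,
                                    fcpn_seed = config$fcpn_seed + i)
    if (verbose && i %% 500L == 0L) {
      message(sprintf("descriptors: %d / %d designs", i, length(library)))
    }
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Write / read a descriptor table (CSV)
#'
#' One row per design; absent values are stored as empty cells. Numeric
#' columns are written with enough digits to round-trip exactly, so a
#' cached table reproduces in-memory results bit for bit.
#'
#' @param descriptors A descriptor data.frame.
#' @param path File path.
#' @export
write_descriptors <- function(descriptors, path) {
  out <- descriptors
  for (f in names(out)) {
    if (is.numeric(out[[f]])) {
      v <- sprintf("%.17g", out[[f]])
      v[is.na(out[[f]])] <- ""
      out[[f]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
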