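# Virtual topography library: design generation, chip layout, rasterization
# and design-file input/output.
#
# A TopoUnit is a square well (default 300 x 300 um) carrying a topography
# composed of primitive shapes (circles, equilateral triangles, rectangles)
# at random sizes, positions and rotations. A chip carries a grid of
# TopoUnits (default 66 x 66) with every design present in duplicate,
# the duplicate displaced diagonally to rule out location bias.

PRIMITIVE_KINDS <- c("circle", "triangle", "rectangle")

#' Construct a single topography design
#'
#' @param design_id Character identifier, unique within a library.
#' @param primitives A data.frame with columns `kind`, `size1`, `size2`,
#'   `cx`, `cy`, `rot`. Sizes and positions are in micrometres; `rot` is in
#'   degrees within `[0, 360)`. `size1` is the circle diameter, triangle side
#'   or rectangle length; `size2` is the rectangle width (`NA` otherwise).
#'   A zero-row data.frame gives the flat control.
#' @param unit_side Side length of the square unit in micrometres.
#' @param feature_height Nominal feature height in micrometres (metadata).
#' @return An object of class `topo_design`.
#' @export
topo_design <- function(design_id, primitives, unit_side = 300,
                        feature_height = 5) {
  validate_primitives(primitives, unit_side, design_id)
  structure(
    list(design_id = as.character(design_id), primitives = primitives,
         unit_side = as.numeric(unit_side),
         feature_height = as.numeric(feature_height)),
    class = "topo_design"
  )
}

validate_primitives <- function(p, unit_side, design_id) {
  need <- c("kind", "size1", "size2", "cx", "cy", "rot")
  if (!is.data.frame(p) || !all(need %in% names(p))) {
    stopf("design '%s': primitives must be a data.frame with columns %s",
          design_id, paste(need, collapse = ", "))
  }
  if (nrow(p) == 0L) return(invisible(TRUE))
  if (!all(p$kind %in% PRIMITIVE_KINDS)) {
    stopf("design '%s': unknown primitive kind", design_id)
  }
  if (any(!is.finite(p$size1)) || any(p$size1 <= 0)) {
    stopf("design '%s': size1 must be positive", design_id)
  }
  rect <- p$kind == "rectangle"
  if (any(rect & (!is.finite(p$size2) | p$size2 <= 0 | p$size2 > p$size1))) {
    stopf("design '%s': rectangle requires 0 < size2 <= size1", design_id)
  }
  if (any(p$cx < 0 | p$cx > unit_side | p$cy < 0 | p$cy > unit_side)) {
    stopf("design '%s': primitive centres must lie within the unit", design_id)
  }
  invisible(TRUE)
}

#' Default per-kind primitive size ranges (micrometres)
#'
#' Sizes are drawn log-uniformly within these intervals so that small and
#' large features are equally represented on a relative scale. Rectangle
#' widths are derived from the length through a log-uniform aspect ratio in
#' `[1, 10]`; rectangles with aspect ratio at least 3 count as "lines".
#'
#' @return A named list of `c(min, max)` intervals.
#' @export
default_size_ranges <- function() {
  list(circle = c(5, 90), triangle = c(5, 90), rectangle = c(5, 90))
}

#' Generate a virtual topography library
#'
#' Draws `n_designs` random designs plus one flat control (`design_id`
#' `"FLAT"`, no primitives). For each design a primitive count is sampled
#' uniformly from `count_range`; each primitive gets a uniform kind, a
#' log-uniform size within the per-kind range, a uniform centre within the
#' unit and a uniform rotation in `[0, 360)`. Deterministic for a given
#' seed and parameter set.
#'
#' @param n_designs Number of non-flat designs (default 2175, a full
#'   TopoChip library).
#' @param seed Integer seed.
#' @param size_ranges Per-kind size intervals, see [default_size_ranges()].
#' @param count_range Integer range of primitives per design.
#' @param unit_side,feature_height Unit geometry in micrometres.
#' @return An object of class `topo_library`: a list of `topo_design`
#'   objects, the flat control last.
#' @export
generate_library <- function(n_designs = 2175, seed = 1,
                             size_ranges = default_size_ranges(),
                             count_range = c(1, 30),
                             unit_side = 300, feature_height = 5) {
  if (!is_count(n_designs)) stopf("`n_designs` must be a positive integer")
  if (length(count_range) != 2L || any(count_range < 1) ||
      count_range[1] > count_range[2]) {
    stopf("`count_range` must be an increasing positive integer pair")
  }
  for (k in PRIMITIVE_KINDS) {
    r <- size_ranges[[k]]
    if (is.null(r) || length(r) != 2L || any(!is.finite(r)) || any(r <= 0) ||
        r[1] > r[2]) {
      stopf("size range for '%s' must be a positive interval", k)
    }
  }
  with_seed(seed, {
    counts <- sample.int(count_range[2] - count_range[1] + 1L, n_designs,
                         replace = TRUE) + count_range[1] - 1L
    total <- sum(counts)
    kind <- PRIMITIVE_KINDS[sample.int(3L, total, replace = TRUE)]
    logu <- function(n, r) exp(stats::runif(n, log(r[1]), log(r[2])))
    size1 <- numeric(total)
    for (k in PRIMITIVE_KINDS) {
      i <- which(kind == k)
      size1[i] <- logu(length(i), size_ranges[[k]])
    }
    size2 <- rep(NA_real_, total)
    rect <- which(kind == "rectangle")
    aspect <- exp(stats::runif(length(rect), log(1), log(10)))
    size2[rect] <- size1[rect] / aspect
    cx <- stats::runif(total, 0, unit_side)
    cy <- stats::runif(total, 0, unit_side)
    rot <- stats::runif(total, 0, 360)
    ids <- sprintf("T%04d", seq_len(n_designs))
    design_of <- rep.int(seq_len(n_designs), counts)
    starts <- c(1L, cumsum(counts) + 1L)
    lib <- vector("list", n_designs + 1L)
    for (d in seq_len(n_designs)) {
      i <- starts[d]:(starts[d + 1L] - 1L)
      prim <- quick_df(list(kind = kind[i], size1 = size1[i], size2 = size2[i],
                            cx = cx[i], cy = cy[i], rot = rot[i]))
      lib[[d]] <- structure(
        list(design_id = ids[d], primitives = prim, unit_side = unit_side,
             feature_height = feature_height),
        class = "topo_design")
    }
    lib[[n_designs + 1L]] <- topo_design("FLAT", empty_primitives(),
                                         unit_side, feature_height)
    structure(lib, class = "topo_library")
  })
}

empty_primitives <- function() {
  quick_df(list(kind = character(0), size1 = numeric(0), size2 = numeric(0),
                cx = numeric(0), cy = numeric(0), rot = numeric(0)))
}

#' @export
print.topo_library <- function(x, ...) {
  n <- length(x)
  flat <- sum(vapply(x, function(d) nrow(d$primitives) == 0L, logical(1)))
  cat(sprintf("topo_library: %d designs (%d flat control%s), unit side %g um\n",
              n, flat, if (flat == 1) "" else "s", x[[1]]$unit_side))
  invisible(x)
}

#' @export
print.topo_design <- function(x, ...) {
  cat(sprintf("topo_design '%s': %d primitives, unit %g um, height %g um\n",
              x$design_id, nrow(x$primitives), x$unit_side, x$feature_height))
  if (nrow(x$primitives)) print(utils::head(x$primitives, 10))
  invisible(x)
}

design_ids <- function(library) {
  vapply(library, function(d) d$design_id, character(1))
}

#' Lay designs out on a chip with diagonal duplicates
#'
#' Every design is placed exactly twice; the second copy sits at a fixed
#' diagonal displacement (default half the grid in both directions, wrapped
#' modulo the grid) so that duplicates never share a row or a column.
#' Placement is deterministic for a given seed.
#'
#' @param library A `topo_library` (or list of `topo_design`).
#' @param rows,cols Grid dimensions (default 66 x 66).
#' @param seed Integer seed.
#' @param offset Integer `c(drow, dcol)` duplicate displacement; both
#'   components must be non-zero modulo the grid.
#' @return An object of class `chip_layout` with elements `rows`, `cols`,
#'   `offset` and `cells` (a data.frame `row`, `col`, `design_id` of occupied
#'   positions; unlisted positions are empty).
#' @export
layout_chip <- function(library, rows = 66, cols = 66, seed = 1,
                        offset = c(floor(rows / 2), floor(cols / 2))) {
  n <- length(library)
  if (2L * n > rows * cols) {
    stopf("library of %d designs does not fit a %d x %d grid in duplicate",
          n, rows, cols)
  }
  dr <- ((offset[1] %% rows) + rows) %% rows
  dc <- ((offset[2] %% cols) + cols) %% cols
  if (dr == 0L || dc == 0L) {
    stopf("duplicate offset must be non-zero in both directions (diagonal)")
  }
  ids <- design_ids(library)
  if (anyDuplicated(ids)) stopf("duplicate design_id in library")
  with_seed(seed, {
    free <- matrix(TRUE, rows, cols)
    order <- sample.int(rows * cols)
    pos_row <- integer(2L * n); pos_col <- integer(2L * n)
    pos_id <- character(2L * n)
    ptr <- 1L
    for (d in seq_len(n)) {
      placed <- FALSE
      for (j in ptr:(rows * cols)) {
        p <- order[j]
        r1 <- ((p - 1L) %% rows) + 1L
        c1 <- ((p - 1L) %/% rows) + 1L
        if (!free[r1, c1]) next
        r2 <- ((r1 - 1L + dr) %% rows) + 1L
        c2 <- ((c1 - 1L + dc) %% cols) + 1L
        if ((r2 == r1 && c2 == c1) || !free[r2, c2]) next
        free[r1, c1] <- FALSE; free[r2, c2] <- FALSE
        k <- 2L * d - 1L
        pos_row[k:(k + 1L)] <- c(r1, r2)
        pos_col[k:(k + 1L)] <- c(c1, c2)
        pos_id[k:(k + 1L)] <- ids[d]
        if (j == ptr) ptr <- ptr + 1L
        placed <- TRUE
        break
      }
      if (!placed) {
        stopf("could not place design '%s' with a free diagonal partner",
              ids[d])
      }
    }
    cells <- quick_df(list(row = pos_row, col = pos_col, design_id = pos_id))
    cells <- cells[order(cells$row, cells$col), , drop = FALSE]
    row.names(cells) <- NULL
    structure(list(rows = rows, cols = cols, offset = c(dr, dc),
                   n_designs = n, cells = cells),
              class = "chip_layout")
  })
}

#' @export
print.chip_layout <- function(x, ...) {
  cat(sprintf(
    "chip_layout: %d x %d grid, %d designs in duplicate (%d occupied, %d empty), offset (+%d, +%d)\n",
    x$rows, x$cols, x$n_designs, nrow(x$cells),
    x$rows * x$cols - nrow(x$cells), x$offset[1], x$offset[2]))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Rasterization

#' Rasterize a design to a binary unit mask
#'
#' A pixel is foreground iff its centre lies inside at least one (rotated)
#' primitive; overlapping primitives are unioned and shapes are clipped at
#' the unit boundary. Pixel centres sit at `(i - 0.5) * resolution` with the
#' origin at the top-left corner.
#'
#' @param design A `topo_design`.
#' @param resolution Pixel size in micrometres per pixel (default 0.5).
#' @return An object of class `unit_mask`: an integer 0/1 matrix with
#'   attributes `resolution` and `unit_side`.
#' @export
rasterize <- function(design, resolution = 0.5) {
  side <- design$unit_side
  if (!is.numeric(resolution) || resolution <= 0 || resolution > side / 10) {
    stopf("resolution must be positive and at most unit_side/10")
  }
  n <- round(side / resolution)
  m <- matrix(0L, n, n)
  p <- design$primitives
  if (nrow(p)) {
    cs <- (seq_len(n) - 0.5) * resolution  # pixel-centre coordinates
    for (i in seq_len(nrow(p))) {
      kind <- p$kind[i]; s1 <- p$size1[i]; s2 <- p$size2[i]
      cx <- p$cx[i]; cy <- p$cy[i]
      half <- switch(kind,
        circle = s1 / 2,
        triangle = s1 / sqrt(3),            # circumradius
        rectangle = sqrt(s1^2 + s2^2) / 2)  # half diagonal
      ci <- max(1L, ceiling((cx - half) / resolution))
      cj <- min(n, floor((cx + half) / resolution + 1))
      ri <- max(1L, ceiling((cy - half) / resolution))
      rj <- min(n, floor((cy + half) / resolution + 1))
      if (ci > cj || ri > rj) next
      x <- cs[ci:cj]; y <- cs[ri:rj]
      X <- matrix(x, length(y), length(x), byrow = TRUE) - cx
      Y <- matrix(y, length(y), length(x)) - cy
      inside <- switch(kind,
        circle = (X * X + Y * Y) <= (s1 / 2)^2,
        rectangle = {
          th <- p$rot[i] * pi / 180
          U <- X * cos(th) + Y * sin(th)
          V <- -X * sin(th) + Y * cos(th)
          abs(U) <= s1 / 2 & abs(V) <= s2 / 2
        },
        triangle = {
          # equilateral triangle, centroid at centre, one vertex at angle
          # rot + 90 degrees; inside = on the inner side of all three edges
          th <- (p$rot[i] + c(90, 210, 330)) * pi / 180
          rc <- s1 / sqrt(3)
          vx <- rc * cos(th); vy <- rc * sin(th)
          ins <- TRUE
          for (e in 1:3) {
            f <- if (e == 3L) 1L else e + 1L
            ex <- vx[f] - vx[e]; ey <- vy[f] - vy[e]
            # sign fixed by the centroid (origin), robust to vertex order
            s0 <- sign(ex * (0 - vy[e]) - ey * (0 - vx[e]))
            cross <- ex * (Y - vy[e]) - ey * (X - vx[e])
            ins <- ins & (s0 * cross >= 0)
          }
          ins
        })
      m[ri:rj, ci:cj] <- m[ri:rj, ci:cj] | inside
    }
  }
  unit_mask(m, resolution = resolution, unit_side = side)
}

#' Construct a unit mask object
#'
#' @param pixels A binary (0/1 or logical) matrix.
#' @param resolution Micrometres per pixel.
#' @param unit_side Unit side in micrometres (default inferred).
#' @return An integer 0/1 matrix of class `unit_mask`.
#' @export
unit_mask <- function(pixels, resolution = 0.5,
                      unit_side = nrow(pixels) * resolution) {
  if (!is.matrix(pixels)) stopf("mask pixels must be a matrix")
  m <- matrix(as.integer(pixels != 0), nrow(pixels), ncol(pixels))
  structure(m, resolution = resolution, unit_side = unit_side,
            class = c("unit_mask", "matrix", "array"))
}

#' @export
print.unit_mask <- function(x, ...) {
  cat(sprintf("unit_mask: %d x %d px at %g um/px, covered fraction %.4f\n",
              nrow(x), ncol(x), attr(x, "resolution"), mean(x)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Design-file input/output

design_to_record <- function(d) {
  list(design_id = d$design_id,
       unit_side_um = d$unit_side,
       feature_height_um = d$feature_height,
       primitives = if (nrow(d$primitives) == 0L) list() else
         quick_df(list(kind = d$primitives$kind,
                       size1_um = d$primitives$size1,
                       size2_um = d$primitives$size2,
                       cx_um = d$primitives$cx,
                       cy_um = d$primitives$cy,
                       rot_deg = d$primitives$rot)))
}

#' Write / read a design library (JSON)
#'
#' The JSON dialect stores one object per design with fields `design_id`,
#' `unit_side_um`, `feature_height_um` and a `primitives` array of records
#' `{kind, size1_um, size2_um, cx_um, cy_um, rot_deg}`. `write_designs()`
#' followed by [read_designs()] is the identity on libraries.
#'
#' @param library A `topo_library`.
#' @param path Output file path.
#' @return `write_designs()` returns `path` invisibly; `read_designs()`
#'   returns a `topo_library`.
#' @export
write_designs <- function(library, path) {
  recs <- lapply(library, design_to_record)
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_designs
#' @export
read_designs <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ids <- vapply(recs, function(r) as.character(r$design_id %||% NA), character(1))
  if (anyNA(ids)) stopf("design file: record without design_id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stopf("design file: duplicate design_id '%s'", dup[1])
  lib <- lapply(recs, function(r) {
    p <- r$primitives
    prim <- if (length(p) == 0L) empty_primitives() else {
      get_num <- function(f) vapply(p, function(q) {
        v <- q[[f]]
        if (is.null(v)) NA_real_ else as.numeric(v)
      }, numeric(1))
      quick_df(list(
        kind = vapply(p, function(q) as.character(q$kind %||% NA), character(1)),
        size1 = get_num("size1_um"), size2 = get_num("size2_um"),
        cx = get_num("cx_um"), cy = get_num("cy_um"),
        rot = get_num("rot_deg")))
    }
    topo_design(r$design_id, prim,
                unit_side = r$unit_side_um %||% 300,
                feature_height = r$feature_height_um %||% 5)
  })
  structure(lib, class = "topo_library")
}

#' Write / read a design library (flat CSV dialect)
#'
#' One primitive per row with the design metadata repeated; flat designs are
#' carried as a single row with empty primitive fields.
#'
#' @inheritParams write_designs
#' @export
write_designs_csv <- function(library, path) {
  rows <- lapply(library, function(d) {
    p <- d$primitives
    if (nrow(p) == 0L) {
      quick_df(list(design_id = d$design_id, unit_side_um = d$unit_side,
                    feature_height_um = d$feature_height,
                    kind = NA_character_, size1_um = NA_real_,
                    size2_um = NA_real_, cx_um = NA_real_, cy_um = NA_real_,
                    rot_deg = NA_real_))
    } else {
      quick_df(list(design_id = rep(d$design_id, nrow(p)),
                    unit_side_um = rep(d$unit_side, nrow(p)),
                    feature_height_um = rep(d$feature_height, nrow(p)),
                    kind = p$kind, size1_um = p$size1, size2_um = p$size2,
                    cx_um = p$cx, cy_um = p$cy, rot_deg = p$rot))
    }
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_designs_csv
#' @export
read_designs_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(df$design_id)
  lib <- lapply(ids, function(id) {
    rows <- df[df$design_id == id, , drop = FALSE]
    flat <- all(is.na(rows$kind) | rows$kind == "")
    prim <- if (flat) empty_primitives() else
      quick_df(list(kind = rows$kind, size1 = rows$size1_um,
                    size2 = rows$size2_um, cx = rows$cx_um, cy = rows$cy_um,
                    rot = rows$rot_deg))
    topo_design(id, prim, unit_side = rows$unit_side_um[1],
                feature_height = rows$feature_height_um[1])
  })
  structure(lib, class = "topo_library")
}

#' Write / read a unit mask as an 8-bit PNG with a JSON sidecar
#'
#' Foreground pixels are stored as 255, background as 0; the sidecar
#' (`<path>.json`) records the resolution and unit side.
#'
#' @param mask A `unit_mask`.
#' @param path Output PNG path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  jsonlite::write_json(
    list(resolution_um_px = attr(mask, "resolution"),
         unit_side_um = attr(mask, "unit_side")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  unit_mask(px > 0.5, resolution = meta$resolution_um_px,
            unit_side = meta$unit_side_um)
}
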