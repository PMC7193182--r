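# Parametric STL export of the planar-loop geometry.
#
# The surface is a tube of varying radius swept along the circular
# centerline. The tube radius is the step profile of per-segment lumen
# radii, smoothed with a cosine ramp over a small angular window at each
# segment boundary so the swept surface stays watertight and C1.

# tube radius b(theta) with cosine-ramp transitions (width `ramp` rad,
# centred on each segment boundary)
tube_radius_profile <- function(geom, theta, ramp = 0.05) {
  angles <- geom$segments$subtended_angle
  radii <- geom$segments$lumen_radius
  bounds <- cumsum(angles)               # segment end angles; last = 2*pi
  theta <- theta %% (2 * pi)
  seg_of <- findInterval(theta, c(0, head(bounds, -1)), rightmost.closed = FALSE)
  b <- radii[seg_of]
  if (ramp <= 0) {
    return(b)
  }
  n_seg <- length(radii)
  for (k in seq_len(n_seg)) {
    boundary <- bounds[k] %% (2 * pi)    # boundary between segment k and k+1
    r_from <- radii[k]
    r_to <- radii[if (k == n_seg) 1L else k + 1L]
    if (r_from == r_to) next
    d <- theta - boundary
    d <- (d + pi) %% (2 * pi) - pi       # signed angular distance in (-pi, pi]
    in_ramp <- abs(d) < ramp / 2
    s <- (d[in_ramp] + ramp / 2) / ramp  # 0 at start of ramp, 1 at end
    b[in_ramp] <- r_from + (r_to - r_from) * (1 - cos(pi * s)) / 2
  }
  b
}

#' Export a labyrinth geometry as an STL surface mesh
#'
#' Writes a watertight triangulated tube-of-varying-radius surface: the
#' circular centerline is swept with a circular cross-section whose radius
#' follows the per-segment lumen radii (cosine-ramp transitions over 0.05
#' rad at segment boundaries). The mesh is a closed torus-topology grid of
#' `n_theta x n_phi` quads, each split into two triangles, with outward
#' facet normals.
#'
#' @param geom a `labyrinth_geometry`.
#' @param path output file path.
#' @param n_theta angular samples along the centerline.
#' @param n_phi samples around the tube cross-section.
#' @param ascii write ASCII STL instead of binary (little-endian) STL.
#' @param ramp angular width (rad) of the radius transition at segment
#'   boundaries.
#' @return Invisibly, the number of facets written
#'   (`2 * n_theta * n_phi`).
#' @export
#' @examples
#' f <- tempfile(fileext = ".stl")
#' export_stl(make_normal_geometry(), f, n_theta = 64, n_phi = 16)
#' mesh <- read_stl(f)
#' nrow(mesh$facets) / 3
export_stl <- function(geom, path, n_theta = 256, n_phi = 32,
                       ascii = FALSE, ramp = 0.05) {
  if (!inherits(geom, "labyrinth_geometry")) {
    abort_validation("`geom` must be a labyrinth_geometry.")
  }
  if (n_theta < 3 || n_phi < 3) {
    abort_validation("`n_theta` and `n_phi` must both be at least 3.")
  }
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, mode = 2) != 0) {
    abort_io(sprintf("Cannot write STL file: directory '%s' is not writable.", dir))
  }

  R <- geom$centerline_radius
  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  b <- tube_radius_profile(geom, theta, ramp = ramp)

  # vertex grid: rows vary phi fastest
  grid_idx <- function(i, j) ((i - 1) %% n_theta) * n_phi + ((j - 1) %% n_phi) + 1
  th <- rep(theta, each = n_phi)
  bb <- rep(b, each = n_phi)
  ph <- rep(phi, times = n_theta)
  verts <- cbind(
    x = (R + bb * cos(ph)) * cos(th),
    y = (R + bb * cos(ph)) * sin(th),
    z = bb * sin(ph)
  )

  ii <- rep(seq_len(n_theta), each = n_phi)
  jj <- rep(seq_len(n_phi), times = n_theta)
  v00 <- grid_idx(ii, jj)
  v10 <- grid_idx(ii + 1, jj)
  v01 <- grid_idx(ii, jj + 1)
  v11 <- grid_idx(ii + 1, jj + 1)
  tri <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))

  a <- verts[tri[, 1], , drop = FALSE]
  bv <- verts[tri[, 2], , drop = FALSE]
  cv <- verts[tri[, 3], , drop = FALSE]
  e1 <- bv - a
  e2 <- cv - a
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  len <- sqrt(nx^2 + ny^2 + nz^2)
  len[len == 0] <- 1
  normals <- cbind(nx / len, ny / len, nz / len)

  n_facets <- nrow(tri)
  if (ascii) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines("solid vestsim", con)
    for (f in seq_len(n_facets)) {
      writeLines(c(
        sprintf("  facet normal %.9e %.9e %.9e", normals[f, 1], normals[f, 2], normals[f, 3]),
        "    outer loop",
        sprintf("      vertex %.9e %.9e %.9e",
                verts[tri[f, ], 1], verts[tri[f, ], 2], verts[tri[f, ], 3]),
        "    endloop",
        "  endfacet"
      ), con)
    }
    writeLines("endsolid vestsim", con)
  } else {
    con <- file(path, open = "wb")
    on.exit(close(con))
    header <- charToRaw(formatC("vestsim parametric labyrinth surface", width = -80))
    length(header) <- 80
    header[is.na(header)] <- as.raw(0)
    writeBin(header, con)
    writeBin(as.integer(n_facets), con, size = 4, endian = "little")
    # per facet: normal, v1, v2, v3 (12 float32) + uint16 attribute
    block <- t(cbind(normals, a, bv, cv))
    for (f in seq_len(n_facets)) {
      writeBin(block[, f], con, size = 4, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    }
  }
  invisible(n_facets)
}

#' Read an STL surface mesh
#'
#' Reads binary or ASCII STL (auto-detected) back into vertex and normal
#' tables, chiefly for round-trip validation of [export_stl()].
#'
#' @param path STL file path.
#' @return A list with `facets` (tibble of `x`, `y`, `z`, three consecutive
#'   rows per facet), `normals` (tibble of `nx`, `ny`, `nz`, one row per
#'   facet) and `n_facets`.
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) {
    abort_io(sprintf("STL file not found: '%s'", path))
  }
  first <- readBin(path, "raw", n = 512)
  is_ascii <- length(first) >= 5 &&
    identical(rawToChar(first[1:5]), "solid") &&
    length(grepRaw("facet", first, fixed = TRUE)) > 0
  if (is_ascii) {
    lines <- readLines(path)
    vex <- grep("^\\s*vertex", lines, value = TRUE)
    nor <- grep("^\\s*facet normal", lines, value = TRUE)
    vmat <- do.call(rbind, lapply(strsplit(trimws(vex), "\\s+"), function(p) as.numeric(p[2:4])))
    nmat <- do.call(rbind, lapply(strsplit(trimws(nor), "\\s+"), function(p) as.numeric(p[3:5])))
    n_facets <- length(nor)
  } else {
    con <- file(path, open = "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80)
    n_facets <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    vmat <- matrix(NA_real_, nrow = 3 * n_facets, ncol = 3)
    nmat <- matrix(NA_real_, nrow = n_facets, ncol = 3)
    for (f in seq_len(n_facets)) {
      vals <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
      readBin(con, "integer", n = 1, size = 2, endian = "little")
      nmat[f, ] <- vals[1:3]
      vmat[3 * f - 2, ] <- vals[4:6]
      vmat[3 * f - 1, ] <- vals[7:9]
      vmat[3 * f, ] <- vals[10:12]
    }
  }
  list(
    facets = tibble(x = vmat[, 1], y = vmat[, 2], z = vmat[, 3]),
    normals = tibble(nx = nmat[, 1], ny = nmat[, 2], nz = nmat[, 3]),
    n_facets = n_facets
  )
}
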