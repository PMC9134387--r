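#' Render parameters for snapshot images
#'
#' Parameters of the multi-angle ball-and-stick rasterizer. The defaults
#' match the standard snapshot protocol: 256 x 256 px RGB images, zoom
#' 100% (molecule's bounding sphere fills 90% of the image edge), atom
#' spheres at 23% of the element van der Waals radius, black background,
#' and an angle increment of 145 degrees on each axis, which enumerates
#' 27 views per compound.
#'
#' `min_bond_distance` and `bond_tolerance` are bond-perception thresholds
#' used only when a record carries no connectivity table: two atoms are
#' bonded when `min_bond_distance < d < r_cov(i) + r_cov(j) + bond_tolerance`.
#'
#' @param image_px square image edge in pixels (>= 16).
#' @param zoom_pct zoom percentage; scales linearly.
#' @param atom_vdw_pct atom sphere radius as percent of vdW radius.
#' @param bond_radius bond cylinder radius in Angstrom.
#' @param min_bond_distance,bond_tolerance distance-based bond perception
#'   thresholds (Angstrom), used only without a connectivity table.
#' @param angle_increment numeric length-3, rotation increments (degrees)
#'   about the x, y and z axes; each in (0, 360].
#' @param background background RGB as numeric length-3 in \[0, 1\].
#' @return a `render_params` list.
#' @export
render_params <- function(image_px = 256L, zoom_pct = 100, atom_vdw_pct = 23,
                          bond_radius = 0.15, min_bond_distance = 0.4,
                          bond_tolerance = 0.8,
                          angle_increment = c(145, 145, 145),
                          background = c(0, 0, 0)) {
  stopifnot(image_px >= 16L, atom_vdw_pct > 0, atom_vdw_pct <= 100,
            length(angle_increment) == 3L,
            all(angle_increment > 0), all(angle_increment <= 360),
            length(background) == 3L)
  structure(list(image_px = as.integer(image_px), zoom_pct = zoom_pct,
                 atom_vdw_pct = atom_vdw_pct, bond_radius = bond_radius,
                 min_bond_distance = min_bond_distance,
                 bond_tolerance = bond_tolerance,
                 angle_increment = as.numeric(angle_increment),
                 background = as.numeric(background)),
            class = "render_params")
}

#' Enumerate snapshot rotation angles
#'
#' Per axis the angles are `0, inc, 2*inc, ...` strictly below 360 degrees
#' (360 duplicates 0 and is excluded); the result is their Cartesian
#' product in lexicographic order on (x, y, z). An increment of
#' (145, 145, 145) gives the standard 27 views; (65, 65, 65) gives 216.
#'
#' @param increment numeric length-3 angle increments in degrees, each in
#'   (0, 360].
#' @return numeric matrix with columns `angle_x`, `angle_y`, `angle_z`.
#' @export
enumerate_angles <- function(increment) {
  if (length(increment) != 3L || any(!is.finite(increment)) ||
      any(increment <= 0) || any(increment > 360))
    stop("angle increments must be three values in (0, 360]")
  ax <- lapply(increment, function(th) th * (seq_len(ceiling(360 / th)) - 1))
  grid <- expand.grid(angle_z = ax[[3L]], angle_y = ax[[2L]], angle_x = ax[[1L]],
                      KEEP.OUT.ATTRS = FALSE)
  m <- as.matrix(grid[, c("angle_x", "angle_y", "angle_z")])
  rownames(m) <- NULL
  m
}

element_palette <- function() {
  p <- sq_data("element_palette.csv")
  rownames(p) <- p$symbol
  p
}

element_color <- function(elements) {
  p <- element_palette()
  i <- match(elements, p$symbol)
  col <- cbind(p$red[i], p$green[i], p$blue[i])
  if (anyNA(i))  # unknown element -> magenta
    col[is.na(i), ] <- matrix(c(1, 0, 1), sum(is.na(i)), 3L, byrow = TRUE)
  col
}

element_radius <- function(elements, what = c("vdw", "cov")) {
  what <- match.arg(what)
  p <- element_palette()
  r <- p[[paste0(what, "_radius")]][match(elements, p$symbol)]
  r[is.na(r)] <- if (what == "vdw") 1.6 else 1.0
  r
}

# Distance-based bond perception, used only when connectivity is absent.
perceive_bonds <- function(coords, params) {
  n <- nrow(coords)
  if (n < 2L) return(data.frame(from = integer(), to = integer(), order = integer()))
  xyz <- as.matrix(coords[, c("x", "y", "z")])
  rc <- element_radius(coords$element, "cov")
  d <- as.matrix(stats::dist(xyz))
  lim <- outer(rc, rc, "+") + params$bond_tolerance
  hit <- which(d < lim & d > params$min_bond_distance & upper.tri(d), arr.ind = TRUE)
  data.frame(from = hit[, 1L], to = hit[, 2L],
             order = rep(1L, nrow(hit)))
}

# Rotation about x, then y, then z (right-handed, degrees). Angles are
# reduced mod 360 first so a full turn is the exact identity.
rotation_matrix <- function(angles) {
  a <- (angles %% 360) * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  rz %*% ry %*% rx
}

#' Rasterize one rotated conformer as a ball-and-stick image
#'
#' Deterministic software rasterizer: the molecule is centered at its
#' geometric centroid (coordinates then quantized to 1e-6 Angstrom so the
#' output is byte-stable under translation of the input), rotated about
#' the x, then y, then z axes, scaled so its bounding sphere fills 90% of
#' the image edge at 100% zoom, and drawn with orthographic projection.
#' Atoms are shaded disks (radial Lambertian falloff) in a CPK-like
#' element palette; bonds are drawn as two half-cylinders colored by the
#' nearer atom. Depth ordering uses the painter's algorithm on primitive
#' centers, so nearer atoms occlude farther ones.
#'
#' @param coords data.frame with columns `element`, `x`, `y`, `z`.
#' @param angle_triple numeric length-3 rotation angles (degrees).
#' @param params a [render_params()].
#' @param bonds optional connectivity data.frame (`from`, `to`, `order`);
#'   when `NULL`, bonds are perceived from interatomic distances.
#' @return numeric array `image_px x image_px x 3` with values in \[0, 1\]
#'   (rows = image y from top, columns = image x).
#' @export
render_snapshot <- function(coords, angle_triple, params = render_params(),
                            bonds = NULL) {
  stopifnot(inherits(params, "render_params"), nrow(coords) >= 1L)
  px <- params$image_px
  xyz <- as.matrix(coords[, c("x", "y", "z")])
  storage.mode(xyz) <- "double"
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  xyz <- sweep(xyz, 2L, colMeans(xyz))
  xyz <- round(xyz, 6L)                       # byte-stable under translation
  if (nrow(xyz) > 1L && all(abs(xyz) < 1e-9))
    sq_log("render", "degenerate all-coincident coordinates; rendering a single sphere")
  if (is.null(bonds)) bonds <- perceive_bonds(coords, params)

  xyz <- xyz %*% t(rotation_matrix(angle_triple))
  r_atom <- element_radius(coords$element, "vdw") * params$atom_vdw_pct / 100
  r_bound <- max(sqrt(rowSums(xyz^2)) + r_atom)
  scale <- (0.9 * params$zoom_pct / 100 * px) / (2 * r_bound)

  # screen coordinates: column = x right, row = y down, depth = z (viewer at +z)
  sx <- px / 2 + scale * xyz[, 1L]
  sy <- px / 2 - scale * xyz[, 2L]
  sz <- xyz[, 3L]
  col <- element_color(coords$element)

  img <- array(rep(params$background, each = px * px), dim = c(px, px, 3L))

  # primitive list: atoms and half-bonds, painter's order by depth
  n_at <- nrow(xyz)
  prim <- data.frame(kind = rep(1L, n_at), a = seq_len(n_at), b = NA_integer_,
                     depth = sz)
  if (nrow(bonds) > 0L) {
    mx <- (sx[bonds$from] + sx[bonds$to]) / 2
    my <- (sy[bonds$from] + sy[bonds$to]) / 2
    mz <- (sz[bonds$from] + sz[bonds$to]) / 2
    prim <- rbind(prim,
      data.frame(kind = 2L, a = bonds$from, b = seq_len(nrow(bonds)),
                 depth = (sz[bonds$from] + mz) / 2),
      data.frame(kind = 2L, a = bonds$to, b = seq_len(nrow(bonds)),
                 depth = (sz[bonds$to] + mz) / 2))
    bmx <- mx; bmy <- my
  }
  ord <- order(prim$depth, seq_len(nrow(prim)))   # far first, stable ties

  halfwidth <- max(scale * params$bond_radius, 0.5)
  for (k in ord) {
    if (prim$kind[k] == 1L) {
      i <- prim$a[k]
      img <- draw_disk(img, sx[i], sy[i], scale * r_atom[i], col[i, ], px)
    } else {
      i <- prim$a[k]; j <- prim$b[k]
      img <- draw_segment(img, sx[i], sy[i], bmx[j], bmy[j], halfwidth,
                          col[i, ] * 0.85, px)
    }
  }
  img
}

# Shaded disk: intensity = 0.35 + 0.65 * sqrt(1 - (d/r)^2).
draw_disk <- function(img, cx, cy, r, color, px) {
  x0 <- max(1L, floor(cx - r)); x1 <- min(px, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(px, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  dx2 <- (xs - 0.5 - cx)^2
  dy2 <- (ys - 0.5 - cy)^2
  d2 <- outer(dy2, dx2, "+")           # rows = y, cols = x
  mask <- d2 <= r^2
  if (!any(mask)) return(img)
  shade <- 0.35 + 0.65 * sqrt(pmax(0, 1 - d2 / r^2))
  for (ch in 1:3) {
    plane <- img[ys, xs, ch, drop = FALSE]
    plane[mask] <- (color[ch] * shade)[mask]
    img[ys, xs, ch] <- plane
  }
  img
}

# Flat-shaded thick segment (projected bond half-cylinder).
draw_segment <- function(img, x1, y1, x2, y2, hw, color, px) {
  x0 <- max(1L, floor(min(x1, x2) - hw)); xe <- min(px, ceiling(max(x1, x2) + hw))
  y0 <- max(1L, floor(min(y1, y2) - hw)); ye <- min(px, ceiling(max(y1, y2) + hw))
  if (x0 > xe || y0 > ye) return(img)
  xs <- x0:xe; ys <- y0:ye
  gx <- matrix(xs - 0.5, length(ys), length(xs), byrow = TRUE)
  gy <- matrix(ys - 0.5, length(ys), length(xs))
  vx <- x2 - x1; vy <- y2 - y1
  len2 <- vx * vx + vy * vy
  t <- if (len2 < 1e-12) gx * 0 else pmin(1, pmax(0, ((gx - x1) * vx + (gy - y1) * vy) / len2))
  d2 <- (gx - (x1 + t * vx))^2 + (gy - (y1 + t * vy))^2
  mask <- d2 <= hw^2
  if (!any(mask)) return(img)
  for (ch in 1:3) {
    plane <- img[ys, xs, ch, drop = FALSE]
    plane[mask] <- color[ch]
    img[ys, xs, ch] <- plane
  }
  img
}

#' Render all snapshot angles for one compound
#'
#' Enumerates the angle grid of `params$angle_increment`, renders one PNG
#' per angle into `out_dir`, and returns the manifest: the ordered table
#' of (angle triple, image path) with the render parameters attached.
#' Re-running with identical inputs reproduces identical files.
#'
#' @param record an embedded [compound_record()].
#' @param params a [render_params()].
#' @param out_dir output directory (created if needed; must be writable).
#' @return a `snapshot_manifest` data.frame with columns `compound_id`,
#'   `angle_x`, `angle_y`, `angle_z`, `path`, attribute `render_params`.
#' @export
snapshot_compound <- function(record, params = render_params(), out_dir) {
  stopifnot(inherits(record, "compound_record"))
  if (is.null(record$coords)) stop("record has no conformer: ", record$compound_id)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  if (file.access(out_dir, 2L) != 0L) stop("output directory not writable: ", out_dir)
  angles <- enumerate_angles(params$angle_increment)
  paths <- file.path(out_dir, sprintf("%s_x%05.1f_y%05.1f_z%05.1f.png",
                                      record$compound_id,
                                      angles[, 1L], angles[, 2L], angles[, 3L]))
  for (k in seq_len(nrow(angles))) {
    img <- render_snapshot(record$coords, angles[k, ], params, bonds = record$bonds)
    png::writePNG(img, paths[k])
  }
  manifest <- data.frame(compound_id = record$compound_id,
                         angle_x = angles[, 1L], angle_y = angles[, 2L],
                         angle_z = angles[, 3L], path = paths,
                         stringsAsFactors = FALSE)
  structure(manifest, render_params = params,
            class = c("snapshot_manifest", "data.frame"))
}

#' Render snapshots for a whole library
#'
#' @param records embedded `compound_library`; records flagged
#'   un-renderable are skipped with a log entry.
#' @param params a [render_params()].
#' @param out_dir output directory.
#' @return one combined `snapshot_manifest` (row-bound per-compound
#'   manifests, input order preserved).
#' @export
snapshot_library <- function(records, params = render_params(), out_dir) {
  keep <- vapply(records, function(r) identical(r$render_flag, "ok") &&
                   !is.null(r$coords), TRUE)
  if (any(!keep))
    sq_log("render", "skipping %d un-renderable compound(s)", sum(!keep))
  parts <- lapply(records[keep], snapshot_compound, params = params, out_dir = out_dir)
  manifest <- do.call(rbind, parts)
  rownames(manifest) <- NULL
  structure(manifest, render_params = params,
            class = c("snapshot_manifest", "data.frame"))
}

#' Write / read a snapshot manifest as delimited text
#'
#' The manifest is a TSV with `#key: value` header lines recording the
#' render parameters for provenance.
#' @param manifest a `snapshot_manifest`.
#' @param path file path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest`
#'   returns the manifest with `render_params` reattached.
#' @export
write_manifest <- function(manifest, path) {
  p <- attr(manifest, "render_params")
  hdr <- sprintf("#%s: %s", names(p),
                 vapply(p, function(v) paste(format(v, digits = 15), collapse = ","), ""))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(manifest), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  kv <- strsplit(sub("^#", "", hdr), ": ", fixed = TRUE)
  pl <- stats::setNames(lapply(kv, function(x) {
    v <- suppressWarnings(as.numeric(strsplit(x[2L], ",", fixed = TRUE)[[1L]]))
    if (anyNA(v)) x[2L] else v
  }), vapply(kv, `[[`, "", 1L))
  params <- do.call(render_params, pl[names(pl) %in% names(formals(render_params))])
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")], sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  structure(tab, render_params = params,
            class = c("snapshot_manifest", "data.frame"))
}
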