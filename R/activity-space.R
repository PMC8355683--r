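#' Project station coordinates to a local plane
#'
#' Azimuthal-equidistant projection on the sphere, centred on the array
#' centroid (or a supplied centre). Distances from the centre are exact and
#' pairwise distance distortion is far below 0.1% over a 50 km array, which
#' is negligible next to receiver detection radii.
#'
#' @param stations data.frame with `lat`, `lon` (decimal degrees WGS84).
#' @param center optional `c(lat, lon)` projection centre.
#' @return The input with `x_km`, `y_km` columns added; the centre is stored
#'   in attribute `"center"`.
#' @export
project_coordinates <- function(stations, center = NULL) {
  if (any(abs(stations$lat) > 90) || any(abs(stations$lon) > 180))
    stop("coordinates outside valid ranges")
  if (is.null(center)) center <- c(mean(stations$lat), mean(stations$lon))
  R <- 6371.0088  # mean earth radius, km
  phi0 <- center[1] * pi / 180; lam0 <- center[2] * pi / 180
  phi <- stations$lat * pi / 180; lam <- stations$lon * pi / 180
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  cosc <- pmin(1, pmax(-1, cosc))
  c_ang <- acos(cosc)
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  stations$x_km <- R * k * cos(phi) * sin(lam - lam0)
  stations$y_km <- R * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0))
  attr(stations, "center") <- center
  stations
}

# projected coordinates per node: centroid of the member stations
.node_coordinates <- function(ds) {
  st <- project_coordinates(ds$stations)
  map <- if (!is.null(ds$node_map)) ds$node_map else default_node_map(st$receiver_id)
  nid <- unname(map$mapping[as.character(st$receiver_id)])
  data.frame(node_id = tapply(nid, nid, unique),
             x_km = tapply(st$x_km, nid, mean),
             y_km = tapply(st$y_km, nid, mean),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Time-stepped relocation series
#'
#' Collapses detections into one relocation per occupied time bin (default
#' 30 min). Within a bin the animal is placed at the node with the most
#' detections; ties go to the node of the latest detection in the bin. Bins
#' without detections yield no relocation — with a non-overlapping array,
#' positions between receivers cannot be interpolated. Relocations sit at
#' the projected node coordinates.
#'
#' @param ds a cleaned, node-merged `"detection_set"` (see
#'   [merge_receiver_nodes()]; falls back to receiver ids if unmerged).
#' @param shark_id animal to extract.
#' @param step_min bin width in minutes.
#' @return data.frame with `bin_start` (POSIXct), `node_id`, `x_km`, `y_km`;
#'   zero rows for an animal without detections.
#' @export
build_relocation_series <- function(ds, shark_id, step_min = 30) {
  stopifnot(inherits(ds, "detection_set"))
  ev <- ds$events[ds$events$transmitter_id == as.character(shark_id), , drop = FALSE]
  nodes <- .node_coordinates(ds)
  if (!nrow(ev)) {
    return(data.frame(bin_start = as.POSIXct(character(), tz = "UTC"),
                      node_id = character(), x_km = numeric(), y_km = numeric()))
  }
  node <- if (!is.null(ev$node_id)) ev$node_id else ev$receiver_id
  step <- step_min * 60
  bin <- floor(as.numeric(ev$timestamp) / step) * step
  pick <- function(i) {
    cnt <- table(node[i])
    best <- names(cnt)[cnt == max(cnt)]
    if (length(best) > 1) {
      late <- i[node[i] %in% best]
      best <- node[late[which.max(as.numeric(ev$timestamp[late]))]]
    }
    best
  }
  idx <- split(seq_along(bin), bin)
  out <- data.frame(
    bin_start = as.POSIXct(as.numeric(names(idx)), origin = "1970-01-01", tz = "UTC"),
    node_id = vapply(idx, pick, character(1)),
    stringsAsFactors = FALSE)
  m <- match(out$node_id, nodes$node_id)
  out$x_km <- nodes$x_km[m]
  out$y_km <- nodes$y_km[m]
  rownames(out) <- NULL
  out
}

#' Bivariate normal kernel density surface
#'
#' Utilization distribution from relocations: an equal-weight mixture of
#' isotropic bivariate normal kernels, `f(x) = (1/n) sum_i N2(x; x_i, h^2 I)`,
#' evaluated on a regular grid padded by at least four bandwidths around the
#' relocation bounding box so that essentially all kernel mass is on the
#' grid. Coincident relocations are collapsed to weighted points, so cost
#' scales with the number of distinct nodes, not relocations.
#'
#' @param series relocation data.frame with `x_km`, `y_km` (e.g. from
#'   [build_relocation_series()]), or a two-column matrix of km coordinates.
#' @param h_m kernel standard deviation (smoothing parameter), metres.
#' @param cell_m grid cell side, metres.
#' @param pad_factor grid padding in bandwidths (>= 4 recommended).
#' @return Object of class `"density_surface"`: grid axes `x`, `y` (km, cell
#'   centres), density matrix `z` (km^-2, rows follow `x`), `h_m`, `cell_m`,
#'   `n` relocations.
#' @export
estimate_kernel_density <- function(series, h_m = 1000, cell_m = 100,
                                    pad_factor = 4) {
  if (is.matrix(series)) series <- data.frame(x_km = series[, 1], y_km = series[, 2])
  if (!nrow(series)) stop("empty relocation series")
  if (h_m <= 0) stop("bandwidth must be positive")
  h <- h_m / 1000; cell <- cell_m / 1000
  key <- paste(series$x_km, series$y_km)
  w <- as.vector(table(key)[unique(key)])
  ux <- series$x_km[!duplicated(key)]
  uy <- series$y_km[!duplicated(key)]
  pad <- pad_factor * h
  gx <- seq(min(ux) - pad, max(ux) + pad, by = cell)
  gy <- seq(min(uy) - pad, max(uy) + pad, by = cell)
  # separable kernels: z[j,k] = sum_i w_i phi(gx_j; ux_i) phi(gy_k; uy_i)
  Gx <- vapply(seq_along(ux), function(i) stats::dnorm(gx, ux[i], h),
               numeric(length(gx)))
  Gy <- vapply(seq_along(uy), function(i) stats::dnorm(gy, uy[i], h),
               numeric(length(gy)))
  z <- (Gx %*% (w * t(Gy))) / sum(w)
  structure(list(x = gx, y = gy, z = z, h_m = h_m, cell_m = cell_m,
                 n = nrow(series)),
            class = "density_surface")
}

#' @export
print.density_surface <- function(x, ...) {
  cat("<density_surface> ", length(x$x), "x", length(x$y), " grid, cell ",
      x$cell_m, " m, h = ", x$h_m, " m, n = ", x$n, " relocations\n", sep = "")
  cat(sprintf("  total mass on grid: %.4f\n", surface_mass(x)))
  invisible(x)
}

#' @rdname estimate_kernel_density
#' @param surface a `"density_surface"`.
#' @export
surface_mass <- function(surface) {
  sum(surface$z) * (surface$cell_m / 1000)^2
}

#' Percent-volume contour area
#'
#' The smallest-area region containing a given fraction of the utilization
#' distribution's mass: cells are ranked by density and accumulated until the
#' requested mass is reached (the cell crossing the threshold is included).
#' The 50% contour is the conventional core activity space, 95% the total
#' activity space.
#'
#' @param surface a `"density_surface"`.
#' @param level mass fraction in (0, 1).
#' @return List with `level`, `area_km2`, `threshold` (density at the contour)
#'   and `polygons` (contour rings from [grDevices::contourLines()], km).
#' @export
percent_volume_contour <- function(surface, level = 0.5) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  cell_area <- (surface$cell_m / 1000)^2
  dens <- sort(as.vector(surface$z), decreasing = TRUE)
  mass <- cumsum(dens) * cell_area
  total <- mass[length(mass)]
  k <- which(mass >= level * total)[1]
  threshold <- dens[k]
  area <- k * cell_area
  polys <- grDevices::contourLines(surface$x, surface$y, surface$z,
                                   levels = threshold)
  list(level = level, area_km2 = area, threshold = threshold, polygons = polys)
}

#' Core activity spaces for a cohort
#'
#' Builds relocation series and kernel-density activity spaces for every
#' retained animal. Animals with fewer than `min_distinct_nodes` distinct
#' relocation nodes or fewer than `min_relocations` relocations are marked
#' ineligible (too little spatial information for a meaningful utilization
#' distribution) and carry `NA` areas.
#'
#' @param ds a cleaned, node-merged `"detection_set"`.
#' @param h_m,cell_m,pad_factor kernel and grid settings, see
#'   [estimate_kernel_density()].
#' @param step_min relocation time step in minutes.
#' @param min_distinct_nodes,min_relocations eligibility thresholds.
#' @param levels percent-volume levels; the first two populate `kd50_km2`
#'   and `kd95_km2`.
#' @return data.frame with `shark_id`, `n_relocations`, `n_nodes`,
#'   `eligible`, `kd50_km2`, `kd95_km2`, `h_m`.
#' @export
core_activity_spaces <- function(ds, h_m = 1000, cell_m = 100, pad_factor = 4,
                                 step_min = 30, min_distinct_nodes = 3,
                                 min_relocations = 10,
                                 levels = c(0.5, 0.95)) {
  stopifnot(inherits(ds, "detection_set"))
  ids <- as.character(ds$sharks$shark_id)
  ids <- ids[ids %in% unique(ds$events$transmitter_id)]
  rows <- lapply(ids, function(id) {
    ser <- build_relocation_series(ds, id, step_min = step_min)
    n_nodes <- length(unique(ser$node_id))
    eligible <- nrow(ser) >= min_relocations && n_nodes >= min_distinct_nodes
    kd <- c(NA_real_, NA_real_)
    if (eligible) {
      surf <- estimate_kernel_density(ser, h_m = h_m, cell_m = cell_m,
                                      pad_factor = pad_factor)
      kd <- vapply(levels[1:2], function(l)
        percent_volume_contour(surf, l)$area_km2, numeric(1))
    }
    data.frame(shark_id = id, n_relocations = nrow(ser), n_nodes = n_nodes,
               eligible = eligible, kd50_km2 = kd[1], kd95_km2 = kd[2],
               h_m = h_m, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group means of core activity space
#'
#' Arithmetic mean and standard deviation of an activity-space column by
#' size class and by sex, over animals with a defined estimate. Empty groups
#' are omitted with a warning.
#'
#' @param tbl data.frame with `size_class`, `sex` and the value column.
#' @param value column to summarise (default `"kd50_km2"`).
#' @return List of two data.frames, `by_size_class` and `by_sex`, each with
#'   `group`, `n`, `mean`, `sd`.
#' @export
summarize_activity_by_class <- function(tbl, value = "kd50_km2") {
  v <- tbl[[value]]
  ok <- !is.na(v)
  one <- function(gvec) {
    g <- as.character(gvec)[ok]
    agg <- lapply(split(v[ok], g), function(x)
      c(n = length(x), mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0))
    data.frame(group = names(agg), do.call(rbind, agg), row.names = NULL,
               stringsAsFactors = FALSE)
  }
  res <- list(by_size_class = one(tbl$size_class), by_sex = one(tbl$sex))
  for (nm in names(res)) {
    all_groups <- unique(as.character(
      if (nm == "by_size_class") tbl$size_class else tbl$sex))
    missing <- setdiff(all_groups, res[[nm]]$group)
    if (length(missing))
      warning("no defined ", value, " in group(s): ",
              paste(missing, collapse = ", "), " (omitted)")
  }
  res
}
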