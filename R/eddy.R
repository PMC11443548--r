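## Mesoscale eddy detection from closed sea-level-anomaly contours, polarity
## counting, and eddy kinetic energy.

#' Eddy kinetic energy from surface currents
#'
#' `EKE = (u^2 + v^2) / 2`, elementwise; missing wherever either component is
#' missing. EKE is proportional to eddy diffusivity and so indexes the
#' stirring that disperses a bloom.
#'
#' @param u,v Zonal and meridional surface-current [geo_field()]s (m/s) on
#'   identical grids and time axes.
#' @return A [geo_field()] in m2/s2.
#' @export
eke <- function(u, v) {
  stopifnot(inherits(u, "geo_field"), inherits(v, "geo_field"))
  if (!isTRUE(all.equal(u$grid$lats, v$grid$lats)) ||
      !isTRUE(all.equal(u$grid$lons, v$grid$lons)) ||
      !identical(as.Date(u$times), as.Date(v$times))) {
    stop("u and v must share grid and time axes")
  }
  geo_field((u$values^2 + v$values^2) / 2, u$grid, u$times,
            units = "m2 s-2", var = "eke")
}

#' Eddy detection criteria
#'
#' Numeric criteria of the closed-contour detector. The defaults are in the
#' range conventional for 25 km altimetry products and are deliberately
#' exposed as configuration.
#'
#' @param contour_interval Spacing of the SLA contour ladder (m; default
#'   0.01 = 1 cm).
#' @param min_amplitude Minimum eddy amplitude, extremum minus edge-contour
#'   level (m; default 0.02).
#' @param min_area_cells,max_area_cells Accepted range of the number of grid
#'   cells enclosed by the eddy edge (defaults 8 and 1000).
#' @param weighted_center Use the SLA-anomaly-weighted centroid of the cells
#'   inside the innermost contour as the center (default); otherwise the
#'   unweighted centroid.
#' @return An `eddy_criteria` list.
#' @export
eddy_criteria <- function(contour_interval = 0.01, min_amplitude = 0.02,
                          min_area_cells = 8L, max_area_cells = 1000L,
                          weighted_center = TRUE) {
  if (contour_interval <= 0) stop("contour_interval must be > 0")
  structure(list(contour_interval = contour_interval,
                 min_amplitude = min_amplitude,
                 min_area_cells = min_area_cells,
                 max_area_cells = max_area_cells,
                 weighted_center = weighted_center),
            class = "eddy_criteria")
}

# closed contour rings of z (lat x lon matrix) at the given levels;
# a ring is closed when its endpoints coincide (contours that intersect the
# domain boundary are open polylines and are discarded)
closed_rings <- function(lats, lons, z, levels) {
  cl <- grDevices::contourLines(x = lats, y = lons, z = z, levels = levels)
  keep <- vapply(cl, function(r) {
    n <- length(r$x)
    n > 3 && abs(r$x[1] - r$x[n]) < 1e-9 && abs(r$y[1] - r$y[n]) < 1e-9
  }, logical(1))
  cl[keep]
}

# strict local maxima of z over a (2k+1)^2 neighborhood, excluding the
# outermost frame of the grid
local_maxima <- function(z, k = 2L) {
  nr <- nrow(z)
  nc <- ncol(z)
  if (nr < 2 * k + 1 || nc < 2 * k + 1) return(matrix(integer(0), 0, 2))
  inner_r <- (k + 1):(nr - k)
  inner_c <- (k + 1):(nc - k)
  is_max <- matrix(TRUE, length(inner_r), length(inner_c))
  zi <- z[inner_r, inner_c]
  for (dr in -k:k) {
    for (dc in -k:k) {
      if (dr == 0 && dc == 0) next
      is_max <- is_max & (zi > z[inner_r + dr, inner_c + dc])
    }
  }
  which(is_max, arr.ind = TRUE) + k  # back to full-grid indices
}

# grow one candidate extremum (a maximum of zs) through the ring ladder;
# ring_extrema[[i]] lists the extremum ids inside ring i (precomputed once)
grow_eddy <- function(zs, lats, lons, rings, ring_levels, ring_extrema,
                      ext_rc, ext_id, extrema_rc, criteria) {
  zext <- zs[ext_rc[1], ext_rc[2]]
  containing <- which(vapply(seq_along(rings), function(i) {
    ring_levels[i] < zext && ext_id %in% ring_extrema[[i]]
  }, logical(1)))
  if (length(containing) == 0) return(NULL)
  # accept rings outward (decreasing level) while no second significant
  # extremum is enclosed: another local maximum counts as a second core only
  # if it rises at least min_amplitude above the contour level, so that
  # sub-gridscale noise bumps on the flank do not truncate the eddy
  ord <- containing[order(ring_levels[containing], decreasing = TRUE)]
  accepted <- integer(0)
  for (i in ord) {
    others <- ring_extrema[[i]]
    others <- others[others != ext_id]
    if (length(others) > 0) {
      # another enclosed maximum is a second eddy core only if it rises at
      # least min_amplitude above the contour level AND is separated from
      # this core by a saddle at least min_amplitude deep; plateau noise
      # bumps fail the saddle test and do not truncate growth
      zo <- extrema_rc[others, , drop = FALSE]
      zvals <- zs[cbind(zo[, 1], zo[, 2])]
      second <- which(zvals - ring_levels[i] >= criteria$min_amplitude)
      is_core <- vapply(second, function(j) {
        saddle_depth(zs, ext_rc, zo[j, ]) >= criteria$min_amplitude
      }, logical(1))
      if (any(is_core)) break
    }
    accepted <- c(accepted, i)
  }
  if (length(accepted) == 0) return(NULL)
  edge_i <- accepted[length(accepted)]     # lowest accepted level
  amplitude <- zext - ring_levels[edge_i]
  if (amplitude < criteria$min_amplitude) return(NULL)
  edge <- rings[[edge_i]]
  cells <- cells_inside(edge, lats, lons)
  if (nrow(cells) < criteria$min_area_cells ||
      nrow(cells) > criteria$max_area_cells) return(NULL)
  # the center-defining core contour: the innermost accepted contour that
  # encloses at least min_area_cells cell centers (smaller contours circle
  # sub-noise residual bumps and carry no positional information)
  core <- NULL
  inner_i <- edge_i
  for (i in accepted) {
    cand <- cells_inside(rings[[i]], lats, lons)
    if (nrow(cand) >= criteria$min_area_cells) {
      core <- cand
      inner_i <- i
      break
    }
  }
  if (is.null(core)) {
    core <- cells
    inner_i <- edge_i
  }
  list(edge_i = edge_i, inner_i = inner_i, amplitude = amplitude,
       zext = zext, cells = cells, core = core, edge = edge)
}

# depth of the saddle between two cells: how far the field drops below the
# lower of the two maxima along the straight grid path connecting them
saddle_depth <- function(zs, rc1, rc2) {
  n <- max(abs(rc1[1] - rc2[1]), abs(rc1[2] - rc2[2])) * 2 + 1
  rr <- round(seq(rc1[1], rc2[1], length.out = n))
  cc <- round(seq(rc1[2], rc2[2], length.out = n))
  path_min <- min(zs[cbind(rr, cc)])
  min(zs[rc1[1], rc1[2]], zs[rc2[1], rc2[2]]) - path_min
}

ring_contains <- function(ring, pts) {
  as.logical(mgcv::in.out(cbind(ring$x, ring$y), pts))
}

# grid-cell centers strictly inside a ring, as (row, col) indices
cells_inside <- function(ring, lats, lons) {
  ri <- which(lats >= min(ring$x) & lats <= max(ring$x))
  ci <- which(lons >= min(ring$y) & lons <= max(ring$y))
  if (length(ri) == 0 || length(ci) == 0) return(matrix(integer(0), 0, 2))
  cand <- as.matrix(expand.grid(row = ri, col = ci, KEEP.OUT.ATTRS = FALSE))
  pts <- cbind(lats[cand[, 1]], lons[cand[, 2]])
  inside <- mgcv::in.out(cbind(ring$x, ring$y), pts)
  cand[as.logical(inside), , drop = FALSE]
}

detect_polarity <- function(zs, lats, lons, criteria, polarity, depth_shallow) {
  rng <- range(zs)
  ci <- criteria$contour_interval
  lo <- floor(rng[1] / ci) * ci
  hi <- ceiling(rng[2] / ci) * ci
  levels <- seq(lo, hi, by = ci)
  levels <- levels[levels > rng[1] & levels < rng[2]]
  if (length(levels) == 0) return(list())
  rings <- closed_rings(lats, lons, zs, levels)
  if (length(rings) == 0) return(list())
  ring_levels <- vapply(rings, `[[`, numeric(1), "level")
  extrema <- local_maxima(zs, k = 2L)
  if (nrow(extrema) == 0) return(list())
  ext_pts <- cbind(lats[extrema[, 1]], lons[extrema[, 2]])
  ring_extrema <- lapply(rings, function(r) {
    which(as.logical(mgcv::in.out(cbind(r$x, r$y), ext_pts)))
  })
  recs <- list()
  for (e in seq_len(nrow(extrema))) {
    g <- grow_eddy(zs, lats, lons, rings, ring_levels, ring_extrema,
                   extrema[e, ], e, extrema, criteria)
    if (is.null(g)) next
    if (!is.null(depth_shallow) &&
        any(depth_shallow[g$cells])) next  # touches water shallower than allowed
    core_z <- zs[g$core]
    w <- if (criteria$weighted_center) {
      pmax(core_z - ring_levels[g$edge_i], 0)
    } else {
      rep(1, nrow(g$core))
    }
    if (sum(w) == 0) w <- rep(1, nrow(g$core))
    center_lat <- sum(lats[g$core[, 1]] * w) / sum(w)
    center_lon <- sum(lons[g$core[, 2]] * w) / sum(w)
    cell_km2 <- mean(diff(lats)) * 111.195 *
      mean(abs(diff(lons))) * 111.195 * cos(center_lat * pi / 180)
    recs[[length(recs) + 1L]] <- list(
      center_lat = center_lat,
      center_lon = center_lon,
      polarity = polarity,
      amplitude = g$amplitude,
      equivalent_radius = sqrt(nrow(g$cells) * abs(cell_km2) / pi),
      n_cells = nrow(g$cells),
      edge = data.frame(lat = g$edge$x, lon = g$edge$y),
      extremum_sla = if (polarity == "anticyclonic") g$zext else -g$zext
    )
  }
  dedupe_records(recs)
}

# two seeds inside one eddy (possible under noise) yield near-identical
# detections; keep the larger-amplitude record when one center falls inside
# another's edge
dedupe_records <- function(recs) {
  if (length(recs) <= 1) return(recs)
  drop <- rep(FALSE, length(recs))
  for (i in seq_along(recs)) {
    if (drop[i]) next
    for (j in seq_along(recs)) {
      if (i == j || drop[j] || drop[i]) next
      inside <- as.logical(mgcv::in.out(
        cbind(recs[[i]]$edge$lat, recs[[i]]$edge$lon),
        cbind(recs[[j]]$center_lat, recs[[j]]$center_lon)))
      if (inside) {
        if (recs[[j]]$amplitude <= recs[[i]]$amplitude) drop[j] <- TRUE else drop[i] <- TRUE
      }
    }
  }
  recs[!drop]
}

#' Detect mesoscale eddies in one SLA time slice
#'
#' Closed-contour detection: SLA contours are traced on a ladder of levels
#' spaced `contour_interval` apart; for each local SLA extremum the innermost
#' closed contour around it defines the eddy center (anomaly-weighted mass
#' center of the enclosed cells), successive enclosing closed contours are
#' accepted outward -- SLA changing monotonically toward the background --
#' until a contour would enclose a second eddy core or fails to close, and
#' the outermost accepted contour is the eddy edge. Amplitude is the
#' extremum minus the edge level. SLA maxima are anticyclones and minima
#' cyclones (Southern Hemisphere convention); minima are found by running
#' the identical detector on the negated field, which makes the
#' polarity-swap symmetry under `sla -> -sla` exact.
#'
#' Detections whose edge-enclosed cells intersect `shallow_mask` are
#' discarded (the contour method is only trusted in deep water).
#'
#' @param sla A [geo_field()] of SLA (m) or a single `(lat, lon)` matrix.
#' @param criteria An [eddy_criteria()].
#' @param shallow_mask Optional logical `(lat, lon)` matrix, `TRUE` where
#'   the ocean is too shallow (e.g. < 200 m).
#' @param t Time index when `sla` is a field.
#' @return An `eddy_census`: counts by polarity plus one record per eddy
#'   (center, polarity, amplitude, equivalent radius in km, edge polygon).
#' @export
detect_eddies <- function(sla, criteria = eddy_criteria(), shallow_mask = NULL,
                          t = 1L) {
  if (inherits(sla, "geo_field")) {
    z <- field_slice(sla, t)
    lats <- sla$grid$lats
    lons <- sla$grid$lons
    time <- sla$times[t]
  } else {
    z <- sla
    lats <- seq_len(nrow(z))
    lons <- seq_len(ncol(z))
    time <- as.Date(NA)
  }
  if (all(is.na(z))) {
    return(new_census(list(), time))
  }
  if (anyNA(z)) {
    # contour tracing needs a complete surface: masked cells are filled with
    # the slice median and any detection touching them is discarded
    na_mask <- is.na(z)
    z[na_mask] <- stats::median(z, na.rm = TRUE)
    shallow_mask <- if (is.null(shallow_mask)) na_mask else (shallow_mask | na_mask)
  }
  # ascending axes for contourLines
  if (is.unsorted(lats)) {
    ord <- order(lats)
    z <- z[ord, ]
    lats <- lats[ord]
    if (!is.null(shallow_mask)) shallow_mask <- shallow_mask[ord, ]
  }
  anti <- detect_polarity(z, lats, lons, criteria, "anticyclonic", shallow_mask)
  cyc <- detect_polarity(-z, lats, lons, criteria, "cyclonic", shallow_mask)
  new_census(c(anti, cyc), time)
}

new_census <- function(records, time) {
  pol <- vapply(records, `[[`, character(1), "polarity")
  structure(list(time = time,
                 n_cyclonic = sum(pol == "cyclonic"),
                 n_anticyclonic = sum(pol == "anticyclonic"),
                 records = records),
            class = "eddy_census")
}

#' @export
print.eddy_census <- function(x, ...) {
  cat(sprintf("<eddy_census> %s: %d cyclonic, %d anticyclonic\n",
              format(x$time), x$n_cyclonic, x$n_anticyclonic))
  invisible(x)
}

#' Eddy census over time within a region
#'
#' Runs [detect_eddies()] on every time slice; an eddy is counted in the
#' region if (and only if) its center lies inside, regardless of where its
#' edge reaches.
#'
#' @param sla An SLA [geo_field()].
#' @param reg A [region()].
#' @param criteria An [eddy_criteria()].
#' @param shallow_mask Optional shallow mask as in [detect_eddies()].
#' @return A data.frame (`time`, `n_cyclonic`, `n_anticyclonic`) with the
#'   per-slice census objects attached as attribute `"censuses"`.
#' @export
census_series <- function(sla, reg, criteria = eddy_criteria(),
                          shallow_mask = NULL) {
  stopifnot(inherits(sla, "geo_field"), inherits(reg, "region"))
  censuses <- lapply(seq_along(sla$times), function(t) {
    cen <- detect_eddies(sla, criteria, shallow_mask, t = t)
    keep <- vapply(cen$records, function(r) {
      r$center_lat >= reg$lat_min && r$center_lat <= reg$lat_max &&
        r$center_lon >= reg$lon_min && r$center_lon <= reg$lon_max
    }, logical(1))
    new_census(cen$records[keep], cen$time)
  })
  out <- data.frame(
    time = sla$times,
    n_cyclonic = vapply(censuses, `[[`, integer(1), "n_cyclonic"),
    n_anticyclonic = vapply(censuses, `[[`, integer(1), "n_anticyclonic")
  )
  attr(out, "censuses") <- censuses
  out
}
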