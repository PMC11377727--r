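# Seeded synthetic 3D refractive-index phantoms with ground-truth
# annotations: polystyrene-style beads, USAF-1951 phase targets, and
# cell-like blobs for the morphology pipeline.

#' Refractive-index volume
#'
#' Container for a 3D refractive-index distribution n(r) on an anisotropic
#' voxel grid.  The array is real for transparent samples; a complex array
#' carries absorption in its imaginary part.  Spatial coordinates are
#' centered: voxel i (0-based) of an axis of length N sits at
#' (i - N \%/\% 2) * pitch, micrometres.
#'
#' @param n 3D numeric (or complex) array of refractive indices.
#' @param pitch voxel pitch (dx, dy, dz) in um; dx == dy required.
#' @param n_m surrounding-medium refractive index.
#' @param annotation optional list of ground-truth metadata.
#' @return Object of class \code{ri_volume}.
#' @export
ri_volume <- function(n, pitch, n_m, annotation = list()) {
  if (length(dim(n)) != 3L) stop("'n' must be a 3D array")
  pitch <- as.numeric(pitch)
  if (length(pitch) != 3L || any(pitch <= 0))
    stop("'pitch' must be three positive values (um)")
  if (abs(pitch[1] - pitch[2]) > 1e-12 * pitch[1])
    stop("lateral pitches must be equal (dx == dy)")
  if (min(Re(n)) < 1) stop("refractive index must be >= 1 everywhere")
  if (is.complex(n) && min(Im(n)) < 0)
    stop("absorption (imaginary part) must be >= 0 everywhere")
  structure(list(n = n, pitch = pitch, n_m = n_m, annotation = annotation),
            class = "ri_volume")
}

#' @export
print.ri_volume <- function(x, ...) {
  ctr <- Re(x$n) - x$n_m
  cat(sprintf(
    "RI volume: %s voxels, pitch %s um, n_m = %.4g, contrast range [%.4g, %.4g]\n",
    paste(dim(x$n), collapse = " x "),
    paste(signif(x$pitch, 4), collapse = "/"), x$n_m, min(ctr), max(ctr)))
  invisible(x)
}

# centered voxel-center coordinates for each axis of a volume
#' @noRd
volume_coords <- function(shape, pitch) {
  lapply(1:3, function(a) centered_coords(shape[a], pitch[a]))
}

#' Microsphere (bead) phantom
#'
#' Places homogeneous spheres of given refractive index in a uniform medium,
#' emulating polystyrene beads (n = 1.594 at 483 nm) immersed in
#' index-matching oil (n = 1.58).  A voxel takes the bead index when its
#' center lies strictly inside the sphere; edges are hard by default.
#'
#' @param shape,pitch grid definition (see \code{\link{ri_volume}}).
#' @param beads list of beads; each a list with \code{center} (x, y, z in um,
#'   relative to the volume center), \code{diameter} (um) and \code{ri}.
#' @param n_m medium refractive index.
#' @return \code{ri_volume} with a \code{beads} annotation.
#' @examples
#' v <- bead_phantom(c(32, 32, 32), rep(0.5, 3),
#'                   list(list(center = c(0, 0, 0), diameter = 5, ri = 1.594)),
#'                   n_m = 1.58)
#' @export
bead_phantom <- function(shape, pitch, beads = list(), n_m = 1.58) {
  shape <- as.integer(shape)
  n <- array(n_m, shape)
  cc <- volume_coords(shape, pitch)
  lo <- vapply(cc, min, 0) - pitch / 2
  hi <- vapply(cc, max, 0) + pitch / 2
  for (b in beads) {
    r <- b$diameter / 2
    if (b$diameter < 2 * pitch[1])
      stop("bead diameter ", b$diameter, " um is below 2 lateral voxels")
    if (any(b$center - r < lo) || any(b$center + r > hi))
      stop(sprintf("bead at (%s), diameter %g um, does not fit in the volume",
                   paste(signif(b$center, 4), collapse = ", "), b$diameter))
    # bounding box in index space, then exact center-inside test
    idx <- lapply(1:3, function(a)
      which(abs(cc[[a]] - b$center[a]) <= r + pitch[a]))
    if (any(vapply(idx, length, 0L) == 0L)) next
    dx2 <- outer((cc[[1]][idx[[1]]] - b$center[1])^2,
                 (cc[[2]][idx[[2]]] - b$center[2])^2, `+`)
    for (kk in seq_along(idx[[3]])) {
      z2 <- (cc[[3]][idx[[3]][kk]] - b$center[3])^2
      inside <- dx2 + z2 < r^2
      sl <- n[idx[[1]], idx[[2]], idx[[3]][kk]]
      sl[inside] <- b$ri
      n[idx[[1]], idx[[2]], idx[[3]][kk]] <- sl
    }
  }
  ri_volume(n, pitch, n_m, annotation = list(beads = beads))
}

#' USAF-1951 line width
#'
#' Standard three-bar target geometry: resolution of group G, element E is
#' \eqn{2^{G + (E-1)/6}} line pairs per mm, i.e. a line width of
#' \eqn{500 \cdot 2^{-(G + (E-1)/6)}} micrometres.
#'
#' @param G group number (integer, may be negative).
#' @param E element number in 1..6.
#' @return Line width in micrometres.
#' @examples
#' usaf_linewidth(9, 3)  # 0.775 um
#' @export
usaf_linewidth <- function(G, E) {
  if (any(E < 1 | E > 6 | E != round(E)))
    stop("'E' must be an integer in 1..6")
  500 * 2^(-(G + (E - 1) / 6))
}

#' Tilted USAF-style phase resolution target phantom
#'
#' Extrudes three-bar elements of the USAF-1951 geometry (bar width w from
#' \code{\link{usaf_linewidth}}, bars 5w long, separated by gaps of width w)
#' into a slab of the given thickness and refractive-index step \code{dn},
#' then tilts the slab about the y axis.  Membership is evaluated
#' analytically in the rotated frame, so no resampling artifacts beyond the
#' voxel grid itself.
#'
#' @param shape,pitch grid definition.
#' @param elements list of elements; each a list with \code{group},
#'   \code{element}, \code{center} (x, y in um) and logical \code{vertical}
#'   (TRUE: bars run along y, stacked along x).
#' @param thickness slab thickness in um.
#' @param dn refractive-index step of the bars above the medium.
#' @param tilt_deg tilt about the y axis, |tilt| < 45 degrees.
#' @param n_m medium refractive index.
#' @return \code{ri_volume} with an \code{elements} annotation.
#' @export
usaf_phase_target <- function(shape, pitch, elements, thickness, dn,
                              tilt_deg = 0, n_m = 1.33) {
  shape <- as.integer(shape)
  if (abs(tilt_deg) >= 45) stop("|tilt_deg| must be < 45")
  for (e in elements) {
    w <- usaf_linewidth(e$group, e$element)
    if (w < 2 * pitch[1])
      stop(sprintf("element (G=%d, E=%d): line width %.4g um below the 2-voxel sampling limit",
                   e$group, e$element, w))
  }
  cc <- volume_coords(shape, pitch)
  th <- tilt_deg * pi / 180
  n <- array(n_m, shape)
  # bar membership of a lateral point (x, y) for one element
  in_element <- function(x, y, e) {
    w <- usaf_linewidth(e$group, e$element)
    u <- x - e$center[1]; v <- y - e$center[2]
    if (!isTRUE(e$vertical)) { tmp <- u; u <- v; v <- tmp }
    # three bars across u at centers -2w, 0, 2w; length 5w along v
    across <- (abs(u + 2 * w) < w / 2) | (abs(u) < w / 2) | (abs(u - 2 * w) < w / 2)
    across & (abs(v) < 2.5 * w)
  }
  for (k in seq_len(shape[3])) {
    z <- cc[[3]][k]
    # rotate (x, z) back into the target frame
    xg <- matrix(cc[[1]], shape[1], shape[2])
    yg <- matrix(cc[[2]], shape[1], shape[2], byrow = TRUE)
    xr <- xg * cos(th) + z * sin(th)
    zr <- -xg * sin(th) + z * cos(th)
    sl <- matrix(FALSE, shape[1], shape[2])
    inz <- abs(zr) <= thickness / 2
    if (any(inz)) {
      for (e in elements) sl <- sl | (inz & in_element(xr, yg, e))
    }
    page <- n[, , k]
    page[sl] <- n_m + dn
    n[, , k] <- page
  }
  ri_volume(n, pitch, n_m,
            annotation = list(elements = elements, thickness = thickness,
                              dn = dn, tilt_deg = tilt_deg))
}

# analytic ellipsoid surface area (Thomsen's approximation, p = 1.6075)
#' @noRd
ellipsoid_area <- function(a, b, c) {
  p <- 1.6075
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}

#' Cell-like phantom with growth-stage morphology
#'
#' Deterministic (seeded) generator of non-overlapping cell-shaped blobs in
#' three morphological classes mimicking macrophage growth stages:
#' stage I, round/oval (near-unit axis ratios); stage II, oval body with
#' spherical pseudopod protrusions; stage III, elongated (shuttle-like,
#' axis ratio about 3).  The annotation records, per cell, the stage label,
#' center, analytic ellipsoid volume/area of the body, and the exact
#' voxel-counted contrast volume.
#'
#' @param shape,pitch grid definition.
#' @param n_cells number of cells (>= 1).
#' @param stage_mix probabilities of stages I..III; must sum to 1.
#' @param n_m medium refractive index.
#' @param dn refractive-index step of the cells.
#' @param radius mean cell body radius in um.
#' @param seed integer RNG seed; fixed seed gives bitwise-identical output.
#' @return \code{ri_volume} with a \code{cells} annotation.
#' @export
cell_phantom <- function(shape, pitch, n_cells, stage_mix = c(1/3, 1/3, 1/3),
                         n_m = 1.33, dn = 0.03, radius = 5, seed = 1) {
  shape <- as.integer(shape)
  if (n_cells < 1) stop("'n_cells' must be >= 1")
  if (abs(sum(stage_mix) - 1) > 1e-9) stop("'stage_mix' must sum to 1")
  set.seed(as.integer(seed))
  stages <- sample.int(3L, n_cells, replace = TRUE, prob = stage_mix)
  cc <- volume_coords(shape, pitch)
  ext_lo <- vapply(cc, min, 0); ext_hi <- vapply(cc, max, 0)
  n <- array(n_m, shape)
  cells <- list()
  placed <- list()   # centers + bounding radii for overlap rejection
  for (i in seq_len(n_cells)) {
    st <- stages[i]
    ok <- FALSE
    for (try in 1:200) {
      r0 <- radius * runif(1, 0.85, 1.15)
      semi <- switch(st,
        r0 * c(runif(1, 0.95, 1.05), runif(1, 0.95, 1.05), runif(1, 0.9, 1.0)),
        r0 * c(runif(1, 1.2, 1.4), runif(1, 0.8, 0.95), runif(1, 0.7, 0.85)),
        r0 * c(runif(1, 2.6, 3.2), runif(1, 0.55, 0.7), runif(1, 0.55, 0.7)))
      rb <- max(semi) * 1.4    # bounding radius incl. pseudopods
      ctr <- vapply(1:3, function(a)
        runif(1, ext_lo[a] + rb, ext_hi[a] - rb), 0)
      if (any(ext_lo + rb >= ext_hi - rb))
        stop("cells do not fit: volume too small for the requested radius")
      clash <- any(vapply(placed, function(p)
        sqrt(sum((p$ctr - ctr)^2)) < (p$rb + rb), TRUE))
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place cell ", i, " without overlap after 200 tries")
    phi <- runif(1, 0, pi)   # in-plane rotation of the body
    npods <- if (st == 2L) sample(2:4, 1) else 0L
    pods <- if (npods > 0) {
      ang <- runif(npods, 0, 2 * pi)
      lapply(seq_len(npods), function(j) {
        pr <- 0.3 * r0
        # attach at the body surface in the x-y plane
        dir <- c(cos(ang[j]), sin(ang[j]), 0)
        a_eff <- 1 / sqrt(sum((dir / semi)^2))
        list(center = ctr + dir * (a_eff + 0.6 * pr), r = pr)
      })
    } else list()
    placed[[length(placed) + 1L]] <- list(ctr = ctr, rb = rb)
    # rasterize: rotated ellipsoid + pods
    cphi <- cos(phi); sphi <- sin(phi)
    mask_count <- 0L
    idx <- lapply(1:3, function(a) which(abs(cc[[a]] - ctr[a]) <= rb + pitch[a]))
    xg <- cc[[1]][idx[[1]]]; yg <- cc[[2]][idx[[2]]]; zg <- cc[[3]][idx[[3]]]
    for (kk in seq_along(zg)) {
      xm <- matrix(xg - ctr[1], length(xg), length(yg))
      ym <- matrix(yg - ctr[2], length(xg), length(yg), byrow = TRUE)
      xr <- xm * cphi + ym * sphi
      yr <- -xm * sphi + ym * cphi
      zz <- zg[kk] - ctr[3]
      inside <- (xr / semi[1])^2 + (yr / semi[2])^2 + (zz / semi[3])^2 < 1
      for (p in pods) {
        inside <- inside |
          ((xm - (p$center[1] - ctr[1]))^2 + (ym - (p$center[2] - ctr[2]))^2 +
             (zg[kk] - p$center[3])^2 < p$r^2)
      }
      sl <- n[idx[[1]], idx[[2]], idx[[3]][kk]]
      newvox <- inside & (sl == n_m)
      mask_count <- mask_count + sum(newvox)
      sl[inside] <- n_m + dn
      n[idx[[1]], idx[[2]], idx[[3]][kk]] <- sl
    }
    va <- 4 / 3 * pi * prod(semi)
    aa <- ellipsoid_area(semi[1], semi[2], semi[3])
    cells[[i]] <- list(
      stage = c("I", "II", "III")[st], center = ctr, semi_axes = semi,
      volume_analytic = va, area_analytic = aa,
      sphericity_analytic = pi^(1/3) * (6 * va)^(2/3) / aa,
      n_pseudopods = npods,
      volume_voxels = mask_count * prod(pitch))
  }
  ri_volume(n, pitch, n_m,
            annotation = list(cells = cells, seed = as.integer(seed), dn = dn))
}
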