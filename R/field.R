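#' Tissue model for the quasi-static field solve
#'
#' @param sigma_brain_S_m Brain conductivity (default 0.2 S/m).
#' @param sigma_glia_S_m Glial-scar conductivity (default 0.166 S/m).
#' @param rel_permittivity Relative permittivity (88.9); recorded for
#'   completeness but unused -- the solve is quasi-static/DC and the
#'   activation criterion is on conduction current density.
#' @param domain_um Side of the cubic tissue domain in um (default 3000).
#' @param glial_thickness_um Scar thickness around rigid implants (40 um).
#' @return An object of class `tissue_model`.
#' @export
tissue_model <- function(sigma_brain_S_m = 0.2, sigma_glia_S_m = 0.166,
                         rel_permittivity = 88.9, domain_um = 3000,
                         glial_thickness_um = 40) {
  stopifnot_scalar(sigma_brain_S_m, "sigma_brain_S_m")
  stopifnot_scalar(sigma_glia_S_m, "sigma_glia_S_m")
  structure(as.list(environment()), class = "tissue_model")
}

#' Neuron-activation model
#'
#' Neurons are counted as activatable wherever the current-density magnitude
#' exceeds `j_threshold_A_m2`; the count is that tissue volume (glial scar
#' excluded) times `neuron_density`. The default density is the printed
#' literature constant, held configurable; matched-current comparisons cancel
#' it entirely.
#'
#' @param j_threshold_A_m2 Activation threshold (default 1000 A/m^2).
#' @param neuron_density Neurons per cubic meter (default 135801).
#' @return An object of class `activation_model`.
#' @export
activation_model <- function(j_threshold_A_m2 = 1000,
                             neuron_density = 135801) {
  stopifnot_scalar(j_threshold_A_m2, "j_threshold_A_m2")
  stopifnot_scalar(neuron_density, "neuron_density")
  structure(list(j_threshold_A_m2 = j_threshold_A_m2,
                 neuron_density = neuron_density),
            class = "activation_model")
}

#' Electrode geometries on the tissue-cube floor
#'
#' Three implant models share one tissue cube, electrodes lying on the bottom
#' face as constant-current surfaces:
#' * `flexible_array` -- eight 16 x 12 um rectangles in a single column at
#'   30 um pitch; no glial scar.
#' * `rigid_array` -- the same eight rectangles under a 40 um glial layer.
#' * `microwire` -- one 100 um-diameter disc (rigid wires conduct only at the
#'   tip) under a 40 um glial layer.
#' The glial layer conformally covers the electrode-bearing footprint,
#' dilated laterally by its own thickness.
#'
#' @param kind One of `"flexible_array"`, `"rigid_array"`, `"microwire"`.
#' @param tissue A [tissue_model()] (supplies the scar thickness).
#' @param glial_thickness_um Override of the scar thickness (e.g. 0 to model
#'   a bare microwire for analytic checks).
#' @return An object of class `electrode_geometry` with the site list, the
#'   scar thickness, and the lateral scar footprint.
#' @export
build_geometry <- function(kind = c("flexible_array", "rigid_array",
                                    "microwire"),
                           tissue = tissue_model(),
                           glial_thickness_um = NULL) {
  kind <- match.arg(kind)
  pitch <- 30
  if (kind == "microwire") {
    sites <- list(list(type = "disc", cx = 0, cy = 0, r = 50))
  } else {
    centers <- (0:7 - 3.5) * pitch
    sites <- lapply(centers, function(cx)
      list(type = "rect", cx = cx, cy = 0, hx = 8, hy = 6))
  }
  gt <- if (kind == "flexible_array") 0 else tissue$glial_thickness_um
  if (!is.null(glial_thickness_um)) gt <- glial_thickness_um
  structure(list(kind = kind, sites = sites, glial_thickness_um = gt,
                 pitch_um = pitch), class = "electrode_geometry")
}

# fraction of a rectangular footprint cell covered by a site
site_overlap <- function(site, x0, x1, y0, y1) {
  if (site$type == "rect") {
    ox <- pmax(0, pmin(x1, site$cx + site$hx) - pmax(x0, site$cx - site$hx))
    oy <- pmax(0, pmin(y1, site$cy + site$hy) - pmax(y0, site$cy - site$hy))
    ox * oy
  } else {
    # disc: 6x6 subsampling of the cell
    m <- 6
    xs <- x0 + (x1 - x0) * (seq_len(m) - 0.5) / m
    ys <- y0 + (y1 - y0) * (seq_len(m) - 0.5) / m
    g <- expand.grid(x = xs, y = ys)
    inside <- (g$x - site$cx)^2 + (g$y - site$cy)^2 <= site$r^2
    (x1 - x0) * (y1 - y0) * mean(inside)
  }
}

site_area <- function(site) {
  if (site$type == "rect") 4 * site$hx * site$hy else pi * site$r^2
}

# lateral scar footprint membership for cell centers
glia_footprint <- function(geom, x, y) {
  gt <- geom$glial_thickness_um
  if (gt <= 0) return(rep(FALSE, length(x)))
  if (geom$kind == "microwire") {
    sqrt(x^2 + y^2) <= geom$sites[[1]]$r + gt
  } else {
    xs <- range(vapply(geom$sites, function(s) s$cx, numeric(1)))
    x >= xs[1] - 8 - gt & x <= xs[2] + 8 + gt & abs(y) <= 6 + gt
  }
}

# geometrically graded 1-D cell boundaries from 0 to `limit`
axis_bounds <- function(fine, extent, limit, growth = 1.4) {
  b <- seq(0, extent, by = fine)
  w <- fine
  while (b[length(b)] < limit) {
    w <- w * growth
    b <- c(b, b[length(b)] + w)
  }
  b[length(b)] <- limit
  if (length(b) >= 2 && diff(b)[length(b) - 1] <= 0) b <- b[-(length(b) - 1)]
  b
}

#' Graded solver grid
#'
#' Tensor-product, cell-centered grid over one symmetry quarter of the
#' domain: fine uniform spacing near the electrodes, geometric coarsening
#' toward the grounded far boundary. All three geometries are mirror
#' symmetric about x = 0 and y = 0, so only the quarter `x, y >= 0` is
#' discretized (symmetry planes are natural no-flux boundaries) and volumes
#' are scaled by 4.
#'
#' @param geom An [build_geometry()] result (sets the default fine extents).
#' @param fine_um Fine spacing near the electrode (default 4 um for arrays,
#'   5 um for the microwire).
#' @param refine Spacing divisor for mesh-convergence checks (default 1).
#' @param tissue A [tissue_model()] (domain size).
#' @param growth Geometric coarsening ratio.
#' @return List of cell-boundary vectors `x`, `y`, `z`.
#' @export
field_grid <- function(geom, fine_um = NULL, refine = 1,
                       tissue = tissue_model(), growth = 1.4) {
  if (geom$kind == "microwire") {
    if (is.null(fine_um)) fine_um <- 5
    ext <- c(x = 200, y = 200, z = 200)
  } else {
    if (is.null(fine_um)) fine_um <- 4
    ext <- c(x = 170, y = 120, z = 150)
  }
  fine_um <- fine_um / refine
  half <- tissue$domain_um / 2
  list(x = axis_bounds(fine_um, ext["x"], half, growth),
       y = axis_bounds(fine_um, ext["y"], half, growth),
       z = axis_bounds(fine_um, ext["z"], tissue$domain_um, growth))
}

#' Solve the quasi-static extracellular field
#'
#' Finite-volume discretization of `div(sigma grad V) = 0` on a graded
#' tensor grid over the tissue cube: constant total current injected as
#' uniform current density over each electrode surface on the bottom face
#' (`current_uA` per site), the remaining bottom face insulating, far faces
#' grounded (V = 0). Face conductances use distance-weighted harmonic means
#' of the brain/glia conductivities; the sparse SPD system is solved with a
#' CHOLMOD Cholesky factorization.
#'
#' @param geom An [build_geometry()] result.
#' @param tissue A [tissue_model()].
#' @param current_uA Injected current per electrode site in uA (> 0).
#' @param grid Optional [field_grid()]; defaults to the geometry's grid.
#' @param refine Mesh-refinement divisor passed to [field_grid()].
#' @return A `field_solution`: potential `V` (V), current-density magnitude
#'   `J` (A/m^2) and conductivity per cell (arrays `nx x ny x nz`), cell
#'   centers/widths, the glia mask, injected and boundary-outflow currents,
#'   and bookkeeping (`symmetry_factor = 4`).
#' @export
solve_field <- function(geom, tissue = tissue_model(), current_uA,
                        grid = NULL, refine = 1) {
  stopifnot_scalar(current_uA, "current_uA")
  if (is.null(grid)) grid <- field_grid(geom, refine = refine,
                                        tissue = tissue)
  um <- 1e-6
  xc <- (utils::head(grid$x, -1) + utils::tail(grid$x, -1)) / 2
  yc <- (utils::head(grid$y, -1) + utils::tail(grid$y, -1)) / 2
  zc <- (utils::head(grid$z, -1) + utils::tail(grid$z, -1)) / 2
  dx <- diff(grid$x); dy <- diff(grid$y); dz <- diff(grid$z)
  nx <- length(xc); ny <- length(yc); nz <- length(zc)
  n <- nx * ny * nz
  id <- function(i, j, k) i + nx * (j - 1L) + nx * ny * (k - 1L)

  # conductivity per cell: glial shell of the configured thickness over the
  # electrode footprint, brain elsewhere
  cc <- expand.grid(x = xc, y = yc, z = zc)
  glia <- glia_footprint(geom, cc$x, cc$y) & cc$z <= geom$glial_thickness_um
  sigma <- ifelse(glia, tissue$sigma_glia_S_m, tissue$sigma_brain_S_m)

  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  diag_acc <- numeric(n)
  add_faces <- function(ida, idb, G) {
    trip_i <<- c(trip_i, ida, idb)
    trip_j <<- c(trip_j, idb, ida)
    trip_x <<- c(trip_x, -G, -G)
    diag_acc[ida] <<- diag_acc[ida] + G
    diag_acc[idb] <<- diag_acc[idb] + G
  }
  # internal faces along each axis (harmonic-mean face conductivity)
  grid3 <- function(ni, nj, nk) NULL  # readability stub
  # x-direction
  if (nx > 1) {
    i <- rep(seq_len(nx - 1), times = ny * nz)
    j <- rep(rep(seq_len(ny), each = nx - 1), times = nz)
    k <- rep(seq_len(nz), each = (nx - 1) * ny)
    a <- id(i, j, k); b <- id(i + 1L, j, k)
    d1 <- dx[i] / 2; d2 <- dx[i + 1L] / 2
    sf <- (d1 + d2) / (d1 / sigma[a] + d2 / sigma[b])
    G <- sf * (dy[j] * dz[k] * um^2) / ((d1 + d2) * um)
    add_faces(a, b, G)
  }
  if (ny > 1) {
    i <- rep(seq_len(nx), times = (ny - 1) * nz)
    j <- rep(rep(seq_len(ny - 1), each = nx), times = nz)
    k <- rep(seq_len(nz), each = nx * (ny - 1))
    a <- id(i, j, k); b <- id(i, j + 1L, k)
    d1 <- dy[j] / 2; d2 <- dy[j + 1L] / 2
    sf <- (d1 + d2) / (d1 / sigma[a] + d2 / sigma[b])
    G <- sf * (dx[i] * dz[k] * um^2) / ((d1 + d2) * um)
    add_faces(a, b, G)
  }
  if (nz > 1) {
    i <- rep(seq_len(nx), times = ny * (nz - 1))
    j <- rep(rep(seq_len(ny), each = nx), times = nz - 1)
    k <- rep(seq_len(nz - 1), each = nx * ny)
    a <- id(i, j, k); b <- id(i, j, k + 1L)
    d1 <- dz[k] / 2; d2 <- dz[k + 1L] / 2
    sf <- (d1 + d2) / (d1 / sigma[a] + d2 / sigma[b])
    G <- sf * (dx[i] * dy[j] * um^2) / ((d1 + d2) * um)
    add_faces(a, b, G)
  }
  # Dirichlet ground on the far faces (x = +half, y = +half, z = top);
  # x = 0 / y = 0 are symmetry planes, z = 0 is insulating outside sites
  dir_G <- numeric(n)
  jk <- expand.grid(j = seq_len(ny), k = seq_len(nz))
  aa <- id(nx, jk$j, jk$k)
  dir_G[aa] <- dir_G[aa] +
    sigma[aa] * (dy[jk$j] * dz[jk$k] * um^2) / (dx[nx] / 2 * um)
  ik <- expand.grid(i = seq_len(nx), k = seq_len(nz))
  aa <- id(ik$i, ny, ik$k)
  dir_G[aa] <- dir_G[aa] +
    sigma[aa] * (dx[ik$i] * dz[ik$k] * um^2) / (dy[ny] / 2 * um)
  ij <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  aa <- id(ij$i, ij$j, nz)
  dir_G[aa] <- dir_G[aa] +
    sigma[aa] * (dx[ij$i] * dy[ij$j] * um^2) / (dz[nz] / 2 * um)
  diag_acc <- diag_acc + dir_G

  # source vector: per-site current split by footprint-overlap area over the
  # bottom cell layer (quarter domain holds a quarter of the total area)
  b <- numeric(n)
  x0 <- utils::head(grid$x, -1); x1 <- utils::tail(grid$x, -1)
  y0 <- utils::head(grid$y, -1); y1 <- utils::tail(grid$y, -1)
  for (site in geom$sites) {
    ov <- outer(seq_len(nx), seq_len(ny), Vectorize(function(i, j)
      site_overlap(site, x0[i], x1[i], y0[j], y1[j])))
    nzv <- which(ov > 0, arr.ind = TRUE)
    if (nrow(nzv) == 0) next
    amps <- current_uA * 1e-6 * ov[nzv] / site_area(site)
    cells <- id(nzv[, 1], nzv[, 2], 1L)
    b[cells] <- b[cells] + amps
  }
  injected <- sum(b)

  A <- Matrix::sparseMatrix(i = c(trip_i, seq_len(n)),
                            j = c(trip_j, seq_len(n)),
                            x = c(trip_x, diag_acc), dims = c(n, n))
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE, super = TRUE)
  V <- as.numeric(Matrix::solve(ch, b))

  # |J| = sigma |grad V| at cell centers via central differences
  Va <- array(V, dim = c(nx, ny, nz))
  gradc <- function(arr, centers, axis) {
    d <- dim(arr); nn <- d[axis]
    if (nn == 1) return(array(0, dim = d))
    sl <- function(idx) {
      switch(axis,
             arr[idx, , , drop = FALSE],
             arr[, idx, , drop = FALSE],
             arr[, , idx, drop = FALSE])
    }
    lower <- sl(c(1, seq_len(nn - 1)))
    upper <- sl(c(seq_len(nn - 1) + 1, nn))
    span <- centers[pmin(seq_len(nn) + 1, nn)] - centers[pmax(seq_len(nn) - 1, 1)]
    shape <- c(1, 1, 1); shape[axis] <- nn
    g <- (upper - lower) / (array(rep(span, each = prod(d[seq_len(axis - 1)])),
                                  dim = d) * um)
    g
  }
  gx <- gradc(Va, xc, 1); gy <- gradc(Va, yc, 2); gz <- gradc(Va, zc, 3)
  J <- array(sigma, dim = c(nx, ny, nz)) * sqrt(gx^2 + gy^2 + gz^2)

  vol_m3 <- outer(outer(dx, dy), dz) * um^3
  structure(list(
    V = Va, J = J, sigma = array(sigma, dim = c(nx, ny, nz)),
    glia = array(glia, dim = c(nx, ny, nz)), cell_vol_m3 = vol_m3,
    xc = xc, yc = yc, zc = zc, grid = grid,
    injected_A = injected, boundary_outflow_A = sum(dir_G * V),
    current_uA = current_uA, symmetry_factor = 4,
    geom = geom, tissue = tissue), class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("<field_solution> %s, %g uA/site, grid %d x %d x %d (quarter)\n",
              x$geom$kind, x$current_uA, length(x$xc), length(x$yc),
              length(x$zc)))
  cat(sprintf("  conservation: injected %.4g uA, boundary outflow %.4g uA\n",
              x$injected_A * 1e6, x$boundary_outflow_A * 1e6))
  invisible(x)
}

#' Count activatable neurons in a solved field
#'
#' Neuron density times the tissue volume (glial scar excluded) where
#' `|J|` strictly exceeds the activation threshold.
#'
#' @param field A [solve_field()] result.
#' @param model An [activation_model()].
#' @return Neuron count (possibly fractional, linear in density); attribute
#'   `volume_mm3` carries the supra-threshold tissue volume.
#' @export
activated_count <- function(field, model = activation_model()) {
  sel <- field$J > model$j_threshold_A_m2 & !field$glia
  vol <- sum(field$cell_vol_m3[sel]) * field$symmetry_factor
  structure(model$neuron_density * vol, volume_mm3 = vol * 1e9)
}

# supra-threshold tissue volume (m^3, full domain) as a function of the
# scaled threshold -- used to exploit linearity in current
vol_above <- function(field, j_star) {
  sel <- !field$glia
  j <- field$J[sel]
  v <- field$cell_vol_m3[sel] * field$symmetry_factor
  ord <- order(j)
  j <- j[ord]
  cv <- rev(cumsum(rev(v[ord])))        # volume with J > j[i] (>= actually)
  function(thr) {
    pos <- findInterval(thr, j) + 1L    # first index with j > thr
    if (pos > length(j)) 0 else cv[pos]
  }
}

#' Activation curve over a current sweep
#'
#' One field solve at unit current is rescaled across the grid (the potential
#' is linear in the injected current), giving the activated-neuron count per
#' current value.
#'
#' @param geom,tissue,model Geometry, tissue and activation models.
#' @param currents_uA Ascending vector of per-site currents (default
#'   1--100 uA).
#' @param field Optional precomputed unit-current [solve_field()] solution.
#' @param ... Passed to [solve_field()].
#' @return Data frame `(current_uA, count, volume_mm3)`, non-decreasing in
#'   current.
#' @export
sweep_current <- function(geom, tissue = tissue_model(),
                          model = activation_model(),
                          currents_uA = 1:100, field = NULL, ...) {
  if (is.unsorted(currents_uA)) {
    stop("currents_uA must be ascending", call. = FALSE)
  }
  if (is.null(field)) field <- solve_field(geom, tissue, 1, ...)
  va <- vol_above(field)
  scale <- field$current_uA
  vols <- vapply(currents_uA, function(I) {
    if (I <= 0) 0 else va(model$j_threshold_A_m2 * scale / I)
  }, numeric(1))
  data.frame(current_uA = currents_uA,
             count = model$neuron_density * vols,
             volume_mm3 = vols * 1e9)
}

#' Current matching a reference activation count
#'
#' Smallest per-site current (bisection to `tol_uA`) whose activated-neuron
#' count reaches `reference_count`, exploiting linearity of the field in the
#' injected current.
#'
#' @param geom,tissue,model Geometry, tissue and activation models.
#' @param reference_count Target count (> 0), e.g. the flexible array's count
#'   at 5 uA.
#' @param max_uA Search ceiling (default 100 uA).
#' @param tol_uA Bisection tolerance (default 0.1 uA).
#' @param field Optional precomputed [solve_field()] solution for `geom`.
#' @param ... Passed to [solve_field()].
#' @return Matching current in uA.
#' @export
matching_current <- function(geom, tissue = tissue_model(),
                             model = activation_model(), reference_count,
                             max_uA = 100, tol_uA = 0.1, field = NULL, ...) {
  if (reference_count <= 0) stop("reference_count must be > 0", call. = FALSE)
  if (is.null(field)) field <- solve_field(geom, tissue, 1, ...)
  va <- vol_above(field)
  scale <- field$current_uA
  count_at <- function(I) {
    model$neuron_density * va(model$j_threshold_A_m2 * scale / I)
  }
  if (count_at(max_uA) < reference_count) {
    stop(sprintf("out-of-range: count at %g uA (%.3g) below reference %.3g",
                 max_uA, count_at(max_uA), reference_count), call. = FALSE)
  }
  lo <- 0; hi <- max_uA
  while (hi - lo > tol_uA) {
    mid <- (lo + hi) / 2
    if (count_at(mid) >= reference_count) hi <- mid else lo <- mid
  }
  hi
}

#' Flux through a box enclosing the electrode
#'
#' Discrete current through the surface of the box `|x|,|y| <= r_um`,
#' `z <= r_um` (full-domain current, using the quarter-domain solution and
#' symmetry). With all sources inside the box this equals the total injected
#' current up to solver tolerance.
#'
#' @param field A [solve_field()] result.
#' @param r_um Box half-size in um.
#' @return Current in A.
#' @export
flux_through_box <- function(field, r_um) {
  um <- 1e-6
  g <- field$grid
  xc <- field$xc; yc <- field$yc; zc <- field$zc
  dx <- diff(g$x); dy <- diff(g$y); dz <- diff(g$z)
  sig <- field$sigma; V <- field$V
  ii <- max(which(xc < r_um)); jj <- max(which(yc < r_um))
  kk <- max(which(zc < r_um))
  flux <- 0
  # +x faces
  for (j in seq_len(jj)) for (k in seq_len(kk)) {
    d1 <- dx[ii] / 2; d2 <- dx[ii + 1] / 2
    sf <- (d1 + d2) / (d1 / sig[ii, j, k] + d2 / sig[ii + 1, j, k])
    G <- sf * dy[j] * dz[k] * um^2 / ((d1 + d2) * um)
    flux <- flux + G * (V[ii, j, k] - V[ii + 1, j, k])
  }
  # +y faces
  for (i in seq_len(ii)) for (k in seq_len(kk)) {
    d1 <- dy[jj] / 2; d2 <- dy[jj + 1] / 2
    sf <- (d1 + d2) / (d1 / sig[i, jj, k] + d2 / sig[i, jj + 1, k])
    G <- sf * dx[i] * dz[k] * um^2 / ((d1 + d2) * um)
    flux <- flux + G * (V[i, jj, k] - V[i, jj + 1, k])
  }
  # +z faces
  for (i in seq_len(ii)) for (j in seq_len(jj)) {
    d1 <- dz[kk] / 2; d2 <- dz[kk + 1] / 2
    sf <- (d1 + d2) / (d1 / sig[i, j, kk] + d2 / sig[i, j, kk + 1])
    G <- sf * dx[i] * dy[j] * um^2 / ((d1 + d2) * um)
    flux <- flux + G * (V[i, j, kk] - V[i, j, kk + 1])
  }
  flux * field$symmetry_factor
}

#' On-axis current density of a uniform-flux disc electrode
#'
#' Closed form for a disc of radius `a_um` on an insulating plane bounding a
#' conductive half-space, injecting total current `I_uA` as uniform current
#' density: `J_z(z) = I/(pi a^2) * (1 - z / sqrt(z^2 + a^2))`. Used as the
#' analytic oracle for the discretized solver.
#'
#' @param z_um Axial distances in um.
#' @param a_um Disc radius in um.
#' @param I_uA Total injected current in uA.
#' @return `J_z` in A/m^2.
#' @export
disc_axis_J <- function(z_um, a_um, I_uA) {
  a <- a_um * 1e-6; z <- z_um * 1e-6
  I_uA * 1e-6 / (pi * a^2) * (1 - z / sqrt(z^2 + a^2))
}
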