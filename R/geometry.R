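#' Material zone: hydraulics, transport and kinetics of one porous material
#'
#' Binds everything the solvers need to know about one material: van
#' Genuchten hydraulics, bulk density, dispersivities, free-water diffusion
#' coefficients, linear sorption, and (optionally) nitrification and
#' denitrification kinetics.
#'
#' @param name Label.
#' @param vg A [vg_params()] object.
#' @param rho_b Bulk density (g cm^-3), > 0.
#' @param lambda_L Longitudinal dispersivity (cm), > 0.
#' @param lambda_T Transverse dispersivity (cm), >= 0.
#' @param D_free Named numeric, free-water diffusion coefficients
#'   (cm^2 d^-1) for `NH4` and `NO3`. Defaults are the literature values
#'   0.067 and 0.061 cm^2 h^-1 converted to daily units.
#' @param Kd Linear sorption coefficient for NH4 (cm^3 g^-1), >= 0;
#'   the soils studied have negligible NH4 sorption, so the default is 0.
#' @param nit,denit Optional [nitrification_params()] /
#'   [denitrification_params()] objects.
#' @return An object of class `material_zone`.
#' @export
material_zone <- function(name, vg, rho_b,
                          lambda_L = 10, lambda_T = 1,
                          D_free = c(NH4 = 0.067 * 24, NO3 = 0.061 * 24),
                          Kd = 0, nit = NULL, denit = NULL) {
  assert_vg(vg)
  if (rho_b <= 0) stop("rho_b must be > 0", call. = FALSE)
  if (lambda_L <= 0) stop("lambda_L must be > 0", call. = FALSE)
  if (lambda_T < 0) stop("lambda_T must be >= 0", call. = FALSE)
  if (Kd < 0) stop("Kd must be >= 0", call. = FALSE)
  if (!all(c("NH4", "NO3") %in% names(D_free))) {
    stop("D_free must be named with NH4 and NO3", call. = FALSE)
  }
  structure(list(name = name, vg = vg, rho_b = rho_b,
                 lambda_L = lambda_L, lambda_T = lambda_T,
                 D_free = D_free, Kd = Kd, nit = nit, denit = denit),
            class = "material_zone")
}

seg <- function(len, n) rep(len / n, n)

mesh_spacing <- function(system) {
  switch(system,
    "PSND" = list(
      dz = c(seg(16, 5), seg(4, 9), seg(25, 16), seg(65, 40), seg(27, 14)),
      dx = seg(15, 7)),
    "GEO" = list(
      dz = c(seg(21, 6), seg(4, 9), seg(1, 2), seg(19, 12), seg(67, 36),
             seg(25, 12)),
      dx = c(2.61, 2.0, 1.62, 1.27, 1.27, 1.62, 2.0, 2.61)),
    "P&S" = list(
      dz = c(seg(42, 12), seg(12, 8), seg(4, 4), seg(4, 9), seg(22, 11),
             seg(2, 5), seg(28, 14), seg(23, 10)),
      dx = c(2.58, 2.0, 1.65, 1.27, 1.27, 1.65, 2.0, 2.58)))
}

default_materials <- function(system) {
  hyd <- drainfield_hydraulics(system)
  # longitudinal dispersivity: one tenth of the soil profile depth below the
  # infiltrative surface; transverse: lambda_L / 10
  lamL <- switch(system, "PSND" = 11.7, "GEO" = 11.2, "P&S" = 5.3)
  mk <- function(nm, vg, rho) {
    material_zone(nm, vg, rho, lambda_L = lamL, lambda_T = lamL / 10)
  }
  switch(system,
    "PSND" = list(
      silt_loam = mk("silt_loam", hyd$silt_loam, 1.38),
      sand      = mk("sand", hyd$sand, 1.63)),
    "GEO" = list(
      silt_loam = mk("silt_loam", hyd$silt_loam, 1.38),
      sand      = mk("sand", hyd$sand, 1.63),
      filament  = mk("filament", hyd$filament, 1.50)),
    "P&S" = list(
      sand      = mk("sand", hyd$sand, 1.63),
      stone     = mk("stone", hyd$stone, 1.50)))
}

default_layers <- function(system) {
  switch(system,
    "PSND" = data.frame(material = c("silt_loam", "sand"),
                        from = c(0, 45), to = c(45, 137)),
    "GEO" = data.frame(material = c("silt_loam", "filament", "silt_loam",
                                    "sand"),
                       from = c(0, 25, 26, 45), to = c(25, 26, 45, 137)),
    "P&S" = data.frame(material = c("sand", "stone", "sand"),
                       from = c(0, 54, 84), to = c(54, 84, 137)))
}

#' Build a drainfield mesocosm model domain
#'
#' Constructs the 2D vertical-plane (x-z) domain of one of the three
#' mesocosm types on a structured quadrilateral mesh with local refinement
#' (element size at most 3.9 cm, at most 0.45 cm around distribution pipes
#' and the infiltrative-surface cover):
#'
#' * `PSND`: silt loam over gravelly-coarse sand; infiltrative surface
#'   20 cm below ground under an impermeable half-pipe cover; pressure
#'   dosing distributed uniformly over the whole infiltrative surface.
#' * `GEO`: as PSND plus a 1-cm entangled-filament core layer and a
#'   2.54-cm distribution pipe; infiltrative surface 25 cm below ground;
#'   dosing localized below the pipe.
#' * `P&S`: a 30-cm crushed-stone layer with an embedded 2.54-cm
#'   distribution pipe 60 cm below ground; infiltrative surface (top of
#'   native soil) 84 cm below ground; dosing localized below the pipe.
#'
#' Coordinates are in cm with z positive downward from the ground surface.
#' Boundaries and observation nodes are assigned by [assign_boundaries()]
#' and [place_observation_nodes()], which this function calls.
#'
#' @param system One of `"PSND"`, `"GEO"`, `"P&S"`.
#' @param overrides Optional list: `width`, `height` (cm), `dx`, `dz`
#'   (spacing vectors; must sum to width/height), `materials` (named list
#'   of [material_zone()]; switches to a generic layered rectangle),
#'   `layers` (data frame `material`, `from`, `to` in cm depth),
#'   `is_depth` (cm), `dose_width` (cm, width of the localized
#'   variable-flux segment; default one pipe diameter, 2.54 cm),
#'   `axisym` (logical: weight cell volumes and face areas by radius,
#'   treating x as distance from the column axis; default `FALSE`,
#'   the plane-faithful choice), `obs_depths` (cm below the infiltrative
#'   surface).
#' @return An object of class `dfn_domain`.
#' @examples
#' d <- build_mesocosm("PSND")
#' d$nx * d$nz  # mesh size comparable to the reference discretization
#' @export
build_mesocosm <- function(system = c("PSND", "GEO", "P&S"),
                           overrides = list()) {
  if (length(system) == 1 && !system %in% c("PSND", "GEO", "P&S")) {
    stop(sprintf("unknown system type '%s'", system), call. = FALSE)
  }
  system <- match.arg(system)
  width <- overrides$width %||% 15
  height <- overrides$height %||% 137
  custom <- !is.null(overrides$materials)
  if (custom) {
    mats <- overrides$materials
    dz <- overrides$dz %||% seg(height, max(2L, ceiling(height / 3.9)))
    dx <- overrides$dx %||% seg(width, max(1L, ceiling(width / 3.9)))
    layers <- overrides$layers %||%
      data.frame(material = names(mats)[1], from = 0, to = height)
    is_depth <- overrides$is_depth %||% 0
  } else {
    sp <- mesh_spacing(system)
    dz <- overrides$dz %||% sp$dz
    dx <- overrides$dx %||% sp$dx
    mats <- default_materials(system)
    layers <- overrides$layers %||% default_layers(system)
    is_depth <- overrides$is_depth %||%
      switch(system, "PSND" = 20, "GEO" = 25, "P&S" = 84)
  }
  if (abs(sum(dz) - height) > 1e-8 * height) {
    stop("dz must sum to the domain height", call. = FALSE)
  }
  if (abs(sum(dx) - width) > 1e-8 * width) {
    stop("dx must sum to the domain width", call. = FALSE)
  }
  nz <- length(dz); nx <- length(dx)
  zf <- cumsum(c(0, dz)); xf <- cumsum(c(0, dx))
  zc <- (zf[-1] + zf[-(nz + 1)]) / 2
  xc <- (xf[-1] + xf[-(nx + 1)]) / 2

  mat_names <- names(mats)
  mat_idx <- matrix(NA_integer_, nz, nx)
  for (i in seq_len(nrow(layers))) {
    rows <- zc > layers$from[i] & zc < layers$to[i] + 1e-12
    mat_idx[rows, ] <- match(layers$material[i], mat_names)
  }
  if (anyNA(mat_idx)) {
    stop("material layers do not tile the domain", call. = FALSE)
  }

  axisym <- isTRUE(overrides$axisym)
  # cell volumes and face areas per unit thickness (plane) or per radian
  # weighted by radius (axisymmetric, x measured from the axis)
  wx <- if (axisym) xc else rep(1, nx)
  Vcell <- outer(dz, dx * wx)                      # nz x nx
  dose_width <- overrides$dose_width %||% 2.54

  dom <- structure(list(
    system = system, width = width, height = height,
    nx = nx, nz = nz, dx = dx, dz = dz, xf = xf, zf = zf, xc = xc, zc = zc,
    Vcell = Vcell, axisym = axisym, wx = wx,
    mat = mat_idx, materials = mats,
    is_depth = is_depth, dose_width = dose_width,
    water_table_depth = height,
    column_area = pi * (width / 2)^2,
    custom = custom
  ), class = "dfn_domain")

  dom <- assign_boundaries(dom, system)
  dom <- place_observation_nodes(dom, overrides$obs_depths %||% c(15, 30))
  dom
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cell_id <- function(dom, j, i) (i - 1L) * dom$nz + j

#' Assign boundary conditions to a mesocosm domain
#'
#' Top boundary: atmospheric (no rain or evaporation is simulated, so it
#' acts as no-flux). Sides and bottom: no-flux, except a single
#' seepage-face node at the bottom through which water leaves only under
#' locally saturated conditions. The effluent-application (variable-flux)
#' segment spans the entire infiltrative surface for PSND and a localized
#' segment below the distribution pipe (default one pipe diameter wide)
#' for GEO and P&S.
#'
#' @param domain A `dfn_domain`.
#' @param system System type; defaults to the domain's own.
#' @return The domain with `$boundaries`, `$dose_cells`, `$dose_weights`,
#'   `$dose_z`, `$seep_cells` set.
#' @export
assign_boundaries <- function(domain, system = domain$system) {
  if (is.null(domain$nz)) stop("domain has no mesh", call. = FALSE)
  nz <- domain$nz; nx <- domain$nx
  # dose row: first cell row whose centre lies below the application level
  dose_z <- if (domain$custom) domain$is_depth else {
    switch(system, "PSND" = domain$is_depth, "GEO" = domain$is_depth,
           "P&S" = 60)  # P&S applies at the pipe, inside the stone layer
  }
  jd <- which(domain$zc > dose_z)[1]
  if (is.na(jd)) jd <- nz
  uniform <- domain$custom || system == "PSND"
  if (uniform) {
    cols <- seq_len(nx)
    w <- domain$dx * domain$wx
  } else {
    # localized segment centred on the column axis
    mid <- domain$width / 2
    cols <- which(abs(domain$xc - mid) <= domain$dose_width / 2 + 1e-9)
    if (length(cols) == 0) cols <- which.min(abs(domain$xc - mid))
    w <- (domain$dx * domain$wx)[cols]
  }
  domain$dose_cells <- cell_id(domain, jd, cols)
  domain$dose_weights <- w / sum(w)
  domain$dose_z <- domain$zf[jd]
  domain$dose_segment_width <- sum(domain$dx[cols])
  # one seepage node: bottom row, first column
  domain$seep_cells <- cell_id(domain, nz, 1L)
  seep_len <- domain$dx[1]
  domain$boundaries <- data.frame(
    side = c("top", "left", "right", "bottom", "bottom",
             "infiltrative_surface"),
    type = c("atmospheric", "no_flux", "no_flux", "no_flux",
             "seepage_face", "variable_flux"),
    length = c(domain$width, domain$height, domain$height,
               domain$width - seep_len, seep_len,
               domain$dose_segment_width),
    internal = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  domain
}

#' Place observation nodes
#'
#' Four observation nodes: at the requested depths below the infiltrative
#' surface (defaults 15 and 30 cm), at the model-domain bottom, and at the
#' column outlet (the seepage node). Nodes snap to the nearest mesh cell
#' centre on the column axis (centreline).
#'
#' @param domain A `dfn_domain`.
#' @param depths_below_is Depths (cm) below the infiltrative surface.
#' @return The domain with `$obs` (data frame `label`, `depth_bgs`, `cell`,
#'   `x`, `z`, `material`).
#' @export
place_observation_nodes <- function(domain, depths_below_is = c(15, 30)) {
  if (is.null(domain$nz)) stop("domain has no mesh", call. = FALSE)
  depth_bgs <- domain$is_depth + depths_below_is
  if (any(depth_bgs < 0 | depth_bgs > domain$height)) {
    stop("observation depth outside the domain", call. = FALSE)
  }
  icol <- which.min(abs(domain$xc - domain$width / 2))
  snap <- function(z) which.min(abs(domain$zc - z))
  jrows <- vapply(depth_bgs, snap, integer(1))
  jbot <- domain$nz
  seep_j <- ((domain$seep_cells[1] - 1L) %% domain$nz) + 1L
  seep_i <- ((domain$seep_cells[1] - 1L) %/% domain$nz) + 1L
  obs <- data.frame(
    label = c(sprintf("is_%gcm", depths_below_is), "bottom", "outlet"),
    depth_bgs = c(domain$zc[jrows], domain$zc[jbot], domain$zc[seep_j]),
    cell = c(cell_id(domain, jrows, icol), cell_id(domain, jbot, icol),
             domain$seep_cells[1]),
    x = c(rep(domain$xc[icol], length(jrows) + 1L), domain$xc[seep_i]),
    z = c(domain$zc[jrows], domain$zc[jbot], domain$zc[seep_j])
  )
  obs$material <- names(domain$materials)[
    domain$mat[cbind(((obs$cell - 1L) %% domain$nz) + 1L,
                     ((obs$cell - 1L) %/% domain$nz) + 1L)]]
  domain$obs <- obs
  domain
}

#' Homogeneous soil column domain
#'
#' A single-material rectangular domain, mostly used for one-dimensional
#' verification problems (unit-gradient infiltration, hydrostatic
#' equilibrium, analytic breakthrough curves).
#'
#' @param material A [material_zone()] (or a [vg_params()], which is
#'   wrapped with nominal transport properties).
#' @param height,width Domain size (cm).
#' @param dz,nx Vertical spacing (cm, scalar or vector) and number of
#'   columns.
#' @param obs_depths Observation depths below the top (cm).
#' @return A `dfn_domain`.
#' @export
column_domain <- function(material, height = 100, width = 15, dz = 2,
                          nx = 1, obs_depths = c(15, 30)) {
  if (inherits(material, "vg_params")) {
    material <- material_zone("soil", material, rho_b = 1.5)
  }
  if (length(dz) == 1) dz <- seg(height, round(height / dz))
  build_mesocosm("PSND", overrides = list(
    width = width, height = height, dz = dz, nx = nx,
    dx = seg(width, nx),
    materials = stats::setNames(list(material), material$name),
    is_depth = 0, obs_depths = obs_depths))
}

#' Export mesh and cell fields to legacy-ASCII VTK
#'
#' Writes a `RECTILINEAR_GRID` file with any number of per-cell scalar
#' fields for inspection in ParaView and similar tools.
#'
#' @param domain A `dfn_domain`.
#' @param fields Named list of `nz x nx` matrices (or vectors of length
#'   `nz * nx`).
#' @param file Output path.
#' @return The path, invisibly.
#' @export
export_vtk <- function(domain, fields = list(), file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "drainfieldN mesh export", "ASCII",
               "DATASET RECTILINEAR_GRID",
               sprintf("DIMENSIONS %d 1 %d", domain$nx + 1L, domain$nz + 1L),
               sprintf("X_COORDINATES %d float", domain$nx + 1L),
               paste(signif(domain$xf, 8), collapse = " "),
               "Y_COORDINATES 1 float", "0",
               sprintf("Z_COORDINATES %d float", domain$nz + 1L),
               paste(signif(-domain$zf, 8), collapse = " ")), con)
  ncell <- domain$nx * domain$nz
  writeLines(sprintf("CELL_DATA %d", ncell), con)
  fields <- c(list(material = domain$mat), fields)
  for (nm in names(fields)) {
    v <- fields[[nm]]
    writeLines(c(sprintf("SCALARS %s float 1", nm),
                 "LOOKUP_TABLE default"), con)
    # VTK expects x fastest; our storage is z fastest
    m <- matrix(as.numeric(v), domain$nz, domain$nx)
    writeLines(paste(signif(as.vector(t(m)), 7), collapse = " "), con)
  }
  invisible(file)
}

#' @export
print.dfn_domain <- function(x, ...) {
  cat(sprintf("drainfield domain [%s]: %g x %g cm, %d x %d cells (%d nodes)\n",
              x$system, x$width, x$height, x$nx, x$nz, x$nx * x$nz))
  cat(sprintf("  infiltrative surface at %g cm bgs; dose segment %g cm; %d seepage node(s)\n",
              x$is_depth, x$dose_segment_width, length(x$seep_cells)))
  cat(sprintf("  materials: %s\n", paste(names(x$materials), collapse = ", ")))
  invisible(x)
}
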