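## Configuration files, field writers (VTK legacy / CSV), run manifests.

.config_defaults <- function() {
  p <- default_parameters()
  list(
    geometry = list(Lx = p$Lx, Ly = p$Ly, H = p$H, d = p$d),
    flow     = list(V0 = p$V0, nu = p$nu, rho = p$rho),
    kinetics = p[c("alpha", "theta0", "chi1", "gamma", "beta", "c", "eps_g",
                   "phi0", "chi2", "k_g", "k_p", "k_b", "k_r", "k_d", "k_u",
                   "Fg0", "D_u", "D_theta", "D_phi", "D_g", "D")],
    wall     = p[c("mu1", "mu2", "tau1", "tau2", "u0")],
    polymer  = p[c("n0", "K", "v0")],
    numerics = list(resolution = 24, bl_factor = 0.35, dt = 0.02,
                    chem_sub = 1, cfl = 0.7, flow_tol = 2e-5,
                    quasi_steady = TRUE, refresh_ds = 0.02, t_max = 5000,
                    steady_tol = 1e-6, run_past_gel_s = 0,
                    upper_exchange = TRUE, Re_max = 500),
    output   = list(every_s = Inf, dir = "stenoclot-out")
  )
}

#' Load (or create) a simulation configuration file
#'
#' Flat-namespace YAML configuration (`geometry.*`, `flow.*`, `kinetics.*`,
#' `wall.*`, `polymer.*`, `numerics.*`, `output.*`); every model constant is
#' a key with its default. Missing keys fall back to defaults; unknown keys
#' are an error.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides character vector of `section.key=value` assignments
#'   (CLI `--set` style) applied after the file.
#' @return nested configuration list.
#' @export
load_config <- function(path = NULL, overrides = character()) {
  cfg <- .config_defaults()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (sec in names(user)) {
      if (!sec %in% names(cfg)) stop("unknown config section '", sec, "'")
      for (k in names(user[[sec]])) {
        if (!k %in% names(cfg[[sec]]))
          stop("unknown config key '", sec, ".", k, "'")
        cfg[[sec]][[k]] <- user[[sec]][[k]]
      }
    }
  }
  for (ov in overrides) {
    m <- regmatches(ov, regexec("^([a-z]+)\\.([A-Za-z0-9_]+)=(.*)$", ov))[[1]]
    if (length(m) != 4) stop("override must look like section.key=value: ", ov)
    if (!m[2] %in% names(cfg) || !m[3] %in% names(cfg[[m[2]]]))
      stop("unknown config key '", m[2], ".", m[3], "'")
    val <- suppressWarnings(as.numeric(m[4]))
    if (is.na(val)) val <- as.logical(m[4])
    if (is.na(val)) val <- m[4]
    cfg[[m[2]]][[m[3]]] <- val
  }
  cfg
}

#' Write a configuration list to YAML
#' @param cfg nested configuration list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Build model parameters and numerical controls from a configuration
#'
#' @param cfg nested configuration list from [load_config()].
#' @return list with `params` (a `stenoclot_params`) and `config`
#'   (a `stenoclot_config`).
#' @export
config_to_setup <- function(cfg) {
  p <- do.call(default_parameters,
               c(cfg$geometry, cfg$flow, cfg$kinetics, cfg$wall, cfg$polymer))
  n <- cfg$numerics
  sc <- simulation_config(p, resolution = n$resolution, bl_factor = n$bl_factor,
                          dt = n$dt, chem_sub = n$chem_sub,
                          quasi_steady = n$quasi_steady, refresh_ds = n$refresh_ds,
                          flow_tol = n$flow_tol, cfl = n$cfl, t_max = n$t_max,
                          steady_tol = n$steady_tol,
                          run_past_gel_s = n$run_past_gel_s,
                          upper_exchange = n$upper_exchange,
                          snapshot_every_s = cfg$output$every_s,
                          Re_max = n$Re_max)
  list(params = p, config = sc)
}

#' Write cell fields as a legacy-VTK unstructured grid
#'
#' ASCII VTK (version 2.0) with quadrilateral cells, readable by standard
#' CFD viewers.
#'
#' @param mesh a `stenoclot_mesh`.
#' @param fields named list of cell vectors (scalars) to attach.
#' @param path output `.vtk` file.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, fields, path) {
  nx <- mesh$nx; ny <- mesh$ny
  npts <- (nx + 1) * (ny + 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 2.0",
               "stenoclot fields", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", npts)), con)
  ## node (i,j) -> point id i*(ny+1)+j (0-based)
  pts <- cbind(as.vector(t(mesh$node_x)), as.vector(t(mesh$node_y)), 0)
  utils::write.table(format(pts, digits = 10, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  nc <- mesh$ncell
  ii <- rep(seq_len(nx), each = ny) - 1L; jj <- rep(seq_len(ny), nx) - 1L
  pid <- function(i, j) i * (ny + 1L) + j
  cells <- cbind(4L, pid(ii, jj), pid(ii + 1L, jj), pid(ii + 1L, jj + 1L),
                 pid(ii, jj + 1L))
  writeLines(sprintf("CELLS %d %d", nc, 5L * nc), con)
  utils::write.table(cells, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", nc), con)
  writeLines(as.character(rep(9L, nc)), con)
  writeLines(sprintf("CELL_DATA %d", nc), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(format(fields[[nm]], digits = 10, trim = TRUE), con)
  }
  invisible(path)
}

#' Write cell fields (and centers) as CSV
#' @param mesh a `stenoclot_mesh`.
#' @param fields named list of cell vectors.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fields_csv <- function(mesh, fields, path) {
  df <- data.frame(x = mesh$cx, y = mesh$cy, area = mesh$area)
  for (nm in names(fields)) df[[nm]] <- fields[[nm]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export the mesh as plain CSV (cell centers, connectivity, patch tags)
#' @param mesh a `stenoclot_mesh`.
#' @param path_prefix files `<prefix>_cells.csv` and `<prefix>_bfaces.csv`.
#' @return the two paths, invisibly.
#' @export
write_mesh_csv <- function(mesh, path_prefix) {
  cells <- data.frame(cell = seq_len(mesh$ncell), x = mesh$cx, y = mesh$cy,
                      area = mesh$area)
  p1 <- paste0(path_prefix, "_cells.csv")
  utils::write.csv(cells, p1, row.names = FALSE)
  patches <- c("inlet", "outlet", "wall_upper", "wall_lower")
  bf <- data.frame(face = seq_along(mesh$b_own), owner = mesh$b_own,
                   patch = patches[mesh$b_patch], x = mesh$b_fcx,
                   y = mesh$b_fcy, length = mesh$b_len)
  p2 <- paste0(path_prefix, "_bfaces.csv")
  utils::write.csv(bf, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Run a configured simulation and write its artifacts
#'
#' Top-level driver: classifies the regime, writes the final fields (VTK +
#' CSV), the per-wall-face diagnostics, the max-`Nw` time series, and a JSON
#' manifest echoing the configuration (hash included) and listing every
#' produced file.
#'
#' @param cfg nested configuration list (see [load_config()]).
#' @param out_dir output directory (created if needed).
#' @param verbose print progress.
#' @return the manifest, invisibly (class `stenoclot_manifest`).
#' @export
run_simulation <- function(cfg, out_dir = cfg$output$dir, verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  setup <- config_to_setup(cfg)
  t0 <- Sys.time()
  sim <- classify_regime(setup$config, verbose = verbose)
  mesh <- sim$mesh
  artifacts <- character()
  add <- function(x) artifacts <<- c(artifacts, x)
  fields <- c(sim$chem, list(Nw = sim$closures$Nw, bp = sim$closures$bp,
                             Df = sim$closures$Df, alpha_p = sim$closures$alpha_p,
                             gel = as.numeric(sim$closures$gel_mask),
                             vel_u = sim$flow$u, vel_v = sim$flow$v,
                             pressure = sim$flow$p))
  add(write_vtk(mesh, fields, file.path(out_dir, "fields.vtk")))
  add(write_fields_csv(mesh, fields, file.path(out_dir, "fields.csv")))
  ws <- sim$shear
  wx <- wall_exchange_fields(mesh, ws, setup$params, setup$config$upper_exchange)
  ws$mu <- wx$mu[ws$face]; ws$u0_sub <- wx$u0[ws$face]
  wpath <- file.path(out_dir, "wall.csv")
  utils::write.csv(ws, wpath, row.names = FALSE); add(wpath)
  series <- data.frame(t = sim$dt * seq_along(sim$max_nw_series),
                       max_nw = sim$max_nw_series)
  spath <- file.path(out_dir, "max_nw.tsv")
  utils::write.table(series, spath, sep = "\t", row.names = FALSE); add(spath)
  cfg_path <- file.path(out_dir, "config.yaml")
  save_config(cfg, cfg_path); add(cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("stenoclot")),
    config = cfg, config_hash = unname(tools::md5sum(cfg_path)),
    groups = unclass(sim$groups),
    mesh = list(nx = mesh$nx, ny = mesh$ny, ncell = mesh$ncell),
    regime = sim$regime, T_star_s = sim$T_star_s, T_star = sim$T_star,
    stop_reason = sim$stop_reason, censored = sim$censored,
    max_shear_rate = sim$max_shear_rate,
    first_gel_xy = as.list(sim$first_gel_xy),
    wall_clock_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    artifacts = basename(artifacts))
  mpath <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  manifest$path <- mpath
  class(manifest) <- "stenoclot_manifest"
  attr(manifest, "sim") <- sim
  invisible(manifest)
}

#' @export
print.stenoclot_manifest <- function(x, ...) {
  cat(sprintf("Run manifest: regime %s (%s), %d artifacts, %.1f s wall clock\n",
              x$regime, x$stop_reason, length(x$artifacts), x$wall_clock_s))
  invisible(x)
}
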