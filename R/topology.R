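## Flow-topology diagnostics: streamfunction, recirculation zone,
## separatrix, reattachment point, and the clot-scenario label.

#' Streamfunction on mesh nodes
#'
#' Integrates the divergence-free face fluxes column-wise from the lower
#' wall (`psi = 0` on the wall, which carries no flux). Consistent across
#' columns because every cell is discretely divergence free.
#'
#' @param flow a `stenoclot_flow`.
#' @param mesh the structured `stenoclot_mesh`.
#' @return `(nx+1) x (ny+1)` matrix of node streamfunction values (cm^2/s).
#' @export
streamfunction <- function(flow, mesh) {
  nx <- mesh$nx; ny <- mesh$ny
  psi <- matrix(0, nx + 1, ny + 1)
  ## interface i = 0: inlet (+x flux = -outward flux)
  Fin <- -flow$b_flux[mesh$b_patch == 1L]
  psi[1, ] <- c(0, cumsum(Fin))
  ## interior interfaces i = 1..nx-1: first (nx-1)*ny interior faces,
  ## ordered interface-major (see build_mesh)
  nv <- (nx - 1L) * ny
  Fv <- matrix(flow$flux[seq_len(nv)], ny, nx - 1L)
  for (i in seq_len(nx - 1L)) psi[i + 1L, ] <- c(0, cumsum(Fv[, i]))
  ## interface i = nx: outlet
  Fout <- flow$b_flux[mesh$b_patch == 2L]
  psi[nx + 1L, ] <- c(0, cumsum(Fout))
  psi
}

#' Flow topology of a (converged) flow state
#'
#' Locates the separation and reattachment points on the stenosed lower
#' wall (sign changes of the wall shear stress), extracts the separatrix --
#' the streamline detaching from the wall that bounds the recirculation
#' eddy behind the stenosis -- and measures the recirculation-zone area
#' (cells with negative streamfunction).
#'
#' @param flow a `stenoclot_flow`.
#' @param mesh the mesh.
#' @param p a `stenoclot_params` object.
#' @return an object of class `stenoclot_topology`: `has_recirculation`,
#'   `reattachment_x`, `separation_x`, `recirc_area` (cm^2), `separatrix`
#'   (data.frame of `x`, `y`), and the node `psi` matrix.
#' @export
flow_topology <- function(flow, mesh, p) {
  ws <- wall_shear(flow, mesh, p)
  low <- ws[ws$patch == "wall_lower", ]
  low <- low[order(low$x), ]
  tau <- low$tau; xw <- low$x
  sgn <- sign(tau)
  cross <- which(sgn[-length(sgn)] * sgn[-1] < 0)
  sep_x <- rea_x <- NA_real_
  for (k in cross) {
    x0 <- xw[k] - tau[k] * (xw[k + 1] - xw[k]) / (tau[k + 1] - tau[k])
    if (tau[k] > 0 && tau[k + 1] < 0 && is.na(sep_x)) sep_x <- x0
    if (tau[k] < 0 && tau[k + 1] > 0) rea_x <- x0     # last one wins
  }
  psi <- streamfunction(flow, mesh)
  pscale <- max(abs(psi))
  ## cell-average streamfunction (4 surrounding nodes)
  nx <- mesh$nx; ny <- mesh$ny
  pc <- 0.25 * (psi[1:nx, 1:ny] + psi[2:(nx + 1), 1:ny] +
                psi[1:nx, 2:(ny + 1)] + psi[2:(nx + 1), 2:(ny + 1)])
  ## cells are stored column-major in (j fastest) order: transpose to match
  neg <- t(pc) < -1e-12 * pscale
  recirc_cells <- as.vector(neg)
  recirc_area <- sum(mesh$area[recirc_cells])
  has <- recirc_area > 0 && !is.na(rea_x)
  separatrix <- NULL
  if (has) {
    lev <- -1e-8 * pscale
    cl <- grDevices::contourLines(x = 0:nx, y = 0:ny, z = psi, levels = lev)
    if (length(cl)) {
      lens <- vapply(cl, function(s) sum(sqrt(diff(s$x)^2 + diff(s$y)^2)), 0)
      s <- cl[[which.max(lens)]]
      ## map fractional node indices to physical coordinates
      xs <- mesh$node_x[, 1]
      px <- xs[1] + (s$x) * (xs[2] - xs[1])
      i0 <- pmin(pmax(floor(s$x), 0), nx - 1); fi <- s$x - i0
      j0 <- pmin(pmax(floor(s$y), 0), ny - 1); fj <- s$y - j0
      ii <- i0 + 1L; jj <- j0 + 1L
      NYm <- mesh$node_y
      py <- (1 - fi) * (1 - fj) * NYm[cbind(ii, jj)] +
            fi * (1 - fj) * NYm[cbind(ii + 1L, jj)] +
            (1 - fi) * fj * NYm[cbind(ii, jj + 1L)] +
            fi * fj * NYm[cbind(ii + 1L, jj + 1L)]
      separatrix <- data.frame(x = px, y = py)
    }
  }
  out <- list(has_recirculation = has, reattachment_x = rea_x,
              separation_x = sep_x, recirc_area = recirc_area,
              recirc_cells = which(recirc_cells), separatrix = separatrix,
              psi = psi)
  class(out) <- "stenoclot_topology"
  out
}

#' @export
print.stenoclot_topology <- function(x, ...) {
  if (!x$has_recirculation) {
    cat("No recirculation zone (wall shear does not change sign)\n")
  } else {
    cat(sprintf("Recirculation zone: separation x = %.3f cm, reattachment x = %.3f cm, area = %.4g cm^2\n",
                x$separation_x, x$reattachment_x, x$recirc_area))
  }
  invisible(x)
}

#' Label the clot-formation scenario
#'
#' Heuristic classification of a regime II end state by where the gel sits
#' relative to the recirculation eddy: mostly inside it and not extending
#' far downstream of the reattachment point gives a localized
#' `"solid"` thrombus; substantial downstream extent beyond the eddy gives
#' the `"floating"` friable structure with its microthrombus tail. The
#' label is a heuristic, not a claim.
#'
#' @param result a `stenoclot_sim` (regime II, ideally run past nucleation).
#' @param topology a `stenoclot_topology` of the corresponding flow.
#' @param inside_frac_threshold gel fraction inside the eddy above which
#'   the clot counts as contained (default 0.5).
#' @param extent_factor allowed downstream extent beyond reattachment, as a
#'   multiple of the eddy length (default 0.5).
#' @return list with `label` (`"solid"`/`"floating"`), `gel_cells`,
#'   `frac_inside`, `downstream_extent` (cm beyond reattachment).
#' @export
scenario_diagnostic <- function(result, topology,
                                inside_frac_threshold = 0.5,
                                extent_factor = 0.5) {
  Nws <- result$closures$constants$Nws
  gel <- which(result$closures$Nw >= Nws)
  if (!length(gel)) stop("no gel cells: scenario label needs a regime II end state")
  mesh <- result$mesh
  if (!topology$has_recirculation) {
    return(list(label = "floating", gel_cells = length(gel), frac_inside = 0,
                downstream_extent = max(mesh$cx[gel])))
  }
  inside <- mean(gel %in% topology$recirc_cells)
  ext <- max(mesh$cx[gel]) - topology$reattachment_x
  eddy_len <- topology$reattachment_x -
    (if (is.na(topology$separation_x)) 0 else topology$separation_x)
  label <- if (inside >= inside_frac_threshold && ext <= extent_factor * eddy_len)
    "solid" else "floating"
  list(label = label, gel_cells = length(gel), frac_inside = inside,
       downstream_extent = ext, eddy_length = eddy_len)
}
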