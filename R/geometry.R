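#' Stenosis wall profile
#'
#' Height of the lower-wall plaque at streamwise position `x`:
#' `f(x) = H exp(-x^2 / (2 d^2))`, a Gaussian bump of height `H` and
#' half-width `d` centered at the apex `x = 0`. The vessel occupies
#' `x` in `[-Lx/3, 2 Lx/3]`, `y` in `[f(x), Ly]`.
#'
#' @param x streamwise coordinate(s), cm; must lie inside the vessel.
#' @param geom a `stenoclot_params` object or list with `Lx`, `H`, `d`.
#' @return wall height(s) in cm.
#' @export
#' @examples
#' wall_profile(0, default_parameters(H = 0.5))  # peak: 0.5
wall_profile <- function(x, geom) {
  if (any(x < -geom$Lx / 3 - 1e-12) || any(x > 2 * geom$Lx / 3 + 1e-12))
    stop("x outside the vessel domain [-Lx/3, 2Lx/3]")
  geom$H * exp(-x^2 / (2 * geom$d^2))
}

## Wall-normal grading of the mapped coordinate eta in [0,1]:
## cells clustered toward both walls so the wall-adjacent cell is about
## bl_factor times the mid-channel cell. tanh stretching; bl >= 1 -> uniform.
.eta_nodes <- function(ny, bl_factor) {
  if (bl_factor >= 1) return(seq(0, 1, length.out = ny + 1))
  ratio_for <- function(a) {
    eta <- 0.5 * (1 + tanh(a * (2 * seq(0, ny) / ny - 1)) / tanh(a))
    d <- diff(eta)
    d[1] / max(d)
  }
  f <- function(a) ratio_for(a) - bl_factor
  if (f(1e-4) < 0) return(seq(0, 1, length.out = ny + 1))  # already finer
  a <- stats::uniroot(f, c(1e-4, 8), tol = 1e-10)$root
  0.5 * (1 + tanh(a * (2 * seq(0, ny) / ny - 1)) / tanh(a))
}

#' Build a body-fitted finite-volume mesh of the stenosed channel
#'
#' Constructs a structured quadrilateral mesh through the mapping
#' `(x, eta) -> (x, f(x) + eta (Ly - f(x)))`, `eta` in `[0, 1]`, with
#' optional wall-normal clustering. Faces are precomputed with owner /
#' neighbour cells, area vectors, centroid distances and non-orthogonal
#' correction vectors; boundary faces are tagged into the four patches
#' `inlet`, `outlet`, `wall_upper`, `wall_lower`.
#'
#' @param geom a `stenoclot_params` object (geometry fields used).
#' @param resolution cells per unit length (cm^-1) in the far field; the
#'   wall-normal direction gets `round(resolution * Ly)` cells spanning the
#'   local gap.
#' @param bl_factor ratio of wall-adjacent to mid-channel cell thickness,
#'   in (0, 1]; default 0.35.
#' @param x_refine optional streamwise refinement factor applied smoothly
#'   over the stenosis and its recirculation region (`x` in `[-2d, 2 + 2d]`);
#'   1 (default) keeps uniform streamwise spacing.
#' @return An object of class `stenoclot_mesh`.
#' @export
build_mesh <- function(geom, resolution = 24, bl_factor = 0.35,
                       x_refine = 1) {
  if (geom$H >= geom$Ly) stop("H must be < Ly")
  ny <- as.integer(round(geom$Ly * resolution))
  if (ny < 8L)
    stop("resolution too coarse: need at least 8 cells across the lumen gap")
  xa <- -geom$Lx / 3; xb <- 2 * geom$Lx / 3
  if (x_refine > 1) {
    x0 <- max(xa, -2 * geom$d); x1 <- min(xb, 2 + 2 * geom$d); sm <- 0.25
    dens <- function(x) 1 + (x_refine - 1) *
      stats::plogis((x - x0) / sm) * stats::plogis((x1 - x) / sm)
    xg <- seq(xa, xb, length.out = 4001)
    cum <- c(0, cumsum((dens(xg[-1]) + dens(xg[-length(xg)])) / 2 * diff(xg)))
    nx <- max(8L, as.integer(round(resolution * cum[length(cum)])))
    xs <- stats::approx(cum, xg, xout = seq(0, cum[length(cum)],
                                            length.out = nx + 1))$y
    xs[1] <- xa; xs[nx + 1] <- xb
  } else {
    nx <- max(8L, as.integer(round(geom$Lx * resolution)))
    xs <- seq(xa, xb, length.out = nx + 1)
  }
  eta <- .eta_nodes(ny, bl_factor)
  fx <- wall_profile(xs, geom)
  ## node coordinates, (nx+1) x (ny+1)
  X <- matrix(rep(xs, ny + 1), nx + 1, ny + 1)
  Y <- outer(fx, eta, function(f, e) f + e * (geom$Ly - f))

  cid <- function(i, j) (i - 1L) * ny + j   # cells 1..nx x 1..ny

  ## cell corner coordinates (vectorized over all cells)
  ii <- rep(seq_len(nx), each = ny); jj <- rep(seq_len(ny), nx)
  n00 <- cbind(ii, jj); idx <- function(di, dj) cbind(ii + di, jj + dj)
  gx <- function(m) X[m]; gy <- function(m) Y[m]
  x1 <- gx(n00); y1 <- gy(n00)              # node (i-1, j-1)
  x2 <- gx(idx(1, 0)); y2 <- gy(idx(1, 0))  # node (i,   j-1)
  x3 <- gx(idx(1, 1)); y3 <- gy(idx(1, 1))  # node (i,   j)
  x4 <- gx(idx(0, 1)); y4 <- gy(idx(0, 1))  # node (i-1, j)
  ## shoelace area and centroid of each quad
  cr <- (x1 * y2 - x2 * y1) + (x2 * y3 - x3 * y2) +
        (x3 * y4 - x4 * y3) + (x4 * y1 - x1 * y4)
  area <- 0.5 * cr
  cx <- ((x1 + x2) * (x1 * y2 - x2 * y1) + (x2 + x3) * (x2 * y3 - x3 * y2) +
         (x3 + x4) * (x3 * y4 - x4 * y3) + (x4 + x1) * (x4 * y1 - x1 * y4)) /
        (6 * area)
  cy <- ((y1 + y2) * (x1 * y2 - x2 * y1) + (y2 + y3) * (x2 * y3 - x3 * y2) +
         (y3 + y4) * (x3 * y4 - x4 * y3) + (y4 + y1) * (x4 * y1 - x1 * y4)) /
        (6 * area)
  if (any(area <= 0)) stop("mesh construction produced a non-positive cell area")
  ## cells in (i,j) order need reordering to cid order: cid = (i-1)*ny + j,
  ## and ii/jj were built in exactly that order already.

  ## ---- interior vertical faces: between (i,j) and (i+1,j), i = 1..nx-1
  iv <- rep(seq_len(nx - 1L), each = ny); jv <- rep(seq_len(ny), nx - 1L)
  vo <- cid(iv, jv); vn <- cid(iv + 1L, jv)
  ## face edge: nodes (iv, jv-1) -> (iv, jv); x constant along a column.
  ## node (i,j) lives at matrix index (i+1, j+1).
  vx0 <- X[cbind(iv + 1L, jv)];     vy0 <- Y[cbind(iv + 1L, jv)]
  vx1 <- X[cbind(iv + 1L, jv + 1L)]; vy1 <- Y[cbind(iv + 1L, jv + 1L)]
  vSx <- (vy1 - vy0); vSy <- -(vx1 - vx0)      # normal from owner(-x) to nbr(+x)
  vfcx <- 0.5 * (vx0 + vx1); vfcy <- 0.5 * (vy0 + vy1)

  ## ---- interior horizontal faces: between (i,j) and (i,j+1), j = 1..ny-1
  ih <- rep(seq_len(nx), each = ny - 1L); jh <- rep(seq_len(ny - 1L), nx)
  ho <- cid(ih, jh); hn <- cid(ih, jh + 1L)
  hx0 <- X[cbind(ih, jh + 1L)];      hy0 <- Y[cbind(ih, jh + 1L)]       # node (ih-1, jh)
  hx1 <- X[cbind(ih + 1L, jh + 1L)]; hy1 <- Y[cbind(ih + 1L, jh + 1L)] # node (ih,   jh)
  hSx <- -(hy1 - hy0); hSy <- (hx1 - hx0)      # normal pointing +y-ish
  hfcx <- 0.5 * (hx0 + hx1); hfcy <- 0.5 * (hy0 + hy1)

  own <- c(vo, ho); nbr <- c(vn, hn)
  Sx <- c(vSx, hSx); Sy <- c(vSy, hSy)
  fcx <- c(vfcx, hfcx); fcy <- c(vfcy, hfcy)
  dx <- cx[nbr] - cx[own]; dy <- cy[nbr] - cy[own]
  Sd <- Sx * dx + Sy * dy
  if (any(Sd <= 0)) stop("face orientation inconsistency")
  E <- (Sx^2 + Sy^2) / Sd                       # over-relaxed orthogonal coeff
  tvx <- Sx - E * dx; tvy <- Sy - E * dy        # non-orthogonal correction
  do <- sqrt((fcx - cx[own])^2 + (fcy - cy[own])^2)
  dn <- sqrt((fcx - cx[nbr])^2 + (fcy - cy[nbr])^2)
  w <- dn / (do + dn)                           # weight of OWNER value at face

  ## ---- boundary faces, patches: 1 inlet, 2 outlet, 3 wall_upper, 4 wall_lower
  bi_j <- seq_len(ny)     # inlet: cells (1, j), outward normal -x
  in_o <- cid(1L, bi_j)
  ix0 <- X[cbind(1L, bi_j)]; iy0 <- Y[cbind(1L, bi_j)]
  ix1 <- X[cbind(1L, bi_j + 1L)]; iy1 <- Y[cbind(1L, bi_j + 1L)]
  in_Sx <- -(iy1 - iy0); in_Sy <- (ix1 - ix0) * 0
  in_fcx <- 0.5 * (ix0 + ix1); in_fcy <- 0.5 * (iy0 + iy1)

  out_o <- cid(nx, bi_j)  # outlet: cells (nx, j), outward +x
  ox0 <- X[cbind(nx + 1L, bi_j)]; oy0 <- Y[cbind(nx + 1L, bi_j)]
  ox1 <- X[cbind(nx + 1L, bi_j + 1L)]; oy1 <- Y[cbind(nx + 1L, bi_j + 1L)]
  out_Sx <- (oy1 - oy0); out_Sy <- 0 * ox0
  out_fcx <- 0.5 * (ox0 + ox1); out_fcy <- 0.5 * (oy0 + oy1)

  wi <- seq_len(nx)       # walls: lower cells (i,1), upper cells (i,ny)
  lo_o <- cid(wi, 1L)
  lx0 <- X[cbind(wi, 1L)]; ly0 <- Y[cbind(wi, 1L)]
  lx1 <- X[cbind(wi + 1L, 1L)]; ly1 <- Y[cbind(wi + 1L, 1L)]
  lo_Sx <- (ly1 - ly0); lo_Sy <- -(lx1 - lx0)   # outward: downward
  lo_fcx <- 0.5 * (lx0 + lx1); lo_fcy <- 0.5 * (ly0 + ly1)

  up_o <- cid(wi, ny)
  ux0 <- X[cbind(wi, ny + 1L)]; uy0 <- Y[cbind(wi, ny + 1L)]
  ux1 <- X[cbind(wi + 1L, ny + 1L)]; uy1 <- Y[cbind(wi + 1L, ny + 1L)]
  up_Sx <- -(uy1 - uy0); up_Sy <- (ux1 - ux0)   # outward: upward
  up_fcx <- 0.5 * (ux0 + ux1); up_fcy <- 0.5 * (uy0 + uy1)

  b_own <- c(in_o, out_o, up_o, lo_o)
  b_patch <- c(rep(1L, ny), rep(2L, ny), rep(3L, nx), rep(4L, nx))
  b_Sx <- c(in_Sx, out_Sx, up_Sx, lo_Sx)
  b_Sy <- c(in_Sy, out_Sy, up_Sy, lo_Sy)
  b_fcx <- c(in_fcx, out_fcx, up_fcx, lo_fcx)
  b_fcy <- c(in_fcy, out_fcy, up_fcy, lo_fcy)
  b_dx <- b_fcx - cx[b_own]; b_dy <- b_fcy - cy[b_own]
  b_Sd <- b_Sx * b_dx + b_Sy * b_dy
  b_E <- (b_Sx^2 + b_Sy^2) / b_Sd
  b_tvx <- b_Sx - b_E * b_dx; b_tvy <- b_Sy - b_E * b_dy
  b_len <- sqrt(b_Sx^2 + b_Sy^2)
  b_dn <- b_Sd / b_len                          # wall-normal distance to center
  ## second cell inward along the structured column (for one-sided gradients)
  b_own2 <- c(cid(pmin(2L, nx), bi_j), cid(pmax(nx - 1L, 1L), bi_j),
              cid(wi, pmax(ny - 1L, 1L)), cid(wi, pmin(2L, ny)))

  m <- list(
    nx = nx, ny = ny, ncell = nx * ny,
    node_x = X, node_y = Y,
    cx = cx, cy = cy, area = area,
    own = own, nbr = nbr, Sx = Sx, Sy = Sy,
    fcx = fcx, fcy = fcy, E = E, tvx = tvx, tvy = tvy, w = w,
    b_own = b_own, b_own2 = b_own2, b_patch = b_patch,
    b_Sx = b_Sx, b_Sy = b_Sy, b_fcx = b_fcx, b_fcy = b_fcy,
    b_E = b_E, b_tvx = b_tvx, b_tvy = b_tvy, b_len = b_len, b_dn = b_dn,
    geom = geom[c("Lx", "Ly", "H", "d")], resolution = resolution,
    bl_factor = bl_factor,
    normal_convention = "boundary normals point outward; wall_normal_gradient reports the inward-normal derivative"
  )
  class(m) <- "stenoclot_mesh"
  m
}

#' Check mesh geometric invariants
#'
#' Verifies that every cell closes (area-weighted outward face normals sum
#' to zero within `1e-12` of the cell perimeter), that all areas are
#' positive, and that boundary patches partition the boundary.
#'
#' @param mesh a `stenoclot_mesh`.
#' @return invisibly, a list with the maximal closure defect.
#' @export
mesh_check <- function(mesh) {
  sumx <- numeric(mesh$ncell); sumy <- numeric(mesh$ncell)
  perim <- numeric(mesh$ncell)
  len <- sqrt(mesh$Sx^2 + mesh$Sy^2)
  for (k in seq_along(mesh$own)) {
    o <- mesh$own[k]; n <- mesh$nbr[k]
    sumx[o] <- sumx[o] + mesh$Sx[k]; sumy[o] <- sumy[o] + mesh$Sy[k]
    sumx[n] <- sumx[n] - mesh$Sx[k]; sumy[n] <- sumy[n] - mesh$Sy[k]
    perim[o] <- perim[o] + len[k]; perim[n] <- perim[n] + len[k]
  }
  for (k in seq_along(mesh$b_own)) {
    o <- mesh$b_own[k]
    sumx[o] <- sumx[o] + mesh$b_Sx[k]; sumy[o] <- sumy[o] + mesh$b_Sy[k]
    perim[o] <- perim[o] + mesh$b_len[k]
  }
  defect <- max(sqrt(sumx^2 + sumy^2) / perim)
  if (defect > 1e-12) stop("mesh closure defect ", defect)
  if (any(mesh$area <= 0)) stop("non-positive cell area")
  invisible(list(max_closure_defect = defect))
}

#' One-sided wall-normal gradient of a cell field on a boundary patch
#'
#' Computes, for every face of the requested patch, the derivative of a
#' cell-centered field along the *inward* wall normal, from the two cells
#' stacked inward of the face (exact for fields linear in the normal
#' coordinate).
#'
#' @param field numeric vector of cell values (length `ncell`).
#' @param mesh a `stenoclot_mesh`.
#' @param patch one of `"inlet"`, `"outlet"`, `"wall_upper"`, `"wall_lower"`.
#' @return data.frame with face centers `x`, `y` and `dfdn` (inward-normal
#'   derivative).
#' @export
wall_normal_gradient <- function(field, mesh, patch) {
  pid <- match(patch, c("inlet", "outlet", "wall_upper", "wall_lower"))
  if (is.na(pid)) stop("unknown patch '", patch, "'")
  sel <- which(mesh$b_patch == pid)
  o1 <- mesh$b_own[sel]; o2 <- mesh$b_own2[sel]
  nhat_x <- -mesh$b_Sx[sel] / mesh$b_len[sel]   # inward normal
  nhat_y <- -mesh$b_Sy[sel] / mesh$b_len[sel]
  s1 <- (mesh$cx[o1] - mesh$b_fcx[sel]) * nhat_x +
        (mesh$cy[o1] - mesh$b_fcy[sel]) * nhat_y
  s2 <- (mesh$cx[o2] - mesh$b_fcx[sel]) * nhat_x +
        (mesh$cy[o2] - mesh$b_fcy[sel]) * nhat_y
  g <- ifelse(abs(s2 - s1) > 0, (field[o2] - field[o1]) / (s2 - s1), 0)
  data.frame(x = mesh$b_fcx[sel], y = mesh$b_fcy[sel], dfdn = g)
}

#' Reshape a cell field into the structured (nx, ny) matrix
#' @param mesh a `stenoclot_mesh`.
#' @param v cell vector.
#' @return `nx` by `ny` matrix (rows: streamwise index).
#' @export
field_matrix <- function(mesh, v) t(matrix(v, mesh$ny, mesh$nx))

#' @export
print.stenoclot_mesh <- function(x, ...) {
  cat(sprintf("Body-fitted FV mesh: %d x %d cells (%d), H = %g, d = %g, Ly = %g cm\n",
              x$nx, x$ny, x$ncell, x$geom$H, x$geom$d, x$geom$Ly))
  cat(sprintf("  resolution %g cells/cm, wall-layer factor %g\n",
              x$resolution, x$bl_factor))
  invisible(x)
}
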