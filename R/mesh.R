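#' Idealized truncated-ellipsoid left-ventricle mesh
#'
#' Generates a hexahedral shell mesh of a truncated prolate ellipsoid:
#' the endocardial surface has semi-axes `r_endo` (equatorial) and
#' `z_endo` (apex-base), the wall has uniform thickness `wall`, and the
#' base is the equatorial plane `z = 0`.  The wall is divided into
#' `n_trans` transmural element sheets (labelled endo/mid/epi in equal
#' thirds), `n_circ` circumferential and `n_long` longitudinal element
#' rows; the final longitudinal row collapses onto the apex pole.
#'
#' Each element carries: a transmural layer label, a longitudinal slice
#' label (base/mid/apex thirds), a circumferential segment label
#' (anterior/lateral/posterior/septal quadrants, septal centred on the
#' -x axis), local wall axes (circumferential, longitudinal, radial), a
#' fiber frame with helix angle -60/0/+60 degrees (epi/mid/endo)
#' relative to the circumferential direction, and an initial sarcomere
#' length of 1910/1850/1780 nm (epi/mid/endo).
#'
#' @param n_trans,n_circ,n_long element counts through the wall, around
#'   the circumference and from base to apex.  `n_trans` must be a
#'   multiple of 3 so the three layers have equal thickness.
#' @param r_endo endocardial equatorial radius (mm).
#' @param z_endo endocardial apex-base semi-axis (mm).
#' @param wall wall thickness (mm).
#' @param fiber_angles helix angles (degrees) for the endo, mid and epi
#'   layers.
#' @param sl0 initial sarcomere lengths (nm) for the endo, mid and epi
#'   layers.
#' @return An object of class `"lv_mesh"`.
#' @export
#' @examples
#' m <- build_lv_mesh()
#' nrow(m$elem)          # 144 elements at the default resolution
build_lv_mesh <- function(n_trans = 3, n_circ = 8, n_long = 6,
                          r_endo = 3.2, z_endo = 6.4, wall = 2.0,
                          fiber_angles = c(endo = 60, mid = 0, epi = -60),
                          sl0 = c(endo = 1780, mid = 1850, epi = 1910)) {
  stopifnot(n_trans %% 3 == 0, n_circ >= 8, n_long >= 6,
            r_endo > 0, z_endo > 0, wall > 0)

  phi <- 2 * pi * (seq_len(n_circ) - 1) / n_circ
  theta <- pi / 2 * (0:n_long) / n_long       # 0 = base, pi/2 = apex
  mu <- (0:n_trans) / n_trans                 # 0 = endo, 1 = epi

  surf_pt <- function(m, th, ph) {
    a <- r_endo + wall * m
    c_ax <- z_endo + wall * m
    c(a * cos(th) * cos(ph), a * cos(th) * sin(ph), -c_ax * sin(th))
  }

  # ring nodes [k][j][i] then pole nodes [k]
  nid <- array(NA_integer_, dim = c(n_trans + 1, n_long, n_circ))
  nodes <- list(); cnt <- 0L
  for (k in 0:n_trans) for (j in 0:(n_long - 1)) for (i in seq_len(n_circ)) {
    cnt <- cnt + 1L
    nid[k + 1, j + 1, i] <- cnt
    nodes[[cnt]] <- surf_pt(mu[k + 1], theta[j + 1], phi[i])
  }
  pole <- integer(n_trans + 1)
  for (k in 0:n_trans) {
    cnt <- cnt + 1L
    pole[k + 1] <- cnt
    nodes[[cnt]] <- surf_pt(mu[k + 1], pi / 2, 0)
  }
  nodes <- do.call(rbind, nodes)

  elems <- list(); meta <- list(); en <- 0L
  nxt <- function(i) if (i == n_circ) 1L else i + 1L
  for (k in 1:n_trans) for (j in 1:n_long) for (i in seq_len(n_circ)) {
    i2 <- nxt(i)
    # node ordering: xi = circumferential, eta = base-ward longitudinal,
    # zeta = transmural outward, giving positive Jacobians
    if (j < n_long) {
      lower <- c(nid[k, j + 1, i], nid[k, j + 1, i2], nid[k, j, i2], nid[k, j, i])
      upper <- c(nid[k + 1, j + 1, i], nid[k + 1, j + 1, i2],
                 nid[k + 1, j, i2], nid[k + 1, j, i])
    } else {
      lower <- c(pole[k], pole[k], nid[k, j, i2], nid[k, j, i])
      upper <- c(pole[k + 1], pole[k + 1], nid[k + 1, j, i2], nid[k + 1, j, i])
    }
    en <- en + 1L
    elems[[en]] <- c(lower, upper)
    meta[[en]] <- c(k = k, j = j, i = i)
  }
  elem <- do.call(rbind, elems)
  meta <- do.call(rbind, meta)

  third <- function(idx, n) {
    cut(idx, breaks = c(0, n / 3, 2 * n / 3, n) + 0.5,
        labels = FALSE, include.lowest = TRUE)
  }
  layer <- c("endo", "mid", "epi")[third(meta[, "k"], n_trans)]
  slice <- c("base", "mid", "apex")[third(meta[, "j"], n_long)]
  phic <- phi[meta[, "i"]] + pi / n_circ       # element-centre azimuth
  phic <- atan2(sin(phic), cos(phic)) * 180 / pi
  segment <- ifelse(phic >= -45 & phic < 45, "lateral",
             ifelse(phic >= 45 & phic < 135, "anterior",
             ifelse(phic >= -135 & phic < -45, "posterior", "septal")))

  ne <- nrow(elem)
  wall_axes <- vector("list", ne)
  fiber <- vector("list", ne)
  for (e in seq_len(ne)) {
    k <- meta[e, "k"]; j <- meta[e, "j"]; i <- meta[e, "i"]
    mc <- (mu[k] + mu[k + 1]) / 2
    thc <- (theta[j] + theta[j + 1]) / 2
    phc <- phi[i] + pi / n_circ
    h <- 1e-5
    e_c <- surf_pt(mc, thc, phc + h) - surf_pt(mc, thc, phc - h)
    e_l <- surf_pt(mc, thc - h, phc) - surf_pt(mc, thc + h, phc)  # base-ward
    e_c <- e_c / sqrt(sum(e_c^2))
    e_l <- e_l - sum(e_l * e_c) * e_c
    e_l <- e_l / sqrt(sum(e_l^2))
    e_r <- c(e_c[2] * e_l[3] - e_c[3] * e_l[2],
             e_c[3] * e_l[1] - e_c[1] * e_l[3],
             e_c[1] * e_l[2] - e_c[2] * e_l[1])
    wall_axes[[e]] <- cbind(circ = e_c, long = e_l, radial = e_r)
    ang <- fiber_angles[[layer[e]]]
    fiber[[e]] <- fiber_frame(e_c, e_l, e_r, ang)
  }

  # endocardial faces: inner face of the innermost element sheet
  inner <- which(meta[, "k"] == 1)
  endo_faces <- elem[inner, 1:4, drop = FALSE]
  rim <- nid[1, 1, ]                          # basal endocardial ring

  mesh <- structure(list(
    nodes = nodes, elem = elem, meta = meta,
    layer = layer, slice = slice, segment = segment,
    wall_axes = wall_axes, fiber = fiber,
    sl0 = unname(sl0[layer]),
    basal_nodes = sort(unique(as.integer(nid[, 1, ]))),
    endo_faces = endo_faces, endo_rim = as.integer(rim),
    dims = c(n_trans = n_trans, n_circ = n_circ, n_long = n_long),
    geometry = c(r_endo = r_endo, z_endo = z_endo, wall = wall)),
    class = "lv_mesh")

  jmin <- min_gauss_jacobian(mesh)
  if (jmin <= 0)
    stop("mesh error: non-positive element Jacobian (min det = ",
         signif(jmin, 4), "); refine the resolution")
  mesh
}

# minimum Jacobian determinant over all elements and Gauss points
min_gauss_jacobian <- function(mesh) {
  g <- 1 / sqrt(3)
  gp <- as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g), zeta = c(-g, g)))
  jmin <- Inf
  for (e in seq_len(nrow(mesh$elem))) {
    X <- mesh$nodes[mesh$elem[e, ], , drop = FALSE]
    for (q in seq_len(nrow(gp))) {
      dN <- hex_shape_grad_ref(gp[q, 1], gp[q, 2], gp[q, 3])
      jmin <- min(jmin, det(t(X) %*% dN))
    }
  }
  jmin
}

#' @method print lv_mesh
#' @export
print.lv_mesh <- function(x, ...) {
  cat(sprintf("idealized LV mesh: %d nodes, %d hexahedral elements\n",
              nrow(x$nodes), nrow(x$elem)))
  cat(sprintf("  resolution %d transmural x %d circumferential x %d longitudinal\n",
              x$dims[1], x$dims[2], x$dims[3]))
  cat(sprintf("  endo radius %.2f mm, long semi-axis %.2f mm, wall %.2f mm\n",
              x$geometry[1], x$geometry[2], x$geometry[3]))
  cat(sprintf("  unloaded cavity volume %.4f mL\n", cavity_volume(x)))
  invisible(x)
}

#' Volume enclosed by an oriented triangulated surface
#'
#' Divergence-theorem volume `V = sum det(a, b, c) / 6` over the
#' triangles of a closed, consistently oriented surface.
#'
#' @param verts vertex coordinate matrix (n x 3, mm).
#' @param tris integer triangle matrix (m x 3), outward-oriented.
#' @return Enclosed volume (mL; 1000 mm^3 = 1 mL).
#' @export
closed_surface_volume <- function(verts, tris) {
  a <- verts[tris[, 1], , drop = FALSE]
  b <- verts[tris[, 2], , drop = FALSE]
  c_ <- verts[tris[, 3], , drop = FALSE]
  v6 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
        a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
        a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(v6) / 6 / 1000
}

# triangulation of the cavity surface: endocardial quads split in two,
# plus a basal-cap fan to a centroid pseudo-vertex (index n_nodes + 1)
cavity_triangulation <- function(mesh) {
  q <- mesh$endo_faces
  tris <- rbind(q[, c(1, 2, 3)], q[, c(1, 3, 4)])
  # drop degenerate triangles from collapsed apex faces
  tris <- tris[tris[, 1] != tris[, 2] & tris[, 2] != tris[, 3] &
               tris[, 1] != tris[, 3], , drop = FALSE]
  rim <- mesh$endo_rim
  nr <- length(rim)
  centroid_id <- nrow(mesh$nodes) + 1L
  cap <- cbind(centroid_id, rim, rim[c(2:nr, 1)])
  list(tris = tris, cap = cap, rim = rim, centroid_id = centroid_id)
}

#' Cavity volume of a (possibly deformed) LV mesh
#'
#' Integrates the volume enclosed by the deformed endocardial surface
#' and the planar basal cap (a fan from the centroid of the basal
#' endocardial rim) by the divergence theorem.
#'
#' @param mesh a [build_lv_mesh()] object.
#' @param u optional nodal displacement matrix (n_nodes x 3, mm).
#' @return Cavity volume (mL).
#' @export
cavity_volume <- function(mesh, u = NULL) {
  x <- mesh$nodes
  if (!is.null(u)) x <- x + u
  tr <- cavity_triangulation(mesh)
  verts <- rbind(x, colMeans(x[tr$rim, , drop = FALSE]))
  v <- closed_surface_volume(verts, rbind(tr$tris, tr$cap))
  abs(v)
}

# gradient of the cavity volume wrt nodal coordinates (n_nodes x 3, mL/mm)
# and the orientation sign used so that volume is positive
cavity_volume_grad <- function(mesh, u = NULL) {
  x <- mesh$nodes
  if (!is.null(u)) x <- x + u
  tr <- cavity_triangulation(mesh)
  verts <- rbind(x, colMeans(x[tr$rim, , drop = FALSE]))
  all_tris <- rbind(tr$tris, tr$cap)
  sgn <- sign(closed_surface_volume(verts, all_tris))
  g <- matrix(0, nrow(verts), 3)
  cross3 <- function(u1, v1) c(u1[2] * v1[3] - u1[3] * v1[2],
                               u1[3] * v1[1] - u1[1] * v1[3],
                               u1[1] * v1[2] - u1[2] * v1[1])
  for (t_ in seq_len(nrow(all_tris))) {
    ia <- all_tris[t_, 1]; ib <- all_tris[t_, 2]; ic <- all_tris[t_, 3]
    g[ia, ] <- g[ia, ] + cross3(verts[ib, ], verts[ic, ]) / 6
    g[ib, ] <- g[ib, ] + cross3(verts[ic, ], verts[ia, ]) / 6
    g[ic, ] <- g[ic, ] + cross3(verts[ia, ], verts[ib, ]) / 6
  }
  # distribute the centroid's share back onto the rim nodes
  nr <- length(tr$rim)
  for (r in tr$rim) g[r, ] <- g[r, ] + g[tr$centroid_id, ] / nr
  sgn * g[seq_len(nrow(x)), , drop = FALSE] / 1000
}
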