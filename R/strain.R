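#' Circumferential-longitudinal shear angle
#'
#' The torsion metric
#' `alpha_CL = asin( 2 E_cl / sqrt((1 + 2 E_cc)(1 + 2 E_ll)) )`,
#' returned in degrees.  Vectorised over its arguments.
#'
#' @param E_cc,E_ll circumferential and longitudinal Green strains.
#' @param E_cl circumferential-longitudinal shear strain.
#' @return Shear angle(s) in degrees.
#' @export
#' @examples
#' cl_shear_angle(0, 0, 0.1)   # asin(0.2) in degrees
cl_shear_angle <- function(E_cc, E_ll, E_cl) {
  sc <- 1 + 2 * E_cc
  sl <- 1 + 2 * E_ll
  if (any(sc <= 0) || any(sl <= 0))
    stop("stretch factors (1 + 2E) must be positive")
  arg <- 2 * E_cl / sqrt(sc * sl)
  bad <- abs(arg) > 1
  if (any(bad))
    stop("arcsin argument out of [-1, 1] for strains E_cc = ",
         paste(signif(E_cc[bad], 4), collapse = ", "), "; E_ll = ",
         paste(signif(E_ll[bad], 4), collapse = ", "), "; E_cl = ",
         paste(signif(E_cl[bad], 4), collapse = ", "))
  asin(arg) * 180 / pi
}

#' Regional averages of end-systolic strain
#'
#' Averages element strain components (and the CL shear angle) over the
#' four circumferential wall segments within one transmural layer and
#' one longitudinal slice, reporting per-segment mean and standard
#' error.  The shear angle is computed element-wise and then averaged;
#' set `angle_of_means = TRUE` to instead evaluate it on the
#' segment-mean strains.
#'
#' @param strains data frame with one row per element and columns
#'   `E_cc`, `E_rr`, `E_ll`, `E_cr`, `E_cl`, `E_rl`.
#' @param mesh an [build_lv_mesh()] object supplying `layer`, `segment`
#'   and `slice` labels, or a data frame with those columns (one row per
#'   element of `strains`).
#' @param layer transmural layer to average over.
#' @param slice longitudinal slice (`"apex"`, `"mid"`, `"base"`).
#' @param angle_of_means compute `alpha_CL` from averaged strains
#'   instead of averaging element-wise angles.
#' @return A data frame of class `"regional_strain"` with columns
#'   `segment`, `component`, `mean`, `se`, `n`.
#' @export
regional_average <- function(strains, mesh,
                             layer = c("mid", "endo", "epi"),
                             slice = c("mid", "apex", "base"),
                             angle_of_means = FALSE) {
  layer <- match.arg(layer)
  slice <- match.arg(slice)
  lab <- if (is.data.frame(mesh)) mesh else
    data.frame(layer = mesh$layer, segment = mesh$segment,
               slice = mesh$slice)
  stopifnot(nrow(lab) == nrow(strains))
  keep <- lab$layer == layer & lab$slice == slice
  if (!any(keep)) stop("no elements in layer '", layer, "', slice '",
                       slice, "'")
  st <- strains[keep, , drop = FALSE]
  seg <- lab$segment[keep]
  comps <- c("E_cc", "E_rr", "E_ll", "E_cr", "E_cl", "E_rl")
  stopifnot(all(comps %in% names(st)))
  st$alpha_CL <- cl_shear_angle(st$E_cc, st$E_ll, st$E_cl)
  out <- do.call(rbind, lapply(sort(unique(seg)), function(s) {
    sub <- st[seg == s, , drop = FALSE]
    if (nrow(sub) == 0L) stop("empty segment: ", s)
    rows <- lapply(c(comps, "alpha_CL"), function(cc) {
      v <- sub[[cc]]
      m <- mean(v)
      if (cc == "alpha_CL" && angle_of_means)
        m <- cl_shear_angle(mean(sub$E_cc), mean(sub$E_ll), mean(sub$E_cl))
      data.frame(segment = s, component = cc, mean = m,
                 se = stats::sd(v) / sqrt(length(v)), n = length(v))
    })
    do.call(rbind, rows)
  }))
  rownames(out) <- NULL
  class(out) <- c("regional_strain", class(out))
  out
}

#' Green strain of each element relative to a reference frame
#'
#' Computes the relative deformation gradient of every element between
#' a reference configuration (typically end diastole) and a target
#' configuration, and returns the Green-Lagrange strain rotated into
#' local circumferential/longitudinal/radial wall coordinates.
#'
#' The element deformation gradient is evaluated at the element centre
#' from the trilinear shape functions; the relative gradient is
#' `F_rel = F_target F_ref^-1`, and
#' `E = (F_rel^T F_rel - I) / 2` is expressed on the reference-frame
#' wall axes.
#'
#' @param mesh a [build_lv_mesh()] object.
#' @param u_ref,u_target nodal displacement matrices (n_nodes x 3, mm)
#'   for the reference (end-diastolic) and target (e.g. end-systolic)
#'   configurations.
#' @return Data frame with one row per element: columns `E_cc`, `E_rr`,
#'   `E_ll`, `E_cr`, `E_cl`, `E_rl`.
#' @export
element_strain_tracking <- function(mesh, u_ref, u_target) {
  ne <- nrow(mesh$elem)
  out <- matrix(0, ne, 6,
                dimnames = list(NULL,
                                c("E_cc", "E_rr", "E_ll", "E_cr", "E_cl", "E_rl")))
  for (e in seq_len(ne)) {
    idx <- mesh$elem[e, ]
    X <- mesh$nodes[idx, , drop = FALSE]
    F_ref <- element_def_grad(X, u_ref[idx, , drop = FALSE])
    F_tgt <- element_def_grad(X, u_target[idx, , drop = FALSE])
    F_rel <- F_tgt %*% solve(F_ref)
    E <- (t(F_rel) %*% F_rel - diag(3)) / 2
    Q <- mesh$wall_axes[[e]]          # columns: circ, long, radial
    El <- t(Q) %*% E %*% Q            # (c, l, r) ordering
    out[e, ] <- c(El[1, 1], El[3, 3], El[2, 2],
                  (El[1, 3] + El[3, 1]) / 2,
                  (El[1, 2] + El[2, 1]) / 2,
                  (El[2, 3] + El[3, 2]) / 2)
  }
  as.data.frame(out)
}

# deformation gradient at the centre of a trilinear hexahedron
element_def_grad <- function(X, u) {
  dN <- hex_shape_grad_ref(0, 0, 0)        # 8 x 3, reference derivs
  J0 <- t(X) %*% dN                        # dX/dxi
  dNdX <- dN %*% solve(J0)                 # 8 x 3
  diag(3) + t(u) %*% dNdX
}

# trilinear shape-function derivatives wrt (xi, eta, zeta) at one point
hex_shape_grad_ref <- function(xi, eta, zeta) {
  sg <- matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1, -1, 1, -1,
                 -1, -1,  1,  1, -1,  1,  1, 1,  1, -1, 1,  1),
               8, 3, byrow = TRUE)
  dN <- matrix(0, 8, 3)
  for (a in 1:8) {
    s <- sg[a, ]
    dN[a, 1] <- s[1] * (1 + s[2] * eta) * (1 + s[3] * zeta) / 8
    dN[a, 2] <- s[2] * (1 + s[1] * xi) * (1 + s[3] * zeta) / 8
    dN[a, 3] <- s[3] * (1 + s[1] * xi) * (1 + s[2] * eta) / 8
  }
  dN
}
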