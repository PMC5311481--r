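# Pure geometry: planes, torsions, pseudorotation, projections.

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector", call. = FALSE)
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Torsion angle of four points
#'
#' Dihedral angle about the p2--p3 axis, IUPAC sign convention: looking from
#' p2 towards p3, a clockwise rotation of p1 onto p4 is positive.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors (Angstrom).
#' @return Angle in degrees in (-180, 180].
#' @export
#' @examples
#' dihedral_angle(c(1, 1, 0), c(0, 0, 0), c(0, 0, 1), c(1, 1, 1)) # cis, 0
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  if (.vnorm(n1) < 1e-9 || .vnorm(n2) < 1e-9) {
    stop("undefined torsion: three consecutive points are collinear",
         call. = FALSE)
  }
  m1 <- .cross(n1, .unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- -atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Ring atoms, in order around the base outline. Purines use the outline of the
# fused bicycle (both aromatic cycles); the shared C4-C5 edge is interior.
.ring_atoms <- function(base) {
  switch(base,
    A = ,
    G = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
    C = ,
    U = c("N1", "C2", "N3", "C4", "C5", "C6"),
    stop("no ring definition for base '", base, "'", call. = FALSE)
  )
}

.is_purine <- function(base) base %in% c("A", "G")

#' Fit a nucleobase plane and ring polygon
#'
#' Least-squares plane through the base ring atoms, plus the ordered in-plane
#' projection of the ring outline (for purines, the outline of the fused
#' bicycle). Used for oxygen-pi stacking tests.
#'
#' @param res Residue atom table (rows of an atom tibble for one residue,
#'   with a `base` column of A/C/G/U).
#' @return An object of class `tt_base_plane`: list with `origin` (ring
#'   centroid), `normal` (unit vector), `ex`, `ey` (in-plane axes), `polygon`
#'   (n x 2 matrix of in-plane ring coordinates) and `rms` (out-of-plane RMS
#'   deviation, Angstrom).
#' @export
fit_base_plane <- function(res) {
  base <- res$base[1]
  ring <- .ring_atoms(base)
  xyz <- .res_xyz(res, ring)
  if (anyNA(xyz)) {
    missing <- ring[apply(is.na(xyz), 1, any)]
    stop(tt_condition("tt_incomplete_base",
                      paste0("incomplete base: missing ring atom(s) ",
                             paste(missing, collapse = ", "))))
  }
  ctr <- colMeans(xyz)
  m <- sweep(xyz, 2, ctr)
  sv <- svd(m)
  normal <- sv$v[, 3]
  # deterministic sign: align with the winding of the first two ring edges
  w <- .cross(xyz[2, ] - xyz[1, ], xyz[3, ] - xyz[2, ])
  if (sum(normal * w) < 0) normal <- -normal
  ex <- .unit(xyz[1, ] - ctr - sum((xyz[1, ] - ctr) * normal) * normal)
  ey <- .cross(normal, ex)
  poly <- cbind(m %*% ex, m %*% ey)
  rownames(poly) <- ring
  rms <- sqrt(mean((m %*% normal)^2))
  structure(list(origin = ctr, normal = normal, ex = ex, ey = ey,
                 polygon = poly, rms = rms, base = base),
            class = "tt_base_plane")
}

#' @export
print.tt_base_plane <- function(x, ...) {
  cat("<tt_base_plane> base", x$base,
      sprintf("| %d ring atoms | out-of-plane RMS %.4f A\n",
              nrow(x$polygon), x$rms))
  invisible(x)
}

# signed distance of a 2D point to a polygon boundary: negative inside
.point_poly_dist <- function(pt, poly) {
  n <- nrow(poly)
  inside <- FALSE
  dmin <- Inf
  j <- n
  for (i in seq_len(n)) {
    a <- poly[j, ]
    b <- poly[i, ]
    # even-odd crossing
    if ((a[2] > pt[2]) != (b[2] > pt[2])) {
      xint <- a[1] + (pt[2] - a[2]) * (b[1] - a[1]) / (b[2] - a[2])
      if (pt[1] < xint) inside <- !inside
    }
    ab <- b - a
    t <- sum((pt - a) * ab) / sum(ab * ab)
    t <- min(1, max(0, t))
    dmin <- min(dmin, .vnorm(pt - (a + t * ab)))
    j <- i
  }
  if (inside) -dmin else dmin
}

#' Project a point onto a base plane and test polygon containment
#'
#' Projects `point` onto the fitted base plane and reports its distance to
#' the plane together with whether the projection falls within the ring
#' polygon dilated outward by `offset` (the crystallographic-inaccuracy
#' allowance used for oxygen-pi contacts).
#'
#' @param point Numeric length-3 coordinates.
#' @param plane A [fit_base_plane()] result.
#' @param offset In-plane polygon dilation in Angstrom (default 0.5).
#' @return A one-row tibble with `distance` (unsigned, Angstrom), `signed`
#'   (signed distance along the plane normal) and `inside` (logical).
#' @export
project_point <- function(point, plane, offset = 0.5) {
  d <- sum((point - plane$origin) * plane$normal)
  proj <- point - d * plane$normal - plane$origin
  pt2 <- c(sum(proj * plane$ex), sum(proj * plane$ey))
  pd <- .point_poly_dist(pt2, plane$polygon)
  tibble::tibble(distance = abs(d), signed = d, inside = pd <= offset,
                 edge_distance = pd)
}

#' Acute angle between two base planes
#'
#' @param plane1,plane2 [fit_base_plane()] results.
#' @return Angle between plane normals in degrees, in \[0, 90\].
#' @export
interbase_angle <- function(plane1, plane2) {
  cosa <- abs(sum(plane1$normal * plane2$normal))
  acos(min(1, cosa)) * 180 / pi
}

#' Glycosidic torsion and syn/anti state
#'
#' chi is O4'-C1'-N1-C2 for pyrimidines and O4'-C1'-N9-C4 for purines.
#' syn is the window (-90, +90] (closed on the +90 side); everything else,
#' including exactly -90, is anti.
#'
#' @param res Residue atom table.
#' @return One-row tibble with `chi` (degrees) and `conformation`
#'   ("syn"/"anti").
#' @export
glycosidic_state <- function(res) {
  pur <- all(c("N9", "C4") %in% res$atom) && !all(c("N1", "C2", "C6") %in% res$atom) ||
    .is_purine(res$base[1])
  at <- if (pur) c("O4'", "C1'", "N9", "C4") else c("O4'", "C1'", "N1", "C2")
  xyz <- .res_xyz(res, at)
  if (anyNA(xyz)) {
    stop(tt_condition("tt_incomplete_base",
                      "glycosidic torsion undefined: missing atoms"))
  }
  chi <- dihedral_angle(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ])
  tibble::tibble(chi = chi,
                 conformation = if (chi > -90 && chi <= 90) "syn" else "anti")
}

#' Sugar pucker by pseudorotation analysis
#'
#' Altona-Sundaralingam pseudorotation phase and amplitude from the five
#' endocyclic ribose torsions nu0..nu4. Phase windows: C3'-endo around 18
#' degrees, C2'-endo for P in \[120, 200) (the conventional crystallographic
#' window); near-planar rings (amplitude < 5 degrees) are classed "flat".
#'
#' @param res Residue atom table with the five ribose ring atoms.
#' @return One-row tibble with `phase` (degrees in \[0, 360)), `amplitude`
#'   (degrees) and `class` ("C3'-endo", "C2'-endo", "other" or "flat").
#' @export
sugar_pucker <- function(res) {
  ring <- c("C4'", "O4'", "C1'", "C2'", "C3'")
  xyz <- .res_xyz(res, ring)
  if (anyNA(xyz)) {
    stop(tt_condition("tt_incomplete_base",
                      "sugar pucker undefined: missing ribose ring atoms"))
  }
  # nu_j spans ring atoms j-1, j, j+1, j+2 with the C1'-C2'-C3' numbering:
  # nu0 = C4'-O4'-C1'-C2', nu1 = O4'-C1'-C2'-C3', nu2 = C1'-C2'-C3'-C4',
  # nu3 = C2'-C3'-C4'-O4', nu4 = C3'-C4'-O4'-C1'
  idx <- rbind(c(1, 2, 3, 4), c(2, 3, 4, 5), c(3, 4, 5, 1),
               c(4, 5, 1, 2), c(5, 1, 2, 3))
  nu <- apply(idx, 1, function(i) {
    dihedral_angle(xyz[i[1], ], xyz[i[2], ], xyz[i[3], ], xyz[i[4], ])
  })
  s36 <- sin(36 * pi / 180)
  s72 <- sin(72 * pi / 180)
  y <- (nu[5] + nu[2]) - (nu[4] + nu[1])
  x <- 2 * nu[3] * (s36 + s72)
  p <- atan2(y, x) * 180 / pi
  if (p < 0) p <- p + 360
  amp <- sqrt(x^2 + y^2) / (2 * (s36 + s72))
  cls <- if (amp < 5) {
    "flat"
  } else if (p >= 120 && p < 200) {
    "C2'-endo"
  } else if (p < 72 || p >= 288) {
    "C3'-endo"
  } else {
    "other"
  }
  tibble::tibble(phase = p, amplitude = amp, class = cls)
}

.torsion_class <- function(x) {
  if (is.na(x)) return("-")
  if (x >= 0 && x < 120) "g+" else if (x >= -120 && x < 0) "g-" else "t"
}

#' Backbone torsion classes of a residue
#'
#' Classifies the six backbone torsions alpha..zeta into the three standard
#' rotamer wells: g+ = \[0, 120), g- = \[-120, 0), t otherwise. Torsions that
#' need atoms from the preceding or following residue are gapped ("-") when
#' those atoms are absent or the chain is broken.
#'
#' @param res_prev,res,res_next Residue atom tables; `res_prev`/`res_next`
#'   may be `NULL` at chain termini.
#' @return One-row tibble with the six class symbols and the combined
#'   `classes` string (e.g. `"t,t,g+,g+,t,g-"`).
#' @export
backbone_classes <- function(res_prev, res, res_next) {
  g <- function(r, nm) if (is.null(r)) rep(NA_real_, 3) else .res_atom(r, nm)
  a <- list(
    alpha   = list(g(res_prev, "O3'"), .res_atom(res, "P"), .res_atom(res, "O5'"), .res_atom(res, "C5'")),
    beta    = list(.res_atom(res, "P"), .res_atom(res, "O5'"), .res_atom(res, "C5'"), .res_atom(res, "C4'")),
    gamma   = list(.res_atom(res, "O5'"), .res_atom(res, "C5'"), .res_atom(res, "C4'"), .res_atom(res, "C3'")),
    delta   = list(.res_atom(res, "C5'"), .res_atom(res, "C4'"), .res_atom(res, "C3'"), .res_atom(res, "O3'")),
    epsilon = list(.res_atom(res, "C4'"), .res_atom(res, "C3'"), .res_atom(res, "O3'"), g(res_next, "P")),
    zeta    = list(.res_atom(res, "C3'"), .res_atom(res, "O3'"), g(res_next, "P"), g(res_next, "O5'"))
  )
  tors <- vapply(a, function(p) {
    if (any(vapply(p, anyNA, logical(1)))) return(NA_real_)
    # guard against exploded "torsions" across a chain break
    if (.vnorm(p[[2]] - p[[1]]) > 2.5 || .vnorm(p[[3]] - p[[2]]) > 2.5 ||
        .vnorm(p[[4]] - p[[3]]) > 2.5) {
      return(NA_real_)
    }
    tryCatch(dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]]),
             error = function(e) NA_real_)
  }, numeric(1))
  cls <- vapply(tors, .torsion_class, character(1))
  out <- tibble::as_tibble(as.list(cls))
  out$classes <- paste(cls, collapse = ",")
  out
}

# --- internal rigid-body / construction helpers -----------------------------

# place atom D given chain A-B-C, bond |C-D|, angle B-C-D, torsion A-B-C-D
.nerf <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# least-squares rigid superposition: returns R, t with  y ~ x %*% R + t
.kabsch <- function(x, y) {
  cx <- colMeans(x)
  cy <- colMeans(y)
  h <- t(sweep(x, 2, cx)) %*% sweep(y, 2, cy)
  sv <- svd(h)
  d <- sign(det(t(sv$v %*% t(sv$u))))
  r <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(R = r, t = cy - as.numeric(cx %*% r))
}

.rot_axis <- function(axis, angle_deg) {
  u <- .unit(axis)
  th <- angle_deg * pi / 180
  ct <- cos(th)
  st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}
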