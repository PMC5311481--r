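# Construction of idealized nucleotides and rigid placement helpers used by
# the synthetic turn generator. Residues are assembled from canonical base
# geometry and standard bond lengths/angles; the ribose ring is grown from
# the glycosidic bond with its endocyclic torsions set from the requested
# pseudorotation phase, so chi and pucker are exact by construction.

# solve the third substituent direction at a tetrahedral-ish center:
# unit vectors u1, u2 known, pairwise angles th13, th23 (deg) requested
.third_direction <- function(u1, u2, th13, th23, sign = 1) {
  c12 <- sum(u1 * u2)
  c13 <- cos(th13 * pi / 180)
  c23 <- cos(th23 * pi / 180)
  den <- 1 - c12^2
  a <- (c13 - c23 * c12) / den
  b <- (c23 - c13 * c12) / den
  w2 <- 1 - a^2 - b^2 - 2 * a * b * c12
  w <- if (w2 > 0) sqrt(w2) else 0
  .unit(a * u1 + b * u2 + sign * w * .unit(.cross(u1, u2)))
}

# Build one nucleotide in the standard base frame (base ring in z = 0).
# chi: glycosidic torsion (deg); pucker_p/amp: pseudorotation phase/amplitude.
.nt_build <- function(base, chi = -158, pucker_p = 18, amp = 38,
                      gamma = 54, beta = 180, b_factor = 20) {
  std <- .std_bases[[base]]
  coords <- list()
  for (nm in setdiff(rownames(std), "C1'")) coords[[nm]] <- std[nm, ]
  n_name <- if (.is_purine(base)) "N9" else "N1"
  c_chi <- if (.is_purine(base)) "C4" else "C2"
  coords[["C1'"]] <- std["C1'", ]
  n <- coords[[n_name]]
  c1 <- coords[["C1'"]]
  # O4' from chi: torsion(O4', C1', N, C_chi) = chi
  coords[["O4'"]] <- .nerf(coords[[c_chi]], n, c1, 1.414, 108.2, chi)
  u1 <- .unit(n - c1)
  u2 <- .unit(coords[["O4'"]] - c1)
  coords[["C2'"]] <- c1 + 1.528 * .third_direction(u1, u2, 113.4, 106.1, sign = 1)
  nu <- function(j) amp * cos((pucker_p + 144 * (j - 2)) * pi / 180)
  coords[["C3'"]] <- .nerf(coords[["O4'"]], c1, coords[["C2'"]], 1.525, 101.5, nu(1))
  coords[["C4'"]] <- .nerf(c1, coords[["C2'"]], coords[["C3'"]], 1.523, 102.7, nu(2))
  pick_far <- function(a, bb, cc, bond, angle, tor, avoid) {
    cand1 <- .nerf(a, bb, cc, bond, angle, tor + 120)
    cand2 <- .nerf(a, bb, cc, bond, angle, tor - 120)
    if (.vnorm(cand1 - avoid) > .vnorm(cand2 - avoid)) cand1 else cand2
  }
  coords[["O2'"]] <- pick_far(coords[["O4'"]], c1, coords[["C2'"]],
                              1.413, 110.6, nu(1), coords[["C3'"]])
  coords[["O3'"]] <- pick_far(c1, coords[["C2'"]], coords[["C3'"]],
                              1.423, 110.0, nu(2), coords[["C4'"]])
  coords[["C5'"]] <- pick_far(coords[["C2'"]], coords[["C3'"]], coords[["C4'"]],
                              1.510, 115.5, nu(3), coords[["O4'"]])
  coords[["O5'"]] <- .nerf(coords[["C3'"]], coords[["C4'"]], coords[["C5'"]],
                           1.440, 110.2, gamma)
  coords[["P"]] <- .nerf(coords[["C4'"]], coords[["C5'"]], coords[["O5'"]],
                         1.593, 120.9, beta)
  coords[["OP1"]] <- .nerf(coords[["C5'"]], coords[["O5'"]], coords[["P"]],
                           1.485, 106.0, 115)
  coords[["OP2"]] <- .nerf(coords[["C5'"]], coords[["O5'"]], coords[["P"]],
                           1.485, 106.0, -115)
  xyz <- do.call(rbind, coords)
  tibble::tibble(
    chain = "A", resno = 0L, ins = "", resname = base, base = base,
    atom = rownames(xyz),
    elem = toupper(substr(gsub("[^A-Za-z].*$", "", rownames(xyz)), 1, 1)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    b = b_factor, occ = 1)
}

.apply_rt <- function(res, R, t) {
  xyz <- as.matrix(res[, c("x", "y", "z")]) %*% t(R)
  res$x <- xyz[, 1] + t[1]
  res$y <- xyz[, 2] + t[2]
  res$z <- xyz[, 3] + t[3]
  res
}

# place residue with chosen rotation R so that atom `anchor` lands on `target`
.place_anchor <- function(res, anchor, target, R = diag(3)) {
  a <- .res_atom(res, anchor)
  .apply_rt(res, R, target - as.numeric(R %*% a))
}

# rigidly place residue so that atoms a1, a2 best match targets t1, t2 while
# the base normal aligns with n_des as closely as the remaining spin allows
.place_two_point <- function(res, a1, t1, a2, t2, n_des) {
  p1 <- .res_atom(res, a1)
  p2 <- .res_atom(res, a2)
  u <- .unit(p2 - p1)
  v <- .unit(t2 - t1)
  ax <- .cross(u, v)
  R1 <- if (.vnorm(ax) < 1e-9) {
    if (sum(u * v) > 0) diag(3) else .rot_axis(.third_direction(u, u + c(0.1, 0, 0), 90, 90), 180)
  } else {
    .rot_axis(ax, acos(min(1, max(-1, sum(u * v)))) * 180 / pi)
  }
  plane <- fit_base_plane(res)
  n0 <- as.numeric(R1 %*% plane$normal)
  # spin about v maximizing alignment of the normal with n_des (closed form)
  npar <- sum(n0 * v) * v
  nperp <- n0 - npar
  dperp <- n_des - sum(n_des * v) * v
  phi <- if (.vnorm(nperp) < 1e-9 || .vnorm(dperp) < 1e-9) 0 else {
    s <- sum(.cross(nperp, dperp) * v)
    cang <- sum(.unit(nperp) * .unit(dperp))
    atan2(s, cang * .vnorm(nperp) * .vnorm(dperp)) * 180 / pi
  }
  R <- .rot_axis(v, phi) %*% R1
  mid_l <- (p1 + p2) / 2
  mid_t <- (t1 + t2) / 2
  .apply_rt(res, R, mid_t - as.numeric(R %*% mid_l))
}

# outward in-plane unit direction at a base atom (away from the ring centroid)
.edge_out <- function(res, atom) {
  plane <- fit_base_plane(res)
  p <- .res_atom(res, atom)
  v <- p - plane$origin
  v <- v - sum(v * plane$normal) * plane$normal
  .unit(v)
}

# in-plane direction of a base donor's N-H: external bisector of the donor's
# ring bonds (sp2 imino N), or the C-N bond extension for exocyclic aminos
.donor_h_dir <- function(res, donor) {
  nb <- switch(paste0(res$base[1], donor),
               GN1 = c("C2", "C6"), UN3 = c("C2", "C4"), CN3 = c("C2", "C4"),
               GN2 = "C2", CN4 = "C4", AN6 = "C6", "C2")
  d <- .res_atom(res, donor)
  if (length(nb) == 2) {
    u <- .unit(.res_atom(res, nb[1]) - d) + .unit(.res_atom(res, nb[2]) - d)
    .unit(-u)
  } else {
    .unit(d - .res_atom(res, nb))
  }
}

.finalize_residue <- function(res, chain, resno, resname, base) {
  res$chain <- chain
  res$resno <- as.integer(resno)
  if (!"ins" %in% names(res)) res$ins <- ""
  res$resname <- resname
  res$base <- base
  res[, c("chain", "resno", "ins", "resname", "base", "atom", "elem",
          "x", "y", "z", "b", "occ")]
}

# idealized stem of cis Watson-Crick pairs below z = 0 (the k = 1 pair is
# the hairpin-closing pair); returns list(strand5, strand3) of residue lists
.make_stem <- function(pairs, rise = 3.3, twist = 33) {
  s5 <- list()
  s3 <- list()
  for (k in seq_along(pairs)) {
    b5 <- substr(pairs[k], 1, 1)
    b3 <- substr(pairs[k], 2, 2)
    r5 <- .nt_build(b5)
    r3 <- .nt_build(b3)
    flip <- diag(c(1, -1, -1))   # standard-frame cis-WC partner
    r3 <- .apply_rt(r3, flip, c(0, 0, 0))
    R <- .rot_axis(c(0, 0, 1), -(k - 1) * twist)
    t <- c(0, 0, -(k - 1) * rise - 5.0)
    s5[[k]] <- .apply_rt(r5, R, t)
    s3[[k]] <- .apply_rt(r3, R, t)
  }
  list(s5 = s5, s3 = s3)
}
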