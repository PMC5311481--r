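test_that("dihedral_angle matches an independent torsion implementation", {
  expect_equal(dihedral_angle(c(1, 1, 0), c(0, 0, 0), c(0, 0, 1), c(1, 1, 1)), 0)
  expect_equal(dihedral_angle(c(1, 1, 0), c(0, 0, 0), c(0, 0, 1), c(-1, -1, 1)),
               180)
  set.seed(42)
  for (i in 1:100) {
    p <- matrix(stats::rnorm(12, sd = 3), nrow = 4)
    # skip near-degenerate quadruples the precondition excludes
    if (min(dist(p)) < 0.5) next
    ours <- tryCatch(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                     error = function(e) NA_real_)
    if (is.na(ours)) next
    ref <- bio3d::torsion.xyz(as.numeric(t(p)))
    expect_equal(ours, as.numeric(ref), tolerance = 1e-6)
  }
})

test_that("dihedral_angle rejects collinear points", {
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("base plane fit is exact on planar bases and rigidly invariant", {
  x <- archetype("U")
  g <- x[x$resno == 1, ]   # stem C actually; use window residue 3 (G1)
  g <- window_residues(x)[[1]]
  pl <- fit_base_plane(g)
  expect_lt(pl$rms, 1e-3)
  expect_equal(sqrt(sum(pl$normal^2)), 1, tolerance = 1e-9)

  set.seed(7)
  for (i in 1:5) {
    tr <- random_rigid_transform()
    pl2 <- fit_base_plane(transform_atoms(g, tr$R, tr$t))
    # polygon edge lengths are invariants of the rigid motion
    e1 <- sqrt(rowSums((pl$polygon - pl$polygon[c(2:nrow(pl$polygon), 1), ])^2))
    e2 <- sqrt(rowSums((pl2$polygon - pl2$polygon[c(2:nrow(pl2$polygon), 1), ])^2))
    expect_equal(e1, e2, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("plane fit reports out-of-plane RMS for puckered rings", {
  g <- window_residues(archetype("U"))[[1]]
  i <- which(g$atom == "N7")
  pl0 <- fit_base_plane(g)
  g$x[i] <- g$x[i] + 0.2 * pl0$normal[1]
  g$y[i] <- g$y[i] + 0.2 * pl0$normal[2]
  g$z[i] <- g$z[i] + 0.2 * pl0$normal[3]
  pl <- fit_base_plane(g)
  # recompute RMS directly from the returned plane
  ring <- g[g$atom %in% rownames(pl$polygon), ]
  xyz <- as.matrix(ring[, c("x", "y", "z")])
  d <- sweep(xyz, 2, pl$origin) %*% pl$normal
  expect_equal(pl$rms, sqrt(mean(d^2)), tolerance = 1e-9)
  expect_gt(pl$rms, 0.02)
})

test_that("incomplete bases are flagged as not assessable", {
  g <- window_residues(archetype("U"))[[1]]
  expect_error(fit_base_plane(g[g$atom != "N7", ]),
               class = "tt_incomplete_base")
})

test_that("point projection agrees with a Monte-Carlo dilated-polygon oracle", {
  g <- window_residues(archetype("U"))[[1]]
  pl <- fit_base_plane(g)
  offset <- 0.5
  # dense edge sampling oracle in the plane's 2D frame
  poly <- pl$polygon
  n <- nrow(poly)
  edge_pts <- do.call(rbind, lapply(seq_len(n), function(i) {
    a <- poly[i, ]
    b <- poly[if (i == n) 1 else i + 1, ]
    tt <- seq(0, 1, length.out = 400)
    cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
  }))
  pip <- function(pt) {
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      a <- poly[j, ]; b <- poly[i, ]
      if ((a[2] > pt[2]) != (b[2] > pt[2]) &&
          pt[1] < a[1] + (pt[2] - a[2]) * (b[1] - a[1]) / (b[2] - a[2])) {
        inside <- !inside
      }
      j <- i
    }
    inside
  }
  oracle_inside <- function(pt) {
    pip(pt) || min(sqrt((edge_pts[, 1] - pt[1])^2 +
                          (edge_pts[, 2] - pt[2])^2)) <= offset
  }
  set.seed(11)
  agree <- 0L
  total <- 0L
  for (i in 1:10000) {
    pt2 <- stats::runif(2, -5, 5)
    h <- stats::runif(1, -4, 4)
    point <- pl$origin + pt2[1] * pl$ex + pt2[2] * pl$ey + h * pl$normal
    pr <- project_point(point, pl, offset = offset)
    # skip the boundary band where edge sampling itself is ambiguous
    if (abs(pr$edge_distance - offset) < 1e-3) next
    total <- total + 1L
    if (pr$inside == oracle_inside(pt2)) agree <- agree + 1L
    # distance identity
    expect_equal(pr$distance, abs(h), tolerance = 1e-9)
  }
  expect_identical(agree, total)
})

test_that("projection centroid case and far-lateral case behave", {
  g <- window_residues(archetype("U"))[[1]]
  pl <- fit_base_plane(g)
  pr <- project_point(pl$origin + 3 * pl$normal, pl, offset = 0.5)
  expect_equal(pr$distance, 3, tolerance = 1e-9)
  expect_true(pr$inside)
  pr2 <- project_point(pl$origin + 5 * pl$ex + 3 * pl$normal, pl, offset = 0.5)
  expect_false(pr2$inside)
})

test_that("glycosidic state windows are as specified", {
  z <- archetype("Z_syn")
  r4 <- window_residues(z)[[4]]
  gs <- glycosidic_state(r4)
  expect_equal(gs$conformation, "syn")
  u <- archetype("U")
  expect_equal(glycosidic_state(window_residues(u)[[4]])$conformation, "anti")
  # boundary behaviour: syn is (-90, +90], closed on the +90 side
  mk <- function(chi) {
    r <- tetraturns:::.nt_build("G", chi = chi)
    tetraturns:::.finalize_residue(r, "A", 1L, "G", "G")
  }
  expect_equal(glycosidic_state(mk(-90))$conformation, "anti")
  expect_equal(glycosidic_state(mk(90))$conformation, "syn")
  expect_equal(glycosidic_state(mk(170))$conformation, "anti")
  expect_equal(glycosidic_state(mk(0))$conformation, "syn")
})

test_that("sugar pucker phase matches a closed-form oracle on templates", {
  # oracle: endocyclic torsions via bio3d, phase via the pseudorotation
  # closed form, written independently of the package implementation
  oracle_phase <- function(res) {
    ring <- c("C4'", "O4'", "C1'", "C2'", "C3'")
    xyz <- do.call(rbind, lapply(ring, function(a) {
      r <- res[res$atom == a, ]
      c(r$x, r$y, r$z)
    }))
    idx <- rbind(c(1, 2, 3, 4), c(2, 3, 4, 5), c(3, 4, 5, 1),
                 c(4, 5, 1, 2), c(5, 1, 2, 3))
    nu <- apply(idx, 1, function(i) {
      bio3d::torsion.xyz(as.numeric(t(xyz[i, ])))
    })
    p <- atan2((nu[5] + nu[2]) - (nu[4] + nu[1]),
               2 * nu[3] * (sin(36 * pi / 180) + sin(72 * pi / 180))) * 180 / pi
    (p + 360) %% 360
  }
  z <- archetype("Z_syn")
  r3 <- window_residues(z)[[3]]   # built C2'-endo
  r1 <- window_residues(z)[[1]]   # built C3'-endo
  pk3 <- sugar_pucker(r3)
  pk1 <- sugar_pucker(r1)
  expect_equal(pk3$phase, oracle_phase(r3), tolerance = 1e-6)
  expect_equal(pk1$phase, oracle_phase(r1), tolerance = 1e-6)
  expect_equal(pk3$class, "C2'-endo")
  expect_equal(pk1$class, "C3'-endo")
  expect_true(pk3$phase >= 120 && pk3$phase < 200)
  expect_true(pk1$phase < 36 || pk1$phase >= 324)
})

test_that("flat ribose rings are classed flat", {
  r <- window_residues(archetype("U"))[[1]]
  ring <- c("C4'", "O4'", "C1'", "C2'", "C3'")
  idx <- match(ring, r$atom)
  xyz <- as.matrix(r[idx, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  nrm <- svd(sweep(xyz, 2, ctr))$v[, 3]
  for (k in seq_along(idx)) {
    v <- xyz[k, ] - sum((xyz[k, ] - ctr) * nrm) * nrm
    r$x[idx[k]] <- v[1]; r$y[idx[k]] <- v[2]; r$z[idx[k]] <- v[3]
  }
  pk <- sugar_pucker(r)
  expect_lt(pk$amplitude, 5)
  expect_equal(pk$class, "flat")
})

test_that("mirror-imaging flips the pucker endo <-> exo (P -> P + 180)", {
  r3 <- window_residues(archetype("Z_syn"))[[3]]
  p0 <- sugar_pucker(r3)$phase
  m <- r3
  m$x <- -m$x   # mirror image
  p1 <- sugar_pucker(m)$phase
  d <- (p1 - p0 - 180) %% 360
  expect_lt(min(d, 360 - d), 1e-6)
  expect_equal(sugar_pucker(m)$amplitude, sugar_pucker(r3)$amplitude,
               tolerance = 1e-6)
})

test_that("backbone torsions bin into g+/g-/t as specified", {
  tc <- tetraturns:::.torsion_class
  expect_equal(tc(60), "g+")
  expect_equal(tc(-60), "g-")
  expect_equal(tc(180), "t")
  expect_equal(tc(0), "g+")
  expect_equal(tc(-120), "g-")   # bins are [0,120), [-120,0), t elsewhere
  expect_equal(tc(-121), "t")
  expect_equal(tc(120), "t")
  expect_equal(tc(NA), "-")
  x <- archetype("U")
  rl <- split(as.data.frame(x), x$resno)
  bb <- backbone_classes(rl[[1]], rl[[2]], rl[[3]])
  expect_match(bb$classes, "^([gt+-]+,){5}[gt+-]+$")
})

test_that("interbase angle is the acute angle between normals", {
  g <- window_residues(archetype("U"))[[1]]
  pl <- fit_base_plane(g)
  expect_equal(interbase_angle(pl, pl), 0, tolerance = 1e-4)
  perp <- pl
  perp$normal <- pl$ex
  expect_equal(interbase_angle(pl, perp), 90, tolerance = 1e-9)
  tilt <- pl
  th <- acos(0.9)
  tilt$normal <- cos(th) * pl$normal + sin(th) * pl$ex
  expect_equal(interbase_angle(pl, tilt), acos(0.9) * 180 / pi,
               tolerance = 1e-6)
})

test_that("geometry is invariant under rigid-body transforms", {
  z <- archetype("Z_syn")
  r3 <- window_residues(z)[[3]]
  r4 <- window_residues(z)[[4]]
  set.seed(99)
  for (i in 1:5) {
    tr <- random_rigid_transform()
    r3t <- transform_atoms(r3, tr$R, tr$t)
    r4t <- transform_atoms(r4, tr$R, tr$t)
    expect_equal(sugar_pucker(r3t)$phase, sugar_pucker(r3)$phase,
                 tolerance = 1e-6)
    expect_equal(glycosidic_state(r4t)$chi, glycosidic_state(r4)$chi,
                 tolerance = 1e-6)
    c1 <- detect_oxygen_pi(r3, "O4'", r4)
    c2 <- detect_oxygen_pi(r3t, "O4'", r4t)
    expect_equal(c2$distance, c1$distance, tolerance = 1e-6)
  }
})
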