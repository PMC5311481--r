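# Synthetic turn structures: idealized archetypes, targeted perturbations.

.kind_defaults <- c(U = "GAAA", U_SH = "UCAC", Z_syn = "UUCG",
                    Z_anti = "CUUG", none = "GAUA")

.template_cache <- new.env(parent = emptyenv())

.split_residues <- function(atoms) {
  ord <- order(atoms$chain, atoms$resno, atoms$ins)
  atoms <- atoms[ord, ]
  key <- paste(atoms$chain, atoms$resno, atoms$ins)
  split(atoms, factor(key, levels = unique(key)))
}

.get_res <- function(atoms, resno, chain = NULL) {
  sel <- atoms$resno == resno
  if (!is.null(chain)) sel <- sel & atoms$chain == chain
  atoms[sel, ]
}

# replace the base moiety of a residue, keeping sugar and backbone in place
.mutate_base <- function(res, new_base) {
  old <- res$base[1]
  if (old == new_base) return(res)
  ring_old <- c(.ring_atoms(old), "C1'")
  obs <- .res_xyz(res, ring_old)
  fit <- .kabsch(.std_bases[[old]][ring_old, ], obs)  # standard -> observed
  new_std <- .std_bases[[new_base]]
  keep_names <- setdiff(rownames(new_std), "C1'")
  new_xyz <- new_std[keep_names, , drop = FALSE] %*% fit$R +
    matrix(fit$t, nrow = length(keep_names), ncol = 3, byrow = TRUE)
  base_atoms_old <- setdiff(rownames(.std_bases[[old]]), "C1'")
  out <- res[!res$atom %in% base_atoms_old, ]
  add <- tibble::tibble(
    chain = res$chain[1], resno = res$resno[1], ins = res$ins[1],
    resname = new_base, base = new_base,
    atom = keep_names,
    elem = toupper(substr(keep_names, 1, 1)),
    x = new_xyz[, 1], y = new_xyz[, 2], z = new_xyz[, 3],
    b = res$b[1], occ = 1)
  out$resname <- new_base
  out$base <- new_base
  dplyr::bind_rows(add, out)[order(c(rep(1, nrow(add)), rep(2, nrow(out)))), ]
}

# orient `res` so its O4'->C1' axis points along `axis_dir`, O4' on `target`,
# then spin about the axis by `spin` degrees
.place_sugar_axis <- function(res, target, axis_dir, spin = 0) {
  o4 <- .res_atom(res, "O4'")
  c1 <- .res_atom(res, "C1'")
  u <- .unit(c1 - o4)
  v <- .unit(axis_dir)
  ax <- .cross(u, v)
  R1 <- if (.vnorm(ax) < 1e-9) {
    if (sum(u * v) > 0) diag(3) else .rot_axis(c(v[2], -v[1], 0) + 1e-3, 180)
  } else {
    .rot_axis(ax, acos(min(1, max(-1, sum(u * v)))) * 180 / pi)
  }
  R <- .rot_axis(v, spin) %*% R1
  .place_anchor(res, "O4'", target, R)
}

# pair-placement targets: put `mobile`'s edge anchors onto `fixed`'s edge
.edge_anchor_atoms <- function(base, edge) {
  switch(edge,
    W = if (base %in% c("A", "G")) {
      c("N1", if (base == "G") "O6" else "N6")
    } else {
      c("N3", if (base == "C") "N4" else "O4")
    },
    H = if (base %in% c("A", "G")) {
      c("N7", if (base == "G") "O6" else "N6")
    } else {
      c(if (base == "C") "N4" else "O4", "C5")
    },
    S = if (base %in% c("A", "G")) c("N3", "N2", "C2") else c("O2", "C2")
  )
}

.coords_mat <- function(res) as.matrix(res[, c("x", "y", "z")])

.min_crossdist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

# clearance of `res` against a list of already-placed residues, ignoring the
# atoms named in `ignore` (intended contact atoms)
.clearance <- function(res, placed, ignore = character(0)) {
  if (!length(placed)) return(4)
  a <- .coords_mat(res[!res$atom %in% ignore, ])
  min(vapply(placed, function(p) .min_crossdist(a, .coords_mat(p)), numeric(1)))
}

# smallest perpendicular component of the two glycosidic bonds against the
# N-N axis (conditioning of the cis/trans virtual torsion)
.pair_lever <- function(res_i, res_j) {
  n_i <- if (.is_purine(res_i$base[1])) "N9" else "N1"
  n_j <- if (.is_purine(res_j$base[1])) "N9" else "N1"
  ni <- .res_atom(res_i, n_i)
  nj <- .res_atom(res_j, n_j)
  ax <- .unit(nj - ni)
  vi <- ni - .res_atom(res_i, "C1'")
  vj <- nj - .res_atom(res_j, "C1'")
  min(.vnorm(vi - sum(vi * ax) * ax), .vnorm(vj - sum(vj * ax) * ax))
}

# Place `mobile` so that two of its edge anchors realize hydrogen bonds onto
# `fixed`'s edge, trying both tangent directions and both base-normal signs
# and keeping the candidate that classifies as requested with best clearance.
.place_pair_search <- function(mobile, fixed, edge_mobile, edge_fixed,
                               orientation, placed = list(), dist = 2.9) {
  am <- .edge_anchor_atoms(mobile$base[1], edge_mobile)
  af <- .edge_anchor_atoms(fixed$base[1], edge_fixed)
  am <- am[am %in% mobile$atom][1:2]
  af <- af[af %in% fixed$atom][1:2]
  pf <- fit_base_plane(fixed)
  t1 <- .res_atom(fixed, af[1]) + dist * .edge_out(fixed, af[1])
  t1_variants <- list(t1)
  if (edge_fixed == "S" && "O2'" %in% fixed$atom && af[1] != "O2'") {
    # sugar-edge bridge point: the partner donor reaches both O2/N3 and the
    # 2'-hydroxyl, doubling the supporting-bond count
    a1p <- .res_atom(fixed, af[1])
    a2p <- .res_atom(fixed, "O2'")
    half <- .vnorm(a2p - a1p) / 2
    if (2 * half < 2 * dist) {
      m <- (a1p + a2p) / 2
      w <- a2p - a1p
      u0 <- .edge_out(fixed, af[1])
      u <- .unit(u0 - sum(u0 * .unit(w)) * .unit(w))
      t1_variants <- c(t1_variants,
                       list(m + sqrt(dist^2 - half^2) * u))
    }
  }
  sep <- .vnorm(.res_atom(mobile, am[2]) - .res_atom(mobile, am[1]))
  tangent <- .unit(.cross(pf$normal, .edge_out(fixed, af[1])))
  fixed_f <- .finalize_residue(fixed, "Z", 98L, fixed$base[1], fixed$base[1])
  score_cand <- function(cand) {
    cand_f <- .finalize_residue(cand, "Z", 99L, mobile$base[1], mobile$base[1])
    pr <- tryCatch(classify_pair(cand_f, fixed_f), error = function(e) NULL)
    ok <- !is.null(pr) && pr$orientation == orientation &&
      pr$edge_i == edge_mobile && pr$edge_j == edge_fixed &&
      .pair_lever(cand_f, fixed_f) >= 0.8
    # favour robust pair geometry: flat pairs with margin to the interbase
    # cutoff, more supporting bonds, and bonds well inside the distance and
    # donor-angle screens survive coordinate noise
    solid <- ok && pr$interbase_angle <= 30
    margin <- if (ok) {
      hb <- pr$hbonds[[1]]
      sum(pmin(hb$donor_angle - 100, 40) / 40 +
            pmin(3.5 - hb$distance, 0.6) / 0.6) +
        # distance of the cis/trans virtual torsion from its 90-degree
        # boundary: orientation flips dominate noise failures
        3 * min(abs(abs(pr$virtual_torsion) - 90), 60) / 60 +
        # conditioning of that torsion: both glycosidic bonds need a
        # perpendicular lever arm against the glycosidic-nitrogen axis
        3 * min(.pair_lever(cand_f, fixed_f), 1.2) / 1.2
    } else 0
    clr <- .clearance(cand, c(placed, list(fixed)), ignore = am)
    ok * 100 + solid * 50 + (if (ok) pmin(pr$n_hbonds, 3) * 2 else 0) +
      margin + min(clr, 3.5)
  }
  # anchor variants: the two edge atoms either way round, plus (when the
  # edge has a donor with a known antecedent) a donor-antecedent pair laid
  # out near-linearly along the acceptor's outward ray, which maximizes the
  # donor-angle margin of the supporting bond
  donors <- .hb_donors[[mobile$base[1]]]
  edge_don <- intersect(names(donors), .edge_atoms[[mobile$base[1]]][[edge_mobile]])
  anchor_sets <- list(list(am, "tan"), list(rev(am), "tan"))
  if (length(edge_don)) {
    anchor_sets <- c(anchor_sets,
                     list(list(c(edge_don[1], donors[[edge_don[1]]]), "out")))
  }
  out_dir <- .edge_out(fixed, af[1])
  best <- NULL
  best_score <- -Inf
  for (t1 in t1_variants) {
  for (aset in anchor_sets) {
  am_ord <- aset[[1]]
  for (s_t in c(1, -1)) {
    for (s_n in c(1, -1)) {
      sep <- .vnorm(.res_atom(mobile, am_ord[2]) - .res_atom(mobile, am_ord[1]))
      t2 <- t1 + if (aset[[2]] == "out") sep * out_dir else s_t * sep * tangent
      cand0 <- .place_two_point(mobile, am_ord[1], t1, am_ord[2], t2,
                                s_n * pf$normal)
      # relax about the anchor-anchor axis: keeps the hydrogen-bond anchor
      # geometry while swinging the rest of the residue clear
      p1a <- .res_atom(cand0, am_ord[1])
      p2a <- .res_atom(cand0, am_ord[2])
      sw_range <- if (aset[[2]] == "out") seq(-180, 165, by = 15) else
        seq(-60, 60, by = 15)
      for (sw in sw_range) {
        R <- .rot_axis(p2a - p1a, sw)
        cand <- .apply_rt(cand0, R, as.numeric(p1a - R %*% p1a))
        score <- score_cand(cand)
        if (score > best_score) {
          best_score <- score
          best <- cand
        }
      }
    }
  }
  }
  }
  best
}

# Orient a residue about a fixed anchor atom, scanning rotations for maximal
# clearance from everything already placed.
.orient_search <- function(res, anchor, target, placed, extra_score = NULL) {
  best <- NULL
  best_score <- -Inf
  for (az in seq(0, 340, by = 20)) {
    for (tilt in c(-45, -20, 0, 20, 45, 70)) {
      R <- .rot_axis(c(0, 0, 1), az) %*% .rot_axis(c(1, 0, 0), tilt)
      cand <- .place_anchor(res, anchor, target, R)
      score <- min(.clearance(cand, placed, ignore = anchor), 4) +
        if (is.null(extra_score)) 0 else extra_score(cand)
      if (score > best_score) {
        best_score <- score
        best <- cand
      }
    }
  }
  best
}

# Spin a residue about its sugar axis (head-to-tail placement); the axis may
# tilt away from perfect antiparallel towards `up` (head-to-tail only needs
# an obtuse angle between the sugar axes). Keeps the candidate with maximal
# clearance.
.spin_search <- function(res, target, axis_dir, placed, up = c(0, 0, 1)) {
  best <- NULL
  best_score <- -Inf
  for (tilt in c(0, 15, 30, 45)) {
    ax <- .unit(cos(tilt * pi / 180) * .unit(axis_dir) +
                  sin(tilt * pi / 180) * .unit(up))
    for (spin in seq(0, 345, by = 15)) {
      cand <- .place_sugar_axis(res, target, ax, spin = spin)
      clr <- .clearance(cand, placed, ignore = "O4'")
      if (clr > best_score) {
        best_score <- clr
        best <- cand
      }
    }
  }
  best
}

# Free-standing filler/bulge: put the residue's ring centroid on a shell
# around `center`, maximizing clearance.
.filler_search <- function(res, center, placed, radius = 6.5) {
  f <- .finalize_residue(res, "Z", 97L, res$base[1], res$base[1])
  ctr0 <- fit_base_plane(f)$origin
  best <- NULL
  best_score <- -Inf
  for (az in seq(0, 330, by = 30)) {
    for (el in c(-30, 0, 30, 60)) {
      u <- c(cos(az * pi / 180) * cos(el * pi / 180),
             sin(az * pi / 180) * cos(el * pi / 180),
             sin(el * pi / 180))
      for (rot in c(0, 90, 180)) {
        R <- .rot_axis(c(0, 0, 1), az + rot)
        t <- center + radius * u - as.numeric(R %*% ctr0)
        cand <- .apply_rt(res, R, t)
        clr <- .clearance(cand, placed)
        if (clr > best_score) {
          best_score <- clr
          best <- cand
        }
      }
    }
  }
  best
}

# ---------------------------------------------------------------------------

#' Build a synthetic tetranucleotide turn structure
#'
#' Constructs an idealized full-atom hairpin: an A-form-like stem of cis
#' Watson-Crick pairs closed by a C=G pair, capped by a loop realizing the
#' requested turn archetype. Templates are assembled from canonical
#' nucleotide geometry with the diagnostic backbone oxygen placed at the
#' turn's characteristic stacking distance over the target base (3.0 A for
#' the OP-pi contact of U-type turns, 3.1 A for the O4'-pi contact of
#' Z-type turns). Deterministic for a given seed; provenance is synthetic
#' throughout (no experimental coordinates are copied).
#'
#' @param kind `"U"`, `"U_SH"`, `"Z_syn"`, `"Z_anti"`, or `"none"` (a
#'   structured window with a 1-4 pair but no oxygen-pi contact).
#' @param sequence Loop sequence: 4 bases, or 5 where the fifth is a bulged
#'   residue outside the tetranucleotide window. Defaults per kind
#'   (GAAA, UCAC, UUCG, CUUG, GAUA).
#' @param stem_bp Number of stem base pairs (>= 1; the first is the closing
#'   pair).
#' @param seed Integer seed controlling the (optional) coordinate noise.
#' @param noise_sd Gaussian noise added to every coordinate (A).
#' @param override Build (kind, sequence) combinations the packaged
#'   sequence-structure matrix marks as absent.
#' @param b_factor Uniform isotropic B assigned to all atoms (A^2).
#' @param start_resno Author number of the first residue (different
#'   structures in a corpus normally carry different numbering; the
#'   redundancy filter treats equal-numbered, structurally identical
#'   windows as copies).
#' @param resolution,pdb_id Metadata recorded for the synthetic structure.
#' @param file Optional path: write the structure as mmCIF (with a JSON
#'   ground-truth sidecar at `<file>.json`).
#' @return A `tt_structure` atom tibble; `attr(x, "ground_truth")` records
#'   the expected category and diagnostics.
#' @export
#' @examples
#' x <- make_turn("Z_syn")
#' attr(x, "ground_truth")$expected_category
make_turn <- function(kind = c("U", "U_SH", "Z_syn", "Z_anti", "none"),
                      sequence = NULL, stem_bp = 2, seed = 1, noise_sd = 0,
                      override = FALSE, b_factor = 20, start_resno = 1,
                      resolution = 2.0, pdb_id = NULL, file = NULL) {
  kind <- match.arg(kind)
  if (is.null(sequence)) sequence <- .kind_defaults[[kind]]
  sequence <- toupper(sequence)
  bases <- strsplit(sequence, "")[[1]]
  if (!length(bases) %in% 4:5 || !all(bases %in% c("A", "C", "G", "U"))) {
    stop("sequence must be 4 (or 5, with bulge) of A/C/G/U", call. = FALSE)
  }
  if (kind != "none" && !override) {
    m <- turn_sequence_matrix()
    st <- m$status[m$first == bases[1] & m$fourth == bases[4] &
                     m$category == kind]
    if (length(st) && st == "absent") {
      stop("sequence-structure matrix records no ", kind, "-turn for ",
           bases[1], "NN", bases[4],
           " windows; pass override = TRUE to build it anyway", call. = FALSE)
    }
  }
  stopifnot(stem_bp >= 1)

  # the clean template is deterministic for a given (kind, sequence, stem);
  # cache it so that noise replicates across seeds are cheap
  cache_key <- paste(kind, sequence, stem_bp, sep = "|")
  cached <- .template_cache[[cache_key]]
  if (is.null(cached)) {
    stem_pairs <- c("CG", rep("GC", stem_bp - 1))
    st <- .make_stem(stem_pairs)
    stem_res <- c(st$s5, st$s3)

    loop <- switch(kind,
      U = .build_loop_u(bases, tsh_pair = FALSE, stem = stem_res),
      U_SH = .build_loop_ush(bases, stem = stem_res),
      Z_syn = .build_loop_z(bases, syn4 = TRUE, stem = stem_res),
      Z_anti = .build_loop_z(bases, syn4 = FALSE, stem = stem_res),
      none = .build_loop_pair_only(bases, stem = stem_res)
    )
    loop$residues <- .separate_from_stem(loop$residues, stem_res)
    res_list <- c(rev(st$s5), loop$residues, st$s3)
    atoms <- dplyr::bind_rows(lapply(seq_along(res_list), function(i) {
      r <- res_list[[i]]
      nm <- if (i <= stem_bp) {
        substr(stem_pairs[stem_bp - i + 1], 1, 1)
      } else if (i > stem_bp + length(loop$residues)) {
        substr(stem_pairs[i - stem_bp - length(loop$residues)], 2, 2)
      } else {
        loop$bases[i - stem_bp]
      }
      .finalize_residue(r, "A", i, nm, nm)
    }))
    cached <- list(atoms = atoms, loop = loop)
    .template_cache[[cache_key]] <- cached
  }
  atoms <- cached$atoms
  loop <- cached$loop
  atoms$b <- b_factor
  atoms$resno <- atoms$resno + as.integer(start_resno) - 1L

  if (noise_sd > 0 || TRUE) set.seed(seed)
  if (noise_sd > 0) {
    n <- nrow(atoms)
    atoms$x <- atoms$x + stats::rnorm(n, 0, noise_sd)
    atoms$y <- atoms$y + stats::rnorm(n, 0, noise_sd)
    atoms$z <- atoms$z + stats::rnorm(n, 0, noise_sd)
  }

  if (is.null(pdb_id)) {
    pdb_id <- sprintf("S%s%02d", toupper(substr(gsub("_", "", kind), 1, 1)), seed %% 100)
  }
  meta <- list(pdb_id = pdb_id, method = "X-RAY DIFFRACTION",
               resolution = resolution, model_index = 1, assembly_id = "1")
  win <- stem_bp + 1:4 + as.integer(start_resno) - 1L
  gt <- list(
    kind = kind,
    sequence = sequence,
    expected_category = if (kind == "none") "uncategorized" else kind,
    window_resno = win,
    bulge_resno = if (length(bases) == 5) {
      stem_bp + 5L + as.integer(start_resno) - 1L
    } else integer(0),
    oxygen = loop$oxygen,
    chi4 = loop$chi4,
    pucker3 = loop$pucker3,
    pair_14 = loop$pair_14,
    seed = seed, noise_sd = noise_sd
  )
  out <- .new_atoms(atoms, meta = meta)
  attr(out, "ground_truth") <- gt
  if (!is.null(file)) {
    write_structure_cif(out, file)
    jsonlite::write_json(gt, paste0(file, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  out
}

# rigidly shift the whole loop block until it clears the stem
.separate_from_stem <- function(res_list, stem, min_gap = 3.0) {
  stem_m <- do.call(rbind, lapply(stem, .coords_mat))
  gap <- function(shift) {
    m <- do.call(rbind, lapply(res_list, .coords_mat))
    m <- sweep(m, 2, shift, FUN = "+")
    .min_crossdist(m, stem_m)
  }
  best <- c(0, 0, 0)
  if (gap(best) >= min_gap) return(res_list)
  cand <- expand.grid(dx = seq(-4, 4, by = 2), dy = seq(-4, 4, by = 2),
                      dz = seq(0, 5, by = 1))
  cand <- cand[order(cand$dx^2 + cand$dy^2 + cand$dz^2), ]
  for (i in seq_len(nrow(cand))) {
    s <- as.numeric(cand[i, ])
    if (gap(s) >= min_gap) { best <- s; break }
    if (gap(s) > gap(best)) best <- s
  }
  lapply(res_list, function(r) {
    r$x <- r$x + best[1]; r$y <- r$y + best[2]; r$z <- r$z + best[3]
    r
  })
}

# The loop is built around z = +2 (each builder lifts its residues by
# `lift`); the stem closing pair sits near z = -5 below it.
.loop_lift <- c(0, 0, 2.0)

.lift_all <- function(res_list) {
  lapply(res_list, function(r) {
    r$x <- r$x + .loop_lift[1]
    r$y <- r$y + .loop_lift[2]
    r$z <- r$z + .loop_lift[3]
    r
  })
}

# stem coordinates expressed in the (pre-lift) loop frame, for clearance
.stem_in_loop_frame <- function(stem) {
  lapply(stem, function(r) {
    r$x <- r$x - .loop_lift[1]
    r$y <- r$y - .loop_lift[2]
    r$z <- r$z - .loop_lift[3]
    r
  })
}

.build_loop_u <- function(bases, tsh_pair = FALSE, op_dist = 3.0,
                          stem = list()) {
  placed <- .stem_in_loop_frame(stem)
  r1 <- .nt_build(bases[1], chi = -158, pucker_p = 18)
  f1 <- .finalize_residue(r1, "A", 1L, bases[1], bases[1])
  p1 <- fit_base_plane(f1)
  up <- -p1$normal            # standard-frame bases wind with normal -z
  placed <- c(placed, list(r1))
  if (tsh_pair) {
    # 1-4 trans Sugar/Hoogsteen pair instead of the base-phosphate bond
    r4 <- .nt_build(bases[4], chi = -158, pucker_p = 18)
    r4 <- .place_pair_search(r4, f1, edge_mobile = "H", edge_fixed = "S",
                             orientation = "trans", placed = placed)
  } else {
    # residue 4: its OP2 receives the 1-4 base-phosphate bond from base 1's
    # Watson-Crick-edge donor(s). G starters get the bidentate 4BPh-style
    # geometry (OP equidistant from N1 and N2); single donors take the
    # N-H direction.
    don <- switch(bases[1], G = "N1", U = "N3", C = "N3", A = "N6")
    ante <- switch(bases[1], G = "C2", U = "C4", C = "C4", A = "C6")
    # bias the OP target away from the antecedent to open the donor angle
    dirn <- .unit(.donor_h_dir(f1, don) +
                    0.45 * .unit(.res_atom(f1, don) - .res_atom(f1, ante)))
    t_bph <- .res_atom(f1, don) + 2.85 * dirn
    r4 <- .nt_build(bases[4], chi = -158, pucker_p = 18)
    # for G starters also reward a second bond, N2 -> OP1 (bidentate 4BPh)
    extra <- if (bases[1] == "G") {
      t2 <- .res_atom(f1, "N2") + 2.85 * .donor_h_dir(f1, "N2")
      function(cand) 2 * max(0, 1 - .vnorm(.res_atom(cand, "OP1") - t2) / 1.5)
    } else NULL
    r4 <- .orient_search(r4, "OP2", t_bph, placed, extra_score = extra)
  }
  placed <- c(placed, list(r4))
  # residue 3: OP2 stacked over base 1 at the U-turn's mean contact distance
  r3 <- .nt_build(bases[3], chi = -158, pucker_p = 18)
  r3 <- .orient_search(r3, "OP2", p1$origin + op_dist * up, placed)
  placed <- c(placed, list(r3))
  # residue 2 (and any bulge): free-standing fillers
  r2 <- .nt_build(bases[2], chi = -158, pucker_p = 18)
  r2 <- .filler_search(r2, p1$origin + 3 * up, placed)
  placed <- c(placed, list(r2))
  res <- list(r1, r2, r3, r4)
  if (length(bases) == 5) {
    r5 <- .nt_build(bases[5], chi = -158, pucker_p = 18)
    res <- c(res, list(.filler_search(r5, p1$origin, placed, radius = 8)))
  }
  list(residues = .lift_all(res), bases = bases,
       oxygen = list(kind = "OP", atom = "OP2", residue_pos = 3,
                     target_pos = 1, distance = op_dist),
       chi4 = "anti", pucker3 = "C3'-endo",
       pair_14 = if (tsh_pair) "tSH" else "BPh")
}

.build_loop_ush <- function(bases, stem = list()) {
  out <- .build_loop_u(bases, tsh_pair = TRUE, stem = stem)
  out$pair_14 <- "tSH"
  out
}

.build_loop_z <- function(bases, syn4 = TRUE, o4_dist = 3.1, stem = list()) {
  placed <- .stem_in_loop_frame(stem)
  # high-syn / mid-anti chi keeps a wide margin to the +/-90 boundary
  chi4 <- if (syn4) 45 else -140
  r4 <- .nt_build(bases[4], chi = chi4, pucker_p = 18)
  f4 <- .finalize_residue(r4, "A", 4L, bases[4], bases[4])
  p4 <- fit_base_plane(f4)
  up <- -p4$normal
  axis4 <- .unit(.res_atom(f4, "C1'") - .res_atom(f4, "O4'"))
  placed <- c(placed, list(r4))
  # residue 1: the 1-4 pair; cis WC for complementary ends, else trans
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  pair14 <- if (comp[[bases[1]]] == bases[4]) "cWW" else
    if (bases[1] %in% c("C", "U")) "tSW" else "tSH"
  r1 <- .nt_build(bases[1], chi = -158, pucker_p = 18)
  if (pair14 == "cWW") {
    r1 <- .apply_rt(r1, diag(c(1, -1, -1)), c(0, 0, 0))
  } else {
    r1 <- .place_pair_search(r1, f4, edge_mobile = "S",
                             edge_fixed = if (pair14 == "tSW") "W" else "H",
                             orientation = "trans", placed = placed)
  }
  placed <- c(placed, list(r1))
  # residue 3: O4' stacked over base 4, sugars 3/4 head-to-tail
  r3 <- .nt_build(bases[3], chi = -158, pucker_p = 162)
  r3 <- .spin_search(r3, p4$origin + o4_dist * up, -axis4, placed, up = up)
  placed <- c(placed, list(r3))
  r2 <- .nt_build(bases[2], chi = -158, pucker_p = 18)
  r2 <- .filler_search(r2, p4$origin + 3 * up, placed)
  placed <- c(placed, list(r2))
  res <- list(r1, r2, r3, r4)
  if (length(bases) == 5) {
    r5 <- .nt_build(bases[5], chi = -158, pucker_p = 18)
    res <- c(res, list(.filler_search(r5, p4$origin, placed, radius = 8)))
  }
  list(residues = .lift_all(res), bases = bases,
       oxygen = list(kind = "O4'", atom = "O4'", residue_pos = 3,
                     target_pos = 4, distance = o4_dist),
       chi4 = if (syn4) "syn" else "anti", pucker3 = "C2'-endo",
       pair_14 = pair14)
}

# structured window with a 1-4 pair but no oxygen-pi stacking (GANC-like)
.build_loop_pair_only <- function(bases, stem = list()) {
  placed <- .stem_in_loop_frame(stem)
  r1 <- .nt_build(bases[1], chi = -158, pucker_p = 18)
  f1 <- .finalize_residue(r1, "A", 1L, bases[1], bases[1])
  p1 <- fit_base_plane(f1)
  placed <- c(placed, list(r1))
  edge4 <- if (.is_purine(bases[4])) "H" else "W"
  r4 <- .nt_build(bases[4], chi = -158, pucker_p = 18)
  r4 <- .place_pair_search(r4, f1, edge_mobile = edge4, edge_fixed = "S",
                           orientation = "trans", placed = placed)
  placed <- c(placed, list(r4))
  # residues 2 and 3 well away from both 1-3 and 3-4 stacking geometries
  r3 <- .nt_build(bases[3], chi = -158, pucker_p = 18)
  r3 <- .filler_search(r3, p1$origin - 3 * p1$normal, placed, radius = 7.5)
  placed <- c(placed, list(r3))
  r2 <- .nt_build(bases[2], chi = -158, pucker_p = 18)
  r2 <- .filler_search(r2, p1$origin - 3 * p1$normal, placed)
  res <- list(r1, r2, r3, r4)
  if (length(bases) == 5) {
    r5 <- .nt_build(bases[5], chi = -158, pucker_p = 18)
    res <- c(res, list(.filler_search(r5, p1$origin, c(placed, list(r2)),
                                      radius = 8)))
  }
  list(residues = .lift_all(res), bases = bases,
       oxygen = NULL, chi4 = "anti", pucker3 = "C3'-endo", pair_14 = "tSH")
}

# ---------------------------------------------------------------------------

#' Apply a targeted perturbation to a synthetic turn
#'
#' Single structural edits used to probe the classifier's decision
#' boundaries; everything not named by the operation is left untouched.
#'
#' @param x A [make_turn()] structure.
#' @param op One of `"displace_oxygen"` (move the diagnostic stacking oxygen
#'   along the target base normal by `value` Angstrom), `"flip_chi4"`
#'   (rotate base 4 by 180 degrees about its glycosidic bond),
#'   `"mutate"` (replace the base at window position `position` with
#'   `value`), `"inflate_b"` (set one atom's B-factor to `value`), or
#'   `"break_pair_14"` (translate residue 4 away from residue 1, removing
#'   the 1-4 interaction).
#' @param value Operation parameter (see `op`).
#' @param position Window position 1-4 for `"mutate"`.
#' @param seed Unused for these deterministic edits; kept for signature
#'   stability.
#' @return The edited structure; `attr(x, "ground_truth")$expected_category`
#'   is updated to the category the edit should produce.
#' @export
perturb_structure <- function(x, op = c("displace_oxygen", "flip_chi4",
                                        "mutate", "inflate_b",
                                        "break_pair_14"),
                              value = NULL, position = NULL, seed = 1) {
  op <- match.arg(op)
  gt <- attr(x, "ground_truth")
  if (is.null(gt)) stop("perturb_structure() needs a make_turn() structure",
                        call. = FALSE)
  meta <- structure_meta(x)
  win <- gt$window_resno
  if (op == "displace_oxygen") {
    if (is.null(gt$oxygen)) stop("no diagnostic oxygen in this template",
                                 call. = FALSE)
    ox <- gt$oxygen
    tgt <- .get_res(x, win[ox$target_pos])
    pl <- fit_base_plane(tgt)
    i <- which(x$resno == win[ox$residue_pos] & x$atom == ox$atom)
    o <- c(x$x[i], x$y[i], x$z[i])
    dir <- .unit(pl$normal * sign(sum((o - pl$origin) * pl$normal)))
    x$x[i] <- x$x[i] + value * dir[1]
    x$y[i] <- x$y[i] + value * dir[2]
    x$z[i] <- x$z[i] + value * dir[3]
    newd <- ox$distance + value
    gt$oxygen$distance <- newd
    if (newd > 3.5) gt$expected_category <- "uncategorized"
  } else if (op == "flip_chi4") {
    # rotate the sugar/backbone (not the base) about the glycosidic bond:
    # chi flips by 180 degrees while the base and its 1-4 pair and any
    # oxygen-pi contact onto it stay in place
    res4 <- .get_res(x, win[4])
    b <- res4$base[1]
    n_name <- if (.is_purine(b)) "N9" else "N1"
    c1 <- .res_atom(res4, "C1'")
    n <- .res_atom(res4, n_name)
    R <- .rot_axis(n - c1, 180)
    base_atoms <- setdiff(rownames(.std_bases[[b]]), "C1'")
    idx <- which(x$resno == win[4] & !x$atom %in% c(base_atoms, "C1'"))
    xyz <- as.matrix(x[idx, c("x", "y", "z")])
    xyz <- sweep(xyz, 2, n) %*% t(R)
    xyz <- sweep(xyz, 2, n, FUN = "+")
    x$x[idx] <- xyz[, 1]; x$y[idx] <- xyz[, 2]; x$z[idx] <- xyz[, 3]
    if (gt$expected_category %in% c("Z_syn", "Z_anti")) {
      gt$expected_category <- if (gt$expected_category == "Z_syn") "Z_anti" else "Z_syn"
      gt$chi4 <- if (gt$chi4 == "syn") "anti" else "syn"
    }
  } else if (op == "mutate") {
    stopifnot(!is.null(position), position %in% 1:4)
    res <- .get_res(x, win[position])
    new_res <- .mutate_base(res, toupper(value))
    x <- dplyr::bind_rows(x[x$resno != win[position], ], new_res) |>
      dplyr::arrange(.data$chain, .data$resno, .data$ins)
    gt$sequence <- paste0(substr(gt$sequence, 1, position - 1), toupper(value),
                          substr(gt$sequence, position + 1, nchar(gt$sequence)))
  } else if (op == "inflate_b") {
    i <- which(x$resno == win[2])[1]
    x$b[i] <- value
    if (value > 79) gt$quality_reject <- TRUE
  } else if (op == "break_pair_14") {
    r1 <- .get_res(x, win[1])
    r4 <- .get_res(x, win[4])
    p1 <- fit_base_plane(r1)
    p4 <- fit_base_plane(r4)
    dir <- .unit(p4$origin - p1$origin)
    idx <- which(x$resno == win[4])
    x$x[idx] <- x$x[idx] + 5 * dir[1]
    x$y[idx] <- x$y[idx] + 5 * dir[2]
    x$z[idx] <- x$z[idx] + 5 * dir[3]
    gt$expected_category <- "no-window"
  }
  out <- .new_atoms(x, meta = meta, other = attr(x, "other_atoms"))
  attr(out, "ground_truth") <- gt
  out
}
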