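# Pairwise interaction detection: hydrogen bonds, Leontis-Westhof pairs,
# base-phosphate contacts, oxygen-pi stacking.

.base_complete <- function(res) {
  b <- res$base[1]
  if (!b %in% c("A", "C", "G", "U")) return(FALSE)
  all(.ring_atoms(b) %in% res$atom)
}

.donors_of <- function(res) {
  b <- res$base[1]
  d <- .hb_donors[[b]]
  out <- tibble::tibble(atom = names(d), antecedent = unname(unlist(d)))
  # the 2'-hydroxyl donates and accepts (sugar edge)
  dplyr::bind_rows(out, tibble::tibble(atom = "O2'", antecedent = "C2'"))
}

.acceptors_of <- function(res) {
  b <- res$base[1]
  c(.hb_acceptors[[b]], "O2'")
}

#' Find hydrogen bonds between two residues
#'
#' Enumerates donor/acceptor heavy-atom pairs on the base edges (plus the
#' 2'-hydroxyl) of two residues within a distance cutoff, screened by the
#' angle at the donor (antecedent-donor-acceptor must open at least
#' `min_angle` so that an in-line proton is geometrically plausible).
#'
#' @param res_a,res_b Distinct residue atom tables.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 3.5).
#' @param min_angle Minimum donor angle in degrees. Protons are inferred,
#'   not observed, so the default is the permissive heavy-atom plausibility
#'   screen (90 degrees) used by HBPLUS-style detectors.
#' @return Tibble with one row per bond: `donor_res`, `donor_atom`,
#'   `acceptor_res`, `acceptor_atom`, `distance`, `donor_angle`.
#' @export
find_hbonds <- function(res_a, res_b, cutoff = 3.5, min_angle = 90) {
  if (identical(.res_id(res_a), .res_id(res_b))) {
    stop("find_hbonds() needs two distinct residues", call. = FALSE)
  }
  one_way <- function(from, to) {
    don <- .donors_of(from)
    acc <- .acceptors_of(to)
    rows <- list()
    for (i in seq_len(nrow(don))) {
      d <- .res_atom(from, don$atom[i])
      a0 <- .res_atom(from, don$antecedent[i])
      if (anyNA(d)) next
      for (acca in acc) {
        a <- .res_atom(to, acca)
        if (anyNA(a)) next
        dist <- .vnorm(d - a)
        if (dist > cutoff || dist < 2.0) next
        ang <- if (anyNA(a0)) 180 else {
          v1 <- a0 - d; v2 <- a - d
          acos(min(1, max(-1, sum(v1 * v2) / (.vnorm(v1) * .vnorm(v2))))) * 180 / pi
        }
        if (ang < min_angle) next
        rows[[length(rows) + 1]] <- tibble::tibble(
          donor_res = .res_id(from), donor_atom = don$atom[i],
          acceptor_res = .res_id(to), acceptor_atom = acca,
          distance = dist, donor_angle = ang)
      }
    }
    dplyr::bind_rows(rows)
  }
  ab <- if (.base_complete(res_a) || TRUE) one_way(res_a, res_b) else NULL
  ba <- one_way(res_b, res_a)
  out <- dplyr::bind_rows(ab, ba)
  if (nrow(out)) dplyr::distinct(out) else out
}

# which edge of `res` do the given own-atom names sit on?
.edge_vote <- function(res, own_atoms, partner_centroid) {
  b <- res$base[1]
  sets <- .edge_atoms[[b]]
  score <- vapply(sets, function(s) sum(own_atoms %in% s), numeric(1))
  top <- names(score)[score == max(score)]
  if (length(top) == 1 && max(score) > 0) return(top)
  # tie (shared corner atom) or no base atom: use the partner's azimuth in
  # this base's standard frame
  ring <- .ring_atoms(b)
  obs <- .res_xyz(res, c(ring, "C1'"))
  std <- .std_bases[[b]][c(ring, "C1'"), ]
  fit <- .kabsch(obs, std)   # observed -> standard frame
  pc <- as.numeric(partner_centroid %*% fit$R + fit$t)
  ctr <- colMeans(.std_bases[[b]][ring, 1:2, drop = FALSE])
  az <- atan2(pc[2] - ctr[2], pc[1] - ctr[1]) * 180 / pi
  ref <- .edge_azimuths[[b]]
  cand <- if (max(score) > 0) top else names(ref)
  dd <- vapply(cand, function(e) {
    d <- abs(az - ref[[e]]) %% 360
    min(d, 360 - d)
  }, numeric(1))
  cand[which.min(dd)]
}

#' Classify a base pair in Leontis-Westhof nomenclature
#'
#' Assigns interacting edges (Watson-Crick, Hoogsteen, Sugar) from the atoms
#' supplying the supporting hydrogen bonds, and cis/trans orientation from
#' the glycosidic-bond vectors relative to the pair axis. Near-parallel
#' stacked arrangements (large normal separation of the ring centroids) and
#' pairs with interbase angle above `max_angle` are rejected.
#'
#' @param res_i,res_j Residue atom tables with complete bases.
#' @param max_angle Maximum interbase angle in degrees (default 45).
#' @param hbond_cutoff Hydrogen-bond heavy-atom cutoff (default 3.5 A).
#' @return One-row tibble (`edge_i`, `edge_j`, `orientation`, `lw_code`,
#'   `n_hbonds`, `interbase_angle`, list-column `hbonds`) or `NULL` when the
#'   residues do not pair.
#' @export
classify_pair <- function(res_i, res_j, max_angle = 45, hbond_cutoff = 3.5) {
  if (!.base_complete(res_i) || !.base_complete(res_j)) {
    stop(tt_condition("tt_incomplete_base",
                      "cannot classify pair: incomplete base"))
  }
  hb <- find_hbonds(res_i, res_j, cutoff = hbond_cutoff)
  if (is.null(hb) || nrow(hb) == 0) return(NULL)
  p_i <- fit_base_plane(res_i)
  p_j <- fit_base_plane(res_j)
  if (interbase_angle(p_i, p_j) > max_angle) return(NULL)
  # stacking guard: paired bases are roughly coplanar, stacked ones are not
  sep_i <- abs(sum((p_j$origin - p_i$origin) * p_i$normal))
  sep_j <- abs(sum((p_i$origin - p_j$origin) * p_j$normal))
  if (min(sep_i, sep_j) > 2.5) return(NULL)

  id_i <- .res_id(res_i)
  own_i <- unique(c(hb$donor_atom[hb$donor_res == id_i],
                    hb$acceptor_atom[hb$acceptor_res == id_i]))
  own_j <- unique(c(hb$donor_atom[hb$donor_res != id_i],
                    hb$acceptor_atom[hb$acceptor_res != id_i]))
  cent_j <- colMeans(.res_xyz(res_j, own_j), na.rm = TRUE)
  cent_i <- colMeans(.res_xyz(res_i, own_i), na.rm = TRUE)
  edge_i <- .edge_vote(res_i, own_i, cent_j)
  edge_j <- .edge_vote(res_j, own_j, cent_i)

  # cis/trans from the standard virtual torsion C1'(i)-N(i)-N(j)-C1'(j)
  # about the glycosidic-nitrogen axis: |torsion| <= 90 is cis
  n_i <- if (.is_purine(res_i$base[1])) "N9" else "N1"
  n_j <- if (.is_purine(res_j$base[1])) "N9" else "N1"
  ni <- .res_atom(res_i, n_i); nj <- .res_atom(res_j, n_j)
  vtors <- tryCatch(
    dihedral_angle(.res_atom(res_i, "C1'"), ni, nj, .res_atom(res_j, "C1'")),
    error = function(e) NA_real_)
  if (is.na(vtors)) return(NULL)
  orientation <- if (abs(vtors) <= 90) "cis" else "trans"
  tibble::tibble(
    res_i = id_i, res_j = .res_id(res_j),
    edge_i = edge_i, edge_j = edge_j, orientation = orientation,
    lw_code = paste0(substr(orientation, 1, 1), edge_i, edge_j),
    n_hbonds = nrow(hb),
    interbase_angle = interbase_angle(p_i, p_j),
    virtual_torsion = vtors,
    hbonds = list(hb))
}

#' Classify a base-phosphate contact
#'
#' Detects hydrogen bonds from base nitrogen/oxygen donors of `res_base` to
#' the non-bridging phosphate oxygens (OP1/OP2) of `res_phosphate`, and types
#' the contact by donor identity (Watson-Crick-edge donors give the
#' 3/4/5BPh family; guanine using both N1 and N2 gives 4BPh). A cytosine N3
#' donor is only plausible when protonated and is annotated as such.
#'
#' @param res_base,res_phosphate Residue atom tables.
#' @param cutoff Heavy-atom distance cutoff (default 3.5 A).
#' @param min_angle Minimum donor angle in degrees (default 90: for ring
#'   imino donors the N-H points along the external bisector of the ring
#'   bonds, so plausible heavy-atom angles run lower than for the in-line
#'   geometries typical of base-edge pairs).
#' @return One-row tibble (`donor_atoms`, `op_atom`, `bph_class`, `distance`,
#'   `note`) or `NULL` when no contact exists.
#' @export
classify_bph <- function(res_base, res_phosphate, cutoff = 3.5,
                         min_angle = 90) {
  b <- res_base$base[1]
  if (!b %in% names(.bph_donors)) return(NULL)
  ops <- c("OP1", "OP2")
  if (!any(ops %in% res_phosphate$atom)) return(NULL)
  donors <- .bph_donors[[b]]
  hits <- list()
  for (dn in names(donors)) {
    d <- .res_atom(res_base, dn)
    if (anyNA(d)) next
    ante_nm <- switch(paste0(b, dn),
                      GN1 = "C2", GN2 = "C2", UN3 = "C4", CN3 = "C4",
                      CN4 = "C4", AN6 = "C6", "C4")
    a0 <- .res_atom(res_base, ante_nm)
    for (op in ops) {
      a <- .res_atom(res_phosphate, op)
      if (anyNA(a)) next
      dist <- .vnorm(d - a)
      if (dist > cutoff || dist < 2.0) next
      ang <- if (anyNA(a0)) 180 else {
        v1 <- a0 - d; v2 <- a - d
        acos(min(1, max(-1, sum(v1 * v2) / (.vnorm(v1) * .vnorm(v2))))) * 180 / pi
      }
      if (ang < min_angle) next
      hits[[length(hits) + 1]] <- tibble::tibble(donor = dn, op = op,
                                                 distance = dist,
                                                 class = unname(donors[dn]))
    }
  }
  if (!length(hits)) return(NULL)
  hits <- dplyr::bind_rows(hits)
  used <- unique(hits$donor)
  cls <- if (b == "G" && all(c("N1", "N2") %in% used)) "4BPh" else
    hits$class[which.min(hits$distance)]
  note <- if (b == "C" && "N3" %in% used) "presumed C+" else ""
  tibble::tibble(donor_atoms = paste(used, collapse = "+"),
                 op_atom = hits$op[which.min(hits$distance)],
                 bph_class = cls,
                 distance = min(hits$distance),
                 note = note)
}

#' Detect an oxygen-pi stacking contact
#'
#' Tests whether a backbone oxygen (OP1, OP2 or O4') sits within `cutoff` of
#' a nucleobase plane with its projection inside the ring polygon dilated by
#' `offset`. An incomplete target base raises a `tt_incomplete_base`
#' condition (not assessable, which is distinct from "no contact").
#'
#' @param oxygen_res Residue atom table carrying the oxygen.
#' @param oxygen_atom Atom name: `"OP1"`, `"OP2"` or `"O4'"`.
#' @param target_base Residue atom table of the stacked-on base.
#' @param cutoff Plane-distance cutoff (default 3.5 A, boundary inclusive).
#' @param offset Polygon dilation (default 0.5 A).
#' @return One-row tibble (`oxygen_kind`, `oxygen_atom`, `oxygen_res`,
#'   `target_res`, `distance`, `signed`, `inside`) or `NULL` when there is no
#'   contact.
#' @export
detect_oxygen_pi <- function(oxygen_res, oxygen_atom, target_base,
                             cutoff = 3.5, offset = 0.5) {
  stopifnot(oxygen_atom %in% c("OP1", "OP2", "O4'"))
  o <- .res_atom(oxygen_res, oxygen_atom)
  if (anyNA(o)) return(NULL)
  plane <- fit_base_plane(target_base)  # raises tt_incomplete_base if broken
  pr <- project_point(o, plane, offset = offset)
  if (!(pr$distance <= cutoff && pr$inside)) return(NULL)
  tibble::tibble(
    oxygen_kind = if (oxygen_atom == "O4'") "O4'" else "OP",
    oxygen_atom = oxygen_atom,
    oxygen_res = .res_id(oxygen_res),
    target_res = .res_id(target_base),
    distance = pr$distance, signed = pr$signed, inside = pr$inside)
}
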