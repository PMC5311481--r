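# Static reference data: standard base frames, edge atom sets, hydrogen-bond
# donor/acceptor atoms, base-phosphate donor classes, the modified-base map
# and the sequence-structure matrix.

tt_condition <- function(class, message) {
  structure(class = c(class, "error", "condition"),
            list(message = message, call = NULL))
}

# residue-atom accessors over a residue atom tibble -------------------------

.res_atom <- function(res, name) {
  i <- which(res$atom == name)
  if (length(i) == 0) return(rep(NA_real_, 3))
  as.numeric(c(res$x[i[1]], res$y[i[1]], res$z[i[1]]))
}

.res_xyz <- function(res, names) {
  out <- t(vapply(names, function(nm) .res_atom(res, nm), numeric(3)))
  rownames(out) <- names
  out
}

.res_id <- function(res) paste0(res$chain[1], ":", res$resno[1], res$ins[1])

# standard reference-frame base coordinates (planar, minor groove at -y side;
# the widely used crystallographic consensus geometry), Angstrom
.std_bases <- list(
  A = rbind(
    "C1'" = c(-2.479, 5.346, 0.000),
    N9  = c(-1.291, 4.498, 0.000),
    C8  = c(0.024, 4.897, 0.000),
    N7  = c(0.877, 3.902, 0.000),
    C5  = c(0.071, 2.771, 0.000),
    C6  = c(0.369, 1.398, 0.000),
    N6  = c(1.611, 0.909, 0.000),
    N1  = c(-0.668, 0.532, 0.000),
    C2  = c(-1.912, 1.023, 0.000),
    N3  = c(-2.320, 2.290, 0.000),
    C4  = c(-1.267, 3.124, 0.000)),
  G = rbind(
    "C1'" = c(-2.477, 5.399, 0.000),
    N9  = c(-1.289, 4.551, 0.000),
    C8  = c(0.023, 4.962, 0.000),
    N7  = c(0.870, 3.969, 0.000),
    C5  = c(0.071, 2.833, 0.000),
    C6  = c(0.424, 1.460, 0.000),
    O6  = c(1.554, 0.955, 0.000),
    N1  = c(-0.700, 0.641, 0.000),
    C2  = c(-1.999, 1.087, 0.000),
    N2  = c(-2.949, 0.139, -0.001),
    N3  = c(-2.342, 2.364, 0.001),
    C4  = c(-1.265, 3.177, 0.000)),
  C = rbind(
    "C1'" = c(-2.477, 5.402, 0.000),
    N1  = c(-1.285, 4.542, 0.000),
    C2  = c(-1.472, 3.158, 0.000),
    O2  = c(-2.628, 2.709, 0.001),
    N3  = c(-0.391, 2.344, 0.000),
    C4  = c(0.837, 2.868, 0.000),
    N4  = c(1.875, 2.027, 0.001),
    C5  = c(1.056, 4.275, 0.000),
    C6  = c(-0.023, 5.068, 0.000)),
  U = rbind(
    "C1'" = c(-2.481, 5.354, 0.000),
    N1  = c(-1.284, 4.500, 0.000),
    C2  = c(-1.462, 3.131, 0.000),
    O2  = c(-2.563, 2.608, 0.000),
    N3  = c(-0.302, 2.397, 0.000),
    C4  = c(0.989, 2.884, 0.000),
    O4  = c(1.935, 2.094, -0.001),
    C5  = c(1.089, 4.311, 0.000),
    C6  = c(-0.024, 5.053, 0.000))
)

# Leontis-Westhof edge atom sets per base. O2' (sugar edge) lives on the
# ribose; shared corner atoms appear in two sets and are disambiguated by the
# partner's azimuth in the standard base frame.
.edge_atoms <- list(
  A = list(W = c("N1", "C2", "N6"), H = c("N6", "N7", "C8"), S = c("N3", "C2", "O2'")),
  G = list(W = c("N1", "N2", "O6"), H = c("O6", "N7", "C8"), S = c("N3", "N2", "O2'")),
  C = list(W = c("N3", "N4", "O2"), H = c("N4", "C5", "C6"), S = c("O2", "O2'")),
  U = list(W = c("N3", "O2", "O4"), H = c("O4", "C5", "C6"), S = c("O2", "O2'"))
)

# hydrogen-bond chemistry on base edges (+ the 2'-hydroxyl)
# donors: heavy atom carrying at least one proton, with its bonded antecedent
.hb_donors <- list(
  A = list(N6 = "C6"),
  G = list(N1 = "C2", N2 = "C2"),
  C = list(N4 = "C4"),
  U = list(N3 = "C4")
)
.hb_acceptors <- list(
  A = c("N1", "N3", "N7"),
  G = c("O6", "N3", "N7"),
  C = c("O2", "N3"),
  U = c("O2", "O4")
)

# base-phosphate donors and the BPh class each maps to (Watson-Crick-edge
# donors give the 3/4/5BPh family; 4BPh when guanine uses both its imino and
# amino nitrogens)
.bph_donors <- list(
  G = c(N1 = "5BPh", N2 = "3BPh"),
  U = c(N3 = "5BPh"),
  C = c(N4 = "7BPh", N3 = "5BPh"),  # N3 only available on protonated C
  A = c(N6 = "6BPh")
)

#' Modified-nucleotide parent map
#'
#' Maps common modified-residue three-letter codes to the standard base used
#' for geometric analysis. Unmapped hetero residues that still carry a
#' ribose/base scaffold are analyzed with `base = "other"`.
#'
#' @return A tibble with columns `code` and `base`.
#' @export
modified_base_table <- function() {
  tibble::tribble(
    ~code, ~base,
    "A", "A", "G", "G", "C", "C", "U", "U",
    "DA", "A", "DG", "G", "DC", "C", "DT", "U",
    "PSU", "U", "H2U", "U", "5MU", "U", "4SU", "U", "OMU", "U", "UR3", "U",
    "1MA", "A", "2MA", "A", "MA6", "A", "6MA", "A", "A2M", "A", "OMA", "A",
    "2MG", "G", "7MG", "G", "M2G", "G", "OMG", "G", "1MG", "G", "G7M", "G",
    "YG",  "G", "QUO", "G",
    "5MC", "C", "OMC", "C", "4OC", "C", "S2C", "C",
    "I",   "G"  # inosine: G-like purine for pairing edges
  )
}

.base_of <- function(code) {
  tab <- modified_base_table()
  i <- match(code, tab$code)
  ifelse(is.na(i), "other", tab$base[i])
}

#' Sequence-structure relationship matrix
#'
#' Which combinations of first and fourth loop nucleotide have been observed
#' for each turn category, which are held to be theoretically possible but
#' unobserved, and which are absent. Assembled from reported hairpin-loop
#' occurrences of each turn type.
#'
#' @return A tibble with columns `first`, `fourth`, `category` and `status`
#'   (`"observed"`, `"possible"` or `"absent"`).
#' @export
turn_sequence_matrix <- function() {
  obs <- tibble::tribble(
    ~first, ~fourth, ~category, ~status,
    # U-turns: GNRA-type, GNNG/GNNU (U-only sequences), anticodon-type U/C+
    "G", "A", "U", "observed",
    "G", "G", "U", "observed",
    "G", "U", "U", "observed",
    "G", "C", "U", "observed",   # GNYA-like windows ending in C (uGACAc)
    "U", "A", "U", "observed",
    "U", "C", "U", "observed",
    "U", "G", "U", "observed",
    "U", "U", "U", "observed",
    "C", "C", "U", "observed",   # protonated-C loops (uC+AACu)
    "C", "A", "U", "possible",
    "C", "U", "U", "possible",
    "C", "G", "U", "possible",
    # U_SH-turns: UNAC-type; CNNC modeled but unobserved; never GNNA
    "U", "C", "U_SH", "observed",
    "C", "C", "U_SH", "possible",
    # Z-turns (syn): UNCG, CNNG, GNRA sequences caught in Z folds
    "U", "G", "Z_syn", "observed",
    "C", "G", "Z_syn", "observed",
    "G", "A", "Z_syn", "observed",
    # Z_anti-turns: CNNG di-loops, GCAAu, UUUAa, uGUUC-type
    "C", "G", "Z_anti", "observed",
    "G", "A", "Z_anti", "observed",
    "U", "A", "Z_anti", "observed",
    "G", "C", "Z_anti", "observed",
    "A", "U", "Z_anti", "possible"
  )
  grid <- tidyr::expand_grid(first = c("A", "C", "G", "U"),
                             fourth = c("A", "C", "G", "U"),
                             category = c("U", "U_SH", "Z_syn", "Z_anti"))
  out <- dplyr::left_join(grid, obs, by = c("first", "fourth", "category"))
  out$status[is.na(out$status)] <- "absent"
  out
}

# edge mean azimuths (degrees) about the ring centroid in the standard frame,
# computed once from .std_bases + .edge_atoms (O2' excluded: not in the frame)
.edge_azimuths <- local({
  res <- list()
  for (b in names(.edge_atoms)) {
    ring <- if (b %in% c("A", "G")) {
      c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
    } else {
      c("N1", "C2", "N3", "C4", "C5", "C6")
    }
    ctr <- colMeans(.std_bases[[b]][ring, 1:2, drop = FALSE])
    az <- lapply(.edge_atoms[[b]], function(atoms) {
      atoms <- intersect(atoms, rownames(.std_bases[[b]]))
      xy <- .std_bases[[b]][atoms, 1:2, drop = FALSE]
      v <- colMeans(sweep(xy, 2, ctr))
      atan2(v[2], v[1]) * 180 / pi
    })
    # the sugar edge faces the C1' side: include C1' for a stable direction
    s_atoms <- unique(c(intersect(.edge_atoms[[b]]$S, rownames(.std_bases[[b]])), "C1'"))
    v <- colMeans(sweep(.std_bases[[b]][s_atoms, 1:2, drop = FALSE], 2, ctr))
    az$S <- atan2(v[2], v[1]) * 180 / pi
    res[[b]] <- unlist(az)
  }
  res
})
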