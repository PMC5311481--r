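# Reading mmCIF/PDB into a uniform atom tibble, and the quality filters.

.new_atoms <- function(df, meta = list(), other = NULL) {
  df <- tibble::as_tibble(df)
  needed <- c("chain", "resno", "ins", "resname", "base", "atom", "elem",
              "x", "y", "z", "b", "occ")
  for (nm in setdiff(needed, names(df))) {
    df[[nm]] <- switch(nm, ins = "", b = 0, occ = 1,
                       elem = substr(gsub("[^A-Za-z]", "", df$atom), 1, 1),
                       stop("missing column ", nm))
  }
  df <- df[, needed]
  structure(df, class = c("tt_structure", class(tibble::tibble()))) |>
    (\(d) { attr(d, "meta") <- meta; attr(d, "other_atoms") <- other; d })()
}

#' Structure metadata
#'
#' @param x A structure read by [read_structure()] or built by [make_turn()].
#' @return A list with `pdb_id`, `method`, `resolution`, `model_index` and
#'   `assembly_id`.
#' @export
structure_meta <- function(x) attr(x, "meta")

# strip only matched surrounding quotes: a trailing chemical prime (O2')
# is part of the atom name
.strip_quotes <- function(x) {
  x <- gsub('^"(.*)"$', "\\1", x)
  gsub("^'(.*)'$", "\\1", x)
}

.grep_tag <- function(lines, tag) {
  hit <- grep(tag, lines, fixed = TRUE, value = TRUE)
  if (length(hit) == 0) return(NA_character_)
  val <- sub(paste0(".*", gsub("\\.", "\\\\.", tag), "[[:space:]]+"), "", hit[1])
  .strip_quotes(trimws(val))
}

#' Read an RNA-containing structure
#'
#' Parses an mmCIF or PDB file (gzip-transparent) into a tidy atom table,
#' keeping nucleotide residues (protein, water and ions are retained in a
#' side channel, see `attr(x, "other_atoms")`). Alternate locations are
#' resolved to the highest-occupancy copy (ties favour altloc "A");
#' modified nucleotides are mapped to a parent base where known.
#'
#' @param path File path (`.cif`, `.pdb`, optionally `.gz`).
#' @param model Model number to keep for multi-model (NMR) files; an error
#'   listing the available models is raised when absent.
#' @param format `"auto"` (by extension), `"cif"` or `"pdb"`.
#' @return A `tt_structure` tibble (one row per atom) with columns `chain`,
#'   `resno`, `ins`, `resname`, `base`, `atom`, `elem`, `x`, `y`, `z`, `b`,
#'   `occ`, and metadata available via [structure_meta()].
#' @export
read_structure <- function(path, model = 1, format = c("auto", "cif", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- path
  if (grepl("\\.gz$", path)) {
    raw <- tempfile(fileext = sub("\\.gz$", "", paste0(".", tools::file_ext(sub("\\.gz$", "", path)))))
    writeLines(readLines(gzfile(path)), raw)
    on.exit(unlink(raw), add = TRUE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path)) "cif" else "pdb"
  }
  lines <- readLines(raw, warn = FALSE)
  if (length(trimws(lines)) == 0 || all(trimws(lines) == "")) {
    stop("parse error: '", basename(path), "' is empty", call. = FALSE)
  }

  if (format == "cif") {
    if (!any(grepl("^data_", lines)) || !any(grepl("_atom_site\\.", lines))) {
      stop("parse error in '", basename(path),
           "': no data_ block with an _atom_site loop", call. = FALSE)
    }
    pdbx <- suppressWarnings(bio3d::read.cif(raw, rm.alt = FALSE,
                                             verbose = FALSE))
    at <- pdbx$atom
    pdb_id <- sub("^data_", "", grep("^data_", lines, value = TRUE)[1])
    method <- .grep_tag(lines, "_exptl.method")
    resol <- suppressWarnings(as.numeric(.grep_tag(lines, "_refine.ls_d_res_high")))
  } else {
    pdbx <- tryCatch(bio3d::read.pdb(raw, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE),
                     error = function(e) {
                       stop("parse error in '", basename(path), "': ",
                            conditionMessage(e), call. = FALSE)
                     })
    nmod <- max(1, nrow(pdbx$xyz))
    if (model > nmod || model < 1) {
      stop("model ", model, " not present; available models: ",
           paste(seq_len(nmod), collapse = ", "), call. = FALSE)
    }
    at <- pdbx$atom
    if (model > 1) {
      xyz <- matrix(pdbx$xyz[model, ], ncol = 3, byrow = TRUE)
      at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    }
    head <- grep("^HEADER", lines, value = TRUE)
    pdb_id <- if (length(head)) trimws(substr(head[1], 63, 66)) else
      sub("\\.(pdb|ent)(\\.gz)?$", "", basename(path))
    if (identical(pdb_id, "")) pdb_id <- basename(path)
    expd <- grep("^EXPDTA", lines, value = TRUE)
    method <- if (length(expd)) trimws(sub("^EXPDTA", "", expd[1])) else NA_character_
    rem2 <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
    resol <- if (length(rem2)) {
      suppressWarnings(as.numeric(sub(".*RESOLUTION\\.?[[:space:]]*([0-9.]+).*", "\\1", rem2[1])))
    } else NA_real_
  }

  df <- tibble::tibble(
    chain = as.character(at$chain),
    resno = suppressWarnings(as.integer(at$resno)),
    ins = ifelse(is.na(at$insert) | at$insert == "", "", as.character(at$insert)),
    resname = .strip_quotes(as.character(at$resid)),
    atom = .strip_quotes(as.character(at$elety)),
    elem = toupper(substr(gsub("[^A-Za-z].*$", "", .strip_quotes(as.character(at$elety))), 1, 1)),
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    b = ifelse(is.na(suppressWarnings(as.numeric(at$b))), 0, as.numeric(at$b)),
    occ = ifelse(is.na(suppressWarnings(as.numeric(at$o))), 1, as.numeric(at$o)),
    altloc = ifelse(is.na(at$alt) | at$alt == "" | at$alt == ".", "", as.character(at$alt))
  )
  df <- df[!is.na(df$resno) & is.finite(df$x) & is.finite(df$y) & is.finite(df$z), ]

  # altloc resolution: per residue+atom keep highest occupancy, tie -> 'A'/first
  df <- df |>
    dplyr::group_by(.data$chain, .data$resno, .data$ins, .data$atom) |>
    dplyr::arrange(dplyr::desc(.data$occ), .data$altloc, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()

  df$base <- .base_of(df$resname)
  # unmapped residues with a ribose+base scaffold stay analyzable as "other"
  scaffold <- df |>
    dplyr::group_by(.data$chain, .data$resno, .data$ins) |>
    dplyr::summarise(is_nt = all(c("C1'", "O4'") %in% .data$atom) &&
                       (any(.data$atom == "N9") || any(.data$atom == "N1")),
                     known = .data$base[1] != "other", .groups = "drop")
  df <- dplyr::left_join(df, scaffold, by = c("chain", "resno", "ins"))
  keep <- df$known | df$is_nt
  other <- df[!keep, c("chain", "resno", "ins", "resname", "atom", "x", "y", "z")]
  df <- df[keep, ]
  df <- dplyr::arrange(df, .data$chain, .data$resno, .data$ins)
  df$known <- df$is_nt <- NULL
  df$altloc <- NULL

  meta <- list(pdb_id = toupper(pdb_id),
               method = method,
               resolution = if (length(resol) && is.finite(resol)) resol else NA_real_,
               model_index = model,
               assembly_id = "1")
  .new_atoms(df, meta = meta, other = other)
}

#' Write a structure as mmCIF
#'
#' Minimal PDBx/mmCIF atom_site writer for the synthetic structures produced
#' by [make_turn()] (single model, author numbering).
#'
#' @param atoms A `tt_structure` atom tibble.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_structure_cif <- function(atoms, path) {
  meta <- structure_meta(atoms)
  if (is.null(meta)) meta <- list(pdb_id = "XXXX", method = "SYNTHETIC", resolution = NA_real_)
  q <- function(x) ifelse(grepl("'", x), paste0('"', x, '"'), x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("data_", meta$pdb_id),
    "#",
    paste0("_exptl.method '", meta$method, "'"),
    if (is.finite(meta$resolution %||% NA_real_))
      paste0("_refine.ls_d_res_high ", format(meta$resolution)) else NULL,
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"
  ), con)
  rows <- sprintf("ATOM %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
                  seq_len(nrow(atoms)), atoms$elem, q(atoms$atom), atoms$resname,
                  atoms$chain, atoms$resno,
                  ifelse(atoms$ins == "", "?", atoms$ins),
                  atoms$x, atoms$y, atoms$z, atoms$occ, atoms$b,
                  atoms$resno, atoms$resname, atoms$chain, q(atoms$atom))
  writeLines(rows, con)
  writeLines("#", con)
  invisible(path)
}

#' Quality screen for a tetranucleotide window
#'
#' Applies the survey's structure-quality criteria to a 4-residue window:
#' every atom of the window must have a B-factor at or below `max_b`
#' (79 A^2 by default) and, for diffraction/EM structures with a reported
#' resolution, the structure resolution must not exceed `max_resolution`
#' (3.0 A by default).
#'
#' @param window Atom tibble restricted to the window's residues.
#' @param meta Structure metadata list ([structure_meta()]), or `NULL`.
#' @param max_b Maximum tolerated isotropic B-factor (A^2).
#' @param max_resolution Maximum tolerated resolution (A).
#' @param xray_only When `TRUE`, the resolution criterion is enforced
#'   whenever a resolution is present.
#' @return One-row tibble with `accept` (logical) and `reason`.
#' @export
quality_filter <- function(window, meta = NULL, max_b = 79,
                           max_resolution = 3.0, xray_only = TRUE) {
  if (!is.null(meta) && xray_only && is.finite(meta$resolution %||% NA_real_) &&
      meta$resolution > max_resolution) {
    return(tibble::tibble(accept = FALSE,
                          reason = sprintf("resolution %.2f A exceeds %.2f A",
                                           meta$resolution, max_resolution)))
  }
  bad <- which(window$b > max_b)
  if (length(bad)) {
    i <- bad[which.max(window$b[bad])]
    return(tibble::tibble(
      accept = FALSE,
      reason = sprintf("B-factor %.1f A^2 above %.1f A^2 (atom %s of %s %s:%d)",
                       window$b[i], max_b, window$atom[i], window$resname[i],
                       window$chain[i], window$resno[i])))
  }
  tibble::tibble(accept = TRUE, reason = "ok")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
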