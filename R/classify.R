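# The turn taxonomy: decision rules and the per-structure annotation driver.

.turn_categories <- c("U", "U_SH", "Z_syn", "Z_anti", "uncategorized")

# best OP1/OP2 oxygen-pi contact from `from` onto `onto`
.best_op_contact <- function(from, onto, cutoff, offset) {
  cands <- list(
    detect_oxygen_pi(from, "OP1", onto, cutoff = cutoff, offset = offset),
    detect_oxygen_pi(from, "OP2", onto, cutoff = cutoff, offset = offset)
  )
  cands <- cands[!vapply(cands, is.null, logical(1))]
  if (!length(cands)) return(NULL)
  cands[[which.min(vapply(cands, function(x) x$distance, numeric(1)))]]
}

#' Classify a tetranucleotide window
#'
#' Applies the oxygen-pi-based taxonomy to four residues in 5'->3' order.
#' Decision order: a valid OP(residue 3)-pi contact onto base 1 makes the
#' window a U-turn when the 1-4 base-phosphate bond is present, or a
#' U_SH-turn when the 1-4 pair is trans Sugar/Hoogsteen; otherwise a valid
#' O4'(residue 3)-pi contact onto base 4 makes it a Z-turn, syn or anti by
#' the glycosidic state of residue 4; otherwise any remaining 1-4
#' interaction leaves the window uncategorized. Sugar pucker of residue 3,
#' the head-to-tail orientation of sugars 3-4 and the 1-4 pair type are
#' reported as diagnostics, not gating criteria.
#'
#' @param res1,res2,res3,res4 Residue atom tables (window positions 1-4).
#' @param cutoff Oxygen-pi plane-distance cutoff (default 3.5 A, inclusive).
#' @param offset Polygon dilation (default 0.5 A).
#' @return One-row tibble: `category`, `seq`, evidence columns
#'   (`oxy_kind`, `oxy_atom`, `oxy_distance`, `pair_14`, `bph_14`,
#'   `bph_note`), diagnostics (`pucker3`, `pucker3_phase`, `chi4`,
#'   `chi4_state`, `head_to_tail_34`, `o4_rev_distance`) and `notes`.
#' @export
classify_turn <- function(res1, res2, res3, res4, cutoff = 3.5,
                          offset = 0.5) {
  seq4 <- paste(vapply(list(res1, res2, res3, res4),
                       function(r) r$base[1], character(1)), collapse = "")
  blank <- tibble::tibble(
    category = "uncategorized", seq = seq4,
    oxy_kind = NA_character_, oxy_atom = NA_character_,
    oxy_distance = NA_real_, pair_14 = NA_character_,
    bph_14 = NA_character_, bph_note = NA_character_,
    pucker3 = NA_character_, pucker3_phase = NA_real_,
    chi4 = NA_real_, chi4_state = NA_character_,
    head_to_tail_34 = NA, o4_rev_distance = NA_real_, notes = "")

  assessable <- all(vapply(list(res1, res2, res3, res4), .base_complete,
                           logical(1)))
  if (!assessable) {
    blank$notes <- "not-assessable: incomplete base in window"
    return(blank)
  }

  pair14 <- tryCatch(classify_pair(res1, res4), error = function(e) NULL)
  bph14 <- classify_bph(res1, res4)

  # reported diagnostics
  pk3 <- tryCatch(sugar_pucker(res3), error = function(e) NULL)
  gs4 <- tryCatch(glycosidic_state(res4), error = function(e) NULL)
  a3 <- .res_atom(res3, "C1'") - .res_atom(res3, "O4'")
  a4 <- .res_atom(res4, "C1'") - .res_atom(res4, "O4'")
  htt <- if (anyNA(a3) || anyNA(a4)) NA else sum(a3 * a4) < 0
  rev_o4 <- detect_oxygen_pi(res4, "O4'", res3, cutoff = cutoff,
                             offset = offset)

  out <- blank
  out$pair_14 <- if (is.null(pair14)) NA_character_ else pair14$lw_code
  out$bph_14 <- if (is.null(bph14)) NA_character_ else bph14$bph_class
  out$bph_note <- if (is.null(bph14)) NA_character_ else bph14$note
  if (!is.null(pk3)) {
    out$pucker3 <- pk3$class
    out$pucker3_phase <- pk3$phase
  }
  if (!is.null(gs4)) {
    out$chi4 <- gs4$chi
    out$chi4_state <- gs4$conformation
  }
  out$head_to_tail_34 <- htt
  out$o4_rev_distance <- if (is.null(rev_o4)) NA_real_ else rev_o4$distance

  op13 <- .best_op_contact(res3, res1, cutoff, offset)
  o434 <- detect_oxygen_pi(res3, "O4'", res4, cutoff = cutoff,
                           offset = offset)

  notes <- character(0)
  if (!is.null(op13) && !is.null(o434)) {
    notes <- c(notes, "both 1-3 OP-pi and 3-4 O4'-pi present; OP-pi wins")
  }
  tsh14 <- !is.null(pair14) && pair14$orientation == "trans" &&
    setequal(c(pair14$edge_i, pair14$edge_j), c("S", "H"))

  if (!is.null(op13)) {
    out$oxy_kind <- op13$oxygen_kind
    out$oxy_atom <- op13$oxygen_atom
    out$oxy_distance <- op13$distance
    if (!is.null(bph14)) {
      out$category <- "U"
      if (nzchar(bph14$note)) notes <- c(notes, bph14$note)
      out$notes <- paste(notes, collapse = "; ")
      return(out)
    }
    if (tsh14) {
      out$category <- "U_SH"
      out$notes <- paste(notes, collapse = "; ")
      return(out)
    }
  }
  if (!is.null(o434)) {
    out$oxy_kind <- o434$oxygen_kind
    out$oxy_atom <- o434$oxygen_atom
    out$oxy_distance <- o434$distance
    if (!is.null(gs4)) {
      out$category <- if (gs4$conformation == "syn") "Z_syn" else "Z_anti"
    } else {
      out$category <- "uncategorized"
      notes <- c(notes, "O4'-pi contact but glycosidic state undefined")
    }
    out$notes <- paste(notes, collapse = "; ")
    return(out)
  }
  if (is.null(pair14) && is.null(bph14)) {
    stop("classify_turn() expects a window with a 1-4 interaction",
         call. = FALSE)
  }
  notes <- c(notes, "1-4 interaction present but no oxygen-pi contact")
  out$notes <- paste(notes, collapse = "; ")
  out
}

#' Check an annotation against the sequence-structure matrix
#'
#' Compares (first nucleotide, fourth nucleotide, category) with the
#' packaged relationship matrix ([turn_sequence_matrix()]).
#'
#' @param annotation One row of a [classify_turn()] / [annotate_turns()]
#'   result (needs `seq` and `category`).
#' @return One-row tibble with `first`, `fourth`, `category` and `status`:
#'   `"observed"`, `"possible"` (held possible but unobserved), `"absent"`
#'   (combination not recorded for this category), or `"unchecked"` for
#'   uncategorized windows.
#' @export
sequence_structure_check <- function(annotation) {
  first <- substr(annotation$seq[1], 1, 1)
  fourth <- substr(annotation$seq[1], 4, 4)
  cat <- annotation$category[1]
  if (!cat %in% c("U", "U_SH", "Z_syn", "Z_anti")) {
    return(tibble::tibble(first = first, fourth = fourth, category = cat,
                          status = "unchecked"))
  }
  m <- turn_sequence_matrix()
  st <- m$status[m$first == first & m$fourth == fourth & m$category == cat]
  tibble::tibble(first = first, fourth = fourth, category = cat,
                 status = if (length(st)) st else "absent")
}

#' Annotate tetranucleotide turns in a structure
#'
#' The full pipeline: find hairpin loops (at most `max_loop` unpaired
#' residues), enumerate candidate tetranucleotide windows with a 1-4
#' interaction, screen each window's quality (B-factors, resolution),
#' classify it, and keep the best-evidenced window per loop (categorized
#' windows beat uncategorized ones; ties go to the shorter oxygen-pi
#' distance).
#'
#' @param atoms A `tt_structure` atom tibble ([read_structure()] or
#'   [make_turn()]).
#' @param config Run parameters from [tt_config()].
#' @param all_windows Keep every candidate window instead of the best one
#'   per loop.
#' @return A `tt_annotations` tibble: one row per window with structure
#'   metadata, window residue numbers, category, evidence and diagnostics.
#'   Quality-rejected windows are reported with `category = "rejected"` and
#'   the reason.
#' @export
annotate_turns <- function(atoms, config = tt_config(), all_windows = FALSE) {
  meta <- structure_meta(atoms) %||%
    list(pdb_id = NA_character_, method = NA_character_,
         resolution = NA_real_, model_index = 1, assembly_id = "1")
  empty <- tibble::tibble()
  rl <- .split_residues(atoms)
  pairs <- base_pairs(atoms, max_angle = config$interbase_max,
                      hbond_cutoff = config$hbond)
  hp <- find_hairpins(atoms, max_loop = config$max_loop, pairs = pairs)
  if (nrow(hp) == 0) return(structure(empty, class = class(tibble::tibble())))
  rows <- list()
  for (h in seq_len(nrow(hp))) {
    wins <- candidate_windows(atoms, hp[h, ], max_bulge = config$max_bulge)
    if (nrow(wins) == 0) next
    wrows <- list()
    for (w in seq_len(nrow(wins))) {
      idx <- c(wins$w1[w], wins$w2[w], wins$w3[w], wins$w4[w])
      wres <- lapply(idx, function(k) rl[[k]])
      watoms <- dplyr::bind_rows(wres)
      qf <- quality_filter(watoms, meta, max_b = config$max_b,
                           max_resolution = config$max_resolution,
                           xray_only = config$xray_only)
      if (!qf$accept) {
        ann <- tibble::tibble(category = "rejected", seq = wins$seq[w],
                              notes = qf$reason)
      } else {
        ann <- classify_turn(wres[[1]], wres[[2]], wres[[3]], wres[[4]],
                             cutoff = config$oxygen_pi,
                             offset = config$polygon_offset)
      }
      base_cols <- tibble::tibble(
        pdb_id = meta$pdb_id, chain = wres[[1]]$chain[1],
        model = meta$model_index %||% 1,
        resolution = meta$resolution %||% NA_real_,
        loop_start = hp$loop_start[h], loop_len = hp$loop_len[h],
        closing_lw = hp$closing_lw[h],
        res1 = wres[[1]]$resno[1], res2 = wres[[2]]$resno[1],
        res3 = wres[[3]]$resno[1], res4 = wres[[4]]$resno[1],
        n_bulged = length(wins$bulged_idx[[w]]))
      wrows[[w]] <- dplyr::bind_cols(base_cols, ann)
    }
    wtab <- dplyr::bind_rows(wrows)
    if (!all_windows) {
      categorized <- wtab$category %in% c("U", "U_SH", "Z_syn", "Z_anti")
      pick <- if (any(categorized)) {
        cand <- which(categorized)
        cand[order(wtab$oxy_distance[cand], wtab$res1[cand])][1]
      } else {
        order(wtab$res1)[1]
      }
      wtab <- wtab[pick, ]
    }
    rows[[length(rows) + 1]] <- wtab
  }
  if (!length(rows)) return(structure(empty, class = class(tibble::tibble())))
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tt_annotations", class(tibble::tibble()))
  out
}

#' Run configuration
#'
#' All tunable cutoffs and filters of the annotation pipeline in one list.
#' Defaults are the survey's operating point: 3.5 A oxygen-pi cutoff, 0.5 A
#' polygon offset, 45 degree maximum interbase angle, 3.5 A hydrogen-bond
#' cutoff, B-factor ceiling 79 A^2, resolution ceiling 3.0 A, hairpin loops
#' of at most 8 residues, and at most 2 bulged-out residues per window.
#'
#' @param oxygen_pi,polygon_offset,interbase_max,hbond Geometry cutoffs.
#' @param max_b,max_resolution,xray_only Quality filters.
#' @param max_loop,max_bulge Loop extraction limits.
#' @param model Model policy for multi-model inputs.
#' @param seed Seed recorded for downstream randomized steps.
#' @return A list of class `tt_config`.
#' @export
tt_config <- function(oxygen_pi = 3.5, polygon_offset = 0.5,
                      interbase_max = 45, hbond = 3.5, max_b = 79,
                      max_resolution = 3.0, xray_only = TRUE, max_loop = 8,
                      max_bulge = 2, model = 1, seed = 1) {
  cfg <- list(oxygen_pi = oxygen_pi, polygon_offset = polygon_offset,
              interbase_max = interbase_max, hbond = hbond, max_b = max_b,
              max_resolution = max_resolution, xray_only = xray_only,
              max_loop = max_loop, max_bulge = max_bulge, model = model,
              seed = seed)
  stopifnot(all(vapply(cfg[c("oxygen_pi", "polygon_offset", "interbase_max",
                             "hbond", "max_b", "max_resolution")],
                       function(x) is.numeric(x) && x > 0, logical(1))))
  class(cfg) <- "tt_config"
  cfg
}

#' @export
print.tt_config <- function(x, ...) {
  cat("<tt_config>\n")
  for (nm in names(x)) cat(" ", nm, "=", format(x[[nm]]), "\n")
  invisible(x)
}
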