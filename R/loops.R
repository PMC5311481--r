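# Secondary structure from 3D: base pairs, hairpin loops, candidate windows.

#' Base pairs of a structure from 3D coordinates
#'
#' Classifies every spatially plausible residue pair (C1'-C1' within
#' `prune`) with [classify_pair()]. Incomplete bases are skipped.
#'
#' @param atoms A `tt_structure` atom tibble.
#' @param max_angle,hbond_cutoff Passed to [classify_pair()].
#' @param prune C1'-C1' pruning radius in Angstrom.
#' @return Tibble of pairs: indices `i`, `j` (position in chain order),
#'   residue ids, and the Leontis-Westhof annotation columns.
#' @export
base_pairs <- function(atoms, max_angle = 45, hbond_cutoff = 3.5,
                       prune = 12) {
  rl <- .split_residues(atoms)
  n <- length(rl)
  if (n < 2) return(tibble::tibble())
  c1 <- t(vapply(rl, function(r) .res_atom(r, "C1'"), numeric(3)))
  ok_base <- vapply(rl, .base_complete, logical(1))
  out <- list()
  for (i in seq_len(n - 1)) {
    if (!ok_base[i] || anyNA(c1[i, ])) next
    for (j in (i + 1):n) {
      if (!ok_base[j] || anyNA(c1[j, ])) next
      if (.vnorm(c1[i, ] - c1[j, ]) > prune) next
      pr <- tryCatch(classify_pair(rl[[i]], rl[[j]], max_angle = max_angle,
                                   hbond_cutoff = hbond_cutoff),
                     error = function(e) NULL)
      if (!is.null(pr)) {
        pr$i <- i
        pr$j <- j
        out[[length(out) + 1]] <- pr
      }
    }
  }
  if (!length(out)) return(tibble::tibble())
  dplyr::bind_rows(out)[, c("i", "j", "res_i", "res_j", "edge_i", "edge_j",
                            "orientation", "lw_code", "n_hbonds",
                            "interbase_angle", "hbonds")]
}

#' Find hairpin loops
#'
#' A hairpin is a base pair (i, j) on one chain whose enclosed residues are
#' contiguous (consecutive author numbering), number between `min_loop` and
#' `max_loop`, and pair with nothing outside the enclosed span. Nested
#' closing pairs report the innermost loop. Pairs wholly inside the loop
#' (e.g. the 1-4 pair of a tetranucleotide window, or the 1-4 cis
#' Watson-Crick pair of a di-loop) do not disqualify it: spans shorter than
#' `min_loop` (default 3, the sterically feasible minimum for an RNA
#' hairpin) are treated as loop-internal pairs, not closings.
#'
#' @param atoms A `tt_structure` atom tibble.
#' @param max_loop Maximum loop length (default 8).
#' @param min_loop Minimum loop length (default 3).
#' @param pairs Optionally, a precomputed [base_pairs()] table.
#' @return Tibble with one row per hairpin: `chain`, `i`, `j` (chain-order
#'   indices of the closing pair), `closing_lw`, `loop_start`, `loop_len`,
#'   and `loop_idx` (list-column of loop residue indices).
#' @export
find_hairpins <- function(atoms, max_loop = 8, min_loop = 3, pairs = NULL) {
  if (is.null(pairs)) pairs <- base_pairs(atoms)
  if (nrow(pairs) == 0) return(tibble::tibble())
  rl <- .split_residues(atoms)
  chain_of <- vapply(rl, function(r) r$chain[1], character(1))
  resno_of <- vapply(rl, function(r) r$resno[1], integer(1))
  paired_with <- function(k) {
    unique(c(pairs$j[pairs$i == k], pairs$i[pairs$j == k]))
  }
  pair_key <- paste(pairs$i, pairs$j)
  cand <- list()
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]
    j <- pairs$j[r]
    if (chain_of[i] != chain_of[j]) next
    len <- j - i - 1
    if (len < min_loop || len > max_loop) next
    inner <- (i + 1):(j - 1)
    # contiguity by author numbering within one chain
    if (any(chain_of[inner] != chain_of[i])) next
    if (any(diff(resno_of[i:j]) != 1)) next
    outside_paired <- any(vapply(inner, function(k) {
      p <- paired_with(k)
      any(p < i | p > j)
    }, logical(1)))
    if (outside_paired) next
    # helix-terminal pairs (supported by a stacked neighbour pair) are true
    # closings; isolated pairs may be loop-internal (e.g. the window's own
    # 1-4 pair)
    stacked <- paste(i - 1, j + 1) %in% pair_key ||
      paste(i + 1, j - 1) %in% pair_key
    cand[[length(cand) + 1]] <- tibble::tibble(
      chain = chain_of[i], i = i, j = j,
      closing_lw = pairs$lw_code[r], stacked = stacked,
      loop_start = resno_of[i + 1], loop_len = len,
      loop_idx = list(inner))
  }
  if (!length(cand)) return(tibble::tibble())
  out <- dplyr::bind_rows(cand)
  # an isolated pair nested inside another candidate span is loop-internal,
  # not a closing; among the rest report the innermost of nested closings
  keep1 <- vapply(seq_len(nrow(out)), function(r) {
    out$stacked[r] ||
      !any(out$i < out$i[r] & out$j > out$j[r])
  }, logical(1))
  out <- out[keep1, ]
  keep2 <- vapply(seq_len(nrow(out)), function(r) {
    !any(out$i > out$i[r] & out$j < out$j[r])
  }, logical(1))
  out[keep2, !names(out) %in% "stacked"]
}

#' Enumerate candidate tetranucleotide windows of a hairpin loop
#'
#' All ordered 4-residue subsequences of the loop whose span skips at most
#' `max_bulge` residues (bulged-out positions), filtered to windows whose
#' first and fourth residues share a 1-4 interaction: a classified base pair
#' or a base-phosphate contact from base 1 onto the phosphate of residue 4.
#'
#' @param atoms A `tt_structure` atom tibble.
#' @param hairpin One row of [find_hairpins()].
#' @param max_bulge Maximum skipped residues within the window span.
#' @return Tibble with one row per window: `w1`..`w4` (chain-order indices),
#'   `bulged_idx` (list), `seq`, `pair_14` (lw code or `NA`), `bph_14`
#'   (class or `NA`).
#' @export
candidate_windows <- function(atoms, hairpin, max_bulge = 2) {
  rl <- .split_residues(atoms)
  loop_idx <- hairpin$loop_idx[[1]]
  if (length(loop_idx) < 4) return(tibble::tibble())
  combs <- utils::combn(loop_idx, 4, simplify = FALSE)
  out <- list()
  for (w in combs) {
    skipped <- setdiff(seq(w[1], w[4]), w)
    if (length(skipped) > max_bulge) next
    r1 <- rl[[w[1]]]
    r4 <- rl[[w[4]]]
    pr <- tryCatch(classify_pair(r1, r4), error = function(e) NULL)
    bph <- classify_bph(r1, r4)
    if (is.null(pr) && is.null(bph)) next
    out[[length(out) + 1]] <- tibble::tibble(
      w1 = w[1], w2 = w[2], w3 = w[3], w4 = w[4],
      bulged_idx = list(setdiff(loop_idx, w)),
      seq = paste(vapply(w, function(k) rl[[k]]$base[1], character(1)),
                  collapse = ""),
      pair_14 = if (is.null(pr)) NA_character_ else pr$lw_code,
      bph_14 = if (is.null(bph)) NA_character_ else bph$bph_class)
  }
  if (!length(out)) return(tibble::tibble())
  dplyr::bind_rows(out)
}
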