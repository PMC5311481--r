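# Corpus survey: fingerprints, redundancy elimination, count aggregation,
# oxygen-pi distance statistics.

# structural fingerprint over the window plus one flanking residue on each
# side: pucker classes, backbone torsion classes, syn/anti states
.fingerprint <- function(atoms, window_resno, chain) {
  rl <- .split_residues(atoms)
  resno_of <- vapply(rl, function(r) r$resno[1], integer(1))
  chain_of <- vapply(rl, function(r) r$chain[1], character(1))
  span <- c(min(window_resno) - 1, sort(window_resno), max(window_resno) + 1)
  feats <- vapply(span, function(no) {
    k <- which(resno_of == no & chain_of == chain)
    if (!length(k)) return(c("-", "-", "-"))
    r <- rl[[k[1]]]
    kp <- which(resno_of == no - 1 & chain_of == chain)
    kn <- which(resno_of == no + 1 & chain_of == chain)
    pk <- tryCatch(sugar_pucker(r)$class, error = function(e) "-")
    bb <- tryCatch(backbone_classes(if (length(kp)) rl[[kp[1]]] else NULL, r,
                                    if (length(kn)) rl[[kn[1]]] else NULL)$classes,
                   error = function(e) "-")
    sa <- tryCatch(glycosidic_state(r)$conformation, error = function(e) "-")
    c(pk, bb, sa)
  }, character(3))
  list(numbers = paste(span, collapse = ","),
       puckers = paste(feats[1, ], collapse = "|"),
       backbone = paste(feats[2, ], collapse = "|"),
       synanti = paste(feats[3, ], collapse = "|"))
}

#' Survey tetranucleotide turns over a corpus
#'
#' Annotates every input structure, attaches the structural fingerprint and
#' the window's mean B-factor to each record, eliminates redundant records,
#' and aggregates category counts and oxygen-pi distance statistics.
#'
#' @param inputs A character vector of file paths, or a list of
#'   `tt_structure` atom tibbles.
#' @param config Run parameters from [tt_config()].
#' @return An object of class `tt_survey`: list with `records` (all
#'   annotations + fingerprints + `keep` flags), `nonredundant`, `counts`
#'   ([aggregate_counts()]) and `stats` ([contact_statistics()]).
#' @export
survey_turns <- function(inputs, config = tt_config()) {
  if (is.character(inputs)) {
    inputs <- lapply(inputs, read_structure, model = config$model)
  }
  if (inherits(inputs, "tt_structure")) inputs <- list(inputs)
  recs <- list()
  for (x in inputs) {
    ann <- annotate_turns(x, config = config)
    if (nrow(ann) == 0) next
    for (r in seq_len(nrow(ann))) {
      win <- c(ann$res1[r], ann$res2[r], ann$res3[r], ann$res4[r])
      fp <- .fingerprint(x, win, ann$chain[r])
      watoms <- x[x$resno %in% win & x$chain == ann$chain[r], ]
      row <- ann[r, ]
      row$fp_numbers <- fp$numbers
      row$fp_puckers <- fp$puckers
      row$fp_backbone <- fp$backbone
      row$fp_synanti <- fp$synanti
      row$avg_b <- mean(watoms$b)
      recs[[length(recs) + 1]] <- row
    }
  }
  records <- if (length(recs)) dplyr::bind_rows(recs) else tibble::tibble()
  flt <- redundancy_filter(records)
  nonred <- flt[flt$keep %in% TRUE, , drop = FALSE]
  out <- list(records = flt, nonredundant = nonred,
              counts = aggregate_counts(nonred),
              stats = contact_statistics(nonred), config = config)
  class(out) <- "tt_survey"
  out
}

#' @export
print.tt_survey <- function(x, ...) {
  cat("<tt_survey>", nrow(x$records), "records,",
      nrow(x$nonredundant), "nonredundant\n")
  if (nrow(x$counts)) {
    tot <- dplyr::count(x$nonredundant, .data$category)
    for (i in seq_len(nrow(tot))) {
      cat(" ", tot$category[i], ":", tot$n[i], "\n")
    }
  }
  invisible(x)
}

#' Eliminate redundant survey records
#'
#' Two records are redundant when they share the window sequence, residue
#' numbers (window plus flanks), ribose pucker classes, backbone torsion
#' class strings and
#' syn/anti states, and either come from the same structure (multi-chain
#' copies) or carry the same chain code in different structures. Within a
#' redundancy group the record with the best (lowest) resolution is kept;
#' at matching resolution the lowest window-average B-factor wins; remaining
#' ties break lexicographically on (pdb_id, chain, residue number), which
#' for same-structure copies keeps the first chain. Records without a
#' resolution (NMR) never merge with resolved ones.
#'
#' @param records Survey record tibble (from [survey_turns()], or any table
#'   with the `fp_*`, `pdb_id`, `chain`, `resolution`, `avg_b` columns).
#' @return The input with `group` (redundancy group id) and `keep` columns.
#' @export
redundancy_filter <- function(records) {
  n <- nrow(records)
  if (n == 0) {
    return(dplyr::mutate(records, group = integer(0), keep = logical(0)))
  }
  fp <- paste(records$seq %||% "", records$fp_numbers, records$fp_puckers,
              records$fp_backbone, records$fp_synanti, sep = " / ")
  has_res <- is.finite(records$resolution)
  # union-find over the pairwise redundancy relation
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (fp[i] != fp[j]) next
      if (has_res[i] != has_res[j]) next
      same_structure <- records$pdb_id[i] == records$pdb_id[j]
      same_chain <- records$chain[i] == records$chain[j]
      if (same_structure || same_chain) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  group <- vapply(seq_len(n), find, integer(1))
  group <- match(group, unique(group))
  keep <- logical(n)
  for (g in unique(group)) {
    idx <- which(group == g)
    res <- records$resolution[idx]
    res[!is.finite(res)] <- Inf
    ord <- order(res, records$avg_b[idx], records$pdb_id[idx],
                 records$chain[idx], records$res1[idx])
    keep[idx[ord[1]]] <- TRUE
  }
  records$group <- group
  records$keep <- keep
  records
}

.seq_class <- function(seq4) {
  paste0(substr(seq4, 1, 1), "NN", substr(seq4, 4, 4))
}

#' Aggregate turn counts by category and sequence class
#'
#' @param records Nonredundant survey records.
#' @return A `tt_counts` tibble (long form): `category`, `seq_class`, `n`,
#'   including only observed combinations; marginals via
#'   [tidyr::pivot_wider()] or [glance.tt_survey()].
#' @export
aggregate_counts <- function(records) {
  if (nrow(records) == 0) {
    out <- tibble::tibble(category = character(0), seq_class = character(0),
                          n = integer(0))
  } else {
    out <- records |>
      dplyr::filter(.data$category %in% .turn_categories) |>
      dplyr::mutate(seq_class = .seq_class(.data$seq)) |>
      dplyr::count(.data$category, .data$seq_class)
  }
  class(out) <- c("tt_counts", class(tibble::tibble()))
  out
}

#' Oxygen-pi contact distance statistics
#'
#' Separate series for OP-pi and O4'-pi contacts: count, mean, population
#' and sample standard deviation, maximum, and a binned histogram.
#'
#' @param records Survey records carrying `oxy_kind` / `oxy_distance`.
#' @param bin_width Histogram bin width in Angstrom (default 0.1).
#' @return Tibble with one row per oxygen kind and a `histogram` list-column
#'   (`bin_left`, `count`); empty series are flagged (`defined = FALSE`).
#' @export
contact_statistics <- function(records, bin_width = 0.1) {
  base <- tibble::tibble(oxy_kind = c("OP", "O4'"))
  rows <- lapply(base$oxy_kind, function(k) {
    d <- if ("oxy_distance" %in% names(records)) {
      records$oxy_distance[records$oxy_kind %in% k]
    } else numeric(0)
    d <- d[is.finite(d)]
    if (!length(d)) {
      return(tibble::tibble(oxy_kind = k, n = 0L, defined = FALSE,
                            mean = NA_real_, sd_pop = NA_real_,
                            sd_sample = NA_real_, max = NA_real_,
                            histogram = list(tibble::tibble(
                              bin_left = numeric(0), count = integer(0)))))
    }
    breaks <- seq(floor(min(d) / bin_width) * bin_width,
                  ceiling(max(d) / bin_width) * bin_width + bin_width,
                  by = bin_width)
    cnt <- hist(d, breaks = breaks, plot = FALSE, right = FALSE)
    tibble::tibble(
      oxy_kind = k, n = length(d), defined = TRUE,
      mean = mean(d),
      sd_pop = sqrt(mean((d - mean(d))^2)),
      sd_sample = if (length(d) > 1) sd(d) else NA_real_,
      max = max(d),
      histogram = list(tibble::tibble(bin_left = cnt$breaks[-length(cnt$breaks)],
                                      count = cnt$counts)))
  })
  dplyr::bind_rows(rows)
}

# --- broom-style methods ----------------------------------------------------

#' Tidy a survey
#'
#' @param x A `tt_survey` object.
#' @param ... Unused.
#' @return The nonredundant annotation records as a tibble.
#' @export
tidy.tt_survey <- function(x, ...) tibble::as_tibble(x$nonredundant)

#' One-row survey summary
#'
#' @param x A `tt_survey` object.
#' @param ... Unused.
#' @return A one-row tibble: record totals, per-category nonredundant
#'   counts, and oxygen-pi distance means/maxima.
#' @export
glance.tt_survey <- function(x, ...) {
  counts <- setNames(
    lapply(.turn_categories, function(cc) sum(x$nonredundant$category == cc)),
    paste0("n_", tolower(.turn_categories)))
  st <- x$stats
  tibble::tibble(
    n_records = nrow(x$records),
    n_nonredundant = nrow(x$nonredundant),
    !!!counts,
    op_pi_mean = st$mean[st$oxy_kind == "OP"],
    op_pi_max = st$max[st$oxy_kind == "OP"],
    o4_pi_mean = st$mean[st$oxy_kind == "O4'"],
    o4_pi_max = st$max[st$oxy_kind == "O4'"])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Write survey outputs to files
#'
#' @param x A `tt_survey` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths: per-record annotations and
#'   the count table as CSV, distance statistics as JSON, histograms as
#'   two-column CSV.
#' @export
write_survey <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(records = file.path(dir, "records.csv"),
             counts = file.path(dir, "counts.csv"),
             stats = file.path(dir, "contact_stats.json"),
             hist_op = file.path(dir, "hist_op.csv"),
             hist_o4 = file.path(dir, "hist_o4.csv"))
  write.csv(dplyr::select(x$records, -dplyr::any_of("hbonds")),
            paths["records"], row.names = FALSE)
  write.csv(x$counts, paths["counts"], row.names = FALSE)
  st <- dplyr::select(x$stats, -"histogram")
  jsonlite::write_json(st, paths["stats"], auto_unbox = TRUE, digits = NA)
  for (k in c("OP", "O4'")) {
    h <- x$stats$histogram[[which(x$stats$oxy_kind == k)]]
    write.csv(h, paths[if (k == "OP") "hist_op" else "hist_o4"],
              row.names = FALSE)
  }
  invisible(paths)
}
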