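make_records <- function(n, base_seed = 1) {
  # synthetic survey records with controllable fingerprints
  set.seed(base_seed)
  tibble::tibble(
    pdb_id = paste0("S", sample(1:8, n, replace = TRUE)),
    chain = sample(c("A", "B"), n, replace = TRUE),
    resolution = sample(c(1.8, 2.4, 2.9), n, replace = TRUE),
    avg_b = stats::runif(n, 10, 70),
    res1 = 3L,
    category = sample(c("U", "Z_syn"), n, replace = TRUE),
    seq = sample(c("GAAA", "UUCG"), n, replace = TRUE),
    oxy_kind = "OP",
    oxy_distance = stats::runif(n, 2.7, 3.4),
    fp_numbers = "2,3,4,5,6,7",
    fp_puckers = sample(c("a|a|a|a|a|a", "b|b|b|b|b|b"), n, replace = TRUE),
    fp_backbone = "x|x|x|x|x|x",
    fp_synanti = sample(c("s", "t"), n, replace = TRUE)
  )
}

test_that("redundancy keeps the best resolution, then the lowest B", {
  rec <- make_records(2)
  rec$pdb_id <- c("S1", "S2")
  rec$chain <- "A"
  rec$seq <- "GAAA"
  rec$fp_puckers <- "a|a|a|a|a|a"
  rec$fp_synanti <- "s"
  rec$resolution <- c(2.9, 2.4)
  out <- redundancy_filter(rec)
  expect_equal(out$keep, c(FALSE, TRUE))

  rec$resolution <- c(2.4, 2.4)
  rec$avg_b <- c(45, 30)
  out2 <- redundancy_filter(rec)
  expect_equal(out2$keep, c(FALSE, TRUE))

  single <- redundancy_filter(rec[1, ])
  expect_true(single$keep)
})

test_that("same-structure multi-chain copies collapse to the first chain", {
  rec <- make_records(2)
  rec$pdb_id <- "S1"
  rec$chain <- c("B", "A")
  rec$seq <- "GAAA"
  rec$resolution <- 2.4
  rec$avg_b <- c(20, 20)
  rec$fp_puckers <- "a|a|a|a|a|a"
  rec$fp_synanti <- "s"
  out <- redundancy_filter(rec)
  expect_equal(out$keep[out$chain == "A"], TRUE)
  expect_equal(out$keep[out$chain == "B"], FALSE)
})

test_that("different fingerprints or cross-structure different chains stay", {
  rec <- make_records(2)
  rec$pdb_id <- c("S1", "S2")
  rec$chain <- c("A", "B")          # different chains, different structures
  rec$seq <- "GAAA"
  rec$fp_puckers <- "a|a|a|a|a|a"
  rec$fp_synanti <- "s"
  expect_true(all(redundancy_filter(rec)$keep))
  rec2 <- make_records(2)
  rec2$pdb_id <- c("S1", "S2")
  rec2$chain <- "A"
  rec2$fp_puckers <- c("a|a|a|a|a|a", "b|b|b|b|b|b")
  expect_true(all(redundancy_filter(rec2)$keep))
})

test_that("records with and without resolution never merge", {
  rec <- make_records(2)
  rec$pdb_id <- c("S1", "S2")
  rec$chain <- "A"
  rec$seq <- "GAAA"
  rec$fp_puckers <- "a|a|a|a|a|a"
  rec$fp_synanti <- "s"
  rec$resolution <- c(2.4, NA)
  expect_true(all(redundancy_filter(rec)$keep))
})

test_that("partition equals a brute-force quadratic oracle on 50 records", {
  rec <- make_records(50, base_seed = 17)
  out <- redundancy_filter(rec)
  # oracle: boolean relation matrix closed to a fixed point
  n <- nrow(rec)
  fp <- paste(rec$seq, rec$fp_numbers, rec$fp_puckers, rec$fp_backbone,
              rec$fp_synanti)
  rel <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
    fp[i] == fp[j] &&
      is.finite(rec$resolution[i]) == is.finite(rec$resolution[j]) &&
      (rec$pdb_id[i] == rec$pdb_id[j] || rec$chain[i] == rec$chain[j])
  }))
  repeat {
    rel2 <- rel | (rel %*% rel > 0)
    if (identical(rel2, rel)) break
    rel <- rel2
  }
  oracle_group <- apply(rel, 1, function(r) min(which(r)))
  expect_equal(match(out$group, unique(out$group)),
               match(oracle_group, unique(oracle_group)))
  # exactly one keeper per group, the oracle-best one
  for (g in unique(oracle_group)) {
    idx <- which(oracle_group == g)
    expect_equal(sum(out$keep[idx]), 1)
    res <- rec$resolution[idx]
    res[!is.finite(res)] <- Inf
    best <- idx[order(res, rec$avg_b[idx], rec$pdb_id[idx],
                      rec$chain[idx])][1]
    expect_true(out$keep[best])
  }
})

test_that("redundancy filtering is idempotent and order-invariant", {
  rec <- make_records(30, base_seed = 23)
  out <- redundancy_filter(rec)
  nonred <- out[out$keep, names(rec)]
  again <- redundancy_filter(nonred)
  expect_true(all(again$keep))
  set.seed(5)
  perm <- sample(nrow(rec))
  out_perm <- redundancy_filter(rec[perm, ])
  kept1 <- sort(paste(out$pdb_id[out$keep], out$chain[out$keep],
                      out$avg_b[out$keep]))
  kept2 <- sort(paste(out_perm$pdb_id[out_perm$keep],
                      out_perm$chain[out_perm$keep],
                      out_perm$avg_b[out_perm$keep]))
  expect_equal(kept1, kept2)
})

test_that("count aggregation matches a hand recount and conserves totals", {
  rec <- make_records(20, base_seed = 31)
  ct <- aggregate_counts(rec)
  expect_equal(sum(ct$n), 20)
  by_hand <- table(rec$category, paste0(substr(rec$seq, 1, 1), "NN",
                                        substr(rec$seq, 4, 4)))
  for (i in seq_len(nrow(ct))) {
    expect_equal(ct$n[i], unname(by_hand[ct$category[i], ct$seq_class[i]]))
  }
  empty <- aggregate_counts(make_records(0))
  expect_equal(nrow(empty), 0)
})

test_that("contact statistics report mean, sds, max and histogram", {
  rec <- tibble::tibble(oxy_kind = "OP", oxy_distance = c(2.9, 3.0, 3.1))
  st <- contact_statistics(rec)
  op <- st[st$oxy_kind == "OP", ]
  expect_equal(op$mean, 3.0)
  expect_equal(op$sd_pop, sqrt(mean((c(2.9, 3, 3.1) - 3)^2)))
  expect_equal(op$sd_pop, 0.1 * sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(op$sd_sample, sd(c(2.9, 3, 3.1)))
  expect_equal(op$max, 3.1)
  expect_equal(sum(op$histogram[[1]]$count), 3)
  o4 <- st[st$oxy_kind == "O4'", ]
  expect_false(o4$defined)
  expect_true(is.na(o4$mean))
})

test_that("survey over fixtures removes duplicated structures", {
  inputs <- list(
    make_turn("U", seed = 1, pdb_id = "SU1", resolution = 2.0),
    make_turn("U", seed = 1, pdb_id = "SU2", resolution = 2.6),  # duplicate
    make_turn("Z_syn", seed = 1, pdb_id = "SZ1"),
    make_turn("Z_anti", seed = 1, pdb_id = "SA1"),
    make_turn("U_SH", seed = 1, pdb_id = "SH1")
  )
  sv <- survey_turns(inputs)
  expect_equal(nrow(sv$records), 5)
  expect_equal(nrow(sv$nonredundant), 4)
  # the duplicate pair kept the better-resolution copy
  u_rec <- sv$records[sv$records$category == "U", ]
  expect_equal(u_rec$pdb_id[u_rec$keep], "SU1")
  expect_equal(sum(sv$counts$n), 4)
  g <- glance(sv)
  expect_equal(g$n_u, 1)
  expect_equal(g$n_z_syn, 1)
  expect_lte(g$op_pi_max, 3.5)
  td <- tidy(sv)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4)
})

test_that("survey outputs are invariant to corpus order", {
  inputs <- list(
    make_turn("U", seed = 2, pdb_id = "SU1"),
    make_turn("Z_syn", seed = 2, pdb_id = "SZ1"),
    make_turn("U_SH", seed = 2, pdb_id = "SH1")
  )
  s1 <- survey_turns(inputs)
  s2 <- survey_turns(rev(inputs))
  expect_equal(dplyr::arrange(s1$counts, .data$category),
               dplyr::arrange(s2$counts, .data$category))
  expect_equal(sort(s1$nonredundant$pdb_id), sort(s2$nonredundant$pdb_id))
})

test_that("survey file outputs are written", {
  dir <- withr::local_tempdir()
  sv <- survey_turns(list(make_turn("Z_syn", pdb_id = "SZ9")))
  paths <- write_survey(sv, dir)
  expect_true(all(file.exists(paths)))
  ct <- read.csv(paths["counts"])
  expect_equal(sum(ct$n), 1)
  h <- read.csv(paths["hist_o4"])
  expect_equal(names(h), c("bin_left", "count"))
})

test_that("plots build without error", {
  sv <- survey_turns(list(make_turn("Z_syn", pdb_id = "SZ8"),
                          make_turn("U", pdb_id = "SU8")))
  p1 <- autoplot(sv)
  expect_s3_class(p1, "ggplot")
  p2 <- autoplot(sv$counts)
  expect_s3_class(p2, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p1))
  expect_no_error(ggplot2::ggplot_build(p2))
})
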