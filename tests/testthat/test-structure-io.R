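test_that("a minimal single-residue mmCIF parses to one guanosine", {
  f <- withr::local_tempfile(fileext = ".cif")
  write_mini_guanosine_cif(f)
  x <- read_structure(f)
  expect_equal(length(unique(x$resno)), 1)
  expect_equal(unique(x$base), "G")
  expect_equal(nrow(x), 23)
  expect_equal(structure_meta(x)$resolution, 1.5)
})

test_that("empty and malformed files raise parse errors", {
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(character(0), f)
  expect_error(read_structure(f), "empty")
  writeLines(c("not", "a structure"), f)
  expect_error(read_structure(f), "parse error")
  expect_error(read_structure(file.path(tempdir(), "nope.cif")), "not found")
})

test_that("fixture structures round-trip through mmCIF", {
  for (kind in c("U", "Z_syn")) {
    f <- withr::local_tempfile(fileext = ".cif")
    x <- make_turn(kind, file = f)
    y <- read_structure(f)
    expect_equal(nrow(y), nrow(x))
    m <- merge(as.data.frame(x), as.data.frame(y),
               by = c("chain", "resno", "atom"))
    expect_equal(nrow(m), nrow(x))
    expect_lt(max(abs(m$x.x - m$x.y), abs(m$y.x - m$y.y),
                  abs(m$z.x - m$z.y)), 1e-3)
    # re-reading a written copy yields the same residues again (idempotence)
    f2 <- withr::local_tempfile(fileext = ".cif")
    attr(y, "meta") <- structure_meta(x)
    write_structure_cif(y, f2)
    z <- read_structure(f2)
    expect_equal(nrow(z), nrow(y))
    m2 <- merge(as.data.frame(y), as.data.frame(z),
                by = c("chain", "resno", "atom"))
    expect_lt(max(abs(m2$x.x - m2$x.y)), 1e-9 + 1e-3)
  }
})

test_that("gzip-compressed files are read transparently", {
  f <- withr::local_tempfile(fileext = ".cif")
  x <- make_turn("U", file = f)
  fgz <- paste0(f, ".gz")
  con <- gzfile(fgz, "w")
  writeLines(readLines(f), con)
  close(con)
  y <- read_structure(fgz)
  expect_equal(nrow(y), nrow(x))
})

test_that("ground-truth JSON sidecar is written alongside the structure", {
  f <- withr::local_tempfile(fileext = ".cif")
  make_turn("Z_anti", file = f)
  gt <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(gt$expected_category, "Z_anti")
  expect_equal(gt$sequence, "CUUG")
})

test_that("quality filter applies the B-factor and resolution criteria", {
  x <- make_turn("U")
  win <- attr(x, "ground_truth")$window_resno
  w <- x[x$resno %in% win, ]
  meta <- structure_meta(x)

  expect_true(quality_filter(w, meta)$accept)

  w2 <- w
  w2$b[5] <- 80
  res <- quality_filter(w2, meta, max_b = 79)
  expect_false(res$accept)
  expect_match(res$reason, "B-factor")
  expect_match(res$reason, w2$atom[5], fixed = TRUE)

  w3 <- w
  w3$b <- 0
  expect_true(quality_filter(w3, meta)$accept)

  meta_bad <- meta
  meta_bad$resolution <- 3.2
  res2 <- quality_filter(w, meta_bad, max_resolution = 3.0)
  expect_false(res2$accept)
  expect_match(res2$reason, "resolution")
})

test_that("quality filter is monotone in max_b", {
  x <- make_turn("U")
  win <- attr(x, "ground_truth")$window_resno
  w <- x[x$resno %in% win, ]
  meta <- structure_meta(x)
  set.seed(5)
  w$b <- stats::runif(nrow(w), 10, 90)
  bstar <- max(w$b)
  for (mb in c(bstar, bstar + 1, bstar + 20)) {
    expect_true(quality_filter(w, meta, max_b = mb)$accept)
  }
  expect_false(quality_filter(w, meta, max_b = bstar - 0.5)$accept)
})

test_that("multi-model PDB input honours model selection", {
  x <- make_turn("Z_syn")
  f <- withr::local_tempfile(fileext = ".pdb")
  # two-model PDB written by hand from the fixture coordinates
  fmt <- function(a, serial, shift) {
    sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, a$atom, a$resname, a$chain, a$resno,
            a$x + shift, a$y, a$z, a$occ, a$b, a$elem)
  }
  lines <- c("MODEL        1",
             vapply(seq_len(nrow(x)), function(i) fmt(x[i, ], i, 0), ""),
             "ENDMDL", "MODEL        2",
             vapply(seq_len(nrow(x)), function(i) fmt(x[i, ], i, 100), ""),
             "ENDMDL", "END")
  writeLines(lines, f)
  m1 <- read_structure(f, model = 1)
  m2 <- read_structure(f, model = 2)
  expect_equal(nrow(m1), nrow(x))
  expect_equal(mean(m2$x) - mean(m1$x), 100, tolerance = 1e-3)
  expect_error(read_structure(f, model = 3), "available models")
})

test_that("altlocs resolve to the highest-occupancy copy", {
  f <- withr::local_tempfile(fileext = ".cif")
  write_mini_guanosine_cif(f)
  lines <- readLines(f)
  i <- grep("^ATOM 1 ", lines)
  fields <- strsplit(lines[i], " +")[[1]]
  # atom_site columns: 5 = label_alt_id, 11:13 = xyz, 14 = occupancy
  fa <- fields; fa[5] <- "A"; fa[14] <- "0.40"
  fb <- fields; fb[5] <- "B"; fb[14] <- "0.60"; fb[11] <- "99.000"
  lines[i] <- paste(fa, collapse = " ")
  writeLines(append(lines, paste(fb, collapse = " "), after = i), f)
  x <- read_structure(f)
  expect_equal(nrow(x), 23)   # still one copy of each atom
  atom1 <- x[x$atom == gsub('"', "", fields[4]), ]
  expect_equal(atom1$x, 99, tolerance = 1e-6)
})

test_that("non-nucleotide residues go to the side channel", {
  f <- withr::local_tempfile(fileext = ".cif")
  write_mini_guanosine_cif(f)
  lines <- readLines(f)
  water <- "ATOM 999 O O . HOH A 1 50 ? 0.000 0.000 0.000 1.00 10.00 50 HOH A O 1"
  writeLines(append(lines, water, after = length(lines) - 1), f)
  x <- read_structure(f)
  expect_false(any(x$resname == "HOH"))
  other <- attr(x, "other_atoms")
  expect_true(any(other$resname == "HOH"))
})

test_that("modified bases map to parent bases", {
  tab <- modified_base_table()
  expect_equal(tab$base[tab$code == "PSU"], "U")
  expect_equal(tab$base[tab$code == "1MA"], "A")
  expect_equal(tab$base[tab$code == "OMG"], "G")
  f <- withr::local_tempfile(fileext = ".cif")
  write_mini_guanosine_cif(f)
  lines <- gsub(" G A ", " OMG A ", readLines(f))
  lines <- gsub(" G 1 ", " OMG 1 ", lines)
  writeLines(lines, f)
  x <- read_structure(f)
  expect_equal(unique(x$base), "G")
  expect_equal(unique(x$resname), "OMG")
})
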