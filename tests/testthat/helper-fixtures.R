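# Shared fixture access. make_turn() caches its clean template per session,
# so repeated calls across test files are cheap.

archetype <- function(kind, ...) make_turn(kind, ...)

window_residues <- function(x) {
  win <- attr(x, "ground_truth")$window_resno
  lapply(win, function(i) x[x$resno == i, ])
}

first_category <- function(x, config = tt_config()) {
  ann <- annotate_turns(x, config = config)
  if (nrow(ann) == 0) "no-window" else ann$category[1]
}

random_rigid_transform <- function() {
  ax <- stats::rnorm(3)
  R <- rotation_about(ax / sqrt(sum(ax^2)), stats::runif(1, 0, 360))
  list(R = R, t = stats::rnorm(3, sd = 10))
}

rotation_about <- function(u, theta_deg) {
  th <- theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

transform_atoms <- function(atoms, R, t) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1] + t[1]
  atoms$y <- xyz[, 2] + t[2]
  atoms$z <- xyz[, 3] + t[3]
  atoms
}

# minimal hand-written mmCIF: one guanosine, 23 heavy atoms
write_mini_guanosine_cif <- function(path) {
  x <- make_turn("U")          # borrow one G residue's coordinates
  g <- x[x$resno == 1, ]
  g$resname <- "G"
  meta <- structure_meta(x)
  attr(g, "meta") <- list(pdb_id = "MINI", method = "X-RAY DIFFRACTION",
                          resolution = 1.5)
  write_structure_cif(g, path)
  path
}
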