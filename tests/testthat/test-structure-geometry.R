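test_that("ideal helix axes are recovered to within a degree", {
  h <- build_ideal_helix(20)
  ax <- fit_helix_axis(h)
  expect_equal(sqrt(sum(ax$axis^2)), 1, tolerance = 1e-9)
  expect_lt(tilt_angle(ax$axis, c(0, 0, 1)), 1)

  r30 <- rotation_matrix(c(1, 0, 0), 30)
  ax30 <- fit_helix_axis(h %*% t(r30))
  expect_equal(tilt_angle(ax30$axis, c(0, 0, 1)), 30, tolerance = 1)

  expect_error(fit_helix_axis(h[1:2, ]), "at least 5")
  expect_error(fit_helix_axis(matrix(1, 6, 3)), "degenerate")
})

test_that("axis fitting is invariant to residue-order reversal", {
  h <- build_ideal_helix(24) %*% t(rotation_matrix(c(0, 1, 0), 20))
  a1 <- fit_helix_axis(h)
  a2 <- fit_helix_axis(h[nrow(h):1, ])
  expect_lt(tilt_angle(a1$axis, a2$axis), 1e-6)
})

test_that("the trimer C3 axis is recovered from chain superposition", {
  tri <- build_synthetic_trimer(n_res = 60)
  c3 <- trimer_c3_axis(tri)
  expect_lt(tilt_angle(c3$axis, c(0, 0, 1)), 1e-6)
  expect_equal(c3$rotation_angle_deg, 120, tolerance = 1e-6)
  expect_lt(c3$consistency_deg, 1e-6)
})

test_that("the C3 axis is equivariant under rigid rotation", {
  tri <- build_synthetic_trimer(n_res = 60)
  r <- rotation_matrix(c(1, 2, 0.5), 37)
  atoms <- tri$atoms
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(r)
  atoms[, c("x", "y", "z")] <- xyz
  c3r <- trimer_c3_axis(structure_model(atoms))
  expect_lt(tilt_angle(c3r$axis, as.numeric(r %*% c(0, 0, 1))), 1e-6)
})

test_that("the C3 axis tolerates coordinate jitter", {
  tri <- build_synthetic_trimer(n_res = 60)
  set.seed(9)
  atoms <- tri$atoms
  atoms$x <- atoms$x + rnorm(nrow(atoms), 0, 0.2)
  atoms$y <- atoms$y + rnorm(nrow(atoms), 0, 0.2)
  atoms$z <- atoms$z + rnorm(nrow(atoms), 0, 0.2)
  c3 <- trimer_c3_axis(structure_model(atoms))
  expect_lt(tilt_angle(c3$axis, c(0, 0, 1)), 1)
})

test_that("short or mismatched chains are refused", {
  tri <- build_synthetic_trimer(n_res = 30) # < 50 matched CA
  expect_error(trimer_c3_axis(tri), "50 matched")
  expect_error(trimer_c3_axis(build_synthetic_trimer(60), chains = c("A", "B")),
               "3 chains")
})

test_that("tilt angles fold into [0, 90] and ignore axis sign", {
  expect_equal(tilt_angle(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(tilt_angle(c(1, 0, 0), c(0, 0, 1)), 90)
  expect_equal(tilt_angle(c(0, 0, -1), c(0, 0, 1)), 0) # antiparallel folds
  expect_error(tilt_angle(c(0, 0, 0), c(0, 0, 1)), "zero")
  # invariant under a global rotation applied to both axes
  r <- rotation_matrix(c(1, 1, 1), 50)
  a <- c(0.3, -0.2, 0.93)
  b <- c(0, 0, 1)
  expect_equal(tilt_angle(as.numeric(r %*% a), as.numeric(r %*% b)),
               tilt_angle(a, b), tolerance = 1e-9)
})

test_that("helix tilt tables recover constructed span tilts", {
  # monomer: one upright helix and one tilted by 25 degrees about y
  up <- sweep(build_ideal_helix(30), 2, c(-14, 0, 0))
  tilted <- build_ideal_helix(30) %*%
    t(rotation_matrix(c(0, 1, 0), 25))
  tilted <- sweep(tilted, 2, c(-6, 3, 0))
  tri <- build_synthetic_trimer(monomer = rbind(up, tilted))
  spans <- data.frame(label = c("M1", "M2"), chain = "A",
                      start = c(1, 31), end = c(30, 60))
  tab <- helix_tilt_table(tri, spans)
  expect_equal(tab$eta_deg[tab$label == "M1"], 0, tolerance = 1)
  expect_equal(tab$eta_deg[tab$label == "M2"], 25, tolerance = 1)
  expect_true(all(tab$eta_deg >= 0 & tab$eta_deg <= 90))
})

test_that("helix span TSV round-trips", {
  spans <- data.frame(label = c("M2a", "M2b"), chain = c("A", "A"),
                      start = c(40, 58), end = c(56, 70),
                      stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_helix_spans(spans, path)
  expect_equal(read_helix_spans(path), spans)
})

test_that("pore profiles classify by the strict radius thresholds", {
  prof <- data.frame(z = 1:6, radius = c(3.0, 1.0, 3.0, 0.9, 0.8, 3.0))
  cls <- classify_pore_profile(prof)
  expect_equal(nrow(cls$constrictions), 2) # two separate gates
  expect_equal(cls$constrictions$min_radius, c(1.0, 0.8))
  expect_equal(cls$profile$class,
               c("wide", "constricted", "wide", "constricted",
                 "constricted", "wide"))

  all_wide <- classify_pore_profile(data.frame(z = 1:4, radius = 3))
  expect_equal(nrow(all_wide$constrictions), 0)
  expect_true(all(all_wide$profile$class == "wide"))

  # boundary contract: thresholds themselves are 'intermediate'
  edge <- classify_pore_profile(data.frame(z = 1:3,
                                           radius = c(1.15, 2.30, 2.31)))
  expect_equal(edge$profile$class,
               c("intermediate", "intermediate", "wide"))

  expect_error(classify_pore_profile(data.frame(z = c(1, 3, 2),
                                                radius = c(1, 1, 1))),
               "monotone")
  expect_error(classify_pore_profile(data.frame(z = 1:2,
                                                radius = c(1, 0))),
               "> 0")
})

test_that("pore profile TSV reads with or without header", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("z_A\tradius_A", "-5\t3.2", "-4\t1.1", "-3\t2.0"), path)
  prof <- read_pore_profile(path)
  expect_equal(names(prof), c("z", "radius"))
  expect_equal(nrow(prof), 3)
  cls <- classify_pore_profile(prof)
  expect_equal(cls$profile$class, c("wide", "constricted", "intermediate"))
})

test_that("coordination contacts use a closed ball and sort by distance", {
  at <- function(x, y, z, atom = "O", element = "O", resno = 1) {
    data.frame(chain = "A", resno = resno, resid = "HOH", atom = atom,
               element = element, x = x, y = y, z = z,
               stringsAsFactors = FALSE)
  }
  s <- structure_model(rbind(at(2.9, 0, 0, resno = 3),
                             at(0, 2.7, 0, resno = 1),
                             at(0, 0, 2.8, resno = 2),
                             at(3.5, 0, 0, atom = "N", element = "N",
                                resno = 4),
                             at(0.5, 0, 0, atom = "H1", element = "H",
                                resno = 5),
                             at(10, 0, 0, resno = 6)))
  cc <- coordination_contacts(s, center = c(0, 0, 0), cutoff = 3.5)
  expect_equal(cc$distance, c(2.7, 2.8, 2.9, 3.5)) # cutoff included
  expect_equal(cc$resno, c(1, 2, 3, 4))
  expect_false(any(grepl("^H", cc$atom))) # hydrogens excluded
  cc_h <- coordination_contacts(s, c(0, 0, 0), 3.5,
                                exclude_hydrogen = FALSE)
  expect_equal(nrow(cc_h), 5)
  expect_error(coordination_contacts(s, c(0, 0, 0), cutoff = 0), "cutoff")
})

test_that("structures written as PDB text are read back faithfully", {
  tri <- build_synthetic_trimer(n_res = 60)
  path <- withr::local_tempfile(fileext = ".pdb")
  a <- tri$atoms
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(a)), a$chain, a$resno, a$x, a$y, a$z)
  writeLines(c(lines, "END"), path)
  s <- read_structure(path)
  expect_equal(sort(unique(s$atoms$chain)), c("A", "B", "C"))
  expect_equal(nrow(s$atoms), nrow(a))
  c3 <- trimer_c3_axis(s)
  expect_lt(tilt_angle(c3$axis, c(0, 0, 1)), 0.1)
})
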