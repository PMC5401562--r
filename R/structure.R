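#' Read an atomic structure from PDB or mmCIF
#'
#' Thin wrapper over [bio3d::read.pdb()] / [bio3d::read.cif()] returning the
#' flat atom table this package's geometry functions consume.
#'
#' @param path path to a `.pdb` or `.cif` file.
#' @param ... passed to the bio3d reader.
#' @return An object of class `"structure_model"`: list with `atoms` (data
#'   frame: `chain`, `resno`, `resid`, `atom`, `element`, `x`, `y`, `z`) and
#'   `source`.
#' @export
read_structure <- function(path, ...) {
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif"))
    bio3d::read.cif(path, ...) else bio3d::read.pdb(path, ...)
  a <- pdb$atom
  structure_model(
    data.frame(chain = a$chain, resno = a$resno, resid = a$resid,
               atom = a$elety,
               element = if (!is.null(a$elesy)) a$elesy else
                 substr(trimws(a$elety), 1, 1),
               x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE),
    source = basename(path)
  )
}

#' Construct a structure model from an atom table
#'
#' @param atoms data frame with columns `chain`, `resno`, `resid`, `atom`,
#'   `element`, `x`, `y`, `z` (coordinates in Angstrom).
#' @param source identifier string.
#' @return A `"structure_model"`.
#' @export
structure_model <- function(atoms, source = "synthetic") {
  need <- c("chain", "resno", "resid", "atom", "element", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("'atoms' must have columns: ", paste(need, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("coordinates must be finite")
  structure(list(atoms = atoms, source = source),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure model '%s': %d atoms, chains %s\n", x$source,
              nrow(x$atoms),
              paste(unique(x$atoms$chain), collapse = " ")))
  invisible(x)
}

# C-alpha coordinates of one chain, ordered by residue number.
.chain_ca <- function(structure, chain, resno = NULL) {
  a <- structure$atoms
  sel <- a$chain == chain & trimws(a$atom) == "CA"
  if (!is.null(resno)) sel <- sel & a$resno %in% resno
  a <- a[sel, , drop = FALSE]
  a <- a[order(a$resno), , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$resno
  m
}

#' Fit the axis of a helical segment
#'
#' Dominant principal direction of the centred C-alpha cloud (first
#' right-singular vector), the standard straight-axis estimate for a
#' transmembrane helix span. For kinked helices, fit the sub-segments
#' separately. The axis orientation is normalised to have a positive
#' component along `reference` so tilt angles are well defined.
#'
#' @param coords numeric matrix (n x 3) of C-alpha coordinates, Angstrom;
#'   n >= 5.
#' @param reference reference direction used only to fix the axis sign
#'   (default +z, i.e. the membrane normal / C3 axis convention).
#' @return List with `axis` (unit 3-vector) and `centroid`.
#' @export
fit_helix_axis <- function(coords, reference = c(0, 0, 1)) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 5)
    stop("need at least 5 C-alpha positions to fit a helix axis")
  centroid <- colMeans(coords)
  x0 <- sweep(coords, 2, centroid)
  s <- svd(x0)
  if (s$d[1] < 1e-8) stop("degenerate coordinates: no principal direction")
  axis <- s$v[, 1]
  if (sum(axis * reference) < 0) axis <- -axis
  list(axis = axis, centroid = centroid)
}

#' Three-fold symmetry axis of a trimer
#'
#' The C3 axis is recovered as the rotation axis of the least-squares rigid
#' superposition (Kabsch) mapping the first chain onto the second; the
#' first-onto-third superposition serves as a consistency check, with a
#' warning when the two axis estimates differ by more than `tol_deg`. The
#' axis passes through the joint C-alpha centroid of the three chains.
#'
#' @param structure a `"structure_model"`.
#' @param chains three chain identifiers with matching residue numbering.
#' @param tol_deg consistency warning threshold, degrees.
#' @return List with `axis` (unit 3-vector, sign normalised so its
#'   largest-magnitude component is positive), `centroid`,
#'   `rotation_angle_deg` (should be near 120), `consistency_deg`.
#' @export
trimer_c3_axis <- function(structure, chains = NULL, tol_deg = 2) {
  stopifnot(inherits(structure, "structure_model"))
  if (is.null(chains)) chains <- unique(structure$atoms$chain)
  if (length(chains) != 3) stop("exactly 3 chains required")
  cas <- lapply(chains, function(ch) .chain_ca(structure, ch))
  common <- Reduce(intersect, lapply(cas, rownames))
  if (length(common) < 50)
    stop("fewer than 50 matched C-alpha atoms across the chains")
  m <- lapply(cas, function(x) x[common, , drop = FALSE])
  r_ab <- .kabsch_rotation(m[[1]], m[[2]])
  r_ac <- .kabsch_rotation(m[[1]], m[[3]])
  ax1 <- .rotation_axis(r_ab)
  ax2 <- .rotation_axis(r_ac)
  consistency <- tilt_angle(ax1, ax2)
  if (consistency > tol_deg)
    warning(sprintf(
      "A->B and A->C symmetry axes differ by %.2f degrees", consistency))
  imax <- which.max(abs(ax1))
  if (ax1[imax] < 0) ax1 <- -ax1
  ang <- acos(pmin(1, pmax(-1, (sum(diag(r_ab)) - 1) / 2))) * 180 / pi
  list(axis = ax1, centroid = colMeans(do.call(rbind, m)),
       rotation_angle_deg = ang, consistency_deg = consistency)
}

# Optimal rotation R such that Q0 ~ P0 %*% t(R) after centring.
.kabsch_rotation <- function(p, q) {
  p0 <- sweep(p, 2, colMeans(p))
  q0 <- sweep(q, 2, colMeans(q))
  h <- t(p0) %*% q0
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

# Rotation axis of a 3x3 rotation matrix (angle != 0, 180).
.rotation_axis <- function(r) {
  v <- c(r[3, 2] - r[2, 3], r[1, 3] - r[3, 1], r[2, 1] - r[1, 2])
  nv <- sqrt(sum(v^2))
  if (nv < 1e-8) {
    e <- eigen(r)
    i <- which.min(abs(e$values - 1))
    v <- Re(e$vectors[, i])
    nv <- sqrt(sum(v^2))
  }
  v / nv
}

#' Tilt angle between a helix axis and a reference axis
#'
#' The angle eta between two axis directions, folded into \[0, 90\] degrees
#' (an axis has no preferred sign, so antiparallel vectors give 0).
#'
#' @param helix_axis,reference_axis numeric 3-vectors (need not be unit
#'   length, but must be nonzero).
#' @return Angle in degrees, in \[0, 90\].
#' @export
tilt_angle <- function(helix_axis, reference_axis) {
  na <- sqrt(sum(helix_axis^2))
  nb <- sqrt(sum(reference_axis^2))
  if (na < 1e-12 || nb < 1e-12) stop("zero-length axis vector")
  acos(pmin(1, abs(sum(helix_axis * reference_axis)) / (na * nb))) *
    180 / pi
}

#' Helix tilt table for a trimeric structure
#'
#' Fits each transmembrane helix span independently (see
#' [fit_helix_axis()]; kinked helices should be supplied as separate a/b
#' sub-spans) and reports its tilt angle eta against the trimer C3 axis.
#'
#' @param structure a `"structure_model"`.
#' @param spans data frame with columns `label`, `chain`, `start`, `end`
#'   (residue numbers, inclusive), e.g. from [read_helix_spans()].
#' @param chains chains defining the C3 axis (default: all, must be 3).
#' @param c3 optional precomputed [trimer_c3_axis()] result.
#' @return Data frame with columns `label`, `chain`, `start`, `end`,
#'   `eta_deg`.
#' @export
helix_tilt_table <- function(structure, spans, chains = NULL, c3 = NULL) {
  stopifnot(inherits(structure, "structure_model"))
  need <- c("label", "chain", "start", "end")
  if (!all(need %in% names(spans)))
    stop("'spans' must have columns: ", paste(need, collapse = ", "))
  if (is.null(c3)) c3 <- trimer_c3_axis(structure, chains)
  eta <- vapply(seq_len(nrow(spans)), function(i) {
    coords <- .chain_ca(structure, spans$chain[i],
                        resno = spans$start[i]:spans$end[i])
    ax <- fit_helix_axis(coords, reference = c3$axis)
    tilt_angle(ax$axis, c3$axis)
  }, numeric(1))
  data.frame(label = spans$label, chain = spans$chain,
             start = spans$start, end = spans$end, eta_deg = eta,
             stringsAsFactors = FALSE)
}

#' Read / write helix span definitions as TSV
#'
#' Columns `label`, `chain`, `start`, `end`.
#'
#' @param spans span data frame.
#' @param path file path.
#' @export
write_helix_spans <- function(spans, path) {
  utils::write.table(spans, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_helix_spans
#' @export
read_helix_spans <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Classify a pore-radius profile into constriction classes
#'
#' Labels each axial position of a pore-radius profile (as produced by a
#' pore-tracing program) as `constricted` (radius < `thresholds[1]`),
#' `intermediate` or `wide` (radius > `thresholds[2]`); radii exactly at a
#' threshold are `intermediate` (the class bounds are strict). Maximal runs
#' of constricted positions are reported as constriction sites (gates) with
#' their minimum radius and axial extent. The default thresholds 1.15 and
#' 2.30 Angstrom are the radius of a dehydrated and a hydrated K+ ion.
#'
#' @param profile data frame whose first two columns are axial coordinate
#'   (Angstrom, strictly monotone) and radius (Angstrom, > 0), e.g. from
#'   [read_pore_profile()].
#' @param thresholds length-2 increasing numeric vector, Angstrom.
#' @return An object of class `"pore_classification"`: list with `profile`
#'   (input plus a `class` column) and `constrictions` (data frame: `z_min`,
#'   `z_max`, `min_radius`, `n_points`).
#' @export
classify_pore_profile <- function(profile, thresholds = c(1.15, 2.30)) {
  z <- profile[[1]]
  r <- profile[[2]]
  if (length(z) == 0) stop("empty profile")
  if (any(r <= 0)) stop("radii must be > 0")
  dz <- diff(z)
  if (length(dz) && !(all(dz > 0) || all(dz < 0)))
    stop("axial coordinate must be strictly monotone")
  if (length(thresholds) != 2 || thresholds[1] >= thresholds[2])
    stop("'thresholds' must be two increasing values")
  cls <- ifelse(r < thresholds[1], "constricted",
                ifelse(r > thresholds[2], "wide", "intermediate"))
  runs <- rle(cls == "constricted")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ci <- which(runs$values)
  constrictions <- data.frame(
    z_min = vapply(ci, function(i) min(z[starts[i]:ends[i]]), numeric(1)),
    z_max = vapply(ci, function(i) max(z[starts[i]:ends[i]]), numeric(1)),
    min_radius = vapply(ci, function(i) min(r[starts[i]:ends[i]]),
                        numeric(1)),
    n_points = runs$lengths[ci]
  )
  out <- data.frame(z = z, radius = r, class = cls,
                    stringsAsFactors = FALSE)
  structure(list(profile = out, constrictions = constrictions,
                 thresholds = thresholds),
            class = "pore_classification")
}

#' @export
print.pore_classification <- function(x, ...) {
  tab <- table(factor(x$profile$class,
                      levels = c("constricted", "intermediate", "wide")))
  cat(sprintf(
    "Pore profile: %d points (%d constricted, %d intermediate, %d wide); %d constriction site(s)\n",
    nrow(x$profile), tab[1], tab[2], tab[3], nrow(x$constrictions)))
  if (nrow(x$constrictions)) print(x$constrictions, digits = 3)
  invisible(x)
}

#' Read a pore-radius profile TSV
#'
#' Two columns: axial coordinate and radius (Angstrom), with or without a
#' header.
#'
#' @param path file path.
#' @return Data frame with columns `z` and `radius`.
#' @export
read_pore_profile <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- !grepl("^\\s*-?[0-9.]", first)
  dat <- utils::read.table(path, header = has_header, sep = "\t",
                           comment.char = "#")
  stats::setNames(dat[, 1:2], c("z", "radius"))
}

#' Coordination contacts around a point
#'
#' All non-hydrogen atoms within `cutoff` Angstrom (closed ball: a distance
#' exactly equal to the cutoff is included) of a centre point, sorted by
#' distance -- the usual way of listing the coordination shell of an ion or
#' water site.
#'
#' @param structure a `"structure_model"`.
#' @param center numeric 3-vector, Angstrom.
#' @param cutoff Angstrom, > 0.
#' @param exclude_hydrogen drop hydrogen atoms (default TRUE).
#' @return Data frame with columns `chain`, `resno`, `resid`, `atom`,
#'   `distance`, sorted ascending by distance.
#' @export
coordination_contacts <- function(structure, center, cutoff = 3.5,
                                  exclude_hydrogen = TRUE) {
  stopifnot(inherits(structure, "structure_model"))
  if (!is.numeric(cutoff) || cutoff <= 0) stop("'cutoff' must be > 0")
  a <- structure$atoms
  if (exclude_hydrogen)
    a <- a[!(toupper(trimws(a$element)) %in% c("H", "D")), , drop = FALSE]
  d <- sqrt((a$x - center[1])^2 + (a$y - center[2])^2 +
              (a$z - center[3])^2)
  keep <- d <= cutoff + 1e-9
  out <- data.frame(chain = a$chain[keep], resno = a$resno[keep],
                    resid = a$resid[keep], atom = a$atom[keep],
                    distance = d[keep], stringsAsFactors = FALSE)
  out[order(out$distance), , drop = FALSE]
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation matrix; a small geometry utility used when building
#' and testing synthetic assemblies.
#'
#' @param axis 3-vector (normalised internally).
#' @param angle_deg rotation angle, degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  kx <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * kx + (1 - cos(th)) * (kx %*% kx)
}

#' Build an ideal alpha-helix C-alpha trace
#'
#' Canonical helical geometry: 1.5 Angstrom rise and 100 degrees twist per
#' residue on a 2.3 Angstrom radius, running along +z. Used as a synthetic
#' fixture for axis-fitting.
#'
#' @param n_res number of residues (>= 2).
#' @param rise rise per residue, Angstrom.
#' @param twist twist per residue, degrees.
#' @param radius helix radius, Angstrom.
#' @return n_res x 3 coordinate matrix.
#' @export
build_ideal_helix <- function(n_res = 20, rise = 1.5, twist = 100,
                              radius = 2.3) {
  i <- seq_len(n_res) - 1
  th <- i * twist * pi / 180
  cbind(x = radius * cos(th), y = radius * sin(th), z = i * rise)
}

#' Build a synthetic C3-symmetric trimer
#'
#' Places three copies of a C-alpha monomer (an ideal helix offset from the
#' symmetry axis) related by exact 120-degree rotations about +z. A labelled
#' synthetic stand-in for a deposited trimer, used to validate the symmetry
#' and tilt machinery.
#'
#' @param n_res residues per chain (>= 50 for [trimer_c3_axis()]).
#' @param offset radial offset of the monomer from the symmetry axis,
#'   Angstrom.
#' @param monomer optional n x 3 coordinate matrix overriding the default
#'   helix monomer.
#' @return A `"structure_model"` with chains A, B, C.
#' @export
build_synthetic_trimer <- function(n_res = 60, offset = 12,
                                   monomer = NULL) {
  if (is.null(monomer))
    monomer <- sweep(build_ideal_helix(n_res), 2, c(-offset, 0, 0))
  n <- nrow(monomer)
  chains <- c("A", "B", "C")
  pieces <- lapply(0:2, function(i) {
    r <- rotation_matrix(c(0, 0, 1), 120 * i)
    xyz <- monomer %*% t(r)
    data.frame(chain = chains[i + 1], resno = seq_len(n), resid = "ALA",
               atom = "CA", element = "C",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE)
  })
  structure_model(do.call(rbind, pieces), source = "synthetic-trimer")
}
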