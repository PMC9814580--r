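#' Read a Gaussian CUBE electron-density file
#'
#' Standard format: two comment lines; a record with the atom count and grid
#' origin (bohr); three axis records (voxel count and step vector per axis);
#' one record per atom (atomic number, nuclear charge, position); then the
#' volumetric values in Fortran order (z fastest).
#'
#' @param path CUBE file path.
#' @return An object of class `cube_grid` with fields `origin`, `axes`
#'   (3 x 3, rows are voxel step vectors, bohr), `counts`, `atoms`
#'   (data.frame: `z`, `charge`, `x`, `y`, `z_pos`), `values` (3D array
#'   indexed \[ix, iy, iz\]) and `total_density` (sum * voxel volume).
#' @export
read_cube <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7L) stop("CUBE parse error: file truncated in header", call. = FALSE)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]))
    if (anyNA(v)) stop("CUBE parse error in ", what, " record (line ", i, ")",
                       call. = FALSE)
    v
  }
  hdr <- num(3L, "natoms/origin")
  natoms <- as.integer(hdr[1])
  if (is.na(natoms) || natoms <= 0L) {
    stop("CUBE parse error: non-positive atom count in header", call. = FALSE)
  }
  origin <- hdr[2:4]
  counts <- integer(3)
  axes <- matrix(0, 3, 3)
  for (a in 1:3) {
    v <- num(3L + a, paste0("axis ", a))
    counts[a] <- as.integer(v[1])
    if (is.na(counts[a]) || counts[a] <= 0L) {
      stop("CUBE parse error: non-positive voxel count in axis ", a, " record",
           call. = FALSE)
    }
    axes[a, ] <- v[2:4]
  }
  if (length(lines) < 6L + natoms) {
    stop("CUBE parse error: truncated atom records", call. = FALSE)
  }
  atoms <- t(vapply(seq_len(natoms),
                    function(k) num(6L + k, paste0("atom ", k)), numeric(5)))
  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(lines[(7L + natoms):length(lines)]), "[[:space:]]+"))))
  vals <- vals[!is.na(vals)]
  nexp <- prod(counts)
  if (length(vals) != nexp) {
    stop(sprintf("CUBE parse error: expected %d voxel values, found %d",
                 nexp, length(vals)), call. = FALSE)
  }
  # file order: x slowest, z fastest -> fill [iz, iy, ix] then permute
  arr <- aperm(array(vals, dim = rev(counts)), c(3, 2, 1))
  vol <- abs(det(axes))
  structure(list(
    origin = origin, axes = axes, counts = counts,
    atoms = data.frame(z = as.integer(atoms[, 1]), charge = atoms[, 2],
                       x = atoms[, 3], y = atoms[, 4], z_pos = atoms[, 5]),
    values = arr, voxel_volume = vol,
    total_density = sum(arr) * vol
  ), class = "cube_grid")
}

#' Write a Gaussian CUBE file
#'
#' @param cube A `cube_grid` (see [read_cube()]).
#' @param path Output path.
#' @param comment Two-line comment header (length-2 character).
#' @export
write_cube <- function(cube, path, comment = c("cube", "written by ramanmix")) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment[1:2], con)
  fmt <- function(i, v) sprintf("%5d %11.6f %11.6f %11.6f", i, v[1], v[2], v[3])
  writeLines(fmt(nrow(cube$atoms), cube$origin), con)
  for (a in 1:3) writeLines(fmt(cube$counts[a], cube$axes[a, ]), con)
  for (k in seq_len(nrow(cube$atoms))) {
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f",
                       cube$atoms$z[k], cube$atoms$charge[k],
                       cube$atoms$x[k], cube$atoms$y[k], cube$atoms$z_pos[k]),
               con)
  }
  vals <- as.vector(aperm(cube$values, c(3, 2, 1)))  # z fastest
  n6 <- ceiling(length(vals) / 6) * 6
  vals6 <- c(vals, rep(NA_real_, n6 - length(vals)))
  mat <- matrix(vals6, ncol = 6, byrow = TRUE)
  rows <- apply(mat, 1, function(r) {
    paste(sprintf("%.16E", r[!is.na(r)]), collapse = " ")
  })
  writeLines(rows, con)
  invisible(path)
}

# voxel center coordinates (n_voxels x 3), same linear order as values[ix,iy,iz]
cube_voxel_centers <- function(cube) {
  ix <- seq_len(cube$counts[1]) - 1L
  iy <- seq_len(cube$counts[2]) - 1L
  iz <- seq_len(cube$counts[3]) - 1L
  g <- expand.grid(ix = ix, iy = iy, iz = iz)   # ix fastest: matches array order
  sweep(as.matrix(g) %*% cube$axes, 2, cube$origin, `+`)
}

#' Molecular dipole from Voronoi integration of a density cube
#'
#' Each voxel is assigned to its nearest atom (plain Euclidean distance,
#' ties to the lowest atom index; the QM box is non-periodic). The dipole of
#' the selected molecule is the electronic contribution
#' -sum over voxels in the subset's cells of rho (r - reference) dV, plus
#' the nuclear contribution sum of Z_a (r_a - reference) over subset atoms.
#'
#' @param cube A `cube_grid`.
#' @param atom_subset Atom indices (1-based) owning the Voronoi cells to
#'   integrate; default all atoms.
#' @param reference Length-3 reference point, bohr (default the origin of
#'   coordinates).
#' @return Length-3 dipole vector in a.u., with attributes
#'   `electronic` and `nuclear` holding the two contributions.
#' @export
voronoi_dipole <- function(cube, atom_subset = seq_len(nrow(cube$atoms)),
                           reference = c(0, 0, 0)) {
  if (length(atom_subset) < 1L) {
    stop("invalid parameter: atom subset is empty", call. = FALSE)
  }
  pos <- as.matrix(cube$atoms[, c("x", "y", "z_pos")])
  centers <- cube_voxel_centers(cube)
  # nearest atom per voxel; ties resolved to the lowest index by strict <
  d2 <- matrix(0, nrow(centers), nrow(pos))
  for (a in seq_len(nrow(pos))) {
    d2[, a] <- (centers[, 1] - pos[a, 1])^2 + (centers[, 2] - pos[a, 2])^2 +
      (centers[, 3] - pos[a, 3])^2
  }
  owner <- max.col(-d2, ties.method = "first")
  sel <- owner %in% atom_subset
  rho <- as.vector(cube$values)[sel]
  rel <- sweep(centers[sel, , drop = FALSE], 2, reference, `-`)
  electronic <- -colSums(rel * rho) * cube$voxel_volume
  nuc_rel <- sweep(pos[atom_subset, , drop = FALSE], 2, reference, `-`)
  nuclear <- colSums(nuc_rel * cube$atoms$charge[atom_subset])
  out <- electronic + nuclear
  attr(out, "electronic") <- electronic
  attr(out, "nuclear") <- nuclear
  out
}
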