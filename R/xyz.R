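#' Read a multi-frame XYZ trajectory
#'
#' Standard XYZ: per frame an atom-count line, a comment line, then
#' `element x y z` records. All frames must have the same atom count.
#'
#' @param path XYZ file path.
#' @return A list with `elements` (character vector, first frame) and
#'   `coords` (3D array: n_atoms x 3 x n_frames, Angstrom).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  i <- 1L
  frames <- list()
  elements <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat <= 0L) {
      stop("malformed XYZ: expected an atom count at line ", i, call. = FALSE)
    }
    if (i + 1L + nat > length(lines)) {
      stop("malformed XYZ: truncated frame starting at line ", i, call. = FALSE)
    }
    rec <- strsplit(trimws(lines[(i + 2L):(i + 1L + nat)]), "[[:space:]]+")
    el <- vapply(rec, `[`, character(1), 1L)
    xyz <- t(vapply(rec, function(r) as.numeric(r[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("malformed XYZ: non-numeric coordinates near line ", i,
                         call. = FALSE)
    if (is.null(elements)) elements <- el
    else if (nat != length(elements)) {
      stop("malformed XYZ: atom count changes between frames", call. = FALSE)
    }
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + nat
  }
  if (length(frames) == 0L) stop("empty XYZ file: ", path, call. = FALSE)
  coords <- array(unlist(frames), dim = c(length(elements), 3L, length(frames)))
  list(elements = elements, coords = coords)
}

#' Write a multi-frame XYZ trajectory
#'
#' @param elements Character vector of element symbols.
#' @param coords 3D array (n_atoms x 3 x n_frames) or a single matrix.
#' @param path Output path.
#' @param comment Comment-line text (recycled over frames).
#' @export
write_xyz <- function(elements, coords, path, comment = "") {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  nfr <- dim(coords)[3]
  comment <- rep_len(comment, nfr)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nfr)) {
    writeLines(c(as.character(length(elements)), comment[f]), con)
    writeLines(sprintf("%s %.8g %.8g %.8g", elements,
                       coords[, 1, f], coords[, 2, f], coords[, 3, f]), con)
  }
  invisible(path)
}
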