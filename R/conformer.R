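#' Dihedral angle of four points
#'
#' IUPAC sign convention: the angle is positive when, viewed from p2 toward
#' p3, the far bond p3-p4 is rotated clockwise relative to the near bond
#' p2-p1. Computed with the atan2 form, so the result is numerically stable
#' near 0 and 180 degrees.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors.
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) {
    stop("undefined dihedral: three consecutive points are collinear", call. = FALSE)
  }
  b2u <- b2 / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2u)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Pseudorotation phase angle and pucker amplitude of a furanose ring
#'
#' Given the five endocyclic torsions nu0..nu4 (degrees), returns the
#' pseudorotation phase angle P and the maximum pucker amplitude tau_m,
#' defined through the generating identity
#' \deqn{\nu_j=\tau_m\cos(P+144^\circ(j-2))}
#' so that
#' \deqn{\tan P=\frac{(\nu_4+\nu_1)-(\nu_3+\nu_0)}
#'   {2\nu_2(\sin 36^\circ+\sin 72^\circ)}}
#' with the quadrant resolved by atan2 and
#' \eqn{\tau_m=\sqrt{\nu_2^2+[((\nu_4+\nu_1)-(\nu_3+\nu_0))/
#' (2(\sin 36^\circ+\sin 72^\circ))]^2}},
#' which reduces to \eqn{\nu_2/\cos P} but stays finite at P = 90, 270
#' degrees. P near 18 degrees is c3'-endo (north); near 162 degrees is
#' c2'-endo (south).
#'
#' @param nu Numeric length-5 vector of torsions nu0..nu4, degrees.
#' @return List with `P` (degrees in \[0, 360)) and `tau_m` (degrees >= 0).
#' @seealso [pucker_torsions()] for the inverse map.
#' @export
pseudorotation <- function(nu) {
  if (length(nu) != 5L) stop("need the five endocyclic torsions nu0..nu4", call. = FALSE)
  if (all(abs(nu) < 1e-6)) {
    stop("flat ring: all torsions are (numerically) zero", call. = FALSE)
  }
  d <- pi / 180
  num <- (nu[5] + nu[2]) - (nu[4] + nu[1])        # (nu4+nu1) - (nu3+nu0)
  den <- 2 * (sin(36 * d) + sin(72 * d))
  sinterm <- num / den                              # tau_m * sin(P)
  costerm <- nu[3]                                  # tau_m * cos(P) = nu2
  P <- atan2(sinterm, costerm) / d
  if (P < 0) P <- P + 360
  list(P = P, tau_m = sqrt(sinterm^2 + costerm^2))
}

#' Generate the five ring torsions for a given pucker state
#'
#' Inverse of [pseudorotation()]: nu_j = tau_m * cos(P + 144 (j - 2)).
#'
#' @param P Pseudorotation phase angle, degrees.
#' @param tau_m Maximum pucker amplitude, degrees.
#' @return Numeric length-5 vector nu0..nu4.
#' @export
pucker_torsions <- function(P, tau_m) {
  j <- 0:4
  tau_m * cos((P + 144 * (j - 2)) * pi / 180)
}

wrap180 <- function(x) {
  # into (-180, 180]
  y <- x - 360 * floor(x / 360)   # [0, 360)
  ifelse(y > 180, y - 360, y)
}

wrap360 <- function(x) x - 360 * floor(x / 360)

#' Classify a conformer from glycosidic torsion and ring pucker
#'
#' The base orientation is syn when chi lies in \[-90, 90) degrees (after
#' wrapping to (-180, 180\]) and anti otherwise; the ribose ring is south
#' when P lies in \[90, 270) (after wrapping to \[0, 360)) and north
#' otherwise. Boundaries are half-open so the rule is total and
#' deterministic.
#'
#' @param chi Glycosidic torsion, degrees.
#' @param P Pseudorotation phase angle, degrees.
#' @return One of `"syn/south"`, `"syn/north"`, `"anti/south"`, `"anti/north"`.
#'   Vectorized over `chi` and `P`.
#' @export
classify_conformer <- function(chi, P) {
  chi <- wrap180(chi)
  P <- wrap360(P)
  base <- ifelse(chi >= -90 & chi < 90, "syn", "anti")
  ring <- ifelse(P >= 90 & P < 270, "south", "north")
  paste(base, ring, sep = "/")
}

#' All four conformer labels, in canonical order
#' @export
conformer_label_levels <- function() {
  c("syn/south", "syn/north", "anti/south", "anti/north")
}

#' Per-frame conformer label series
#'
#' @param labels Character vector of conformer labels.
#' @param frame_interval_ps Time between retained frames, ps (> 0).
#' @param chi,P Optional per-frame angle series kept for inspection.
#' @return An object of class `conformer_labels`.
#' @export
conformer_labels <- function(labels, frame_interval_ps, chi = NULL, P = NULL) {
  if (length(labels) < 1L) stop("empty label series", call. = FALSE)
  if (!is.finite(frame_interval_ps) || frame_interval_ps <= 0) {
    stop("frame_interval_ps must be positive", call. = FALSE)
  }
  structure(list(labels = as.character(labels),
                 frame_interval_ps = frame_interval_ps,
                 chi = chi, P = P),
            class = "conformer_labels")
}

#' @export
print.conformer_labels <- function(x, ...) {
  cat(sprintf("<conformer_labels: %d frames at %.4g ps>\n",
              length(x$labels), x$frame_interval_ps))
  print(round(populations(x), 4))
  invisible(x)
}

#' Torsion specification for a nucleoside trajectory
#'
#' @param chi_atoms Four 0-based atom indices defining the glycosidic
#'   torsion (O4'-C1'-N9-C4 for purines, O4'-C1'-N1-C2 for pyrimidines).
#' @param ring_atoms Five 0-based atom indices, ordered C4', O4', C1', C2',
#'   C3', from which the endocyclic torsions nu0..nu4 are formed.
#' @param base_class `"purine"` or `"pyrimidine"`.
#' @return An object of class `torsion_spec` (indices stored 0-based, as in
#'   the JSON interchange format).
#' @export
torsion_spec <- function(chi_atoms, ring_atoms,
                         base_class = c("purine", "pyrimidine")) {
  base_class <- match.arg(base_class)
  chi_atoms <- as.integer(chi_atoms)
  ring_atoms <- as.integer(ring_atoms)
  if (length(chi_atoms) != 4L || length(ring_atoms) != 5L) {
    stop("need 4 chi atoms and 5 ring atoms", call. = FALSE)
  }
  if (anyDuplicated(c(chi_atoms)) || anyDuplicated(ring_atoms)) {
    stop("atom indices within a torsion definition must be distinct", call. = FALSE)
  }
  structure(list(chi_atoms = chi_atoms, ring_atoms = ring_atoms,
                 base_class = base_class),
            class = "torsion_spec")
}

#' Read a torsion specification from JSON
#'
#' Keys `chi_atoms`, `ring_atoms` (0-based indices) and `base_class`.
#' @param path JSON file path.
#' @export
read_torsion_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  torsion_spec(j$chi_atoms, j$ring_atoms, j$base_class)
}

# nu_j dihedral atom quadruples (1-based positions into ring_atoms ordered
# C4', O4', C1', C2', C3'), chosen so nu2 = C1'-C2'-C3'-C4' and P ~ 18 deg
# is c3'-endo.
ring_torsion_quads <- rbind(
  c(1, 2, 3, 4),  # nu0: C4'-O4'-C1'-C2'
  c(2, 3, 4, 5),  # nu1: O4'-C1'-C2'-C3'
  c(3, 4, 5, 1),  # nu2: C1'-C2'-C3'-C4'
  c(4, 5, 1, 2),  # nu3: C2'-C3'-C4'-O4'
  c(5, 1, 2, 3)   # nu4: C3'-C4'-O4'-C1'
)

frame_angles <- function(coords, spec) {
  ci <- spec$chi_atoms + 1L
  ri <- spec$ring_atoms + 1L
  chi <- dihedral_angle(coords[ci[1], ], coords[ci[2], ], coords[ci[3], ],
                        coords[ci[4], ])
  nu <- vapply(1:5, function(j) {
    q <- ri[ring_torsion_quads[j, ]]
    dihedral_angle(coords[q[1], ], coords[q[2], ], coords[q[3], ], coords[q[4], ])
  }, numeric(1))
  ps <- pseudorotation(nu)
  c(chi = chi, P = ps$P, tau_m = ps$tau_m)
}

#' Label every retained frame of a trajectory
#'
#' Computes chi and the ring pseudorotation per frame and classifies each
#' retained frame as syn/anti x north/south. With `stride` > 1, every
#' stride-th frame (starting at the first) is retained and the output frame
#' interval is `frame_interval_ps * stride`.
#'
#' @param frames List of coordinate matrices (n_atoms x 3), or a 3D array
#'   with dim (n_atoms, 3, n_frames), e.g. from [read_xyz()].
#' @param spec A [torsion_spec()].
#' @param stride Keep every stride-th frame (default 1).
#' @param frame_interval_ps Time between *input* frames, ps.
#' @param hysteresis Optional angular buffer in degrees around the
#'   classification boundaries: a frame whose chi or P lies within the
#'   buffer keeps the previous frame's state for that coordinate,
#'   suppressing rate inflation from boundary recrossing. Default 0 (off).
#' @return A [conformer_labels()] series carrying the chi and P series.
#' @export
label_trajectory <- function(frames, spec, stride = 1L, frame_interval_ps = 10,
                             hysteresis = 0) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  }
  if (stride < 1L) stop("stride must be >= 1", call. = FALSE)
  keep <- seq(1L, length(frames), by = stride)
  need <- max(spec$chi_atoms, spec$ring_atoms) + 1L
  ang <- vapply(frames[keep], function(co) {
    if (!is.matrix(co) || nrow(co) < need || ncol(co) != 3L) {
      stop("malformed trajectory: a frame is missing atoms required by the torsion spec",
           call. = FALSE)
    }
    frame_angles(co, spec)
  }, numeric(3))
  chi <- ang["chi", ]
  P <- ang["P", ]
  if (hysteresis > 0) {
    labs <- classify_hysteresis(chi, P, hysteresis)
  } else {
    labs <- classify_conformer(chi, P)
  }
  conformer_labels(labs, frame_interval_ps * stride, chi = chi, P = P)
}

# Debounced classification: within `h` degrees of a boundary the previous
# frame's state is kept for that coordinate.
classify_hysteresis <- function(chi, P, h) {
  chi <- wrap180(chi)
  P <- wrap360(P)
  n <- length(chi)
  base <- character(n)
  ring <- character(n)
  base[1] <- if (chi[1] >= -90 && chi[1] < 90) "syn" else "anti"
  ring[1] <- if (P[1] >= 90 && P[1] < 270) "south" else "north"
  for (i in 2:n) {
    dchi <- min(abs(wrap180(chi[i] - 90)), abs(wrap180(chi[i] + 90)))
    base[i] <- if (dchi < h) base[i - 1]
               else if (chi[i] >= -90 && chi[i] < 90) "syn" else "anti"
    dP <- min(abs(wrap180(P[i] - 90)), abs(wrap180(P[i] - 270)))
    ring[i] <- if (dP < h) ring[i - 1]
               else if (P[i] >= 90 && P[i] < 270) "south" else "north"
  }
  paste(base, ring, sep = "/")
}

#' Conformer populations from a label series
#'
#' @param series A [conformer_labels()] series.
#' @return Named numeric vector of label frequencies summing to 1 (labels
#'   present in the series only).
#' @export
populations <- function(series) {
  if (!inherits(series, "conformer_labels")) stop("expected conformer_labels", call. = FALSE)
  tab <- table(series$labels)
  p <- as.numeric(tab) / length(series$labels)
  names(p) <- names(tab)
  lv <- conformer_label_levels()
  p[order(match(names(p), lv, nomatch = length(lv) + 1L))]
}

#' Exchange rates and mean lifetimes from a label series
#'
#' Rates are counted transitions normalized by occupancy time:
#' k\[a->b\] = (number of a->b label changes) / (total time spent in a, ns).
#' Mean lifetimes are the mean contiguous dwell time per label. For a
#' two-state series, mean_lifetime\[a\] * sum_b k\[a->b\] ~ 1.
#'
#' @param series A [conformer_labels()] series of at least two frames.
#' @return List with `rates_ns` (matrix, from-label rows, per ns),
#'   `mean_lifetime_ns` (named vector), `occupancy_ns` and
#'   `n_transitions` (matrix of counts).
#' @export
transition_kinetics <- function(series) {
  if (!inherits(series, "conformer_labels")) stop("expected conformer_labels", call. = FALSE)
  labs <- series$labels
  if (length(labs) < 2L) stop("insufficient data: need at least 2 frames", call. = FALSE)
  dt_ns <- series$frame_interval_ps / 1000
  states <- unique(labs)
  r <- rle(labs)
  k <- matrix(0, length(states), length(states),
              dimnames = list(from = states, to = states))
  if (length(r$values) > 1L) {
    for (i in seq_len(length(r$values) - 1L)) {
      k[r$values[i], r$values[i + 1L]] <- k[r$values[i], r$values[i + 1L]] + 1
    }
  }
  occ <- vapply(states, function(s) sum(labs == s) * dt_ns, numeric(1))
  rates <- sweep(k, 1, occ, "/")
  life <- vapply(states, function(s) mean(r$lengths[r$values == s]) * dt_ns,
                 numeric(1))
  list(rates_ns = rates, mean_lifetime_ns = life, occupancy_ns = occ,
       n_transitions = k)
}
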