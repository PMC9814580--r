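# Shared fixtures, built in code at test time.

# Three well-separated Lorentzian peak lists per conformer region.
fixture_peaks <- list(
  A = list(peak_spec(700, 1, 8), peak_spec(1000, 0.7, 10), peak_spec(1400, 0.5, 9)),
  B = list(peak_spec(820, 0.9, 9), peak_spec(1150, 1, 8), peak_spec(1520, 0.6, 10)),
  C = list(peak_spec(860, 0.9, 8), peak_spec(1240, 1, 10), peak_spec(1560, 0.7, 9))
)

fixture_subspectra <- function(labels = c("A", "B"), seed0 = 11L, step = 0.5) {
  subspectrum_set(lapply(seq_along(labels), function(i) {
    gen_subspectrum(fixture_peaks[[labels[i]]],
                    sim_config(seed = seed0 + i, step = step),
                    label = labels[i])
  }))
}

# Two-state exchange rate matrix, ns^-1.
two_state_rates <- function(k12, k21 = k12,
                            labels = c("syn/south", "syn/north")) {
  matrix(c(0, k12, k21, 0), 2, 2, byrow = TRUE,
         dimnames = list(labels, labels))
}

# Place atoms of a puckered five-ring plus a two-atom "base" arm so that
# both the ring torsions and the glycosidic dihedral are well defined.
# Ring: regular pentagon of radius 1.2 in the xy plane with sinusoidal
# out-of-plane displacement (amplitude `amp`, phase `phase` in degrees);
# atoms ordered C4', O4', C1', C2', C3'. The arm (N, C) hangs off C1' with
# the final atom rotated about the C1'-N bond by `chi_target`.
fixture_ring_frame <- function(phase, amp = 0.45, chi_target = 0) {
  k <- 0:4
  ring <- cbind(1.2 * cos(2 * pi * k / 5),
                1.2 * sin(2 * pi * k / 5),
                amp * cos(4 * pi * k / 5 + phase * pi / 180))
  c1p <- ring[3, ]
  o4p <- ring[2, ]
  # local frame at C1': e1 away from ring center, e2 along z
  e1 <- c1p - c(mean(ring[, 1]), mean(ring[, 2]), mean(ring[, 3]))
  e1 <- e1 / sqrt(sum(e1^2))
  nn <- c1p + 1.4 * e1
  # place the terminal base atom so dihedral(O4', C1', N, X) == chi_target
  b <- nn - c1p; b <- b / sqrt(sum(b^2))
  u <- o4p - c1p; u <- u - sum(u * b) * b; u <- u / sqrt(sum(u^2))
  v <- c(b[2] * u[3] - b[3] * u[2], b[3] * u[1] - b[1] * u[3],
         b[1] * u[2] - b[2] * u[1])
  th <- chi_target * pi / 180
  x <- nn + 1.4 * (cos(th) * u - sin(th) * v) + 0.9 * b
  rbind(ring, nn, x)   # 7 atoms: ring(5), N, base C
}

fixture_torsion_spec <- function() {
  # 0-based: chi = O4'(1) - C1'(2) - N(5) - C(6); ring atoms 0..4
  torsion_spec(chi_atoms = c(1, 2, 5, 6), ring_atoms = 0:4,
               base_class = "purine")
}
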