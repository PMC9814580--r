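test_that("dihedral angle follows the IUPAC atan2 convention", {
  p1 <- c(1, 0, 0); p2 <- c(0, 0, 0); p3 <- c(0, 1, 0)
  expect_equal(dihedral_angle(p1, p2, p3, c(1, 1, 0)), 0)
  expect_equal(dihedral_angle(p1, p2, p3, c(-1, 1, 0)), 180)

  # perpendicular case: sign fixed by the independent atan2-formula oracle
  oracle <- function(a, b, c, d) {
    b1 <- b - a; b2 <- c - b; b3 <- d - c
    cross <- function(u, v) c(u[2]*v[3]-u[3]*v[2], u[3]*v[1]-u[1]*v[3],
                              u[1]*v[2]-u[2]*v[1])
    n1 <- cross(b1, b2); n2 <- cross(b2, b3)
    atan2(sum(cross(n1, n2) * b2 / sqrt(sum(b2^2))), sum(n1 * n2)) * 180 / pi
  }
  d <- c(0, 1, 1)
  expect_equal(dihedral_angle(p1, p2, p3, d), oracle(p1, p2, p3, d))
  expect_equal(abs(dihedral_angle(p1, p2, p3, d)), 90)

  # agreement with bio3d on random geometries
  skip_if_not_installed("bio3d")
  set.seed(4)
  for (i in 1:20) {
    pts <- matrix(rnorm(12), 4, 3)
    ref <- bio3d::torsion.xyz(as.vector(t(pts)), atm.inc = 4)
    expect_equal(dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                 as.numeric(ref), tolerance = 1e-6)
  }

  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("pseudorotation analysis is the exact inverse of the generating identity", {
  ps <- pseudorotation(pucker_torsions(162, 40))
  expect_equal(ps$P, 162, tolerance = 1e-10)      # c2'-endo range
  expect_equal(ps$tau_m, 40, tolerance = 1e-10)

  ps <- pseudorotation(pucker_torsions(18, 40))
  expect_equal(ps$P, 18, tolerance = 1e-10)       # c3'-endo range

  # round trip over 1000 random pucker states
  set.seed(7)
  P <- runif(1000, 0, 360); tm <- runif(1000, 1e-3, 60)
  err <- vapply(seq_along(P), function(i) {
    out <- pseudorotation(pucker_torsions(P[i], tm[i]))
    max(abs(out$P - P[i]), abs(out$tau_m - tm[i]))
  }, numeric(1))
  expect_lt(max(err), 1e-9)

  expect_error(pseudorotation(rep(0, 5)), "flat ring")
})

test_that("conformer classification is total with half-open boundaries", {
  expect_identical(classify_conformer(45, 100), "syn/south")
  expect_identical(classify_conformer(180, 0), "anti/north")
  expect_identical(classify_conformer(90, 270), "anti/north")   # boundary rule
  expect_identical(classify_conformer(-90, 90), "syn/south")
  expect_identical(classify_conformer(45 + 720, 100 - 720), "syn/south")  # wrapping

  set.seed(12)
  lab <- classify_conformer(runif(500, -720, 720), runif(500, -720, 720))
  expect_true(all(lab %in% conformer_label_levels()))
})

test_that("trajectory labelling reproduces generating states and handles strides", {
  # templates verified above: phase 90 -> south, phase 0 -> north;
  # chi_target 45 -> syn, chi_target -120 -> anti
  spec <- fixture_torsion_spec()
  templates <- list(
    "syn/south" = fixture_ring_frame(90, chi_target = 45),
    "anti/north" = fixture_ring_frame(0, chi_target = -120)
  )
  set.seed(3)
  states <- sample(names(templates), 1000, replace = TRUE)
  frames <- templates[states]
  series <- label_trajectory(frames, spec, frame_interval_ps = 10)
  expect_identical(series$labels, states)
  expect_identical(series$frame_interval_ps, 10)

  # stride 50 on 50,000 frames keeps 1000 labels at 50x the interval
  big <- rep(templates["syn/south"], 50000)
  s50 <- label_trajectory(big, spec, stride = 50, frame_interval_ps = 10)
  expect_length(s50$labels, 1000)
  expect_identical(s50$frame_interval_ps, 500)

  # stride beyond the trajectory keeps only frame 0
  s1 <- label_trajectory(frames[1:10], spec, stride = 100, frame_interval_ps = 10)
  expect_length(s1$labels, 1L)

  # missing atoms
  expect_error(label_trajectory(list(matrix(0, 3, 3)), spec, frame_interval_ps = 10),
               "malformed trajectory")
})

test_that("populations count label frequencies and sum to one", {
  labs <- c(rep("syn/south", 600), rep("anti/north", 400))
  p <- populations(conformer_labels(labs, 10))
  expect_equal(unname(p["syn/south"]), 0.6)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  expect_equal(unname(populations(conformer_labels(rep("syn/south", 5), 10))), 1)

  # invariant under label-preserving permutation
  set.seed(5)
  perm <- sample(length(labs))
  expect_equal(populations(conformer_labels(labs[perm], 10)), p)

  # stationary distribution of a two-state Markov generator (pi_1 = 0.7)
  rates <- two_state_rates(0.3, 0.7)   # k12/k21 = 3/7 -> pi_1 = 0.7
  ser <- gen_conformer_chain(rates, frame_interval_ps = 10, n_frames = 1e6,
                             sim = sim_config(seed = 31))
  expect_equal(unname(populations(ser)["syn/south"]), 0.7, tolerance = 0.01)
})

test_that("transition kinetics recover dwell times and generator rates", {
  # strictly alternating 5 ns dwells at 100 ps frames
  dwell <- rep(c("A", "B"), each = 50)       # 50 frames x 100 ps = 5 ns
  labs <- rep(dwell, 20)
  kin <- transition_kinetics(conformer_labels(labs, 100))
  expect_equal(kin$rates_ns["A", "B"], 0.2, tolerance = 1e-12)
  expect_equal(unname(kin$mean_lifetime_ns["A"]), 5)

  # no transitions: zero rates, lifetime = total duration
  kin0 <- transition_kinetics(conformer_labels(rep("A", 100), 10))
  expect_equal(unname(kin0$mean_lifetime_ns["A"]), 1)
  expect_true(all(kin0$rates_ns == 0))

  # two-state Markov chain at k = 0.4 ns^-1, 10 ps frames, 5e5 frames
  ser <- gen_conformer_chain(two_state_rates(0.4), frame_interval_ps = 10,
                             n_frames = 5e5, sim = sim_config(seed = 17))
  kin <- transition_kinetics(ser)
  expect_equal(kin$rates_ns["syn/south", "syn/north"], 0.4, tolerance = 0.1)
  expect_equal(kin$rates_ns["syn/north", "syn/south"], 0.4, tolerance = 0.1)
  # two-state consistency: lifetime ~ 1 / exit rate
  expect_equal(kin$mean_lifetime_ns["syn/south"] *
                 sum(kin$rates_ns["syn/south", ]), 1, tolerance = 0.05,
               ignore_attr = TRUE)

  # order matters: kinetics are not permutation invariant
  set.seed(6)
  shuffled <- conformer_labels(sample(labs), 100)
  expect_false(isTRUE(all.equal(transition_kinetics(shuffled)$rates_ns["A", "B"],
                                0.2, tolerance = 0.2)))

  expect_error(transition_kinetics(conformer_labels("A", 10)), "insufficient")
})

test_that("torsion spec JSON and XYZ trajectories round-trip", {
  spec <- fixture_torsion_spec()
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE)
  spec2 <- read_torsion_spec(path)
  expect_identical(spec2$chi_atoms, spec$chi_atoms)
  expect_identical(spec2$ring_atoms, spec$ring_atoms)

  fr <- fixture_ring_frame(90, chi_target = 45)
  coords <- array(c(fr, fr + 0.001), dim = c(nrow(fr), 3, 2))
  xyz <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(rep("C", nrow(fr)), coords, xyz)
  tr <- read_xyz(xyz)
  expect_equal(tr$coords, coords, tolerance = 1e-7)
  expect_identical(tr$elements, rep("C", nrow(fr)))

  series <- label_trajectory(tr$coords, spec, frame_interval_ps = 10)
  expect_identical(series$labels, rep("syn/south", 2))
})
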