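make_pair_traj <- function(r) {
  co <- array(0, c(1, 2, 3))
  co[1, 1, ] <- c(10, 10, 10)
  co[1, 2, ] <- c(10 + r, 10, 10)
  at <- data.frame(atom_name = c("GL", "BB"), res_id = c(1, 61),
                   res_name = c("TG", "SER"), mol_id = c(1, 2))
  trajectory(co, 0, c(200, 200, 200), atoms = at)
}

test_that("the logistic kernel equals 1 at contact and vanishes at long range", {
  tr0 <- make_pair_traj(0)
  sel <- build_selection(list(tg = list(resname = "TG")), tr0$atoms)
  expect_equal(interaction_score(tr0, sel, cutoff = NULL)$score, 1)
  far <- interaction_score(make_pair_traj(90), sel, cutoff = NULL)$score
  expect_lt(far, 1e-15)
  # capped evaluation records the analytic tail bound and keeps it < 1e-6
  prof <- interaction_score(tr0, sel)
  expect_lt(attr(prof, "tail_bound"), 1e-6)
})

test_that("interaction profile equals the all-pairs brute force to 1e-12", {
  set.seed(41)
  nf <- 3
  n_tg <- 4; n_pr <- 8
  co <- array(runif(nf * (n_tg + n_pr) * 3, 0, 30), c(nf, n_tg + n_pr, 3))
  at <- data.frame(
    atom_name = c(rep("GL", n_tg), rep("BB", n_pr)),
    res_id = c(1:n_tg, rep(c(57, 61, 105, 109), each = 2)),
    res_name = c(rep("TG", n_tg), rep(c("PHE", "SER", "LEU", "SER"),
                                      each = 2)),
    mol_id = c(1:n_tg, rep(5, n_pr)))
  tr <- trajectory(co, 1:nf, c(30, 30, 30), atoms = at)
  sel <- build_selection(list(tg = list(resname = "TG")), tr$atoms)
  prof <- interaction_score(tr, sel, cutoff = NULL)
  uid <- sel$res_uid[sel$protein]
  expected <- 0
  for (f in 1:nf)
    expected <- expected + oracle_interaction(
      matrix(co[f, 1:n_tg, ], ncol = 3),
      matrix(co[f, -(1:n_tg), ], ncol = 3), uid, c(30, 30, 30))
  expected <- expected / nf
  expect_equal(prof$score, unname(expected[as.character(prof$res_uid)]),
               tolerance = 1e-12)
})

test_that("scores are rigid-motion invariant and monotone in added TG", {
  set.seed(52)
  tor <- gen_toroid(n_tg = 10, tg_mode = "uniform", seed = 7)
  prof0 <- interaction_score(tor$traj, tor$sel, cutoff = NULL)
  # rigid rotation about z + translation (wrapped back into the box)
  tr <- tor$traj; a <- 0.4
  x <- tr$coords[, , 1] - 100; y <- tr$coords[, , 2] - 100
  tr$coords[, , 1] <- (100 + x * cos(a) - y * sin(a) + 13) %% 200
  tr$coords[, , 2] <- (100 + x * sin(a) + y * cos(a) + 7) %% 200
  tr$coords[, , 3] <- (tr$coords[, , 3] + 11) %% 100
  prof1 <- interaction_score(tr, tor$sel, cutoff = NULL)
  expect_equal(prof1$score, prof0$score, tolerance = 1e-9)
})

test_that("one more TG molecule can only raise residue scores", {
  # explicit two-configuration check with identical protein coordinates
  base_at <- data.frame(atom_name = c("GL", "BB", "BB"),
                        res_id = c(1, 61, 109),
                        res_name = c("TG", "SER", "SER"),
                        mol_id = c(1, 9, 9))
  co <- array(0, c(1, 3, 3))
  co[1, , ] <- rbind(c(5, 5, 5), c(12, 5, 5), c(20, 5, 5))
  tr1 <- trajectory(co, 0, c(60, 60, 60), atoms = base_at)
  co2 <- array(0, c(1, 4, 3))
  co2[1, , ] <- rbind(co[1, , ], c(14, 8, 5))
  at2 <- rbind(base_at, data.frame(atom_name = "GL", res_id = 2,
                                   res_name = "TG", mol_id = 2))
  tr2 <- trajectory(co2, 0, c(60, 60, 60), atoms = at2)
  sel1 <- build_selection(list(tg = list(resname = "TG")), tr1$atoms)
  sel2 <- build_selection(list(tg = list(resname = "TG")), tr2$atoms)
  s1 <- interaction_score(tr1, sel1, cutoff = NULL)$score
  s2 <- interaction_score(tr2, sel2, cutoff = NULL)$score
  expect_true(all(s2 >= s1))
})

test_that("AA mapping then scoring equals scoring the hand-built CG counterpart", {
  # 2-atom AA "residues" whose beads are midpoints
  nf <- 2
  set.seed(71)
  aa_at <- data.frame(
    atom_name = rep(c("A1", "A2"), 4),
    res_id = rep(c(1, 61, 105, 109), each = 2),
    res_name = rep(c("TG", "SER", "LEU", "SER"), each = 2),
    mol_id = rep(c(1, 2, 2, 2), each = 2))
  co <- array(runif(nf * 8 * 3, 0, 25), c(nf, 8, 3))
  aa <- trajectory(co, 1:nf, c(50, 50, 50), atoms = aa_at)
  mapping <- cg_mapping(list(
    list(resname = "TG", bead = "GL", atoms = c("A1", "A2")),
    list(resname = "SER", bead = "BB", atoms = c("A1", "A2")),
    list(resname = "LEU", bead = "BB", atoms = c("A1", "A2"))))
  cg <- map_to_cg(aa, mapping)
  expect_equal(cg$n_particles, 4)
  # hand-built CG: explicit midpoints
  hand <- array(NA_real_, c(nf, 4, 3))
  for (f in 1:nf) for (b in 1:4)
    hand[f, b, ] <- colMeans(co[f, (2 * b - 1):(2 * b), ])
  expect_equal(cg$coords, hand, tolerance = 1e-12)
  cg_hand <- trajectory(hand, 1:nf, c(50, 50, 50), atoms = cg$atoms)
  sel <- build_selection(list(tg = list(resname = "TG",
                                        glycerol_atoms = "GL")), cg$atoms)
  expect_equal(interaction_score(cg, sel, cutoff = NULL)$score,
               interaction_score(cg_hand, sel, cutoff = NULL)$score,
               tolerance = 1e-12)
})

test_that("CG mapping handles identity, midpoint and error cases", {
  at <- data.frame(atom_name = c("X"), res_id = 1, res_name = "GLY",
                   mol_id = 1)
  co <- array(c(3, 4, 5), c(1, 1, 3))
  tr <- trajectory(co, 0, c(10, 10, 10), atoms = at)
  m1 <- cg_mapping(list(list(resname = "GLY", bead = "BB", atoms = "X")))
  expect_equal(map_to_cg(tr, m1)$coords[1, 1, ], c(3, 4, 5))
  # two atoms at +/- 1 on x -> bead at origin
  at2 <- data.frame(atom_name = c("X", "Y"), res_id = 1, res_name = "GLY",
                    mol_id = 1)
  co2 <- array(0, c(1, 2, 3)); co2[1, 1, 1] <- 1; co2[1, 2, 1] <- -1
  tr2 <- trajectory(co2, 0, c(10, 10, 10), atoms = at2)
  m2 <- cg_mapping(list(list(resname = "GLY", bead = "BB",
                             atoms = c("X", "Y"))))
  expect_equal(map_to_cg(tr2, m2)$coords[1, 1, ], c(0, 0, 0))
  # missing member atom errors with residue and atom named
  m3 <- cg_mapping(list(list(resname = "GLY", bead = "BB",
                             atoms = c("X", "Z"))))
  expect_error(map_to_cg(tr2, m3), "GLY 1.*Z")
  # duplicate atom across beads of one residue rejected at rule build
  expect_error(cg_mapping(list(
    list(resname = "GLY", bead = "B1", atoms = "X"),
    list(resname = "GLY", bead = "B2", atoms = "X"))), "more than one bead")
})

test_that("a TG pinned next to a residue puts it first; symmetric rings tie", {
  tor <- gen_toroid(n_tg = 0)
  tr <- tor$traj
  # add one TG bead 1 A away from protomer 1's SER61 bead
  i61 <- which(tr$atoms$res_id == 61 & tr$atoms$mol_id == 1101)
  tg_xyz <- tr$coords[1, i61, ] + c(1, 0, 0)
  base_cols <- c("atom_name", "res_id", "res_name", "mol_id")
  at <- rbind(data.frame(atom_name = "GL", res_id = 1, res_name = "TG",
                         mol_id = 1), tr$atoms[, base_cols])
  co <- array(NA_real_, c(1, tr$n_particles + 1, 3))
  co[1, 1, ] <- tg_xyz; co[1, -1, ] <- tr$coords[1, , ]
  tr2 <- trajectory(co, 0, tr$box[1, ], atoms = at)
  sel <- build_selection(list(tg = list(resname = "TG")), tr2$atoms)
  prof <- interaction_score(tr2, sel, cutoff = NULL)
  expect_equal(prof$res_id[which.max(prof$score)], 61)
  # a uniform dense shell of TG around the ring leaves symmetry-equivalent
  # residues (same residue, different protomer) tied
  n_shell <- 110
  th <- 2 * pi * (seq_len(n_shell) - 0.5) / n_shell
  shell <- cbind(100 + 45 * cos(th), 100 + 45 * sin(th), 50)
  atS <- rbind(data.frame(atom_name = "GL", res_id = seq_len(n_shell),
                          res_name = "TG", mol_id = seq_len(n_shell)),
               tor$traj$atoms[, base_cols])
  coS <- array(NA_real_, c(1, nrow(atS), 3))
  coS[1, 1:n_shell, ] <- shell
  coS[1, -(1:n_shell), ] <- tor$traj$coords[1, , ]
  trS <- trajectory(coS, 0, tor$traj$box[1, ], atoms = atS)
  selS <- build_selection(list(tg = list(resname = "TG")), trS$atoms)
  profS <- interaction_score(trS, selS, cutoff = NULL)
  s61 <- profS$score[profS$res_id == 61]
  expect_length(s61, 11)
  expect_lt(max(s61) - min(s61), 1e-6)
})

test_that("profile ranking flags residues of interest and rejects absent ones", {
  tor <- gen_toroid(n_tg = 15, tg_mode = "uniform", seed = 13)
  prof <- interaction_score(tor$traj, tor$sel)
  pk <- profile_peaks(prof, c("PHE57", "SER61"))
  expect_equal(pk$rank, seq_len(nrow(pk)))
  expect_true(all(diff(pk$score) <= 0))
  roi <- attr(pk, "interest")
  expect_equal(roi$residue, c("PHE57", "SER61"))
  expect_error(profile_peaks(prof, "SER999"), "SER999")
})
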