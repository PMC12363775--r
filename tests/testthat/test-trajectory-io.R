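test_that("columnar format round-trips coordinates exactly at declared precision", {
  cfg <- brownian_config(7, 50, 0.5, 3, d_bulk = 2, seed = 42)
  tr <- gen_brownian_trap(cfg)
  path <- withr::local_tempfile(fileext = ".trj")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(back$n_particles, 7)
  expect_equal(back$n_frames, 3)
  expect_equal(back$coords, tr$coords, tolerance = 1e-6, ignore_attr = TRUE)
  # written with 6 decimals -> exact on re-read of the rounded values
  expect_true(max(abs(back$coords - round(tr$coords, 6))) == 0)
  expect_true(max(abs(back$unwrapped - round(tr$unwrapped, 6))) == 0)
  expect_equal(back$times, tr$times)
  expect_equal(back$box, tr$box, ignore_attr = TRUE)
})

test_that("truncated columnar file errors naming the last good frame", {
  cfg <- brownian_config(5, 50, 1, 4, d_bulk = 1, seed = 1)
  tr <- gen_brownian_trap(cfg)
  path <- withr::local_tempfile(fileext = ".trj")
  write_trajectory(tr, path)
  lines <- readLines(path)
  writeLines(lines[1:(length(lines) - 3)], path)   # cut into frame 4
  expect_error(read_trajectory(path), "last good frame.*frame 3|frame 4.*last good frame")
})

test_that("GRO files convert nm to Angstrom and reject triclinic boxes", {
  gro <- c("test t= 2000.0", "    3",
           "    1TG      GL    1   1.000   2.000   0.500",
           "    2TG      GL    2   2.500   0.100   0.500",
           "    3SER     BB    3   0.000   0.000   0.250",
           "   4.00000   4.00000   1.00000")
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(gro, path)
  tr <- read_trajectory(path)
  expect_equal(tr$coords[1, 1, ], c(10, 20, 5))
  expect_equal(tr$box[1, ], c(40, 40, 10))
  expect_equal(tr$times, 2)                 # t= in ps -> ns
  expect_equal(tr$atoms$res_name, c("TG", "TG", "SER"))
  writeLines(c(gro[1:5],
               "   4.00000   4.00000   1.00000   0.0   0.0   2.0   0.0   0.0   0.0"),
             path)
  expect_error(read_trajectory(path), "triclinic")
})

test_that("GRO round-trip through write_gro preserves coordinates to format precision", {
  tor <- gen_toroid(n_tg = 5, seed = 2)
  path <- withr::local_tempfile(fileext = ".gro")
  write_gro(tor$traj, path)
  back <- read_trajectory(path)
  expect_equal(back$n_particles, tor$traj$n_particles)
  # GRO stores nm with 3 decimals -> 1e-2 Angstrom precision
  expect_lt(max(abs(back$coords - tor$traj$coords)), 5e-3 + 1e-9)
})

test_that("unwrap makes boundary-crossing coordinates continuous and is idempotent", {
  # particle drifting +x across the boundary of a 10 A box
  x <- seq(8, 15.5, by = 0.5)
  co <- array(0, c(length(x), 1, 3))
  co[, 1, 1] <- x %% 10; co[, 1, 2] <- 1; co[, 1, 3] <- 1
  tr <- trajectory(co, seq_along(x), c(10, 10, 10))
  un <- unwrap(tr)
  expect_equal(un$unwrapped[, 1, 1], x - 8 + co[1, 1, 1])
  expect_true(all(diff(un$unwrapped[, 1, 1]) > 0))
  expect_identical(unwrap(un)$unwrapped, un$unwrapped)
  # stationary particle: unwrapped equals wrapped
  co2 <- array(rep(c(3, 4, 5), each = 6), c(6, 1, 3))
  st <- unwrap(trajectory(co2, 1:6, c(10, 10, 10)))
  expect_equal(st$unwrapped, st$coords)
})

test_that("MSD from unwrapped coordinates dominates wrapped at large lag", {
  cfg <- brownian_config(40, 30, 1, 400, d_bulk = 1.5, seed = 9)
  tr <- gen_brownian_trap(cfg)
  wrapped_as_un <- trajectory(tr$coords, tr$times, tr$box,
                              unwrapped = tr$coords, atoms = tr$atoms)
  m_un <- msd(tr)$all
  m_wr <- msd(wrapped_as_un)$all
  big <- m_un$lag > 100
  expect_true(all(m_un$msd[big] > m_wr$msd[big]))
})

test_that("XTC input and missing DCD units are explicit hard errors", {
  fake <- withr::local_tempfile(fileext = ".xtc")
  writeLines("x", fake)
  gro <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("t", "    1",
               "    1TG      GL    1   1.000   2.000   0.500",
               "   4.0   4.0   1.0"), gro)
  expect_error(read_trajectory(gro, fake), "XTC")
  dcd <- withr::local_tempfile(fileext = ".dcd")
  writeLines("x", dcd)
  expect_error(read_trajectory(gro, dcd, units = NULL), "unit metadata")
})

test_that("selection resolves groups, TG molecules and reports unresolved residues", {
  tor <- gen_toroid(n_tg = 4, seed = 1)
  top <- tor$traj$atoms
  sel <- build_selection(list(
    tg = list(resname = "TG"),
    groups = list(ser61 = list(residues = list("SER61")),
                  ser109 = list(residues = list(109)))), top)
  expect_length(sel$groups$ser61, 11)       # one bead per protomer
  expect_length(sel$groups$ser109, 11)
  expect_length(sel$tg_glycerol, 4)
  expect_error(build_selection(list(
    tg = list(resname = "TG"),
    groups = list(bad = list(residues = list("SER999")))), top),
    "SER999")
  expect_error(build_selection(list(tg = list(resname = "NOPE")), top),
               "empty")
})

test_that("a multi-chain CG TG topology maps to one molecule ID", {
  # 18 beads = 3 chains x (1 Na + 4 C1 + 1 C3), one residue id
  at <- data.frame(atom_name = rep(c("Na", paste0("C1", letters[1:4]), "C3"), 3),
                   res_id = 1, res_name = "TG", mol_id = 1)
  co <- array(runif(18 * 3), c(1, 18, 3))
  tr <- trajectory(co, 0, c(50, 50, 50), atoms = at)
  sel <- build_selection(list(tg = list(resname = "TG",
                                        glycerol_atoms = "Na")), tr$atoms)
  expect_length(lipidlens:::.tg_molecules(sel), 1)
  expect_length(sel$tg_glycerol, 3)   # the three Na linker beads
  expect_length(sel$tg_beads, 18)
})
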