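test_that("MSD is zero for stationary particles and exactly quadratic for ballistic motion", {
  co <- array(rep(c(5, 6, 7), each = 8 * 4), c(8, 4, 3))
  tr <- make_traj(co, atoms = data.frame(atom_name = "GL", res_id = 1:4,
                                         res_name = "TG", mol_id = 1:4))
  expect_lt(max(msd(tr)$all$msd), 1e-9)
  v <- c(2, -1)
  bal <- make_ballistic(v = v, n = 60)
  cu <- msd(bal, max_lag = 30)$all
  expect_equal(cu$msd, sum(v^2) * cu$lag^2, tolerance = 1e-9)
})

test_that("production MSD equals the O(n^2) brute-force oracle", {
  cfg <- brownian_config(5, 60, 1, 200, d_bulk = 1.3, seed = 17)
  tr <- gen_brownian_trap(cfg)
  cu <- msd(tr, max_lag = 150)$all
  # pooled oracle across molecules: weighted by per-lag sample counts
  nf <- 200
  ss <- numeric(151); nn <- numeric(151)
  for (m in 1:5) {
    o <- oracle_msd(tr$unwrapped[, m, 1:2], 150)
    ss <- ss + o * (nf - 0:150)
    nn <- nn + (nf - 0:150)
  }
  expect_equal(cu$msd, ss / nn, tolerance = 1e-9)
})

test_that("MSD invariants hold: msd(0)=0, non-negative, sample counts non-increasing", {
  cfg <- brownian_config(10, 60, 1, 100, d_bulk = 0.8, seed = 30)
  cu <- msd(gen_brownian_trap(cfg))$all
  expect_equal(cu$msd[1], 0)
  expect_true(all(cu$msd >= 0))
  expect_true(all(diff(cu$n) <= 0))
})

test_that("homogeneous random walks recover D with vanishing intercept, converging with size", {
  err <- sapply(c(50, 200, 800), function(np) {
    cfg <- brownian_config(np, 300, 1, 500, d_bulk = 1.0, seed = 100 + np)
    f <- fit_diffusion(msd(gen_brownian_trap(cfg))$all)
    abs(f$d - 1.0)
  })
  expect_lt(err[3], 0.05)
  expect_lt(err[3], err[1] + 0.02)   # larger runs do not get worse
  cfg <- brownian_config(400, 300, 1, 800, d_bulk = 1.0, seed = 55)
  f <- fit_diffusion(msd(gen_brownian_trap(cfg))$all)
  # intercept is negligible against the MSD scale inside the fit window
  expect_lt(abs(f$intercept), 0.02 * 4 * 1.0 * f$fit_window[2])
  expect_gt(f$r_squared, 0.99)
})

test_that("an exact line msd = 4 D tau fits D exactly with R^2 = 1", {
  lag <- 0:50
  cu <- structure(data.frame(lag = lag, msd = 4 * 1.0 * lag,
                             n = 100 - lag),
                  class = c("msd_curve", "data.frame"),
                  category = "all", dt = 1, segment_min_frames = 100)
  f <- suppressWarnings(fit_diffusion(cu))  # lm flags the perfect fit
  expect_equal(f$d, 1.0, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  expect_equal(f$intercept, 0, tolerance = 1e-10)
})

test_that("white measurement noise leaves D unbiased but lowers R^2", {
  set.seed(61)
  ds <- replicate(50, {
    lag <- 1:40
    msd_true <- 4 * 0.5 * lag
    cu <- structure(data.frame(lag = lag, msd = msd_true + rnorm(40, 0, 3),
                               n = 200 - lag),
                    class = c("msd_curve", "data.frame"),
                    category = "all", dt = 1, segment_min_frames = 81)
    fit_diffusion(cu, fit_window = c(1, 40))$d
  })
  expect_equal(mean(ds), 0.5, tolerance = 0.02)
  lag <- 1:40
  cu <- structure(data.frame(lag = lag, msd = 4 * 0.5 * lag + rnorm(40, 0, 3),
                             n = 200 - lag),
                  class = c("msd_curve", "data.frame"),
                  category = "all", dt = 1, segment_min_frames = 81)
  expect_lt(fit_diffusion(cu, fit_window = c(1, 40))$r_squared, 1)
})

test_that("trap and bulk coefficients separate with non-overlapping standard errors", {
  cfg <- brownian_config(300, 400, 1, 1000, d_bulk = 1.1, d_trap = 0.2,
                         trap_center = c(200, 200), trap_radius = 50,
                         n_trap_init = 100, seed = 19)
  tr <- gen_brownian_trap(cfg)
  sel <- tg_selection(tr)
  res <- diffusion_analysis(tr, sel, region_model(c(200, 200), 50, 60),
                            window = 200)
  expect_lt(res$fits$complex$d, res$fits$bulk$d)
  expect_gt(res$fits$bulk$d - 2 * res$fits$bulk$d_se,
            res$fits$complex$d + 2 * res$fits$complex$d_se)
  expect_gt(res$fold$ratio, 1)
})

test_that("fold reduction propagates uncertainty and rejects non-positive D", {
  r1 <- structure(list(d = 1.1, d_se = 0.02, category = "bulk"),
                  class = "diffusion_result")
  r2 <- structure(list(d = 0.2, d_se = 0.01, category = "complex"),
                  class = "diffusion_result")
  fr <- fold_reduction(r1, r2)
  expect_equal(fr$ratio, 5.5)
  expect_equal(fr$se, 5.5 * sqrt((0.02 / 1.1)^2 + (0.01 / 0.2)^2))
  r0 <- structure(list(d = 0, d_se = 0, category = "complex"),
                  class = "diffusion_result")
  expect_error(fold_reduction(r1, r0), "> 0")
  # equal coefficients give a unit ratio
  expect_equal(fold_reduction(r1, r1)$ratio, 1)
})

test_that("empty categories are omitted from MSD with a warning", {
  cfg <- brownian_config(10, 200, 1, 40, d_bulk = 1, seed = 3)
  tr <- gen_brownian_trap(cfg)
  sel <- tg_selection(tr)
  asg <- classify_regions(tr, sel, region_model(c(500, 500) * 0 + 100, 1, 2),
                          window = 40)
  expect_false(any(asg$category == "complex"))
  expect_warning(msd(tr, sel, asg), "complex")
})
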