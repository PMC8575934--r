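grid <- default_grid()
wl <- as.numeric(grid)

test_that("gaussian_band obeys peak and FWHM definitions", {
  v <- gaussian_band(grid, 350, 40, 2.5)
  expect_equal(v[wl == 350], 2.5)
  expect_equal(v[wl == 330], 1.25)   # center - fwhm/2
  expect_equal(v[wl == 370], 1.25)   # center + fwhm/2
  expect_equal(gaussian_band(grid, 350, 40, 0), rep(0, 201))
  expect_error(gaussian_band(grid, 350, -1, 1), "positive")
  expect_error(gaussian_band(grid, 200, 40, 1), "230")
})

test_that("preset bases honor the qualitative spectral constraints", {
  cosim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  for (a in c("PEA", "PMP", "PGL", "PPA")) {
    b <- make_preset_basis(a)
    for (sv in c("DCE", "MeOH")) {
      r <- render_basis(b, sv)
      expect_true(all(r$uv >= 0), info = paste(a, sv))
      # S basis is exactly the mirror of R for CD, identical for UV
      s <- render_basis(b, sv, "S")
      expect_equal(s$cd, -r$cd)
      expect_equal(s$uv, r$uv)
    }
  }
  # PMP CD crosses zero at 340 +/- 2 nm in DCE
  pmp <- render_basis(make_preset_basis("PMP"), "DCE")$cd
  crossings <- wl[which(diff(sign(pmp)) != 0)]
  expect_true(any(abs(crossings - 340) <= 2))
  # PEA is CD-silent at 400 nm but strong at 340 nm
  pea <- render_basis(make_preset_basis("PEA"), "DCE")$cd
  expect_lt(abs(pea[wl == 400]), 0.01 * max(abs(pea)))
  expect_gt(abs(pea[wl == 340]), 0.2 * max(abs(pea)))
  # solvent dependence: PMP nearly invariant, PEA and PPA strongly altered
  expect_gt(cosim(render_basis(make_preset_basis("PMP"), "DCE")$cd,
                  render_basis(make_preset_basis("PMP"), "MeOH")$cd), 0.95)
  expect_lt(cosim(render_basis(make_preset_basis("PEA"), "DCE")$cd,
                  render_basis(make_preset_basis("PEA"), "MeOH")$cd), 0.8)
  expect_lt(cosim(render_basis(make_preset_basis("PPA"), "DCE")$cd,
                  render_basis(make_preset_basis("PPA"), "MeOH")$cd), 0.8)
  # UV bases distinguish analytes in DCE; PEA and PPA UV nearly merge in
  # MeOH but split in DCE (the solvent effect motivating two solvents)
  uv <- function(a, sv) render_basis(make_preset_basis(a), sv)$uv
  expect_lt(cosim(uv("PEA", "DCE"), uv("PMP", "DCE")), 0.9)
  expect_gt(cosim(uv("PEA", "MeOH"), uv("PPA", "MeOH")), 0.95)
  expect_lt(cosim(uv("PEA", "DCE"), uv("PPA", "DCE")), 0.8)
  expect_error(make_preset_basis("XXX"), "no preset basis")
})

test_that("mixture simulation is linear with mirror-image enantiomer response", {
  bases <- list(make_preset_basis("PEA"), make_preset_basis("PMP"))
  comp <- composition(PEA = c(R = 3, S = 1), PMP = c(R = 2, S = 5))
  sp <- simulate_mixture(bases, comp, "DCE")
  # racemic mixture: CD identically zero, UV positive
  rac <- simulate_mixture(bases, composition(PEA = c(R = 2, S = 2),
                                             PMP = c(R = 1, S = 1)), "DCE")
  expect_equal(rac$cd$intensities, rep(0, 201))
  expect_true(all(rac$uv$intensities > 0))
  # doubling all concentrations doubles both spectra
  dbl <- simulate_mixture(bases, composition(PEA = c(R = 6, S = 2),
                                             PMP = c(R = 4, S = 10)), "DCE")
  expect_equal(dbl$cd$intensities, 2 * sp$cd$intensities)
  expect_equal(dbl$uv$intensities, 2 * sp$uv$intensities)
  # swapping R and S everywhere negates CD, leaves UV untouched
  mir <- simulate_mixture(bases, composition(PEA = c(R = 1, S = 3),
                                             PMP = c(R = 5, S = 2)), "DCE")
  expect_equal(mir$cd$intensities, -sp$cd$intensities)
  expect_equal(mir$uv$intensities, sp$uv$intensities)
  # additivity across compositions
  c1 <- simulate_mixture(bases, composition(PEA = c(R = 3, S = 0),
                                            PMP = c(R = 0, S = 0)), "DCE")
  c2 <- simulate_mixture(bases, composition(PEA = c(R = 0, S = 1),
                                            PMP = c(R = 2, S = 5)), "DCE")
  expect_equal(c1$cd$intensities + c2$cd$intensities, sp$cd$intensities,
               tolerance = 1e-12)
  expect_error(simulate_mixture(bases[1], comp, "DCE"), "no basis")
})

test_that("designs have the stated shapes and are seed-reproducible", {
  ds <- simulate_design("quaternary", 16, 5, seed = 9)
  expect_length(ds$sample_ids, 21L)
  expect_named(ds$blocks, c("CD_DCE", "UV_DCE"))
  expect_equal(dim(ds$Y), c(21L, 4L))
  expect_identical(attr(ds, "roles"),
                   c(rep("train", 16), rep("test", 5)))
  ds2 <- simulate_design("quaternary", 16, 5, seed = 9)
  expect_identical(ds$Y, ds2$Y)
  expect_identical(ds$blocks$CD_DCE$matrix, ds2$blocks$CD_DCE$matrix)

  oc <- simulate_design("octonary", 12, 6, seed = 2)
  expect_named(oc$blocks, c("CD_DCE", "UV_DCE", "CD_MeOH", "UV_MeOH"),
               ignore.order = TRUE)
  expect_equal(ncol(oc$Y), 8L)
  expect_error(simulate_design("quaternary", 3, 2), "ill-posed")
})

test_that("per-sample noise streams are stable under design extension", {
  a <- simulate_design("quaternary", 16, 2, seed = 5)
  b <- simulate_design("quaternary", 16, 5, seed = 5)
  # the first 18 samples are bit-identical even though b has 3 more
  expect_identical(a$blocks$CD_DCE$matrix,
                   b$blocks$CD_DCE$matrix[1:18, ])
})

test_that("noiseless fused data have the composition-degree rank", {
  ds <- quaternary_noiseless(8, 0)
  X <- cbind(ds$blocks$CD_DCE$matrix, ds$blocks$UV_DCE$matrix)
  d <- svd(scale(X, scale = FALSE))$d
  expect_equal(sum(d > 1e-8 * d[1]), 4L)
  oc <- simulate_design("octonary", 12, 0, seed = 4, noise = NULL)
  Xo <- do.call(cbind, lapply(oc$blocks, `[[`, "matrix"))
  do <- svd(scale(Xo, scale = FALSE))$d
  expect_equal(sum(do > 1e-8 * do[1]), 8L)
})

test_that("export/load round-trips a design through CSV + manifest", {
  dir <- withr::local_tempdir()
  ds <- simulate_design("quaternary", 4, 1, seed = 7)
  man <- export_design(ds, dir)
  ds2 <- load_design(man)
  expect_equal(ds2$Y, ds$Y, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(ds2$blocks$CD_DCE$matrix, ds$blocks$CD_DCE$matrix,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(attr(ds2, "roles"), attr(ds, "roles"))
})
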