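test_that("image stacks validate frame shapes and counts", {
  f <- matrix(1, 4, 5)
  expect_s3_class(image_stack(list(f, f), "dark"), "image_stack")
  expect_error(image_stack(list(f, matrix(1, 5, 4)), "dark"),
               "shape mismatch")
  expect_error(image_stack(list(matrix(-1, 2, 2)), "flat"), "non-negative")
  expect_error(image_stack(list(), "dark"), "non-empty")
  expect_error(image_stack(list(f, f), "tomo", angles = 1), "one entry per")
})

test_that("dark/flat stacks load at most ten frames by default, sorted", {
  d <- withr::local_tempdir()
  for (i in 1:12)
    write_count_tiff(matrix(i, 4, 4), file.path(d, sprintf("dark_%02d.tif", i)))
  st <- load_stack(d, "dark")
  expect_length(st$frames, 10)
  expect_equal(st$frames[[1]][1, 1], 1)   # filename order
  expect_equal(st$frames[[10]][1, 1], 10)
  expect_equal(default_frame_limit("flat"), 10)
  expect_equal(default_frame_limit("tomo"), Inf)
  # single flat frame: averaging is a no-op
  one <- load_stack(file.path(d, "dark_03.tif"), "flat")
  expect_length(one$frames, 1)
  expect_equal(average_stack(one), one$frames[[1]])
  # edge/tomo load everything
  expect_length(load_stack(d, "tomo")$frames, 12)
  expect_error(load_stack(character(), "dark"), "empty file list")
})

test_that("loading rejects mixed shapes and groups tomo slices by pattern", {
  d <- withr::local_tempdir()
  write_count_tiff(matrix(1, 4, 4), file.path(d, "a.tif"))
  write_count_tiff(matrix(1, 5, 5), file.path(d, "b.tif"))
  expect_error(load_stack(d, "flat"), "shape mismatch")

  d2 <- withr::local_tempdir()
  for (s in 1:2) for (i in 1:3)
    write_count_tiff(matrix(10 * s + i, 4, 4),
                     file.path(d2, sprintf("tomo_s%d_p%d.tif", s, i)))
  grp <- load_stack(d2, "tomo", slice_pattern = "_s([0-9]+)_")
  expect_length(grp, 2)
  expect_length(grp[[1]]$frames, 3)
  expect_equal(grp[[2]]$frames[[1]][1, 1], 21)
})

test_that("stack averaging is an arithmetic mean, invariant to file order", {
  st <- image_stack(list(matrix(0, 1, 1), matrix(2, 1, 1)), "dark")
  expect_equal(average_stack(st), matrix(1.0, 1, 1))
  set.seed(4)
  frames <- replicate(10, matrix(rpois(400, 100), 20, 20), simplify = FALSE)
  m1 <- average_stack(image_stack(frames, "dark"))
  m2 <- average_stack(image_stack(rev(frames), "dark"))
  expect_identical(m1, m2)
  # standard error of the mean of 10 Poisson(100) frames
  expect_lt(abs(mean(m1) - 100), 4 * sqrt(100 / 10) / sqrt(400))
  expect_lt(max(abs(m1 - 100)), 6 * sqrt(100 / 10))
})

test_that("float TIFF output stores 32-bit values readably", {
  x <- matrix(rnorm(60) * 50, 6, 10)
  f <- withr::local_tempfile(fileext = ".tif")
  write_float_tiff(x, f)
  y <- tiff::readTIFF(f)
  expect_equal(dim(y), dim(x))
  expect_lt(max(abs(y - x)), 1e-4)        # float32 precision
  g <- matrix(sample(0:65535, 24), 4, 6)
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_count_tiff(g, f2)
  expect_equal(as.integer(tiff::readTIFF(f2, as.is = TRUE)), as.integer(g))
})

test_that("keyed archives round-trip doubles bit-exactly", {
  ent <- list(a = matrix(c(pi, 1/3, exp(1), .Machine$double.xmin), 2, 2),
              b = array(runif(24), c(2, 3, 4)),
              c = 1:7, s = "hello world", v = c("two", "lines"))
  f <- withr::local_tempfile(fileext = ".xsar")
  write_archive(ent, f)
  back <- read_archive(f)
  expect_identical(back$a, ent$a)
  expect_identical(back$b, ent$b)
  expect_identical(back$c, ent$c)
  expect_identical(back$s, "hello world")
  expect_identical(back$v, c("two", "lines"))
  expect_error(read_archive(withr::local_tempfile(fileext = ".txt",
                                                  lines = "nope")),
               "not an XSAR")
})

test_that("session archives save and reload losslessly", {
  g <- system_geometry(reflection = c(1, 1, 1), edge_energy = 12.658,
                       pixel_size = 0.009, focus_to_detector = 500)
  emap <- structure(list(energies = matrix(runif(40, 12, 13), 8, 5)),
                    class = "energy_map")
  region <- structure(list(top = rep(1L, 5), bottom = rep(7L, 5),
                           excluded = rep(FALSE, 5)), class = "beam_region")
  maps <- structure(list(materials = c("selenate", "water"),
                         maps = list(selenate = matrix(runif(15), 3, 5),
                                     water = matrix(runif(15), 3, 5)),
                         mode = "ct", angles = c(0, 60, 120),
                         residual_rms = matrix(runif(15), 3, 5)),
                    class = "material_maps")
  refs <- list(species_spectrum("selenate"))
  arch <- session_archive(g, energy_map = emap, beam_region = region,
                          references_used = refs, fit_results = maps,
                          settings_record = c("mode = ct", "nonneg = FALSE"))
  d <- withr::local_tempdir()
  paths <- save_session(arch, d)
  expect_true(file.exists(file.path(d, "session.xsar")))
  expect_true(file.exists(file.path(d, "selenate_sino.tif")))
  expect_true(file.exists(file.path(d, "settings.txt")))
  back <- load_session(d)
  expect_equal(back$geometry, g)
  expect_identical(back$energy_map$energies, emap$energies)
  expect_identical(back$fit_results$maps$selenate, maps$maps$selenate)
  expect_identical(back$fit_results$angles, maps$angles)
  expect_identical(back$beam_region$top, region$top)
  expect_identical(back$references_used[[1]]$mu_rho, refs[[1]]$mu_rho)
  expect_identical(back$settings_record, arch$settings_record)
})

test_that("a session without fit results writes no maps and warns", {
  g <- system_geometry(reflection = c(1, 1, 1), edge_energy = 12.658,
                       pixel_size = 0.009, focus_to_detector = 500)
  d <- withr::local_tempdir()
  expect_warning(save_session(session_archive(g), d), "no fit results")
  expect_length(list.files(d, pattern = "\\.tif$"), 0)
  expect_true(file.exists(file.path(d, "session.xsar")))
})
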