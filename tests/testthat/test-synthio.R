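test_that("scene generation is deterministic and hits contact extremes", {
  base <- function(f) scene_spec(size = 180, scale_um_per_px = 18,
                                 n_particles = 2, contact_fraction = f,
                                 noise_sd = 10, seed = 21)
  a <- make_histology_scene(base(0.5))
  b <- make_histology_scene(base(0.5))
  expect_identical(a$image, b$image)
  expect_identical(a$truth$mask, b$truth$mask)
  expect_identical(a$truth$particles, b$truth$particles)

  full <- make_histology_scene(base(1))
  expect_equal(full$truth$bmc_pct, 100.0)
  none <- make_histology_scene(base(0))
  expect_equal(none$truth$bmc_pct, 0.0)
})

test_that("per-particle bookkeeping matches independent edge re-measurement", {
  sp <- scene_spec(size = 380, scale_um_per_px = 14, n_particles = 20,
                   particle_um_range = c(250, 600),
                   contact_fraction = function(n) runif(n, 0.2, 0.8),
                   noise_sd = 0, seed = 9)
  sc <- make_histology_scene(sp)
  tr <- sc$truth
  mat <- binarize(tr$mask, "BIOMATERIAL")
  bone <- binarize(tr$mask, "BONE")
  ref <- oracle_edges(mat, tr$roi2_mask, bone = bone)
  expect_equal(tr$perimeter_edges, ref$perimeter)
  expect_equal(tr$contact_edges, ref$contact)
  expect_equal(tr$bmc_pct,
               100 * sum(tr$particles$contact_edges) /
                 sum(tr$particles$perimeter_edges))
  expect_equal(tr$bmc_pct, 100 * ref$contact / ref$perimeter)
})

test_that("measuring the generated mask reproduces truth exactly", {
  sp <- scene_spec(size = 240, scale_um_per_px = 15, n_particles = 4,
                   contact_fraction = 0.4, noise_sd = 0, seed = 13)
  sc <- make_histology_scene(sp)
  res <- measure_defect(sc$truth$mask, sc$truth$roi1_mask, sc$truth$roi2_mask)
  expect_equal(res$bmc_pct, sc$truth$bmc_pct)
  expect_equal(res$perimeter_edges, sc$truth$perimeter_edges)
  expect_equal(c(res$pct_bone_roi1, res$pct_material_roi1, res$pct_soft_roi1),
               unname(sc$truth$fractions_roi1))
})

test_that("particle diameters fall in the requested micrometre range", {
  rng <- c(300, 800)
  sp <- scene_spec(size = 300, scale_um_per_px = 14, n_particles = 6,
                   particle_um_range = rng, contact_fraction = 0.5,
                   noise_sd = 0, seed = 31)
  sc <- make_histology_scene(sp)
  d <- sc$truth$particles$diameter_um
  expect_true(all(d >= rng[1] & d <= rng[2]))
  expect_equal(d, 2 * sc$truth$particles$semi_major_px * 14)
})

test_that("unplaceable particle requests fail with an explicit message", {
  sp <- scene_spec(size = 128, scale_um_per_px = 5, n_particles = 2,
                   particle_um_range = c(900, 1000), contact_fraction = 0.5,
                   noise_sd = 0, seed = 1)
  expect_error(make_histology_scene(sp), "cannot fit|without overlap")
})

test_that("study tables honour the planted mean structure and balance", {
  sp0 <- study_spec(n_animals = 5, defects_per_animal = 6,
                    means = c(HAN = 30, HA820 = 28, HA1200 = 15),
                    sd_animal = 0, sd_resid = 0, seed = 4)
  tab0 <- make_study_table(sp0)
  expect_equal(nrow(tab0), 30)
  expect_equal(unname(table(tab0$group)), rep(10L, 3), ignore_attr = TRUE)
  for (g in levels(tab0$group))
    expect_true(all(tab0$outcome[tab0$group == g] == sp0$means[[g]]))
  # seeded determinism
  expect_identical(tab0, make_study_table(sp0))
  # invalid designs fail
  expect_error(study_spec(n_animals = 0), "positive")
  expect_error(study_spec(defects_per_animal = 5), "multiple")
  expect_error(study_spec(sd_resid = -1), "non-negative")
})

test_that("out-of-range outcomes are truncated with a warning", {
  sp <- study_spec(means = c(HAN = 98, HA820 = 50, HA1200 = 2),
                   sd_animal = 0, sd_resid = 10, seed = 8)
  expect_warning(tab <- make_study_table(sp), "truncated")
  expect_true(all(tab$outcome >= 0 & tab$outcome <= 100))
})

test_that("between-animal variance of animal means matches the closed form", {
  # balanced one-way-within-animal layout: var of an animal mean is
  # sigma_a^2 + sigma_e^2 / m with m defects per animal
  sa <- 4; se <- 9; m <- 6
  set.seed(123)
  vs <- replicate(1000, {
    sp <- study_spec(n_animals = 4, defects_per_animal = m,
                     means = c(HAN = 50, HA820 = 50, HA1200 = 50),
                     sd_animal = sa, sd_resid = se,
                     truncate = NULL, seed = sample.int(1e6, 1))
    tab <- make_study_table(sp)
    var(tapply(tab$outcome, tab$animal, mean))
  })
  expected <- sa^2 + se^2 / m
  # 1000 replicates x 3 df each: relative MC s.e. ~ sqrt(2/3000) ~ 2.6%
  expect_equal(mean(vs), expected, tolerance = 0.1)
})

test_that("scene files round-trip through disk", {
  sp <- scene_spec(size = 150, scale_um_per_px = 20, n_particles = 2,
                   contact_fraction = 0.5, noise_sd = 5, seed = 2)
  sc <- make_histology_scene(sp)
  dir <- tempfile()
  write_scene(sc, dir)
  img <- read_image(file.path(dir, "image.png"))
  expect_equal(img, sc$image, ignore_attr = TRUE)
  mask <- read_label_mask(file.path(dir, "truth_mask.png"))
  expect_equal(unclass(mask), unclass(sc$truth$mask), ignore_attr = TRUE)
  r2 <- read_roi_json(file.path(dir, "roi2.json"))
  expect_equal(r2$polygon, sc$truth$roi2$polygon, ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})
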