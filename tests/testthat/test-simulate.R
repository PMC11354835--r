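test_that("reference means respect separation and landmark count", {
  m0 <- make_reference_means(19, separation = 0, seed = 71)
  expect_length(m0, 4)
  expect_true(all(vapply(m0, nrow, 1L) == 19))
  expect_lt(max(abs(m0[[1]] - m0[[4]])), 1e-12)
  # pairwise Procrustes distance grows monotonically with separation
  seps <- c(0.02, 0.05, 0.1)
  mean_d <- vapply(seps, function(s) {
    ms <- make_reference_means(19, s, seed = 72)
    mean(c(procrustes_fit(ms[[1]], ms[[2]])$residual,
           procrustes_fit(ms[[2]], ms[[3]])$residual,
           procrustes_fit(ms[[3]], ms[[4]])$residual))
  }, numeric(1))
  expect_true(all(diff(mean_d) > 0))
  expect_equal(mean_d[3] / mean_d[1], 5, tolerance = 0.2)
})

test_that("noise-free single-reference populations collapse to the mean", {
  means <- make_reference_means(10, 0.1, seed = 73)
  ds <- sample_population("pure", 6, means, c(0, 0, 0, 1), sigma_w = 0,
                          nuisance = FALSE, seed = 74)
  shp <- apply(ds$coords, 3, function(m) {
    m <- sweep(m, 2, colMeans(m)); as.vector(m / sqrt(sum(m^2)))
  })
  expect_lt(max(abs(shp - as.vector(means[["scutellata"]]))), 1e-12)
})

test_that("the study-shaped dataset has the survey structure", {
  sim <- simulate_study(seed = 75)
  expect_equal(sim$n, 950)
  expect_equal(sim$k, 19)
  m <- sim$meta
  expect_equal(sum(!is.na(m$group_label)), 200)
  expect_equal(as.vector(table(m$group_label)), rep(50, 4))
  study <- m[is.na(m$group_label), ]
  expect_equal(nrow(study), 750)
  expect_equal(length(unique(study$apiary)), 15)
  expect_equal(as.vector(table(study$apiary)), rep(50, 15))
  expect_equal(length(unique(study$colony)), 75)
  expect_true(all(study$altitude_masl >= 2600 & study$altitude_masl <= 3274))
  expect_false(any(is.na(altitude_floor(study$altitude_masl))))
  cfg <- attr(sim, "config")
  expect_equal(cfg$seed, 75)
  expect_equal(cfg$lambda, 0.8)
})

test_that("a seeded study simulation reproduces exactly", {
  s1 <- simulate_study(seed = 76)
  s2 <- simulate_study(seed = 76)
  expect_identical(s1$coords, s2$coords)
  expect_identical(s1$meta, s2$meta)
})

test_that("superimposing simulated data gives 2k tangent variables and a centered noise model", {
  sim <- simulate_study(seed = 77)
  g <- gpa_align(sim)
  expect_equal(ncol(g$tangent), 38)           # 19 landmarks -> 2k = 38
  expect_equal(nrow(g$tangent), 950)
  # within each reference group the recovered tangent scatter matches the
  # isotropic noise model: per-coordinate SD near sigma_w (deflated by the
  # four nuisance dimensions projected out), no strong correlation structure
  ref <- sim$meta$group_label
  dev <- do.call(rbind, lapply(unique(stats::na.omit(ref)), function(lv) {
    Xg <- g$tangent[!is.na(ref) & ref == lv, ]
    sweep(Xg, 2, colMeans(Xg))
  }))
  sds <- apply(dev, 2, stats::sd)
  expect_equal(mean(sds), 0.01 * sqrt(34 / 38), tolerance = 0.05)
  cors <- stats::cor(dev)
  expect_lt(mean(abs(cors[upper.tri(cors)])), 0.2)
})

test_that("altitude-size coupling reproduces the target correlation", {
  sim <- simulate_study(seed = 78)
  study <- is.na(sim$meta$group_label)
  r <- stats::cor(centroid_size(sim)[study], sim$meta$altitude_masl[study])
  expect_equal(r, -0.32, tolerance = 0.08)
  # reference wings carry no altitude
  expect_true(all(is.na(sim$meta$altitude_masl[!study])))
})

test_that("raising the hybrid weight pulls populations toward scutellata", {
  set.seed(79)
  means <- make_reference_means(19, 0.08)
  d0 <- sample_population("p", 40, means, c(1, 0, 0, 0) , 0.01, seed = 80)
  d1 <- sample_population("p", 40, means, c(0, 0, 0, 1), 0.01, seed = 80)
  m_scut <- means[["scutellata"]]
  dist_to_scut <- function(d) mean(apply(d$coords, 3, function(m)
    procrustes_fit(m, m_scut)$residual))
  expect_gt(dist_to_scut(d0), dist_to_scut(d1))
})

test_that("simulation output survives the TPS + metadata round-trip", {
  sim <- simulate_study(seed = 81, n_apiaries = 2, colonies_per_apiary = 2,
                        wings_per_colony = 3, n_ref = 4)
  dir <- withr::local_tempdir()
  paths <- save_simulation(sim, dir)
  expect_true(all(file.exists(file.path(dir, c("wings.tps", "metadata.csv",
                                               "config.yml")))))
  back <- attach_metadata(read_tps(file.path(dir, "wings.tps")),
                          file.path(dir, "metadata.csv"))
  expect_equal(back$ids, sim$ids)
  expect_equal(back$coords, sim$coords, tolerance = 1e-5)
  expect_equal(back$meta$apiary, sim$meta$apiary)
  cfg <- yaml::read_yaml(file.path(dir, "config.yml"))
  expect_equal(cfg$seed, 81)
})

test_that("sequence mutation respects the rate parameter", {
  panel <- make_haplotype_panel(3, 400, seed = 82)
  same <- mutate_sequences(panel, rate = 0, n_per = 2, seed = 83)
  expect_true(all(same$seq == panel$seq[match(same$true_haplotype,
                                              panel$haplotype)]))
  qs <- mutate_sequences(panel, rate = 0.03, n_per = 10, seed = 84)
  ident <- mapply(function(s, h) global_align_identity(s, panel$seq[panel$haplotype == h]),
                  qs$seq, qs$true_haplotype)
  expect_equal(mean(ident), 97, tolerance = 0.02)
  expect_error(mutate_sequences(panel, rate = 0.5), "rate")
})
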