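test_that("simulation is reproducible and configs are validated", {
  s1 <- simulate_gift(small_sim_config(n_fam = 10L, fam_size = 6, seed = 3))
  s2 <- simulate_gift(small_sim_config(n_fam = 10L, fam_size = 6, seed = 3))
  expect_identical(s1$records, s2$records)
  expect_identical(as.data.frame(s1$pedigree), as.data.frame(s2$pedigree))
  expect_identical(s1$truth$breeding_values, s2$truth$breeding_values)

  s3 <- simulate_gift(small_sim_config(n_fam = 10L, fam_size = 6, seed = 4))
  expect_false(identical(s1$records$bw, s3$records$bw))

  # non-PSD genetic correlation structure is rejected at validation
  expect_error(
    sim_config(environments = c("A", "B"),
               n_generations = c(A = 1L, B = 1L), n_families = c(A = 5L, B = 5L),
               family_size = c(A = 5, B = 5), transfer_schedule = NULL,
               mean_bw = c(A = 222, B = 222), growout_days = c(A = 230, B = 230),
               sigma_a2 = c(A = 1, B = 1),
               rg = matrix(c(1, 0.99, 0.99, 1), 2, 2,
                           dimnames = list(c("A", "B"), c("A", "B"))),
               sigma_c2 = c(A = 1, B = 1), sigma_e2 = c(A = 1, B = 1),
               sigma_astar2 = 1, rho = c(A = 0.9, B = -0.9),
               sigma_cstar2 = c(A = 0.1, B = 0.1)),
    "positive")
  expect_error(small_sim_config(rho = 1.5), "rho")
})

test_that("record counts scale as generations x families x family size", {
  # scaled-down nucleus: 13 generations x 20 families x Poisson(41) offspring
  cfg <- small_sim_config(n_gen = 13L, n_fam = 20L, fam_size = 41, seed = 6)
  sim <- simulate_gift(cfg)
  expected <- 13 * 20 * 41
  expect_lt(abs(nrow(sim$records) - expected) / expected, 0.05)
  expect_equal(length(unique(sim$records$family)), 13 * 20)
})

test_that("square-root transform recovers the generative analysis scale exactly", {
  sim <- simulate_gift(small_sim_config(n_fam = 12L, fam_size = 8, seed = 7))
  bv <- sim$truth$breeding_values
  t_true <- bv$sqrt_bw[match(sim$records$animal, bv$animal)]
  expect_equal(sqrt_transform(sim$records), t_true, tolerance = 1e-12)
})

test_that("degenerate dispersion config gives homoskedastic residuals", {
  cfg <- small_sim_config(n_fam = 80L, fam_size = 30, sigma_astar2 = 0,
                          rho = 0, sigma_cstar2 = 0, scheme = "random",
                          spawning_sd = 0, seed = 8)
  sim <- simulate_gift(cfg)
  bv <- sim$truth$breeding_values
  fam <- sim$truth$families
  rec <- sim$records
  i <- match(rec$animal, bv$animal)
  f <- match(rec$family, fam$family)
  mu <- sim$truth$intercepts[["MY"]] +
    cfg$sex_effect * (rec$sex == "M") +
    cfg$rearing_effect * (rec$rearing == "pond") +
    cfg$age_slope * (rec$age - cfg$growout_days[["MY"]])
  e <- sqrt(rec$bw) - mu - bv$u_MY[i] - fam$c[f]
  expect_equal(var(e), 1.98, tolerance = 0.1)
})

test_that("full-sib resemblance rises with the hapa variance share", {
  grid <- seq(0.1, 6, length.out = 20)
  icc <- vapply(seq_along(grid), function(k) {
    sim <- simulate_gift(small_sim_config(n_fam = 60L, fam_size = 12,
                                          sigma_c2 = grid[k],
                                          scheme = "random", seed = 100 + k))
    y <- sqrt(sim$records$bw)
    fit <- stats::anova(stats::lm(y ~ factor(sim$records$family)))
    msb <- fit$`Mean Sq`[1]; msw <- fit$`Mean Sq`[2]
    n0 <- 12
    (msb - msw) / (msb + (n0 - 1) * msw)
  }, numeric(1))
  expect_gt(cor(grid, icc, method = "spearman"), 0.9)
})

test_that("selection on body weight lifts mean breeding values across generations", {
  sim <- simulate_gift(small_sim_config(n_gen = 6L, n_fam = 60L,
                                        fam_size = 30, sigma_a2 = 1.84,
                                        sigma_c2 = 0.5, sigma_e2 = 1.0,
                                        seed = 9))
  bv <- sim$truth$breeding_values
  bv <- bv[bv$generation > 0, ]  # recorded offspring generations
  m <- tapply(bv$u_MY, bv$generation, mean)
  expect_true(all(diff(m) > 0))
  # whereas random 'selection' shows no comparable systematic gain
  sim0 <- simulate_gift(small_sim_config(n_gen = 6L, n_fam = 60L,
                                         fam_size = 30, sigma_a2 = 1.84,
                                         sigma_c2 = 0.5, sigma_e2 = 1.0,
                                         scheme = "random", seed = 9))
  bv0 <- sim0$truth$breeding_values
  m0 <- tapply(bv0$u_MY[bv0$generation > 0], bv0$generation[bv0$generation > 0],
               mean)
  expect_lt(m0[length(m0)] - m0[1], m[length(m)] - m[1])
})

test_that("transfers seed the satellite environment with nucleus genetics", {
  sim <- simulate_gift(two_env_config(n_fam = c(MY = 20L, CN = 15L),
                                      fam_size = c(MY = 10, CN = 10),
                                      n_gen = c(MY = 2L, CN = 2L), seed = 10))
  ped <- as.data.frame(sim$pedigree)
  cn <- ped[ped$environment == "CN", ]
  # satellite generation-1 parents are nucleus animals
  par1 <- unique(c(cn$sire[cn$generation == 1], cn$dam[cn$generation == 1]))
  expect_true(all(ped$environment[match(par1, ped$animal)] == "MY"))
  expect_equal(sort(unique(sim$records$environment)), c("CN", "MY"))
})

test_that("datasets round-trip losslessly and rewrites are byte-identical", {
  sim <- simulate_gift(small_sim_config(n_fam = 8L, fam_size = 5, seed = 11))
  d1 <- file.path(tempdir(), "gift_rt1")
  d2 <- file.path(tempdir(), "gift_rt2")
  write_gift(sim, d1)
  back <- read_gift(d1)
  expect_equal(back$records$bw, sim$records$bw)  # full precision retained
  expect_equal(back$records$age, sim$records$age)
  expect_equal(as.data.frame(back$pedigree), as.data.frame(sim$pedigree))
  expect_equal(back$records$generation, sim$records$generation)
  expect_equal(back$truth$config$seed, 11)

  write_gift(sim, d2)
  for (f in c("pedigree.csv", "phenotypes.csv", "truth.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }

  sim$records <- sim$records[0, ]
  expect_error(write_gift(sim, d1), "empty")
})
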