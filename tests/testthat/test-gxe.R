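# Half-sib breeding design generated outside the package machinery:
# n_sire sires each mated to n_dam unrelated dams, one offspring per mating.
halfsib_data <- function(n_sire = 80, n_dam = 8, sigma_a2 = 1.2,
                         sigma_e2 = 2.0, mu = 12, seed = 31) {
  set.seed(seed)
  sires <- sprintf("S%03d", seq_len(n_sire))
  dams <- sprintf("D%04d", seq_len(n_sire * n_dam))
  off <- sprintf("O%04d", seq_len(n_sire * n_dam))
  os <- rep(sires, each = n_dam)
  ped <- pedigree(c(sires, dams, off),
                  c(rep(NA, n_sire + length(dams)), os),
                  c(rep(NA, n_sire + length(dams)), dams))
  us <- rnorm(n_sire, 0, sqrt(sigma_a2))
  ud <- rnorm(length(dams), 0, sqrt(sigma_a2))
  uo <- 0.5 * (rep(us, each = n_dam) + ud) +
    rnorm(length(off), 0, sqrt(sigma_a2 / 2))
  sex <- sample(c("F", "M"), length(off), replace = TRUE)
  age <- runif(length(off), 200, 260)
  y <- mu + 0.5 * (sex == "M") + 0.01 * (age - 230) + uo +
    rnorm(length(off), 0, sqrt(sigma_e2))
  rec <- data.frame(animal = off, environment = "E1", bw = y^2, sex = sex,
                    spawning = 1L, line = "selection", rearing = "pond",
                    age = age, family = rep(dams, 1), generation = 1L,
                    stringsAsFactors = FALSE)
  list(ped = ped, rec = rec, sire = os, y = y)
}

test_that("single-trait posterior mean matches the half-sib ANOVA oracle", {
  hs <- halfsib_data()
  # closed-form oracle: 4 x the sire variance component from a balanced ANOVA
  av <- anova(lm(hs$y ~ factor(hs$sire)))
  sig_s <- (av$`Mean Sq`[1] - av$`Mean Sq`[2]) / 8
  sigma_a2_anova <- 4 * sig_s

  set.seed(1)
  suppressWarnings(
    fit <- fit_gxe(hs$rec, hs$ped, family_effect = FALSE,
                   mcmc = mcmc_control(n_iter = 8000, burnin = 2000,
                                       thin = 5, n_chains = 2)))
  sa2 <- coef(fit)[["G[E1,E1]"]]
  expect_equal(sa2, sigma_a2_anova, tolerance = 0.35 / sigma_a2_anova)
  # conjugate single-trait chains converge under the default diagnostics
  core <- grep("^(G\\[|sige2)", names(fit$psrf), value = TRUE)
  expect_true(all(fit$psrf[core] < 1.1))
})

test_that("homoskedastic variance components are recovered within 15 percent", {
  cfg <- small_sim_config(n_gen = 2L, n_fam = 100L, fam_size = 40,
                          sigma_a2 = 1.8, sigma_c2 = 2.4, sigma_e2 = 2.0,
                          sigma_astar2 = 0, rho = 0, sigma_cstar2 = 0,
                          scheme = "random", seed = 41)
  sim <- simulate_gift(cfg)
  set.seed(2)
  fit <- fit_gxe(sim$records, sim$pedigree,
                 mcmc = mcmc_control(n_iter = 30000, burnin = 8000,
                                     thin = 10, n_chains = 3))
  est <- coef(fit)
  expect_equal(est[["G[MY,MY]"]], 1.8, tolerance = 0.15)
  expect_equal(est[["sigc2[MY]"]], 2.4, tolerance = 0.15)
  expect_equal(est[["sige2[MY]"]], 2.0, tolerance = 0.15)
  expect_equal(est[["h2[MY]"]], 1.8 / 6.2, tolerance = 0.15)
})

test_that("genetic correlations follow the covariance-to-correlation formula", {
  expect_equal(genetic_correlations(diag(3)), diag(3))
  expect_equal(genetic_correlations(matrix(c(1, 0.7, 0.7, 1), 2))[1, 2], 0.7)

  set.seed(5)
  L <- matrix(rnorm(9), 3)
  G <- crossprod(L) + diag(0.1, 3)
  R <- genetic_correlations(G)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(R[i, j], G[i, j] / sqrt(G[i, i] * G[j, j]))
  }
  expect_error(genetic_correlations(matrix(c(0, 0, 0, 1), 2)), "diagonal")
})

test_that("retained genetic-correlation samples respect the [-1, 1] bound", {
  sim <- simulate_gift(two_env_config(n_fam = c(MY = 20L, CN = 15L),
                                      fam_size = c(MY = 10, CN = 10),
                                      seed = 51))
  set.seed(3)
  fit <- fit_gxe(sim$records, sim$pedigree,
                 mcmc = mcmc_control(n_iter = 2000, burnin = 500, thin = 5,
                                     n_chains = 2))
  rg <- do.call(rbind, fit$chains)[, "rg[MY,CN]"]
  expect_true(all(abs(rg) <= 1))
  # point estimates are a valid correlation matrix
  expect_true(all(abs(fit$rg) <= 1))
  expect_equal(diag(fit$rg), c(MY = 1, CN = 1))
})

test_that("trait-order permutation permutes the estimates consistently", {
  sim <- simulate_gift(two_env_config(n_fam = c(MY = 30L, CN = 25L),
                                      fam_size = c(MY = 15, CN = 15),
                                      n_gen = c(MY = 2L, CN = 1L),
                                      seed = 52))
  set.seed(4)
  f1 <- fit_gxe(sim$records, sim$pedigree, envs = c("MY", "CN"),
                mcmc = mcmc_control(n_iter = 6000, burnin = 1500, thin = 5,
                                    n_chains = 2))
  set.seed(4)
  f2 <- fit_gxe(sim$records, sim$pedigree, envs = c("CN", "MY"),
                mcmc = mcmc_control(n_iter = 6000, burnin = 1500, thin = 5,
                                    n_chains = 2))
  # same posterior up to Monte-Carlo error, with labels permuted: the
  # permuted fit's point estimate falls inside the other fit's 95% HPD
  hpd_of <- function(fit, par) {
    unlist(fit$summary[match(par, fit$summary$parameter),
                       c("hpd_lo", "hpd_hi")])
  }
  for (e in c("MY", "CN")) {
    h <- hpd_of(f1, paste0("G[", e, ",", e, "]"))
    expect_gte(f2$G[e, e], h[1]); expect_lte(f2$G[e, e], h[2])
  }
  h <- hpd_of(f1, "rg[MY,CN]")
  expect_gte(f2$rg["CN", "MY"], h[1]); expect_lte(f2$rg["CN", "MY"], h[2])
  expect_identical(rownames(f1$rg), c("MY", "CN"))
  expect_identical(rownames(f2$rg), c("CN", "MY"))
})

test_that("disconnected trait blocks are flagged as prior-identified", {
  # two founder populations with no shared ancestry, one per environment
  n <- 40
  ped <- pedigree(sprintf("U%03d", 1:(2 * n)), rep(NA, 2 * n), rep(NA, 2 * n))
  set.seed(6)
  rec <- data.frame(animal = sprintf("U%03d", 1:(2 * n)),
                    environment = rep(c("MY", "CN"), each = n),
                    bw = runif(2 * n, 150, 350),
                    sex = sample(c("F", "M"), 2 * n, TRUE),
                    spawning = 1L, line = "selection", rearing = "pond",
                    age = runif(2 * n, 200, 260),
                    family = rep(sprintf("f%02d", 1:8), length.out = 2 * n),
                    generation = 1L, stringsAsFactors = FALSE)
  w <- capture_warnings(
    fit_gxe(rec, ped, mcmc = mcmc_control(n_iter = 300, burnin = 100,
                                          thin = 2, n_chains = 2)))
  expect_true(any(grepl("no pedigree ancestry", w)))
})

test_that("each animal may be recorded in only one environment", {
  sim <- simulate_gift(small_sim_config(n_fam = 6L, fam_size = 4, seed = 53))
  rec2 <- sim$records
  rec2$environment[1] <- "CN"
  rec2 <- rbind(rec2, transform(sim$records[1, ], environment = "MY"))
  expect_error(fit_gxe(rec2, sim$pedigree), "exactly one environment")
})

test_that("per-generation trend series is computed and flags bad input", {
  sim <- simulate_gift(two_env_config(n_fam = c(MY = 15L, CN = 12L),
                                      fam_size = c(MY = 8, CN = 8),
                                      n_gen = c(MY = 1L, CN = 2L), seed = 54))
  set.seed(7)
  tr <- gxe_trend(sim$records, sim$pedigree, "CN",
                  mcmc = mcmc_control(n_iter = 1500, burnin = 500, thin = 5,
                                      n_chains = 2))
  expect_equal(tr$generation, c(1, 2))
  expect_true(all(is.finite(tr$rg)))
  expect_true(all(abs(tr$rg) <= 1))
  expect_true(all(tr$hpd_lo <= tr$rg & tr$rg <= tr$hpd_hi))

  expect_error(gxe_trend(sim$records, sim$pedigree, "CN", generations = 7),
               "generation 7")
})
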