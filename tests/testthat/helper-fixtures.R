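# Shared fixtures and independent oracles for the test suite.
# Oracles here are deliberately naive (double loops, dense algebra) and
# independent of the package's compiled kernels.

# Random valid pedigree: animals added sequentially, parents drawn among
# earlier animals with probability p_parent (possibly one unknown parent).
random_pedigree <- function(n, p_parent = 0.7, seed = 1) {
  set.seed(seed)
  animal <- sprintf("R%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in 3:n) {
    if (runif(1) < p_parent) {
      sire[i] <- animal[sample.int(i - 1L, 1L)]
      if (runif(1) < 0.9) {
        repeat {
          d <- animal[sample.int(i - 1L, 1L)]
          if (d != sire[i]) break
        }
        dam[i] <- d
      }
    }
  }
  pedigree(animal, sire, dam)
}

# Naive dense tabular-method oracle (plain R double loop over a sorted
# pedigree data frame with NA-coded unknown parents).
amatrix_oracle <- function(ped) {
  n <- nrow(ped)
  pos <- seq_len(n)
  names(pos) <- ped$animal
  s <- ifelse(is.na(ped$sire), 0L, pos[ped$sire])
  d <- ifelse(is.na(ped$dam), 0L, pos[ped$dam])
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1L)) {
      v <- 0
      if (s[j] > 0L) v <- v + 0.5 * A[i, s[j]]
      if (d[j] > 0L) v <- v + 0.5 * A[i, d[j]]
      A[i, j] <- A[j, i] <- v
    }
    A[j, j] <- 1 + if (s[j] > 0L && d[j] > 0L) 0.5 * A[s[j], d[j]] else 0
  }
  dimnames(A) <- list(ped$animal, ped$animal)
  A
}

# Five-animal pedigree with a full-sib mating (inbred final animal).
fullsib_mating_pedigree <- function() {
  pedigree(animal = c("s", "d", "o1", "o2", "x"),
           sire   = c(NA, NA, "s", "s", "o1"),
           dam    = c(NA, NA, "d", "d", "o2"))
}

# Small single-environment simulation used across tests.
small_sim_config <- function(n_gen = 1L, n_fam = 40L, fam_size = 20,
                             sigma_a2 = 1.84, sigma_c2 = 2.43,
                             sigma_e2 = 1.98, sigma_astar2 = 0.34,
                             rho = -0.53, sigma_cstar2 = 0.14,
                             scheme = "family", p_control = 0,
                             spawning_sd = 0.5, seed = 1) {
  sim_config(environments = "MY",
             n_generations = c(MY = n_gen), n_families = c(MY = n_fam),
             family_size = c(MY = fam_size), transfer_schedule = NULL,
             mean_bw = c(MY = 222), growout_days = c(MY = 230),
             sigma_a2 = c(MY = sigma_a2),
             rg = matrix(1, 1, 1, dimnames = list("MY", "MY")),
             sigma_c2 = c(MY = sigma_c2), sigma_e2 = c(MY = sigma_e2),
             sigma_astar2 = sigma_astar2, rho = c(MY = rho),
             sigma_cstar2 = c(MY = sigma_cstar2),
             selection = list(scheme = scheme, frac_family = 0.5),
             p_control = p_control, spawning_sd = spawning_sd, seed = seed)
}

# Two-environment config: nucleus plus one satellite founded by transfer.
two_env_config <- function(n_fam = c(MY = 40L, CN = 40L),
                           fam_size = c(MY = 20, CN = 20),
                           rg_val = 0.7, n_gen = c(MY = 1L, CN = 1L),
                           sigma_astar2 = 0.1,
                           rho = c(MY = 0, CN = 0), seed = 1, ...) {
  sim_config(environments = c("MY", "CN"),
             n_generations = n_gen, n_families = n_fam,
             family_size = fam_size,
             transfer_schedule = data.frame(from = "MY", to = "CN",
                                            generation = n_gen["MY"],
                                            n_families = min(30L, n_fam[["MY"]])),
             mean_bw = c(MY = 222, CN = 244),
             growout_days = c(MY = 230, CN = 344),
             sigma_a2 = c(MY = 1.84, CN = 1.74),
             rg = matrix(c(1, rg_val, rg_val, 1), 2, 2,
                         dimnames = list(c("MY", "CN"), c("MY", "CN"))),
             sigma_c2 = c(MY = 2.43, CN = 1.70),
             sigma_e2 = c(MY = 1.98, CN = 2.62),
             sigma_astar2 = sigma_astar2, rho = rho,
             sigma_cstar2 = c(MY = 0.14, CN = 0.122),
             p_control = 0, seed = seed, ...)
}
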