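#' Configuration for the multi-environment breeding-program simulator
#'
#' Defaults emulate the GIFT tilapia design: a 13-generation nucleus program
#' in Malaysia (`MY`) with a selection and a control line, satellite programs
#' founded by transferring offspring of 60 nucleus families to China (`CN`)
#' after five generations and to India (`IN`) after nine, between- and
#' within-family selection on harvest body weight, and full-sib families
#' reared together in hapas (one net enclosure per family) that induce a
#' common-environment effect on both the mean and the log residual variance.
#'
#' Genetic truths default to the estimates the package's models are designed
#' to recover: per-environment additive variances on the square-root-gram
#' scale, cross-environment genetic correlations (the G\eqn{\times}E
#' structure), a genetic effect on the log residual variance with variance
#' `sigma_astar2`, and a mean--variance genetic correlation `rho` per
#' environment. Each founder carries one 4-variate normal breeding-value
#' vector (one mean-level value per environment plus one dispersion value);
#' descendants follow the standard recursion with inbreeding-adjusted
#' Mendelian sampling variance.
#'
#' @param environments character vector of environment labels; the first is
#'   the nucleus.
#' @param n_generations named integer vector: generations bred per environment.
#' @param n_families named integer vector: full-sib families per generation.
#' @param family_size named numeric vector: mean family size (Poisson).
#' @param transfer_schedule data frame with columns `from`, `to`, `generation`,
#'   `n_families`: offspring of that many randomly chosen nucleus families are
#'   shipped to found the satellite program at the stated nucleus generation.
#' @param mean_bw named vector, target mean raw body weight (g) per environment.
#' @param growout_days named vector, mean grow-out period (days); harvest age
#'   is drawn uniformly within 15 percent of it.
#' @param sigma_a2 named vector, additive genetic variance of the mean
#'   (square-root-gram scale) per environment.
#' @param rg cross-environment genetic correlation matrix (dimnames =
#'   environments).
#' @param sigma_c2 named vector, common-environment (hapa) variance on the mean.
#' @param sigma_e2 named vector, baseline residual variance; its log is the
#'   intercept of the log-variance model.
#' @param sigma_astar2 scalar, additive genetic variance of the log residual
#'   variance (one dispersion effect per animal).
#' @param rho named vector, genetic correlation between the mean-level
#'   breeding value in that environment and the dispersion breeding value.
#' @param sigma_cstar2 named vector, hapa variance on the log residual variance.
#' @param sex_effect fixed effect of male sex on the square-root scale.
#' @param spawning_sd SD of per-spawning-season effects (drawn once per
#'   environment and generation; a spawning season coincides with a generation).
#' @param line_effect fixed effect of the selection line (nucleus only).
#' @param rearing_effect fixed effect of pond vs. cage rearing (per hapa).
#' @param age_slope regression of square-root body weight on harvest age
#'   (per day).
#' @param selection list: `scheme` (`"family"` for between- and within-family
#'   selection, `"mass"`, or `"random"`) and `frac_family`, the fraction of
#'   families retained before within-family ranking.
#' @param dams_per_sire nested-mating ratio: each selected sire is mated to
#'   this many dams (default 2, giving the paternal half-sib structure that
#'   separates additive from hapa variance; 1 gives strict pair mating).
#' @param p_control fraction of nucleus families bred as the unselected
#'   control line.
#' @param seed integer seed; all randomness derives from it.
#' @return a validated `sim_config` list.
#' @seealso [simulate_gift()]
#' @export
sim_config <- function(environments = c("MY", "CN", "IN"),
                       n_generations = c(MY = 13L, CN = 3L, IN = 4L),
                       n_families = c(MY = 87L, CN = 71L, IN = 54L),
                       family_size = c(MY = 41, CN = 32, IN = 52),
                       transfer_schedule = data.frame(
                         from = c("MY", "MY"), to = c("CN", "IN"),
                         generation = c(5L, 9L), n_families = c(60L, 60L),
                         stringsAsFactors = FALSE),
                       mean_bw = c(MY = 222, CN = 244, IN = 313),
                       growout_days = c(MY = 230, CN = 344, IN = 232),
                       sigma_a2 = c(MY = 1.84, CN = 1.74, IN = 0.72),
                       rg = matrix(c(1, 0.71, 0.37,
                                     0.71, 1, 0.33,
                                     0.37, 0.33, 1), 3, 3,
                                   dimnames = list(c("MY", "CN", "IN"),
                                                   c("MY", "CN", "IN"))),
                       sigma_c2 = c(MY = 2.43, CN = 1.70, IN = 0.73),
                       sigma_e2 = c(MY = 1.98, CN = 2.62, IN = 2.16),
                       sigma_astar2 = 0.34,
                       rho = c(MY = -0.53, CN = -0.70, IN = -0.03),
                       sigma_cstar2 = c(MY = 0.14, CN = 0.122, IN = 0.09),
                       sex_effect = 1.5,
                       spawning_sd = 0.5,
                       line_effect = 0.5,
                       rearing_effect = 0.5,
                       age_slope = 0.03,
                       selection = list(scheme = "family", frac_family = 0.5),
                       dams_per_sire = 2L,
                       p_control = 0.1,
                       seed = 1L) {
  cfg <- list(environments = environments,
              n_generations = n_generations, n_families = n_families,
              family_size = family_size, transfer_schedule = transfer_schedule,
              mean_bw = mean_bw, growout_days = growout_days,
              sigma_a2 = sigma_a2, rg = rg, sigma_c2 = sigma_c2,
              sigma_e2 = sigma_e2, sigma_astar2 = sigma_astar2, rho = rho,
              sigma_cstar2 = sigma_cstar2, sex_effect = sex_effect,
              spawning_sd = spawning_sd, line_effect = line_effect,
              rearing_effect = rearing_effect, age_slope = age_slope,
              selection = selection, dams_per_sire = as.integer(dams_per_sire),
              p_control = p_control,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  envs <- cfg$environments
  ne <- length(envs)
  for (nm in c("n_generations", "n_families", "family_size", "mean_bw",
               "growout_days", "sigma_a2", "sigma_c2", "sigma_e2", "rho",
               "sigma_cstar2")) {
    v <- cfg[[nm]]
    if (!all(envs %in% names(v))) {
      stop("config field '", nm, "' must be named for every environment")
    }
  }
  if (!is.matrix(cfg$rg) || !all(envs %in% rownames(cfg$rg))) {
    stop("rg must be a correlation matrix with environment dimnames")
  }
  for (v in c(cfg$sigma_a2[envs], cfg$sigma_c2[envs], cfg$sigma_e2[envs],
              cfg$sigma_cstar2[envs], cfg$sigma_astar2)) {
    if (v < 0) stop("variances must be non-negative")
  }
  if (any(abs(cfg$rho[envs]) > 1)) stop("|rho| must be <= 1")
  if (any(abs(cfg$rg) > 1)) stop("|rg| entries must be <= 1")
  fr <- cfg$selection$frac_family
  if (!is.null(fr) && (fr <= 0 || fr > 1)) stop("frac_family must be in (0, 1]")
  if (!cfg$selection$scheme %in% c("family", "mass", "random")) {
    stop("selection scheme must be one of 'family', 'mass', 'random'")
  }
  if (is.null(cfg$dams_per_sire) || cfg$dams_per_sire < 1L) {
    stop("dams_per_sire must be a positive integer")
  }
  # joint 4-variate (mean levels + dispersion) covariance must be PSD
  Sig <- bv_covariance(cfg)
  ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(ev)) {
    stop("configured genetic correlation structure is not positive ",
         "semi-definite (min eigenvalue ", format(min(ev)), ")")
  }
  invisible(cfg)
}

# Joint covariance of (u_env1, ..., u_envK, u*) for one base-population animal.
bv_covariance <- function(cfg) {
  envs <- cfg$environments
  ne <- length(envs)
  sa <- sqrt(cfg$sigma_a2[envs])
  sstar <- sqrt(cfg$sigma_astar2)
  Sig <- matrix(0, ne + 1L, ne + 1L,
                dimnames = list(c(envs, "ustar"), c(envs, "ustar")))
  Sig[seq_len(ne), seq_len(ne)] <-
    cfg$rg[envs, envs, drop = FALSE] * tcrossprod(sa)
  Sig[seq_len(ne), ne + 1L] <- cfg$rho[envs] * sa * sstar
  Sig[ne + 1L, seq_len(ne)] <- Sig[seq_len(ne), ne + 1L]
  Sig[ne + 1L, ne + 1L] <- sstar^2
  Sig
}

#' Simulate a multi-environment breeding program
#'
#' Runs the breeding design described in [sim_config()]: founders are drawn
#' with joint mean- and dispersion-level breeding values, full-sib families
#' are produced by pairing selected sires and dams (one dam per sire per
#' spawning season), each family is reared in its own hapa with common
#' environmental effects on the mean and on the log residual variance, and
#' satellite environments are founded from transferred nucleus families.
#' Phenotypes are generated on the square-root-gram analysis scale
#' \deqn{t = \mu_E + \mathrm{fixed} + \beta(\mathrm{age}-\bar{a}) + u_E + c + e,
#'   \quad e \sim N(0, \exp(\log\sigma^2_{e,E} + u^* + c^*))}
#' and squared to raw grams, so the documented square-root transformation is
#' exactly model-consistent.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `gift_sim`: a list with elements
#'   `pedigree` (a [pedigree()] object), `records` (phenotype data frame with
#'   columns `animal`, `environment`, `bw`, `sex`, `spawning`, `line`,
#'   `rearing`, `age`, `family`, `generation`), and `truth` (the ledger of
#'   realized effects: config echo, per-animal breeding values, per-family
#'   hapa effects, fixed-effect values and per-environment intercepts).
#' @examples
#' cfg <- sim_config(environments = "MY",
#'                   n_generations = c(MY = 2L), n_families = c(MY = 10L),
#'                   family_size = c(MY = 10), transfer_schedule = NULL,
#'                   seed = 7)
#' sim <- simulate_gift(cfg)
#' nrow(sim$records)
#' @export
simulate_gift <- function(config = sim_config()) {
  cfg <- config
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  envs <- cfg$environments
  nucleus <- envs[1L]
  ne <- length(envs)
  Sig <- bv_covariance(cfg)
  Lsig <- t(chol(Sig + diag(1e-12, ne + 1L)))

  ts <- cfg$transfer_schedule
  if (is.null(ts)) {
    ts <- data.frame(from = character(), to = character(),
                     generation = integer(), n_families = integer())
  }

  # growing pedigree state
  id <- character(0); sire <- character(0); dam <- character(0)
  gen <- integer(0); env_of <- character(0)
  sex <- character(0); fam_of <- character(0)
  Fcoef <- numeric(0)
  U <- matrix(numeric(0), 0, ne + 1L)
  counter <- 0L
  new_ids <- function(k) sprintf("A%07d", seq.int(counter + 1L, counter + k))

  # per-environment fixed-effect truths
  spawn_eff <- lapply(envs, function(e) {
    stats::rnorm(cfg$n_generations[e], 0, cfg$spawning_sd)
  })
  names(spawn_eff) <- envs
  intercept <- vapply(envs, function(e) {
    base <- sqrt(cfg$mean_bw[e]) - 0.5 * cfg$sex_effect -
      0.5 * cfg$rearing_effect - mean(spawn_eff[[e]])
    if (e == nucleus) base <- base - (1 - cfg$p_control) * cfg$line_effect
    unname(base)
  }, numeric(1))
  names(intercept) <- envs

  fam_rows <- list()   # per-family truth: family, env, c, cstar, rearing, line
  fam_line <- character(0)  # family id -> line label (named)
  rec_rows <- list()
  pheno_of <- numeric(0)  # sqrt-scale phenotype aligned with id (NA = no record)
  transfer_pool <- list()  # per target env: data.frame of parent candidates

  draw_bv_founders <- function(k) t(Lsig %*% matrix(stats::rnorm((ne + 1L) * k),
                                                    ne + 1L, k))

  # breed one generation in environment `e` from a parent table
  # parents: data.frame(id, family, sex) restricted to one line
  breed <- function(e, g, matings, line_label) {
    n_off_each <- pmax(2L, stats::rpois(nrow(matings), cfg$family_size[e]))
    ei <- match(e, envs)
    for (m in seq_len(nrow(matings))) {
      sid <- matings$sire[m]; did <- matings$dam[m]
      k <- n_off_each[m]
      ids <- new_ids(k)
      counter <<- counter + k
      fam <- sprintf("%s_g%d_f%03d", e, g, m)
      si <- match(sid, id); di <- match(did, id)
      msv <- 0.5 - 0.25 * (Fcoef[si] + Fcoef[di])
      mids <- t(Lsig %*% matrix(stats::rnorm((ne + 1L) * k), ne + 1L, k)) *
        sqrt(msv)
      u_par <- 0.5 * (U[si, ] + U[di, ])
      u_kids <- sweep(mids, 2L, u_par, "+")
      kid_sex <- ifelse(stats::rbinom(k, 1L, 0.5) == 1L, "M", "F")
      c_fam <- stats::rnorm(1, 0, sqrt(cfg$sigma_c2[e]))
      cs_fam <- stats::rnorm(1, 0, sqrt(cfg$sigma_cstar2[e]))
      rearing <- sample(c("cage", "pond"), 1L)
      age <- stats::runif(k, 0.85 * cfg$growout_days[e],
                          1.15 * cfg$growout_days[e])
      eta <- log(cfg$sigma_e2[e]) + u_kids[, ne + 1L] + cs_fam
      eres <- stats::rnorm(k, 0, sqrt(exp(eta)))
      t_val <- intercept[e] +
        cfg$sex_effect * (kid_sex == "M") +
        spawn_eff[[e]][g] +
        (if (e == nucleus) cfg$line_effect * (line_label == "selection") else 0) +
        cfg$rearing_effect * (rearing == "pond") +
        cfg$age_slope * (age - cfg$growout_days[e]) +
        u_kids[, ei] + c_fam + eres
      t_val <- pmax(t_val, 0.05)  # guard: raw weight must stay positive

      id <<- c(id, ids); sire <<- c(sire, rep(sid, k)); dam <<- c(dam, rep(did, k))
      gen <<- c(gen, rep(g, k)); env_of <<- c(env_of, rep(e, k))
      sex <<- c(sex, kid_sex); fam_of <<- c(fam_of, rep(fam, k))
      U <<- rbind(U, u_kids)
      Fcoef <<- c(Fcoef, rep(NA_real_, k))  # filled after the generation
      pheno_of <<- c(pheno_of, t_val)
      fam_line[fam] <<- line_label

      fam_rows[[length(fam_rows) + 1L]] <<- data.frame(
        family = fam, environment = e, generation = g, line = line_label,
        c = c_fam, cstar = cs_fam, rearing = rearing,
        stringsAsFactors = FALSE)
      rec_rows[[length(rec_rows) + 1L]] <<- data.frame(
        animal = ids, environment = e, bw = t_val^2, sex = kid_sex,
        spawning = g, line = line_label, rearing = rearing, age = age,
        family = fam, generation = g, stringsAsFactors = FALSE)
    }
  }

  refresh_inbreeding <- function() {
    si <- ifelse(is.na(sire) | !(sire %in% id), -1L, match(sire, id) - 1L)
    di <- ifelse(is.na(dam) | !(dam %in% id), -1L, match(dam, id) - 1L)
    Fcoef <<- inbreeding_cpp(as.integer(si), as.integer(di))
  }

  # between-and-within-family (or mass/random) choice of sires and dams;
  # nested mating: each sire serves `dams_per_sire` dams (paternal half sibs)
  select_parents <- function(cand, n_matings, scheme) {
    # cand: data.frame(id, family, sex, pheno)
    dps <- cfg$dams_per_sire
    pick_sex <- function(s, need) {
      pool <- cand[cand$sex == s, , drop = FALSE]
      if (nrow(pool) == 0L) stop("no candidates of sex ", s)
      if (scheme == "random") {
        return(pool$id[sample.int(nrow(pool), min(need, nrow(pool)))])
      }
      if (scheme == "mass") {
        pool <- pool[order(-pool$pheno, pool$id), , drop = FALSE]
        return(utils::head(pool$id, need))
      }
      # family scheme: rank families by family mean, keep top fraction,
      # then take best individuals round-robin across selected families
      fm <- tapply(cand$pheno, cand$family, mean)
      keep_n <- max(1L, ceiling(cfg$selection$frac_family * length(fm)))
      keep <- names(sort(fm, decreasing = TRUE))[seq_len(keep_n)]
      pool <- pool[pool$family %in% keep, , drop = FALSE]
      pool <- pool[order(pool$family, -pool$pheno, pool$id), , drop = FALSE]
      pool$rank_in_fam <- stats::ave(pool$pheno, pool$family,
                                     FUN = function(z) seq_along(z))
      pool <- pool[order(pool$rank_in_fam, -pool$pheno, pool$id), , drop = FALSE]
      utils::head(pool$id, need)
    }
    sires <- pick_sex("M", max(1L, ceiling(n_matings / dps)))
    dams <- pick_sex("F", n_matings)
    n <- min(length(sires) * dps, length(dams), n_matings)
    dams <- dams[sample.int(length(dams))][seq_len(n)]  # random allocation
    data.frame(sire = rep(sires, each = dps)[seq_len(n)], dam = dams,
               stringsAsFactors = FALSE)
  }

  candidates <- function(e, g, line_label) {
    idx <- which(env_of == e & gen == g)
    idx <- idx[fam_line[fam_of[idx]] == line_label]
    data.frame(id = id[idx], family = fam_of[idx], sex = sex[idx],
               pheno = pheno_of[idx], stringsAsFactors = FALSE)
  }
  fam_line_lookup <- function(fams) unname(fam_line[fams])

  ## ---- nucleus founders ----
  n_fam0 <- cfg$n_families[nucleus]
  nf <- 2L * n_fam0
  fids <- new_ids(nf); counter <- counter + nf
  id <- fids; sire <- rep(NA_character_, nf); dam <- rep(NA_character_, nf)
  gen <- rep(0L, nf); env_of <- rep(nucleus, nf)
  sex <- rep(c("M", "F"), length.out = nf)
  fam_of <- rep("", nf); Fcoef <- rep(0, nf)
  pheno_of <- rep(NA_real_, nf)
  U <- draw_bv_founders(nf)

  n_control <- if (ne >= 1) max(0L, round(cfg$p_control * n_fam0)) else 0L

  ## ---- nucleus generations ----
  for (g in seq_len(cfg$n_generations[nucleus])) {
    if (g == 1L) {
      males <- id[sex == "M" & gen == 0L]
      females <- id[sex == "F" & gen == 0L]
      females <- females[sample.int(length(females))]
      dps <- cfg$dams_per_sire
      matings <- data.frame(
        sire = rep(males[seq_len(ceiling(n_fam0 / dps))],
                   each = dps)[seq_len(n_fam0)],
        dam = females[seq_len(n_fam0)],
        stringsAsFactors = FALSE)
      line_of_mating <- rep("selection", n_fam0)
      if (n_control > 0L) {
        line_of_mating[sample.int(n_fam0, n_control)] <- "control"
      }
      for (l in unique(line_of_mating)) {
        breed(nucleus, g, matings[line_of_mating == l, , drop = FALSE], l)
      }
    } else {
      for (l in c("selection", if (n_control > 0L) "control")) {
        n_mat <- if (l == "control") n_control else cfg$n_families[nucleus] - n_control
        cand <- candidates(nucleus, g - 1L, l)
        scheme <- if (l == "control") "random" else cfg$selection$scheme
        matings <- select_parents(cand, n_mat, scheme)
        breed(nucleus, g, matings, l)
      }
    }
    refresh_inbreeding()

    # ship representatives of randomly chosen selection-line families
    tr <- ts[ts$from == nucleus & ts$generation == g, , drop = FALSE]
    for (r in seq_len(nrow(tr))) {
      tgt <- tr$to[r]
      idx <- which(env_of == nucleus & gen == g)
      fams <- fam_of[idx]
      lines <- fam_line_lookup(fams)
      sel_fams <- unique(fams[lines == "selection"])
      take <- sel_fams[sample.int(length(sel_fams),
                                  min(tr$n_families[r], length(sel_fams)))]
      need_each <- ceiling(2 * cfg$n_families[tgt] / length(take))
      pool_idx <- integer(0)
      for (f in take) {
        fi <- idx[fam_of[idx] == f]
        fi <- fi[sample.int(length(fi))]
        pool_idx <- c(pool_idx, utils::head(fi, need_each))
      }
      transfer_pool[[tgt]] <- data.frame(
        id = id[pool_idx], family = fam_of[pool_idx], sex = sex[pool_idx],
        pheno = 0, stringsAsFactors = FALSE)
    }
  }

  ## ---- satellite environments ----
  for (e in setdiff(envs, nucleus)) {
    for (g in seq_len(cfg$n_generations[e])) {
      if (g == 1L) {
        pool <- transfer_pool[[e]]
        if (is.null(pool)) {
          stop("no transfer schedule delivers founders to environment ", e)
        }
        matings <- select_parents(pool, cfg$n_families[e], "random")
      } else {
        cand <- candidates(e, g - 1L, "selection")
        matings <- select_parents(cand, cfg$n_families[e],
                                  cfg$selection$scheme)
      }
      breed(e, g, matings, "selection")
      refresh_inbreeding()
    }
  }

  records <- do.call(rbind, rec_rows)
  rownames(records) <- NULL
  if (is.null(records) || nrow(records) == 0L) stop("simulation produced no records")
  ped <- pedigree(id, sire, dam, generation = gen, environment = env_of)

  bv <- data.frame(animal = id, stringsAsFactors = FALSE)
  colnames(U) <- c(paste0("u_", envs), "ustar")
  bv <- cbind(bv, as.data.frame(U), F = Fcoef, generation = gen,
              environment = env_of, sqrt_bw = pheno_of)
  truth <- list(config = cfg,
                intercepts = intercept,
                spawning_effects = spawn_eff,
                breeding_values = bv,
                families = do.call(rbind, fam_rows))
  structure(list(pedigree = ped, records = records, truth = truth),
            class = "gift_sim")
}

#' @export
print.gift_sim <- function(x, ...) {
  cat("Simulated breeding program:", nrow(x$pedigree), "animals,",
      nrow(x$records), "records\n")
  tab <- table(x$records$environment)
  cat("Records per environment:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes `pedigree.csv`, `phenotypes.csv` (header
#' `animal,environment,bw,sex,spawning,line,rearing,age,family`) and
#' `truth.json` (the realized-effect ledger, including the seed) into `dir`.
#' Numeric columns are written with 17 significant digits so a write/read
#' round trip is lossless.
#'
#' @param sim a [simulate_gift()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_gift <- function(sim, dir) {
  stopifnot(inherits(sim, "gift_sim"))
  if (nrow(sim$records) == 0L) stop("empty record list")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(sim$pedigree, file.path(dir, "pedigree.csv"))
  rec <- sim$records[, c("animal", "environment", "bw", "sex", "spawning",
                         "line", "rearing", "age", "family")]
  rec$bw <- sprintf("%.17g", rec$bw)
  rec$age <- sprintf("%.17g", rec$age)
  utils::write.csv(rec, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  truth$config$transfer_schedule <- as.data.frame(truth$config$transfer_schedule)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "columns",
                       matrix = "rowmajor")
  invisible(dir)
}

#' Read a dataset written by [write_gift()]
#'
#' @param dir directory containing `pedigree.csv` and `phenotypes.csv`.
#' @return list with `pedigree`, `records` (with `generation` joined back from
#'   the pedigree) and, when present, the parsed `truth` ledger.
#' @export
read_gift <- function(dir) {
  ped <- read_pedigree(file.path(dir, "pedigree.csv"))
  rec <- utils::read.csv(file.path(dir, "phenotypes.csv"),
                         colClasses = c(animal = "character",
                                        family = "character"))
  rec$generation <- ped$generation[match(rec$animal, ped$animal)]
  out <- list(pedigree = ped, records = rec)
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) out$truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  out
}
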