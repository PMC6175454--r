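#' Fit the multi-trait animal model for genotype-by-environment interaction
#'
#' Treats square-root body weight in each environment as a different trait of
#' the same genotype and fits
#' \deqn{y = Xb + Za + Wc + e, \quad
#'   \mathrm{Var}(a) = A \otimes G, \ \mathrm{Var}(c) = I \otimes C, \
#'   \mathrm{Var}(e) = I \otimes R,}
#' with \eqn{A} the pedigree relationship matrix. \eqn{C} and \eqn{R} are
#' diagonal (no animal or hapa is recorded in two environments, so cross-trait
#' residual and common-environment covariances are not identifiable); only
#' \eqn{G} has estimable off-diagonals, and its correlations
#' \eqn{r_g = G_{kl}/\sqrt{G_{kk}G_{ll}}} measure the magnitude of
#' G\eqn{\times}E (genotype re-ranking). Inference is by Gibbs sampling with
#' weakly informative inverse-Wishart and scaled-inverse-chi-square priors;
#' posterior means are the point estimates.
#'
#' @param records phenotype data frame covering one or more environments.
#' @param ped the joint [pedigree()] across all environments.
#' @param envs environments to model as traits (default: all present, in
#'   order of appearance).
#' @param mcmc an [mcmc_control()]; default 50,000 iterations, 10,000 burn-in,
#'   thin 10, 3 chains.
#' @param prior list: `nu_g`, `S_g` (inverse-Wishart on G; defaults `t + 2`
#'   and `0.1 diag(var(y_k))` — prior scales track the phenotypic variance so
#'   the prior is invariant to the trait's measurement unit), `nu_s`, `s2_c`,
#'   `s2_e` (scaled-inv-chi-square on the hapa and residual variances;
#'   defaults 3 and `0.1 var(y)`).
#' @param family_effect include the hapa common-environment effect
#'   (default `TRUE`).
#' @return an object of class `gxe_fit`: posterior summaries (`summary`),
#'   estimated `G`, `rg`, per-trait `h2`, `c2`, retained `chains`, convergence
#'   diagnostics, and posterior-mean fixed effects and breeding values.
#' @seealso [genetic_correlations()], [gxe_trend()]
#' @export
fit_gxe <- function(records, ped, envs = NULL,
                    mcmc = mcmc_control(n_iter = 50000L, burnin = 10000L,
                                        thin = 10L, n_chains = 3L),
                    prior = list(), family_effect = TRUE) {
  stopifnot(inherits(ped, "gift_pedigree"))
  if (is.null(envs)) envs <- unique(records$environment)
  t <- length(envs)
  if (t < 1L) stop("no environments to fit")
  seen <- records$animal[records$environment %in% envs]
  if (anyDuplicated(seen)) {
    stop("each animal must be recorded in exactly one environment")
  }
  bundles <- lapply(envs, function(e) build_design(records, e, ped))
  names(bundles) <- envs

  vy <- vapply(bundles, function(b) stats::var(b$y), numeric(1))
  # default prior scales follow the observed phenotypic variance so the
  # prior is invariant to the measurement unit of the trait
  prior <- utils::modifyList(
    list(nu_g = t + 2, S_g = diag(0.1 * vy, t), nu_s = 3,
         s2_c = 0.1 * mean(vy), s2_e = 0.1 * mean(vy)),
    prior)
  Acsc <- csc_parts(ainverse(ped))
  N <- nrow(ped)

  # trait blocks sharing no pedigree ancestry leave rg prior-identified
  if (t > 1L) check_connectedness(bundles, ped)
  facs <- chain_dispersal(mcmc$n_chains)
  chains <- vector("list", mcmc$n_chains)
  b_mean <- NULL; a_mean <- NULL
  for (ch in seq_len(mcmc$n_chains)) {
    Gi <- diag(vy / 3, t) * facs[ch]
    init <- list(G = Gi,
                 a = sapply(seq_len(t), function(k) {
                   stats::rnorm(N, 0, sqrt(Gi[k, k]))
                 }),
                 sigc2 = vy / 3 * facs[ch],
                 sige2 = vy / 3 * facs[ch])
    if (t == 1L) init$a <- matrix(init$a, ncol = 1L)
    fit <- mt_gibbs_cpp(lapply(bundles, `[[`, "y"),
                        lapply(bundles, `[[`, "X"),
                        lapply(bundles, `[[`, "zi"),
                        lapply(bundles, function(b) {
                          if (family_effect) b$wi else rep(-1L, b$n)
                        }),
                        Acsc$p, Acsc$i, Acsc$x, N,
                        mcmc$n_iter, mcmc$burnin, mcmc$thin,
                        prior$nu_g, prior$S_g, prior$nu_s,
                        prior$s2_c, prior$s2_e, init)
    chains[[ch]] <- label_mt_samples(fit$samples, envs)
    if (ch == 1L) { b_mean <- fit$b_mean; a_mean <- fit$a_mean }
  }

  smry <- summarize_chains(chains)
  est <- mt_point_estimates(smry, envs)
  structure(list(environments = envs, summary = smry,
                 G = est$G, rg = est$rg, C = est$C, R = est$R,
                 h2 = est$h2, c2 = est$c2,
                 chains = chains, psrf = stats::setNames(smry$psrf, smry$parameter),
                 b_mean = stats::setNames(b_mean, envs),
                 a_mean = a_mean,
                 bundles_meta = lapply(bundles, function(b) {
                   list(n = b$n, p = ncol(b$X), q = length(b$family_levels))
                 }),
                 mcmc = mcmc, prior = prior,
                 family_effect = family_effect),
            class = "gxe_fit")
}

check_connectedness <- function(bundles, ped) {
  # ancestor closure of each trait's recorded animals; warn on empty overlap
  anc_set <- function(animals) {
    pos <- attr(ped, "index")[animals] + 1L
    seen <- logical(nrow(ped))
    seen[pos] <- TRUE
    sire_pos <- match(ped$sire, ped$animal)
    dam_pos <- match(ped$dam, ped$animal)
    frontier <- pos
    while (length(frontier)) {
      pars <- unique(stats::na.omit(c(sire_pos[frontier], dam_pos[frontier])))
      pars <- pars[!seen[pars]]
      seen[pars] <- TRUE
      frontier <- pars
    }
    which(seen)
  }
  sets <- lapply(bundles, function(b) anc_set(b$animal))
  for (i in seq_along(sets)) {
    for (j in seq_len(i - 1L)) {
      if (length(intersect(sets[[i]], sets[[j]])) == 0L) {
        warning("traits ", names(bundles)[j], " and ", names(bundles)[i],
                " share no pedigree ancestry: their genetic correlation is ",
                "not identified by the data (posterior ~ prior)")
      }
    }
  }
  invisible(NULL)
}

label_mt_samples <- function(s, envs) {
  t <- length(envs)
  gnames <- character(0)
  for (k in seq_len(t)) {
    for (l in seq.int(k, t)) {
      gnames <- c(gnames, if (k == l) paste0("G[", envs[k], ",", envs[k], "]")
                  else paste0("G[", envs[k], ",", envs[l], "]"))
    }
  }
  colnames(s) <- c(gnames, paste0("sigc2[", envs, "]"),
                   paste0("sige2[", envs, "]"))
  # derived per-draw statistics
  extra <- NULL
  for (k in seq_len(t)) {
    gkk <- s[, paste0("G[", envs[k], ",", envs[k], "]")]
    vp <- gkk + s[, paste0("sigc2[", envs[k], "]")] +
      s[, paste0("sige2[", envs[k], "]")]
    add <- cbind(gkk / vp, s[, paste0("sigc2[", envs[k], "]")] / vp)
    colnames(add) <- paste0(c("h2[", "c2["), envs[k], "]")
    extra <- cbind(extra, add)
  }
  for (k in seq_len(t)) {
    for (l in seq.int(k + 1L, length.out = max(0L, t - k))) {
      num <- s[, paste0("G[", envs[k], ",", envs[l], "]")]
      den <- sqrt(s[, paste0("G[", envs[k], ",", envs[k], "]")] *
                    s[, paste0("G[", envs[l], ",", envs[l], "]")])
      rg <- cbind(num / den)
      colnames(rg) <- paste0("rg[", envs[k], ",", envs[l], "]")
      extra <- cbind(extra, rg)
    }
  }
  cbind(s, extra)
}

mt_point_estimates <- function(smry, envs) {
  t <- length(envs)
  get <- function(nm) smry$mean[match(nm, smry$parameter)]
  G <- matrix(0, t, t, dimnames = list(envs, envs))
  for (k in seq_len(t)) for (l in seq.int(k, t)) {
    G[k, l] <- G[l, k] <- get(paste0("G[", envs[k], ",", envs[l], "]"))
  }
  rg <- matrix(1, t, t, dimnames = list(envs, envs))
  for (k in seq_len(t)) for (l in seq.int(k + 1L, length.out = max(0L, t - k))) {
    rg[k, l] <- rg[l, k] <- get(paste0("rg[", envs[k], ",", envs[l], "]"))
  }
  list(G = G, rg = rg,
       C = diag(get(paste0("sigc2[", envs, "]")), t),
       R = diag(get(paste0("sige2[", envs, "]")), t),
       h2 = stats::setNames(get(paste0("h2[", envs, "]")), envs),
       c2 = stats::setNames(get(paste0("c2[", envs, "]")), envs))
}

#' Genetic correlation matrix from a genetic covariance matrix
#'
#' \eqn{r_{kl} = G_{kl} / \sqrt{G_{kk} G_{ll}}}.
#'
#' @param G positive semi-definite covariance matrix with positive diagonal.
#' @return correlation matrix of the same dimension.
#' @examples genetic_correlations(matrix(c(1, 0.7, 0.7, 1), 2))
#' @export
genetic_correlations <- function(G) {
  G <- as.matrix(G)
  d <- diag(G)
  if (any(d <= 0)) stop("G has non-positive diagonal entries")
  G / sqrt(tcrossprod(d))
}

#' @export
print.gxe_fit <- function(x, digits = 3, ...) {
  cat("Multi-trait animal model (", length(x$environments),
      " traits: ", paste(x$environments, collapse = ", "), ")\n", sep = "")
  cat("Posterior-mean heritabilities and hapa ratios:\n")
  print(round(rbind(h2 = x$h2, c2 = x$c2), digits))
  if (length(x$environments) > 1L) {
    cat("Cross-environment genetic correlations (G x E measure):\n")
    print(round(x$rg, digits))
  }
  bad <- x$psrf[is.finite(x$psrf) & x$psrf > 1.1]
  if (length(bad)) {
    cat("Warning: PSRF > 1.1 for:", paste(names(bad), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.gxe_fit <- function(object, ...) {
  out <- object$summary
  class(out) <- c("summary.gxe_fit", "data.frame")
  out
}

#' @export
coef.gxe_fit <- function(object, ...) {
  stats::setNames(object$summary$mean, object$summary$parameter)
}

#' @export
plot.gxe_fit <- function(x, parameters = NULL, ...) {
  nm <- colnames(x$chains[[1L]])
  if (is.null(parameters)) parameters <- grep("^(G\\[|rg\\[)", nm, value = TRUE)
  parameters <- intersect(parameters, nm)
  old <- graphics::par(mfrow = c(min(3L, length(parameters)), 1L),
                       mar = c(3, 4, 1, 1))
  on.exit(graphics::par(old))
  for (pm in utils::head(parameters, 3L)) {
    graphics::matplot(sapply(x$chains, function(ch) ch[, pm]), type = "l",
                      lty = 1, ylab = pm, xlab = "")
  }
  invisible(x)
}

#' Per-generation trend of the cross-environment genetic correlation
#'
#' Refits the two-trait animal model on reduced datasets that pair each
#' post-transfer generation of a satellite environment with the full nucleus
#' data, tracking how the genetic correlation (and hence G\eqn{\times}E)
#' evolves after the transfer.
#'
#' @param records phenotype data frame with a `generation` column.
#' @param ped the joint [pedigree()].
#' @param env satellite environment.
#' @param nucleus nucleus environment (kept in full).
#' @param generations generations of `env` to analyse (default: all present).
#' @param mcmc an [mcmc_control()].
#' @param ... passed to [fit_gxe()].
#' @return data frame with one row per generation: posterior mean `rg`,
#'   `hpd_lo`, `hpd_hi`, `psrf` and record count `n_env`.
#' @export
gxe_trend <- function(records, ped, env, nucleus = "MY", generations = NULL,
                      mcmc = mcmc_control(n_iter = 20000L, burnin = 4000L,
                                          thin = 10L, n_chains = 2L), ...) {
  if (is.null(generations)) {
    generations <- sort(unique(records$generation[records$environment == env]))
  }
  rows <- lapply(generations, function(g) {
    red <- reduce_by_generation(records, env, g, nucleus = nucleus)
    fit <- fit_gxe(red, ped, envs = c(nucleus, env), mcmc = mcmc, ...)
    key <- paste0("rg[", nucleus, ",", env, "]")
    i <- match(key, fit$summary$parameter)
    data.frame(generation = g,
               rg = fit$summary$mean[i],
               hpd_lo = fit$summary$hpd_lo[i],
               hpd_hi = fit$summary$hpd_hi[i],
               psrf = fit$summary$psrf[i],
               n_env = sum(red$environment == env))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
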