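#' Fit the genetically structured environmental variance model
#'
#' Single-trait, single-environment double hierarchical animal model for
#' micro-environmental sensitivity: square-root body weight follows
#' \deqn{y \mid b, a, c \sim N(Xb + Za + Wc, \mathrm{Diag}(\sigma^2_{e,i})),
#'   \qquad \ln \sigma^2_{e,i} = x^*_i{}' b^* + a^*_{z(i)} + c^*_{w(i)},}
#' with mean- and variance-level breeding values jointly normal,
#' \eqn{(a, a^*) \sim N(0, G_2 \otimes A)} where
#' \eqn{G_2 = \begin{pmatrix}\sigma^2_a & \rho\sigma_a\sigma_{a^*}\\
#' \rho\sigma_a\sigma_{a^*} & \sigma^2_{a^*}\end{pmatrix}}, and independent
#' hapa effects \eqn{c \sim N(0, I\sigma^2_c)},
#' \eqn{c^* \sim N(0, I\sigma^2_{c^*})} on the two levels (no
#' mean--variance covariance for hapa effects). Location parameters are drawn
#' from their exact heteroskedastic normal conditionals; dispersion
#' parameters use single-site random-walk Metropolis--Hastings with proposal
#' scales adapted during burn-in only; \eqn{G_2} is updated from its
#' conjugate inverse-Wishart conditional.
#'
#' A positive \eqn{\sigma^2_{a^*}} means the residual variance of the trait
#' is heritable: \eqn{\sigma_{a^*}} is the proportional change in residual
#' variance per unit change in the dispersion breeding value (see
#' [variance_response()]).
#'
#' @param records phenotype data frame.
#' @param ped the [pedigree()] (may cover more environments; records are
#'   mapped into it).
#' @param env environment to analyse.
#' @param mcmc an [mcmc_control()]; default 30,000 iterations, 5,000 burn-in,
#'   thin 10, 3 chains.
#' @param variance_design `"same"` uses the mean-level fixed-effect design for
#'   the log-variance level as well; `"intercept"` fits an intercept-only
#'   variance model.
#' @param prior list: `nu_g`, `S_g` (inverse-Wishart on \eqn{G_2}; defaults
#'   `nu_g = 3` — the smallest proper degree of freedom, implying a uniform
#'   marginal prior on \eqn{\rho} — and `S_g = diag(0.1 var(y), 0.1)`:
#'   mean-level prior scales track the phenotypic variance, the log-variance
#'   level is dimensionless), `nu_s`, `s2_c`, `s2_cs` (scaled-inv-chi-square
#'   on the hapa variances; defaults 3 and `0.1 var(y)` / 0.1).
#' @param psrf_threshold chains with any PSRF above this are flagged (not an
#'   error); default 1.1.
#' @return an object of class `gsevm_fit` with posterior summaries
#'   (`summary`: mean, SD, HPD95, PSRF per parameter), retained `chains`,
#'   Metropolis acceptance rates, posterior-mean breeding values on both
#'   levels (`a_mean`, `as_mean`) and the `converged` flag.
#' @export
fit_gsevm <- function(records, ped, env,
                      mcmc = mcmc_control(n_iter = 30000L, burnin = 5000L,
                                          thin = 10L, n_chains = 3L),
                      variance_design = c("same", "intercept"),
                      prior = list(), psrf_threshold = 1.1) {
  variance_design <- match.arg(variance_design)
  stopifnot(inherits(ped, "gift_pedigree"))
  bundle <- build_design(records, env, ped)
  Xs <- if (variance_design == "same") bundle$X else
    matrix(1, bundle$n, 1L, dimnames = list(NULL, "(Intercept)"))
  vy <- stats::var(bundle$y)
  # mean-level prior scales follow the observed phenotypic variance (unit
  # invariance); the log-variance level is already dimensionless
  prior <- utils::modifyList(
    list(nu_g = 3, S_g = diag(c(0.1 * vy, 0.1), 2), nu_s = 3,
         s2_c = 0.1 * vy, s2_cs = 0.1),
    prior)
  Acsc <- csc_parts(ainverse(ped))
  N <- nrow(ped)
  q <- length(bundle$family_levels)

  facs <- chain_dispersal(mcmc$n_chains)
  chains <- vector("list", mcmc$n_chains)
  accepts <- vector("list", mcmc$n_chains)
  a_mean <- NULL; as_mean <- NULL
  for (ch in seq_len(mcmc$n_chains)) {
    G2i <- diag(c(vy / 3, 0.2), 2) * facs[ch]
    init <- list(b = rep(0, ncol(bundle$X)),
                 a = stats::rnorm(N, 0, sqrt(G2i[1, 1])), c = rep(0, q),
                 bs = c(log(vy / 2 * facs[ch]), rep(0, ncol(Xs) - 1L)),
                 as = stats::rnorm(N, 0, sqrt(G2i[2, 2])), cs = rep(0, q),
                 G2 = G2i,
                 sigc2 = vy / 3 * facs[ch], sigcs2 = 0.05 * facs[ch])
    fit <- gsevm_cpp(bundle$y, bundle$X, Xs, bundle$zi, bundle$wi,
                     Acsc$p, Acsc$i, Acsc$x,
                     N, mcmc$n_iter, mcmc$burnin, mcmc$thin,
                     prior$nu_g, prior$S_g, prior$nu_s,
                     prior$s2_c, prior$s2_cs,
                     init, 0.5, 0.5, rep(0.1, ncol(Xs)),
                     TRUE, FALSE)
    s <- fit$samples
    colnames(s) <- c("sigma_a2", "sigma_astar2", "rho", "sigma_c2",
                     "sigma_cstar2",
                     paste0("b[", colnames(bundle$X), "]"),
                     paste0("bstar[", colnames(Xs), "]"))
    chains[[ch]] <- s
    accepts[[ch]] <- fit$accept
    if (ch == 1L) { a_mean <- fit$a_mean; as_mean <- fit$as_mean }
  }

  smry <- summarize_chains(chains)
  psrf <- stats::setNames(smry$psrf, smry$parameter)
  core <- c("sigma_a2", "sigma_astar2", "rho", "sigma_c2", "sigma_cstar2")
  converged <- !any(is.finite(psrf[core]) & psrf[core] > psrf_threshold)
  structure(list(environment = env, summary = smry, chains = chains,
                 accept = accepts, psrf = psrf, converged = converged,
                 psrf_threshold = psrf_threshold,
                 a_mean = stats::setNames(a_mean, ped$animal),
                 as_mean = stats::setNames(as_mean, ped$animal),
                 variance_design = variance_design,
                 bundle_meta = list(n = bundle$n, p = ncol(bundle$X),
                                    ps = ncol(Xs), q = q),
                 mcmc = mcmc, prior = prior),
            class = "gsevm_fit")
}

#' @export
print.gsevm_fit <- function(x, digits = 3, ...) {
  cat("Genetically structured environmental variance model [",
      x$environment, "]\n", sep = "")
  core <- c("sigma_a2", "sigma_c2", "sigma_astar2", "sigma_cstar2", "rho")
  i <- match(core, x$summary$parameter)
  tab <- x$summary[i, c("mean", "hpd_lo", "hpd_hi", "psrf")]
  rownames(tab) <- core
  print(round(tab, digits))
  if (!x$converged) {
    cat("NOT CONVERGED: some PSRF exceed", x$psrf_threshold, "\n")
  }
  invisible(x)
}

#' @export
summary.gsevm_fit <- function(object, ...) {
  out <- object$summary
  class(out) <- c("summary.gsevm_fit", "data.frame")
  out
}

#' @export
coef.gsevm_fit <- function(object, ...) {
  stats::setNames(object$summary$mean, object$summary$parameter)
}

#' @export
plot.gsevm_fit <- function(x, parameters = c("sigma_a2", "sigma_astar2",
                                             "rho"), ...) {
  parameters <- intersect(parameters, colnames(x$chains[[1L]]))
  old <- graphics::par(mfrow = c(length(parameters), 1L), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(old))
  for (pm in parameters) {
    graphics::matplot(sapply(x$chains, function(ch) ch[, pm]), type = "l",
                      lty = 1, ylab = pm, xlab = "")
  }
  invisible(x)
}

#' GSEVM log-likelihood of a parameter state
#'
#' Sum over records of the normal log-density with record-specific residual
#' variance \eqn{\exp(x^*_i{}'b^* + a^*_{z(i)} + c^*_{w(i)})}; the
#' observation-level likelihood underlying the sampler.
#'
#' @param state list with `b`, `a`, `c`, `bs`, `as`, `cs` (`a`/`as` indexed by
#'   pedigree position; `c`/`cs` by family level).
#' @param bundle a [build_design()] bundle.
#' @param Xstar variance-level design matrix (default: the bundle's `X`).
#' @return scalar log-likelihood; an error if non-finite (divergence).
#' @export
gsevm_loglik <- function(state, bundle, Xstar = bundle$X) {
  mu <- drop(bundle$X %*% state$b) + state$a[bundle$zi + 1L]
  eta <- drop(Xstar %*% state$bs) + state$as[bundle$zi + 1L]
  hasfam <- bundle$wi >= 0L
  if (length(state$c)) mu[hasfam] <- mu[hasfam] + state$c[bundle$wi[hasfam] + 1L]
  if (length(state$cs)) eta[hasfam] <- eta[hasfam] + state$cs[bundle$wi[hasfam] + 1L]
  ll <- sum(stats::dnorm(bundle$y, mu, sqrt(exp(eta)), log = TRUE))
  if (!is.finite(ll)) stop("non-finite GSEVM log-likelihood (divergence)")
  ll
}

# One sweep of the GSEVM sampler from a given full state; used by the
# joint-distribution (successive-conditional) validation tests.
gsevm_sweep <- function(state, y, X, Xs, zi, wi, Ainv, N, prior,
                        scales = list(as = 0.5, cs = 0.5, bs = 0.1)) {
  Acsc <- csc_parts(Ainv)
  fit <- gsevm_cpp(y, X, Xs, zi, wi, Acsc$p, Acsc$i, Acsc$x, N,
                   1L, 1L, 1L,
                   prior$nu_g, prior$S_g, prior$nu_s,
                   prior$s2_c, prior$s2_cs,
                   state, scales$as, scales$cs,
                   rep(scales$bs, length.out = max(1L, ncol(Xs)))[seq_len(ncol(Xs))],
                   FALSE, TRUE)
  fit$state
}
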