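#' MCMC run configuration
#'
#' Chain lengths for the Gibbs / Metropolis-within-Gibbs samplers. The
#' `"test"` preset is the desk-scale default used throughout the package's
#' examples and tests; the `"paper"` preset mirrors the full-length runs
#' (10^6 iterations, 10^5 burn-in) used for production analyses.
#'
#' @param n_iter total iterations per chain.
#' @param burnin burn-in iterations (discarded; adaptive proposal scaling is
#'   frozen at the end of burn-in).
#' @param thin retain every `thin`-th post-burn-in draw.
#' @param n_chains number of chains started from dispersed initial values.
#' @param preset optional shortcut overriding the lengths: `"test"` or
#'   `"paper"`.
#' @return an `mcmc_control` list.
#' @export
mcmc_control <- function(n_iter = 30000L, burnin = 5000L, thin = 10L,
                         n_chains = 3L, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("test", "paper"))
    if (preset == "paper") {
      n_iter <- 1000000L; burnin <- 100000L; thin <- 100L
    } else {
      n_iter <- 30000L; burnin <- 5000L; thin <- 10L
    }
  }
  stopifnot(n_iter > burnin, thin >= 1L, n_chains >= 1L)
  structure(list(n_iter = as.integer(n_iter), burnin = as.integer(burnin),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 preset = preset),
            class = "mcmc_control")
}

# Raw compressed-sparse-column arrays of a dgCMatrix for the C++ kernels.
csc_parts <- function(M) {
  M <- methods::as(M, "CsparseMatrix")
  list(p = M@p, i = M@i, x = M@x)
}

# Dispersed multiplicative factors for chain starting values.
chain_dispersal <- function(n_chains) {
  facs <- c(1, 0.3, 3, 0.5, 2)
  facs[((seq_len(n_chains) - 1L) %% length(facs)) + 1L]
}

# Posterior summary table: mean, sd, HPD95, PSRF for named sample matrices.
summarize_chains <- function(chains) {
  all <- do.call(rbind, chains)
  psrf <- if (length(chains) >= 2L) gelman_rubin(chains) else
    stats::setNames(rep(NA_real_, ncol(all)), colnames(all))
  hpd <- apply(all, 2L, hpd_interval)
  data.frame(parameter = colnames(all),
             mean = colMeans(all),
             sd = apply(all, 2L, stats::sd),
             hpd_lo = hpd[1L, ],
             hpd_hi = hpd[2L, ],
             psrf = psrf,
             row.names = NULL)
}
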