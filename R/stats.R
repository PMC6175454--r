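#' Heritability
#'
#' \eqn{h^2 = V_A / V_P}, the fraction of phenotypic variance attributable to
#' additive genetic variance. \eqn{V_P} is taken explicitly because published
#' phenotypic variances do not always equal the sum of the printed components.
#'
#' @param va additive genetic variance (\eqn{\ge 0}).
#' @param vp phenotypic variance (\eqn{> 0}, \eqn{\ge} `va`).
#' @return \eqn{h^2} in \[0, 1\].
#' @examples heritability(1.84, 6.25)
#' @export
heritability <- function(va, vp) {
  if (any(vp <= 0)) stop("vp must be positive")
  if (any(va < 0)) stop("va must be non-negative")
  if (any(va > vp)) stop("va exceeds vp")
  va / vp
}

#' Common-environment (full-sib) variance ratio
#'
#' \eqn{c^2 = V_C / V_P}: the fraction of phenotypic variance shared by full
#' sibs reared together (one hapa per family) beyond their relatedness.
#'
#' @param vc common-environment variance (\eqn{\ge 0}).
#' @param vp phenotypic variance (\eqn{> 0}).
#' @return \eqn{c^2}.
#' @examples common_env_ratio(2.43, 6.25)
#' @export
common_env_ratio <- function(vc, vp) {
  if (any(vp <= 0)) stop("vp must be positive")
  if (any(vc < 0)) stop("vc must be non-negative")
  vc / vp
}

#' Coefficient of variation
#'
#' @param mean trait mean (\eqn{> 0}).
#' @param sd trait standard deviation (\eqn{\ge 0}).
#' @return `sd / mean`.
#' @examples coefficient_of_variation(222, 87.77)
#' @export
coefficient_of_variation <- function(mean, sd) {
  if (any(mean <= 0)) stop("mean must be positive")
  if (any(sd < 0)) stop("sd must be non-negative")
  sd / mean
}

#' Predicted residual-variance response to selection on uniformity
#'
#' When the log residual variance carries additive genetic variation, one
#' generation of selection shifting the dispersion breeding value by
#' \eqn{\Delta G_v} multiplies the residual variance:
#' \eqn{\sigma^2_{e,new} = \sigma^2_{e,old}\exp(\Delta G_v)}. A one-SD
#' decrease corresponds to \eqn{\Delta G_v = -\sigma_{a^*}}.
#'
#' @param sigma_e2_old residual variance before selection (\eqn{> 0}).
#' @param delta_gv genetic change on the log-variance scale.
#' @return list with `sigma_e2_new` and `percent_change`
#'   (\eqn{100(1 - \exp(\Delta G_v))}; positive = variance decrease).
#' @examples variance_response(1, -0.58)  # 44 percent decrease
#' @export
variance_response <- function(sigma_e2_old, delta_gv) {
  if (any(sigma_e2_old <= 0)) stop("sigma_e2_old must be positive")
  list(sigma_e2_new = sigma_e2_old * exp(delta_gv),
       percent_change = 100 * (1 - exp(delta_gv)))
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing the requested mass of the
#' empirical distribution, found by an exact sliding window over the sorted
#' samples (no kernel smoothing).
#'
#' @param samples numeric vector of at least 100 posterior draws.
#' @param mass probability mass in (0, 1), default 0.95.
#' @return numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 100L) stop("need at least 100 samples for an HPD interval")
  s <- sort(samples)
  k <- ceiling(mass * n)
  if (k >= n) return(c(s[1L], s[n]))
  widths <- s[seq.int(k, n)] - s[seq_len(n - k + 1L)]
  i <- which.min(widths)
  c(s[i], s[i + k - 1L])
}

#' Gelman--Rubin potential scale reduction factor
#'
#' PSRF \eqn{= \sqrt{((n-1)/n\,W + B/n)/W}} from the between-chain variance
#' \eqn{B} and the mean within-chain variance \eqn{W} (the original 1992
#' criterion, without chain splitting; set `split = TRUE` for the split-chain
#' variant).
#'
#' @param chains list of \eqn{\ge 2} equal-length numeric vectors, or
#'   equal-dimension matrices (one column per parameter).
#' @param split halve each chain before computing the diagnostic.
#' @return numeric PSRF, one value per parameter.
#' @export
gelman_rubin <- function(chains, split = FALSE) {
  if (!is.list(chains) || length(chains) < 2L) {
    stop("need at least 2 chains")
  }
  chains <- lapply(chains, function(ch) {
    if (is.null(dim(ch))) matrix(ch, ncol = 1L) else as.matrix(ch)
  })
  lens <- vapply(chains, nrow, integer(1))
  if (length(unique(lens)) != 1L) stop("chains must have equal length")
  if (split) {
    h <- lens[1L] %/% 2L
    chains <- c(lapply(chains, function(ch) ch[seq_len(h), , drop = FALSE]),
                lapply(chains, function(ch) ch[seq.int(h + 1L, 2L * h), ,
                                               drop = FALSE]))
  }
  n <- nrow(chains[[1L]])
  means <- sapply(chains, colMeans)
  vars <- sapply(chains, function(ch) apply(ch, 2L, stats::var))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1L)
    vars <- matrix(vars, nrow = 1L)
  }
  B <- n * apply(means, 1L, stats::var)
  W <- rowMeans(vars)
  psrf <- sqrt(((n - 1) / n * W + B / n) / W)
  stats::setNames(psrf, colnames(chains[[1L]]))
}
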