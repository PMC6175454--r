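#' Run the full robustness-analysis pipeline
#'
#' Orchestrates simulate \eqn{\to} transform \eqn{\to} fit both models
#' \eqn{\to} summarize: generates (or loads) a multi-environment dataset,
#' computes descriptive statistics per environment, fits the multi-trait
#' G\eqn{\times}E model (when at least two environments are present), the
#' per-generation genetic-correlation trend for satellite environments
#' (optional), and the GSEVM per environment, then writes a machine-readable
#' JSON report plus chain CSVs. Every artifact records the seed; with a fixed
#' seed a rerun is byte-identical.
#'
#' @param config a [sim_config()] describing the breeding program to simulate.
#' @param out_dir output directory.
#' @param seed integer seed governing simulation and all samplers (overrides
#'   `config$seed`).
#' @param mcmc_gxe,mcmc_gsevm [mcmc_control()] settings for the two models.
#' @param preset `"test"` or `"paper"`: overrides both mcmc controls.
#' @param desk_guard refuse presets whose total iteration count exceeds
#'   `10^5` per chain (guard for interactive desk use); default `FALSE`.
#' @param trend also fit the per-generation rg trend for each satellite
#'   environment (slow; default `FALSE`).
#' @return the report, invisibly (also written to `out_dir/report.json`).
#' @export
run_pipeline <- function(config = sim_config(), out_dir, seed = config$seed,
                         mcmc_gxe = mcmc_control(n_iter = 6000L,
                                                 burnin = 1000L, thin = 5L,
                                                 n_chains = 2L),
                         mcmc_gsevm = mcmc_control(n_iter = 6000L,
                                                   burnin = 1000L, thin = 5L,
                                                   n_chains = 2L),
                         preset = NULL, desk_guard = FALSE, trend = FALSE) {
  if (!is.null(preset)) {
    mcmc_gxe <- mcmc_control(preset = preset)
    mcmc_gsevm <- mcmc_control(preset = preset)
  }
  if (desk_guard &&
      (mcmc_gxe$n_iter > 1e5 || mcmc_gsevm$n_iter > 1e5)) {
    stop("desk_guard: preset exceeds 1e5 iterations per chain; ",
         "drop desk_guard = TRUE to run it")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config$seed <- as.integer(seed)

  stage <- function(name, expr) {
    message("[pipeline] stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sim <- stage("simulate", simulate_gift(config))
  stage("write-dataset", write_gift(sim, file.path(out_dir, "data")))
  envs <- unique(sim$records$environment)

  descriptives <- stage("descriptives", {
    lapply(stats::setNames(envs, envs), function(e) {
      r <- sim$records[sim$records$environment == e, ]
      fs <- table(r$family)
      list(n_records = nrow(r),
           n_generations = length(unique(r$generation)),
           n_families = length(fs),
           mean_family_size = round(mean(fs), 1),
           mean_growout_days = round(mean(r$age), 1),
           mean_bw = round(mean(r$bw), 1),
           sd_bw = round(stats::sd(r$bw), 2),
           cv_bw = round(coefficient_of_variation(mean(r$bw),
                                                  stats::sd(r$bw)), 3))
    })
  })

  gxe <- NULL
  if (length(envs) >= 2L) {
    gxe <- stage("fit-gxe", {
      set.seed(config$seed + 1L)
      fit_gxe(sim$records, sim$pedigree, envs = envs, mcmc = mcmc_gxe)
    })
    utils::write.csv(do.call(rbind, lapply(seq_along(gxe$chains), function(i) {
      cbind(chain = i, as.data.frame(gxe$chains[[i]]))
    })), file.path(out_dir, "chains_gxe.csv"), row.names = FALSE)
  } else {
    warning("single environment: G x E stage skipped, GSEVM still runs")
  }

  trend_tab <- NULL
  if (trend && length(envs) >= 2L) {
    trend_tab <- stage("trend", {
      set.seed(config$seed + 2L)
      do.call(rbind, lapply(setdiff(envs, envs[1L]), function(e) {
        cbind(environment = e,
              gxe_trend(sim$records, sim$pedigree, e, nucleus = envs[1L]))
      }))
    })
    utils::write.csv(trend_tab, file.path(out_dir, "trend_rg.csv"),
                     row.names = FALSE)
  }

  gsevm <- stage("fit-gsevm", {
    out <- list()
    for (i in seq_along(envs)) {
      set.seed(config$seed + 10L + i)
      out[[envs[i]]] <- fit_gsevm(sim$records, sim$pedigree, envs[i],
                                  mcmc = mcmc_gsevm)
      utils::write.csv(do.call(rbind, lapply(
        seq_along(out[[envs[i]]]$chains), function(j) {
          cbind(chain = j, as.data.frame(out[[envs[i]]]$chains[[j]]))
        })), file.path(out_dir, paste0("chains_gsevm_", envs[i], ".csv")),
        row.names = FALSE)
    }
    out
  })

  report <- list(
    seed = config$seed,
    environments = envs,
    descriptives = descriptives,
    variance_components = if (!is.null(gxe)) list(
      G = gxe$G, C = diag(gxe$C), R = diag(gxe$R),
      h2 = gxe$h2, c2 = gxe$c2, psrf = gxe$psrf),
    genetic_correlations = if (!is.null(gxe)) gxe$rg,
    trend = trend_tab,
    gsevm = lapply(gsevm, function(f) {
      core <- c("sigma_a2", "sigma_c2", "sigma_astar2", "sigma_cstar2", "rho")
      i <- match(core, f$summary$parameter)
      list(posterior_mean = stats::setNames(f$summary$mean[i], core),
           hpd_lo = stats::setNames(f$summary$hpd_lo[i], core),
           hpd_hi = stats::setNames(f$summary$hpd_hi[i], core),
           psrf = stats::setNames(f$summary$psrf[i], core),
           sigma_astar = sqrt(f$summary$mean[match("sigma_astar2",
                                                   f$summary$parameter)]),
           predicted_variance_decrease_pct = variance_response(
             1, -sqrt(f$summary$mean[match("sigma_astar2",
                                           f$summary$parameter)])
           )$percent_change,
           converged = f$converged)
    }))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE,
                       matrix = "rowmajor")
  writeLines(format_report(report), file.path(out_dir, "report.txt"))
  invisible(report)
}

format_report <- function(report) {
  out <- c(sprintf("Robustness analysis report (seed %d)", report$seed),
           "", "Descriptives:")
  for (e in names(report$descriptives)) {
    d <- report$descriptives[[e]]
    out <- c(out, sprintf(
      "  %s: %d records, %d families, mean BW %.1f g (CV %.3f)",
      e, d$n_records, d$n_families, d$mean_bw, d$cv_bw))
  }
  if (!is.null(report$genetic_correlations)) {
    out <- c(out, "", "Genetic correlations (G x E):",
             utils::capture.output(print(round(report$genetic_correlations, 3))))
  }
  out <- c(out, "", "GSEVM posterior means:")
  for (e in names(report$gsevm)) {
    g <- report$gsevm[[e]]
    out <- c(out, sprintf(
      "  %s: sigma_a*2 = %.3f, rho = %.3f, predicted variance decrease %.1f%%%s",
      e, g$posterior_mean[["sigma_astar2"]], g$posterior_mean[["rho"]],
      g$predicted_variance_decrease_pct,
      if (!g$converged) "  [NOT CONVERGED]" else ""))
  }
  out
}
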