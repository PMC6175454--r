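#' Square-root transformation of body weight
#'
#' Harvest body weights are analysed on the square-root scale to meet the
#' normality assumptions of the linear mixed models; this applies
#' \eqn{y = \sqrt{bw}} record-wise, preserving order.
#'
#' @param bw numeric vector of raw body weights (g), or a records data frame
#'   with columns `bw` and `animal`.
#' @return numeric vector of transformed responses.
#' @examples
#' sqrt_transform(c(225, 100))  # 15, 10
#' @export
sqrt_transform <- function(bw) {
  animal <- NULL
  if (is.data.frame(bw)) {
    animal <- bw$animal
    bw <- bw$bw
  }
  bad <- which(!is.finite(bw) | bw <= 0)
  if (length(bad)) {
    lab <- if (!is.null(animal)) animal[bad] else bad
    stop("non-positive body weight for record(s): ",
         paste(utils::head(lab, 5L), collapse = ", "))
  }
  sqrt(bw)
}

#' Build the fixed-effect design for one environment
#'
#' Implements the per-environment fixed-effect models for square-root body
#' weight. The nucleus environment (where both a selection and a control line
#' are recorded) uses a rearing-system main effect, a combined
#' sex \eqn{\times} spawning-season \eqn{\times} line factor, and a separate
#' harvest-age slope per spawning \eqn{\times} line cell. Satellite
#' environments use rearing system, a combined sex \eqn{\times} spawning
#' factor, and a single age slope. Combined factors are built from observed
#' level combinations only; the first level of each factor is absorbed as the
#' reference; the age covariate is centred within environment.
#'
#' @param records phenotype data frame (columns `animal`, `environment`, `bw`,
#'   `sex`, `spawning`, `line`, `rearing`, `age`, `family`).
#' @param env environment label to subset.
#' @param ped the joint [pedigree()]; records are mapped to pedigree positions.
#' @param model `"auto"` chooses `"nested"` (age slope per spawning\eqn{\times}
#'   line cell) when more than one line is recorded in `env`, else `"simple"`.
#' @return an object of class `design_bundle`: list with `environment`, `y`,
#'   `X`, `zi`/`wi` (0-based animal and family indices), `animal`, `family`,
#'   `family_levels`, `level_maps` (factor levels and age centre) and `model`.
#' @export
build_design <- function(records, env, ped, model = c("auto", "nested", "simple")) {
  model <- match.arg(model)
  stopifnot(inherits(ped, "gift_pedigree"))
  rec <- records[records$environment == env, , drop = FALSE]
  if (nrow(rec) < 2L) {
    stop("need at least 2 records in environment ", env,
         " to build an identifiable design")
  }
  rec <- rec[order(rec$animal), , drop = FALSE]  # canonical row order
  y <- sqrt_transform(rec)

  lev <- function(x) sort(unique(as.character(x)))
  fac <- function(x) factor(as.character(x), levels = lev(x))
  sex <- fac(rec$sex); sp <- fac(rec$spawning); line <- fac(rec$line)
  rearing <- fac(rec$rearing)
  if (model == "auto") {
    model <- if (nlevels(line) > 1L) "nested" else "simple"
  }
  age_center <- mean(rec$age)
  age_c <- rec$age - age_center

  drop_single <- function(f, nm) {
    if (nlevels(f) < 2L) {
      warning("factor '", nm, "' has a single level in ", env, "; dropped")
      NULL
    } else f
  }
  terms <- list()
  r2 <- drop_single(rearing, "rearing")
  if (!is.null(r2)) terms$rearing <- r2

  if (model == "nested") {
    comb <- droplevels(interaction(sex, sp, line, drop = TRUE, sep = ":"))
    slope_cell <- droplevels(interaction(sp, line, drop = TRUE, sep = ":"))
  } else {
    comb <- droplevels(interaction(sex, sp, drop = TRUE, sep = ":"))
    slope_cell <- NULL
  }
  comb <- drop_single(comb, "combined sex/spawning factor")
  if (!is.null(comb)) terms$comb <- comb

  X <- matrix(1, nrow(rec), 1L, dimnames = list(NULL, "(Intercept)"))
  for (nm in names(terms)) {
    mm <- stats::model.matrix(~f, data.frame(f = terms[[nm]]))[, -1L, drop = FALSE]
    colnames(mm) <- paste0(nm, sub("^f", ":", colnames(mm)))
    X <- cbind(X, mm)
  }
  if (is.null(slope_cell) || nlevels(slope_cell) < 2L) {
    X <- cbind(X, age = age_c)
  } else {
    mm <- stats::model.matrix(~0 + f, data.frame(f = slope_cell)) * age_c
    colnames(mm) <- paste0("age:", levels(slope_cell))
    X <- cbind(X, mm)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]
    warning("dropping ", length(drop), " aliased design column(s) in ", env,
            ": ", paste(colnames(X)[drop], collapse = ", "))
    X <- X[, -drop, drop = FALSE]
  }

  idx <- attr(ped, "index")
  if (any(!rec$animal %in% names(idx))) {
    stop("records reference animals missing from the pedigree: ",
         paste(utils::head(setdiff(rec$animal, names(idx)), 5L), collapse = ", "))
  }
  zi <- as.integer(idx[rec$animal])
  fam_levels <- lev(rec$family)
  wi <- match(as.character(rec$family), fam_levels) - 1L

  structure(list(environment = env, y = y, X = X,
                 zi = zi, wi = wi, animal = rec$animal,
                 family = as.character(rec$family),
                 family_levels = fam_levels,
                 level_maps = list(sex = levels(sex), spawning = levels(sp),
                                   line = levels(line),
                                   rearing = levels(rearing),
                                   age_center = age_center),
                 model = model, n = nrow(rec)),
            class = "design_bundle")
}

#' @export
print.design_bundle <- function(x, ...) {
  cat("Design bundle [", x$environment, "]: ", x$n, " records, ",
      ncol(x$X), " fixed-effect columns, ", length(x$family_levels),
      " families (model: ", x$model, ")\n", sep = "")
  invisible(x)
}

#' Reduced dataset for the per-generation G\eqn{\times}E trend
#'
#' Returns the records of one satellite environment at a single generation
#' together with the full data of the nucleus environment, the dataset on
#' which the multi-trait model is refitted to monitor how the
#' cross-environment genetic correlation evolves after transfer.
#'
#' @param records phenotype data frame with a `generation` column.
#' @param env satellite environment label (must differ from `nucleus`).
#' @param generation generation of `env` to retain.
#' @param nucleus nucleus environment label kept in full (default `"MY"`).
#' @return the filtered records (no duplication).
#' @export
reduce_by_generation <- function(records, env, generation, nucleus = "MY") {
  if (env == nucleus) {
    stop("env must be a satellite environment, not the nucleus '", nucleus, "'")
  }
  if (!env %in% records$environment) {
    stop("no records for environment ", env)
  }
  if (is.null(records$generation)) {
    stop("records need a 'generation' column (see read_gift)")
  }
  keep_env <- records$environment == env & records$generation == generation
  if (!any(keep_env)) {
    stop("no records for environment ", env, " at generation ", generation)
  }
  out <- records[records$environment == nucleus | keep_env, , drop = FALSE]
  rownames(out) <- NULL
  out
}
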