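#' Construct and validate a breeding-program pedigree
#'
#' Builds a validated, topologically sorted pedigree: founders first and every
#' parent before its offspring. Unknown parents (founder animals) are coded as
#' `NA`, `""` or `"0"` on input and stored as `NA`. The sorted pedigree is the
#' common substrate of the additive relationship matrix used by both the
#' multi-trait G\eqn{\times}E model and the GSEVM.
#'
#' @param animal character or integer vector of unique animal ids.
#' @param sire,dam parent ids; `NA`, `""` or `"0"` marks an unknown parent.
#'   A parent id that never occurs in `animal` is an error: founders must have
#'   their own rows.
#' @param generation optional non-negative integer generation labels.
#' @param environment optional environment labels (e.g. `"MY"`, `"CN"`, `"IN"`).
#' @return an object of class `gift_pedigree`: a data frame with columns
#'   `animal`, `sire`, `dam` (and `generation`/`environment` when given),
#'   sorted parent-first, with an `index` attribute mapping each animal id to
#'   its 0-based position in the sorted order.
#' @examples
#' ped <- pedigree(animal = c("o1", "s", "d"),
#'                 sire   = c("s", NA, NA),
#'                 dam    = c("d", NA, NA))
#' ped$animal  # parents first
#' @seealso [inbreeding()], [amatrix()], [ainverse()], [read_pedigree()]
#' @export
pedigree <- function(animal, sire, dam, generation = NULL, environment = NULL) {
  animal <- as.character(animal)
  sire <- normalize_parent(sire)
  dam <- normalize_parent(dam)
  n <- length(animal)
  stopifnot(length(sire) == n, length(dam) == n)
  if (anyDuplicated(animal)) {
    stop("duplicated animal ids: ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  }
  self_par <- which(!is.na(sire) & sire == animal | !is.na(dam) & dam == animal)
  if (length(self_par)) {
    stop("animal is its own parent (cycle): ",
         paste(animal[self_par], collapse = ", "))
  }
  known <- c(sire[!is.na(sire)], dam[!is.na(dam)])
  missing_par <- setdiff(known, animal)
  if (length(missing_par)) {
    stop("parent ids absent from animal list (add founder rows): ",
         paste(sort(missing_par), collapse = ", "))
  }

  ord <- topo_order(animal, sire, dam)

  df <- data.frame(animal = animal, sire = sire, dam = dam,
                   stringsAsFactors = FALSE)
  if (!is.null(generation)) {
    generation <- as.integer(generation)
    if (any(is.na(generation)) || any(generation < 0)) {
      stop("generation must be non-negative integers")
    }
    df$generation <- generation
  }
  if (!is.null(environment)) df$environment <- as.character(environment)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  idx <- seq_len(nrow(df)) - 1L
  names(idx) <- df$animal
  structure(df, index = idx, class = c("gift_pedigree", "data.frame"))
}

normalize_parent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "" | x == "0")] <- NA_character_
  x
}

# Kahn topological sort, stable within ready sets; reports a cycle's member ids.
topo_order <- function(animal, sire, dam) {
  n <- length(animal)
  pos <- seq_len(n)
  names(pos) <- animal
  si <- ifelse(is.na(sire), 0L, pos[sire])
  di <- ifelse(is.na(dam), 0L, pos[dam])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in unique(c(si[i], di[i]))) {
      if (p > 0L) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  out <- integer(0)
  ready <- which(indeg == 0L)
  while (length(ready)) {
    v <- ready[1L]
    ready <- ready[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) ready <- c(ready, ch)
    }
  }
  if (length(out) < n) {
    stop("pedigree contains a cycle involving: ",
         paste(animal[setdiff(seq_len(n), out)], collapse = ", "))
  }
  out
}

#' @export
print.gift_pedigree <- function(x, ...) {
  n_founder <- sum(is.na(x$sire) & is.na(x$dam))
  cat("Pedigree:", nrow(x), "animals (", n_founder, "founders )\n")
  if (!is.null(x$environment)) {
    cat("Environments:",
        paste(names(table(x$environment)), table(x$environment),
              sep = "=", collapse = ", "), "\n")
  }
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

# 0-based parent position vectors for the C++ kernels; -1 = unknown.
parent_positions <- function(ped) {
  idx <- attr(ped, "index")
  si <- ifelse(is.na(ped$sire), -1L, as.integer(idx[ped$sire]))
  di <- ifelse(is.na(ped$dam), -1L, as.integer(idx[ped$dam]))
  list(sire = si, dam = di)
}

#' Inbreeding coefficients
#'
#' Per-animal inbreeding coefficient \eqn{F_i = 0.5\,a_{sd}} where
#' \eqn{a_{sd}} is the additive relationship between the animal's parents;
#' founders and animals with an unknown parent have \eqn{F = 0}.
#'
#' @param ped a [pedigree()] object.
#' @return named numeric vector of F, in pedigree order.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "gift_pedigree"))
  pp <- parent_positions(ped)
  stats::setNames(inbreeding_cpp(pp$sire, pp$dam), ped$animal)
}

#' Additive (numerator) relationship matrix
#'
#' Dense A by the tabular method: \eqn{a_{ij} = (a_{i,s(j)} + a_{i,d(j)})/2}
#' for \eqn{i < j}, diagonal \eqn{1 + F_j}. Intended for desk-scale pedigrees;
#' model fitting uses the sparse inverse ([ainverse()]) instead.
#'
#' @param ped a [pedigree()] object.
#' @return symmetric numeric matrix with animal-id dimnames.
#' @export
amatrix <- function(ped) {
  stopifnot(inherits(ped, "gift_pedigree"))
  pp <- parent_positions(ped)
  A <- amatrix_cpp(pp$sire, pp$dam)
  dimnames(A) <- list(ped$animal, ped$animal)
  A
}

#' Sparse inverse of the additive relationship matrix
#'
#' Builds \eqn{A^{-1}} directly from the pedigree by Henderson's rules with
#' Mendelian sampling variances adjusted for parental inbreeding:
#' each animal contributes \eqn{\alpha_i = 1/d_i} where \eqn{d_i} is
#' \eqn{0.5 - 0.25(F_s + F_d)} (both parents known),
#' \eqn{0.75 - 0.25 F_p} (one parent known) or 1 (founder).
#'
#' @param ped a [pedigree()] object.
#' @return a sparse symmetric `dgCMatrix` with animal-id dimnames.
#' @export
ainverse <- function(ped) {
  stopifnot(inherits(ped, "gift_pedigree"))
  pp <- parent_positions(ped)
  Fcoef <- inbreeding_cpp(pp$sire, pp$dam)
  n <- nrow(ped)
  s <- pp$sire + 1L  # 1-based, 0 = unknown
  d <- pp$dam + 1L
  Fs <- ifelse(s > 0L, Fcoef[pmax(s, 1L)], 0)
  Fd <- ifelse(d > 0L, Fcoef[pmax(d, 1L)], 0)
  nk <- (s > 0L) + (d > 0L)
  dvar <- ifelse(nk == 2L, 0.5 - 0.25 * (Fs + Fd),
                 ifelse(nk == 1L, 0.75 - 0.25 * (Fs + Fd), 1))
  alpha <- 1 / dvar
  i <- seq_len(n)

  ii <- c(i, i[s > 0L], i[d > 0L], s[s > 0L], d[d > 0L],
          s[s > 0L & d > 0L])
  jj <- c(i, s[s > 0L], d[d > 0L], s[s > 0L], d[d > 0L],
          d[s > 0L & d > 0L])
  xx <- c(alpha,
          -alpha[s > 0L] / 2, -alpha[d > 0L] / 2,
          alpha[s > 0L] / 4, alpha[d > 0L] / 4,
          alpha[s > 0L & d > 0L] / 4)
  # symmetrize off-diagonal contributions
  off <- ii != jj
  ii2 <- c(ii, jj[off])
  jj2 <- c(jj, ii[off])
  xx2 <- c(xx, xx[off])
  Ainv <- Matrix::sparseMatrix(i = ii2, j = jj2, x = xx2, dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  methods::as(Ainv, "generalMatrix")
}

#' Read a pedigree CSV
#'
#' Expects a header `animal,sire,dam[,generation][,environment]`; unknown
#' parents coded `0` or empty.
#'
#' @param path file path.
#' @return a [pedigree()] object.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(df))) {
    stop("pedigree file must have columns: ", paste(need, collapse = ", "))
  }
  pedigree(df$animal, df$sire, df$dam,
           generation = if ("generation" %in% names(df)) df$generation,
           environment = if ("environment" %in% names(df)) df$environment)
}

#' Write a pedigree CSV
#'
#' @param ped a [pedigree()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  df <- as.data.frame(ped)
  df$sire[is.na(df$sire)] <- "0"
  df$dam[is.na(df$dam)] <- "0"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export the sparse A-inverse in Matrix Market format
#'
#' @param ped a [pedigree()] object.
#' @param path output `.mtx` path.
#' @return `path`, invisibly.
#' @export
write_ainverse_mtx <- function(ped, path) {
  Matrix::writeMM(ainverse(ped), path)
  invisible(path)
}
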