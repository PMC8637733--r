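# Genotype-stratified trait-pair summaries and polynomial trend fits.

#' Polynomial least-squares fit of one trait on another
#'
#' Fits `y = c0 + c1*x + ... + cd*x^d` by ordinary least squares and reports
#' the coefficient of determination.  Used to draw the trend of a
#' trait-trait scatter, overall or within a genotype class.
#'
#' @param x,y numeric vectors (pairs with a missing value are dropped).
#' @param degree polynomial degree (>= 1).
#' @return list with `coefficients` (length `degree + 1`, ascending powers,
#'   named `c0..cd`), `r_squared` and `n`.
#' @export
polyfit_pair <- function(x, y, degree = 3L) {
  stopifnot(degree >= 1L)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < degree + 2L) {
    stop("polynomial fit of degree ", degree, " needs at least ",
         degree + 2L, " complete pairs (got ", n, ")")
  }
  if (length(unique(x)) <= degree) {
    stop("rank-deficient design: only ", length(unique(x)),
         " distinct x values for degree ", degree)
  }
  fit <- stats::lm(y ~ poly(x, degree, raw = TRUE))
  beta <- unname(stats::coef(fit))
  if (anyNA(beta)) stop("rank-deficient polynomial design matrix")
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  list(coefficients = stats::setNames(beta, paste0("c", 0:degree)),
       r_squared = r2, n = n)
}

#' Genotype-stratified summary of a trait pair at one marker
#'
#' Splits the population by genotype class at a marker (per-marker complete
#' cases) and reports, per class, the count, the bivariate mean and a
#' polynomial trend fit of trait2 on trait1; classes too small for the
#' requested degree keep their means but carry a note instead of a fit.
#' This reproduces, in numbers, the genotype-coloured scatter summaries
#' used to interpret how a covQTL remoulds a trait-trait relationship.
#'
#' @param map a [linkage_map()].
#' @param marker marker id.
#' @param phen a [phenotype_table()].
#' @param pair length-2 character vector of trait names.
#' @param degree polynomial degree for the per-class trend (default 3).
#' @return list of class `strat_summary`: `marker`, `pair`, `table`
#'   (class, n, mean_x, mean_y, c0..cd, r2, note) and `grand_mean`.
#' @export
stratify_marker <- function(map, marker, phen, pair, degree = 3L) {
  pair <- trait_pair(pair[[1]], pair[[2]], phen)
  phen <- align_phenotypes(map, phen)
  row <- match(marker, map$markers$id)
  if (is.na(row)) stop("marker ", marker, " not in map")
  g <- map$geno[row, ]
  x <- phen[[pair[[1]]]]; y <- phen[[pair[[2]]]]
  used <- !is.na(g) & stats::complete.cases(x, y)
  g <- g[used]; x <- x[used]; y <- y[used]
  classes <- sort(unique(g))
  rows <- lapply(classes, function(cl) {
    in_cl <- g == cl
    rec <- data.frame(class = cl, n = sum(in_cl),
                      mean_x = mean(x[in_cl]), mean_y = mean(y[in_cl]),
                      stringsAsFactors = FALSE)
    fit <- tryCatch(polyfit_pair(x[in_cl], y[in_cl], degree),
                    error = function(e) NULL)
    coefs <- stats::setNames(rep(NA_real_, degree + 1L), paste0("c", 0:degree))
    if (!is.null(fit)) coefs[] <- fit$coefficients
    rec <- cbind(rec, as.data.frame(as.list(coefs)))
    rec$r2 <- if (is.null(fit)) NA_real_ else fit$r_squared
    rec$note <- if (is.null(fit)) "class too small for polynomial fit" else ""
    rec
  })
  structure(list(marker = marker, pair = pair,
                 table = do.call(rbind, rows),
                 grand_mean = c(mean(x), mean(y)), n_used = length(x)),
            class = "strat_summary")
}

#' @export
print.strat_summary <- function(x, ...) {
  cat(sprintf("strat_summary at %s for %s-%s (n = %d)\n",
              x$marker, x$pair[[1]], x$pair[[2]], x$n_used))
  print(x$table, digits = 4)
  invisible(x)
}

#' Population-level overview of a trait pair
#'
#' Grand mean point, a polynomial trend fit, and — when the two parental
#' phenotypes are supplied — the number of transgressive segregants per
#' axis: offspring whose trait value lies strictly outside the range
#' spanned by the parents.
#'
#' @param phen a [phenotype_table()].
#' @param pair length-2 character vector of trait names.
#' @param degree polynomial degree for the trend fit.
#' @param parents optional 2 x 2 numeric matrix: one row per parent,
#'   columns in `pair` order.
#' @return list with `mean_x`, `mean_y`, `n`, `fit` and (when parents are
#'   given) `transgressive` = c(x =, y =) counts.
#' @export
pair_overview <- function(phen, pair, degree = 3L, parents = NULL) {
  pair <- trait_pair(pair[[1]], pair[[2]], phen)
  x <- phen[[pair[[1]]]]; y <- phen[[pair[[2]]]]
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  out <- list(mean_x = mean(x), mean_y = mean(y), n = length(x),
              fit = polyfit_pair(x, y, degree))
  if (!is.null(parents)) {
    parents <- as.matrix(parents)
    stopifnot(nrow(parents) == 2L, ncol(parents) == 2L)
    out$transgressive <- c(
      x = sum(x < min(parents[, 1]) | x > max(parents[, 1])),
      y = sum(y < min(parents[, 2]) | y > max(parents[, 2])))
  }
  out
}

#' Write a stratified summary table to TSV
#' @param strat a `strat_summary` (or list of them).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stratified <- function(strat, path) {
  if (inherits(strat, "strat_summary")) strat <- list(strat)
  tabs <- lapply(strat, function(s) {
    cbind(data.frame(marker = s$marker,
                     pair = paste(s$pair, collapse = ","),
                     stringsAsFactors = FALSE), s$table)
  })
  utils::write.table(do.call(rbind, tabs), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
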