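# Genome-wide LR scan and permutation threshold.
#
# Marker eligibility (complete cases, class counts) does not change when
# phenotype rows are permuted, so the scan precomputes an index structure
# once and evaluates the whole LR profile from scatter-matrix identities:
# for marker m with complete-case scatter S0 and pooled within-class
# scatter S1, LR_m = n_m * log(det S0 / det S1).  This is algebraically the
# log-likelihood difference of the two closed-form MLE fits (an identity
# the test suite checks against fit_h0/fit_h1 directly) and makes the
# thousands of re-scans behind a permutation threshold cheap.

# Precompute per-marker complete-case indices and class assignments.
scan_context <- function(map, phen, pair, min_class_size = 5L) {
  pair <- trait_pair(pair[[1]], pair[[2]], phen)
  phen <- align_phenotypes(map, phen)
  Y <- cbind(phen[[pair[[1]]]], phen[[pair[[2]]]])
  # standardize once for numerical conditioning: the LR is affine invariant,
  # but raw-moment scatter terms cancel catastrophically for traits with a
  # large offset.  Permutations only reorder rows, so this is done here, not
  # per profile evaluation; class means are mapped back on report.
  ctr <- colMeans(Y, na.rm = TRUE)
  scl <- pmax(apply(Y, 2L, stats::sd, na.rm = TRUE), .Machine$double.eps)
  Y <- sweep(sweep(Y, 2L, ctr), 2L, scl, "/")
  n_ind <- n_individuals(map)
  M <- n_markers(map)
  y_ok <- stats::complete.cases(Y)

  reason <- character(M)
  idx_list <- vector("list", M)
  cls_list <- vector("list", M)
  codes_list <- vector("list", M)
  n_used <- integer(M)
  k_classes <- integer(M)
  for (m in seq_len(M)) {
    g <- map$geno[m, ]
    used <- which(y_ok & !is.na(g))
    f <- factor(g[used])
    k <- nlevels(f)
    if (length(used) < 3L) {
      reason[m] <- "fewer than 3 complete cases"
    } else if (k < 2L) {
      reason[m] <- "monomorphic: fewer than 2 genotype classes"
    } else if (min(tabulate(f, k)) < min_class_size) {
      reason[m] <- sprintf("class too small (min %d < %d)",
                           min(tabulate(f, k)), min_class_size)
    } else {
      idx_list[[m]] <- used
      cls_list[[m]] <- as.integer(f)
      codes_list[[m]] <- levels(f)
      n_used[m] <- length(used)
      k_classes[m] <- k
    }
  }
  elig <- which(reason == "")
  if (!length(elig)) stop("no eligible marker for pair ",
                          paste(pair, collapse = ","))

  idx <- unlist(idx_list[elig], use.names = FALSE)
  obs_marker <- rep.int(seq_along(elig), n_used[elig])
  # globally unique class ids, grouped by marker
  class_offset <- c(0L, cumsum(k_classes[elig]))
  obs_class <- unlist(cls_list[elig], use.names = FALSE) +
    rep.int(class_offset[-length(class_offset)], n_used[elig])
  class_marker <- rep.int(seq_along(elig), k_classes[elig])
  class_n <- as.vector(rowsum(rep(1L, length(idx)), obs_class))

  list(pair = pair, Y = Y, ctr = ctr, scl = scl,
       n_ind = n_ind, elig = elig, reason = reason,
       idx = idx, obs_marker = obs_marker, obs_class = obs_class,
       class_marker = class_marker, class_n = class_n,
       n_used = n_used[elig], k = k_classes[elig],
       codes = codes_list[elig], min_class_size = min_class_size)
}

# LR profile over eligible markers for phenotype matrix Y (possibly a
# row-permuted copy of ctx$Y).  Returns the lr vector; with means = TRUE
# also the per-class mean vectors.
lr_profile <- function(ctx, Y = ctx$Y, means = FALSE) {
  Yi <- Y[ctx$idx, , drop = FALSE]
  cs <- rowsum(Yi, ctx$obs_class)                       # class sums
  ss <- rowsum(cbind(Yi[, 1]^2, Yi[, 2]^2, Yi[, 1] * Yi[, 2]),
               ctx$obs_marker)                          # raw scatter terms
  ts <- rowsum(cs, ctx$class_marker)                    # per-marker totals
  n <- ctx$n_used
  s0_11 <- ss[, 1] - ts[, 1]^2 / n
  s0_22 <- ss[, 2] - ts[, 2]^2 / n
  s0_12 <- ss[, 3] - ts[, 1] * ts[, 2] / n
  w <- rowsum(cbind(cs[, 1]^2, cs[, 2]^2, cs[, 1] * cs[, 2]) / ctx$class_n,
              ctx$class_marker)
  s1_11 <- ss[, 1] - w[, 1]
  s1_22 <- ss[, 2] - w[, 2]
  s1_12 <- ss[, 3] - w[, 3]
  det0 <- s0_11 * s0_22 - s0_12^2
  det1 <- s1_11 * s1_22 - s1_12^2
  lr <- ifelse(det0 > 0 & det1 > 0, n * (log(det0) - log(det1)), NA_real_)
  lr[!is.na(lr) & lr < 0] <- 0
  if (!means) return(lr)
  cm <- sweep(sweep(cs / ctx$class_n, 2L, ctx$scl, "*"), 2L, ctx$ctr, "+")
  list(lr = lr, class_means = cm)
}

#' Genome-wide bivariate LR scan for one trait pair
#'
#' Computes the log-likelihood-ratio statistic of the covariation-QTL model
#' (genotype-class-specific bivariate means, shared covariance) against the
#' single-mean null at every eligible marker of the map.  Individuals
#' missing either trait or the marker's genotype are dropped for that
#' marker only; markers that are monomorphic after this, or have a genotype
#' class smaller than `min_class_size`, or a singular scatter matrix, are
#' skipped with a recorded reason.
#'
#' @param map a [linkage_map()].
#' @param phen a [phenotype_table()] aligned (or alignable) with `map`.
#' @param pair length-2 character vector of trait names (or [trait_pair()]).
#' @param min_class_size smallest genotype class accepted at a marker.
#' @return A `covqtl_scan` object: list with `pair`, a per-marker `table`
#'   (`marker`, `lg`, `pos_cM`, `lr`, `df`, `n_used`, `skipped_reason`),
#'   per-marker genotype-class means (`class_means`), and threshold slots
#'   filled in by [permutation_threshold()].
#' @export
scan_pair <- function(map, phen, pair, min_class_size = 5L) {
  ctx <- scan_context(map, phen, pair, min_class_size)
  prof <- lr_profile(ctx, means = TRUE)
  M <- n_markers(map)
  lr <- rep(NA_real_, M)
  df <- rep(NA_integer_, M)
  n_used <- rep(NA_integer_, M)
  lr[ctx$elig] <- prof$lr
  df[ctx$elig] <- 2L * (ctx$k - 1L)
  n_used[ctx$elig] <- ctx$n_used
  reason <- ctx$reason
  reason[ctx$elig][is.na(prof$lr)] <- "singular scatter matrix"
  tab <- data.frame(marker = map$markers$id, lg = map$markers$lg,
                    pos_cM = map$markers$pos_cM, lr = lr, df = df,
                    n_used = n_used, skipped_reason = reason,
                    stringsAsFactors = FALSE)
  cm <- vector("list", M)
  names(cm) <- map$markers$id
  split_means <- split.data.frame(prof$class_means, ctx$class_marker)
  for (i in seq_along(ctx$elig)) {
    m <- split_means[[i]]
    dimnames(m) <- list(ctx$codes[[i]], ctx$pair)
    cm[[ctx$elig[i]]] <- m
  }
  structure(list(pair = ctx$pair, table = tab, class_means = cm,
                 threshold = NA_real_, alpha = NA_real_,
                 n_permutations = NA_integer_, seed = NA_integer_,
                 min_class_size = min_class_size),
            class = "covqtl_scan")
}

#' @export
print.covqtl_scan <- function(x, ...) {
  ok <- !is.na(x$table$lr)
  cat(sprintf("covqtl_scan %s-%s: %d markers scanned (%d skipped)\n",
              x$pair[[1]], x$pair[[2]], sum(ok), sum(!ok)))
  if (any(ok)) {
    top <- x$table[ok, ][which.max(x$table$lr[ok]), ]
    cat(sprintf("  max LR = %.3f at %s (lg %s, %.2f cM)\n",
                top$lr, top$marker, top$lg, top$pos_cM))
  }
  if (!is.na(x$threshold)) {
    cat(sprintf("  threshold = %.3f (alpha = %g, %d permutations, seed %s)\n",
                x$threshold, x$alpha, x$n_permutations, x$seed))
  }
  invisible(x)
}

# smallest of the top floor(alpha * n_perm) recorded maxima; i.e. the
# empirical critical value leaving the top alpha fraction significant
perm_critical_value <- function(maxima, alpha) {
  k <- max(1L, floor(alpha * length(maxima)))
  sort(maxima, decreasing = TRUE)[k]
}

#' Permutation-based genome-wide LR threshold
#'
#' Phenotype rows are reshuffled against the genotypes as intact bivariate
#' couples (preserving the trait-trait correlation under the null of no
#' marker-phenotype association); for each permutation the genome-wide
#' maximum LR is recorded, and the critical threshold is the smallest of
#' the top `alpha` fraction of the maxima (with 1,000 permutations at
#' `alpha = 0.05`, the 50th-largest maximum).
#'
#' @inheritParams scan_pair
#' @param n_perm number of permutations (>= 20).
#' @param alpha genome-wide significance level in (0, 1).
#' @param seed integer seed for the permutation stream; `NULL` continues the
#'   current RNG stream.
#' @return The threshold (numeric scalar) with the `n_perm` recorded maxima
#'   attached as attribute `"maxima"`.
#' @export
permutation_threshold <- function(map, phen, pair, n_perm = 1000L,
                                  alpha = 0.05, seed = NULL,
                                  min_class_size = 5L) {
  stopifnot(n_perm >= 20L, alpha > 0, alpha < 1)
  ctx <- scan_context(map, phen, pair, min_class_size)
  if (!is.null(seed)) set.seed(seed)
  maxima <- vapply(seq_len(n_perm), function(p) {
    Yp <- ctx$Y[sample.int(ctx$n_ind), , drop = FALSE]
    max(lr_profile(ctx, Yp), na.rm = TRUE)
  }, numeric(1))
  structure(perm_critical_value(maxima, alpha), maxima = maxima)
}

#' Attach a permutation threshold to a scan
#'
#' @param scan a `covqtl_scan`.
#' @param threshold critical LR value.
#' @param alpha,n_perm,seed bookkeeping echoed into the scan object.
#' @return The updated `covqtl_scan`.
#' @export
set_threshold <- function(scan, threshold, alpha = 0.05,
                          n_perm = NA_integer_, seed = NA_integer_) {
  scan$threshold <- as.numeric(threshold)
  scan$alpha <- alpha
  scan$n_permutations <- as.integer(n_perm)
  scan$seed <- seed
  scan
}

#' Call significant covariation QTLs
#'
#' Markers whose LR reaches the scan's threshold (ties significant) become
#' covQTL calls, sorted by linkage group and position, each carrying the
#' genotype-class mean vectors at the marker.
#'
#' @param scan a `covqtl_scan` with its threshold set.
#' @return data.frame with columns `marker`, `lg`, `pos_cM`, `lr`, `df`,
#'   `n_used`, `pair` and a list column `class_means`.
#' @export
call_significant <- function(scan) {
  if (is.na(scan$threshold)) stop("scan has no threshold; run permutation_threshold first")
  tab <- scan$table
  hit <- which(!is.na(tab$lr) & tab$lr >= scan$threshold)
  out <- tab[hit, c("marker", "lg", "pos_cM", "lr", "df", "n_used")]
  out$pair <- rep(paste(scan$pair, collapse = ","), nrow(out))
  out <- out[order(out$lg, out$pos_cM), , drop = FALSE]
  out$class_means <- scan$class_means[out$marker]
  rownames(out) <- NULL
  out
}

#' Co-location of covQTLs across trait pairs
#'
#' Collates significant-marker lists from several trait pairs into one
#' table keyed by marker, reporting for each marker the set of pairs it was
#' called in.  A marker significant for two or more pairs is a co-location,
#' suggesting pleiotropic control of both trait relationships.
#'
#' @param calls list of covQTL tables from [call_significant()].
#' @param min_pairs report `n_ge_k` = number of markers significant in at
#'   least this many pairs.
#' @return data.frame `marker`, `lg`, `pos_cM`, `n_pairs`, `pairs`, with
#'   attributes `n_total` (covQTL calls summed over pairs), `n_unique`
#'   (distinct markers) and `n_ge_k`.
#' @export
colocate <- function(calls, min_pairs = 2L) {
  stopifnot(length(calls) >= 1L)
  all <- do.call(rbind, lapply(calls, function(x)
    x[, c("marker", "lg", "pos_cM", "pair"), drop = FALSE]))
  if (nrow(all) == 0L) {
    out <- data.frame(marker = character(), lg = character(),
                      pos_cM = numeric(), n_pairs = integer(),
                      pairs = character(), stringsAsFactors = FALSE)
    attr(out, "n_total") <- 0L; attr(out, "n_unique") <- 0L
    attr(out, "n_ge_k") <- 0L
    return(out)
  }
  sp <- split(all, all$marker)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(marker = d$marker[1], lg = d$lg[1], pos_cM = d$pos_cM[1],
               n_pairs = length(unique(d$pair)),
               pairs = paste(sort(unique(d$pair)), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$lg, out$pos_cM), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_total") <- nrow(all)
  attr(out, "n_unique") <- nrow(out)
  attr(out, "n_ge_k") <- sum(out$n_pairs >= min_pairs)
  out
}

#' Merge significant markers into QTL peak regions
#'
#' Consecutive significant markers on one linkage group separated by at
#' most `gap_cM` are merged into a region; the region's peak is its
#' maximum-LR marker (first in map order on an exact tie).
#'
#' @param covqtls covQTL table for one trait pair ([call_significant()]).
#' @param gap_cM largest within-region gap between consecutive significant
#'   markers (default 10 cM).
#' @return data.frame `lg`, `start_cM`, `end_cM`, `n_markers`,
#'   `peak_marker`, `peak_lr`.
#' @export
peak_regions <- function(covqtls, gap_cM = 10) {
  if (nrow(covqtls) == 0L) {
    return(data.frame(lg = character(), start_cM = numeric(),
                      end_cM = numeric(), n_markers = integer(),
                      peak_marker = character(), peak_lr = numeric(),
                      stringsAsFactors = FALSE))
  }
  covqtls <- covqtls[order(covqtls$lg, covqtls$pos_cM), , drop = FALSE]
  out <- lapply(split(covqtls, covqtls$lg), function(d) {
    brk <- cumsum(c(0, diff(d$pos_cM) > gap_cM))
    do.call(rbind, lapply(split(d, brk), function(r) {
      peak <- which.max(r$lr)  # first index on exact ties
      data.frame(lg = r$lg[1], start_cM = min(r$pos_cM),
                 end_cM = max(r$pos_cM), n_markers = nrow(r),
                 peak_marker = r$marker[peak], peak_lr = r$lr[peak],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write a scan result to a TSV with a parameter header block
#'
#' @param scan a `covqtl_scan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pair=%s threshold=%s alpha=%s n_perm=%s seed=%s",
                     paste(scan$pair, collapse = ","),
                     format(scan$threshold), format(scan$alpha),
                     format(scan$n_permutations), format(scan$seed)), con)
  tab <- scan$table
  tab$significant <- !is.na(tab$lr) & !is.na(scan$threshold) &
    tab$lr >= scan$threshold
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
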