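# Synthetic full-sib F1 population generator.
#
# Meiosis in each parent is modelled as a two-state Markov chain along the
# markers of a linkage group: the transmitted allele switches between
# adjacent markers with the Haldane recombination fraction
# r = (1 - exp(-2d/100))/2 for map distance d cM (no interference).
# Testcross markers read the allele transmitted by parent 1 only (one
# informative parent, 1:1 segregation in expectation, codes "a"/"b");
# intercross markers read both parents (1:2:1, heterozygote phase collapsed
# to one class, codes "A"/"H"/"B").  Planted pleiotropic QTLs shift the
# bivariate phenotype mean per genotype class, in units of the residual SD.

#' Haldane map function
#'
#' Converts a map distance in centimorgan to a recombination fraction
#' assuming no crossover interference: r = (1 - exp(-2 d / 100)) / 2.
#'
#' @param d_cM map distance in cM (non-negative).
#' @return recombination fraction in [0, 0.5).
#' @export
haldane_r <- function(d_cM) {
  stopifnot(all(d_cM >= 0))
  (1 - exp(-2 * d_cM / 100)) / 2
}

#' Simulation configuration for a synthetic full-sib population
#'
#' Defaults emulate the mapping population behind the covariation-QTL
#' design: 200 full-sib individuals, 20 linkage groups carrying ~6,440
#' markers over ~3,152 cM in total, with roughly 17% intercross (1:2:1)
#' and 83% testcross (1:1) markers.
#'
#' @param n_individuals population size.
#' @param groups data.frame with columns `n_markers` and `length_cM`, one
#'   row per linkage group.
#' @param prop_intercross probability that a marker is intercross type.
#' @param qtls list of planted QTLs; each element is a list with `lg`
#'   (group index), `pos_cM` (requested position; the QTL is realised at
#'   the nearest marker) and `effects`, a k x 2 numeric matrix of genotype
#'   class mean shifts in residual-SD units (k = 2 forces a testcross
#'   marker with rows in class order a, b; k = 3 an intercross marker with
#'   rows A, H, B).
#' @param rho residual trait-trait correlation in (-1, 1).
#' @param sigma1,sigma2 residual standard deviations of the two traits.
#' @param trait_names names for the two simulated traits.
#' @param geno_missing_rate,phen_missing_rate fraction of genotype calls /
#'   phenotype cells set to missing (default 0).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 200L,
                       groups = data.frame(n_markers = rep(322L, 20L),
                                           length_cM = rep(157.6, 20L)),
                       prop_intercross = 1084 / 6446,
                       qtls = list(),
                       rho = 0.5, sigma1 = 1, sigma2 = 1,
                       trait_names = c("trait1", "trait2"),
                       geno_missing_rate = 0, phen_missing_rate = 0) {
  stopifnot(n_individuals >= 2L, is.data.frame(groups),
            all(c("n_markers", "length_cM") %in% names(groups)),
            prop_intercross >= 0, prop_intercross <= 1,
            abs(rho) < 1, sigma1 > 0, sigma2 > 0,
            geno_missing_rate >= 0, geno_missing_rate < 1,
            phen_missing_rate >= 0, phen_missing_rate < 1,
            length(trait_names) == 2L)
  for (q in qtls) {
    if (!all(c("lg", "pos_cM", "effects") %in% names(q))) {
      stop("each QTL needs lg, pos_cM and effects")
    }
    if (q$lg < 1 || q$lg > nrow(groups)) {
      stop("QTL placed on nonexistent linkage group ", q$lg)
    }
    ek <- nrow(as.matrix(q$effects))
    if (!(ek %in% c(2L, 3L)) || ncol(as.matrix(q$effects)) != 2L) {
      stop("QTL effects must be a 2x2 (testcross) or 3x2 (intercross) matrix")
    }
  }
  structure(list(n_individuals = as.integer(n_individuals), groups = groups,
                 prop_intercross = prop_intercross, qtls = qtls, rho = rho,
                 sigma1 = sigma1, sigma2 = sigma2, trait_names = trait_names,
                 geno_missing_rate = geno_missing_rate,
                 phen_missing_rate = phen_missing_rate),
            class = "sim_config")
}

TESTCROSS_CODES <- c("a", "b")
INTERCROSS_CODES <- c("A", "H", "B")

#' Simulate a full-sib F1 mapping population
#'
#' Places markers uniformly at random along each linkage group, simulates
#' linked genotypes by Haldane meiosis in both parents, and draws bivariate
#' phenotypes as the sum of the planted QTL class effects (in residual-SD
#' units) and a correlated bivariate-normal residual.  Fully reproducible
#' from `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return list with `map` (a [linkage_map()]), `phen` (a
#'   [phenotype_table()]) and `truth` (class `sim_truth`: realised QTL
#'   markers, positions and class-effect matrices, plus the seed).
#' @export
simulate_population <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_individuals
  G <- nrow(config$groups)
  ind <- sprintf("ind%03d", seq_len(n))

  marker_rows <- list()
  geno_rows <- list()
  qtl_marker_of <- integer(length(config$qtls))  # global marker row index
  total <- 0L
  for (g in seq_len(G)) {
    m <- config$groups$n_markers[g]
    len <- config$groups$length_cM[g]
    pos <- sort(stats::runif(m, 0, len))
    type <- ifelse(stats::runif(m) < config$prop_intercross,
                   "intercross", "testcross")
    # realise QTLs of this group at the nearest marker, forcing its type
    for (qi in seq_along(config$qtls)) {
      q <- config$qtls[[qi]]
      if (q$lg == g) {
        at <- which.min(abs(pos - q$pos_cM))
        type[at] <- if (nrow(as.matrix(q$effects)) == 2L) "testcross" else "intercross"
        qtl_marker_of[qi] <- total + at
      }
    }
    # parental meioses: allele switches with Haldane probability
    r <- haldane_r(diff(pos))
    A1 <- matrix(0L, n, m)
    A2 <- matrix(0L, n, m)
    A1[, 1] <- stats::rbinom(n, 1L, 0.5)
    A2[, 1] <- stats::rbinom(n, 1L, 0.5)
    for (k in seq_len(m - 1L)) {
      A1[, k + 1L] <- (A1[, k] + stats::rbinom(n, 1L, r[k])) %% 2L
      A2[, k + 1L] <- (A2[, k] + stats::rbinom(n, 1L, r[k])) %% 2L
    }
    geno <- matrix(NA_character_, m, n)
    tc <- type == "testcross"
    geno[tc, ] <- t(matrix(TESTCROSS_CODES[A1[, tc, drop = FALSE] + 1L],
                           n, sum(tc)))
    geno[!tc, ] <- t(matrix(INTERCROSS_CODES[A1[, !tc, drop = FALSE] +
                                               A2[, !tc, drop = FALSE] + 1L],
                            n, sum(!tc)))
    marker_rows[[g]] <- data.frame(
      id = sprintf("lg%d_%03d", g, seq_len(m)), lg = paste0("lg", g),
      pos_cM = pos, seg_type = type, stringsAsFactors = FALSE)
    geno_rows[[g]] <- geno
    total <- total + m
  }
  markers <- do.call(rbind, marker_rows)
  geno <- do.call(rbind, geno_rows)
  colnames(geno) <- ind

  # phenotypes: QTL class effects (in residual-SD units) + correlated noise
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  y1 <- config$sigma1 * z1
  y2 <- config$sigma2 * (config$rho * z1 + sqrt(1 - config$rho^2) * z2)
  truth_qtls <- vector("list", length(config$qtls))
  for (qi in seq_along(config$qtls)) {
    q <- config$qtls[[qi]]
    row <- qtl_marker_of[qi]
    eff <- as.matrix(q$effects)
    codes <- if (nrow(eff) == 2L) TESTCROSS_CODES else INTERCROSS_CODES
    cls <- match(geno[row, ], codes)
    y1 <- y1 + eff[cls, 1] * config$sigma1
    y2 <- y2 + eff[cls, 2] * config$sigma2
    truth_qtls[[qi]] <- list(marker = markers$id[row], lg = markers$lg[row],
                             pos_requested = q$pos_cM,
                             pos_cM = markers$pos_cM[row],
                             seg_type = markers$seg_type[row],
                             effects = eff)
  }

  if (config$geno_missing_rate > 0) {
    drop <- stats::runif(length(geno)) < config$geno_missing_rate
    geno[drop] <- NA_character_
  }
  if (config$phen_missing_rate > 0) {
    y1[stats::runif(n) < config$phen_missing_rate] <- NA_real_
    y2[stats::runif(n) < config$phen_missing_rate] <- NA_real_
  }

  phen <- data.frame(individual = ind, y1, y2, stringsAsFactors = FALSE)
  names(phen)[2:3] <- config$trait_names
  list(map = linkage_map(markers, geno),
       phen = phenotype_table(phen),
       truth = structure(list(qtls = truth_qtls, seed = seed,
                              config = config), class = "sim_truth"))
}

#' Chi-square check of marker segregation ratios
#'
#' Compares the observed genotype-class counts of every marker against the
#' expected 1:1 (testcross) or 1:2:1 (intercross) ratio.  For intercross
#' markers the heterozygote class must be identifiable by code (`het_code`,
#' default the simulator's `"H"`).
#'
#' @param map a [linkage_map()].
#' @param het_code genotype code of the intercross heterozygote class.
#' @return data.frame `marker`, `seg_type`, `chisq`, `df`, `p_value`.
#' @export
segregation_check <- function(map, het_code = "H") {
  res <- lapply(seq_len(n_markers(map)), function(m) {
    g <- map$geno[m, ]
    g <- g[!is.na(g)]
    type <- map$markers$seg_type[m]
    codes <- sort(unique(g))
    if (type == "testcross") {
      expected_prop <- stats::setNames(rep(0.5, 2), codes[seq_len(min(2, length(codes)))])
      if (length(codes) == 1L) {
        # absent second class still contributes its expected count
        expected_prop <- stats::setNames(c(0.5, 0.5), c(codes, ".absent"))
      }
    } else {
      all_codes <- union(codes, het_code)
      others <- setdiff(all_codes, het_code)
      if (length(others) == 1L) others <- c(others, ".absent")
      expected_prop <- stats::setNames(
        c(0.5, rep(0.25, length(others))), c(het_code, others))
    }
    obs <- stats::setNames(rep(0, length(expected_prop)), names(expected_prop))
    tab <- table(g)
    obs[names(tab)] <- as.numeric(tab)
    exp_cnt <- expected_prop * length(g)
    chisq <- sum((obs - exp_cnt)^2 / exp_cnt)
    df <- length(expected_prop) - 1L
    data.frame(marker = map$markers$id[m], seg_type = type, chisq = chisq,
               df = df, p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write a simulated dataset to disk
#'
#' Writes the genotype/map TSV, the phenotype CSV and a plain-text truth
#' table (realised QTL markers and class effects), in the formats read by
#' [read_genotype_map()] and [read_phenotypes()].
#'
#' @param sim result of [simulate_population()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotype_map(sim$map, file.path(dir, "genotypes.tsv"))
  write_phenotypes(sim$phen, file.path(dir, "phenotypes.csv"))
  truth <- do.call(rbind, lapply(sim$truth$qtls, function(q) {
    data.frame(marker = q$marker, lg = q$lg, pos_cM = q$pos_cM,
               pos_requested = q$pos_requested, seg_type = q$seg_type,
               effects = paste(apply(q$effects, 1L, paste, collapse = ":"),
                               collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(truth)) {
    truth <- data.frame(marker = character(), lg = character(),
                        pos_cM = numeric(), pos_requested = numeric(),
                        seg_type = character(), effects = character())
  }
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
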