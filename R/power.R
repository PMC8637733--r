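# Operating characteristics of the permutation-calibrated scan, estimated
# by Monte-Carlo simulation with the package's own population generator.

#' Family-wise type-I error of the permutation-calibrated scan
#'
#' Simulates independent null populations (no planted QTL), computes the
#' permutation threshold for each and records whether any marker's LR
#' reaches it.  The fraction of replicates with at least one call estimates
#' the family-wise error rate, which should match the nominal `alpha`.
#'
#' @param config a [sim_config()] without QTLs.
#' @param n_replicates number of simulated null experiments.
#' @param n_perm permutations per replicate.
#' @param alpha nominal genome-wide significance level.
#' @param seed integer seed for the whole replicate schedule; `NULL`
#'   continues the current RNG stream.
#' @return list with `fwer`, `n_replicates`, `alpha`, `calls` (logical per
#'   replicate) and the 95% binomial standard-error-based interval
#'   `ci95`.
#' @export
estimate_fwer <- function(config = sim_config(), n_replicates = 200L,
                          n_perm = 200L, alpha = 0.05, seed = NULL) {
  if (length(config$qtls)) stop("null calibration requires a config without QTLs")
  if (!is.null(seed)) set.seed(seed)
  calls <- vapply(seq_len(n_replicates), function(rep) {
    sim <- simulate_population(config, seed = NULL)
    ctx <- scan_context(sim$map, sim$phen, config$trait_names)
    obs_max <- max(lr_profile(ctx), na.rm = TRUE)
    maxima <- vapply(seq_len(n_perm), function(p) {
      Yp <- ctx$Y[sample.int(ctx$n_ind), , drop = FALSE]
      max(lr_profile(ctx, Yp), na.rm = TRUE)
    }, numeric(1))
    obs_max >= perm_critical_value(maxima, alpha)
  }, logical(1))
  fwer <- mean(calls)
  se <- sqrt(alpha * (1 - alpha) / n_replicates)
  list(fwer = fwer, n_replicates = n_replicates, alpha = alpha,
       calls = calls, ci95 = c(alpha - 1.96 * se, alpha + 1.96 * se))
}

#' Detection power and localisation of a planted pleiotropic QTL
#'
#' For each effect size, simulates populations carrying one testcross QTL
#' whose second genotype class is shifted by `effect` residual SDs on both
#' traits, scans the pair, and records (i) whether the genome-wide maximum
#' LR reaches the per-replicate permutation threshold (power) and (ii)
#' whether the peak marker lies within `loc_tol_cM` of the true QTL.
#'
#' @param effects numeric vector of class-mean shifts in residual-SD units.
#' @param config base [sim_config()]; its `qtls` are replaced per effect.
#' @param qtl_lg,qtl_pos_cM where to plant the QTL.
#' @param n_replicates replicates per effect size.
#' @param n_perm permutations per replicate.
#' @param alpha genome-wide significance level.
#' @param loc_tol_cM localisation tolerance around the true position.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return data.frame `effect`, `power`, `loc_rate` (fraction of replicates
#'   with the peak within tolerance), `n_replicates`.
#' @export
detection_power <- function(effects = c(0, 0.25, 0.5, 1),
                            config = sim_config(
                              groups = data.frame(n_markers = rep(50L, 3L),
                                                  length_cM = rep(100, 3L))),
                            qtl_lg = 1L, qtl_pos_cM = 50,
                            n_replicates = 100L, n_perm = 100L,
                            alpha = 0.05, loc_tol_cM = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(effects, function(e) {
    qtls <- if (e == 0) list() else
      list(list(lg = qtl_lg, pos_cM = qtl_pos_cM,
                effects = rbind(c(0, 0), c(e, e))))
    cfg <- sim_config(
      n_individuals = config$n_individuals, groups = config$groups,
      prop_intercross = config$prop_intercross, qtls = qtls,
      rho = config$rho, sigma1 = config$sigma1, sigma2 = config$sigma2,
      trait_names = config$trait_names,
      geno_missing_rate = config$geno_missing_rate,
      phen_missing_rate = config$phen_missing_rate)
    hit <- logical(n_replicates)
    near <- logical(n_replicates)
    for (rep in seq_len(n_replicates)) {
      sim <- simulate_population(cfg, seed = NULL)
      ctx <- scan_context(sim$map, sim$phen, cfg$trait_names)
      lr <- lr_profile(ctx)
      peak <- ctx$elig[which.max(lr)]
      maxima <- vapply(seq_len(n_perm), function(p) {
        Yp <- ctx$Y[sample.int(ctx$n_ind), , drop = FALSE]
        max(lr_profile(ctx, Yp), na.rm = TRUE)
      }, numeric(1))
      hit[rep] <- max(lr, na.rm = TRUE) >= perm_critical_value(maxima, alpha)
      if (e > 0) {
        truth <- sim$truth$qtls[[1]]
        near[rep] <- sim$map$markers$lg[peak] == truth$lg &&
          abs(sim$map$markers$pos_cM[peak] - truth$pos_cM) <= loc_tol_cM
      }
    }
    data.frame(effect = e, power = mean(hit),
               loc_rate = if (e > 0) mean(near) else NA_real_,
               n_replicates = n_replicates)
  })
  do.call(rbind, rows)
}
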