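test_that("simulation is bit-reproducible from its seed", {
  cfg <- sim_config(n_individuals = 50L,
                    groups = data.frame(n_markers = c(10L, 8L),
                                        length_cM = c(60, 90)),
                    qtls = list(list(lg = 1, pos_cM = 30,
                                     effects = rbind(c(0, 0), c(1, 1)))))
  a <- simulate_population(cfg, seed = 71)
  b <- simulate_population(cfg, seed = 71)
  expect_identical(a$map$geno, b$map$geno)
  expect_identical(a$map$markers, b$map$markers)
  expect_identical(a$phen, b$phen)
  expect_identical(a$truth$qtls, b$truth$qtls)
})

test_that("declared seg types match the simulated class counts everywhere", {
  set.seed(72)
  sim <- simulate_population(sim_config(
    n_individuals = 300L,
    groups = data.frame(n_markers = rep(40L, 2L), length_cM = rep(120, 2L))))
  observed <- apply(sim$map$geno, 1L, classify_segregation)
  expect_equal(unname(observed), sim$map$markers$seg_type)
})

test_that("intercross fraction tracks prop_intercross", {
  set.seed(73)
  sim <- simulate_population(sim_config(
    n_individuals = 500L,
    groups = data.frame(n_markers = 400L, length_cM = 2000),
    prop_intercross = 0.3))
  frac <- mean(sim$map$markers$seg_type == "intercross")
  expect_lt(abs(frac - 0.3), 3 / sqrt(400))
})

test_that("zero map distance duplicates genotype vectors exactly", {
  set.seed(74)
  sim <- simulate_population(sim_config(
    n_individuals = 100L,
    groups = data.frame(n_markers = 4L, length_cM = 0),
    prop_intercross = 0))
  for (m in 2:4) {
    expect_identical(sim$map$geno[m, ], sim$map$geno[1, ])
  }
  sim2 <- simulate_population(sim_config(
    n_individuals = 100L,
    groups = data.frame(n_markers = 3L, length_cM = 0),
    prop_intercross = 1))
  expect_identical(sim2$map$geno[2, ], sim2$map$geno[1, ])
})

test_that("adjacent-marker recombination matches the Haldane prediction", {
  expect_equal(haldane_r(0), 0)
  expect_lt(abs(haldane_r(1e4) - 0.5), 1e-10)
  set.seed(75)
  n <- 10000L
  sim <- simulate_population(sim_config(
    n_individuals = n,
    groups = data.frame(n_markers = 8L, length_cM = 120),
    prop_intercross = 0))
  pos <- sim$map$markers$pos_cM
  for (m in seq_len(7L)) {
    r_hat <- mean(sim$map$geno[m, ] != sim$map$geno[m + 1L, ])
    r_exp <- haldane_r(pos[m + 1L] - pos[m])
    tol <- 4 * sqrt(max(r_exp * (1 - r_exp), 0.01) / n)
    expect_lt(abs(r_hat - r_exp), tol)
  }
  # long-range limit: far markers approach free recombination (r = 1/2)
  r_far <- mean(sim$map$geno[1, ] != sim$map$geno[8, ])
  expect_lt(abs(r_far - haldane_r(pos[8] - pos[1])), 0.03)
})

test_that("a QTL-free population is pure correlated bivariate noise", {
  set.seed(76)
  sim <- simulate_population(sim_config(
    n_individuals = 2000L,
    groups = data.frame(n_markers = 5L, length_cM = 50),
    rho = 0.6, sigma1 = 2, sigma2 = 0.5))
  expect_lt(abs(cor(sim$phen$trait1, sim$phen$trait2) - 0.6), 3 / sqrt(2000))
  expect_lt(abs(sd(sim$phen$trait1) - 2), 0.15)
  expect_lt(abs(sd(sim$phen$trait2) - 0.5), 0.05)
})

test_that("planted QTLs are realised at in-map markers with forced type", {
  set.seed(77)
  cfg <- sim_config(
    groups = data.frame(n_markers = rep(20L, 3L), length_cM = rep(100, 3L)),
    qtls = list(
      list(lg = 2, pos_cM = 50, effects = rbind(c(0, 0), c(1, -1))),
      list(lg = 3, pos_cM = 10,
           effects = rbind(c(0, 0), c(0.5, 0.5), c(1, 1)))))
  sim <- simulate_population(cfg, seed = 77)
  for (q in sim$truth$qtls) {
    row <- match(q$marker, sim$map$markers$id)
    expect_false(is.na(row))
    expect_equal(sim$map$markers$lg[row], q$lg)
    expect_equal(sim$map$markers$seg_type[row], q$seg_type)
  }
  expect_equal(sim$truth$qtls[[1]]$seg_type, "testcross")
  expect_equal(sim$truth$qtls[[2]]$seg_type, "intercross")
  expect_error(sim_config(groups = data.frame(n_markers = 5L, length_cM = 50),
                          qtls = list(list(lg = 4, pos_cM = 1,
                                           effects = rbind(c(0, 0), c(1, 1))))),
               "nonexistent")
})

test_that("segregation chi-square reproduces hand-computed values", {
  g_even <- matrix(rep(c("a", "b"), each = 100), 1, 200)
  chk <- segregation_check(make_map(g_even))
  expect_equal(chk$chisq, 0)
  g_121 <- matrix(rep(c("A", "H", "B"), c(50, 100, 50)), 1, 200)
  chk2 <- segregation_check(make_map(g_121))
  expect_equal(chk2$chisq, 0)
  g_skew <- matrix(rep(c("a", "b"), c(80, 120)), 1, 200)
  chk3 <- segregation_check(make_map(g_skew))
  expect_equal(chk3$chisq, 8)          # 400/100 + 400/100
  expect_equal(chk3$df, 1L)
  expect_equal(chk3$p_value, pchisq(8, 1, lower.tail = FALSE))
})

test_that("simulated markers segregate 1:1 and 1:2:1 in aggregate", {
  set.seed(78)
  sim <- simulate_population(sim_config(
    n_individuals = 400L,
    groups = data.frame(n_markers = 60L, length_cM = 600)))
  chk <- segregation_check(sim$map)
  # p-values behave like null p-values: few tiny ones
  expect_lt(mean(chk$p_value < 0.01), 0.1)
})

test_that("missing-data injection hits roughly its configured rate", {
  set.seed(79)
  sim <- simulate_population(sim_config(
    n_individuals = 200L,
    groups = data.frame(n_markers = 50L, length_cM = 100),
    geno_missing_rate = 0.1, phen_missing_rate = 0.15))
  expect_lt(abs(mean(is.na(sim$map$geno)) - 0.1), 0.02)
  expect_lt(abs(mean(is.na(sim$phen$trait1)) - 0.15), 0.1)
})

test_that("simulated datasets round-trip through their on-disk formats", {
  sim <- simulate_population(sim_config(
    n_individuals = 30L,
    groups = data.frame(n_markers = 6L, length_cM = 50),
    qtls = list(list(lg = 1, pos_cM = 25,
                     effects = rbind(c(0, 0), c(1, 1))))), seed = 80)
  dir <- tempfile()
  write_simulation(sim, dir)
  map2 <- read_genotype_map(file.path(dir, "genotypes.tsv"))
  phen2 <- read_phenotypes(file.path(dir, "phenotypes.csv"), map = map2)
  expect_identical(map2$geno, sim$map$geno)
  expect_identical(phen2$trait1, sim$phen$trait1)
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(truth$marker, sim$truth$qtls[[1]]$marker)
})
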