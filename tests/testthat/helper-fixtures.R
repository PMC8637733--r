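# Small in-code fixtures shared across test files.

# 3-marker, 4-individual toy genotype/map TSV written to a temp file
write_toy_map_file <- function(path = tempfile(fileext = ".tsv"),
                               lines = NULL) {
  if (is.null(lines)) {
    lines <- c(
      "marker\tlg\tpos_cM\tseg_type\ti1\ti2\ti3\ti4",
      "m1\tlg1\t0.0\ttestcross\ta\tb\ta\tb",
      "m2\tlg1\t5.1\ttestcross\ta\ta\tb\tb",
      "m3\tlg1\t9.0\tintercross\tA\tH\tB\tH")
  }
  writeLines(lines, path)
  path
}

write_toy_phen_file <- function(path = tempfile(fileext = ".csv"),
                                lines = NULL) {
  if (is.null(lines)) {
    lines <- c("individual,LL,LW",
               "i1,10.5,5.2", "i2,12.0,6.1", "i3,9.8,4.9", "i4,11.1,5.5")
  }
  writeLines(lines, path)
  path
}

# linkage map built directly in code: m markers x n individuals
make_map <- function(geno, pos = seq_len(nrow(geno)) - 1, lg = "lg1",
                     seg_type = NULL) {
  if (is.null(seg_type)) {
    seg_type <- apply(geno, 1L, classify_segregation)
  }
  linkage_map(
    data.frame(id = paste0("m", seq_len(nrow(geno))), lg = lg,
               pos_cM = pos, seg_type = seg_type, stringsAsFactors = FALSE),
    geno)
}

make_phen <- function(y, ids = NULL, traits = c("t1", "t2")) {
  y <- as.matrix(y)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(y)))
  df <- data.frame(individual = ids, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(y))) df[[traits[j]]] <- y[, j]
  phenotype_table(df)
}

# correlated bivariate normal draws
rbvn <- function(n, rho = 0.5, sigma1 = 1, sigma2 = 1,
                 mu = c(0, 0)) {
  z1 <- rnorm(n); z2 <- rnorm(n)
  cbind(mu[1] + sigma1 * z1,
        mu[2] + sigma2 * (rho * z1 + sqrt(1 - rho^2) * z2))
}

# independent oracle: scatter matrices computed longhand
scatter_lr_oracle <- function(y, classes) {
  n <- nrow(y)
  center <- function(block) {
    mu <- colMeans(block)
    d <- sweep(block, 2, mu)
    t(d) %*% d
  }
  s0 <- center(y)
  s1 <- matrix(0, 2, 2)
  for (cl in unique(classes)) s1 <- s1 + center(y[classes == cl, , drop = FALSE])
  n * log(det(s0) / det(s1))
}

# independent oracle: two-sample Hotelling T^2 with pooled unbiased covariance
hotelling_t2_oracle <- function(y, classes) {
  cls <- unique(classes)
  stopifnot(length(cls) == 2)
  a <- y[classes == cls[1], , drop = FALSE]
  b <- y[classes == cls[2], , drop = FALSE]
  n1 <- nrow(a); n2 <- nrow(b)
  sp <- ((n1 - 1) * cov(a) + (n2 - 1) * cov(b)) / (n1 + n2 - 2)
  d <- colMeans(a) - colMeans(b)
  as.numeric(n1 * n2 / (n1 + n2) * t(d) %*% solve(sp) %*% d)
}
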