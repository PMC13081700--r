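# Mass-univariate model fitting and permutation null maps.

test_that("t statistic matches the closed-form simple-regression oracle", {
  y <- c(1.1, 1.9, 3.2, 3.8, 5.1, 5.9)
  x <- 1:6
  # independent matrix-algebra oracle
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (6 - 2)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  t_oracle <- beta[2] / se

  img <- imaging_matrix(matrix(y, ncol = 1))
  des <- phenotype_design(data.frame(x3 = x), "x3")
  obs <- fit_association_map(img, des)
  expect_equal(obs$values[1], t_oracle, tolerance = 1e-10)
})

test_that("t map matches per-location lm() fits with nuisance covariates", {
  dat <- tiny_dataset(N = 20, V = 8)
  obs <- fit_association_map(dat$imaging, dat$design)
  expect_equal(obs$values, naive_tmap(dat$Y, dat$covs, "x3", c("x1", "x2")),
               tolerance = 1e-8)
  # partial correlation and F transforms of the same fit
  r <- fit_association_map(dat$imaging, dat$design, "pearson_r")$values
  f <- fit_association_map(dat$imaging, dat$design, "F")$values
  df <- 20 - 4
  expect_equal(r, obs$values / sqrt(obs$values^2 + df), tolerance = 1e-12)
  expect_equal(f, obs$values^2, tolerance = 1e-8)
  expect_false(any(f < 0))
})

test_that("nuisance-only and constant locations are handled", {
  set.seed(9)
  covs <- data.frame(x1 = rnorm(15), x2 = rnorm(15), x3 = rnorm(15))
  Y <- cbind(2 * covs$x1 - covs$x2 + 1,   # exact nuisance combination
             rnorm(15),
             rep(3.7, 15))                # constant
  img <- imaging_matrix(Y)
  des <- phenotype_design(covs, "x3", c("x1", "x2"))
  obs <- fit_association_map(img, des)
  expect_equal(obs$values[1], 0, tolerance = 1e-6)
  expect_true(obs$valid[2])
  expect_false(obs$valid[3])
  expect_true(is.na(obs$values[3]))
})

test_that("rank-deficient designs are refused with the offending column named", {
  covs <- data.frame(x1 = 1:10, x2 = 2 * (1:10), x3 = rnorm(10))
  expect_error(phenotype_design(covs, "x3", c("x1", "x2")),
               "rank deficient.*x2")
})

test_that("identity permutation reproduces the observed map bit-for-bit", {
  dat <- tiny_dataset(N = 18, V = 25)
  plan <- permutation_plan(18, 3, "freedman_lane", seed = 2)
  plan$permutations[2, ] <- 1:18
  obs <- fit_association_map(dat$imaging, dat$design)
  nulls <- freedman_lane_null_maps(dat$imaging, dat$design, plan)
  expect_identical(nulls$maps[2, ], unname(obs$values))
  # shape contract: K maps over the same analyzable locations
  expect_equal(nrow(nulls$maps), 3)
  expect_identical(is.na(nulls$maps[1, ]), !obs$valid)
  expect_error(freedman_lane_null_maps(dat$imaging, dat$design,
                                       permutation_plan(18, 2, "simple")),
               "freedman_lane")
})

test_that("Freedman-Lane nulls match literal lm() refits", {
  dat <- tiny_dataset(N = 16, V = 6, seed = 13)
  plan <- permutation_plan(16, 4, "freedman_lane", seed = 3)
  nulls <- freedman_lane_null_maps(dat$imaging, dat$design, plan)
  for (k in 1:4) {
    perm <- plan$permutations[k, ]
    Ystar <- matrix(0, 16, 6)
    for (v in 1:6) {
      fit <- lm(dat$Y[, v] ~ x1 + x2, data = dat$covs)
      Ystar[, v] <- fitted(fit) + resid(fit)[perm]
    }
    expect_equal(nulls$maps[k, ], naive_tmap(Ystar, dat$covs, "x3", c("x1", "x2")),
                 tolerance = 1e-8)
  }
})

test_that("simple-scheme nulls match refitting with a permuted target", {
  dat <- tiny_dataset(N = 16, V = 6, seed = 14)
  plan <- permutation_plan(16, 3, "simple", seed = 4)
  nulls <- null_association_maps(dat$imaging, dat$design, plan)
  for (k in 1:3) {
    covs_k <- dat$covs
    covs_k$x3 <- dat$covs$x3[plan$permutations[k, ]]
    expect_equal(nulls$maps[k, ], naive_tmap(dat$Y, covs_k, "x3", c("x1", "x2")),
                 tolerance = 1e-8)
  }
})

test_that("pooled null t-values have t-distribution moments under iid noise", {
  set.seed(5)
  N <- 12
  df <- N - 2   # intercept + target only
  Y <- matrix(rnorm(N * 300), N, 300)
  img <- imaging_matrix(Y)
  des <- phenotype_design(data.frame(x3 = rnorm(N)), "x3")
  plan <- permutation_plan(N, 40, "freedman_lane", seed = 6)
  nulls <- freedman_lane_null_maps(img, des, plan)
  pooled <- as.vector(nulls$maps)
  expect_equal(mean(pooled), 0, tolerance = 0.02)
  expect_equal(var(pooled), df / (df - 2), tolerance = 0.05)
})

test_that("null-map spatial correlation mirrors residual correlation", {
  set.seed(15)
  N <- 60
  shared <- rnorm(N)
  Y <- cbind(shared + rnorm(N, sd = 0.6), shared + rnorm(N, sd = 0.6),
             rnorm(N))
  img <- imaging_matrix(Y)
  des <- phenotype_design(data.frame(x3 = rnorm(N)), "x3")
  plan <- permutation_plan(N, 400, "freedman_lane", seed = 16)
  nulls <- freedman_lane_null_maps(img, des, plan)
  res <- apply(Y, 2, function(y) resid(lm(y ~ 1)))
  expect_equal(cor(nulls$maps[, 1], nulls$maps[, 2]), cor(res[, 1], res[, 2]),
               tolerance = 0.1)
  expect_equal(cor(nulls$maps[, 1], nulls$maps[, 3]), cor(res[, 1], res[, 3]),
               tolerance = 0.1)
})

test_that("permutation plans are reproducible, stratified, and uniform", {
  p1 <- permutation_plan(20, 5, "simple", seed = 10)
  p2 <- permutation_plan(20, 5, "simple", seed = 10)
  expect_identical(p1$permutations, p2$permutations)
  expect_true(all(apply(p1$permutations, 1, function(r) all(sort(r) == 1:20))))

  fam <- rep(1:4, each = 5)
  ps <- permutation_plan(20, 50, "stratified", seed = 11, strata = fam)
  for (k in 1:50)
    expect_identical(fam[ps$permutations[k, ]], fam)
  expect_warning(permutation_plan(3, 2, "stratified", seed = 1,
                                  strata = c(1, 1, 2)),
                 "size 1")

  # uniformity: position-1 frequencies over K = 1000 draws from N = 50
  pu <- permutation_plan(50, 1000, "simple", seed = 12)
  freq <- tabulate(pu$permutations[, 1], 50) / 1000
  expect_true(all(abs(freq - 1 / 50) < 4 * sqrt(0.02 * 0.98 / 1000)))
})

test_that("permute_phenotype reorders only the target column", {
  dat <- tiny_dataset(N = 12, V = 4)
  plan <- permutation_plan(12, 3, "simple", seed = 8)
  perms <- permute_phenotype(dat$design, plan)
  expect_length(perms, 3)
  for (k in 1:3) {
    expect_identical(perms[[k]]$values$x1, dat$covs$x1)
    expect_identical(perms[[k]]$values$x2, dat$covs$x2)
    expect_identical(perms[[k]]$values$x3,
                     dat$covs$x3[plan$permutations[k, ]])
  }
})
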