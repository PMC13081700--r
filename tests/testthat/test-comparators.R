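# Comparator enrichment tests and their surrogate-map generators.

test_that("thresholded Fisher's-exact enrichment matches the hypergeometric tail", {
  # s = 0: the sum covers the full support, so p = 1 (Vandermonde)
  part10 <- network_partition(rep(c(1, 0), c(3, 7)), 1)
  vals <- c(0.1, 0.2, 0.3, 2.5, 2.7, 0.1, 0.4, 0.2, 3.1, 0.0)
  expect_equal(rigea_test(vals, part10, "right"), 1)

  # V=4, m=2, S=2, s=2: p = C(2,2) C(2,0) / C(4,2) = 1/6
  part4 <- network_partition(c(1, 1, 0, 0), 1)
  expect_equal(rigea_test(c(2, 2.5, 0, 0.5), part4, "right"), 1 / 6)

  # V=100, m=10, S=10, s=5 vs direct summation
  vals100 <- c(rep(3, 5), rep(0, 5), rep(3, 5), rep(0, 85))
  part100 <- network_partition(rep(c(1, 0), c(10, 90)), 1)
  expect_equal(rigea_test(vals100, part100, "right"),
               hyper_tail(5, 10, 10, 100), tolerance = 1e-12)

  # left side thresholds at -1.96
  expect_equal(rigea_test(-c(2, 2.5, 0, 0.5), part4, "left"), 1 / 6)

  # no significant locations: vacuous table
  expect_warning(p0 <- rigea_test(rep(0, 4), part4, "right"), "p = 1")
  expect_equal(p0, 1)
})

test_that("Fisher's-exact tail agrees with phyper and summation over many tables", {
  set.seed(50)
  for (i in 1:60) {
    V <- sample(10:200, 1)
    m <- sample(2:(V - 2), 1)
    S <- sample(1:V, 1)
    smax <- min(S, m)
    smin <- max(0, S - (V - m))
    s <- sample(smin:smax, 1)
    p_pkg <- {
      vals <- numeric(V)
      vals[seq_len(m)][seq_len(s)] <- 3                    # s in-network hits
      if (S - s > 0) vals[m + seq_len(S - s)] <- 3         # rest outside
      part <- network_partition(rep(c(1, 0), c(m, V - m)), 1)
      suppressWarnings(rigea_test(vals, part, "right"))
    }
    expect_equal(p_pkg, hyper_tail(s, S, m, V), tolerance = 1e-10)
    expect_equal(p_pkg, stats::phyper(s - 1, m, V - m, S, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("enrichment score is the difference in means and shift-invariant", {
  part <- network_partition(c(1, 1, 0, 0), 1)
  expect_equal(enrichment_score(c(2, 2, 1, 1), part), 1)
  part5 <- network_partition(rep(c(1, 0), c(3, 2)), 1)
  expect_equal(enrichment_score(c(1, 3, 5, 0, 2), part5), 2)
  expect_equal(enrichment_score(c(1, 3, 5, 0, 2) + 7.3, part5), 2)
})

test_that("surrogate mean-difference test counts ties and honors validity", {
  part <- network_partition(rep(c(1, 0), c(2, 3)), 1)
  obs <- c(3, 3, 1, 1, 1)                          # ES_obs = 2
  surr <- surrogate_map_set(rbind(c(1, 1, 1, 1, 1),  # ES = 0
                                  c(3, 3, 1, 1, 1),  # ES = 2 (tie)
                                  c(0, 0, 2, 2, 2)), # ES = -2
                            "spin")
  expect_equal(as.numeric(surrogate_test(obs, part, surr, "right")),
               (1 + 1) / 4)
  expect_equal(as.numeric(surrogate_test(obs, part, surr, "left")),
               (1 + 3) / 4)   # all three ES_k (0, 2, -2) are <= ES_obs = 2
  obs_neg <- c(1, 1, 3, 3, 3)                      # ES_obs = -2
  expect_equal(as.numeric(surrogate_test(obs_neg, part, surr, "left")),
               (1 + 1) / 4)   # only the -2 surrogate ties at <=
  # ES_obs above all surrogates: permutation floor
  surr2 <- surrogate_map_set(matrix(rep(c(1, 1, 1, 1, 1), 9), 9, 5,
                                    byrow = TRUE), "spin")
  expect_equal(as.numeric(surrogate_test(obs, part, surr2, "right")), 1 / 10)
  # a surrogate with the whole network invalid is excluded, K decremented
  surr3 <- surrogate_map_set(rbind(c(NA, NA, 1, 1, 1),
                                   c(1, 1, 1, 1, 1)), "spin")
  expect_warning(p <- surrogate_test(obs, part, surr3, "right"), "excluded")
  expect_equal(attr(p, "K"), 1)
  expect_equal(as.numeric(p), 1 / 2)
})

test_that("weighted-KS running sum matches hand enumeration", {
  part <- network_partition(rep(c(1, 0), c(2, 4)), 1)
  # all in-network at the top of the ranking: score reaches 1
  s_top <- netdom:::.wks_score(c(5, 4, 1, 2, 0.5, 0.3), c(TRUE, TRUE, rep(FALSE, 4)),
                               "right")
  expect_equal(s_top, 1)
  # all in-network at the bottom: negative score
  s_bot <- netdom:::.wks_score(c(0.1, 0.2, 1, 2, 3, 4), c(TRUE, TRUE, rep(FALSE, 4)),
                               "right")
  expect_lt(s_bot, 0)
  # 6-location toy: enumerate the running sum by hand
  vals <- c(3, 1, 2.5, 2, 0.5, 1.5)
  memb <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  # descending order: 3(in), 2.5(out), 2(in), 1.5(out), 1(in), 0.5(out)
  # steps: +3/6, -1/3, +2/6, -1/3, +1/6, -1/3 -> running:
  run <- cumsum(c(3 / 6, -1 / 3, 2 / 6, -1 / 3, 1 / 6, -1 / 3))
  expect_equal(netdom:::.wks_score(vals, memb, "right"),
               run[which.max(abs(run))])
  expect_error(netdom:::.wks_score(c(0, 0, 1, 2, 3, 4),
                                   c(TRUE, TRUE, rep(FALSE, 4)), "right"),
               "zero")
  # p-value wiring against phenotype-permutation surrogates
  surr <- surrogate_map_set(rbind(vals, rev(vals), vals / 2), "phenotype_permutation")
  p <- weighted_ks_enrichment(vals, part, surr, "right")
  expect_true(as.numeric(p) >= 1 / 4 && as.numeric(p) <= 1)
})

test_that("spin surrogates: identity rotation, value multiset, invalidation", {
  geom <- make_geometry("sphere", 300, 40, seed = 8)
  sg <- geom$sphere
  vals <- rnorm(sum(geom$analyzable))
  full <- rep(NA_real_, length(geom$labels))
  full[geom$analyzable] <- vals
  hemi_idx <- list(L = which(sg$hemisphere == "L"),
                   R = which(sg$hemisphere == "R"))
  # zero rotation: every vertex is its own nearest neighbor
  ident <- netdom:::.spin_one(full, sg, hemi_idx, c(0, 0, 0))
  expect_identical(ident, full)
  # random spins: valid values form a sub-multiset of the original values
  surr <- spin_surrogates(vals, sg, K = 12, seed = 9)
  expect_equal(nrow(surr$maps), 12)
  for (k in 1:12) {
    got <- surr$maps[k, ]
    got <- got[!is.na(got)]
    expect_true(all(got %in% vals))
    # multiset check: no value used more often than it appears (plus
    # nearest-neighbor duplication is allowed only from distinct vertices)
    expect_true(length(got) <= length(vals))
  }
  expect_error(spin_surrogates(vals[-1], sg, 2, 1), "non-medial-wall")
})

test_that("mean spin enrichment score matches random network relocation", {
  geom <- make_geometry("sphere", 220, 30, seed = 10, medial_frac = 0)
  sg <- geom$sphere
  Va <- sum(geom$analyzable)
  # a smooth map: value = z-coordinate (plus mild noise)
  set.seed(11)
  vals <- geom$coords[geom$analyzable, 3] + rnorm(Va, sd = 0.05)
  part <- network_partition(geom$labels[geom$analyzable], 1)
  surr <- spin_surrogates(vals, sg, K = 600, seed = 12)
  es_spin <- apply(surr$maps, 1, function(r)
    mean(r[part$in_idx], na.rm = TRUE) - mean(r[-part$in_idx], na.rm = TRUE))
  # direct random relocation of the network labels
  es_rand <- replicate(2000, {
    idx <- sample(Va, part$m)
    mean(vals[idx]) - mean(vals[-idx])
  })
  expect_equal(mean(es_spin), mean(es_rand), tolerance = 0.05)
})

test_that("variogram surrogates preserve autocorrelation and variance", {
  geom <- make_geometry("grid", 15, 30, seed = 13)
  # smooth synthetic field
  x <- as.vector(sample_autocorrelated_noise(geom, 1, 1, 1.5, seed = 14))
  coords <- geom$coords
  # degenerate config: zero smoothing + no transform = pure permutation
  s0 <- variogram_surrogates(x, coords, K = 3, seed = 15,
                             config = list(widths = 0, transform = FALSE))
  for (k in 1:3) expect_equal(sort(s0$maps[k, ]), sort(x))
  expect_error(variogram_surrogates(x, coords, 2, 1, config = list(nbins = 2)),
               "3 distance bins")

  surr <- variogram_surrogates(x, coords, K = 8, seed = 16)
  # SSE criterion: the surrogate variogram fits the target better than a
  # naive permutation's variogram does
  D <- as.matrix(dist(coords))
  pr <- which(upper.tri(D), arr.ind = TRUE)
  pd <- D[pr]
  breaks <- quantile(pd, seq(0, 1, length.out = 26))
  bin <- cut(pd, unique(breaks), include.lowest = TRUE)
  vario <- function(v) tapply(0.5 * (v[pr[, 1]] - v[pr[, 2]])^2, bin, mean)
  v_t <- vario(x)
  set.seed(17)
  sse_perm <- mean(replicate(8, sum((vario(sample(x)) - v_t)^2)))
  sse_surr <- mean(apply(surr$maps, 1, function(r) sum((vario(r) - v_t)^2)))
  expect_lt(sse_surr, sse_perm)
  # marginal variance within 20% of the target variance
  expect_equal(mean(apply(surr$maps, 1, var)), var(x), tolerance = 0.2)
})
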