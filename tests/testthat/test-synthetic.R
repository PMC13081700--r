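# Synthetic geometries, autocorrelated noise, effect fields, and datasets.

# independent breadth-first search over grid adjacency
bfs_connected <- function(cells, neighbors) {
  seen <- cells[1]
  frontier <- cells[1]
  while (length(frontier) > 0) {
    nxt <- unique(unlist(neighbors[frontier]))
    nxt <- nxt[nxt %in% cells & !nxt %in% seen]
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(cells)
}

test_that("grid networks have the requested sizes and are connected", {
  geom <- make_geometry("grid", 50, 200, seed = 21)
  expect_equal(sum(geom$labels == 1), 200)
  expect_true(bfs_connected(which(geom$labels == 1), geom$neighbors))

  geom3 <- make_geometry("grid", 30, c(120, 80, 40), seed = 22)
  for (net in 1:3) {
    cells <- which(geom3$labels == net)
    expect_length(cells, c(120, 80, 40)[net])
    expect_true(bfs_connected(cells, geom3$neighbors))
  }
  # labels partition: no overlap by construction, remainder is background
  expect_equal(sum(geom3$labels == 0), 900 - 240)
  expect_error(make_geometry("grid", 10, c(60, 50), seed = 1), "infeasible|fewer")
})

test_that("sphere geometry has two mirrored hemispheres and a medial wall", {
  geom <- make_geometry("sphere", 300, 40, seed = 23)
  sg <- geom$sphere
  expect_equal(sum(sg$hemisphere == "L"), sum(sg$hemisphere == "R"))
  expect_equal(rowSums(sg$coords^2), rep(1, nrow(sg$coords)), tolerance = 1e-10)
  expect_true(any(sg$medial_wall))
  expect_true(all(geom$labels[!geom$analyzable] == 0))
  expect_equal(sum(geom$labels == 1), 40)
})

test_that("noise fields have the requested marginal variance and SA", {
  geom <- make_geometry("grid", 20, 30, seed = 24)
  # kernel width 0: iid, lag-1 correlation near zero
  e0 <- sample_autocorrelated_noise(geom, 250, 1, 0, seed = 25)
  nbr1 <- vapply(seq_len(400), function(v) geom$neighbors[[v]][1], integer(1))
  r0 <- cor(as.vector(e0), as.vector(e0[, nbr1]))
  expect_lt(abs(r0), 0.05)

  # marginal variance within 5% at every location (pooled over draws)
  e1 <- sample_autocorrelated_noise(geom, 10000 %/% 20, 0.36, 2, seed = 26)
  vars <- apply(e1, 2, var)
  expect_equal(mean(vars), 0.36, tolerance = 0.05)

  # SA increases monotonically with kernel width
  lag1 <- vapply(c(0.5, 1, 2, 4), function(w) {
    e <- sample_autocorrelated_noise(geom, 120, 1, w, seed = 27)
    cor(as.vector(e), as.vector(e[, nbr1]))
  }, numeric(1))
  expect_true(all(diff(lag1) > 0))
  expect_error(sample_autocorrelated_noise(geom, 5, -1, 1), "sigma2")
})

test_that("effect fields follow the four configurations", {
  geom <- make_geometry("grid", 30, 150, seed = 28)
  in_net <- geom$labels == 1

  b_eq <- sample_beta3("null_equal", geom)
  expect_true(all(b_eq == 0.04))
  b_dir <- sample_beta3("null_directional", geom)
  expect_true(all(b_dir[in_net] == 0) && all(b_dir[!in_net] == -0.03))
  b_sh <- sample_beta3("shifted", geom)
  expect_true(all(b_sh[in_net] == 0.06) && all(b_sh[!in_net] == 0.04))

  # gamma fields: equal means 2/40 = 20/400 = 0.05, tenfold variance ratio
  draws_in <- replicate(60, mean(sample_beta3("gamma_variance", geom,
                                              seed = sample.int(1e6, 1))[in_net]))
  expect_equal(mean(draws_in), 0.05, tolerance = 0.02)
  b_g <- sample_beta3("gamma_variance", geom, seed = 29)
  expect_equal(var(b_g[in_net]), 2 / 40^2, tolerance = 0.25)
  expect_equal(var(b_g[!in_net]), 20 / 400^2, tolerance = 0.25)
  expect_gt(var(b_g[in_net]), 5 * var(b_g[!in_net]))
  expect_error(sample_beta3("bogus", geom), "unknown")
})

test_that("simulated datasets match the generating equation's moments", {
  geom <- make_geometry("grid", 20, 60, seed = 30)
  st <- simulation_setting(400, "low", "null_equal", seed = 31,
                           kernel_width = 0)
  st$beta3_config <- "null_directional"   # beta3 = 0 in-network
  ds <- simulate_dataset(st, geom)
  # E[Y] = beta0 + 0.05 * E[x1] = 3 + 0.025 at in-network locations
  in_net <- geom$labels == 1
  expect_equal(mean(ds$imaging$data[, in_net]), 3.025, tolerance = 0.01)
  # Var(Y) = 0.05^2 * 0.25 + 0.05^2 + beta3^2 + sigma2
  v_expect <- 0.05^2 * 0.25 + 0.05^2 + 0.09
  expect_equal(mean(apply(ds$imaging$data[, in_net], 2, var)), v_expect,
               tolerance = 0.05)
  # out-of-network adds beta3^2 = 0.03^2 (negligible but included)
  v_out <- v_expect + 0.03^2
  expect_equal(mean(apply(ds$imaging$data[, !in_net], 2, var)), v_out,
               tolerance = 0.05)
  # seed determinism, bitwise
  ds2 <- simulate_dataset(st, geom)
  expect_identical(ds$imaging$data, ds2$imaging$data)
  expect_identical(ds$design$values, ds2$design$values)
  expect_identical(ds$true_beta3, ds2$true_beta3)
})

test_that("rejection studies respect the permutation floor and reproduce", {
  geom <- make_geometry("grid", 12, 30, seed = 32)
  st <- simulation_setting(20, "low", "null_equal")
  # alpha below 1/(K+1): nothing can ever be rejected
  s <- run_rejection_study("netdom", st, geom, 1, reps = 4, K = 9,
                           alpha = 0.05, seed = 33)
  expect_true(all(s$p_values >= 1 / 10))
  expect_equal(s$rate, 0)   # alpha = 0.05 is below the floor 1/(K+1) = 0.1
  s_floor <- run_rejection_study("netdom", st, geom, 1, reps = 4, K = 9,
                                 alpha = 0.05, seed = 33)
  expect_identical(s$p_values, s_floor$p_values)   # determinism
  s_low <- run_rejection_study("rigea", st, geom, 1, reps = 6, K = 1,
                               alpha = 1e-6, seed = 34)
  expect_equal(s_low$rate, 0)
  expect_error(run_rejection_study("bogus", st, geom, 1, 5, 9), "unknown method")
  expect_error(run_rejection_study("spin", st, geom, 1, 5, 9), "sphere")
})
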