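test_that("triangle transects have the design geometry", {
  tr <- build_triangle(c(10, 20), rotation = 0.3, side = 4)
  edge_len <- sqrt(rowSums((tr$vertices[c(2, 3, 1), ] - tr$vertices)^2))
  expect_equal(unname(edge_len), rep(4, 3))            # perimeter 12 km
  expect_equal(colMeans(tr$vertices), c(x = 10, y = 20),
               tolerance = 1e-9)                       # centroid = centre
  # 3-fold symmetry: rotating by 2 pi / 3 gives the same vertex set
  tr2 <- build_triangle(c(10, 20), rotation = 0.3 + 2 * pi / 3, side = 4)
  match_dist <- sapply(1:3, function(i) {
    min(sqrt(rowSums((tr2$vertices -
                        matrix(tr$vertices[i, ], 3, 2, byrow = TRUE))^2)))
  })
  expect_lt(max(match_dist), 1e-9)
  expect_error(build_triangle(c(0, 0), side = -1), "side")
})

test_that("crossing counts follow the geometric conventions", {
  tr <- build_triangle(c(0, 0), rotation = pi / 2, side = 4)
  # one path straight through the triangle: in through the bottom edge,
  # out through a side edge
  traj <- straight_trajectories(x0 = 0.3, y0 = -4, heading = pi / 2,
                                step_len = 1.2, n_steps = 6)
  expect_equal(count_crossings(traj, tr, day = 1), 2)  # enters and leaves
  # a path ending inside crosses once
  traj_in <- straight_trajectories(0, -2, pi / 2, step_len = 0.3)
  expect_equal(count_crossings(traj_in, tr, day = 1), 1)
  # parallel path outside never crosses
  traj_out <- straight_trajectories(10, -4, pi / 2, step_len = 1)
  expect_equal(count_crossings(traj_out, tr, day = 1), 0)
  # a group of 5 contributes 5 tracks per geometric crossing
  traj_g <- straight_trajectories(0, -2, pi / 2, step_len = 0.3,
                                  group_size = 5)
  expect_equal(count_crossings(traj_g, tr, day = 1), 5)
  expect_equal(count_crossings(traj_g, tr, day = 1, count_groups = FALSE), 1)
})

test_that("crossing counts are invariant to path direction and vertex order", {
  set.seed(10)
  tr <- build_triangle(c(0, 0), rotation = 1.1, side = 4)
  for (k in 1:20) {
    n <- 5
    X <- apply(matrix(rnorm(7 * n, sd = 2), 7, n), 2, cumsum)
    Y <- apply(matrix(rnorm(7 * n, sd = 2), 7, n), 2, cumsum)
    traj <- structure(list(x = X, y = Y, t_days = (0:6) / 6, id = 1:n,
                           group_size = rep(1, n)), class = "trajectories")
    rev_traj <- traj
    rev_traj$x <- X[7:1, , drop = FALSE]
    rev_traj$y <- Y[7:1, , drop = FALSE]
    tr_rot <- tr
    tr_rot$vertices <- tr$vertices[c(3, 1, 2), ]
    c0 <- count_crossings(traj, tr, day = 1)
    expect_identical(count_crossings(rev_traj, tr, day = 1), c0)
    expect_identical(count_crossings(traj, tr_rot, day = 1), c0)
  }
})

test_that("the counting window covers exactly the counting day", {
  tr <- build_triangle(c(0, 0), rotation = pi / 2, side = 4)
  # 2 days of fixes; the crossing happens during day 1 only
  x <- c(seq(-4, 2, by = 1), rep(2, 6))  # moves east through the triangle
  traj <- structure(list(x = matrix(x, ncol = 1),
                         y = matrix(rep(-0.5, 13), ncol = 1),
                         t_days = (0:12) / 6, id = 1, group_size = 1),
                    class = "trajectories")
  expect_gt(count_crossings(traj, tr, day = 1), 0)
  expect_equal(count_crossings(traj, tr, day = 2), 0)
})

test_that("transect networks respect the reference-habitat constraint", {
  dom <- square_domain(60)
  runi <- uniform_raster(dom)
  set.seed(11)
  net <- generate_transect_network(25, dom, runi)
  expect_length(net, 25)
  expect_true(all(sapply(net, function(t) domain_contains(dom, t$center[1],
                                                          t$center[2]))))
  # coarse two-class landscape: placement achieves >= 90 % forest perimeter
  rs <- split_raster(dom, split = 40)
  net2 <- generate_transect_network(10, dom, rs,
                                    min_reference_fraction = 0.9,
                                    spacing = 0.1)
  fr <- sapply(net2, function(t) {
    lens <- perimeter_by_habitat(t, rs, dom, spacing = 0.1)
    lens["forest"] / sum(lens)
  })
  expect_true(all(fr >= 0.9))
  # reproducible under a fixed seed
  set.seed(99)
  a <- generate_transect_network(5, dom, runi)
  set.seed(99)
  b <- generate_transect_network(5, dom, runi)
  expect_identical(sapply(a, `[[`, "center"), sapply(b, `[[`, "center"))
  # all-water landscape cannot satisfy the constraint
  rw <- split_raster(dom, split = -1)
  expect_error(generate_transect_network(2, dom, rw,
                                         min_reference_fraction = 0.9,
                                         spacing = 0.5, max_tries = 100),
               "cap exceeded")
})

test_that("yearly survey sampling is uniform over transects and days", {
  dom <- square_domain(80)
  runi <- uniform_raster(dom)
  set.seed(12)
  net <- generate_transect_network(23, dom, runi)
  all_s <- sample_survey_year(net, 23)
  expect_length(all_s, 23)
  expect_error(sample_survey_year(net, 24), "exceeds")

  days <- unlist(replicate(40, sapply(sample_survey_year(net, 23),
                                      `[[`, "counting_day")))
  expect_true(all(days >= 1 & days <= 60))
  expect_gt(chisq.test(tabulate(days, 60))$p.value, 0.01)
  ids <- unlist(replicate(120, sapply(sample_survey_year(net, 10),
                                      `[[`, "id")))
  incl <- tabulate(ids, 23) / 120
  expect_lt(max(abs(incl - 10 / 23)), 0.15)
})

test_that("effective effort weights perimeter lengths by habitat", {
  dom <- square_domain(60)
  runi <- uniform_raster(dom)
  tr <- build_triangle(c(30, 30), 0.7)
  expect_equal(effective_effort(tr, runi, c(forest = 1), dom, spacing = 0.05),
               12, tolerance = 1e-6)
  # per-habitat lengths sum to the in-domain perimeter
  rs <- split_raster(dom, split = 30)
  lens <- perimeter_by_habitat(tr, rs, dom, spacing = 0.01)
  expect_equal(sum(lens), 12, tolerance = 1e-6)
  expect_equal(effective_effort(tr, rs, c(forest = 1, water = 0.05), dom,
                                spacing = 0.01),
               unname(lens["forest"] + 0.05 * lens["water"]),
               tolerance = 1e-9)
  # weighting arithmetic: 6 km forest + 6 km water at h = 0.05 -> 6.3 km
  rec <- data.frame(transect_id = 1, year = 1, count = 0, counting_day = 1,
                    D_days = 1, x = 0, y = 0, len_forest = 6, len_water = 6)
  out <- apply_effort_weights(rec, c(forest = 1, water = 0.05))
  expect_equal(out$M_km, 6.3)
  # transect fully outside the domain has zero effort and is excluded
  tr_out <- build_triangle(c(500, 500), 0)
  expect_equal(sum(perimeter_by_habitat(tr_out, runi, dom)), 0)
  rec$len_forest <- 0
  rec$len_water <- 0
  expect_equal(nrow(apply_effort_weights(rec, c(forest = 1, water = 1))), 0)
})

test_that("crossings obey the random-encounter (ideal gas) law", {
  # uniform straight movers at known density around one transect:
  # E[X] = (2 / pi) a L M D.  Down-scaled version of the full oracle run
  # in the acceptance suite.
  set.seed(13)
  dom <- square_domain(2000)
  tr <- build_triangle(c(1000, 1000), 0.4)
  L <- 10
  B <- 26
  n <- 40
  a <- n / B^2
  nrep <- 1500
  xs <- numeric(nrep)
  for (k in seq_len(nrep)) {
    x0 <- runif(n, 1000 - B / 2, 1000 + B / 2)
    y0 <- runif(n, 1000 - B / 2, 1000 + B / 2)
    traj <- straight_trajectories(x0, y0, runif(n, 0, 2 * pi),
                                  step_len = L / 6)
    xs[k] <- count_crossings(traj, tr, day = 1)
  }
  expected <- (2 / pi) * a * L * 12
  se <- sd(xs) / sqrt(nrep)
  expect_lt(abs(mean(xs) - expected), 3 * se)
})
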