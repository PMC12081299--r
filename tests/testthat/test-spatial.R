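test_that("CLR normalization matches its closed form", {
  m <- rbind(c(1, 1, 1), c(1, exp(1), 1))
  u <- normalize_clr(rbind(c(4, 4, 4)), pseudocount = 0)
  expect_true(all(u == 0))
  two <- normalize_clr(rbind(c(1, exp(1))), pseudocount = 0)
  expect_equal(unname(two[1, ]), c(-0.5, 0.5), tolerance = 1e-12)
  withr::with_seed(5, {
    r <- matrix(rgamma(50, 2), 10, 5)
    out <- normalize_clr(r)
    expect_true(all(abs(rowSums(out)) < 1e-9))
  })
  expect_error(normalize_clr(rbind(c(0, 0)), pseudocount = 0), "all-zero")
})

test_that("neighborhood density solves the worked geometry example", {
  d <- tibble::tibble(cell = c("center", "near", "far"),
                      x = c(0, 30, 50), y = c(0, 0, 0),
                      marker = c(99, 2, 10))
  got <- neighborhood_density(d, "marker", radius = 40, index = "center")
  expect_identical(got$cell, "center")
  expect_identical(got$n_neighbors, 1L)   # only the 30-µm neighbour
  expect_identical(got$density, 2)        # its own 99 is excluded
  # an isolated index cell is omitted and counted
  iso <- tibble::tibble(cell = c("a", "b"), x = c(0, 100), y = c(0, 0),
                        marker = c(1, 1))
  got2 <- neighborhood_density(iso, "marker", radius = 40)
  expect_identical(nrow(got2), 0L)
  expect_identical(attr(got2, "n_omitted"), 2L)
  expect_error(neighborhood_density(d, "absent"), "marker")
})

test_that("density and nearest distance match brute-force oracles exactly", {
  withr::with_seed(11, {
    n <- 500
    d <- tibble::tibble(cell = sprintf("c%03d", 1:n),
                        x = runif(n, 0, 400), y = runif(n, 0, 400),
                        cell_type = sample(c("t", "m"), n, replace = TRUE),
                        marker = rgamma(n, 2))
    got <- neighborhood_density(d, "marker", radius = 40)
    # O(n^2) double loop
    for (pick in sample(nrow(got), 25)) {
      i <- match(got$cell[pick], d$cell)
      vals <- c()
      for (j in seq_len(n)) {
        if (j == i) next
        if (sqrt((d$x[j] - d$x[i])^2 + (d$y[j] - d$y[i])^2) <= 40)
          vals <- c(vals, d$marker[j])
      }
      expect_identical(got$density[pick], mean(vals))
    }

    nd <- nearest_distance(d, "t", "m")
    to <- d[d$cell_type == "m", ]
    for (pick in sample(nrow(nd), 25)) {
      i <- match(nd$cell[pick], d$cell)
      best <- Inf
      for (j in seq_len(nrow(to)))
        best <- min(best, sqrt((to$x[j] - d$x[i])^2 + (to$y[j] - d$y[i])^2))
      expect_identical(nd$distance[pick], best)
    }
  })
})

test_that("spatial statistics are invariant to rigid motions", {
  withr::with_seed(21, {
    n <- 200
    d <- tibble::tibble(cell = sprintf("c%03d", 1:n),
                        x = runif(n, 0, 300), y = runif(n, 0, 300),
                        cell_type = sample(c("t", "m"), n, replace = TRUE),
                        marker = rgamma(n, 2))
    th <- 0.7
    d2 <- d
    d2$x <- cos(th) * d$x - sin(th) * d$y + 123
    d2$y <- sin(th) * d$x + cos(th) * d$y - 77
    a <- neighborhood_density(d, "marker", radius = 40)
    b <- neighborhood_density(d2, "marker", radius = 40)
    expect_identical(a$cell, b$cell)
    expect_equal(a$density, b$density, tolerance = 1e-9)
    expect_equal(nearest_distance(d, "t", "m")$distance,
                 nearest_distance(d2, "t", "m")$distance, tolerance = 1e-9)
  })
})

test_that("nearest distances handle exact hits and per-sample gaps", {
  d <- tibble::tibble(cell = c("a", "b", "c", "d"),
                      x = c(0, 3, 6, 5), y = c(0, 4, 8, 5),
                      cell_type = c("t", "m", "m", "t"),
                      sample = c("s1", "s1", "s1", "s2"))
  got <- nearest_distance(d, "t", "m", sample_col = "sample")
  expect_identical(got$distance[got$cell == "a"], 5)  # 3-4-5 triangle
  expect_warning(nearest_distance(d, "t", "m", sample_col = "sample"),
                 "s2")
  co <- tibble::tibble(cell = c("a", "b"), x = c(1, 1), y = c(2, 2),
                       cell_type = c("t", "m"))
  expect_identical(nearest_distance(co, "t", "m")$distance, 0)
})

test_that("colocalization scores and permutation p-values behave", {
  withr::with_seed(15, {
    n <- 150
    d <- tibble::tibble(cell = sprintf("c%03d", 1:n),
                        x = runif(n, 0, 300), y = runif(n, 0, 300),
                        ligand_pos = rep(TRUE, n),
                        receptor_pos = c(rep(TRUE, 30), rep(FALSE, n - 30)))
    got <- colocalization_score(d, radius = 40, n_permutations = 99)
    expect_identical(got$score, 1)    # ligand everywhere
    expect_identical(got$p_value, 1)

    sim <- generate_spatial(spatial_config(rng_seed = 33))
    g1 <- colocalization_score(sim$cells, radius = 30, n_permutations = 199,
                               rng_seed = 5)
    g2 <- colocalization_score(sim$cells, radius = 30, n_permutations = 199,
                               rng_seed = 5)
    expect_identical(g1, g2)          # deterministic under the seed
    expect_lt(g1$p_value, 0.05)       # planted proximity is detected
    expect_error(colocalization_score(dplyr::mutate(d, ligand_pos = FALSE)),
                 "non-empty")
  })
})

test_that("group comparisons match exact rank enumeration", {
  v <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("a", "b"), each = 3)
  got <- compare_groups(v, g, test = "ranksum")
  expect_equal(got$p_value, oracle_rank_sum(v[1:3], v[4:6], "two.sided"),
               tolerance = 1e-12)
  one <- compare_groups(v, g, test = "ranksum", alternative = "less")
  expect_equal(one$p_value, oracle_rank_sum(v[1:3], v[4:6], "less"),
               tolerance = 1e-12)
  # reversing the label vector swaps which group is "first"
  sw <- compare_groups(v, rev(g), test = "ranksum", alternative = "greater")
  expect_equal(sw$p_value, oracle_rank_sum(v[1:3], v[4:6], "greater"),
               tolerance = 1e-12)

  withr::with_seed(4, {
    x <- rnorm(30); y <- rnorm(30)
    sym <- compare_groups(c(x, x), rep(c("a", "b"), each = 30))
    expect_gt(sym$p_value, 0.9)      # identical groups
    tt <- compare_groups(c(x, y + 2), rep(c("a", "b"), each = 30),
                         test = "t", alternative = "less")
    expect_lt(tt$p_value, 1e-3)
    tg <- compare_groups(c(x, y + 2), rep(c("a", "b"), each = 30),
                         test = "t", alternative = "greater")
    expect_equal(tt$p_value + tg$p_value, 1, tolerance = 1e-12)
  })
  expect_error(compare_groups(1:3, c("a", "a", "a")), "two groups")
})
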