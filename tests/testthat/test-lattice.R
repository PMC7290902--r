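test_that("largest-remainder allocation reproduces worked examples exactly", {
  expect_identical(allocate_counts(c(0.493, 0.507), 10000), c(4930L, 5070L))
  expect_identical(allocate_counts(c(1, 0), 7), c(7L, 0L))
  # three equal thirds of 10: remainder unit goes to the first category
  expect_identical(allocate_counts(rep(1 / 3, 3), 10), c(4L, 3L, 3L))
})

test_that("allocation rejects malformed fractions and always sums to the total", {
  expect_error(allocate_counts(c(-0.1, 1.1), 10), "non-negative")
  expect_error(allocate_counts(c(0.5, 0.4), 10), "sum to 1")
  withr::with_seed(42, {
    for (i in 1:25) {
      k <- sample(2:6, 1)
      f <- stats::runif(k)
      f <- f / sum(f)
      total <- sample(1:5000, 1)
      counts <- allocate_counts(f, total)
      expect_identical(sum(counts), as.integer(total))
      expect_true(all(counts >= floor(f * total) - 1e-9))
      expect_true(all(counts <= floor(f * total) + 1))
    }
  })
})

test_that("the 3x3 torus neighbourhood of every cell is all 8 other cells", {
  nb <- torus_neighbors(3)
  for (i in 1:9) expect_setequal(nb[i, ], setdiff(1:9, i))
})

test_that("torus neighbour index has degree 8, no self-loops and is symmetric", {
  expect_error(torus_neighbors(2), ">= 3")
  for (n in c(3, 4, 5, 7, 100)) {
    nb <- torus_neighbors(n)
    expect_identical(dim(nb), as.integer(c(n^2, 8))) # 8 * n^2 directed pairs
    expect_true(all(apply(nb, 1, anyDuplicated) == 0)) # 8 distinct neighbours
    expect_false(any(nb == seq_len(n^2)))        # never its own neighbour
    # symmetry: the directed edge multiset equals its transpose
    edges <- cbind(rep(seq_len(n^2), 8), as.vector(nb))
    expect_identical(sort(edges[, 1] * n^2 + edges[, 2]),
                     sort(edges[, 2] * n^2 + edges[, 1]))
  }
})

test_that("assigned payoff-category counts match the six-fraction apportionment", {
  pop <- assign_population(fs_pop(100), fs_game(), seed = 1)
  counts <- table(factor(pop$payoff, levels = c(15, 10, 9, 6, 1, -1)))
  expect_identical(as.integer(counts), c(300L, 200L, 4500L, 3000L, 1380L, 620L))
  expect_identical(sum(pop$gender == "male"), 4930L)
  expect_identical(sum(pop$kind == "A"), 6000L)
})

test_that("stored payoffs are recomputable from attributes, never inconsistent", {
  pop <- assign_population(fs_pop(20), fs_game(), seed = 5)
  expect_equal(pop$payoff,
               payoff_value(pop$education, pop$outcome, pop$kind, fs_game()))
})

test_that("populations are reproducible under a seed and vary without one", {
  a <- assign_population(fs_pop(15), fs_game(), seed = 99)
  b <- assign_population(fs_pop(15), fs_game(), seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- assign_population(fs_pop(15), fs_game(), seed = 100)
  expect_false(identical(a$payoff, c$payoff))
})

test_that("parameter corners are honoured: success fractions at 0 and at their bounds", {
  gp <- fs_game()
  # everyone successful: payoffs p and s absent
  pp <- population_params(n = 10, rho_NE = 0.2, rho_NE_S = 0.2, rho_E_S = 0.8)
  pop <- assign_population(pp, gp, seed = 1)
  expect_false(any(pop$payoff %in% c(1, -1)))
  # nobody successful: only p and s present
  pp0 <- population_params(n = 10, rho_NE = 0.2, rho_NE_S = 0, rho_E_S = 0)
  pop0 <- assign_population(pp0, gp, seed = 1)
  expect_true(all(pop0$payoff %in% c(1, -1)))
  expect_identical(sum(pop0$payoff == 1), 20L)
  # inconsistent fractions are rejected before any sampling
  expect_error(population_params(n = 10, rho_NE = 0.1, rho_NE_S = 0.2),
               "rho_NE_S")
  expect_error(population_params(n = 10, rho_NE = 0.3, rho_E_S = 0.8),
               "rho_E_S")
  expect_error(population_params(n = 10, male_fraction = 1), "male_fraction")
})

test_that("gender is assigned independently of payoff category", {
  # pool the gender x payoff table over independent realizations; under
  # independent shuffles there is no systematic association
  tab <- 0
  for (s in 1:15) {
    pop <- assign_population(fs_pop(30), fs_game(), seed = 1000 + s)
    tab <- tab + table(pop$gender, factor(pop$payoff))
  }
  p <- suppressWarnings(stats::chisq.test(tab))$p.value
  expect_gt(p, 1e-3)
})
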