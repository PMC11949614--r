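test_that("mirror_bilateral places blocks by the bilateral-symmetry rule", {
  # single homologous pair
  sc1 <- mirror_bilateral(matrix(0, 1, 1), matrix(3, 1, 1), "X")
  expect_equal(unname(sc1$weights), matrix(c(0, 3, 3, 0), 2))
  expect_identical(sc1$regions, c("X_A", "X_B"))

  # h = 2 worked instance: every cell enumerated from the block rule
  ipsi <- matrix(c(0, 2, 1, 0), 2, byrow = TRUE)    # rows: from, cols: to
  contra <- matrix(c(5, 6, 7, 8), 2, byrow = TRUE)
  sc <- mirror_bilateral(ipsi, contra, c("P", "Q"))
  expect_equal(unname(sc$weights),
               rbind(c(0, 2, 5, 6),
                     c(1, 0, 7, 8),
                     c(5, 6, 0, 2),
                     c(7, 8, 1, 0)))

  # hemisphere-swap invariant on a random instance
  set.seed(9)
  h <- 5
  sc <- mirror_bilateral(matrix(runif(h * h), h), matrix(runif(h * h), h),
                         letters[1:h])
  W <- sc$weights
  A <- 1:h; B <- h + 1:h
  expect_equal(W[A, A], W[B, B], ignore_attr = TRUE)
  expect_equal(W[A, B], W[B, A], ignore_attr = TRUE)

  expect_error(mirror_bilateral(matrix(0, 2, 2), matrix(0, 3, 3), c("a", "b")),
               "square")
  expect_error(mirror_bilateral(matrix(-1, 1, 1), matrix(0, 1, 1), "a"),
               "nonnegative")
})

test_that("to_undirected sums the two directions", {
  sc <- tiny_sc(matrix(c(0, 2, 1, 0), 2, byrow = TRUE))
  u <- to_undirected(sc)
  expect_equal(unname(u$weights), matrix(c(0, 3, 3, 0), 2))
  expect_false(u$directed)
  expect_error(to_undirected(u), "already undirected")

  set.seed(4)
  W <- matrix(runif(25), 5); diag(W) <- 0
  u <- to_undirected(tiny_sc(W))
  expect_equal(unname(u$weights), W + t(W))      # elementwise oracle
  expect_equal(u$weights, t(u$weights))
})

test_that("normalize zeroes the diagonal then rescales to unit maximum", {
  sc <- tiny_sc(matrix(c(5, 2, 4, 0), 2, byrow = TRUE))
  nz <- normalize_connectome(sc)
  expect_equal(unname(nz$weights), matrix(c(0, 0.5, 1, 0), 2, byrow = TRUE))

  # idempotence and order preservation
  set.seed(11)
  W <- matrix(runif(49), 7)
  n1 <- normalize_connectome(tiny_sc(W))
  n2 <- normalize_connectome(n1)
  expect_equal(n1$weights, n2$weights)
  expect_equal(max(n1$weights), 1)
  off <- row(W) != col(W)
  expect_equal(order(n1$weights[off]), order(W[off]))

  expect_warning(z <- normalize_connectome(tiny_sc(matrix(0, 3, 3))),
                 "all-zero")
  expect_equal(unname(z$weights), matrix(0, 3, 3))
})

test_that("reduce_to_regions extracts the submatrix without renormalizing", {
  set.seed(2)
  W <- matrix(runif(16, 0, 0.5), 4); diag(W) <- 0
  sc <- tiny_sc(W, labels = c("a", "b", "c", "d"))
  expect_equal(reduce_to_regions(sc, sc$regions)$weights, sc$weights)
  one <- reduce_to_regions(sc, "c")
  expect_equal(unname(one$weights), matrix(0, 1, 1))
  two <- reduce_to_regions(sc, c("b", "d"))
  expect_equal(unname(two$weights), W[c(2, 4), c(2, 4)])  # index oracle
  expect_lt(max(two$weights), 1)                           # not rescaled
  expect_error(reduce_to_regions(sc, "zz"), "unknown region")
})

test_that("randomize_directed conserves degrees and the weight multiset", {
  sc2 <- tiny_sc(matrix(c(0, 1, 2, 0), 2, byrow = TRUE))
  expect_equal(randomize_directed(sc2, 20, seed = 1)$weights, sc2$weights)

  set.seed(31)
  W <- matrix(runif(50 * 50) * (runif(50 * 50) < 0.4), 50); diag(W) <- 0
  sc <- tiny_sc(W)
  r1 <- randomize_directed(sc, 20, seed = 7)
  expect_equal(colSums(r1$weights > 0), colSums(W > 0),
               ignore_attr = TRUE)                   # in-degree
  expect_equal(rowSums(r1$weights > 0), rowSums(W > 0),
               ignore_attr = TRUE)                   # out-degree
  expect_equal(sort(r1$weights[r1$weights > 0]), sort(W[W > 0]))
  expect_true(all(diag(r1$weights) == 0))

  r1b <- randomize_directed(sc, 20, seed = 7)
  expect_identical(r1$weights, r1b$weights)                # same seed
  r2 <- randomize_directed(sc, 20, seed = 8)
  expect_false(identical(r1$weights, r2$weights))          # different seed
})

test_that("global efficiency matches closed forms and brute force", {
  expect_equal(global_efficiency(tiny_sc(matrix(c(0, 1, 1, 0), 2))), 1)
  expect_equal(global_efficiency(tiny_sc(matrix(c(0, .5, .5, 0), 2))), 0.5)
  expect_equal(global_efficiency(tiny_sc(matrix(0, 3, 3))), 0)

  # 3-node directed chain with mixed weights, against path enumeration
  W <- matrix(0, 3, 3); W[1, 2] <- 0.5; W[2, 3] <- 0.25
  expect_equal(global_efficiency(tiny_sc(W)), brute_ge(W))

  for (s in 1:5) {
    set.seed(s)
    n <- sample(3:6, 1)
    W <- matrix(runif(n * n) * (runif(n * n) < 0.5), n); diag(W) <- 0
    expect_equal(global_efficiency(tiny_sc(W)), brute_ge(W),
                 tolerance = 1e-12)
  }
})

test_that("global efficiency never increases when weights are reduced", {
  for (s in 1:5) {
    set.seed(100 + s)
    n <- 8
    W <- matrix(runif(n * n) * (runif(n * n) < 0.6), n); diag(W) <- 0
    ge0 <- global_efficiency(tiny_sc(W))
    lesion <- matrix(runif(n * n, 0.2, 1), n)
    expect_lte(global_efficiency(tiny_sc(W * lesion)), ge0 + 1e-12)
  }
})

test_that("connectome CSV round trip preserves the object", {
  set.seed(5)
  sc <- synth_connectome(synth_config(regions_per_hemisphere = 6, seed = 5))
  mf <- tempfile(fileext = ".csv"); lf <- tempfile(fileext = ".csv")
  jf <- tempfile(fileext = ".json")
  write_connectome(sc, mf, lf, jf)
  back <- read_connectome(mf, lf, directed = TRUE)
  expect_equal(back$weights, sc$weights, tolerance = 1e-12)
  expect_identical(back$regions, sc$regions)
  expect_identical(back$hemisphere, sc$hemisphere)
  meta <- jsonlite::read_json(jf)
  expect_true(meta$normalized)
  expect_equal(meta$n_nodes, 12)
})
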