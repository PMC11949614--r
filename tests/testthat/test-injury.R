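bilat_sc <- function(h, seed) {
  synth_connectome(synth_config(regions_per_hemisphere = h, seed = seed))
}

test_that("apply_injury scales targeted rows and columns once", {
  set.seed(7)
  W <- matrix(runif(16, 0.1, 1), 4); diag(W) <- 0
  sc <- tiny_sc(W, labels = c("a", "b", "c", "d"),
                hemisphere = rep("A", 4), base = c("a", "b", "c", "d"))

  expect_equal(apply_injury(sc, "b", 0)$weights, sc$weights)

  full <- apply_injury(sc, "b", 1)
  expect_true(all(full$weights[2, ] == 0) && all(full$weights[, 2] == 0))
  expect_equal(full$weights[-2, -2], W[-2, -2], ignore_attr = TRUE)

  # hand-scaled mask at fraction 0.25
  inj <- apply_injury(sc, "b", 0.25)
  expected <- W
  expected[2, ] <- expected[2, ] * 0.75
  expected[, 2] <- W[, 2] * 0.75          # single multiplication, not squared
  expected[2, 2] <- 0
  expect_equal(unname(inj$weights), expected)

  expect_error(apply_injury(sc, "zz", 0.5), "no target region")
  expect_error(apply_injury(sc, "b", 1.5), "fraction")
})

test_that("injury composition follows the single-mask rule exactly", {
  sc <- bilat_sc(6, seed = 71)
  targets <- sc$base[1:2]
  f <- 0.3; g <- 0.4
  twice <- apply_injury(apply_injury(sc, targets, f), targets, g)
  once <- apply_injury(sc, targets, 1 - (1 - f) * (1 - g))
  # every touched edge (including target-target edges) is scaled once per
  # application, so composition equals the combined single application
  expect_equal(twice$weights, once$weights, tolerance = 1e-12)
  # idempotence at complete disconnection
  d1 <- apply_injury(sc, targets, 1)
  expect_equal(apply_injury(d1, targets, 1)$weights, d1$weights)
})

test_that("injury only touches hemisphere A nodes", {
  sc <- bilat_sc(5, seed = 72)
  inj <- apply_injury(sc, sc$base[1], 0.5)
  ia <- which(sc$base == sc$base[1] & sc$hemisphere == "A")
  ib <- which(sc$base == sc$base[1] & sc$hemisphere == "B")
  expect_equal(inj$weights[ib, -ia], sc$weights[ib, -ia])
  expect_equal(inj$weights[ia, -ia], 0.5 * sc$weights[ia, -ia])
})

test_that("fc_distance has its closed forms", {
  set.seed(73)
  Z <- matrix(runif(36, -0.4, 0.4), 6); S <- (Z + t(Z)) / 2; diag(S) <- 1
  f <- tiny_fc(S)
  expect_equal(fc_distance(f, f), 0)

  delta <- 0.05
  f2 <- tiny_fc(S + delta * (1 - diag(6)))
  m <- 6
  expect_equal(fc_distance(f2, f), delta * sqrt(m - 1))
  # excluding nodes reduces the row dimension accordingly
  expect_equal(fc_distance(f2, f, exclude = f$regions[1]),
               delta * sqrt(m - 2))
  # frobenius variant: rms over the upper triangle
  expect_equal(fc_distance(f2, f, method = "frobenius"),
               sqrt(delta^2))
})

test_that("injury spec defaults to the packaged 14 regions and 20 levels", {
  spec <- injury_spec()
  expect_length(spec$target_regions, 14)
  expect_true(all(c("CA3", "DG", "SSp-bfd", "VISp") %in% spec$target_regions))
  expect_length(spec$levels, 20)
  expect_equal(spec$levels[1], 0.05)
  expect_equal(spec$levels[20], 1.00)
  expect_error(injury_spec(levels = c(0.5, 0.4)), "increasing")
  expect_error(injury_spec(levels = c(0, 0.5)), "\\(0, 1\\]")
  flags <- default_injury_regions(with_flags = TRUE)
  expect_equal(sum(flags$excluded_by_voxel_threshold), 5)
})

test_that("injury sweep metrics degrade monotonically where guaranteed", {
  sc <- bilat_sc(8, seed = 74)
  omega <- draw_frequencies(16, 75)
  spec <- injury_spec(target_regions = unique(sc$base)[1:3],
                      levels = c(0.2, 0.5, 0.8, 1.0))
  res <- injury_sweep(sc, omega, g = 0.3, spec = spec, seed = 9,
                      duration_s = 60)
  expect_equal(nrow(res$table), 4)
  ge <- c(res$baseline_global_efficiency, res$table$global_efficiency)
  expect_true(all(diff(ge) <= 1e-12))
  expect_lt(res$table$corr_to_baseline[4], res$table$corr_to_baseline[1])
  expect_gt(res$table$mean_distance[4], res$table$mean_distance[1])
  # level-0 strengths row stores the uninjured baseline
  expect_equal(res$strengths["0", ],
               nodal_fc_strength(res$baseline_fc))
  expect_true(all(is.finite(res$strengths)))
})

test_that("strength decrease frequencies match a counting oracle", {
  # three fabricated models on four shared regions, one injury level;
  # the u-v edge weakens in models 1 and 2 only, so u (and v) drop with
  # frequency 2/3 while w and x are tied -- and ties are not decreases
  regs <- c("u", "v", "w", "x")
  base_mat <- function(uv) {
    M <- diag(4); M[upper.tri(M)] <- uv; M <- M + t(M) - diag(4); diag(M) <- 1
    M
  }
  mk_model <- function(drop_u) {
    b <- tiny_fc(base_mat(0.5), labels = regs)
    inj_off <- if (drop_u) c(0.1, 0.5, 0.5, 0.5, 0.5, 0.5) else
      rep(0.5, 6)   # edge order: uv uw vw ux vx wx
    M <- diag(4); M[upper.tri(M)] <- inj_off
    M <- M + t(M) - diag(4); diag(M) <- 1
    i <- tiny_fc(M, labels = regs)
    structure(list(baseline_fc = b, fc = list(i), injured_nodes = character(0),
                   spec = injury_spec(levels = 0.5)),
              class = "injury_sweep_result")
  }
  models <- list(mk_model(TRUE), mk_model(TRUE), mk_model(FALSE))
  res <- strength_change_analysis(models, injured_regions = character(0))
  expect_equal(res$freq["0.5", "u"], 2 / 3)
  expect_equal(res$freq["0.5", "w"], 0)      # w unchanged: tie, not decrease
  expect_true(all(res$freq >= 0 & res$freq <= 1))
  # null injury: identical FCs give all-zero frequencies
  null_models <- lapply(1:2, function(i) {
    b <- tiny_fc(base_mat(0.4), labels = regs)
    structure(list(baseline_fc = b, fc = list(b), injured_nodes = character(0),
                   spec = injury_spec(levels = 0.5)),
              class = "injury_sweep_result")
  })
  res0 <- strength_change_analysis(null_models, injured_regions = character(0))
  expect_true(all(res0$freq == 0))
})
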