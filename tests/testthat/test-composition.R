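test_that("closure rescales proportionally and preserves order", {
  expect_equal(close_composition(c(1, 2, 3), total = 60), c(10, 20, 30))
  expect_equal(close_composition(rep(1, 9), 960), rep(960 / 9, 9))
  x <- c(5, 1, 4)
  expect_equal(sum(close_composition(x, 100)), 100)
  expect_equal(order(close_composition(x, 100)), order(x))
  expect_error(close_composition(c(0, 0, 0)), "all-zero")
  # matrix form closes row-wise
  m <- rbind(c(1, 1), c(1, 3))
  expect_equal(rowSums(close_composition(m, 10)), c(10, 10))
})

test_that("closing the nine-band reference values reproduces their shares", {
  raw <- c(722.9, 105.7, 51.1, 27.8, 15.4, 9.1, 5.8, 14.3, 8.0)
  closed <- close_composition(raw, 960)
  # raw values sum to 960.1, so closure moves each band < 0.1 min
  expect_lt(max(abs(closed - raw)), 0.1)
  expect_equal(round(100 * closed[1] / 960, 1), 75.3)
})

test_that("clr centres logs and sums to zero", {
  expect_equal(clr(rep(4, 5)), rep(0, 5))
  expect_equal(clr(c(1, 2, 4)), c(-log(2), 0, log(2)))
  X <- random_compositions(50, seed = 3)
  expect_lt(max(abs(rowSums(clr(X)))), 1e-12)
  expect_error(clr(c(1, 0, 2)), "non-positive")
  x <- c(a = 1, b = 0, c = 2)
  expect_error(clr(x), "b")
  # closure invariance
  expect_equal(clr(c(1, 2, 4)), clr(close_composition(c(1, 2, 4), 960)))
})

test_that("pivot basis is orthonormal in clr space for every rotation", {
  for (D in c(3, 4, 9)) {
    for (lead in seq_len(D)) {
      V <- pivot_basis(D, lead)$V
      expect_lt(max(abs(crossprod(V) - diag(D - 1))), 1e-12)
      expect_lt(max(abs(colSums(V))), 1e-12)  # columns live in the clr plane
    }
  }
  expect_error(pivot_basis(9, lead = 10), "lead")
  expect_error(pivot_basis(4, lead = 1, order = c(2, 2, 3)), "permutation")
})

test_that("pivot_ilr matches its defining formula", {
  # uniform composition maps to the origin
  expect_equal(pivot_ilr(rep(10, 9)), rep(0, 8))
  # hand evaluation of z1 = sqrt((D-1)/D) log(x1 / gm(rest)) for (1,2,4)
  x <- c(1, 2, 4)
  z <- pivot_ilr(x, pivot_basis(3, lead = 1))
  expect_equal(z[1], sqrt(2 / 3) * log(1 / sqrt(8)), tolerance = 1e-12)
  expect_equal(z[1], -0.8489, tolerance = 1e-4)
  # z2 closes the recursion: sqrt(1/2) log(x2/x3)
  expect_equal(z[2], sqrt(1 / 2) * log(2 / 4), tolerance = 1e-12)
})

test_that("z1 equals sqrt(D/(D-1)) * clr of the lead for every rotation", {
  X <- random_compositions(20, D = 9, seed = 7)
  C <- clr(X)
  for (lead in 1:9) {
    Z <- pivot_ilr(X, pivot_basis(9, lead))
    expect_equal(Z[, 1], sqrt(9 / 8) * C[, lead], tolerance = 1e-12)
  }
})

test_that("z1 is invariant to the ordering of the remaining parts", {
  x <- close_composition(c(4, 1, 7, 2), 960)
  perms <- list(c(2, 3, 4), c(2, 4, 3), c(3, 2, 4), c(3, 4, 2),
                c(4, 2, 3), c(4, 3, 2))
  z1 <- vapply(perms, function(p) {
    pivot_ilr(x, pivot_basis(4, lead = 1, order = p))[1]
  }, numeric(1))
  expect_lt(diff(range(z1)), 1e-12)
})

test_that("pivot_ilr and its inverse are mutual identities", {
  b <- pivot_basis(9, lead = 5)
  expect_equal(pivot_ilr_inverse(rep(0, 8), b, total = 960),
               rep(960 / 9, 9))
  ref <- close_composition(c(722.9, 105.7, 51.1, 27.8, 15.4, 9.1, 5.8,
                             14.3, 8.0), 960)
  expect_composition_equal(pivot_ilr_inverse(pivot_ilr(ref, b), b), ref)
  X <- random_compositions(1000, seed = 11)
  Z <- pivot_ilr(X, b)
  back <- pivot_ilr_inverse(Z, b, total = 960)
  expect_lt(max(abs(back - X) / X), 1e-9)
  # inverse then forward
  Z2 <- pivot_ilr(back, b)
  expect_lt(max(abs(Z2 - Z)), 1e-9)
})

test_that("geometric-mean composition is the Aitchison centre", {
  x <- close_composition(c(3, 2, 9), 960)
  expect_composition_equal(gmean_composition(matrix(x, nrow = 1)), x)
  # clr reflections average to the uniform composition
  z <- c(0.4, -0.1, -0.3)
  pair <- rbind(clr_inverse(z, 960), clr_inverse(-z, 960))
  expect_composition_equal(gmean_composition(pair), rep(320, 3))
  # minimises summed squared Aitchison distance vs a grid of candidates
  X <- close_composition(rbind(c(1, 2, 3), c(4, 1, 1), c(2, 2, 5)), 1)
  g <- gmean_composition(X, total = 1)
  ssd <- function(cand) {
    sum(vapply(seq_len(nrow(X)), function(i) {
      sum((clr(X[i, ]) - clr(cand))^2)
    }, numeric(1)))
  }
  best <- ssd(g)
  grid <- expand.grid(p1 = seq(0.05, 0.9, by = 0.05),
                      p2 = seq(0.05, 0.9, by = 0.05))
  grid <- grid[grid$p1 + grid$p2 < 0.95, ]
  for (i in seq_len(nrow(grid))) {
    cand <- c(grid$p1[i], grid$p2[i], 1 - grid$p1[i] - grid$p2[i])
    expect_gte(ssd(cand), best)
  }
  expect_error(gmean_composition(matrix(numeric(0), 0, 3)), "empty")
})

test_that("variation matrix matches a direct elementwise computation", {
  X <- close_composition(rbind(c(1, 2, 3), c(2, 2, 1), c(5, 1, 2)), 960)
  V <- variation_matrix(X)
  expect_equal(V, t(V))
  expect_equal(diag(V), rep(0, 3), ignore_attr = TRUE)
  expect_true(all(V >= 0))
  for (i in 1:3) for (j in 1:3) {
    expect_equal(V[i, j], stats::var(log(X[, i] / X[, j])),
                 tolerance = 1e-12)
  }
  # repeated identical compositions have no log-ratio spread
  same <- X[c(1, 1, 1), ]
  expect_equal(variation_matrix(same), matrix(0, 3, 3),
               ignore_attr = TRUE)
  expect_error(variation_matrix(X[1, , drop = FALSE]), "at least 2")
})

test_that("one-for-remaining reallocation conserves time and inverts", {
  x <- stats::setNames(close_composition(c(724, 108, 52, 28, 15, 9, 5, 13,
                                           6.3), 960), bands9)
  expect_equal(reallocate(x, "700+", 0), x)
  y <- reallocate(x, "700+", 5)
  expect_equal(y[["700+"]], x[["700+"]] + 5)
  expect_equal(unname(y[1:8]), unname(x[1:8] - 5 / 8))
  expect_equal(round(y[["700+"]], 1), 11.3)
  expect_lt(abs(sum(y) - 960), 1e-9)
  # reallocating -t undoes +t
  expect_composition_equal(reallocate(y, "700+", -5), x)
  # infeasible reallocation names the violated band
  expect_error(reallocate(x, "0-50", 60), "700\\+")
  expect_error(reallocate(x, "nope", 1), "unknown band")
})

test_that("zero replacement only touches zero parts", {
  x <- c(10, 0, 5, 0)
  y <- zero_replace(x)
  expect_equal(y, c(10, 1 / 120, 5, 1 / 120))
  expect_equal(zero_replace(x, pseudo = 0.25), c(10, 0.25, 5, 0.25))
  expect_error(zero_replace(x, pseudo = 0), "positive")
})

test_that("composition CSV round-trips through read/write", {
  X <- random_compositions(5, seed = 2)
  colnames(X) <- bands9
  rownames(X) <- paste0("p", 1:5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_compositions(X, f, id_col = "participant_id")
  back <- read_compositions(f, id_col = "participant_id")
  expect_equal(back, X)
  expect_equal(colnames(back), bands9)
})
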