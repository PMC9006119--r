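test_that("bootstrap indices are uniform with replacement and seed-stable", {
  expect_identical(esindy:::with_seed(1, bootstrap_indices(1)), 1L)
  a <- esindy:::with_seed(5, bootstrap_indices(100))
  b <- esindy:::with_seed(5, bootstrap_indices(100))
  expect_identical(a, b)
  expect_true(all(a >= 1 & a <= 100))
})

test_that("bootstrap distinct fraction approaches 1 - 1/e", {
  set.seed(99)
  frac <- replicate(200, length(unique(bootstrap_indices(10000))) / 10000)
  expect_lt(abs(mean(frac) - (1 - exp(-1))), 0.01)
})

test_that("identity resampling with q = 1 reproduces the plain fit", {
  lib <- rigged_library()
  rconf <- regression_config(lambda1 = 0.1)
  em <- fit_ensemble(lib, ensemble_config(q = 1L, inclusion_tol = 0.5),
                     rconf, resample_fn = seq_len)
  plain <- stridge(lib, rconf)
  expect_equal(em$aggregate$Xi, plain$Xi, tolerance = 1e-14)
  expect_true(all(em$inclusion %in% c(0, 1)))
})

test_that("bagging means and bragging medians aggregate as documented", {
  lib <- rigged_library()
  members <- list(matrix(1, 6, 1), matrix(1, 6, 1), matrix(100, 6, 1))
  incl <- matrix(1, 6, 1)
  expect_equal(esindy:::aggregate_members(members, incl, "bagging")[1, 1], 34)
  expect_equal(esindy:::aggregate_members(members, incl, "bragging")[1, 1], 1)
})

test_that("bragging is robust to a corrupted minority; bagging is not", {
  members <- replicate(11, matrix(c(1, -2), 2, 1), simplify = FALSE)
  incl <- matrix(1, 2, 1)
  clean_med <- esindy:::aggregate_members(members, incl, "bragging")
  for (j in 1:5) members[[j]] <- members[[j]] * 100  # < q/2 outlier members
  expect_equal(esindy:::aggregate_members(members, incl, "bragging"),
               clean_med)
  bag <- esindy:::aggregate_members(members, incl, "bagging")
  expect_gt(abs(bag[1, 1] - 1), 10)
})

test_that("clean Lorenz bagging puts inclusion 1 on all seven true terms", {
  em <- fit_ensemble(lorenz_library(), ensemble_config(q = 40L, seed = 3),
                     regression_config(lambda1 = 0.1))
  truth <- true_model(lorenz_spec())
  expect_true(all(em$inclusion[truth$support] == 1))
  expect_identical(em$aggregate$support, truth$support)
})

test_that("library bagging with l = D reproduces the plain fit", {
  lib <- rigged_library()
  rconf <- regression_config(lambda1 = 0.1)
  em <- fit_library_ensemble(lib, ensemble_config(q = 8L, mode = "library",
                                                  l = ncol(lib$Theta),
                                                  inclusion_tol = 0.5,
                                                  seed = 4), rconf)
  plain <- stridge(lib, rconf)
  expect_equal(em$aggregate$Xi, plain$Xi, tolerance = 1e-13)
  expect_true(all(em$inclusion %in% c(0, 1)))
})

test_that("library subsampling offers each term q*l/D times on average", {
  lib <- lorenz_library()
  D <- ncol(lib$Theta)
  em <- fit_library_ensemble(lib, ensemble_config(q = 400L, mode = "library",
                                                  l = 5L, seed = 6),
                             regression_config(lambda1 = 0.1))
  offered <- colSums(em$availability)
  expected <- 400 * 5 / D
  expect_true(all(abs(offered - expected) <= 3 * sqrt(expected)))
})

test_that("library bagging separates the Lorenz support at the 65% threshold", {
  lib <- lorenz_library()
  em <- fit_library_ensemble(lib, ensemble_config(q = 200L, mode = "library",
                                                  l = 15L, seed = 7),
                             regression_config(lambda1 = 0.1))
  truth <- true_model(lorenz_spec())
  expect_true(all(em$inclusion[truth$support] >= 0.9))
  expect_true(all(em$inclusion[!truth$support] < 0.65))
  expect_identical(em$aggregate$support, truth$support)
})

test_that("inclusion probabilities are permutation-equivariant", {
  lib <- rigged_library()
  rconf <- regression_config(lambda1 = 0.1)
  em <- fit_ensemble(lib, ensemble_config(q = 15L, seed = 8), rconf,
                     resample_fn = seq_len)
  perm <- c(3, 1, 2, 6, 5, 4)
  plib <- lib
  plib$Theta <- lib$Theta[, perm]
  plib$terms <- esindy:::subset_terms(lib$terms, perm)
  emp <- fit_ensemble(plib, ensemble_config(q = 15L, seed = 8), rconf,
                      resample_fn = seq_len)
  expect_equal(unname(emp$inclusion), unname(em$inclusion[perm, , drop = FALSE]))
})

test_that("prescreening keeps high-inclusion terms and validates thresholds", {
  lib <- lorenz_library()
  # bagging on clean data: inclusion is exactly 1 on the true support, 0 off
  em <- fit_ensemble(lib, ensemble_config(q = 30L, seed = 7),
                     regression_config(lambda1 = 0.1))
  expect_identical(prescreen_library(lib, em, 0)$terms$label,
                   lib$terms$label)
  truth <- true_model(lorenz_spec())
  kept <- prescreen_library(lib, em, 1)
  expect_setequal(kept$terms$label,
                  rownames(truth$Xi)[apply(truth$support, 1, any)])
  expect_error(prescreen_library(lib, em, 1.01), "lower keep_tol")
})

test_that("member fit cost grows super-linearly in library size", {
  set.seed(10)
  M <- 3000
  Theta <- matrix(rnorm(M * 40), M, 40)
  y <- rnorm(M)
  time_l <- function(l, reps) {
    cols <- seq_len(l)
    system.time(for (i in seq_len(reps))
      ridge_solve(Theta[, cols], y, 0.01))[["elapsed"]]
  }
  reps <- 20L
  t10 <- time_l(10, reps)
  while (t10 < 0.05 && reps < 2000L) {  # calibrate away timer noise
    reps <- reps * 4L
    t10 <- time_l(10, reps)
  }
  t40 <- time_l(40, reps)
  expect_gt(t40 / t10, 2)  # O(M l^2) trend, not linear in l
})
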