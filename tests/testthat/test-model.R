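test_that("model data assembly builds intercept-first X and incidence Z", {
  ped <- trio_ped()
  phen <- tibble::tibble(id = c("s", "d", "i"), y = c(1, 2, 3),
                         sex = c("M", "F", "F"))
  md <- build_model_data(ped, phen)
  expect_equal(unname(md$X[, 1]), rep(1, 3))
  expect_equal(ncol(md$X), 1)
  expect_equal(dim(md$Z), c(3, 3))

  md2 <- build_model_data(ped, phen, fixed = "sex")
  expect_equal(ncol(md2$X), 2)

  phen$y[2] <- NA  # missing phenotype dropped; pedigree link retained
  md3 <- build_model_data(ped, phen)
  expect_equal(length(md3$y), 2)
  expect_equal(ncol(md3$Z), 3)

  expect_error(build_model_data(ped, tibble::tibble(id = "zz", y = 1)),
               "absent from pedigree: zz")
})

test_that("BLUP solutions match the dense GLS oracle", {
  set.seed(41)
  for (s in 1:4) {
    ped <- sim_random_pedigree(sample(20:50, 1), seed = 40 + s)
    n <- nrow(ped)
    A <- relationship_matrix(ped)
    u <- as.numeric(t(chol(A)) %*% rnorm(n))
    phen <- tibble::tibble(id = ped$id, y = 2 + u + rnorm(n))
    fit <- fit_animal_model(ped, phen, mode = "basic",
                            varcomp = list(sigma2_A = 1, sigma2_E = 1))
    oracle <- dense_blup(matrix(1, n, 1), diag(n), phen$y, A, 1, 1)
    expect_equal(unname(fit$beta), oracle$beta, tolerance = 1e-8)
    expect_equal(unname(fit$a), oracle$u, tolerance = 1e-8)
  }
})

test_that("explicit and implicit group models give identical answers", {
  set.seed(55)
  for (s in 1:3) {
    ped <- sim_random_pedigree(150, seed = 50 + s)
    gp <- assign_groups(ped, rule = "flag")
    phen <- sim_phen_on_ped(gp, g_true = c(0, 2))
    vc <- list(sigma2_A = 1, sigma2_E = 1)
    fe <- fit_animal_model(gp, phen, mode = "explicit", varcomp = vc)
    fi <- fit_animal_model(gp, phen, mode = "implicit", varcomp = vc)
    expect_equal(fe$g, fi$g, tolerance = 1e-6)
    expect_equal(fe$beta, fi$beta, tolerance = 1e-6)
    expect_equal(fe$a, fi$a, tolerance = 1e-6)
    expect_equal(fe$u, fi$u, tolerance = 1e-6)
    # group-effect standard errors agree too
    expect_equal(fe$g_se[-1], fi$g_se[-1], tolerance = 1e-6)
  }
})

test_that("breeding values shrink to zero as sigma2_A vanishes", {
  ped <- sim_random_pedigree(60, seed = 61)
  phen <- tibble::tibble(id = ped$id, y = rnorm(60))
  fit <- fit_animal_model(ped, phen, mode = "basic",
                          varcomp = list(sigma2_A = 1e-8, sigma2_E = 1))
  expect_lt(max(abs(fit$a)), 1e-5)
})

test_that("u = Qg + a conversions are exact inverses", {
  ped <- sim_random_pedigree(80, seed = 71)
  gp <- assign_groups(ped, rule = "flag")
  Q <- q_matrix(gp)
  a <- rnorm(80); g <- c(0, 3)
  u <- total_additive_effects(a, Q, g)
  expect_equal(breeding_values_from_total(u, Q, g), a)
  expect_equal(total_additive_effects(rep(0, 80), Q, g),
               as.numeric(Q %*% g))
  # r = 1, g = 0: u == a
  g1 <- assign_groups(ped, rule = "single")
  expect_equal(total_additive_effects(a, q_matrix(g1), 0), a)
  # worked number: a = 0, q = (0.25, 0.75), g = (0, 4) -> u = 3
  expect_equal(total_additive_effects(0, matrix(c(0.25, 0.75), 1), c(0, 4)), 3)
})

test_that("sparse profile REML matches the dense V-based likelihood", {
  set.seed(82)
  ped <- sim_random_pedigree(120, n_founders = 12, p_unknown = 0.1, seed = 82)
  gp <- assign_groups(ped, rule = "flag")
  phen <- sim_phen_on_ped(gp, g_true = c(0, 2), s2a = 2, s2e = 1)
  vc <- reml_estimate(gp, phen, mode = "explicit")
  expect_true(vc$converged)
  n <- nrow(ped)
  A <- relationship_matrix(ped)
  Xl <- cbind(1, q_matrix(gp)[, -1])
  m2l <- dense_reml_m2l(Xl, diag(n), phen$y, A, vc$sigma2_A, vc$sigma2_E)
  expect_equal(-2 * vc$loglik, m2l, tolerance = 1e-6)
  # the reported optimum beats nearby variance ratios under the dense oracle
  for (fac in c(0.7, 1.4)) {
    alt <- dense_reml_m2l(Xl, diag(n), phen$y, A,
                          vc$sigma2_E / (vc$lambda * fac), vc$sigma2_E)
    expect_lte(-2 * vc$loglik, alt + 1e-6)
  }
})

test_that("REML flags a boundary estimate when data carry no genetic signal", {
  set.seed(91)
  ped <- sim_random_pedigree(300, seed = 91)
  phen <- tibble::tibble(id = ped$id, y = rnorm(300))  # a == 0
  vc <- reml_estimate(ped, phen, mode = "basic")
  expect_lt(vc$sigma2_A, 0.05)
  expect_false(vc$converged)
})

test_that("REML recovers known variance components on simulated data", {
  set.seed(95)
  ped <- sim_random_pedigree(800, n_founders = 60, p_unknown = 0.05, seed = 95)
  gp <- assign_groups(ped, rule = "single")
  phen <- sim_phen_on_ped(gp, g_true = 0, s2a = 1, s2e = 1)
  vc <- reml_estimate(tibble::as_tibble(ped), phen, mode = "basic")
  expect_true(vc$converged)
  expect_gt(vc$sigma2_A, 0.6)
  expect_lt(vc$sigma2_A, 1.5)
})

test_that("tidy and glance expose fits in broom style", {
  ped <- sim_random_pedigree(60, seed = 97)
  gp <- assign_groups(ped, rule = "flag")
  phen <- sim_phen_on_ped(gp, g_true = c(0, 1))
  fit <- fit_animal_model(gp, phen, mode = "explicit",
                          varcomp = list(sigma2_A = 1, sigma2_E = 1))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(td$estimate[1], 0)  # reference contrast
  rf <- tidy(fit, "ranef")
  expect_equal(nrow(rf), 60)
  expect_equal(rf$u, unname(fit$u))
  gl <- glance(fit)
  expect_equal(gl$sigma2_A, 1)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("confounded group structure is reported as an error", {
  # every individual a pure member of the non-reference group: its Q column
  # is constant, exactly collinear with the intercept
  ped <- order_pedigree(tibble::tibble(id = c("a", "b"), dam = NA_character_,
                                       sire = NA_character_))
  gp <- assign_groups(ped, rule = "table",
                      table = tibble::tibble(id = c("a", "b"), group = "gB"),
                      labels = c("gA", "gB"))
  phen <- tibble::tibble(id = c("a", "b"), y = c(1, 2))
  expect_error(
    suppressWarnings(
      fit_animal_model(gp, phen, mode = "explicit",
                       varcomp = list(sigma2_A = 1, sigma2_E = 1))),
    "confounded")
})
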