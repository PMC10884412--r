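test_that("the neutral folded spectrum matches the Watterson closed form", {
  e4 <- expected_folded_sfs(0, theta = 1, n_chrom = 4)
  expect_equal(e4 / sum(e4), c(8 / 11, 3 / 11))
  e24 <- expected_folded_sfs(0, theta = 2.5, n_chrom = 24)
  u <- 2.5 / seq_len(23)
  expect_equal(e24, u[1:12] + c(u[23:13], 0))
})

test_that("folding equals summing complementary unfolded classes", {
  u <- polyrekit:::sfs_shape_unfolded(-3, 10)
  f <- polyrekit:::fold_sfs_vector(u)
  expect_equal(f, c(u[1] + u[9], u[2] + u[8], u[3] + u[7], u[4] + u[6],
                    u[5]))
})

test_that("selected spectra match adaptive quadrature to 1e-8", {
  dens <- function(q, S) {
    (1 - exp(-S * (1 - q))) / ((1 - exp(-S)) * q * (1 - q))
  }
  for (S in c(-5, -0.5, 2)) {
    n <- 24
    f <- expected_folded_sfs(S, 1, n)
    ref_unfolded <- vapply(seq_len(n - 1), function(i) {
      integrate(function(q) dens(q, S) * dbinom(i, n, q), 0, 1,
                rel.tol = 1e-12)$value
    }, numeric(1))
    ref <- polyrekit:::fold_sfs_vector(ref_unfolded)
    expect_lt(max(abs(f - ref) / ref), 1e-8)
  }
})

test_that("strong purifying selection empties the spectrum", {
  weak <- expected_folded_sfs(-1, 1, 12)
  strong <- expected_folded_sfs(-100, 1, 12)
  lethal <- expected_folded_sfs(-5e5, 1, 12)
  expect_true(all(strong < weak))
  expect_true(all(lethal < 1e-3))
  # monotone decreasing in |S|, classwise
  grid <- t(vapply(c(0, -2, -10, -50, -200),
                   function(S) expected_folded_sfs(S, 1, 12), numeric(6)))
  expect_true(all(apply(grid, 2, function(col) all(diff(col) < 0))))
})

test_that("the gamma mixture agrees with direct integration", {
  shape <- 0.4; mean_nes <- 2000; n <- 12
  m <- polyrekit:::dfe_mixture_shape(shape, mean_nes, n)
  ref <- vapply(seq_len(n %/% 2), function(i) {
    integrate(function(x) {
      vapply(x, function(b) {
        polyrekit:::fold_sfs_vector(
          polyrekit:::sfs_shape_unfolded(-b, n))[i]
      }, numeric(1)) * dgamma(x, shape, scale = mean_nes / shape)
    }, 0, Inf, rel.tol = 1e-10)$value
  }, numeric(1))
  expect_lt(max(abs(m - ref) / ref), 1e-6)
})

test_that("neutral simulations give matching 0-fold and 4-fold shapes", {
  cfg <- sim_config(seed = 61, dfe_mean_nes = 0, alpha_true = 0)
  sel <- simulate_selection_data(cfg, n_genes_per_class = 400)
  p0 <- sel$pooled_sfs0 / sum(sel$pooled_sfs0)
  p4 <- sel$pooled_sfs4 / sum(sel$pooled_sfs4)
  expect_lt(max(abs(p0 - p4)), 0.02)
})

test_that("DFE fitting recovers the generating gamma", {
  cfg <- sim_config(seed = 67)  # shape 0.4, mean 2000
  sel <- simulate_selection_data(cfg, n_genes_per_class = 500)
  fit <- fit_gamma_dfe(sel)
  expect_lt(abs(fit$shape - 0.4), 0.1)
  true_bins <- diff(pgamma(c(0, 1, 10, 100, Inf), 0.4, scale = 5000))
  expect_true(all(abs(fit$bin_props - true_bins) < 0.05))
  expect_equal(sum(fit$bin_props), 1)
  # likelihood at the truth beats perturbed parameters on expected data
  ll <- function(shape, mean_nes) {
    polyrekit:::dfe_loglik(log(shape), log(mean_nes), sel$pooled_sfs0,
                           sel$n_chrom,
                           fit$theta_ns)$ll
  }
  expect_gte(ll(fit$shape, fit$mean_nes), ll(0.8, 200))
  expect_gte(ll(fit$shape, fit$mean_nes), ll(0.2, 2e4))
})

test_that("neutral zero-fold data concentrate mass in the weakest bin", {
  cfg <- sim_config(seed = 71, dfe_mean_nes = 0, alpha_true = 0)
  sel <- simulate_selection_data(cfg, n_genes_per_class = 400)
  fit <- fit_gamma_dfe(sel)
  expect_gt(fit$bin_props[1], 0.9)
})

test_that("fixation index follows the MK arithmetic and corrections", {
  expect_equal(fixation_index(10, 10, 10, 10)$FI, 1)
  expect_equal(fixation_index(10, 10, 5, 10)$FI, 2)
  ps0 <- fixation_index(10, 10, 5, 0)
  expect_true(ps0$corrected)
  expect_equal(ps0$FI, (10.5 / 10.5) / (5.5 / 0.5))
  allz <- fixation_index(0, 0, 0, 0)
  expect_true(allz$undefined)
  expect_true(is.na(allz$FI))
  expect_error(fixation_index(-1, 1, 1, 1), ">= 0")
})

test_that("constraint and selection effects reduce to zero when balanced", {
  # Pn/Ps equal to L0/L4 after correction
  ef <- snipre_like_effects(Dn = 5.5 - 0.5, Ds = 5.5 - 0.5, Pn = 8.5 - 0.5,
                            Ps = 2.5 - 0.5, L0 = 8.5 / 2.5 * 100, L4 = 100)
  expect_equal(ef$constraint_effect, 0)
  ef2 <- snipre_like_effects(3, 7, 3, 7, 100, 100)
  expect_equal(ef2$selection_effect, 0)
  ef3 <- snipre_like_effects(12, 4, 2, 6, 300, 100)
  expect_equal(ef3$constraint_effect, log(2.5 / 6.5) - log(3))
  expect_equal(ef3$selection_effect, log(12.5 / 4.5) - log(2.5 / 6.5))
  expect_error(snipre_like_effects(1, 1, 1, 1, 0, 100), "L0")
})

test_that("gene bootstrap is deterministic and degenerate-safe", {
  cfg <- sim_config(seed = 73)
  sel <- simulate_selection_data(cfg, n_genes_per_class = 50)
  stat <- function(inp) c(pn = sum(inp$genes$Pn), ps = sum(inp$genes$Ps))
  b1 <- bootstrap_by_gene(sel, stat, n_reps = 40, seed = 9)
  b2 <- bootstrap_by_gene(sel, stat, n_reps = 40, seed = 9)
  expect_identical(b1, b2)
  expect_equal(dim(b1), c(2L, 40L))
  # constant genes give a zero-width distribution
  sel_const <- sel
  sel_const$genes <- sel$genes[rep(1L, 10), ]
  sel_const$sfs0 <- sel$sfs0[rep(1L, 10), , drop = FALSE]
  sel_const$sfs4 <- sel$sfs4[rep(1L, 10), , drop = FALSE]
  bc <- bootstrap_by_gene(sel_const, stat, n_reps = 10, seed = 1)
  expect_equal(length(unique(bc["pn", ])), 1L)
})

test_that("bootstrap standard errors track the analytic expectation", {
  cfg <- sim_config(seed = 79)
  sel <- simulate_selection_data(cfg, n_genes_per_class = 200)
  stat <- function(inp) c(m = mean(inp$genes$Ps))
  b <- bootstrap_by_gene(sel, stat, n_reps = 400, seed = 3)
  analytic <- sd(sel$genes$Ps) / sqrt(nrow(sel$genes))
  expect_lt(abs(sd(b["m", ]) - analytic) / analytic, 0.2)
})

test_that("pairwise class contrasts annotate significance correctly", {
  same <- list(c1 = c(1, 2, 3, 4), c2 = c(1, 2, 3, 4))
  res <- compare_retention_classes(same)
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)
  set.seed(5)
  shifted <- list(a = rnorm(50), b = rnorm(50, 1), c = rnorm(50, 5))
  res2 <- compare_retention_classes(shifted)
  ref <- t.test(shifted$a, shifted$b)
  row <- res2[res2$class_a == "a" & res2$class_b == "b", ]
  expect_equal(row$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(row$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res2$stars[res2$class_b == "c"], c("***", "***"))
  # star thresholds
  expect_equal(nrow(res2), 3L)
})

test_that("alpha estimation hits its neutral and lethal limits", {
  cfg <- sim_config(seed = 83, dfe_mean_nes = 0, alpha_true = 0)
  sel <- simulate_selection_data(cfg, n_genes_per_class = 400)
  fit <- fit_gamma_dfe(sel)
  ada <- estimate_alpha_omega_a(fit, sel, n_boot = 0)
  expect_lt(abs(ada$alpha), 0.1)
  # a DFE entirely at strongly deleterious values fixes nothing, so any
  # observed Dn is called adaptive
  fake_fit <- list(shape = 20, mean_nes = 5e4)
  ada2 <- polyrekit:::alpha_point(fake_fit, sel)
  expect_gt(ada2$alpha, 0.95)
  sel0 <- sel
  sel0$genes$Ds <- 0L
  expect_error(estimate_alpha_omega_a(fit, sel0, n_boot = 0), "positive")
})

test_that("class-graded selection reproduces the expected ordering", {
  mk <- function(seed, mean_nes, alpha) {
    cfg <- sim_config(seed = seed, dfe_mean_nes = mean_nes,
                      alpha_true = alpha)
    simulate_selection_data(cfg, n_genes_per_class = 300)
  }
  sels <- list(mk(91, 200, 0.05), mk(92, 1000, 0.3), mk(93, 5000, 0.55))
  alphas <- numeric(3); fis <- numeric(3); seleff <- numeric(3)
  for (i in 1:3) {
    fit <- fit_gamma_dfe(sels[[i]])
    alphas[i] <- estimate_alpha_omega_a(fit, sels[[i]], n_boot = 0)$alpha
    g <- sels[[i]]$genes
    fis[i] <- fixation_index(sum(g$Dn), sum(g$Ds), sum(g$Pn),
                             sum(g$Ps))$FI
    seleff[i] <- mean(snipre_like_effects(g$Dn, g$Ds, g$Pn, g$Ps, g$L0,
                                          g$L4)$selection_effect)
  }
  expect_true(all(diff(alphas) > 0))
  expect_true(all(diff(fis) > 0))
  expect_true(all(diff(seleff) > 0))
})
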