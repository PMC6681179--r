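# Model family, expected SFS engines, composite likelihood, AIC.

test_that("the scenario catalogue has 34 members with the documented k", {
  cat34 <- model_catalogue()
  expect_equal(nrow(cat34), 34)
  expect_equal(sum(duplicated(cat34$model)), 0)
  # SI cannot carry 2M2P
  expect_false(any(grepl("^SI2M2P", cat34$model)))
  expect_equal(cat34$k[cat34$model == "PSCex"], 10)
  expect_equal(cat34$k[cat34$model == "PSC2M2Pex"], 12)
  expect_equal(cat34$k[cat34$model == "SI"], 4)
  expect_equal(cat34$k[cat34$model == "IM"], 6)
  expect_equal(cat34$k[cat34$model == "PSC2N"], 9)
})

test_that("epoch schedules match the scenario definitions", {
  si <- build_epochs(demographic_model("SI", c(nu1 = 1, nu2 = 2,
                                               t_iso = 0.3, O = 1)))
  expect_equal(nrow(si), 1)
  expect_equal(si$M12, 0)
  expect_equal(si$M21, 0)

  psc <- build_epochs(demographic_model(
    "PSC", c(nu1 = 1, nu2 = 2, M12 = 3, M21 = 1, t_iso = 0.4,
             t_sc = 0.2, O = 1)))
  expect_equal(nrow(psc), 4)
  expect_equal(psc$M12, c(0, 3, 0, 3)) # ends at present in contact
  expect_equal(psc$duration, c(0.2, 0.1, 0.2, 0.1))

  # SC with t_sc = 0 degenerates to the SI schedule
  sc0 <- build_epochs(demographic_model(
    "SC", c(nu1 = 1, nu2 = 2, M12 = 3, M21 = 1, t_iso = 0.3,
            t_sc = 0, O = 1)))
  expect_equal(nrow(sc0), 1)
  expect_equal(sc0$M12, 0)

  # ex appends a growth epoch continuing the final migration regime
  scex <- build_epochs(demographic_model(
    "SC", c(nu1 = 2, nu2 = 3, M12 = 3, M21 = 1, t_iso = 0.3, t_sc = 0.1,
            nu_a1 = 0.5, nu_a2 = 0.8, t_scg = 0.05, O = 1),
    flags = "ex"))
  expect_equal(nrow(scex), 3)
  expect_equal(scex$nu1_start, c(0.5, 0.5, 0.5))
  expect_equal(scex$nu1_end[3], 2)
  expect_equal(scex$M12[3], 3)

  expect_error(demographic_model("SC", c(nu1 = 1, nu2 = 2, M12 = 1,
                                         M21 = 1, t_iso = 0.3, O = 1)),
               "missing")
})

test_that("single-population equilibrium follows the 1/i law", {
  e <- equilibrium_sfs_single(10)
  expect_lt(max(abs(e[2:10] / (1 / (1:9)) - 1)), 0.005)
  # size scales the spectrum linearly
  e2 <- equilibrium_sfs_single(10, nu = 2.5)
  expect_equal(e2, 2.5 * e, tolerance = 1e-12)
})

test_that("mis-polarization transform follows O*M + (1-O)*reverse(M)", {
  withr::with_seed(2, {
    M <- matrix(runif(25), 5, 5)
  })
  expect_equal(apply_misid(M, 1), M)
  half <- apply_misid(M, 0.5 + 1e-12)
  expect_equal(half, half[5:1, 5:1], tolerance = 1e-9)

  # unit mass at (1,0) with O = 0.97 over n1 = n2 = 4
  one <- matrix(0, 5, 5); one[2, 1] <- 1
  out <- apply_misid(one, 0.97)
  expect_equal(out[2, 1], 0.97)
  expect_equal(out[4, 5], 0.03) # (3,4), the reversed entry
  expect_equal(sum(out), 1)
  expect_error(apply_misid(M, 0.4), "O must be")

  folded <- fold(joint_sfs(matrix(1, 3, 3)))
  expect_error(apply_misid(folded, 0.9), "unfolded")
})

test_that("symmetric IM expectation is exchange-symmetric (exact engine)", {
  m <- demographic_model("IM", c(nu1 = 1.3, nu2 = 1.3, M12 = 2.5,
                                 M21 = 2.5, t_sc = 0.6, O = 1))
  ex <- expected_sfs(m, 4, 4, engine = "exact")
  expect_lt(max(abs(ex$counts - t(ex$counts))), 1e-8)
})

test_that("identity locus-class mixtures reduce to the base model", {
  base <- demographic_model("SC", c(nu1 = 1, nu2 = 2, M12 = 2, M21 = 1,
                                    t_iso = 0.3, t_sc = 0.1, O = 1))
  with2n <- demographic_model("SC", c(nu1 = 1, nu2 = 2, M12 = 2, M21 = 1,
                                      t_iso = 0.3, t_sc = 0.1, nr = 0.5,
                                      bf = 1, O = 1), flags = "2N")
  e1 <- expected_sfs(base, 4, 4)
  e2 <- expected_sfs(with2n, 4, 4)
  expect_equal(e1$counts, e2$counts, tolerance = 1e-10)

  # 2M2P with both island weights at zero equals the base model
  with2m <- demographic_model("SC", c(nu1 = 1, nu2 = 2, M12 = 2, M21 = 1,
                                      t_iso = 0.3, t_sc = 0.1, P1 = 1e-3,
                                      P2 = 1e-3, O = 1), flags = "2M2P")
  e3 <- expected_sfs(with2m, 4, 4)
  expect_equal(e1$counts, e3$counts, tolerance = 0.02)
})

test_that("exact and Monte-Carlo engines agree within 3 MC SEs", {
  withr::with_seed(17, {
    models <- lapply(1:5, function(i) {
      demographic_model("SC", c(nu1 = exp(runif(1, log(0.3), log(3))),
                                nu2 = exp(runif(1, log(0.3), log(3))),
                                M12 = runif(1, 0, 5), M21 = runif(1, 0, 5),
                                t_iso = runif(1, 0.05, 0.6),
                                t_sc = runif(1, 0.05, 0.4), O = 1))
    })
  })
  # 5 models x 23 unmasked entries = 115 comparisons: even exact agreement
  # exceeds 3 SEs somewhere with ~25% probability, so the per-entry 3-SE
  # check is paired with a 4-SE cap on the worst entry
  zs <- c()
  for (k in seq_along(models)) {
    ex <- expected_sfs(models[[k]], 4, 4, engine = "exact", pad = 16)
    mc <- expected_sfs(models[[k]], 4, 4, engine = "mc", mc_loci = 20000,
                       seed = 100 + k)
    se <- attr(mc, "se")
    un <- !ex$mask & se > 0
    zs <- c(zs, abs(ex$counts - mc$counts)[un] / se[un])
  }
  expect_gte(mean(zs < 3), 0.97)
  expect_lt(max(zs), 4)
})

test_that("the no-migration joint marginal matches the single-population law", {
  # equal sizes, no migration: the pop-1 margin of the joint SFS equals the
  # single-population expectation with the same size history
  m <- demographic_model("SI", c(nu1 = 1, nu2 = 1, t_iso = 50, O = 1))
  ex <- expected_sfs(m, 6, 2, pad = 0)
  marg <- rowSums(ex$counts)
  eq <- equilibrium_sfs_single(6)
  # after a very long isolated epoch at nu = 1 the margin re-equilibrates
  expect_equal(marg[2:6] / eq[2:6], rep(1, 5), tolerance = 0.01)
})

test_that("2M2P expands to the weighted three-class mixture", {
  base <- c(nu1 = 1, nu2 = 1.5, M12 = 4, M21 = 1, t_iso = 0.3, t_sc = 0.2)
  m <- demographic_model("SC", c(base, P1 = 0.2, P2 = 0.1, O = 0.97),
                         flags = "2M2P")
  raw <- function(p) expected_sfs(demographic_model("SC", c(p, O = 1)),
                                  4, 4)$counts
  p0 <- base; p0["M12"] <- 0
  p2 <- base; p2["M21"] <- 0
  manual <- apply_misid(0.7 * raw(base) + 0.2 * raw(p0) + 0.1 * raw(p2),
                        0.97)
  expect_equal(expected_sfs(m, 4, 4)$counts, manual, tolerance = 1e-8)
})

test_that("composite likelihood profiles the scale analytically", {
  withr::with_seed(4, {
    M <- matrix(runif(25, 0.1, 2), 5, 5)
  })
  alpha <- 3.7
  D <- round(alpha * M)
  obs <- joint_sfs(D)
  ll <- composite_loglik(obs, M)
  # direct Poisson evaluation at the profiled alpha
  un <- !obs$mask
  ahat <- sum(D[un]) / sum(M[un])
  expect_equal(ll, sum(dpois(D[un], ahat * M[un], log = TRUE)))

  # doubling both observed and expected leaves the fit of shape unchanged
  ll2 <- composite_loglik(joint_sfs(2 * D), 2 * M)
  a2 <- sum(2 * D[un]) / sum(2 * M[un])
  expect_equal(a2, ahat)

  # all-zero observation: alpha-hat = 0 convention, lnL = 0
  expect_equal(composite_loglik(joint_sfs(matrix(0, 5, 5)), M), 0)

  # zero expectation under observed counts is -Inf with a warning
  idx <- which(D > 0 & !obs$mask)[1]
  M0 <- M; M0[idx] <- 0
  expect_warning(llz <- composite_loglik(obs, M0), "zero")
  expect_identical(llz, -Inf)
})

test_that("AIC arithmetic and model ranking", {
  expect_equal(aic(list(loglik = 0, k = 0)), 0)
  f1 <- list(model = "A", loglik = -100, k = 5)
  f2 <- list(model = "B", loglik = -98, k = 8)
  tab <- rank_models(list(f1, f2))
  expect_equal(tab$model, c("A", "B"))
  expect_equal(tab$dAIC, c(0, 2))
})

test_that("unit conversion to demographic units", {
  par <- c(nu1 = 1, nu2 = 0.5, M12 = 1, t_iso = 0.25, O = 0.97)
  out <- to_demographic_units(par, Nref = 1e6, generation_time_years = 1)
  expect_equal(unname(out["N1"]), 1e6)
  expect_equal(unname(out["N2"]), 5e5)
  expect_equal(unname(out["m12"]), 5e-7)
  expect_equal(unname(out["Tiso_years"]), 0.25 * 2e6)
  expect_equal(unname(out["O"]), 0.97)
  expect_equal(unname(to_demographic_units(
    c(nu1 = 1, t_sc = 0, O = 0.97), Nref = 2156641)["N1"]), 2156641)
})

test_that("refitting from a returned optimum is a fixed point", {
  m <- quick_sc_model()
  sim <- simulate_joint_sfs(m, 4, 4, n_loci = 4000, theta_locus = 0.4,
                            seed = 5)
  # a consistent engine configuration across stages makes the optimum a
  # fixed point of refitting
  fit <- fit_model(sim$sfs, "SC", n_starts = 2, seed = 11, maxit = 600,
                   pad = 8, pad_polish = 8)
  # determinism under an identical seed
  fit2 <- fit_model(sim$sfs, "SC", n_starts = 2, seed = 11, maxit = 600,
                    pad = 8, pad_polish = 8)
  expect_identical(fit$par, fit2$par)
  expect_identical(fit$loglik, fit2$loglik)
  # refitting never loses likelihood, and moves it only within the
  # asymptotic wiggle of restarted Nelder-Mead on this ridge (~1e-2),
  # far below the scale at which models are compared
  refit <- fit_model(sim$sfs, "SC", n_starts = 0, init = fit$par,
                     seed = 11, maxit = 600, pad = 8, pad_polish = 8)
  expect_gte(refit$loglik, fit$loglik - 1e-6)
  expect_lt(abs(refit$loglik - fit$loglik), 0.01)
})

test_that("bootstrap uncertainty has near-zero SD on identical replicates", {
  m <- quick_sc_model()
  sim <- simulate_joint_sfs(m, 4, 4, n_loci = 3000, theta_locus = 0.4,
                            seed = 6)
  fit <- fit_model(sim$sfs, "SC", n_starts = 2, seed = 3, maxit = 300,
                   pad = 6, pad_polish = 6)
  reps <- replicate(4, sim$sfs, simplify = FALSE)
  bu <- bootstrap_uncertainty("SC", reps, fit, maxit = 200, pad = 6,
                              pad_polish = 6)
  expect_true(all(bu$sd / pmax(abs(fit$par), 1e-6) < 0.05))
  expect_equal(bu$failed_fraction, 0)
})

test_that("star bands follow the published uncertainty coding", {
  expect_equal(popscape:::star_band(0.1, 1), "")
  expect_equal(popscape:::star_band(0.35, 1), "*")
  expect_equal(popscape:::star_band(1.0, 1), "**")
  expect_equal(popscape:::star_band(2.0, 1), "***")
})

test_that("simulated data under a model beats a misspecified neighbour", {
  m <- demographic_model("SC", c(nu1 = 1, nu2 = 3, M12 = 4, M21 = 1.5,
                                 t_iso = 0.4, t_sc = 0.2, O = 0.97))
  wrong <- demographic_model("SC", c(nu1 = 3, nu2 = 1, M12 = 0.5,
                                     M21 = 6, t_iso = 0.05, t_sc = 0.7,
                                     O = 0.97))
  wins <- 0
  for (r in 1:10) {
    sim <- simulate_joint_sfs(m, 4, 4, n_loci = 3000, theta_locus = 0.4,
                              seed = 300 + r)
    llT <- composite_loglik(sim$sfs, expected_sfs(m, 4, 4))
    llW <- composite_loglik(sim$sfs, expected_sfs(wrong, 4, 4))
    if (llT > llW) wins <- wins + 1
  }
  expect_gte(wins, 9)
})
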