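test_that("offset optimum has the closed form and peaks at zero discrepancy", {
  sol <- optimize_offset(3.2, 3.2, 0.4, 0.03)
  expect_equal(sol$q_star, 0)
  expect_equal(sol$eps_star, 0)
  expect_equal(sol$logp, dnorm(0, 0, 0.4, log = TRUE) +
                 dnorm(0, 0, 0.03, log = TRUE))

  # equal sigmas split the discrepancy evenly
  sol <- optimize_offset(2, 0, 1, 1)
  expect_equal(sol$q_star, 1)
  expect_equal(sol$eps_star, 1)

  # sigma_q = 0 pins the offset at zero
  sol <- optimize_offset(5, 3, 0, 0.5)
  expect_equal(sol$q_star, 0)
  expect_equal(sol$eps_star, 2)
  expect_equal(sol$logp, dnorm(2, 0, 0.5, log = TRUE))

  expect_error(optimize_offset(1, 0, 0.1, 0), "sigma_ex")

  # logp is maximal over ens_avg exactly at ens_avg = target
  avgs <- seq(-2, 2, by = 0.05)
  lp <- vapply(avgs, function(a) optimize_offset(0, a, 0.3, 0.7)$logp,
               numeric(1))
  expect_equal(avgs[which.max(lp)], 0)
})

test_that("offset optimum matches a numerical maximization oracle", {
  set.seed(101)
  for (i in 1:300) {
    target <- rnorm(1, 0, 5); avg <- rnorm(1, 0, 5)
    sq <- runif(1, 0.01, 3); se <- runif(1, 0.05, 3)
    sol <- optimize_offset(target, avg, sq, se)
    orc <- offset_oracle(target, avg, sq, se)
    expect_equal(sol$logp, orc$logp, tolerance = 1e-8)
    expect_equal(sol$q_star, orc$q, tolerance = 1e-5)
    # stationarity identity q* sigma_ex^2 = eps* sigma_q^2
    expect_lt(abs(sol$q_star * se^2 - sol$eps_star * sq^2), 1e-10)
  }
})

test_that("karplus optimum is exact at zero discrepancy and in limits", {
  kp <- uncertainty_config()$jc
  sol <- optimize_karplus(1, 1, 6.51 - 1.76 + 1.60, kp, 0.5)
  expect_equal(sol$A_star, 6.51)
  expect_equal(sol$B_star, -1.76)
  expect_equal(sol$C_star, 1.60)
  expect_equal(sol$eps_star, 0)

  # vanishing coefficient priors reduce to a fixed-Karplus residual
  kp0 <- utils::modifyList(kp, list(sigma_A = 1e-9, sigma_B = 1e-9,
                                    sigma_C = 1e-9))
  a1 <- 0.3; a2 <- 0.4; J <- 5.0
  sol <- optimize_karplus(a1, a2, J, kp0, 0.5)
  fixed_resid <- J - (kp$mu_A * a2 + kp$mu_B * a1 + kp$mu_C)
  expect_equal(sol$eps_star, fixed_resid, tolerance = 1e-6)
  quad <- sol$logp - (dnorm(0, 0, 1e-9, log = TRUE) * 3 +
                        dnorm(0, 0, 0.5, log = TRUE))
  expect_equal(quad, -fixed_resid^2 / (2 * 0.5^2), tolerance = 1e-6)

  expect_error(optimize_karplus(0.9, 0.5, 6, kp, 0.5), "Jensen")
  expect_error(optimize_karplus(1.5, 1, 6, kp, 0.5), "a1")

  # logp is maximal exactly where the prior-mean back-calculation hits J
  a1s <- seq(-1, 1, by = 0.02)
  lp <- vapply(a1s, function(a) {
    a2 <- a^2 + (1 - a^2) * 0.3
    optimize_karplus(a, a2, kp$mu_A * a2 + kp$mu_B * a + kp$mu_C, kp,
                     0.5)$logp
  }, numeric(1))
  expect_equal(max(lp), dnorm(0, 0, kp$sigma_A, log = TRUE) +
                 dnorm(0, 0, kp$sigma_B, log = TRUE) +
                 dnorm(0, 0, kp$sigma_C, log = TRUE) +
                 dnorm(0, 0, 0.5, log = TRUE))
})

test_that("karplus optimum matches a 3-D numerical oracle", {
  kp <- uncertainty_config()$jc
  set.seed(202)
  for (i in 1:200) {
    a1 <- runif(1, -1, 1)
    a2 <- runif(1, a1^2, 1)
    J <- runif(1, -2, 12)
    se <- runif(1, 0.1, 2)
    sol <- optimize_karplus(a1, a2, J, kp, se)
    orc <- karplus_oracle(a1, a2, J, kp, se)
    expect_equal(sol$logp, orc$logp, tolerance = 1e-6)
    # stationarity: the gradient of the four-Gaussian objective vanishes
    g <- c((sol$A_star - kp$mu_A) / kp$sigma_A^2 -
             sol$eps_star * a2 / se^2,
           (sol$B_star - kp$mu_B) / kp$sigma_B^2 -
             sol$eps_star * a1 / se^2,
           (sol$C_star - kp$mu_C) / kp$sigma_C^2 - sol$eps_star / se^2)
    expect_lt(max(abs(g)), 1e-10)
  }
})

test_that("r^-6 ensemble-averaged distances behave as the convention demands", {
  expect_equal(ensemble_average_distance(rep(7.3, 5)), 7.3)
  expect_equal(ensemble_average_distance(c(4, 8)),
               (0.5 * (4^-6 + 8^-6))^(-1 / 6))
  expect_equal(ensemble_average_distance(c(4, 8)), 4.478, tolerance = 1e-3)
  set.seed(5)
  d <- runif(20, 3, 30)
  avg <- ensemble_average_distance(d)
  expect_gt(avg, min(d)); expect_lt(avg, max(d))
  expect_lt(avg, mean(d))  # weighted toward the minimum
  expect_lt(ensemble_average_distance(c(d, min(d) * 0.5)), avg)
  expect_error(ensemble_average_distance(numeric(0)), "empty")
  expect_error(ensemble_average_distance(c(3, -1)), "> 0")
})

test_that("Shannon channel count is D_max (q_max - q_min) / pi", {
  expect_equal(shannon_channels(pi, 0, 3), 3)
  expect_equal(shannon_channels(0, 0, 1), 0)
  expect_equal(shannon_channels(60, 0.01, 0.30), 60 * 0.29 / pi)
  expect_equal(shannon_channels(60, 0.01, 0.30), 5.539, tolerance = 1e-3)
  expect_error(shannon_channels(60, 0.3, 0.3), "exceed")
})

test_that("type scores decompose into independent per-restraint optima", {
  study <- make_study(n_pool = 50L, types = c("CS", "NOE", "FRET"))
  members <- sample_subensemble(50L, 5L, seed = 77L)
  cfg <- study$ctx$cfg

  cs_rs <- study$exper$CS[1:3, ]
  tab <- backcalc_table(study$pool$values$CS[, 1:3], "CS", cs_rs)
  sc <- score_type(cs_rs, tab, members, cfg)
  by_hand <- sum(vapply(1:3, function(j)
    optimize_offset(cs_rs$target[j],
                    mean(study$pool$values$CS[members, j]),
                    cs_rs$sigma_q[j], cs_rs$sigma_exp[j])$logp, numeric(1)))
  expect_equal(sc$total, by_hand)

  # NOE uses the r^-6 ensemble average, not the arithmetic mean
  noe_rs <- study$exper$NOE
  ntab <- backcalc_table(study$pool$values$NOE, "NOE", noe_rs)
  nsc <- score_type(noe_rs, ntab, members, cfg)
  j <- 4L
  avg <- ensemble_average_distance(study$pool$values$NOE[members, j])
  expect_equal(nsc$per_restraint$logp[j],
               optimize_offset(noe_rs$target[j], avg, noe_rs$sigma_q[j],
                               noe_rs$sigma_exp[j])$logp)

  # FRET averages per-conformer efficiencies (fast-exchange regime)
  fr_rs <- study$exper$FRET
  ftab <- backcalc_table(study$pool$values$FRET, "FRET", fr_rs)
  fsc <- score_type(fr_rs, ftab, members, cfg)
  expect_equal(fsc$per_restraint$logp[1],
               optimize_offset(fr_rs$target[1],
                               mean(study$pool$values$FRET[members, 1]),
                               fr_rs$sigma_q[1], fr_rs$sigma_exp[1])$logp)

  # an ensemble of copies of one conformer averages to that conformer
  one <- rep(members[1], 10)
  sc1 <- score_type(cs_rs, tab, one, cfg)
  expect_equal(sc1$total, sum(vapply(1:3, function(j)
    optimize_offset(cs_rs$target[j], study$pool$values$CS[members[1], j],
                    cs_rs$sigma_q[j], cs_rs$sigma_exp[j])$logp, numeric(1))))
})

test_that("SAXS scoring applies the Shannon weight multiplicatively", {
  study <- make_study(n_pool = 40L, types = "SAXS")
  rs <- study$exper$SAXS
  tab <- backcalc_table(study$pool$values$SAXS, "SAXS", rs)
  members <- sample_subensemble(40L, 10L, seed = 3L)
  nq <- nrow(rs)

  cfg <- study$ctx$cfg
  cfg$saxs$ns_override <- nq
  unweighted <- score_saxs(rs, tab, members, cfg)
  expect_equal(unweighted$weight, 1)
  expect_equal(unweighted$total, sum(unweighted$per_restraint$logp))

  cfg$saxs$ns_override <- nq / 2
  half <- score_saxs(rs, tab, members, cfg)
  expect_equal(half$weight, 0.5)
  expect_equal(half$total, unweighted$total / 2)

  # default drkN-like grid: N_s ~ 3 against N_q = 37
  cfg <- study$ctx$cfg
  sc <- score_saxs(rs, tab, members, cfg)
  expect_equal(nq, 37L)
  expect_equal(sc$weight, 3 / 37, tolerance = 0.02)
  cfg_bad <- cfg
  cfg_bad$saxs$ns_override <- -1
  expect_error(score_type(study$exper$SAXS, tab, members, cfg_bad),
               "Shannon")

  # residual-only weighting keeps the normalization constants unscaled
  cfg$saxs$weight_mode <- "residual"
  res <- score_saxs(rs, tab, members, cfg)
  const <- sum(dnorm(0, 0, rs$sigma_q, log = TRUE) +
                 dnorm(0, 0, rs$sigma_exp, log = TRUE))
  expect_equal(res$total, const + sc$weight * (unweighted$total - const))
})

test_that("totals are additive over restraints and data types", {
  study <- make_study(n_pool = 80L)
  members <- sample_subensemble(80L, 20L, seed = 12L)
  scores <- lapply(names(study$exper), function(tp)
    score_type(study$exper[[tp]],
               backcalc_table(study$pool$values[[tp]], tp,
                              study$exper[[tp]]),
               members, study$ctx$cfg))
  tot <- total_score(scores)
  expect_equal(tot, sum(vapply(scores, `[[`, numeric(1), "total")))
  expect_identical(total_score(scores, character(0)), 0)
  expect_equal(total_score(scores, "JC"),
               scores[[which(names(study$exper) == "JC")]]$total)
  # removing a restraint changes the total by exactly its logp
  cs <- scores[[1]]
  rs_less <- study$exper$CS[-1, ]
  sc_less <- score_type(rs_less,
                        backcalc_table(study$pool$values$CS[, -1], "CS",
                                       rs_less),
                        members, study$ctx$cfg)
  expect_equal(cs$total - sc_less$total, cs$per_restraint$logp[1])
})
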