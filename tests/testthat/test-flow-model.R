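# constant-draw posterior for exactness checks
degenerate_flow_fit <- function(md, beta, sigma_u = 0, sigma_v = 0,
                                rho = 0, n_draws = 6) {
  design <- build_design(md)
  stopifnot(all(names(beta) %in% design$term_names))
  b <- setNames(numeric(length(design$term_names)), design$term_names)
  b[names(beta)] <- beta
  pn <- c(design$term_names, paste0("u[", design$dog_ids, "]"),
          paste0("v[", design$dog_ids, "]"), "sigma_u", "sigma_v", "rho")
  arr <- array(0, dim = c(2, n_draws, length(pn)),
               dimnames = list(NULL, NULL, pn))
  for (i in seq_along(b)) arr[, , i] <- b[i]
  arr[, , "sigma_u"] <- sigma_u; arr[, , "sigma_v"] <- sigma_v
  arr[, , "rho"] <- rho
  fit <- posterior_draws(arr)
  attr(fit, "design") <- design
  fit
}

test_that("build_design expands the full interaction structure", {
  md <- expand.grid(ig_class = c("IgA", "IgG"),
                    cohort = c("healthy", "DRE", "ARE", "IRE"),
                    stage = c("before", "after"),
                    stringsAsFactors = FALSE)
  md$dog_id <- paste0("d", seq_len(nrow(md)))
  des <- build_design(md)
  expect_equal(ncol(des$fixed), 16)   # 2 * 4 * 2 full-rank expansion
  # reference cell: healthy / IgA / before -> only the intercept is 1
  ref <- which(md$ig_class == "IgA" & md$cohort == "healthy" &
                 md$stage == "before")[1]
  expect_equal(unname(des$fixed[ref, ]), c(1, rep(0, 15)))
  expect_equal(des$ig, as.integer(md$ig_class == "IgG"))
  # single-level factor contributes no columns
  md2 <- md[md$stage == "before", ]
  expect_equal(ncol(build_design(md2)$fixed), 8)
  # stated reference missing from the data is rejected
  expect_error(build_design(md2, reference_levels = c(ig_class = "IgA",
                                                      cohort = "healthy",
                                                      stage = "remission")),
               "absent from the data")
})

test_that("fit_flow_model validates input and enforces >= 2 chains", {
  fx <- flow_fixture(n_dogs = 4, trials = 100)
  expect_error(fit_flow_model(fx$counts, chains = 1), "2 chains")
  bad <- fx$counts; bad$positive[1] <- bad$total[1] + 1
  expect_error(fit_flow_model(bad), "positive <= total")
  one_dog <- fx$counts[fx$counts$dog_id == fx$counts$dog_id[1], ]
  expect_error(fit_flow_model(one_dog, chains = 2, iter = 50, warmup = 50),
               "2 dogs")
})

test_that("fit_flow_model is seed-reproducible and recovers generating values", {
  fx <- flow_fixture(n_dogs = 25, seed = 7)
  fit <- fit_flow_model(fx$counts, chains = 2, iter = 600, warmup = 600,
                        seed = 5, check = FALSE)
  fit2 <- fit_flow_model(fx$counts, chains = 2, iter = 600, warmup = 600,
                         seed = 5, check = FALSE)
  expect_identical(fit$draws, fit2$draws)
  s <- posterior_summary(fit, interval_mass = 0.9,
                         params = c("(Intercept)", "ig_classIgG",
                                    "stageafter", "sigma_u"))
  # posterior medians within 3 posterior SDs of the generating values
  truth <- c(qlogis(0.28), 0.3, -0.2, 0.5)
  for (i in 1:4) {
    psd <- sd(pooled_draws(fit, s$parameter[i]))
    expect_lt(abs(s$median[i] - truth[i]), 3 * psd + 0.05)
  }
})

test_that("half data positive with zero variance concentrates the intercept at 0", {
  md <- expand.grid(dog_id = sprintf("d%d", 1:8),
                    ig_class = c("IgA", "IgG"), stage = c("before", "after"),
                    stringsAsFactors = FALSE)
  md$cohort <- "healthy"
  counts <- data.frame(md, positive = 5000, total = 10000)
  fit <- fit_flow_model(counts, chains = 2, iter = 400, warmup = 400,
                        seed = 2, check = FALSE)
  expect_lt(abs(median(pooled_draws(fit, "(Intercept)"))), 0.05)
})

test_that("predict_proportions: degenerate posterior, monotonicity, marginal mode", {
  md <- expand.grid(ig_class = c("IgA", "IgG"),
                    cohort = c("healthy", "DRE"),
                    stage = c("before", "after"), stringsAsFactors = FALSE)
  md$dog_id <- paste0("d", rep(1:4, 2))
  fit0 <- degenerate_flow_fit(md, beta = c("(Intercept)" = 0))
  pr <- predict_proportions(fit0, interval_mass = 0.9)
  expect_true(all(pr$median == 0.5))
  expect_true(all(pr$upper - pr$lower == 0))
  # adding a positive coefficient raises the predicted proportion
  fit1 <- degenerate_flow_fit(md, beta = c("(Intercept)" = 0,
                                           ig_classIgG = 1))
  pr1 <- predict_proportions(fit1)
  expect_true(all(pr1$median[pr1$ig_class == "IgG"] >
                  pr1$median[pr1$ig_class == "IgA"]))
  # marginalising over random effects pulls proportions toward 1/2
  fit2 <- degenerate_flow_fit(md, beta = c("(Intercept)" = 2), sigma_u = 1)
  pop <- predict_proportions(fit2, mode = "population")
  mar <- predict_proportions(fit2, mode = "marginal", n_mc = 4000, seed = 9)
  expect_true(all(mar$median < pop$median))
  expect_error(predict_proportions(fit2, grid = data.frame(ig_class = "IgM",
                                                           cohort = "healthy",
                                                           stage = "before")),
               "outside fitted")
})

test_that("glmm_r2 matches the Nakagawa plug-in and its degenerate identities", {
  md <- data.frame(ig_class = rep(c("IgA", "IgG"), 10),
                   cohort = "healthy", stage = "before",
                   dog_id = paste0("d", rep(1:10, each = 2)))
  # var(X beta) = 1 (balanced 0/2), sigma_u = 1: marginal 1/(2 + pi^2/3)
  fit <- degenerate_flow_fit(md, beta = c("(Intercept)" = 0,
                                          ig_classIgG = 2), sigma_u = 1)
  r2 <- glmm_r2(fit)
  expect_equal(unname(r2["marginal"]), 1 / (2 + pi^2 / 3), tolerance = 0.05)
  expect_equal(unname(r2["conditional"]), 2 / (2 + pi^2 / 3),
               tolerance = 0.05)
  # no random variance: marginal == conditional
  fit0 <- degenerate_flow_fit(md, beta = c("(Intercept)" = 0,
                                           ig_classIgG = 2))
  r20 <- glmm_r2(fit0)
  expect_equal(unname(r20["marginal"]), unname(r20["conditional"]))
  # null fixed effects beyond the intercept: marginal = 0
  fitn <- degenerate_flow_fit(md, beta = c("(Intercept)" = 1), sigma_u = 1)
  expect_equal(unname(glmm_r2(fitn)["marginal"]), 0)
})

test_that("posterior contracts as trials grow", {
  fx1 <- flow_fixture(n_dogs = 12, seed = 3, sigma_u = 0, sigma_v = 0,
                      trials = 500)
  fx2 <- flow_fixture(n_dogs = 12, seed = 3, sigma_u = 0, sigma_v = 0,
                      trials = 8000)
  f1 <- fit_flow_model(fx1$counts, chains = 2, iter = 500, warmup = 500,
                       seed = 4, check = FALSE)
  f2 <- fit_flow_model(fx2$counts, chains = 2, iter = 500, warmup = 500,
                       seed = 4, check = FALSE)
  expect_lt(sd(pooled_draws(f2, "(Intercept)")),
            sd(pooled_draws(f1, "(Intercept)")))
})

test_that("row order does not change posterior summaries beyond MCMC error", {
  fx <- flow_fixture(n_dogs = 15, seed = 10)
  fit <- fit_flow_model(fx$counts, chains = 2, iter = 600, warmup = 600,
                        seed = 6, check = FALSE)
  set.seed(1)
  perm <- sample(nrow(fx$counts))
  fitp <- fit_flow_model(fx$counts[perm, ], chains = 2, iter = 600,
                         warmup = 600, seed = 6, check = FALSE)
  expect_lt(abs(median(pooled_draws(fit, "(Intercept)")) -
                median(pooled_draws(fitp, "(Intercept)"))), 0.08)
  expect_lt(abs(median(pooled_draws(fit, "sigma_u")) -
                median(pooled_draws(fitp, "sigma_u"))), 0.08)
})
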