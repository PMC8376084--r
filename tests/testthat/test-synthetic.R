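test_that("simulate_cohort reproduces the study layout and rejects empty designs", {
  d <- simulate_cohort(11, 11, 8, 3, seed = 1)
  expect_equal(nrow(d$dogs), 33)
  expect_equal(as.vector(table(factor(d$dogs$cohort,
                                      c("healthy", "DRE", "ARE", "IRE")))),
               c(11, 11, 8, 3))
  md <- d$metadata[!d$metadata$is_control, ]
  # one diseased dog contributes only the "before" stage
  stages_per_dog <- tapply(md$stage, md$dog_id, function(s) length(unique(s)))
  expect_equal(sum(stages_per_dog == 1), 1)
  one_stage_dog <- names(stages_per_dog)[stages_per_dog == 1]
  expect_true(d$dogs$cohort[d$dogs$dog_id == one_stage_dog] != "healthy")
  # full crossing for a two-stage dog: 2 stages x 2 ig x 3 fractions x 2 reps
  two_stage <- names(stages_per_dog)[stages_per_dog == 2][1]
  expect_equal(sum(md$dog_id == two_stage), 2 * 2 * 3 * 2)
  expect_equal(sum(d$metadata$is_control), 10)

  d1 <- simulate_cohort(1, 0, 0, 0, seed = 1)
  expect_equal(d1$dogs$cohort, "healthy")
  expect_error(simulate_cohort(0, 0, 0, 0, seed = 1), "empty design")
  expect_error(simulate_cohort(-1, 0, 0, 0), "non-negative")
})

test_that("generators are deterministic given the seed", {
  d <- simulate_cohort(4, 3, 0, 0, seed = 5)
  p <- generator_params(taxa = c("A", "B"), depth_mean = 500,
                        beta_taxa = taxa_betas_from_proportions(
                          c(A = 0.2, B = 0.3)), seed = 11)
  expect_identical(simulate_cohort(4, 3, 0, 0, seed = 5), d)
  f1 <- simulate_flow_counts(d, p); f2 <- simulate_flow_counts(d, p)
  expect_identical(f1, f2)
  t1 <- simulate_fraction_counts(d, p)
  t2 <- simulate_fraction_counts(d, p)
  expect_identical(t1, t2)
  expect_identical(spike_contaminants(t1, d$metadata, p),
                   spike_contaminants(t2, d$metadata, p))
  p2 <- generator_params(taxa = c("A", "B"), depth_mean = 500,
                         beta_taxa = taxa_betas_from_proportions(
                           c(A = 0.2, B = 0.3)), seed = 12)
  expect_false(identical(simulate_flow_counts(d, p2), f1))
})

test_that("flow counts respect conservation and recover generating moments", {
  # null model: beta = 0, sigma = 0 -> every true p is 0.5
  d <- simulate_cohort(25, 0, 0, 0, seed = 2, drop_one_after = FALSE)
  p0 <- generator_params(beta_flow = c("(Intercept)" = 0),
                         sigma_dog_flow = 0, sigma_ig_dog = 0,
                         flow_trials = 1e4, seed = 3)
  fc <- simulate_flow_counts(d, p0)
  expect_true(all(fc$positive <= fc$total))
  expect_true(all(fc$true_p == 0.5))
  band <- 3.29 * sqrt(0.25 / (1e4 * nrow(fc)))  # 99.9% band on the mean
  expect_lt(abs(mean(fc$positive / fc$total) - 0.5), band)

  # intercept logit(0.28), sigma = 0, trials 1e5: mean within 3 MC SEs
  p1 <- generator_params(beta_flow = c("(Intercept)" = qlogis(0.28)),
                         sigma_dog_flow = 0, sigma_ig_dog = 0,
                         flow_trials = 1e5, seed = 4)
  fc1 <- simulate_flow_counts(d, p1)
  se <- sqrt(0.28 * 0.72 / (1e5 * nrow(fc1)))
  expect_lt(abs(mean(fc1$positive / fc1$total) - 0.28), 3 * se)

  # sigma_dog = 1, beta = 0, 200 dogs: SD of per-dog logit proportion ~ 1
  d2 <- simulate_cohort(200, 0, 0, 0, seed = 6, drop_one_after = FALSE)
  p2 <- generator_params(beta_flow = c("(Intercept)" = 0),
                         sigma_dog_flow = 1, sigma_ig_dog = 0,
                         flow_trials = 1e4, seed = 7)
  fc2 <- simulate_flow_counts(d2, p2)
  per_dog <- tapply(qlogis(fc2$positive / fc2$total), fc2$dog_id, mean)
  expect_lt(abs(sd(per_dog) - 1), 0.15)
})

test_that("fraction counts: conservation, symmetric null, truth record", {
  d <- simulate_cohort(6, 0, 0, 0, seed = 2, drop_one_after = FALSE)
  # symmetric null: all four categories equiprobable
  p0 <- generator_params(taxa = c("A", "B", "C"),
                         beta_taxa = matrix(0, 1, 3,
                           dimnames = list("(Intercept)", NULL)),
                         sigma_dog_taxa = 0, depth_mean = 5000, seed = 3)
  tab <- simulate_fraction_counts(d, p0)
  expect_equal(rownames(tab), c("A", "B", "C", "other"))
  rel <- rowSums(tab) / sum(tab)
  expect_true(all(abs(rel - 0.25) < 0.01))
  tr <- attr(tab, "truth")
  expect_true(all(abs(as.matrix(tr$enrichment[, c("A", "B", "C", "other")]) - 1)
                  < 1e-12))

  # constructed enrichment: 0.30 in ig_pos vs 0.10 in presort -> ratio 3
  bt <- taxa_betas_from_proportions(presort = c(A = 0.10, B = 0.25),
                                    bound = c(A = 0.30, B = 0.25))
  p1 <- generator_params(taxa = c("A", "B"), beta_taxa = bt,
                         sigma_dog_taxa = 0.5, depth_mean = 14000, seed = 4)
  tab1 <- simulate_fraction_counts(d, p1)
  tr1 <- attr(tab1, "truth")
  expect_equal(unique(tr1$enrichment$A), 3, tolerance = 1e-12)
  expect_equal(unique(tr1$enrichment$B), 1, tolerance = 1e-12)
  # conservation: column sums equal the recorded depths
  expect_equal(unname(colSums(tab1)), unname(tr1$depths))
  # realized depth close to the Poisson mean (3% at ~140 samples)
  expect_lt(abs(mean(colSums(tab1)) / 14000 - 1), 0.03)
})

test_that("spike_contaminants separates controls, leaks at the stated rate", {
  d <- simulate_cohort(5, 0, 0, 0, seed = 8, n_negative_controls = 10,
                       drop_one_after = FALSE)
  base <- generator_params(taxa = c("A", "B"),
                           beta_taxa = taxa_betas_from_proportions(
                             c(A = 0.3, B = 0.3)),
                           depth_mean = 2000, seed = 9)

  # zero leak: true samples unchanged, controls pure contaminant
  p0 <- within_params(base, contaminant_load = 0)
  tab <- simulate_fraction_counts(d, p0)
  sp <- spike_contaminants(tab, d$metadata, p0)
  real <- d$metadata$sample_id[!d$metadata$is_control]
  ctrl <- d$metadata$sample_id[d$metadata$is_control]
  expect_equal(unclass(sp)[rownames(tab), real], unclass(tab)[, real])
  expect_true(all(sp[p0$contaminant_taxa, ctrl] > 0 |
                  colSums(sp[p0$contaminant_taxa, ctrl, drop = FALSE]) > 0))
  expect_true(all(sp[rownames(tab), ctrl] == 0))
  expect_true(all(sp[p0$contaminant_taxa, real] == 0))

  # positive load: 100% prevalence in controls, partial in samples
  p5 <- within_params(base, contaminant_load = 0.05)
  sp5 <- spike_contaminants(simulate_fraction_counts(d, p5), d$metadata, p5)
  prev_ctrl <- mean(colSums(sp5[p5$contaminant_taxa, ctrl, drop = FALSE]) > 0)
  expect_equal(prev_ctrl, 1)
  expect_error(spike_contaminants(sp5, d$metadata, p5),
               "already present")

  # run-specific contaminants stay in their run's columns
  pr <- within_params(base, contaminant_load = 0.05,
                      contaminant_runs = c(contam_sheath = "run1",
                                           contam_buffer = "run2"))
  spr <- spike_contaminants(simulate_fraction_counts(d, pr), d$metadata, pr)
  md <- d$metadata
  run2_cols <- md$sample_id[md$run == "run2"]
  run1_cols <- md$sample_id[md$run == "run1"]
  expect_true(all(spr["contam_sheath", run2_cols] == 0))
  expect_true(all(spr["contam_buffer", run1_cols] == 0))
  expect_true(any(spr["contam_sheath",
                      intersect(run1_cols, ctrl)] > 0))
})

test_that("generator parameter validation is strict", {
  expect_error(generator_params(contaminant_load = 1), "contaminant_load")
  expect_error(generator_params(sigma_dog_flow = -1))
  expect_error(generator_params(taxa = c("A", "B"),
                                beta_taxa = matrix(0, 1, 3)),
               "one column per taxon")
  d <- simulate_cohort(2, 0, 0, 0, seed = 1)
  p <- generator_params(beta_flow = c(nonsense_term = 1))
  expect_error(simulate_flow_counts(d, p), "unknown coefficient")
})
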