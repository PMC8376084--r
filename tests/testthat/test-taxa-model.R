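# simulate a single-Ig sorted study and return the merged per-fraction table
taxa_fixture <- function(n_dogs = 30, presort, bound, sigma = 0.5,
                         depth = 10000, seed = 1) {
  design <- simulate_cohort(n_dogs, 0, 0, 0, seed = seed,
                            replicates_per_sample = 1, n_runs = 1,
                            n_negative_controls = 0, drop_one_after = FALSE)
  params <- generator_params(
    taxa = names(presort),
    beta_taxa = taxa_betas_from_proportions(presort, bound),
    sigma_dog_taxa = sigma, depth_mean = depth, seed = seed)
  tab <- simulate_fraction_counts(design, params)
  md <- design$metadata
  keep <- md$sample_id[!md$is_control & md$ig_class == "IgA"]
  sub <- feature_table(unclass(tab)[, keep, drop = FALSE])
  list(table = sub, metadata = md, truth = attr(tab, "truth"),
       design = design)
}

test_that("fit_taxa_model validates its inputs", {
  fx <- taxa_fixture(4, presort = c(A = 0.2, B = 0.2),
                     bound = c(A = 0.2, B = 0.2), depth = 500, seed = 2)
  tab_noother <- feature_table(unclass(fx$table)[1:2, , drop = FALSE])
  expect_error(fit_taxa_model(tab_noother, fx$metadata), "'other'")
  expect_error(fit_taxa_model(fx$table, fx$metadata, chains = 1), "2 chains")
})

test_that("predicted proportions are a proper composition and flat at beta = 0", {
  fit <- degenerate_taxa_fit(p_pre = 0.5, p_pos = 0.5)
  # beta0 = 0 here: both categories equiprobable
  p <- predict_taxon_proportions(fit, list(fraction = "presort"))
  expect_true(all(abs(p - 0.5) < 1e-12))
  fit2 <- degenerate_taxa_fit(p_pre = 0.1, p_pos = 0.3)
  p2 <- predict_taxon_proportions(fit2, list(fraction = "ig_pos"))
  expect_true(all(abs(rowSums(p2) - 1) < 1e-12))
  expect_equal(unname(p2[1, "A"]), 0.3, tolerance = 1e-12)
  # subject mode shifts by that dog's random effect through the softmax
  p3 <- predict_taxon_proportions(fit2, list(fraction = "ig_pos"),
                                  mode = "subject", dog = "d1")
  expect_equal(p3, p2)   # u draws are zero in the degenerate fit
  expect_error(predict_taxon_proportions(fit2, list(fraction = "ig_pos"),
                                         mode = "subject", dog = "nope"),
               "dog id")
})

test_that("enrichment_ratio is exact on degenerate posteriors", {
  fit <- degenerate_taxa_fit(p_pre = 0.1, p_pos = 0.3)
  enr <- enrichment_ratio(fit, list(fraction = "ig_pos"),
                          list(fraction = "presort"))
  a <- enr[enr$taxon == "A", ]
  expect_equal(a$ratio_median, 3, tolerance = 1e-12)
  expect_equal(a$hi90 - a$lo90, 0)
  expect_equal(a$lo50, 3, tolerance = 1e-12)
  # interval nesting invariant
  expect_true(all(enr$lo90 <= enr$lo50 & enr$hi50 <= enr$hi90))
  # bound == baseline: ratio identically 1
  same <- enrichment_ratio(fit, list(fraction = "ig_pos"),
                           list(fraction = "ig_pos"))
  expect_true(all(same$ratio_median == 1 & same$lo90 == 1 & same$hi90 == 1))
})

test_that("taxa model recovers a +1 log-odds bound effect", {
  presort <- c(A = 0.15, B = 0.25, C = 0.20)
  # raise taxon A's baseline-category log-odds by 1 in the bound fraction
  bt <- taxa_betas_from_proportions(presort, presort)
  bt["fractionig_pos", "A"] <- 1
  design <- simulate_cohort(30, 0, 0, 0, seed = 3, replicates_per_sample = 1,
                            n_runs = 1, n_negative_controls = 0,
                            drop_one_after = FALSE)
  params <- generator_params(taxa = names(presort), beta_taxa = bt,
                             sigma_dog_taxa = 0.5, depth_mean = 10000,
                             seed = 3)
  tab <- simulate_fraction_counts(design, params)
  md <- design$metadata
  keep <- md$sample_id[!md$is_control & md$ig_class == "IgA"]
  sub <- feature_table(unclass(tab)[, keep, drop = FALSE])
  fit <- fit_taxa_model(sub, md, chains = 2, iter = 600, warmup = 600,
                        seed = 4, check = FALSE)
  est <- median(pooled_draws(fit, "b[fractionig_pos|A]"))
  expect_gte(est, 0.6)
  expect_lte(est, 1.4)
})

test_that("relabeling taxa permutes enrichment output without changing values", {
  fx <- taxa_fixture(8, presort = c(A = 0.10, B = 0.25, C = 0.20),
                     bound = c(A = 0.30, B = 0.25, C = 0.20),
                     depth = 4000, seed = 5)
  perm <- c(2, 3, 1)
  tab_perm <- feature_table(unclass(fx$table)[c(perm, 4), , drop = FALSE])
  fit1 <- fit_taxa_model(fx$table, fx$metadata, chains = 2, iter = 300,
                         warmup = 300, seed = 6, check = FALSE)
  fit2 <- fit_taxa_model(tab_perm, fx$metadata, chains = 2, iter = 300,
                         warmup = 300, seed = 6, check = FALSE)
  e1 <- enrichment_ratio(fit1, list(fraction = "ig_pos", stage = "before"),
                         list(fraction = "presort", stage = "before"))
  e2 <- enrichment_ratio(fit2, list(fraction = "ig_pos", stage = "before"),
                         list(fraction = "presort", stage = "before"))
  # same posterior per taxon up to MCMC noise; here compare medians loosely
  m1 <- setNames(e1$ratio_median, e1$taxon)
  m2 <- setNames(e2$ratio_median, e2$taxon)
  for (tx in c("A", "B", "C"))
    expect_lt(abs(log(m1[[tx]] / m2[[tx]])), 0.25)
})

test_that("raw_palm_index matches hand arithmetic and the pseudocount limit", {
  ids <- c("p1", "p2", "b1", "b2")
  md <- toy_metadata(ids, dog_id = c("d1", "d2", "d1", "d2"),
                     fraction = c("presort", "presort", "ig_pos", "ig_pos"))
  m <- rbind(A = c(10, 10, 30, 30), B = c(60, 60, 40, 40),
             C = c(30, 30, 30, 30), D = c(0, 0, 0, 0))
  tab <- toy_table(m, features = rownames(m), samples = ids)
  out <- raw_palm_index(tab, md, pseudocount = 1e-9)
  r <- setNames(out$raw_ratio, out$taxon)
  expect_equal(unname(r["A"]), 3, tolerance = 1e-6)
  expect_equal(unname(r["C"]), 1, tolerance = 1e-6)
  expect_equal(unname(r["D"]), 1)     # absent in both: psi / psi
  expect_error(raw_palm_index(tab, md[md$fraction == "presort", ]),
               "appear in metadata")
})

test_that("raw index and posterior ratio agree on large weak-noise data", {
  fx <- taxa_fixture(20, presort = c(A = 0.10, B = 0.25, C = 0.20),
                     bound = c(A = 0.30, B = 0.25, C = 0.20),
                     sigma = 0.1, depth = 10000, seed = 8)
  fit <- fit_taxa_model(fx$table, fx$metadata, chains = 2, iter = 400,
                        warmup = 400, seed = 9, check = FALSE)
  enr <- enrichment_ratio(fit, list(fraction = "ig_pos", stage = "before"),
                          list(fraction = "presort", stage = "before"))
  md <- fx$metadata[fx$metadata$sample_id %in% colnames(fx$table), ]
  raw <- raw_palm_index(fx$table, md, pseudocount = 1e-6,
                        group_by = c("ig_class", "cohort", "stage"))
  raw_before <- raw[raw$stage == "before", ]
  for (tx in c("A", "B", "C")) {
    r_model <- enr$ratio_median[enr$taxon == tx]
    r_raw <- raw_before$raw_ratio[raw_before$taxon == tx]
    expect_lt(abs(log(r_model / r_raw)), log(1.2))
  }
})
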