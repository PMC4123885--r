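test_that("1-D threshold fitting splits separable groups at the gap centre", {
  expect_equal(fit_threshold(c(1, 2, 3), c(7, 8, 9)), 5)
  # overlapping groups: minimal training error
  thr <- fit_threshold(c(1, 2, 3, 6), c(4, 5, 7, 8))
  err <- sum(c(1, 2, 3, 6) >= thr) + sum(c(4, 5, 7, 8) < thr)
  expect_equal(err, 1)
})

test_that("workflow on separable guilds is perfect and recovers the gaps", {
  set <- generate_specimens(separable_config(seed = 4))
  model <- fit_workflow(set)
  ev <- evaluate_workflow(model, set)
  expect_equal(ev$percent_correct, 100)
  expect_equal(unname(ev$per_group_recall), rep(1, 5))
  # fitted thresholds sit inside the generating gaps
  agg <- add_scs(aggregate_observations(set))
  expect_gt(model$scs_carnivore_cutoff,
            max(agg$scs[agg$guild == "carnivore"]))
  expect_lt(model$scs_carnivore_cutoff,
            min(agg$scs[agg$guild %in% c("grazer", "browser", "hard_object") &
                          agg$body_mass_g >= 500]))
  expect_gt(model$bm_insectivore_ceiling,
            max(agg$body_mass_g[agg$guild == "insectivore"]))
  # confusion matrix row sums equal true guild counts
  expect_equal(unname(rowSums(ev$confusion_matrix)),
               unname(as.vector(table(factor(guild_of_specimens(set),
                                             levels = GUILDS)))))
})

test_that("threshold overrides pass through unchanged", {
  set <- generate_specimens(separable_config(seed = 4))
  model <- fit_workflow(set, bm_herbivore_floor = 1000,
                        scs_carnivore_cutoff = 1.23)
  expect_equal(model$bm_herbivore_floor, 1000)
  expect_equal(model$scs_carnivore_cutoff, 1.23)
})

test_that("decision traces are deterministic and end at the assigned guild", {
  set <- generate_specimens(default_config(seed = 8, n_species = 4,
                                           individuals_per_species = 3))
  model <- fit_workflow(set)
  one <- set[set$specimen_id == set$specimen_id[1], ]
  a1 <- classify_specimen(model, one)
  a2 <- classify_specimen(model, one)
  expect_identical(a1$guild, a2$guild)
  expect_identical(a1$trace, a2$trace)
  expect_gt(nrow(a1$trace), 0)
  expect_equal(a1$trace$branch[nrow(a1$trace)], a1$guild)
})

test_that("branches route on the stated comparisons", {
  set <- generate_specimens(separable_config(seed = 2))
  model <- fit_workflow(set)
  proto <- add_scs(aggregate_observations(set))[1, ]

  # large herbivore with grazer-like wear -> grazer via the herbivore LDA
  big <- proto
  big$body_mass_g <- 3e5
  big[c("length_mm", "width_mm", "crest_mm")] <- c(20, 16, 55)
  big[MICROWEAR_FEATURES] <- c(40, 30, 4, 1)
  big$scs <- NULL
  a <- classify_specimen(model, add_scs(big))
  expect_equal(a$guild, "grazer")
  expect_true("herbivore" %in% a$trace$branch)

  # large animal, SCS below cutoff -> carnivore with a 2-step trace, no LDA
  carn <- proto
  carn$body_mass_g <- 1e5
  carn[c("length_mm", "width_mm", "crest_mm")] <- c(10, 8, 4)
  carn$scs <- NULL
  a <- classify_specimen(model, add_scs(carn))
  expect_equal(a$guild, "carnivore")
  expect_equal(nrow(a$trace), 2)
  expect_null(a$posterior)

  # tiny animal -> small-body stage
  small <- proto
  small$body_mass_g <- 50
  small[MICROWEAR_FEATURES] <- c(30, 30, 30, 30)
  a <- classify_specimen(model, small)
  expect_equal(a$trace$branch[1], "small_body")
  expect_equal(a$guild, "insectivore")
})

test_that("missing modalities raise errors naming the modality", {
  set <- generate_specimens(separable_config(seed = 2))
  model <- fit_workflow(set)
  proto <- add_scs(aggregate_observations(set))[1, ]

  no_bm <- proto
  no_bm$body_mass_g <- NA_real_
  expect_error(classify_specimen(model, no_bm), "body_mass")

  no_scs <- proto
  no_scs$body_mass_g <- 1e5
  no_scs$scs <- NA_real_
  expect_error(classify_specimen(model, no_scs), "scs")

  no_mw <- proto
  no_mw$body_mass_g <- 50
  no_mw[MICROWEAR_FEATURES] <- NA_real_
  expect_error(classify_specimen(model, no_mw), "microwear")

  # training with a missing guild fails up front
  drop_carn <- set[guild_of_specimens(set)[set$specimen_id] != "carnivore", ]
  expect_error(fit_workflow(drop_carn), "carnivore")
})

test_that("raising the SCS cutoff only moves herbivores toward carnivore", {
  set <- generate_specimens(default_config(seed = 3, n_species = 6,
                                           individuals_per_species = 3))
  model_lo <- fit_workflow(set)
  model_hi <- model_lo
  model_hi$scs_carnivore_cutoff <- model_lo$scs_carnivore_cutoff + 0.8
  agg <- add_scs(aggregate_observations(set))
  for (i in seq_len(nrow(agg))) {
    lo <- classify_specimen(model_lo, agg[i, ])$guild
    hi <- classify_specimen(model_hi, agg[i, ])$guild
    if (lo != hi) expect_equal(hi, "carnivore")
    if (lo == "carnivore") expect_equal(hi, "carnivore")
  }
})

test_that("the ambiguity flag marks close insectivore/hard-object calls", {
  set <- generate_specimens(default_config(seed = 6, n_species = 8,
                                           individuals_per_species = 4))
  model <- fit_workflow(set)
  agg <- add_scs(aggregate_observations(set))
  small <- agg[agg$body_mass_g < model$bm_insectivore_ceiling, ]
  flags <- vapply(seq_len(nrow(small)), function(i) {
    a <- classify_specimen(model, small[i, ])
    gap <- abs(a$posterior[["insectivore"]] - a$posterior[["hard_object"]])
    identical(a$ambiguous, gap < model$ambiguity_margin)
  }, logical(1))
  expect_true(all(flags))
})

test_that("evaluation demands labels and reports conserved counts", {
  set <- generate_specimens(default_config(seed = 9, n_species = 4,
                                           individuals_per_species = 3))
  model <- fit_workflow(set)
  unlabeled <- set
  unlabeled$guild[unlabeled$specimen_id == unlabeled$specimen_id[1]] <- NA
  expect_error(evaluate_workflow(model, unlabeled), "unlabeled")
  ev <- evaluate_workflow(model, set)
  expect_equal(sum(ev$confusion_matrix), length(unique(set$specimen_id)))
  expect_equal(ev$percent_correct,
               100 * sum(diag(ev$confusion_matrix)) /
                 sum(ev$confusion_matrix))
})

test_that("leave-one-out workflow evaluation refits per fold and stays sane", {
  set <- generate_specimens(separable_config(seed = 5))
  rep_loo <- workflow_loo(set)
  expect_equal(rep_loo$percent_correct, 100)
})
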