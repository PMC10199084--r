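test_that("the energy cutoff is strict and records elimination reasons", {
  t1 <- load_fixture("table1")
  analogs <- t1[t1$role == "analog", ]
  res <- apply_energy_cutoff(analogs, cutoff = -8.0)
  expect_equal(nrow(res$survivors), 7) # A1-A7 all strictly below -8.00
  expect_equal(sort(res$survivors$compound_id), paste0("A", 1:7))

  # a compound at exactly the cutoff is eliminated, one just below survives
  edge <- data.frame(compound_id = c("at", "below"),
                     binding_energy = c(-8.00, -8.10))
  res <- apply_energy_cutoff(edge, -8.0)
  expect_equal(res$survivors$compound_id, "below")
  expect_match(res$eliminations$reason, "not <")

  expect_equal(nrow(apply_energy_cutoff(edge[0, ], -8)$survivors), 0)
  expect_equal(nrow(apply_energy_cutoff(edge, -100)$survivors), 0)
})

test_that("the rule stage eliminates exactly the rule failures", {
  prof <- table3_profiles()
  outcomes <- screen_rules(prof)
  res <- apply_rule_stage(prof$compound_id, outcomes, c("lipinski", "pfizer"))
  expect_setequal(res$eliminations$compound_id, c("Rofecoxib", "A5"))
  expect_match(res$eliminations$reason[res$eliminations$compound_id == "A5"],
               "pfizer")
  # empty requirement set keeps everyone
  all_pass <- apply_rule_stage(prof$compound_id, outcomes, character(0))
  expect_equal(all_pass$survivors, prof$compound_id)
  # a missing outcome is a contract error
  expect_error(apply_rule_stage("ghost", outcomes, "lipinski"),
               "no outcome")
})

test_that("the metric stage eliminates threshold failures with named reasons", {
  reports <- evaluate_metrics(paper_metric_inputs())
  res <- apply_metric_stage(reports$compound_id, reports)
  expect_setequal(res$eliminations$compound_id, c("A5", "Rofecoxib", "Aspirin"))
  expect_match(res$eliminations$reason[res$eliminations$compound_id == "A5"],
               "LELP 10\\.4.* outside \\[-10, 10\\]")
  expect_error(apply_metric_stage("ghost", reports), "no efficiency report")
})

test_that("single-criterion consensus reproduces the published rescoring order", {
  # MM/GBSA-style scores encoding the published affinity order
  # (most negative binding free energy first)
  mmgbsa <- tibble::tibble(
    compound_id = c("A3", "A1", "A5", "Rofecoxib", "A2", "A4", "A6", "A7",
                    "AGP", "Aspirin"),
    mmgbsa = c(-55.37, -52, -50, -48, -46, -44, -42, -40, -38, -20))
  cfg <- consensus_config(data.frame(metric = "mmgbsa", direction = "lower",
                                     weight = 1))
  rk <- consensus_rank(mmgbsa[sample(10), ], cfg)
  expect_equal(rk$compound_id,
               c("A3", "A1", "A5", "Rofecoxib", "A2", "A4", "A6", "A7",
                 "AGP", "Aspirin"))
  expect_equal(rk$final_rank, 1:10)
})

test_that("consensus ranking is tie-aware with deterministic id tie-breaking", {
  one <- consensus_rank(tibble::tibble(compound_id = "only", x = 1),
                        consensus_config(data.frame(metric = "x",
                                                    direction = "lower",
                                                    weight = 1)))
  expect_equal(one$final_rank, 1)

  # two perfectly anti-correlated criteria with equal weights: every
  # aggregate ties, order falls back to the id
  anti <- tibble::tibble(compound_id = c("b", "a"), up = c(1, 2), down = c(2, 1))
  cfg <- consensus_config(data.frame(metric = c("up", "down"),
                                     direction = c("lower", "lower"),
                                     weight = c(1, 1)))
  rk <- consensus_rank(anti, cfg)
  expect_equal(rk$aggregate, c(1.5, 1.5))
  expect_equal(rk$compound_id, c("a", "b"))
  expect_equal(rk$final_rank, c(1.5, 1.5))

  expect_error(consensus_rank(tibble::tibble(compound_id = "x", y = 1),
                              consensus_config(data.frame(metric = "z",
                                                          direction = "lower",
                                                          weight = 1))),
               "missing column")
})

test_that("the full funnel on the reference tables reproduces the staged narrative", {
  t1 <- load_fixture("table1")
  prof <- table3_profiles()
  res <- run_funnel(t1, prof)
  ledger <- res$ledger
  # dock stage keeps A1-A7 and rofecoxib; rules remove A5 and rofecoxib
  expect_setequal(ledger$docking_cutoff$surviving,
                  c(paste0("A", 1:7), "Rofecoxib"))
  expect_setequal(ledger$rules$eliminations$compound_id, c("A5", "Rofecoxib"))
  expect_setequal(res$survivors, c("A1", "A2", "A3", "A4", "A6", "A7"))
  # default consensus (binding energy, lower better) puts A1 first
  expect_equal(res$ranking$compound_id[1], "A1")
  # join failure names the orphan
  expect_error(run_funnel(t1, prof[prof$compound_id != "A3", ]), "A3")
})

test_that("ledger conservation holds at every stage and survivors ignore row order", {
  lib <- generate_library(library_spec(n_compounds = 120, seed = 42))
  res <- run_funnel(lib$scores, lib$profiles)
  for (stage in res$ledger) {
    expect_equal(length(stage$entering),
                 length(stage$surviving) + nrow(stage$eliminations))
    expect_length(intersect(stage$surviving, stage$eliminations$compound_id), 0)
  }
  # chaining: survivors of stage k enter stage k+1
  expect_equal(res$ledger$rules$entering, res$ledger$docking_cutoff$surviving)
  expect_equal(res$ledger$metrics$entering, res$ledger$rules$surviving)

  shuffled_scores <- lib$scores[sample(nrow(lib$scores)), ]
  res2 <- run_funnel(shuffled_scores, lib$profiles)
  expect_setequal(res2$survivors, res$survivors)
})

test_that("relaxing the cutoff or thresholds never shrinks the survivor set", {
  lib <- generate_library(library_spec(n_compounds = 150, seed = 7))
  strict <- run_funnel(lib$scores, lib$profiles,
                       funnel_config(dock_cutoff = -8.0))
  relaxed <- run_funnel(lib$scores, lib$profiles,
                        funnel_config(dock_cutoff = -7.5))
  expect_true(all(strict$survivors %in% relaxed$survivors))

  loose_thresholds <- funnel_config(metric_thresholds = metric_thresholds(
    le_min = 0.2, lle_min = 2, fq_min = 0.5, lelp_range = c(-20, 20)))
  loose <- run_funnel(lib$scores, lib$profiles, loose_thresholds)
  expect_true(all(strict$survivors %in% loose$survivors))
})

test_that("an empty library flows through as empty stages and ranking", {
  empty_scores <- tibble::tibble(compound_id = character(0),
                                 binding_energy = numeric(0))
  empty_prof <- tibble::tibble(compound_id = character(0), mw = numeric(0),
                               heavy_atoms = numeric(0), n_hba = numeric(0),
                               n_hbd = numeric(0), tpsa = numeric(0),
                               logp = numeric(0))
  res <- run_funnel(empty_scores, empty_prof)
  expect_length(res$survivors, 0)
  expect_equal(nrow(res$ranking), 0)
})
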