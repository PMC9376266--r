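test_that("presentation sequences are seeded permutations", {
  d <- disjoint_dataset(10, 4)
  s1 <- generate_sequence(d, 42)
  expect_setequal(s1, 1:10)
  expect_identical(s1, generate_sequence(d, 42))
  expect_false(identical(s1, generate_sequence(d, 43)))
  expect_equal(generate_sequence(disjoint_dataset(1, 2), 1), 1L)
})

test_that("evaluation runs t * C trials per step and never touches weights", {
  d <- generate_synthetic(ehos_like_spec(seed = 2, i_tot = 12))
  net <- init_network(d$schema)
  seqn <- generate_sequence(d, 3)
  for (t in 1:3) net <- associate(net, d$memories[seqn[t], ])
  cb <- enumerate_combos(8, 4, dataset_u_factors(d))
  log <- metrics_log(d, cb, seqn)
  W_before <- net$W
  set.seed(9)
  evaluate_step(net, d, seqn, t = 3, cb, log)
  expect_identical(net$W, W_before)              # read-only contract
  expect_true(all(log$trials[3, ] == 3L))        # t trials per combo
  expect_equal(sum(log$trials[3, ]), 3L * 70L)
  expect_true(all(log$hits[3, ] <= log$trials[3, ]))
})

test_that("batched evaluation equals the trial-by-trial reference exactly", {
  set.seed(77)
  for (seed in 1:4) {
    d <- generate_synthetic(ehos_like_spec(seed = seed, i_tot = 8))
    cfg <- function(b) simulation_config(seed_sequence = seed, seed_ties = seed + 100)
    rb <- run_simulation(d, cfg(), batched = TRUE)
    rr <- run_simulation(d, cfg(), batched = FALSE)
    expect_identical(rb$metrics$hits, rr$metrics$hits)
    expect_identical(rb$metrics$trials, rr$metrics$trials)
    expect_identical(rb$metrics$occurrences, rr$metrics$occurrences)
    expect_identical(rb$metrics$umr, rr$metrics$umr)
    expect_identical(rb$network$W, rr$network$W)
  }
})

test_that("full determinism given the two seeds", {
  d <- generate_synthetic(ehos_like_spec(seed = 1, i_tot = 10))
  cfg <- simulation_config(seed_sequence = 4, seed_ties = 5)
  r1 <- run_simulation(d, cfg)
  r2 <- run_simulation(d, cfg)
  expect_identical(r1$metrics$hits, r2$metrics$hits)
  expect_identical(r1$metrics$umr, r2$metrics$umr)
  expect_identical(r1$sequence, r2$sequence)
  # changing behaviors must not perturb the memory order
  cfg2 <- simulation_config(seed_sequence = 4, seed_ties = 5,
                            behaviors = behavior_config(forgetting = TRUE,
                                                        d_rate = 0.05))
  expect_identical(run_simulation(d, cfg2)$sequence, r1$sequence)
})

test_that("feature-disjoint memories are interference-free: all hits, UMR 1", {
  d <- disjoint_dataset(6, 8)
  res <- run_simulation(d, simulation_config(seed_sequence = 2, seed_ties = 3))
  expect_true(all(res$metrics$hits == res$metrics$trials))
  expect_equal(res$metrics$umr, rep(1, 6))
})

test_that("eval_every thins evaluation without changing evaluated steps", {
  d <- disjoint_dataset(6, 4)
  res <- run_simulation(d, simulation_config(k_input = 2, eval_every = 3,
                                             seed_sequence = 2, seed_ties = 3))
  evaluated <- which(!is.na(res$metrics$umr))
  expect_equal(evaluated, c(3L, 6L))
  expect_true(all(res$metrics$trials[c(3, 6), ] == c(3L, 6L)))
})

test_that("simulation manifest echoes everything needed to reproduce", {
  d <- disjoint_dataset(3, 4)
  res <- run_simulation(d, simulation_config(k_input = 2,
                                             seed_sequence = 10, seed_ties = 11))
  mf <- res$manifest
  expect_equal(mf$I_tot, 3L)
  expect_equal(mf$k_input, 2L)
  expect_equal(mf$seed_sequence, 10L)
  expect_identical(mf$sequence, res$sequence)
  expect_false(mf$behaviors$predictive)
})

test_that("the CLI drives synth, run and metrics end to end", {
  dir <- withr::local_tempdir()
  spec_path <- file.path(dir, "spec.json")
  jsonlite::write_json(
    list(n_sets = 4, i_tot = 12, target_m = c(12, 4, 2, 12), seed = 7),
    spec_path, auto_unbox = TRUE)
  csv_path <- file.path(dir, "synth.csv")
  expect_message(san_cli(c("synth", "--spec", spec_path, "--out", csv_path)),
                 "12 memories")
  expect_true(file.exists(csv_path))
  expect_true(file.exists(paste0(csv_path, ".spec.json")))
  d <- load_dataset(csv_path)
  expect_equal(unname(dataset_u_factors(d)), c(12, 4, 2, 12) / 12)

  cfg_path <- file.path(dir, "cfg.json")
  jsonlite::write_json(
    list(k_input = 2, seed_sequence = 1, seed_ties = 2,
         behaviors = list(forgetting = TRUE, d_rate = 0.01)),
    cfg_path, auto_unbox = TRUE)
  out_dir <- file.path(dir, "run")
  suppressMessages(
    san_cli(c("run", "--config", cfg_path, "--dataset", csv_path,
              "--out", out_dir)))
  expect_true(file.exists(file.path(out_dir, "hit_rate.csv")))
  expect_true(file.exists(file.path(out_dir, "manifest.json")))
  out <- capture.output(res <- san_cli(c("metrics", "--run", out_dir)))
  expect_true(any(grepl("final UMR", out)))
  expect_true(res$final_umr >= 0 && res$final_umr <= 2)
})
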