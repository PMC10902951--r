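test_that("simulated pathways cover planted genes and are reproducible", {
  spec <- synthetic_spec(n_samples = 50, n_genes = 100, n_pathways = 10,
                         pathway_size = 10, planted_genes = 8, seed = 21)
  pw <- simulate_pathways(spec)
  expect_equal(length(pw$pathway_names), 10L)
  expect_true(all(paste0("g", sprintf("%04d", 1:8)) %in% unlist(pw$members)))
  # disjoint partition covering all genes here (capacity == n_genes)
  expect_equal(sort(unlist(pw$members)), sort(pathsurvnet:::gene_names(100)))
  pw2 <- simulate_pathways(spec)
  expect_identical(pw, pw2)
  expect_error(simulate_pathways(
    synthetic_spec(n_genes = 100, n_pathways = 2, pathway_size = 2,
                   planted_genes = 8)), "capacity")
})

test_that("cohort simulation is seed-deterministic with aligned truth", {
  spec <- synthetic_spec(n_samples = 60, n_genes = 50, n_pathways = 5,
                         pathway_size = 10, planted_genes = 5, seed = 33)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$cohort$expression, b$cohort$expression)
  expect_identical(a$cohort$survival, b$cohort$survival)
  # truth risk reproducible from the expression matrix
  r <- drop(a$cohort$expression[, a$truth$planted_genes] %*%
              rep(spec$effect_size, 5))
  expect_equal(r, a$truth$true_risk, ignore_attr = TRUE)
})

test_that("null effect size gives chance-level concordance of the true risk", {
  spec <- synthetic_spec(n_samples = 2000, n_genes = 20, n_pathways = 4,
                         pathway_size = 5, planted_genes = 5, effect_size = 0,
                         target_censoring = 0.3, seed = 8)
  sim <- simulate_cohort(spec)
  # risk is identically zero -> all pairs tied -> exactly 0.5 under the
  # half-credit convention; perturb with exchangeable noise for a strict check
  set.seed(1)
  ci <- concordance_index(rnorm(2000), sim$cohort$survival$time,
                          sim$cohort$survival$event)
  expect_lt(abs(ci - 0.5), 0.05)
})

test_that("censoring calibration hits its target over the supported range", {
  for (target in c(0.2, 0.5, 0.75, 0.9)) {
    spec <- synthetic_spec(n_samples = 1000, n_genes = 20, n_pathways = 4,
                           pathway_size = 5, planted_genes = 4,
                           target_censoring = target, seed = 13)
    sim <- simulate_cohort(spec)
    realized <- mean(sim$cohort$survival$event == 0)
    expect_lt(abs(realized - target), 0.05)
  }
  spec0 <- synthetic_spec(n_samples = 200, n_genes = 20, n_pathways = 4,
                          pathway_size = 5, planted_genes = 4,
                          target_censoring = 0, seed = 2)
  expect_true(all(simulate_cohort(spec0)$cohort$survival$event == 1))
})

test_that("stronger planted effects raise the true-risk concordance", {
  cis <- vapply(c(0, 0.3, 0.8), function(es) {
    mean(vapply(1:3, function(sd) {
      spec <- synthetic_spec(n_samples = 300, n_genes = 50, n_pathways = 5,
                             pathway_size = 10, planted_genes = 5,
                             effect_size = es, target_censoring = 0.3,
                             seed = sd)
      sim <- simulate_cohort(spec)
      risk <- sim$truth$true_risk + rnorm(300, sd = 1e-9)  # break exact ties
      concordance_index(risk, sim$cohort$survival$time,
                        sim$cohort$survival$event)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(cis) > 0))
})

test_that("module correlation shows up in within-pathway gene correlations", {
  spec <- synthetic_spec(n_samples = 500, n_genes = 40, n_pathways = 4,
                         pathway_size = 10, planted_genes = 4,
                         module_cor = 0.4, cluster_shift = 0, seed = 9)
  sim <- simulate_cohort(spec)
  pw <- simulate_pathways(spec)
  within <- cor(sim$cohort$expression[, pw$members[[1]]])
  off_diag <- within[upper.tri(within)]
  expect_gt(mean(off_diag), 0.3)
  across <- cor(sim$cohort$expression[, pw$members[[1]]],
                sim$cohort$expression[, pw$members[[2]]])
  expect_lt(abs(mean(across)), 0.1)
})

test_that("written cohorts round-trip through the readers", {
  spec <- synthetic_spec(n_samples = 20, n_genes = 15, n_pathways = 3,
                         pathway_size = 5, planted_genes = 3, seed = 14)
  sim <- simulate_cohort(spec)
  pw <- simulate_pathways(spec)
  d <- withr::local_tempdir()
  write_cohort(sim$cohort, pw, d, truth = sim$truth)
  back <- read_cohort(d)
  expect_equal(back$expression, sim$cohort$expression)
  expect_equal(back$survival$time, sim$cohort$survival$time)
  expect_equal(nrow(back$survival), 20L)
  pw2 <- read_gmt(file.path(d, "pathways.gmt"))
  expect_equal(pw2$members, pw$members)
  truth <- jsonlite::read_json(file.path(d, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$planted_genes, sim$truth$planted_genes)
})
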