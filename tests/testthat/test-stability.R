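test_that("identical species columns are recapitulated in every bootstrap replicate", {
  set.seed(5)
  vals <- matrix(rnorm(24), 4, 6,
                 dimnames = list(paste0("a", 1:4), LETTERS[1:6]))
  vals[, "B"] <- vals[, "A"]
  am <- assay_matrix(vals)
  rep <- bootstrap_stability(am, list(AB = c("A", "B")), n_boot = 300,
                             seed = 9)
  expect_equal(unname(rep$recapitulation["AB"]), 1.0)
})

test_that("Monte-Carlo recapitulation matches exhaustive enumeration on a 3-assay matrix", {
  set.seed(13)
  vals <- matrix(rnorm(12), 3, 4,
                 dimnames = list(paste0("a", 1:3), c("A", "B", "C", "D")))
  am <- assay_matrix(vals)
  target <- c("A", "B")
  exact <- enum_bootstrap_freq(am, target)     # all 27 ordered row samples
  mc <- bootstrap_stability(am, list(t = target), n_boot = 5000, seed = 2)
  p <- unname(mc$recapitulation["t"])
  se <- sqrt(max(exact * (1 - exact), 0.25 / 5000) / 5000)
  expect_lt(abs(p - exact), 3 * se + 1e-9)
})

test_that("planted cluster structure yields near-certain recapitulation", {
  am <- planted_matrix(effect_size = 10, noise_sd = 1, n_driver = 10,
                       n_null = 0, seed = 6)
  rep <- bootstrap_stability(am, list(AB = c("A", "B"),
                                      CDE = c("C", "D", "E")),
                             n_boot = 500, seed = 4)
  expect_gt(rep$recapitulation[["AB"]], 0.95)
  expect_gt(rep$recapitulation[["CDE"]], 0.95)
  # planted partition is recovered exactly by a 2-cut on the full matrix
  memb <- cut_tree(cluster_species(zscore_rows(am)), 2)
  expect_identical(length(unique(memb[c("A", "B")])), 1L)
  expect_identical(length(unique(memb[c("C", "D", "E")])), 1L)
  expect_false(memb[["A"]] == memb[["C"]])
})

test_that("null matrices recapitulate a fixed pair at its chance level", {
  # direct-simulation oracle for the chance that {A,B} is a clade of a
  # 5-species tree built from pure-noise assays
  set.seed(17)
  n_direct <- 1500
  hits <- 0
  for (i in seq_len(n_direct)) {
    m <- matrix(rnorm(5 * 6), 6, 5,
                dimnames = list(paste0("a", 1:6), LETTERS[1:5]))
    if (is_clade(cluster_species(zscore_rows(m)), c("A", "B"))) hits <- hits + 1
  }
  p_direct <- hits / n_direct
  # bootstrap recapitulation averaged over independent null matrices
  freqs <- vapply(1:25, function(i) {
    am <- planted_matrix(effect_size = 0, n_driver = 3, n_null = 3,
                         seed = 100 + i)
    bootstrap_stability(am, list(AB = c("A", "B")), n_boot = 200,
                        seed = i)$recapitulation[["AB"]]
  }, numeric(1))
  se <- sd(freqs) / sqrt(length(freqs)) +
    sqrt(p_direct * (1 - p_direct) / n_direct)
  expect_lt(abs(mean(freqs) - p_direct), 3 * se + 0.02)
})

test_that("stability reports are deterministic and invariant to matrix layout", {
  am <- planted_matrix(effect_size = 4, seed = 8)
  t1 <- bootstrap_stability(am, list(AB = c("A", "B")), n_boot = 400,
                            seed = 3)
  t2 <- bootstrap_stability(am, list(AB = c("A", "B")), n_boot = 400,
                            seed = 3)
  expect_identical(t1$recapitulation, t2$recapitulation)
  expect_identical(t1$cooccurrence, t2$cooccurrence)

  # permuting species columns relabels but does not change frequencies
  perm <- c(3, 1, 5, 2, 4)
  am_p <- assay_matrix(am$values[, perm], assay_type = am$assay_type,
                       coregulators = am$coregulators)
  t3 <- bootstrap_stability(am_p, list(AB = c("A", "B")), n_boot = 400,
                            seed = 3)
  expect_equal(t3$recapitulation[["AB"]], t1$recapitulation[["AB"]],
               tolerance = 1e-12)

  # reordering assay rows changes only which rows a resample index picks;
  # frequencies agree up to Monte-Carlo error
  rperm <- c(4, 1, 10, 2, 9, 3, 8, 5, 7, 6)
  am_r <- assay_matrix(am$values[rperm, ], assay_type = am$assay_type[rperm],
                       coregulators = am$coregulators[rperm])
  t4 <- bootstrap_stability(am_r, list(AB = c("A", "B")), n_boot = 400,
                            seed = 3)
  p <- t1$recapitulation[["AB"]]
  expect_lt(abs(t4$recapitulation[["AB"]] - p),
            3 * sqrt(max(p * (1 - p), 0.02) / 400) + 0.02)
})

test_that("report invariants hold: frequencies in [0,1], co-occurrence symmetric with unit diagonal", {
  am <- planted_matrix(effect_size = 2, seed = 12)
  rep <- bootstrap_stability(am, list(AB = c("A", "B"), AC = c("A", "C")),
                             n_boot = 200, seed = 7)
  expect_true(all(rep$recapitulation >= 0 & rep$recapitulation <= 1))
  expect_equal(rep$cooccurrence, t(rep$cooccurrence))
  expect_equal(unname(diag(rep$cooccurrence)), rep(1, 5))
  expect_true(all(rep$cooccurrence >= 0 & rep$cooccurrence <= 1))
  # k-cut recapitulation mode runs and stays in [0,1]
  repk <- bootstrap_stability(am, list(AB = c("A", "B")), n_boot = 100,
                              seed = 7, mode = "kcut", k = 2)
  expect_true(repk$recapitulation[["AB"]] >= 0 &&
                repk$recapitulation[["AB"]] <= 1)
  expect_error(bootstrap_stability(am, list(AB = c("A", "Q")), 10, 1),
               "unknown species")
  expect_error(bootstrap_stability(am, list(AB = c("A", "B")), n_boot = 0),
               "positive integer")
})

test_that("reports serialize to JSON", {
  am <- planted_matrix(effect_size = 5, seed = 2)
  rep <- bootstrap_stability(am, list(AB = c("A", "B")), n_boot = 50,
                             seed = 1)
  f <- tempfile(fileext = ".json")
  write_report_json(rep, f)
  parsed <- jsonlite::read_json(f)
  expect_equal(parsed$recapitulation$AB, rep$recapitulation[["AB"]])
  expect_equal(parsed$n_boot, 50)
})
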