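test_that("manifest generation is deterministic, ordered and validated", {
  expect_error(generate_manifest(0), "n_probes")
  expect_error(generate_manifest(10, n_chromosomes = 20), "at least")

  mf <- generate_manifest(1000, 2, 50, seed = 1)
  expect_identical(mf, generate_manifest(1000, 2, 50, seed = 1))
  expect_equal(as.vector(table(mf$chromosome)), c(500, 500))
  expect_false(anyDuplicated(mf$probe_id) > 0)
  for (ch in unique(mf$chromosome)) {
    expect_true(all(diff(mf$position[mf$chromosome == ch]) > 0))
  }
  known <- c("snp_affected", "non_cpg", "multi_mapping", "sex_chromosome")
  flags <- unlist(strsplit(mf$flags[mf$flags != ""], ";"))
  expect_true(all(flags %in% known))
  # each gene label is one contiguous block
  runs <- rle(mf$gene)
  expect_true(all(table(runs$values[runs$values != ""]) == 1))
})

test_that("cohort generation matches requested design and is reproducible", {
  mf <- generate_manifest(800, 2, 30, seed = 3)
  ch <- generate_cohort(mf, n_cases = 41, n_controls = 48, seed = 3)
  expect_equal(ncol(ch$beta), 89)
  expect_equal(nrow(ch$beta), 800)
  expect_true(all(ch$beta >= 0 & ch$beta <= 1))
  expect_equal(sum(ch$sheet$group == "case"), 41)
  expect_true(all(ch$sheet$age >= 0))
  expect_true(mean(ch$detection_p < 0.01) > 0.99)
  expect_true(mean(ch$bead_counts >= 3) > 0.99)

  ch2 <- generate_cohort(mf, n_cases = 41, n_controls = 48, seed = 3)
  expect_identical(ch$beta, ch2$beta)

  # degenerate noise: every sample equals the per-probe baseline
  ch0 <- generate_cohort(mf, n_cases = 3, n_controls = 4, noise_sd = 0,
                         outlier_rate = 0, seed = 3)
  expect_true(all(apply(ch0$beta, 1, function(r) length(unique(r)) == 1)))

  expect_error(generate_cohort(mf[0, ], 2, 2), "non-empty")
})

test_that("epivariant injection shifts targets beyond fences and records truth", {
  co <- small_cohort(seed = 9)
  no_inj <- inject_epivariants(co$beta, co$manifest, co$sheet,
                               n_isolated = 0, n_regions = 0, seed = 9)
  expect_identical(no_inj$beta, co$beta)
  expect_equal(nrow(no_inj$truth$injected_sevs), 0)

  inj <- inject_epivariants(co$beta, co$manifest, co$sheet,
                            n_isolated = 3, n_regions = 2, region_length = 5,
                            shift = 0.12, seed = 9)
  tr <- inj$truth
  expect_equal(nrow(tr$injected_regions), 2)
  expect_equal(nrow(tr$injected_sevs), 3)
  expect_true(all(tr$injected_sevs$probe_id %in% co$manifest$probe_id))
  expect_true(all(tr$injected_sevs$sample_id %in%
                    co$sheet$sample_id[co$sheet$group == "case"]))
  expect_true(all(inj$beta >= 0 & inj$beta <= 1))

  ctrl <- co$sheet$sample_id[co$sheet$group == "control"]
  ranges <- reference_ranges(co$beta[, ctrl])
  for (r in seq_len(nrow(tr$injected_regions))) {
    pids <- strsplit(tr$injected_regions$probe_ids[r], ";")[[1]]
    expect_gte(length(pids), 2)
    # consecutive probes of one gene
    genes <- co$manifest$gene[match(pids, co$manifest$probe_id)]
    expect_true(all(genes == tr$injected_regions$gene[r]))
    smp <- tr$injected_regions$sample_id[r]
    ri <- match(pids, ranges$probe_id)
    if (tr$injected_regions$direction[r] == "hyper") {
      expect_true(all(inj$beta[pids, smp] > ranges$upper[ri]))
      expect_true(all(inj$beta[pids, smp] > co$beta[pids, smp]))
    } else {
      expect_true(all(inj$beta[pids, smp] < ranges$lower[ri]))
      expect_true(all(inj$beta[pids, smp] < co$beta[pids, smp]))
    }
  }

  # downstream: detect_sevs flags every injected region probe, right direction
  sevs <- detect_sevs(inj$beta, ranges)
  for (r in seq_len(nrow(tr$injected_regions))) {
    pids <- strsplit(tr$injected_regions$probe_ids[r], ";")[[1]]
    hit <- sevs[sevs$sample_id == tr$injected_regions$sample_id[r] &
                  sevs$probe_id %in% pids, ]
    expect_equal(nrow(hit), length(pids))
    expect_true(all(hit$direction == tr$injected_regions$direction[r]))
  }

  expect_error(inject_epivariants(co$beta, co$manifest, co$sheet,
                                  n_regions = 5000, region_length = 4, seed = 1),
               "exceed")
})

test_that("uninjected cohorts give near-nominal burden rejection end to end", {
  rate <- sev_chain_null_rejection_rate(n_sim = 200, seed = 11)
  # nominal alpha 0.05 with a small positive bias from the in-sample
  # reference (controls partly mask their own outliers); bound at the
  # design point plus two binomial standard errors over 200 cohorts
  expect_lte(rate, 0.07 + 2 * sqrt(0.07 * 0.93 / 200))
})
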