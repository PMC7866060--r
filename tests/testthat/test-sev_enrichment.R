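test_that("hypergeometric upper tail matches enumeration and handles edges", {
  expect_equal(hypergeom_upper_tail(0, K = 10, n = 11, N = 100), 1)
  expect_equal(hypergeom_upper_tail(6, K = 5, n = 11, N = 100), 0)
  # frozen from the enumeration oracle: C(5,5)*C(15,6)/C(20,11) = 5005/167960
  expect_equal(hypergeom_upper_tail(5, K = 5, n = 11, N = 20), 5005 / 167960,
               tolerance = 1e-12)

  expect_error(hypergeom_upper_tail(1, K = 30, n = 5, N = 20), "K <= N")
  expect_error(hypergeom_upper_tail(-1, K = 3, n = 5, N = 20), "x >= 0")

  # non-increasing in x; agrees with the oracle on a seeded grid
  set.seed(7)
  for (i in 1:50) {
    N <- sample(5:300, 1)
    K <- sample(0:N, 1)
    n <- sample(0:min(N, 20), 1)
    xs <- 0:(min(n, K) + 1L)
    p <- hypergeom_upper_tail(xs, K = K, n = n, N = N)
    expect_true(all(diff(p) <= 1e-15))
    oracle <- vapply(xs, hyper_tail_oracle, numeric(1), K = K, n = n, N = N)
    expect_equal(p, oracle, tolerance = 1e-12)
  }
})

test_that("sliding window scan retains clustered SEVs and discards by rule", {
  # one chromosome, 41 probes, window 11 -> centers 6..36
  mf <- toy_manifest(rep("", 41))
  uni <- mf$probe_id

  sev_at <- function(idx, sample = "s1") {
    data.frame(sample_id = sample, probe_id = mf$probe_id[idx],
               direction = "hyper", beta = 0.9, excess = 0.1,
               stringsAsFactors = FALSE)
  }

  # a contiguous run of 6 SEVs: all run members with full windows retained
  run <- 15:20
  scan <- sliding_window_scan(sev_at(run), mf, uni, n = 11, alpha = 0.05)
  expect_equal(nrow(scan), 31)  # 41 - 10 centers
  kept <- scan$central_probe[scan$retained]
  expect_identical(sort(kept), sort(mf$probe_id[run]))
  # retained SEVs are a subset of the SEV calls
  expect_true(all(kept %in% sev_at(run)$probe_id))

  # central probe that is not an SEV is never retained, however small p
  non_central <- scan[scan$central_probe == mf$probe_id[17], ]
  expect_true(non_central$retained)
  no_sev_center <- scan[scan$central_probe == mf$probe_id[12], ]
  expect_false(no_sev_center$retained)  # window may touch run but center clean

  # edge probes (fewer than 5 same-chromosome neighbours) get no window test
  expect_false(any(scan$central_probe %in% mf$probe_id[c(1:5, 37:41)]))

  # order invariance of supplied calls
  shuffled <- sev_at(rev(run))
  scan2 <- sliding_window_scan(shuffled, mf, uni, n = 11, alpha = 0.05)
  expect_equal(scan2, scan)

  expect_error(sliding_window_scan(sev_at(15), mf, uni, n = 10), "odd")
  expect_error(sliding_window_scan(sev_at(15), mf, uni, n = 1), "n")
})

test_that("lone SEVs can pass only when the sample's total burden K is tiny", {
  mf <- generate_manifest(10000, 1, 200, seed = 1)
  uni <- mf$probe_id

  # K = 1: p = n/N = 11/10000 = 0.0011 < 0.05 -> retained
  one <- data.frame(sample_id = "s1", probe_id = mf$probe_id[5000],
                    direction = "hyper", beta = 0.9, excess = 0.1)
  scan <- sliding_window_scan(one, mf, uni, n = 11, alpha = 0.05)
  row <- scan[scan$central_probe == mf$probe_id[5000], ]
  expect_equal(row$x, 1)
  expect_equal(row$p_value, 0.0011, tolerance = 1e-12)
  expect_true(row$retained)

  # K = 200 scattered: an isolated member (x = 1) has p ~ 0.199 -> discarded
  set.seed(3)
  idx <- seq(25, 9975, by = 50)[1:200]  # well separated
  many <- data.frame(sample_id = "s1", probe_id = mf$probe_id[idx],
                     direction = "hyper", beta = 0.9, excess = 0.1)
  scan200 <- sliding_window_scan(many, mf, uni, n = 11, alpha = 0.05)
  row1 <- scan200[scan200$central_probe == mf$probe_id[idx[3]], ]
  expect_equal(row1$x, 1)
  expect_equal(row1$K, 200)
  expect_equal(row1$p_value, hyper_tail_oracle(1, 200, 11, 10000),
               tolerance = 1e-12)
  expect_false(row1$retained)
})

test_that("windows never span chromosomes and p-values use genome-wide K, N", {
  mf <- rbind(toy_manifest(rep("", 20), chromosome = "chr1"),
              toy_manifest(rep("", 20), chromosome = "chr2"))
  mf$probe_id <- sprintf("cg%03d", 1:40)
  uni <- mf$probe_id
  sevs <- data.frame(sample_id = "s1", probe_id = mf$probe_id[c(10, 30)],
                     direction = "hyper", beta = 0.9, excess = 0.1)
  scan <- sliding_window_scan(sevs, mf, uni, n = 11, alpha = 0.05)
  # centers 6..15 per chromosome: 10 + 10 rows
  expect_equal(nrow(scan), 20)
  expect_true(all(scan$K == 2))
  expect_true(all(scan$N == 40))
  # windows near the chr1/chr2 boundary don't see the other chromosome's SEV
  boundary <- scan[scan$central_probe == mf$probe_id[15], ]
  expect_equal(boundary$x, 1)
})

test_that("retained_sevs re-attaches call metadata", {
  mf <- toy_manifest(rep("G1", 15))
  sevs <- data.frame(sample_id = "s1", probe_id = mf$probe_id[7:9],
                     direction = "hypo", beta = 0.01, excess = 0.2,
                     stringsAsFactors = FALSE)
  scan <- sliding_window_scan(sevs, mf, mf$probe_id, n = 11)
  ret <- retained_sevs(scan, sevs)
  expect_true(all(ret$direction == "hypo"))
  expect_true(all(ret$probe_id %in% sevs$probe_id))
  expect_true(all(ret$p_value < 0.05))
})
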