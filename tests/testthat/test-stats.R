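test_that("signed rank handles degenerate and canonical inputs", {
  z <- signed_rank(c(0, 0, 0))
  expect_equal(z$p_value, 1)
  expect_equal(z$statistic, 0)

  # n = 5, all positive, distinct: two-sided p = 2/32
  r5 <- signed_rank(c(0.2, 0.1, 0.3, 0.15, 0.25))
  expect_equal(r5$p_value, 0.0625)
  expect_equal(r5$statistic, 15)

  # symmetry: negating the differences leaves p unchanged
  d <- c(0.3, -0.1, 0.25, 0.4, -0.05, 0.2)
  expect_equal(signed_rank(d)$p_value, signed_rank(-d)$p_value)
})

test_that("exact signed-rank p matches enumeration and wilcox.test oracles", {
  set.seed(41)
  for (k in 1:20) {
    n <- sample(4:9, 1)
    d <- round(rnorm(n), 3)
    d <- d[d != 0]
    if (length(d) < 2) next
    expect_equal(signed_rank(d)$p_value, oracle_signrank_p(d),
                 tolerance = 1e-12)
    if (!any(duplicated(abs(d)))) {
      w <- stats::wilcox.test(d, exact = TRUE)
      expect_equal(signed_rank(d)$p_value, w$p.value, tolerance = 1e-12)
    }
  }
})

test_that("large-sample normal approximation tracks wilcox.test", {
  set.seed(43)
  d <- rnorm(40, mean = 0.2)
  ours <- signed_rank(d)
  expect_equal(ours$method, "normal approximation")
  ref <- stats::wilcox.test(d, exact = FALSE, correct = FALSE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
})

test_that("B-H step-up reproduces the worked example and stays a prefix", {
  res <- bh_adjust(c(0.01, 0.02, 0.04, 0.2), q = 0.05)
  expect_equal(res$critical, c(0.0125, 0.025, 0.0375, 0.05))
  expect_equal(sum(res$significant), 2)
  expect_equal(attr(res, "cutoff_index"), 2L)
  # significant set is a prefix of the sorted order
  expect_true(all(diff(as.integer(res$significant)) <= 0))

  all_ones <- bh_adjust(rep(1, 6))
  expect_equal(sum(all_ones$significant), 0)

  expect_error(bh_adjust(numeric(0)), "empty")
  expect_error(bh_adjust(c(0.2, 1.4)), "0, 1")
})

test_that("B-H matches the p.adjust oracle on 200 random p-vectors", {
  set.seed(47)
  for (k in 1:200) {
    m <- sample(5:100, 1)
    p <- runif(m)^sample(c(1, 2, 3), 1)  # mix of uniform and skewed nulls
    res <- bh_adjust(p, q = 0.05)
    expect_equal(sum(res$significant), oracle_bh_significant(p, 0.05))
    expect_true(all(diff(as.integer(res$significant)) <= 0))
  }
})

test_that("pair differences exclude same-electrode pairs and track phase presence", {
  mk <- function(sid, phase, vals) {
    tibble::tibble(seizure_id = sid, phase = phase,
                   src = c("LJ1", "LK1", "LJ1", "LK1", "LJ1", "LJ2"),
                   dst = c("LK1", "LJ1", "LJ2", "LJ2", "LF1", "LF1"),
                   h2 = vals)
  }
  coupling <- dplyr::bind_rows(
    mk(1, "baseline", c(0.1, 0.2, 0.3, 0.1, 0.2, 0.1)),
    mk(1, "onset",    c(0.5, 0.4, 0.3, 0.1, 0.6, 0.2)),
    mk(2, "baseline", c(0.1, 0.1, 0.1, 0.1, 0.1, 0.1)),
    mk(2, "onset",    c(0.2, 0.3, 0.1, 0.1, 0.1, 0.1)),
    mk(2, "ictal1",   c(0.7, 0.2, 0.2, 0.2, 0.3, 0.3)))
  d <- pair_differences(coupling)

  # LJ1-LJ2 shares an electrode: never present
  expect_false(any(contact_electrode(d$pair_a) ==
                     contact_electrode(d$pair_b)))
  # onset present in both seizures, ictal1 only in seizure 2
  expect_equal(sum(d$phase == "onset" & d$pair_a == "LJ1" &
                     d$pair_b == "LK1"), 2)
  expect_equal(sum(d$phase == "ictal1" & d$pair_a == "LJ1" &
                     d$pair_b == "LK1"), 1)
  # max collapse: seizure 1 onset LJ1-LK1 = max(.5,.4) - max(.1,.2)
  v <- d$diff[d$phase == "onset" & d$seizure_id == 1 &
                d$pair_a == "LJ1" & d$pair_b == "LK1"]
  expect_equal(v, 0.5 - 0.2)
  # mean collapse flag
  dm <- pair_differences(coupling, collapse = "mean")
  vm <- dm$diff[dm$phase == "onset" & dm$seizure_id == 1 &
                  dm$pair_a == "LJ1" & dm$pair_b == "LK1"]
  expect_equal(vm, 0.45 - 0.15)
  # identical event and control give all-zero diffs
  same <- dplyr::bind_rows(mk(1, "baseline", c(0.1, 0.2, 0.3, 0.1, 0.2, 0.1)),
                           mk(1, "onset", c(0.1, 0.2, 0.3, 0.1, 0.2, 0.1)))
  expect_true(all(pair_differences(same)$diff == 0))
})

test_that("phase tests apply B-H within phase and order deterministically", {
  set.seed(53)
  pairs <- expand.grid(a = c("LJ1", "LK1", "LF1"), b = c("RF1", "RJ1"),
                       stringsAsFactors = FALSE)
  diffs <- dplyr::bind_rows(lapply(seq_len(nrow(pairs)), function(i) {
    tibble::tibble(pair_a = pairs$a[i], pair_b = pairs$b[i],
                   phase = "onset", seizure_id = 1:8,
                   diff = rnorm(8, mean = ifelse(i <= 2, 0.3, 0)))
  }))
  res <- phase_signed_rank(diffs, q = 0.05)
  expect_true(all(res$bh_critical > 0))
  expect_equal(nrow(res), 6)
  expect_false(is.unsorted(res$p_value))
  g <- glance(res)
  expect_equal(g$n_tests, 6L)
})

test_that("top_pairs selects k smallest p with lexicographic ties", {
  results <- tibble::tibble(
    pair_a = c("B1", "A1", "C1"), pair_b = c("Z1", "Z1", "Z1"),
    phase = "onset", p_value = c(0.01, 0.01, 0.5))
  diffs <- tibble::tibble(
    pair_a = rep(c("B1", "A1", "C1"), each = 2),
    pair_b = "Z1", phase = "onset",
    seizure_id = rep(1:2, 3), diff = rnorm(6))
  top <- top_pairs(results, diffs, k = 2)
  expect_equal(unique(top$pair_a), c("A1", "B1"))  # tie broken by label
  expect_warning(top_pairs(results, diffs, k = 25), "exceeds")
  top_all <- suppressWarnings(top_pairs(results, diffs, k = 25))
  expect_equal(dplyr::n_distinct(top_all$pair_a), 3)
})

test_that("planted onset increase is detected at the planted pairs", {
  # event vs control h2 for planted pairs across 8 simulated seizures
  set.seed(59)
  n_seiz <- 8
  planted <- c("LJ1-LK1", "LJ2-LK2")
  nulls <- c("LF1-RF1", "LF2-RF2", "LJ1-RF1")
  rows <- list()
  for (s in seq_len(n_seiz)) {
    for (p in c(planted, nulls)) {
      ab <- strsplit(p, "-")[[1]]
      ctl <- null_h2()
      evt <- if (p %in% planted) {
        spec <- coupling_spec(ab[1], ab[2], lag_ms = 20, gain = 0.9,
                              noise_sd = 0.1)
        rec <- generate_coupled_signals(spec, duration_s = 5.12)
        h2(rec$samples[1, ], rec$samples[2, ])
      } else null_h2()
      rows[[length(rows) + 1]] <- tibble::tibble(
        pair_a = ab[1], pair_b = ab[2], phase = "onset",
        seizure_id = s, diff = evt - ctl)
    }
  }
  diffs <- dplyr::bind_rows(rows)
  res <- phase_signed_rank(diffs, q = 0.05)
  sig <- res[res$significant, ]
  sig_pairs <- paste(sig$pair_a, sig$pair_b, sep = "-")
  expect_true(all(sig_pairs %in% planted))
  expect_gte(length(sig_pairs) / length(planted), 0.8)
  med <- stats::aggregate(diff ~ pair_a + pair_b,
                          data = diffs[paste(diffs$pair_a, diffs$pair_b,
                                             sep = "-") %in% planted, ],
                          FUN = stats::median)
  expect_true(all(med$diff > 0))
})
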