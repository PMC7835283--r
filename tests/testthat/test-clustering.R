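test_that("cosine similarity handles parallel, disjoint and zero rows", {
  M <- rbind(A = c(0, 1, 1, 0), B = c(0, 1, 1, 0),
             C = c(1, 0, 0, 0), D = c(0, 0, 0, 0))
  colnames(M) <- c("A", "B", "C", "D")
  S <- cosine_similarity(M)
  expect_equal(unname(S["A", "B"]), 1)
  expect_equal(unname(S["A", "C"]), 0)
  expect_equal(unname(S["A", "D"]), 0)
  expect_equal(unname(S["D", "D"]), 0)
  expect_equal(unname(diag(S)[1:3]), rep(1, 3))
  expect_true(isSymmetric(unclass(S)))
  expect_error(cosine_similarity(-M), "nonnegative")
})

test_that("binary-row similarity equals the overlap closed form, exhaustively", {
  # all pairs of binary vectors of length <= 6
  for (len in c(3, 6)) {
    vecs <- as.matrix(expand.grid(rep(list(0:1), len)))
    for (i in seq_len(nrow(vecs))) {
      for (j in seq_len(nrow(vecs))) {
        x <- vecs[i, ]; y <- vecs[j, ]
        M <- rbind(X = x, Y = y)
        S <- cosine_similarity(M)
        dx <- sum(x); dy <- sum(y); ov <- sum(x * y)
        expected <- if (dx == 0 || dy == 0) 0 else ov / sqrt(dx * dy)
        expect_equal(unname(S["X", "Y"]), expected, tolerance = 1e-12)
      }
    }
  }
})

test_that("matrix implementation equals the double-loop oracle on random input", {
  set.seed(19)
  for (k in 1:10) {
    M <- matrix(rbinom(64, 1, 0.4), 8, 8)
    dimnames(M) <- list(paste0("v", 1:8), paste0("v", 1:8))
    diag(M) <- 0
    expect_equal(unclass(cosine_similarity(M)), oracle_cosine(M),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("similarity is invariant under positive row scaling", {
  set.seed(23)
  M <- matrix(runif(36), 6, 6)
  dimnames(M) <- list(paste0("v", 1:6), paste0("v", 1:6))
  scaled <- diag(c(2, 0.5, 7, 1, 3, 10)) %*% M
  dimnames(scaled) <- dimnames(M)
  expect_equal(unclass(cosine_similarity(M)),
               unclass(cosine_similarity(scaled)), tolerance = 1e-12)
})

test_that("two perfectly similar vertices merge at height zero", {
  M <- rbind(A = c(1, 1, 0), B = c(1, 1, 0))
  colnames(M) <- c("A", "B", "C")
  d <- agglomerate(cosine_similarity(M))
  expect_equal(nrow(d$merges), 1)
  expect_equal(d$merges$height, 0)
  expect_equal(d$merges$size, 2)
})

test_that("three-vertex average linkage matches the hand computation", {
  S <- matrix(c(1, 0.9, 0.1,
                0.9, 1, 0.1,
                0.1, 0.1, 1), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  class(S) <- c("similarity_matrix", class(S))
  d <- agglomerate(S)
  expect_equal(d$merges$cluster_a, c("A", "A"))
  expect_equal(d$merges$cluster_b, c("B", "C"))
  expect_equal(d$merges$height, c(0.1, 0.9))
  expect_equal(d$merges$size, c(2, 3))
})

test_that("agglomeration equals the naive oracle, including forced ties", {
  set.seed(29)
  for (k in 1:12) {
    n <- 8
    vals <- if (k <= 6) runif(n * (n - 1) / 2) else
      sample(c(0, 0.25, 0.5, 0.75, 1), n * (n - 1) / 2, replace = TRUE)
    S <- diag(n)
    S[upper.tri(S)] <- vals
    S <- S + t(S) - diag(n)
    dimnames(S) <- list(paste0("v", 1:n), paste0("v", 1:n))
    d <- agglomerate(S)
    orc <- oracle_agglomerate(S)
    expect_equal(d$merges$height,
                 vapply(orc, function(m) m$height, 1), tolerance = 1e-12)
    expect_equal(dend_member_sets(d),
                 lapply(orc, function(m) m$members))
  }
})

test_that("merge heights agree with hclust average linkage on tie-free input", {
  set.seed(31)
  for (k in 1:5) {
    n <- 7
    S <- diag(n)
    S[upper.tri(S)] <- runif(n * (n - 1) / 2)
    S <- S + t(S) - diag(n)
    dimnames(S) <- list(paste0("v", 1:n), paste0("v", 1:n))
    d <- agglomerate(S)
    hc <- stats::hclust(stats::as.dist(1 - S), method = "average")
    expect_equal(d$height, hc$height, tolerance = 1e-12)
  }
})

test_that("dendrogram heights are monotone and bounded, isolated leaves last", {
  M <- rbind(A = c(0, 1, 1, 0), B = c(0, 1, 0, 0),
             C = c(1, 0, 0, 1), D = c(0, 0, 0, 0))
  colnames(M) <- rownames(M)
  d <- agglomerate(cosine_similarity(M))
  expect_equal(nrow(d$merges), 3)  # n - 1 merges even with isolated D
  expect_true(all(diff(d$height) >= -1e-12))
  expect_true(all(d$height >= 0 & d$height <= 1))
  expect_equal(d$merges$height[3], 1)  # D joins last at maximal height
  expect_true("D" %in% c(d$merges$cluster_a[3], d$merges$cluster_b[3]))
})

test_that("dendrograms convert to hclust and export Newick", {
  set.seed(37)
  S <- diag(5)
  S[upper.tri(S)] <- runif(10)
  S <- S + t(S) - diag(5)
  dimnames(S) <- list(paste0("v", 1:5), paste0("v", 1:5))
  d <- agglomerate(S)
  hc <- stats::as.hclust(d)
  expect_s3_class(hc, "hclust")
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(d, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, paste0("v", 1:5))
})

test_that("similarity distribution counts pairs, honours zero flag and adds", {
  M1 <- rbind(A = c(1, 1), B = c(1, 1), C = c(0, 0))
  colnames(M1) <- c("x", "y")
  S1 <- cosine_similarity(M1)
  one <- similarity_distribution(list(S1))
  expect_equal(one$similarity, 1)
  expect_equal(one$n_pairs, 1L)

  withz <- similarity_distribution(list(S1), include_zero = TRUE)
  expect_equal(sum(withz$n_pairs), 3L)  # all unordered pairs

  # additivity: identical matrices across 3 events triple the counts
  three <- similarity_distribution(list(S1, S1, S1))
  expect_equal(three$n_pairs, 3L * one$n_pairs)

  grouped <- similarity_distribution(list(S1, S1), phases = c("onset",
                                                              "ictal1"))
  expect_equal(sort(unique(grouped$phase)), c("ictal1", "onset"))
})

test_that("similarity vs h2 table joins on event and filters same-electrode pairs", {
  labs <- c("LJ1", "LJ2", "LK1")
  H <- matrix(NA_real_, 3, 3, dimnames = list(labs, labs))
  H[row(H) != col(H)] <- c(0.2, 0.3, 0.5, 0.6, 0.1, 0.4)
  ev <- event_annotations(2, "onset", 0, 10, list(character()))
  cm <- structure(list(labels = labs, h2 = H,
                       lags = matrix(0L, 3, 3, dimnames = list(labs, labs)),
                       event = ev), class = "coupling_matrix")
  M <- rbind(LJ1 = c(1, 1, 0), LJ2 = c(1, 0, 0), LK1 = c(0, 1, 1))
  colnames(M) <- labs
  S <- cosine_similarity(M)

  tbl <- similarity_vs_h2(list(S), list(cm))
  # LJ1-LJ2 share electrode LJ and must be excluded
  expect_equal(nrow(tbl), 2)
  expect_true(all(contact_electrode(tbl$pair_a) !=
                    contact_electrode(tbl$pair_b)))
  expect_equal(unique(tbl$seizure_id), 2L)
  # h2 collapses to the max over directions
  row_jk <- tbl[tbl$pair_a == "LJ1" & tbl$pair_b == "LK1", ]
  expect_equal(row_jk$h2, max(H["LJ1", "LK1"], H["LK1", "LJ1"]))

  all_tbl <- similarity_vs_h2(list(S), list(cm),
                              different_electrodes_only = FALSE)
  expect_equal(nrow(all_tbl), 3)
})
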