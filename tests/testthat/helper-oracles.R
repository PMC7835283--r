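# Independent oracle implementations. These deliberately share no code
# with the package: plain-loop formulas used to cross-check the fast paths.

# brute-force nonlinear correlation coefficient: equal-width bins over the
# observed x range, mean-of-y knots at bin midpoints, linear interpolation,
# constant extrapolation beyond the outer midpoints
oracle_h2 <- function(x, y, n_bins = 10) {
  lo <- min(x); hi <- max(x)
  w <- (hi - lo) / n_bins
  bin_of <- function(v) min(n_bins, floor((v - lo) / w) + 1)
  bins <- vapply(x, bin_of, 1)
  mids <- numeric(0); means <- numeric(0)
  for (b in seq_len(n_bins)) {
    in_b <- which(bins == b)
    if (length(in_b) > 0) {
      mids <- c(mids, lo + (b - 0.5) * w)
      means <- c(means, mean(y[in_b]))
    }
  }
  f <- function(v) {
    m <- length(mids)
    if (m == 1) return(means[1])
    if (v <= mids[1]) return(means[1])
    if (v >= mids[m]) return(means[m])
    i <- max(which(mids <= v))
    if (mids[i] == v) return(means[i])
    means[i] + (means[i + 1] - means[i]) * (v - mids[i]) /
      (mids[i + 1] - mids[i])
  }
  pred <- vapply(x, f, 1)
  val <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  max(0, min(1, val))
}

# double-loop cosine similarity straight from the definition
oracle_cosine <- function(M) {
  n <- nrow(M)
  S <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      num <- sum(M[a, ] * M[b, ])
      den <- sqrt(sum(M[a, ]^2) * sum(M[b, ]^2))
      S[a, b] <- if (den > 0) num / den else 0
    }
  }
  dimnames(S) <- dimnames(M)
  S
}

# naive O(n^3) average-linkage agglomeration over d = 1 - S, label-keyed
# clusters, identical tie rule (smallest member label, then partner label);
# returns list of merges: height + sorted member labels of the new cluster
oracle_agglomerate <- function(S) {
  labs <- rownames(S)
  d <- 1 - S
  diag(d) <- 0
  clusters <- as.list(labs)
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        take <- is.null(best) || dd < best$d - 1e-12 ||
          (abs(dd - best$d) <= 1e-12 &&
             (key[1] < best$key[1] ||
                (key[1] == best$key[1] && key[2] < best$key[2])))
        if (take) best <- list(d = dd, i = i, j = j, key = key)
      }
    }
    newc <- c(clusters[[best$i]], clusters[[best$j]])
    merges[[length(merges) + 1]] <- list(height = best$d,
                                         members = sort(newc))
    clusters <- clusters[-c(best$i, best$j)]
    clusters[[length(clusters) + 1]] <- newc
  }
  merges
}

# member sets created at each merge step of a package dendrogram
dend_member_sets <- function(dend) {
  n <- length(dend$labels)
  sets <- vector("list", n - 1)
  expand <- function(i) {
    if (i < 0) return(dend$labels[-i])
    sets[[i]]
  }
  for (k in seq_len(n - 1)) {
    sets[[k]] <- sort(c(expand(dend$merge[k, 1]), expand(dend$merge[k, 2])))
  }
  sets
}

# exhaustive two-sided signed-rank p by enumerating all sign assignments
oracle_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  Ws <- apply(grid, 1, function(s) sum(r[unlist(s)]))
  p_le <- mean(Ws <= W + 1e-9)
  p_ge <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# step-up FDR oracle via the adjusted p-values route
oracle_bh_significant <- function(p, q) sum(p.adjust(p, "BH") <= q)
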