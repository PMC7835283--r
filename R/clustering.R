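#' Cosine vertex similarity of adjacency rows
#'
#' For vertices x and y with adjacency rows `M[x, ]` and `M[y, ]`, the
#' similarity is `sigma_xy = sum_k M[x,k] M[y,k] / sqrt(sum_k M[x,k]^2 *
#' sum_k M[y,k]^2)` — the cosine of the angle between the two
#' out-neighbour profiles. For binary rows this reduces to
#' `overlap / sqrt(deg_x * deg_y)`. Vertices with an all-zero row get
#' similarity 0 against everything, including themselves.
#'
#' @param adj Nonnegative adjacency matrix with labelled rows (see
#'   [to_adjacency()]).
#' @return A symmetric matrix of class `similarity_matrix` with values in
#'   `[0, 1]`; diagonal 1 where the row is nonzero, 0 otherwise.
#' @examples
#' M <- rbind(A = c(0, 1, 1), B = c(0, 1, 1), C = c(1, 0, 0))
#' colnames(M) <- rownames(M)
#' cosine_similarity(M)
#' @export
cosine_similarity <- function(adj) {
  adj <- as.matrix(adj)
  if (any(adj < 0)) {
    stop_ictalnet("adjacency entries must be nonnegative",
                  "ictalnet_similarity_error")
  }
  G <- adj %*% t(adj)
  nrm <- sqrt(diag(G))
  S <- G / outer(nrm, nrm)
  S[!is.finite(S)] <- 0          # all-zero rows
  S <- clamp01((S + t(S)) / 2)   # exact symmetry under fp noise
  dimnames(S) <- list(rownames(adj), rownames(adj))
  class(S) <- c("similarity_matrix", class(S))
  S
}

# average-linkage dissimilarity between two clusters given full d matrix
avg_link <- function(d, a, b) mean(d[a, b])

#' Agglomerative clustering of vertices by cosine similarity
#'
#' Hierarchical agglomeration on the dissimilarity `d = 1 - sigma` with
#' average linkage: the two clusters with the smallest mean pairwise
#' dissimilarity merge first, repeatedly, until one cluster remains. Ties
#' are broken deterministically toward the pair containing the
#' lexicographically smallest member label. Isolated vertices (all-zero
#' similarity) sit at dissimilarity 1 from everything and therefore merge
#' last, at the maximal height.
#'
#' @param S A [cosine_similarity()] matrix (or any symmetric similarity
#'   matrix with values in `[0, 1]` and labelled rows).
#' @return An object of class `ictal_dendrogram`: `merges` (tibble
#'   `cluster_a, cluster_b, height, size`, clusters named by their
#'   lexicographically smallest member), `labels`, plus hclust-compatible
#'   `merge`, `height` and `order` fields. `as.hclust()` and
#'   [write_newick()] convert it for plotting and export.
#' @examples
#' M <- rbind(A = c(0, 1, 1, 0), B = c(0, 1, 1, 0),
#'            C = c(1, 0, 0, 1), D = c(0, 0, 0, 0))
#' colnames(M) <- rownames(M)
#' agglomerate(cosine_similarity(M))
#' @export
agglomerate <- function(S) {
  labs <- rownames(S)
  n <- length(labs)
  d <- 1 - unclass(S)
  diag(d) <- 0
  members <- as.list(seq_len(n))       # leaf indices per active cluster
  ids <- -seq_len(n)                   # hclust convention: leaves negative
  minlab <- labs                       # lexicographic representative
  merge <- matrix(0L, max(n - 1L, 0L), 2L)
  height <- numeric(max(n - 1L, 0L))
  merges <- vector("list", max(n - 1L, 0L))
  active <- seq_len(n)
  for (step in seq_len(n - 1L)) {
    best <- NULL; best_d <- Inf
    for (ai in seq_along(active)) {
      for (bi in seq_len(ai - 1L)) {
        a <- active[ai]; b <- active[bi]
        dd <- avg_link(d, members[[a]], members[[b]])
        lo <- if (minlab[a] <= minlab[b]) c(a, b) else c(b, a)
        if (dd < best_d - 1e-12) {
          best_d <- dd; best <- lo
        } else if (abs(dd - best_d) <= 1e-12) {
          # tie: smallest member label, then the partner's smallest label
          cur <- c(minlab[lo[1]], minlab[lo[2]])
          prev <- c(minlab[best[1]], minlab[best[2]])
          if (cur[1] < prev[1] || (cur[1] == prev[1] && cur[2] < prev[2])) {
            best <- lo
          }
        }
      }
    }
    a <- best[1]; b <- best[2]
    new <- length(members) + 1L
    members[[new]] <- c(members[[a]], members[[b]])
    ids[new] <- step
    minlab[new] <- min(minlab[a], minlab[b])
    merge[step, ] <- sort(c(ids[a], ids[b]))
    height[step] <- best_d
    merges[[step]] <- tibble(
      cluster_a = minlab[a], cluster_b = minlab[b],
      height = best_d, size = length(members[[new]]))
    active <- c(setdiff(active, c(a, b)), new)
  }
  ord <- if (n > 1L) {
    # leaf order by recursive traversal of the merge matrix
    walk <- function(i) {
      if (i < 0L) return(-i)
      c(walk(merge[i, 1]), walk(merge[i, 2]))
    }
    walk(n - 1L)
  } else 1L
  structure(list(
    merges = dplyr::bind_rows(merges),
    labels = labs,
    merge = merge, height = height, order = ord),
    class = "ictal_dendrogram")
}

#' @export
print.ictal_dendrogram <- function(x, ...) {
  cat(sprintf("<ictal_dendrogram> %d leaves, %d merges\n",
              length(x$labels), nrow(x$merges)))
  print(x$merges)
  invisible(x)
}

#' @method as.hclust ictal_dendrogram
#' @export
as.hclust.ictal_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "average",
                 call = match.call(), dist.method = "1 - cosine"),
            class = "hclust")
}

#' @rdname agglomerate
#' @param x An `ictal_dendrogram`.
#' @param ... Unused.
#' @export
tidy.ictal_dendrogram <- function(x, ...) x$merges

#' Export a dendrogram in Newick format
#'
#' @param dend An [agglomerate()] dendrogram.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dend, path) {
  ape::write.tree(ape::as.phylo(stats::as.hclust(dend)), file = path)
  invisible(path)
}

#' Dendrogram plot
#'
#' @param object An `ictal_dendrogram`.
#' @param ... Unused.
#' @return A ggplot object; leaf labels on the x axis, merge
#'   dissimilarity (`1 - cosine similarity`) on the y axis.
#' @export
autoplot.ictal_dendrogram <- function(object, ...) {
  hc <- stats::as.hclust(object)
  n <- length(hc$labels)
  xpos <- numeric(n - 1L)  # x of each internal node
  leaf_x <- setNames(seq_len(n), hc$order)
  segs <- list()
  node_x <- function(i) if (i < 0L) leaf_x[[as.character(-i)]] else xpos[i]
  node_y <- function(i) if (i < 0L) 0 else hc$height[i]
  for (k in seq_len(n - 1L)) {
    a <- hc$merge[k, 1]; b <- hc$merge[k, 2]
    xa <- node_x(a); xb <- node_x(b)
    xpos[k] <- (xa + xb) / 2
    h <- hc$height[k]
    segs[[k]] <- tibble(
      x = c(xa, xa, xb), xend = c(xa, xb, xb),
      y = c(node_y(a), h, h), yend = c(h, h, node_y(b)))
  }
  ggplot2::ggplot(dplyr::bind_rows(segs)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = seq_len(n),
                                labels = hc$labels[hc$order]) +
    ggplot2::labs(x = NULL, y = "dissimilarity (1 - cosine similarity)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid.major.x = ggplot2::element_blank())
}

#' Distribution of cosine similarity values over events
#'
#' Counts unordered vertex pairs per similarity value (rounded to 6
#' decimals, the precision at which the values are conventionally
#' reported), aggregated over a list of event similarity matrices and
#' optionally grouped by phase. Pairs with similarity 0 are excluded by
#' default, matching the usual presentation in which the zero bin would
#' swamp the histogram.
#'
#' @param S_list List of [cosine_similarity()] matrices (consistent
#'   labels).
#' @param phases Optional character vector, one phase per matrix; when
#'   given, counts are grouped by phase.
#' @param include_zero Keep pairs with similarity 0? Default `FALSE`.
#' @return A tibble `similarity`, (`phase`,) `n_pairs`, sorted by
#'   decreasing similarity.
#' @export
similarity_distribution <- function(S_list, phases = NULL,
                                    include_zero = FALSE) {
  stopifnot(is.list(S_list))
  if (!is.null(phases)) stopifnot(length(phases) == length(S_list))
  rows <- purrr::imap(S_list, function(S, i) {
    ut <- upper.tri(S)
    tibble(similarity = round(S[ut], 6),
           phase = if (is.null(phases)) NA_character_ else phases[[i]])
  })
  out <- dplyr::bind_rows(rows)
  if (!include_zero) out <- dplyr::filter(out, .data$similarity != 0)
  grp <- if (is.null(phases)) "similarity" else c("phase", "similarity")
  out |>
    dplyr::count(dplyr::across(dplyr::all_of(grp)), name = "n_pairs") |>
    dplyr::arrange(dplyr::desc(.data$similarity))
}

#' Pair table of cosine similarity against coupling strength
#'
#' Joins, per event, the cosine similarity of each unordered vertex pair
#' with its coupling strength (the maximum h2 over the two directions),
#' restricted by default to contacts on distinct electrodes — the table
#' behind the similarity-versus-correlation scatter.
#'
#' @param S_list List of [cosine_similarity()] matrices, one per event.
#' @param cm_list List of matching `coupling_matrix` objects (same order
#'   and labels).
#' @param different_electrodes_only Drop pairs sharing an electrode name
#'   prefix? Default `TRUE`.
#' @return A tibble `seizure_id, phase, pair_a, pair_b, similarity, h2`.
#' @export
similarity_vs_h2 <- function(S_list, cm_list,
                             different_electrodes_only = TRUE) {
  stopifnot(length(S_list) == length(cm_list))
  rows <- purrr::map2(S_list, cm_list, function(S, cm) {
    if (!identical(rownames(S), cm$labels)) {
      stop_ictalnet("similarity and coupling matrices have mismatched labels",
                    "ictalnet_similarity_error")
    }
    ut <- which(upper.tri(S), arr.ind = TRUE)
    a <- cm$labels[ut[, 1]]; b <- cm$labels[ut[, 2]]
    tibble(
      seizure_id = if (is.null(cm$event)) NA_integer_ else
        cm$event$seizure_id[1],
      phase = if (is.null(cm$event)) NA_character_ else cm$event$phase[1],
      pair_a = pmin(a, b), pair_b = pmax(a, b),
      similarity = S[ut],
      h2 = pmax(cm$h2[cbind(ut[, 1], ut[, 2])],
                cm$h2[cbind(ut[, 2], ut[, 1])]))
  })
  out <- dplyr::bind_rows(rows)
  if (different_electrodes_only) {
    out <- dplyr::filter(out, contact_electrode(.data$pair_a) !=
                           contact_electrode(.data$pair_b))
  }
  out
}

#' Bar plot of the similarity distribution
#'
#' @param dist_tbl A [similarity_distribution()] table.
#' @return A ggplot object; pair counts per similarity value, coloured by
#'   phase when the table is grouped.
#' @export
plot_similarity_distribution <- function(dist_tbl) {
  p <- ggplot2::ggplot(dist_tbl, ggplot2::aes(x = factor(.data$similarity),
                                              y = .data$n_pairs))
  p <- if ("phase" %in% names(dist_tbl) && !all(is.na(dist_tbl$phase))) {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$phase))
  } else {
    p + ggplot2::geom_col()
  }
  p + ggplot2::labs(x = "cosine similarity", y = "electrode pairs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}
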