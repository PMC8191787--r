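#' Delaunay triangulation (Bowyer-Watson)
#'
#' Incremental Bowyer-Watson triangulation of 2D points with a strict
#' in-circumcircle predicate, so exactly cocircular configurations
#' (e.g. a square) resolve deterministically by insertion order.
#'
#' @param x,y point coordinates.
#' @return data.frame of unique undirected edges: columns \code{i},
#'   \code{j} (point indices, i < j) and \code{length}.
#' @export
delaunay_edges <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3L) stop("need at least 3 points")
  ## super-triangle enclosing everything
  cx <- mean(range(x)); cy <- mean(range(y))
  r <- max(diff(range(x)), diff(range(y)), 1) * 1e3
  px <- c(x, cx - 2 * r, cx + 2 * r, cx)
  py <- c(y, cy - r, cy - r, cy + 2 * r)
  sup <- n + 1:3
  tris <- matrix(sup, 1, 3)
  incircle <- function(tri, p) {
    ## positive when p lies strictly inside the circumcircle of tri
    ax <- px[tri[1]] - px[p]; ay <- py[tri[1]] - py[p]
    bx <- px[tri[2]] - px[p]; by <- py[tri[2]] - py[p]
    cx2 <- px[tri[3]] - px[p]; cy2 <- py[tri[3]] - py[p]
    det <- (ax^2 + ay^2) * (bx * cy2 - by * cx2) -
      (bx^2 + by^2) * (ax * cy2 - ay * cx2) +
      (cx2^2 + cy2^2) * (ax * by - ay * bx)
    ## orientation of tri
    o <- (px[tri[2]] - px[tri[1]]) * (py[tri[3]] - py[tri[1]]) -
      (py[tri[2]] - py[tri[1]]) * (px[tri[3]] - px[tri[1]])
    if (o < 0) det <- -det
    det > 1e-9 * max(1, abs(det))
  }
  for (p in seq_len(n)) {
    bad <- which(vapply(seq_len(nrow(tris)), function(t)
      incircle(tris[t, ], p), logical(1)))
    if (length(bad) == 0L) {
      ## numerically on the hull of current triangulation; attach to the
      ## triangle whose circumcenter is nearest (degenerate safeguard)
      bad <- 1L
    }
    ## boundary polygon = edges of bad triangles appearing exactly once
    edges <- do.call(rbind, lapply(bad, function(t) {
      tr <- tris[t, ]
      rbind(sort(tr[1:2]), sort(tr[2:3]), sort(tr[c(1, 3)]))
    }))
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1L)), ,
                      drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    tris <- rbind(tris, cbind(boundary, p))
  }
  keep <- rowSums(matrix(tris %in% sup, nrow(tris))) == 0L
  tris <- tris[keep, , drop = FALSE]
  e <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(1, 3)])
  e <- t(apply(e, 1, sort))
  e <- unique(e)
  data.frame(i = e[, 1], j = e[, 2],
             length = sqrt((x[e[, 1]] - x[e[, 2]])^2 +
                             (y[e[, 1]] - y[e[, 2]])^2))
}

#' Delaunay spatial network with distance cutoff
#'
#' Builds the Delaunay triangulation of cell centroids and prunes edges
#' longer than \code{cutoff}, except that every node retains at least
#' its \code{min_nn} shortest Delaunay edges. With fewer than 3 points
#' the complete graph is returned with a warning.
#'
#' @param centroids data.frame with \code{x}, \code{y} (and optionally
#'   \code{cell_id}).
#' @param cutoff maximum edge length (default 400, same units as the
#'   centroids).
#' @param min_nn minimum neighbours preserved per node (default 2).
#' @return object of class \code{spatial_graph}: list with
#'   \code{edges} (i, j, length), \code{centroids}, \code{n}.
#' @export
delaunay_network <- function(centroids, cutoff = 400, min_nn = 2) {
  n <- nrow(centroids)
  if (n < 3L) {
    warning("fewer than 3 centroids; complete graph returned")
    if (n < 2L) e <- data.frame(i = integer(0), j = integer(0),
                                length = numeric(0))
    else e <- data.frame(i = 1L, j = 2L,
                         length = sqrt(sum((centroids[1, c("x", "y")] -
                                              centroids[2, c("x", "y")])^2)))
    return(structure(list(edges = e, centroids = centroids, n = n),
                     class = "spatial_graph"))
  }
  e <- delaunay_edges(centroids$x, centroids$y)
  keep <- e$length <= cutoff
  if (min_nn > 0L) {
    for (v in seq_len(n)) {
      inc <- which(e$i == v | e$j == v)
      shortest <- inc[order(e$length[inc])][seq_len(min(min_nn,
                                                        length(inc)))]
      keep[shortest] <- TRUE
    }
  }
  structure(list(edges = e[keep, , drop = FALSE], centroids = centroids,
                 n = n),
            class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("spatial graph: %d nodes, %d edges\n", x$n, nrow(x$edges)))
  invisible(x)
}

#' Cell-type interaction enrichment by label permutation
#'
#' For every unordered pair of node labels the observed edge count is
#' compared with its expectation under \code{n_sim} uniform permutations
#' of the labels over nodes (label counts preserved, graph fixed). The
#' ratio observed/expected and a two-sided empirical p-value are
#' reported, with the central 95% band of the simulated ratios.
#'
#' @param graph \code{spatial_graph}.
#' @param labels character/factor vector, one label per node.
#' @param n_sim number of reshuffles (default 2000).
#' @param seed RNG seed for the permutations.
#' @return data.frame: label_a, label_b, observed, expected, ratio,
#'   p_value, band_lo, band_hi (2.5% / 97.5% simulated ratios).
#' @export
interaction_enrichment <- function(graph, labels, n_sim = 2000, seed = 1) {
  stopifnot(length(labels) == graph$n)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  L <- length(lev)
  npair <- L * (L + 1L) / 2L
  pair_id <- function(a, b) {
    lo <- pmin(a, b); hi <- pmax(a, b)
    ## row lo holds pairs (lo, lo..L): offset is the pairs of rows < lo
    (lo - 1L) * (L + 1L) - lo * (lo - 1L) / 2L + hi - lo + 1L
  }
  li <- match(labels, lev)
  ei <- graph$edges$i; ej <- graph$edges$j
  count_pairs <- function(lab_idx) {
    tabulate(pair_id(lab_idx[ei], lab_idx[ej]), nbins = npair)
  }
  obs <- count_pairs(li)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sims <- matrix(0L, n_sim, npair)
  for (s in seq_len(n_sim)) sims[s, ] <- count_pairs(sample(li))
  expected <- colMeans(sims)
  ratio <- ifelse(expected > 0, obs / expected, NA_real_)
  p <- vapply(seq_len(npair), function(k) {
    lo <- (sum(sims[, k] <= obs[k]) + 1) / (n_sim + 1)
    hi <- (sum(sims[, k] >= obs[k]) + 1) / (n_sim + 1)
    min(1, 2 * min(lo, hi))
  }, numeric(1))
  qs <- apply(sims, 2, stats::quantile, probs = c(0.025, 0.975))
  ab <- which(upper.tri(matrix(0, L, L), diag = TRUE), arr.ind = TRUE)
  ## enumerate pairs in the same order as pair_id
  out <- do.call(rbind, lapply(seq_len(L), function(a)
    data.frame(label_a = lev[a], label_b = lev[a:L])))
  out$observed <- obs
  out$expected <- expected
  out$ratio <- ratio
  out$p_value <- p
  out$band_lo <- ifelse(expected > 0, qs[1, ] / expected, NA_real_)
  out$band_hi <- ifelse(expected > 0, qs[2, ] / expected, NA_real_)
  out
}

#' Gene-gene spatial proximity by label permutation
#'
#' Counts amplicon pairs of two genes lying within \code{radius} of each
#' other and normalises by the mean count under permutations of the
#' gene labels over amplicon positions. Values above 1 indicate genes
#' found together more often than chance; the matrix is symmetric and
#' suitable for hierarchical clustering. This normalisation is a
#' permutation-null co-occurrence statistic.
#'
#' @param positions data.frame with \code{x}, \code{y} amplicon
#'   coordinates.
#' @param genes gene label per amplicon.
#' @param radius proximity radius in the same units (default 50).
#' @param n_sim permutations (default 200).
#' @param seed RNG seed.
#' @return list with \code{proximity} (gene x gene matrix),
#'   \code{observed}, \code{expected} and \code{low_support} (genes with
#'   fewer than 2 amplicons).
#' @export
gene_proximity <- function(positions, genes, radius = 50, n_sim = 200,
                           seed = 1) {
  genes <- as.character(genes)
  lev <- sort(unique(genes))
  G <- length(lev)
  gi <- match(genes, lev)
  n <- nrow(positions)
  d2 <- as.matrix(stats::dist(cbind(positions$x, positions$y)))^2
  close <- which(upper.tri(d2) & d2 <= radius^2, arr.ind = TRUE)
  count_mat <- function(g) {
    m <- matrix(0, G, G, dimnames = list(lev, lev))
    if (nrow(close) == 0L) return(m)
    a <- pmin(g[close[, 1]], g[close[, 2]])
    b <- pmax(g[close[, 1]], g[close[, 2]])
    cnt <- tabulate((a - 1L) * G + b, nbins = G * G)
    for (p in which(cnt > 0L)) {
      ia <- (p - 1L) %/% G + 1L; ib <- (p - 1L) %% G + 1L
      m[ia, ib] <- m[ia, ib] + cnt[p]
      if (ia != ib) m[ib, ia] <- m[ib, ia] + cnt[p]
    }
    m
  }
  obs <- count_mat(gi)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expm <- matrix(0, G, G, dimnames = list(lev, lev))
  for (s in seq_len(n_sim)) expm <- expm + count_mat(sample(gi))
  expm <- expm / n_sim
  prox <- ifelse(expm > 0, obs / expm, NA_real_)
  dimnames(prox) <- list(lev, lev)
  list(proximity = prox, observed = obs, expected = expm,
       low_support = lev[tabulate(gi, G) < 2L])
}
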