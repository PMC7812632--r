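#' @include stats-adjacency.R
NULL

#' Sign-flip permutation t-test with FDR correction
#'
#' Per-cell one-sample t statistic against zero (e.g. on within-dyad
#' condition differences), with p-values from the sign-flip permutation
#' distribution (exact enumeration of all 2^n sign patterns when that count
#' does not exceed \code{nPermutations}, random flips otherwise) and a
#' Benjamini-Hochberg significance mask at \code{alpha}. Cells with zero
#' variance are flagged undefined and excluded from the FDR family. The
#' p-value convention includes the observed labeling:
#' (1 + exceedances) / (1 + permutations).
#'
#' @param data subjects x cells numeric matrix of condition differences.
#' @param nPermutations number of sign-flip permutations (>= 100).
#' @param alpha FDR level (default 0.05).
#' @param tail 0 two-sided (default), 1 positive, -1 negative.
#' @param seed optional integer seed for the random flips.
#' @return An \linkS4class{FdrTestResult}; \code{tObsPlot} carries the
#'   observed t where significant and 0 elsewhere, ready for
#'   [plotSignificantSensors()].
#' @export
permTtestFdr <- function(data, nPermutations = 5000L, alpha = 0.05,
                         tail = 0L, seed = NULL) {
  data <- as.matrix(data)
  n <- nrow(data); nCell <- ncol(data)
  if (n < 2L) stop("need at least 2 subjects")
  nPermutations <- as.integer(nPermutations)
  if (nPermutations < 100L) stop("need at least 100 permutations")
  stopifnot(tail %in% c(-1L, 0L, 1L))
  mu <- colMeans(data)
  s <- apply(data, 2L, stats::sd)
  excluded <- s < .EPS
  tObs <- ifelse(excluded, NA_real_, mu / (s / sqrt(n)))
  ## sign-flip distribution: variance recomputed per flip from the fixed
  ## per-cell sum of squares
  q <- colSums(data^2)
  if (2^n <= nPermutations) {
    flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    B <- nrow(flips)
    flips <- t(flips)
  } else {
    if (!is.null(seed)) set.seed(seed)
    B <- nPermutations
    flips <- matrix(sample(c(-1, 1), n * B, replace = TRUE), nrow = n)
  }
  M <- crossprod(data, flips) / n                      # cells x B flip means
  V <- (q - n * M^2) / (n - 1)
  Tperm <- M / sqrt(pmax(V, .EPS) / n)
  pv <- rep(NA_real_, nCell)
  for (c0 in which(!excluded)) {
    exc <- switch(as.character(tail),
      "0" = sum(abs(Tperm[c0, ]) >= abs(tObs[c0]) - 1e-10),
      "1" = sum(Tperm[c0, ] >= tObs[c0] - 1e-10),
      "-1" = sum(Tperm[c0, ] <= tObs[c0] + 1e-10))
    pv[c0] <- (1 + exc) / (1 + B)
  }
  mask <- rep(FALSE, nCell)
  fam <- which(!excluded)
  if (length(fam))
    mask[fam] <- stats::p.adjust(pv[fam], method = "BH") <= alpha
  tPlot <- ifelse(mask, tObs, 0)
  tPlot[is.na(tPlot)] <- 0
  new("FdrTestResult", tObs = tObs, pValues = pv, mask = mask,
      tObsPlot = tPlot, excluded = excluded, alpha = alpha,
      nPermutations = B, tail = as.integer(tail))
}

## connected components among `idx` cells under logical adjacency `adj`
## (NULL adjacency: every cell its own component). Plain BFS; this sits in
## the permutation hot loop, so no graph objects.
cellComponents <- function(idx, adj) {
  if (!length(idx)) return(list())
  if (is.null(adj)) return(as.list(idx))
  comps <- list()
  seen <- logical(length(idx))
  for (s in seq_along(idx)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      members <- c(members, idx[v])
      nb <- which(adj[idx[v], idx] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

## vectorized statistic maps over permutations ------------------------------

indTtestStat <- function(X, g1mask, n1, n2) {
  ## X: subjects x cells; g1mask: subjects x B logical/0-1
  S1 <- crossprod(X, g1mask)                   # cells x B
  Q1 <- crossprod(X^2, g1mask)
  sAll <- colSums(X); qAll <- colSums(X^2)
  S2 <- sAll - S1; Q2 <- qAll - Q1
  m1 <- S1 / n1; m2 <- S2 / n2
  v1 <- (Q1 - n1 * m1^2) / (n1 - 1)
  v2 <- (Q2 - n2 * m2^2) / (n2 - 1)
  sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(pmax(sp, .EPS) * (1 / n1 + 1 / n2))
}

fOnewayStat <- function(X, masks, sizes) {
  ## masks: list of subjects x B indicator matrices, one per group
  k <- length(masks)
  n <- nrow(X)
  qAll <- colSums(X^2); sAll <- colSums(X)
  ssb <- 0
  for (g in seq_len(k)) {
    Sg <- crossprod(X, masks[[g]])
    ssb <- ssb + Sg^2 / sizes[g]
  }
  ssb <- ssb - outer(sAll^2 / n, rep(1, ncol(masks[[1L]])))
  ssw <- outer(qAll, rep(1, ncol(masks[[1L]]))) -
    (ssb + outer(sAll^2 / n, rep(1, ncol(masks[[1L]]))))
  (ssb / (k - 1)) / pmax(ssw / (n - k), .EPS)
}

#' Cluster-based permutation test over space-frequency cell maps
#'
#' Computes the observed statistic per cell (independent-samples t, paired t
#' or one-way F across the supplied groups), groups suprathreshold cells into
#' connected components under the supplied adjacency (no adjacency: every
#' cell is its own cluster), and compares each cluster's mass (sum of its
#' statistics) to the permutation null distribution of the maximum cluster
#' mass under group-label exchange (sign flips for the paired test). The
#' cluster-forming threshold defaults to the parametric critical value of the
#' test at \code{alpha}; pass \code{clusterThreshold} to use a raw statistic
#' value instead. With \code{tail = 0}, positive and negative clusters are
#' formed separately and compared on |mass|. Multi-way ANOVA designs
#' (\code{factorLevel}) are not implemented.
#'
#' @param data list of subjects x cells matrices, one per group/condition
#'   (equal cell counts; equal subject counts for the paired test).
#' @param test "ind_ttest", "rel_ttest" or "f_oneway".
#' @param adjacency an \linkS4class{AdjacencyStructure} (its expanded
#'   \code{chConFreq} is used), a logical cell-adjacency matrix, or NULL.
#' @param tail 0 two-sided (default), 1 positive, -1 negative; F tests are
#'   always right-tailed.
#' @param nPermutations permutation count (default 5000).
#' @param alpha cluster-forming and reporting level (default 0.05).
#' @param clusterThreshold optional raw statistic threshold overriding the
#'   parametric critical value.
#' @param seed optional integer seed.
#' @param factorLevel accepted for interface compatibility; any non-NULL
#'   value is rejected (multi-way ANOVA clustering is not implemented).
#' @return A \linkS4class{ClusterStatsResult}.
#' @seealso [conMatrix()], [interCellAdjacency()], [permTtestFdr()]
#' @export
statsCluster <- function(data, test = c("ind_ttest", "rel_ttest", "f_oneway"),
                         adjacency = NULL, tail = 0L,
                         nPermutations = 5000L, alpha = 0.05,
                         clusterThreshold = NULL, seed = NULL,
                         factorLevel = NULL) {
  test <- match.arg(test)
  if (!is.null(factorLevel))
    stop("multi-way ANOVA cluster statistics are not implemented; ",
         "factorLevel must be NULL")
  stopifnot(is.list(data), length(data) >= 2L)
  data <- lapply(data, as.matrix)
  nCell <- unique(vapply(data, ncol, integer(1L)))
  if (length(nCell) != 1L)
    stop("all groups must share the cell count")
  k <- length(data)
  if (test %in% c("ind_ttest", "rel_ttest") && k != 2L)
    stop("t-tests compare exactly 2 groups; got ", k,
         " (use f_oneway for k > 2)")
  if (test == "rel_ttest" &&
      nrow(data[[1L]]) != nrow(data[[2L]]))
    stop("paired test requires equal group sizes")
  if (is(adjacency, "AdjacencyStructure")) {
    adjacency <- adjacency@chConFreq
  }
  if (!is.null(adjacency)) {
    stopifnot(is.matrix(adjacency))
    if (nrow(adjacency) != nCell)
      stop("adjacency has ", nrow(adjacency), " nodes but maps have ",
           nCell, " cells")
  }
  tail <- as.integer(tail)
  nPermutations <- as.integer(nPermutations)
  if (!is.null(seed)) set.seed(seed)

  if (test == "f_oneway") tail <- 1L
  sizes <- vapply(data, nrow, integer(1L))
  n <- sum(sizes)

  if (test == "rel_ttest") {
    D <- data[[1L]] - data[[2L]]
    nd <- nrow(D)
    df <- nd - 1L
    mu <- colMeans(D); s <- apply(D, 2L, stats::sd)
    tObs <- mu / pmax(s / sqrt(nd), .EPS)
    flips <- matrix(sample(c(-1, 1), nd * nPermutations, replace = TRUE),
                    nrow = nd)
    q <- colSums(D^2)
    M <- crossprod(D, flips) / nd
    V <- (q - nd * M^2) / (nd - 1)
    Tperm <- M / sqrt(pmax(V, .EPS) / nd)
  } else if (test == "ind_ttest") {
    X <- rbind(data[[1L]], data[[2L]])
    n1 <- sizes[1L]; n2 <- sizes[2L]
    df <- n - 2L
    g1obs <- matrix(0, n, 1L); g1obs[seq_len(n1), 1L] <- 1
    tObs <- drop(indTtestStat(X, g1obs, n1, n2))
    g1perm <- matrix(0, n, nPermutations)
    for (b in seq_len(nPermutations))
      g1perm[sample.int(n, n1), b] <- 1
    Tperm <- indTtestStat(X, g1perm, n1, n2)
  } else {
    X <- do.call(rbind, data)
    df <- c(k - 1L, n - k)
    labs <- rep(seq_len(k), sizes)
    masksObs <- lapply(seq_len(k), function(g)
      matrix(as.numeric(labs == g), ncol = 1L))
    tObs <- drop(fOnewayStat(X, masksObs, sizes))
    permLabs <- replicate(nPermutations, sample(labs))
    masks <- lapply(seq_len(k), function(g)
      matrix(as.numeric(permLabs == g), nrow = n))
    Tperm <- fOnewayStat(X, masks, sizes)
  }

  thr <- if (!is.null(clusterThreshold)) clusterThreshold else {
    if (test == "f_oneway") stats::qf(1 - alpha, df[1L], df[2L])
    else if (tail == 0L) stats::qt(1 - alpha / 2, df)
    else stats::qt(1 - alpha, df)
  }

  supra <- function(stat) {
    pos <- if (tail >= 0L) which(stat > thr) else integer(0)
    neg <- if (tail <= 0L && test != "f_oneway") which(stat < -thr)
      else integer(0)
    list(pos = pos, neg = neg)
  }
  obsIdx <- supra(tObs)
  clusters <- c(cellComponents(obsIdx$pos, adjacency),
                cellComponents(obsIdx$neg, adjacency))
  masses <- vapply(clusters, function(cl) sum(tObs[cl]), numeric(1L))

  nullMax <- numeric(nPermutations)
  for (b in seq_len(nPermutations)) {
    st <- Tperm[, b]
    si <- supra(st)
    mx <- 0
    if (length(si$pos)) {
      cm <- vapply(cellComponents(si$pos, adjacency),
                   function(cl) sum(st[cl]), numeric(1L))
      mx <- max(mx, abs(cm))
    }
    if (length(si$neg)) {
      cm <- vapply(cellComponents(si$neg, adjacency),
                   function(cl) sum(st[cl]), numeric(1L))
      mx <- max(mx, abs(cm))
    }
    nullMax[b] <- mx
  }
  pvals <- vapply(masses, function(m)
    (1 + sum(nullMax >= abs(m) - 1e-10)) / (1 + nPermutations), numeric(1L))
  mask <- rep(FALSE, nCell)
  if (length(clusters))
    mask[unlist(clusters[pvals <= alpha])] <- TRUE
  new("ClusterStatsResult", tObs = tObs, clusters = clusters,
      clusterMasses = masses, clusterP = pvals, significantMask = mask,
      nPermutations = nPermutations, test = test, tail = tail,
      alpha = alpha, threshold = thr)
}

#' Surrogate dyad schemes for permutation nulls
#'
#' Builds the permutation-null ingredients for inter-brain coupling:
#' \describe{
#'   \item{shuffle_time}{an independent epoch-index permutation per
#'     participant (destroys across-participant epoch alignment while
#'     preserving each participant's signal statistics); requires
#'     \code{nEpochs}. A circular sample shift is available via
#'     \code{granularity = "sample"}, which returns per-participant random
#'     shift offsets instead.}
#'   \item{fake_pairs_within}{re-pairs participants inside each group by a
#'     derangement of the partner assignment, so no surrogate pair equals a
#'     true pair (a group of 1 dyad is infeasible and errors).}
#'   \item{fake_pairs_between}{pairs first members of each dyad in one group
#'     with second members in the other group.}
#' }
#'
#' @param participants data.frame with columns \code{id}, \code{dyad},
#'   \code{group} and \code{role} (1 or 2 within each dyad).
#' @param scheme one of "shuffle_time", "fake_pairs_within",
#'   "fake_pairs_between".
#' @param seed integer seed; results are reproducible given it.
#' @param nEpochs epoch count, required for shuffle_time.
#' @param granularity for shuffle_time: "epoch" (default) permutes epoch
#'   indices, "sample" draws circular sample-shift offsets (requires
#'   \code{nSamplesEpoch}).
#' @param nSamplesEpoch samples per epoch for \code{granularity = "sample"}.
#' @return For shuffle_time, a named list per participant id of epoch
#'   permutations (or shift offsets); for the pairing schemes, a data.frame
#'   of surrogate pairs with columns id1, id2, group1, group2.
#' @export
permuteDyads <- function(participants,
                         scheme = c("shuffle_time", "fake_pairs_within",
                                    "fake_pairs_between"),
                         seed = 1L, nEpochs = NULL,
                         granularity = c("epoch", "sample"),
                         nSamplesEpoch = NULL) {
  scheme <- match.arg(scheme)
  granularity <- match.arg(granularity)
  stopifnot(is.data.frame(participants),
            all(c("id", "dyad", "group", "role") %in% names(participants)))
  set.seed(as.integer(seed))
  if (scheme == "shuffle_time") {
    if (granularity == "epoch") {
      if (is.null(nEpochs)) stop("shuffle_time requires nEpochs")
      out <- lapply(seq_len(nrow(participants)),
                    function(i) sample.int(nEpochs))
    } else {
      if (is.null(nSamplesEpoch))
        stop("sample-level shuffle_time requires nSamplesEpoch")
      out <- lapply(seq_len(nrow(participants)),
                    function(i) sample.int(nSamplesEpoch, 1L))
    }
    names(out) <- participants$id
    return(out)
  }
  p1 <- participants[participants$role == 1L, , drop = FALSE]
  p2 <- participants[participants$role == 2L, , drop = FALSE]
  if (scheme == "fake_pairs_within") {
    pieces <- lapply(split(seq_len(nrow(p1)), p1$group), function(ix) {
      m <- length(ix)
      if (m < 2L)
        stop("fake_pairs_within is infeasible for a group with a single ",
             "dyad")
      ## derangement of the partner assignment
      repeat {
        perm <- sample.int(m)
        if (!any(perm == seq_len(m))) break
      }
      d1 <- p1[ix, , drop = FALSE]
      mates <- p2[match(d1$dyad[perm], p2$dyad), , drop = FALSE]
      data.frame(id1 = d1$id, id2 = mates$id,
                 group1 = d1$group, group2 = mates$group,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    return(out)
  }
  ## fake_pairs_between
  groups <- unique(participants$group)
  if (length(groups) < 2L)
    stop("fake_pairs_between requires at least two groups")
  gA <- p1[p1$group == groups[1L], , drop = FALSE]
  gB <- p2[p2$group == groups[2L], , drop = FALSE]
  if (!nrow(gA) || !nrow(gB))
    stop("fake_pairs_between: a group has no members in the required role")
  m <- min(nrow(gA), nrow(gB))
  ia <- sample(seq_len(nrow(gA)), m)
  ib <- sample(seq_len(nrow(gB)), m)
  data.frame(id1 = gA$id[ia], id2 = gB$id[ib],
             group1 = gA$group[ia], group2 = gB$group[ib],
             stringsAsFactors = FALSE)
}
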