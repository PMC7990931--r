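#' Kruskal-Wallis rank sum test (tie-corrected)
#'
#' Nonparametric k-group location test on pooled midranks. With group rank
#' sums R_i, group sizes n_i, total N and tie blocks of size t:
#' \deqn{H = \frac{\frac{12}{N(N+1)} \sum R_i^2/n_i - 3(N+1)}
#'            {1 - \sum (t^3 - t)/(N^3 - N)},}
#' with the p-value from the chi-square distribution on k - 1 df.
#'
#' @param groups Named or unnamed list of numeric vectors (>= 2 groups,
#'   total N >= 3).
#' @return List of class `kw_result`: `H`, `df`, `p_value`, `group_sizes`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  n_i <- lengths(groups)
  if (any(n_i == 0L)) stop("empty group", call. = FALSE)
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  if (N < 3L) stop("need total N >= 3", call. = FALSE)
  if (length(unique(pooled)) == 1L) {
    stop("degenerate data: all values identical (tie correction divides by zero)",
         call. = FALSE)
  }
  r <- rank(pooled)  # midranks
  grp <- rep(seq_len(k), n_i)
  R_i <- tapply(r, grp, sum)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  H_raw <- 12 / (N * (N + 1)) * sum(R_i^2 / n_i) - 3 * (N + 1)
  H <- H_raw / (1 - tie_term / (N^3 - N))
  df <- k - 1L
  structure(list(H = H, df = df,
                 p_value = stats::pchisq(H, df, lower.tail = FALSE),
                 group_sizes = as.integer(n_i)),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g (n = %s)\n",
              x$H, x$df, x$p_value, paste(x$group_sizes, collapse = ", ")))
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' p_adj(i) = min over j >= i of p_(j) * m / j, capped at 1, mapped back to
#' the input order. Monotone in the order statistics of the input.
#'
#' @param p Raw p-values.
#' @return Adjusted p-values in the input order.
#' @keywords internal
bh_adjust <- function(p) {
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Dunn's multiple-comparison post-hoc test
#'
#' Pairwise z-tests on mean pooled midranks following a significant
#' Kruskal-Wallis test. For groups i, j with tie blocks of size t:
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}
#'   {\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum (t^3 - t)}{12(N-1)}\right)
#'          \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}},}
#' with two-sided normal p-values and, by default, Benjamini-Hochberg
#' adjustment across all k(k-1)/2 pairs jointly.
#'
#' @param groups As in [kruskal_wallis()].
#' @param adjust `"bh"` (default) or `"none"`.
#' @return Data frame of class `dunn_result`: `group_a`, `group_b`, `z`,
#'   `p_raw`, `p_adj`, one row per unordered pair.
#' @export
dunn_posthoc <- function(groups, adjust = c("bh", "none")) {
  adjust <- match.arg(adjust)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("group", seq_len(k))
  n_i <- lengths(groups)
  if (any(n_i == 0L)) stop("empty group", call. = FALSE)
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  if (N < 3L) stop("need total N >= 3", call. = FALSE)
  if (length(unique(pooled)) == 1L) {
    stop("degenerate data: all values identical", call. = FALSE)
  }
  r <- rank(pooled)
  grp <- rep(seq_len(k), n_i)
  mean_rank <- tapply(r, grp, mean)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  var_base <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  pairs <- utils::combn(k, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    z <- (mean_rank[i] - mean_rank[j]) /
      sqrt(var_base * (1 / n_i[i] + 1 / n_i[j]))
    data.frame(group_a = labels[i], group_b = labels[j],
               z = unname(z),
               p_raw = 2 * stats::pnorm(-abs(unname(z))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (adjust == "bh") bh_adjust(out$p_raw) else out$p_raw
  class(out) <- c("dunn_result", class(out))
  out
}

#' UPGMA (average-linkage) clustering of specimen delta-18O_P
#'
#' Agglomerative clustering on pairwise absolute delta-18O_P differences
#' (Euclidean distance in one dimension). Inter-cluster distance is the
#' unweighted mean over all cross pairs, maintained by the Lance-Williams
#' size-weighted update. Deterministic tie-break: among merge candidates at
#' the minimal distance, merge the pair whose earliest member (input order)
#' comes first, then the pair whose other cluster's earliest member comes
#' first.
#'
#' @param records Specimen data frame with `specimen_id` and `d18O_p`, or a
#'   (optionally named) numeric vector of values.
#' @return Object of class `cluster_tree`: `labels` (leaf ids, input
#'   order), `merge` ((n-1) x 2 matrix, hclust encoding: negative = leaf
#'   index, positive = earlier merge), `height` (merge distances, per mil).
#' @export
upgma_cluster <- function(records) {
  if (is.data.frame(records)) {
    values <- records$d18O_p
    labels <- records$specimen_id
  } else {
    values <- as.numeric(records)
    labels <- names(records)
  }
  keep <- !is.na(values)
  values <- values[keep]
  if (is.null(labels)) labels <- paste0("leaf", seq_along(values)) else labels <- labels[keep]
  n <- length(values)
  if (n < 2L) stop("need at least 2 records with d18O_p", call. = FALSE)

  d <- abs(outer(values, values, "-"))
  diag(d) <- Inf
  size <- rep(1L, n)                 # cluster sizes
  node <- -seq_len(n)                # hclust node codes
  min_leaf <- seq_len(n)             # earliest input index per cluster
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    dmin <- min(d[idx, idx])
    cand <- which(d == dmin & upper.tri(d), arr.ind = TRUE)
    cand <- cand[active[cand[, 1L]] & active[cand[, 2L]], , drop = FALSE]
    key_a <- pmin(min_leaf[cand[, 1L]], min_leaf[cand[, 2L]])
    key_b <- pmax(min_leaf[cand[, 1L]], min_leaf[cand[, 2L]])
    pick <- order(key_a, key_b)[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]
    height[step] <- dmin
    merge[step, ] <- sort(c(node[i], node[j]))
    # average-linkage update into slot i; retire slot j
    others <- setdiff(which(active), c(i, j))
    if (length(others) > 0L) {
      d[i, others] <- (size[i] * d[i, others] + size[j] * d[j, others]) /
        (size[i] + size[j])
      d[others, i] <- d[i, others]
    }
    size[i] <- size[i] + size[j]
    min_leaf[i] <- min(min_leaf[i], min_leaf[j])
    node[i] <- step
    active[j] <- FALSE
    d[j, ] <- Inf; d[, j] <- Inf
  }
  if (any(diff(height) < -1e-12)) {
    warning("non-monotone merge heights: distances are not ultrametric under average linkage")
  }
  structure(list(labels = labels, merge = merge, height = height),
            class = "cluster_tree")
}

#' Convert a cluster tree to an hclust object
#'
#' @param tree A `cluster_tree`.
#' @return A [stats::hclust] object (for plotting or [stats::cutree]).
#' @export
as_hclust <- function(tree) {
  n <- length(tree$labels)
  order_leaves <- function(node) {
    if (node < 0) return(-node)
    c(order_leaves(tree$merge[node, 1L]), order_leaves(tree$merge[node, 2L]))
  }
  structure(list(merge = tree$merge, height = tree$height,
                 order = order_leaves(n - 1L), labels = tree$labels,
                 method = "average", dist.method = "euclidean"),
            class = "hclust")
}

#' Cut a cluster tree into k groups
#'
#' Removes the k - 1 highest merges (equivalently: keeps the first n - k
#' merges, heights being non-decreasing) and returns the resulting leaf
#' groups.
#'
#' @param tree A `cluster_tree`.
#' @param k Number of groups, 1 <= k <= number of leaves.
#' @return List of k character vectors of leaf labels, ordered by earliest
#'   member.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$labels)
  if (k < 1L || k > n) stop("k must be between 1 and the number of leaves",
                            call. = FALSE)
  member <- seq_len(n)  # cluster id per leaf
  cluster_of_node <- integer(n - 1L)
  take <- function(node) {
    if (node < 0) member[-node] else cluster_of_node[node]
  }
  n_keep <- n - k
  for (step in seq_len(n_keep)) {
    a <- take(tree$merge[step, 1L])
    b <- take(tree$merge[step, 2L])
    member[member == b] <- a
    cluster_of_node[step] <- a
  }
  if (n_keep < n - 1L) {
    for (step in seq(n_keep + 1L, n - 1L)) {
      # record representatives for later merges so `take` stays valid
      cluster_of_node[step] <- take(tree$merge[step, 1L])
    }
  }
  ids <- unique(member)
  lapply(ids, function(id) tree$labels[member == id])
}

#' Export a cluster tree as Newick
#'
#' Ultrametric export: each node sits at depth equal to its merge height,
#' so a branch length is the height difference between a node and its
#' parent (leaves sit at height 0).
#'
#' @param tree A `cluster_tree`.
#' @return A single Newick string, semicolon-terminated.
#' @export
as_newick <- function(tree) {
  clean <- gsub("[,;:()\\s]", "_", tree$labels)
  node_height <- function(node) if (node < 0) 0 else tree$height[node]
  render <- function(node, parent_height) {
    bl <- parent_height - node_height(node)
    if (node < 0) {
      sprintf("%s:%.10g", clean[-node], bl)
    } else {
      sprintf("(%s,%s):%.10g",
              render(tree$merge[node, 1L], tree$height[node]),
              render(tree$merge[node, 2L], tree$height[node]),
              bl)
    }
  }
  root <- length(tree$labels) - 1L
  sprintf("(%s,%s);",
          render(tree$merge[root, 1L], tree$height[root]),
          render(tree$merge[root, 2L], tree$height[root]))
}

#' Per-group mean, SD and n
#'
#' @param records Specimen data frame.
#' @param value Column to summarise (default `d18O_p`).
#' @param by Grouping column (default `region`).
#' @return Data frame `label`, `n`, `mean`, `sd` (sample SD, n - 1
#'   denominator; `NA` for singleton groups), in order of first appearance.
#' @export
group_summary <- function(records, value = "d18O_p", by = "region") {
  labels <- unique(records[[by]])
  rows <- lapply(labels, function(lab) {
    v <- records[[value]][records[[by]] == lab]
    v <- v[!is.na(v)]
    data.frame(label = lab, n = length(v),
               mean = if (length(v) > 0L) mean(v) else NA_real_,
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standardize a GLG profile to its first growth layer
#'
#' Subtracts the first-GLG value from every value of an analyte, so each
#' profile starts at 0 and pairwise differences are preserved. Used to
#' overlay within-tooth time series from teeth with different absolute
#' levels.
#'
#' @param profile Data frame for one specimen with `glg_index` and analyte
#'   columns `d18O_sc` and/or `d13C_sc`.
#' @return The profile with each present analyte standardized.
#' @export
standardize_profile <- function(profile) {
  for (col in intersect(c("d18O_sc", "d13C_sc"), names(profile))) {
    v <- profile[[col]]
    if (all(is.na(v))) next
    if (is.na(v[1L])) {
      stop("cannot standardize ", col, ": first GLG value is missing",
           call. = FALSE)
    }
    profile[[col]] <- v - v[1L]
  }
  profile
}

#' Within-tooth variation index
#'
#' Sample SD and range (max - min) of one analyte's per-GLG series — the
#' index of interannual variation in an individual's distribution.
#'
#' @param profile Data frame for one specimen (see [standardize_profile()]),
#'   or a numeric vector.
#' @param analyte Analyte column when `profile` is a data frame.
#' @return List with `sd` and `range`, per mil.
#' @export
within_tooth_index <- function(profile, analyte = "d18O_sc") {
  v <- if (is.data.frame(profile)) profile[[analyte]] else as.numeric(profile)
  v <- v[!is.na(v)]
  if (length(v) < 2L) {
    stop("need at least 2 non-missing values", call. = FALSE)
  }
  list(sd = stats::sd(v), range = max(v) - min(v))
}
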