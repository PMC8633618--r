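#' Paired t map over channels and time
#'
#' Two-tailed paired-sample t statistics at every (channel, time)
#' point: `t = mean(d) / (sd(d)/sqrt(n))` with `d = A - B` and
#' `df = n - 1`. Points with zero-variance differences get `t = 0` and
#' are flagged.
#'
#' @param A,B arrays of identical shape, subjects x channels x time.
#' @return channels x time matrix of t values with attributes `df` and
#'   `degenerate` (logical matrix of zero-variance points).
#' @export
paired_t_map <- function(A, B) {
  if (!identical(dim(A), dim(B))) stop("A and B must have identical shape")
  n <- dim(A)[1]
  if (n < 3) stop("need at least 3 subjects for a paired t map")
  d <- A - B
  m <- apply(d, c(2, 3), mean)
  s <- apply(d, c(2, 3), stats::sd)
  degen <- s <= 0
  t <- ifelse(degen, 0, m / (s / sqrt(n)))
  attr(t, "df") <- n - 1
  attr(t, "degenerate") <- degen
  t
}

# adjacency argument normalisation: accept hep_adjacency or a plain
# neighbour list
adjacency_neighbors <- function(adjacency, nch) {
  nb <- if (inherits(adjacency, "hep_adjacency")) adjacency$neighbors
        else adjacency
  if (length(nb) != nch) {
    stop("adjacency covers ", length(nb), " channels but the data have ", nch)
  }
  lapply(nb, as.integer)
}

#' Form spatio-temporal clusters from a t map
#'
#' Thresholds the map at the two-tailed critical t value for `df` at
#' level `alpha`, then finds connected components over temporal
#' adjacency (neighbouring time points, same channel) and spatial
#' adjacency (neighbouring channels, same time point), separately for
#' positive and negative signs. A suprathreshold sample is retained
#' only if at least `min_neighbors` of its spatial neighbours are also
#' suprathreshold (set 0 to disable this pruning; it is the
#' interpretation of the "at least two neighbouring channels" rule and
#' is configurable). The cluster mass is the sum of member t values.
#'
#' @param tmap channels x time t matrix (e.g. from [paired_t_map()]).
#' @param adjacency a `hep_adjacency` or per-channel neighbour list.
#' @param df degrees of freedom for the critical value; taken from the
#'   `df` attribute of `tmap` when missing.
#' @param alpha two-tailed cluster-forming alpha.
#' @param min_neighbors spatial-neighbour pruning parameter.
#' @return list with `clusters` (each: `channels`, `times`, `sign`,
#'   `mass`), `labels` matrix, and `threshold`.
#' @export
form_clusters <- function(tmap, adjacency, df = NULL, alpha = 0.05,
                          min_neighbors = 2) {
  if (any(!is.finite(tmap))) stop("tmap must be finite")
  df <- df %||% attr(tmap, "df")
  if (is.null(df)) stop("df must be supplied (or carried by tmap)")
  thresh <- stats::qt(1 - alpha / 2, df)
  nb <- adjacency_neighbors(adjacency, nrow(tmap))
  res <- cpp_form_clusters(unclass(tmap), thresh, nb,
                           as.integer(min_neighbors))
  clusters <- lapply(seq_along(res$masses), function(k) {
    idx <- which(res$labels == k, arr.ind = TRUE)
    list(channels = sort(unique(idx[, 1])),
         times = sort(unique(idx[, 2])),
         members = idx,
         sign = res$signs[k],
         mass = res$masses[k])
  })
  list(clusters = clusters, labels = res$labels, threshold = thresh)
}

#' Spatio-temporal cluster-based permutation test for paired data
#'
#' The observed clusters come from [form_clusters()] on the paired t
#' map of the (optionally time-windowed) data. The null distribution is
#' built by per-subject random condition swaps - sign flips of the
#' difference maps, the standard paired permutation scheme - taking the
#' maximum absolute cluster mass of each of `n_perm` Monte-Carlo
#' permutations. Each observed cluster's p value is
#' `(1 + #[null >= |mass|]) / (1 + n_perm)` (the +1 correction avoids
#' p = 0). Both signs are tested against the same max-|mass| null; the
#' default significance label uses p < alpha/2 per tail, with raw p
#' always reported.
#'
#' @param A,B subjects x channels x time arrays (condition A minus B is
#'   tested).
#' @param adjacency a `hep_adjacency` covering the channel dimension.
#' @param times_ms optional time axis (ms) for windowing and reporting.
#' @param window_ms optional analysis window in ms (e.g. `c(350, 650)`).
#' @param n_perm number of Monte-Carlo permutations (default 5000).
#' @param alpha two-tailed alpha used both for cluster forming and for
#'   the significance label.
#' @param min_neighbors spatial pruning parameter (see
#'   [form_clusters()]).
#' @param seed RNG seed for the permutation draws.
#' @param labels optional channel labels for reporting.
#' @return object of class `hep_cluster_test`: a data.frame `clusters`
#'   (sign, mass, p, time range, channels), the `null_distribution`,
#'   and the configuration echo.
#' @export
cluster_permutation_test <- function(A, B, adjacency, times_ms = NULL,
                                     window_ms = NULL, n_perm = 5000,
                                     alpha = 0.05, min_neighbors = 2,
                                     seed = 1, labels = NULL) {
  if (!identical(dim(A), dim(B))) stop("A and B must have identical shape")
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p value")
  n <- dim(A)[1]; nch <- dim(A)[2]
  if (!is.null(window_ms)) {
    if (is.null(times_ms)) stop("window_ms requires times_ms")
    if (window_ms[2] <= window_ms[1]) {
      stop("invalid analysis window: end must exceed start")
    }
    sel <- times_ms >= window_ms[1] & times_ms <= window_ms[2]
    if (!any(sel)) stop("analysis window contains no samples")
    A <- A[, , sel, drop = FALSE]
    B <- B[, , sel, drop = FALSE]
    times_ms <- times_ms[sel]
  }
  nt <- dim(A)[3]
  tmap <- paired_t_map(A, B)
  fc <- form_clusters(tmap, adjacency, df = n - 1, alpha = alpha,
                      min_neighbors = min_neighbors)
  d <- A - B
  d_mat <- matrix(aperm(d, c(2, 3, 1)), nrow = n, ncol = nch * nt,
                  byrow = TRUE)
  nb <- adjacency_neighbors(adjacency, nch)
  set.seed(seed)
  flips <- matrix(sample(c(-1L, 1L), n_perm * n, replace = TRUE), n_perm, n)
  null <- cpp_null_max_mass(d_mat, flips, nch, nt, fc$threshold, nb,
                            as.integer(min_neighbors))
  ch_labels <- labels %||%
    (if (inherits(adjacency, "hep_adjacency")) adjacency$labels else
       paste0("ch", seq_len(nch)))
  clusters <- if (length(fc$clusters)) {
    do.call(rbind, lapply(seq_along(fc$clusters), function(k) {
      cl <- fc$clusters[[k]]
      # tolerance guard: null masses arising from the same sign
      # pattern as the observed data are equal up to roundoff
      p <- (1 + sum(null >= abs(cl$mass) * (1 - 1e-9))) / (1 + n_perm)
      data.frame(
        cluster = k,
        sign = if (cl$sign > 0) "positive" else "negative",
        mass = cl$mass,
        p = p,
        start_ms = if (!is.null(times_ms)) min(times_ms[cl$times]) else NA,
        end_ms = if (!is.null(times_ms)) max(times_ms[cl$times]) else NA,
        n_channels = length(cl$channels),
        channels = paste(ch_labels[cl$channels], collapse = ","),
        stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(cluster = integer(0), sign = character(0), mass = numeric(0),
               p = numeric(0), start_ms = numeric(0), end_ms = numeric(0),
               n_channels = integer(0), channels = character(0))
  }
  if (nrow(clusters)) clusters <- clusters[order(clusters$p), ]
  structure(
    list(clusters = clusters, detail = fc$clusters,
         null_distribution = null, tmap = tmap, times_ms = times_ms,
         labels = ch_labels, n_perm = n_perm, alpha = alpha,
         min_neighbors = min_neighbors, window_ms = window_ms,
         threshold = fc$threshold, n_subjects = n, seed = seed),
    class = "hep_cluster_test")
}

#' @export
print.hep_cluster_test <- function(x, ...) {
  cat("Cluster-based permutation test (", x$n_subjects, " subjects, ",
      x$n_perm, " permutations", sep = "")
  if (!is.null(x$window_ms)) {
    cat(", window ", x$window_ms[1], "-", x$window_ms[2], " ms", sep = "")
  }
  cat(")\n")
  if (nrow(x$clusters) == 0) {
    cat("No suprathreshold clusters.\n")
  } else {
    df <- x$clusters
    df$mass <- round(df$mass, 2)
    df$p <- signif(df$p, 3)
    print(df[, c("cluster", "sign", "mass", "p", "start_ms", "end_ms",
                 "n_channels")], row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.hep_cluster_test <- function(object, ...) {
  print(object)
  cat("Cluster-forming threshold |t| >", round(object$threshold, 3),
      "; two-tailed label at p <", object$alpha / 2, "per tail\n")
  if (nrow(object$clusters)) {
    sig <- object$clusters$p < object$alpha / 2
    cat(sum(sig), "cluster(s) significant at the per-tail level;",
        sum(object$clusters$p < object$alpha),
        "below the overall alpha of", object$alpha, "\n")
    cat("Channels of best cluster:", object$clusters$channels[1], "\n")
  }
  invisible(object)
}

#' Serialize a cluster test result to JSON
#' @param x a `hep_cluster_test`.
#' @param path JSON file path.
#' @export
write_cluster_result <- function(x, path) {
  jsonlite::write_json(
    list(clusters = x$clusters,
         null_summary = list(
           n_perm = x$n_perm,
           max = max(c(0, x$null_distribution)),
           q95 = unname(stats::quantile(x$null_distribution, 0.95))),
         alpha = x$alpha, min_neighbors = x$min_neighbors,
         window_ms = x$window_ms, seed = x$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pointwise permutation test for a single channel
#'
#' Paired t tests at each time point of per-subject waveforms (e.g. the
#' averaged ECG), each observed t contrasted against the distribution
#' of t values at the same time point across `n_perm` sign-flip
#' permutations; two-tailed p per point, uncorrected.
#'
#' @param a,b subjects x time matrices.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list with `t` (observed), `p` (uncorrected, per time point),
#'   `n_perm`.
#' @export
pointwise_permutation_test <- function(a, b, n_perm = 5000, seed = 1) {
  if (!identical(dim(a), dim(b))) stop("a and b must have identical shape")
  n <- nrow(a)
  if (n < 3) stop("need at least 3 subjects")
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p value")
  d <- a - b
  ss <- colSums(d^2)
  tstat <- function(mean_d) {
    v <- (ss - n * mean_d^2) / (n - 1)
    ifelse(v > 0, mean_d / (sqrt(v) / sqrt(n)), 0)
  }
  t_obs <- tstat(colMeans(d))
  set.seed(seed)
  flips <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  mean_null <- (flips %*% d) / n
  v_null <- sweep(-n * mean_null^2, 2, ss, "+") / (n - 1)
  t_null <- ifelse(v_null > 0, mean_null / (sqrt(v_null) / sqrt(n)), 0)
  exceed <- colSums(sweep(abs(t_null), 2, abs(t_obs), ">="))
  p <- (1 + exceed) / (1 + n_perm)
  list(t = t_obs, p = p, n_perm = n_perm)
}

#' Benjamini-Hochberg FDR rejection mask
#'
#' Step-up procedure at level `q`: reject the hypotheses corresponding
#' to the largest k such that the k-th smallest p value satisfies
#' `p_(k) <= k q / m`.
#'
#' @param pvalues p values in [0, 1].
#' @param q FDR level.
#' @return logical rejection mask aligned with `pvalues`.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (any(pvalues < 0 | pvalues > 1 | !is.finite(pvalues))) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH") <= q
}
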