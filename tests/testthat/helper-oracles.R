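# Independent brute-force oracles used to validate the package's
# statistical machinery. These deliberately share no code with the
# implementation under test.

# flood-fill clustering oracle over a channels x time t map:
# suprathreshold cells of one sign are connected through (same channel,
# adjacent time) and (neighbouring channel, same time); optional
# single-pass spatial pruning on the suprathreshold map
oracle_clusters <- function(tmap, thresh, adj_mat, min_neighbors = 0) {
  nch <- nrow(tmap); nt <- ncol(tmap)
  sgn <- matrix(0L, nch, nt)
  sgn[tmap > thresh] <- 1L
  sgn[tmap < -thresh] <- -1L
  keep <- sgn
  if (min_neighbors > 0) {
    for (t in seq_len(nt)) for (c in seq_len(nch)) {
      if (sgn[c, t] == 0L) next
      nb <- which(adj_mat[c, ])
      if (sum(sgn[nb, t] == sgn[c, t]) < min_neighbors) keep[c, t] <- 0L
    }
  }
  seen <- matrix(FALSE, nch, nt)
  clusters <- list()
  for (t0 in seq_len(nt)) for (c0 in seq_len(nch)) {
    if (keep[c0, t0] == 0L || seen[c0, t0]) next
    s <- keep[c0, t0]
    queue <- list(c(c0, t0))
    seen[c0, t0] <- TRUE
    cells <- list()
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      cells[[length(cells) + 1]] <- cur
      c1 <- cur[1]; t1 <- cur[2]
      cand <- list()
      if (t1 > 1) cand <- c(cand, list(c(c1, t1 - 1)))
      if (t1 < nt) cand <- c(cand, list(c(c1, t1 + 1)))
      for (nb in which(adj_mat[c1, ])) cand <- c(cand, list(c(nb, t1)))
      for (cc in cand) {
        if (keep[cc[1], cc[2]] == s && !seen[cc[1], cc[2]]) {
          seen[cc[1], cc[2]] <- TRUE
          queue <- c(queue, list(cc))
        }
      }
    }
    mass <- sum(vapply(cells, function(cc) tmap[cc[1], cc[2]], numeric(1)))
    clusters[[length(clusters) + 1]] <-
      list(cells = cells, mass = mass, sign = s)
  }
  clusters
}

# canonical representation of a clustering for comparison: sorted list
# of sorted member strings
canon_clusters <- function(cl_cells) {
  sort(vapply(cl_cells, function(cells) {
    paste(sort(vapply(cells, paste, "", collapse = ",")), collapse = ";")
  }, ""))
}

# exhaustive sign-flip null of the max |cluster mass| computed wholly
# in R (paired t map by hand + oracle clustering)
oracle_exhaustive_null <- function(d, adj_mat, thresh, min_neighbors = 0) {
  n <- dim(d)[1]
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  apply(signs, 1, function(s) {
    ds <- sweep(d, 1, s, "*")
    m <- apply(ds, c(2, 3), mean)
    sdv <- apply(ds, c(2, 3), sd)
    tm <- ifelse(sdv > 0, m / (sdv / sqrt(n)), 0)
    cl <- oracle_clusters(tm, thresh, adj_mat, min_neighbors)
    if (length(cl)) max(abs(vapply(cl, `[[`, numeric(1), "mass"))) else 0
  })
}

# Benjamini-Hochberg step-up by its definition
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(below)) reject[o[seq_len(max(below))]] <- TRUE
  reject
}

# exact two-sided signed-rank p by enumeration (no zeros, no ties)
oracle_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  p <- if (v_obs > mu) mean(vs >= v_obs) else mean(vs <= v_obs)
  min(2 * p, 1)
}

# textbook paired t statistic
oracle_paired_t <- function(x, y) {
  d <- x - y
  mean(d) / (sd(d) / sqrt(length(d)))
}
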