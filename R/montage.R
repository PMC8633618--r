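#' Standard 10-20 template positions
#'
#' Returns schematic 2-D head coordinates (unit head radius, x = left to
#' right, y = posterior to anterior) for the classic 19-channel 10-20
#' montage. These template positions drive channel-adjacency construction
#' for spatio-temporal clustering and the default fronto-central
#' topography of the synthetic heartbeat-locked component.
#'
#' @param labels character vector of channel labels to look up; defaults
#'   to the full 19-channel set.
#' @return data.frame with columns `label`, `x`, `y`.
#' @export
ten_twenty_positions <- function(labels = NULL) {
  pos <- data.frame(
    label = c("Fp1", "Fp2",
              "F7", "F3", "Fz", "F4", "F8",
              "T3", "C3", "Cz", "C4", "T4",
              "T5", "P3", "Pz", "P4", "T6",
              "O1", "O2"),
    x = c(-0.31, 0.31,
          -0.81, -0.40, 0.00, 0.40, 0.81,
          -1.00, -0.50, 0.00, 0.50, 1.00,
          -0.81, -0.40, 0.00, 0.40, 0.81,
          -0.31, 0.31),
    y = c(0.95, 0.95,
          0.59, 0.52, 0.50, 0.52, 0.59,
          0.00, 0.00, 0.00, 0.00, 0.00,
          -0.59, -0.52, -0.50, -0.52, -0.59,
          -0.95, -0.95),
    stringsAsFactors = FALSE
  )
  # modern synonyms used by some amplifiers
  synonyms <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")
  if (is.null(labels)) return(pos)
  idx <- match(labels, pos$label)
  missing <- is.na(idx) & labels %in% names(synonyms)
  idx[missing] <- match(synonyms[labels[missing]], pos$label)
  if (anyNA(idx)) {
    stop("no 10-20 template position for channel(s): ",
         paste(labels[is.na(idx)], collapse = ", "))
  }
  out <- pos[idx, ]
  out$label <- labels
  rownames(out) <- NULL
  out
}

#' Build a channel adjacency graph from 10-20 template positions
#'
#' Two channels are neighbours when their template distance is below a
#' threshold. If no threshold is given, the smallest distance for which
#' the median per-channel neighbour count reaches `target_median` is
#' used, which on the full 19-channel montage yields a median of about
#' four neighbours per channel.
#'
#' @param labels EEG channel labels (must have 10-20 template positions).
#' @param threshold neighbour distance threshold in template units, or
#'   `NULL` to choose it from `target_median`.
#' @param target_median desired median neighbour count when the
#'   threshold is chosen automatically.
#' @return an object of class `hep_adjacency`: a list with `labels`,
#'   `neighbors` (per-channel integer index vectors) and the symmetric
#'   logical `matrix`.
#' @export
build_adjacency <- function(labels, threshold = NULL, target_median = 4) {
  pos <- ten_twenty_positions(labels)
  n <- nrow(pos)
  d <- as.matrix(stats::dist(pos[, c("x", "y")]))
  if (is.null(threshold)) {
    cand <- sort(unique(round(d[upper.tri(d)], 6)))
    for (th in cand) {
      m <- d <= th + 1e-9 & d > 0
      if (stats::median(rowSums(m)) >= target_median) {
        threshold <- th + 1e-9
        break
      }
    }
    if (is.null(threshold)) threshold <- max(d)
  }
  mat <- d <= threshold & d > 0
  diag(mat) <- FALSE
  mat <- mat | t(mat)
  dimnames(mat) <- list(labels, labels)
  structure(
    list(labels = labels,
         neighbors = lapply(seq_len(n), function(i) which(mat[i, ])),
         matrix = mat,
         threshold = threshold),
    class = "hep_adjacency"
  )
}

#' @export
print.hep_adjacency <- function(x, ...) {
  cat("Channel adjacency (", length(x$labels), " channels, threshold ",
      signif(x$threshold, 3), ")\n", sep = "")
  cat("Median neighbours per channel:",
      stats::median(lengths(x$neighbors)), "\n")
  invisible(x)
}

# fronto-central template weights in [0, 1]; used as the default scalp
# topography of the injected heartbeat-locked component
frontocentral_weights <- function(labels) {
  pos <- ten_twenty_positions(labels)
  w <- exp(-((pos$x / 0.75)^2 + ((pos$y - 0.35) / 0.55)^2))
  stats::setNames(w / max(w), labels)
}
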