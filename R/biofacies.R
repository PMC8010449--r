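#' SHE analysis with biozone break detection
#'
#' Levels are accumulated stratigraphically upward; after each accumulation
#' step the decomposition `ln S = H + ln E` is computed from the cumulative
#' counts (S = richness, H = Shannon information in nats, E = exp(H)/S).
#' Within a homogeneous biozone, `ln E` declines roughly linearly in
#' `ln N`; a structural break is declared when the newest point's residual
#' from the running segment regression of `ln E` on `ln N` exceeds
#' `break_tolerance` residual standard deviations for two consecutive
#' levels, after which accumulation restarts.
#'
#' @param m An [abundance_matrix()].
#' @param break_tolerance Residual threshold in SD units (default 2).
#' @param min_segment Minimum accumulated levels before break testing.
#' @return A `she_series` list: `series` data frame (level, N, S, H, E,
#'   segment), `boundaries` (level indices starting each new segment).
#' @export
she_analysis <- function(m, break_tolerance = 2, min_segment = 5) {
  L <- nrow(m$counts)
  if (L < 6) stop("need at least 6 levels for SHE analysis")
  tot <- rowSums(m$counts)
  out <- data.frame(level = seq_len(L), N = NA_real_, S = NA_real_,
                    H = NA_real_, E = NA_real_, segment = NA_integer_)
  boundaries <- integer(0)
  seg_id <- 1L
  acc <- numeric(ncol(m$counts))
  seg_x <- numeric(0); seg_y <- numeric(0)
  strikes <- 0L; strike_at <- NA_integer_

  for (i in seq_len(L)) {
    if (tot[i] == 0) {
      warning(sprintf("level %d has no specimens; skipped", i))
      out$segment[i] <- seg_id
      next
    }
    acc <- acc + m$counts[i, ]
    p <- acc[acc > 0] / sum(acc)
    S <- length(p)
    H <- -sum(p * log(p))
    E <- exp(H) / S
    out[i, c("N", "S", "H", "E")] <- c(sum(acc), S, H, E)
    x <- log(sum(acc)); y <- log(E)

    broke <- FALSE
    if (length(seg_x) >= min_segment && stats::var(seg_x) > 0) {
      fit <- stats::lm.fit(cbind(1, seg_x), seg_y)
      s <- sqrt(sum(fit$residuals^2) / max(1, length(seg_x) - 2))
      s <- max(s, 1e-6)
      # prediction SE at the new point (accounts for extrapolation
      # leverage along ln N)
      nseg <- length(seg_x)
      sxx <- sum((seg_x - mean(seg_x))^2)
      se_pred <- s * sqrt(1 + 1 / nseg + (x - mean(seg_x))^2 / sxx)
      pred <- fit$coefficients[1] + fit$coefficients[2] * x
      if (abs(y - pred) > break_tolerance * se_pred) {
        strikes <- strikes + 1L
        if (strikes == 1L) strike_at <- i
        if (strikes >= 2L) broke <- TRUE
      } else {
        strikes <- 0L; strike_at <- NA_integer_
      }
    }

    if (broke) {
      boundaries <- c(boundaries, strike_at)
      seg_id <- seg_id + 1L
      # restart accumulation at the level where the deviation began
      acc <- numeric(ncol(m$counts))
      seg_x <- numeric(0); seg_y <- numeric(0)
      for (j in strike_at:i) {
        acc <- acc + m$counts[j, ]
        p <- acc[acc > 0] / sum(acc)
        S2 <- length(p); H2 <- -sum(p * log(p)); E2 <- exp(H2) / S2
        out[j, c("N", "S", "H", "E")] <- c(sum(acc), S2, H2, E2)
        out$segment[j] <- seg_id
        seg_x <- c(seg_x, log(sum(acc))); seg_y <- c(seg_y, log(E2))
      }
      strikes <- 0L; strike_at <- NA_integer_
    } else {
      seg_x <- c(seg_x, x); seg_y <- c(seg_y, y)
      out$segment[i] <- seg_id
    }
  }
  structure(list(series = out, boundaries = boundaries,
                 break_tolerance = break_tolerance),
            class = "she_series")
}

#' @export
print.she_series <- function(x, ...) {
  cat(sprintf("she_series: %d levels, %d candidate boundaries at {%s}\n",
              nrow(x$series), length(x$boundaries),
              paste(x$boundaries, collapse = ", ")))
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' Bray-Curtis dissimilarities between levels; the R statistic compares
#' mean between-group and within-group dissimilarity ranks,
#' `R = (mean_between - mean_within) / (M / 2)` with `M = C(n, 2)`. The
#' p-value is obtained by permuting group labels.
#'
#' @param m An [abundance_matrix()].
#' @param partition Group label per level; every group needs >= 2 levels.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed for the permutations.
#' @return List with `R`, `p`, `n_perm`.
#' @export
anosim_test <- function(m, partition, n_perm = 999, seed = 1) {
  partition <- as.character(partition)
  if (length(partition) != nrow(m$counts)) {
    stop("partition must label every level")
  }
  sizes <- table(partition)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) stop("every group needs at least 2 levels")
  d <- vegan::vegdist(m$counts, method = "bray")
  rk <- rank(as.vector(d))
  n <- nrow(m$counts)
  M <- n * (n - 1) / 2
  pair_i <- utils::combn(n, 2)
  same <- partition[pair_i[1, ]] == partition[pair_i[2, ]]
  r_stat <- function(same_vec) {
    (mean(rk[!same_vec]) - mean(rk[same_vec])) / (M / 2)
  }
  R <- r_stat(same)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    pp <- sample(partition)
    same_p <- pp[pair_i[1, ]] == pp[pair_i[2, ]]
    if (r_stat(same_p) >= R) exceed <- exceed + 1L
  }
  list(R = R, p = (exceed + 1) / (n_perm + 1), n_perm = n_perm)
}

#' Detect sub-assemblages by SHEBI + ANOSIM consensus
#'
#' SHE analysis proposes candidate biozone boundaries; each candidate is
#' retained only if ANOSIM on the two adjacent segments rejects homogeneity
#' at `alpha`. Segments are labeled oldest-first A, B, C, ...
#'
#' @param m An [abundance_matrix()].
#' @param break_tolerance,min_segment Passed to [she_analysis()].
#' @param alpha ANOSIM significance level per boundary (default 0.05).
#' @param n_perm,seed ANOSIM permutation settings.
#' @return A `facies_partition` list: `boundaries` (level index starting
#'   each new segment), `labels` per level, `segments` summary with ANOSIM
#'   support.
#' @export
detect_subassemblages <- function(m, break_tolerance = 2, min_segment = 5,
                                  alpha = 0.05, n_perm = 999, seed = 1) {
  cand <- she_analysis(m, break_tolerance, min_segment)$boundaries
  L <- nrow(m$counts)
  kept <- integer(0)
  support <- list()
  prev <- 1L
  for (k in seq_along(cand)) {
    b <- cand[k]
    nxt <- if (k < length(cand)) cand[k + 1] - 1L else L
    seg1 <- prev:(b - 1L); seg2 <- b:nxt
    if (length(seg1) < 2 || length(seg2) < 2) next
    idx <- c(seg1, seg2)
    part <- rep(c("below", "above"), c(length(seg1), length(seg2)))
    sub <- abundance_matrix(m$counts[idx, , drop = FALSE],
                            level_ids = m$level_ids[idx],
                            thickness_cm = m$thickness_cm[idx])
    res <- anosim_test(sub, part, n_perm = n_perm, seed = seed + b)
    if (res$p <= alpha) {
      kept <- c(kept, b)
      support[[length(support) + 1]] <-
        data.frame(boundary = b, R = res$R, p = res$p)
      prev <- b
    }
  }
  seg <- findInterval(seq_len(L), c(1, kept))
  labels <- LETTERS[seg]
  structure(list(boundaries = kept, labels = labels,
                 segments = if (length(support)) do.call(rbind, support)
                            else data.frame(boundary = integer(0),
                                            R = numeric(0), p = numeric(0)),
                 candidates = cand),
            class = "facies_partition")
}

#' @export
print.facies_partition <- function(x, ...) {
  cat(sprintf("facies_partition: %d segments (%s), boundaries at {%s}\n",
              length(unique(x$labels)),
              paste(unique(x$labels), collapse = ", "),
              paste(x$boundaries, collapse = ", ")))
  invisible(x)
}
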