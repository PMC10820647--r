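# Independent reference implementations used to cross-check the pipeline.
# These deliberately take different numerical routes from the package code.

# Angle at vertex B via atan2 of the cross/dot magnitudes (vs the package's
# clamped arccos).
oracle_angle_deg <- function(A, B, C) {
  ba <- A - B
  bc <- C - B
  cr <- c(ba[2] * bc[3] - ba[3] * bc[2],
          ba[3] * bc[1] - ba[1] * bc[3],
          ba[1] * bc[2] - ba[2] * bc[1])
  atan2(sqrt(sum(cr^2)), sum(ba * bc)) * 180 / pi
}

# Exhaustive nearest-within-radius selection: all pairwise distances, full
# stable sort on (distance, index), then filter and truncate.
oracle_select <- function(fitted, kp_u, kp_v, radius, k_max) {
  d <- numeric(nrow(fitted))
  for (i in seq_len(nrow(fitted))) {
    d[i] <- sqrt((fitted$u[i] - kp_u)^2 + (fitted$v[i] - kp_v)^2)
  }
  ord <- order(d, fitted$source_index)
  ord <- ord[d[ord] <= radius]
  fitted$source_index[ord[seq_len(min(k_max, length(ord)))]]
}

# Direct formula evaluations of the metric suite.
oracle_metrics <- function(est, truth) {
  e <- est - truth
  n <- length(e)
  list(
    mae = sum(abs(e)) / n,
    rmse = sqrt(sum(e^2) / n),
    mape = 100 * mean(abs(e[truth != 0]) / abs(truth[truth != 0])),
    nrmse = sqrt(sum(e^2) / n) / (max(truth) - min(truth)),
    std = sqrt(sum((e - mean(e))^2) / (n - 1)),
    r_squared = 1 - sum(e^2) / sum((truth - mean(truth))^2)
  )
}

# Random non-degenerate point triple.
random_triple <- function() {
  repeat {
    A <- stats::runif(3, -5, 5)
    B <- stats::runif(3, -5, 5)
    C <- stats::runif(3, -5, 5)
    if (sqrt(sum((A - B)^2)) > 1e-3 && sqrt(sum((C - B)^2)) > 1e-3) {
      return(list(A = A, B = B, C = C))
    }
  }
}

# Small random cloud for fit/selection tests.
random_cloud <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  point_cloud(stats::runif(n, -1, 1), stats::runif(n, 2, 4),
              stats::runif(n, -1, 1))
}

# Distance from point p to segment p0-p1.
dist_point_segment <- function(p, p0, p1) {
  a <- p1 - p0
  tt <- sum((p - p0) * a) / sum(a^2)
  tt <- min(1, max(0, tt))
  sqrt(sum((p - (p0 + tt * a))^2))
}
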