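#' PCA basis of population rate data
#'
#' Principal component analysis of a channel-by-(time x condition) data
#' matrix: the covariance matrix over the concatenated samples is
#' eigendecomposed (column means removed) and the leading eigenvectors are
#' returned as an orthonormal projection basis.  Used for 3-D visualization
#' of population trajectories; all quantitative distance measures stay in
#' the native channel space.
#'
#' @param x matrix channels x samples (finite values).
#' @param n_components requested number of components (default 3); when the
#'   data have lower rank, fewer components are returned with a warning.
#' @return list with `basis` (channels x k, orthonormal), `eigenvalues`
#'   (descending, all of them), `center` (channel means).
#' @export
pca_fit <- function(x, n_components = 3) {
  stopifnot(is.matrix(x), all(is.finite(x)))
  if (nrow(x) < n_components)
    stop("need at least ", n_components, " channels", call. = FALSE)
  cc <- rowMeans(x)
  cov_m <- stats::cov(t(x))
  eg <- eigen(cov_m, symmetric = TRUE)
  tol <- max(eg$values) * 1e-10
  rank_ <- sum(eg$values > tol)
  k <- min(n_components, rank_)
  if (k < n_components)
    warning("data rank ", rank_, " < ", n_components,
            " requested components; returning ", k)
  list(basis = eg$vectors[, seq_len(k), drop = FALSE],
       eigenvalues = eg$values,
       center = cc)
}

# Internal: native-space condition structure of a rate tensor.
# Returns, per condition key, the trial indices.
condition_split <- function(trials, by) {
  key <- interaction(trials[by], drop = TRUE, sep = "|")
  split(seq_len(nrow(trials)), key)
}

#' Trial-averaged population trajectories with covariance ellipsoid data
#'
#' Projects single-trial population rate vectors (from a 30/1 ms rate
#' tensor) onto a PCA basis and averages within condition, yielding one mean
#' trajectory per condition.  Baseline and endpoint covariances are computed
#' in the native channel space from the single-trial vectors in a 200 ms
#' pre-stimulus window and the last 200 ms of the plateau, respectively.
#'
#' @param rt a `rate_tensor` (30 ms window, 1 ms step recommended).
#' @param basis projection basis from [pca_fit()] (or `NULL` to fit one from
#'   the tensor itself).
#' @param by condition columns defining one trajectory each.
#' @param baseline_window_ms 2-vector, pre-stimulus sampling window.
#' @param endpoint_ms length of the endpoint window (taken from the end of
#'   the recorded trace); when the plateau is missing the endpoint
#'   covariance is omitted with a flag.
#' @return a `trajectory_set`: per condition a list with `trajectory`
#'   (time x k matrix), `time_ms`, `baseline_cov`, `endpoint_cov` (native
#'   space), plus the basis.
#' @export
build_trajectories <- function(rt, basis = NULL,
                               by = c("stimulus_id", "ramp_ms", "intensity"),
                               baseline_window_ms = c(-200, 0),
                               endpoint_ms = 200) {
  stopifnot(inherits(rt, "rate_tensor"))
  cen <- rt$bin_centers_ms
  if (is.null(basis)) {
    flat <- matrix(aperm(rt$values, c(2, 1, 3)), dim(rt$values)[2])
    basis <- pca_fit(flat)$basis
  } else if (is.list(basis)) basis <- basis$basis
  base_bins <- which(cen >= baseline_window_ms[1] & cen < baseline_window_ms[2])
  end_bins <- which(cen >= max(cen) - endpoint_ms)
  groups <- condition_split(rt$trials, by)
  out <- lapply(groups, function(idx) {
    m <- apply(rt$values[idx, , , drop = FALSE], c(2, 3), mean)
    traj <- t(m) %*% basis
    covs <- function(bins) {
      if (!length(bins)) return(NULL)
      # trial-to-trial covariance of the window-averaged native vector
      v <- t(apply(rt$values[idx, , bins, drop = FALSE], c(1, 2), mean))
      stats::cov(t(v))
    }
    list(trajectory = traj, time_ms = cen,
         baseline_cov = covs(base_bins),
         endpoint_cov = covs(end_bins),
         endpoint_missing = !length(end_bins))
  })
  structure(list(conditions = out, basis = basis, by = by),
            class = "trajectory_set")
}

#' Covariance ellipsoid mesh
#'
#' Maps a tessellated unit sphere through the (matrix) square root of a
#' covariance matrix scaled by `scale`, translated to `center` — the mesh
#' used to visualize baseline and endpoint covariance structure around
#' trajectories.
#'
#' @param cov_m symmetric positive semi-definite covariance matrix (d x d,
#'   d >= 2; typically 3 x 3 in the projected space).
#' @param scale scalar multiplier of the square-rooted covariance
#'   (default 0.5).
#' @param center point to translate the mesh to (default origin).
#' @param n sphere tessellation resolution (n x n grid, default 20).
#' @return matrix of mesh points, (n * n) x d.
#' @export
covariance_ellipsoid <- function(cov_m, scale = 0.5, center = NULL, n = 20) {
  stopifnot(is.matrix(cov_m), nrow(cov_m) == ncol(cov_m))
  if (max(abs(cov_m - t(cov_m))) > 1e-8 * max(1, max(abs(cov_m))))
    stop("covariance matrix is not symmetric", call. = FALSE)
  eg <- eigen((cov_m + t(cov_m)) / 2, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(1, max(abs(eg$values))))
    stop("covariance matrix is not positive semi-definite", call. = FALSE)
  root <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  d <- nrow(cov_m)
  if (is.null(center)) center <- numeric(d)
  theta <- seq(0, 2 * pi, length.out = n)
  phi <- seq(0, pi, length.out = n)
  grid <- expand.grid(theta = theta, phi = phi)
  if (d == 2) {
    sphere <- cbind(cos(grid$theta), sin(grid$theta))
  } else {
    sphere <- cbind(sin(grid$phi) * cos(grid$theta),
                    sin(grid$phi) * sin(grid$theta),
                    cos(grid$phi))
    if (d > 3) sphere <- cbind(sphere, matrix(0, nrow(sphere), d - 3))
  }
  pts <- scale * (sphere %*% t(root))
  sweep(pts, 2, center, `+`)
}

#' Native-space distance time series of population trajectories
#'
#' For each stimulus category: the Euclidean distance (native channel
#' space) of each stimulus-mean population vector from the baseline
#' reference (mean vector over a 200 ms pre-stimulus window), averaged over
#' stimuli, and the mean pairwise Euclidean distance between stimulus-mean
#' vectors ("separation") at every time point.
#'
#' @param rt a `rate_tensor`.
#' @param baseline_window_ms pre-stimulus reference window.
#' @return data.frame with `category`, `time_ms`, `dist_to_baseline`,
#'   `separation` (`NA` separation when a category has a single stimulus).
#' @export
distance_series <- function(rt, baseline_window_ms = c(-200, 0)) {
  stopifnot(inherits(rt, "rate_tensor"))
  cen <- rt$bin_centers_ms
  base_bins <- which(cen >= baseline_window_ms[1] & cen < baseline_window_ms[2])
  out <- list()
  for (cat in unique(rt$trials$category)) {
    in_cat <- rt$trials$category == cat
    stim <- unique(rt$trials$stimulus_id[in_cat])
    means <- lapply(stim, function(s) {
      idx <- which(in_cat & rt$trials$stimulus_id == s)
      apply(rt$values[idx, , , drop = FALSE], c(2, 3), mean)
    })
    baseline <- rowMeans(do.call(
      cbind, lapply(means, function(m) m[, base_bins, drop = FALSE])))
    dist_b <- rowMeans(matrix(vapply(means, function(m)
      sqrt(colSums((m - baseline)^2)), numeric(length(cen))),
      nrow = length(cen)))
    sep <- if (length(stim) < 2) rep(NA_real_, length(cen)) else {
      pairs <- utils::combn(length(stim), 2)
      rowMeans(matrix(vapply(seq_len(ncol(pairs)), function(p)
        sqrt(colSums((means[[pairs[1, p]]] - means[[pairs[2, p]]])^2)),
        numeric(length(cen))), nrow = length(cen)))
    }
    out[[cat]] <- data.frame(category = cat, time_ms = cen,
                             dist_to_baseline = dist_b, separation = sep)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Trajectory discriminability index
#'
#' Ratio, at every time point and per stimulus category, between the
#' inter-trajectory distance (mean pairwise Euclidean distance between
#' stimulus-mean population vectors) and the trajectory variability
#' (root-mean-square distance of single-trial vectors from their own
#' stimulus mean, averaged over stimuli — or pooled across the category).
#' Both terms are computed in the native channel space.  The index is
#' dimensionless, invariant to channel permutation and to uniform positive
#' scaling of all rates.
#'
#' @param rt a `rate_tensor`.
#' @param variability `"per_stimulus"` (RMS dispersion per stimulus, then
#'   averaged; default) or `"pooled"` (RMS over all trials of the category).
#' @param eps denominators below `eps` yield `NA` (recorded, not dropped).
#' @return data.frame with `category`, `time_ms`, `index`, `separation`,
#'   `variability`.
#' @export
discriminability_index <- function(rt, variability = c("per_stimulus", "pooled"),
                                   eps = 1e-12) {
  variability <- match.arg(variability)
  stopifnot(inherits(rt, "rate_tensor"))
  cen <- rt$bin_centers_ms
  nb <- length(cen)
  out <- list()
  for (cat in unique(rt$trials$category)) {
    in_cat <- rt$trials$category == cat
    stim <- unique(rt$trials$stimulus_id[in_cat])
    if (length(stim) < 2)
      stop("category '", cat, "' has a single stimulus; separation undefined",
           call. = FALSE)
    idx_s <- lapply(stim, function(s) which(in_cat & rt$trials$stimulus_id == s))
    if (any(lengths(idx_s) < 2))
      stop("need >= 2 trials per stimulus", call. = FALSE)
    means <- lapply(idx_s, function(idx)
      apply(rt$values[idx, , , drop = FALSE], c(2, 3), mean))
    pairs <- utils::combn(length(stim), 2)
    sep <- rowMeans(matrix(vapply(seq_len(ncol(pairs)), function(p)
      sqrt(colSums((means[[pairs[1, p]]] - means[[pairs[2, p]]])^2)),
      numeric(nb)), nrow = nb))
    nch <- dim(rt$values)[2]
    disp_s <- vapply(seq_along(stim), function(si) {
      idx <- idx_s[[si]]
      sq <- matrix(vapply(idx, function(ti)
        colSums((matrix(rt$values[ti, , ], nrow = nch) - means[[si]])^2),
        numeric(nb)), nrow = nb)
      rowMeans(sq)   # mean over trials of squared distance, per bin
    }, numeric(nb))
    disp_s <- matrix(disp_s, nrow = nb)
    varb <- if (variability == "per_stimulus") {
      rowMeans(sqrt(disp_s))
    } else {
      w <- lengths(idx_s)
      sqrt(as.numeric(disp_s %*% w) / sum(w))
    }
    index <- ifelse(varb < eps, NA_real_, sep / varb)
    out[[cat]] <- data.frame(category = cat, time_ms = cen, index = index,
                             separation = sep, variability = varb)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
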