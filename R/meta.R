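#' Convert a two-sample t statistic to Hedges g and its variance
#'
#' Standard small-sample-corrected standardized mean difference:
#' `d = t * sqrt(1/n1 + 1/n2)`, correction `J = 1 - 3 / (4(n1+n2-2) - 1)`,
#' `g = J * d`, `var_g = (n1+n2)/(n1*n2) + g^2 / (2(n1+n2-2))`.
#'
#' @param t signed t statistic (finite).
#' @param n1,n2 group sizes, both >= 2.
#' @return list with elements `g` and `var_g` (vectorized over `t`).
#' @export
t_to_effect <- function(t, n1, n2) {
  if (any(!is.finite(t))) stop("non-finite t statistic")
  if (any(n1 < 2) || any(n2 < 2)) stop("group sizes must be >= 2")
  d <- t * sqrt(1 / n1 + 1 / n2)
  J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  g <- J * d
  var_g <- (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2 - 2))
  list(g = g, var_g = var_g)
}

#' Reconstruct a study's effect-size map from its peaks
#'
#' Spreads each reported peak over the grid with an isotropic Gaussian
#' kernel (`sigma = fwhm_mm / 2.3548`). At voxel v with kernel weights
#' `w_k(v) = exp(-d(v, peak_k)^2 / (2 sigma^2))`, the effect is the
#' weighted sum `sum(w_k g_k) / max(sum(w_k), 1)` — a weighted mean where
#' kernels overlap strongly, tapering to zero away from all peaks. Weights
#' below `exp(-9/2)` (3 sigma) are truncated to zero. The sampling variance
#' is interpolated with the same weights; voxels with no kernel support get
#' `g = 0` and a large default variance (10 times the median peak variance,
#' or 10 times the no-effect variance for a peakless study) so unsupported
#' regions never drive significance.
#'
#' @param study a [study_record].
#' @param grid a [volume_map] defining voxels and mask.
#' @param fwhm_mm Gaussian kernel full width at half maximum, mm (default
#'   20, the value used for coordinate-based map reconstruction).
#' @return An object of class `effect_size_map`: list with per-in-mask-voxel
#'   vectors `g` and `var_g` (ordering of [mask_coordinates()]), and `grid`.
#' @export
reconstruct_study_map <- function(study, grid, fwhm_mm = 20) {
  stopifnot(inherits(study, "study_record"), inherits(grid, "volume_map"))
  vox <- mask_coordinates(grid)
  if (nrow(vox) == 0L) stop("empty grid: analysis mask has no voxels")
  V <- nrow(vox)
  n1 <- study$n_patients; n2 <- study$n_controls
  base_var <- (n1 + n2) / (n1 * n2)
  if (nrow(study$peaks) == 0L) {
    return(structure(list(g = rep(0, V), var_g = rep(10 * base_var, V),
                          grid = grid, study_id = study$study_id),
                     class = "effect_size_map"))
  }
  bb_lo <- apply(vox, 2, min); bb_hi <- apply(vox, 2, max)
  pk <- as.matrix(study$peaks[, c("x", "y", "z")])
  if (any(t(pk) < bb_lo - 1e-9) || any(t(pk) > bb_hi + 1e-9))
    stop("peak outside the grid bounding box in study ", study$study_id)
  eff <- t_to_effect(study$peaks$t, n1, n2)
  sigma <- fwhm_mm / 2.3548
  cutoff <- exp(-9 / 2)
  W <- matrix(0, V, nrow(pk))
  for (k in seq_len(nrow(pk))) {
    d2 <- (vox[, 1] - pk[k, 1])^2 + (vox[, 2] - pk[k, 2])^2 +
          (vox[, 3] - pk[k, 3])^2
    W[, k] <- exp(-d2 / (2 * sigma^2))
  }
  W[W < cutoff] <- 0
  sw <- rowSums(W)
  denom <- pmax(sw, 1)
  g <- as.vector(W %*% eff$g) / denom
  var_default <- 10 * stats::median(eff$var_g)
  var_g <- as.vector(W %*% eff$var_g) / denom
  unsupported <- sw == 0
  var_g[unsupported] <- var_default
  # partially supported voxels: blend toward the default prior variance
  part <- !unsupported & sw < 1
  var_g[part] <- var_g[part] + (1 - sw[part]) * var_default
  structure(list(g = g, var_g = var_g, grid = grid, study_id = study$study_id),
            class = "effect_size_map")
}

#' Combine study effect-size maps with a DerSimonian-Laird random-effects model
#'
#' Per voxel: fixed-effect weights `w_i = 1/var_i`, Cochran
#' `Q = sum w_i (g_i - g_fixed)^2`, method-of-moments between-study variance
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`, random-effects
#' weights `w*_i = 1/(var_i + tau2)`, pooled `g = sum(w* g)/sum(w*)`,
#' `z = g * sqrt(sum w*)`, `I2 = max(0, 100 (Q - (k-1)) / Q)` (clamped to
#' [0, 100]), and a one-sided p map `1 - pnorm(|z|)`.
#'
#' @param maps list of >= 2 [reconstruct_study_map()] results on identical
#'   grids.
#' @return An object of class `meta_result`: per-voxel vectors `g`, `se`,
#'   `z`, `p`, `tau2`, `Q`, `I2`, plus `grid` and `k` (number of studies).
#' @export
random_effects_combine <- function(maps) {
  if (length(maps) < 2L) stop("at least 2 study maps required")
  dims <- lapply(maps, function(m) dim(m$grid$data))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])) ||
      !all(vapply(maps, function(m) identical(m$grid$affine, maps[[1]]$grid$affine),
                  logical(1))))
    stop("study maps are on mismatched grids")
  k <- length(maps)
  G <- do.call(rbind, lapply(maps, `[[`, "g"))       # k x V
  Vr <- do.call(rbind, lapply(maps, `[[`, "var_g"))  # k x V
  W <- 1 / Vr
  sw <- colSums(W)
  g_fix <- colSums(W * G) / sw
  Q <- colSums(W * (sweep(G, 2, g_fix))^2)
  denom <- sw - colSums(W^2) / sw
  tau2 <- pmax(0, (Q - (k - 1)) / denom)
  Ws <- 1 / sweep(Vr, 2, tau2, `+`)
  sws <- colSums(Ws)
  g_hat <- colSums(Ws * G) / sws
  se <- 1 / sqrt(sws)
  z <- g_hat / se
  I2 <- ifelse(Q > 0, pmax(0, pmin(100, 100 * (Q - (k - 1)) / Q)), 0)
  structure(list(g = g_hat, se = se, z = z, p = z_to_p(z), tau2 = tau2,
                 Q = Q, I2 = I2, grid = maps[[1]]$grid, k = k),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat("meta_result:", x$k, "studies,", length(x$z), "in-mask voxels\n")
  cat("z range:", paste(signif(range(x$z), 4), collapse = " .. "), "\n")
  invisible(x)
}

#' One-sided normal tail probability of a meta-analytic z value
#'
#' `p = 1 - pnorm(|z|)`: the tail in the reported direction of effect,
#' the convention under which printed z/p pairs of cluster tables agree.
#'
#' @param z finite statistic (vectorized).
#' @return one-sided tail probability, monotone decreasing in `|z|`.
#' @export
z_to_p <- function(z) {
  if (any(!is.finite(z))) stop("non-finite z")
  stats::pnorm(abs(z), lower.tail = FALSE)
}

# 26-connected components of a logical array; returns integer label array
label_components <- function(supra) {
  d <- dim(supra)
  labels <- array(0L, d)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  idx_all <- which(supra)
  cur <- 0L
  for (start in idx_all) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      ijk <- arrayInd(v, d)
      cand <- sweep(nb, 2, as.integer(ijk), `+`)
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
            cand[, 2] >= 1 & cand[, 2] <= d[2] &
            cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      lin <- cand[, 1] + d[1] * (cand[, 2] - 1L + d[2] * (cand[, 3] - 1L))
      new <- lin[supra[lin] & labels[lin] == 0L]
      if (length(new)) {
        labels[new] <- cur
        queue <- c(queue, new)
      }
    }
  }
  labels
}

#' Threshold a meta-analytic z map into clusters
#'
#' Suprathreshold voxels (one-sided voxel-level p below `p_voxel`,
#' separately for positive and negative z) are grouped by 26-connectivity;
#' clusters smaller than `extent` voxels are dropped.
#'
#' @param result a [meta_result].
#' @param p_voxel uncorrected one-sided voxel-level threshold (default
#'   0.005).
#' @param extent minimum cluster extent in voxels (default 20).
#' @return data frame with one row per cluster: `cluster_id`, `sign`
#'   (+1/-1), `size`, `peak_x`, `peak_y`, `peak_z` (MNI mm), `peak_z_value`,
#'   `peak_p`. The voxel membership is attached as attribute `"voxels"`
#'   (list of in-mask linear index vectors) for downstream overlap checks.
#' @export
threshold_clusters <- function(result, p_voxel = 0.005, extent = 20L) {
  stopifnot(inherits(result, "meta_result"))
  grid <- result$grid
  z_arr <- values_to_array(result$z, grid)
  z_crit <- stats::qnorm(1 - p_voxel)
  rows <- list(); vox_list <- list(); cid <- 0L
  mask_lin <- which(grid$mask)
  for (sgn in c(1, -1)) {
    supra <- grid$mask & (sgn * z_arr > z_crit)
    if (!any(supra)) next
    labels <- label_components(supra)
    for (lab in seq_len(max(labels))) {
      lin <- which(labels == lab)
      if (length(lin) < extent) next
      cid <- cid + 1L
      zc <- z_arr[lin]
      pk <- lin[which.max(sgn * zc)]
      mm <- voxel_to_mm(arrayInd(pk, dim(z_arr)) - 1L, grid$affine)
      rows[[cid]] <- data.frame(
        cluster_id = cid, sign = sgn, size = length(lin),
        peak_x = mm[1], peak_y = mm[2], peak_z = mm[3],
        peak_z_value = z_arr[pk], peak_p = z_to_p(z_arr[pk]))
      vox_list[[cid]] <- match(lin, mask_lin)
    }
  }
  out <- if (cid) do.call(rbind, rows) else
    data.frame(cluster_id = integer(), sign = numeric(), size = integer(),
               peak_x = numeric(), peak_y = numeric(), peak_z = numeric(),
               peak_z_value = numeric(), peak_p = numeric())
  attr(out, "voxels") <- vox_list
  out
}

#' Per-cluster heterogeneity summary
#'
#' Mean I-squared over each cluster's voxels, labelled by the conventional
#' 25/50/75 percent anchors (values at a boundary take the higher category:
#' below 25 "negligible", 25-50 "low", 50-75 "medium", 75 and above "high").
#'
#' @param result a [meta_result].
#' @param clusters cluster table from [threshold_clusters()] on `result`.
#' @return data frame `cluster_id`, `I2_mean`, `label`.
#' @export
heterogeneity_report <- function(result, clusters) {
  vox <- attr(clusters, "voxels")
  if (nrow(clusters) && (is.null(vox) || length(vox) < nrow(clusters)))
    stop("cluster table lacks voxel membership; pass the table returned by threshold_clusters()")
  i2 <- vapply(seq_len(nrow(clusters)), function(i)
    mean(result$I2[vox[[clusters$cluster_id[i]]]]), numeric(1))
  # boundary values take the higher category; the 1e-9 guard absorbs the
  # floating error of I2 values computed as 100 (Q - df) / Q
  lab <- cut(i2 + 1e-9, breaks = c(-Inf, 25, 50, 75, Inf),
             labels = c("negligible", "low", "medium", "high"),
             right = FALSE)
  data.frame(cluster_id = clusters$cluster_id, I2_mean = i2,
             label = as.character(lab))
}

#' Small-study-effect and excess-significance tests at cluster peaks
#'
#' At each cluster's peak voxel, using the per-study reconstructed effects
#' g_i and standard errors SE_i: the Egger test regresses the standardized
#' effect `g_i / SE_i` on precision `1 / SE_i` and t-tests the intercept
#' (reported unavailable when fewer than 3 studies or the precisions are
#' constant); the excess-significance test compares the observed number O of
#' individually significant studies (two-sided alpha = 0.05) with the
#' expected number E = sum of normal-approximation powers to detect the
#' pooled effect, via a one-sided binomial test of O against E/k.
#'
#' @param study_maps list of [reconstruct_study_map()] results (one per
#'   study, same grids).
#' @param result the [meta_result] combining them.
#' @param clusters cluster table from [threshold_clusters()].
#' @param alpha per-study two-sided significance level (default 0.05).
#' @return data frame `cluster_id`, `egger_intercept`, `egger_p`,
#'   `o_significant`, `e_significant`, `excess_sig_p`.
#' @export
small_study_tests <- function(study_maps, result, clusters, alpha = 0.05) {
  vox <- attr(clusters, "voxels")
  k <- length(study_maps)
  zc <- stats::qnorm(1 - alpha / 2)
  out <- lapply(seq_len(nrow(clusters)), function(i) {
    lin <- vox[[clusters$cluster_id[i]]]
    pk <- lin[which.max(abs(result$z[lin]))]
    g <- vapply(study_maps, function(m) m$g[pk], numeric(1))
    se <- vapply(study_maps, function(m) sqrt(m$var_g[pk]), numeric(1))
    egger_int <- NA_real_; egger_p <- NA_real_
    prec <- 1 / se
    if (k >= 3 && stats::sd(prec) > 1e-10) {
      fit <- stats::lm(I(g / se) ~ prec)
      cf <- summary(fit)$coefficients
      egger_int <- cf[1, 1]; egger_p <- cf[1, 4]
    }
    zi <- g / se
    O <- sum(abs(zi) > zc)
    g_pool <- result$g[pk]
    pow <- stats::pnorm(-zc + abs(g_pool) / se) +
           stats::pnorm(-zc - abs(g_pool) / se)
    E <- sum(pow)
    excess_p <- stats::binom.test(O, k, p = min(1, E / k),
                                  alternative = "greater")$p.value
    data.frame(cluster_id = clusters$cluster_id[i],
               egger_intercept = egger_int, egger_p = egger_p,
               o_significant = O, e_significant = E, excess_sig_p = excess_p)
  })
  if (!length(out))
    return(data.frame(cluster_id = integer(), egger_intercept = numeric(),
                      egger_p = numeric(), o_significant = integer(),
                      e_significant = numeric(), excess_sig_p = numeric()))
  do.call(rbind, out)
}

#' Jackknife (leave-one-out) consistency of meta-analytic clusters
#'
#' Repeats the random-effects combination K times, leaving out one study
#' each time, and reports for every full-analysis cluster the fraction of
#' reruns in which a suprathreshold cluster of the same sign overlaps it by
#' at least one voxel.
#'
#' @param study_maps list of >= 3 [reconstruct_study_map()] results.
#' @param p_voxel,extent thresholds passed to [threshold_clusters()].
#' @return data frame `cluster_id`, `consistency` (in [0, 1]), plus the full
#'   cluster table columns.
#' @export
jackknife_consistency <- function(study_maps, p_voxel = 0.005, extent = 20L) {
  K <- length(study_maps)
  if (K < 3L) stop("jackknife needs at least 3 studies")
  full <- random_effects_combine(study_maps)
  cl_full <- threshold_clusters(full, p_voxel, extent)
  vox_full <- attr(cl_full, "voxels")
  if (!nrow(cl_full))
    return(data.frame(cluster_id = integer(), consistency = numeric()))
  hits <- integer(nrow(cl_full))
  for (drop in seq_len(K)) {
    res <- random_effects_combine(study_maps[-drop])
    cl <- threshold_clusters(res, p_voxel, extent)
    vox <- attr(cl, "voxels")
    for (i in seq_len(nrow(cl_full))) {
      same_sign <- which(cl$sign == cl_full$sign[i])
      ov <- any(vapply(same_sign, function(j)
        length(intersect(vox[[cl$cluster_id[j]]], vox_full[[cl_full$cluster_id[i]]])) > 0,
        logical(1)))
      if (ov) hits[i] <- hits[i] + 1L
    }
  }
  cbind(cl_full, consistency = hits / K)
}
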