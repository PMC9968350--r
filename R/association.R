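#' Mean map value inside spheres around MNI points
#'
#' For each coordinate, averages the map over in-mask voxels whose centres
#' lie within `radius_mm` (Euclidean, inclusive — a centre exactly at the
#' radius counts) of the point. A point whose sphere contains no in-mask
#' voxel is returned as `NA` under the default `"drop"` policy, or takes the
#' value of the nearest in-mask voxel under `"nearest"`.
#'
#' @param map a [volume_map].
#' @param coords n x 3 matrix of MNI mm points (finite).
#' @param radius_mm sphere radius in mm (default 3).
#' @param empty_policy `"drop"` (default) or `"nearest"`.
#' @return numeric vector of length n.
#' @export
extract_sphere_values <- function(map, coords, radius_mm = 3,
                                  empty_policy = c("drop", "nearest")) {
  stopifnot(inherits(map, "volume_map"))
  empty_policy <- match.arg(empty_policy)
  coords <- rbind2mat(coords)
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  vox_mm <- mask_coordinates(map)
  vals <- map$data[map$mask]
  out <- numeric(nrow(coords))
  r2 <- radius_mm^2
  for (i in seq_len(nrow(coords))) {
    d2 <- (vox_mm[, 1] - coords[i, 1])^2 + (vox_mm[, 2] - coords[i, 2])^2 +
          (vox_mm[, 3] - coords[i, 3])^2
    inside <- d2 <= r2 + 1e-9
    if (any(inside)) {
      out[i] <- mean(vals[inside])
    } else if (empty_policy == "nearest") {
      out[i] <- vals[which.min(d2)]
    } else {
      out[i] <- NA_real_
    }
  }
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH q-values (`q_i = min over j >= rank(i) of p_(j) m / j`, capped
#' at 1) with rejection at `q <= alpha` — the standard step-up rule, under
#' which the largest rejected p satisfies `p_(k) <= k alpha / m`.
#'
#' @param pvals probabilities in [0, 1].
#' @param alpha FDR level (default 0.05).
#' @return list with `q` (same length/order as `pvals`) and `rejected`
#'   (logical).
#' @export
bh_fdr <- function(pvals, alpha = 0.05) {
  if (!length(pvals)) return(list(q = numeric(), rejected = logical()))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  q <- stats::p.adjust(pvals, method = "BH")
  list(q = q, rejected = !is.na(q) & q <= alpha)
}

#' Gene-wise spatial correlation with a per-sample statistic vector
#'
#' Pearson correlation of every gene's cross-sample expression with the
#' per-sample values (e.g. sphere-averaged meta-analytic z), two-sided p
#' from the t transform with n - 2 degrees of freedom, and BH q-values over
#' the tested genes. Constant genes get `NA` r and are excluded from
#' testing; samples with `NA` in `zvec` are dropped for all genes.
#'
#' @param matrix numeric samples x genes expression matrix (>= 4 complete
#'   samples).
#' @param zvec per-sample values, row-aligned with `matrix` (`NA` allowed,
#'   those samples are dropped).
#' @param alpha FDR level for the significance flag (default 0.05).
#' @return data frame (`gene_id`, `r`, `p`, `q`, `significant`) — one row
#'   per gene, in column order of `matrix`.
#' @export
genewise_correlation <- function(matrix, zvec, alpha = 0.05) {
  if (length(zvec) != nrow(matrix))
    stop("`zvec` must have one value per row of `matrix`")
  ok <- is.finite(zvec)
  matrix <- matrix[ok, , drop = FALSE]
  zvec <- zvec[ok]
  n <- nrow(matrix)
  if (n < 4L) stop("need >= 4 samples with finite z values")
  sds <- apply(matrix, 2, stats::sd)
  r <- rep(NA_real_, ncol(matrix))
  testable <- sds > 0 & stats::sd(zvec) > 0
  if (any(testable))
    r[testable] <- as.vector(stats::cor(matrix[, testable, drop = FALSE], zvec))
  r <- pmin(1, pmax(-1, r))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  q <- rep(NA_real_, length(p))
  fdr <- bh_fdr(p[testable], alpha)
  q[testable] <- fdr$q
  data.frame(gene_id = colnames(matrix), r = r, p = p, q = q,
             significant = !is.na(q) & q <= alpha, row.names = NULL,
             stringsAsFactors = FALSE)
}
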