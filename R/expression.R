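#' Probe-level expression table with sample annotations
#'
#' @param probe_info data frame with columns `probe_id`, `gene_id` (each
#'   probe maps to exactly one gene).
#' @param expression numeric matrix, probes x samples, rownames = probe ids.
#' @param above_background logical matrix of the same shape flagging
#'   measurements that exceed background noise.
#' @param samples data frame of per-sample annotations: `sample_id`,
#'   `donor`, `region`, `hemisphere`, `structure`, `x`, `y`, `z` (MNI mm).
#' @return An object of class `probe_table`.
#' @export
probe_table <- function(probe_info, expression, above_background, samples) {
  stopifnot(all(c("probe_id", "gene_id") %in% names(probe_info)),
            nrow(expression) == nrow(probe_info),
            identical(dim(expression), dim(above_background)),
            ncol(expression) == nrow(samples))
  if (anyDuplicated(probe_info$probe_id))
    stop("duplicate probe ids")
  rownames(expression) <- probe_info$probe_id
  rownames(above_background) <- probe_info$probe_id
  structure(list(probe_info = probe_info, expression = expression,
                 above_background = above_background, samples = samples),
            class = "probe_table")
}

#' @export
print.probe_table <- function(x, ...) {
  cat("probe_table:", nrow(x$expression), "probes,",
      length(unique(x$probe_info$gene_id)), "genes,",
      ncol(x$expression), "samples\n")
  invisible(x)
}

#' Sample x gene expression bundle
#'
#' Container for the post-probe-selection expression matrix with its sample
#' annotations and, once computed, per-gene differential-stability scores.
#'
#' @param expr numeric matrix, samples x genes, dimnames set.
#' @param samples per-sample annotation data frame (see [probe_table()]),
#'   row-aligned with `expr`.
#' @param ds optional named per-gene DS vector.
#' @return An object of class `expression_bundle`.
#' @export
expression_bundle <- function(expr, samples, ds = NULL) {
  stopifnot(is.matrix(expr), nrow(expr) == nrow(samples))
  structure(list(expr = expr, samples = samples, ds = ds),
            class = "expression_bundle")
}

#' @export
print.expression_bundle <- function(x, ...) {
  cat("expression_bundle:", nrow(x$expr), "samples x", ncol(x$expr), "genes",
      if (!is.null(x$ds)) "(DS computed)" else "", "\n")
  invisible(x)
}

#' Intensity-based probe filtering
#'
#' Keeps a probe when it exceeds background noise in at least `min_frac` of
#' all samples pooled across donors (boundary inclusive: exactly `min_frac`
#' is kept).
#'
#' @param probes a [probe_table] with background flags.
#' @param min_frac minimum fraction of above-background samples (default
#'   0.5).
#' @return Filtered [probe_table].
#' @export
filter_probes_intensity <- function(probes, min_frac = 0.5) {
  stopifnot(inherits(probes, "probe_table"))
  if (is.null(probes$above_background)) stop("background flags missing")
  frac <- rowMeans(probes$above_background)
  keep <- frac >= min_frac
  probe_table(probes$probe_info[keep, , drop = FALSE],
              probes$expression[keep, , drop = FALSE],
              probes$above_background[keep, , drop = FALSE],
              probes$samples)
}

#' RNA-seq-guided representative probe selection
#'
#' For every gene present in the RNA-seq reference, correlates each of its
#' probes with the reference across matched samples (Spearman by default),
#' drops probes with correlation below `min_r`, and represents the gene by
#' its highest-correlating surviving probe. Genes absent from the reference
#' or with no surviving probe are dropped.
#'
#' @param probes a [probe_table].
#' @param rnaseq genes x samples reference matrix; rownames are gene ids,
#'   colnames sample ids matched against `probes$samples$sample_id`.
#' @param min_r minimum correlation to keep a probe (default 0.2; strictly
#'   below is dropped).
#' @param method correlation type, `"spearman"` (default) or `"pearson"`.
#' @return An [expression_bundle] (samples x genes) of representative
#'   probes, with attribute `"probe_map"` (gene_id -> probe_id, r).
#' @export
select_probes_rnaseq <- function(probes, rnaseq, min_r = 0.2,
                                 method = c("spearman", "pearson")) {
  stopifnot(inherits(probes, "probe_table"))
  method <- match.arg(method)
  matched <- intersect(probes$samples$sample_id, colnames(rnaseq))
  if (length(matched) < 3L) {
    warning("fewer than 3 matched samples between platforms; no probe can be selected")
    matched <- character()
  }
  genes <- intersect(unique(probes$probe_info$gene_id), rownames(rnaseq))
  si <- match(matched, probes$samples$sample_id)
  rows <- list()
  for (gid in genes) {
    pid <- probes$probe_info$probe_id[probes$probe_info$gene_id == gid]
    if (!length(matched)) next
    r <- vapply(pid, function(p)
      suppressWarnings(stats::cor(probes$expression[p, si], rnaseq[gid, matched],
                                  method = method)), numeric(1))
    r[is.na(r)] <- -Inf
    if (max(r) < min_r) next
    best <- pid[which.max(r)]
    rows[[gid]] <- list(probe_id = best, r = max(r))
  }
  if (!length(rows)) {
    expr <- matrix(numeric(), nrow(probes$samples), 0)
  } else {
    expr <- t(probes$expression[vapply(rows, `[[`, "", "probe_id"), , drop = FALSE])
    colnames(expr) <- names(rows)
  }
  rownames(expr) <- probes$samples$sample_id
  out <- expression_bundle(expr, probes$samples)
  attr(out, "probe_map") <- data.frame(
    gene_id = names(rows),
    probe_id = vapply(rows, `[[`, "", "probe_id"),
    r = vapply(rows, `[[`, 0, "r"), row.names = NULL)
  out
}

#' Restrict samples to left-hemisphere cortex inside the analysis mask
#'
#' @param bundle an [expression_bundle] with annotated samples.
#' @param mask a [volume_map]; samples whose MNI coordinate falls outside an
#'   in-mask voxel are dropped.
#' @return Filtered [expression_bundle].
#' @export
filter_samples <- function(bundle, mask) {
  stopifnot(inherits(bundle, "expression_bundle"), inherits(mask, "volume_map"))
  s <- bundle$samples
  keep <- s$hemisphere == "left" & s$structure == "cortex" &
    in_mask(as.matrix(s[, c("x", "y", "z")]), mask)
  if (!any(keep)) warning("no samples survive the left-cortex/mask filter")
  expression_bundle(bundle$expr[keep, , drop = FALSE],
                    s[keep, , drop = FALSE], bundle$ds)
}

#' Scaled robust sigmoid of one vector
#'
#' `s(x_i) = 1 / (1 + exp(-(x_i - median(x)) / (IQR(x) / 1.35)))`, min-max
#' rescaled to [0, 1]. Quartiles use linear interpolation (type 7). A
#' zero-IQR vector maps to 0.5 throughout. Monotone, and invariant to
#' affine transforms of the input.
#'
#' @param x numeric vector (>= 3 values).
#' @return numeric vector in [0, 1].
#' @export
scaled_robust_sigmoid <- function(x) {
  if (length(x) < 3L) stop("need >= 3 values")
  iqr <- stats::IQR(x, type = 7)
  if (iqr == 0) return(rep(0.5, length(x)))
  s <- 1 / (1 + exp(-(x - stats::median(x)) / (iqr / 1.35)))
  (s - min(s)) / (max(s) - min(s))
}
srs_vector <- scaled_robust_sigmoid

#' Two-stage scaled robust sigmoid normalization
#'
#' Applies the scaled robust sigmoid
#' `s(x_i) = 1 / (1 + exp(-(x_i - median(x)) / (IQR(x) / 1.35)))`, min-max
#' rescaled to [0, 1], first across genes within each sample, then across
#' samples within each gene — per donor by default, which removes donor
#' offset and scale effects. Quartiles use linear interpolation (type 7);
#' the constant 1.35 converts the IQR to a normal-sigma estimate. A
#' zero-IQR vector is set to 0.5 throughout (with a warning).
#'
#' @param matrix numeric samples x genes matrix (>= 3 genes and >= 3 samples
#'   per normalized vector).
#' @param donors optional per-sample donor labels; when given, each donor's
#'   block is normalized separately (the default mode of the pipeline), and
#'   each donor must contribute >= 3 samples.
#' @return Normalized matrix with values in [0, 1].
#' @export
srs_normalize <- function(matrix, donors = NULL) {
  if (ncol(matrix) < 3L) stop("need >= 3 genes to normalize within samples")
  norm_block <- function(m) {
    if (nrow(m) < 3L) stop("need >= 3 samples per donor to normalize within genes")
    zi <- apply(m, 1, stats::IQR, type = 7) == 0
    if (any(zi)) warning(sum(zi), " sample vector(s) with zero IQR set to 0.5")
    m <- t(apply(m, 1, srs_vector))   # within sample, across genes
    zg <- apply(m, 2, stats::IQR, type = 7) == 0
    if (any(zg)) warning(sum(zg), " gene vector(s) with zero IQR set to 0.5")
    apply(m, 2, srs_vector)           # within gene, across samples
  }
  if (is.null(donors)) return(norm_block(matrix))
  stopifnot(length(donors) == nrow(matrix))
  out <- matrix
  for (d in unique(donors)) {
    i <- donors == d
    out[i, ] <- norm_block(matrix[i, , drop = FALSE])
  }
  out
}

#' Differential stability of gene expression across donors
#'
#' For each gene, expression is averaged per region label within each donor;
#' DS is the mean over donor pairs of the correlation (Spearman by default)
#' between the two donors' regional profiles over their shared regions.
#' Donor pairs sharing fewer than 3 regions are skipped; if no pair
#' qualifies, DS is undefined for all genes.
#'
#' @param bundle an [expression_bundle] with `donor` and `region` sample
#'   annotations (>= 2 donors).
#' @param method correlation type, `"spearman"` (default) or `"pearson"`.
#' @return The bundle with `ds` set to the named per-gene DS vector.
#' @export
differential_stability <- function(bundle, method = c("spearman", "pearson")) {
  stopifnot(inherits(bundle, "expression_bundle"))
  method <- match.arg(method)
  s <- bundle$samples
  donors <- unique(s$donor)
  if (length(donors) < 2L) stop("differential stability needs >= 2 donors")
  # per-donor region-mean profiles: list of regions x genes matrices
  prof <- lapply(donors, function(d) {
    i <- s$donor == d
    m <- rowsum(bundle$expr[i, , drop = FALSE], s$region[i])
    cnt <- table(s$region[i])
    m / as.vector(cnt[rownames(m)])
  })
  names(prof) <- donors
  G <- ncol(bundle$expr)
  npair <- 0L
  sum_r <- rep(0, G)
  for (a in seq_along(donors)[-length(donors)]) {
    for (b in seq((a + 1), length(donors))) {
      shared <- intersect(rownames(prof[[a]]), rownames(prof[[b]]))
      if (length(shared) < 3L) next
      ra <- prof[[a]][shared, , drop = FALSE]
      rb <- prof[[b]][shared, , drop = FALSE]
      if (method == "spearman") {
        ra <- apply(ra, 2, rank); rb <- apply(rb, 2, rank)
      }
      r <- suppressWarnings(
        vapply(seq_len(G), function(g) stats::cor(ra[, g], rb[, g]), numeric(1)))
      r[is.na(r)] <- 0
      sum_r <- sum_r + r
      npair <- npair + 1L
    }
  }
  if (npair == 0L) {
    warning("no donor pair shares >= 3 regions; DS undefined")
    ds <- rep(NA_real_, G)
  } else {
    ds <- sum_r / npair
  }
  names(ds) <- colnames(bundle$expr)
  bundle$ds <- ds
  bundle
}

#' Keep the genes with the highest differential stability
#'
#' Genes are ranked by DS descending (ties broken by gene identifier,
#' ascending) and the first `ceiling(top_frac * G)` are kept.
#'
#' @param bundle an [expression_bundle] with `ds` computed.
#' @param top_frac fraction of genes to keep (default 0.5; sensitivity
#'   settings 0.4 and 0.6 give nested subsets).
#' @return Filtered [expression_bundle].
#' @export
filter_genes_ds <- function(bundle, top_frac = 0.5) {
  stopifnot(inherits(bundle, "expression_bundle"))
  if (is.null(bundle$ds)) stop("compute differential_stability() first")
  G <- ncol(bundle$expr)
  ord <- order(-bundle$ds, colnames(bundle$expr))
  keep <- sort(ord[seq_len(ceiling(top_frac * G))])
  expression_bundle(bundle$expr[, keep, drop = FALSE], bundle$samples,
                    bundle$ds[keep])
}

#' Run the full expression preprocessing chain
#'
#' Fixed order: intensity-based probe filter, RNA-seq-guided probe
#' selection, left-cortex/mask sample filter, per-donor two-stage scaled
#' robust sigmoid normalization, differential-stability gene filter. The
#' counts surviving each step are recorded in attribute `"log"` and emitted
#' as messages.
#'
#' @param probes a [probe_table].
#' @param rnaseq genes x samples reference matrix.
#' @param mask analysis-mask [volume_map].
#' @param min_frac,min_r,top_frac_ds stage parameters (defaults 0.5, 0.2,
#'   0.5).
#' @param normalize_by_donor normalize each donor separately (default TRUE).
#' @return Processed [expression_bundle] (values in [0, 1], DS attached).
#' @export
process_expression <- function(probes, rnaseq, mask, min_frac = 0.5,
                               min_r = 0.2, top_frac_ds = 0.5,
                               normalize_by_donor = TRUE) {
  log <- c(probes_in = nrow(probes$expression))
  probes <- filter_probes_intensity(probes, min_frac)
  log["probes_intensity"] <- nrow(probes$expression)
  bundle <- select_probes_rnaseq(probes, rnaseq, min_r)
  log["genes_selected"] <- ncol(bundle$expr)
  log["samples_in"] <- nrow(bundle$expr)
  bundle <- filter_samples(bundle, mask)
  log["samples_kept"] <- nrow(bundle$expr)
  bundle$expr <- srs_normalize(bundle$expr,
                               donors = if (normalize_by_donor) bundle$samples$donor)
  bundle <- differential_stability(bundle)
  bundle <- filter_genes_ds(bundle, top_frac_ds)
  log["genes_ds"] <- ncol(bundle$expr)
  message("expression processing: ",
          paste(names(log), log, sep = "=", collapse = ", "))
  attr(bundle, "log") <- log
  bundle
}
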