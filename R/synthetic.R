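#' Specification of a toy brain grid
#'
#' Defines a small isotropic volumetric grid with a cubic or ellipsoidal
#' analysis mask, standing in for a gray-matter mask in MNI space. The grid
#' is centred on the MNI origin.
#'
#' @param grid_shape integer vector of 3 voxel counts, all >= 4.
#' @param voxel_size_mm isotropic voxel edge length in mm (> 0).
#' @param mask_kind `"full_cube"` or `"ellipsoid"`. The ellipsoid is the
#'   largest one whose semi-axes reach the outermost voxel centres, i.e.
#'   `(grid_shape - 1) / 2 * voxel_size_mm` per axis, so it always fits
#'   inside the grid.
#' @param seed integer seed recorded with the spec (mask construction is
#'   deterministic; the seed is carried for provenance).
#' @return An object of class `toy_brain_spec`.
#' @export
toy_brain_spec <- function(grid_shape = c(20L, 20L, 20L), voxel_size_mm = 2,
                           mask_kind = c("full_cube", "ellipsoid"), seed = 1L) {
  mask_kind <- match.arg(mask_kind)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    stop("`grid_shape` must give 3 axes, each >= 4 voxels")
  if (!is.numeric(voxel_size_mm) || voxel_size_mm <= 0)
    stop("`voxel_size_mm` must be > 0")
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 mask_kind = mask_kind, seed = as.integer(seed)),
            class = "toy_brain_spec")
}

#' Generate the analysis grid and mask
#'
#' @param spec a [toy_brain_spec].
#' @return A [volume_map] with zero data, the mask implied by
#'   `spec$mask_kind`, and an affine centring the grid on the origin.
#' @export
gen_brain_grid <- function(spec) {
  stopifnot(inherits(spec, "toy_brain_spec"))
  d <- spec$grid_shape
  vs <- spec$voxel_size_mm
  affine <- diag(c(vs, vs, vs, 1))
  affine[1:3, 4] <- -(d - 1) / 2 * vs
  if (spec$mask_kind == "full_cube") {
    mask <- array(TRUE, dim = d)
  } else {
    semi <- (d - 1) / 2 * vs
    i <- (seq_len(d[1]) - 1 - (d[1] - 1) / 2) * vs
    j <- (seq_len(d[2]) - 1 - (d[2] - 1) / 2) * vs
    k <- (seq_len(d[3]) - 1 - (d[3] - 1) / 2) * vs
    q <- outer(outer((i / semi[1])^2, (j / semi[2])^2, `+`), (k / semi[3])^2, `+`)
    mask <- q <= 1
  }
  volume_map(array(0, dim = d), affine, mask)
}

#' Ground truth for a synthetic study
#'
#' Records what the generators plant: which genes carry signal and at what
#' population spatial correlation, the per-cluster pooled effect sizes and
#' cluster centres used to place study peaks, and the spatial
#' autocorrelation length of the expression fields.
#'
#' @param true_gene_ids character vector of planted gene identifiers.
#' @param target_r planted population spatial correlation, |r| < 1; recycled
#'   over `true_gene_ids`.
#' @param pooled_effect per-cluster true Hedges-g effect sizes.
#' @param cluster_centers_mm numeric matrix (clusters x 3) of MNI mm peak
#'   locations, one row per element of `pooled_effect`.
#' @param autocorr_length_mm exponential covariance length scale (mm) of the
#'   expression fields; >= 0 (0 gives spatially independent fields).
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(true_gene_ids, target_r, pooled_effect,
                            cluster_centers_mm, autocorr_length_mm = 15) {
  if (any(abs(target_r) >= 1)) stop("|target_r| must be < 1")
  if (autocorr_length_mm < 0) stop("`autocorr_length_mm` must be >= 0")
  cluster_centers_mm <- rbind2mat(cluster_centers_mm)
  if (nrow(cluster_centers_mm) != length(pooled_effect))
    stop("one cluster centre per pooled effect required")
  structure(list(true_gene_ids = as.character(true_gene_ids),
                 target_r = rep_len(target_r, length(true_gene_ids)),
                 pooled_effect = pooled_effect,
                 cluster_centers_mm = cluster_centers_mm,
                 autocorr_length_mm = autocorr_length_mm),
            class = "synthetic_truth")
}

#' One published study: group sizes and signed peaks
#'
#' @param study_id label.
#' @param n_patients,n_controls group sizes, both >= 2.
#' @param peaks data frame with columns `x`, `y`, `z` (MNI mm) and `t`
#'   (signed statistic); may have zero rows (a null-result study that
#'   contributes a zero map).
#' @param measure metadata label (e.g. ALFF, ReHo, CBF).
#' @return An object of class `study_record`.
#' @export
study_record <- function(study_id, n_patients, n_controls,
                         peaks = data.frame(x = numeric(), y = numeric(),
                                            z = numeric(), t = numeric()),
                         measure = "ALFF") {
  if (n_patients < 2 || n_controls < 2) stop("group sizes must be >= 2")
  if (!all(c("x", "y", "z", "t") %in% names(peaks)))
    stop("`peaks` needs columns x, y, z, t")
  if (nrow(peaks) && any(!is.finite(peaks$t))) stop("non-finite t value in peaks")
  structure(list(study_id = as.character(study_id),
                 n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 peaks = peaks, measure = measure),
            class = "study_record")
}

#' Group sizes of the eight first-episode psychosis studies
#'
#' The per-study patient and control counts of the eight resting-state
#' studies (ALFF/fALFF, ReHo, CBF) entering the meta-analysis; the counts
#' sum to 500 patients and 469 controls.
#'
#' @return data frame with columns `study_id`, `n_patients`, `n_controls`,
#'   `measure`.
#' @export
dfp_study_table <- function() {
  data.frame(
    study_id   = c("Li", "Yan", "Zhao", "Wu", "Liu", "Lei", "Ren", "Scheef"),
    n_patients = c(72L, 69L, 44L, 32L, 48L, 124L, 100L, 11L),
    n_controls = c(79L, 74L, 26L, 32L, 31L, 102L, 100L, 25L),
    measure    = c("ALFF", "ReHo", "ReHo", "fALFF", "ReHo", "ALFF", "ALFF", "CBF"),
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic study peak tables
#'
#' Each study reports one peak per planted cluster, with per-study effect
#' size `pooled_effect + N(0, noise_sd)` on the Hedges-g scale, stored as
#' the t statistic that converts back to exactly that g for the study's
#' group sizes. Peak coordinates are snapped to the nearest in-mask voxel
#' centre.
#'
#' @param n_studies number of studies (>= 1).
#' @param truth a [synthetic_truth] (cluster centres must fall in the mask).
#' @param grid a [volume_map].
#' @param noise_sd between-study SD of the peak effect, g units.
#' @param seed integer seed.
#' @param group_sizes optional data frame with `n_patients`, `n_controls`
#'   (and optionally `study_id`, `measure`); defaults to the eight
#'   first-episode psychosis studies' sizes ([dfp_study_table()]) when
#'   `n_studies == 8`, otherwise sizes are drawn uniformly in 20..120.
#' @return list of [study_record]s.
#' @export
gen_study_peaks <- function(n_studies, truth, grid, noise_sd = 0.1, seed = 1L,
                            group_sizes = NULL) {
  stopifnot(n_studies >= 1, inherits(truth, "synthetic_truth"),
            inherits(grid, "volume_map"))
  centers <- truth$cluster_centers_mm
  if (!all(in_mask(centers, grid)))
    stop("all cluster centres must lie inside the analysis mask")
  # snap to voxel centres so coordinates are on-grid
  centers <- voxel_to_mm(mm_to_voxel(centers, grid$affine), grid$affine)
  set.seed(seed)
  if (is.null(group_sizes)) {
    if (n_studies == 8L) {
      group_sizes <- dfp_study_table()
    } else {
      group_sizes <- data.frame(
        study_id = sprintf("S%02d", seq_len(n_studies)),
        n_patients = sample(20:120, n_studies, replace = TRUE),
        n_controls = sample(20:120, n_studies, replace = TRUE),
        measure = rep_len(c("ALFF", "ReHo", "CBF"), n_studies))
    }
  }
  stopifnot(nrow(group_sizes) >= n_studies)
  if (is.null(group_sizes$study_id))
    group_sizes$study_id <- sprintf("S%02d", seq_len(nrow(group_sizes)))
  if (is.null(group_sizes$measure)) group_sizes$measure <- "ALFF"
  lapply(seq_len(n_studies), function(i) {
    n1 <- group_sizes$n_patients[i]; n2 <- group_sizes$n_controls[i]
    g <- truth$pooled_effect + stats::rnorm(length(truth$pooled_effect), 0, noise_sd)
    J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
    t <- g / (J * sqrt(1 / n1 + 1 / n2))
    study_record(group_sizes$study_id[i], n1, n2,
                 peaks = data.frame(x = centers[, 1], y = centers[, 2],
                                    z = centers[, 3], t = t),
                 measure = group_sizes$measure[i])
  })
}

# Gaussian random fields with exponential covariance exp(-d / lambda) over
# the rows of `coords`; returns n x m matrix of independent standardized
# fields. lambda = 0 gives white noise.
grf_fields <- function(coords, m, lambda) {
  n <- nrow(coords)
  z <- matrix(stats::rnorm(n * m), n, m)
  if (lambda <= 0) return(z)
  D <- as.matrix(stats::dist(coords))
  C <- exp(-D / lambda)
  L <- chol(C + diag(1e-8, n))
  crossprod(L, z)
}

std <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(x * 0)
  (x - mean(x)) / s
}

#' Generate a synthetic multi-donor expression dataset
#'
#' Emulates the structure of a six-donor postmortem microarray atlas:
#' spatially autocorrelated gene expression at left-cortical tissue sample
#' coordinates, multiple probes per gene, background-noise flags, a
#' correlated RNA-seq reference, donor offset/scale effects, region labels
#' shared across donors, and a configurable fraction of right-hemisphere /
#' subcortical decoy samples.
#'
#' Non-planted genes are Gaussian random fields with exponential spatial
#' covariance `exp(-d / autocorr_length_mm)`. Each planted gene mixes the
#' standardized sphere-sampled target map `t` with an independent field `e`
#' as `r * std(t) + sqrt(1 - r^2) * std(e)` (with `e` residualized against
#' `t` first), which fixes the population correlation with the target at
#' `r`. Measured expression adds donor-specific spatial fields: each gene
#' carries a stability weight `s` (1 for planted genes — genes whose
#' expression tracks a disease map are donor-conserved by premise, which is
#' what the differential-stability filter selects for; drawn from
#' `donor_stability` for background genes), and a donor measures
#' `sqrt(s) * shared + sqrt(1 - s) * donor_field`. Each probe then adds
#' independent probe noise; one probe of every planted gene is flagged below
#' background in `bad_probe_frac` of samples so the intensity filter has
#' true positives to remove.
#'
#' @param grid a [volume_map]; sample coordinates are drawn at in-mask voxel
#'   centres.
#' @param target_map a [volume_map] on the same grid providing the spatial
#'   pattern planted genes track.
#' @param n_donors number of donors (>= 2; differential stability needs
#'   donor pairs). Default 6, the donor count of the atlas it emulates.
#' @param n_samples_per_donor tissue samples per donor (>= 10).
#' @param n_genes gene universe size.
#' @param probes_per_gene probes measuring each gene (>= 1).
#' @param truth a [synthetic_truth]; `true_gene_ids` must be a subset of the
#'   generated universe `g0001..`.
#' @param seed integer seed.
#' @param probe_noise_sd,rnaseq_noise_sd probe- and platform-level noise SDs.
#' @param bad_probe_frac fraction of samples in which the flagged probe of a
#'   planted gene falls below background (default 0.7, above the 50 percent
#'   filter threshold).
#' @param decoy_frac fraction of extra samples labelled right-hemisphere or
#'   subcortical, to exercise sample filtering.
#' @param donor_offset_sd,donor_scale_sd donor additive offset SD and scale
#'   jitter SD (removed downstream by per-donor normalization).
#' @param donor_stability range (min, max) of the uniform distribution the
#'   per-gene donor-stability weight of background genes is drawn from;
#'   planted genes have weight 1.
#' @param region_blocks blocks per axis used to assign region labels from
#'   coordinates (labels shared across donors).
#' @return list with elements `probes` (a `probe_table`), `rnaseq` (genes x
#'   samples reference matrix), `gene_signal` (samples x genes noiseless
#'   shared signal), `stability` (per-gene donor-stability weights),
#'   `samples` (annotation data frame) and `truth`.
#' @export
gen_expression_dataset <- function(grid, target_map, n_donors = 6L,
                                   n_samples_per_donor = 30L, n_genes = 200L,
                                   probes_per_gene = 2L, truth, seed = 1L,
                                   probe_noise_sd = 0.3, rnaseq_noise_sd = 0.2,
                                   bad_probe_frac = 0.7, decoy_frac = 0.1,
                                   donor_offset_sd = 0.5, donor_scale_sd = 0.15,
                                   donor_stability = c(0.2, 1),
                                   region_blocks = 3L) {
  stopifnot(inherits(grid, "volume_map"), inherits(target_map, "volume_map"),
            inherits(truth, "synthetic_truth"))
  if (n_donors < 2) stop("`n_donors` must be >= 2 (differential stability needs donor pairs)")
  if (n_samples_per_donor < 10) stop("`n_samples_per_donor` must be >= 10")
  if (!identical(dim(target_map$data), dim(grid$data)))
    stop("`target_map` grid does not match `grid`")
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  if (!all(truth$true_gene_ids %in% gene_ids))
    stop("`truth$true_gene_ids` must be a subset of the generated universe")

  set.seed(seed)
  vox_mm <- mask_coordinates(grid)
  n_core <- n_donors * n_samples_per_donor
  n_decoy <- round(decoy_frac * n_core)
  n_tot <- n_core + n_decoy
  pick <- sample(nrow(vox_mm), n_tot, replace = n_tot > nrow(vox_mm))
  coords <- vox_mm[pick, , drop = FALSE]

  donor <- rep(sprintf("donor%02d", seq_len(n_donors)), length.out = n_tot)
  hemisphere <- rep("left", n_tot)
  structure_class <- rep("cortex", n_tot)
  if (n_decoy > 0) {
    di <- n_core + seq_len(n_decoy)
    flip <- stats::runif(n_decoy) < 0.5
    hemisphere[di][flip] <- "right"
    structure_class[di][!flip] <- "subcortex"
  }
  # region labels from a fixed spatial block partition, shared across donors
  rng <- apply(vox_mm, 2, range)
  cuts <- lapply(1:3, function(a)
    seq(rng[1, a] - 1e-6, rng[2, a] + 1e-6, length.out = region_blocks + 1))
  blk <- sapply(1:3, function(a)
    pmin(region_blocks, findInterval(coords[, a], cuts[[a]])))
  region <- sprintf("R%d.%d.%d", blk[, 1], blk[, 2], blk[, 3])
  sample_id <- sprintf("s%04d", seq_len(n_tot))

  # gene-level spatial signal
  signal <- grf_fields(coords, n_genes, truth$autocorr_length_mm)
  colnames(signal) <- gene_ids
  tv <- extract_sphere_values(target_map, coords, radius_mm = 3,
                              empty_policy = "nearest")
  tvs <- std(tv)
  for (i in seq_along(truth$true_gene_ids)) {
    gid <- truth$true_gene_ids[i]
    r <- truth$target_r[i]
    # residualize the independent field against the target first: smooth
    # fields share sample-level correlation by chance, which would otherwise
    # shift the realized correlation away from target_r
    e <- std(signal[, gid])
    e <- std(e - stats::cor(e, tvs) * tvs)
    signal[, gid] <- r * tvs + sqrt(1 - r^2) * e
  }

  # donor-specific spatial variability: background genes are only partly
  # conserved across donors, planted genes fully (their stability weight = 1)
  stab <- stats::runif(n_genes, donor_stability[1], donor_stability[2])
  names(stab) <- gene_ids
  stab[truth$true_gene_ids] <- 1
  di <- match(donor, sprintf("donor%02d", seq_len(n_donors)))
  measured <- signal
  for (d in seq_len(n_donors)) {
    rows <- which(di == d)
    dn <- grf_fields(coords[rows, , drop = FALSE], n_genes,
                     truth$autocorr_length_mm)
    measured[rows, ] <- sweep(signal[rows, , drop = FALSE], 2, sqrt(stab), `*`) +
      sweep(dn, 2, sqrt(1 - stab), `*`)
  }

  # donor offset and scale effects on the measured (microarray) platform
  offs <- stats::rnorm(n_donors, 0, donor_offset_sd)
  scls <- exp(stats::rnorm(n_donors, 0, donor_scale_sd))
  measured <- measured * scls[di] + offs[di]

  n_probes <- n_genes * probes_per_gene
  probe_gene <- rep(gene_ids, each = probes_per_gene)
  probe_id <- sprintf("%s_p%d", probe_gene, rep(seq_len(probes_per_gene), n_genes))
  expr <- t(measured[, probe_gene, drop = FALSE]) +
    matrix(stats::rnorm(n_probes * n_tot, 0, probe_noise_sd), n_probes, n_tot)
  dimnames(expr) <- list(probe_id, sample_id)

  above <- matrix(TRUE, n_probes, n_tot, dimnames = dimnames(expr))
  if (probes_per_gene > 1) {
    for (gid in truth$true_gene_ids) {
      p_bad <- sprintf("%s_p%d", gid, probes_per_gene)
      above[p_bad, ] <- stats::runif(n_tot) >= bad_probe_frac
    }
  }

  rnaseq <- t(signal) + matrix(stats::rnorm(n_genes * n_tot, 0, rnaseq_noise_sd),
                               n_genes, n_tot)
  dimnames(rnaseq) <- list(gene_ids, sample_id)

  samples <- data.frame(sample_id = sample_id, donor = donor, region = region,
                        hemisphere = hemisphere, structure = structure_class,
                        x = coords[, 1], y = coords[, 2], z = coords[, 3],
                        stringsAsFactors = FALSE)
  probes <- probe_table(
    probe_info = data.frame(probe_id = probe_id, gene_id = probe_gene,
                            stringsAsFactors = FALSE),
    expression = expr, above_background = above, samples = samples)
  list(probes = probes, rnaseq = rnaseq, gene_signal = signal,
       stability = stab, samples = samples, truth = truth)
}

# separable 3-D Gaussian smoothing of an array (reflecting boundaries)
smooth3d <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  half <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(seq(-half, half), sd = sigma_vox)
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    ap <- aperm(a, perm)
    d <- dim(ap)
    m <- matrix(ap, d[1], d[2] * d[3])
    idx <- outer(seq_len(d[1]), seq(-half, half), `+`)
    idx <- pmin(pmax(abs(idx - 1) + 1, 1), d[1])  # reflect
    idx[idx > d[1]] <- 2 * d[1] - idx[idx > d[1]]
    sm <- matrix(0, d[1], ncol(m))
    for (o in seq_along(k)) sm <- sm + k[o] * m[idx[, o], , drop = FALSE]
    out <- array(sm, d)
    aperm(out, order(perm))
  }
  for (ax in 1:3) arr <- smooth_axis(arr, ax)
  arr
}

#' Generate gene-set, PPI-edge and term-map annotation assets
#'
#' Produces the stand-ins for disease gene-set collections, a
#' high-confidence protein interaction edge list, and smooth behavioral
#' term activation maps. One gene set is planted to be enriched in
#' `target_list` with a configured odds ratio; the others are uniform draws.
#'
#' @param gene_universe character vector of gene identifiers.
#' @param n_sets number of gene sets (the first is the planted one when
#'   `target_list` is given).
#' @param edge_density edge probability of the interaction graph, in (0, 1).
#' @param n_terms number of term activation maps.
#' @param grid a [volume_map] on which term maps are generated.
#' @param seed integer seed.
#' @param target_list genes the planted set is enriched in (default: none,
#'   all sets uniform).
#' @param planted_or planted odds ratio of membership inside vs outside
#'   `target_list`.
#' @param base_rate baseline membership probability outside the target list.
#' @param term_smooth_mm Gaussian smoothing FWHM (mm) of term maps.
#' @return list with `gene_sets` (named list of character vectors),
#'   `edges` (data frame `gene_a`, `gene_b`, `score`) and `term_maps`
#'   (named list of [volume_map]s).
#' @export
gen_annotation_assets <- function(gene_universe, n_sets = 50L,
                                  edge_density = 0.02, n_terms = 3L,
                                  grid, seed = 1L, target_list = NULL,
                                  planted_or = 4, base_rate = 0.1,
                                  term_smooth_mm = 12) {
  if (!length(gene_universe)) stop("`gene_universe` must be non-empty")
  if (edge_density <= 0 || edge_density >= 1)
    stop("`edge_density` must be in (0, 1)")
  set.seed(seed)
  G <- length(gene_universe)

  odds0 <- base_rate / (1 - base_rate)
  p1 <- planted_or * odds0 / (1 + planted_or * odds0)
  gene_sets <- vector("list", n_sets)
  names(gene_sets) <- sprintf("set%03d", seq_len(n_sets))
  for (s in seq_len(n_sets)) {
    if (s == 1L && !is.null(target_list)) {
      pr <- ifelse(gene_universe %in% target_list, p1, base_rate)
      gene_sets[[s]] <- gene_universe[stats::runif(G) < pr]
      names(gene_sets)[1] <- "planted_set"
    } else {
      gene_sets[[s]] <- gene_universe[stats::runif(G) < base_rate]
    }
  }

  g <- igraph::sample_gnp(G, edge_density)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(gene_a = gene_universe[el[, 1]],
                      gene_b = gene_universe[el[, 2]],
                      score = stats::runif(nrow(el)),
                      stringsAsFactors = FALSE)

  sigma_vox <- term_smooth_mm / 2.3548 / voxel_size(grid)[1]
  term_maps <- lapply(seq_len(n_terms), function(i) {
    arr <- smooth3d(array(stats::rnorm(prod(dim(grid$data))), dim(grid$data)),
                    sigma_vox)
    volume_map(arr / stats::sd(arr), grid$affine, grid$mask)
  })
  names(term_maps) <- sprintf("term%02d", seq_len(n_terms))
  list(gene_sets = gene_sets, edges = edges, term_maps = term_maps)
}
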