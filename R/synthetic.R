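## Digital phantoms: mirrored box parcellations, straight jittered streamline
## bundles realising a target connectome, partial-region resection masks, and
## outcome-labelled cohorts with planted informative features. The generators
## exist to exercise conventions and statistics, not anatomy.

#' Generate a mirrored two-hemisphere box parcellation
#'
#' Places `regions_per_hemisphere` cubic regions per hemisphere on a regular
#' lattice, mirrored across the mid-sagittal plane, with a homologue table
#' pairing L_k with R_k. Fully deterministic.
#'
#' @param regions_per_hemisphere number of regions per side.
#' @param region_edge region cube edge in voxels.
#' @param gap background margin between regions in voxels.
#' @param voxel_size isotropic voxel edge in mm.
#' @return a [parcellation()] with populated region table.
#' @export
make_parcellation <- function(regions_per_hemisphere = 4, region_edge = 4,
                              gap = 2, voxel_size = 2) {
  Rh <- regions_per_hemisphere
  if (!is_count(Rh) || Rh < 1) stopf("regions_per_hemisphere must be >= 1")
  gy <- ceiling(sqrt(Rh))
  gz <- ceiling(Rh / gy)
  nx <- 2L * (region_edge + 2L * gap)
  ny <- gy * (region_edge + gap) + gap
  nz <- gz * (region_edge + gap) + gap
  labels <- array(0L, c(nx, ny, nz))
  xs_left <- (gap + 1L):(gap + region_edge)
  for (k in seq_len(Rh)) {
    iy <- (k - 1L) %% gy
    iz <- (k - 1L) %/% gy
    ys <- gap + iy * (region_edge + gap) + seq_len(region_edge)
    zs <- gap + iz * (region_edge + gap) + seq_len(region_edge)
    labels[xs_left, ys, zs] <- k
    labels[nx + 1L - xs_left, ys, zs] <- k + Rh
  }
  affine <- diag(c(voxel_size, voxel_size, voxel_size, 1))
  affine[1:3, 4] <- -c(nx, ny, nz) * voxel_size / 2
  regions <- data.frame(
    id = seq_len(2L * Rh),
    name = c(paste0("L", seq_len(Rh)), paste0("R", seq_len(Rh))),
    hemisphere = rep(c("left", "right"), each = Rh),
    homologue_id = c(seq_len(Rh) + Rh, seq_len(Rh))
  )
  parcellation(labels, affine, regions)
}

region_voxels <- function(parc, id) {
  which(parc$labels == id, arr.ind = TRUE) # 1-based array indices
}

#' Generate straight jittered streamlines realising a target connectome
#'
#' For every edge (i, j) with target count w, emits w polylines running from
#' a jittered random voxel centre inside region i to one inside region j,
#' with points spaced at most `step` mm apart. Diagonal entries of the
#' target are emitted as self-connections (both endpoints in the region).
#'
#' @param parc a [parcellation()] from [make_parcellation()].
#' @param target symmetric matrix of non-negative integer streamline counts,
#'   ordered like the parcellation's region ids.
#' @param endpoint_jitter isotropic endpoint jitter standard deviation (mm);
#'   keep well below half the voxel edge so rebuilt counts match the target.
#' @param step maximum spacing between consecutive polyline points (mm);
#'   keep below the voxel edge so mask membership is convention-independent.
#' @param seed optional integer seed (caller's RNG state preserved).
#' @return a [streamline_set()] carrying the parcellation's affine.
#' @export
make_streamlines <- function(parc, target, endpoint_jitter = 0.2, step = 0.9,
                             seed = NULL) {
  ids <- region_ids_of(parc)
  target <- as.matrix(target)
  if (!all(dim(target) == length(ids))) {
    stopf("target connectome must be %d x %d", length(ids), length(ids))
  }
  if (any(target < 0) || any(target != round(target))) {
    stopf("target counts must be non-negative integers")
  }
  if (max(abs(target - t(target))) > 0) stopf("target must be symmetric")
  vox_lists <- lapply(ids, function(id) {
    v <- region_voxels(parc, id)
    if (!nrow(v)) stopf("region %d has no voxels", id)
    v
  })
  with_seed(seed, {
    out <- list()
    R <- length(ids)
    for (i in seq_len(R)) {
      for (j in i:R) {
        w <- target[i, j]
        if (w == 0) next
        for (k in seq_len(w)) {
          p1 <- jittered_point(vox_lists[[i]], parc$affine, endpoint_jitter)
          p2 <- jittered_point(vox_lists[[j]], parc$affine, endpoint_jitter)
          out[[length(out) + 1L]] <- segment_polyline(p1, p2, step)
        }
      }
    }
    streamline_set(out, parc$affine)
  })
}

jittered_point <- function(voxels, affine, jitter) {
  v <- voxels[sample.int(nrow(voxels), 1L), ] - 1L # to 0-based
  as.numeric(voxel_to_world(v, affine)) + rnorm(3L, 0, jitter)
}

segment_polyline <- function(p1, p2, step) {
  len <- sqrt(sum((p2 - p1)^2))
  np <- max(2L, as.integer(ceiling(len / step)) + 1L)
  t <- seq(0, 1, length.out = np)
  cbind(p1[1] + t * (p2[1] - p1[1]),
        p1[2] + t * (p2[2] - p1[2]),
        p1[3] + t * (p2[3] - p1[3]))
}

#' Generate a partial-region resection mask
#'
#' Covers approximately the requested fraction of each target region's
#' voxels with a contiguous slab (voxels taken in slice order along the
#' anterior-posterior axis). All target regions must lie in one hemisphere.
#'
#' @param parc a [parcellation()].
#' @param fractions named numeric vector (names = region ids) of resected
#'   fractions in \[0, 1\].
#' @param seed unused placeholder for interface symmetry (the slab is
#'   deterministic).
#' @return a [resection_mask()] on the parcellation grid.
#' @export
make_resection_mask <- function(parc, fractions, seed = NULL) {
  if (is.null(names(fractions))) stopf("fractions must be named by region id")
  ids <- as.integer(names(fractions))
  if (any(is.na(ids)) || !all(ids %in% region_ids_of(parc))) {
    stopf("unknown region id in fractions")
  }
  if (any(fractions < 0 | fractions > 1)) stopf("fractions must be in [0, 1]")
  if (!is.null(parc$regions)) {
    hemi <- parc$regions$hemisphere[match(ids, parc$regions$id)]
    hemi <- unique(hemi[fractions > 0])
    if (length(hemi) > 1L) {
      stopf("target regions must lie in a single hemisphere")
    }
  }
  values <- array(0L, dim(parc$labels))
  for (k in seq_along(ids)) {
    if (fractions[k] == 0) next
    v <- region_voxels(parc, ids[k])
    v <- v[order(v[, 2], v[, 3], v[, 1]), , drop = FALSE]
    take <- ceiling(fractions[k] * nrow(v))
    values[v[seq_len(take), , drop = FALSE]] <- 1L
  }
  resection_mask(values, parc$affine)
}

#' Generate an outcome-labelled cohort with planted informative features
#'
#' Change-ratio features are drawn from Beta distributions parameterised by
#' mean and concentration (support \[0, 1\] matches ratio semantics). For
#' the planted subset of connection features the class means differ by
#' `delta`: seizure-free subjects (+1) have mean `baseline_mean - delta`
#' (greater reduction), non-seizure-free subjects (-1) keep `baseline_mean`.
#' All other features are class-independent.
#'
#' @param n_per_class subjects per class; length 1 (balanced) or 2
#'   (+1 class, then -1 class).
#' @param block_sizes named integer vector of feature-block sizes
#'   (connection_strength, region_strength, region_volume).
#' @param n_informative number of planted connection features (<= the
#'   connection block size).
#' @param delta between-class difference of mean change ratio, in \[0, 1\].
#' @param baseline_mean class-independent mean change ratio.
#' @param concentration Beta concentration (shape1 + shape2); larger means
#'   less noise. 20 gives an sd of about 0.11 at mean 0.5.
#' @param seed optional integer seed (caller's RNG state preserved).
#' @return list with `features` (a [cohort_features()]) and `truth` (list
#'   with `informative` names, `indices`, and the generating parameters).
#' @export
make_cohort <- function(n_per_class = 30,
                        block_sizes = c(connection_strength = 170,
                                        region_strength = 20,
                                        region_volume = 10),
                        n_informative = 10, delta = 0.4,
                        baseline_mean = 0.9, concentration = 20,
                        seed = NULL) {
  if (length(n_per_class) == 1L) n_per_class <- rep(n_per_class, 2L)
  if (any(n_per_class < 1)) stopf("both classes must be non-empty")
  if (delta < 0 || delta > 1) stopf("delta must be in [0, 1]")
  blocks <- c("connection_strength", "region_strength", "region_volume")
  if (is.null(names(block_sizes))) names(block_sizes) <- blocks[seq_along(block_sizes)]
  block_sizes <- block_sizes[blocks[blocks %in% names(block_sizes)]]
  m <- sum(block_sizes)
  n_conn <- if ("connection_strength" %in% names(block_sizes)) {
    block_sizes[["connection_strength"]]
  } else 0L
  if (n_informative > n_conn) {
    stopf("n_informative exceeds the connection block size")
  }
  mu_pos <- baseline_mean - delta
  if (mu_pos <= 0 || mu_pos >= 1 || baseline_mean <= 0 || baseline_mean >= 1) {
    stopf("infeasible delta/baseline_mean: class means must lie in (0, 1)")
  }
  n <- sum(n_per_class)
  y <- c(rep(1, n_per_class[1]), rep(-1, n_per_class[2]))
  with_seed(seed, {
    planted <- sort(sample.int(n_conn, n_informative))
    A <- matrix(
      rbeta(n * m, baseline_mean * concentration,
            (1 - baseline_mean) * concentration),
      n, m
    )
    for (jj in planted) {
      A[y > 0, jj] <- rbeta(n_per_class[1], mu_pos * concentration,
                            (1 - mu_pos) * concentration)
    }
    colnames(A) <- unlist(lapply(names(block_sizes), function(b) {
      prefix <- c(connection_strength = "conn", region_strength = "strength",
                  region_volume = "volume")[[b]]
      sprintf("%s_%03d", prefix, seq_len(block_sizes[[b]]))
    }))
    block <- rep(names(block_sizes), block_sizes)
    features <- cohort_features(A, block, y)
    list(
      features = features,
      truth = list(informative = colnames(A)[planted], indices = planted,
                   delta = delta, baseline_mean = baseline_mean,
                   concentration = concentration, seed = seed)
    )
  })
}
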