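#' Partition streamlines by resection-mask intersection
#'
#' A streamline is removed iff at least one of its stored points maps
#' (nearest-voxel, see [world_to_voxel()]) to an in-bounds voxel with mask
#' value 1; out-of-bounds points count as outside the mask. The partition is
#' exhaustive and disjoint. No segment rasterisation is performed between
#' points: generated and typical tractography step sizes are below the voxel
#' edge, so every traversed voxel carries a stored point.
#'
#' @param streamlines a [streamline_set()] in the mask's world space.
#' @param mask a [resection_mask()] on the parcellation grid.
#' @return list with [streamline_set()] elements `kept` and `removed`.
#' @export
filter_streamlines <- function(streamlines, mask) {
  if (!inherits(mask, "resection_mask")) stopf("mask must be a resection_mask")
  if (!inherits(streamlines, "streamline_set")) {
    stopf("streamlines must be a streamline_set")
  }
  if (!same_affine(streamlines$affine, mask$affine)) {
    stopf("streamline reference affine does not match the mask")
  }
  n <- length(streamlines)
  hit <- logical(n)
  if (n > 0L) {
    counts <- vapply(streamlines$streamlines, nrow, 0L)
    pts <- do.call(rbind, streamlines$streamlines)
    vox <- world_to_voxel(pts, mask$affine)
    d <- dim(mask$values)
    inb <- vox[, 1] >= 0L & vox[, 1] < d[1] &
           vox[, 2] >= 0L & vox[, 2] < d[2] &
           vox[, 3] >= 0L & vox[, 3] < d[3]
    inmask <- logical(nrow(vox))
    if (any(inb)) {
      lin <- 1L + vox[inb, 1] + d[1] * (vox[inb, 2] + d[2] * vox[inb, 3])
      inmask[inb] <- mask$values[lin] == 1L
    }
    grp <- rep.int(seq_len(n), counts)
    hit <- as.logical(tapply(inmask, grp, any))
  }
  list(
    kept = structure(list(streamlines = streamlines$streamlines[!hit],
                          affine = streamlines$affine),
                     class = "streamline_set"),
    removed = structure(list(streamlines = streamlines$streamlines[hit],
                             affine = streamlines$affine),
                        class = "streamline_set")
  )
}

#' Fraction of each region's tissue remaining after resection
#'
#' For every region, 1 - (masked voxels of the region) / (total voxels of the
#' region): 1 means intact, 0 means fully removed.
#'
#' @param parc a [parcellation()].
#' @param mask a [resection_mask()] on the same grid.
#' @return named numeric vector of fractions in \[0, 1\], one per region id.
#' @export
region_volume_remaining <- function(parc, mask) {
  if (!identical(dim(parc$labels), dim(mask$values))) {
    stopf("mask grid shape does not match the parcellation")
  }
  if (!same_affine(parc$affine, mask$affine)) {
    stopf("mask affine does not match the parcellation")
  }
  ids <- region_ids_of(parc)
  lab <- as.integer(parc$labels)
  total <- tabulate(lab, nbins = max(ids))[ids]
  if (any(total == 0L)) {
    stopf("region(s) with zero voxels: %s",
          paste(ids[total == 0L], collapse = ", "))
  }
  masked_lab <- lab[as.integer(mask$values) == 1L]
  removed <- tabulate(masked_lab, nbins = max(ids))[ids]
  out <- 1 - removed / total
  names(out) <- ids
  out
}

#' Infer the predicted post-operative network
#'
#' Removes every streamline intersecting the resection mask, rebuilds the
#' endpoint connectome from the kept streamlines, and computes per-region
#' tissue remaining. On the count scale the post-operative matrix is
#' elementwise no greater than the pre-operative one.
#'
#' @param streamlines a [streamline_set()].
#' @param parc a [parcellation()].
#' @param mask a [resection_mask()] on the parcellation grid.
#' @return an object of class `resection_result`: list with `kept`,
#'   `removed` (streamline sets), `postop_connectome` (count-weighted
#'   [connectivity_matrix()]) and `volume_remaining`.
#' @export
predict_postop_network <- function(streamlines, parc, mask) {
  parts <- filter_streamlines(streamlines, mask)
  structure(
    list(
      kept = parts$kept,
      removed = parts$removed,
      postop_connectome = build_connectome(parts$kept, parc),
      volume_remaining = region_volume_remaining(parc, mask)
    ),
    class = "resection_result"
  )
}

#' @export
print.resection_result <- function(x, ...) {
  cat(sprintf(
    "Virtual resection: %d streamlines kept, %d removed; %d region(s) touched\n",
    length(x$kept), length(x$removed), sum(x$volume_remaining < 1)))
  invisible(x)
}
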