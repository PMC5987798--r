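#' Construct a connectivity matrix object
#'
#' @param weights symmetric non-negative R x R matrix; the diagonal holds
#'   self-connection weights, which are recorded but excluded from every
#'   downstream network measure.
#' @param region_ids integer region labels in matrix order.
#' @param weight_kind "streamline_count" or "log10_transformed".
#' @param flipped logical; whether hemispheres have been swapped so the
#'   surgical side reads as ipsilateral.
#' @return an object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(weights, region_ids,
                                weight_kind = c("streamline_count",
                                                "log10_transformed"),
                                flipped = FALSE) {
  weight_kind <- match.arg(weight_kind)
  weights <- as.matrix(weights)
  region_ids <- as.integer(region_ids)
  if (nrow(weights) != ncol(weights) || nrow(weights) != length(region_ids)) {
    stopf("weights must be square with one row per region id")
  }
  if (anyDuplicated(region_ids)) stopf("region ids must be unique")
  if (any(weights < 0)) stopf("weights must be non-negative")
  if (max(abs(weights - t(weights))) > 1e-9) stopf("weights must be symmetric")
  dimnames(weights) <- list(region_ids, region_ids)
  structure(list(weights = weights, region_ids = region_ids,
                 weight_kind = weight_kind, flipped = flipped),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  w <- x$weights; diag(w) <- 0
  cat(sprintf(
    "Connectivity matrix: %d regions, %d connections, %s weights%s\n",
    length(x$region_ids), sum(w[upper.tri(w)] > 0), x$weight_kind,
    if (x$flipped) " (hemispheres flipped)" else ""))
  invisible(x)
}

#' Build the endpoint-based streamline-count connectome
#'
#' Two regions are connected by a streamline when its two endpoints (first
#' and last polyline point) fall in those regions' voxels. Streamlines with
#' either endpoint in background (label 0, or out of the grid) are discarded;
#' streamlines with both endpoints in the same region are recorded on the
#' diagonal as self-connections.
#'
#' @param streamlines a [streamline_set()] in the parcellation's world space.
#' @param parc a [parcellation()] with at least one labelled region.
#' @return a [connectivity_matrix()] of kind "streamline_count" with
#'   attribute `n_discarded` (streamlines dropped for background endpoints).
#' @export
build_connectome <- function(streamlines, parc) {
  if (!inherits(parc, "parcellation")) stopf("parc must be a parcellation")
  if (!inherits(streamlines, "streamline_set")) {
    stopf("streamlines must be a streamline_set")
  }
  if (!same_affine(streamlines$affine, parc$affine)) {
    stopf("streamline reference affine does not match the parcellation")
  }
  ids <- region_ids_of(parc)
  if (!length(ids)) stopf("parcellation has no labelled regions")
  R <- length(ids)
  W <- matrix(0, R, R)
  n <- length(streamlines)
  n_disc <- 0L
  if (n > 0L) {
    ends <- matrix(0, 2L * n, 3L)
    for (k in seq_len(n)) {
      m <- streamlines$streamlines[[k]]
      ends[2L * k - 1L, ] <- m[1L, ]
      ends[2L * k, ] <- m[nrow(m), ]
    }
    lab <- labels_at(parc, world_to_voxel(ends, parc$affine))
    a <- lab[seq(1L, 2L * n, by = 2L)]
    b <- lab[seq(2L, 2L * n, by = 2L)]
    ok <- a > 0L & b > 0L
    n_disc <- sum(!ok)
    ia <- match(a[ok], ids)
    ib <- match(b[ok], ids)
    lo <- pmin(ia, ib)
    hi <- pmax(ia, ib)
    M <- matrix(tabulate(hi + (lo - 1L) * R, nbins = R * R), R, R)
    W <- M + t(M)
    diag(W) <- diag(M)
  }
  out <- connectivity_matrix(W, ids, "streamline_count")
  attr(out, "n_discarded") <- n_disc
  out
}

region_ids_of <- function(parc) {
  if (!is.null(parc$regions)) sort(parc$regions$id)
  else setdiff(sort(unique(as.integer(parc$labels))), 0L)
}

# vectorised label lookup; out-of-bounds voxels map to background 0
labels_at <- function(parc, voxels) {
  d <- dim(parc$labels)
  inb <- voxels[, 1] >= 0L & voxels[, 1] < d[1] &
         voxels[, 2] >= 0L & voxels[, 2] < d[2] &
         voxels[, 3] >= 0L & voxels[, 3] < d[3]
  out <- integer(nrow(voxels))
  if (any(inb)) {
    lin <- 1L + voxels[inb, 1] + d[1] * (voxels[inb, 2] + d[2] * voxels[inb, 3])
    out[inb] <- parc$labels[lin]
  }
  out
}

#' Log-transform connection weights
#'
#' Maps every off-diagonal weight w to log10(1 + w), so absent connections
#' stay 0 and single-streamline connections stay positive. The diagonal
#' (self-connections) is left on the count scale; it is excluded from all
#' measures anyway.
#'
#' @param cm a [connectivity_matrix()] of kind "streamline_count".
#' @return a [connectivity_matrix()] of kind "log10_transformed".
#' @export
log_transform <- function(cm) {
  if (!inherits(cm, "connectivity_matrix")) {
    stopf("cm must be a connectivity_matrix")
  }
  if (cm$weight_kind != "streamline_count") {
    stopf("weights are already log-transformed")
  }
  W <- log10(1 + cm$weights)
  diag(W) <- diag(cm$weights)
  connectivity_matrix(W, cm$region_ids, "log10_transformed", cm$flipped)
}

#' Swap hemispheres so the surgical side is ipsilateral
#'
#' For right-sided surgery, rows and columns of homologous region pairs are
#' exchanged (midline regions stay fixed), so that the left side of every
#' matrix uniformly denotes the surgical hemisphere. Left-sided patients are
#' returned unchanged. Applying the flip twice restores the original matrix.
#'
#' @param cm a [connectivity_matrix()].
#' @param parc a [parcellation()] whose region table pairs every non-midline
#'   region with its homologue.
#' @param surgery_side "left" or "right".
#' @return a [connectivity_matrix()] with `flipped` toggled for right-sided
#'   input.
#' @export
flip_hemispheres <- function(cm, parc, surgery_side = c("left", "right")) {
  surgery_side <- match.arg(surgery_side)
  if (surgery_side == "left") return(cm)
  perm <- homologue_permutation(parc, cm$region_ids)
  W <- cm$weights[perm, perm]
  connectivity_matrix(W, cm$region_ids, cm$weight_kind, !cm$flipped)
}

homologue_permutation <- function(parc, region_ids) {
  if (is.null(parc$regions)) stopf("hemisphere flip needs a region table")
  reg <- parc$regions
  idx <- match(region_ids, reg$id)
  if (anyNA(idx)) stopf("region ids missing from region table")
  hemi <- reg$hemisphere[idx]
  homol <- reg$homologue_id[idx]
  bad <- hemi != "midline" & is.na(homol)
  if (any(bad)) {
    stopf("non-midline region(s) without homologue: %s",
          paste(region_ids[bad], collapse = ", "))
  }
  perm <- seq_along(region_ids)
  paired <- !is.na(homol)
  perm[paired] <- match(homol[paired], region_ids)
  if (anyNA(perm)) stopf("homologue id not present in matrix")
  perm
}

#' Write a connectivity matrix as TSV (+ JSON sidecar)
#'
#' The TSV carries region ids as header row and first column; the sidecar
#' `<path>.json` records `weight_kind` and the flip state.
#'
#' @param cm a [connectivity_matrix()].
#' @param path destination TSV path.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(cm, path) {
  df <- data.frame(region_id = cm$region_ids, cm$weights, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(weight_kind = cm$weight_kind, flipped = cm$flipped),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' Read a connectivity matrix written by [write_connectome()]
#' @param path TSV path.
#' @return a [connectivity_matrix()].
#' @export
read_connectome <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE)
  ids <- as.integer(df$region_id)
  W <- as.matrix(df[, -1, drop = FALSE])
  meta <- list(weight_kind = "streamline_count", flipped = FALSE)
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  connectivity_matrix(W, ids, meta$weight_kind, isTRUE(meta$flipped))
}
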