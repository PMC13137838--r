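# Junction-marker segmentation: multiscale Hessian ridge enhancement of the
# junctional band, h-minima-suppressed watershed of the inverted ridge map,
# small-region merging, and a 1-px border skeleton between cell labels.

#' Segmentation result
#'
#' Builds the canonical segmentation container from a full label image
#' (every pixel assigned a cell id >= 1). The 1-px border skeleton is the
#' inter-label boundary; in the stored `labels` image border pixels are 0.
#'
#' @param full_labels integer matrix of cell ids (>= 1 everywhere).
#' @return an object of class `segmentation_result` with fields `labels`
#'   (0 = border), `full_labels`, `border_skeleton` (logical), `adjacency`
#'   (two-column matrix of cell-id pairs sharing border), `edge_cells`
#'   (ids touching the field edge).
#' @export
segmentation_result <- function(full_labels) {
  full_labels <- relabel_consecutive(full_labels)
  border <- label_boundaries(full_labels)
  labels <- full_labels
  labels[border] <- 0L
  nr <- nrow(full_labels); nc <- ncol(full_labels)
  adj <- label_adjacency(full_labels)
  edge_ids <- sort(unique(c(full_labels[1, ], full_labels[nr, ],
                            full_labels[, 1], full_labels[, nc])))
  structure(list(labels = labels, full_labels = full_labels,
                 border_skeleton = border, adjacency = adj,
                 edge_cells = edge_ids),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> %d x %d px, %d cells (%d at field edge), %d border px\n",
    nrow(x$labels), ncol(x$labels), max(x$full_labels),
    length(x$edge_cells), sum(x$border_skeleton)))
  invisible(x)
}

#' Cell ids of a segmentation
#' @param seg a [segmentation_result()].
#' @param interior_only drop cells touching the field edge.
#' @return integer vector of cell ids.
#' @export
cell_ids <- function(seg, interior_only = FALSE) {
  ids <- seq_len(max(seg$full_labels))
  if (interior_only) ids <- setdiff(ids, seg$edge_cells)
  ids
}

# Relabel a full label image to consecutive ids 1..n in row-major order of
# first occurrence (deterministic).
relabel_consecutive <- function(labels) {
  u <- unique(as.vector(labels))
  map <- integer(max(u))
  map[u] <- seq_along(u)
  matrix(map[labels], nrow(labels))
}

# Unordered pairs of labels sharing an 8-adjacency interface.
label_adjacency <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  pairs <- rbind(
    cbind(as.vector(labels[-nr, ]), as.vector(labels[-1, ])),
    cbind(as.vector(labels[, -nc]), as.vector(labels[, -1])),
    cbind(as.vector(labels[-nr, -nc]), as.vector(labels[-1, -1])),
    cbind(as.vector(labels[-nr, -1]), as.vector(labels[-1, -nc])))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0) return(matrix(integer(0), 0, 2))
  pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  unique(pairs)
}

# Multiscale Hessian ridge filter: response to bright line-like structure,
# max over scales of sigma^2 * max(0, -lambda_min(Hessian of G_sigma * I)).
ridge_filter <- function(frame, sigmas) {
  resp <- matrix(0, nrow(frame), ncol(frame))
  for (s in sigmas) {
    g0 <- gauss_kernel_1d(s, 0)
    g1 <- gauss_kernel_1d(s, 1)
    g2 <- gauss_kernel_1d(s, 2)
    ixx <- conv_sep(frame, g0, g2)
    iyy <- conv_sep(frame, g2, g0)
    ixy <- conv_sep(frame, g1, g1)
    tr <- ixx + iyy
    disc <- sqrt(pmax(0, (ixx - iyy)^2 + 4 * ixy^2))
    lmin <- (tr - disc) / 2
    resp <- pmax(resp, s^2 * pmax(0, -lmin))
  }
  resp
}

# Fill label-0 pixels by iteratively adopting a 4-neighbour label.
fill_zero_labels <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  while (any(labels == 0L)) {
    prev <- labels
    for (shift in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      src_r <- pmin(pmax(seq_len(nr) + shift[1], 1L), nr)
      src_c <- pmin(pmax(seq_len(nc) + shift[2], 1L), nc)
      cand <- prev[src_r, src_c]
      take <- labels == 0L & cand != 0L
      labels[take] <- cand[take]
    }
    if (all(labels == prev)) break
  }
  labels
}

# Merge regions smaller than min_area into the neighbour with the longest
# shared boundary; repeats until stable.
merge_small_regions <- function(labels, min_area) {
  repeat {
    sizes <- tabulate(labels, nbins = max(labels))
    small <- which(sizes > 0 & sizes < min_area)
    if (length(small) == 0) break
    if (all(sizes[sizes > 0] < min_area))
      stop("over-merged: all regions below the minimum area", call. = FALSE)
    id <- small[which.min(sizes[small])]
    nr <- nrow(labels); nc <- ncol(labels)
    m <- labels == id
    # boundary-length with each 4-neighbour label
    neigh <- c(labels[cbind(pmax(which(m, arr.ind = TRUE)[, 1] - 1, 1),
                            which(m, arr.ind = TRUE)[, 2])],
               labels[cbind(pmin(which(m, arr.ind = TRUE)[, 1] + 1, nr),
                            which(m, arr.ind = TRUE)[, 2])],
               labels[cbind(which(m, arr.ind = TRUE)[, 1],
                            pmax(which(m, arr.ind = TRUE)[, 2] - 1, 1))],
               labels[cbind(which(m, arr.ind = TRUE)[, 1],
                            pmin(which(m, arr.ind = TRUE)[, 2] + 1, nc))])
    neigh <- neigh[neigh != id & neigh != 0]
    if (length(neigh) == 0) break
    target <- as.integer(names(which.max(table(neigh))))
    labels[m] <- target
  }
  labels
}

#' Segment one junction-marker frame
#'
#' Ridge-enhances the junctional band with a multiscale eigenvalue-of-
#' Hessian filter, suppresses shallow minima of the inverted ridge map by
#' `h_minima`, watersheds it so each basin becomes a cell, merges regions
#' below `min_cell_area_px` into the neighbour with the longest shared
#' boundary, and emits the inter-label boundary as the 1-px border skeleton.
#'
#' @param frame single-channel intensity matrix, or an [image_series]
#'   (first frame, first channel used).
#' @param ridge_sigma_px ridge-filter scale(s), pixels.
#' @param h_minima minimum basin depth, in units of ridge response relative
#'   to its maximum (0-1).
#' @param min_cell_area_px minimum cell area, pixels.
#' @return a [segmentation_result()].
#' @export
segment_junction_frame <- function(frame, ridge_sigma_px = c(1, 2),
                                   h_minima = 0.05,
                                   min_cell_area_px = 64) {
  if (inherits(frame, "image_series")) frame <- get_frame(frame, 1, 1)
  stopifnot(is.matrix(frame))
  if (diff(range(frame)) == 0)
    stop("no junction signal: frame is constant", call. = FALSE)
  ridge <- ridge_filter(frame, ridge_sigma_px)
  rmax <- max(ridge)
  if (rmax <= 0) stop("no junction signal: no ridge response", call. = FALSE)
  # height map: inverted ridge response, sharpened with the inverted
  # band intensity itself so the watershed line sits on the band crest
  sm <- gauss_smooth(frame, min(ridge_sigma_px))
  inv <- 0.3 * (rmax - ridge) / rmax + 0.7 * (max(sm) - sm) / diff(range(sm))
  ws <- EBImage::watershed(EBImage::as.Image(t(inv) + 1e-6),
                           tolerance = h_minima, ext = 1)
  labels <- t(EBImage::imageData(ws))
  storage.mode(labels) <- "integer"
  labels <- fill_zero_labels(labels)
  if (any(labels == 0L)) labels[labels == 0L] <- max(labels) + 1L
  labels <- relabel_consecutive(labels)
  labels <- merge_small_regions(labels, min_cell_area_px)
  segmentation_result(labels)
}

#' Band mask around the border skeleton
#'
#' Pixels whose Euclidean distance to the border skeleton is `<= w_px`
#' (band width `2 w + 1` including the line itself). With `cell_id`, only
#' the skeleton pixels bounding that cell seed the band.
#'
#' @param seg a [segmentation_result()].
#' @param w_px half-width in pixels (>= 0); the junctional ROI of the
#'   intensity statistic uses 5.
#' @param cell_id optional cell id.
#' @return logical matrix.
#' @export
band_mask <- function(seg, w_px = 5, cell_id = NULL) {
  stopifnot(inherits(seg, "segmentation_result"), w_px >= 0)
  skel <- seg$border_skeleton
  if (!is.null(cell_id)) {
    if (!(cell_id %in% cell_ids(seg)))
      stop("no such cell: ", cell_id, call. = FALSE)
    skel <- cell_border_pixels(seg, cell_id)
  }
  if (!any(skel)) stop("no border", call. = FALSE)
  d <- EBImage::distmap(matrix(as.numeric(!skel), nrow(skel)),
                        metric = "euclidean")
  d <= w_px
}

# Skeleton pixels 8-adjacent to a given cell label (the part of the border
# bounding that cell).
cell_border_pixels <- function(seg, cell_id) {
  skel <- seg$border_skeleton
  lab <- seg$labels
  nr <- nrow(lab); nc <- ncol(lab)
  near <- matrix(FALSE, nr, nc)
  cm <- lab == cell_id
  for (dr in -1:1) for (dc in -1:1) {
    rs <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    cs <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    near <- near | cm[rs, cs]
  }
  skel & near
}

#' Match cells between two segmentations
#'
#' Greedy maximum-overlap matching of cell labels by Jaccard index of their
#' pixel sets, accepting pairs with Jaccard >= `min_jaccard`; the mapping is
#' injective, ties broken deterministically toward lower cell ids.
#'
#' @param seg_t,seg_t2 [segmentation_result()]s of the same image shape.
#' @param min_jaccard acceptance threshold, default 0.5.
#' @return a list of class `cell_correspondence` with `mapping` (named
#'   integer vector, id in `seg_t` -> id in `seg_t2`), `unmatched_t`,
#'   `unmatched_t2`.
#' @export
match_cells <- function(seg_t, seg_t2, min_jaccard = 0.5) {
  stopifnot(inherits(seg_t, "segmentation_result"),
            inherits(seg_t2, "segmentation_result"),
            all(dim(seg_t$labels) == dim(seg_t2$labels)))
  a <- seg_t$full_labels; b <- seg_t2$full_labels
  tab <- table(factor(a, levels = seq_len(max(a))),
               factor(b, levels = seq_len(max(b))))
  sa <- rowSums(tab); sb <- colSums(tab)
  inter <- as.matrix(tab)
  jac <- inter / (outer(sa, sb, "+") - inter)
  jac[!is.finite(jac)] <- 0
  cand <- which(jac >= min_jaccard, arr.ind = TRUE)
  if (nrow(cand) > 0) {
    ord <- order(-jac[cand], cand[, 1], cand[, 2])
    cand <- cand[ord, , drop = FALSE]
  }
  map <- integer(0)
  used_b <- integer(0)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!(i %in% as.integer(names(map))) && !(j %in% used_b)) {
      map[as.character(i)] <- j
      used_b <- c(used_b, j)
    }
  }
  structure(list(
    mapping = map,
    unmatched_t = setdiff(seq_len(max(a)), as.integer(names(map))),
    unmatched_t2 = setdiff(seq_len(max(b)), unname(map))),
    class = "cell_correspondence")
}

#' Border-pixel precision/recall/F1 against a reference skeleton
#'
#' Scores a predicted border skeleton against a reference with a
#' localization tolerance: a pixel counts as matched when a pixel of the
#' other set lies within `tol_px` (Euclidean).
#'
#' @param pred,ref logical matrices (same shape).
#' @param tol_px matching tolerance in pixels, default 1.
#' @return list with `precision`, `recall`, `f1`.
#' @export
border_f1 <- function(pred, ref, tol_px = 1) {
  stopifnot(all(dim(pred) == dim(ref)))
  dref <- EBImage::distmap(matrix(as.numeric(!ref), nrow(ref)))
  dpred <- EBImage::distmap(matrix(as.numeric(!pred), nrow(pred)))
  tp_p <- sum(dref[pred] <= tol_px)      # predicted pixels near reference
  tp_r <- sum(dpred[ref] <= tol_px)      # reference pixels found
  precision <- if (sum(pred) == 0) 0 else tp_p / sum(pred)
  recall <- if (sum(ref) == 0) 0 else tp_r / sum(ref)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

#' Write segmentation labels and skeleton to 16-bit TIFF
#'
#' @param seg a [segmentation_result()].
#' @param base output path base; writes `<base>_labels.tif`,
#'   `<base>_skeleton.tif` and `<base>_adjacency.csv`.
#' @return invisibly, the paths written.
#' @export
write_segmentation <- function(seg, base) {
  lab_path <- paste0(base, "_labels.tif")
  skel_path <- paste0(base, "_skeleton.tif")
  adj_path <- paste0(base, "_adjacency.csv")
  tiff::writeTIFF(seg$labels / 65535, lab_path, bits.per.sample = 16L)
  tiff::writeTIFF(matrix(as.numeric(seg$border_skeleton),
                         nrow(seg$border_skeleton)), skel_path,
                  bits.per.sample = 16L)
  adj <- as.data.frame(seg$adjacency)
  names(adj) <- c("cell_a", "cell_b")
  utils::write.csv(adj, adj_path, row.names = FALSE)
  invisible(c(lab_path, skel_path, adj_path))
}
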