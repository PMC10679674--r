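# Seed segmentation and segmentation metrics.
#
# The segmentation stage is deliberately deterministic: Otsu global
# threshold, 8-connected components, area floor, then labels renumbered
# row-major by centroid. It is scored against ground-truth masks with the
# standard semantic-segmentation metrics (pixel accuracy and mean IoU).

# 8-connected component labelling of a logical matrix (iterative flood fill)
label_components <- function(bin) {
  nr <- nrow(bin); nc <- ncol(bin)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offs_r <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  offs_c <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  todo <- which(bin)
  for (start in todo) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    lab[start] <- nxt
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((cur - 1L) %% nr) + 1L
      cc <- ((cur - 1L) %/% nr) + 1L
      rr <- r + offs_r; ccn <- cc + offs_c
      ok <- rr >= 1L & rr <= nr & ccn >= 1L & ccn <= nc
      nb <- (ccn[ok] - 1L) * nr + rr[ok]
      nb <- nb[bin[nb] & lab[nb] == 0L]
      if (length(nb) > 0) {
        lab[nb] <- nxt
        stack <- c(stack, nb)
      }
    }
  }
  lab
}

# renumber labels 1..K row-major by centroid: centroid rows are grouped into
# plate rows (gap > typical component height), then ordered left to right
renumber_row_major <- function(lab) {
  K <- max(lab)
  if (K == 0) return(lab)
  cy <- tapply(row(lab)[lab > 0], lab[lab > 0], mean)
  cx <- tapply(col(lab)[lab > 0], lab[lab > 0], mean)
  heights <- tapply(row(lab)[lab > 0], lab[lab > 0],
                    function(r) diff(range(r)) + 1)
  ord_y <- order(cy)
  gap_thr <- max(1, stats::median(heights) * 0.75)
  row_group <- cumsum(c(1, diff(cy[ord_y]) > gap_thr))
  grp <- integer(K); grp[ord_y] <- row_group
  new_order <- order(grp, cx)
  remap <- integer(K); remap[new_order] <- seq_len(K)
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

#' Segment seeds on a single-band plate image
#'
#' Global Otsu threshold, 8-connected components, removal of components
#' below an area floor, and row-major renumbering by centroid.
#'
#' @param band_image single-channel numeric matrix (seeds brighter than
#'   background).
#' @param min_area smallest component area (pixels) kept.
#' @return Integer label matrix (0 background, 1..K seeds), class
#'   `vs_mask`.
#' @export
segment_plate <- function(band_image, min_area = 5) {
  img <- as.matrix(band_image)
  rng <- range(img)
  if (diff(rng) == 0) stopf("segmentation failed: image is constant")
  scaled <- (img - rng[1]) / diff(rng)
  thr <- EBImage::otsu(scaled, range = c(0, 1))
  bin <- scaled > thr
  lab <- label_components(bin)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    drop_ids <- which(areas < min_area)
    if (length(drop_ids) > 0) {
      lab[lab %in% drop_ids] <- 0L
      keep <- sort(unique(lab[lab > 0]))
      remap <- integer(max(keep)); remap[keep] <- seq_along(keep)
      lab[lab > 0] <- remap[lab[lab > 0]]
    }
  }
  if (max(lab) == 0) stopf("segmentation found no components above the area floor")
  structure(renumber_row_major(lab), class = c("vs_mask", "matrix", "array"))
}

.binarize_pair <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    stopf("mask shapes differ: %s vs %s",
          paste(dim(pred), collapse = "x"), paste(dim(truth), collapse = "x"))
  }
  list(pred = as.integer(pred > 0), truth = as.integer(truth > 0))
}

#' Pixel accuracy of a segmentation (percent)
#'
#' Masks are binarized to background/seed (two semantic classes) and scored
#' as the fraction of pixels whose class matches,
#' \eqn{\mathrm{PA} = \sum_i n_{ii} / \sum_{ij} n_{ij} \times 100\%}.
#'
#' @param pred,truth label matrices of one shape.
#' @return Percentage in `[0, 100]`.
#' @export
pixel_accuracy <- function(pred, truth) {
  b <- .binarize_pair(pred, truth)
  mean(b$pred == b$truth) * 100
}

#' Mean intersection-over-union of a segmentation (percent)
#'
#' Per class c, \eqn{\mathrm{IoU}_c = n_{cc} / (\sum_j n_{cj} + \sum_j n_{jc}
#' - n_{cc})}; the score is the mean over the observed classes, times 100.
#' A class absent from both masks is excluded from the mean (and noted).
#'
#' @param pred,truth label matrices of one shape.
#' @return Percentage in `[0, 100]`.
#' @export
mean_iou <- function(pred, truth) {
  b <- .binarize_pair(pred, truth)
  ious <- numeric(0)
  for (cls in 0:1) {
    inter <- sum(b$pred == cls & b$truth == cls)
    uni <- sum(b$pred == cls) + sum(b$truth == cls) - inter
    if (uni == 0) {
      inform(sprintf("mean_iou: class %d absent from both masks; excluded", cls))
      next
    }
    ious <- c(ious, inter / uni)
  }
  mean(ious) * 100
}
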