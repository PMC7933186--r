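#' Single-molecule FISH spot detection
#'
#' Detection follows the classic two-step enhancement + local-maximum scheme:
#' the diffuse background (convolution with a large Gaussian kernel) is
#' subtracted, the residual is clamped at zero and smoothed with a small
#' Gaussian kernel matched to the spot size, and spots are strict local
#' maxima of the enhanced image above an intensity threshold, optionally
#' restricted to a region-of-interest mask (e.g. the somatic blastomeres).
#'
#' @name smfish_spots
NULL

## Gaussian convolution with mirror (reflect) padding
gaussian_blur <- function(img, sigma) {
  r <- as.integer(2 * ceiling(3 * sigma) + 1)
  r <- min(r, 2L * min(dim(img)) - 1L)
  if (r %% 2L == 0L) r <- r - 1L
  pad <- (r - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  ridx <- c(rev(seq_len(min(pad, nr))), seq_len(nr),
            nr + 1 - rev(seq_len(min(pad, nr))))
  cidx <- c(rev(seq_len(min(pad, nc))), seq_len(nc),
            nc + 1 - rev(seq_len(min(pad, nc))))
  padded <- img[ridx, cidx, drop = FALSE]
  k <- EBImage::makeBrush(r, shape = "Gaussian", sigma = sigma)
  sm <- EBImage::filter2(padded, k, boundary = "circular")
  sm[pad + seq_len(nr), pad + seq_len(nc), drop = FALSE]
}

#' Enhance diffraction-limited spots
#'
#' Computes `G(sigma_spot) * max(I - G(sigma_bg) * I, 0)`: background
#' estimated with a large Gaussian kernel is subtracted, negative residuals
#' are clamped to zero, and the result is smoothed with a small kernel.
#'
#' @param image 2-D numeric matrix of non-negative intensities (>= 3x3).
#' @param sigma_bg Background kernel SD in pixels (must exceed `sigma_spot`).
#' @param sigma_spot Spot kernel SD in pixels (> 0).
#' @return Enhanced image matrix of the same dimensions.
#' @export
enhance <- function(image, sigma_bg = 10, sigma_spot = 1.5) {
  if (length(dim(image)) != 2L)
    stop("only 2-D central-plane images are supported")
  if (nrow(image) < 3 || ncol(image) < 3) stop("image must be at least 3x3")
  if (anyNA(image) || any(!is.finite(image))) stop("image must be finite")
  if (!(sigma_bg > sigma_spot && sigma_spot > 0))
    stop("need sigma_bg > sigma_spot > 0")
  bg <- gaussian_blur(image, sigma_bg)
  gaussian_blur(pmax(image - bg, 0), sigma_spot)
}

neighbor_shift <- function(m, dr, dc, fill = -Inf) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Detect spots by local maxima of the enhanced image
#'
#' A spot is a pixel that strictly exceeds its full 8-connected neighborhood
#' in the enhanced image and lies above `threshold`. Plateaus (connected
#' regions of equal value that dominate their surroundings) yield one spot at
#' the lexicographically smallest (row, column) coordinate. Maxima within
#' `ceiling(sigma_spot)` pixels of the border are discarded as unreliable,
#' and a mask restricts detection to the region of interest.
#'
#' When `threshold` is `NULL` it is set to the median of the enhanced image
#' plus `k` times its robust noise SD (median absolute deviation x 1.4826) —
#' a robust z-score cut; the location term accounts for the positive noise
#' floor the zero-clamp in [enhance()] leaves behind.
#'
#' @inheritParams enhance
#' @param threshold Intensity threshold on the enhanced image (> 0), or
#'   `NULL` for the automatic robust threshold.
#' @param k Multiplier for the automatic threshold (default 5).
#' @param mask Optional logical matrix congruent with `image`; spots outside
#'   it are dropped.
#' @param pre_enhanced If TRUE, `image` is taken as already enhanced (e.g.
#'   filtered upstream) and used directly for maximum finding.
#' @return Object of class `spot_set`: list with `spots` (data.frame `x`
#'   (column), `y` (row), `intensity`), and `params`.
#' @export
detect_spots <- function(image, sigma_bg = 10, sigma_spot = 1.5,
                         threshold = NULL, k = 5, mask = NULL,
                         pre_enhanced = FALSE) {
  enh <- if (pre_enhanced) image else enhance(image, sigma_bg, sigma_spot)
  if (is.null(threshold)) {
    # the clamp in enhance() leaves a positive noise floor, so the robust
    # threshold is a z-score: floor (median) + k robust-SDs (MAD x 1.4826)
    threshold <- stats::median(enh) + k * stats::mad(enh)
  }
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(image)))
      stop("mask shape does not match image")
    mask <- mask > 0
  }
  if (threshold <= 0)
    stop("threshold must be > 0 (flat image yields no automatic threshold)")
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  strict <- matrix(TRUE, nrow(enh), ncol(enh))
  ge <- matrix(TRUE, nrow(enh), ncol(enh))
  for (i in seq_len(nrow(offs))) {
    nb <- neighbor_shift(enh, offs$dr[i], offs$dc[i])
    strict <- strict & (enh > nb)
    ge <- ge & (enh >= nb)
  }
  above <- enh > threshold
  cand <- strict & above
  # plateau handling: equal-valued flat maxima -> one spot per component
  plateau <- ge & !strict & above
  if (any(plateau)) {
    lab <- EBImage::bwlabel(plateau)
    box <- EBImage::makeBrush(3, shape = "box")
    for (comp in setdiff(unique(as.integer(lab)), 0L)) {
      cm <- lab == comp
      v <- max(enh[cm])
      ring <- (EBImage::dilate(cm + 0, box) > 0) & !cm
      if (any(ring) && max(enh[ring]) >= v) next  # shoulder of a higher peak
      px <- which(cm, arr.ind = TRUE)
      px <- px[order(px[, 1], px[, 2]), , drop = FALSE]
      cand[px[1, 1], px[1, 2]] <- TRUE
    }
  }
  border <- ceiling(sigma_spot)
  if (border > 0) {
    cand[c(seq_len(border), nrow(cand) + 1 - seq_len(border)), ] <- FALSE
    cand[, c(seq_len(border), ncol(cand) + 1 - seq_len(border))] <- FALSE
  }
  if (!is.null(mask)) cand <- cand & mask
  idx <- which(cand, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  spots <- data.frame(x = unname(idx[, 2]), y = unname(idx[, 1]),
                      intensity = enh[idx])
  structure(list(spots = spots,
                 params = list(sigma_bg = sigma_bg, sigma_spot = sigma_spot,
                               threshold = threshold)),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("<spot_set> %d spot(s), threshold %.4g (sigma_bg=%g, sigma_spot=%g)\n",
              nrow(x$spots), x$params$threshold, x$params$sigma_bg,
              x$params$sigma_spot))
  invisible(x)
}

#' Count spots inside a region of interest
#'
#' @param spots A [detect_spots()] result.
#' @param mask Logical matrix; spots at (y, x) positions where it is TRUE are
#'   counted.
#' @return Integer count.
#' @export
count_in_roi <- function(spots, mask) {
  if (nrow(spots$spots) == 0) return(0L)
  sum(mask[cbind(spots$spots$y, spots$spots$x)] > 0)
}

#' Write detected spots to CSV
#'
#' @param spots A [detect_spots()] result.
#' @param path Output CSV path (columns x, y, intensity).
#' @export
write_spots <- function(spots, path) {
  utils::write.csv(spots$spots, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
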