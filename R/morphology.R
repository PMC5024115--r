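# Binary-raster morphology shared by the cloudmask, island-detection and
# plume modules: disk dilation, connected-component labelling.

disk_offsets <- function(radius_px) {
  r <- as.integer(radius_px)
  if (r < 0L) stop("radius must be >= 0")
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off[off$dy^2 + off$dx^2 <= r^2, , drop = FALSE]
}

shift_mask <- function(mask, dy, dx) {
  ny <- nrow(mask); nx <- ncol(mask)
  out <- matrix(FALSE, ny, nx)
  ys <- seq_len(ny); xs <- seq_len(nx)
  ysrc <- ys - dy; xsrc <- xs - dx
  keep_y <- ysrc >= 1L & ysrc <= ny
  keep_x <- xsrc >= 1L & xsrc <= nx
  if (any(keep_y) && any(keep_x))
    out[ys[keep_y], xs[keep_x]] <- mask[ysrc[keep_y], xsrc[keep_x]]
  out
}

#' Dilate a binary mask with a Euclidean disk
#'
#' Morphological dilation with a disk of radius `ceil(radius_m / pixel_m)`
#' pixels (offsets with dx^2 + dy^2 <= r^2). The default 500 m radius at
#' 250 m pixels gives a 2-pixel disk of 13 offsets. The output always
#' contains the input.
#'
#' @param mask logical matrix.
#' @param radius_m dilation radius in metres (default 500).
#' @param pixel_m pixel size in metres (default 250).
#' @return logical matrix of the same dimension.
#' @export
dilate_mask <- function(mask, radius_m = 500, pixel_m = 250) {
  stopifnot(is.logical(mask), radius_m >= 0, pixel_m > 0)
  r <- as.integer(ceiling(radius_m / pixel_m))
  dilate_mask_px(mask, r)
}

#' @rdname dilate_mask
#' @param radius_px dilation radius directly in pixels.
#' @export
dilate_mask_px <- function(mask, radius_px) {
  if (radius_px == 0L || !any(mask)) return(mask)
  off <- disk_offsets(radius_px)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(off))) {
    out <- out | shift_mask(mask, off$dy[k], off$dx[k])
  }
  attributes(out) <- attributes(mask)
  out
}

#' Label 8-connected components of a binary mask
#'
#' Diagonal neighbours belong to the same component (8-connectivity).
#'
#' @param mask logical matrix.
#' @return integer matrix; 0 for background, 1..k for components.
#' @export
label_components <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  cur <- 0L
  stack <- integer(length(idx))
  for (s in idx) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    top <- 1L
    stack[1L] <- s
    lab[s] <- cur
    while (top > 0L) {
      p <- stack[top]
      top <- top - 1L
      r0 <- (p - 1L) %% ny + 1L
      c0 <- (p - 1L) %/% ny + 1L
      for (dc in -1L:1L) {
        cc <- c0 + dc
        if (cc < 1L || cc > nx) next
        base <- (cc - 1L) * ny
        for (dr in -1L:1L) {
          rr <- r0 + dr
          if (rr < 1L || rr > ny) next
          q <- base + rr
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            top <- top + 1L
            stack[top] <- q
          }
        }
      }
    }
  }
  lab
}
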