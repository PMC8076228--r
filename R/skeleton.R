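#' Morphological skeleton by Zhang-Suen thinning
#'
#' Iteratively peels boundary pixels that do not break 8-connectivity until
#' the mask is one pixel wide, using the two-subiteration Zhang-Suen
#' scheme (the behaviour of the classical ImageJ "Skeletonize").  The
#' border outside the mask is treated as background.
#'
#' Foreground that touches the image border is reflect-padded before
#' thinning (and cropped after), so a suture band running off the crop keeps
#' its endpoints instead of being eroded back by roughly half its width.
#'
#' @param mask Logical matrix, `TRUE` = foreground.
#' @param max_iter Safety cap on thinning sweeps.
#' @return Logical matrix of the same shape: the 8-connected skeleton.
#' @export
skeletonize_mask <- function(mask, max_iter = 1000L) {
  border_fg <- any(mask[1, ]) || any(mask[nrow(mask), ]) ||
    any(mask[, 1]) || any(mask[, ncol(mask)])
  if (border_fg) {
    pad <- max(3L, ceiling(max(rowSums(mask), colSums(mask)) / 2) + 1L)
    pad <- min(pad, nrow(mask) - 1L, ncol(mask) - 1L)
    refl <- function(m) {
      m <- rbind(m[pad:1, , drop = FALSE], m, m[nrow(m):(nrow(m) - pad + 1), , drop = FALSE])
      cbind(m[, pad:1, drop = FALSE], m, m[, ncol(m):(ncol(m) - pad + 1), drop = FALSE])
    }
    sk <- thin_core(refl(mask), max_iter)
    return(sk[pad + seq_len(nrow(mask)), pad + seq_len(ncol(mask))])
  }
  thin_core(mask, max_iter)
}

thin_core <- function(mask, max_iter) {
  m <- mask
  ny <- nrow(m); nx <- ncol(m)
  shift <- function(M, di, dj) {
    out <- matrix(FALSE, ny, nx)
    ri <- seq_len(ny) + di; rj <- seq_len(nx) + dj
    ok_i <- ri >= 1 & ri <= ny; ok_j <- rj >= 1 & rj <= nx
    out[ok_i, ok_j] <- M[ri[ok_i], rj[ok_j]]
    out
  }
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbours P2..P9 clockwise from north (row-1)
      P2 <- shift(m, -1, 0); P3 <- shift(m, -1, 1); P4 <- shift(m, 0, 1)
      P5 <- shift(m, 1, 1);  P6 <- shift(m, 1, 0);  P7 <- shift(m, 1, -1)
      P8 <- shift(m, 0, -1); P9 <- shift(m, -1, -1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
           (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      cond <- m & B >= 2 & B <= 6 & A == 1
      if (sub == 1) cond <- cond & !(P2 & P4 & P6) & !(P4 & P6 & P8)
      else          cond <- cond & !(P2 & P4 & P8) & !(P2 & P6 & P8)
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}
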