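## SVD low-rank movie denoising: per temporal segment, decompose the
## frames x pixels matrix as M = U C with semi-unitary U (top-k left singular
## vectors), denoise each coefficient image, and recombine U C-hat. The
## per-component denoiser is a pluggable image -> image map; the default is a
## deterministic edge-preserving (median) smoother standing in for the
## pretrained network used upstream of this toolkit.

#' Top-k SVD decomposition of a movie segment
#'
#' @param segment T x H x W array (or a frames x pixels matrix).
#' @param k retained rank (default 5).
#' @return object of class `lowrank_decomposition` with `U` (p x k,
#'   semi-unitary), `C` (k x d), and the spatial dims.
#' @export
svd_lowrank <- function(segment, k = 5) {
  if (is.matrix(segment)) {
    m <- segment
    spatial <- c(ncol(segment), 1L)
  } else {
    d <- dim(segment)
    m <- matrix(segment, nrow = d[1])
    spatial <- d[2:3]
  }
  if (k > min(dim(m))) stop("k exceeds matrix dimensions")
  if (k < nrow(m)) {
    sv <- svd(m, nu = k, nv = 0)
    u <- sv$u
  } else {
    u <- qr.Q(qr(m))[, seq_len(k), drop = FALSE]
  }
  structure(list(U = u, C = crossprod(u, m), k = k, spatial = spatial,
                 n_frames = nrow(m)),
            class = "lowrank_decomposition")
}

#' Reconstruct a movie segment from its low-rank decomposition
#' @param x a `lowrank_decomposition`.
#' @export
lowrank_reconstruct <- function(x) {
  m <- x$U %*% x$C
  array(m, c(x$n_frames, x$spatial))
}

#' Denoise a movie by segmented low-rank decomposition
#'
#' Splits the movie into temporal segments (default 2500 frames), keeps the
#' top `k` temporal components per segment, passes each spatial coefficient
#' image through `component_denoiser`, recombines, and concatenates the
#' segments in order.
#'
#' @param movie T x H x W numeric array (an unmixed voltage movie).
#' @param k retained rank per segment (default 5).
#' @param segment_len frames per segment (default 2500).
#' @param component_denoiser `"smooth"` (edge-preserving median filter),
#'   `"identity"`, or any `function(image) -> image`.
#' @export
denoise_movie <- function(movie, k = 5, segment_len = 2500,
                          component_denoiser = "smooth") {
  den <- if (is.function(component_denoiser)) component_denoiser
  else switch(component_denoiser,
              smooth = median_filter_3x3,
              identity = identity,
              stop("unknown component denoiser"))
  d <- dim(movie)
  out <- array(0, d)
  starts <- seq(1, d[1], by = segment_len)
  for (s in starts) {
    idx <- s:min(d[1], s + segment_len - 1)
    seg <- movie[idx, , , drop = FALSE]
    dec <- svd_lowrank(seg, min(k, length(idx)))
    for (i in seq_len(dec$k)) {
      img <- matrix(dec$C[i, ], dec$spatial[1], dec$spatial[2])
      dec$C[i, ] <- as.numeric(den(img))
    }
    out[idx, , ] <- lowrank_reconstruct(dec)
  }
  out
}

#' 3 x 3 median filter (edge-preserving smoother)
#' @param img numeric matrix.
#' @export
median_filter_3x3 <- function(img) {
  h <- nrow(img); w <- ncol(img)
  if (h < 3 || w < 3) return(img)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- img
  pad[1, ] <- pad[2, ]; pad[h + 2, ] <- pad[h + 1, ]
  pad[, 1] <- pad[, 2]; pad[, w + 2] <- pad[, w + 1]
  stack <- sapply(1:9, function(s) {
    di <- (s - 1) %% 3; dj <- (s - 1) %/% 3
    as.numeric(pad[(1 + di):(h + di), (1 + dj):(w + dj)])
  })
  matrix(apply(stack, 1, stats::median), h, w)
}
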