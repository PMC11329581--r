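# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. All package randomness goes through this so that no
# function leaves a footprint on the global stream.
withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a base seed and a stream label, keeping the
# result inside the 32-bit integer range.
childSeed <- function(seed, stream) {
  h <- utf8ToInt(as.character(stream))
  as.integer((as.numeric(seed) * 7919 + sum(h * seq_along(h))) %% 2147483646 + 1)
}

clampRange <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Bilinear sampling of a matrix at continuous pixel coordinates.
# Convention: x indexes columns, y indexes rows, both 0-based with the
# origin at the centre of the top-left pixel. Points outside the grid get
# `fill` (or NA) and are reported in the "valid" attribute.
bilinearSample <- function(img, x, y, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  valid <- x >= 0 & x <= (W - 1) & y >= 0 & y <= (H - 1) &
    is.finite(x) & is.finite(y)
  xc <- clampRange(x, 0, W - 1)
  yc <- clampRange(y, 0, H - 1)
  x0 <- pmin(floor(xc), W - 2); x0[W == 1] <- 0
  y0 <- pmin(floor(yc), H - 2); y0[H == 1] <- 0
  if (W == 1) x0 <- rep(0, length(xc))
  if (H == 1) y0 <- rep(0, length(yc))
  fx <- xc - x0; fy <- yc - y0
  x1 <- pmin(x0 + 1, W - 1); y1 <- pmin(y0 + 1, H - 1)
  i00 <- y0 + 1 + H * x0; i10 <- y1 + 1 + H * x0
  i01 <- y0 + 1 + H * x1; i11 <- y1 + 1 + H * x1
  v <- (1 - fx) * ((1 - fy) * img[i00] + fy * img[i10]) +
    fx * ((1 - fy) * img[i01] + fy * img[i11])
  v[!valid] <- fill
  attr(v, "valid") <- valid
  v
}

# Nearest-neighbour sampling under the same coordinate convention.
nearestSample <- function(img, x, y, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  xi <- round(x); yi <- round(y)
  valid <- xi >= 0 & xi <= (W - 1) & yi >= 0 & yi <= (H - 1) &
    is.finite(xi) & is.finite(yi)
  xi <- clampRange(xi, 0, W - 1); yi <- clampRange(yi, 0, H - 1)
  v <- img[yi + 1 + H * xi]
  v[!valid] <- fill
  attr(v, "valid") <- valid
  v
}

# stopifnot() with a formatted message.
assertThat <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}
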