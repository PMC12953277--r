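#' Deterministic binary phantoms with known fractal dimension
#'
#' Test objects for the box-counting estimator: a solid cube (FD 3), a
#' one-voxel-thick slab (FD 2), a one-voxel line (FD 1), a digital ball, and
#' the level-`L` Menger sponge (side `3^L`, exactly `20^L` foreground
#' voxels, FD `log(20)/log(3)`). Slab and line are embedded in a cubic grid
#' so the usual box-size schedules apply.
#'
#' @param kind One of `"cube"`, `"slab"`, `"line"`, `"sphere"`, `"menger"`.
#' @param size Edge length in voxels (cube/slab/line), radius in voxels
#'   (sphere), or recursion level >= 1 (menger).
#' @param spacing Isotropic voxel spacing in mm (default 1).
#' @return A [seg_mask()].
#' @examples
#' sum(make_phantom("menger", 2)$data)  # 400 = 20^2
#' @export
make_phantom <- function(kind = c("cube", "slab", "line", "sphere", "menger"),
                         size, spacing = 1) {
  kind <- match.arg(kind)
  sp <- rep(spacing, 3)
  if (kind == "menger") {
    L <- as.integer(size)
    if (L < 1L) stop("menger level must be >= 1")
    n <- 3L^L
    co <- 0:(n - 1L)
    # a voxel is removed iff at some recursion level at least two of its
    # three base-3 digits equal 1 (the "cross" of each subdivision)
    keep1d <- matrix(TRUE, n, L)
    for (k in seq_len(L)) keep1d[, k] <- (co %/% 3L^(k - 1L)) %% 3L == 1L
    arr <- array(1L, c(n, n, n))
    for (k in seq_len(L)) {
      ax <- keep1d[, k]
      gx <- array(rep(ax, times = n * n), c(n, n, n))
      gy <- array(rep(rep(ax, each = n), times = n), c(n, n, n))
      gz <- array(rep(ax, each = n * n), c(n, n, n))
      remove <- (gx & gy) | (gx & gz) | (gy & gz)
      arr[remove] <- 0L
    }
    return(seg_mask(arr, spacing = sp))
  }
  n <- as.integer(size)
  if (n < 2L) stop("phantom size must be >= 2")
  if (kind == "sphere") {
    return(digital_ball(n, margin = 4L, spacing = spacing))
  }
  arr <- array(0L, c(n, n, n))
  if (kind == "cube") {
    arr[] <- 1L
  } else if (kind == "slab") {
    arr[, , 1L] <- 1L
  } else {
    arr[, 1L, 1L] <- 1L
  }
  seg_mask(arr, spacing = sp)
}

# Digital ball of radius r voxels centred in a cubic grid with `margin`
# background voxels on every side; voxel centres at integer coordinates.
digital_ball <- function(r, margin = 4L, spacing = 1) {
  side <- 2L * (as.integer(ceiling(r)) + margin) + 1L
  c0 <- (side + 1L) / 2
  co <- seq_len(side) - c0
  d2 <- outer(outer(co^2, co^2, "+"), co^2, "+")
  seg_mask((d2 <= r^2 + 1e-9) + 0L, spacing = rep(spacing, 3))
}

# Real spherical-harmonic basis, orders lmin..lmax, evaluated at unit
# vectors (rows of u). Returns an n x sum(2l+1) matrix of orthonormal Y_lm.
real_sh_basis <- function(u, lmin = 2L, lmax = 8L) {
  x <- u[, 3]                      # cos(theta)
  phi <- atan2(u[, 2], u[, 1])
  sin_t2 <- pmax(1 - x^2, 0)
  # associated Legendre P_l^m(x) with Condon-Shortley phase, l <= lmax
  P <- vector("list", lmax + 1L)
  for (l in 0:lmax) P[[l + 1L]] <- vector("list", l + 1L)
  P[[1L]][[1L]] <- rep(1, length(x))
  for (m in 1:lmax) {
    P[[m + 1L]][[m + 1L]] <- (-1)^m * prod(seq(1, 2 * m - 1, 2)) *
      sin_t2^(m / 2)
  }
  for (m in 0:(lmax - 1L)) {
    P[[m + 2L]][[m + 1L]] <- x * (2 * m + 1) * P[[m + 1L]][[m + 1L]]
    if (m + 2L <= lmax) {
      for (l in (m + 2L):lmax) {
        P[[l + 1L]][[m + 1L]] <-
          (x * (2 * l - 1) * P[[l]][[m + 1L]] -
             (l + m - 1) * P[[l - 1L]][[m + 1L]]) / (l - m)
      }
    }
  }
  cols <- list()
  for (l in lmin:lmax) {
    nl0 <- sqrt((2 * l + 1) / (4 * pi))
    cols[[length(cols) + 1L]] <- nl0 * P[[l + 1L]][[1L]]
    for (m in 1:l) {
      nlm <- nl0 * sqrt(exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
      plm <- P[[l + 1L]][[m + 1L]]
      cols[[length(cols) + 1L]] <- sqrt(2) * nlm * plm * cos(m * phi)
      cols[[length(cols) + 1L]] <- sqrt(2) * nlm * plm * sin(m * phi)
    }
  }
  do.call(cbind, cols)
}

# Evaluate the unit-variance band-limited random field Z at unit vectors u
# given coefficient vector a (length sum(2l+1), l = 2..8).
sh_field <- function(u, a, lmin = 2L, lmax = 8L) {
  Y <- real_sh_basis(u, lmin, lmax)
  scale <- sqrt(4 * pi / sum(2 * (lmin:lmax) + 1))
  as.vector(Y %*% a) * scale
}

# Run expr with a locally-seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Synthetic rough tumor mask
#'
#' Stand-in for a segmented lesion: a star-shaped solid whose radial surface
#' is `r(u) = radius * (1 + roughness * Z(u))`, with `Z` a fixed-seed,
#' band-limited random field on the sphere (orthonormal real spherical
#' harmonics of orders 2-8 with i.i.d. standard-normal coefficients, scaled
#' to unit pointwise variance). Larger `roughness` produces a more convoluted
#' boundary and hence a higher box-counting dimension at finite scales.
#' `roughness = 0` reproduces `make_phantom("sphere", radius)` exactly.
#' A disconnected result (possible at extreme roughness) is regenerated with
#' a derived seed, up to `max_attempts` times, and flagged via the
#' `"attempts"` attribute.
#'
#' @param radius Sphere radius in voxels (>= 4).
#' @param roughness Non-negative amplitude of the radial perturbation.
#' @param seed Integer seed; fixed seed gives a bitwise-identical mask.
#' @param margin Background margin in voxels (>= 4).
#' @param with_ct If `TRUE`, also return a textured pseudo-CT volume.
#' @param max_attempts Regeneration attempts if the mask is disconnected.
#' @return A [seg_mask()] (or `list(mask, volume)` if `with_ct`), with
#'   attribute `"attempts"`.
#' @export
make_rough_tumor <- function(radius, roughness = 0.15, seed = 1L,
                             margin = 4L, with_ct = FALSE,
                             max_attempts = 5L) {
  if (radius < 4) stop("'radius' must be >= 4 voxels")
  if (roughness < 0) stop("'roughness' must be >= 0")
  margin <- max(4L, as.integer(margin))

  build <- function(sd) {
    if (roughness == 0) {
      mask <- digital_ball(radius, margin = margin)
      return(mask)
    }
    a <- with_local_seed(sd, stats::rnorm(sum(2 * (2:8) + 1)))
    # probe the field maximum on a Fibonacci point set to size the grid
    kprobe <- 1500L
    i <- seq_len(kprobe) - 0.5
    zp <- 1 - 2 * i / kprobe
    th <- pi * (1 + sqrt(5)) * i
    up <- cbind(sqrt(1 - zp^2) * cos(th), sqrt(1 - zp^2) * sin(th), zp)
    zmax <- max(abs(sh_field(up, a))) * 1.05
    rmax <- radius * (1 + roughness * zmax)
    rmin <- max(radius * (1 - roughness * zmax), 0)
    side <- 2L * (as.integer(ceiling(rmax)) + margin) + 1L
    c0 <- (side + 1L) / 2
    co <- seq_len(side) - c0
    d2 <- outer(outer(co^2, co^2, "+"), co^2, "+")
    dist <- sqrt(d2)
    arr <- array(0L, c(side, side, side))
    arr[dist <= rmin - 0.5] <- 1L
    shell <- which(dist > rmin - 0.5 & dist <= rmax + 0.5)
    if (length(shell) > 0L) {
      ijk <- arrayInd(shell, dim(arr))
      v <- sweep(ijk, 2, c0)
      dn <- sqrt(rowSums(v^2))
      inner <- dn < 1e-9
      u <- v / pmax(dn, 1e-9)
      z <- sh_field(u, a)
      keep <- dn <= radius * (1 + roughness * z) + 1e-9
      keep[inner] <- TRUE
      arr[shell[keep]] <- 1L
    }
    seg_mask(arr, spacing = c(1, 1, 1))
  }

  attempt <- 1L
  mask <- build(seed)
  while (attempt <= max_attempts) {
    lab <- label_components(mask$data)
    if (lab$n <= 1L) break
    attempt <- attempt + 1L
    if (attempt > max_attempts)
      stop("rough tumor remained disconnected after ", max_attempts,
           " attempts (roughness too large)")
    mask <- build(seed + attempt * 1000003L)
  }
  attr(mask, "attempts") <- attempt
  if (!with_ct) return(mask)

  hu <- with_local_seed(seed + 7L, {
    arr <- array(stats::rnorm(length(mask$data), mean = 30, sd = 10),
                 dim(mask$data))
    arr[mask$data == 1L] <- stats::rnorm(sum(mask$data), mean = 85, sd = 15)
    arr
  })
  vol <- ct_volume(hu, spacing = mask$spacing, origin = mask$origin)
  out <- list(mask = mask, volume = vol)
  attr(out, "attempts") <- attempt
  out
}
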