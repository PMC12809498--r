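#' Reciprocal space: structure factors and map synthesis
#'
#' Structure factors are computed by direct summation over all atoms of all
#' symmetry copies in the (orthogonal) unit cell,
#' \deqn{F(hkl) = \sum_j f_j(s)\, e^{-B_j s^2/4}\, e^{2\pi i (h x_j + k y_j + l z_j)},}
#' with fractional coordinates, s = 1/d, and unit occupancies. Density and
#' Patterson maps are synthesised by FFT with the F(000) term omitted, so
#' both maps are mean-zero (the CCP4 FFT convention). The Patterson map is
#' available by two routes — squared-amplitude synthesis and density
#' autocorrelation — which agree to numerical precision.
#'
#' @name scatter
NULL

# Cromer-Mann 4-Gaussian coefficients (International Tables Vol. C):
# f(s) = sum_i a_i exp(-b_i s^2 / 4) + c, with s = 1/d in 1/angstrom.
CROMER_MANN <- list(
  C = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
           b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
           b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
           b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  S = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
           b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900)
)

ATOMIC_NUMBER <- c(C = 6, N = 7, O = 8, S = 16)

#' X-ray scattering factor of an element
#'
#' @param element one of C, N, O, S.
#' @param s reciprocal resolution 1/d in 1/angstrom (vectorised); `s = 2
#'   sin(theta)/lambda`.
#' @param mode `"cromer-mann"` for the 4-Gaussian parameterisation, or
#'   `"constant-z"` for the atomic number (a resolution-independent testing
#'   oracle).
#' @return dimensionless scattering factor, same length as `s`.
#' @export
scattering_factor <- function(element, s, mode = c("cromer-mann", "constant-z")) {
  mode <- match.arg(mode)
  if (!element %in% SUPPORTED_ELEMENTS) {
    rlang::abort(paste0("unknown element: ", element))
  }
  if (any(s < 0)) rlang::abort("s must be non-negative")
  if (mode == "constant-z") return(rep(ATOMIC_NUMBER[[element]], length(s)))
  cm <- CROMER_MANN[[element]]
  out <- rep(cm$c, length(s))
  for (i in 1:4) out <- out + cm$a[i] * exp(-cm$b[i] * s^2 / 4)
  out
}

#' Construct a reflection set
#'
#' One row per reflection of the stored Friedel hemisphere; the mate of
#' every (h, k, l) is derivable as the complex conjugate. (0, 0, 0) is
#' excluded.
#'
#' @param entries tibble with columns `h`, `k`, `l` (integer), `f`
#'   (complex structure factor) and `d` (resolution, angstroms).
#' @param cell length-3 axis lengths, angstroms.
#' @param d_min resolution limit, angstroms.
#' @export
reflection_set <- function(entries, cell, d_min) {
  entries <- tibble::as_tibble(entries)
  stopifnot(all(c("h", "k", "l", "f", "d") %in% names(entries)))
  if (any(entries$d < d_min - 1e-9)) rlang::abort("reflection beyond d_min")
  if (any(entries$h == 0 & entries$k == 0 & entries$l == 0)) {
    rlang::abort("F(000) must not be stored")
  }
  structure(entries,
            cell = as.numeric(cell), d_min = d_min,
            class = c("reflection_set", class(entries)))
}

#' @export
`[.reflection_set` <- function(x, ...) {
  out <- NextMethod()
  attr(out, "cell") <- attr(x, "cell")
  attr(out, "d_min") <- attr(x, "d_min")
  class(out) <- class(x)
  out
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("<reflection_set: %d reflections to %.2f A, cell %.1f %.1f %.1f>\n",
              nrow(x), attr(x, "d_min"), attr(x, "cell")[1],
              attr(x, "cell")[2], attr(x, "cell")[3]))
  NextMethod()
}

# Resolution of (h,k,l) in an orthogonal cell: 1/d^2 = h^2/a^2 + k^2/b^2 + l^2/c^2
hkl_resolution <- function(h, k, l, cell) {
  1 / sqrt(h^2 / cell[1]^2 + k^2 / cell[2]^2 + l^2 / cell[3]^2)
}

#' Structure factors of a unit cell by direct summation
#'
#' Enumerates all Miller indices with d >= d_min (full sphere, then reduced
#' to the Friedel hemisphere for storage) and sums over every atom of every
#' symmetry copy. The Debye-Waller factor uses sin^2(theta)/lambda^2 =
#' s^2/4.
#'
#' @param cell a `unit_cell` (P1 or P21; symmetry copies must be present as
#'   explicit atoms).
#' @param d_min resolution limit in angstroms.
#' @param mode scattering-factor mode, see [scattering_factor()].
#' @return a [reflection_set()].
#' @export
calc_structure_factors <- function(cell, d_min,
                                   mode = c("cromer-mann", "constant-z")) {
  mode <- match.arg(mode)
  if (nrow(cell$atoms) == 0) rlang::abort("empty cell")
  if (d_min <= 0) rlang::abort("d_min must be positive")
  hmax <- floor(cell$cell / d_min)
  g <- expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                   l = -hmax[3]:hmax[3])
  keep <- g$h > 0 | (g$h == 0 & g$k > 0) | (g$h == 0 & g$k == 0 & g$l > 0)
  g <- g[keep, ]
  d <- hkl_resolution(g$h, g$k, g$l, cell$cell)
  g <- g[d >= d_min, ]
  d <- d[d >= d_min]
  s <- 1 / d

  frac <- frac_coords(cell)
  bfac <- cell$atoms$b
  elem <- cell$atoms$element
  f_elem <- vapply(SUPPORTED_ELEMENTS,
                   function(e) scattering_factor(e, s, mode),
                   numeric(length(s)))
  f_atom_col <- match(elem, SUPPORTED_ELEMENTS)

  hmat <- as.matrix(g)
  n <- nrow(hmat)
  f <- complex(length.out = n)
  chunk <- max(1L, floor(4e6 / max(nrow(frac), 1)))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    phase <- exp(2i * pi * (hmat[idx, , drop = FALSE] %*% t(frac)))
    dw <- exp(-outer(s[idx]^2 / 4, bfac))
    fs <- f_elem[idx, f_atom_col, drop = FALSE]
    f[idx] <- rowSums(fs * dw * phase)
  }
  reflection_set(tibble::tibble(h = as.integer(hmat[, 1]),
                                k = as.integer(hmat[, 2]),
                                l = as.integer(hmat[, 3]),
                                f = f, d = d),
                 cell = cell$cell, d_min = d_min)
}

#' Construct a map grid
#'
#' @param values real 3D array.
#' @param cell axis lengths, angstroms.
#' @param flavor `"density"`, `"patterson"` or `"template"`.
#' @param d_min resolution limit the map was synthesised at.
#' @param sampling_factor grid-sampling factor (dimensionless), if known.
#' @export
map_grid <- function(values, cell, flavor = c("density", "patterson", "template"),
                     d_min = NA_real_, sampling_factor = NA_real_) {
  flavor <- match.arg(flavor)
  stopifnot(is.array(values), length(dim(values)) == 3, all(is.finite(values)))
  structure(list(values = values, cell = as.numeric(cell), flavor = flavor,
                 d_min = d_min, sampling_factor = sampling_factor),
            class = "map_grid")
}

#' @export
print.map_grid <- function(x, ...) {
  cat(sprintf("<map_grid %s: %s grid, cell %.1f %.1f %.1f A, d_min %.2f>\n",
              x$flavor, paste(dim(x$values), collapse = "x"),
              x$cell[1], x$cell[2], x$cell[3], x$d_min))
  invisible(x)
}

#' @export
dim.map_grid <- function(x) dim(x$values)

# Place hemisphere coefficients plus Friedel mates into an FFT array and
# run the forward transform; shared by density and Patterson synthesis.
synthesise <- function(coeff, hkl, cell, shape) {
  hmax <- apply(abs(hkl), 2, max)
  if (any(shape < 2 * hmax + 1)) {
    rlang::abort("grid too coarse for the reflection set (aliasing)")
  }
  arr <- array(complex(real = 0), dim = shape)
  i1 <- (hkl[, 1] %% shape[1]) + 1
  i2 <- (hkl[, 2] %% shape[2]) + 1
  i3 <- (hkl[, 3] %% shape[3]) + 1
  j1 <- ((-hkl[, 1]) %% shape[1]) + 1
  j2 <- ((-hkl[, 2]) %% shape[2]) + 1
  j3 <- ((-hkl[, 3]) %% shape[3]) + 1
  arr[cbind(i1, i2, i3)] <- coeff
  arr[cbind(j1, j2, j3)] <- Conj(coeff)
  Re(stats::fft(arr)) / prod(cell)
}

#' Electron-density synthesis (inverse Fourier transform of F)
#'
#' rho(x, y, z) = (1/V) sum_hkl F(hkl) exp(-2 pi i (hx + ky + lz)),
#' evaluated on the fractional grid by FFT. F(000) is omitted, so the map
#' mean is zero.
#'
#' @param refl a [reflection_set()].
#' @param shape integer length-3 grid shape; must satisfy the Shannon
#'   condition for the stored indices.
#' @param flavor flavor tag of the output map (density or template).
#' @return a `map_grid`.
#' @export
density_map <- function(refl, shape, flavor = "density") {
  cell <- attr(refl, "cell")
  vals <- synthesise(refl$f, cbind(refl$h, refl$k, refl$l), cell, shape)
  map_grid(vals, cell, flavor, d_min = attr(refl, "d_min"))
}

#' Patterson synthesis (squared amplitudes, zero phases)
#'
#' P(u, v, w) = (1/V) sum_hkl |F(hkl)|^2 cos(2 pi (hu + kv + lw)).
#' Implemented by replacing every F with |F|^2 and running the same
#' synthesis as [density_map()]; |F(000)|^2 is omitted.
#'
#' @inheritParams density_map
#' @return a `map_grid` of flavor `"patterson"`.
#' @export
patterson_map <- function(refl, shape) {
  cell <- attr(refl, "cell")
  coeff <- complex(real = Mod(refl$f)^2)
  vals <- synthesise(coeff, cbind(refl$h, refl$k, refl$l), cell, shape)
  map_grid(vals, cell, "patterson", d_min = attr(refl, "d_min"))
}

#' Patterson map as the autocorrelation of a density map
#'
#' p = Re(IFFT(FFT(e) * FFT(e-inverse-shifted))) with the elementwise
#' product, scaled to the same 1/V convention as [patterson_map()]. The
#' inverse-shifted map is e[-i mod n, -j mod n, -k mod n].
#'
#' @param e a density `map_grid`.
#' @return a `map_grid` of flavor `"patterson"` on the same grid.
#' @export
patterson_via_autocorrelation <- function(e) {
  v <- e$values
  n <- dim(v)
  rev_idx <- function(m) c(1L, if (m > 1) m:2L)
  v_rev <- v[rev_idx(n[1]), rev_idx(n[2]), rev_idx(n[3]), drop = FALSE]
  big_e <- stats::fft(v)
  big_rev <- stats::fft(v_rev)
  vol <- prod(e$cell)
  p <- Re(stats::fft(big_e * big_rev)) * vol / prod(n)^2
  map_grid(p, e$cell, "patterson", d_min = e$d_min,
           sampling_factor = e$sampling_factor)
}

#' Structure factors of a real-space map
#'
#' Inverts the synthesis convention of [density_map()]: F(hkl) = (V/N)
#' sum_x rho(x) exp(2 pi i (hx + ky + lz)) evaluated by FFT and read out
#' at the Miller indices of `template`. Useful for scoring a predicted
#' map against reference reflections.
#'
#' @param map a `map_grid`.
#' @param template a [reflection_set()] supplying the (h, k, l) to read
#'   out (indices must satisfy the grid's Shannon bound).
#' @return a [reflection_set()] over the template's indices.
#' @export
map_to_structure_factors <- function(map, template) {
  n <- dim(map$values)
  hkl <- cbind(template$h, template$k, template$l)
  if (any(n < 2 * apply(abs(hkl), 2, max) + 1)) {
    rlang::abort("map grid too coarse for the requested indices")
  }
  big_f <- stats::fft(map$values, inverse = TRUE) * prod(map$cell) / prod(n)
  idx <- cbind((hkl[, 1] %% n[1]) + 1, (hkl[, 2] %% n[2]) + 1,
               (hkl[, 3] %% n[3]) + 1)
  reflection_set(tibble::tibble(h = template$h, k = template$k,
                                l = template$l,
                                f = big_f[idx], d = template$d),
                 cell = map$cell, d_min = attr(template, "d_min"))
}
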