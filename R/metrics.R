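#' Map and phase evaluation metrics
#'
#' Predicted maps are judged by the Pearson correlation against the
#' ground-truth density (optionally restricted to the region of the cell
#' occupied by the atomic model) and by phase-error statistics between the
#' predicted and true structure factors: unweighted and figure-of-merit
#' weighted mean phase error in degrees, plus the corresponding mean
#' cosines. A sigma-A / FOM baseline produces weighted map coefficients
#' from a partial model, playing the role a SIGMAA-style reweighting plays
#' for incomplete molecular-replacement solutions.
#'
#' @name metrics
NULL

#' Pearson correlation between two maps
#'
#' @param a,b `map_grid` objects (or bare arrays) of identical shape.
#' @param mask optional logical array of the same shape; the correlation is
#'   computed over `TRUE` voxels only (at least 2 required).
#' @return correlation in `[-1, 1]`.
#' @export
pearson_cc <- function(a, b, mask = NULL) {
  av <- if (inherits(a, "map_grid")) a$values else a
  bv <- if (inherits(b, "map_grid")) b$values else b
  if (!identical(dim(av), dim(bv))) rlang::abort("map shapes differ")
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(av))) rlang::abort("mask shape differs")
    if (sum(mask) < 2) rlang::abort("mask must select at least 2 voxels")
    av <- av[mask]; bv <- bv[mask]
  }
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) {
    rlang::abort("zero variance: correlation undefined")
  }
  stats::cor(as.vector(av), as.vector(bv))
}

#' In-model region mask
#'
#' Voxels within `radius` angstroms (periodic minimum-image distance) of
#' any atom of the cell contents.
#'
#' @param cell a `unit_cell` holding the ground-truth model.
#' @param shape grid shape.
#' @param radius mask radius in angstroms (default 2.0).
#' @return logical 3D array.
#' @export
in_model_mask <- function(cell, shape, radius = 2.0) {
  min_distance_grid(cell, shape) <= radius
}

wrap_phase_deg <- function(x) ((x + 180) %% 360) - 180

#' Phase-error comparison between two reflection sets
#'
#' Per-reflection absolute phase difference in `[0, 180]` degrees, with
#' unweighted and FOM-weighted aggregates (weighted means normalise by the
#' FOM sum). No origin-shift search is performed: maps generated by this
#' package share a common origin by construction.
#'
#' @param pred,truth [reflection_set()]s over identical Miller indices.
#' @param foms optional per-reflection figures of merit aligned with `pred`
#'   rows; default 1 for every reflection.
#' @return object of class `phase_comparison`: a per-reflection tibble
#'   (`h`, `k`, `l`, `dphi`, `fom`, `centric`) with aggregate attributes;
#'   see [glance.phase_comparison()].
#' @export
phase_error <- function(pred, truth, foms = NULL) {
  key_p <- paste(pred$h, pred$k, pred$l)
  key_t <- paste(truth$h, truth$k, truth$l)
  if (length(key_p) != length(key_t) || !setequal(key_p, key_t)) {
    rlang::abort("reflection index sets differ")
  }
  truth_ord <- truth[match(key_p, key_t), ]
  dphi <- abs(wrap_phase_deg(Arg(pred$f) * 180 / pi -
                               Arg(truth_ord$f) * 180 / pi))
  m <- if (is.null(foms)) rep(1, nrow(pred)) else foms
  stopifnot(length(m) == nrow(pred), all(m >= 0), all(m <= 1))
  out <- tibble::tibble(h = pred$h, k = pred$k, l = pred$l,
                        dphi = dphi, fom = m, centric = pred$k == 0L)
  structure(out,
            mean_dphi = mean(dphi),
            mean_dphi_weighted = sum(m * dphi) / sum(m),
            mean_cos = mean(cos(dphi * pi / 180)),
            mean_cos_weighted = sum(m * cos(dphi * pi / 180)) / sum(m),
            class = c("phase_comparison", class(out)))
}

#' One-row summary of a phase comparison
#'
#' @param x a `phase_comparison`.
#' @param ... unused.
#' @return tibble with `phase_error_unweighted`,
#'   `phase_error_unweighted_cosine`, `phase_error_weighted`,
#'   `phase_error_weighted_cosine` and `n_reflections`.
#' @export
#' @exportS3Method generics::glance
glance.phase_comparison <- function(x, ...) {
  tibble::tibble(
    phase_error_unweighted = attr(x, "mean_dphi"),
    phase_error_unweighted_cosine = attr(x, "mean_cos"),
    phase_error_weighted = attr(x, "mean_dphi_weighted"),
    phase_error_weighted_cosine = attr(x, "mean_cos_weighted"),
    n_reflections = nrow(x))
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' Per-reflection phase errors as a tibble
#' @param x a `phase_comparison`.
#' @param ... unused.
#' @export
#' @exportS3Method generics::tidy
tidy.phase_comparison <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Normalised structure-factor amplitudes (E values)
#'
#' E_h = |F_h| / sqrt(mean |F|^2 in shell), over equal-count resolution
#' shells, so that the mean E^2 is 1 within every shell.
#'
#' @param refl a [reflection_set()].
#' @param n_shells requested number of shells; reduced if reflections are
#'   too few to give every shell at least 3 members.
#' @return tibble: reflection indices, `amp`, `e`, `shell`, `d`.
#' @export
normalized_amplitudes <- function(refl, n_shells = 10) {
  n <- nrow(refl)
  n_shells <- max(1L, min(n_shells, n %/% 3L))
  # equal-count shells from low resolution (large d) to high
  ord_rank <- rank(-refl$d, ties.method = "first")
  shell <- ceiling(ord_rank / (n / n_shells))
  shell <- pmin(pmax(shell, 1L), n_shells)
  amp <- Mod(refl$f)
  ms <- tapply(amp^2, shell, mean)
  e <- amp / sqrt(ms[as.character(shell)])
  tibble::tibble(h = refl$h, k = refl$k, l = refl$l,
                 d = refl$d, amp = amp, e = as.numeric(e),
                 shell = as.integer(shell))
}

#' Estimate sigma-A per resolution shell
#'
#' A moment estimator built on the identity corr(E_obs^2, E_calc^2) =
#' sigma_A^4 for acentric data: per shell, the observed correlation is
#' shrunk linearly so that three null standard errors map to zero while a
#' perfect correlation stays at one ((r - 3/sqrt(n)) / (1 - 3/sqrt(n)),
#' floored at 0) before taking the fourth root; without the shrinkage the
#' fourth root strongly inflates sampling noise around zero. The amplitude scale is D = sigma_A *
#' sqrt(mean |F_obs|^2 / mean |F_calc|^2). Deterministic and monotone in
#' the observed correlation; a likelihood-based refinement is out of scope.
#'
#' @param e_obs,e_calc tibbles from [normalized_amplitudes()] over identical
#'   Miller indices and shells (shells taken from `e_obs`).
#' @return object of class `sigma_a_estimate`: per-shell tibble with
#'   `shell`, `sigma_a`, `d_scale`, `n`.
#' @export
estimate_sigma_a <- function(e_obs, e_calc) {
  key_o <- paste(e_obs$h, e_obs$k, e_obs$l)
  key_c <- paste(e_calc$h, e_calc$k, e_calc$l)
  if (!setequal(key_o, key_c)) rlang::abort("reflection index sets differ")
  e_calc <- e_calc[match(key_o, key_c), ]
  per_shell <- lapply(split(seq_len(nrow(e_obs)), e_obs$shell), function(idx) {
    if (length(idx) < 3) rlang::abort("shell with fewer than 3 reflections")
    r <- suppressWarnings(stats::cor(e_obs$e[idx]^2, e_calc$e[idx]^2))
    if (is.na(r)) r <- 0
    thr <- 3 / sqrt(length(idx))     # null sampling-noise scale
    r <- (r - thr) / (1 - thr)
    sa <- max(min(r, 1), 0)^(1 / 4)
    sa <- min(sa, 1 - 1e-6)
    tibble::tibble(shell = e_obs$shell[idx[1]],
                   sigma_a = sa,
                   d_scale = sa * sqrt(mean(e_obs$amp[idx]^2) /
                                         mean(e_calc$amp[idx]^2)),
                   n = length(idx))
  })
  out <- dplyr::bind_rows(per_shell)
  class(out) <- c("sigma_a_estimate", class(out))
  out
}

#' Figures of merit from sigma-A
#'
#' X = 2 sigma_A E_obs E_calc / (1 - sigma_A^2); acentric reflections get
#' m = I1(X)/I0(X) (modified Bessel ratio), centric ones m = tanh(X/2).
#' In P21 the centric zone is the h0l plane (k = 0).
#'
#' @param e_obs,e_calc per-reflection E values (aligned vectors).
#' @param sigma_a per-reflection sigma-A (aligned; e.g. the shell estimate
#'   expanded to reflections).
#' @param centric logical per-reflection centric flag.
#' @return per-reflection figures of merit in `[0, 1]`.
#' @export
fom <- function(e_obs, e_calc, sigma_a, centric) {
  sa <- sigma_a
  if (any(sa >= 1)) {
    rlang::warn("sigma_a = 1 clamped to 1 - 1e-6")
    sa <- pmin(sa, 1 - 1e-6)
  }
  x <- 2 * sa * e_obs * e_calc / (1 - sa^2)
  m <- numeric(length(x))
  ac <- !centric
  # scaled Bessel functions keep the ratio finite for moderate X; beyond
  # that the ratio follows its asymptotic expansion 1 - 1/(2X)
  big <- x > 500
  safe <- ac & !big
  m[safe] <- besselI(x[safe], 1, expon.scaled = TRUE) /
    besselI(x[safe], 0, expon.scaled = TRUE)
  m[ac & big] <- 1 - 1 / (2 * x[ac & big])
  m[centric] <- tanh(x[centric] / 2)
  pmin(pmax(m, 0), 1)
}

#' Sigma-A weighted map from a partial model
#'
#' Synthesises a density map from the weighted coefficients
#' (2 m |F_obs| - D |F_calc|) exp(i phi_calc) for acentric reflections and
#' m |F_obs| exp(i phi_calc) for centric ones.
#'
#' @param obs_amps per-reflection observed amplitudes aligned with
#'   `partial_refl` rows.
#' @param partial_refl [reflection_set()] of the partial model (source of
#'   the phases and |F_calc|).
#' @param d_scale per-reflection D values.
#' @param foms per-reflection figures of merit.
#' @param centric logical per-reflection centric flags.
#' @param shape grid shape for the synthesis.
#' @return a density `map_grid`.
#' @export
sigmaa_weighted_map <- function(obs_amps, partial_refl, d_scale, foms,
                                centric, shape) {
  phi <- Arg(partial_refl$f)
  fc <- Mod(partial_refl$f)
  amp <- ifelse(centric, foms * obs_amps,
                2 * foms * obs_amps - d_scale * fc)
  coeff <- complex(modulus = abs(amp), argument = phi + ifelse(amp < 0, pi, 0))
  vals <- synthesise(coeff, cbind(partial_refl$h, partial_refl$k,
                                  partial_refl$l),
                     attr(partial_refl, "cell"), shape)
  map_grid(vals, attr(partial_refl, "cell"), "density",
           d_min = attr(partial_refl, "d_min"))
}

#' Full sigma-A weighting pipeline for a truth/partial reflection pair
#'
#' Convenience composition: E values for both sets, per-shell sigma-A,
#' per-reflection FOMs and the weighted map.
#'
#' @param truth_refl,partial_refl [reflection_set()]s over identical
#'   indices ("observed" amplitudes are taken from `truth_refl`).
#' @param shape grid shape for the weighted map.
#' @param n_shells resolution shells for normalisation.
#' @return list: `map` (weighted density map), `foms`, `sigma_a`
#'   (per-shell tibble), `coefficients` (tibble `h`, `k`, `l`, `amp`,
#'   `phase` of the weighted synthesis, phase in radians), `refl_order`
#'   (the row order used, matching `truth_refl`).
#' @export
sigmaa_pipeline <- function(truth_refl, partial_refl, shape, n_shells = 10) {
  e_o <- normalized_amplitudes(truth_refl, n_shells)
  e_c <- normalized_amplitudes(partial_refl, n_shells)
  key_o <- paste(e_o$h, e_o$k, e_o$l)
  key_c <- paste(e_c$h, e_c$k, e_c$l)
  e_c <- e_c[match(key_o, key_c), ]
  e_c$shell <- e_o$shell   # shells follow the observed set
  sa <- estimate_sigma_a(e_o, e_c)
  sa_refl <- sa$sigma_a[match(e_o$shell, sa$shell)]
  d_refl <- sa$d_scale[match(e_o$shell, sa$shell)]
  centric <- e_o$k == 0L
  m <- fom(e_o$e, e_c$e, sa_refl, centric)
  key_p <- paste(partial_refl$h, partial_refl$k, partial_refl$l)
  ord <- match(key_o, key_p)
  part <- partial_refl[ord, ]
  wmap <- sigmaa_weighted_map(e_o$amp, part, d_refl, m, centric, shape)
  amp <- ifelse(centric, m * e_o$amp, 2 * m * e_o$amp - d_refl * Mod(part$f))
  coeff <- tibble::tibble(h = e_o$h, k = e_o$k, l = e_o$l,
                          amp = abs(amp),
                          phase = Arg(part$f) + ifelse(amp < 0, pi, 0))
  list(map = wmap, foms = m, sigma_a = sa, coefficients = coeff,
       refl_order = ord)
}
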