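#' Synthetic peptide fixtures
#'
#' Stand-ins for experimentally derived coordinate files: an idealised
#' peptide-backbone builder produces ground-truth fragments, and a
#' noise model produces "predicted" counterparts at a controlled C-alpha
#' RMSD, emulating structure predictions already aligned to the truth.
#'
#' @name fixtures
NULL

# Ideal backbone geometry (angstroms / degrees), standard peptide values.
IDEAL_GEOM <- list(
  n_ca = 1.46, ca_c = 1.52, c_n = 1.33, c_o = 1.23, ca_cb = 1.53,
  ang_n_ca_c = 111.0, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, ang_n_ca_cb = 110.5,
  omega = 180.0, chi_cb = -122.6
)

#' Fixture generation settings
#'
#' @param n_residues number of residues (default 15).
#' @param composition named sampling weights over residue names. The default
#'   mixes ALA and GLY, the two residues whose full heavy-atom complement is
#'   covered by the builder (side chains are truncated at C-beta).
#' @param b_range interval (A^2) from which ground-truth B factors are drawn.
#' @param target_rmsd C-alpha RMSD (angstroms) of the perturbed counterpart.
#' @param terminal_extra extra displacement multiplier applied to the first
#'   and last residue before rescaling (models less confident termini).
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_residues = 15,
                         composition = c(ALA = 0.7, GLY = 0.3),
                         b_range = c(10, 40),
                         target_rmsd = 0.5,
                         terminal_extra = 1.0) {
  stopifnot(n_residues >= 1, target_rmsd >= 0, all(composition >= 0),
            length(b_range) == 2, b_range[1] >= 0, b_range[2] >= b_range[1])
  if (!all(names(composition) %in% STANDARD_RESIDUES)) {
    rlang::abort("composition names must be standard residues")
  }
  structure(list(n_residues = n_residues, composition = composition,
                 b_range = b_range, target_rmsd = target_rmsd,
                 terminal_extra = terminal_extra),
            class = "fixture_spec")
}

# Place atom D bonded to C, given positions of A, B, C, the bond length
# |CD|, the angle B-C-D and the torsion A-B-C-D (NERF construction).
place_atom <- function(a, b, c, r, theta_deg, phi_deg) {
  theta <- theta_deg * pi / 180
  phi <- phi_deg * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-r * cos(theta), r * sin(theta) * cos(phi), r * sin(theta) * sin(phi))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Build a synthetic peptide fragment
#'
#' Grows an extended/coiled backbone from ideal bond lengths and angles
#' (N-CA 1.46, CA-C 1.52, C-N 1.33 angstroms; trans peptide bonds), with
#' backbone torsions drawn from broad allowed regions (a beta/alpha
#' mixture). A carbonyl O is placed on every residue and a C-beta on every
#' non-glycine residue; no hydrogens. B factors are uniform over
#' `spec$b_range`.
#'
#' @param spec a [fixture_spec()].
#' @param seed optional integer seed; identical seeds give identical output.
#' @return a fragment (see [new_fragment()]).
#' @export
make_fragment <- function(spec = fixture_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- IDEAL_GEOM
  nres <- spec$n_residues
  resnames <- sample(names(spec$composition), nres, replace = TRUE,
                     prob = spec$composition)
  # torsion draws: beta-ish with p = 0.6, alpha-ish otherwise
  draw_phipsi <- function() {
    if (stats::runif(1) < 0.6) {
      c(stats::runif(1, -150, -90), stats::runif(1, 110, 150))
    } else {
      c(stats::runif(1, -75, -55), stats::runif(1, -50, -30))
    }
  }
  tor <- t(vapply(seq_len(nres), function(i) draw_phipsi(), numeric(2)))

  pos <- list()  # pos[[i]] = list(N=, CA=, C=)
  # first residue seeded in a canonical frame
  n1 <- c(0, 0, 0)
  ca1 <- c(g$n_ca, 0, 0)
  ang <- g$ang_n_ca_c * pi / 180
  c1 <- ca1 + g$ca_c * c(-cos(ang), sin(ang), 0)
  pos[[1]] <- list(N = n1, CA = ca1, C = c1)
  for (i in seq_len(nres - 1)) {
    p <- pos[[i]]
    ni <- place_atom(p$N, p$CA, p$C, g$c_n, g$ang_ca_c_n, tor[i, 2])   # psi_i
    cai <- place_atom(p$CA, p$C, ni, g$n_ca, g$ang_c_n_ca, g$omega)
    ci <- place_atom(p$C, ni, cai, g$ca_c, g$ang_n_ca_c, tor[i + 1, 1]) # phi_{i+1}
    pos[[i + 1]] <- list(N = ni, CA = cai, C = ci)
  }

  rows <- list()
  for (i in seq_len(nres)) {
    p <- pos[[i]]
    # carbonyl O trans to the next amide N (torsion psi + 180)
    o <- place_atom(p$N, p$CA, p$C, g$c_o, g$ang_ca_c_o, tor[i, 2] + 180)
    atoms <- list(N = list(p$N, "N"), CA = list(p$CA, "C"),
                  C = list(p$C, "C"), O = list(o, "O"))
    if (resnames[i] != "GLY") {
      cb <- place_atom(p$C, p$N, p$CA, g$ca_cb, g$ang_n_ca_cb, g$chi_cb)
      atoms$CB <- list(cb, "C")
    }
    for (an in names(atoms)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        resid = i, resname = resnames[i], atom = an,
        element = atoms[[an]][[2]],
        x = atoms[[an]][[1]][1], y = atoms[[an]][[1]][2],
        z = atoms[[an]][[1]][3],
        b = stats::runif(1, spec$b_range[1], spec$b_range[2]), occ = 1.0)
    }
  }
  new_fragment(dplyr::bind_rows(rows),
               source_id = paste0("fixture-", seed %||% "live"))
}

#' Perturb a fragment into a synthetic "prediction"
#'
#' Adds per-atom Gaussian displacements, optionally inflated on the two
#' terminal residues, then rescales the whole displacement field so the
#' realised C-alpha RMSD to the input equals `spec$target_rmsd`. All B
#' factors of the output are reset to the constant 20.0 A^2 used for
#' predicted templates.
#'
#' @param fragment ground-truth fragment.
#' @param spec a [fixture_spec()]; only `target_rmsd` / `terminal_extra` used.
#' @param seed optional integer seed.
#' @return a fragment with identical topology and B = 20 throughout.
#' @export
make_prediction <- function(fragment, spec = fixture_spec(), seed = NULL) {
  if (spec$target_rmsd < 0) rlang::abort("target_rmsd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  out <- fragment
  if (spec$target_rmsd > 0) {
    m <- coords_matrix(fragment)
    disp <- matrix(stats::rnorm(length(m)), ncol = 3)
    rid <- fragment$resid
    term <- rid == min(rid) | rid == max(rid)
    disp[term, ] <- disp[term, ] * spec$terminal_extra
    ca <- fragment$atom == "CA"
    realized <- sqrt(mean(rowSums(disp[ca, , drop = FALSE]^2)))
    disp <- disp * (spec$target_rmsd / realized)
    out <- set_coords(out, m + disp)
  }
  out$b <- 20.0
  attr(out, "source_id") <- paste0(attr(fragment, "source_id") %||% "frag",
                                   "-pred")
  out
}

#' Derive a child seed from a master seed
#'
#' A small splitmix-style integer hash so that every stochastic stage of a
#' pipeline run can draw from its own reproducible stream. Result is in
#' `[0, 2^31 - 1)`.
#' @param master master seed (integer).
#' @param i stream index (integer).
#' @export
derive_seed <- function(master, i) {
  x <- (as.double(master) * 2654435761 + as.double(i) * 40503 + 12345) %% 2147483647
  as.integer(x)
}
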