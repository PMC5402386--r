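## Solvent-accessible surface area by numerical sphere-point integration
## (Shrake-Rupley): each heavy atom is covered with a deterministic
## golden-spiral point lattice at radius vdW + probe; points buried inside
## any neighbouring atom's expanded sphere are rejected.

#' Per-atom solvent-accessible surface area
#'
#' @param atoms atom table (rows define the occluding context).
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points sphere points per atom (default 960).
#' @return Numeric vector of per-atom SASA (Angstrom^2), hydrogens get 0 and
#'   are ignored as occluders.
#' @export
atom_sasa <- function(atoms, probe = 1.4, n_points = 960) {
  hv <- atoms$element != "H"
  xyz <- atom_xyz(atoms[hv, , drop = FALSE])
  radii <- vdw_radius(atoms$element[hv]) + probe
  n <- nrow(xyz)
  out_hv <- numeric(n)
  if (n > 0) {
    pts <- sphere_points(n_points)
    d <- cross_dist(xyz, xyz)
    for (i in seq_len(n)) {
      nb <- which(d[i, ] < radii[i] + radii & seq_len(n) != i)
      surf <- sweep(pts * radii[i], 2, xyz[i, ], "+")
      if (length(nb)) {
        dd <- cross_dist(surf, xyz[nb, , drop = FALSE])
        buried <- rowSums(dd < rep(radii[nb], each = n_points)) > 0
        frac <- mean(!buried)
      } else frac <- 1
      out_hv[i] <- 4 * pi * radii[i]^2 * frac
    }
  }
  out <- numeric(nrow(atoms))
  out[hv] <- out_hv
  out
}

## SASA of a residue / of a residue set, computed in the context of the whole
## complex (protein + ligand + waters occlude).
complex_atoms <- function(model) rbind(model$protein, model$ligand, model$water)

#' Solvent accessibility of one residue within its complex
#' @param model a \code{complex_model}.
#' @param resno residue number.
#' @param chain optional chain.
#' @inheritParams atom_sasa
#' @return Total SASA of the residue's atoms (Angstrom^2).
#' @export
residue_sasa <- function(model, resno, chain = NULL, probe = 1.4, n_points = 960) {
  at <- complex_atoms(model)
  sa <- atom_sasa(at, probe = probe, n_points = n_points)
  sel <- at$resno == resno & at$type == "ATOM"
  if (!is.null(chain)) sel <- sel & at$chain == chain
  if (!any(sel)) return(NA_real_)
  sum(sa[sel])
}

#' Surface-area features of a wild-type/mutant pair
#'
#' Computes the total accessible surface of the binding-site residue set, the
#' mutated residue's accessibility and its relative solvent accessibility
#' (RSA; accessibility divided by the residue type's theoretical maximum),
#' for both structures plus absolute differences.
#'
#' @param wt,mt wild-type and mutant \code{complex_model}s.
#' @param site a \code{binding_site} (from the wild type).
#' @param pos residue number of the mutated residue.
#' @inheritParams atom_sasa
#' @return Named list of scalars; entries are \code{NA} (with provenance
#'   "unknown" downstream) when atoms are missing.
#' @export
surface_accessibility_features <- function(wt, mt, site, pos,
                                           probe = 1.4, n_points = 960) {
  one <- function(model) {
    at <- complex_atoms(model)
    sa <- atom_sasa(at, probe = probe, n_points = n_points)
    in_site <- at$type == "ATOM" &
      paste(at$chain, at$resno) %in% paste(site$residues$chain, site$residues$resno)
    res_sel <- at$type == "ATOM" & at$resno == pos
    res_aa <- if (any(res_sel)) aa_one(at$resid[res_sel][1]) else NA
    res_sasa <- if (any(res_sel)) sum(sa[res_sel]) else NA_real_
    rsa <- if (!is.na(res_aa)) res_sasa / MAX_ASA_TIEN[[res_aa]] else NA_real_
    list(site = sum(sa[in_site]), res = res_sasa, rsa = rsa)
  }
  w <- one(wt); m <- one(mt)
  list(site_sasa_wt = w$site, site_sasa_mt = m$site,
       site_sasa_absdiff = abs(w$site - m$site),
       res_sasa_wt = w$res, res_sasa_mt = m$res,
       res_sasa_absdiff = abs(w$res - m$res),
       rsa_wt = w$rsa, rsa_mt = m$rsa, rsa_absdiff = abs(w$rsa - m$rsa))
}
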