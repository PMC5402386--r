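## Sequence and structural feature extractors for a wild-type/mutant
## protein-ligand complex pair.  Each extractor is usable standalone;
## `assemble_feature_vector()` combines them under a fixed schema.

## ---- half-sphere exposure ----

## CB (or idealized pseudo-CB for glycine) of a residue.
cb_or_pseudo <- function(at) {
  cb <- at[at$elety == "CB", , drop = FALSE]
  if (nrow(cb)) return(as.numeric(cb[1, c("x", "y", "z")]))
  g <- function(nm) {
    r <- at[at$elety == nm, , drop = FALSE]
    if (!nrow(r)) return(NULL)
    as.numeric(r[1, c("x", "y", "z")])
  }
  N <- g("N"); CA <- g("CA"); C <- g("C")
  if (is.null(N) || is.null(CA) || is.null(C)) return(NULL)
  place_cb(N, CA, C)
}

#' Half-sphere exposure of a residue
#'
#' Counts the alpha carbons of all other residues within \code{radius} of the
#' residue's CA, split into the half sphere facing the side chain (CA-CB
#' direction; "up") and the opposite one ("down").  Glycine uses a pseudo-CB
#' built from backbone geometry.
#'
#' @param model a \code{complex_model}.
#' @param pos residue number.
#' @param radius sphere radius in Angstrom (default 13).
#' @return \code{c(up =, down =)} neighbour counts, or NAs if CA is missing.
#' @export
half_sphere_exposure <- function(model, pos, radius = 13) {
  at <- residue_atoms(model, pos)
  ca_row <- at[at$elety == "CA", , drop = FALSE]
  if (!nrow(ca_row)) return(c(up = NA_real_, down = NA_real_))
  ca <- as.numeric(ca_row[1, c("x", "y", "z")])
  cb <- cb_or_pseudo(at)
  if (is.null(cb)) return(c(up = NA_real_, down = NA_real_))
  axis <- vunit(cb - ca)
  p <- model$protein
  others <- p[p$elety == "CA" & p$resno != pos, , drop = FALSE]
  if (!nrow(others)) return(c(up = 0, down = 0))
  rel <- sweep(atom_xyz(others), 2, ca)
  d <- sqrt(rowSums(rel^2))
  keep <- d <= radius & d > 1e-6
  dots <- rel[keep, , drop = FALSE] %*% axis
  c(up = sum(dots > 0), down = sum(dots <= 0))
}

## ---- hydrogen bonds ----

## Polar (donor/acceptor-capable) heavy atoms: nitrogens, oxygens, fluorine.
polar_sel <- function(at) at$element %in% c("N", "O", "F")

#' Hydrogen bonding between a residue and the ligand
#'
#' A hydrogen bond is called when a donor/acceptor-capable heavy atom (N, O
#' or F) of the residue lies within \code{cutoff} of one of the ligand; the
#' closest such pair is reported.  Carbon-carbon contacts never qualify.
#'
#' @param model a \code{complex_model}.
#' @param pos residue number.
#' @param cutoff donor-acceptor upper bound in Angstrom (default 3.2).
#' @return list(present, distance, residue_atom, ligand_atom,
#'   backbone) - distance is NA when absent.
#' @export
hydrogen_bond_features <- function(model, pos, cutoff = 3.2) {
  res <- heavy(residue_atoms(model, pos))
  lig <- heavy(model$ligand)
  rp <- res[polar_sel(res), , drop = FALSE]
  lp <- lig[polar_sel(lig), , drop = FALSE]
  if (!nrow(rp) || !nrow(lp))
    return(list(present = FALSE, distance = NA_real_, residue_atom = NA,
                ligand_atom = NA, backbone = NA))
  d <- cross_dist(atom_xyz(rp), atom_xyz(lp))
  ij <- arrayInd(which.min(d), dim(d))
  dmin <- d[ij]
  list(present = dmin <= cutoff, distance = dmin,
       residue_atom = rp$elety[ij[1]], ligand_atom = lp$elety[ij[2]],
       backbone = rp$elety[ij[1]] %in% c("N", "O"))
}

## ---- structural & sequence environment encodings ----

aa_presence_vector <- function(aas) {
  v <- stats::setNames(rep(0, 20), AA1)
  aas <- aas[!is.na(aas)]
  v[unique(aas)] <- 1
  v
}

#' Environment encodings around a mutated residue
#'
#' Three encodings: (i) six 20-length presence vectors for the annular
#' distance shells (0,1], (1,2], ..., (5,6] Angstrom around the residue
#' (nearest heavy-atom distance between residues); (ii) a 20-length presence
#' vector over the +/-5 sequence window (truncated at chain ends and
#' flagged); (iii) the mutation vector with -1 at the wild-type amino acid,
#' +1 at the mutant one.
#'
#' @param model wild-type \code{complex_model}.
#' @param pos residue number of the mutated residue.
#' @param ref_aa,alt_aa one-letter codes of the change.
#' @return list(shells = 6x20 matrix, seq_window = length-20 vector,
#'   mutation = length-20 vector, window_truncated flag).
#' @export
environment_encodings <- function(model, pos, ref_aa, alt_aa) {
  p <- heavy(model$protein)
  res <- p[p$resno == pos, , drop = FALSE]
  others <- p[p$resno != pos, , drop = FALSE]
  shells <- matrix(0, nrow = 6, ncol = 20,
                   dimnames = list(paste0("shell", 1:6), AA1))
  if (nrow(res) && nrow(others)) {
    d <- cross_dist(atom_xyz(others), atom_xyz(res))
    dmin_atom <- apply(d, 1, min)
    dmin_res <- tapply(dmin_atom, others$resno, min)
    aa_res <- tapply(others$resid, others$resno, function(r) aa_one(r[1]))
    for (s in 1:6) {
      inside <- dmin_res > (s - 1) & dmin_res <= s
      shells[s, ] <- aa_presence_vector(aa_res[inside])
    }
  }
  rt <- residue_table(model)
  idx <- match(pos, rt$resno)
  lo <- max(1, idx - 5); hi <- min(nrow(rt), idx + 5)
  win <- rt$aa[setdiff(lo:hi, idx)]
  mutation <- stats::setNames(rep(0, 20), AA1)
  mutation[ref_aa] <- -1
  mutation[alt_aa] <- 1
  list(shells = shells, seq_window = aa_presence_vector(win),
       mutation = mutation,
       window_truncated = (idx - 5 < 1) || (idx + 5 > nrow(rt)))
}

## ---- secondary structure ----

dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

backbone_xyz <- function(model, resno, name) {
  at <- model$protein
  r <- at[at$resno == resno & at$elety == name, , drop = FALSE]
  if (!nrow(r)) return(NULL)
  as.numeric(r[1, c("x", "y", "z")])
}

#' Three-state secondary structure of a residue
#'
#' Backbone-dihedral assigner: phi/psi are computed from the previous and
#' next residues; helix (H) for phi in [-100, -30] and psi in [-80, -5],
#' strand (E) for phi in [-180, -45] and psi in [90, 180] or [-180, -150],
#' coil (C) otherwise.  Residues lacking a complete +/-1 backbone window are
#' assigned C with \code{known = FALSE}.
#'
#' @param model a \code{complex_model}.
#' @param pos residue number.
#' @return list(label = "H"|"E"|"C", known = logical, phi, psi).
#' @export
secondary_structure <- function(model, pos) {
  rt <- residue_table(model)
  i <- match(pos, rt$resno)
  unknown <- list(label = "C", known = FALSE, phi = NA_real_, psi = NA_real_)
  if (is.na(i) || i == 1 || i == nrow(rt)) return(unknown)
  prev <- rt$resno[i - 1]; nxt <- rt$resno[i + 1]
  Cm <- backbone_xyz(model, prev, "C")
  N0 <- backbone_xyz(model, pos, "N")
  CA0 <- backbone_xyz(model, pos, "CA")
  C0 <- backbone_xyz(model, pos, "C")
  Np <- backbone_xyz(model, nxt, "N")
  if (any(vapply(list(Cm, N0, CA0, C0, Np), is.null, logical(1)))) return(unknown)
  phi <- dihedral(Cm, N0, CA0, C0)
  psi <- dihedral(N0, CA0, C0, Np)
  label <- if (phi >= -100 && phi <= -30 && psi >= -80 && psi <= -5) "H"
  else if (phi >= -180 && phi <= -45 && (psi >= 90 || psi <= -150)) "E"
  else "C"
  list(label = label, known = TRUE, phi = phi, psi = psi)
}

## ---- stability surrogate ----

#' Stability change surrogate for a point mutation
#'
#' A documented heuristic standing behind the stability-backend interface:
#' \deqn{\Delta\Delta G = 0.4\,(h_{alt} - h_{wt})\,(1 - RSA_{wt}) -
#'       0.02\,|V_{alt} - V_{wt}|}
#' in kcal/mol, where h is the Kyte-Doolittle hydropathy, RSA the wild-type
#' relative solvent accessibility, and V the residue volume: burying a more
#' hydrophobic residue stabilises, while any volume mismatch in a packed
#' environment destabilises.  The category is STABLE for positive values,
#' UNSTABLE for negative ones and UNKNOWN when the backend cannot score.
#'
#' @param wt wild-type \code{complex_model}.
#' @param mutation an \code{aa_mutation}.
#' @param rsa_wt optional precomputed wild-type RSA (recomputed if NULL).
#' @param backend a function(wt, mutation, rsa_wt) returning a numeric ddG
#'   or NA; defaults to the surrogate above.
#' @param offset residue-number offset.
#' @return list(ddG, category) with category in STABLE/UNSTABLE/UNKNOWN.
#' @export
stability_change <- function(wt, mutation, rsa_wt = NULL, backend = NULL,
                             offset = 0) {
  if (is.null(backend)) {
    backend <- function(wt, mutation, rsa_wt) {
      if (is.null(rsa_wt) || is.na(rsa_wt)) {
        s <- residue_sasa(wt, mutation$protein_position + offset)
        rsa_wt <- s / MAX_ASA_TIEN[[mutation$ref_aa]]
      }
      dh <- KYTE_DOOLITTLE[[mutation$alt_aa]] - KYTE_DOOLITTLE[[mutation$ref_aa]]
      dv <- abs(RESIDUE_VOLUME[[mutation$alt_aa]] - RESIDUE_VOLUME[[mutation$ref_aa]])
      0.4 * dh * (1 - min(rsa_wt, 1)) - 0.02 * dv
    }
  }
  ddg <- try(backend(wt, mutation, rsa_wt), silent = TRUE)
  if (inherits(ddg, "try-error") || !length(ddg) || is.na(ddg))
    return(list(ddG = NA_real_, category = "UNKNOWN"))
  list(ddG = as.numeric(ddg),
       category = if (ddg >= 0) "STABLE" else "UNSTABLE")
}

## ---- conservation ----

#' Column conservation score from a multiple alignment
#'
#' Mean pairwise BLOSUM62 substitution score over all non-gap residues in
#' the column (all unordered pairs; a single-sequence column scores its
#' self-substitution).  Columns that are entirely gaps return NA.
#'
#' @param alignment character vector of aligned sequences (equal width) or a
#'   path to a FASTA alignment.
#' @param column 1-based column index.
#' @export
conservation_score <- function(alignment, column) {
  if (length(alignment) == 1 && file.exists(alignment)) {
    aln <- Biostrings::readAAStringSet(alignment)
    alignment <- as.character(aln)
  }
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1) stop("alignment sequences differ in width")
  if (column < 1 || column > widths[1]) stop("column outside alignment width")
  col <- toupper(substr(alignment, column, column))
  col <- col[col %in% AA1]
  if (!length(col)) return(NA_real_)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- get("BLOSUM62", envir = environment())
  n <- length(col)
  if (n == 1) return(unname(B[col, col]))
  tot <- 0; cnt <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + B[col[i], col[j]]; cnt <- cnt + 1
  }
  tot / cnt
}

## ---- structural alignment RMSD ----

#' Raw and refined RMSD between wild-type and mutant structures
#'
#' Shared heavy atoms (matched by chain, residue number and atom name) are
#' superposed by least squares; the raw RMSD is taken over all shared atoms.
#' The refined RMSD iteratively rejects atom pairs whose deviation exceeds
#' the mean + 2 standard deviations of the current deviations, re-superposes,
#' and repeats until no pair is rejected (or fewer than 3 atoms remain).
#'
#' @param wt,mt \code{complex_model}s.
#' @return c(raw =, refined =) in Angstrom.
#' @export
alignment_rmsd <- function(wt, mt) {
  a <- heavy(wt$protein); b <- heavy(mt$protein)
  ka <- paste(a$chain, a$resno, a$elety)
  kb <- paste(b$chain, b$resno, b$elety)
  shared <- intersect(ka, kb)
  if (length(shared) < 3) stop("fewer than 3 shared atoms between structures")
  xa <- atom_xyz(a[match(shared, ka), , drop = FALSE])
  xb <- atom_xyz(b[match(shared, kb), , drop = FALSE])
  fit <- kabsch_superpose(xb, xa)
  raw <- fit$rmsd
  keep <- seq_along(shared)
  repeat {
    f <- kabsch_superpose(xb[keep, , drop = FALSE], xa[keep, , drop = FALSE])
    dev <- sqrt(rowSums((f$xyz - xa[keep, , drop = FALSE])^2))
    cut <- mean(dev) + 2 * stats::sd(dev)
    bad <- dev > cut & dev > 1e-9
    if (!any(bad) || sum(!bad) < 3) {
      refined <- f$rmsd
      break
    }
    keep <- keep[!bad]
  }
  c(raw = raw, refined = refined)
}

## ---- ligand distances ----

#' CA-to-ligand distance features of a residue
#'
#' Min/max/mean distance from the residue's alpha carbon to all heavy ligand
#' atoms.
#' @param model a \code{complex_model}.
#' @param pos residue number.
#' @return c(min =, max =, mean =), NAs if CA absent.
#' @export
ligand_distance_features <- function(model, pos) {
  ca <- backbone_xyz(model, pos, "CA")
  lig <- heavy(model$ligand)
  if (is.null(ca) || !nrow(lig))
    return(c(min = NA_real_, max = NA_real_, mean = NA_real_))
  d <- sqrt(rowSums(sweep(atom_xyz(lig), 2, ca)^2))
  c(min = min(d), max = max(d), mean = mean(d))
}

## ---- charge & hydrophobicity ----

#' Charge vector and hydrophobicity change of an amino-acid mutation
#'
#' The 20-position charge vector carries each amino acid's formal side-chain
#' charge (-1 ASP/GLU, +1 LYS/ARG, 0 otherwise) at the wild-type and mutant
#' positions, 0 elsewhere.  The hydrophobicity delta is the Kyte-Doolittle
#' scale difference (mutant minus wild type).
#'
#' @param ref_aa,alt_aa one-letter codes.
#' @return list(charge = length-20 vector, dhydro = scalar).
#' @export
charge_hydrophobicity_features <- function(ref_aa, alt_aa) {
  stopifnot(ref_aa %in% AA1, alt_aa %in% AA1)
  v <- stats::setNames(rep(0, 20), AA1)
  v[ref_aa] <- AA_CHARGE[[ref_aa]]
  v[alt_aa] <- AA_CHARGE[[alt_aa]]
  list(charge = v, dhydro = KYTE_DOOLITTLE[[alt_aa]] - KYTE_DOOLITTLE[[ref_aa]])
}

## ---- salt bridges & disulfides ----

residue_charged_atoms <- function(at, kind = c("anion", "cation")) {
  kind <- match.arg(kind)
  groups <- if (kind == "anion") ANION_ATOMS else CATION_GROUPS[c("LYS", "ARG")]
  resid <- at$resid[1]
  nm <- groups[[resid]]
  if (is.null(nm)) return(at[0, , drop = FALSE])
  at[at$elety %in% nm, , drop = FALSE]
}

#' Salt-bridge features of a residue
#'
#' Protein-protein: the number of salt bridges involving the residue, i.e.
#' anionic-group oxygens of ASP/GLU within \code{cutoff} of cationic-group
#' nitrogens of LYS/ARG (counted per partner residue).  Protein-ligand: a
#' salt bridge between the residue's charged group and an oppositely charged
#' ligand group (see \code{\link{ligand_charged_groups}}), with distance and
#' group class.
#'
#' @param model a \code{complex_model}.
#' @param pos residue number.
#' @param cutoff upper bound in Angstrom (default 4.0).
#' @return list(pp_count, lig_present, lig_distance, lig_group,
#'   residue_role).
#' @export
salt_bridge_features <- function(model, pos, cutoff = 4.0) {
  at <- residue_atoms(model, pos)
  p <- model$protein
  pp_count <- 0
  for (kind in c("anion", "cation")) {
    mine <- residue_charged_atoms(at, kind)
    if (!nrow(mine)) next
    other_kind <- if (kind == "anion") "cation" else "anion"
    partners <- unique(p$resno[p$resno != pos])
    for (r in partners) {
      theirs <- residue_charged_atoms(p[p$resno == r, , drop = FALSE], other_kind)
      if (!nrow(theirs)) next
      d <- cross_dist(atom_xyz(mine), atom_xyz(theirs))
      if (min(d) <= cutoff) pp_count <- pp_count + 1
    }
  }
  lig_groups <- ligand_charged_groups(model)
  lig_present <- FALSE; lig_distance <- NA_real_; lig_group <- NA_character_
  role <- NA_character_
  for (kind in c("anion", "cation")) {
    mine <- residue_charged_atoms(at, kind)
    if (!nrow(mine)) next
    want <- if (kind == "anion") c("guanidine", "tert-amine", "quart-amine")
    else c("phosphate", "carboxylate")
    for (g in lig_groups) {
      if (!(g$class %in% want)) next
      d <- cross_dist(atom_xyz(mine), g$xyz)
      if (min(d) <= cutoff && (!lig_present || min(d) < lig_distance)) {
        lig_present <- TRUE; lig_distance <- min(d); lig_group <- g$class
        role <- kind
      }
    }
  }
  list(pp_count = pp_count, lig_present = lig_present,
       lig_distance = lig_distance, lig_group = lig_group, residue_role = role)
}

#' Disulfide-bond check for a residue
#'
#' TRUE iff the residue is a cysteine whose SG lies within [lo, hi] Angstrom
#' of another cysteine's SG.
#' @param model a \code{complex_model}.
#' @param pos residue number.
#' @param lo,hi distance window (default 1.8-2.2 Angstrom).
#' @export
disulfide_check <- function(model, pos, lo = 1.8, hi = 2.2) {
  at <- residue_atoms(model, pos)
  if (!nrow(at) || at$resid[1] != "CYS") return(FALSE)
  sg <- at[at$elety == "SG", , drop = FALSE]
  if (!nrow(sg)) return(FALSE)
  p <- model$protein
  others <- p[p$resid == "CYS" & p$elety == "SG" & p$resno != pos, , drop = FALSE]
  if (!nrow(others)) return(FALSE)
  d <- cross_dist(atom_xyz(sg), atom_xyz(others))
  any(d >= lo & d <= hi)
}
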