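## Amino-acid reference tables used across the feature extractors.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

AA3TO1 <- stats::setNames(names(AA3), unname(AA3))

#' Convert between one- and three-letter amino-acid codes
#' @param x character vector of codes.
#' @rdname aa_codes
#' @export
aa_three <- function(x) unname(AA3[x])

#' @rdname aa_codes
#' @export
aa_one <- function(x) unname(AA3TO1[toupper(x)])

## Kyte-Doolittle hydropathy scale.
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

## Tien et al. 2013 theoretical maximum accessible surface areas (Å^2),
## denominators of relative solvent accessibility.
MAX_ASA_TIEN <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223,
  G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
  P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174)

## Mean residue volumes (Å^3), used by the stability surrogate.
RESIDUE_VOLUME <- c(
  A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5, Q = 143.8,
  E = 138.4, G = 60.1, H = 153.2, I = 166.7, L = 166.7, K = 168.6,
  M = 162.9, F = 189.9, P = 112.7, S = 89.0, T = 116.1, W = 227.8,
  Y = 193.6, V = 140.0)

## Formal side-chain charge at physiological pH used by the 20-vector charge
## encoding: -1 for ASP/GLU, +1 for LYS/ARG, 0 otherwise.
AA_CHARGE <- c(
  A = 0, R = 1, N = 0, D = -1, C = 0, Q = 0, E = -1, G = 0, H = 0, I = 0,
  L = 0, K = 1, M = 0, F = 0, P = 0, S = 0, T = 0, W = 0, Y = 0, V = 0)

## Van der Waals radii (Å) for the surface-area integrator.
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
VDW_DEFAULT <- 1.70

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- VDW_DEFAULT
  unname(r)
}

## Side-chain heavy-atom graph templates for the graft modelling backend:
## each atom names its parent (the atom it is bonded to).  Backbone atoms
## N/CA/C/O are implicit; CB's parent is CA.
SIDECHAIN_TREE <- list(
  G = character(0),
  A = c(CB = "CA"),
  S = c(CB = "CA", OG = "CB"),
  C = c(CB = "CA", SG = "CB"),
  T = c(CB = "CA", OG1 = "CB", CG2 = "CB"),
  V = c(CB = "CA", CG1 = "CB", CG2 = "CB"),
  L = c(CB = "CA", CG = "CB", CD1 = "CG", CD2 = "CG"),
  I = c(CB = "CA", CG1 = "CB", CG2 = "CB", CD1 = "CG1"),
  M = c(CB = "CA", CG = "CB", SD = "CG", CE = "SD"),
  P = c(CB = "CA", CG = "CB", CD = "CG"),
  F = c(CB = "CA", CG = "CB", CD1 = "CG", CD2 = "CG", CE1 = "CD1",
        CE2 = "CD2", CZ = "CE1"),
  Y = c(CB = "CA", CG = "CB", CD1 = "CG", CD2 = "CG", CE1 = "CD1",
        CE2 = "CD2", CZ = "CE1", OH = "CZ"),
  W = c(CB = "CA", CG = "CB", CD1 = "CG", CD2 = "CG", NE1 = "CD1",
        CE2 = "CD2", CE3 = "CD2", CZ2 = "CE2", CZ3 = "CE3", CH2 = "CZ2"),
  H = c(CB = "CA", CG = "CB", ND1 = "CG", CD2 = "CG", CE1 = "ND1",
        NE2 = "CD2"),
  K = c(CB = "CA", CG = "CB", CD = "CG", CE = "CD", NZ = "CE"),
  R = c(CB = "CA", CG = "CB", CD = "CG", NE = "CD", CZ = "NE",
        NH1 = "CZ", NH2 = "CZ"),
  D = c(CB = "CA", CG = "CB", OD1 = "CG", OD2 = "CG"),
  E = c(CB = "CA", CG = "CB", CD = "CG", OE1 = "CD", OE2 = "CD"),
  N = c(CB = "CA", CG = "CB", OD1 = "CG", ND2 = "CG"),
  Q = c(CB = "CA", CG = "CB", CD = "CG", OE1 = "CD", NE2 = "CD"))

## Aromatic-ring heavy atoms per residue type (six-membered ring used for
## tryptophan) for pi-stacking / pi-cation detection.
AROMATIC_RINGS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))

## Cationic side-chain groups (atoms defining the charge centre).
CATION_GROUPS <- list(LYS = "NZ", ARG = c("CZ", "NH1", "NH2", "NE"),
                      HIS = c("CE1", "ND1", "NE2"))

## Anionic side-chain oxygens.
ANION_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

## Element symbol from a PDB atom name (first non-digit character run; two
## letter elements recognised from the standard set).
element_from_name <- function(name) {
  vapply(name, function(nm) {
    nm <- gsub("[0-9'\"]", "", toupper(nm))
    if (nchar(nm) >= 2 && substr(nm, 1, 2) %in% c("CL", "BR", "SE", "FE", "ZN", "MG"))
      return(substr(nm, 1, 2))
    substr(nm, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}
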