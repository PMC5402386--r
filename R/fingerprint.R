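## Protein-ligand interaction fingerprints: halogen bonds, pi-stacking,
## pi-cation, water bridges and hydrophobic contacts, plus the ligand-side
## chemistry perception (bonds from distances, charged-group and
## aromatic-ring detection) they rely on.  The geometric thresholds are the
## published defaults of the standard profiler family, pinned here and
## configurable.

#' Default interaction-fingerprint thresholds
#' @export
FINGERPRINT_DEFAULTS <- list(
  halogen_dist = 4.0, halogen_angle = 140,
  pistack_dist = 5.5, pistack_parallel = 30, pistack_tshape = c(60, 90),
  pication_dist = 6.0,
  water_bridge_dist = 3.6,
  hydrophobic_dist = 4.0)

## Covalent bonds inferred from interatomic distances (heavy atoms).
infer_bonds <- function(at, scale = 1.25) {
  at <- heavy(at)
  n <- nrow(at)
  if (n < 2) return(cbind(integer(0), integer(0)))
  xyz <- atom_xyz(at)
  cov <- c(C = 0.77, N = 0.75, O = 0.73, S = 1.02, P = 1.06, F = 0.71,
           CL = 0.99, BR = 1.14, I = 1.33)
  r <- cov[at$element]; r[is.na(r)] <- 0.77
  d <- cross_dist(xyz, xyz)
  lim <- outer(r, r, "+") * scale
  hit <- which(d < lim & upper.tri(d), arr.ind = TRUE)
  hit
}

#' Charged functional groups of the ligand
#'
#' Classifies ligand groups from distance-inferred connectivity:
#' phosphate (P bonded to >=3 O), carboxylate (C bonded to exactly 2 O, no
#' N), guanidine (C bonded to 3 N), quart-amine (N bonded to 4 C),
#' tert-amine (N bonded to 3 C).
#'
#' @param model a \code{complex_model}.
#' @return List of groups: list(class, atoms, xyz).
#' @export
ligand_charged_groups <- function(model) {
  lig <- heavy(model$ligand)
  if (!nrow(lig)) return(list())
  bonds <- infer_bonds(lig)
  nb <- function(i) {
    j <- c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
    lig$element[j]
  }
  groups <- list()
  for (i in seq_len(nrow(lig))) {
    el <- lig$element[i]
    neigh <- nb(i)
    cls <- NULL
    if (el == "P" && sum(neigh == "O") >= 3) cls <- "phosphate"
    if (el == "C" && sum(neigh == "O") == 2 && sum(neigh == "N") == 0)
      cls <- "carboxylate"
    if (el == "C" && sum(neigh == "N") == 3) cls <- "guanidine"
    if (el == "N" && sum(neigh == "C") == 4) cls <- "quart-amine"
    if (el == "N" && sum(neigh == "C") == 3) cls <- "tert-amine"
    if (!is.null(cls)) {
      j <- c(i, c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1]))
      groups <- c(groups, list(list(class = cls, atoms = lig$elety[j],
                                    xyz = atom_xyz(lig[j, , drop = FALSE]))))
    }
  }
  groups
}

## Planarity check: max deviation of ring atoms from their best-fit plane.
ring_planarity <- function(xyz) {
  c0 <- sweep(xyz, 2, colMeans(xyz))
  s <- svd(c0)
  max(abs(c0 %*% s$v[, 3]))
}

ring_normal <- function(xyz) {
  c0 <- sweep(xyz, 2, colMeans(xyz))
  svd(c0)$v[, 3]
}

#' Aromatic rings of the ligand
#'
#' Perceives planar 5- and 6-membered C/N cycles from distance-inferred
#' connectivity; an optional annotation overrides perception.
#'
#' @param model a \code{complex_model}.
#' @param annotation optional list of character vectors of ligand atom names
#'   forming rings (overrides perception).
#' @param planarity_tol maximum out-of-plane deviation (Angstrom).
#' @return List of rings: list(atoms, centroid, normal).
#' @export
ligand_aromatic_rings <- function(model, annotation = NULL, planarity_tol = 0.35) {
  lig <- heavy(model$ligand)
  if (!is.null(annotation)) {
    return(lapply(annotation, function(nms) {
      xyz <- atom_xyz(lig[match(nms, lig$elety), , drop = FALSE])
      list(atoms = nms, centroid = colMeans(xyz), normal = ring_normal(xyz))
    }))
  }
  ring_ok <- lig$element %in% c("C", "N")
  bonds <- infer_bonds(lig)
  keep <- ring_ok[bonds[, 1]] & ring_ok[bonds[, 2]]
  bonds <- bonds[keep, , drop = FALSE]
  if (!nrow(bonds)) return(list())
  g <- igraph::graph_from_edgelist(cbind(bonds[, 1], bonds[, 2]), directed = FALSE)
  if (igraph::vcount(g) < nrow(lig))
    g <- igraph::add_vertices(g, nrow(lig) - igraph::vcount(g))
  rings <- list()
  seen <- character(0)
  for (n in c(5, 6)) {
    iso <- igraph::subgraph_isomorphisms(igraph::make_ring(n), g, induced = TRUE)
    for (m in iso) {
      idx <- sort(as.integer(m))
      key <- paste(idx, collapse = "-")
      if (key %in% seen) next
      seen <- c(seen, key)
      xyz <- atom_xyz(lig[idx, , drop = FALSE])
      if (ring_planarity(xyz) > planarity_tol) next
      rings <- c(rings, list(list(atoms = lig$elety[idx],
                                  centroid = colMeans(xyz),
                                  normal = ring_normal(xyz))))
    }
  }
  rings
}

## Aromatic rings of a residue (named-atom based, crystal geometry).
residue_aromatic_rings <- function(at) {
  nm <- AROMATIC_RINGS[[at$resid[1]]]
  if (is.null(nm)) return(list())
  rows <- match(nm, at$elety)
  if (anyNA(rows)) return(list())
  xyz <- atom_xyz(at[rows, , drop = FALSE])
  list(list(atoms = nm, centroid = colMeans(xyz), normal = ring_normal(xyz)))
}

residue_cation_centres <- function(at) {
  nm <- CATION_GROUPS[[at$resid[1]]]
  if (is.null(nm)) return(NULL)
  rows <- match(nm, at$elety)
  rows <- rows[!is.na(rows)]
  if (!length(rows)) return(NULL)
  colMeans(atom_xyz(at[rows, , drop = FALSE]))
}

## Apolar carbons: carbons not covalently bonded to N or O.
apolar_carbons <- function(at) {
  at <- heavy(at)
  if (!nrow(at)) return(at)
  bonds <- infer_bonds(at)
  polar_neighbour <- rep(FALSE, nrow(at))
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    if (at$element[j] %in% c("N", "O")) polar_neighbour[i] <- TRUE
    if (at$element[i] %in% c("N", "O")) polar_neighbour[j] <- TRUE
  }
  at[at$element == "C" & !polar_neighbour, , drop = FALSE]
}

#' Interaction fingerprint between a residue and the ligand
#'
#' Per-type presence, distance and participating groups for: halogen bonds
#' (ligand C-X donor to residue N/O acceptor, distance <= 4.0 Angstrom and
#' C-X...A angle >= 140 degrees), pi-stacking (ring centroids <= 5.5
#' Angstrom with planes parallel within 30 degrees or perpendicular within
#' 60-90 degrees), pi-cation (centroid-cation <= 6.0 Angstrom, both
#' directions), water bridges (a water oxygen within 3.6 Angstrom of both a
#' residue and a ligand polar atom), and hydrophobic contacts (apolar
#' carbon pairs <= 4.0 Angstrom).
#'
#' @param model a \code{complex_model}.
#' @param pos residue number.
#' @param thresholds override entries of \code{FINGERPRINT_DEFAULTS}.
#' @param ring_annotation optional ligand ring annotation (see
#'   \code{\link{ligand_aromatic_rings}}).
#' @return An \code{interaction_fingerprint}: named list per type with
#'   \code{present}, \code{distance}, \code{groups}.
#' @export
ligand_interaction_fingerprint <- function(model, pos, thresholds = list(),
                                           ring_annotation = NULL) {
  th <- utils::modifyList(FINGERPRINT_DEFAULTS, thresholds)
  res <- heavy(residue_atoms(model, pos))
  lig <- heavy(model$ligand)
  none <- list(present = FALSE, distance = NA_real_, groups = NA_character_)
  fp <- list(halogen = none, pi_stacking = none, pi_cation = none,
             water_bridge = none, hydrophobic = none)

  ## halogen bonds: ligand halogen X bonded to carbon, residue N/O acceptor
  hal_idx <- which(lig$element %in% c("CL", "BR", "I", "F"))
  acc <- res[res$element %in% c("N", "O"), , drop = FALSE]
  if (length(hal_idx) && nrow(acc)) {
    bonds <- infer_bonds(lig)
    best <- Inf; best_groups <- NA_character_
    for (i in hal_idx) {
      partners <- c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
      cpart <- partners[lig$element[partners] == "C"]
      if (!length(cpart)) next
      X <- as.numeric(lig[i, c("x", "y", "z")])
      Cat <- as.numeric(lig[cpart[1], c("x", "y", "z")])
      for (j in seq_len(nrow(acc))) {
        A <- as.numeric(acc[j, c("x", "y", "z")])
        dXA <- vnorm(X - A)
        if (dXA <= th$halogen_dist && vangle(Cat, X, A) >= th$halogen_angle &&
            dXA < best) {
          best <- dXA
          best_groups <- paste0(lig$elety[i], "...", acc$elety[j])
        }
      }
    }
    if (is.finite(best))
      fp$halogen <- list(present = TRUE, distance = best, groups = best_groups)
  }

  ## pi-stacking
  rrings <- residue_aromatic_rings(res)
  lrings <- ligand_aromatic_rings(model, annotation = ring_annotation)
  for (rr in rrings) for (lr in lrings) {
    d <- vnorm(rr$centroid - lr$centroid)
    if (d > th$pistack_dist) next
    ang <- acos(min(1, abs(sum(vunit(rr$normal) * vunit(lr$normal))))) * 180 / pi
    mode <- if (ang <= th$pistack_parallel) "parallel"
    else if (ang >= th$pistack_tshape[1] && ang <= th$pistack_tshape[2]) "t-shaped"
    else NA
    if (!is.na(mode) && (!fp$pi_stacking$present || d < fp$pi_stacking$distance))
      fp$pi_stacking <- list(present = TRUE, distance = d, groups = mode)
  }

  ## pi-cation, both directions
  rcat <- residue_cation_centres(res)
  lig_groups <- ligand_charged_groups(model)
  lcat <- lapply(Filter(function(g) g$class %in% c("guanidine", "tert-amine", "quart-amine"),
                        lig_groups), function(g) colMeans(g$xyz))
  cand <- list()
  for (lr in lrings) if (!is.null(rcat))
    cand <- c(cand, list(c(vnorm(lr$centroid - rcat), "ligand-ring/residue-cation")))
  for (rr in rrings) for (ct in lcat)
    cand <- c(cand, list(c(vnorm(rr$centroid - ct), "residue-ring/ligand-cation")))
  for (cc in cand) {
    d <- as.numeric(cc[1])
    if (d <= th$pication_dist && (!fp$pi_cation$present || d < fp$pi_cation$distance))
      fp$pi_cation <- list(present = TRUE, distance = d, groups = cc[2])
  }

  ## water bridges
  wat <- model$water[model$water$element == "O", , drop = FALSE]
  rp <- res[polar_sel(res), , drop = FALSE]
  lp <- lig[polar_sel(lig), , drop = FALSE]
  if (nrow(wat) && nrow(rp) && nrow(lp)) {
    dw_r <- cross_dist(atom_xyz(wat), atom_xyz(rp))
    dw_l <- cross_dist(atom_xyz(wat), atom_xyz(lp))
    for (w in seq_len(nrow(wat))) {
      if (min(dw_r[w, ]) <= th$water_bridge_dist &&
          min(dw_l[w, ]) <= th$water_bridge_dist) {
        d <- max(min(dw_r[w, ]), min(dw_l[w, ]))
        if (!fp$water_bridge$present || d < fp$water_bridge$distance)
          fp$water_bridge <- list(present = TRUE, distance = d,
                                  groups = paste0(rp$elety[which.min(dw_r[w, ])],
                                                  "/HOH/",
                                                  lp$elety[which.min(dw_l[w, ])]))
      }
    }
  }

  ## hydrophobic contacts
  rc <- apolar_carbons(res); lc <- apolar_carbons(lig)
  if (nrow(rc) && nrow(lc)) {
    d <- cross_dist(atom_xyz(rc), atom_xyz(lc))
    if (min(d) <= th$hydrophobic_dist)
      fp$hydrophobic <- list(present = TRUE, distance = min(d),
                             groups = "C...C")
  }
  structure(fp, class = "interaction_fingerprint")
}
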