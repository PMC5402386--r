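## Mutant structural model generation.  The default "graft" backend replaces
## the side chain of the mutated residue with an idealized one grown from the
## unchanged backbone: the backbone (and every other residue) is untouched,
## which keeps backbone RMSD between wild type and mutant exactly zero.  An
## external-command backend hook is provided for comparative-modelling
## engines.

BOND_CC <- 1.52
BOND_CS <- 1.81
BOND_RING <- 1.39

## Idealized CB position from backbone N, CA, C (tetrahedral geometry).
place_cb <- function(N, CA, C) {
  n <- vunit(N - CA); c <- vunit(C - CA)
  bis <- vunit(n + c)
  perp <- vunit(vcross(n, c))
  CA + 1.526 * (sqrt(1 / 3) * (-bis) + sqrt(2 / 3) * perp)
}

## Planar regular ring of `n` atoms starting at `start`, grown in the plane
## spanned by dir (start -> ring) and ref.
place_ring <- function(start, dir, ref, n) {
  r <- BOND_RING / (2 * sin(pi / n))
  centre <- start + dir * r
  e1 <- vunit(start - centre)
  e2 <- vunit(ref - sum(ref * e1) * e1)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  t(vapply(ang, function(a) centre + r * (cos(a) * e1 + sin(a) * e2),
           numeric(3)))
}

## Grow an idealized side chain for one-letter amino acid `aa` from backbone
## coordinates.  Returns a matrix of heavy-atom coordinates with rownames =
## atom names (possibly 0 rows for glycine).
ideal_sidechain <- function(aa, N, CA, C) {
  tree <- SIDECHAIN_TREE[[aa]]
  if (!length(tree)) return(matrix(numeric(0), ncol = 3,
                                   dimnames = list(NULL, c("x", "y", "z"))))
  coords <- list(N = N, CA = CA, C = C)
  coords$CB <- place_cb(N, CA, C)
  perp <- vunit(vcross(vunit(N - CA), vunit(C - CA)))

  if (aa %in% c("F", "Y", "H", "W")) {
    ## aromatic residues: CG along CB extension, then planar ring(s)
    dir <- vunit(coords$CB - CA)
    coords$CG <- coords$CB + BOND_CC * dir
    ring_names <- switch(aa,
      F = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
      Y = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
      H = c("CG", "ND1", "CE1", "NE2", "CD2"),
      W = c("CG", "CD1", "NE1", "CE2", "CD2"))
    ring <- place_ring(coords$CG, dir, perp, length(ring_names))
    for (i in seq_along(ring_names)) coords[[ring_names[i]]] <- ring[i, ]
    if (aa == "Y")
      coords$OH <- coords$CZ + 1.36 * vunit(coords$CZ - coords$CG)
    if (aa == "W") {
      ## fused six-membered ring grown off the CE2-CD2 edge
      edge_mid <- (coords$CE2 + coords$CD2) / 2
      pent_centre <- Reduce(`+`, coords[ring_names]) / length(ring_names)
      out_dir <- vunit(edge_mid - pent_centre)
      hex <- place_ring(coords$CE2, out_dir, perp, 6)
      hex_names <- c("CE2b", "CZ2", "CH2", "CZ3", "CE3", "CD2b")
      for (i in 2:5) coords[[hex_names[i]]] <- hex[i, ]
    }
    keep <- names(SIDECHAIN_TREE[[aa]])
    out <- do.call(rbind, coords[keep])
    rownames(out) <- keep
    return(out)
  }

  ## aliphatic / polar chains: zig-zag growth along the parent-grandparent
  ## axis, branches fanned around the parent bond
  parent_of <- c(tree, CB = "CA")
  grandparent <- function(atom) parent_of[[parent_of[[atom]]]] %||% "CA"
  children_seen <- list()
  for (atom in names(tree)) {
    if (atom == "CB") next
    par <- tree[[atom]]
    gp <- if (par == "CB") "CA" else parent_of[[par]]
    axis <- vunit(coords[[par]] - coords[[gp]])
    k <- length(children_seen[[par]] %||% character(0))
    children_seen[[par]] <- c(children_seen[[par]], atom)
    ## ~109.5 deg from the incoming bond, alternating/fanning branches
    bend_axis <- vunit(vcross(axis, perp + 1e-3))
    dir <- as.numeric(rotation_matrix(bend_axis, 70.5) %*% axis)
    if (k > 0)
      dir <- as.numeric(rotation_matrix(axis, 120 * k) %*% dir)
    len <- if (grepl("^S", atom) || grepl("^S", par)) BOND_CS else BOND_CC
    coords[[atom]] <- coords[[par]] + len * dir
  }
  keep <- names(tree)
  out <- do.call(rbind, coords[keep])
  rownames(out) <- keep
  out
}

#' Build a mutant structural model
#'
#' The default \code{"graft"} backend removes the side chain of the mutated
#' residue and grafts an idealized side chain of the target amino acid onto
#' the unchanged backbone; no other atom of the structure moves.  An
#' \code{"external"} backend shells out to a user-supplied command (a hook
#' for comparative-modelling engines) which must read a WT PDB and a mutation
#' spec and write a mutant PDB.
#'
#' @param model wild-type \code{complex_model}.
#' @param spec an \code{aa_mutation} (only position/ref_aa/alt_aa are used).
#' @param backend \code{"graft"} (default) or \code{"external"}.
#' @param offset residue-number offset (structure resno = protein position +
#'   offset).
#' @param chain chain of the mutated residue (default: first chain carrying
#'   that residue number).
#' @param external_cmd for the external backend: \code{function(wt_pdb_path,
#'   spec, out_pdb_path)} invoking the engine.
#' @return A \code{mutant_model}: list(spec, structure = complex_model,
#'   backend).
#' @export
build_mutant_model <- function(model, spec, backend = c("graft", "external"),
                               offset = 0, chain = NULL, external_cmd = NULL) {
  backend <- match.arg(backend)
  stopifnot(inherits(model, "complex_model"), inherits(spec, "aa_mutation"))
  resno <- spec$protein_position + offset
  at <- residue_atoms(model, resno, chain)
  if (!nrow(at)) stop("residue ", resno, " not present in the structure")
  chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  cur_aa <- aa_one(at$resid[1])
  if (!identical(cur_aa, spec$ref_aa))
    stop("reference mismatch at residue ", resno, ": structure has ", cur_aa,
         ", mutation spec expects ", spec$ref_aa)
  if (identical(spec$alt_aa, cur_aa))
    stop("alt_aa equals the structure's residue type: not a mutation")

  if (backend == "external") {
    if (!is.function(external_cmd))
      stop("external backend requires an `external_cmd` function")
    wt_path <- tempfile(fileext = ".pdb"); mt_path <- tempfile(fileext = ".pdb")
    write_complex_pdb(model, wt_path)
    ok <- try(external_cmd(wt_path, spec, mt_path), silent = TRUE)
    if (inherits(ok, "try-error") || !file.exists(mt_path))
      stop("external modelling backend failed for ", mutation_label(spec),
           ": ", if (inherits(ok, "try-error")) conditionMessage(attr(ok, "condition")) else "no output")
    structure(list(spec = spec, structure = load_complex(mt_path, model$ligand_id),
                   backend = "external"), class = "mutant_model")
  } else {
    bb_names <- c("N", "CA", "C", "O", "OXT")
    bb <- at[at$elety %in% bb_names, , drop = FALSE]
    need <- c("N", "CA", "C")
    if (!all(need %in% bb$elety))
      stop("incomplete backbone at residue ", resno)
    getxyz <- function(nm) as.numeric(bb[bb$elety == nm, c("x", "y", "z")][1, ])
    sc <- ideal_sidechain(spec$alt_aa, getxyz("N"), getxyz("CA"), getxyz("C"))
    new_res <- bb
    new_res$resid <- aa_three(spec$alt_aa)
    if (nrow(sc)) {
      extra <- bb[rep(1, nrow(sc)), , drop = FALSE]
      extra$elety <- rownames(sc)
      extra$element <- element_from_name(rownames(sc))
      extra[, c("x", "y", "z")] <- sc
      extra$resid <- aa_three(spec$alt_aa)
      extra$o <- 1; extra$b <- 0
      new_res <- rbind(new_res, extra)
    }
    p <- model$protein
    sel <- p$chain == chain & p$resno == resno
    before <- p[seq_len(nrow(p)) < which(sel)[1], , drop = FALSE]
    after <- p[seq_len(nrow(p)) > max(which(sel)), , drop = FALSE]
    prot <- rbind(before, new_res, after)
    prot$eleno <- seq_len(nrow(prot))
    mt <- model
    mt$protein <- prot
    mt$source <- paste0(model$source, "+", mutation_label(spec))
    structure(list(spec = spec, structure = mt, backend = "graft"),
              class = "mutant_model")
  }
}

#' @export
print.mutant_model <- function(x, ...) {
  cat(sprintf("<mutant_model %s (%s backend)>\n", mutation_label(x$spec), x$backend))
  invisible(x)
}
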