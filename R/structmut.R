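## Protein-ligand complex handling: loading PDB complexes, defining the drug
## binding site by a ligand-distance cutoff, enumerating the SNV-reachable
## binding-site mutants, and exporting per-residue scores for 3D rendering.

#' Construct a complex model from an atom table
#'
#' @param atoms data.frame with columns \code{type} ("ATOM"/"HETATM"),
#'   \code{eleno}, \code{elety} (atom name), \code{resid} (3-letter residue
#'   name), \code{chain}, \code{resno}, \code{x,y,z}, \code{o}, \code{b},
#'   \code{element}.
#' @param ligand_id residue name of the ligand heteroatom group.
#' @param source free-text provenance label.
#' @return A \code{complex_model} with \code{$protein}, \code{$ligand} and
#'   \code{$water} atom tables.
#' @export
complex_model <- function(atoms, ligand_id, source = "in-memory") {
  req <- c("type", "eleno", "elety", "resid", "chain", "resno",
           "x", "y", "z", "o", "b", "element")
  stopifnot(is.data.frame(atoms), all(req %in% names(atoms)))
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  water <- atoms[atoms$resid %in% c("HOH", "WAT", "H2O"), , drop = FALSE]
  lig <- atoms[atoms$type == "HETATM" & atoms$resid == ligand_id, , drop = FALSE]
  prot <- atoms[atoms$type == "ATOM" & atoms$resid %in% names(AA3TO1), , drop = FALSE]
  if (nrow(lig) == 0) {
    het <- unique(atoms$resid[atoms$type == "HETATM" &
                                !atoms$resid %in% c("HOH", "WAT", "H2O")])
    stop("ligand '", ligand_id, "' not found; heteroatom groups present: ",
         if (length(het)) paste(het, collapse = ", ") else "(none)")
  }
  key <- paste(prot$chain, prot$resno)
  if (anyDuplicated(unique(data.frame(key, prot$resid))$key))
    stop("duplicated residue numbering within a chain")
  structure(list(protein = prot, ligand = lig, water = water,
                 ligand_id = ligand_id, source = source),
            class = "complex_model")
}

#' @export
print.complex_model <- function(x, ...) {
  cat(sprintf("<complex_model %s: %d residues, ligand %s (%d atoms), %d waters>\n",
              x$source, nrow(residue_table(x)), x$ligand_id, nrow(x$ligand),
              length(unique(x$water$resno))))
  invisible(x)
}

#' Load a protein-ligand complex from a PDB file
#'
#' Keeps protein ATOM records (alternate locations: blank or 'A'; highest
#' occupancy on tie), the named ligand heteroatom group, and crystallographic
#' waters (retained separately for water-bridge detection).
#'
#' @param path PDB file.
#' @param ligand_id heteroatom residue name of the co-crystallized ligand.
#' @export
load_complex <- function(path, ligand_id) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  keep_alt <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep_alt, , drop = FALSE]
  element <- at$elesy
  bad <- is.na(element) | element == ""
  element[bad] <- element_from_name(at$elety[bad])
  atoms <- data.frame(type = at$type, eleno = at$eleno, elety = at$elety,
                      resid = at$resid, chain = ifelse(is.na(at$chain), "A", at$chain),
                      resno = at$resno, x = at$x, y = at$y, z = at$z,
                      o = ifelse(is.na(at$o), 1, at$o),
                      b = ifelse(is.na(at$b), 0, at$b),
                      element = toupper(element), stringsAsFactors = FALSE)
  complex_model(atoms, ligand_id, source = basename(path))
}

#' Write a complex model to a PDB file
#' @param model a \code{complex_model}.
#' @param path output file.
#' @export
write_complex_pdb <- function(model, path) {
  at <- rbind(model$protein, model$ligand, model$water)
  bio3d::write.pdb(file = path,
                   type = at$type, eleno = at$eleno, elety = at$elety,
                   resid = at$resid, chain = at$chain, resno = at$resno,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   o = at$o, b = at$b, elesy = at$element)
  invisible(path)
}

#' Residue table of a complex model
#' @param model a \code{complex_model}.
#' @return data.frame(chain, resno, resid, aa) in order of appearance.
#' @export
residue_table <- function(model) {
  p <- model$protein
  key <- paste(p$chain, p$resno)
  idx <- !duplicated(key)
  data.frame(chain = p$chain[idx], resno = p$resno[idx], resid = p$resid[idx],
             aa = aa_one(p$resid[idx]), stringsAsFactors = FALSE)
}

residue_atoms <- function(model, resno, chain = NULL) {
  p <- model$protein
  sel <- p$resno == resno
  if (!is.null(chain)) sel <- sel & p$chain == chain
  p[sel, , drop = FALSE]
}

atom_xyz <- function(at) as.matrix(at[, c("x", "y", "z"), drop = FALSE])

heavy <- function(at) at[at$element != "H", , drop = FALSE]

#' Define the drug binding site of a complex
#'
#' The binding site is the set of residues with at least one atom within
#' \code{cutoff} of any ligand atom.  Heavy atoms only by default
#' (hydrogens are typically absent from crystal structures).
#'
#' @param model a \code{complex_model}.
#' @param cutoff distance cutoff in Angstrom (default 9.5).
#' @param heavy_only ignore hydrogens (default TRUE).
#' @return A \code{binding_site}: list(residues = data.frame(chain, resno,
#'   resid, aa, min_dist), cutoff).
#' @export
define_binding_site <- function(model, cutoff = 9.5, heavy_only = TRUE) {
  prot <- if (heavy_only) heavy(model$protein) else model$protein
  lig <- if (heavy_only) heavy(model$ligand) else model$ligand
  d <- cross_dist(atom_xyz(prot), atom_xyz(lig))
  min_by_atom <- apply(d, 1, min)
  key <- paste(prot$chain, prot$resno)
  min_by_res <- tapply(min_by_atom, key, min)
  rt <- residue_table(model)
  rt$min_dist <- as.numeric(min_by_res[paste(rt$chain, rt$resno)])
  res <- rt[!is.na(rt$min_dist) & rt$min_dist <= cutoff, , drop = FALSE]
  rownames(res) <- NULL
  structure(list(residues = res, cutoff = cutoff), class = "binding_site")
}

#' @export
print.binding_site <- function(x, ...) {
  cat(sprintf("<binding_site: %d residues within %.1f A of the ligand>\n",
              nrow(x$residues), x$cutoff))
  invisible(x)
}

#' Enumerate SNV-reachable missense mutants of a binding site
#'
#' Maps each site residue to its CDS protein position via
#' \code{cds_position = resno - offset} and unions the per-codon missense
#' enumerations.  Stop-gained changes are never produced (no structural
#' models are built for truncations).  Residues that do not map onto the CDS
#' or whose CDS amino acid disagrees with the structure are skipped and
#' listed in the \code{"skipped"} attribute rather than raising an error.
#'
#' @param site a \code{binding_site}.
#' @param cds a \code{coding_sequence}.
#' @param offset residue-number offset so that \code{resno - offset} is the
#'   1-based CDS protein position (0 when the construct starts at residue 1).
#' @return List of \code{aa_mutation} with attributes \code{skipped}
#'   (data.frame of unmapped residues) and \code{n} (count).
#' @export
enumerate_binding_site_mutants <- function(site, cds, offset = 0) {
  stopifnot(inherits(site, "binding_site"), inherits(cds, "coding_sequence"))
  out <- list()
  skipped <- data.frame(chain = character(0), resno = integer(0),
                        reason = character(0), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(site$residues))) {
    r <- site$residues[k, ]
    pos <- r$resno - offset
    if (is.na(pos) || pos < 1 || pos > cds$n_codons) {
      skipped <- rbind(skipped, data.frame(chain = r$chain, resno = r$resno,
                                           reason = "outside CDS"))
      next
    }
    cds_aa <- translate_codon(codon_at(cds, pos))
    if (!identical(cds_aa, r$aa)) {
      skipped <- rbind(skipped, data.frame(
        chain = r$chain, resno = r$resno,
        reason = sprintf("CDS has %s, structure has %s", cds_aa, r$aa)))
      next
    }
    out <- c(out, enumerate_missense_snvs(cds, pos))
  }
  attr(out, "skipped") <- skipped
  attr(out, "n") <- length(out)
  out
}

#' Export per-residue scores into the B-factor column of a PDB file
#'
#' Overwrites every atom's B-factor with its residue's score (clipped to the
#' PDB field range [-99.99, 999.99]); residues without a score get 0.00.
#' Realizes 3D score mapping for molecular viewers.
#'
#' @param model a \code{complex_model}.
#' @param scores numeric vector named by residue number (single chain) or by
#'   \code{"chain:resno"}.
#' @param path output PDB path.
#' @export
export_residue_scores_to_bfactor <- function(model, scores, path) {
  p <- model$protein
  keys2 <- paste0(p$chain, ":", p$resno)
  keys1 <- as.character(p$resno)
  lookup <- function(nm) if (grepl(":", nm, fixed = TRUE)) keys2 else keys1
  b <- rep(0, nrow(p))
  if (length(scores)) {
    if (is.null(names(scores))) stop("scores must be a named vector")
    for (nm in names(scores)) {
      hit <- lookup(nm) == nm
      if (!any(hit)) stop("score key '", nm, "' matches no residue")
      b[hit] <- scores[[nm]]
    }
  }
  b <- pmin(pmax(b, -99.99), 999.99)
  model$protein$b <- b
  model$ligand$b <- 0
  if (nrow(model$water)) model$water$b <- 0
  write_complex_pdb(model, path)
}
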