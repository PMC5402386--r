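## Seeded synthetic-fixture generation.  The generators produce fully
## self-contained inputs carrying the statistical and geometric structure
## the other modules assume: valid 96-context signature catalogs with
## exposure profiles, matched toy CDS + complex pairs with ligand atoms at
## scripted distances, boundary-geometry structures that flip each detector
## exactly at its cutoff, and training tables with a class-separating signal
## planted in physically meaningful features (ligand distances, hydrogen
## bonding) so that feature extraction itself is on the test path.
## Regeneration with the same seed is byte-identical.

fixture_seed <- function(seed, salt) (as.integer(seed) + salt) %% .Machine$integer.max

#' Generate a toy mutational-signature catalog with exposure profiles
#'
#' Writes a COSMIC-layout TSV of \code{n_signatures} signatures (ids
#' "1".."n"), each a random distribution over the 96 pyrimidine contexts,
#' plus two exposure profiles with distinct weights.  The last signature is
#' designated strand-biased so the purine-zeroing path is exercised.
#'
#' @param n_signatures number of signatures (>= 1).
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return list(catalog, exposures (two paths), ids, biased_id).
#' @export
make_toy_signature_catalog <- function(n_signatures = 3, seed = 1,
                                       dir = tempfile("sigcat")) {
  stopifnot(n_signatures >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(fixture_seed(seed, 101))
  ids <- as.character(seq_len(n_signatures))
  probs <- vapply(ids, function(id) {
    x <- stats::rexp(96)
    x / sum(x)
  }, numeric(96))
  catalog <- file.path(dir, "catalog.tsv")
  header <- paste(c("context", paste0("Signature.", ids)), collapse = "\t")
  rows <- vapply(seq_len(96), function(r)
    paste(c(PYRIMIDINE_CONTEXTS[r], sprintf("%.15e", probs[r, ])),
          collapse = "\t"), character(1))
  writeLines(c(header, rows), catalog)
  exposures <- character(2)
  for (e in 1:2) {
    w <- stats::runif(n_signatures)
    w <- 0.9 * w / sum(w)
    exposures[e] <- file.path(dir, sprintf("exposure_%d.tsv", e))
    writeLines(c("signature_id\tweight",
                 sprintf("%s\t%.15e", ids, w)), exposures[e])
  }
  list(catalog = catalog, exposures = exposures, ids = ids,
       biased_id = ids[n_signatures])
}

## ---- toy complexes ----

empty_atoms <- function() {
  data.frame(type = character(0), eleno = integer(0), elety = character(0),
             resid = character(0), chain = character(0), resno = integer(0),
             x = numeric(0), y = numeric(0), z = numeric(0), o = numeric(0),
             b = numeric(0), element = character(0), stringsAsFactors = FALSE)
}

atom_rows <- function(type, elety, resid, resno, xyz, chain = "A",
                      element = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  if (is.null(element)) element <- element_from_name(elety)
  data.frame(type = type, eleno = 0L, elety = elety, resid = resid,
             chain = chain, resno = resno, x = xyz[, 1], y = xyz[, 2],
             z = xyz[, 3], o = 1, b = 0, element = element,
             stringsAsFactors = FALSE)
}

finish_atoms <- function(...) {
  at <- do.call(rbind, list(...))
  at$eleno <- seq_len(nrow(at))
  at
}

## Backbone + idealized side chain for one residue of the extended toy chain.
toy_residue_atoms <- function(aa, resno) {
  x0 <- 3.8 * resno
  zig <- 0.6 * (-1)^resno
  N <- c(x0 - 1.2, 0.5, zig)
  CA <- c(x0, 0, zig)
  C <- c(x0 + 1.2, 0.5, zig)
  O <- c(x0 + 1.4, 1.7, zig)
  bb <- atom_rows("ATOM", c("N", "CA", "C", "O"), aa_three(aa), resno,
                  rbind(N, CA, C, O))
  sc <- ideal_sidechain(aa, N, CA, C)
  if (nrow(sc))
    bb <- rbind(bb, atom_rows("ATOM", rownames(sc), aa_three(aa), resno, sc))
  bb
}

toy_protein_atoms <- function(sequence) {
  do.call(rbind, lapply(seq_along(sequence), function(i)
    toy_residue_atoms(sequence[i], i)))
}

## Small drug-like ligand: a planar aromatic six-ring (5 C + 1 N) with a
## carbonyl-like oxygen and a chlorine substituent.  Returned positioned so
## that its O1 atom sits at `o1_at`.
toy_ligand_atoms <- function(o1_at = c(0, 0, 0), resid = "LIG") {
  r <- BOND_RING / (2 * sin(pi / 6))
  ang <- 2 * pi * (0:5) / 6
  ring <- cbind(r * cos(ang), r * sin(ang), 0)
  names_ring <- c("C1", "C2", "C3", "C4", "C5", "N1")
  o1 <- ring[1, ] + 1.23 * vunit(ring[1, ] - colMeans(ring))
  cl1 <- ring[3, ] + 1.73 * vunit(ring[3, ] - colMeans(ring))
  xyz <- rbind(ring, o1, cl1)
  xyz <- sweep(xyz, 2, o1 - o1_at)
  atom_rows("HETATM", c(names_ring, "O1", "CL1"), resid, 1L, xyz,
            element = c("C", "C", "C", "C", "C", "N", "O", "CL"))
}

## Deterministic codon choice per amino acid (first codon in genetic-code
## order), so the CDS translates exactly to the structure's sequence.
codon_for <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  names(gc[gc == aa])[1]
}

#' Generate a matched toy complex, CDS and boundary-geometry set
#'
#' The main complex is an extended \code{n_residues}-residue chain with
#' idealized side chains, a small aromatic ligand whose O1 atom is placed
#' 3.0 Angstrom from the backbone oxygen of the central residue (a scripted
#' hydrogen bond), and one bridging water.  The matched CDS translates
#' exactly to the structure's sequence.  The boundary set contains
#' structures whose geometries sit exactly at the documented detector
#' cutoffs: binding-site membership at 9.4/9.6 Angstrom, donor-acceptor
#' pairs at 3.19/3.21, SG-SG at 2.0/2.3, salt bridges at 3.9/4.1.
#'
#' @param n_residues chain length (>= 3; default 8).
#' @param seed integer seed (sequence choice).
#' @param dir output directory.
#' @return list(pdb, cds_fasta, sequence, ligand_id, hbond_resno,
#'   boundary = named list of PDB paths).
#' @export
make_toy_complex <- function(n_residues = 8, seed = 1, dir = tempfile("complex")) {
  stopifnot(n_residues >= 3)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(fixture_seed(seed, 202))
  ## fixed functional core (serine, charged pair, cysteine, aromatic), the
  ## rest drawn from the non-glycine alphabet
  core <- c("S", "D", "K", "C", "F")
  extra <- sample(setdiff(AA1, "G"), max(0, n_residues - length(core)),
                  replace = TRUE)
  sequence <- c(core, extra)[seq_len(n_residues)]

  prot <- toy_protein_atoms(sequence)
  mid <- ceiling(n_residues / 2)
  o_mid <- as.numeric(prot[prot$resno == mid & prot$elety == "O",
                           c("x", "y", "z")])
  lig <- toy_ligand_atoms(o1_at = o_mid + c(0, 3.0, 0))
  wat_pos <- o_mid + c(2.2, 1.6, 0)
  wat <- atom_rows("HETATM", "O", "HOH", 900L, wat_pos, element = "O")
  model <- complex_model(finish_atoms(prot, lig, wat), "LIG",
                         source = "toy complex")
  pdb <- file.path(dir, "complex_wt.pdb")
  write_complex_pdb(model, pdb)

  cds <- paste(vapply(sequence, codon_for, character(1)), collapse = "")
  cds_fasta <- file.path(dir, "cds.fasta")
  writeLines(c(">toy_gene", cds), cds_fasta)

  boundary <- make_boundary_set(dir)
  list(pdb = pdb, cds_fasta = cds_fasta, sequence = sequence,
       ligand_id = "LIG", hbond_resno = mid, boundary = boundary)
}

## A minimal glycine-like residue whose nearest atom to the origin-side is
## the named `near` atom at the given position; remaining atoms trail away
## along `away` (unit vector).
trailing_residue <- function(resno, near_name, near_pos, away,
                             names = c("O", "C", "CA", "N"), resid = "GLY") {
  names <- union(near_name, names)
  xyz <- t(vapply(seq_along(names), function(k)
    near_pos + (k - 1) * 1.4 * away, numeric(3)))
  atom_rows("ATOM", names, resid, resno, xyz)
}

#' Boundary-geometry fixture structures
#'
#' Four PDB files whose geometries sit exactly at the detector cutoffs (see
#' \code{\link{make_toy_complex}}).
#' @param dir output directory.
#' @return Named list of paths: site, hbond, disulfide, saltbridge.
#' @export
make_boundary_set <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()

  ## binding-site membership: closest atoms at 9.4 / 9.6 A from a 1-atom ligand
  lig <- atom_rows("HETATM", "C1", "LIG", 1L, c(0, 0, 0), element = "C")
  r1 <- trailing_residue(1L, "CA", c(9.4, 0, 0), c(1, 0, 0),
                         names = c("CA", "N", "C", "O"))
  r2 <- trailing_residue(2L, "CA", c(-9.6, 0, 0), c(-1, 0, 0),
                         names = c("CA", "N", "C", "O"))
  out$site <- file.path(dir, "boundary_site.pdb")
  write_complex_pdb(complex_model(finish_atoms(r1, r2, lig), "LIG",
                                  "boundary site"), out$site)

  ## hydrogen bond: backbone O at 3.19 / 3.21 A from a ligand oxygen, plus a
  ## residue offering only carbon within range (no donor/acceptor)
  ligo <- atom_rows("HETATM", c("O1", "C9"), "LIG", 1L,
                    rbind(c(0, 0, 0), c(0, -40, 0)), element = c("O", "C"))
  h1 <- trailing_residue(1L, "O", c(3.19, 0, 0), c(1, 0, 0))
  h2 <- trailing_residue(2L, "O", c(-3.21, 0, 0), c(-1, 0, 0))
  h3 <- trailing_residue(3L, "CA", c(2.9, -40, 0), c(1, 0, 0),
                         names = c("CA", "C", "O", "N"))
  out$hbond <- file.path(dir, "boundary_hbond.pdb")
  write_complex_pdb(complex_model(finish_atoms(h1, h2, h3, ligo), "LIG",
                                  "boundary hbond"), out$hbond)

  ## disulfide: SG-SG at 2.0 (present) and 2.3 (absent)
  cys <- function(resno, sg_pos, away) {
    at <- trailing_residue(resno, "SG", sg_pos, away,
                           names = c("SG", "CB", "CA", "C", "O", "N"),
                           resid = "CYS")
    at
  }
  c1 <- cys(1L, c(0, 0, 0), c(0, 1, 0)); c2 <- cys(2L, c(2.0, 0, 0), c(0, -1, 0))
  c3 <- cys(3L, c(0, 30, 0), c(0, 1, 0)); c4 <- cys(4L, c(2.3, 30, 0), c(0, -1, 0))
  dlig <- atom_rows("HETATM", "C1", "LIG", 1L, c(0, -50, 0), element = "C")
  out$disulfide <- file.path(dir, "boundary_disulfide.pdb")
  write_complex_pdb(complex_model(finish_atoms(c1, c2, c3, c4, dlig), "LIG",
                                  "boundary disulfide"), out$disulfide)

  ## salt bridge: ASP OD1 to LYS NZ at 3.9 (counted) and 4.1 (not)
  asp <- function(resno, od_pos, away)
    trailing_residue(resno, "OD1", od_pos, away,
                     names = c("OD1", "CG", "CB", "CA", "C", "O", "N"),
                     resid = "ASP")
  lys <- function(resno, nz_pos, away)
    trailing_residue(resno, "NZ", nz_pos, away,
                     names = c("NZ", "CE", "CD", "CG", "CB", "CA", "C", "O", "N"),
                     resid = "LYS")
  s1 <- asp(1L, c(0, 0, 0), c(0, 1, 0)); s2 <- lys(2L, c(3.9, 0, 0), c(0, -1, 0))
  s3 <- asp(3L, c(0, 40, 0), c(0, 1, 0)); s4 <- lys(4L, c(4.1, 40, 0), c(0, -1, 0))
  out$saltbridge <- file.path(dir, "boundary_saltbridge.pdb")
  write_complex_pdb(complex_model(finish_atoms(s1, s2, s3, s4, dlig), "LIG",
                                  "boundary saltbridge"), out$saltbridge)
  out
}

## ---- planted-signal training tables ----

## Class-dependent ligand displacement (Angstrom) along the axis away from
## the mutated residue; the planted signal that separates the phenotypes.
CLASS_SHIFT <- c(SRES = 2.5, RES = 1.0, NEU = 0.0, ISEN = -1.0)

#' Generate a training table with a planted class-separating signal
#'
#' Emulates an affinity fold-change training table: for each instance a
#' binding-site residue of the toy complex is mutated (graft backend), the
#' ligand of the mutant structure is displaced along the residue-to-ligand
#' axis by a class-dependent amount scaled by \code{signal_strength} (plus
#' isotropic noise), and an affinity fold change is drawn inside the class's
#' band (drop >= 5 for SRES, (1.2, 5) for RES, within the 1.2 band for NEU,
#' increase >= 1.2 for ISEN).  The displacement perturbs ligand-distance and
#' hydrogen-bond features, so the signal must survive feature extraction to
#' be learnable.  A configurable number of multi-mutant decoy rows (random
#' n_mutations of 2 or 3) exercises the single-mutant filter.
#'
#' @param n_per_class instances per class: a single number or a named vector
#'   over SRES/RES/NEU/ISEN (default the balanced design 180/180/70/180).
#' @param signal_strength displacement scale (0 = pure noise, 1 = full
#'   separation).
#' @param seed integer seed.
#' @param dir output directory for structures and CSV.
#' @param n_decoys number of multi-mutant decoy rows (default 5).
#' @param atom_jitter_sd per-instance coordinate noise (default 0.05 A).
#' @return list(csv, dir, n_decoys, n_instances, complex = toy-complex
#'   metadata).
#' @export
make_toy_training_table <- function(n_per_class = c(SRES = 180, RES = 180,
                                                    NEU = 70, ISEN = 180),
                                    signal_strength = 1, seed = 1,
                                    dir = tempfile("training"),
                                    n_decoys = 5, atom_jitter_sd = 0.05) {
  if (length(n_per_class) == 1)
    n_per_class <- stats::setNames(rep(n_per_class, 4), PHENOTYPE_CLASSES)
  stopifnot(all(PHENOTYPE_CLASSES %in% names(n_per_class)),
            all(n_per_class >= 10))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  toy <- make_toy_complex(n_residues = 8, seed = seed, dir = dir)
  base <- load_complex(toy$pdb, toy$ligand_id)
  cds <- read_cds_fasta(toy$cds_fasta)
  site <- define_binding_site(base)
  candidates <- enumerate_binding_site_mutants(site, cds)
  stopifnot(length(candidates) > 0)

  set.seed(fixture_seed(seed, 303))
  rows <- list()
  idx <- 0
  for (cls in PHENOTYPE_CLASSES) {
    for (k in seq_len(n_per_class[[cls]])) {
      idx <- idx + 1
      id <- sprintf("inst%04d", idx)
      mut <- candidates[[sample.int(length(candidates), 1)]]
      wt <- base
      jit <- function(at) {
        at[, c("x", "y", "z")] <- at[, c("x", "y", "z")] +
          stats::rnorm(3 * nrow(at), sd = atom_jitter_sd)
        at
      }
      wt$protein <- jit(wt$protein); wt$ligand <- jit(wt$ligand)
      wt$water <- jit(wt$water)
      mm <- build_mutant_model(wt, mut)
      mt <- mm$structure
      ca <- backbone_xyz(wt, mut$protein_position, "CA")
      lig_centre <- colMeans(atom_xyz(mt$ligand))
      axis <- vunit(lig_centre - ca)
      shift <- signal_strength * CLASS_SHIFT[[cls]] +
        stats::rnorm(1, sd = 0.15)
      mt$ligand[, c("x", "y", "z")] <-
        sweep(as.matrix(mt$ligand[, c("x", "y", "z")]), 2, -shift * axis)
      fold <- switch(cls,
        SRES = exp(stats::runif(1, log(5), log(50))),
        RES  = stats::runif(1, 1.3, 4.8),
        NEU  = exp(stats::runif(1, -log(1.15), log(1.15))),
        ISEN = 1 / exp(stats::runif(1, log(1.3), log(12))))
      aff_wt <- 10^stats::runif(1, 0, 3)
      wt_path <- file.path(dir, paste0("wt_", id, ".pdb"))
      mt_path <- file.path(dir, paste0("mt_", id, ".pdb"))
      write_complex_pdb(wt, wt_path)
      write_complex_pdb(mt, mt_path)
      rows[[idx]] <- data.frame(
        id = id, protein = "toy", mutation = mutation_label(mut),
        n_mutations = 1L, wt_structure = wt_path, mt_structure = mt_path,
        affinity_wt = aff_wt, affinity_mt = aff_wt * fold,
        measure = sample(c("Ki", "Kd", "IC50"), 1), ligand_id = "LIG",
        stringsAsFactors = FALSE)
    }
  }
  n_real <- idx
  for (d in seq_len(n_decoys)) {
    idx <- idx + 1
    tmpl <- rows[[sample.int(n_real, 1)]]
    tmpl$id <- sprintf("decoy%03d", d)
    tmpl$n_mutations <- sample(2:3, 1)
    rows[[idx]] <- tmpl
  }
  tab <- do.call(rbind, rows)
  csv <- file.path(dir, "training.csv")
  utils::write.csv(tab, csv, row.names = FALSE, quote = FALSE)
  list(csv = csv, dir = dir, n_decoys = n_decoys, n_instances = n_real,
       complex = toy)
}

#' Generate a candidate-compound panel for screening
#'
#' Writes \code{n_compounds} ligand-only pose PDBs (copies of the toy ligand
#' displaced by small seeded offsets within the binding pocket, i.e. already
#' in the target frame) plus an affinity TSV mixing co-crystal and docked
#' provenance; one extra docked record above the IC50 cutoff and one without
#' affinity exercise the load filters.
#'
#' @param toy output of \code{\link{make_toy_complex}}.
#' @param n_compounds number of usable candidate compounds.
#' @param seed integer seed.
#' @param dir output directory.
#' @return list(poses_dir, affinity_table).
#' @export
make_toy_candidates <- function(toy, n_compounds = 3, seed = 1,
                                dir = tempfile("cand")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(fixture_seed(seed, 404))
  base <- load_complex(toy$pdb, toy$ligand_id)
  o1 <- as.numeric(base$ligand[base$ligand$elety == "O1", c("x", "y", "z")])
  tab <- data.frame(compound_id = character(0), affinity_nM = numeric(0),
                    measure = character(0), source = character(0),
                    stringsAsFactors = FALSE)
  for (k in seq_len(n_compounds)) {
    id <- sprintf("CPD%02d", k)
    off <- stats::rnorm(3, sd = 0.4)
    lig <- toy_ligand_atoms(o1_at = o1 + off, resid = sprintf("L%02d", k))
    lig$eleno <- seq_len(nrow(lig))
    bio3d::write.pdb(file = file.path(dir, paste0(id, ".pdb")),
                     type = lig$type, eleno = lig$eleno, elety = lig$elety,
                     resid = lig$resid, chain = lig$chain, resno = lig$resno,
                     xyz = as.numeric(t(as.matrix(lig[, c("x", "y", "z")]))),
                     o = lig$o, b = lig$b, elesy = lig$element)
    tab <- rbind(tab, data.frame(
      compound_id = id, affinity_nM = round(10^stats::runif(1, 0, 2), 2),
      measure = "IC50", source = if (k == 1) "cocrystal" else "docked"))
  }
  tab <- rbind(tab,
               data.frame(compound_id = "CPDHI", affinity_nM = 5000,
                          measure = "IC50", source = "docked"),
               data.frame(compound_id = "CPDNA", affinity_nM = NA,
                          measure = "IC50", source = "manual"))
  aff <- file.path(dir, "affinities.tsv")
  utils::write.table(tab, aff, sep = "\t", quote = FALSE, row.names = FALSE)
  list(poses_dir = dir, affinity_table = aff)
}

#' Generate the full fixture bundle
#'
#' One call producing every synthetic input the pipeline consumes, all under
#' one seed: signature catalog + exposures, toy complex + CDS + boundary
#' set, a (reduced-size unless \code{full}) planted-signal training table,
#' and a candidate panel.
#'
#' @param seed integer seed.
#' @param dir output directory.
#' @param full use the full balanced design (180/180/70/180); otherwise a
#'   small 12/12/10/12 table for quick runs.
#' @export
make_fixture_bundle <- function(seed = 1, dir = tempfile("bundle"),
                                full = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig <- make_toy_signature_catalog(3, seed, file.path(dir, "signatures"))
  complex <- make_toy_complex(8, seed, file.path(dir, "complex"))
  n <- if (full) c(SRES = 180, RES = 180, NEU = 70, ISEN = 180)
  else c(SRES = 12, RES = 12, NEU = 10, ISEN = 12)
  training <- make_toy_training_table(n, signal_strength = 1, seed = seed,
                                      dir = file.path(dir, "training"))
  candidates <- make_toy_candidates(complex, 3, seed,
                                    file.path(dir, "candidates"))
  list(seed = seed, dir = dir, signatures = sig, complex = complex,
       training = training, candidates = candidates)
}
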