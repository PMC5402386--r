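## Compound screening: assemble a candidate panel, score every mutation x
## compound pair with the ligand-schema classifier, and emit the sensitivity
## map and targetability groups.

#' Load a candidate-compound panel
#'
#' The affinity table is a TSV with columns compound_id, affinity_nM,
#' measure (Ki|Kd|IC50) and source (cocrystal|docked|manual).  Records
#' without a measured affinity are rejected; records of docked/extended
#' provenance additionally must meet the IC50 cutoff (the cutoff does not
#' apply to co-crystallized compounds).  Each compound's pose is the PDB
#' file \code{<compound_id>.pdb} under \code{poses_dir}; unreadable poses
#' drop the record with a log entry.
#'
#' @param poses_dir directory of pose PDB files.
#' @param affinity_table path to the affinity TSV (or a data.frame).
#' @param ic50_cutoff_nM cutoff applied to docked/extended records
#'   (default 100 nM; inclusive).
#' @return List of \code{compound_record}s with a \code{dropped} attribute.
#' @export
load_candidates <- function(poses_dir, affinity_table, ic50_cutoff_nM = 100) {
  tab <- if (is.data.frame(affinity_table)) affinity_table
  else utils::read.delim(affinity_table, stringsAsFactors = FALSE)
  stopifnot(all(c("compound_id", "affinity_nM", "measure", "source") %in% names(tab)))
  records <- list()
  dropped <- data.frame(compound_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  drop <- function(id, why)
    dropped <<- rbind(dropped, data.frame(compound_id = id, reason = why))
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    if (is.na(row$affinity_nM)) { drop(row$compound_id, "no measured affinity"); next }
    if (row$source %in% c("docked", "extended") &&
        row$affinity_nM > ic50_cutoff_nM) {
      drop(row$compound_id, sprintf("affinity %.1f nM above cutoff", row$affinity_nM))
      next
    }
    pose <- file.path(poses_dir, paste0(row$compound_id, ".pdb"))
    if (!file.exists(pose)) { drop(row$compound_id, "pose file missing"); next }
    parsed <- try(bio3d::read.pdb(pose, verbose = FALSE), silent = TRUE)
    if (inherits(parsed, "try-error")) { drop(row$compound_id, "pose unparseable"); next }
    records <- c(records, list(structure(
      list(id = row$compound_id, source = row$source, pose = pose,
           affinity_nM = row$affinity_nM, measure = row$measure),
      class = "compound_record")))
  }
  attr(records, "dropped") <- dropped
  records
}

## Complex of the target protein with one candidate's ligand.  If the pose
## PDB contains protein atoms it is used as a self-contained complex;
## otherwise the ligand atoms are merged into the target's frame (poses are
## assumed pre-superposed onto the target).
candidate_complex <- function(target, record) {
  pdb <- bio3d::read.pdb(record$pose, verbose = FALSE)
  at <- pdb$atom
  lig_ids <- setdiff(unique(at$resid[at$type == "HETATM"]), c("HOH", "WAT", "H2O"))
  if (!length(lig_ids)) stop("pose for ", record$id, " has no heteroatom group")
  has_protein <- any(at$type == "ATOM" & at$resid %in% names(AA3TO1))
  if (has_protein) return(load_complex(record$pose, lig_ids[1]))
  tmp <- load_complex(record$pose, lig_ids[1])
  atoms <- rbind(target$protein, tmp$ligand, target$water)
  complex_model(atoms, lig_ids[1],
                source = paste0(target$source, "+", record$id))
}

#' Score a mutation x compound panel into a sensitivity map
#'
#' For every (compound, mutation) pair: the mutant complex is built with the
#' graft backend, ligand-schema features are extracted against that
#' compound's pose, class confidences are predicted, and the Resistance
#' Score is computed with the model's class precisions.  Normalized scores
#' (NRS) are scaled across the whole map (one experiment).  Failed cells
#' are flagged missing, not fatal.
#'
#' @param candidates list of \code{compound_record} (see
#'   \code{\link{load_candidates}}).
#' @param mutations list of \code{aa_mutation}.
#' @param model a lig-schema \code{resistance_classifier} with class
#'   precisions attached.
#' @param target wild-type \code{complex_model} providing the protein frame.
#' @param offset residue-number offset.
#' @param n_points surface-integrator density.
#' @return A \code{sensitivity_map}: list(nrs, rs, class) matrices
#'   (compounds x mutations) plus metadata.
#' @export
screen_compounds <- function(candidates, mutations, model, target,
                             offset = 0, n_points = 960) {
  stopifnot(inherits(model, "resistance_classifier"))
  if (is.null(model$precisions))
    stop("model carries no class precisions; run cross_validate + set_class_precisions")
  if (model$schema_name != "lig-v1")
    warning("screening expects the lig-v1 schema; model uses ", model$schema_name)
  schema <- feature_schema(model$schema_name)
  comp_ids <- vapply(candidates, function(r) r$id, character(1))
  mut_ids <- vapply(mutations, mutation_label, character(1))
  rs <- matrix(NA_real_, length(candidates), length(mutations),
               dimnames = list(comp_ids, mut_ids))
  cls <- matrix(NA_character_, length(candidates), length(mutations),
                dimnames = list(comp_ids, mut_ids))
  failures <- character(0)
  for (ci in seq_along(candidates)) {
    rec <- candidates[[ci]]
    cell <- try({
      wt <- candidate_complex(target, rec)
      site <- define_binding_site(wt)
      wt
    }, silent = TRUE)
    if (inherits(cell, "try-error")) {
      failures <- c(failures, paste0(rec$id, ": ", attr(cell, "condition")$message))
      next
    }
    wt <- cell
    for (mi in seq_along(mutations)) {
      res <- try({
        mm <- build_mutant_model(wt, mutations[[mi]], offset = offset)
        fv <- extract_features(wt, mm$structure, site, mutations[[mi]], schema,
                               wt_affinity_nM = rec$affinity_nM,
                               measure = rec$measure, offset = offset,
                               n_points = n_points)
        sc <- predict_scores(model, fv)
        list(rs = resistance_score(sc, model$precisions), class = sc$class)
      }, silent = TRUE)
      if (inherits(res, "try-error")) {
        failures <- c(failures, paste0(rec$id, "/", mut_ids[mi], ": ",
                                       attr(res, "condition")$message))
        next
      }
      rs[ci, mi] <- res$rs
      cls[ci, mi] <- res$class
    }
  }
  ok <- is.finite(rs)
  nrs <- rs
  if (any(ok)) nrs[ok] <- normalize_scores(rs[ok])
  structure(list(nrs = nrs, rs = rs, class = cls, compounds = comp_ids,
                 mutations = mut_ids, failures = failures),
            class = "sensitivity_map")
}

#' @export
print.sensitivity_map <- function(x, ...) {
  cat(sprintf("<sensitivity_map: %d compounds x %d mutations (%d missing cells)>\n",
              nrow(x$nrs), ncol(x$nrs), sum(!is.finite(x$nrs))))
  invisible(x)
}

#' Group mutations by targetability
#'
#' A mutation is hardly targetable when at least \code{frac} of its scored
#' cells have NRS >= \code{high} (resistant to nearly every compound),
#' easily targetable when at least \code{frac} are <= \code{low}, and
#' targetable otherwise.  Columns with fewer than half their cells scored
#' are undetermined.
#'
#' @param map a \code{sensitivity_map}.
#' @param low,high NRS thresholds (defaults 0.3 / 0.7).
#' @param frac required fraction of cells (default 0.8).
#' @return data.frame(mutation, group).
#' @export
classify_targetability <- function(map, low = 0.3, high = 0.7, frac = 0.8) {
  stopifnot(inherits(map, "sensitivity_map"))
  groups <- vapply(seq_along(map$mutations), function(mi) {
    col <- map$nrs[, mi]
    scored <- col[is.finite(col)]
    if (length(scored) < 0.5 * length(col)) return("undetermined")
    if (mean(scored >= high) >= frac) return("hardly targetable")
    if (mean(scored <= low) >= frac) return("easily targetable")
    "targetable"
  }, character(1))
  data.frame(mutation = map$mutations, group = groups, stringsAsFactors = FALSE)
}

#' Export a sensitivity map
#'
#' TSV: compounds x mutations matrix of NRS (lossless round trip via
#' \code{\link{read_sensitivity_map}}).  JSON: NRS, RS and per-cell class
#' labels.  PNG: a heatmap rendering.
#'
#' @param map a \code{sensitivity_map}.
#' @param path output file.
#' @param fmt "tsv", "json" or "png".
#' @export
export_map <- function(map, path, fmt = c("tsv", "json", "png")) {
  fmt <- match.arg(fmt)
  stopifnot(inherits(map, "sensitivity_map"))
  if (!length(map$nrs)) stop("empty sensitivity map")
  if (fmt == "tsv") {
    df <- data.frame(compound = rownames(map$nrs), map$nrs,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (fmt == "json") {
    jsonlite::write_json(list(compounds = map$compounds,
                              mutations = map$mutations,
                              nrs = map$nrs, rs = map$rs, class = map$class),
                         path, digits = NA, matrix = "rowmajor", na = "null")
  } else {
    grDevices::png(path, width = 140 * ncol(map$nrs) + 200,
                   height = 40 * nrow(map$nrs) + 200)
    op <- graphics::par(mar = c(8, 8, 2, 2))
    on.exit({ graphics::par(op); grDevices::dev.off() })
    z <- t(map$nrs)[, rev(seq_len(nrow(map$nrs))), drop = FALSE]
    graphics::image(seq_len(nrow(z)), seq_len(ncol(z)), z, zlim = c(0, 1),
                    col = grDevices::hcl.colors(50, "YlOrRd", rev = TRUE),
                    xlab = "", ylab = "", axes = FALSE)
    graphics::axis(1, at = seq_along(map$mutations), labels = map$mutations,
                   las = 2)
    graphics::axis(2, at = seq_along(map$compounds),
                   labels = rev(map$compounds), las = 2)
  }
  invisible(path)
}

#' Read back a TSV sensitivity map matrix
#' @param path TSV written by \code{\link{export_map}}.
#' @return Numeric matrix (compounds x mutations).
#' @export
read_sensitivity_map <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
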