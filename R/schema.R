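## Feature schemas and vector assembly.  The schema registry is the source
## of truth for what the classifiers consume: "aa-v1" is the amino-acid
## level schema (includes half-sphere exposure, protein-protein salt-bridge
## counts and disulfide checks), "lig-v1" is the ligand-level schema (drops
## those, adds the interaction-fingerprint block).  Counts quoted for the
## original feature families refer to items before one-hot expansion; the
## expanded lengths here are documented by the registry itself.

schema_core_names <- function() {
  c("site_sasa_wt", "site_sasa_mt", "site_sasa_absdiff",
    "res_sasa_wt", "res_sasa_mt", "res_sasa_absdiff",
    "rsa_wt", "rsa_mt", "rsa_absdiff", "sasa_known",
    paste0("mut_", AA1),
    "hbond_present", "hbond_distance", "hbond_backbone",
    as.vector(t(outer(paste0("shell", 1:6), AA1, paste, sep = "_"))),
    paste0("seqwin_", AA1),
    "ss_wt_H", "ss_wt_E", "ss_wt_C", "ss_mt_H", "ss_mt_E", "ss_mt_C", "ss_known",
    "ddg", "ddg_stable", "ddg_unstable", "ddg_unknown",
    "conservation", "conservation_known",
    "rmsd_raw", "rmsd_refined",
    "ligdist_min_wt", "ligdist_max_wt", "ligdist_mean_wt",
    "ligdist_min_mt", "ligdist_max_mt", "ligdist_mean_mt",
    "ligdist_min_absdiff", "ligdist_max_absdiff", "ligdist_mean_absdiff",
    "ligdist_known",
    paste0("charge_", AA1), "dhydro",
    "wt_affinity_log10nM", "measure_Ki", "measure_Kd", "measure_IC50",
    "sb_lig_present", "sb_lig_distance")
}

schema_aa_only_names <- function() {
  c("hse_up_wt", "hse_down_wt", "hse_up_mt", "hse_down_mt",
    "hse_up_absdiff", "hse_down_absdiff", "hse_known",
    "sb_pp_count_wt", "sb_pp_count_mt", "sb_pp_count_absdiff",
    "disulfide_wt", "disulfide_mt")
}

schema_lig_only_names <- function() {
  c("fp_halogen_present", "fp_halogen_distance",
    "fp_pistack_present", "fp_pistack_distance", "fp_pistack_parallel",
    "fp_pication_present", "fp_pication_distance",
    "fp_waterbridge_present", "fp_waterbridge_distance",
    "fp_hydrophobic_present", "fp_hydrophobic_distance",
    "sb_lig_group_phosphate", "sb_lig_group_carboxylate",
    "sb_lig_group_guanidine", "sb_lig_group_tertamine",
    "sb_lig_group_quartamine")
}

#' Feature schema registry
#'
#' @param name \code{"aa-v1"} or \code{"lig-v1"}.
#' @return A \code{feature_schema}: list(name, features = ordered names).
#' @export
feature_schema <- function(name = c("aa-v1", "lig-v1")) {
  name <- match.arg(name)
  features <- switch(name,
    "aa-v1" = c(schema_core_names(), schema_aa_only_names()),
    "lig-v1" = c(schema_core_names(), schema_lig_only_names()))
  stopifnot(!anyDuplicated(features))
  structure(list(name = name, features = features), class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat(sprintf("<feature_schema %s: %d features>\n", x$name, length(x$features)))
  invisible(x)
}

num <- function(x, default = 0) {
  x <- suppressWarnings(as.numeric(x))
  if (!length(x) || is.na(x)) default else x
}

#' Assemble a schema-conformant feature vector
#'
#' Combines the outputs of the individual extractors into a numeric vector
#' in the schema's fixed order.  Missing parts use the sentinel 0 and flip
#' the corresponding "known" indicator to 0, with provenance "unknown", so
#' tree models can split on missingness.  The wild-type affinity is encoded
#' as log10(nM) plus a one-hot of the measure type (Ki / Kd / IC50).
#'
#' @param parts named list with entries \code{sasa} (from
#'   \code{\link{surface_accessibility_features}}), \code{mutation}
#'   (aa_mutation), \code{hbond}, \code{env}, \code{ss_wt}, \code{ss_mt},
#'   \code{stability}, \code{conservation}, \code{rmsd}, \code{ligdist_wt},
#'   \code{ligdist_mt}, \code{chg}, \code{saltbridge}, and for aa-v1
#'   \code{hse_wt}/\code{hse_mt}/\code{disulfide_wt}/\code{disulfide_mt}/
#'   \code{saltbridge_mt}, for lig-v1 \code{fingerprint}.  Missing entries
#'   become sentinels.
#' @param schema a \code{feature_schema}.
#' @param wt_affinity_nM measured wild-type affinity in nM.
#' @param measure one of "Ki", "Kd", "IC50".
#' @return A \code{feature_vector}: list(schema, values, provenance).
#' @export
assemble_feature_vector <- function(parts, schema, wt_affinity_nM,
                                    measure = c("Ki", "Kd", "IC50")) {
  stopifnot(inherits(schema, "feature_schema"))
  measure <- match.arg(measure)
  v <- stats::setNames(rep(0, length(schema$features)), schema$features)
  prov <- stats::setNames(rep("computed", length(schema$features)),
                          schema$features)
  unknown <- function(keys) prov[keys] <<- "unknown"

  sasa <- parts$sasa
  sasa_keys <- c("site_sasa_wt", "site_sasa_mt", "site_sasa_absdiff",
                 "res_sasa_wt", "res_sasa_mt", "res_sasa_absdiff",
                 "rsa_wt", "rsa_mt", "rsa_absdiff")
  if (!is.null(sasa) && !anyNA(unlist(sasa))) {
    v[sasa_keys] <- unlist(sasa)[sasa_keys]
    v["sasa_known"] <- 1
  } else unknown(c(sasa_keys, "sasa_known"))

  m <- parts$mutation
  if (!is.null(m)) {
    v[paste0("mut_", m$ref_aa)] <- -1
    v[paste0("mut_", m$alt_aa)] <- 1
  }

  hb <- parts$hbond
  if (!is.null(hb)) {
    v["hbond_present"] <- as.numeric(isTRUE(hb$present))
    v["hbond_distance"] <- if (isTRUE(hb$present)) hb$distance else 0
    v["hbond_backbone"] <- as.numeric(isTRUE(hb$backbone) && isTRUE(hb$present))
  } else unknown(c("hbond_present", "hbond_distance", "hbond_backbone"))

  env <- parts$env
  if (!is.null(env)) {
    for (s in 1:6) v[paste0("shell", s, "_", AA1)] <- env$shells[s, AA1]
    v[paste0("seqwin_", AA1)] <- env$seq_window[AA1]
  }

  for (side in c("wt", "mt")) {
    ss <- parts[[paste0("ss_", side)]]
    if (!is.null(ss)) {
      v[paste0("ss_", side, "_", ss$label)] <- 1
    }
  }
  v["ss_known"] <- as.numeric(isTRUE(parts$ss_wt$known) && isTRUE(parts$ss_mt$known))

  st <- parts$stability
  if (!is.null(st) && st$category != "UNKNOWN") {
    v["ddg"] <- st$ddG
    v[paste0("ddg_", tolower(st$category))] <- 1
    prov["ddg"] <- "surrogate"
  } else {
    v["ddg_unknown"] <- 1
    unknown("ddg")
  }

  if (!is.null(parts$conservation) && !is.na(parts$conservation)) {
    v["conservation"] <- parts$conservation
    v["conservation_known"] <- 1
  } else unknown(c("conservation", "conservation_known"))

  if (!is.null(parts$rmsd)) {
    v["rmsd_raw"] <- parts$rmsd[["raw"]]
    v["rmsd_refined"] <- parts$rmsd[["refined"]]
  } else unknown(c("rmsd_raw", "rmsd_refined"))

  lw <- parts$ligdist_wt; lm <- parts$ligdist_mt
  ld_keys <- c("ligdist_min_wt", "ligdist_max_wt", "ligdist_mean_wt",
               "ligdist_min_mt", "ligdist_max_mt", "ligdist_mean_mt",
               "ligdist_min_absdiff", "ligdist_max_absdiff",
               "ligdist_mean_absdiff")
  if (!is.null(lw) && !is.null(lm) && !anyNA(c(lw, lm))) {
    v[ld_keys] <- c(lw[["min"]], lw[["max"]], lw[["mean"]],
                    lm[["min"]], lm[["max"]], lm[["mean"]],
                    abs(lw - lm)[c("min", "max", "mean")])
    v["ligdist_known"] <- 1
  } else unknown(c(ld_keys, "ligdist_known"))

  chg <- parts$chg
  if (!is.null(chg)) {
    v[paste0("charge_", AA1)] <- chg$charge[AA1]
    v["dhydro"] <- chg$dhydro
  }

  v["wt_affinity_log10nM"] <- log10(max(wt_affinity_nM, 1e-6))
  v[paste0("measure_", measure)] <- 1

  sb <- parts$saltbridge
  if (!is.null(sb)) {
    v["sb_lig_present"] <- as.numeric(isTRUE(sb$lig_present))
    v["sb_lig_distance"] <- if (isTRUE(sb$lig_present)) sb$lig_distance else 0
  }

  if (schema$name == "aa-v1") {
    hw <- parts$hse_wt; hm <- parts$hse_mt
    hse_keys <- c("hse_up_wt", "hse_down_wt", "hse_up_mt", "hse_down_mt",
                  "hse_up_absdiff", "hse_down_absdiff")
    if (!is.null(hw) && !is.null(hm) && !anyNA(c(hw, hm))) {
      v[hse_keys] <- c(hw[["up"]], hw[["down"]], hm[["up"]], hm[["down"]],
                       abs(hw - hm)[c("up", "down")])
      v["hse_known"] <- 1
    } else unknown(c(hse_keys, "hse_known"))
    sbm <- parts$saltbridge_mt
    if (!is.null(sb) && !is.null(sbm)) {
      v["sb_pp_count_wt"] <- sb$pp_count
      v["sb_pp_count_mt"] <- sbm$pp_count
      v["sb_pp_count_absdiff"] <- abs(sb$pp_count - sbm$pp_count)
    }
    v["disulfide_wt"] <- as.numeric(isTRUE(parts$disulfide_wt))
    v["disulfide_mt"] <- as.numeric(isTRUE(parts$disulfide_mt))
  } else {
    fp <- parts$fingerprint
    if (!is.null(fp)) {
      put <- function(prefix, entry, extra = NULL) {
        v[paste0(prefix, "_present")] <<- as.numeric(isTRUE(entry$present))
        v[paste0(prefix, "_distance")] <<- if (isTRUE(entry$present)) entry$distance else 0
        if (!is.null(extra))
          v[extra] <<- as.numeric(isTRUE(entry$present) &&
                                    identical(entry$groups, "parallel"))
      }
      put("fp_halogen", fp$halogen)
      put("fp_pistack", fp$pi_stacking, extra = "fp_pistack_parallel")
      put("fp_pication", fp$pi_cation)
      put("fp_waterbridge", fp$water_bridge)
      put("fp_hydrophobic", fp$hydrophobic)
    } else unknown(grep("^fp_", schema$features, value = TRUE))
    if (!is.null(sb) && isTRUE(sb$lig_present) && !is.na(sb$lig_group)) {
      key <- paste0("sb_lig_group_", gsub("-", "", sb$lig_group))
      if (key %in% names(v)) v[key] <- 1
    }
  }

  if (any(!is.finite(v))) stop("assembled feature vector contains non-finite values")
  structure(list(schema = schema, values = v, provenance = prov),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector %s: %d values, %d unknown>\n", x$schema$name,
              length(x$values), sum(x$provenance == "unknown")))
  invisible(x)
}

#' Extract the full feature vector for a wild-type/mutant pair
#'
#' Runs every extractor of the schema against the pair and assembles the
#' result.  This is the single entry point used by training and screening.
#'
#' @param wt,mt wild-type and mutant \code{complex_model}s.
#' @param site a \code{binding_site} on the wild type.
#' @param mutation an \code{aa_mutation}.
#' @param schema a \code{feature_schema}.
#' @param wt_affinity_nM,measure wild-type affinity annotation.
#' @param alignment optional multiple alignment (sequences or FASTA path)
#'   for the conservation score; skipped (sentinel) when NULL.
#' @param offset residue-number offset (resno = protein position + offset).
#' @param n_points sphere-point density for the surface integrator.
#' @return A \code{feature_vector}.
#' @export
extract_features <- function(wt, mt, site, mutation, schema,
                             wt_affinity_nM, measure = "IC50",
                             alignment = NULL, offset = 0, n_points = 960) {
  pos <- mutation$protein_position + offset
  parts <- list(
    sasa = surface_accessibility_features(wt, mt, site, pos, n_points = n_points),
    mutation = mutation,
    hbond = hydrogen_bond_features(mt, pos),
    env = environment_encodings(wt, pos, mutation$ref_aa, mutation$alt_aa),
    ss_wt = secondary_structure(wt, pos),
    ss_mt = secondary_structure(mt, pos),
    conservation = if (is.null(alignment)) NA_real_
      else conservation_score(alignment, mutation$protein_position),
    rmsd = alignment_rmsd(wt, mt),
    ligdist_wt = ligand_distance_features(wt, pos),
    ligdist_mt = ligand_distance_features(mt, pos),
    chg = charge_hydrophobicity_features(mutation$ref_aa, mutation$alt_aa),
    saltbridge = salt_bridge_features(wt, pos))
  parts$stability <- stability_change(wt, mutation,
                                      rsa_wt = parts$sasa$rsa_wt,
                                      offset = offset)
  if (schema$name == "aa-v1") {
    parts$hse_wt <- half_sphere_exposure(wt, pos)
    parts$hse_mt <- half_sphere_exposure(mt, pos)
    parts$saltbridge_mt <- salt_bridge_features(mt, pos)
    parts$disulfide_wt <- disulfide_check(wt, pos)
    parts$disulfide_mt <- disulfide_check(mt, pos)
  } else {
    parts$fingerprint <- ligand_interaction_fingerprint(mt, pos)
  }
  assemble_feature_vector(parts, schema, wt_affinity_nM, measure)
}
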