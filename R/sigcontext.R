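## Trinucleotide mutational-signature catalogs, exposure profiles and the
## cancer-type-specific amino-acid mutation likelihood model.
##
## A signature assigns a probability to each of the 96 pyrimidine-context
## single-base substitutions written as "A[C>T]G" (5' flank, ref>alt, 3'
## flank).  For use on a fixed coding strand the catalog is extended to all
## 192 contexts: purine-context entries take the probability of their
## reverse-complement pyrimidine context, except for signatures with a strong
## transcriptional strand bias whose purine contexts are set to zero.

BASES <- c("A", "C", "G", "T")
PYRIMIDINES <- c("C", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Trinucleotide context key
#'
#' Builds a COSMIC-style context string such as \code{"A[C>T]G"}.
#'
#' @param five,three 5' and 3' flanking bases.
#' @param ref,alt reference and alternate base of the substitution.
#' @return Character context key.
#' @export
context_key <- function(five, ref, alt, three) {
  paste0(five, "[", ref, ">", alt, "]", three)
}

parse_context_key <- function(key) {
  m <- regmatches(key, regexec("^([ACGT])\\[([ACGT])>([ACGT])\\]([ACGT])$", key))[[1]]
  if (length(m) != 5)
    stop("malformed context string: '", key, "'")
  list(five = m[2], ref = m[3], alt = m[4], three = m[5])
}

#' Reverse complement of a context key
#'
#' \code{"A[C>T]G"} becomes \code{"C[G>A]T"}: both flanks are complemented and
#' swapped, and the substitution is complemented.
#'
#' @param key context string.
#' @return The reverse-complement context string.
#' @export
revcomp_context <- function(key) {
  p <- parse_context_key(key)
  context_key(COMPLEMENT[[p$three]], COMPLEMENT[[p$ref]],
              COMPLEMENT[[p$alt]], COMPLEMENT[[p$five]])
}

## The 96 pyrimidine-context keys in a fixed deterministic order
## (substitution-major, then 5' flank, then 3' flank), and the 96 purine ones.
all_context_keys <- function(refs = PYRIMIDINES) {
  keys <- character(0)
  for (ref in refs)
    for (alt in setdiff(BASES, ref))
      for (five in BASES)
        for (three in BASES)
          keys <- c(keys, context_key(five, ref, alt, three))
  keys
}

PYRIMIDINE_CONTEXTS <- all_context_keys(PYRIMIDINES)
PURINE_CONTEXTS <- all_context_keys(c("A", "G"))

#' Signatures flagged with strong transcriptional strand bias
#'
#' COSMIC v2 signatures 4, 7, 11, 22, 24 and 29 show a strong strand bias;
#' their purine-context probabilities are zeroed on extension by default.
#' @export
STRAND_BIASED_SIGNATURES <- c("4", "7", "11", "22", "24", "29")

new_mut_signature <- function(id, probs, strand_biased = FALSE, extended = FALSE) {
  structure(list(id = as.character(id), probs = probs,
                 strand_biased = isTRUE(strand_biased),
                 extended = isTRUE(extended)),
            class = "mut_signature")
}

#' @export
print.mut_signature <- function(x, ...) {
  cat(sprintf("<mut_signature %s: %d contexts%s%s>\n", x$id, length(x$probs),
              if (x$strand_biased) ", strand-biased" else "",
              if (x$extended) ", extended" else ""))
  invisible(x)
}

#' Parse a COSMIC-layout mutational-signature catalog
#'
#' The catalog is a tab-separated file whose first column holds the 96
#' pyrimidine context strings (\code{"A[C>A]A"} style) and whose remaining
#' columns hold one signature each (header row = signature ids).  Each
#' signature's 96 probabilities must be non-negative and sum to 1 (checked to
#' a tolerance of 1e-3).
#'
#' @param path path to the TSV file.
#' @param biased_ids character vector of signature ids to flag as
#'   strand-biased (defaults to \code{\link{STRAND_BIASED_SIGNATURES}}).
#' @param tol tolerance on the sum-to-one check.
#' @return A named list of \code{mut_signature} objects (96 contexts each).
#' @export
parse_signature_catalog <- function(path, biased_ids = STRAND_BIASED_SIGNATURES,
                                    tol = 1e-3) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("catalog needs a context column plus >=1 signature column")
  ctx <- as.character(tab[[1]])
  for (k in ctx) {
    p <- parse_context_key(k)
    if (!(p$ref %in% PYRIMIDINES))
      stop("catalog context '", k, "' is not pyrimidine-based")
  }
  if (anyDuplicated(ctx)) stop("duplicated context rows in catalog")
  if (length(ctx) != 96)
    stop("expected 96 pyrimidine context rows, found ", length(ctx))
  ids <- sub("^Signature[ ._]*", "", colnames(tab)[-1])
  sigs <- list()
  for (j in seq_along(ids)) {
    p <- as.numeric(tab[[j + 1]])
    if (any(!is.finite(p)) || any(p < 0))
      stop("signature ", ids[j], ": probabilities must be finite and >= 0")
    if (abs(sum(p) - 1) > tol)
      stop("signature ", ids[j], ": probabilities sum to ", format(sum(p)),
           ", outside 1 ± ", tol)
    probs <- stats::setNames(p, ctx)[PYRIMIDINE_CONTEXTS]
    if (anyNA(probs))
      stop("signature ", ids[j], ": catalog is missing contexts")
    sigs[[ids[j]]] <- new_mut_signature(ids[j], probs,
                                        strand_biased = ids[j] %in% biased_ids)
  }
  sigs
}

#' Extend a 96-context signature to all 192 strand-resolved contexts
#'
#' For a signature without strand bias each purine-context probability is set
#' to that of its reverse-complement pyrimidine context.  For a strand-biased
#' signature the default rule zeroes all purine contexts (the rule stated for
#' the ultraviolet signature); other rules can be supplied per signature via
#' \code{bias_rules}.  No renormalisation is applied after zeroing.
#'
#' @param sig a \code{mut_signature} with 96 pyrimidine contexts.
#' @param bias_rules named list mapping signature id to a function
#'   \code{f(pyr_probs)} returning the 96 purine-context probabilities in
#'   \code{PURINE_CONTEXTS} order; \code{"zero"} (the default rule) may be
#'   given as a string.
#' @return The signature with 192 context probabilities.
#' @export
extend_to_full_context <- function(sig, bias_rules = list()) {
  stopifnot(inherits(sig, "mut_signature"))
  if (sig$extended) return(sig)
  if (length(sig$probs) != 96) stop("signature must carry 96 pyrimidine contexts")
  if (sig$strand_biased) {
    rule <- bias_rules[[sig$id]]
    if (is.null(rule)) rule <- "zero"
    if (identical(rule, "zero")) {
      purine <- stats::setNames(rep(0, 96), PURINE_CONTEXTS)
    } else if (is.function(rule)) {
      purine <- rule(sig$probs)
      if (length(purine) != 96 || any(!is.finite(purine)) || any(purine < 0))
        stop("bias rule for signature ", sig$id, " returned invalid probabilities")
      names(purine) <- PURINE_CONTEXTS
    } else {
      stop("unknown bias rule for strand-biased signature ", sig$id)
    }
  } else {
    purine <- vapply(PURINE_CONTEXTS,
                     function(k) sig$probs[[revcomp_context(k)]], numeric(1))
  }
  new_mut_signature(sig$id, c(sig$probs, purine),
                    strand_biased = sig$strand_biased, extended = TRUE)
}

#' Extend every signature of a catalog to 192 contexts
#' @param catalog named list of \code{mut_signature}.
#' @inheritParams extend_to_full_context
#' @export
extend_catalog <- function(catalog, bias_rules = list()) {
  lapply(catalog, extend_to_full_context, bias_rules = bias_rules)
}

#' Read a per-cancer-type signature exposure profile
#'
#' Two-column TSV (signature_id, weight).  Weights are the contribution of
#' each signature's mutational process to the cancer type; they are used as
#' given (not renormalised).  A warning is emitted if they sum to more than
#' 1.05.
#'
#' @param path path to the TSV.
#' @param cancer_type label for the profile (defaults to the file stem).
#' @return An \code{exposure_profile}: list(cancer_type, weights).
#' @export
read_exposure_profile <- function(path, cancer_type = NULL) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("exposure profile needs (signature_id, weight) columns")
  w <- stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
  exposure_profile(w, cancer_type %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Construct an exposure profile from a named weight vector
#' @param weights named non-negative numeric vector (names = signature ids).
#' @param cancer_type label.
#' @export
exposure_profile <- function(weights, cancer_type = "unspecified") {
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("exposure weights must be finite and >= 0")
  if (!any(weights > 0)) stop("at least one exposure weight must be > 0")
  if (sum(weights) > 1.05)
    warning("exposure weights sum to ", format(sum(weights)), " (> 1.05)")
  structure(list(cancer_type = cancer_type, weights = weights),
            class = "exposure_profile")
}

#' Amino-acid mutation likelihood under a cancer type's signature exposures
#'
#' The likelihood of an amino-acid mutation is the sum, over all
#' single-nucleotide substitutions that cause it and over all signatures
#' active in the cancer type, of the signature's context probability weighted
#' by its exposure:
#' \deqn{L = \sum_{snv \in M} \sum_{s \in S} W_s \, P_{snv,s}.}
#' SNVs whose context contains an unknown flank (\code{"N"}, at a CDS edge)
#' contribute zero.
#'
#' @param m an \code{aa_mutation} (see \code{\link{enumerate_missense_snvs}}).
#' @param exposure an \code{exposure_profile}.
#' @param catalog named list of extended (192-context) signatures.
#' @param breakdown if TRUE, attach a per-SNV contribution attribute.
#' @return Non-negative likelihood (dimensionless).
#' @export
mutation_likelihood <- function(m, exposure, catalog, breakdown = FALSE) {
  stopifnot(inherits(m, "aa_mutation"), inherits(exposure, "exposure_profile"))
  active <- names(exposure$weights)[exposure$weights > 0]
  missing <- setdiff(active, names(catalog))
  if (length(missing))
    stop("exposure references signatures absent from the catalog: ",
         paste(missing, collapse = ", "))
  per_snv <- vapply(m$causal_snvs, function(snv) {
    if (snv$fiveprime == "N" || snv$threeprime == "N") return(0)
    key <- context_key(snv$fiveprime, snv$ref_base, snv$alt_base, snv$threeprime)
    total <- 0
    for (id in active) {
      sig <- catalog[[id]]
      if (!sig$extended)
        stop("signature ", id, " must be extended to 192 contexts first")
      total <- total + exposure$weights[[id]] * sig$probs[[key]]
    }
    total
  }, numeric(1))
  L <- sum(per_snv)
  if (breakdown) {
    names(per_snv) <- vapply(m$causal_snvs, function(s)
      context_key(s$fiveprime, s$ref_base, s$alt_base, s$threeprime), character(1))
    attr(L, "per_snv") <- per_snv
  }
  L
}

## Pyrimidine-collapsed 6-class substitution label ("C>A", ..., "T>G") of an
## SNV; purine substitutions are reported via their reverse complement.
substitution_class <- function(ref, alt) {
  if (ref %in% PYRIMIDINES) paste0(ref, ">", alt)
  else paste0(COMPLEMENT[[ref]], ">", COMPLEMENT[[alt]])
}

#' Dominant substitution class of an amino-acid mutation
#'
#' The pyrimidine-collapsed base-change class of the causal SNV contributing
#' the most likelihood under the given exposures (ties: first in context-key
#' order).
#' @inheritParams mutation_likelihood
#' @export
dominant_substitution <- function(m, exposure, catalog) {
  L <- mutation_likelihood(m, exposure, catalog, breakdown = TRUE)
  per <- attr(L, "per_snv")
  best <- m$causal_snvs[[which.max(per)]]
  substitution_class(best$ref_base, best$alt_base)
}

#' Rank a mutational landscape by likelihood
#'
#' @param entries data.frame with columns \code{position}, \code{ref_aa},
#'   \code{alt_aa}, \code{likelihood}, \code{dominant_substitution}.
#' @return A \code{ranked_landscape}: the same data.frame sorted by
#'   likelihood (descending), ties broken by (position ascending, alt_aa
#'   ascending), with a \code{rank} column.
#' @export
rank_landscape <- function(entries) {
  stopifnot(is.data.frame(entries), nrow(entries) >= 1,
            all(c("position", "ref_aa", "alt_aa", "likelihood",
                  "dominant_substitution") %in% names(entries)))
  ord <- order(-entries$likelihood, entries$position, entries$alt_aa)
  out <- entries[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("ranked_landscape", "data.frame")
  out
}

#' Enrichment odds ratio of a substitution class among the top-ranked mutations
#'
#' Classical 2x2 odds ratio contrasting the frequency of a base-change class
#' within ranks 1..i against ranks (i+1)..N:
#' \deqn{OR = \frac{a/(i-a)}{b/((N-i)-b)}}
#' where a and b count the class above and below the cut.  When any cell is
#' zero the Haldane-Anscombe correction (+0.5 on all four cells) is applied
#' and the result is flagged with attribute \code{corrected = TRUE}.  When
#' the class is absent from the whole landscape the result is \code{NA} with
#' attribute \code{undefined = TRUE}.
#'
#' @param land a \code{ranked_landscape}.
#' @param subst_class one of the 12 base changes (e.g. \code{"C>T"} or
#'   \code{"G>A"}); purine classes are collapsed onto their reverse
#'   complement before counting.
#' @param i cut rank, \code{0 < i < N}.
#' @export
enrichment_odds_ratio <- function(land, subst_class, i = 50) {
  stopifnot(inherits(land, "ranked_landscape"))
  N <- nrow(land)
  if (!(i > 0 && i < N)) stop("cut rank i must satisfy 0 < i < N (N = ", N, ")")
  parts <- strsplit(subst_class, ">", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !all(parts %in% BASES) || parts[1] == parts[2])
    stop("invalid substitution class: ", subst_class)
  cls <- substitution_class(parts[1], parts[2])
  hits <- land$dominant_substitution == cls
  a <- sum(hits[seq_len(i)])
  b <- sum(hits[(i + 1):N])
  if (a + b == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  cells <- c(a, i - a, b, (N - i) - b)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  out <- (cells[1] / cells[2]) / (cells[3] / cells[4])
  attr(out, "corrected") <- corrected
  out
}

#' Likelihood landscape of a set of protein positions
#'
#' Convenience wrapper: enumerates the SNV-reachable missense mutations at
#' \code{positions} of \code{cds}, scores each under the exposures, and
#' returns the ranked landscape.
#'
#' @param cds a \code{coding_sequence}.
#' @param positions protein positions (1-based).
#' @param exposure an \code{exposure_profile}.
#' @param catalog extended signature catalog.
#' @export
likelihood_landscape <- function(cds, positions, exposure, catalog) {
  muts <- enumerate_missense_snvs(cds, positions)
  if (!length(muts)) stop("no missense mutations reachable at these positions")
  entries <- do.call(rbind, lapply(muts, function(m) {
    data.frame(position = m$protein_position, ref_aa = m$ref_aa,
               alt_aa = m$alt_aa,
               likelihood = as.numeric(mutation_likelihood(m, exposure, catalog)),
               dominant_substitution = dominant_substitution(m, exposure, catalog),
               stringsAsFactors = FALSE)
  }))
  rank_landscape(entries)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
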