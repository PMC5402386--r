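## In-frame coding sequences and enumeration of the amino-acid changes
## reachable by a single nucleotide substitution.  Several nucleotide changes
## can produce the same amino-acid change; the enumeration groups them so the
## likelihood model can sum their context probabilities.

#' Construct an in-frame coding sequence
#'
#' @param seq nucleotide string (A/C/G/T), length divisible by 3, no internal
#'   stop codon; a trailing stop codon is allowed and trimmed from the
#'   protein.
#' @param gene label.
#' @return A \code{coding_sequence}.
#' @export
coding_sequence <- function(seq, gene = "gene") {
  seq <- toupper(gsub("\\s", "", seq))
  if (nchar(seq) %% 3 != 0) stop("CDS length must be divisible by 3")
  if (grepl("[^ACGT]", seq)) stop("CDS contains non-ACGT characters")
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                             no.init.codon = TRUE))
  n <- nchar(prot)
  internal <- substr(prot, 1, n - 1)
  if (grepl("*", internal, fixed = TRUE))
    stop("CDS contains an internal stop codon")
  structure(list(gene = gene, seq = seq, protein = prot,
                 n_codons = nchar(seq) / 3), class = "coding_sequence")
}

#' Read the first record of a FASTA file as a coding sequence
#' @param path FASTA file; the first record is used.
#' @param gene optional label (defaults to the record name).
#' @export
read_cds_fasta <- function(path, gene = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  if (!length(set)) stop("no records in ", path)
  coding_sequence(as.character(set[[1]]),
                  gene = gene %||% sub("\\s.*$", "", names(set)[1]))
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence %s: %d codons>\n", x$gene, x$n_codons))
  invisible(x)
}

#' Codon at a protein position (1-based)
#' @param cds a \code{coding_sequence}.
#' @param i protein position.
#' @export
codon_at <- function(cds, i) {
  if (any(i < 1 | i > cds$n_codons)) stop("codon index out of range")
  substring(cds$seq, 3 * (i - 1) + 1, 3 * i)
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[[codon]])
}

## Flanking base at absolute CDS coordinate `pos` (1-based); "N" beyond the
## sequence ends.
flank_base <- function(cds, pos) {
  if (pos < 1 || pos > nchar(cds$seq)) "N" else substr(cds$seq, pos, pos)
}

new_aa_mutation <- function(position, ref_aa, alt_aa, causal_snvs) {
  structure(list(protein_position = position, ref_aa = ref_aa, alt_aa = alt_aa,
                 causal_snvs = causal_snvs), class = "aa_mutation")
}

#' @export
print.aa_mutation <- function(x, ...) {
  ctx <- vapply(x$causal_snvs, function(s)
    context_key(s$fiveprime, s$ref_base, s$alt_base, s$threeprime), character(1))
  cat(sprintf("<aa_mutation %s%d%s via %s>\n", x$ref_aa, x$protein_position,
              x$alt_aa, paste(ctx, collapse = ", ")))
  invisible(x)
}

#' Format an amino-acid mutation as e.g. "T790M"
#' @param m an \code{aa_mutation}.
#' @export
mutation_label <- function(m) paste0(m$ref_aa, m$protein_position, m$alt_aa)

#' Enumerate SNV-reachable missense mutations at protein positions
#'
#' For each requested position all nine single-nucleotide substitutions of
#' its codon are applied; substitutions that are synonymous or that create a
#' stop codon are discarded, and the remainder are grouped by the amino acid
#' they produce.  Each causal SNV records its 5' and 3' flanking bases read
#' from the coding strand of the CDS; at the extreme CDS ends the missing
#' flank is \code{"N"} (such SNVs contribute zero likelihood) and a warning
#' is emitted.
#'
#' @param cds a \code{coding_sequence}.
#' @param positions protein positions (1-based).
#' @return List of \code{aa_mutation}, ordered by (position, alt_aa).
#' @export
enumerate_missense_snvs <- function(cds, positions) {
  if (any(positions < 1 | positions > cds$n_codons))
    stop("protein position out of range (1..", cds$n_codons, ")")
  out <- list()
  warned_edge <- FALSE
  for (pos in sort(unique(positions))) {
    codon <- codon_at(cds, pos)
    ref_aa <- translate_codon(codon)
    groups <- list()
    for (cp in 1:3) {
      ref_base <- substr(codon, cp, cp)
      abs_pos <- 3 * (pos - 1) + cp
      five <- flank_base(cds, abs_pos - 1)
      three <- flank_base(cds, abs_pos + 1)
      if ((five == "N" || three == "N") && !warned_edge) {
        warning("CDS-edge codon lacks a flank; affected SNVs contribute zero likelihood")
        warned_edge <- TRUE
      }
      for (alt_base in setdiff(BASES, ref_base)) {
        mut_codon <- codon
        substr(mut_codon, cp, cp) <- alt_base
        alt_aa <- translate_codon(mut_codon)
        if (alt_aa == ref_aa || alt_aa == "*") next
        snv <- list(codon_position = cp, ref_base = ref_base,
                    alt_base = alt_base, fiveprime = five, threeprime = three)
        groups[[alt_aa]] <- c(groups[[alt_aa]], list(snv))
      }
    }
    for (alt_aa in sort(names(groups)))
      out <- c(out, list(new_aa_mutation(pos, ref_aa, alt_aa, groups[[alt_aa]])))
  }
  out
}
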