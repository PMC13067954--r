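#' Mucin-domain peptide specification
#'
#' Describes a peptide by its one-letter sequence, its biological residue
#' numbering and the residue numbers carrying O-linked GalNAc-Gal glycans.
#' Residue `first_residue_number + i - 1` is the i-th sequence position.
#'
#' @param sequence Uppercase one-letter amino-acid string.
#' @param first_residue_number Biological number of the first residue.
#' @param glyco_sites Integer vector of glycosylated residue numbers; every
#'   site must fall on a threonine or serine.
#' @param name Free-text label.
#' @return Object of class `peptide_spec`.
#' @seealso [lubricin_model_peptide()], [threonine_tetrapeptide()]
#' @export
peptide_spec <- function(sequence, first_residue_number = 1L,
                         glyco_sites = integer(), name = "") {
  stopifnot(is.character(sequence), length(sequence) == 1, nzchar(sequence))
  check_sequence(sequence)
  n <- nchar(sequence)
  nums <- first_residue_number + seq_len(n) - 1L
  glyco_sites <- as.integer(sort(unique(glyco_sites)))
  if (length(glyco_sites)) {
    if (!all(glyco_sites %in% nums))
      stop("glyco_sites outside the residue numbering of the peptide")
    res <- residue_letters(sequence)[match(glyco_sites, nums)]
    if (!all(res %in% c("T", "S")))
      stop("glyco_sites must fall on threonine or serine residues")
  }
  structure(list(sequence = sequence,
                 first_residue_number = as.integer(first_residue_number),
                 residue_numbers = nums,
                 glyco_sites = glyco_sites,
                 name = name),
            class = "peptide_spec")
}

#' @export
print.peptide_spec <- function(x, ...) {
  cat(sprintf("Peptide%s: %s (residues %d-%d)\n",
              if (nzchar(x$name)) paste0(" '", x$name, "'") else "",
              x$sequence, x$residue_numbers[1],
              x$residue_numbers[length(x$residue_numbers)]))
  if (length(x$glyco_sites))
    cat("  O-glycosylated residues:", paste(x$glyco_sites, collapse = ", "), "\n")
  invisible(x)
}

residue_letters <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

check_sequence <- function(sequence) {
  aa <- residue_letters(sequence)
  bad <- which(!aa %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  if (length(bad))
    stop(sprintf("invalid residue letter '%s' at position %d",
                 aa[bad[1]], bad[1]))
  invisible(TRUE)
}

#' The two-tandem-repeat lubricin mucin-domain model peptide
#'
#' Residues 393-410 of lubricin (PKEPAPTTTKEPAPTTPK), spanning one exact
#' KEPAPTTP tandem repeat and its most common variant KEPAPTTT. Thr401,
#' the third threonine of the peptide, is not glycosylated in vivo, so the
#' default glycosylation pattern covers the other four threonines
#' (399, 400, 405, 406).
#'
#' @param glycosylated Logical; attach the default glycosylation pattern.
#' @return A [peptide_spec()].
#' @export
lubricin_model_peptide <- function(glycosylated = TRUE) {
  spec <- peptide_spec("PKEPAPTTTKEPAPTTPK", first_residue_number = 393L,
                       name = "lubricin mucin-domain model peptide")
  if (glycosylated)
    spec$glyco_sites <- glycosylation_sites(spec, excluded = 401L)
  spec
}

#' The threonine tetrapeptide (TTTT)
#'
#' Four-residue threonine peptide used to probe threonine's intrinsic PPII
#' propensity; in its glycosylated form every threonine carries an O-linked
#' GalNAc-Gal glycan.
#'
#' @param glycosylated Logical; glycosylate every threonine.
#' @return A [peptide_spec()].
#' @export
threonine_tetrapeptide <- function(glycosylated = TRUE) {
  peptide_spec("TTTT", first_residue_number = 1L,
               glyco_sites = if (glycosylated) 1:4 else integer(),
               name = "threonine tetrapeptide")
}

#' Locate mucin tandem repeats in a peptide sequence
#'
#' Scans for the canonical lubricin mucin-domain tandem repeat KEPAPTTP
#' and its most common variant KEPAPTTT. Matches of the two motifs never
#' overlap each other (they differ only in their final residue but a
#' shared 8-residue window cannot satisfy both).
#'
#' @param spec A [peptide_spec()] or a plain sequence string.
#' @param motifs Character vector of motifs to scan for.
#' @return Data frame with columns `motif`, `start` (1-based sequence
#'   position) and `residue_number` (biological numbering); zero rows when
#'   no motif occurs.
#' @examples
#' annotate_repeats(lubricin_model_peptide())
#' @export
annotate_repeats <- function(spec, motifs = c("KEPAPTTP", "KEPAPTTT")) {
  if (is.character(spec)) spec <- peptide_spec(spec)
  stopifnot(inherits(spec, "peptide_spec"))
  hits <- do.call(rbind, lapply(motifs, function(m) {
    st <- gregexpr(m, spec$sequence, fixed = TRUE)[[1]]
    if (st[1] == -1) return(NULL)
    data.frame(motif = m, start = as.integer(st))
  }))
  if (is.null(hits))
    return(data.frame(motif = character(), start = integer(),
                      residue_number = integer()))
  hits <- hits[order(hits$start), , drop = FALSE]
  hits$residue_number <- spec$first_residue_number + hits$start - 1L
  rownames(hits) <- NULL
  hits
}

#' Count residues with high PPII propensity
#'
#' Proline, alanine and lysine are the residues with the highest intrinsic
#' propensity for the polyproline-II conformation; counting them across a
#' repeat shows how PPII-prone a mucin tandem repeat is (5 of the 8
#' residues of KEPAPTTP).
#'
#' @param sequence One-letter sequence string (may be empty).
#' @param high_set Character vector of one-letter codes counted as
#'   high-propensity; defaults to P, A, K.
#' @return Integer count.
#' @examples
#' ppii_propensity_count("KEPAPTTP")
#' @export
ppii_propensity_count <- function(sequence, high_set = c("P", "A", "K")) {
  if (!nzchar(sequence)) return(0L)
  check_sequence(sequence)
  sum(residue_letters(sequence) %in% high_set)
}

#' Glycosylation sites of a peptide under the mucin-domain rule
#'
#' Returns the biological residue numbers of all threonines except an
#' excluded set. For the lubricin model peptide the excluded set is
#' Thr401 (the third threonine), which is not glycosylated in vivo,
#' leaving 4 glycosylated threonines.
#'
#' @param spec A [peptide_spec()].
#' @param excluded Integer vector of residue numbers to exclude. An
#'   excluded number that is not a threonine triggers a warning and is
#'   ignored.
#' @param include_serine Logical; also count serines as sites.
#' @return Sorted integer vector of residue numbers.
#' @examples
#' glycosylation_sites(lubricin_model_peptide(glycosylated = FALSE),
#'                     excluded = 401)
#' @export
glycosylation_sites <- function(spec, excluded = integer(),
                                include_serine = FALSE) {
  stopifnot(inherits(spec, "peptide_spec"))
  aa <- residue_letters(spec$sequence)
  keep <- if (include_serine) c("T", "S") else "T"
  thr <- spec$residue_numbers[aa %in% keep]
  excluded <- as.integer(excluded)
  bad <- setdiff(excluded, thr)
  if (length(bad))
    warning("excluded residue number(s) not matching a site residue, ignored: ",
            paste(bad, collapse = ", "))
  sort(setdiff(thr, excluded))
}
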