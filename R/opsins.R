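#' Read an aligned protein FASTA
#'
#' @param path Aligned FASTA file (gaps as `-`); all sequences must have
#'   equal length.
#' @param numbering_offset Integer mapping published site numbers to
#'   alignment columns: column = site + offset. Default 0 (site n is
#'   column n).
#' @return An `aa_alignment`: named character vector of aligned sequences.
#' @export
read_opsin_alignment <- function(path, numbering_offset = 0L) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  if (length(unique(nchar(seqs))) != 1) {
    abort(paste0(path, ": sequences are not aligned (unequal lengths)"))
  }
  structure(seqs, numbering_offset = as.integer(numbering_offset),
            class = "aa_alignment")
}

#' Write an alignment as FASTA
#'
#' @param aln An `aa_alignment`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_opsin_alignment <- function(aln, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(unclass(aln)), path)
  invisible(path)
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("Protein alignment:", length(x), "sequences x", nchar(x[[1]]),
      "columns (numbering offset", attr(x, "numbering_offset"), ")\n")
  for (i in seq_along(x)) {
    s <- x[[i]]
    cat(sprintf("  %-12s %s%s\n", names(x)[i], substr(s, 1, 50),
                if (nchar(s) > 50) "..." else ""))
  }
  invisible(x)
}

site_column <- function(aln, site) {
  col <- site + (attr(aln, "numbering_offset") %||% 0L)
  if (col < 1 || col > nchar(aln[[1]])) {
    abort(paste0("site ", site, " maps outside the alignment"))
  }
  col
}

#' Residue at a published tuning-site position
#'
#' @param aln An `aa_alignment`.
#' @param id Sequence identifier.
#' @param site Published site number (mapped to an alignment column via the
#'   alignment's numbering offset).
#' @return Single character; `"-"` (with a warning) when the site is a gap.
#' @export
residue_at <- function(aln, id, site) {
  if (!id %in% names(aln)) abort(paste0("no sequence named '", id, "'"))
  r <- substr(aln[[id]], site_column(aln, site), site_column(aln, site))
  if (r == "-") warn(paste0("gap at site ", site, " in '", id, "'"))
  r
}

#' Predict the blue-rhodopsin peak class from the site-195 residue
#'
#' In nymphalid blue opsins the residue at tuning site 195 sets the peak
#' absorbance class: tyrosine gives ~431 nm and phenylalanine gives the
#' ~4 nm red-shifted ~435 nm pigment (established by site-directed
#' mutagenesis and expressed-pigment spectroscopy). Any other residue (or a
#' gap) is outside the rule and returns `NA`.
#'
#' @param residue195 Single amino-acid character.
#' @return 431 or 435 (nm), or `NA_real_` for residues the rule does not
#'   cover (with a warning for gaps).
#' @examples
#' predict_blue_peak("Y")
#' predict_blue_peak("F")
#' @export
predict_blue_peak <- function(residue195) {
  if (!is.character(residue195) || length(residue195) != 1 ||
      nchar(residue195) != 1) {
    abort("`residue195` must be a single residue character")
  }
  if (residue195 == "-") {
    warn("gap at site 195; peak class unknown")
    return(NA_real_)
  }
  switch(toupper(residue195), Y = 431, `F` = 435, NA_real_)
}

#' Pairwise percent identity between two aligned sequences
#'
#' Columns with a gap in either sequence are excluded from the denominator.
#'
#' @param aln An `aa_alignment`.
#' @param id_a,id_b Sequence identifiers.
#' @return A tibble with `identical` (count), `compared` (columns) and
#'   `percent`.
#' @export
percent_identity <- function(aln, id_a, id_b) {
  for (id in c(id_a, id_b)) {
    if (!id %in% names(aln)) abort(paste0("no sequence named '", id, "'"))
  }
  a <- strsplit(aln[[id_a]], "")[[1]]
  b <- strsplit(aln[[id_b]], "")[[1]]
  comparable <- a != "-" & b != "-"
  if (!any(comparable)) abort("no comparable (gap-free) columns")
  ident <- sum(a[comparable] == b[comparable])
  tibble(identical = ident, compared = sum(comparable),
         percent = 100 * ident / sum(comparable))
}

#' Tuning-site report for every sequence in an alignment
#'
#' Extracts the residues at blue-opsin tuning sites 135 and 195 and the
#' site-195 peak-class prediction. Site 135 has a documented tuning effect
#' but no usable prediction rule, so its residue is reported without
#' interpretation.
#'
#' @param aln An `aa_alignment`.
#' @return A tibble with `id`, `residue_135`, `residue_195`,
#'   `predicted_blue_peak` (nm or `NA`).
#' @export
tuning_report <- function(aln) {
  purrr::map(names(aln), function(id) {
    r135 <- residue_at(aln, id, 135)
    r195 <- residue_at(aln, id, 195)
    tibble(id = id, residue_135 = r135, residue_195 = r195,
           predicted_blue_peak = suppressWarnings(predict_blue_peak(r195)))
  }) |> bind_rows()
}
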