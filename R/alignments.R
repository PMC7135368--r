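#' Construct a pairwise target-template alignment
#'
#' Holds the two gapped rows of a pairwise alignment plus the column map
#' giving, for every alignment column, the target residue number it carries
#' (`NA` for target-gap columns). The ungapped target row reproduces the
#' target sequence.
#'
#' @param target_seq,template_seq Gapped sequences (single strings) of equal
#'   length; gap symbols `-` and `.` are normalized to `-`.
#' @param target_name,template_name Sequence identifiers.
#' @param target_start Residue number of the first target residue, default 1.
#' @return A list of class `pairwise_alignment` with elements `target_name`,
#'   `template_name`, `target_row`, `template_row`, `column_map`.
#' @export
pairwise_alignment <- function(target_seq, template_seq,
                               target_name = "target",
                               template_name = "template",
                               target_start = 1L) {
  norm <- function(s) {
    s <- toupper(gsub("[.]", "-", s))
    strsplit(s, "")[[1]]
  }
  trow <- norm(target_seq)
  prow <- norm(template_seq)
  if (length(trow) != length(prow)) {
    stop("alignment rows have unequal lengths (", length(trow), " vs ",
         length(prow), ")", call. = FALSE)
  }
  if (length(trow) == 0) stop("empty alignment", call. = FALSE)
  column_map <- rep(NA_integer_, length(trow))
  is_res <- trow != "-"
  column_map[is_res] <- seq_len(sum(is_res)) + as.integer(target_start) - 1L
  structure(list(target_name = target_name, template_name = template_name,
                 target_row = paste(trow, collapse = ""),
                 template_row = paste(prow, collapse = ""),
                 column_map = column_map),
            class = "pairwise_alignment")
}

#' Read a pairwise alignment from FASTA or Clustal text
#'
#' Exactly two sequences are expected: the target first, the template
#' second.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @param target_start Residue number of the first target residue.
#' @return A [pairwise_alignment()].
#' @export
read_alignment <- function(path, format = c("fasta", "clustal"),
                           target_start = 1L) {
  format <- match.arg(format)
  if (format == "fasta") {
    aln <- seqinr::read.alignment(path, format = "fasta",
                                  forceToLower = FALSE)
    seqs <- unlist(aln$seq)
    nams <- aln$nam
  } else {
    maln <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    seqs <- as.character(Biostrings::unmasked(maln))
    nams <- names(seqs)
  }
  if (length(seqs) != 2) {
    stop("expected exactly 2 sequences, found ", length(seqs), call. = FALSE)
  }
  pairwise_alignment(seqs[[1]], seqs[[2]],
                     target_name = nams[1], template_name = nams[2],
                     target_start = target_start)
}

#' @rdname read_alignment
#' @param aln A `pairwise_alignment`.
#' @return `write_alignment()` returns `path` invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  seqinr::write.fasta(
    sequences = list(strsplit(aln$target_row, "")[[1]],
                     strsplit(aln$template_row, "")[[1]]),
    names = c(aln$target_name, aln$template_name),
    file.out = path
  )
  invisible(path)
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Pairwise alignment:", x$target_name, "vs", x$template_name,
      sprintf("(%d columns)\n", nchar(x$target_row)))
  invisible(x)
}

#' Region-restricted percent sequence identity
#'
#' Percent identity between target and template over a region of the target
#' sequence (e.g. the TM bundle or the binding-site residue list). The
#' denominator is the region size on the target: a region residue aligned to
#' a template gap counts as a mismatch, so gaps in structurally critical
#' regions penalize the template. Comparison is case-insensitive and `X`
#' never matches.
#'
#' @param aln A [pairwise_alignment()].
#' @param region Integer vector of target residue numbers, or a
#'   [region_definition()] (its `resno` column is used), or a character
#'   vector of BW positions with `numbering_map`.
#' @param numbering_map Optional named vector mapping BW positions to target
#'   residue numbers.
#' @return Percent identity in \[0, 100\].
#' @examples
#' aln <- pairwise_alignment("ACDEFGHIKL", "ACDEFGHIKL")
#' region_identity(aln, 1:10)
#' @export
region_identity <- function(aln, region, numbering_map = NULL) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  if (inherits(region, "region_definition") || is.data.frame(region)) {
    region <- region$resno
  }
  if (!is.null(numbering_map)) {
    region <- region_definition(region, numbering_map = numbering_map)$resno
  }
  region <- unique(as.integer(region))
  if (length(region) == 0) stop("empty region", call. = FALSE)
  absent <- setdiff(region, aln$column_map)
  if (length(absent) > 0) {
    stop("region position(s) absent from target sequence: ",
         paste(utils::head(absent, 10), collapse = ", "), call. = FALSE)
  }
  cols <- match(region, aln$column_map)
  t_res <- strsplit(aln$target_row, "")[[1]][cols]
  p_res <- strsplit(aln$template_row, "")[[1]][cols]
  match_col <- t_res == p_res & t_res != "-" & p_res != "-" & t_res != "X"
  100 * sum(match_col) / length(region)
}

#' Region identity table for a set of templates
#'
#' @param alignments Named list of [pairwise_alignment()]s (one per
#'   template).
#' @param regions Named list of region position vectors (e.g.
#'   `list(TM = ..., BS = ...)`).
#' @param numbering_map Optional BW-position map applied to every region.
#' @return A tibble with columns `template`, `region`, `percent_identity`.
#' @export
identity_table <- function(alignments, regions, numbering_map = NULL) {
  purrr::imap_dfr(alignments, function(aln, template) {
    purrr::imap_dfr(regions, function(positions, name) {
      pid <- region_identity(aln, positions, numbering_map)
      tibble::tibble(
        template = if (nzchar(template)) template else aln$template_name,
        region = name,
        percent_identity = pid
      )
    })
  })
}
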