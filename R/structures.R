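#' Read a receptor structure from a PDB file
#'
#' Parses ATOM records into a flat atom table. Alternate locations are
#' resolved to the highest-occupancy conformer (ties broken toward altLoc
#' "A"); waters and hydrogens are excluded by default since none of the
#' accuracy metrics use them.
#'
#' @param path Path to a PDB coordinate file.
#' @param model_id Identifier attached to the structure; defaults to the file
#'   name without extension.
#' @param keep_hetatm Keep HETATM records (excluding waters)? Default `FALSE`.
#' @return A structure tibble with columns `chain`, `resno`, `resid`,
#'   `elety` (atom name), `x`, `y`, `z`, `model_id`.
#' @export
read_structure <- function(path, model_id = NULL, keep_hetatm = FALSE) {
  if (is.null(model_id)) {
    model_id <- sub("\\.[^.]*$", "", basename(path))
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("PDB parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  if (!keep_hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  elesym <- trimws(at$elesy)
  is_h <- (!is.na(elesym) & elesym %in% c("H", "D")) |
    grepl("^[0-9]*H", at$elety)
  at <- at[!is_h, , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM coordinate records in ", path, call. = FALSE)

  tbl <- tibble::tibble(
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = as.integer(at$resno),
    resid = at$resid,
    elety = at$elety,
    alt = ifelse(is.na(at$alt), "", at$alt),
    occ = ifelse(is.na(at$o), 1, at$o),
    x = at$x, y = at$y, z = at$z
  )
  if (any(!is.finite(tbl$x) | !is.finite(tbl$y) | !is.finite(tbl$z))) {
    stop("malformed coordinate field in ", path, call. = FALSE)
  }
  # resolve altLocs (highest occupancy, then altLoc "A") keeping file order
  tbl <- tbl |>
    dplyr::mutate(.file_order = dplyr::row_number()) |>
    dplyr::group_by(.data$chain, .data$resno, .data$resid, .data$elety) |>
    dplyr::arrange(dplyr::desc(.data$occ), .data$alt, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.file_order) |>
    dplyr::select("chain", "resno", "resid", "elety", "x", "y", "z") |>
    dplyr::mutate(model_id = model_id)
  validate_structure(tbl)
}

#' @rdname read_structure
#' @param structure A structure tibble.
#' @return `write_structure()` returns `path` invisibly.
#' @export
write_structure <- function(structure, path) {
  structure <- validate_structure(structure)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(structure[, c("x", "y", "z")]))),
    resno = structure$resno,
    resid = structure$resid,
    chain = structure$chain,
    elety = structure$elety,
    eleno = seq_len(nrow(structure))
  )
  invisible(path)
}

#' Validate a structure atom table
#'
#' @param structure Data frame with columns `chain`, `resno`, `resid`,
#'   `elety`, `x`, `y`, `z` (and optionally `model_id`).
#' @return The structure as a tibble.
#' @export
validate_structure <- function(structure) {
  required <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  missing <- setdiff(required, names(structure))
  if (length(missing) > 0) {
    stop("structure is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure <- tibble::as_tibble(structure)
  if (!"model_id" %in% names(structure)) structure$model_id <- "model"
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) {
    stop("structure has non-finite coordinates", call. = FALSE)
  }
  dup <- structure |>
    dplyr::count(.data$chain, .data$resno, .data$elety) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicated atom name within residue(s): ",
         paste(utils::head(paste0(dup$chain, dup$resno, ":", dup$elety), 5),
               collapse = ", "),
         call. = FALSE)
  }
  structure
}

#' Define a structural/sequence region by residue numbers
#'
#' Regions (the TM helix bundle, the orthosteric binding site, or any custom
#' selection) are sets of `(chain, residue number)` pairs. When a receptor's
#' residues are indexed by Ballesteros-Weinstein (BW) positions, pass the BW
#' position labels together with a numbering map.
#'
#' @param resno Integer vector of author residue numbers, or character vector
#'   of BW positions (e.g. `"3.32"`) when `numbering_map` is given.
#' @param chain Chain id(s), recycled.
#' @param name Region name (e.g. `"TM"`, `"BS"`).
#' @param numbering_map Optional named integer vector mapping BW position
#'   labels to author residue numbers.
#' @return A tibble of class `region_definition` with columns `chain`,
#'   `resno` and a `name` attribute.
#' @examples
#' region_definition(c(75, 110, 114), name = "BS")
#' region_definition(c("3.32", "5.46"), name = "BS",
#'                   numbering_map = c("3.32" = 114, "5.46" = 193))
#' @export
region_definition <- function(resno, chain = "A", name = "custom",
                              numbering_map = NULL) {
  if (!is.null(numbering_map)) {
    labels <- as.character(resno)
    unknown <- setdiff(labels, names(numbering_map))
    if (length(unknown) > 0) {
      stop("BW position(s) absent from numbering map: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    resno <- unname(numbering_map[labels])
  }
  resno <- as.integer(resno)
  if (length(resno) == 0 || any(is.na(resno))) {
    stop("a region needs at least one valid residue number", call. = FALSE)
  }
  out <- tibble::tibble(chain = rep_len(as.character(chain), length(resno)),
                        resno = resno) |>
    dplyr::distinct()
  structure(out, class = c("region_definition", class(out)), name = name)
}

in_region <- function(structure, region) {
  if (is.null(region)) return(rep(TRUE, nrow(structure)))
  paste(structure$chain, structure$resno) %in%
    paste(region$chain, region$resno)
}
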