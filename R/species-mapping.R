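#' Map gene-copy labels to species names
#'
#' Gene family trees carry one leaf per gene copy; rooting and
#' decomposition need to know which species each copy belongs to. Two
#' conventions are supported: a delimiter rule (species = label prefix
#' before the first occurrence of a delimiter, the common
#' `SPECIES_copyid` convention of GDL simulators), or an explicit
#' two-column table.
#'
#' @param delimiter Single character used by the delimiter rule
#'   (default `"_"`). A label without the delimiter maps to itself, so
#'   species-labeled single-copy trees pass through unchanged.
#' @param table Optional data frame with columns `label` and `species`
#'   (a two-column TSV read with [read_species_mapping()] works). When
#'   given, it takes precedence over the delimiter rule.
#' @return An object of class `species_map`.
#' @export
#' @examples
#' m <- species_mapping()
#' map_species(c("A_1", "A_2", "B_1"), m)
species_mapping <- function(delimiter = "_", table = NULL) {
  if (!is.null(table)) {
    stopifnot(is.data.frame(table), all(c("label", "species") %in% names(table)))
    if (anyDuplicated(table$label)) {
      abort("duplicate labels in mapping table")
    }
    lut <- setNames(as.character(table$species), as.character(table$label))
  } else {
    lut <- NULL
  }
  structure(list(delimiter = delimiter, table = lut), class = "species_map")
}

#' @param path Path to a two-column TSV (gene-copy label, species), no header.
#' @rdname species_mapping
#' @export
read_species_mapping <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("label", "species"),
                          colClasses = "character")
  species_mapping(table = df)
}

#' @param labels Character vector of gene-copy leaf labels.
#' @param mapping A `species_map`.
#' @rdname species_mapping
#' @export
map_species <- function(labels, mapping = species_mapping()) {
  stopifnot(inherits(mapping, "species_map"))
  if (!is.null(mapping$table)) {
    sp <- unname(mapping$table[labels])
    if (anyNA(sp)) {
      bad <- labels[is.na(sp)]
      abort(paste0("unmapped leaf label(s): ", paste(head(bad, 5), collapse = ", ")),
            class = "multiroot_mapping_error")
    }
    return(sp)
  }
  sub(paste0(mapping$delimiter, ".*$"), "", labels)
}
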